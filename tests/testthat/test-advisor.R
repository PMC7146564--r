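# CART induction, DNF rule extraction, prediction, recommendation.

random_kpi_vectors <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(ES = runif(n, 0, 100), AM = runif(n, 0, 100),
             HH = runif(n, 0, 100), HT = runif(n, 0, 100),
             LT = runif(n, 0, 100))
}

test_that("a single perfectly separable feature is split in the gap", {
  set.seed(9)
  x <- c(runif(100, 20, 60), runif(100, 70, 95))
  y <- rep(c("A", "B"), each = 100)
  tab <- data.frame(x = x, meat_quality = y, stringsAsFactors = FALSE)
  tree <- fit_cart(tab, features = "x", min_leaf = 1)
  expect_false(tree$root$leaf)
  expect_true(tree$root$left$leaf && tree$root$right$leaf)
  expect_gt(tree$root$threshold, 60)
  expect_lt(tree$root$threshold, 70)

  # and the threshold equals the brute-force best-split oracle's
  oracle <- best_split_oracle(x, y)
  expect_equal(tree$root$threshold, oracle$threshold)
  expect_equal(tree$root$decrease, oracle$decrease)
})

test_that("split selection matches the brute-force oracle on noisy data", {
  set.seed(19)
  for (rep in 1:5) {
    x <- runif(80, 0, 100)
    y <- ifelse(x > 50, "B", "A")
    flip <- sample(80, 12)
    y[flip] <- ifelse(y[flip] == "A", "B", "A")
    tab <- data.frame(x = x, meat_quality = y, stringsAsFactors = FALSE)
    tree <- fit_cart(tab, features = "x", max_depth = 1, min_leaf = 1)
    oracle <- best_split_oracle(x, y)
    expect_equal(tree$root$threshold, oracle$threshold)
  }
})

test_that("degenerate inputs give leaves and errors as contracted", {
  tab <- data.frame(x = runif(10), meat_quality = rep("A", 10))
  tree <- fit_cart(tab, features = "x")
  expect_true(tree$root$leaf)
  expect_equal(tree$root$class, "A")
  expect_equal(unname(predict(tree, data.frame(x = 0.5))), "A")

  expect_error(fit_cart(tab, features = character(0)),
               class = "poultrykpi_configuration_error")
  tab2 <- data.frame(x = letters[1:4], meat_quality = c("A", "B", "A", "B"),
                     stringsAsFactors = FALSE)
  expect_error(fit_cart(tab2, features = "x"),
               class = "poultrykpi_configuration_error")
})

test_that("the planted chain structure is recovered at zero noise", {
  tab <- gen_chain_dataset(chain_scenario(n_chains = 2000, label_noise = 0,
                                          seed = 2))
  tree <- fit_cart(tab, features = c("ES", "AM", "HH", "HT", "LT"),
                   max_depth = 6, min_leaf = 5)
  # depth 3 and six leaves, like the planted tree
  expect_lte(poultrykpi:::tree_depth(tree$root), 3)
  expect_equal(poultrykpi:::count_leaves(tree$root), 6L)
  expect_equal(cart_accuracy(tree, tab), 1)

  # recovered thresholds sit within +-2 of the planted ones
  planted <- c(ES = 65, AM = 40, HH = 20, HT = 50, LT = 35)
  collect <- function(node) {
    if (node$leaf) return(NULL)
    rbind(data.frame(feature = node$feature, threshold = node$threshold),
          collect(node$left), collect(node$right))
  }
  splits <- collect(tree$root)
  for (i in seq_len(nrow(splits))) {
    expect_lt(abs(splits$threshold[i] - planted[[splits$feature[i]]]), 2)
  }

  # same partition as the planted rules on fresh points away from thresholds
  fresh <- random_kpi_vectors(500, seed = 77)
  keep <- rep(TRUE, nrow(fresh))
  for (f in names(planted)) keep <- keep & abs(fresh[[f]] - planted[[f]]) > 2
  fresh <- fresh[keep, ]
  expect_equal(predict(tree, fresh),
               predict(planted_quality_tree(), fresh))
})

test_that("redundant-subtree pruning preserves the decision function", {
  tab <- gen_chain_dataset(chain_scenario(n_chains = 2000, label_noise = 0,
                                          seed = 7))
  tree <- fit_cart(tab, features = c("ES", "AM", "HH", "HT", "LT"),
                   max_depth = 6, min_leaf = 5)
  pruned <- prune_redundant(tree)
  expect_lte(poultrykpi:::count_leaves(pruned$root),
             poultrykpi:::count_leaves(tree$root))
  grid <- random_kpi_vectors(800, seed = 44)
  expect_equal(predict(pruned, grid), predict(tree, grid))
})

test_that("training accuracy is non-decreasing in depth", {
  tab <- gen_chain_dataset(chain_scenario(n_chains = 600, label_noise = 0.1,
                                          seed = 14))
  accs <- vapply(1:5, function(d) {
    cart_accuracy(fit_cart(tab, features = c("ES", "AM", "HH", "HT", "LT"),
                           max_depth = d), tab)
  }, numeric(1))
  expect_true(all(diff(accs) >= -1e-12))
})

test_that("rule extraction yields one rule per leaf, matching the paths", {
  # single-leaf tree: one unconditional rule
  tab <- data.frame(x = runif(10), meat_quality = rep("B", 10))
  r1 <- extract_rules(fit_cart(tab, features = "x"))
  expect_length(r1, 1)
  expect_equal(nrow(r1[[1]]$conditions), 0)
  expect_equal(as.character(predict_rules(r1, list(x = 1))), "B")

  # the planted quality tree yields exactly the six published-style rules
  rules <- planted_quality_rules()
  expect_length(rules, 6)
  classes <- vapply(rules, function(r) r$class, character(1))
  expect_equal(sort(classes), c("A", "A", "A", "B", "B", "B"))
  # locate the rule ES > 65 & AM <= 40 & HT <= 50 -> A
  target <- Filter(function(r) {
    c4 <- r$conditions
    nrow(c4) == 3 && r$class == "A" &&
      any(c4$feature == "ES" & c4$op == ">" & c4$threshold == 65) &&
      any(c4$feature == "AM" & c4$op == "<=" & c4$threshold == 40) &&
      any(c4$feature == "HT" & c4$op == "<=" & c4$threshold == 50)
  }, rules)
  expect_length(target, 1)
})

test_that("rule-set prediction equals tree traversal everywhere", {
  # fitted trees on random data
  set.seed(23)
  for (rep in 1:3) {
    tab <- gen_chain_dataset(chain_scenario(n_chains = 400,
                                            label_noise = 0.2,
                                            seed = 100 + rep))
    tree <- fit_cart(tab, features = c("ES", "AM", "HH", "HT", "LT"),
                     max_depth = 4, min_leaf = 10)
    rules <- extract_rules(tree)
    grid <- random_kpi_vectors(1000, seed = 200 + rep)
    expect_equal(predict(rules, grid), unname(predict(tree, grid)))
  }
})

test_that("exactly one rule matches any complete feature vector", {
  rules <- planted_quality_rules()
  grid <- random_kpi_vectors(1000, seed = 31)
  for (i in seq_len(200)) {
    x <- as.list(grid[i, ])
    status <- vapply(rules, poultrykpi:::rule_match_status, logical(1), kpis = x)
    expect_equal(sum(status), 1)
  }
})

test_that("the chain-manager worked example predicts quality A", {
  rules <- planted_quality_rules()
  kpis <- c(ES = 68.30, AM = 9.32, HT = 0, HH = 17, LT = 0)
  pred <- predict_rules(rules, kpis)
  expect_equal(as.character(pred), "A")
  matched <- rules[[attr(pred, "rule")]]
  # matched via the ES > 65 & AM <= 40 & HT <= 50 path
  expect_true(all(c("ES", "AM", "HT") %in% matched$conditions$feature))

  # direct application of the low-emergency branch
  expect_equal(as.character(predict_rules(rules, c(ES = 60, LT = 40,
                                                   AM = 0, HH = 0, HT = 0))),
               "B")

  # a feature needed for disambiguation must be present
  expect_error(predict_rules(rules, c(ES = 68.30)),
               class = "poultrykpi_missing_feature")
})

test_that("recommendation keeps compatible rules and residual constraints", {
  rules <- planted_quality_rules()
  rec <- recommend(rules, c(ES = 68.30), "A")
  expect_length(rec, 2)
  residuals <- lapply(rec, function(r) {
    apply(r$residual, 1, function(row) paste(row["feature"], row["op"],
                                             as.numeric(row["threshold"])))
  })
  expect_true(any(vapply(residuals, function(r) {
    setequal(r, c("AM <= 40", "HT <= 50"))
  }, logical(1))))
  expect_true(any(vapply(residuals, function(r) {
    setequal(r, c("AM > 40", "HH <= 20"))
  }, logical(1))))

  # a low-emergency chain instead matches the LT rule for A
  rec2 <- recommend(rules, c(ES = 50), "A")
  expect_length(rec2, 1)
  expect_equal(unname(unlist(rec2[[1]]$residual[1, c("feature", "op")])),
               c("LT", "<="))

  # fixed values satisfying a full rule leave an empty residual
  rec3 <- recommend(rules, c(ES = 50, LT = 10), "A")
  expect_length(rec3, 1)
  expect_equal(nrow(rec3[[1]]$residual), 0)

  # absent desired class is a value error
  expect_error(recommend(rules, c(ES = 50), "Z"),
               class = "poultrykpi_value_error")
})

test_that("rule sets round-trip through the structured file form", {
  tab <- gen_chain_dataset(chain_scenario(n_chains = 300, seed = 9))
  rules <- extract_rules(fit_cart(tab, features = c("ES", "AM", "HH", "HT", "LT"),
                                  max_depth = 3))
  f <- withr::local_tempfile(fileext = ".json")
  write_rule_set(rules, f)
  back <- read_rule_set(f)
  expect_equal(length(back), length(rules))
  grid <- random_kpi_vectors(300, seed = 5)
  expect_equal(predict(back, grid), predict(rules, grid))
  # the text form shows every rule
  expect_length(format(rules), length(rules))
})

test_that("our learner agrees with rpart on a separable planted problem", {
  library(rpart)
  tab <- gen_chain_dataset(chain_scenario(n_chains = 1500, label_noise = 0,
                                          seed = 55))
  ours <- fit_cart(tab, features = c("ES", "AM", "HH", "HT", "LT"),
                   max_depth = 5, min_leaf = 5)
  ref <- rpart(meat_quality ~ ES + AM + HH + HT + LT, data = tab,
               method = "class",
               control = rpart.control(minbucket = 5, cp = 0, xval = 0))
  grid <- random_kpi_vectors(800, seed = 8)
  ref_pred <- as.character(predict(ref, grid, type = "class"))
  expect_gt(mean(unname(predict(ours, grid)) == ref_pred), 0.98)
})
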