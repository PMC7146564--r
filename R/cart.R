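# Classification and regression trees over chain-KPI tables.
#
# The tree learner is implemented in-package because the decision-support
# layer needs full access to node internals: every root-to-leaf path is
# later extracted as a disjunctive-normal-form rule, and recommendations
# are computed by simplifying those paths.  Greedy binary recursive
# partitioning: Gini impurity for categorical targets, variance reduction
# for numeric ones; split candidates are midpoints between consecutive
# distinct sorted feature values; the left branch is always "<= threshold".

gini <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts / n
  1 - sum(p^2)
}

# exhaustive best split for one feature: returns threshold and impurity
# decrease, honouring the minimum leaf size; NULL if no admissible split
best_split_feature <- function(x, y, min_leaf, classes) {
  ord <- order(x)
  xs <- x[ord]
  n <- length(xs)
  new_val <- which(diff(xs) > 0)        # split after these positions
  if (length(new_val) == 0) return(NULL)
  if (is.null(classes)) {               # regression: variance reduction
    ys <- y[ord]
    csum <- cumsum(ys)
    csq <- cumsum(ys^2)
    tot_sse <- csq[n] - csum[n]^2 / n
    k <- new_val
    sse_l <- csq[k] - csum[k]^2 / k
    sse_r <- (csq[n] - csq[k]) - (csum[n] - csum[k])^2 / (n - k)
    dec <- (tot_sse - sse_l - sse_r) / n
  } else {
    ys <- y[ord]
    cum <- sapply(classes, function(cl) cumsum(ys == cl))
    if (is.null(dim(cum))) cum <- matrix(cum, nrow = n)
    tot <- cum[n, ]
    k <- new_val
    g_parent <- gini(tot)
    left <- cum[k, , drop = FALSE]
    dec <- vapply(seq_along(k), function(j) {
      cl <- left[j, ]
      cr <- tot - cl
      g_parent - (k[j] / n) * gini(cl) - ((n - k[j]) / n) * gini(cr)
    }, numeric(1))
  }
  ok <- k >= min_leaf & (n - k) >= min_leaf
  if (!any(ok)) return(NULL)
  dec[!ok] <- -Inf
  best <- max(dec)
  # smallest admissible threshold among ties (within numerical tolerance)
  j <- which(dec >= best - 1e-12)[1]
  list(threshold = (xs[k[j]] + xs[k[j] + 1]) / 2, decrease = best)
}

grow_node <- function(data, y, features, classes, depth, params) {
  n <- length(y)
  make_leaf <- function() {
    if (is.null(classes)) {
      list(leaf = TRUE, value = mean(y), n = n)
    } else {
      dist <- table(factor(y, levels = classes))
      cls <- classes[which(dist == max(dist))]
      # deterministic tie-break: lexicographically first majority label
      list(leaf = TRUE, class = sort(cls)[1], dist = as.integer(dist),
           classes = classes, n = n)
    }
  }
  pure <- if (is.null(classes)) stats::var(y) %in% c(0, NA) || stats::var(y) < 1e-24
          else length(unique(y)) == 1
  if (pure || depth >= params$max_depth || n < 2 * params$min_leaf) {
    return(make_leaf())
  }
  best <- NULL
  for (f in sort(features)) {   # lexicographic feature order breaks ties
    s <- best_split_feature(data[[f]], y, params$min_leaf, classes)
    if (is.null(s)) next
    if (is.null(best) || s$decrease > best$decrease + 1e-12) {
      best <- c(s, feature = f)
    }
  }
  if (is.null(best) || best$decrease <= params$min_impurity_decrease ||
      best$decrease <= 1e-12) {
    return(make_leaf())
  }
  go_left <- data[[best$feature]] <= best$threshold
  list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
       n = n, decrease = best$decrease,
       left = grow_node(data[go_left, , drop = FALSE], y[go_left],
                        features, classes, depth + 1L, params),
       right = grow_node(data[!go_left, , drop = FALSE], y[!go_left],
                         features, classes, depth + 1L, params))
}

#' Fit a binary decision tree to a chain-KPI table
#'
#' Greedy recursive partitioning.  For a categorical target, splits
#' minimise Gini impurity; for a numeric target, within-node variance.
#' Candidate thresholds are midpoints between consecutive distinct sorted
#' values of each feature; the left branch holds rows with
#' `feature <= threshold`.  Ties between equally good splits are broken
#' deterministically: lexicographically smallest feature name, then
#' smallest threshold.  A single-class input yields a single-leaf tree.
#'
#' @param table data.frame with one row per completed production chain.
#' @param target name of the column to predict (default `"meat_quality"`).
#' @param features character vector of numeric feature columns; defaults to
#'   every numeric column except the target and any `chain_id`.
#' @param max_depth maximum tree depth (root = depth 0).
#' @param min_leaf minimum rows in each child of a split.
#' @param min_impurity_decrease minimum impurity decrease for a split to be
#'   accepted; plays the role of a complexity parameter.
#' @return an object of class `cart_tree`.
#' @export
fit_cart <- function(table, target = "meat_quality", features = NULL,
                     max_depth = 5L, min_leaf = 5L, min_impurity_decrease = 0) {
  if (!target %in% names(table)) err_config(sprintf("no target column '%s'", target))
  if (is.null(features)) {
    num <- names(table)[vapply(table, is.numeric, logical(1))]
    features <- setdiff(num, c(target, "chain_id"))
  }
  if (length(features) == 0) err_config("empty feature set")
  miss <- setdiff(features, names(table))
  if (length(miss)) err_config(paste("unknown feature(s):", paste(miss, collapse = ", ")))
  for (f in features) {
    if (!is.numeric(table[[f]])) err_config(sprintf("feature '%s' is not numeric", f))
  }
  y <- table[[target]]
  classes <- if (is.numeric(y)) NULL else sort(unique(as.character(y)))
  if (!is.null(classes)) y <- as.character(y)
  if (nrow(table) < 1) err_empty_input("empty training table")
  params <- list(max_depth = as.integer(max_depth), min_leaf = as.integer(min_leaf),
                 min_impurity_decrease = min_impurity_decrease)
  root <- grow_node(table[, features, drop = FALSE], y, features, classes, 0L, params)
  structure(list(root = root, target = target, features = features,
                 classes = classes, params = params),
            class = "cart_tree")
}

tree_depth <- function(node) {
  if (node$leaf) 0L else 1L + max(tree_depth(node$left), tree_depth(node$right))
}

count_leaves <- function(node) {
  if (node$leaf) 1L else count_leaves(node$left) + count_leaves(node$right)
}

#' @export
print.cart_tree <- function(x, ...) {
  cat(sprintf("<cart_tree> target '%s', %d leaves, depth %d\n",
              x$target, count_leaves(x$root), tree_depth(x$root)))
  print_node <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$leaf) {
      lab <- if (is.null(x$classes)) sprintf("%.4g", node$value) else node$class
      cat(sprintf("%s* %s (n=%d)\n", pad, lab, node$n))
    } else {
      cat(sprintf("%s%s <= %.4g:\n", pad, node$feature, node$threshold))
      print_node(node$left, indent + 1L)
      cat(sprintf("%s%s > %.4g:\n", pad, node$feature, node$threshold))
      print_node(node$right, indent + 1L)
    }
  }
  print_node(x$root, 0L)
  invisible(x)
}

traverse <- function(node, row) {
  while (!node$leaf) {
    v <- row[[node$feature]]
    if (is.null(v) || is.na(v)) {
      err_missing_feature(sprintf("missing feature '%s'", node$feature))
    }
    node <- if (v <= node$threshold) node$left else node$right
  }
  node
}

#' Predict from a fitted tree
#'
#' @param object a `cart_tree`.
#' @param newdata data.frame (or single named list/vector) of feature
#'   values.
#' @param ... unused.
#' @return character vector of predicted classes (or numeric means for a
#'   regression tree).
#' @export
predict.cart_tree <- function(object, newdata, ...) {
  if (!is.data.frame(newdata)) newdata <- as.data.frame(as.list(newdata))
  out <- vapply(seq_len(nrow(newdata)), function(i) {
    leaf <- traverse(object$root, newdata[i, , drop = FALSE])
    if (is.null(object$classes)) leaf$value else leaf$class
  }, if (is.null(object$classes)) numeric(1) else character(1))
  out
}

#' Collapse subtrees that predict a single class
#'
#' Greedy impurity splitting can produce internal nodes whose children all
#' predict the same class (the split reduced impurity without changing any
#' prediction).  Collapsing them leaves a smaller tree with an identical
#' decision function, and hence a more parsimonious extracted rule set.
#'
#' @param tree a `cart_tree` fitted to a categorical target.
#' @return a `cart_tree` predicting identically to the input.
#' @export
prune_redundant <- function(tree) {
  stopifnot(inherits(tree, "cart_tree"))
  if (is.null(tree$classes)) err_config("pruning is defined for classification trees")
  leaf_classes <- function(node) {
    if (node$leaf) return(node$class)
    unique(c(leaf_classes(node$left), leaf_classes(node$right)))
  }
  prune <- function(node) {
    if (node$leaf) return(node)
    node$left <- prune(node$left)
    node$right <- prune(node$right)
    cls <- leaf_classes(node)
    if (length(cls) == 1) {
      return(list(leaf = TRUE, class = cls, dist = NA_integer_,
                  classes = tree$classes, n = node$n))
    }
    node
  }
  tree$root <- prune(tree$root)
  tree
}

#' Training accuracy of a classification tree
#'
#' @param tree a `cart_tree` fitted to a categorical target.
#' @param table the table to score.
#' @return fraction of rows predicted correctly.
#' @export
cart_accuracy <- function(tree, table) {
  if (is.null(tree$classes)) err_config("accuracy is defined for classification trees")
  mean(predict(tree, table[, tree$features, drop = FALSE]) ==
         as.character(table[[tree$target]]))
}
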