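# Rule extraction and rule-based recommendation.
#
# Every root-to-leaf path of a fitted classification tree is a conjunction
# of threshold conditions; the set of all paths is the tree's disjunctive
# normal form.  Because the paths partition the feature space, exactly one
# rule matches any complete feature vector, so rule-based prediction is
# equivalent to tree traversal.  Recommendation filters the rules of a
# desired class by a partial (fixed) feature assignment and reports the
# residual constraints on the free features.

new_rule <- function(conditions, class) {
  stopifnot(is.data.frame(conditions), all(c("feature", "op", "threshold") %in%
                                             names(conditions)))
  list(conditions = conditions, class = class)
}

empty_conditions <- function() {
  data.frame(feature = character(), op = character(), threshold = numeric(),
             stringsAsFactors = FALSE)
}

# keep only the tightest bound per (feature, direction): the largest ">"
# and the smallest "<=" threshold
simplify_conditions <- function(cond) {
  if (nrow(cond) <= 1) return(cond)
  keep <- logical(nrow(cond))
  seen <- character(0)
  for (i in seq_len(nrow(cond))) {
    key <- paste(cond$feature[i], cond$op[i])
    if (key %in% seen) next
    seen <- c(seen, key)
    same <- cond$feature == cond$feature[i] & cond$op == cond$op[i]
    thr <- if (cond$op[i] == ">") max(cond$threshold[same]) else min(cond$threshold[same])
    j <- which(same & cond$threshold == thr)[1]
    keep[j] <- TRUE
  }
  cond[keep, , drop = FALSE]
}

#' Build a rule set
#'
#' Normally obtained from [extract_rules()]; the constructor is exported so
#' published rule sets can be encoded directly.
#'
#' @param rules list of rules, each a list with `conditions` (data.frame
#'   `feature`, `op` in `{">", "<="}`, `threshold`) and `class`.
#' @param provenance optional description of where the rules came from.
#' @return an object of class `rule_set`.
#' @export
rule_set <- function(rules, provenance = NULL) {
  for (r in rules) {
    stopifnot(is.list(r), !is.null(r$class), is.data.frame(r$conditions))
    if (!all(r$conditions$op %in% c(">", "<="))) {
      err_config("rule conditions must use '>' or '<='")
    }
  }
  structure(rules, class = "rule_set", provenance = provenance)
}

#' Extract the DNF rule set of a classification tree
#'
#' One rule per leaf: the conjunction of the edge conditions on the
#' root-to-leaf path (per feature, redundant conditions are collapsed to
#' the tightest bound), predicting the leaf's class.  The rule count equals
#' the leaf count, and the rules partition the feature space.
#'
#' @param tree a `cart_tree` fitted to a categorical target.
#' @return a [rule_set()].
#' @export
extract_rules <- function(tree) {
  stopifnot(inherits(tree, "cart_tree"))
  if (is.null(tree$classes)) {
    err_config("rules are extracted from classification trees only")
  }
  rules <- list()
  walk <- function(node, cond) {
    if (node$leaf) {
      rules[[length(rules) + 1L]] <<- new_rule(simplify_conditions(cond), node$class)
      return(invisible())
    }
    walk(node$left, rbind(cond, data.frame(feature = node$feature, op = "<=",
                                           threshold = node$threshold,
                                           stringsAsFactors = FALSE)))
    walk(node$right, rbind(cond, data.frame(feature = node$feature, op = ">",
                                            threshold = node$threshold,
                                            stringsAsFactors = FALSE)))
  }
  walk(tree$root, empty_conditions())
  rule_set(rules, provenance = sprintf("cart_tree(target=%s)", tree$target))
}

format_condition <- function(cond) {
  if (nrow(cond) == 0) return("TRUE")
  paste(sprintf("%s %s %g", cond$feature, cond$op, cond$threshold),
        collapse = " AND ")
}

#' @export
format.rule_set <- function(x, ...) {
  vapply(seq_along(x), function(i) {
    sprintf("Rule (%d): IF %s THEN class = %s",
            i, format_condition(x[[i]]$conditions), x[[i]]$class)
  }, character(1))
}

#' @export
print.rule_set <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

# three-valued match: TRUE / FALSE / NA (some needed feature absent)
rule_match_status <- function(rule, kpis) {
  cond <- rule$conditions
  if (nrow(cond) == 0) return(TRUE)
  status <- vapply(seq_len(nrow(cond)), function(i) {
    v <- kpis[[cond$feature[i]]]
    if (is.null(v) || is.na(v)) return(NA)
    if (cond$op[i] == ">") v > cond$threshold[i] else v <= cond$threshold[i]
  }, logical(1))
  if (any(status %in% FALSE)) FALSE else if (anyNA(status)) NA else TRUE
}

#' Predict a class from a rule set
#'
#' Because the rules partition the feature space, exactly one rule matches a
#' complete feature vector.  If the provided KPIs are insufficient to single
#' out a rule, a missing-feature error names the features needed.
#'
#' @param rules a [rule_set()].
#' @param kpis named list or numeric vector of feature values.
#' @return the matched rule's class, with the matched rule index as
#'   attribute `rule`.
#' @export
predict_rules <- function(rules, kpis) {
  stopifnot(inherits(rules, "rule_set"))
  kpis <- as.list(kpis)
  status <- vapply(rules, rule_match_status, logical(1), kpis = kpis)
  hit <- which(status %in% TRUE)
  if (length(hit) > 1) {
    err_config("rule set is not mutually exclusive for this input")
  }
  if (length(hit) == 1) {
    # mutual exclusivity guarantees no undecided rule can also match
    out <- rules[[hit]]$class
    attr(out, "rule") <- hit
    return(out)
  }
  if (anyNA(status)) {
    provided <- names(kpis)[!vapply(kpis, function(v) {
      is.null(v) || all(is.na(v))
    }, logical(1))]
    need <- unique(unlist(lapply(rules[is.na(status)], function(r) {
      setdiff(r$conditions$feature, provided)
    })))
    err_missing_feature(paste("cannot disambiguate; missing feature(s):",
                              paste(sort(need), collapse = ", ")))
  }
  err_config("no rule matches; rule set is not exhaustive")
}

#' @export
predict.rule_set <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    return(vapply(seq_len(nrow(newdata)), function(i) {
      as.character(predict_rules(object, as.list(newdata[i, , drop = FALSE])))
    }, character(1)))
  }
  predict_rules(object, newdata)
}

#' Recommend rules compatible with fixed KPI values
#'
#' Given already-determined KPIs (e.g. the breeding phase has ended, so the
#' emergency-situation exposure is fixed) and a desired outcome class, keep
#' the rules of that class whose conditions on the fixed features are all
#' satisfied, and report the residual constraints on the still-free
#' features -- the levers a chain manager can act on.
#'
#' @param rules a [rule_set()].
#' @param fixed named list or numeric vector of fixed feature values.
#' @param desired desired class; must occur in the rule set.
#' @return a list (possibly empty) of entries with elements `rule` (index),
#'   `class`, and `residual` (data.frame of remaining conditions on free
#'   features).
#' @export
recommend <- function(rules, fixed, desired) {
  stopifnot(inherits(rules, "rule_set"))
  fixed <- as.list(fixed)
  classes <- vapply(rules, function(r) as.character(r$class), character(1))
  if (!desired %in% classes) {
    err_value(sprintf("desired class '%s' does not appear in the rule set", desired))
  }
  out <- list()
  for (i in which(classes == desired)) {
    cond <- rules[[i]]$conditions
    on_fixed <- cond$feature %in% names(fixed)
    ok <- all(vapply(which(on_fixed), function(j) {
      v <- fixed[[cond$feature[j]]]
      if (cond$op[j] == ">") v > cond$threshold[j] else v <= cond$threshold[j]
    }, logical(1)))
    if (!ok) next
    out[[length(out) + 1L]] <- list(rule = i, class = desired,
                                    residual = cond[!on_fixed, , drop = FALSE])
  }
  out
}

#' Serialise / read a rule set
#'
#' The structured form is JSON (round-trippable); the human-readable DNF
#' text is what [print.rule_set()] shows.
#'
#' @param rules a [rule_set()].
#' @param file destination / source path.
#' @return the file path, invisibly, for the writer; a [rule_set()] for the
#'   reader.
#' @export
write_rule_set <- function(rules, file) {
  stopifnot(inherits(rules, "rule_set"))
  payload <- list(
    provenance = attr(rules, "provenance"),
    rules = lapply(rules, function(r) {
      list(class = as.character(r$class),
           conditions = r$conditions)
    })
  )
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_rule_set
#' @export
read_rule_set <- function(file) {
  payload <- jsonlite::read_json(file, simplifyVector = TRUE)
  rules <- lapply(seq_len(length(payload$rules$class)), function(i) {
    cond <- payload$rules$conditions[[i]]
    if (is.null(cond) || length(cond) == 0) cond <- empty_conditions()
    new_rule(as.data.frame(cond, stringsAsFactors = FALSE),
             payload$rules$class[i])
  })
  rule_set(rules, provenance = payload$provenance)
}

#' The planted meat-quality tree used by the chain simulator
#'
#' A depth-3 binary tree over the five cross-phase features
#' `ES` (breeding emergency-situation exposure, %), `AM` (transport abrupt
#' movements, %), `HH` (transport high relative humidity, %), `HT`
#' (transport high temperature, %) and `LT` (transport low temperature, %),
#' with default thresholds 65, 40, 20, 50 and 35.  Its six extracted rules
#' classify a chain's final meat quality as `"A"` or `"B"`; the chain-table
#' generator uses it as ground truth.
#'
#' @param thresholds named numeric: thresholds for `ES`, `AM`, `HH`, `HT`,
#'   `LT`.
#' @return a `cart_tree`.
#' @export
planted_quality_tree <- function(thresholds = c(ES = 65, AM = 40, HH = 20,
                                                HT = 50, LT = 35)) {
  need <- c("ES", "AM", "HH", "HT", "LT")
  if (!all(need %in% names(thresholds))) {
    err_config(paste("thresholds must name", paste(need, collapse = ", ")))
  }
  leaf <- function(class) list(leaf = TRUE, class = class, dist = c(NA_integer_,
                               NA_integer_), classes = c("A", "B"), n = 0L)
  node <- function(f, thr, left, right) {
    list(leaf = FALSE, feature = f, threshold = unname(thresholds[[thr]]),
         n = 0L, decrease = NA_real_, left = left, right = right)
  }
  root <- node("ES", "ES",
               left = node("LT", "LT", leaf("A"), leaf("B")),
               right = node("AM", "AM",
                            left = node("HT", "HT", leaf("A"), leaf("B")),
                            right = node("HH", "HH", leaf("A"), leaf("B"))))
  structure(list(root = root, target = "meat_quality",
                 features = need, classes = c("A", "B"),
                 params = list(max_depth = 3L, min_leaf = 1L,
                               min_impurity_decrease = 0)),
            class = "cart_tree")
}

#' @rdname planted_quality_tree
#' @return `planted_quality_rules()`: the corresponding six-rule
#'   [rule_set()].
#' @export
planted_quality_rules <- function(thresholds = c(ES = 65, AM = 40, HH = 20,
                                                 HT = 50, LT = 35)) {
  extract_rules(planted_quality_tree(thresholds))
}
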