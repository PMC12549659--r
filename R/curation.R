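# Feature curation: (c1) Pearson correlation pruning with
# mutual-information tie-breaking, (c2) recursive feature elimination
# wrapped around a 100-tree random forest. Both are fitted strictly on
# training rows; the evaluation module's leakage guard enforces the
# caller contract.

#' Pairwise Pearson correlation matrix of feature columns
#'
#' Full precision is kept internally; threshold comparisons downstream
#' use coefficients rounded to two decimals. A zero-variance column's
#' correlations are defined as 0 (with a warning) rather than NA.
#'
#' @param x numeric matrix or data.frame of feature columns (>= 2 rows,
#'   no missing values).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop_crisp("crisp_config_error", "need >= 2 rows")
  if (anyNA(x)) stop_crisp("crisp_config_error", "missing values in features")
  const <- apply(x, 2, function(v) max(v) == min(v))
  r <- suppressWarnings(cor(x))
  if (any(const)) {
    warn_crisp("crisp_zero_variance",
               "zero-variance column(s), correlations set to 0: %s",
               paste(colnames(x)[const], collapse = ", "))
    r[const, ] <- 0; r[, const] <- 0
  }
  diag(r) <- 1
  r
}

#' Mutual information between a feature and class labels (nats)
#'
#' Plug-in estimator on the contingency table of the quantile-discretized
#' feature against the label; invariant to strictly monotone transforms
#' of the feature. Always nonnegative; exactly 0 for a constant feature
#' or single-class labels (with a warning for the latter).
#'
#' @param feature numeric vector.
#' @param labels factor or vector of class labels.
#' @param bins number of quantile bins (default 10).
#' @return MI estimate in nats.
#' @export
mutual_information <- function(feature, labels, bins = 10) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2) {
    warn_crisp("crisp_single_class", "single-class labels, MI = 0")
    return(0)
  }
  breaks <- unique(quantile(feature, probs = seq(0, 1, length.out = bins + 1)))
  if (length(breaks) < 2) return(0)
  binned <- cut(feature, breaks = breaks, include.lowest = TRUE)
  contingency_mi(table(binned, labels))
}

# Plug-in MI of a contingency table, in nats.
contingency_mi <- function(tab) {
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  terms <- p * log(p / outer(px, py))
  sum(terms[p > 0])
}

#' Correlation pruning with mutual-information tie-breaking
#'
#' Flags every feature pair whose absolute Pearson correlation, rounded
#' to two decimals, is at or above `r_threshold`; pairs are processed
#' greedily in order of descending rounded correlation, dropping the
#' lower-MI member (MI ties drop the lexicographically later name), and
#' the flag set is re-checked over the survivors until no retained pair
#' remains above threshold.
#'
#' @param x numeric matrix/data.frame of training-fold feature columns.
#' @param labels training-fold class labels (for MI).
#' @param r_threshold rounded-|r| threshold (default 0.80).
#' @param bins quantile bins for the MI estimator.
#' @return object of class `prune_result`: `retained` (input order),
#'   `dropped` (data.frame: feature, partner, r_abs, mi_dropped,
#'   mi_partner), `r_threshold`, `mi` (per input column).
#' @export
correlation_prune <- function(x, labels, r_threshold = 0.80, bins = 10) {
  x <- as.data.frame(x)
  cols <- colnames(x)
  r <- pearson_matrix(x)
  rabs <- round(abs(r), 2)
  mi <- vapply(cols, function(cn)
    suppressWarnings(mutual_information(x[[cn]], labels, bins)), numeric(1))
  retained <- cols
  dropped <- data.frame(feature = character(0), partner = character(0),
                        r_abs = numeric(0), mi_dropped = numeric(0),
                        mi_partner = numeric(0))
  repeat {
    sub <- rabs[retained, retained, drop = FALSE]
    flag <- which(sub >= r_threshold & upper.tri(sub), arr.ind = TRUE)
    if (!nrow(flag)) break
    pairs <- data.frame(a = retained[flag[, 1]], b = retained[flag[, 2]],
                        r = sub[flag])
    pairs <- pairs[order(-pairs$r, pairs$a, pairs$b), , drop = FALSE]
    for (k in seq_len(nrow(pairs))) {
      a <- pairs$a[k]; b <- pairs$b[k]
      if (!(a %in% retained && b %in% retained)) next
      drop <- if (mi[a] < mi[b]) a
        else if (mi[b] < mi[a]) b
        else max(a, b)  # MI tie: lexicographically later name
      keep <- setdiff(c(a, b), drop)
      retained <- setdiff(retained, drop)
      dropped <- rbind(dropped, data.frame(
        feature = drop, partner = keep, r_abs = pairs$r[k],
        mi_dropped = mi[drop], mi_partner = mi[keep]))
    }
  }
  structure(list(retained = cols[cols %in% retained], dropped = dropped,
                 r_threshold = r_threshold, mi = mi),
            class = "prune_result")
}

#' @export
print.prune_result <- function(x, ...) {
  cat(sprintf("<prune_result> retained %d of %d features (|r| >= %.2f, lower MI dropped)\n",
              length(x$retained), length(x$retained) + nrow(x$dropped),
              x$r_threshold))
  invisible(x)
}

#' Recursive feature elimination with a random forest
#'
#' Iteratively fits a random forest (`n_trees` trees) on the surviving
#' columns and removes the `step` lowest-importance features (mean
#' decrease in Gini impurity) until `n_keep` remain. Deterministic given
#' `seed`.
#'
#' @param x numeric matrix/data.frame of training-fold feature columns
#'   (already correlation-pruned).
#' @param labels training-fold class labels.
#' @param n_keep number of features to retain (default 10).
#' @param n_trees forest size per iteration (default 100).
#' @param step features removed per iteration (default 1).
#' @param seed integer seed.
#' @return object of class `rfe_result`: `selected` (by descending final
#'   importance), `ranking` (named elimination rank, 1 = best),
#'   `importances` (final model), `n_trees`, `seed`.
#' @export
rfe_select <- function(x, labels, n_keep = 10, n_trees = 100, step = 1,
                       seed = 1) {
  x <- as.data.frame(x)
  labels <- droplevels(as.factor(labels))
  cols <- colnames(x)
  if (length(cols) < n_keep)
    stop_crisp("crisp_config_error",
               "cannot keep %d features from %d columns", n_keep,
               length(cols))
  set.seed(seed)
  surviving <- cols
  elim_order <- character(0)
  final_imp <- NULL
  while (TRUE) {
    rf <- randomForest::randomForest(
      x = x[, surviving, drop = FALSE], y = labels, ntree = n_trees)
    imp <- rf$importance[, "MeanDecreaseGini"]
    if (length(surviving) <= n_keep) { final_imp <- imp; break }
    n_drop <- min(step, length(surviving) - n_keep)
    worst <- names(sort(imp))[seq_len(n_drop)]
    elim_order <- c(elim_order, worst)
    surviving <- setdiff(surviving, worst)
  }
  selected <- names(sort(final_imp, decreasing = TRUE))
  ranking <- setNames(
    c(seq_along(selected),
      rev(seq_along(elim_order)) + length(selected)),
    c(selected, rev(elim_order)))
  structure(list(selected = selected, ranking = ranking,
                 importances = final_imp, n_trees = n_trees, seed = seed),
            class = "rfe_result")
}

#' @export
print.rfe_result <- function(x, ...) {
  cat(sprintf("<rfe_result> %d features selected by %d-tree RF RFE: %s\n",
              length(x$selected), x$n_trees,
              paste(x$selected, collapse = ", ")))
  invisible(x)
}
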