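# SMOTE minority oversampling, implemented from the interpolation rule
# x_new = x_i + delta * (x_zi - x_i), delta ~ Uniform[0,1], with x_zi one
# of the k same-class nearest neighbors of x_i. Every synthetic row's
# (base, neighbor, delta) provenance is recorded so its geometry can be
# audited exactly.

#' SMOTE configuration
#'
#' @param k_neighbors number of same-class nearest neighbors to draw the
#'   interpolation partner from (default 5; truncated with a warning for
#'   classes smaller than `k + 1`).
#' @param target `"equalize_to_majority"` or a named integer vector of
#'   explicit per-class output counts.
#' @param seed integer seed.
#' @return list of class `smote_config`.
#' @export
smote_config <- function(k_neighbors = 5, target = "equalize_to_majority",
                         seed = 1) {
  if (k_neighbors < 1)
    stop_crisp("crisp_config_error", "k_neighbors must be >= 1")
  structure(list(k_neighbors = k_neighbors, target = target, seed = seed),
            class = "smote_config")
}

# k nearest neighbors (indices) within one class, computed on
# standardized columns; chunked so large classes stay within memory.
class_knn <- function(z, k) {
  m <- nrow(z)
  nn <- matrix(0L, m, k)
  chunk <- max(1L, floor(2e7 / m))
  sq <- rowSums(z^2)
  for (start in seq(1L, m, by = chunk)) {
    idx <- start:min(start + chunk - 1L, m)
    d2 <- outer(sq[idx], sq, "+") - 2 * z[idx, , drop = FALSE] %*% t(z)
    for (j in seq_along(idx)) {
      ord <- order(d2[j, ], seq_len(m))
      nn[idx[j], ] <- setdiff(ord, idx[j])[seq_len(k)]
    }
  }
  nn
}

#' SMOTE oversampling of training-fold minority classes
#'
#' Original rows are returned unchanged as a prefix of the output;
#' synthetic rows are appended until every class meets the target count.
#' Base rows are visited round-robin in their original order; the
#' interpolation partner is drawn uniformly from the base's `k` nearest
#' same-class neighbors (Euclidean distance on columns standardized to
#' the training mean/SD); `delta ~ U[0, 1]`.
#'
#' @param x numeric matrix/data.frame of training rows (curated feature
#'   columns only).
#' @param labels training class labels.
#' @param config a [smote_config()].
#' @return list: `x` (augmented matrix), `labels` (augmented),
#'   `provenance` (data.frame: class, base_index, neighbor_index, delta —
#'   indices into the original `x`), `n_original`.
#' @export
smote_oversample <- function(x, labels, config = smote_config()) {
  x <- as.matrix(x)
  labels <- droplevels(as.factor(labels))
  counts <- table(labels)
  target <- if (identical(config$target, "equalize_to_majority")) {
    setNames(rep(max(counts), nlevels(labels)), levels(labels))
  } else {
    tgt <- config$target
    if (!all(levels(labels) %in% names(tgt)))
      stop_crisp("crisp_config_error", "explicit target must name every class")
    tgt[levels(labels)]
  }
  set.seed(config$seed)
  mu <- colMeans(x)
  sds <- apply(x, 2, sd); sds[sds == 0] <- 1
  prov <- data.frame(class = character(0), base_index = integer(0),
                     neighbor_index = integer(0), delta = numeric(0))
  new_rows <- NULL
  for (cl in levels(labels)) {
    need <- target[[cl]] - counts[[cl]]
    if (need <= 0) next
    members <- which(labels == cl)
    m <- length(members)
    if (m < 2)
      stop_crisp("crisp_balance_error",
                 "class '%s' has a single member; cannot oversample", cl)
    k <- config$k_neighbors
    if (k > m - 1) {
      warn_crisp("crisp_k_truncated",
                 "k = %d exceeds class '%s' size - 1; truncated to %d",
                 k, cl, m - 1)
      k <- m - 1
    }
    z <- scale(x[members, , drop = FALSE], center = mu, scale = sds)
    nn <- class_knn(z, k)
    local_base <- (seq_len(need) - 1L) %% m + 1L
    bi <- members[local_base]
    zi <- members[nn[cbind(local_base,
                           sample.int(k, need, replace = TRUE))]]
    delta <- runif(need)
    syn <- x[bi, , drop = FALSE] +
      delta * (x[zi, , drop = FALSE] - x[bi, , drop = FALSE])
    new_rows <- rbind(new_rows, syn)
    prov <- rbind(prov, data.frame(class = cl, base_index = bi,
                                   neighbor_index = zi, delta = delta))
  }
  x_aug <- rbind(x, new_rows)
  rownames(x_aug) <- NULL
  labels_aug <- factor(c(as.character(labels), prov$class),
                       levels = levels(labels))
  list(x = x_aug, labels = labels_aug, provenance = prov,
       n_original = nrow(x))
}

#' Audit the geometry of SMOTE synthetic rows
#'
#' Recomputes every synthetic row from its recorded (base, neighbor,
#' delta) provenance and asserts the interpolation identity holds to
#' within `tol` per coordinate, and that each synthetic row carries its
#' base row's class.
#'
#' @param result output of [smote_oversample()].
#' @param tol maximum allowed per-coordinate residual (default 1e-9).
#' @return list: `ok`, `n_checked`, `max_residual`, `violations` (row
#'   indices into the synthetic block).
#' @export
verify_synthetic_geometry <- function(result, tol = 1e-9) {
  prov <- result$provenance
  n0 <- result$n_original
  orig <- result$x[seq_len(n0), , drop = FALSE]
  n_syn <- nrow(prov)
  if (n_syn == 0)
    return(list(ok = TRUE, n_checked = 0L, max_residual = 0,
                violations = integer(0)))
  max_res <- 0
  bad <- integer(0)
  for (s in seq_len(n_syn)) {
    expect <- orig[prov$base_index[s], ] +
      prov$delta[s] * (orig[prov$neighbor_index[s], ] -
                         orig[prov$base_index[s], ])
    res <- max(abs(result$x[n0 + s, ] - expect))
    class_ok <- result$labels[n0 + s] == prov$class[s] &&
      result$labels[prov$base_index[s]] == prov$class[s]
    if (res >= tol || !class_ok) bad <- c(bad, s)
    max_res <- max(max_res, res)
  }
  list(ok = length(bad) == 0L, n_checked = n_syn, max_residual = max_res,
       violations = bad)
}
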