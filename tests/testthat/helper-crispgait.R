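# Shared fixtures and independent oracles, built in code at test time.

# Ground-truth events of one foot mapped into the trimmed timebase,
# restricted to complete stances (both HS and TO inside the window with a
# small margin); cut stances are discarded by the detector by design.
complete_truth_events <- function(sim, pp, foot, margin = 0.05) {
  tr <- sim$truth$events[[foot]]
  hs <- tr$hs - pp$time_offset
  to <- tr$to - pp$time_offset
  end <- max(pp$time)
  keep <- hs > margin & to < end - margin
  data.frame(hs = hs[keep], to = to[keep])
}

# Distance from each truth event to its nearest detected event (seconds).
match_err <- function(truth, detected) {
  vapply(truth, function(t) min(abs(detected - t)), numeric(1))
}

# Detected events for one foot of a preprocessed walk.
foot_events <- function(pp, foot) {
  detect_events(if (foot == "left") pp$total_left else pp$total_right,
                pp$sample_rate, foot = foot, time = pp$time)
}

# Brute-force sliding-window median with reflect padding (oracle for
# median_filter).
brute_median <- function(x, k) {
  h <- (k - 1) %/% 2
  padded <- c(x[(h + 1):2], x, x[(length(x) - 1):(length(x) - h)])
  vapply(seq_along(x), function(i) median(padded[i:(i + k - 1)]),
         numeric(1))
}

# Brute-force confusion-matrix metrics (oracle for compute_metrics,
# binary with `pos` as positive class; percentages).
brute_binary_metrics <- function(y_true, y_pred, pos) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(y_true)) {
    if (y_pred[i] == pos && y_true[i] == pos) tp <- tp + 1
    else if (y_pred[i] == pos) fp <- fp + 1
    else if (y_true[i] == pos) fn <- fn + 1
    else tn <- tn + 1
  }
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  c(accuracy = 100 * (tp + tn) / length(y_true),
    precision = 100 * prec, recall = 100 * rec,
    specificity = 100 * (if (tn + fp == 0) 0 else tn / (tn + fp)),
    f1 = 100 * (if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)))
}

# Brute-force mode-with-posterior-tie-break recount (oracle for
# subject_vote).
brute_vote <- function(pred, proba, subject_ids) {
  classes <- levels(pred)
  vapply(unique(subject_ids), function(s) {
    rows <- which(subject_ids == s)
    counts <- vapply(classes, function(cl) sum(pred[rows] == cl),
                     numeric(1))
    winners <- classes[counts == max(counts)]
    if (length(winners) == 1) return(winners)
    mp <- vapply(winners, function(cl) mean(proba[rows, cl]), numeric(1))
    winners[which.max(mp)]
  }, character(1))
}

# Planted-signal design: `n_signal` informative columns (class-shifted
# Gaussians) plus `n_noise` pure-noise columns, balanced binary labels.
make_planted_matrix <- function(n = 2000, n_signal = 10, n_noise = 20,
                                effect = 0.5, seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("A", "B"), length.out = n))
  shift <- ifelse(y == "B", effect, 0)
  x <- cbind(
    matrix(rnorm(n * n_signal), n) + shift,
    matrix(rnorm(n * n_noise), n))
  colnames(x) <- c(sprintf("sig%02d", seq_len(n_signal)),
                   sprintf("noise%02d", seq_len(n_noise)))
  list(x = as.data.frame(x), y = y,
       planted = sprintf("sig%02d", seq_len(n_signal)))
}

# Small simulated binary cohort -> feature matrix, used by several tests.
small_feature_matrix <- function(n_per_class = 5, seed = 42,
                                 severity_gradient = 2, noise_sd = 4,
                                 task = "binary") {
  cfg <- gait_sim_config(n_per_class = n_per_class, seed = seed,
                         severity_gradient = severity_gradient,
                         noise_sd = noise_sd)
  co <- simulate_cohort(cfg, task)
  suppressWarnings(extract_features(co$records, co$demographics, task))
}
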