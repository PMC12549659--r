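# Per-cycle spatiotemporal gait features. Timing features come straight
# from the HS/TO events; lengths use the reference-speed model
# stride_length = reference_speed * stride_time (VGRF alone does not
# determine distance), with step length splitting the stride by the
# walk's mean step-time fractions.

#' Names of the default feature panel columns
#' @return character vector of feature column names.
#' @export
feature_columns <- function() c(
  "stride_time", "stance_time", "swing_time", "stance_pct", "swing_pct",
  "cadence", "step_length", "stride_length", "speed", "stance_swing_ratio",
  "stride_time_sd", "stance_time_sd", "swing_time_sd", "cadence_sd",
  "stride_time_rmean", "stance_time_rmean",
  "asym_stride_time", "asym_stance_time", "asym_swing_time", "foot_right"
)

#' Per-cycle spatiotemporal features from cycle timings
#'
#' Definitional arithmetic: `stance_pct = 100 * stance/stride`,
#' `swing_pct = 100 - stance_pct`, `cadence = 120/stride_time` (two steps
#' per stride), `stride_length = reference_speed * stride_time`,
#' `step_length = stride_length * step_fraction`,
#' `speed = stride_length / stride_time`.
#'
#' @param cycles data.frame with `stride_time`, `stance_time`,
#'   `swing_time` (one row per valid cycle).
#' @param reference_speed walking speed in m/s used by the length model.
#' @param step_fraction this foot's share of the stride time taken by its
#'   step (0.5 = symmetric split).
#' @return data.frame of per-cycle features.
#' @export
cycle_features <- function(cycles, reference_speed = 1.2,
                           step_fraction = 0.5) {
  stride <- cycles$stride_time
  stance <- cycles$stance_time
  swing <- cycles$swing_time
  stance_pct <- 100 * stance / stride
  stride_length <- reference_speed * stride
  data.frame(
    stride_time = stride, stance_time = stance, swing_time = swing,
    stance_pct = stance_pct, swing_pct = 100 - stance_pct,
    cadence = 120 / stride,
    step_length = stride_length * step_fraction,
    stride_length = stride_length,
    speed = stride_length / stride,
    stance_swing_ratio = stance / swing
  )
}

#' Trailing rolling standard deviation of a per-cycle series
#'
#' Element `i` is the sample SD of the `window` values ending at `i`;
#' the first `window - 1` elements are `NA` (no leakage of future
#' cycles into a cycle's variability value).
#'
#' @param values numeric series ordered by cycle time.
#' @param window trailing window length in cycles (>= 2).
#' @return numeric series of the same length.
#' @export
rolling_variability <- function(values, window = 10) {
  if (window < 2) stop_crisp("crisp_config_error", "window must be >= 2")
  n <- length(values)
  out <- rep(NA_real_, n)
  if (n >= window)
    for (i in window:n) out[i] <- sd(values[(i - window + 1):i])
  out
}

rolling_mean <- function(values, window = 10) {
  n <- length(values)
  out <- rep(NA_real_, n)
  if (n >= window)
    for (i in window:n) out[i] <- mean(values[(i - window + 1):i])
  out
}

# Mean fraction of the stride spent between this foot's HS and the
# opposite foot's next HS (the step-time split used for step length).
step_time_fraction <- function(own_hs, own_stride, opp_hs) {
  if (length(opp_hs) == 0L || length(own_hs) == 0L) return(0.5)
  opp_hs <- sort(opp_hs)
  fr <- vapply(seq_along(own_hs), function(i) {
    nxt <- opp_hs[opp_hs > own_hs[i]]
    if (!length(nxt)) return(NA_real_)
    (nxt[1] - own_hs[i]) / own_stride[i]
  }, numeric(1))
  fr <- fr[is.finite(fr) & fr > 0 & fr < 1]
  if (!length(fr)) 0.5 else mean(fr)
}

walk_feature_rows <- function(cycles, reference_speed, window = 10) {
  cycles <- cycles[cycles$valid, , drop = FALSE]
  if (!nrow(cycles)) return(NULL)
  by_foot <- split(cycles, cycles$foot)
  mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
  asym <- function(col) {
    l <- mean_or_na(by_foot$left[[col]]); r <- mean_or_na(by_foot$right[[col]])
    if (is.na(l) || is.na(r)) return(0)
    abs(l - r) / mean(cycles[[col]])
  }
  a_stride <- asym("stride_time")
  a_stance <- asym("stance_time")
  a_swing <- asym("swing_time")
  out <- NULL
  for (foot in names(by_foot)) {
    cy <- by_foot[[foot]][order(by_foot[[foot]]$start_hs), , drop = FALSE]
    opp <- setdiff(c("left", "right"), foot)
    frac <- step_time_fraction(cy$start_hs, cy$stride_time,
                               if (opp %in% names(by_foot))
                                 by_foot[[opp]]$start_hs else numeric(0))
    f <- cycle_features(cy, reference_speed, frac)
    f$stride_time_sd <- rolling_variability(f$stride_time, window)
    f$stance_time_sd <- rolling_variability(f$stance_time, window)
    f$swing_time_sd <- rolling_variability(f$swing_time, window)
    f$cadence_sd <- rolling_variability(f$cadence, window)
    f$stride_time_rmean <- rolling_mean(f$stride_time, window)
    f$stance_time_rmean <- rolling_mean(f$stance_time, window)
    f$asym_stride_time <- a_stride
    f$asym_stance_time <- a_stance
    f$asym_swing_time <- a_swing
    f$foot_right <- as.numeric(foot == "right")
    f$subject_id <- cy$subject_id
    f$walk_id <- cy$walk_id
    f$foot <- foot
    f$start_hs <- cy$start_hs
    out <- rbind(out, f)
  }
  out
}

#' Assemble the per-cycle feature matrix for a task
#'
#' Only valid cycles enter; rows whose trailing-window variability is
#' undefined (the first `window - 1` cycles of each foot) are dropped and
#' counted in attribute `n_warmup_dropped`. Rows are sorted canonically
#' by subject, walk, foot, and cycle time, and get a `cycle_index`
#' within each (subject, walk, foot). Labels: binary task attaches
#' `PD`/`HC` from demographics; severity task keeps PD rows only,
#' labelled with their Hoehn--Yahr grade.
#'
#' @param cycles data.frame of segmented cycles from all walks (see
#'   [walk_cycles()]), with `subject_id`/`walk_id` columns.
#' @param demographics data.frame from [read_demographics()] (a `speed`
#'   column, when present, supplies the per-subject reference speed).
#' @param task `"binary"` or `"severity"`.
#' @param window trailing window for variability features.
#' @param reference_speed fallback walking speed (m/s) when demographics
#'   carry none.
#' @return data.frame: metadata columns `subject_id`, `walk_id`, `foot`,
#'   `cycle_index`, `start_time` (cycle start in the trimmed timebase),
#'   `label` plus the [feature_columns()] panel;
#'   attributes `feature_cols` and `n_warmup_dropped`.
#' @export
build_feature_matrix <- function(cycles, demographics,
                                 task = c("binary", "severity"),
                                 window = 10, reference_speed = 1.2) {
  task <- match.arg(task)
  missing <- setdiff(unique(cycles$subject_id), demographics$subject_id)
  if (length(missing))
    stop_crisp("crisp_integrity_error",
               "subjects missing from demographics: %s",
               paste(missing, collapse = ", "))
  speed_of <- function(sid) {
    if ("speed" %in% names(demographics)) {
      s <- demographics$speed[demographics$subject_id == sid]
      if (length(s) == 1L && is.finite(s)) return(s)
    }
    reference_speed
  }
  rows <- NULL
  for (key in unique(paste(cycles$subject_id, cycles$walk_id, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    wc <- cycles[cycles$subject_id == parts[1] & cycles$walk_id == parts[2], ,
                 drop = FALSE]
    rows <- rbind(rows, walk_feature_rows(wc, speed_of(parts[1]), window))
  }
  if (is.null(rows))
    stop_crisp("crisp_integrity_error", "no valid cycles to featurize")
  n_before <- nrow(rows)
  rows <- rows[complete.cases(rows[, feature_columns()]), , drop = FALSE]
  n_dropped <- n_before - nrow(rows)
  rows <- rows[order(rows$subject_id, rows$walk_id, rows$foot,
                     rows$start_hs), , drop = FALSE]
  idx <- ave(seq_len(nrow(rows)),
             paste(rows$subject_id, rows$walk_id, rows$foot),
             FUN = seq_along)
  grp <- setNames(demographics$group, demographics$subject_id)
  hy <- setNames(demographics$hoehn_yahr, demographics$subject_id)
  out <- data.frame(subject_id = rows$subject_id, walk_id = rows$walk_id,
                    foot = rows$foot, cycle_index = idx,
                    start_time = rows$start_hs,
                    rows[, feature_columns()], row.names = NULL)
  if (task == "binary") {
    out$label <- factor(grp[out$subject_id], levels = c("HC", "PD"))
  } else {
    keep <- grp[out$subject_id] == "PD" & !is.na(hy[out$subject_id])
    out <- out[keep, , drop = FALSE]
    out$label <- factor(hy[out$subject_id])
  }
  rownames(out) <- NULL
  attr(out, "feature_cols") <- feature_columns()
  attr(out, "n_warmup_dropped") <- n_dropped
  out
}

#' Per-subject mean and SD of every feature
#'
#' @param matrix a feature matrix from [build_feature_matrix()].
#' @return data.frame, one row per subject, columns `<feature>_mean` and
#'   `<feature>_sd` (SD reported as 0, with a warning, for single-cycle
#'   subjects).
#' @export
subject_summary <- function(matrix) {
  if (!nrow(matrix)) stop_crisp("crisp_integrity_error", "empty matrix")
  fc <- attr(matrix, "feature_cols") %||% feature_columns()
  subs <- unique(matrix$subject_id)
  single <- character(0)
  out <- do.call(rbind, lapply(subs, function(s) {
    m <- matrix[matrix$subject_id == s, fc, drop = FALSE]
    mu <- colMeans(m)
    sds <- if (nrow(m) > 1) apply(m, 2, sd) else {
      single <<- c(single, s); rep(0, ncol(m))
    }
    row <- as.data.frame(as.list(c(setNames(mu, paste0(fc, "_mean")),
                                   setNames(sds, paste0(fc, "_sd")))))
    cbind(data.frame(subject_id = s, label = matrix$label[
      match(s, matrix$subject_id)], n_cycles = nrow(m)), row)
  }))
  if (length(single))
    warn_crisp("crisp_single_cycle",
               "single-cycle subject(s), SD reported as 0: %s",
               paste(single, collapse = ", "))
  rownames(out) <- NULL
  out
}

#' Run preprocessing, event detection, and featurization over a cohort
#'
#' Convenience wrapper mapping a set of recordings to one feature matrix.
#'
#' @param records list of [vgrf_recording()] objects.
#' @param demographics demographics data.frame.
#' @param task `"binary"` or `"severity"`.
#' @param preprocess a [preprocess_config()].
#' @param validity a [validity_config()].
#' @param threshold_frac event-detection threshold fraction.
#' @param window variability window in cycles.
#' @return feature matrix (see [build_feature_matrix()]).
#' @export
extract_features <- function(records, demographics,
                             task = c("binary", "severity"),
                             preprocess = preprocess_config(),
                             validity = validity_config(),
                             threshold_frac = 0.2, window = 10) {
  cycles <- do.call(rbind, lapply(records, function(r)
    walk_cycles(preprocess_walk(r, preprocess), threshold_frac, validity)))
  build_feature_matrix(cycles, demographics, match.arg(task), window)
}
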