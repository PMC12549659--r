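# Signal conditioning for VGRF walks: per-channel min-max normalization
# to [0,1], exclusion of the unsteady head/tail of each walk, and median
# filtering of every force channel. Order (normalize, trim, filter)
# follows the pipeline's stated procedure; the downstream 20%-of-peak
# event threshold is proportional, so normalization does not move events.

#' Preprocessing configuration
#'
#' @param head_trim seconds removed from the start of each walk
#'   (default 20, matching the exclusion of gait initiation).
#' @param tail_trim seconds removed from the end (default 10, gait
#'   termination).
#' @param median_kernel odd sample count for the median filter
#'   (default 9).
#' @param normalize apply per-channel min-max scaling to `[0, 1]`.
#' @param proportional_trim when `TRUE`, walks shorter than
#'   `head_trim + tail_trim + 10` seconds are trimmed proportionally
#'   (1/3 head, 1/6 tail) instead of raising an error.
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(head_trim = 20, tail_trim = 10,
                              median_kernel = 9, normalize = TRUE,
                              proportional_trim = FALSE) {
  if (median_kernel < 1 || median_kernel %% 2 == 0)
    stop_crisp("crisp_config_error", "median_kernel must be odd and >= 1")
  if (head_trim < 0 || tail_trim < 0)
    stop_crisp("crisp_config_error", "trims must be >= 0")
  structure(list(head_trim = head_trim, tail_trim = tail_trim,
                 median_kernel = median_kernel, normalize = normalize,
                 proportional_trim = proportional_trim),
            class = "preprocess_config")
}

minmax_channel <- function(x, what) {
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warn_crisp("crisp_constant_channel",
               "constant channel %s normalized to all zeros", what)
    return(rep(0, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Min-max normalize every force channel of a recording
#'
#' Each channel is independently mapped to `[0, 1]` via
#' `(x - min) / (max - min)` over the recording; a constant channel maps
#' to all zeros with a warning.
#'
#' @param rec a [vgrf_recording()].
#' @return the normalized recording.
#' @export
minmax_normalize <- function(rec) {
  rec$total_left <- minmax_channel(rec$total_left, "total_left")
  rec$total_right <- minmax_channel(rec$total_right, "total_right")
  if (!is.null(rec$sensors))
    for (j in seq_len(ncol(rec$sensors)))
      rec$sensors[, j] <- minmax_channel(rec$sensors[, j],
                                         colnames(rec$sensors)[j])
  rec
}

#' Trim the head and tail of a walk
#'
#' Removes samples with `t < head_trim` or `t > t_end - tail_trim`,
#' re-zeroes time, and accumulates the removed head duration into the
#' recording's `time_offset` so trimmed event times can be mapped back to
#' the raw timebase. Errors if less than 10 s would remain (unless
#' `proportional_trim` applies).
#'
#' @param rec a [vgrf_recording()].
#' @param config a [preprocess_config()].
#' @return the trimmed recording.
#' @export
trim_walk <- function(rec, config = preprocess_config()) {
  dur <- rec$time[length(rec$time)] - rec$time[1]
  head_trim <- config$head_trim; tail_trim <- config$tail_trim
  if (dur - head_trim - tail_trim < 10) {
    if (config$proportional_trim) {
      head_trim <- dur / 3; tail_trim <- dur / 6
    } else {
      stop_crisp("crisp_trim_error",
                 "walk of %.1f s leaves < 10 s after %g + %g s trim",
                 dur, head_trim, tail_trim)
    }
  }
  keep <- rec$time >= rec$time[1] + head_trim &
    rec$time <= rec$time[length(rec$time)] - tail_trim
  off <- rec$time[keep][1]
  rec$time_offset <- rec$time_offset + off
  rec$time <- rec$time[keep] - off
  rec$total_left <- rec$total_left[keep]
  rec$total_right <- rec$total_right[keep]
  if (!is.null(rec$sensors)) rec$sensors <- rec$sensors[keep, , drop = FALSE]
  rec
}

#' Sliding-window median filter with reflect padding
#'
#' Output length equals input length; edges are handled by reflecting the
#' signal at the boundaries. Kernel 1 is the identity.
#'
#' @param x numeric signal.
#' @param kernel odd window size in samples.
#' @return filtered signal.
#' @export
median_filter <- function(x, kernel = 9) {
  if (kernel %% 2 == 0 || kernel < 1)
    stop_crisp("crisp_config_error", "median kernel must be odd and >= 1")
  if (kernel == 1) return(x)
  if (length(x) < kernel)
    stop_crisp("crisp_config_error",
               "signal shorter than median kernel (%d < %d)",
               length(x), kernel)
  h <- (kernel - 1L) %/% 2L
  padded <- c(x[(h + 1L):2L], x, x[(length(x) - 1L):(length(x) - h)])
  out <- runmed(padded, kernel, endrule = "keep")
  as.numeric(out[(h + 1L):(h + length(x))])
}

#' Full preprocessing of one walk
#'
#' Applies min-max normalization, head/tail trimming, and median
#' filtering of every force channel, in that order.
#'
#' @param rec a [vgrf_recording()].
#' @param config a [preprocess_config()].
#' @return the preprocessed recording.
#' @export
preprocess_walk <- function(rec, config = preprocess_config()) {
  if (config$normalize) rec <- minmax_normalize(rec)
  rec <- trim_walk(rec, config)
  rec$total_left <- median_filter(rec$total_left, config$median_kernel)
  rec$total_right <- median_filter(rec$total_right, config$median_kernel)
  if (!is.null(rec$sensors))
    for (j in seq_len(ncol(rec$sensors)))
      rec$sensors[, j] <- median_filter(rec$sensors[, j],
                                        config$median_kernel)
  rec
}
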