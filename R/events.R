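# Heel-strike / toe-off detection by threshold crossing of each foot's
# total force, and segmentation into gait cycles (two successive
# same-foot heel strikes).

#' Validity bounds for segmented gait cycles
#'
#' The physiological plausibility window for adult walking; cycles
#' outside it are retained with `valid = FALSE` and a reason code, never
#' silently dropped.
#'
#' @param stride_range stride time bounds in seconds.
#' @param stance_frac_range stance-fraction (stance/stride) bounds.
#' @return list of class `validity_config`.
#' @export
validity_config <- function(stride_range = c(0.4, 2.5),
                            stance_frac_range = c(0.40, 0.90)) {
  structure(list(stride_range = stride_range,
                 stance_frac_range = stance_frac_range),
            class = "validity_config")
}

#' Detect heel-strike and toe-off events in a force channel
#'
#' A heel strike is an upward crossing of `threshold_frac` times the
#' channel's peak force (previous sample below threshold, current at or
#' above); the subsequent downward crossing is the matching toe off.
#' Event times are refined by linear interpolation between the bracketing
#' samples. A leading partial stance (signal starting above threshold)
#' and a trailing heel strike without a toe off are discarded. Crossings
#' within `debounce` seconds of the previous accepted event of the same
#' kind are ignored.
#'
#' @param force numeric force channel (preprocessed).
#' @param sample_rate samples per second.
#' @param threshold_frac fraction of peak force (default 0.2).
#' @param foot `"left"` or `"right"` label carried on the result.
#' @param debounce refractory period in seconds (default 0.1).
#' @param time optional explicit time vector (defaults to
#'   `(0:(n-1))/sample_rate`).
#' @return object of class `gait_events`: `foot`, `heel_strikes`,
#'   `toe_offs` (seconds, paired and alternating HS < TO < HS ...),
#'   `peak_force`, `threshold`.
#' @export
detect_events <- function(force, sample_rate, threshold_frac = 0.2,
                          foot = "left", debounce = 0.1, time = NULL) {
  n <- length(force)
  if (n < sample_rate)
    stop_crisp("crisp_config_error", "need at least 1 s of samples")
  if (is.null(time)) time <- (seq_len(n) - 1L) / sample_rate
  peak <- max(force)
  out <- structure(list(foot = foot, heel_strikes = numeric(0),
                        toe_offs = numeric(0), peak_force = peak,
                        threshold = threshold_frac * peak),
                   class = "gait_events")
  if (peak <= 0 || peak == min(force)) {
    warn_crisp("crisp_no_events", "constant or zero force; no events")
    return(out)
  }
  thr <- threshold_frac * peak
  above <- force >= thr
  hs <- numeric(0); to <- numeric(0)
  state <- if (above[1]) "skip_partial" else "swing"
  last_hs <- -Inf; last_to <- -Inf
  for (i in 2:n) {
    if (state == "skip_partial") {
      if (!above[i]) state <- "swing"
    } else if (state == "swing" && above[i] && !above[i - 1]) {
      t_ev <- time[i - 1] + (thr - force[i - 1]) /
        (force[i] - force[i - 1]) * (time[i] - time[i - 1])
      if (t_ev - last_hs >= debounce) {
        hs <- c(hs, t_ev); last_hs <- t_ev; state <- "stance"
      }
    } else if (state == "stance" && !above[i] && above[i - 1]) {
      t_ev <- time[i - 1] + (force[i - 1] - thr) /
        (force[i - 1] - force[i]) * (time[i] - time[i - 1])
      if (t_ev - last_to >= debounce) {
        to <- c(to, t_ev); last_to <- t_ev; state <- "swing"
      }
    }
  }
  if (length(hs) > length(to)) hs <- hs[seq_along(to)]
  out$heel_strikes <- hs
  out$toe_offs <- to
  out
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> %s foot: %d heel strikes (threshold %.3g = 20%% of peak %.3g)\n",
              x$foot, length(x$heel_strikes), x$threshold, x$peak_force))
  invisible(x)
}

#' Segment detected events into gait cycles
#'
#' A cycle spans two successive same-foot heel strikes and must contain
#' exactly one toe off; cycles violating the validity bounds are kept
#' with `valid = FALSE` and a reason code. Heel-strike pairs with no toe
#' off between them emit no cycle and increment the `n_skipped`
#' attribute.
#'
#' @param events a `gait_events` object.
#' @param validity a [validity_config()].
#' @return data.frame with columns `foot`, `start_hs`, `toe_off`,
#'   `next_hs`, `stride_time`, `stance_time`, `swing_time`, `valid`,
#'   `reason`; attribute `n_skipped` counts heel-strike pairs lacking a
#'   toe off.
#' @export
segment_cycles <- function(events, validity = validity_config()) {
  hs <- events$heel_strikes; to <- events$toe_offs
  empty <- data.frame(foot = character(0), start_hs = numeric(0),
                      toe_off = numeric(0), next_hs = numeric(0),
                      stride_time = numeric(0), stance_time = numeric(0),
                      swing_time = numeric(0), valid = logical(0),
                      reason = character(0))
  attr(empty, "n_skipped") <- 0L
  if (length(hs) < 2L) return(empty)
  rows <- empty; skipped <- 0L
  for (i in seq_len(length(hs) - 1L)) {
    tos <- to[to > hs[i] & to < hs[i + 1L]]
    if (length(tos) != 1L) { skipped <- skipped + 1L; next }
    stride <- hs[i + 1L] - hs[i]
    stance <- tos - hs[i]
    frac <- stance / stride
    reason <- ""
    if (stride < validity$stride_range[1] ||
        stride > validity$stride_range[2]) {
      reason <- "stride_out_of_range"
    } else if (frac < validity$stance_frac_range[1] ||
               frac > validity$stance_frac_range[2]) {
      reason <- "stance_fraction_out_of_range"
    }
    rows <- rbind(rows, data.frame(
      foot = events$foot, start_hs = hs[i], toe_off = tos,
      next_hs = hs[i + 1L], stride_time = stride, stance_time = stance,
      swing_time = stride - stance, valid = reason == "",
      reason = reason))
  }
  attr(rows, "n_skipped") <- skipped
  rows
}

#' Detect and segment both feet of a preprocessed walk
#'
#' @param rec a preprocessed [vgrf_recording()].
#' @param threshold_frac fraction of peak force.
#' @param validity a [validity_config()].
#' @return data.frame of cycles from both feet (see [segment_cycles()]),
#'   with the recording's `subject_id`/`walk_id` attached.
#' @export
walk_cycles <- function(rec, threshold_frac = 0.2,
                        validity = validity_config()) {
  cyc <- rbind(
    segment_cycles(detect_events(rec$total_left, rec$sample_rate,
                                 threshold_frac, foot = "left",
                                 time = rec$time), validity),
    segment_cycles(detect_events(rec$total_right, rec$sample_rate,
                                 threshold_frac, foot = "right",
                                 time = rec$time), validity))
  if (nrow(cyc)) {
    cyc$subject_id <- rec$subject_id
    cyc$walk_id <- rec$walk_id
  } else {
    cyc$subject_id <- character(0)
    cyc$walk_id <- character(0)
  }
  cyc
}
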