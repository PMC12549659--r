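# Synthetic VGRF cohort generator. Each foot's total force is a train of
# double-bump stance templates (loading response + push-off, raised-cosine
# edges) supported on [heel strike, toe off], zero during swing, plus
# Gaussian sensor noise. Ground-truth event times and per-cycle timing are
# recorded exactly, so the event detector and feature extractor can be
# validated against known truth.

#' Configuration for the synthetic gait cohort simulator
#'
#' Timing parameters follow a severity-score model: a healthy control has
#' severity 0 and a PD subject at Hoehn--Yahr stage h has severity h, so
#' `stride_time = stride_time_base + severity_gradient * stride_time_effect * h`
#' (and analogously for stance fraction and walking speed), with
#' per-subject random effects drawn once per subject and smaller
#' per-cycle variation within a walk. Defaults emulate adult walking with
#' the canonical PD gait signature: longer stride and swing times, higher
#' stance percentage, reduced cadence and speed.
#'
#' @param n_per_class subjects per label class; a scalar, or a named
#'   vector over class labels to induce class imbalance.
#' @param walk_duration seconds per walk (default 60; must be >= 40 so
#'   the 20 s / 10 s trim leaves at least 10 s).
#' @param sample_rate samples per second.
#' @param body_force peak vertical force in Newtons.
#' @param stride_time_base,stance_fraction_base,speed_base healthy-control
#'   means (seconds, dimensionless, m/s).
#' @param stride_time_effect,stance_fraction_effect,speed_effect shift per
#'   severity unit.
#' @param severity_gradient multiplier on all three effects; 0 gives a
#'   null cohort, larger values give stronger class separation.
#' @param stride_time_subject_sd,stance_fraction_subject_sd,speed_subject_sd
#'   between-subject SDs of the timing parameters.
#' @param stride_time_cycle_sd,stance_fraction_cycle_sd within-walk
#'   per-cycle SDs (healthy baseline).
#' @param variability_effect relative increase of the per-cycle SDs per
#'   severity unit (PD gait is more variable).
#' @param stance_asym_sd between-subject SD of the left/right
#'   stance-fraction offset in controls.
#' @param asymmetry_effect relative increase of the asymmetry SD per
#'   severity unit (PD gait is more asymmetric).
#' @param stage_set Hoehn--Yahr stages assigned to PD subjects.
#' @param stage_weights sampling weights over `stage_set` for the binary
#'   task (the severity skew knob).
#' @param n_walks walks per subject.
#' @param noise_sd Gaussian noise SD in Newtons added to the force traces.
#' @param seed integer seed.
#' @return a list of class `gait_sim_config`.
#' @export
gait_sim_config <- function(n_per_class = 10, walk_duration = 60,
                            sample_rate = 100, body_force = 800,
                            stride_time_base = 1.05,
                            stance_fraction_base = 0.62,
                            speed_base = 1.25,
                            stride_time_effect = 0.035,
                            stance_fraction_effect = 0.010,
                            speed_effect = -0.07,
                            severity_gradient = 1,
                            stride_time_subject_sd = 0.03,
                            stance_fraction_subject_sd = 0.010,
                            speed_subject_sd = 0.06,
                            stride_time_cycle_sd = 0.02,
                            stance_fraction_cycle_sd = 0.006,
                            variability_effect = 0.25,
                            stance_asym_sd = 0.005,
                            asymmetry_effect = 0.25,
                            stage_set = 1:3,
                            stage_weights = c(1, 1, 1),
                            n_walks = 1, noise_sd = 8, seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "gait_sim_config"
  max_sev <- max(c(0, stage_set))
  fr <- stance_fraction_base +
    severity_gradient * stance_fraction_effect * c(0, max_sev)
  if (any(fr <= 0 | fr >= 1))
    stop_crisp("crisp_config_error",
               "stance fraction must stay inside (0, 1) for every class")
  if (stride_time_base + severity_gradient * stride_time_effect * max_sev <= 0 ||
      stride_time_base <= 0)
    stop_crisp("crisp_config_error", "stride_time must be positive")
  if (walk_duration < 40)
    stop_crisp("crisp_config_error",
               "walk_duration must be >= 40 s so trimming leaves >= 10 s")
  cfg
}

# Per-subject timing parameters from the severity-score model. Severity
# also scales within-walk variability and left/right asymmetry, the two
# secondary gait signatures of parkinsonism.
draw_subject_params <- function(cfg, severity) {
  g <- cfg$severity_gradient
  vscale <- 1 + cfg$variability_effect * g * severity
  list(
    stride = max(0.5, rnorm(1, cfg$stride_time_base +
                              g * cfg$stride_time_effect * severity,
                            cfg$stride_time_subject_sd)),
    frac = min(0.88, max(0.45, rnorm(1, cfg$stance_fraction_base +
                                       g * cfg$stance_fraction_effect * severity,
                                     cfg$stance_fraction_subject_sd))),
    speed = max(0.3, rnorm(1, cfg$speed_base + g * cfg$speed_effect * severity,
                           cfg$speed_subject_sd)),
    stride_cycle_sd = cfg$stride_time_cycle_sd * vscale,
    frac_cycle_sd = cfg$stance_fraction_cycle_sd * vscale,
    frac_asym = rnorm(1, 0, cfg$stance_asym_sd *
                        (1 + cfg$asymmetry_effect * g * severity))
  )
}

# Right-foot events phase-locked to the left foot: each right heel
# strike lands half a stride after the corresponding left one (plus
# timing jitter), as in coupled human gait.
derive_right_events <- function(ev_l, pars, cfg, dur) {
  k <- nrow(ev_l)
  stride_l <- c(diff(ev_l$hs), pars$stride)
  hs <- ev_l$hs + 0.5 * stride_l +
    rnorm(k, 0, pars$stride_cycle_sd / 2)
  hs <- hs[hs < dur - 0.05]
  m <- length(hs)
  nxt <- c(hs[-1], hs[m] + pars$stride)
  frac <- pmin(0.89, pmax(0.41, rnorm(m, pars$frac + pars$frac_asym,
                                      pars$frac_cycle_sd)))
  to <- pmin(hs + frac * (nxt - hs), dur - 0.01)
  data.frame(hs = hs, to = to)
}

# One foot's event train: heel strikes and toe offs over [t0, dur].
gen_foot_events <- function(t0, dur, pars, cfg) {
  hs <- numeric(0); to <- numeric(0)
  t <- t0
  repeat {
    stride <- max(0.45, rnorm(1, pars$stride, pars$stride_cycle_sd))
    if (t + stride > dur - 0.05) break
    frac <- min(0.89, max(0.41, rnorm(1, pars$frac,
                                      pars$frac_cycle_sd)))
    hs <- c(hs, t)
    to <- c(to, t + stride * frac)
    t <- t + stride
  }
  data.frame(hs = hs, to = to)
}

# Double-bump stance template evaluated at sample times `tt` for one
# stance [hs, to]: raised-cosine rise/fall edges with an 8 ms time
# constant (VGRF loading transients are fast, and the steep edge keeps
# the 20% threshold crossing within a few ms of the true event) around a
# two-humped mid-stance shape whose dip stays well above 20% of peak.
stance_template <- function(tt, hs, to, body_force, rise = 0.008) {
  u <- (tt - hs) / (to - hs)
  env <- 0.25 * (1 - cos(pi * pmin((tt - hs) / rise, 1))) *
    (1 - cos(pi * pmin((to - tt) / rise, 1)))
  shape <- 0.775 + 0.225 * cos(2 * pi * u)
  body_force * env * shape
}

foot_force <- function(time, ev, body_force) {
  f <- numeric(length(time))
  for (i in seq_len(nrow(ev))) {
    idx <- which(time >= ev$hs[i] & time <= ev$to[i])
    if (length(idx))
      f[idx] <- f[idx] + stance_template(time[idx], ev$hs[i], ev$to[i],
                                         body_force)
  }
  f
}

# Fixed nonnegative per-foot sensor split weights (sum to 1).
SENSOR_SPLIT <- c(0.18, 0.16, 0.14, 0.12, 0.11, 0.10, 0.10, 0.09)

#' Simulate one VGRF walk with ground truth
#'
#' @param config a [gait_sim_config()].
#' @param label `"HC"` or `"PD"`.
#' @param stage Hoehn--Yahr stage for PD subjects (ignored for HC).
#' @param subject_id,walk_id identifiers for the emitted recording.
#' @param subject_params optional pre-drawn per-subject timing parameters
#'   (used by [simulate_cohort()] so a subject's walks share parameters).
#' @param seed optional integer; when given, the RNG is seeded so
#'   repeated calls are bit-identical.
#' @return list with `recording` (a [vgrf_recording()]) and `truth`
#'   (per-foot event tables, a per-cycle timing table in the feature
#'   module's column names, the label/stage, and the subject's true
#'   walking speed).
#' @export
simulate_walk <- function(config, label = c("HC", "PD"), stage = NA,
                          subject_id = "SYNCo01", walk_id = "01",
                          subject_params = NULL, seed = NULL) {
  label <- match.arg(label)
  if (!is.null(seed)) set.seed(seed)
  severity <- if (label == "HC") 0 else as.numeric(stage)
  if (label == "PD" && (is.na(severity) || !severity %in% config$stage_set))
    stop_crisp("crisp_config_error", "PD walk needs a stage in stage_set")
  pars <- subject_params %||% draw_subject_params(config, severity)

  dur <- config$walk_duration
  n <- round(dur * config$sample_rate) + 1L
  time <- (seq_len(n) - 1L) / config$sample_rate
  t0_l <- runif(1, 0.3, 0.8)
  ev_l <- gen_foot_events(t0_l, dur, pars, config)
  ev_r <- derive_right_events(ev_l, pars, config, dur)
  fl <- foot_force(time, ev_l, config$body_force)
  fr <- foot_force(time, ev_r, config$body_force)
  if (config$noise_sd > 0) {
    tl <- pmax(0, fl + rnorm(n, 0, config$noise_sd))
    tr <- pmax(0, fr + rnorm(n, 0, config$noise_sd))
    sens <- cbind(outer(fl, SENSOR_SPLIT) +
                    matrix(rnorm(n * 8, 0, config$noise_sd / 4), n),
                  outer(fr, SENSOR_SPLIT) +
                    matrix(rnorm(n * 8, 0, config$noise_sd / 4), n))
    sens <- pmax(sens, 0)
  } else {
    tl <- fl; tr <- fr
    sens <- cbind(outer(fl, SENSOR_SPLIT), outer(fr, SENSOR_SPLIT))
  }
  colnames(sens) <- SENSOR_NAMES
  rec <- vgrf_recording(subject_id, walk_id, "SYN", time = time,
                        sensors = sens, total_left = tl, total_right = tr,
                        sample_rate = config$sample_rate)
  truth <- list(
    events = list(left = ev_l, right = ev_r),
    cycles = rbind(truth_cycles(ev_l, "left", pars$speed),
                   truth_cycles(ev_r, "right", pars$speed)),
    label = label, stage = if (label == "PD") severity else NA,
    speed = pars$speed, params = pars
  )
  list(recording = rec, truth = truth)
}

truth_cycles <- function(ev, foot, speed) {
  k <- nrow(ev)
  if (k < 2L)
    return(data.frame(foot = character(0), start_hs = numeric(0),
                      toe_off = numeric(0), next_hs = numeric(0),
                      stride_time = numeric(0), stance_time = numeric(0),
                      swing_time = numeric(0), stance_pct = numeric(0),
                      swing_pct = numeric(0), cadence = numeric(0),
                      stride_length = numeric(0)))
  stride <- diff(ev$hs)
  stance <- ev$to[-k] - ev$hs[-k]
  data.frame(
    foot = foot, start_hs = ev$hs[-k], toe_off = ev$to[-k],
    next_hs = ev$hs[-1L], stride_time = stride, stance_time = stance,
    swing_time = stride - stance, stance_pct = 100 * stance / stride,
    swing_pct = 100 * (1 - stance / stride), cadence = 120 / stride,
    stride_length = speed * stride
  )
}

#' Simulate a labelled VGRF cohort
#'
#' Draws per-subject timing parameters once and shares them across that
#' subject's walks, so between-subject variance exceeds within-subject
#' variance and subject-wise evaluation is meaningfully different from
#' cycle-level evaluation.
#'
#' @param config a [gait_sim_config()].
#' @param task `"binary"` (HC vs PD; PD subjects get stages sampled from
#'   `stage_set` with `stage_weights`) or `"severity"` (all PD, one class
#'   per stage in `stage_set`).
#' @return list with `records` (list of [vgrf_recording()]),
#'   `demographics` (data.frame: subject_id, group, hoehn_yahr, speed),
#'   `truth` (per-walk ground truth, named `<subject>_<walk>`), and the
#'   config.
#' @export
simulate_cohort <- function(config, task = c("binary", "severity")) {
  task <- match.arg(task)
  set.seed(config$seed)
  classes <- if (task == "binary") c("HC", "PD") else
    as.character(config$stage_set)
  npc <- config$n_per_class
  if (length(npc) == 1L) npc <- setNames(rep(npc, length(classes)), classes)
  if (!all(classes %in% names(npc)))
    stop_crisp("crisp_config_error", "n_per_class must name every class")
  if (any(npc[classes] < 2))
    stop_crisp("crisp_config_error",
               "need >= 2 subjects per class for cross-validation")

  records <- list(); truth <- list()
  demo <- NULL
  ct_pt <- 0L; ct_co <- 0L
  for (cl in classes) {
    for (s in seq_len(npc[[cl]])) {
      if (task == "binary" && cl == "HC") {
        group <- "HC"; stage <- NA
        ct_co <- ct_co + 1L
        sid <- sprintf("SYNCo%02d", ct_co)
      } else {
        group <- "PD"
        stage <- if (task == "binary")
          sample(config$stage_set, 1L, prob = config$stage_weights)
        else as.integer(cl)
        ct_pt <- ct_pt + 1L
        sid <- sprintf("SYNPt%02d", ct_pt)
      }
      sev <- if (group == "HC") 0 else stage
      pars <- draw_subject_params(config, sev)
      demo <- rbind(demo, data.frame(
        subject_id = sid, group = group,
        hoehn_yahr = if (group == "PD") stage else NA_integer_,
        speed = pars$speed))
      for (w in seq_len(config$n_walks)) {
        wid <- sprintf("%02d", w)
        sim <- simulate_walk(config, label = group, stage = stage,
                             subject_id = sid, walk_id = wid,
                             subject_params = pars)
        key <- paste0(sid, "_", wid)
        records[[key]] <- sim$recording
        truth[[key]] <- sim$truth
      }
    }
  }
  list(records = records, demographics = demo, truth = truth,
       config = config, task = task)
}
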