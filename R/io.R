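# Reading/writing VGRF walk records in the PhysioNet gait-database text
# dialect: whitespace-delimited rows sampled at 100 Hz, columns
# time, 16 sensor forces (L1..L8 then R1..R8), total left, total right.

SENSOR_NAMES <- c(paste0("L", 1:8), paste0("R", 1:8))

#' Construct a VGRF walk recording
#'
#' The canonical in-memory container for one walk: a time vector at a
#' constant sample rate, optional 16 per-sensor force channels, and the
#' per-foot total vertical ground-reaction forces (Newtons).
#'
#' @param subject_id,walk_id opaque identifier strings.
#' @param cohort one of `"Ga"`, `"Ju"`, `"Si"` (PhysioNet sub-cohorts) or
#'   `"SYN"` (simulated).
#' @param time numeric vector of sample times in seconds, strictly
#'   increasing with constant step `1/sample_rate`.
#' @param sensors numeric matrix with 16 columns (`L1..L8`, `R1..R8`) or
#'   `NULL` for the minimal 3-column dialect.
#' @param total_left,total_right per-foot total force vectors, same length
#'   as `time`.
#' @param sample_rate samples per second (100 for PhysioNet records).
#' @param time_offset seconds trimmed off the front of the original walk
#'   (0 for untrimmed recordings); lets event times be mapped back to the
#'   raw timebase.
#' @return an object of class `vgrf_recording`.
#' @export
vgrf_recording <- function(subject_id, walk_id, cohort, time, sensors,
                           total_left, total_right, sample_rate = 100,
                           time_offset = 0) {
  rec <- structure(list(
    subject_id = as.character(subject_id),
    walk_id = as.character(walk_id),
    cohort = match.arg(cohort, c("Ga", "Ju", "Si", "SYN")),
    sample_rate = sample_rate,
    time = as.numeric(time),
    sensors = sensors,
    total_left = as.numeric(total_left),
    total_right = as.numeric(total_right),
    time_offset = time_offset
  ), class = "vgrf_recording")
  validate_vgrf_recording(rec)
}

validate_vgrf_recording <- function(rec) {
  n <- length(rec$time)
  if (n == 0L) stop_crisp("crisp_format_error", "recording has no samples")
  if (length(rec$total_left) != n || length(rec$total_right) != n)
    stop_crisp("crisp_format_error",
               "force channels and time vector differ in length")
  if (!is.null(rec$sensors)) {
    if (!is.matrix(rec$sensors) || ncol(rec$sensors) != 16L ||
        nrow(rec$sensors) != n)
      stop_crisp("crisp_format_error",
                 "sensors must be an n x 16 matrix matching time")
  }
  if (n > 1L) {
    dt <- diff(rec$time)
    if (any(dt <= 0))
      stop_crisp("crisp_format_error", "time is not strictly increasing")
    if (max(abs(dt - 1 / rec$sample_rate)) > 1e-6)
      stop_crisp("crisp_format_error",
                 "time step deviates from 1/sample_rate by more than 1e-6 s")
  }
  vals <- c(rec$total_left, rec$total_right, rec$sensors)
  if (any(!is.finite(vals)))
    stop_crisp("crisp_format_error", "non-finite force values")
  rec
}

#' @export
print.vgrf_recording <- function(x, ...) {
  cat(sprintf(
    "<vgrf_recording> %s walk %s (%s): %d samples @ %g Hz, %.1f s%s\n",
    x$subject_id, x$walk_id, x$cohort, length(x$time), x$sample_rate,
    length(x$time) / x$sample_rate,
    if (is.null(x$sensors)) " [totals only]" else ""
  ))
  invisible(x)
}

#' Number of samples in a recording
#' @param rec a `vgrf_recording`.
#' @return integer sample count.
#' @export
n_samples <- function(rec) length(rec$time)

#' Parse a walk file name into cohort, subject, and walk identifiers
#'
#' Accepts the gait-database convention `<Co><Grp><NN>_<WW>.txt`
#' (e.g. `GaPt03_01.txt`, cohorts Ga/Ju/Si, groups Pt/Co) and the
#' simulator convention `SYN<Grp><NN>_<WW>.txt`.
#'
#' @param name file name (directories are stripped).
#' @return list with `cohort`, `subject_id`, `walk_id`, `group_tag`
#'   (`"Pt"` or `"Co"`).
#' @export
parse_walk_filename <- function(name) {
  base <- basename(name)
  m <- regmatches(base,
    regexec("^(Ga|Ju|Si|SYN)(Pt|Co)(\\d+)_(\\d+)\\.txt$", base))[[1]]
  if (length(m) == 0L)
    stop_crisp("crisp_naming_error", paste0(
      "unrecognized walk file name '%s'; accepted patterns: ",
      "<Ga|Ju|Si>(Pt|Co)<NN>_<WW>.txt or SYN(Pt|Co)<NN>_<WW>.txt"), base)
  list(cohort = m[2], subject_id = paste0(m[2], m[3], m[4]),
       walk_id = m[5], group_tag = m[3])
}

#' Read a VGRF walk record
#'
#' Reads a whitespace-delimited walk file. The `physionet19` dialect has
#' 19 numeric columns (time, 16 sensors, total left, total right); the
#' minimal `simple3` dialect has time and the two totals only. The sample
#' rate is inferred from the median time step and, for `physionet19`,
#' must round to 100 Hz. Negative force readings are clipped to zero
#' (force sensors cannot pull); the clipped count is attached as
#' attribute `n_negative_clipped`.
#'
#' @param path path to the record file; subject/walk identity is parsed
#'   from the file name (see [parse_walk_filename()]).
#' @param dialect `"physionet19"` or `"simple3"`.
#' @return a [vgrf_recording()].
#' @export
read_vgrf_record <- function(path, dialect = c("physionet19", "simple3")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop_crisp("crisp_io_error", "file not found: %s", path)
  if (length(readLines(path, n = 1L)) == 0L)
    stop_crisp("crisp_format_error", "empty record file: %s", path)
  dat <- tryCatch(
    read.table(path, header = FALSE, colClasses = "numeric"),
    error = function(e) stop_crisp("crisp_parse_error",
      "cannot parse '%s': %s", path, conditionMessage(e)))
  if (nrow(dat) == 0L)
    stop_crisp("crisp_format_error", "empty record file: %s", path)
  want <- if (dialect == "physionet19") 19L else 3L
  if (ncol(dat) != want)
    stop_crisp("crisp_parse_error",
               "'%s': expected %d columns, found %d (line 1)",
               path, want, ncol(dat))
  id <- parse_walk_filename(path)
  time <- dat[[1L]]
  if (any(diff(time) <= 0))
    stop_crisp("crisp_format_error", "'%s': time is not monotone", path)
  dt <- median(diff(time))
  rate <- 1 / dt
  if (dialect == "physionet19" && round(rate) != 100)
    stop_crisp("crisp_format_error",
               "'%s': inferred sample rate %.2f Hz does not round to 100",
               path, rate)
  force <- as.matrix(dat[, -1L, drop = FALSE])
  n_neg <- sum(force < 0)
  if (n_neg > 0) force[force < 0] <- 0
  if (dialect == "physionet19") {
    sensors <- force[, 1:16, drop = FALSE]
    colnames(sensors) <- SENSOR_NAMES
    tl <- force[, 17L]; tr <- force[, 18L]
  } else {
    sensors <- NULL
    tl <- force[, 1L]; tr <- force[, 2L]
  }
  rec <- vgrf_recording(id$subject_id, id$walk_id, id$cohort,
                        time = time, sensors = sensors,
                        total_left = tl, total_right = tr,
                        sample_rate = round(rate))
  attr(rec, "n_negative_clipped") <- n_neg
  rec
}

#' Write a VGRF recording back to the text dialect it was read from
#'
#' Emits the 19-column layout when sensor channels are present, otherwise
#' the 3-column layout, at fixed printed precision so a read/write
#' round-trip reproduces the numeric content.
#'
#' @param rec a [vgrf_recording()].
#' @param path output file path.
#' @param digits printed decimal digits (default 5).
#' @return `path`, invisibly.
#' @export
write_vgrf_record <- function(rec, path, digits = 5) {
  cols <- if (is.null(rec$sensors)) {
    cbind(rec$time, rec$total_left, rec$total_right)
  } else {
    cbind(rec$time, rec$sensors, rec$total_left, rec$total_right)
  }
  txt <- apply(cols, 1L, function(r)
    paste(formatC(r, digits = digits, format = "f"), collapse = "\t"))
  writeLines(txt, path)
  invisible(path)
}

#' Read a subject demographics table
#'
#' Expects a delimited table (comma or tab, header required) with at
#' least subject id, group (`PD`/`HC`), and Hoehn--Yahr severity columns;
#' extra columns are kept. Controls get an absent (`NA`) severity grade;
#' a PD row with missing severity is kept with an `NA` grade and a
#' warning. Duplicate subject ids are an integrity error.
#'
#' @param path path to the CSV/TSV file.
#' @return data.frame with columns `subject_id`, `group`, `hoehn_yahr`
#'   plus any extras (e.g. a per-subject `speed` used as the reference
#'   walking speed for stride-length features).
#' @export
read_demographics <- function(path) {
  if (!file.exists(path))
    stop_crisp("crisp_io_error", "file not found: %s", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  dat <- read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, strip.white = TRUE)
  names(dat) <- tolower(names(dat))
  need <- c("subject_id", "group", "hoehn_yahr")
  if (!all(need %in% names(dat)))
    stop_crisp("crisp_format_error",
               "demographics must have columns: %s", paste(need, collapse = ", "))
  dat$subject_id <- as.character(dat$subject_id)
  if (anyDuplicated(dat$subject_id))
    stop_crisp("crisp_integrity_error", "duplicate subject_id: %s",
               paste(unique(dat$subject_id[duplicated(dat$subject_id)]),
                     collapse = ", "))
  if (!all(dat$group %in% c("PD", "HC")))
    stop_crisp("crisp_format_error", "group must be PD or HC")
  hy <- suppressWarnings(as.integer(dat$hoehn_yahr))
  hy[dat$group == "HC"] <- NA_integer_
  if (any(dat$group == "PD" & is.na(hy)))
    warn_crisp("crisp_missing_severity",
               "PD subject(s) with missing Hoehn-Yahr grade: %s",
               paste(dat$subject_id[dat$group == "PD" & is.na(hy)],
                     collapse = ", "))
  dat$hoehn_yahr <- hy
  dat
}
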