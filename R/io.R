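#' Read and write measurement tables
#'
#' Measurement CSV schema: header `s0,t,p,replicate,label`, decimal point,
#' UTF-8; comment lines starting with `#` carry unit metadata
#' (`# conc_unit: ...`, `# time_unit: ...`). Write-then-read round-trips
#' are value-identical.
#'
#' @param path File path.
#' @param m An `mm_measurements` table (see [measurements()]).
#' @param conc_unit,time_unit Unit labels written as comment metadata.
#' @return `read_measurements()` returns a validated `mm_measurements`
#'   table with `conc_unit`/`time_unit` attributes; `write_measurements()`
#'   returns `path` invisibly.
#' @export
read_measurements <- function(path) {
  units <- read_unit_comments(path)
  d <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop("malformed measurement CSV '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  need <- c("s0", "t", "p")
  if (!all(need %in% names(d)))
    stop("malformed measurement CSV '", path, "': missing column(s) ",
         paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
  for (col in need)
    if (!is.numeric(d[[col]]))
      stop("malformed measurement CSV '", path, "': column '", col,
           "' is not numeric", call. = FALSE)
  if (is.null(d$replicate)) d$replicate <- NA_integer_
  if (is.null(d$label)) d$label <- NA_character_
  m <- validate_measurements(d[c("s0", "t", "p", "replicate", "label")])
  attr(m, "conc_unit") <- units$conc_unit
  attr(m, "time_unit") <- units$time_unit
  m
}

#' @rdname read_measurements
#' @export
write_measurements <- function(m, path, conc_unit = "arb",
                               time_unit = "arb") {
  stopifnot(is.data.frame(m))
  m <- validate_measurements(as.data.frame(m))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# conc_unit: %s", conc_unit),
               sprintf("# time_unit: %s", time_unit)), con)
  utils::write.csv(m, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_unit_comments <- function(path) {
  hdr <- readLines(path, n = 10L, warn = FALSE)
  hdr <- hdr[startsWith(hdr, "#")]
  grab <- function(key) {
    hit <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (length(hit)) trimws(sub(paste0("^#\\s*", key, ":"), "", hit[1]))
    else "arb"
  }
  list(conc_unit = grab("conc_unit"), time_unit = grab("time_unit"))
}

#' Read and write monitored reaction time courses
#'
#' Time-course CSV schema: columns `t,signal`; `#`-comment metadata lines
#' carry `s0_nominal` (nominal initial substrate concentration) and
#' `signal_factor` (multiplicative signal-to-concentration conversion).
#'
#' @param path File path.
#' @param tc A `time_course` object.
#' @return `read_time_course()` returns a `time_course`: a data.frame
#'   `(t, signal)` with attributes `s0_nominal` and `signal_factor`.
#' @export
read_time_course <- function(path) {
  hdr <- readLines(path, n = 10L, warn = FALSE)
  hdr <- hdr[startsWith(hdr, "#")]
  grab <- function(key, default) {
    hit <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (length(hit))
      as.numeric(trimws(sub(paste0("^#\\s*", key, ":"), "", hit[1])))
    else default
  }
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("t", "signal") %in% names(d)))
    stop("malformed time-course CSV '", path, "': need columns t, signal",
         call. = FALSE)
  time_course(d$t, d$signal, s0_nominal = grab("s0_nominal", NA_real_),
              signal_factor = grab("signal_factor", 1))
}

#' @rdname read_time_course
#' @export
write_time_course <- function(tc, path) {
  stopifnot(inherits(tc, "time_course"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# s0_nominal: %.10g", attr(tc, "s0_nominal")),
               sprintf("# signal_factor: %.10g", attr(tc, "signal_factor"))),
             con)
  utils::write.csv(as.data.frame(tc)[c("t", "signal")], con,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a time-course object
#'
#' @param t Strictly increasing reading times (instrument clock; the first
#'   reading defines t = 0 of the usable record).
#' @param signal Monitored signal (product, up to `signal_factor`).
#' @param s0_nominal Nominal initial substrate concentration at mixing.
#' @param signal_factor Multiplies `signal` to give concentration.
#' @return A data.frame of class `time_course`.
#' @export
time_course <- function(t, signal, s0_nominal = NA_real_,
                        signal_factor = 1) {
  stopifnot(length(t) == length(signal), length(t) >= 2)
  if (is.unsorted(t, strictly = TRUE))
    stop("time-course times must be strictly increasing", call. = FALSE)
  structure(data.frame(t = t, signal = signal),
            class = c("time_course", "data.frame"),
            s0_nominal = s0_nominal, signal_factor = signal_factor)
}

#' Generate synthetic chromogenic progress curves
#'
#' Emulates a continuously monitored beta-lactamase / nitrocefin style
#' assay: exact Lambert-W progress curves for each nominal substrate
#' concentration, followed to near-completion at a fixed sampling rate,
#' recorded only after a mixing dead time, with additive Gaussian signal
#' noise. The record's clock starts at the first reading, so product
#' already formed during the dead time is hidden in the first reading —
#' exactly the situation [preprocess_time_course()] corrects.
#'
#' Defaults emulate `V = 0.55` concentration/s (33/min), `Km = 29`, five
#' substrate concentrations between 11 and 64, 2 readings/s and a 7.5 s
#' dead time. All synthetic; units nominally micromolar and seconds.
#'
#' @param params True [kinetic_parameters()] (time unit: seconds).
#' @param s0 Nominal initial substrate concentrations.
#' @param dead_time Mixing dead time (s) before the first reading.
#' @param noise_sd SD of additive Gaussian signal noise (concentration).
#' @param readings_per_s Sampling rate (default 2).
#' @param completion Follow each curve until this conversion (default 0.999).
#' @param seed Optional seed; a given seed reproduces curves exactly.
#' @return List of [time_course()] objects, one per `s0`.
#' @export
generate_fixture <- function(params = kinetic_parameters(V = 0.55, Km = 29),
                             s0 = c(11, 22, 32, 48, 64),
                             dead_time = 7.5,
                             noise_sd = 0.2,
                             readings_per_s = 2,
                             completion = 0.999,
                             seed = NULL) {
  stopifnot(inherits(params, "kinetic_parameters"),
            dead_time >= 0, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  lapply(s0, function(s) {
    t_end <- time_to_product(params, s, completion * s)
    tt <- seq(0, max(t_end - dead_time, 2), by = 1 / readings_per_s)
    p_true <- product_at_time(params, s, tt + dead_time)
    sig <- p_true + stats::rnorm(length(tt), 0, noise_sd)
    time_course(tt, sig, s0_nominal = s, signal_factor = 1)
  })
}

#' Dead-time preprocessing of a time course to a single measurement
#'
#' Product formed during the mixing dead time never appears in the record:
#' the first reading already contains it, and the nominal `s0` overstates
#' the substrate remaining at the first reading. For a reaction followed
#' to completion, the effective initial substrate concentration at the
#' record's t = 0 is the final reading minus the first reading, and
#' product is measured relative to the first reading. The re-zeroed curve
#' obeys the same integrated rate equation with the same V and Km, so the
#' correction is exact for noiseless data.
#'
#' One point of the (possibly very dense) record is then selected — at a
#' target conversion fraction of the effective `s0`, or at a target time —
#' and returned as a single measurement.
#'
#' @param tc A [time_course()], followed to a final plateau.
#' @param target_fraction Conversion fraction (of effective s0) at which
#'   to take the measurement. Exactly one of `target_fraction`,
#'   `target_time` must be given.
#' @param target_time Record time at which to take the measurement.
#' @param plateau_tol Allowed signal drift across the end of the record,
#'   as a fraction of the effective s0: the medians of the final 5\% of
#'   readings and of the preceding 5\% may differ by at most this much
#'   (medians make the check robust to reading noise). A larger drift
#'   raises an incomplete-reaction error.
#' @return A one-row `mm_measurements` table (effective `s0`, `t` since
#'   first reading, `p` above first reading), with the full effective
#'   values in attributes `s0_effective` and `selected_index`.
#' @export
preprocess_time_course <- function(tc, target_fraction = NULL,
                                   target_time = NULL,
                                   plateau_tol = 0.02) {
  stopifnot(inherits(tc, "time_course"))
  if (is.null(target_fraction) == is.null(target_time))
    stop("give exactly one of target_fraction, target_time", call. = FALSE)
  sig <- tc$signal * attr(tc, "signal_factor")
  tt <- tc$t - tc$t[1]
  s0_eff <- sig[length(sig)] - sig[1]
  if (!is.finite(s0_eff) || s0_eff <= 0)
    stop("incomplete reaction: no signal increase between first and final ",
         "readings", call. = FALSE)
  n <- length(sig)
  i2 <- seq(max(1L, ceiling(0.95 * n)), n)
  i1 <- seq(max(1L, ceiling(0.90 * n)), min(i2) - 1L)
  drift <- abs(stats::median(sig[i2]) - stats::median(sig[i1]))
  if (drift > plateau_tol * s0_eff)
    stop(sprintf(paste0("incomplete reaction: signal still drifting by ",
                        "%.3g near the end of the record (> %.3g allowed); ",
                        "no plateau detected"),
                 drift, plateau_tol * s0_eff), call. = FALSE)
  p_series <- sig - sig[1]
  idx_ok <- which(tt > 0 & p_series > 0 & p_series < s0_eff)
  if (!length(idx_ok))
    stop("no usable reading strictly between 0 and full conversion",
         call. = FALSE)
  idx <- if (!is.null(target_fraction)) {
    if (target_fraction <= 0 || target_fraction >= 1)
      stop("target_fraction must be in (0, 1)", call. = FALSE)
    idx_ok[which.min(abs(p_series[idx_ok] / s0_eff - target_fraction))]
  } else {
    idx_ok[which.min(abs(tt[idx_ok] - target_time))]
  }
  m <- measurements(s0 = s0_eff, t = tt[idx], p = p_series[idx])
  attr(m, "s0_effective") <- s0_eff
  attr(m, "selected_index") <- idx
  m
}
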