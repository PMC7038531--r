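#' Detect heel-strike proxies (anteroposterior maxima)
#'
#' The heel strike of each step produces a pronounced maximum in the
#' anteroposterior acceleration (MAPA). Candidate peaks are local maxima of
#' the filtered anteroposterior channel after the warm-up interval, separated
#' by at least `min_peak_separation` seconds and higher than
#' `median + peak_iqr_mult * IQR` of the post-warm-up signal. Ties and
#' sub-threshold ripples are rejected; of two peaks closer than the
#' separation gate, only the higher survives.
#'
#' @param trace A filtered `acceleration_trace`.
#' @param cfg An [inertial_config()].
#' @return Numeric vector of event times (s), strictly increasing.
#' @export
detect_mapa <- function(trace, cfg = inertial_config()) {
  stopifnot(inherits(trace, "acceleration_trace"))
  if (!trace$filtered) lw_stop("trace must be filtered first", "domain_error")
  keep <- trace$t >= trace$t[1] + cfg$warmup
  if (sum(keep) < 3) lw_stop("trace shorter than the warm-up interval", "no_steps_error")
  x <- trace$a_ap[keep]
  tt <- trace$t[keep]
  height <- stats::median(x) + cfg$peak_iqr_mult * stats::IQR(x)
  pk <- pracma::findpeaks(x, minpeakheight = height,
                          minpeakdistance = max(1L, round(cfg$min_peak_separation * trace$f)))
  if (is.null(pk) || nrow(pk) < 2)
    lw_stop("fewer than two heel-strike peaks detected", "no_steps_error")
  sort(tt[pk[, 2]])
}

#' Detect vertical-minimum events between heel strikes
#'
#' For each pair of consecutive heel-strike times, returns the time of the
#' minimum vertical acceleration (NPVA) strictly inside the open interval.
#' When the minimum is attained at several samples, the earliest is returned.
#'
#' @param trace A filtered `acceleration_trace`.
#' @param mapa_times Heel-strike event times from [detect_mapa()].
#' @return Numeric vector of length `length(mapa_times) - 1`.
#' @export
detect_npva <- function(trace, mapa_times) {
  stopifnot(inherits(trace, "acceleration_trace"))
  if (length(mapa_times) < 2) return(numeric(0))
  vapply(seq_len(length(mapa_times) - 1), function(i) {
    idx <- which(trace$t > mapa_times[i] & trace$t < mapa_times[i + 1])
    if (length(idx) == 0) return(NA_real_)
    trace$t[idx[which.min(trace$a_vert[idx])]]  # which.min takes the earliest tie
  }, numeric(1))
}

#' Segment a trace into steps
#'
#' Composes the two event detectors and applies cadence gating: steps whose
#' cadence (reciprocal of the heel-strike interval) falls outside `sc_range`
#' are excluded and reported, not silently dropped. Step `i` runs from
#' heel strike `tmax_s` to the next heel strike `tmax_next_s`, with the
#' vertical-minimum event `tmin_s` in between.
#'
#' @param trace A filtered `acceleration_trace`.
#' @param cfg An [inertial_config()].
#' @return A `step_events` data frame with columns `step`, `tmax_s`,
#'   `tmin_s`, `tmax_next_s` and attribute `excluded` (a data frame of
#'   gated-out steps with reasons).
#' @export
segment_steps <- function(trace, cfg = inertial_config()) {
  tmax <- detect_mapa(trace, cfg)
  tmin <- detect_npva(trace, tmax)
  n <- length(tmax) - 1
  steps <- data.frame(step = seq_len(n),
                      tmax_s = tmax[seq_len(n)],
                      tmin_s = tmin,
                      tmax_next_s = tmax[seq_len(n) + 1])
  sc <- 1 / (steps$tmax_next_s - steps$tmax_s)
  bad_sc <- sc < cfg$sc_range[1] | sc > cfg$sc_range[2]
  bad_min <- !is.finite(steps$tmin_s)
  excluded <- steps[bad_sc | bad_min, , drop = FALSE]
  excluded$reason <- ifelse(bad_min[bad_sc | bad_min], "no-vertical-minimum",
                            "cadence-range")
  steps <- steps[!(bad_sc | bad_min), , drop = FALSE]
  if (nrow(steps) == 0) lw_stop("no steps survive cadence gating", "no_steps_error")
  steps$step <- seq_len(nrow(steps))
  attr(steps, "excluded") <- excluded
  class(steps) <- c("step_events", "data.frame")
  steps
}

#' Write detected step events to CSV
#'
#' @param steps A `step_events` data frame from [segment_steps()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(steps, path) {
  utils::write.csv(steps[, c("step", "tmax_s", "tmin_s", "tmax_next_s")],
                   path, row.names = FALSE)
  invisible(path)
}
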