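#' Inertial acquisition and analysis configuration
#'
#' Bundles the constants that govern the whole pipeline: the sensor sample
#' frequency, the per-channel low-pass cut-offs, the limit of the human eye
#' (LHE) below which a flight phase is invisible to a judge, the number of
#' steps in a judged sequence, and the warm-up interval discarded at the start
#' of a trial while the athlete accelerates.
#'
#' @param f Sample frequency of the inertial sensor (Hz).
#' @param cutoff_vertical Low-pass cut-off for the vertical channel (Hz).
#' @param cutoff_ap Low-pass cut-off for the anteroposterior channel (Hz).
#' @param filter_order Butterworth filter order (even, applied forward and
#'   backward so the magnitude response is effectively squared).
#' @param lhe Limit of the human eye (s); flight durations at or below it are
#'   deemed legal.
#' @param ns Number of steps per judged step sequence.
#' @param warmup Leading interval excluded from analysis (s).
#' @param sc_range Valid step-cadence range (steps/s); steps outside it are
#'   excluded from analysis.
#' @param min_peak_separation Minimum separation between heel-strike peaks (s).
#' @param peak_iqr_mult Peak-height gate: a heel-strike candidate must exceed
#'   `median(a_ap) + peak_iqr_mult * IQR(a_ap)`.
#'
#' @return An object of class `inertial_config`.
#' @examples
#' cfg <- inertial_config()
#' cfg$lhe # 0.04 s
#' @export
inertial_config <- function(f = 200, cutoff_vertical = 20, cutoff_ap = 30,
                            filter_order = 4, lhe = 0.040, ns = 30L,
                            warmup = 10, sc_range = c(2.8, 4.0),
                            min_peak_separation = 0.25,
                            peak_iqr_mult = 5) {
  stopifnot(f > 0, lhe > 0, warmup >= 0, ns >= 1)
  if (cutoff_vertical >= f / 2 || cutoff_ap >= f / 2)
    lw_stop("filter cut-offs must be below the Nyquist frequency f/2", "config_error")
  if (filter_order <= 0 || filter_order %% 2 != 0)
    lw_stop("filter_order must be a positive even integer", "config_error")
  if (length(sc_range) != 2 || sc_range[1] <= 0 || sc_range[2] <= sc_range[1])
    lw_stop("sc_range must be an increasing positive pair", "config_error")
  structure(list(f = f, cutoff_vertical = cutoff_vertical, cutoff_ap = cutoff_ap,
                 filter_order = as.integer(filter_order), lhe = lhe,
                 ns = as.integer(ns), warmup = warmup, sc_range = sc_range,
                 min_peak_separation = min_peak_separation,
                 peak_iqr_mult = peak_iqr_mult),
            class = "inertial_config")
}

#' Cadence-dependent threshold model
#'
#' The threshold `E` subtracted from the interval between the vertical-minimum
#' event and the next heel strike is modelled as a no-intercept quadratic in
#' step cadence, `E(SC) = SC^2/a + SC/b`, with coefficients estimated on elite
#' athletes. With the default coefficients `E` decreases with cadence and
#' crosses zero at `SC = -a/b` (about 3.64 steps/s).
#'
#' @param a Quadratic coefficient (default -40.921).
#' @param b Linear coefficient (default 11.242).
#' @param sc_range Cadence range over which the model is valid (steps/s).
#' @return An object of class `threshold_model`.
#' @examples
#' m <- threshold_model()
#' variable_threshold(3.10, m) # about 0.0409 s
#' @export
threshold_model <- function(a = -40.921, b = 11.242, sc_range = c(2.8, 4.0)) {
  if (a == 0 || b == 0) lw_stop("coefficients must be non-zero", "config_error")
  structure(list(a = a, b = b, sc_range = sc_range), class = "threshold_model")
}

#' Trial metadata
#'
#' Mean speed and athlete stature needed for the step-length ratio and the
#' smoothness normalization. Speed is an external input (course markers, GPS);
#' it is not derived from the sensor.
#'
#' @param v_mean Mean speed over the trial (m/s).
#' @param stature Athlete stature (m).
#' @param label Optional nominal speed label (e.g. "14.0 km/h").
#' @return An object of class `trial_meta`.
#' @export
trial_meta <- function(v_mean, stature, label = NULL) {
  if (!is.numeric(v_mean) || v_mean <= 0)
    lw_stop("v_mean must be positive", "domain_error")
  if (!is.numeric(stature) || stature < 1.2 || stature > 2.2)
    lw_stop("stature must lie in [1.2, 2.2] m", "domain_error")
  structure(list(v_mean = v_mean, stature = stature, label = label),
            class = "trial_meta")
}

#' @export
print.inertial_config <- function(x, ...) {
  cat("Inertial configuration\n")
  cat(sprintf("  f = %g Hz, cutoffs = %g/%g Hz (vertical/AP), order %d\n",
              x$f, x$cutoff_vertical, x$cutoff_ap, x$filter_order))
  cat(sprintf("  LHE = %g ms, NS = %d steps, warmup = %g s, SC range [%g, %g] steps/s\n",
              1000 * x$lhe, x$ns, x$warmup, x$sc_range[1], x$sc_range[2]))
  invisible(x)
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf("Cadence threshold model: E(SC) = SC^2/%g + SC/%g, valid on [%g, %g] steps/s\n",
              x$a, x$b, x$sc_range[1], x$sc_range[2]))
  invisible(x)
}

#' Write a threshold model to JSON
#'
#' @param model A [threshold_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_threshold_model <- function(model, path) {
  jsonlite::write_json(list(a = model$a, b = model$b, sc_range = model$sc_range),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a threshold model from JSON
#'
#' @param path JSON file written by [write_threshold_model()].
#' @return A [threshold_model()].
#' @export
read_threshold_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  threshold_model(a = x$a, b = x$b, sc_range = x$sc_range)
}
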