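#' Specification of a synthetic race-walking trial
#'
#' The generator emulates the trunk-acceleration morphology the detectors
#' rely on: each heel strike produces a raised-cosine pulse in the
#' anteroposterior channel, and each step's vertical channel dips (gravity
#' minus a raised-cosine pulse) at the point preceding toe-off by the
#' cadence-dependent threshold, so that the estimated timing of a perfectly
#' detected step equals the true flight time. Cadence and flight time may be
#' constant or per-step vectors; Gaussian sensor noise is seeded and the
#' output is bit-reproducible for a fixed spec and seed.
#'
#' @param duration Trial duration (s); must exceed the warm-up plus 2 steps.
#' @param cadence Step cadence (steps/s), scalar or per-step.
#' @param flight_time True flight time (s), scalar or per-step; 0 means
#'   double support.
#' @param speed Mean trial speed (m/s).
#' @param stature Athlete stature (m).
#' @param ap_amp,ap_width Anteroposterior pulse amplitude (m/s^2) and
#'   half-width (s).
#' @param vert_amp,vert_width Vertical pulse amplitude (m/s^2) and
#'   half-width (s).
#' @param noise_sd Additive Gaussian noise SD (m/s^2).
#' @param seed RNG seed.
#' @param f Sample frequency (Hz).
#' @param fr Video frame rate (frames/s).
#' @param model [threshold_model()] used to place the vertical minimum.
#' @param warmup Warm-up the analysis will discard (s); steps are generated
#'   throughout.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(duration = 60, cadence = 3.2, flight_time = 0.045,
                     speed = 3.5, stature = 1.745,
                     ap_amp = 8, ap_width = 0.025,
                     vert_amp = 12, vert_width = 0.030,
                     noise_sd = 0, seed = 1L, f = 200, fr = 240,
                     model = threshold_model(), warmup = 10) {
  if (any(flight_time < 0)) lw_stop("flight_time must be non-negative", "spec_error")
  if (any(cadence <= 0)) lw_stop("cadence must be positive", "spec_error")
  if (any(flight_time >= 1 / cadence))
    lw_stop("flight_time must be shorter than the step time 1/cadence", "spec_error")
  if (ap_amp <= 0 || vert_amp <= 0 || ap_width <= 0 || vert_width <= 0)
    lw_stop("pulse amplitudes and widths must be positive", "spec_error")
  if (duration <= warmup + 2 / min(cadence))
    lw_stop("duration must exceed warmup + 2 steps", "spec_error")
  structure(list(duration = duration, cadence = cadence,
                 flight_time = flight_time, speed = speed, stature = stature,
                 ap_amp = ap_amp, ap_width = ap_width,
                 vert_amp = vert_amp, vert_width = vert_width,
                 noise_sd = noise_sd, seed = as.integer(seed), f = f, fr = fr,
                 model = model, warmup = warmup),
            class = "sim_spec")
}

## raised-cosine pulse of unit amplitude centred at c with half-width w
rc_pulse <- function(t, centre, w) {
  u <- (t - centre) / w
  out <- numeric(length(t))
  inside <- abs(u) <= 1
  out[inside] <- 0.5 * (1 + cos(pi * u[inside]))
  out
}

#' Generate a synthetic trial with known ground truth
#'
#' Heel-strike times follow from the cadence profile; the toe-off of step `i`
#' is the next heel strike minus the true flight time. The anteroposterior
#' channel holds pulses at the heel strikes; the vertical channel dips at
#' `toe-off - E(SC)` so the timing model is exactly invertible and recovery
#' tests isolate detector and quantization error.
#'
#' @param spec A [sim_spec()].
#' @return A list with `trace` (raw `acceleration_trace`), `truth` (data
#'   frame `step`, `heel_s`, `heel_next_s`, `toe_s`, `npva_s`, `sc`, `ft_s`),
#'   `meta` ([trial_meta()]) and `spec`.
#' @examples
#' tr <- generate_trial(sim_spec(duration = 15, warmup = 2))
#' tr$trace
#' @export
generate_trial <- function(spec = sim_spec()) {
  stopifnot(inherits(spec, "sim_spec"))
  # heel strikes spanning the duration, first one shortly after start
  h <- 0.5 / spec$cadence[1]
  sc_of <- function(i) spec$cadence[min(i, length(spec$cadence))]
  ft_of <- function(i) spec$flight_time[min(i, length(spec$flight_time))]
  i <- 1
  while (utils::tail(h, 1) + 1 / sc_of(i) <= spec$duration - 0.1) {
    h <- c(h, utils::tail(h, 1) + 1 / sc_of(i))
    i <- i + 1
  }
  n <- length(h) - 1
  if (n < 2) lw_stop("duration too short for two steps", "spec_error")
  sc <- vapply(seq_len(n), sc_of, numeric(1))
  ft <- vapply(seq_len(n), ft_of, numeric(1))
  toe <- h[-1] - ft
  e <- suppressWarnings(variable_threshold(sc, spec$model))
  npva <- toe - e
  # the vertical dip must stay inside its step, clear of both heel pulses
  if (any(npva - h[-length(h)] < spec$ap_width + spec$vert_width) ||
      any(h[-1] - npva < spec$vert_width))
    lw_stop("pulses overlap: flight time too close to the step time", "spec_error")
  t <- seq(0, spec$duration, by = 1 / spec$f)
  a_ap <- numeric(length(t))
  for (hk in h) a_ap <- a_ap + spec$ap_amp * rc_pulse(t, hk, spec$ap_width)
  a_vert <- rep(9.81, length(t))
  for (ck in npva) a_vert <- a_vert - spec$vert_amp * rc_pulse(t, ck, spec$vert_width)
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    a_ap <- a_ap + stats::rnorm(length(t), sd = spec$noise_sd)
    a_vert <- a_vert + stats::rnorm(length(t), sd = spec$noise_sd)
  }
  truth <- data.frame(step = seq_len(n), heel_s = h[-length(h)],
                      heel_next_s = h[-1], toe_s = toe, npva_s = npva,
                      sc = sc, ft_s = ft)
  list(trace = acceleration_trace(t, a_vert, a_ap, f = spec$f),
       truth = truth,
       meta = trial_meta(spec$speed, spec$stature),
       spec = spec)
}

#' Frame-quantized video annotations for simulated steps
#'
#' Emulates an annotator stepping through high-speed footage at `fr` frames
#' per second: `fna` is the last frame at or before toe-off
#' (`floor(toe * fr)`), and `fnd` the first frame strictly after the next
#' heel strike (`floor(heel_next * fr) + 1`; the next frame when the contact
#' falls exactly on one). The resulting camera bracket always contains the
#' true flight time. Steps without flight get the `no_flight` flag.
#'
#' @param truth Ground-truth data frame from [generate_trial()].
#' @param fr Frame rate (frames/s).
#' @return A `video_annotations` data frame.
#' @export
generate_video_annotations <- function(truth, fr = 240) {
  if (fr <= 0) lw_stop("fr must be positive", "domain_error")
  fna <- floor(truth$toe_s * fr + 1e-9)
  fnd <- floor(truth$heel_next_s * fr + 1e-9) + 1
  ann <- data.frame(step = truth$step, fr = fr,
                    fna = fna, fnb = fna + 1,
                    fnc = fnd - 1, fnd = fnd,
                    no_flight = truth$ft_s <= 0)
  video_annotations(ann)
}

#' Write a trace to CSV (t, ax, az)
#'
#' @param trace An `acceleration_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(data.frame(t = trace$t, ax = trace$a_vert, az = trace$a_ap),
                   path, row.names = FALSE)
  invisible(path)
}
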