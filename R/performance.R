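#' Step cadence
#'
#' Reciprocal of the interval between two consecutive heel strikes.
#'
#' @param tmax_s,tmax_next_s Heel-strike times of the current and next step (s).
#' @return Cadence (steps/s); vectorized.
#' @examples
#' step_cadence(0, 0.3125) # 3.2 steps/s
#' @export
step_cadence <- function(tmax_s, tmax_next_s) {
  if (any(tmax_next_s <= tmax_s))
    lw_stop("heel-strike interval must be positive", "domain_error")
  1 / (tmax_next_s - tmax_s)
}

#' Step-length ratio
#'
#' Step length (speed divided by cadence) as a percentage of the athlete's
#' stature: `100 * v / (SC * h)`.
#'
#' @param v_mean Mean step speed (m/s).
#' @param sc Step cadence (steps/s).
#' @param h Athlete stature (m).
#' @return Step-length ratio in percent.
#' @examples
#' step_length_ratio(3.5, 3.2, 1.745) # ~62.7 %
#' @export
step_length_ratio <- function(v_mean, sc, h) {
  if (any(c(v_mean, sc, h) <= 0)) lw_stop("all inputs must be positive", "domain_error")
  100 * v_mean / (sc * h)
}

#' Jerk-based smoothness of one step
#'
#' Dimensionless jerk cost of the anteroposterior acceleration over one step
#' window: `S = T^5 * (SC / v)^2 * integral(j^2)`, where `T` is the window
#' duration and `j` the time derivative of the anteroposterior acceleration
#' (central differences inside the window, one-sided at its edges; trapezoid
#' integration). The `(SC/v)^2` factor divides by step length squared, making
#' `S` invariant under joint rescaling of time and length units. Lower is
#' smoother; elite race walking lands roughly in 1 (ideal) to 10 (worst).
#'
#' @param trace A filtered `acceleration_trace`.
#' @param window Numeric pair: step window `(tmax_s, tmax_next_s)`.
#' @param sc Step cadence (steps/s).
#' @param v_mean Mean step speed (m/s).
#' @return Smoothness value `S >= 0`.
#' @export
smoothness <- function(trace, window, sc, v_mean) {
  stopifnot(inherits(trace, "acceleration_trace"), length(window) == 2)
  idx <- which(trace$t >= window[1] & trace$t <= window[2])
  if (length(idx) < 8) lw_stop("step window too short for jerk estimation", "domain_error")
  t <- trace$t[idx]
  a <- trace$a_ap[idx]
  n <- length(a)
  j <- numeric(n)
  j[1] <- (a[2] - a[1]) / (t[2] - t[1])
  j[n] <- (a[n] - a[n - 1]) / (t[n] - t[n - 1])
  j[2:(n - 1)] <- (a[3:n] - a[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  integral <- pracma::trapz(t, j^2)
  T <- window[2] - window[1]
  T^5 * (sc / v_mean)^2 * integral
}

#' Sequence means of per-step performance values
#'
#' Plain arithmetic mean over exactly `ns` per-step values (cadence,
#' step-length ratio or smoothness).
#'
#' @param values Numeric vector of per-step values, length `ns`.
#' @param ns Steps per judged sequence.
#' @return The sequence mean.
#' @export
sequence_performance <- function(values, ns = 30L) {
  if (length(values) != ns)
    lw_stop(sprintf("expected %d per-step values, got %d", ns, length(values)),
            "domain_error")
  mean(values)
}
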