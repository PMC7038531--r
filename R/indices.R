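#' Calibration constants for the normalized indices
#'
#' The cadence and step-length-ratio indices are anchored on elite-competition
#' regressions: the value attained at the qualifying-standard speed maps to
#' index 0.4 ("sufficient") and the value at the world-record speed maps to 0
#' ("optimal"). Defaults are the printed anchors for the 50 km qualifying
#' standard (12.20 km/h) and the 20 km world record. Smoothness is anchored
#' at 1 (ideal) and 10 (worst).
#'
#' @param sc_at_04,sc_at_0 Sequence-cadence anchors (steps/s) mapped to
#'   gamma = 0.4 and gamma = 0.
#' @param slr_at_04,slr_at_0 Step-length-ratio anchors (percent) mapped to
#'   rho = 0.4 and rho = 0.
#' @param s_min,s_max Smoothness anchors mapped to mu = 0 and mu = 1.
#' @return An object of class `calibration_constants`.
#' @export
calibration_constants <- function(sc_at_04 = 3.130, sc_at_0 = 3.380,
                                  slr_at_04 = 62.8, slr_at_0 = 71.4,
                                  s_min = 1, s_max = 10) {
  if (sc_at_04 >= sc_at_0 || slr_at_04 >= slr_at_0)
    lw_stop("anchor at 0.4 must be below anchor at 0", "config_error")
  if (s_max <= s_min) lw_stop("s_max must exceed s_min", "config_error")
  structure(list(sc_at_04 = sc_at_04, sc_at_0 = sc_at_0,
                 slr_at_04 = slr_at_04, slr_at_0 = slr_at_0,
                 s_min = s_min, s_max = s_max),
            class = "calibration_constants")
}

#' Derive index anchors from reference speeds
#'
#' Evaluates the elite-competition correlations `SC = 0.259 v + 2.253`
#' (cadence, with `v` in m/s) and `SLR = 2.47 v + 32.73` (step-length ratio,
#' with `v` in km/h) at the qualifying-standard speed (anchor mapped to index
#' 0.4) and the world-record speed (anchor mapped to 0). The unit convention
#' per correlation is the one that reproduces the published anchors.
#'
#' @param v_e_ms,v_e_kmh Qualifying-standard speed in m/s and km/h
#'   (defaults 3.39 m/s = 12.20 km/h).
#' @param v_r_ms,v_r_kmh World-record speed in m/s and km/h
#'   (defaults 4.38 m/s = 15.76 km/h).
#' @return A [calibration_constants()] object.
#' @examples
#' calibrate_boundaries()$sc_at_04 # 3.131, the published 3.130
#' @export
calibrate_boundaries <- function(v_e_ms = 3.39, v_e_kmh = 12.20,
                                 v_r_ms = 4.38, v_r_kmh = 15.76) {
  if (any(c(v_e_ms, v_e_kmh, v_r_ms, v_r_kmh) <= 0))
    lw_stop("speeds must be positive", "domain_error")
  calibration_constants(sc_at_04 = 0.259 * v_e_ms + 2.253,
                        sc_at_0 = 0.259 * v_r_ms + 2.253,
                        slr_at_04 = 2.47 * v_e_kmh + 32.73,
                        slr_at_0 = 2.47 * v_r_kmh + 32.73)
}

#' Normalized timing index (delta)
#'
#' Single linear ramp through the anchors `(lhe - 2/f, 0)`, `(lhe, 0.4)` and
#' `(lhe + 3/f, 1)` (collinear, slope `f/5`), clamped to \[0, 1\].
#'
#' @param logct_seq_s Sequence mean timing (s).
#' @param lhe Limit of the human eye (s).
#' @param f Sample frequency (Hz).
#' @return delta in \[0, 1\]; vectorized.
#' @examples
#' delta_index(c(0.030, 0.040, 0.055)) # 0, 0.4, 1
#' @export
delta_index <- function(logct_seq_s, lhe = 0.040, f = 200) {
  pmin(pmax((logct_seq_s - (lhe - 2 / f)) * f / 5, 0), 1)
}

#' Compute the five normalized biomechanical indices for one sequence
#'
#' All indices run from 0 (best) to 1 (worst): `delta` from the sequence
#' timing ramp, `alpha` equal to the infringement fraction, `gamma` and `rho`
#' as linear ramps between their calibration anchors (0 at the optimal
#' anchor, 0.4 at the sufficient anchor, clamped at 1), and `mu` as the
#' linear rescaling of smoothness between `s_min` and `s_max`.
#'
#' @param logct_seq_s Sequence mean timing (s).
#' @param logcc_seq Infringement fraction in \[0, 1\].
#' @param sc_seq Sequence mean cadence (steps/s).
#' @param slr_seq Sequence mean step-length ratio (percent).
#' @param s_seq Sequence mean smoothness.
#' @param calib A [calibration_constants()].
#' @param cfg An [inertial_config()] supplying `lhe` and `f`.
#' @return A one-row `index_profile` data frame with columns `delta`,
#'   `alpha`, `gamma`, `rho`, `mu`.
#' @export
compute_indices <- function(logct_seq_s, logcc_seq, sc_seq, slr_seq, s_seq,
                            calib = calibration_constants(),
                            cfg = inertial_config()) {
  if (any(logcc_seq < 0 | logcc_seq > 1))
    lw_stop("infringement fraction must lie in [0, 1]", "domain_error")
  delta <- delta_index(logct_seq_s, cfg$lhe, cfg$f)
  gamma <- pmin(pmax(0.4 - 0.4 * (sc_seq - calib$sc_at_04) /
                       (calib$sc_at_0 - calib$sc_at_04), 0), 1)
  rho <- pmin(pmax(0.4 - 0.4 * (slr_seq - calib$slr_at_04) /
                     (calib$slr_at_0 - calib$slr_at_04), 0), 1)
  mu <- pmin(pmax((s_seq - calib$s_min) / (calib$s_max - calib$s_min), 0), 1)
  out <- data.frame(delta = delta, alpha = logcc_seq, gamma = gamma,
                    rho = rho, mu = mu)
  class(out) <- c("index_profile", "data.frame")
  out
}

#' Radar-chart axis order
#'
#' Infringement indices (alpha, delta) on the right of the chart, performance
#' indices (mu, rho, gamma) on the left. Polygon area depends on the axis
#' order, so it is fixed and recorded with every score.
#' @export
radar_axis_order <- c("alpha", "delta", "mu", "rho", "gamma")

#' Radar synthesis score (epsilon)
#'
#' Each index is drawn on its own axis with radius `1 - index` (a wider
#' polygon is a better gesture). Axes are spaced 72 degrees apart starting at
#' 90 degrees; the polygon area `A` is computed by the shoelace formula and
#' normalized by the area of the regular pentagon with unit radius,
#' `A_max = (5/2) sin(72deg)`, giving `epsilon = A / A_max` in \[0, 1\].
#'
#' @param profile A one-row `index_profile` (or anything with the five index
#'   columns).
#' @param axis_order Character vector naming the five axes in drawing order.
#' @return A list with `epsilon`, `area`, `area_max`, `vertices` (5 x 2
#'   matrix) and `axis_order`.
#' @examples
#' p <- data.frame(delta = 0, alpha = 0, gamma = 0, rho = 0, mu = 0)
#' radar_epsilon(p)$epsilon # 1: the unit pentagon
#' @export
radar_epsilon <- function(profile, axis_order = radar_axis_order) {
  vals <- unlist(profile[1, axis_order], use.names = FALSE)
  if (any(!is.finite(vals)) || any(vals < 0 | vals > 1))
    lw_stop("indices must lie in [0, 1]", "domain_error")
  r <- 1 - vals
  ang <- pi / 2 + (seq_along(r) - 1) * 2 * pi / 5
  v <- cbind(x = r * cos(ang), y = r * sin(ang))
  area <- 0.5 * abs(sum(v[, 1] * v[c(2:5, 1), 2] - v[c(2:5, 1), 1] * v[, 2]))
  area_max <- 2.5 * sin(2 * pi / 5)
  list(epsilon = area / area_max, area = area, area_max = area_max,
       vertices = v, axis_order = axis_order)
}

#' Best admissible radar score
#'
#' Among a set of sequence profiles, the maximum epsilon subject to an
#' admissible technique: timing index `delta <= 0.4` and infringement
#' fraction `alpha <= 0.4`. When no profile is admissible the result is an
#' explicit empty answer, not an error.
#'
#' @param profiles An `index_profile` data frame (one row per sequence) with
#'   an `epsilon` column, or without one (epsilon is then computed).
#' @param axis_order Axis order used when epsilon must be computed.
#' @return A list with `epsilon_opt` (NA when none admissible), `index` (row
#'   of the argmax or NA) and `admissible` (logical vector).
#' @export
best_admissible <- function(profiles, axis_order = radar_axis_order) {
  if (nrow(profiles) == 0) lw_stop("empty profile list", "domain_error")
  if (is.null(profiles$epsilon))
    profiles$epsilon <- vapply(seq_len(nrow(profiles)), function(i)
      radar_epsilon(profiles[i, , drop = FALSE], axis_order)$epsilon, numeric(1))
  ok <- profiles$delta <= 0.4 & profiles$alpha <= 0.4
  if (!any(ok))
    return(list(epsilon_opt = NA_real_, index = NA_integer_, admissible = ok))
  i <- which(ok)[which.max(profiles$epsilon[ok])]
  list(epsilon_opt = profiles$epsilon[i], index = i, admissible = ok)
}

#' Write an index profile to JSON
#'
#' @param profile One-row `index_profile` with `epsilon`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_indices_json <- function(profile, path) {
  jsonlite::write_json(list(delta = profile$delta[1], alpha = profile$alpha[1],
                            gamma = profile$gamma[1], rho = profile$rho[1],
                            mu = profile$mu[1],
                            epsilon = if (is.null(profile$epsilon)) {
                              radar_epsilon(profile)$epsilon
                            } else profile$epsilon[1],
                            axis_order = radar_axis_order),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Plot a radar chart of one index profile
#'
#' Base-graphics radar chart: the unit pentagon as reference, the profile
#' polygon shaded, axes labelled by index name.
#'
#' @param profile One-row `index_profile`.
#' @param axis_order Axis order.
#' @param main Plot title.
#' @return The [radar_epsilon()] result, invisibly.
#' @export
plot_radar <- function(profile, axis_order = radar_axis_order, main = "") {
  re <- radar_epsilon(profile, axis_order)
  ang <- pi / 2 + (0:4) * 2 * pi / 5
  graphics::plot.new()
  graphics::plot.window(c(-1.3, 1.3), c(-1.3, 1.3), asp = 1)
  graphics::polygon(cos(ang), sin(ang), border = "grey60")
  graphics::segments(0, 0, cos(ang), sin(ang), col = "grey80")
  graphics::polygon(re$vertices[, 1], re$vertices[, 2],
                    col = grDevices::adjustcolor("steelblue", 0.4),
                    border = "steelblue")
  graphics::text(1.18 * cos(ang), 1.18 * sin(ang), axis_order)
  graphics::text(0, -1.3, sprintf("epsilon = %.3f", re$epsilon))
  if (nzchar(main)) graphics::text(0, 1.3, main, font = 2)
  invisible(re)
}

#' Export a radar chart as an SVG file
#'
#' Writes a self-contained SVG (reference pentagon, axes, shaded profile
#' polygon) without requiring a graphics device.
#'
#' @param profile One-row `index_profile`.
#' @param path Output SVG path.
#' @param axis_order Axis order.
#' @param size Image side length in pixels.
#' @return `path`, invisibly.
#' @export
write_radar_svg <- function(profile, path, axis_order = radar_axis_order,
                            size = 400) {
  re <- radar_epsilon(profile, axis_order)
  half <- size / 2
  scale <- 0.38 * size
  px <- function(xy) sprintf("%.2f,%.2f", half + scale * xy[, 1],
                             half - scale * xy[, 2])
  ang <- pi / 2 + (0:4) * 2 * pi / 5
  ref <- cbind(cos(ang), sin(ang))
  lab <- 1.12 * ref
  lines <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
            size, size),
    sprintf('<polygon points="%s" fill="none" stroke="#999"/>',
            paste(px(ref), collapse = " ")),
    sprintf('<line x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f" stroke="#ccc"/>',
            half, half, half + scale * ref[, 1], half - scale * ref[, 2]),
    sprintf('<polygon points="%s" fill="#4682b4" fill-opacity="0.4" stroke="#4682b4"/>',
            paste(px(re$vertices), collapse = " ")),
    sprintf('<text x="%.2f" y="%.2f" text-anchor="middle" font-size="%d">%s</text>',
            half + scale * lab[, 1], half - scale * lab[, 2],
            max(10, size %/% 33), axis_order),
    sprintf('<text x="%.2f" y="%.2f" text-anchor="middle" font-size="%d">epsilon = %.3f</text>',
            half, size - 8, max(10, size %/% 33), re$epsilon),
    '</svg>')
  writeLines(lines, path)
  invisible(path)
}
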