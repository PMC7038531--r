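#' Cadence-dependent threshold
#'
#' Evaluates `E(SC) = SC^2/a + SC/b`. The threshold is the fraction of the
#' interval between the vertical-minimum event and the next heel strike that
#' is still ground contact; it shrinks as cadence rises and is clamped below
#' at zero (a threshold is a non-negative duration). Cadences outside the
#' model's valid range are clamped to the nearest endpoint with a warning.
#'
#' @param sc Step cadence (steps/s); vectorized.
#' @param model A [threshold_model()].
#' @return Threshold values `E` (s), same length as `sc`.
#' @examples
#' variable_threshold(3.10) # ~0.0409 s
#' variable_threshold(3.64) # ~0: the model's zero crossing
#' @export
variable_threshold <- function(sc, model = threshold_model()) {
  if (any(!is.finite(sc)) || any(sc <= 0))
    lw_stop("cadence must be positive and finite", "domain_error")
  out_of_range <- sc < model$sc_range[1] | sc > model$sc_range[2]
  if (any(out_of_range)) {
    lw_warn(sprintf("%d cadence value(s) outside [%g, %g] steps/s clamped to range",
                    sum(out_of_range), model$sc_range[1], model$sc_range[2]),
            "cadence_clamp")
    sc <- pmin(pmax(sc, model$sc_range[1]), model$sc_range[2])
  }
  e <- sc^2 / model$a + sc / model$b
  neg <- e < 0
  if (any(neg)) e[neg] <- 0
  e
}

#' Per-step loss-of-ground-contact timing
#'
#' For each step, `LOGCT = tmax_next - tmin - E(SC)`: the interval between
#' the vertical-minimum event and the next heel strike, minus the
#' cadence-dependent threshold. A value at or below zero means no flight
#' phase was detected (double support). The one-sample uncertainty on each of
#' the two detected events gives bounds `LOGCT -+ 2/f` (interval width `4/f`).
#'
#' @param events A `step_events` data frame from [segment_steps()].
#' @param model A [threshold_model()].
#' @param cfg An [inertial_config()].
#' @return A `logc_steps` data frame with columns `step`, `sc`, `e_s`,
#'   `logct_s`, `logct_min_s`, `logct_max_s`, `double_support`.
#' @export
logc_timing <- function(events, model = threshold_model(), cfg = inertial_config()) {
  sc <- 1 / (events$tmax_next_s - events$tmax_s)
  e <- variable_threshold(sc, model)
  logct <- events$tmax_next_s - events$tmin_s - e
  out <- data.frame(step = events$step,
                    tmax_s = events$tmax_s, tmin_s = events$tmin_s,
                    tmax_next_s = events$tmax_next_s,
                    sc = sc, e_s = e,
                    logct_s = logct,
                    logct_min_s = logct - 2 / cfg$f,
                    logct_max_s = logct + 2 / cfg$f,
                    double_support = logct <= 0)
  class(out) <- c("logc_steps", "data.frame")
  out
}

#' Aggregate per-step timings into judged step sequences
#'
#' Judges assess a sequence of steps, not a single step. Steps are grouped
#' into consecutive non-overlapping windows of exactly `ns` steps; the
#' trailing remainder is dropped and reported in the `dropped` attribute.
#' Sequence values are plain arithmetic means over the window; double-support
#' steps contribute their actual (non-positive) timing.
#'
#' @param steps A `logc_steps` data frame from [logc_timing()].
#' @param cfg An [inertial_config()] supplying `ns`.
#' @return A data frame with one row per sequence: `sequence`, `n_steps`,
#'   `logct_seq_s`, `logct_seq_min_s`, `logct_seq_max_s`.
#' @export
aggregate_sequences <- function(steps, cfg = inertial_config()) {
  ns <- cfg$ns
  n <- nrow(steps)
  if (n < ns)
    lw_stop(sprintf("need at least %d steps for one sequence, got %d", ns, n),
            "insufficient_steps_error")
  nseq <- n %/% ns
  idx <- rep(seq_len(nseq), each = ns)
  used <- steps[seq_len(nseq * ns), , drop = FALSE]
  out <- data.frame(sequence = seq_len(nseq), n_steps = ns,
                    logct_seq_s = tapply(used$logct_s, idx, mean),
                    logct_seq_min_s = tapply(used$logct_min_s, idx, mean),
                    logct_seq_max_s = tapply(used$logct_max_s, idx, mean),
                    row.names = NULL)
  attr(out, "dropped") <- n - nseq * ns
  out
}

## least-absolute-residual fit on the linear basis (SC^2, SC) via IRLS
lar_fit <- function(sc, ot, maxit = 100, tol = 1e-10) {
  X <- cbind(sc^2, sc)
  w <- rep(1, length(ot))
  beta <- rep(0, 2)
  for (i in seq_len(maxit)) {
    fit <- stats::lm.wfit(X, ot, w)
    if (max(abs(fit$coefficients - beta)) < tol) break
    beta <- fit$coefficients
    r <- drop(ot - X %*% beta)
    w <- 1 / pmax(abs(r), 1e-8)
  }
  drop(fit$coefficients)
}

#' Fit the cadence threshold model from optimal-threshold data
#'
#' The optimal threshold (OT) for a step is the `E` value that makes the
#' inertial timing agree with the camera benchmark. The model
#' `OT = SC^2/a + SC/b` is linear in `(1/a, 1/b)` on the basis `(SC^2, SC)`
#' and is fitted by no-intercept least squares. Points are first excluded
#' when (i) cadence lies outside the valid range or (ii) OT is negative
#' (toe-off is necessarily after the vertical-acceleration minimum); then
#' points outside the 99% prediction bounds are removed and the model refitted
#' until stable. A least-absolute-residual (robust) fit on the surviving
#' points is reported alongside.
#'
#' @param ot Optimal threshold values (s).
#' @param sc Corresponding step cadences (steps/s).
#' @param sc_range Valid cadence range.
#' @param max_iter Maximum number of 99%-bounds exclusion rounds.
#' @return A `threshold_fit` list: `a`, `b` (least squares), `a_robust`,
#'   `b_robust`, `r_squared`, `r_squared_robust` (percent), `residuals`,
#'   `excluded` (data frame with reason codes), `n_used`, `model`.
#' @export
fit_threshold_model <- function(ot, sc, sc_range = c(2.8, 4.0), max_iter = 20) {
  if (length(ot) != length(sc)) lw_stop("ot and sc lengths differ", "domain_error")
  reason <- rep(NA_character_, length(ot))
  reason[sc < sc_range[1] | sc > sc_range[2]] <- "cadence-range"
  reason[is.na(reason) & ot < 0] <- "negative-OT"
  keep <- is.na(reason)
  if (sum(keep) < 10)
    lw_stop("fewer than 10 points remain after range/sign exclusions", "fit_error")
  if (length(unique(sc[keep])) < 2)
    lw_stop("degenerate design: all cadences equal", "fit_error")
  dat <- data.frame(ot = ot, sc = sc)
  active <- which(keep)
  for (it in seq_len(max_iter)) {
    fit <- stats::lm(ot ~ 0 + I(sc^2) + sc, data = dat[active, ])
    pb <- stats::predict(fit, newdata = dat[active, ], interval = "prediction",
                         level = 0.99)
    # small absolute slack so an (near-)exact fit never evicts its own points
    out99 <- dat$ot[active] < pb[, "lwr"] - 1e-9 |
      dat$ot[active] > pb[, "upr"] + 1e-9
    if (!any(out99)) break
    reason[active[out99]] <- "99pct-bounds"
    active <- active[!out99]
    if (length(active) < 10) lw_stop("99%-bounds exclusion left too few points", "fit_error")
  }
  cf <- stats::coef(fit)
  cf_rob <- lar_fit(dat$sc[active], dat$ot[active])
  if (any(!is.finite(c(cf, cf_rob))) || any(c(cf, cf_rob) == 0))
    lw_stop("threshold fit is degenerate", "fit_error")
  sst <- sum(dat$ot[active]^2)  # no-intercept model: uncentered total SS
  r2 <- 100 * (1 - sum(stats::residuals(fit)^2) / sst)
  res_rob <- dat$ot[active] - cbind(dat$sc[active]^2, dat$sc[active]) %*% cf_rob
  r2_rob <- 100 * (1 - sum(res_rob^2) / sst)
  excluded <- data.frame(index = which(!is.na(reason)),
                         ot = ot[!is.na(reason)], sc = sc[!is.na(reason)],
                         reason = reason[!is.na(reason)])
  structure(list(a = 1 / cf[[1]], b = 1 / cf[[2]],
                 a_robust = 1 / cf_rob[[1]], b_robust = 1 / cf_rob[[2]],
                 r_squared = r2, r_squared_robust = r2_rob,
                 residuals = stats::residuals(fit),
                 excluded = excluded, n_used = length(active),
                 model = threshold_model(a = 1 / cf[[1]], b = 1 / cf[[2]],
                                         sc_range = sc_range)),
            class = "threshold_fit")
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat(sprintf("Threshold fit on %d steps (%d excluded): a = %.3f, b = %.3f, R^2 = %.1f%%\n",
              x$n_used, nrow(x$excluded), x$a, x$b, x$r_squared))
  cat(sprintf("  robust (least absolute residuals): a = %.3f, b = %.3f, R^2 = %.1f%%\n",
              x$a_robust, x$b_robust, x$r_squared_robust))
  invisible(x)
}

#' Write per-step timing results to CSV
#'
#' @param steps A `logc_steps` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_steps_csv <- function(steps, path) {
  keep <- c(step = "step", SC = "sc", E_s = "e_s", LOGCT_s = "logct_s",
            LOGCT_min_s = "logct_min_s", LOGCT_max_s = "logct_max_s",
            double_support = "double_support")
  out <- steps[, keep]
  names(out) <- names(keep)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
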