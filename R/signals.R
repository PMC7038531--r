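#' Construct an acceleration trace
#'
#' A uniformly sampled two-channel acceleration record: the vertical and
#' anteroposterior acceleration of the centre of mass as proxied by a sensor
#' at the base of the spine.
#'
#' @param t Time stamps (s), strictly increasing and uniform at 1/f.
#' @param a_vert Vertical acceleration (m/s^2).
#' @param a_ap Anteroposterior acceleration (m/s^2).
#' @param f Sample frequency (Hz).
#' @param filtered Whether the channels have been low-pass filtered.
#' @return An object of class `acceleration_trace`.
#' @export
acceleration_trace <- function(t, a_vert, a_ap, f, filtered = FALSE) {
  n <- length(t)
  if (length(a_vert) != n || length(a_ap) != n)
    lw_stop("t, a_vert and a_ap must have equal length", "domain_error")
  if (!all(is.finite(t)) || !all(is.finite(a_vert)) || !all(is.finite(a_ap)))
    lw_stop("trace contains non-finite values", "parse_error")
  if (n >= 2) {
    dt <- diff(t)
    tol <- max(1e-6, 0.01 / f)  # loggers jitter slightly
    if (any(dt <= 0) || any(abs(dt - 1 / f) > tol))
      lw_stop(sprintf("non-uniform sampling: expected dt = %g s, worst deviation %.3g s",
                      1 / f, max(abs(dt - 1 / f))), "sampling_error")
  }
  structure(list(t = as.numeric(t), a_vert = as.numeric(a_vert),
                 a_ap = as.numeric(a_ap), f = f, filtered = isTRUE(filtered)),
            class = "acceleration_trace")
}

#' @export
print.acceleration_trace <- function(x, ...) {
  cat(sprintf("Acceleration trace: %d samples at %g Hz (%.2f s), %s\n",
              length(x$t), x$f, diff(range(x$t)),
              if (x$filtered) "filtered" else "raw"))
  invisible(x)
}

#' Load an acceleration trace from CSV
#'
#' Reads a comma-separated file with a header naming a vertical column `ax`
#' and an anteroposterior column `az`; an optional time column `t` (seconds).
#' If `t` is absent, time stamps `k/f` for `k = 0, 1, ...` are synthesized.
#' Extra columns are ignored.
#'
#' @param path CSV file path.
#' @param f Sample frequency (Hz).
#' @return An `acceleration_trace`.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write.csv(data.frame(t = (0:9) / 200, ax = 9.81, az = 0), tf, row.names = FALSE)
#' load_trace(tf, f = 200)
#' @export
load_trace <- function(path, f) {
  if (!file.exists(path)) lw_stop(paste("file not found:", path), "input_error")
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("ax", "az")
  if (!all(need %in% names(df)))
    lw_stop("CSV must name columns 'ax' (vertical) and 'az' (anteroposterior)",
            "parse_error")
  for (col in intersect(c("t", need), names(df))) {
    v <- df[[col]]
    if (!is.numeric(v) || anyNA(v)) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(v))))[1]
      lw_stop(sprintf("non-numeric or missing value in column '%s', row %d", col, bad),
              "parse_error")
    }
  }
  t <- if ("t" %in% names(df)) df$t else (seq_len(nrow(df)) - 1) / f
  acceleration_trace(t, df$ax, df$az, f = f, filtered = FALSE)
}

## pad length that lets the zero-state startup transient decay below ~1e-13:
## governed by the largest pole magnitude of the filter
transient_pad <- function(bf, order) {
  r <- max(Mod(polyroot(rev(bf$a))))
  max(3 * order, ceiling(log(1e-13) / log(min(r, 0.999))))
}

## odd (point-symmetric) reflection padding, then one forward and one backward
## pass of the same filter, so the net phase is zero
two_pass <- function(bf, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1)
  left  <- 2 * x[1] - x[seq(pad + 1, 2)]
  right <- 2 * x[n] - x[seq(n - 1, n - pad)]
  xx <- c(left, x, right)
  y <- signal::filter(bf, xx)
  y <- rev(signal::filter(bf, rev(y)))
  as.numeric(y[seq(pad + 1, pad + n)])
}

#' Zero-phase Butterworth low-pass filtering
#'
#' Applies an order-`filter_order` Butterworth low-pass filter once forward
#' and once backward per channel, cancelling the phase shift (the magnitude
#' response is squared). The vertical channel uses `cutoff_vertical`, the
#' anteroposterior channel `cutoff_ap`. Edge transients are suppressed with
#' odd-reflection padding long enough for the filter's zero-state transient
#' (set by its largest pole magnitude) to decay below 1e-13.
#'
#' @param trace A raw `acceleration_trace`.
#' @param cfg An [inertial_config()].
#' @return A new `acceleration_trace` with `filtered = TRUE`.
#' @export
lowpass_zero_phase <- function(trace, cfg = inertial_config()) {
  stopifnot(inherits(trace, "acceleration_trace"))
  if (trace$filtered) lw_stop("trace is already filtered", "domain_error")
  n <- length(trace$t)
  if (n <= 3 * cfg$filter_order)
    lw_stop("trace too short for stable zero-phase filtering", "length_error")
  bv <- signal::butter(cfg$filter_order, 2 * cfg$cutoff_vertical / trace$f, type = "low")
  ba <- signal::butter(cfg$filter_order, 2 * cfg$cutoff_ap / trace$f, type = "low")
  acceleration_trace(trace$t,
                     two_pass(bv, trace$a_vert, transient_pad(bv, cfg$filter_order)),
                     two_pass(ba, trace$a_ap, transient_pad(ba, cfg$filter_order)),
                     f = trace$f, filtered = TRUE)
}
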