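step_label_levels <- c("legal", "doubt", "illegal")

#' Binary legal/illegal classification
#'
#' A step (or step sequence) is legal when its loss-of-ground-contact timing
#' does not exceed the limit of the human eye; equality is legal (the
#' athlete-favourable convention). Double-support values (non-positive) are
#' trivially legal.
#'
#' @param logct Timing value(s) (s); may be non-positive.
#' @param lhe Limit of the human eye (s).
#' @return Factor with levels legal/doubt/illegal (doubt never emitted).
#' @examples
#' classify_binary(c(0.039, 0.040, 0.041))
#' @export
classify_binary <- function(logct, lhe = 0.040) {
  if (any(!is.finite(logct))) lw_stop("timing must be finite", "domain_error")
  factor(ifelse(logct <= lhe, "legal", "illegal"), levels = step_label_levels)
}

#' Three-level classification from timing bounds
#'
#' Uses the uncertainty interval of the timing: legal when the whole interval
#' lies at or below the eye limit, illegal when it lies strictly above, doubt
#' when the interval straddles the limit. Endpoints exactly at the limit
#' resolve toward the lenient side, consistent with the binary rule.
#'
#' @param logct_min,logct_max Lower/upper timing bounds (s); vectorized.
#' @param lhe Limit of the human eye (s).
#' @return Factor with levels legal/doubt/illegal.
#' @examples
#' classify_three_level(c(0.020, 0.035, 0.045), c(0.030, 0.045, 0.055))
#' @export
classify_three_level <- function(logct_min, logct_max, lhe = 0.040) {
  if (any(logct_min > logct_max)) lw_stop("inverted bounds", "domain_error")
  factor(ifelse(logct_max <= lhe, "legal",
                ifelse(logct_min > lhe, "illegal", "doubt")),
         levels = step_label_levels)
}

#' Fuzzy infringement membership
#'
#' Maps a timing value to a membership in the illegal class: 0 at or below
#' `lhe - 2/f`, 1 at or above `lhe + 2/f`, with a linear ramp across the
#' doubt band in between (at 200 Hz the band is 30-50 ms).
#'
#' @param logct Timing value(s) (s).
#' @param lhe Limit of the human eye (s).
#' @param f Sample frequency of the inertial sensor (Hz).
#' @return Membership value(s) in \[0, 1\].
#' @examples
#' fuzzy_membership(c(0.030, 0.040, 0.050), f = 200) # 0, 0.5, 1
#' @export
fuzzy_membership <- function(logct, lhe = 0.040, f = 200) {
  if (f <= 0) lw_stop("f must be positive", "domain_error")
  pmin(pmax((logct - (lhe - 2 / f)) / (4 / f), 0), 1)
}

#' Infringement fraction of a judged sequence
#'
#' The fraction of illegal steps among the `ns` binary step labels of one
#' step sequence.
#'
#' @param labels Factor of binary step labels (legal/illegal), length `ns`.
#' @param ns Expected number of steps per sequence.
#' @return A number in \[0, 1\].
#' @examples
#' infringement_fraction(classify_binary(c(rep(0.02, 24), rep(0.06, 6))))
#' @export
infringement_fraction <- function(labels, ns = 30L) {
  if (length(labels) != ns)
    lw_stop(sprintf("expected %d step labels, got %d", ns, length(labels)),
            "domain_error")
  if (any(labels == "doubt"))
    lw_stop("infringement fraction is defined on binary labels", "domain_error")
  mean(labels == "illegal")
}
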