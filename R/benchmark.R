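#' Validate a set of video step annotations
#'
#' Each annotated step carries four frame numbers from the high-speed camera:
#' `fna`, the last frame with visible ground contact before flight; `fnb`,
#' the first frame without it; `fnc`, the last frame before contact resumes;
#' `fnd`, the first frame with visible contact again. `fnb = fna + 1` and
#' `fnd = fnc + 1` by construction.
#'
#' @param ann Data frame with columns `step`, `fr`, `fna`, `fnb`, `fnc`,
#'   `fnd`, `no_flight`.
#' @return The validated data frame (class `video_annotations`).
#' @export
video_annotations <- function(ann) {
  need <- c("step", "fr", "fna", "fnb", "fnc", "fnd", "no_flight")
  if (!all(need %in% names(ann)))
    lw_stop(paste("annotations need columns:", paste(need, collapse = ", ")),
            "annotation_error")
  bad <- which(ann$fnb != ann$fna + 1 | ann$fnd != ann$fnc + 1 |
                 (!ann$no_flight & ann$fnc < ann$fnb - 1))
  if (length(bad) > 0)
    lw_stop(sprintf("frame invariants violated at step(s) %s",
                    paste(ann$step[bad], collapse = ", ")), "annotation_error")
  class(ann) <- c("video_annotations", "data.frame")
  ann
}

#' Read video step annotations from CSV
#'
#' Expects columns `step,FR,FNA,FNB,FNC,FND,no_flight` (case-insensitive).
#'
#' @param path CSV file path.
#' @return A `video_annotations` data frame.
#' @export
read_annotations_csv <- function(path) {
  if (!file.exists(path)) lw_stop(paste("file not found:", path), "input_error")
  df <- utils::read.csv(path)
  names(df) <- tolower(names(df))
  if (nrow(df) == 0) lw_stop("annotation file is empty", "annotation_error")
  df$no_flight <- as.logical(df$no_flight)
  video_annotations(df)
}

#' Write video step annotations to CSV
#'
#' @param ann A `video_annotations` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations_csv <- function(ann, path) {
  out <- ann[, c("step", "fr", "fna", "fnb", "fnc", "fnd", "no_flight")]
  names(out) <- c("step", "FR", "FNA", "FNB", "FNC", "FND", "no_flight")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Benchmark flight timing from frame annotations
#'
#' The camera brackets the true flight time between
#' `LOGCB_min = (fnc - fnb)/fr` (clamped at 0 when the flight is shorter
#' than a frame) and `LOGCB_max = (fnd - fna)/fr`; the central estimate is
#' the midpoint of the bracket. No-flight steps get a timing of 0. Sequence
#' values are means over consecutive windows of `ns` steps, mirroring the
#' inertial aggregation.
#'
#' @param ann A `video_annotations` data frame.
#' @param ns Steps per judged sequence (set to `NA` to skip sequence output).
#' @return A list with `steps` (data frame `step`, `logcb_s`, `logcb_min_s`,
#'   `logcb_max_s`, `no_flight`) and `sequences` (or `NULL`).
#' @export
benchmark_timing <- function(ann, ns = 30L) {
  ann <- video_annotations(as.data.frame(ann))
  lmax <- (ann$fnd - ann$fna) / ann$fr
  lmin <- pmax((ann$fnc - ann$fnb) / ann$fr, 0)
  mid <- (lmax + lmin) / 2
  lmax[ann$no_flight] <- 0
  lmin[ann$no_flight] <- 0
  mid[ann$no_flight] <- 0
  steps <- data.frame(step = ann$step, logcb_s = mid,
                      logcb_min_s = lmin, logcb_max_s = lmax,
                      no_flight = ann$no_flight)
  sequences <- NULL
  if (!is.na(ns) && nrow(steps) >= ns) {
    nseq <- nrow(steps) %/% ns
    idx <- rep(seq_len(nseq), each = ns)
    used <- steps[seq_len(nseq * ns), ]
    sequences <- data.frame(sequence = seq_len(nseq),
                            logcb_seq_s = tapply(used$logcb_s, idx, mean),
                            logcb_seq_min_s = tapply(used$logcb_min_s, idx, mean),
                            logcb_seq_max_s = tapply(used$logcb_max_s, idx, mean),
                            row.names = NULL)
  }
  list(steps = steps, sequences = sequences)
}

#' Benchmark fuzzy membership
#'
#' Same trapezoidal membership as the inertial system, applied to the
#' camera timing; the doubt band is expressed with the inertial sample
#' frequency so the two memberships share a scale.
#'
#' @param logcb Benchmark timing value(s) (s).
#' @param lhe Limit of the human eye (s).
#' @param f Inertial sample frequency (Hz).
#' @return Membership value(s) lambda in \[0, 1\].
#' @export
benchmark_membership <- function(logcb, lhe = 0.040, f = 200) {
  fuzzy_membership(logcb, lhe, f)
}

#' Fuzzy agreement between inertial and benchmark memberships
#'
#' The membership difference `sigma = eta - lambda` measures the distance
#' between the two systems per item; `|sigma| < 0.5` is an acceptable
#' classification (AC), `|sigma| >= 0.5` a wrong one (WC). `tau` is the
#' fraction of acceptable classifications.
#'
#' @param eta Inertial memberships in \[0, 1\].
#' @param lambda Benchmark memberships in \[0, 1\].
#' @return A list with `sigma`, `ac`, `wc`, `tau`.
#' @examples
#' fuzzy_agreement(c(0, 0.5, 1), c(0, 0.5, 0))$tau # 2/3
#' @export
fuzzy_agreement <- function(eta, lambda) {
  if (length(eta) != length(lambda)) lw_stop("length mismatch", "domain_error")
  sigma <- eta - lambda
  acc <- abs(sigma) < 0.5  # |sigma| = 0.5 exactly counts as wrong
  list(sigma = sigma, ac = sum(acc), wc = sum(!acc), tau = mean(acc))
}

#' Confusion statistics between inertial and benchmark labels
#'
#' The benchmark labels are taken as truth. In binary mode the positive
#' class is "legal": `tpr = P(pred legal | truth legal)`,
#' `fpr = P(pred legal | truth illegal)`, false alarm `= 1 - tpr`
#' (legal steps flagged illegal), miss alarm `= fpr` (illegal steps passed
#' as legal). In three-level mode per-class recall (TPR) and precision (PPV)
#' are reported. Rates conditioned on an empty class are `NA` (undefined),
#' not zero.
#'
#' @param pred Factor of predicted labels.
#' @param truth Factor of benchmark labels.
#' @param mode `"binary"` or `"three_level"`.
#' @return A list with the confusion `matrix`, `accuracy`, and either the
#'   binary rates (`tpr`, `fpr`, `false_alarm`, `miss_alarm`,
#'   `roc_distance` to the ideal point (0, 1)) or per-class `tpr` and `ppv`.
#' @export
agreement_stats <- function(pred, truth, mode = c("binary", "three_level")) {
  mode <- match.arg(mode)
  if (length(pred) != length(truth)) lw_stop("length mismatch", "domain_error")
  lv <- if (mode == "binary") c("legal", "illegal") else step_label_levels
  pred <- factor(as.character(pred), levels = lv)
  truth <- factor(as.character(truth), levels = lv)
  if (anyNA(pred) || anyNA(truth))
    lw_stop(sprintf("labels outside the %s label set", mode), "domain_error")
  cm <- table(truth = truth, pred = pred)
  acc <- sum(diag(cm)) / sum(cm)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  if (mode == "binary") {
    tpr <- rate(cm["legal", "legal"], sum(cm["legal", ]))
    fpr <- rate(cm["illegal", "legal"], sum(cm["illegal", ]))
    list(matrix = unclass(cm), accuracy = acc, tpr = tpr, fpr = fpr,
         false_alarm = if (is.na(tpr)) NA_real_ else 1 - tpr,
         miss_alarm = fpr,
         roc_distance = sqrt(fpr^2 + (1 - tpr)^2))
  } else {
    tpr <- vapply(lv, function(k) rate(cm[k, k], sum(cm[k, ])), numeric(1))
    ppv <- vapply(lv, function(k) rate(cm[k, k], sum(cm[, k])), numeric(1))
    list(matrix = unclass(cm), accuracy = acc, tpr = tpr, ppv = ppv)
  }
}

#' Area under the precision-recall curve
#'
#' Prepends the anchor point (recall 0, precision 1), sorts by recall
#' (ties broken by descending precision) and integrates precision over
#' recall with the trapezoid rule.
#'
#' @param recall Recall (TPR) values in \[0, 1\].
#' @param precision Precision (PPV) values in \[0, 1\].
#' @return The AUC.
#' @examples
#' pr_auc(c(0.55, 0.83, 1.00), c(1.00, 0.21, 0.86)) # ~0.81
#' @export
pr_auc <- function(recall, precision) {
  if (length(recall) != length(precision)) lw_stop("length mismatch", "domain_error")
  if (any(recall < 0 | recall > 1 | precision < 0 | precision > 1))
    lw_stop("recall and precision must lie in [0, 1]", "domain_error")
  r <- c(0, recall)
  p <- c(1, precision)
  o <- order(r, -p)
  r <- r[o]; p <- p[o]
  sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}

#' Event-detection and timing comparison against the benchmark
#'
#' Pairs inertial and benchmark steps by order. A flight event is declared
#' by the inertial system when `logct > 0` and by the camera when
#' `logcb > 0`. Reports agreement counts (including flights missed by the
#' sensor and double supports flagged as flights) and the paired timing
#' difference (inertial minus benchmark) as mean and SD.
#'
#' @param logct Inertial per-step timings (s).
#' @param logcb Benchmark per-step timings (s).
#' @return A list with `n`, `both_event`, `both_no_event`, `missed_events`,
#'   `false_events`, `detection_agreement`, `md_mean`, `md_sd`.
#' @export
detection_comparison <- function(logct, logcb) {
  if (length(logct) != length(logcb)) lw_stop("length mismatch", "domain_error")
  ie <- logct > 0
  be <- logcb > 0
  d <- logct - logcb
  list(n = length(logct),
       both_event = sum(ie & be), both_no_event = sum(!ie & !be),
       missed_events = sum(!ie & be), false_events = sum(ie & !be),
       detection_agreement = mean(ie == be),
       md_mean = mean(d), md_sd = stats::sd(d))
}

#' Hedges' g effect size
#'
#' Bias-corrected standardized mean difference with pooled SD and the
#' small-sample correction `J = 1 - 3 / (4 (n1 + n2) - 9)`.
#'
#' @param x,y Numeric samples from the two groups (each of length >= 2).
#' @return Hedges' g (NA with a warning when the pooled SD is zero).
#' @export
hedges_g <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) lw_stop("each group needs at least 2 values", "domain_error")
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2))
  if (sp == 0) {
    lw_warn("zero pooled SD: effect size undefined", "undefined_effect")
    return(NA_real_)
  }
  j <- 1 - 3 / (4 * (n1 + n2) - 9)
  j * (mean(x) - mean(y)) / sp
}

effect_size_label <- function(g) {
  g <- abs(g)
  ifelse(is.na(g), NA_character_,
         ifelse(g <= 0.25, "trivial",
                ifelse(g < 0.5, "small",
                       ifelse(g < 1.0, "moderate", "large"))))
}

#' Per-index effect sizes and radar weights
#'
#' Computes Hedges' g between two speed groups for each of the five indices,
#' labels the magnitude on the trivial / small / moderate / large scale, and
#' derives the normalized weights `kappa_i = |g_i| / sum |g_i|` (summing to 1)
#' that quantify each index's contribution to the overall radar score.
#'
#' @param group_m,group_n Data frames of index values (columns `delta`,
#'   `alpha`, `gamma`, `rho`, `mu`) for the minimum- and maximum-speed groups.
#' @return A data frame with columns `index`, `g`, `label`, `kappa`.
#' @export
effect_sizes <- function(group_m, group_n) {
  idx <- c("delta", "alpha", "gamma", "rho", "mu")
  if (!all(idx %in% names(group_m)) || !all(idx %in% names(group_n)))
    lw_stop("both groups need the five index columns", "domain_error")
  g <- vapply(idx, function(k) hedges_g(group_m[[k]], group_n[[k]]), numeric(1))
  kappa <- if (anyNA(g)) rep(NA_real_, length(g)) else abs(g) / sum(abs(g))
  data.frame(index = idx, g = g, label = effect_size_label(g), kappa = kappa,
             row.names = NULL)
}
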