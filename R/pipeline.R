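#' Full analysis pipeline for one trial
#'
#' Runs filtering, step segmentation, loss-of-ground-contact timing, the
#' three classifiers, the performance parameters, and the normalized indices
#' with their radar score, per judged sequence. `mode = "judge"` restricts
#' the output to what a referee needs (sequence timings and labels);
#' `mode = "trainer"` returns everything, including the per-step table and
#' the index profiles. The trainer mode requires trial metadata (speed and
#' stature) for the step-length ratio and smoothness.
#'
#' @param trace A raw or filtered `acceleration_trace`.
#' @param meta A [trial_meta()] (required in trainer mode).
#' @param cfg An [inertial_config()].
#' @param model A [threshold_model()].
#' @param calib A [calibration_constants()].
#' @param mode `"trainer"` or `"judge"`.
#' @return An object of class `trial_analysis`: a list with `steps`,
#'   `sequences`, `profiles` (with `epsilon`), `epsilon_opt`, `mode`,
#'   `events`, `cfg`.
#' @examples
#' \donttest{
#' tr <- generate_trial(sim_spec(duration = 25, warmup = 2))
#' cfg <- inertial_config(warmup = 2, ns = 10)
#' res <- analyze_trial(tr$trace, tr$meta, cfg = cfg)
#' res$sequences
#' }
#' @export
analyze_trial <- function(trace, meta = NULL, cfg = inertial_config(),
                          model = threshold_model(),
                          calib = calibration_constants(),
                          mode = c("trainer", "judge")) {
  mode <- match.arg(mode)
  if (mode == "trainer" && is.null(meta))
    lw_stop("trainer mode needs trial metadata (speed, stature)", "input_error")
  if (!trace$filtered) trace <- lowpass_zero_phase(trace, cfg)
  events <- segment_steps(trace, cfg)
  steps <- logc_timing(events, model, cfg)
  steps$label_binary <- classify_binary(steps$logct_s, cfg$lhe)
  steps$label_threelevel <- classify_three_level(steps$logct_min_s,
                                                 steps$logct_max_s, cfg$lhe)
  steps$eta <- fuzzy_membership(steps$logct_s, cfg$lhe, cfg$f)
  if (mode == "trainer") {
    steps$slr_pct <- step_length_ratio(meta$v_mean, steps$sc, meta$stature)
    steps$smoothness <- vapply(seq_len(nrow(steps)), function(i)
      smoothness(trace, c(events$tmax_s[i], events$tmax_next_s[i]),
                 steps$sc[i], meta$v_mean), numeric(1))
  }

  seqs <- aggregate_sequences(steps, cfg)
  names(seqs)[names(seqs) == "logct_seq_s"] <- "logct_seq_s"
  ns <- cfg$ns
  nseq <- nrow(seqs)
  grp <- rep(seq_len(nseq), each = ns)
  used <- steps[seq_len(nseq * ns), ]
  seqs$logcc_seq <- tapply(used$label_binary == "illegal", grp, mean)
  seqs$label_binary <- classify_binary(seqs$logct_seq_s, cfg$lhe)
  seqs$label_threelevel <- classify_three_level(seqs$logct_seq_min_s,
                                                seqs$logct_seq_max_s, cfg$lhe)
  seqs$eta <- fuzzy_membership(seqs$logct_seq_s, cfg$lhe, cfg$f)
  seqs$sc_seq <- tapply(used$sc, grp, mean)

  profiles <- NULL
  epsilon_opt <- NULL
  if (mode == "trainer") {
    seqs$slr_seq_pct <- tapply(used$slr_pct, grp, mean)
    seqs$s_seq <- tapply(used$smoothness, grp, mean)
    profiles <- compute_indices(seqs$logct_seq_s, seqs$logcc_seq, seqs$sc_seq,
                                seqs$slr_seq_pct, seqs$s_seq, calib, cfg)
    profiles$epsilon <- vapply(seq_len(nrow(profiles)), function(i)
      radar_epsilon(profiles[i, , drop = FALSE])$epsilon, numeric(1))
    epsilon_opt <- best_admissible(profiles)
  } else {
    seqs <- seqs[, c("sequence", "n_steps", "logct_seq_s", "logct_seq_min_s",
                     "logct_seq_max_s", "logcc_seq", "label_binary",
                     "label_threelevel", "eta")]
    steps <- steps[, c("step", "sc", "e_s", "logct_s", "logct_min_s",
                       "logct_max_s", "double_support", "label_binary",
                       "label_threelevel", "eta")]
  }
  structure(list(steps = steps, sequences = seqs, profiles = profiles,
                 epsilon_opt = epsilon_opt, mode = mode, events = events,
                 cfg = cfg),
            class = "trial_analysis")
}

#' @export
print.trial_analysis <- function(x, ...) {
  cat(sprintf("Trial analysis (%s mode): %d steps, %d sequences\n",
              x$mode, nrow(x$steps), nrow(x$sequences)))
  cat(sprintf("  mean LOGC timing %.1f ms; %d sequence(s) illegal (binary)\n",
              1000 * mean(x$steps$logct_s),
              sum(x$sequences$label_binary == "illegal")))
  if (!is.null(x$epsilon_opt) && !is.na(x$epsilon_opt$epsilon_opt))
    cat(sprintf("  best admissible epsilon = %.3f (sequence %d)\n",
                x$epsilon_opt$epsilon_opt, x$epsilon_opt$index))
  invisible(x)
}

#' Write sequence results to CSV
#'
#' @param analysis A `trial_analysis`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sequences_csv <- function(analysis, path) {
  utils::write.csv(analysis$sequences, path, row.names = FALSE)
  invisible(path)
}

#' Validate an analysis against video annotations
#'
#' Pairs the analyzed steps with camera-annotated steps by order, computes
#' the benchmark timings and memberships, and reports: event-detection
#' agreement and timing mean difference, binary and three-level confusion
#' statistics on steps and on judged sequences, and the fuzzy agreement
#' `tau` on both levels.
#'
#' @param analysis A `trial_analysis` (or a `logc_steps` data frame).
#' @param ann A `video_annotations` data frame covering the same steps.
#' @param cfg An [inertial_config()].
#' @return An object of class `agreement_report`.
#' @export
validate_against_video <- function(analysis, ann, cfg = inertial_config()) {
  steps <- if (inherits(analysis, "trial_analysis")) analysis$steps else analysis
  if (nrow(ann) == 0) lw_stop("empty annotation set", "annotation_error")
  if (nrow(ann) != nrow(steps))
    lw_stop(sprintf("cannot pair %d analyzed steps with %d annotated steps",
                    nrow(steps), nrow(ann)), "pairing_error")
  bm <- benchmark_timing(ann, ns = cfg$ns)
  det <- detection_comparison(steps$logct_s, bm$steps$logcb_s)

  truth_bin <- classify_binary(bm$steps$logcb_s, cfg$lhe)
  pred_bin <- classify_binary(steps$logct_s, cfg$lhe)
  step_binary <- agreement_stats(pred_bin, truth_bin, "binary")

  eta <- fuzzy_membership(steps$logct_s, cfg$lhe, cfg$f)
  lambda <- benchmark_membership(bm$steps$logcb_s, cfg$lhe, cfg$f)
  step_fuzzy <- fuzzy_agreement(eta, lambda)

  seq_binary <- seq_threelevel <- seq_fuzzy <- NULL
  if (!is.null(bm$sequences)) {
    nseq <- nrow(bm$sequences)
    grp <- rep(seq_len(nseq), each = cfg$ns)
    used <- steps[seq_len(nseq * cfg$ns), ]
    iseq <- data.frame(
      logct_seq_s = tapply(used$logct_s, grp, mean),
      logct_seq_min_s = tapply(used$logct_min_s, grp, mean),
      logct_seq_max_s = tapply(used$logct_max_s, grp, mean))
    seq_binary <- agreement_stats(
      classify_binary(iseq$logct_seq_s, cfg$lhe),
      classify_binary(bm$sequences$logcb_seq_s, cfg$lhe), "binary")
    seq_threelevel <- agreement_stats(
      classify_three_level(iseq$logct_seq_min_s, iseq$logct_seq_max_s, cfg$lhe),
      classify_three_level(bm$sequences$logcb_seq_min_s,
                           bm$sequences$logcb_seq_max_s, cfg$lhe),
      "three_level")
    seq_fuzzy <- fuzzy_agreement(
      fuzzy_membership(iseq$logct_seq_s, cfg$lhe, cfg$f),
      benchmark_membership(bm$sequences$logcb_seq_s, cfg$lhe, cfg$f))
  }
  structure(list(detection = det, step_binary = step_binary,
                 step_fuzzy = step_fuzzy, seq_binary = seq_binary,
                 seq_threelevel = seq_threelevel, seq_fuzzy = seq_fuzzy,
                 benchmark = bm),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Inertial vs camera agreement\n")
  cat(sprintf("  event detection: %.1f%% agreement, MD = %.1f +- %.1f ms\n",
              100 * x$detection$detection_agreement,
              1000 * x$detection$md_mean, 1000 * x$detection$md_sd))
  cat(sprintf("  step binary accuracy %.1f%%; step fuzzy tau %.2f\n",
              100 * x$step_binary$accuracy, x$step_fuzzy$tau))
  if (!is.null(x$seq_binary))
    cat(sprintf("  sequence binary accuracy %.1f%%; sequence fuzzy tau %.2f\n",
                100 * x$seq_binary$accuracy, x$seq_fuzzy$tau))
  invisible(x)
}

#' Write an agreement report to JSON
#'
#' Confusion matrices are written as nested integer arrays.
#'
#' @param report An `agreement_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  strip <- function(s) {
    if (is.null(s)) return(NULL)
    s$matrix <- unname(apply(s$matrix, 1, as.integer, simplify = FALSE))
    s
  }
  out <- list(detection = report$detection,
              step_binary = strip(report$step_binary),
              step_fuzzy = report$step_fuzzy[c("ac", "wc", "tau")],
              seq_binary = strip(report$seq_binary),
              seq_threelevel = strip(report$seq_threelevel),
              seq_fuzzy = if (is.null(report$seq_fuzzy)) NULL else
                report$seq_fuzzy[c("ac", "wc", "tau")])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
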