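# Shared fixtures: short synthetic trials and truth matching.

short_cfg <- function(...) inertial_config(warmup = 2, ...)

short_trial <- function(duration = 25, noise_sd = 0, seed = 1, ...) {
  generate_trial(sim_spec(duration = duration, noise_sd = noise_sd,
                          seed = seed, warmup = 2, ...))
}

# truth rows whose step starts after the warm-up (what the detector can see)
post_warmup_truth <- function(trial, warmup = 2) {
  trial$truth[trial$truth$heel_s >= trial$trace$t[1] + warmup - 1e-9, , drop = FALSE]
}

# pair each detected step with the nearest ground-truth heel strike;
# truth columns come back prefixed with "truth_"
match_truth <- function(steps, truth, max_gap = 0.15) {
  idx <- vapply(steps$tmax_s, function(tm) {
    k <- which.min(abs(truth$heel_s - tm))
    if (abs(truth$heel_s[k] - tm) <= max_gap) k else NA_integer_
  }, integer(1))
  tt <- truth[idx[!is.na(idx)], , drop = FALSE]
  names(tt) <- paste0("truth_", names(tt))
  cbind(steps[!is.na(idx), , drop = FALSE], tt)
}

table10_rows <- function() {
  # published group-mean index profiles used as fixed regression inputs
  data.frame(speed = c(12.0, 13.0, 14.0, 14.5),
             delta = c(0.10, 0.34, 0.63, 0.75),
             alpha = c(0.02, 0.22, 0.62, 0.79),
             gamma = c(0.42, 0.29, 0.14, 0.08),
             rho = c(0.44, 0.31, 0.20, 0.13),
             mu = c(0.55, 0.49, 0.42, 0.40),
             epsilon = c(0.48, 0.45, 0.38, 0.36))
}
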