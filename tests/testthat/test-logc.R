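test_that("cadence threshold matches its closed form and clamps sensibly", {
  m <- threshold_model()
  expect_equal(variable_threshold(3.10, m), 3.10^2 / -40.921 + 3.10 / 11.242,
               tolerance = 1e-12)
  expect_equal(variable_threshold(3.10, m), 0.0409, tolerance = 1e-3)
  # zero crossing at SC = -a/b; above it the raw value is negative -> clamped
  expect_equal(variable_threshold(40.921 / 11.242, m), 0, tolerance = 1e-12)
  expect_identical(variable_threshold(3.90, m), 0)
  expect_equal(variable_threshold(2.8, m), 0.0575, tolerance = 1e-3)
  expect_warning(variable_threshold(2.5, m), class = "logcwalk_cadence_clamp")
  expect_error(variable_threshold(-1, m), class = "logcwalk_domain_error")
})

test_that("threshold is continuous and non-increasing over the valid range", {
  sc <- seq(2.8, 4.0, by = 0.001)
  e <- variable_threshold(sc)
  expect_true(all(diff(e) <= 1e-12))
  expect_true(all(e >= 0))
})

test_that("per-step timing follows the threshold subtraction with 2/f bounds", {
  ev <- data.frame(step = 1L, tmax_s = 1.065 - 1 / 3.10, tmin_s = 1.000,
                   tmax_next_s = 1.065)
  st <- logc_timing(ev, cfg = inertial_config())
  expect_equal(st$sc, 3.10, tolerance = 1e-9)
  expect_equal(st$logct_s, 0.0241, tolerance = 1e-3)
  expect_equal(st$logct_min_s, st$logct_s - 0.010)
  expect_equal(st$logct_max_s, st$logct_s + 0.010)
  expect_false(st$double_support)

  # interval exactly equal to the threshold: no flight
  e <- variable_threshold(3.2)
  ev2 <- data.frame(step = 1L, tmax_s = 0, tmin_s = 1 / 3.2 - e, tmax_next_s = 1 / 3.2)
  st2 <- logc_timing(ev2)
  expect_equal(st2$logct_s, 0, tolerance = 1e-12)
  expect_true(st2$double_support)
})

test_that("sequence aggregation averages windows of exactly NS steps", {
  mk <- function(logct, n) {
    data.frame(step = seq_len(n), sc = 3.2, e_s = 0.03, logct_s = logct,
               logct_min_s = logct - 0.01, logct_max_s = logct + 0.01,
               double_support = logct <= 0)
  }
  cfg <- inertial_config()
  s <- aggregate_sequences(mk(rep(0.045, 60), 60), cfg)
  expect_equal(s$logct_seq_s, c(0.045, 0.045))
  s <- aggregate_sequences(mk(rep(c(0.020, 0.060), 15), 30), cfg)
  expect_equal(s$logct_seq_s, 0.040)
  s <- aggregate_sequences(mk(rep(0.045, 75), 75), cfg)
  expect_equal(nrow(s), 2)
  expect_identical(attr(s, "dropped"), 15L)
  expect_error(aggregate_sequences(mk(rep(0.045, 29), 29), cfg),
               class = "logcwalk_insufficient_steps_error")
  # mean of bounds equals bounds of mean here (linear)
  s <- aggregate_sequences(mk(seq(0.02, 0.06, length.out = 30), 30), cfg)
  expect_equal(s$logct_seq_s, mean(seq(0.02, 0.06, length.out = 30)),
               tolerance = 1e-12)
})

test_that("threshold refit recovers the generating coefficients exactly", {
  set.seed(7)
  sc <- runif(50, 2.8, 4.0)
  ot <- sc^2 / -40.921 + sc / 11.242
  fit <- fit_threshold_model(ot, sc)
  expect_equal(fit$a, -40.921, tolerance = 1e-6)
  expect_equal(fit$b, 11.242, tolerance = 1e-6)
  expect_equal(fit$a_robust, -40.921, tolerance = 1e-4)
  expect_equal(fit$r_squared, 100, tolerance = 1e-6)
})

test_that("refit exclusions are reported with reason codes", {
  set.seed(8)
  sc <- runif(40, 2.9, 3.9)
  ot <- sc^2 / -40.921 + sc / 11.242
  sc <- c(sc, 2.5, 3.3)
  ot <- c(ot, 0.05, -0.01)
  fit <- fit_threshold_model(ot, sc)
  expect_setequal(fit$excluded$reason, c("cadence-range", "negative-OT"))
  expect_equal(nrow(fit$excluded) + fit$n_used, length(ot))
  expect_equal(fit$a, -40.921, tolerance = 1e-6)
})

test_that("noisy refit recovers coefficients within 10%", {
  set.seed(11)
  sc <- runif(700, 2.8, 4.0)
  ot <- sc^2 / -40.921 + sc / 11.242 + rnorm(700, sd = 0.008)
  fit <- fit_threshold_model(ot, sc)
  expect_lt(abs(fit$a - -40.921) / 40.921, 0.10)
  expect_lt(abs(fit$b - 11.242) / 11.242, 0.10)
  expect_true(fit$r_squared >= 0 && fit$r_squared <= 100)
})

test_that("degenerate designs are rejected", {
  expect_error(fit_threshold_model(rep(0.03, 20), rep(3.2, 20)),
               class = "logcwalk_fit_error")
  expect_error(fit_threshold_model(rep(0.03, 5), seq(2.9, 3.9, length.out = 5)),
               class = "logcwalk_fit_error")
})
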