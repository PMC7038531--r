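test_that("calibration anchors reproduce the published values", {
  cal <- calibrate_boundaries()
  expect_equal(cal$sc_at_04, 3.130, tolerance = 0.005 / 3.130)
  expect_equal(cal$slr_at_04, 62.8, tolerance = 0.1 / 62.8)
  expect_equal(cal$slr_at_0, 71.4, tolerance = 0.5 / 71.4)
  # the printed record speed implies 3.387, slightly above the printed 3.380
  expect_equal(cal$sc_at_0, 3.387, tolerance = 1e-3)
})

test_that("delta ramp hits its three anchors, which are collinear", {
  expect_equal(delta_index(0.040), 0.4)
  expect_equal(delta_index(0.030), 0)
  expect_equal(delta_index(0.055), 1)
  # slope f/5 on both sides of the middle anchor
  expect_equal((delta_index(0.040) - delta_index(0.030)) / 0.010, 200 / 5)
  expect_equal((delta_index(0.055) - delta_index(0.040)) / 0.015, 200 / 5)
})

test_that("gamma, rho and mu interpolate between their anchors", {
  cfg <- inertial_config()
  cal <- calibration_constants()
  p <- compute_indices(0.040, 0.2, c(3.380, 3.130, 2.755), 62.8, 5.5, cal, cfg)
  expect_equal(p$gamma, c(0, 0.4, 1))
  expect_equal(p$alpha, rep(0.2, 3))
  expect_equal(p$rho, rep(0.4, 3))
  expect_equal(p$mu, rep(0.5, 3))
  p2 <- compute_indices(0.040, 0, 3.2, c(71.4, 62.8, 71.4 - 2.5 * (71.4 - 62.8)),
                        1, cal, cfg)
  expect_equal(p2$rho, c(0, 0.4, 1))
  expect_error(compute_indices(0.04, 1.2, 3.2, 62.8, 5, cal, cfg),
               class = "logcwalk_domain_error")
})

test_that("indices worsen monotonically with their parameter", {
  cfg <- inertial_config()
  cal <- calibration_constants()
  lt <- seq(0.01, 0.08, by = 0.002)
  expect_true(all(diff(delta_index(lt)) >= 0))
  sc <- seq(2.6, 3.6, by = 0.02)
  g <- compute_indices(0.03, 0, sc, 62.8, 5, cal, cfg)$gamma
  expect_true(all(diff(g) <= 0))
  slr <- seq(55, 75, by = 0.5)
  r <- compute_indices(0.03, 0, 3.2, slr, 5, cal, cfg)$rho
  expect_true(all(diff(r) <= 0))
  s <- seq(0, 12, by = 0.25)
  m <- compute_indices(0.03, 0, 3.2, 62.8, s, cal, cfg)$mu
  expect_true(all(diff(m) >= 0))
})

test_that("radar score agrees with a brute-force shoelace oracle", {
  oracle <- function(vals) {
    r <- 1 - vals
    ang <- pi / 2 + (0:4) * 2 * pi / 5
    x <- r * cos(ang); y <- r * sin(ang)
    a <- 0
    for (k in 1:5) {
      k2 <- if (k == 5) 1 else k + 1
      a <- a + x[k] * y[k2] - x[k2] * y[k]
    }
    abs(a) / 2 / (2.5 * sin(72 * pi / 180))
  }
  set.seed(9)
  for (i in 1:100) {
    p <- as.data.frame(as.list(setNames(runif(5), radar_axis_order)))
    expect_equal(radar_epsilon(p)$epsilon,
                 oracle(unname(unlist(p[1, radar_axis_order]))), tolerance = 1e-12)
  }
})

test_that("radar score spans the unit pentagon down to a point", {
  all0 <- data.frame(delta = 0, alpha = 0, gamma = 0, rho = 0, mu = 0)
  all1 <- all0 + 1
  expect_equal(radar_epsilon(all0)$epsilon, 1, tolerance = 1e-12)
  expect_equal(radar_epsilon(all1)$epsilon, 0)
  expect_equal(radar_epsilon(all0)$area, 2.5 * sin(2 * pi / 5), tolerance = 1e-12)
  expect_error(radar_epsilon(all0 - 0.5), class = "logcwalk_domain_error")
})

test_that("published mean index profiles yield the published radar scores", {
  t10 <- table10_rows()
  for (i in 1:2) {  # 12.0 and 13.0 km/h rows
    eps <- radar_epsilon(t10[i, ])$epsilon
    expect_lt(abs(eps - t10$epsilon[i]), 0.02)
  }
})

test_that("best admissible profile honours the infringement constraints", {
  p <- data.frame(delta = c(0.1, 0.7, 0.3), alpha = c(0.05, 0.1, 0.2),
                  gamma = 0.3, rho = 0.3, mu = 0.5,
                  epsilon = c(0.48, 0.50, 0.40))
  ba <- best_admissible(p)
  expect_equal(ba$epsilon_opt, 0.48)
  expect_equal(ba$index, 1L)
  none <- best_admissible(transform(p, delta = 0.9))
  expect_true(is.na(none$epsilon_opt))
  one <- best_admissible(p[3, , drop = FALSE])
  expect_equal(one$epsilon_opt, 0.40)
})

test_that("radar SVG export writes the polygon and score", {
  p <- data.frame(delta = 0.1, alpha = 0.02, gamma = 0.42, rho = 0.44, mu = 0.55)
  tf <- withr::local_tempfile(fileext = ".svg")
  write_radar_svg(p, tf)
  svg <- readLines(tf)
  expect_true(any(grepl("polygon", svg)))
  expect_true(any(grepl("epsilon = 0.486", svg, fixed = TRUE)))
})
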