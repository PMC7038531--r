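test_that("frame annotations bracket the benchmark timing", {
  ann <- data.frame(step = 1L, fr = 240, fna = 100, fnb = 101, fnc = 110,
                    fnd = 111, no_flight = FALSE)
  bm <- benchmark_timing(ann, ns = NA)
  expect_equal(bm$steps$logcb_max_s, 11 / 240)       # 45.83 ms
  expect_equal(bm$steps$logcb_min_s, 9 / 240)        # 37.5 ms
  expect_equal(bm$steps$logcb_s, 10 / 240)           # midpoint, 41.67 ms
  expect_equal(bm$steps$logcb_max_s - bm$steps$logcb_min_s, 2 / 240)

  # one-frame flight: lower bound collapses to zero
  ann1 <- data.frame(step = 1L, fr = 240, fna = 100, fnb = 101, fnc = 101,
                     fnd = 102, no_flight = FALSE)
  bm1 <- benchmark_timing(ann1, ns = NA)
  expect_equal(bm1$steps$logcb_min_s, 0)
  expect_equal(bm1$steps$logcb_max_s, 2 / 240)

  # no-flight step is legal under any classifier
  ann0 <- data.frame(step = 1L, fr = 240, fna = 100, fnb = 101, fnc = 100,
                     fnd = 101, no_flight = TRUE)
  bm0 <- benchmark_timing(ann0, ns = NA)
  expect_equal(bm0$steps$logcb_s, 0)
  expect_equal(as.character(classify_binary(bm0$steps$logcb_s)), "legal")

  bad <- transform(ann, fnb = 103)
  expect_error(benchmark_timing(bad), class = "logcwalk_annotation_error")
})

test_that("benchmark membership mirrors the inertial fuzzy band", {
  expect_equal(benchmark_membership(c(0.030, 0.050), f = 200), c(0, 1))
  expect_equal(benchmark_membership(0.045, f = 200), 0.75)
})

test_that("fuzzy agreement counts acceptable classifications", {
  eta <- rep(0.3, 10)
  expect_equal(fuzzy_agreement(eta, eta)$tau, 1)
  eta2 <- eta; eta2[1] <- 0
  lambda <- eta; lambda[1] <- 1  # one full disagreement among ten
  expect_equal(fuzzy_agreement(eta2, lambda)$tau, 0.9)
  # |sigma| = 0.5 exactly is a wrong classification
  expect_equal(fuzzy_agreement(0.5, 0)$tau, 0)
  expect_equal(fuzzy_agreement(0.49, 0)$tau, 1)
  expect_error(fuzzy_agreement(c(0, 1), 0), class = "logcwalk_domain_error")
})

test_that("tau is symmetric and perfect on identical memberships", {
  set.seed(3)
  eta <- runif(50); lambda <- runif(50)
  expect_equal(fuzzy_agreement(eta, lambda)$tau, fuzzy_agreement(lambda, eta)$tau)
  expect_equal(fuzzy_agreement(lambda, lambda)$tau, 1)
})

test_that("binary agreement statistics use legal as the positive class", {
  truth <- factor(c(rep("legal", 10), rep("illegal", 10)),
                  levels = c("legal", "doubt", "illegal"))
  pred <- truth
  pred[1:2] <- "illegal"  # two legal steps flagged
  st <- agreement_stats(pred, truth, "binary")
  expect_equal(st$false_alarm, 0.2)
  expect_equal(st$miss_alarm, 0)
  expect_equal(st$tpr, 0.8)
  expect_equal(st$fpr, 0)
  expect_equal(st$accuracy, 0.9)
  expect_equal(st$roc_distance, 0.2)

  perfect <- agreement_stats(truth, truth, "binary")
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$false_alarm, 0)

  all_legal <- factor(rep("legal", 20), levels = levels(truth))
  st2 <- agreement_stats(all_legal, truth, "binary")
  expect_equal(st2$miss_alarm, 1)
  expect_equal(st2$fpr, 1)

  # undefined rates stay NA rather than 0
  st3 <- agreement_stats(all_legal, all_legal, "binary")
  expect_true(is.na(st3$fpr))
})

test_that("three-level statistics report per-class recall and precision", {
  lv <- c("legal", "doubt", "illegal")
  truth <- factor(rep(lv, times = c(6, 3, 3)), levels = lv)
  pred <- truth
  pred[1:3] <- "doubt"  # half the legal sequences downgraded to doubt
  st <- agreement_stats(pred, truth, "three_level")
  expect_equal(unname(st$tpr["legal"]), 0.5)
  expect_equal(unname(st$ppv["legal"]), 1)
  expect_equal(unname(st$ppv["doubt"]), 0.5)
  expect_equal(st$accuracy, 0.75)
  expect_equal(sum(st$matrix), 12)
})

test_that("precision-recall AUC reproduces the published comparison", {
  expect_equal(round(pr_auc(c(0.55, 0.83, 1.00), c(1.00, 0.21, 0.86)), 2), 0.81)
  expect_equal(round(pr_auc(c(0.19, 0.83, 1.00), c(1.00, 0.13, 0.86)), 2), 0.64)
  expect_equal(pr_auc(1, 1), 1)
  expect_error(pr_auc(c(0.5, 1.2), c(1, 1)), class = "logcwalk_domain_error")
})

test_that("detection comparison flags missed and spurious flights", {
  logct <- c(0.045, 0.045, -0.002, 0.01)
  expect_equal(detection_comparison(logct, logct)$detection_agreement, 1)
  expect_equal(detection_comparison(logct, logct)$md_mean, 0)
  cmp <- detection_comparison(c(0.045, -0.002), c(0.040, 0.004))
  expect_equal(cmp$false_events, 0)
  expect_equal(cmp$missed_events, 1)
  expect_error(detection_comparison(1, c(1, 2)), class = "logcwalk_domain_error")
})

test_that("noiseless simulated timing differs from the camera only by quantization", {
  tr <- short_trial(duration = 25)
  cfg <- short_cfg()
  res <- analyze_trial(tr$trace, tr$meta, cfg)
  truth <- post_warmup_truth(tr)
  m <- match_truth(res$steps, truth)
  ann <- generate_video_annotations(tr$truth, 240)
  bm <- benchmark_timing(ann[match(m$truth_step, ann$step), ], ns = NA)
  cmp <- detection_comparison(m$logct_s, bm$steps$logcb_s)
  expect_equal(cmp$detection_agreement, 1)
  expect_lt(abs(cmp$md_mean), 2 / cfg$f + 1 / 240)
})

test_that("effect sizes follow Hedges' g with small-sample correction", {
  expect_equal(hedges_g(rep(c(1, 2), 10), rep(c(1, 2), 10)), 0)
  expect_warning(g0 <- hedges_g(rep(1, 5), rep(1, 5)),
                 class = "logcwalk_undefined_effect")
  expect_true(is.na(g0))
  set.seed(21)
  g <- hedges_g(rnorm(400, 1), rnorm(400, 0))
  expect_equal(g, 1.0, tolerance = 0.1)

  idx <- c("delta", "alpha", "gamma", "rho", "mu")
  set.seed(22)
  gm <- as.data.frame(setNames(lapply(idx, function(k) rnorm(50, 0.3, 0.1)), idx))
  gn <- as.data.frame(setNames(lapply(idx, function(k) rnorm(50, 0.5, 0.1)), idx))
  es <- effect_sizes(gm, gn)
  expect_equal(sum(es$kappa), 1)
  expect_true(all(es$kappa >= 0))
  expect_true(all(es$label %in% c("trivial", "small", "moderate", "large")))
})

test_that("equal Hedges' g values split the weights evenly", {
  idx <- c("delta", "alpha", "gamma", "rho", "mu")
  gm <- as.data.frame(setNames(rep(list(rep(c(0, 1), 10)), 5), idx))
  gn <- as.data.frame(setNames(rep(list(rep(c(1, 2), 10)), 5), idx))
  es <- effect_sizes(gm, gn)
  expect_equal(es$kappa, rep(0.2, 5))
})
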