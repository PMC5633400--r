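# Delta-delta-Cq quantification and the calibration-slope check.

test_that("textbook ddCq arithmetic is exact", {
  wells <- rbind(wells_df("s", 25.0, 24.0), wells_df("cal", 24.0, 24.0))
  res <- ddcq_wt_fraction(wells, "cal")
  s <- res[res$sample_id == "s", ]
  expect_equal(s$delta_delta_cq, 1.0)
  expect_equal(s$wt_percent, 50)
  # sample with the calibrator's dCq reads 100%
  cal <- res[res$sample_id == "cal", ]
  expect_equal(cal$wt_percent, 100)
})

test_that("replicate summaries match closed-form mean/SD/SEM", {
  set.seed(41)
  cq <- rnorm(3, 24, 0.2)
  s <- summarize_replicates(wells_df("a", cq, cq + 1))
  t <- s[s$channel == "target", ]
  expect_equal(t$mean_cq, mean(cq))
  expect_equal(t$sd, sd(cq))
  expect_equal(t$sem, sd(cq) / sqrt(3))
})

test_that("the 0.5-cycle outlier rule excludes a deviant replicate", {
  s <- summarize_replicates(wells_df("a", c(24.0, 24.1, 27.0),
                                     c(24, 24, 24)))
  t <- s[s$channel == "target", ]
  expect_equal(t$n_outliers, 1)
  expect_equal(t$mean_cq, 24.05)
  r <- s[s$channel == "reference", ]
  expect_equal(r$mean_cq, 24)
  expect_equal(r$sd, 0)
})

test_that("wt estimates are invariant to a constant plate-wide Cq shift", {
  set.seed(43)
  wells <- rbind(wells_df("s", rnorm(3, 26, 0.1), rnorm(3, 24, 0.1)),
                 wells_df("cal", rnorm(3, 24, 0.1), rnorm(3, 24, 0.1)))
  shifted <- wells
  shifted$cq <- shifted$cq + 3.7
  r1 <- ddcq_wt_fraction(wells, "cal")
  r2 <- ddcq_wt_fraction(shifted, "cal")
  expect_equal(r1$wt_percent, r2$wt_percent, tolerance = 1e-12)
})

test_that("wt estimate decreases as the target Cq rises", {
  base <- rbind(wells_df("s", 25, 24), wells_df("cal", 24, 24))
  ests <- vapply(c(0, 0.5, 1, 2), function(d) {
    w <- base
    w$cq[w$sample_id == "s" & w$channel == "target"] <- 25 + d
    ddcq_wt_fraction(w, "cal")$wt_percent[2]
  }, 1)
  expect_true(all(diff(ests) < 0))
})

test_that("simulated plates recover a 30% wt fraction", {
  pops <- list(s = two_allele_population(0.30),
               cal = calibrator_population())
  # averaged over fixed-seed plates so the check does not hinge on a single
  # noise draw; per-plate SD at sigma = 0.1 is ~2.4 points
  ests <- vapply(1:25, function(s) {
    wells <- simulate_qpcr(pops, assay_physics(cq_sigma = 0.1), seed = s)
    res <- ddcq_wt_fraction(wells, "cal")
    res$wt_percent[res$sample_id == "s"]
  }, 1)
  expect_lt(abs(mean(ests) - 30), 1.5)
  expect_true(all(abs(ests - 30) < 3 * 2.4))
})

test_that("partial edited-allele binding inflates the wt estimate (oligo bias)", {
  phys_oligo <- assay_physics(cq_sigma = 0, edited_binding = 0.5)
  phys_lna <- assay_physics(cq_sigma = 0, edited_binding = 0)
  for (f in c(0.05, 0.30, 0.70, 0.95)) {
    pops <- list(s = two_allele_population(f), cal = calibrator_population())
    est_o <- ddcq_wt_fraction(simulate_qpcr(pops, phys_oligo, seed = 1),
                              "cal")
    est_l <- ddcq_wt_fraction(simulate_qpcr(pops, phys_lna, seed = 1),
                              "cal")
    expect_gt(est_o$wt_percent[est_o$sample_id == "s"], 100 * f)
    expect_equal(est_l$wt_percent[est_l$sample_id == "s"], 100 * f,
                 tolerance = 1e-9)
  }
})

test_that("no-amplification and missing channels are flagged per sample", {
  wells <- rbind(
    data.frame(sample_id = "dead", channel = "target", replicate = 1:3,
               cq = NA_real_, flag = "noamp"),
    data.frame(sample_id = "dead", channel = "reference", replicate = 1:3,
               cq = 24, flag = ""),
    wells_df("cal", 24, 24))
  res <- ddcq_wt_fraction(wells, "cal")
  dead <- res[res$sample_id == "dead", ]
  expect_equal(dead$wt_percent, 0)
  expect_identical(dead$flag, "below_detection")

  half <- rbind(wells_df("cal", 24, 24),
                data.frame(sample_id = "lonely", channel = "target",
                           replicate = 1, cq = 25, flag = ""))
  res2 <- ddcq_wt_fraction(half, "cal")
  expect_identical(res2$flag[res2$sample_id == "lonely"], "missing_channel")
})

test_that("values above the calibrator are clipped with raw retained", {
  wells <- rbind(wells_df("hot", 23.0, 24.0), wells_df("cal", 24.0, 24.0))
  res <- ddcq_wt_fraction(wells, "cal")
  hot <- res[res$sample_id == "hot", ]
  expect_equal(hot$wt_percent, 100)
  expect_equal(hot$wt_percent_raw, 200)
  expect_identical(hot$flag, "above_calibrator")
})

test_that("calibration slope handles exact and fitted series", {
  flat <- data.frame(log10_input = -2:2, delta_cq = rep(1.3, 5))
  r <- calibration_slope(flat)
  expect_equal(r$slope, 0)
  expect_true(r$pass)

  rising <- data.frame(log10_input = -2:2,
                       delta_cq = 1 + 0.15 * (-2:2))
  r2 <- calibration_slope(rising)
  expect_equal(r2$slope, 0.15, tolerance = 1e-12)
  expect_false(r2$pass)

  set.seed(47)
  x <- runif(8, -3, 1)
  y <- rnorm(8)
  fit <- calibration_slope(data.frame(log10_input = x, delta_cq = y))
  # closed-form normal equations
  beta <- cov(x, y) / var(x)
  alpha <- mean(y) - beta * mean(x)
  expect_equal(fit$slope, beta, tolerance = 1e-9)
  expect_equal(fit$intercept, alpha, tolerance = 1e-9)

  expect_error(calibration_slope(data.frame(log10_input = c(1, 2),
                                            delta_cq = c(1, 1))),
               "3 distinct")
})
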