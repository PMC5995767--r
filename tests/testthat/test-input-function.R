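test_that("cross-calibration recovers an exact multiplicative scalar", {
  truth <- sampled_curve(0:100, 100 + (0:100))
  cont <- sampled_curve(0:100, truth$activity * 0.5, allow_negative = TRUE)
  disc <- discrete_samples(c(20, 50, 80),
                           wholeblood = curve_at(truth, c(20, 50, 80)))
  out <- cross_calibrate(cont, disc)
  expect_equal(attr(out, "scale"), 2, tolerance = 1e-9)
  expect_rel_equal(out$activity, truth$activity, 1e-9)

  # identity when discrete equals continuous
  disc_id <- discrete_samples(c(20, 50), wholeblood = curve_at(cont, c(20, 50)))
  expect_equal(attr(cross_calibrate(cont, disc_id), "scale"), 1,
               tolerance = 1e-9)
})

test_that("cross-calibration least squares lands inside the ratio spread", {
  cont <- sampled_curve(0:100, rep(10, 101))
  disc <- discrete_samples(c(10, 50, 90), wholeblood = c(19, 20, 21))
  s <- attr(cross_calibrate(cont, disc), "scale")
  # oracle: with a constant continuous curve the LS scalar is the mean ratio
  expect_equal(s, mean(c(1.9, 2.0, 2.1)), tolerance = 1e-12)
  expect_true(s >= 1.9 && s <= 2.1)
})

test_that("cross-calibration errors without overlap and clamps negatives", {
  cont <- sampled_curve(0:100, c(-1, rep(5, 100)), allow_negative = TRUE)
  far <- discrete_samples(5000, wholeblood = 3)
  expect_error(cross_calibrate(cont, far), "overlap")
  out <- cross_calibrate(cont, discrete_samples(50, wholeblood = 5))
  expect_equal(attr(out, "n_clamped"), 1L)
  expect_true(all(out$activity >= 0))
})

test_that("plasma-over-blood ratio is interpolated linearly over time", {
  wb <- sampled_curve(0:100, rep(10, 101))
  # identity ratio
  d1 <- discrete_samples(c(10, 90), wholeblood = c(10, 10), plasma = c(10, 10))
  expect_equal(apply_plasma_over_blood(wb, d1)$activity, rep(10, 101))
  # constant ratio 1.3
  d2 <- discrete_samples(c(10, 90), wholeblood = c(10, 10), plasma = c(13, 13))
  expect_equal(apply_plasma_over_blood(wb, d2)$activity, rep(13, 101))
  # linear 1.0 -> 1.2 over [0, 100]: midpoint scaled by 1.1
  d3 <- discrete_samples(c(0, 100), wholeblood = c(10, 10), plasma = c(10, 12))
  expect_equal(apply_plasma_over_blood(wb, d3)$activity[51], 11)
  # zero whole blood with positive plasma is undefined
  d4 <- discrete_samples(c(10, 90), wholeblood = c(0, 10), plasma = c(5, 10))
  expect_error(apply_plasma_over_blood(wb, d4), "undefined")
})

test_that("tail merge follows a generating exponential within 2%", {
  tau <- 2000
  cont <- sampled_curve(0:900, 1000 * exp(-(0:900) / tau))
  tail_t <- c(1200, 1800, 2700, 3600, 4500, 5430)
  disc <- discrete_samples(tail_t, plasma = 1000 * exp(-tail_t / tau))
  merged <- merge_continuous_discrete(cont, disc)
  expect_equal(max(merged$time), 5430)
  tail_grid <- merged$time[merged$time > 900]
  expect_rel_equal(merged$activity[merged$time > 900],
                   1000 * exp(-tail_grid / tau), 0.02)
  # verbatim inside the continuous window
  expect_identical(merged$activity[merged$time <= 900], cont$activity)
})

test_that("tail merge degenerates to a flat line for one equal sample", {
  cont <- sampled_curve(0:100, rep(7, 101))
  disc <- discrete_samples(500, plasma = 7)
  merged <- merge_continuous_discrete(cont, disc)
  expect_equal(merged$activity[merged$time > 100], rep(7, 400))
  expect_error(merge_continuous_discrete(cont, discrete_samples(50, plasma = 7)),
               "beyond the continuous window")
})

test_that("parent-fraction fit recovers generating parameters within 1%", {
  truth <- parent_fraction_fit(A = 0.8, T50 = 1200, h = 1.5)
  t <- c(300, 600, 900, 1200, 1800, 2700, 3600, 4500, 5430)
  d <- discrete_samples(t, parent_fraction = parent_fraction_at(truth, t))
  fit <- fit_parent_fraction(d)
  expect_rel_equal(fit$A, 0.8, 0.01)
  expect_rel_equal(fit$T50, 1200, 0.01)
  expect_rel_equal(fit$h, 1.5, 0.01)
  expect_identical(parent_fraction_at(fit, 0), 1)
})

test_that("all-unity fractions fit to no metabolism (A near 0, f = 1)", {
  d <- discrete_samples(c(300, 1200, 3600), parent_fraction = c(1, 1, 1))
  fit <- fit_parent_fraction(d)
  expect_lt(fit$A, 1e-6)
  expect_equal(parent_fraction_at(fit, c(0, 1000, 5000)), rep(1, 3),
               tolerance = 1e-6)
  expect_error(fit_parent_fraction(discrete_samples(c(100, 200),
                                                    parent_fraction = c(1, 0.9))),
               ">= 3")
})

test_that("fitted parent fraction is 1 at time zero and non-increasing", {
  fit <- attr(fx_ppif0(), "parent_fraction")
  expect_identical(parent_fraction_at(fit, 0), 1)
  f <- parent_fraction_at(fit, seq(0, 5400, by = 10))
  expect_true(all(diff(f) <= 1e-12))
  expect_true(all(f >= 0 & f <= 1))
})

test_that("ppIF reconstruction recovers the generating input function", {
  pp <- fx_ppif0()
  tr <- fx_truth_if()
  expect_rel_equal(auc_trapz(pp), auc_trapz(tr), 0.01)
  late <- pp$time > 60
  expect_rel_equal(pp$value[late], tr$value[late], 0.03)
  expect_true(all(pp$value >= 0))
})

test_that("ppIF never exceeds the merged plasma curve", {
  bl <- fx_blood0()
  calib <- cross_calibrate(bl$continuous, bl$discrete)
  plasma <- merge_continuous_discrete(
    apply_plasma_over_blood(calib, bl$discrete), bl$discrete)
  pp <- fx_ppif0()
  expect_true(all(pp$value <= curve_at(plasma, pp$time) + 1e-9))
})

test_that("each input-function stage is scale-equivariant in activity", {
  bl <- fx_blood0()
  c_scaled <- sampled_curve(bl$continuous$time, bl$continuous$activity * 3,
                            allow_negative = TRUE)
  d <- bl$discrete
  d_scaled <- discrete_samples(d$time, d$wholeblood * 3, d$plasma * 3,
                               d$parent_fraction)
  pp1 <- build_ppif(bl$continuous, d, 5400)
  pp3 <- build_ppif(c_scaled, d_scaled, 5400)
  expect_rel_equal(pp3$value[pp3$value > 0], 3 * pp1$value[pp3$value > 0], 1e-6)
})

test_that("ppif passes whole blood through when POB and parent fraction are 1", {
  cont <- sampled_curve(0:900, pmin(0:900, 500))
  t_d <- c(300, 600, 900, 1800, 3600, 5430)
  wb_d <- curve_at(cont, t_d)
  disc <- discrete_samples(t_d, wholeblood = wb_d, plasma = wb_d,
                           parent_fraction = rep(1, 6))
  pp <- build_ppif(cont, disc, 5400)
  expect_rel_equal(pp$value[100:900 + 1], cont$activity[100:900 + 1], 1e-6)
  expect_equal(pp$value[pp$time >= 900], rep(500, 4501), tolerance = 1e-6)
})
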