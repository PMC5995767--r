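test_that("rate boundaries are reciprocals of the time constants", {
  expect_equal(beta_from_time_constant(5), 0.2)
  expect_equal(beta_from_time_constant(5100), 0.000196, tolerance = 1e-3)
  expect_equal(beta_from_time_constant(1), 1)
  expect_error(beta_from_time_constant(0), "> 0")
})

test_that("basis grid spans the boundaries, log-spaced and increasing", {
  g <- basis_grid()
  expect_length(g$beta, 100)
  expect_equal(range(g$beta), c(0.000196, 0.2))
  expect_true(all(diff(g$beta) > 0))
  expect_true(all(g$beta >= g$slow_boundary & g$beta <= g$fast_boundary))
  expect_equal(stats::sd(diff(log(g$beta))), 0, tolerance = 1e-12)
  expect_error(basis_grid(fast_boundary = 0.0001, slow_boundary = 0.2),
               "slow_boundary < fast_boundary")
})

test_that("fast-limit basis column approaches Cp/beta", {
  sched <- frame_schedule(seq(600, 1500, by = 100), rep(100, 10),
                          injection_offset = 0)
  t <- 0:1600
  cp <- 1000 * exp(-t / 3000)
  inf <- input_function(t, cp)
  g <- basis_grid(n_basis = 2, include_vascular = FALSE)
  B <- make_basis(inf, g, sched)
  expected <- frame_average(t, cp, sched) / 0.2
  expect_rel_equal(B[, 2], expected, 0.05)
})

test_that("basis convolution matches the closed-form convolution oracle", {
  sched <- frame_schedule(seq(0, 2700, by = 300), rep(300, 10),
                          injection_offset = 0)
  tau <- 800
  t <- 0:3000
  inf <- input_function(t, exp(-t / tau))
  beta <- 0.002
  g <- basis_grid(slow_boundary = beta, fast_boundary = 0.2, n_basis = 2,
                  include_vascular = FALSE)
  B <- make_basis(inf, g, sched)
  # closed form: conv of e^(-t/tau) with e^(-beta t), then exact frame mean
  conv_cf <- function(x) (exp(-x / tau) - exp(-beta * x)) / (beta - 1 / tau)
  prim <- function(x) (-tau * exp(-x / tau) + exp(-beta * x) / beta) /
    (beta - 1 / tau)
  fb <- frame_bounds(sched)
  expected <- (prim(fb$end) - prim(fb$start)) / fb$duration
  expect_rel_equal(B[, 1], expected, 1e-3)
  # zero input -> zero basis
  inf0 <- input_function(t, rep(0, length(t)))
  expect_true(all(make_basis(inf0, g, sched) == 0))
})

test_that("closed-form VT follows the compartmental identities", {
  expect_equal(vt_closed_form(kinetic_params(0.1, 0.1, 0.05, 0.05)), 2)
  expect_equal(vt_closed_form(kinetic_params(0.2, 0.02)), 10)
  # k3 = 0 reduces to K1/k2 regardless of k4
  expect_equal(vt_closed_form(kinetic_params(0.1, 0.05, 0, 0.3)), 2)
  expect_error(vt_closed_form(kinetic_params(0.1, 0.05, 0.1, 0)),
               "unbounded")
  expect_error(kinetic_params(0.1, 0), "k2")
})

test_that("spectral fit recovers a single planted component", {
  inf <- fx_truth_if()
  sched <- fx_sched()
  g <- basis_grid(include_vascular = FALSE)
  B <- make_basis(inf, g, sched)
  j <- 40
  tac <- B[, j] * 0.05
  fit <- spectral_fit(tac, B)
  expect_rel_equal(fit$vt, 0.05 / g$beta[j], 0.01)
  expect_true(all(fit$alpha >= 0))
  # zero TAC -> zero spectrum, zero VT
  fit0 <- spectral_fit(rep(0, nrow(B)), B)
  expect_equal(fit0$vt, 0)
  expect_true(all(fit0$alpha == 0))
  expect_error(spectral_fit(tac, B * 0), "all-zero")
  expect_error(spectral_fit(tac, B, weights = rep(-1, nrow(B))), "negative")
})

test_that("noiseless 1TC VT agrees with K1/k2 within 2%", {
  inf <- fx_truth_if()
  sched <- fx_sched()
  p <- kinetic_params(0.3, 0.03)   # VT = 10
  tac <- frame_average(inf$time, model_tissue_curve(inf, p), sched)
  g <- basis_grid(include_vascular = FALSE)
  fit <- spectral_fit(tac, make_basis(inf, g, sched),
                      weights = frame_bounds(sched)$duration)
  expect_rel_equal(fit$vt, 10, 0.02)
})

test_that("spectral fit is scale-equivariant", {
  inf <- fx_truth_if()
  sched <- fx_sched()
  p <- kinetic_params(0.25, 0.04, 0.03, 0.03)
  tac <- frame_average(inf$time, model_tissue_curve(inf, p), sched)
  g <- basis_grid(include_vascular = FALSE)
  B <- make_basis(inf, g, sched)
  f1 <- spectral_fit(tac, B)
  f2 <- spectral_fit(tac * 3, B)
  expect_rel_equal(f2$vt, 3 * f1$vt, 1e-6)
  expect_equal(f2$alpha, 3 * f1$alpha, tolerance = 1e-6)
  # scaling the input function scales VT by the reciprocal
  inf2 <- input_function(inf$time, inf$value * 2)
  B2 <- make_basis(inf2, g, sched)
  f3 <- spectral_fit(tac, B2)
  expect_rel_equal(f3$vt, f1$vt / 2, 1e-6)
})

test_that("noiseless phantom ROI means recover ground truth within 2%", {
  r <- vt_image(fx_dyn0(), fx_truth_if(), basis_grid(), fx_roi(),
                wholeblood = fx_blood0()$wholeblood)
  truth <- vapply(fx_params(), vt_closed_form, numeric(1))
  expect_rel_equal(r$roi_means$vt, truth[r$roi_means$region], 0.02)
  expect_true(all(truth[r$roi_means$region] >= 8 &
                    truth[r$roi_means$region] <= 13))
  expect_true(all(r$roi_means$vt >= 0))
  # voxels outside any ROI carry NA
  expect_true(is.na(r$vt_image[1, 1, 1]))
})

test_that("uniform images give identical ROI means; empty ROIs are missing", {
  d <- dim(fx_dyn0()$data)
  one_tac <- fx_dyn0()$data[2, 2, 2, ]
  uni <- dynamic_image(array(rep(one_tac, each = prod(d[1:3])), d), fx_sched())
  lab <- array(0L, d[1:3])
  lab[2, 2, 2] <- 1L
  lab[3, 3, 3] <- 2L
  roi <- roi_map(lab, data.frame(label = 1:3, region = c("a", "b", "empty")))
  r <- vt_image(uni, fx_truth_if(), basis_grid(), roi,
                wholeblood = fx_blood0()$wholeblood)
  expect_equal(r$roi_means$vt[1], r$roi_means$vt[2])
  expect_true(is.na(r$roi_means$vt[r$roi_means$region == "empty"]))
  expect_equal(r$roi_means$n_voxels, c(1L, 1L, 0L))
})
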