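toy_cohort <- function(weights = c(70, 80, 90), doses = c(187, 187, 187),
                       ages = c(30, 40, 50)) {
  lapply(seq_along(weights), function(i) {
    participant_meta(sprintf("T%d", i), weights[i], doses[i], ages[i])
  })
}

toy_curves <- function(n = 3, peak = 80) {
  t <- 0:600
  lapply(seq_len(n), function(i) {
    input_function(t, i * exp(-((t - peak)^2) / 2000), id = sprintf("T%d", i))
  })
}

test_that("magnitude normalisation multiplies by median/value ratios", {
  metas <- toy_cohort()
  curves <- toy_curves()
  # identical covariates leave curves unchanged
  same <- toy_cohort(weights = rep(70, 3), ages = rep(40, 3))
  out <- normalise_magnitude(curves, same)
  expect_equal(out[[2]]$value, curves[[2]]$value)
  # single off-median covariate: weight 80 vs median 70 scales by 70/80
  metas2 <- toy_cohort(weights = c(70, 80, 70), ages = rep(40, 3))
  out2 <- normalise_magnitude(curves, metas2)
  expect_equal(out2[[2]]$value, curves[[2]]$value * 70 / 80)
  # brute-force product oracle over all three covariates
  out3 <- normalise_magnitude(curves, metas)
  w <- c(70, 80, 90); d <- c(187, 187, 187); a <- c(30, 40, 50)
  for (i in 1:3) {
    f <- (median(w) / w[i]) * (median(d) / d[i]) * (median(a) / a[i])
    expect_equal(out3[[i]]$value, curves[[i]]$value * f)
  }
  bad <- toy_cohort(ages = c(0, 40, 50))
  expect_error(normalise_magnitude(curves, bad), "positive")
})

test_that("peak alignment moves every maximum to the target time", {
  t <- 0:600
  c60 <- input_function(t, exp(-((t - 60)^2) / 2000))
  c80 <- input_function(t, exp(-((t - 80)^2) / 2000))
  out <- align_peaks(list(c60, c80), target_peak_s = 80)
  expect_equal(out[[1]]$time[which.max(out[[1]]$value)], 80, tolerance = 1)
  expect_equal(out[[2]]$time[which.max(out[[2]]$value)], 80, tolerance = 1)
  # already-aligned curve is unchanged
  expect_equal(out[[2]]$value, c80$value, tolerance = 1e-9)
  # monotone curve has no interior peak
  mono <- input_function(t, as.numeric(t))
  expect_error(align_peaks(list(mono)), "interior maximum")
})

test_that("median curve is the pointwise order statistic", {
  t <- 0:10
  cs <- lapply(c(1, 2, 10), function(v) input_function(t, rep(v, 11)))
  m <- median_curve(cs)
  expect_equal(m$value, rep(2, 11))
  # identical curves return themselves
  same <- lapply(1:3, function(i) input_function(t, t * 2))
  expect_equal(median_curve(same)$value, as.numeric(t * 2))
  # bounded by pointwise min and max
  rcs <- lapply(1:5, function(i) input_function(t, runif(11)))
  vals <- vapply(rcs, `[[`, numeric(11), "value")
  m2 <- median_curve(rcs)
  expect_true(all(m2$value <= apply(vals, 1, max) + 1e-12))
  expect_true(all(m2$value >= apply(vals, 1, min) - 1e-12))
  expect_error(median_curve(rcs[1:2]), ">= 3")
  bad <- c(rcs[1:2], list(input_function(0:20 / 2, rep(1, 21))))
  expect_error(median_curve(bad), "mismatch")
})

test_that("AUC regression recovers exact linear structure", {
  t <- 0:100
  anchors <- c(10, 20, 30, 40)
  curves <- lapply(anchors, function(a) {
    input_function(t, rep(a * 50, 101))   # AUC = 5000 * a
  })
  fit <- fit_auc_regression(curves, anchors)
  expect_rel_equal(fit$slope, 5000, 1e-6)
  expect_lt(abs(fit$intercept), 1e-6 * 5000 * 10)
  expect_error(fit_auc_regression(curves[1:2], anchors[1:2]), ">= 3")
  expect_error(fit_auc_regression(curves, rep(1, 4)), "zero variance")
})

test_that("AUC regression equals the closed-form normal equations", {
  set.seed(9)
  t <- 0:100
  anchors <- runif(6, 5, 50)
  auc_true <- 4000 * anchors + 2e4 + rnorm(6, 0, 1e3)
  curves <- lapply(auc_true, function(a) input_function(t, rep(a / 100, 101)))
  fit <- fit_auc_regression(curves, anchors)
  aucs <- vapply(curves, auc_trapz, numeric(1))
  sl <- sum((anchors - mean(anchors)) * (aucs - mean(aucs))) /
    sum((anchors - mean(anchors))^2)
  expect_equal(fit$slope, sl, tolerance = 1e-9)
  expect_equal(fit$intercept, mean(aucs) - sl * mean(anchors),
               tolerance = 1e-6)
})

test_that("anchored scaling is a fixed point at the median AUC", {
  t <- 0:600
  std <- input_function(t, exp(-((t - 80)^2) / 2000), provenance = "pbif")
  reg <- list(slope = 2, intercept = 0, n = 5)
  model <- pbif_model(std, reg, training_ids = letters[1:5])
  a_fix <- auc_trapz(std) / 2
  out <- scale_pbif(model, a_fix)
  expect_equal(out$value, std$value, tolerance = 1e-12)
  # doubling the predicted AUC doubles the curve
  out2 <- scale_pbif(model, 2 * a_fix)
  expect_equal(out2$value, 2 * std$value, tolerance = 1e-12)
  expect_error(scale_pbif(model, -1), "> 0")
  reg_neg <- list(slope = -5, intercept = 0, n = 5)
  model_neg <- pbif_model(std, reg_neg, letters[1:5])
  expect_error(scale_pbif(model_neg, 10), "impossible")
})

test_that("pbif_model rejects a mis-peaked standardised curve", {
  t <- 0:600
  off <- input_function(t, exp(-((t - 50)^2) / 2000), provenance = "pbif")
  expect_error(pbif_model(off, list(slope = 1, intercept = 0, n = 5), "a"),
               "peaks at")
})

test_that("an identity cohort returns each member's own input function", {
  spec <- fx_spec0()
  m1 <- fx_metas0()[[1]]
  metas <- lapply(1:5, function(i) {
    participant_meta(sprintf("P%02d", i), m1$weight, m1$injected_dose,
                     m1$age, m1$subgroup)
  })
  pp <- fx_ppif0()
  ppifs <- lapply(metas, function(m) {
    input_function(pp$time, pp$value, id = m$id, provenance = "ppif")
  })
  d <- fx_blood0()$discrete
  anchor <- d$plasma[nrow(d)] * d$parent_fraction[nrow(d)]
  anchors <- anchor * (1 + c(-2, -1, 0, 1, 2) * 1e-6)
  pb <- pbif_cohort(ppifs, metas, anchors, loo = TRUE)
  for (i in 1:5) {
    expect_rel_equal(auc_trapz(pb[[i]]), auc_trapz(pp), 0.01)
  }
})

test_that("identity-cohort PBIF VT matches ppIF VT within SA tolerance", {
  spec <- fx_spec0()
  m1 <- fx_metas0()[[1]]
  metas <- lapply(1:5, function(i) {
    participant_meta(sprintf("P%02d", i), m1$weight, m1$injected_dose,
                     m1$age, m1$subgroup)
  })
  pp <- fx_ppif0()
  ppifs <- lapply(metas, function(m) {
    input_function(pp$time, pp$value, id = m$id, provenance = "ppif")
  })
  d <- fx_blood0()$discrete
  anchor <- d$plasma[nrow(d)] * d$parent_fraction[nrow(d)]
  pb <- pbif_cohort(ppifs, metas, anchor * (1 + (-2:2) * 1e-6), loo = TRUE)
  wb <- fx_blood0()$wholeblood
  v_pp <- vt_image(fx_dyn0(), pp, basis_grid(), fx_roi(), wholeblood = wb)
  v_pb <- vt_image(fx_dyn0(), pb[[3]], basis_grid(), fx_roi(), wholeblood = wb)
  expect_rel_equal(v_pb$roi_means$vt, v_pp$roi_means$vt, 0.02)
})

test_that("the PBIF pipeline is invariant to participant ordering", {
  spec <- cohort_spec(n_participants = 5, seed = 11, noise_blood = 0.03,
                      noise_dynamic = 0)
  metas <- make_cohort(spec)
  sims <- lapply(seq_along(metas), function(i) simulate_blood(metas[[i]], spec, i))
  ppifs <- lapply(seq_along(metas), function(i) {
    build_ppif(sims[[i]]$continuous, sims[[i]]$discrete, 5400,
               id = metas[[i]]$id)
  })
  anchors <- vapply(sims, function(s) {
    d <- s$discrete
    d$plasma[nrow(d)] * d$parent_fraction[nrow(d)]
  }, numeric(1))
  pb <- pbif_cohort(ppifs, metas, anchors, loo = TRUE)
  perm <- c(3, 1, 5, 2, 4)
  pb_perm <- pbif_cohort(ppifs[perm], metas[perm], anchors[perm], loo = TRUE)
  for (k in seq_along(perm)) {
    expect_equal(pb_perm[[k]]$value, pb[[perm[k]]]$value, tolerance = 1e-9)
  }
})
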