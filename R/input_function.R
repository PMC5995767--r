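#' Cross-calibrate the continuous detector against discrete samples
#'
#' The online blood detector and the well counter used for discrete
#' samples are cross-calibrated by a single multiplicative scalar, fitted
#' by least squares over all discrete whole-blood samples falling inside
#' the continuous window: c = sum(d_i g_i) / sum(g_i^2) where g_i is the
#' continuous curve linearly interpolated at sample time i and d_i the
#' discrete measurement. Negative detector values (background-subtraction
#' noise) are clamped to zero first; the number clamped is recorded in
#' attribute `n_clamped`.
#'
#' @param continuous a `sampled_curve` (raw detector, may contain
#'   negatives).
#' @param discrete a `discrete_samples` table.
#' @param match_window_s samples within this margin beyond the continuous
#'   support still count as overlapping (default 5 s).
#' @return the calibrated `sampled_curve`, with attributes `scale` and
#'   `n_clamped`.
#' @export
cross_calibrate <- function(continuous, discrete, match_window_s = 5) {
  n_clamped <- sum(continuous$activity < 0)
  act <- pmax(continuous$activity, 0)
  cont <- sampled_curve(continuous$time, act)
  t_max <- max(cont$time) + match_window_s
  t_min <- min(cont$time) - match_window_s
  ok <- !is.na(discrete$wholeblood) &
    discrete$time >= t_min & discrete$time <= t_max
  if (!any(ok)) {
    stop("no discrete whole-blood samples overlap the continuous window",
         call. = FALSE)
  }
  g <- curve_at(cont, discrete$time[ok])
  d <- discrete$wholeblood[ok]
  if (all(g == 0)) {
    stop("continuous activity is zero at every matched sample", call. = FALSE)
  }
  scale <- sum(d * g) / sum(g^2)
  out <- sampled_curve(cont$time, cont$activity * scale)
  attr(out, "scale") <- scale
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Convert whole-blood to plasma activity via the plasma-over-blood ratio
#'
#' The ratio plasma/wholeblood is computed at every discrete sample where
#' both are measured, linearly interpolated over time (constant beyond
#' the first/last ratio sample), and multiplied pointwise into the
#' calibrated whole-blood curve.
#'
#' @param calibrated a whole-blood `sampled_curve`.
#' @param discrete a `discrete_samples` table with >= 2 paired
#'   plasma/whole-blood measurements.
#' @return plasma `sampled_curve`.
#' @export
apply_plasma_over_blood <- function(calibrated, discrete) {
  ok <- !is.na(discrete$plasma) & !is.na(discrete$wholeblood)
  if (sum(ok) < 2L) {
    stop("need >= 2 samples with both plasma and whole blood measured",
         call. = FALSE)
  }
  wb <- discrete$wholeblood[ok]
  pl <- discrete$plasma[ok]
  if (any(wb == 0 & pl > 0)) {
    stop("whole blood 0 with plasma > 0: plasma-over-blood ratio undefined",
         call. = FALSE)
  }
  keep <- wb > 0
  ratio <- pl[keep] / wb[keep]
  tt <- discrete$time[ok][keep]
  pob <- stats::approx(tt, ratio, xout = calibrated$time, rule = 2)$y
  sampled_curve(calibrated$time, calibrated$activity * pob)
}

#' Extend the continuous plasma curve over the late discrete samples
#'
#' Inside the continuous window the curve is kept verbatim. Beyond it,
#' a shape-preserving (monotone-safe) piecewise-cubic interpolant is
#' drawn through the later discrete plasma samples, anchored at the
#' continuous curve's final point, and evaluated on a 1-s grid to the
#' last sample. Negative undershoot is impossible by construction of the
#' monotone interpolant between non-negative knots.
#'
#' @param plasma_cont continuous-window plasma `sampled_curve`.
#' @param discrete a `discrete_samples` with at least one plasma sample
#'   beyond the continuous window.
#' @param field which discrete column to extend over: `"plasma"` (the
#'   input-function path) or `"wholeblood"` (used to carry the vascular
#'   signal to the scan end).
#' @return merged plasma `sampled_curve` from the continuous start to the
#'   last discrete sample.
#' @export
merge_continuous_discrete <- function(plasma_cont, discrete,
                                      field = c("plasma", "wholeblood")) {
  field <- match.arg(field)
  t_end <- max(plasma_cont$time)
  vals <- discrete[[field]]
  ok <- !is.na(vals) & discrete$time > t_end
  if (!any(ok)) {
    stop("no discrete ", field, " sample beyond the continuous window",
         call. = FALSE)
  }
  knots_t <- c(t_end, discrete$time[ok])
  knots_v <- c(plasma_cont$activity[which.max(plasma_cont$time)],
               vals[ok])
  tail_t <- seq(ceiling(t_end), max(knots_t))
  tail_t <- tail_t[tail_t > t_end]
  if (length(knots_t) == 2L) {
    tail_v <- stats::approx(knots_t, knots_v, xout = tail_t)$y
  } else {
    f <- stats::splinefun(knots_t, knots_v, method = "monoH.FC")
    tail_v <- pmax(f(tail_t), 0)
  }
  sampled_curve(c(plasma_cont$time, tail_t),
                c(plasma_cont$activity, tail_v))
}

#' Sigmoid parent-fraction model
#'
#' f(t) = 1 - A t^h / (t^h + T50^h): a decreasing sigmoid equal to 1 at
#' injection by construction, with asymptote 1 - A, half-drop time T50
#' (seconds) and Hill coefficient h.
#'
#' @param A drop amplitude in [0, 1]; `T50` seconds > 0; `h` > 0.
#' @param T50,h see above.
#' @return object of class `parent_fraction_fit`; evaluate with
#'   [parent_fraction_at()].
#' @export
parent_fraction_fit <- function(A, T50, h) {
  if (A < 0 || A > 1) stop("A must be in [0, 1]", call. = FALSE)
  if (T50 <= 0 || h <= 0) stop("T50 and h must be > 0", call. = FALSE)
  structure(list(A = A, T50 = T50, h = h), class = "parent_fraction_fit")
}

#' @rdname parent_fraction_fit
#' @param fit a `parent_fraction_fit`.
#' @param t times, seconds post-injection (>= 0).
#' @export
parent_fraction_at <- function(fit, t) {
  th <- pmax(t, 0)^fit$h
  1 - fit$A * th / (th + fit$T50^fit$h)
}

#' Fit the sigmoid parent-fraction model to discrete metabolite data
#'
#' Least-squares fit of the three parameters (A, T50, h) with f(0) = 1
#' enforced by the functional form; weights are uniform. Needs at least
#' three measurements at distinct positive times. Starting values come
#' from a coarse profile over T50 and h with A solved linearly; the
#' refinement runs Nelder-Mead on transformed parameters
#' (logit A, log T50, log h), which removes both the box constraints and
#' the poor scaling between A (order 1) and T50 (order 1000 s).
#'
#' @param discrete a `discrete_samples` with `parent_fraction` entries.
#' @return a `parent_fraction_fit` with attributes `residuals` and
#'   `rss`.
#' @export
fit_parent_fraction <- function(discrete) {
  ok <- !is.na(discrete$parent_fraction) & discrete$time > 0
  t <- discrete$time[ok]
  y <- discrete$parent_fraction[ok]
  if (length(t) < 3L) {
    stop("need >= 3 parent-fraction measurements at positive times", call. = FALSE)
  }
  if (any(y < 0 | y > 1)) stop("parent fractions outside [0, 1]", call. = FALSE)

  sse <- function(p) {
    f <- 1 - p[1] * t^p[3] / (t^p[3] + p[2]^p[3])
    sum((f - y)^2)
  }
  # coarse grid start: for each (T50, h), optimal A is linear LS
  best <- NULL
  for (T50 in stats::quantile(t, c(.1, .25, .5, .75, .9), names = FALSE)) {
    for (h in c(0.5, 1, 1.5, 2, 3)) {
      s <- t^h / (t^h + T50^h)
      A <- sum((1 - y) * s) / sum(s^2)
      A <- min(max(A, 1e-8), 1 - 1e-8)
      v <- sse(c(A, T50, h))
      if (is.null(best) || v < best$v) best <- list(p = c(A, T50, h), v = v)
    }
  }
  to_par <- function(q) c(stats::plogis(q[1]), exp(q[2]), exp(q[3]))
  opt <- stats::optim(c(stats::qlogis(best$p[1]), log(best$p[2]),
                        log(best$p[3])),
                      function(q) sse(to_par(q)),
                      control = list(maxit = 5000, reltol = 1e-13))
  par <- to_par(opt$par)
  if (opt$convergence != 0 && opt$value > best$v) {
    stop("parent-fraction fit did not converge; last iterate A=",
         signif(par[1], 4), " T50=", signif(par[2], 4),
         " h=", signif(par[3], 4), call. = FALSE)
  }
  fit <- parent_fraction_fit(par[1], par[2], par[3])
  attr(fit, "residuals") <- parent_fraction_at(fit, t) - y
  attr(fit, "rss") <- opt$value
  fit
}

#' Build a continuous parent-plasma input function from blood data
#'
#' Chains the four derivation steps: (1) cross-calibration of the
#' continuous detector against discrete whole-blood samples; (2)
#' conversion to plasma by the interpolated plasma-over-blood ratio;
#' (3) extension over the late discrete plasma samples by
#' shape-preserving spline; (4) multiplication by the fitted sigmoid
#' parent fraction. The result lives on a uniform 1-s grid from 0 to
#' `scan_end` (values clamped at 0; the parent curve can never exceed
#' the plasma curve because the fitted fraction is <= 1).
#'
#' @param continuous raw continuous whole-blood `sampled_curve`.
#' @param discrete a `discrete_samples` table.
#' @param scan_end_s end of the grid, seconds post-injection.
#' @param id participant id stored in the result.
#' @return an `input_function` (provenance `"ppif"`) with attribute
#'   `parent_fraction` (the fit).
#' @export
build_ppif <- function(continuous, discrete, scan_end_s, id = NA_character_) {
  calib <- cross_calibrate(continuous, discrete)
  plasma_cont <- apply_plasma_over_blood(calib, discrete)
  merged <- merge_continuous_discrete(plasma_cont, discrete)
  if (max(merged$time) < scan_end_s) {
    stop("blood data end before the requested scan end", call. = FALSE)
  }
  pf <- fit_parent_fraction(discrete)
  grid <- seq(0, scan_end_s, by = 1)
  plasma <- curve_at(merged, grid)
  value <- pmax(plasma * parent_fraction_at(pf, grid), 0)
  out <- input_function(grid, value, id = id, provenance = "ppif")
  attr(out, "parent_fraction") <- pf
  out
}

#' Continuous whole-blood curve to the scan end
#'
#' Cross-calibrates the continuous detector record and extends it over
#' the discrete whole-blood samples. Used as the vascular-signal curve
#' in voxel fits: it is the participant's own correctly-timed blood
#' record, so it stays valid even when the kinetic input function is a
#' population-based one.
#'
#' @param continuous raw continuous whole-blood `sampled_curve`.
#' @param discrete a `discrete_samples` table.
#' @return a whole-blood `sampled_curve` covering 0 to the last sample.
#' @export
build_wholeblood_curve <- function(continuous, discrete) {
  calib <- cross_calibrate(continuous, discrete)
  merge_continuous_discrete(calib, discrete, field = "wholeblood")
}
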