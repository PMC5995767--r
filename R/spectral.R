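#' Convert a time constant to a spectral rate boundary
#'
#' Classic spectral analysis bounds its rate grid by the reciprocals of a
#' fast and a slow time constant; e.g. 5 s maps to 0.2 s^-1 and 5100 s to
#' ~0.000196 s^-1.
#'
#' @param tc time constant in seconds, > 0.
#' @return rate in s^-1.
#' @export
beta_from_time_constant <- function(tc) {
  if (any(tc <= 0)) stop("time constant must be > 0", call. = FALSE)
  1 / tc
}

#' Spectral basis rate grid
#'
#' Log-spaced grid of `n_basis` exponential rates between the slow and
#' fast boundaries (inclusive). The defaults are the 90-min boundaries:
#' fast 0.2 s^-1 (5-s time constant), slow 0.000196 s^-1 (5100-s time
#' constant). `include_vascular` adds a whole-blood column to the design
#' matrix, excluded from VT.
#'
#' @param fast_boundary,slow_boundary rates, s^-1.
#' @param n_basis number of tissue basis rates (default 100).
#' @param include_vascular logical.
#' @return object of class `basis_grid`.
#' @export
basis_grid <- function(fast_boundary = 0.2,
                       slow_boundary = 0.000196,
                       n_basis = 100,
                       include_vascular = TRUE) {
  if (slow_boundary <= 0 || fast_boundary <= slow_boundary) {
    stop("need 0 < slow_boundary < fast_boundary", call. = FALSE)
  }
  if (n_basis < 2) stop("n_basis must be >= 2", call. = FALSE)
  beta <- exp(seq(log(slow_boundary), log(fast_boundary), length.out = n_basis))
  beta[1] <- slow_boundary          # guard endpoint rounding
  beta[n_basis] <- fast_boundary
  structure(list(beta = beta, n_basis = n_basis,
                 fast_boundary = fast_boundary,
                 slow_boundary = slow_boundary,
                 include_vascular = include_vascular),
            class = "basis_grid")
}

#' Frame-averaged spectral design matrix
#'
#' Column j is the input function convolved with exp(-beta_j t) on the
#' input function's fine grid, then averaged over the scan frames. When
#' the grid includes a vascular component, the final column is the
#' frame-averaged whole-blood curve (or, if none is supplied, the input
#' function itself).
#'
#' @param input_fn an `input_function` covering the schedule.
#' @param grid a `basis_grid`.
#' @param schedule a `frame_schedule`.
#' @param wholeblood optional `sampled_curve` for the vascular column.
#' @return numeric matrix, n_frames x (n_basis [+ 1]); the vascular
#'   column (if any) is named `"vascular"`, attribute `beta` carries the
#'   tissue rates.
#' @export
make_basis <- function(input_fn, grid, schedule, wholeblood = NULL) {
  if (scan_end(schedule) > max(input_fn$time) + 1e-6) {
    stop("input function does not cover the frame schedule", call. = FALSE)
  }
  B <- vapply(grid$beta, function(b) {
    frame_average(input_fn$time, convolve_exp(input_fn$time, input_fn$value, b),
                  schedule)
  }, numeric(n_frames(schedule)))
  colnames(B) <- sprintf("beta_%g", grid$beta)
  if (grid$include_vascular) {
    vb_curve <- if (is.null(wholeblood)) {
      input_fn$value
    } else {
      curve_at(wholeblood, input_fn$time)
    }
    B <- cbind(B, vascular = frame_average(input_fn$time, vb_curve, schedule))
  }
  attr(B, "beta") <- grid$beta
  B
}

#' Nonnegative spectral fit of a time-activity curve
#'
#' Solves alpha = argmin || W^(1/2) (B alpha - tac) ||^2 subject to
#' alpha >= 0 by nonnegative least squares, then reports
#' VT = sum_j alpha_j / beta_j over the tissue components (the vascular
#' column, if present, is excluded).
#'
#' @param tac frame activity vector (Bq/mL), length = rows of `basis`.
#' @param basis matrix from [make_basis()].
#' @param weights per-frame non-negative weights; default frame durations
#'   are supplied by [vt_image()] and friends. `NULL` = uniform.
#' @return object of class `spectral_result`: list with `alpha`, `beta`,
#'   `vt`, `vascular_coeff`, `residual_rss`.
#' @export
spectral_fit <- function(tac, basis, weights = NULL) {
  beta <- attr(basis, "beta")
  if (length(tac) != nrow(basis)) {
    stop("tac length must equal basis rows", call. = FALSE)
  }
  if (all(basis == 0)) stop("all-zero basis matrix", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(tac))
  if (any(weights < 0)) stop("negative weights", call. = FALSE)
  sw <- sqrt(weights)
  A <- sw * basis
  # unit-norm columns: pure conditioning, alphas are rescaled back below
  cn <- sqrt(colSums(A^2))
  cn[cn == 0] <- 1
  fit <- pracma::lsqnonneg(sweep(A, 2, cn, "/"), sw * tac)
  alpha <- fit$x / cn
  has_vasc <- ncol(basis) == length(beta) + 1L
  tissue <- alpha[seq_along(beta)]
  structure(list(alpha = tissue,
                 beta = beta,
                 vt = sum(tissue / beta),
                 vascular_coeff = if (has_vasc) alpha[length(alpha)] else NA_real_,
                 residual_rss = fit$resid.norm),
            class = "spectral_result")
}

#' @export
print.spectral_result <- function(x, ...) {
  k <- sum(x$alpha > 0)
  cat(sprintf("<spectral_result> VT = %.3f, %d active component%s, RSS %.3g\n",
              x$vt, k, if (k == 1) "" else "s", x$residual_rss))
  invisible(x)
}

#' Voxelwise VT image and per-ROI means
#'
#' Runs [spectral_fit()] on every voxel inside the ROI map (background,
#' label 0, is skipped) and reports the VT image plus the mean voxel VT
#' within each region. Identical voxel time-activity curves are fitted
#' once (noise-free phantoms collapse to one fit per region). Regions
#' with no voxels are reported as NA, not 0.
#'
#' When the basis includes a vascular column, the voxel VT is corrected
#' for the fractional blood volume: the voxel signal is
#' (1 - vb) C_tissue + vb C_blood, so the tissue spectral sum estimates
#' (1 - vb) VT and the fitted vascular coefficient estimates vb; the
#' reported VT is sum(alpha/beta) / (1 - vascular_coeff) (coefficient
#' clamped below 0.95). Without a vascular column the raw spectral sum
#' is reported.
#'
#' @param dyn a `dynamic_image`.
#' @param input_fn an `input_function`.
#' @param grid a `basis_grid`.
#' @param roi a `roi_map` matching the image's spatial dimensions.
#' @param weights_mode `"duration"` (default), `"uniform"`, or
#'   `"duration_activity"` (duration / max(activity, small) heuristic).
#' @param wholeblood optional whole-blood `sampled_curve` for the
#'   vascular basis column.
#' @return list with `vt_image` (3-D array, NA outside ROIs) and
#'   `roi_means` (data frame: region, vt, n_voxels).
#' @export
vt_image <- function(dyn, input_fn, grid, roi,
                     weights_mode = c("duration", "uniform",
                                      "duration_activity"),
                     wholeblood = NULL) {
  weights_mode <- match.arg(weights_mode)
  d <- dim(dyn$data)
  if (!all(d[1:3] == dim(roi$labels))) {
    stop("ROI map dimensions do not match the image", call. = FALSE)
  }
  sched <- dyn$schedule
  basis <- make_basis(input_fn, grid, sched, wholeblood = wholeblood)
  w <- spectral_weights(weights_mode, sched)

  vox <- which(roi$labels != 0L)
  tacs <- matrix(dyn$data, prod(d[1:3]), d[4])[vox, , drop = FALSE]
  # fit each distinct TAC once
  key <- apply(tacs, 1, function(r) paste(r, collapse = ","))
  first <- !duplicated(key)
  idx <- match(key, key[first])
  vt_unique <- vapply(which(first), function(i) {
    wi <- if (weights_mode == "duration_activity") {
      w / pmax(abs(tacs[i, ]), max(abs(tacs[i, ])) * 1e-3)
    } else w
    fit <- spectral_fit(tacs[i, ], basis, weights = wi)
    if (grid$include_vascular) {
      fit$vt / (1 - min(fit$vascular_coeff, 0.95))
    } else {
      fit$vt
    }
  }, numeric(1))
  vt_vox <- vt_unique[idx]

  img <- array(NA_real_, d[1:3])
  img[vox] <- vt_vox
  lab <- as.integer(roi$labels)[vox]
  tab <- roi$label_table
  means <- vapply(tab$label, function(l) {
    v <- vt_vox[lab == l]
    if (length(v) == 0L) NA_real_ else mean(v)
  }, numeric(1))
  nv <- vapply(tab$label, function(l) sum(lab == l), integer(1))
  list(vt_image = img,
       roi_means = data.frame(region = tab$region, vt = means, n_voxels = nv))
}

spectral_weights <- function(mode, schedule) {
  fb <- frame_bounds(schedule)
  w <- switch(mode,
              uniform = rep(1, nrow(fb)),
              duration = fb$duration,
              duration_activity = fb$duration)
  # pre-injection frames carry no kinetic information
  w[fb$end <= 0] <- 0
  w / max(w)
}
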