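#' Duration-matched spectral slow boundaries
#'
#' Shortened acquisitions cannot support spectral components slower than
#' the scan itself; each supported duration therefore has its own slow
#' boundary: 0.000290 s^-1 at 60 min, 0.000256 at 70, 0.000222 at 80 and
#' 0.000196 at 90 min. The values follow no closed formula, so other
#' durations require an explicit boundary from the caller.
#'
#' @param duration_min scan duration, one of 60, 70, 80, 90.
#' @return slow boundary, s^-1.
#' @export
slow_boundary_for <- function(duration_min) {
  tab <- c(`60` = 0.000290, `70` = 0.000256, `80` = 0.000222,
           `90` = 0.000196)
  key <- as.character(duration_min)
  if (!key %in% names(tab)) {
    stop(sprintf(paste("no slow boundary defined for a %g-min scan;",
                       "supply one explicitly via basis_grid()"),
                 duration_min), call. = FALSE)
  }
  unname(tab[key])
}

#' Truncate a dynamic acquisition at a frame boundary
#'
#' Keeps the frames ending at or before `t_end_s` post-injection.
#' `t_end_s` must coincide with a frame boundary and lie within the
#' scan; truncating at the scan end is the identity.
#'
#' @param dyn a `dynamic_image`.
#' @param t_end_s truncation time, seconds post-injection.
#' @return a shorter `dynamic_image`.
#' @export
truncate_frames <- function(dyn, t_end_s) {
  fb <- frame_bounds(dyn$schedule)
  if (t_end_s > max(fb$end) + 1e-9) {
    stop("truncation time beyond the scan end", call. = FALSE)
  }
  splits <- fb$start < t_end_s - 1e-9 & fb$end > t_end_s + 1e-9
  if (any(splits)) {
    stop(sprintf("t_end = %g s falls mid-frame (frame %d: %g-%g s)",
                 t_end_s, which(splits)[1], fb$start[which(splits)[1]],
                 fb$end[which(splits)[1]]), call. = FALSE)
  }
  keep <- fb$end <= t_end_s + 1e-9
  if (!any(keep)) stop("no frames remain after truncation", call. = FALSE)
  sched <- frame_schedule(dyn$schedule$frame_start[keep],
                          dyn$schedule$frame_duration[keep],
                          dyn$schedule$injection_offset)
  nd <- dim(dyn$data)
  dynamic_image(dyn$data[, , , keep, drop = FALSE], sched)
}

#' Scan-shortening study: regional VT across durations
#'
#' For each requested duration the acquisition is truncated, the
#' spectral basis is rebuilt with the duration-matched slow boundary
#' (fast boundary unchanged), voxelwise spectral analysis is re-run, and
#' regional mean VT is reported together with the percent difference
#' relative to the longest requested duration (conventionally 90 min).
#' The full-length input function is used for every duration.
#'
#' @param dyn a `dynamic_image` (full acquisition).
#' @param input_fn the participant's `input_function`.
#' @param roi an `roi_map`.
#' @param durations_min durations in minutes (must include the reference,
#'   i.e. the maximum, which the percent differences are taken against).
#' @param fast_boundary,n_basis,include_vascular,weights_mode,wholeblood
#'   forwarded to [basis_grid()] / [vt_image()].
#' @param boundaries optional named numeric vector overriding
#'   [slow_boundary_for()] (names = durations in minutes).
#' @return data frame: duration_min, region, vt, pct_diff_vs_ref.
#' @export
truncation_study <- function(dyn, input_fn, roi,
                             durations_min = c(60, 70, 80, 90),
                             fast_boundary = 0.2, n_basis = 100,
                             include_vascular = TRUE,
                             weights_mode = "duration",
                             wholeblood = NULL,
                             boundaries = NULL) {
  durations_min <- sort(unique(durations_min))
  ref <- max(durations_min)
  res <- lapply(durations_min, function(d) {
    slow <- if (!is.null(boundaries) && as.character(d) %in% names(boundaries)) {
      unname(boundaries[as.character(d)])
    } else {
      slow_boundary_for(d)
    }
    short <- truncate_frames(dyn, d * 60)
    grid <- basis_grid(fast_boundary = fast_boundary, slow_boundary = slow,
                       n_basis = n_basis, include_vascular = include_vascular)
    vt <- vt_image(short, input_fn, grid, roi, weights_mode = weights_mode,
                   wholeblood = wholeblood)$roi_means
    data.frame(duration_min = d, region = vt$region, vt = vt$vt)
  })
  out <- do.call(rbind, res)
  ref_vt <- out[out$duration_min == ref, c("region", "vt")]
  out$pct_diff_vs_ref <- 100 * (out$vt /
    ref_vt$vt[match(out$region, ref_vt$region)] - 1)
  out
}
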