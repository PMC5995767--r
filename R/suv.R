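#' Standardised uptake value over a post-injection epoch
#'
#' SUV = C * weight(g) / dose(Bq), where C is the duration-weighted mean
#' decay-corrected activity (Bq/mL) over the frames spanning
#' [t0, t1] seconds post-injection. The epoch must be tiled exactly by
#' whole frames: a boundary splitting a frame is an error, as is an
#' epoch extending beyond the scan.
#'
#' @param dyn a `dynamic_image` (decay-corrected activity).
#' @param meta a `participant_meta` (weight kg, dose MBq).
#' @param t0,t1 epoch bounds, seconds post-injection.
#' @param roi optional `roi_map` for regional means.
#' @return object of class `suv_result`: list with `epoch`, `suv_image`
#'   (3-D unitless array) and `roi_means` (data frame or NULL).
#' @export
suv_epoch <- function(dyn, meta, t0, t1, roi = NULL) {
  fb <- frame_bounds(dyn$schedule)
  if (t0 < min(fb$start) - 1e-9 || t1 > max(fb$end) + 1e-9 || t1 <= t0) {
    stop("epoch outside the scan or empty", call. = FALSE)
  }
  eps <- 1e-6
  inside <- fb$start >= t0 - eps & fb$end <= t1 + eps
  if (!any(inside) ||
      abs(min(fb$start[inside]) - t0) > eps ||
      abs(max(fb$end[inside]) - t1) > eps ||
      abs(sum(fb$duration[inside]) - (t1 - t0)) > eps) {
    stop(sprintf("epoch [%g, %g] s is not aligned with frame boundaries",
                 t0, t1), call. = FALSE)
  }
  w <- fb$duration[inside]
  d <- dim(dyn$data)
  flat <- matrix(dyn$data, prod(d[1:3]), d[4])
  cbar <- as.numeric(flat[, inside, drop = FALSE] %*% w) / sum(w)
  suv <- cbar * (meta$weight * 1000) / (meta$injected_dose * 1e6)
  img <- array(suv, d[1:3])
  roi_means <- NULL
  if (!is.null(roi)) {
    lab <- as.integer(roi$labels)
    roi_means <- data.frame(
      region = roi$label_table$region,
      suv = vapply(roi$label_table$label, function(l) {
        v <- suv[lab == l]
        if (length(v) == 0L) NA_real_ else mean(v)
      }, numeric(1)))
  }
  structure(list(epoch = c(t0, t1), suv_image = img, roi_means = roi_means),
            class = "suv_result")
}

#' The standard SUV epoch set
#'
#' The seven 10-min epochs from 20-30 to 80-90 min post-injection plus
#' the 30-60 and 60-90 min epochs.
#'
#' @return 9 x 2 matrix of (t0, t1) in seconds.
#' @export
default_suv_epochs <- function() {
  ep <- rbind(cbind(seq(20, 80, 10), seq(30, 90, 10)),
              c(30, 60), c(60, 90)) * 60
  colnames(ep) <- c("t0", "t1")
  ep
}

#' SUVs over a series of epochs
#'
#' @param dyn,meta,roi as in [suv_epoch()].
#' @param epochs n x 2 matrix of (t0, t1) seconds; default
#'   [default_suv_epochs()].
#' @return list of `suv_result`, one per epoch (empty list for an empty
#'   epoch set).
#' @export
suv_epoch_series <- function(dyn, meta, epochs = default_suv_epochs(),
                             roi = NULL) {
  if (is.null(epochs) || nrow(epochs) == 0L) return(list())
  lapply(seq_len(nrow(epochs)), function(i) {
    suv_epoch(dyn, meta, epochs[i, 1], epochs[i, 2], roi = roi)
  })
}
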