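#' Magnitude-normalise a cohort's input functions
#'
#' Each participant's parent-plasma input function is multiplied by the
#' ratio (cohort median / participant value) for weight, then injected
#' dose, then age. The three medians are computed once from the raw
#' covariates; because the factors act multiplicatively, applying them
#' in sequence equals applying their product.
#'
#' @param ppifs list of `input_function`.
#' @param metas matching list of `participant_meta`.
#' @param use_age include the age factor (TRUE, the default, mirrors the
#'   observed age dependence of the parent-fraction AUC; set FALSE to
#'   normalise by weight and dose only).
#' @return list of normalised `input_function`s, attribute `factors`
#'   carrying the per-participant scale factors.
#' @export
normalise_magnitude <- function(ppifs, metas, use_age = TRUE) {
  if (length(ppifs) != length(metas)) {
    stop("one meta per input function required", call. = FALSE)
  }
  w <- vapply(metas, `[[`, numeric(1), "weight")
  d <- vapply(metas, `[[`, numeric(1), "injected_dose")
  a <- vapply(metas, `[[`, numeric(1), "age")
  if (any(c(w, d, a) <= 0)) {
    stop("weight, dose and age must all be positive", call. = FALSE)
  }
  f <- (stats::median(w) / w) * (stats::median(d) / d)
  if (use_age) f <- f * (stats::median(a) / a)
  out <- lapply(seq_along(ppifs), function(i) {
    x <- ppifs[[i]]
    input_function(x$time, x$value * f[i], id = x$id, provenance = x$provenance)
  })
  attr(out, "factors") <- f
  out
}

#' Align input-function peaks to a common time
#'
#' Each curve is shifted by a whole number of grid steps so its maximum
#' (located after a mild 5-s moving-average smoothing, to avoid
#' noise-spike peaks) falls at `target_peak_s`. Curves shifted late are
#' padded on the left with their initial value (pre-arrival baseline);
#' curves shifted early lose their last samples, and all curves are then
#' truncated to the common support. A maximum on the grid edge means no
#' identifiable interior peak and is an error.
#'
#' @param curves list of `input_function` on identical grids.
#' @param target_peak_s target peak time, seconds (default 80).
#' @return list of aligned `input_function`s on the common grid.
#' @export
align_peaks <- function(curves, target_peak_s = 80) {
  t0 <- curves[[1]]$time
  dt <- t0[2] - t0[1]
  shifts <- vapply(curves, function(x) {
    if (!isTRUE(all.equal(x$time, t0))) {
      stop("all curves must share one grid", call. = FALSE)
    }
    k <- max(1L, round(5 / dt))
    sm <- stats::filter(x$value, rep(1 / k, k), sides = 2)
    sm[is.na(sm)] <- -Inf
    pk <- which.max(sm)
    if (pk <= k || pk >= length(t0) - k) {
      stop("curve has no interior maximum; cannot align its peak", call. = FALSE)
    }
    round((target_peak_s - t0[pk]) / dt)
  }, numeric(1))
  n <- length(t0)
  # right-shifted curves keep full support; left shifts lose the tail
  n_keep <- n - max(c(0, -shifts))
  out <- lapply(seq_along(curves), function(i) {
    v <- curves[[i]]$value
    s <- shifts[i]
    shifted <- if (s >= 0) c(rep(v[1], s), v)[1:n] else v[(1 - s):n]
    input_function(t0[1:n_keep], shifted[1:n_keep],
                   id = curves[[i]]$id, provenance = curves[[i]]$provenance)
  })
  attr(out, "shifts_s") <- shifts * dt
  out
}

#' Pointwise median of aligned input functions
#'
#' @param aligned list of >= 3 `input_function` on one common grid.
#' @return the median `input_function` (provenance `"pbif"`).
#' @export
median_curve <- function(aligned) {
  if (length(aligned) < 3L) stop("need >= 3 curves", call. = FALSE)
  t0 <- aligned[[1]]$time
  for (x in aligned) {
    if (!isTRUE(all.equal(x$time, t0))) stop("grid mismatch", call. = FALSE)
  }
  vals <- vapply(aligned, `[[`, numeric(length(t0)), "value")
  input_function(t0, apply(vals, 1, stats::median), provenance = "pbif")
}

#' Regression of input-function AUC on the late plasma anchor sample
#'
#' Ordinary least squares of trapezoidal AUC (Bq s/mL over the full
#' grid) on the parent-plasma activity of the late (90-min) anchor
#' sample. Needs at least three pairs and non-constant anchors.
#'
#' @param ppifs list of `input_function` (>= 3).
#' @param anchor_samples numeric vector of anchor activities (Bq/mL).
#' @return list with `slope`, `intercept`, `n`.
#' @export
fit_auc_regression <- function(ppifs, anchor_samples) {
  if (length(ppifs) < 3L || length(anchor_samples) != length(ppifs)) {
    stop("need >= 3 (input function, anchor) pairs", call. = FALSE)
  }
  if (stats::sd(anchor_samples) == 0) {
    stop("anchor samples have zero variance; regression undefined", call. = FALSE)
  }
  auc <- vapply(ppifs, auc_trapz, numeric(1))
  fit <- stats::lm(auc ~ anchor_samples)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = length(auc))
}

#' Population-based input-function model
#'
#' The standardised (median) curve plus the AUC-vs-anchor regression
#' used to scale it to an individual.
#'
#' @param standardised_curve median `input_function`, peak at the target
#'   time.
#' @param regression list with `slope`, `intercept`, `n` from
#'   [fit_auc_regression()].
#' @param training_ids participant ids used to build the model.
#' @param target_peak_s peak time of the standardised curve.
#' @return object of class `pbif_model`.
#' @export
pbif_model <- function(standardised_curve, regression, training_ids,
                       target_peak_s = 80) {
  pk <- standardised_curve$time[which.max(standardised_curve$value)]
  if (abs(pk - target_peak_s) > 1 + 1e-9) {
    stop(sprintf("standardised curve peaks at %g s, not the %g s target",
                 pk, target_peak_s), call. = FALSE)
  }
  if (regression$n < 3L) stop("regression fitted on < 3 points", call. = FALSE)
  structure(list(standardised_curve = standardised_curve,
                 regression = regression,
                 training_ids = training_ids,
                 target_peak_s = target_peak_s),
            class = "pbif_model")
}

#' Build a population-based input-function model from a training cohort
#'
#' Magnitude normalisation (weight, dose, age), peak alignment to 80 s,
#' pointwise median, and AUC-vs-anchor regression -- all computed from
#' the training participants only. With the default leave-one-out
#' protocol, call this once per target participant with that participant
#' excluded.
#'
#' @param ppifs,metas training cohort curves and metadata.
#' @param anchors parent-plasma anchor activities (Bq/mL) of the
#'   training participants.
#' @param target_peak_s peak-alignment target (s).
#' @param use_age include the age normalisation factor.
#' @return a `pbif_model`.
#' @export
build_pbif_model <- function(ppifs, metas, anchors, target_peak_s = 80,
                             use_age = TRUE) {
  normed <- normalise_magnitude(ppifs, metas, use_age = use_age)
  aligned <- align_peaks(normed, target_peak_s)
  med <- median_curve(aligned)
  reg <- fit_auc_regression(ppifs, anchors)
  pbif_model(med, reg,
             training_ids = vapply(metas, `[[`, character(1), "id"),
             target_peak_s = target_peak_s)
}

#' Scale the standardised curve to an individual via the anchor sample
#'
#' The returned curve is the standardised median curve multiplied by
#' (predicted AUC / AUC of the standardised curve), the predicted AUC
#' being the regression evaluated at the participant's anchor activity.
#'
#' @param model a `pbif_model`.
#' @param anchor parent-plasma activity (Bq/mL) at the late sample, > 0.
#' @param id participant id stored in the result.
#' @return an `input_function` with provenance `"pbif"`.
#' @export
scale_pbif <- function(model, anchor, id = NA_character_) {
  if (anchor <= 0) stop("anchor activity must be > 0", call. = FALSE)
  pred <- model$regression$slope * anchor + model$regression$intercept
  if (pred <= 0) {
    stop("predicted AUC <= 0; anchored scaling impossible", call. = FALSE)
  }
  std <- model$standardised_curve
  sc <- pred / auc_trapz(std)
  input_function(std$time, std$value * sc, id = id, provenance = "pbif")
}

#' Leave-one-out population-based input functions for a whole cohort
#'
#' For each participant, builds the model from the other participants
#' (median of the others' normalised, aligned curves; regression on the
#' others' AUC/anchor pairs) and scales it with the participant's own
#' anchor sample. `loo = FALSE` fits one all-participant model instead.
#'
#' @param ppifs,metas cohort curves and metadata (same order).
#' @param anchors cohort anchor activities (Bq/mL).
#' @param loo leave-one-out protocol (default TRUE).
#' @param target_peak_s,use_age passed to [build_pbif_model()].
#' @return list of `input_function`s (provenance "pbif"), same order as
#'   the cohort.
#' @export
pbif_cohort <- function(ppifs, metas, anchors, loo = TRUE,
                        target_peak_s = 80, use_age = TRUE) {
  n <- length(ppifs)
  if (!loo) {
    model <- build_pbif_model(ppifs, metas, anchors, target_peak_s, use_age)
    return(lapply(seq_len(n), function(i) {
      scale_pbif(model, anchors[i], id = metas[[i]]$id)
    }))
  }
  lapply(seq_len(n), function(i) {
    model <- build_pbif_model(ppifs[-i], metas[-i], anchors[-i],
                              target_peak_s, use_age)
    scale_pbif(model, anchors[i], id = metas[[i]]$id)
  })
}
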