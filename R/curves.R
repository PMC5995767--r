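#' Sampled activity curve
#'
#' A `sampled_curve` is the universal container for blood, plasma and
#' tissue activity time courses: a set of `(time, activity)` pairs with
#' time in seconds post-injection and activity in Bq/mL. Times must be
#' strictly increasing and activities non-negative unless
#' `allow_negative = TRUE` (raw detector data can dip below zero from
#' background subtraction; such values are clamped later, see
#' [cross_calibrate()]).
#'
#' @param time numeric vector, seconds post-injection, strictly increasing.
#' @param activity numeric vector, Bq/mL, same length as `time`.
#' @param allow_negative keep negative activities instead of erroring.
#' @return An object of class `sampled_curve`: a data frame with columns
#'   `time` and `activity`.
#' @export
sampled_curve <- function(time, activity, allow_negative = FALSE) {
  if (length(time) != length(activity)) {
    stop("`time` and `activity` must have the same length", call. = FALSE)
  }
  if (length(time) == 0L) {
    stop("a sampled_curve needs at least one sample", call. = FALSE)
  }
  if (anyNA(time) || anyNA(activity)) {
    stop("sampled_curve does not accept missing values", call. = FALSE)
  }
  ord <- order(time)
  time <- time[ord]
  activity <- activity[ord]
  if (any(diff(time) <= 0)) {
    stop("times must be strictly increasing (no duplicates)", call. = FALSE)
  }
  if (any(time < 0)) {
    stop("negative sample times are not allowed", call. = FALSE)
  }
  if (!allow_negative && any(activity < 0)) {
    stop("negative activities; pass allow_negative = TRUE for raw detector data",
         call. = FALSE)
  }
  structure(data.frame(time = time, activity = activity),
            class = c("sampled_curve", "data.frame"))
}

#' Uniform-grid parent-plasma input function
#'
#' An `input_function` is a parent-plasma activity curve on a uniform
#' 1-second (by default) grid covering 0 to the scan end, the form every
#' kinetic computation in the package consumes. `provenance` records
#' whether the curve came from the participant's own arterial data
#' (`"ppif"`), from the population-based method (`"pbif"`), or from the
#' synthetic generator's ground truth (`"true"`).
#'
#' @param time numeric, uniform grid in seconds post-injection starting at 0.
#' @param value numeric, parent-plasma activity Bq/mL, non-negative.
#' @param id participant identifier (optional).
#' @param provenance one of `"ppif"`, `"pbif"`, `"true"`.
#' @return object of class `input_function`.
#' @export
input_function <- function(time, value, id = NA_character_,
                           provenance = c("ppif", "pbif", "true")) {
  provenance <- match.arg(provenance)
  if (length(time) != length(value) || length(time) < 2L) {
    stop("time/value must match and contain >= 2 points", call. = FALSE)
  }
  dt <- diff(time)
  if (any(abs(dt - dt[1]) > 1e-9 * dt[1])) {
    stop("input_function requires a uniform time grid", call. = FALSE)
  }
  if (abs(time[1]) > 1e-9) {
    stop("input_function grid must start at time 0", call. = FALSE)
  }
  if (any(value < 0)) {
    stop("input_function values must be non-negative", call. = FALSE)
  }
  structure(list(time = as.numeric(time), value = as.numeric(value),
                 id = id, provenance = provenance),
            class = "input_function")
}

#' @export
print.input_function <- function(x, ...) {
  cat(sprintf("<input_function %s> %d points, 0-%g s, peak %.1f Bq/mL at %g s\n",
              x$provenance, length(x$time), max(x$time),
              max(x$value), x$time[which.max(x$value)]))
  invisible(x)
}

#' Trapezoidal area under a curve
#'
#' @param time,value paired numeric vectors.
#' @return scalar AUC in (value unit) x seconds.
#' @export
auc_trapz <- function(time, value) {
  if (inherits(time, "input_function")) {
    value <- time$value
    time <- time$time
  }
  if (inherits(time, "sampled_curve")) {
    value <- time$activity
    time <- time$time
  }
  pracma::trapz(time, value)
}

#' Evaluate a curve at arbitrary times by linear interpolation
#'
#' Constant extrapolation beyond the sampled support (the first/last value
#' is held), which is the behaviour the plasma-over-blood ratio stage
#' requires.
#'
#' @param curve a `sampled_curve` or `input_function`.
#' @param at times (s) at which to evaluate.
#' @return numeric vector of interpolated values.
#' @export
curve_at <- function(curve, at) {
  if (inherits(curve, "input_function")) {
    tt <- curve$time
    vv <- curve$value
  } else {
    tt <- curve$time
    vv <- curve$activity
  }
  stats::approx(tt, vv, xout = at, rule = 2)$y
}

#' F-18 decay-correction factor
#'
#' Factor by which measured activity at time `t` after the reference time
#' must be multiplied to refer it back to the reference (injection) time.
#'
#' @param t seconds elapsed since the reference time.
#' @param half_life_s isotope half-life in seconds (default F-18, 109.77 min).
#' @return numeric factor `2^(t / half_life)`, >= 1 for positive `t`.
#' @export
decay_correction_factor <- function(t, half_life_s = 109.77 * 60) {
  2^(t / half_life_s)
}
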