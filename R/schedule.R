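#' Dynamic-scan frame schedule
#'
#' Frame timing for a dynamic acquisition. `frame_start` and
#' `frame_duration` are in seconds from the start of image acquisition;
#' the tracer is injected `injection_offset` seconds after acquisition
#' starts (30 s by default, so a short pre-injection background frame can
#' be acquired). All kinetic computation in the package works in seconds
#' post-injection; use [frame_mid_times()] / [frame_bounds()] to obtain
#' post-injection frame times.
#'
#' @param frame_start numeric, seconds from acquisition start, strictly
#'   increasing.
#' @param frame_duration numeric, seconds, all positive; frames must not
#'   overlap.
#' @param injection_offset seconds between acquisition start and injection.
#' @return object of class `frame_schedule`.
#' @export
frame_schedule <- function(frame_start, frame_duration, injection_offset = 30) {
  if (length(frame_start) != length(frame_duration) || length(frame_start) == 0L) {
    stop("frame_start and frame_duration must be non-empty and match", call. = FALSE)
  }
  if (any(frame_duration <= 0)) {
    stop("all frame durations must be positive", call. = FALSE)
  }
  if (is.unsorted(frame_start, strictly = TRUE)) {
    stop("frame starts must be strictly increasing", call. = FALSE)
  }
  ends <- frame_start + frame_duration
  if (any(frame_start[-1] < ends[-length(ends)] - 1e-9)) {
    stop("frames must not overlap", call. = FALSE)
  }
  if (injection_offset < 0) {
    stop("injection_offset must be >= 0", call. = FALSE)
  }
  structure(list(frame_start = as.numeric(frame_start),
                 frame_duration = as.numeric(frame_duration),
                 injection_offset = as.numeric(injection_offset)),
            class = "frame_schedule")
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule> %d frames, %g-%g s acquisition, injection at %g s\n",
              n_frames(x), x$frame_start[1],
              max(x$frame_start + x$frame_duration), x$injection_offset))
  invisible(x)
}

#' @rdname frame_schedule
#' @param schedule a `frame_schedule`.
#' @export
n_frames <- function(schedule) length(schedule$frame_start)

#' Frame boundaries in seconds post-injection
#'
#' @param schedule a `frame_schedule`.
#' @return data frame with columns `start`, `end`, `duration`, `mid`
#'   (all seconds post-injection; pre-injection frames have negative times).
#' @export
frame_bounds <- function(schedule) {
  start <- schedule$frame_start - schedule$injection_offset
  data.frame(start = start,
             end = start + schedule$frame_duration,
             duration = schedule$frame_duration,
             mid = start + schedule$frame_duration / 2)
}

#' @rdname frame_bounds
#' @export
frame_mid_times <- function(schedule) frame_bounds(schedule)$mid

#' Scan end in seconds post-injection
#' @param schedule a `frame_schedule`.
#' @export
scan_end <- function(schedule) max(frame_bounds(schedule)$end)

#' Default 90-minute frame schedule
#'
#' A variable-length framing scheme typical of long dynamic brain
#' acquisitions: one 30-s pre-injection background frame, then
#' progressively longer frames post-injection (6 x 10 s, 6 x 20 s,
#' 4 x 30 s, 5 x 60 s, 8 x 150 s, 12 x 300 s; 41 frames totalling
#' 90 min). Frame boundaries fall on every 10-min mark from 20 min
#' onward, so the standard SUV epochs and the 60/70/80-min truncation
#' points are all frame-aligned.
#'
#' @return a `frame_schedule` with 42 frames (incl. background frame).
#' @export
default_frame_schedule <- function() {
  dur <- c(30,                       # pre-injection background
           rep(10, 6), rep(20, 6), rep(30, 4),
           rep(60, 5), rep(150, 8), rep(300, 12))
  frame_schedule(frame_start = cumsum(c(0, dur[-length(dur)])),
                 frame_duration = dur,
                 injection_offset = 30)
}

#' Average a fine-grid curve over scan frames
#'
#' Frame value = time-average of the curve over the frame interval
#' (trapezoidal integration on the fine grid). Frames entirely before
#' injection (end <= 0) average the curve's value at 0, i.e. 0 activity
#' for curves starting at zero.
#'
#' @param time fine uniform grid, seconds post-injection, starting at 0.
#' @param value curve values on `time`.
#' @param schedule a `frame_schedule`; frames must end within the grid.
#' @return numeric vector, one mean value per frame.
#' @export
frame_average <- function(time, value, schedule) {
  fb <- frame_bounds(schedule)
  if (max(fb$end) > max(time) + 1e-6) {
    stop("curve grid does not cover the frame schedule", call. = FALSE)
  }
  dt <- time[2] - time[1]
  # cumulative trapezoid integral on the fine grid
  ct <- c(0, cumsum((value[-1] + value[-length(value)]) / 2 * dt))
  integ_to <- function(t) {
    # integral of curve from 0 to t (t clamped into the grid; <=0 -> 0)
    t <- pmin(pmax(t, time[1]), max(time))
    stats::approx(time, ct, xout = t)$y
  }
  lo <- pmax(fb$start, 0)
  hi <- pmax(fb$end, 0)
  out <- numeric(nrow(fb))
  pos <- hi > lo
  out[pos] <- (integ_to(hi[pos]) - integ_to(lo[pos])) / (hi[pos] - lo[pos])
  out
}
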