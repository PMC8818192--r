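#' Frame schedules for dynamic PET sampling
#'
#' A frame schedule is an ordered set of contiguous, non-overlapping frames
#' given as run-length blocks `list(c(n_frames, duration_s), ...)`. The
#' default is the five-minute liver protocol: 12 frames of 5 s followed by
#' 4 frames of 60 s (16 frames, 300 s total).
#'
#' @param blocks list of `c(n_frames, duration_s)` pairs.
#' @return A tibble of class `frame_schedule` with columns `start_s`,
#'   `duration_s`, `mid_s`, `end_s`.
#' @examples
#' frame_schedule()                       # 12 x 5 s + 4 x 60 s
#' frame_schedule(list(c(6, 10), c(2, 120)))
#' @export
frame_schedule <- function(blocks = list(c(12, 5), c(4, 60))) {
  stopifnot(is.list(blocks), length(blocks) >= 1L)
  durs <- unlist(purrr::map(blocks, function(b) {
    if (length(b) != 2L || b[1] < 1 || b[2] <= 0) {
      stop("each block must be c(n_frames, duration_s) with n >= 1, duration > 0")
    }
    rep(b[2], b[1])
  }))
  start <- cumsum(c(0, head(durs, -1L)))
  out <- tibble::tibble(
    start_s = start,
    duration_s = durs,
    mid_s = start + durs / 2,
    end_s = start + durs
  )
  class(out) <- c("frame_schedule", class(out))
  out
}

is_frame_schedule <- function(x) inherits(x, "frame_schedule")

#' Coerce a data frame to a frame schedule
#'
#' Accepts any data frame with `start_s` and `duration_s` columns; validates
#' contiguity (each frame starts where the previous one ends) and a first
#' start of 0.
#'
#' @param x data frame with columns `start_s`, `duration_s`.
#' @return A `frame_schedule` tibble.
#' @export
as_frame_schedule <- function(x) {
  if (is_frame_schedule(x)) return(x)
  stopifnot(is.data.frame(x), all(c("start_s", "duration_s") %in% names(x)))
  if (x$start_s[1] != 0) stop("first frame must start at 0 s")
  exp_start <- cumsum(c(0, head(x$duration_s, -1L)))
  if (any(abs(x$start_s - exp_start) > 1e-9)) {
    stop("frames must be contiguous and non-overlapping")
  }
  out <- tibble::tibble(
    start_s = x$start_s, duration_s = x$duration_s,
    mid_s = x$start_s + x$duration_s / 2, end_s = x$start_s + x$duration_s
  )
  class(out) <- c("frame_schedule", class(out))
  out
}

#' Reduce a continuous curve to per-frame values
#'
#' Each frame value is the time average of the curve over
#' `[start, start + duration]`, matching how a PET frame integrates
#' activity over its acquisition window.
#'
#' @param curve an [input_function()] spanning the schedule.
#' @param schedule a [frame_schedule()].
#' @return A tibble: the schedule plus a `value` column (one row per frame).
#' @examples
#' f <- input_function(c(0, 300), c(0, 300))  # linear ramp
#' sample_frames(f, frame_schedule())
#' @export
sample_frames <- function(curve, schedule = frame_schedule()) {
  stopifnot(inherits(curve, "input_function"))
  schedule <- as_frame_schedule(schedule)
  if (max(schedule$end_s) > span_s(curve) + 1e-9) {
    stop(sprintf("schedule extends to %g s but curve ends at %g s",
                 max(schedule$end_s), span_s(curve)))
  }
  idx <- frame_indices(schedule, curve$dt_s)
  vals <- .frame_averages(curve$value, idx$i0, idx$i1)
  out <- tibble::as_tibble(schedule)
  out$value <- vals
  out
}

# Grid indices (1-based) of the frame boundaries; boundaries must fall on
# grid nodes, which holds for the default 0.1 s grid and integer-second frames.
frame_indices <- function(schedule, dt_s) {
  i0 <- round(schedule$start_s / dt_s) + 1L
  i1 <- round(schedule$end_s / dt_s) + 1L
  if (any(abs(schedule$start_s / dt_s - (i0 - 1L)) > 1e-6) ||
      any(abs(schedule$end_s / dt_s - (i1 - 1L)) > 1e-6)) {
    stop("frame boundaries must align with the model grid")
  }
  list(i0 = as.integer(i0), i1 = as.integer(i1))
}

#' Bundle per-frame values with a schedule and group label
#'
#' @param values per-frame activity (SUV); one per frame, finite.
#' @param schedule a [frame_schedule()].
#' @param label group tag, e.g. `"HCC"` or `"liver"`.
#' @return A tibble of class `tissue_curve` with schedule columns,
#'   `value` and `label`.
#' @export
tissue_curve <- function(values, schedule = frame_schedule(), label = NA_character_) {
  schedule <- as_frame_schedule(schedule)
  if (length(values) != nrow(schedule)) {
    stop(sprintf("%d values for %d frames", length(values), nrow(schedule)))
  }
  if (any(!is.finite(values))) stop("tissue values must be finite")
  out <- tibble::as_tibble(schedule)
  out$value <- as.numeric(values)
  out$label <- label
  class(out) <- c("tissue_curve", class(out))
  out
}
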