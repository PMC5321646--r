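#' Acquisition frame schedule
#'
#' Contiguous half-open frames `[start, end)` in seconds, first frame
#' starting at 0. Frame values of a modeled curve are frame averages, so the
#' schedule also carries midpoints and durations.
#'
#' @param starts,ends Numeric vectors of frame start/end times in seconds.
#' @return An object of class `frame_schedule` with elements `starts`,
#'   `ends`, `durations` (seconds) and `mid_min` (frame midpoints, minutes).
#' @export
frame_schedule <- function(starts, ends) {
  starts <- as.numeric(starts)
  ends <- as.numeric(ends)
  if (length(starts) == 0L || length(starts) != length(ends)) {
    stop("starts and ends must be equal-length, non-empty")
  }
  if (starts[1] != 0) stop("first frame must start at 0 s")
  if (any(ends <= starts)) stop("frame durations must be positive")
  if (length(starts) > 1L && any(abs(starts[-1L] - ends[-length(ends)]) > 1e-9)) {
    stop("frames must be contiguous")
  }
  structure(list(starts = starts, ends = ends,
                 durations = ends - starts,
                 mid_min = (starts + ends) / 2 / 60),
            class = "frame_schedule")
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule> %d frames, %.0f s total\n",
              length(x$starts), x$ends[length(x$ends)]))
  invisible(x)
}

#' Default 60-min 21-frame schedule
#'
#' The standard dynamic acquisition used throughout: 6 x 10, 4 x 30, 2 x 60,
#' 1 x 120, 1 x 180, 4 x 300 and 3 x 600 s frames (21 frames, 3600 s).
#'
#' @return A [frame_schedule()].
#' @export
default_frame_schedule <- function() {
  durs <- c(rep(10, 6), rep(30, 4), rep(60, 2), 120, 180, rep(300, 4),
            rep(600, 3))
  ends <- cumsum(durs)
  frame_schedule(c(0, ends[-length(ends)]), ends)
}

# Internal fine time grid (minutes) aligned to the frame boundaries.
# dt_s must divide every frame boundary; 0.5 s does for standard schedules.
fine_grid <- function(schedule, dt_s = 0.5) {
  total <- schedule$ends[length(schedule$ends)]
  seq(0, total, by = dt_s) / 60
}

# Frame-averaging weight matrix W (n_frames x n_grid): trapezoidal average
# of a fine-grid curve over each frame, divided by frame duration.
frame_average_matrix <- function(schedule, dt_s = 0.5) {
  t_fine <- fine_grid(schedule, dt_s)
  n <- length(t_fine)
  nf <- length(schedule$starts)
  W <- matrix(0, nf, n)
  for (i in seq_len(nf)) {
    i0 <- round(schedule$starts[i] / dt_s) + 1L
    i1 <- round(schedule$ends[i] / dt_s) + 1L
    if (i1 > n || abs((i0 - 1L) * dt_s - schedule$starts[i]) > 1e-9 ||
        abs((i1 - 1L) * dt_s - schedule$ends[i]) > 1e-9) {
      stop("dt_s must divide all frame boundaries")
    }
    w <- rep(1, i1 - i0 + 1L)
    w[c(1L, length(w))] <- 0.5
    W[i, i0:i1] <- w * dt_s / (schedule$ends[i] - schedule$starts[i])
  }
  W
}

# Frame-average a fine-grid vector.
frame_average <- function(y, W) as.numeric(W %*% y)
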