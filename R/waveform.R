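# Complex spike waveform measurements: normalized averaging, first-peak
# half-maximum width, rectified spike area over the -0.5..+3 ms window.

new_waveform <- function(time_ms, amplitude) {
  dt <- diff(time_ms)
  if (length(dt) < 2L || any(!is.finite(dt)) ||
      max(abs(dt - dt[1L])) > 1e-9 * max(abs(dt[1L]), 1e-12)) {
    stop_validation("waveform time axis must be uniformly sampled")
  }
  structure(list(time_ms = as.numeric(time_ms),
                 amplitude = as.numeric(amplitude),
                 sample_period_ms = dt[1L]),
            class = "average_waveform")
}

#' Construct a waveform on a uniform millisecond time axis
#'
#' Wraps a time/amplitude pair (time in ms relative to spike onset, onset at
#' 0) for use with [half_max_width()] and [spike_area()]. No normalization
#' is applied; use [average_waveform()] to average and peak-normalize
#' snippets.
#'
#' @param time_ms Uniformly spaced sample times (ms), onset at 0.
#' @param amplitude Amplitudes (arbitrary units).
#' @return An object of class `average_waveform`.
#' @export
waveform <- function(time_ms, amplitude) {
  if (length(time_ms) != length(amplitude)) {
    stop_validation("`time_ms` and `amplitude` must have the same length")
  }
  new_waveform(time_ms, amplitude)
}

#' Average waveform snippets and peak-normalize
#'
#' Averages onset-aligned snippets sample-wise and scales the result so that
#' its maximum absolute amplitude is 1. Snippets must share one uniform time
#' axis (alignment at spike onset, t = 0); the averaging suppresses
#' independent noise by `1/sqrt(n)`.
#'
#' @param snippets Either the object returned by [generate_cs_waveform()] or
#'   a numeric matrix with one column per snippet.
#' @param time_ms Sample times (ms); required when `snippets` is a matrix.
#' @return An `average_waveform` with `max(abs(amplitude)) == 1`.
#' @export
average_waveform <- function(snippets, time_ms = NULL) {
  if (inherits(snippets, "cs_waveform_set")) {
    time_ms <- snippets$time_ms
    snippets <- snippets$snippets
  }
  if (is.null(dim(snippets))) snippets <- matrix(snippets, ncol = 1L)
  if (ncol(snippets) < 1L || nrow(snippets) < 3L) {
    stop_validation("need at least one snippet with at least 3 samples")
  }
  if (is.null(time_ms) || length(time_ms) != nrow(snippets)) {
    stop_validation("`time_ms` must match the snippet sample count")
  }
  avg <- rowMeans(snippets)
  peak <- max(abs(avg))
  if (peak == 0) stop_validation("average waveform is identically zero")
  new_waveform(time_ms, avg / peak)
}

# First local maximum of the positive-rectified signal at t >= 0 exceeding
# half the global maximum (guards against pre-onset noise peaks).
first_peak_index <- function(wf) {
  p <- pmax(wf$amplitude, 0)
  gmax <- max(p)
  if (gmax <= 0) stop_undefined_metric("waveform has no positive excursion")
  n <- length(p)
  candidates <- which(wf$time_ms >= 0 & p > 0.5 * gmax)
  for (i in candidates) {
    left <- if (i == 1L) -Inf else p[i - 1L]
    right <- if (i == n) -Inf else p[i + 1L]
    if (p[i] >= left && p[i] >= right) return(i)
  }
  stop_undefined_metric("no first peak found after onset")
}

#' Half-maximum width of the first waveform peak
#'
#' Width of the first positive peak at half its maximum amplitude (FWHM),
#' with linear interpolation between samples at the upward and downward
#' half-maximum crossings. Invariant under amplitude scaling.
#'
#' @param wf An `average_waveform` (see [waveform()], [average_waveform()]).
#' @return Width in ms.
#' @export
half_max_width <- function(wf) {
  stopifnot(inherits(wf, "average_waveform"))
  a <- wf$amplitude
  t <- wf$time_ms
  i <- first_peak_index(wf)
  half <- a[i] / 2
  # falling crossing to the right of the peak
  right <- NULL
  if (i < length(a)) {
    for (j in i:(length(a) - 1L)) {
      if (a[j] >= half && a[j + 1L] < half) {
        right <- t[j] + (half - a[j]) / (a[j + 1L] - a[j]) * (t[j + 1L] - t[j])
        break
      }
    }
  }
  if (is.null(right)) {
    stop_undefined_metric("no falling half-maximum crossing after the first peak")
  }
  left <- NULL
  if (i > 1L) {
    for (j in i:2L) {
      if (a[j] >= half && a[j - 1L] < half) {
        left <- t[j] + (half - a[j]) / (a[j - 1L] - a[j]) * (t[j - 1L] - t[j])
        break
      }
    }
  }
  if (is.null(left)) {
    stop_undefined_metric("no rising half-maximum crossing before the first peak")
  }
  right - left
}

trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}

#' Rectified spike area
#'
#' Trapezoidal integral of the rectified waveform `|amplitude|` over exactly
#' the window 0.5 ms before to 3 ms after spike onset (onset at t = 0), the
#' conventional complex spike area window. Amplitudes at the window edges
#' are linearly interpolated if no sample falls exactly on them.
#'
#' @param wf An `average_waveform` covering at least `[-0.5, 3]` ms.
#' @param window_ms Integration window (ms), default `c(-0.5, 3)`.
#' @return Area in amplitude-units x ms.
#' @export
spike_area <- function(wf, window_ms = c(-0.5, 3)) {
  stopifnot(inherits(wf, "average_waveform"))
  t <- wf$time_ms
  tol <- wf$sample_period_ms / 2
  if (t[1L] > window_ms[1L] + tol || t[length(t)] < window_ms[2L] - tol) {
    stop_validation(sprintf(
      "waveform covers [%g, %g] ms but the area window is [%g, %g] ms",
      t[1L], t[length(t)], window_ms[1L], window_ms[2L]))
  }
  r <- abs(wf$amplitude)
  lo <- max(window_ms[1L], t[1L])
  hi <- min(window_ms[2L], t[length(t)])
  inside <- t > lo & t < hi
  tt <- c(lo, t[inside], hi)
  yy <- c(stats::approx(t, r, xout = lo)$y, r[inside],
          stats::approx(t, r, xout = hi)$y)
  trapz(tt, yy)
}

#' @export
print.average_waveform <- function(x, ...) {
  cat(sprintf("<average_waveform> %d samples, [%g, %g] ms, dt = %g ms\n",
              length(x$time_ms), x$time_ms[1L], x$time_ms[length(x$time_ms)],
              x$sample_period_ms))
  invisible(x)
}
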