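# Per-cell spike-train statistics and inclusion filters.

#' Mean firing rate
#'
#' Event count divided by recording duration. An empty train has rate 0.
#'
#' @param times Event times (s).
#' @param duration Recording duration (s), > 0.
#' @return Rate in Hz.
#' @export
firing_rate <- function(times, duration) {
  check_number(duration, "duration", lower = 0, strict_lower = TRUE,
               stop_fun = stop_invalid_input)
  length(times) / duration
}

#' Coefficient of variation of interspike intervals
#'
#' Sample standard deviation (n - 1 denominator) of the interspike
#' intervals divided by their mean: a whole-recording regularity measure,
#' 0 for a perfectly regular train and 1 in expectation for a Poisson
#' train.
#'
#' @param times Event times (s), at least 3 events (2 ISIs).
#' @return Dimensionless CV.
#' @export
isi_cv <- function(times) {
  if (length(times) < 3L) {
    stop_undefined_metric("CV needs at least 3 events (2 interspike intervals)")
  }
  isi <- diff(times)
  sd(isi) / mean(isi)
}

#' Mean CV2 of adjacent interspike intervals
#'
#' The mean over consecutive interval pairs of
#' `2 * |ISI[n+1] - ISI[n]| / (ISI[n+1] + ISI[n])`: a short-timescale
#' regularity measure, 0 for a regular train, 1 in expectation for a
#' Poisson train, bounded in `[0, 2)`. One term needs three spikes; a
#' warning is emitted when fewer than 100 terms are available.
#'
#' @param times Event times (s), at least 3 events.
#' @return Dimensionless mean CV2.
#' @export
mean_cv2 <- function(times) {
  if (length(times) < 3L) {
    stop_undefined_metric("mean CV2 needs at least 3 events (one adjacent ISI pair)")
  }
  isi <- diff(times)
  n <- length(isi)
  cv2 <- 2 * abs(isi[-1L] - isi[-n]) / (isi[-1L] + isi[-n])
  if (length(cv2) < 100L) {
    warning(sprintf("mean CV2 averaged over only %d adjacent-interval terms",
                    length(cv2)), call. = FALSE)
  }
  mean(cv2)
}

#' Climbing fiber pause
#'
#' The minimum, over all complex spikes that are followed by at least one
#' simple spike, of the latency from the complex spike to the next simple
#' spike. Complex spikes with no subsequent simple spike are skipped.
#' `aggregate = "mean"` returns the mean of the per-CS latencies instead of
#' the minimum.
#'
#' @param ss_times Simple spike times (s), sorted.
#' @param cs_times Complex spike times (s), sorted.
#' @param aggregate `"min"` (default) or `"mean"`.
#' @return Pause in ms.
#' @export
climbing_fiber_pause <- function(ss_times, cs_times,
                                 aggregate = c("min", "mean")) {
  aggregate <- match.arg(aggregate)
  if (length(cs_times) == 0L) {
    stop_undefined_metric("climbing fiber pause needs at least one complex spike")
  }
  nxt <- findInterval(cs_times, ss_times) + 1L
  valid <- nxt <= length(ss_times)
  if (!any(valid)) {
    stop_undefined_metric("no complex spike is followed by a simple spike")
  }
  lat <- ss_times[nxt[valid]] - cs_times[valid]
  1000 * if (aggregate == "min") min(lat) else mean(lat)
}

#' Firing rate stability profile in 30-s bins
#'
#' Bins the recording into consecutive `bin_s` windows (`[k*bin, (k+1)*bin)`;
#' a trailing partial bin is dropped), computes the rate per bin, and
#' normalizes each bin by the whole-recording rate. Bins deviating more
#' than `flag_threshold` (default 20%) from the whole-recording average are
#' flagged.
#'
#' @param times Event times (s).
#' @param duration Recording duration (s); must cover at least two bins.
#' @param bin_s Bin width (s), default 30.
#' @param flag_threshold Fractional deviation that flags a bin, default 0.2.
#' @return A data frame with columns `bin_start_s`, `rate_hz`, `normalized`,
#'   `flagged`.
#' @export
stability_profile <- function(times, duration, bin_s = 30,
                              flag_threshold = 0.2) {
  check_number(bin_s, "bin_s", lower = 0, strict_lower = TRUE)
  if (!is.numeric(duration) || duration < 2 * bin_s) {
    stop_undefined_metric(sprintf(
      "stability profile needs at least two %g-s bins", bin_s))
  }
  n_bins <- floor(duration / bin_s)
  starts <- (seq_len(n_bins) - 1L) * bin_s
  counts <- vapply(starts, function(s) {
    sum(times >= s & times < s + bin_s)
  }, numeric(1))
  overall <- length(times) / duration
  rate <- counts / bin_s
  normalized <- if (overall > 0) rate / overall else rep(NA_real_, n_bins)
  data.frame(bin_start_s = starts, rate_hz = rate, normalized = normalized,
             flagged = !is.na(normalized) &
               abs(normalized - 1) > flag_threshold)
}

#' Apply context-dependent inclusion criteria
#'
#' Implements the recording quality filters: in vivo recordings must last
#' at least 120 s and have stable spike amplitude (no amplitude sample
#' deviating more than 20% from the median); in vitro recordings must last
#' at least 120 s, have whole-recording CV < 0.2, and change their rate by
#' less than 20% between the first and last 30 s; drug and wash-in
#' recordings must last at least 60 s.
#'
#' @param recording A [spike_train_recording()].
#' @param cv Optional precomputed simple spike CV (computed from the
#'   recording when missing).
#' @return A list with `included` (logical) and `reasons` (character vector
#'   of violated criteria, empty when included).
#' @export
apply_inclusion_criteria <- function(recording, cv = NULL) {
  stopifnot(inherits(recording, "spike_train_recording"))
  ctx <- recording$context
  reasons <- character()
  if (ctx == "in_vivo") {
    if (recording$duration < 120) reasons <- c(reasons, "duration")
    amp <- recording$amplitude_series
    if (!is.null(amp) && nrow(amp) > 0) {
      med <- median(amp$amplitude)
      if (med <= 0 || max(abs(amp$amplitude - med)) / med > 0.2) {
        reasons <- c(reasons, "amplitude")
      }
    }
  } else if (ctx == "in_vitro") {
    if (recording$duration < 120) reasons <- c(reasons, "duration")
    if (is.null(cv)) {
      cv <- tryCatch(isi_cv(recording$ss_times), zt_undefined_metric = function(e) NA_real_)
    }
    if (is.na(cv) || cv >= 0.2) reasons <- c(reasons, "cv")
    if (recording$duration >= 60) {
      first <- sum(recording$ss_times < 30) / 30
      last <- sum(recording$ss_times >= recording$duration - 30) / 30
      if (first <= 0 || abs(last - first) / first >= 0.2) {
        reasons <- c(reasons, "rate_drift")
      }
    }
  } else if (ctx %in% c("drug", "washin")) {
    if (recording$duration < 60) reasons <- c(reasons, "duration")
  } else {
    stop_invalid_config(sprintf("unknown recording context '%s'", ctx))
  }
  list(included = length(reasons) == 0L, reasons = reasons)
}

#' Per-cell metrics row
#'
#' Computes the full set of per-cell statistics for one recording: SS and
#' CS firing rate, SS CV and mean CV2, CS CV, climbing fiber pause, and the
#' inclusion verdict. Metrics that are undefined for the data (too few
#' events) are returned as `NA`.
#'
#' @param recording A [spike_train_recording()].
#' @return A one-row data frame.
#' @export
cell_metrics <- function(recording) {
  stopifnot(inherits(recording, "spike_train_recording"))
  safe <- function(expr) {
    tryCatch(suppressWarnings(expr),
             zt_undefined_metric = function(e) NA_real_)
  }
  ss <- recording$ss_times
  cs <- recording$cs_times
  d <- recording$duration
  verdict <- apply_inclusion_criteria(recording)
  data.frame(
    cell_id = recording$cell_id,
    zebrin_identity = recording$zebrin_identity,
    lobule = recording$lobule,
    context = recording$context,
    duration = d,
    ss_rate = firing_rate(ss, d),
    cs_rate = firing_rate(cs, d),
    ss_cv = safe(isi_cv(ss)),
    ss_mean_cv2 = safe(mean_cv2(ss)),
    cs_cv = safe(isi_cv(cs)),
    cf_pause_ms = safe(climbing_fiber_pause(ss, cs)),
    included = verdict$included,
    exclusion_reasons = paste(verdict$reasons, collapse = ";"),
    stringsAsFactors = FALSE)
}

#' Metrics table for a cohort
#'
#' @param recordings A list of [spike_train_recording()] objects, or the
#'   list returned by [generate_population()].
#' @return A data frame with one [cell_metrics()] row per cell.
#' @export
cohort_metrics <- function(recordings) {
  if (is.list(recordings) && !is.null(recordings$recordings)) {
    recordings <- recordings$recordings
  }
  do.call(rbind, lapply(recordings, cell_metrics))
}
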