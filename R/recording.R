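#' A labelled spike-train recording from one Purkinje cell
#'
#' Container for one cell's labelled event times: sorted simple spike (SS)
#' and complex spike (CS) times in seconds from recording start, together
#' with the metadata the analysis stages need (zebrin identity, lobule,
#' experimental context, duration) and, optionally, a relative spike
#' amplitude series for stability screening and generator ground truth.
#'
#' @param cell_id Cell identifier string.
#' @param zebrin_identity `"positive"`, `"negative"` or `"unknown"`.
#' @param lobule Lobule label (free string, e.g. `"III"`, `"X"`, `"CrI-II"`),
#'   or `NA`.
#' @param context One of `"in_vivo"`, `"in_vitro"`, `"drug"`, `"washin"`.
#' @param duration Recording duration (s), > 0.
#' @param ss_times,cs_times Strictly increasing event times in `[0, duration]`
#'   (s).
#' @param amplitude_series Optional data frame with columns `time_s` and
#'   `amplitude` (relative units).
#' @param ground_truth Optional list of generator metadata (true response
#'   type, drawn rates, seed).
#' @return An object of class `spike_train_recording`.
#' @export
spike_train_recording <- function(cell_id,
                                  zebrin_identity = "unknown",
                                  lobule = NA_character_,
                                  context = "in_vivo",
                                  duration,
                                  ss_times = numeric(),
                                  cs_times = numeric(),
                                  amplitude_series = NULL,
                                  ground_truth = NULL) {
  if (!is.character(cell_id) || length(cell_id) != 1L || !nzchar(cell_id)) {
    stop_validation("`cell_id` must be a non-empty string")
  }
  zebrin_identity <- match.arg(zebrin_identity, ZEBRIN_IDENTITIES)
  context <- match.arg(context, RECORDING_CONTEXTS)
  check_number(duration, "duration", lower = 0, strict_lower = TRUE,
               stop_fun = stop_validation)
  check_train(ss_times, "ss_times", duration, cell_id)
  check_train(cs_times, "cs_times", duration, cell_id)
  if (!is.null(amplitude_series)) {
    if (!is.data.frame(amplitude_series) ||
        !all(c("time_s", "amplitude") %in% names(amplitude_series))) {
      stop_validation("`amplitude_series` must have columns time_s and amplitude")
    }
  }
  structure(
    list(cell_id = cell_id, zebrin_identity = zebrin_identity,
         lobule = lobule, context = context, duration = duration,
         ss_times = as.numeric(ss_times), cs_times = as.numeric(cs_times),
         amplitude_series = amplitude_series, ground_truth = ground_truth),
    class = "spike_train_recording")
}

check_train <- function(times, name, duration, cell_id) {
  if (length(times) == 0L) return(invisible(times))
  if (!is.numeric(times) || anyNA(times)) {
    stop_validation(sprintf("[%s] `%s` must be numeric without NA", cell_id, name))
  }
  bad <- which(times < 0 | times > duration)
  if (length(bad)) {
    stop_validation(sprintf(
      "[%s] `%s` entry %d (t = %g s) lies outside [0, %g]",
      cell_id, name, bad[1L], times[bad[1L]], duration))
  }
  bad <- which(diff(times) <= 0)
  if (length(bad)) {
    stop_validation(sprintf(
      "[%s] `%s` is not strictly increasing at entry %d (t = %g s)",
      cell_id, name, bad[1L] + 1L, times[bad[1L] + 1L]))
  }
  invisible(times)
}

#' @export
print.spike_train_recording <- function(x, ...) {
  cat(sprintf("<spike_train_recording> %s (%s, zebrin %s, lobule %s)\n",
              x$cell_id, x$context, x$zebrin_identity,
              ifelse(is.na(x$lobule), "?", x$lobule)))
  cat(sprintf("  duration %g s | %d SS (%.1f Hz) | %d CS (%.2f Hz)\n",
              x$duration,
              length(x$ss_times), length(x$ss_times) / x$duration,
              length(x$cs_times), length(x$cs_times) / x$duration))
  if (!is.null(x$ground_truth)) {
    cat(sprintf("  ground truth: type %s, SS %.1f Hz, CS %.2f Hz\n",
                x$ground_truth$type, x$ground_truth$ss_rate,
                x$ground_truth$cs_rate))
  }
  invisible(x)
}
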