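RESPONSE_TYPES <- c("normal", "facilitation", "suppression", "oscillation")
ZEBRIN_IDENTITIES <- c("positive", "negative", "unknown")
RECORDING_CONTEXTS <- c("in_vivo", "in_vitro", "drug", "washin")

#' Default post-complex-spike modulation kernels
#'
#' Multiplicative rate kernels applied to the simple spike train after the
#' enforced climbing fiber pause, one per response type. The facilitation
#' kernel raises the rate by 50% for 50 ms, the suppression kernel halves it
#' for 100 ms, and the oscillation kernel is a damped cosine (40% depth,
#' 100 ms decay time constant) whose frequency defaults to the cell's own
#' simple spike rate (`frequency_hz = NA`). These shapes are generator
#' conventions chosen to be recoverable by [classify_response_type()]; all
#' parameters can be overridden.
#'
#' @return A named list with `facilitation`, `suppression` and `oscillation`
#'   components.
#' @export
default_kernels <- function() {
  list(
    facilitation = list(amplitude = 0.5, duration_ms = 50),
    suppression = list(amplitude = -0.5, duration_ms = 100),
    oscillation = list(depth = 0.4, decay_ms = 100, duration_ms = 300,
                       frequency_hz = NA_real_)
  )
}

#' Generative parameters for one synthetic Purkinje cell population
#'
#' A cell preset fixes the across-cell distribution from which individual
#' synthetic cells are drawn: the simple spike (SS) rate is sampled once per
#' cell from Normal(`ss_rate_mean`, `ss_rate_sd`) truncated at 1 Hz, the
#' complex spike (CS) rate likewise from Normal(`cs_rate`, `cs_rate_sd`)
#' truncated at 0.05 Hz. Within a cell the SS train is a gamma renewal
#' process with shape `ss_shape` (shape 1 = Poisson; larger shapes are more
#' regular, lowering CV and mean CV2), the CS train is Poisson with a 20 ms
#' absolute refractory period, every CS deletes all SS in the following
#' `cf_pause_ms`, and the post-pause SS rate is modulated by the kernel of
#' the cell's response type, drawn from `response_type_probs`.
#'
#' @param zebrin_identity `"positive"`, `"negative"` or `"unknown"`.
#' @param ss_rate_mean,ss_rate_sd Across-cell mean and SD of the SS rate (Hz).
#' @param ss_shape Gamma renewal shape (>= 1, dimensionless); controls
#'   within-cell regularity.
#' @param cs_rate,cs_rate_sd Across-cell mean and SD of the CS rate (Hz).
#' @param cf_pause_ms Enforced SS-free interval after each CS (ms).
#' @param response_type_probs Probability vector over the four response types
#'   (named `normal`, `facilitation`, `suppression`, `oscillation`); must sum
#'   to 1.
#' @param kernel_params Kernel parameters, see [default_kernels()].
#' @param waveform_params Target complex spike waveform metrics:
#'   `hmw_ms` (first-peak half-maximum width) and `area` (rectified area over
#'   -0.5 to +3 ms, dimensionless x ms).
#' @param amplitude_drift Fractional linear drop of spike amplitude over the
#'   recording (0 = stable); drives the amplitude-stability inclusion filter.
#' @return An object of class `cell_preset`.
#' @seealso [zebrin_preset()] for presets at the published group parameters.
#' @export
cell_preset <- function(zebrin_identity = "unknown",
                        ss_rate_mean,
                        ss_rate_sd,
                        ss_shape = 4,
                        cs_rate,
                        cs_rate_sd = 0,
                        cf_pause_ms = 10,
                        response_type_probs = c(normal = 1, facilitation = 0,
                                                suppression = 0, oscillation = 0),
                        kernel_params = default_kernels(),
                        waveform_params = list(hmw_ms = 0.3, area = 0.6),
                        amplitude_drift = 0) {
  zebrin_identity <- match.arg(zebrin_identity, ZEBRIN_IDENTITIES)
  check_number(ss_rate_mean, "ss_rate_mean", lower = 0, strict_lower = TRUE)
  check_number(ss_rate_sd, "ss_rate_sd", lower = 0)
  check_number(ss_shape, "ss_shape", lower = 1)
  check_number(cs_rate, "cs_rate", lower = 0, strict_lower = TRUE)
  check_number(cs_rate_sd, "cs_rate_sd", lower = 0)
  check_number(cf_pause_ms, "cf_pause_ms", lower = 0)
  check_number(amplitude_drift, "amplitude_drift", lower = 0, upper = 1)
  if (ss_rate_mean <= cs_rate) {
    stop_invalid_config("`ss_rate_mean` must exceed `cs_rate`")
  }
  p <- response_type_probs
  if (length(p) != 4L || is.null(names(p)) || !setequal(names(p), RESPONSE_TYPES)) {
    stop_invalid_config(
      "`response_type_probs` must be a length-4 vector named normal, facilitation, suppression, oscillation")
  }
  p <- p[RESPONSE_TYPES]
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop_invalid_config("`response_type_probs` must be non-negative and sum to 1 (within 1e-9)")
  }
  structure(
    list(zebrin_identity = zebrin_identity,
         ss_rate_mean = ss_rate_mean, ss_rate_sd = ss_rate_sd,
         ss_shape = ss_shape,
         cs_rate = cs_rate, cs_rate_sd = cs_rate_sd,
         cf_pause_ms = cf_pause_ms,
         response_type_probs = p,
         kernel_params = utils::modifyList(default_kernels(), kernel_params),
         waveform_params = waveform_params,
         amplitude_drift = amplitude_drift),
    class = "cell_preset")
}

#' Presets at the published zebrin-group parameters
#'
#' Convenience presets reproducing the across-cell statistics reported for
#' awake-mouse recordings: zebrin-negative cells fire simple spikes at
#' 96.1 +/- 15.4 Hz with complex spikes at 1.13 +/- 0.25 Hz, zebrin-positive
#' cells at 61.4 +/- 19.3 Hz and 0.92 +/- 0.28 Hz. Facilitation-type
#' post-CS responses occur in 17/47 zebrin-negative and 6/57 zebrin-positive
#' cells; suppression and oscillation types occur only in zebrin-positive
#' cells (their preset probabilities are figure-informed estimates, the
#' exact counts not being printed).
#'
#' @param identity `"negative"` or `"positive"`.
#' @return A [cell_preset()].
#' @export
zebrin_preset <- function(identity = c("negative", "positive")) {
  identity <- match.arg(identity)
  if (identity == "negative") {
    cell_preset(
      zebrin_identity = "negative",
      ss_rate_mean = 96.1, ss_rate_sd = 15.4, ss_shape = 4,
      cs_rate = 1.13, cs_rate_sd = 0.25, cf_pause_ms = 10,
      response_type_probs = c(normal = 30 / 47, facilitation = 17 / 47,
                              suppression = 0, oscillation = 0),
      waveform_params = list(hmw_ms = 0.25, area = 0.55))
  } else {
    cell_preset(
      zebrin_identity = "positive",
      ss_rate_mean = 61.4, ss_rate_sd = 19.3, ss_shape = 4,
      cs_rate = 0.92, cs_rate_sd = 0.28, cf_pause_ms = 10,
      response_type_probs = c(normal = 38 / 57, facilitation = 6 / 57,
                              suppression = 8 / 57, oscillation = 5 / 57),
      waveform_params = list(hmw_ms = 0.35, area = 0.75))
  }
}

#' Drug wash-in specification
#'
#' Describes an exponential approach of the simple spike rate towards a
#' reduced plateau after a drug reaches the recording chamber:
#' `r(t) = r0 * (1 - effect_fraction * (1 - exp(-(t - drug_onset_s) / time_constant_s)))`
#' for `t >= drug_onset_s`.
#'
#' @param drug_onset_s Seconds from recording start at which the drug arrives.
#' @param effect_fraction Fractional rate reduction at plateau, in `[0, 1]`.
#' @param time_constant_s Time constant of the exponential approach (s).
#' @return An object of class `washin_spec`.
#' @export
washin_spec <- function(drug_onset_s, effect_fraction, time_constant_s) {
  check_number(drug_onset_s, "drug_onset_s", lower = 0)
  check_number(effect_fraction, "effect_fraction", lower = 0, upper = 1)
  check_number(time_constant_s, "time_constant_s", lower = 0, strict_lower = TRUE)
  structure(list(drug_onset_s = drug_onset_s,
                 effect_fraction = effect_fraction,
                 time_constant_s = time_constant_s),
            class = "washin_spec")
}

#' Configuration of a synthetic cohort
#'
#' @param presets A list of entries `list(preset = <cell_preset>, n_cells = n)`.
#' @param duration Recording duration per cell (s).
#' @param seed Integer master seed; cell `k` of the cohort is generated with
#'   seed `seed + k`, so cohorts are reproducible and any single cell can be
#'   re-generated in isolation.
#' @param washin Optional [washin_spec()]; when given, every cell is a
#'   wash-in series (context `"washin"`).
#' @return An object of class `population_config`.
#' @export
population_config <- function(presets, duration = 120, seed = 1, washin = NULL) {
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  check_number(seed, "seed")
  if (!is.list(presets) || length(presets) == 0L) {
    stop_invalid_config("`presets` must be a non-empty list of (preset, n_cells) entries")
  }
  for (entry in presets) {
    if (!is.list(entry) || !inherits(entry$preset, "cell_preset")) {
      stop_invalid_config("each presets entry must contain a `preset` of class cell_preset")
    }
    n <- entry$n_cells
    if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1 || n != round(n)) {
      stop_invalid_config("each presets entry must contain an integer `n_cells` >= 1")
    }
  }
  if (!is.null(washin) && !inherits(washin, "washin_spec")) {
    stop_invalid_config("`washin` must be a washin_spec or NULL")
  }
  structure(list(presets = presets, duration = duration,
                 seed = as.integer(seed), washin = washin),
            class = "population_config")
}

#' @export
print.cell_preset <- function(x, ...) {
  cat(sprintf("<cell_preset> zebrin %s\n", x$zebrin_identity))
  cat(sprintf("  SS: %.1f +/- %.1f Hz (gamma shape %.1f)   CS: %.2f +/- %.2f Hz\n",
              x$ss_rate_mean, x$ss_rate_sd, x$ss_shape, x$cs_rate, x$cs_rate_sd))
  cat(sprintf("  CF pause: %g ms   amplitude drift: %g\n",
              x$cf_pause_ms, x$amplitude_drift))
  cat("  response type probs:",
      paste(sprintf("%s %.2f", names(x$response_type_probs),
                    x$response_type_probs), collapse = ", "), "\n")
  invisible(x)
}
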