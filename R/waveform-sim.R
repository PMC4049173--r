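# Synthetic complex spike waveform snippets with controlled first-peak
# half-maximum width and rectified area.

# Noiseless template on [-0.5, 3] ms: a positive gaussian first lobe whose
# FWHM is the requested HMW and whose 10%-of-peak rising crossing sits at
# t = 0 (the spike onset convention), followed by smaller after-components
# (a trough and a late bump) whose common scale is solved so that the
# rectified area over the window matches the requested target.
cs_waveform_template <- function(hmw_ms, area, sample_period_ms = 0.02) {
  check_number(hmw_ms, "hmw_ms", lower = 0, strict_lower = TRUE)
  check_number(area, "area", lower = 0, strict_lower = TRUE)
  check_number(sample_period_ms, "sample_period_ms", lower = 0,
               strict_lower = TRUE)
  if (hmw_ms >= 1.5) {
    stop_invalid_config("target HMW must be well below the 3.5 ms snippet span")
  }
  t <- seq(-0.5, 3, by = sample_period_ms)
  sigma <- hmw_ms / (2 * sqrt(2 * log(2)))
  mu <- sigma * sqrt(2 * log(10)) # 10%-of-peak crossing at t = 0
  g <- exp(-(t - mu)^2 / (2 * sigma^2))
  after <- -0.55 * exp(-(t - (mu + 5 * sigma))^2 / (2 * (1.5 * sigma)^2)) +
    0.35 * exp(-(t - (mu + 8 * sigma))^2 / (2 * (2.5 * sigma)^2))
  a_g <- trapz(t, abs(g))
  if (area < a_g - 1e-9) {
    stop_invalid_config(sprintf(
      "target area %g is below the first-peak area %.3g; infeasible HMW/area pair",
      area, a_g))
  }
  # solve the after-component scale so that the rectified area of the full
  # template (with component overlap) matches the target exactly
  w_max <- 0.95 / 0.55 # keeps the first peak the global extremum
  area_at <- function(w) trapz(t, abs(g + w * after))
  w <- if (area_at(0) >= area) {
    0
  } else if (area_at(w_max) < area) {
    stop_invalid_config(
      "target area requires after-components rivalling the first peak; infeasible HMW/area pair")
  } else {
    stats::uniroot(function(w) area_at(w) - area, c(0, w_max),
                   tol = 1e-10)$root
  }
  list(time_ms = t, template = g + w * after, sample_period_ms = sample_period_ms)
}

#' Generate synthetic complex spike waveform snippets
#'
#' Builds a noiseless complex spike template whose first positive peak has
#' the requested half-maximum width and whose rectified area over
#' `[-0.5, 3]` ms matches the requested target, then draws `n_snippets`
#' noisy copies (independent gaussian noise per sample, SD `noise_sd` in
#' units of the unit peak). Averaging the snippets with
#' [average_waveform()] suppresses the noise by `1/sqrt(n_snippets)`.
#'
#' @param params List with `hmw_ms` (target first-peak FWHM, ms) and `area`
#'   (target rectified area, dimensionless x ms); the `waveform_params`
#'   field of a [cell_preset()] has this shape.
#' @param seed Integer seed.
#' @param n_snippets Number of noisy snippets.
#' @param noise_sd Noise SD relative to the unit peak.
#' @param sample_period_ms Sampling period (ms); the default 0.02 ms
#'   corresponds to 50 kHz acquisition.
#' @return An object of class `cs_waveform_set`: list with `time_ms`,
#'   `template` (noiseless), `snippets` (matrix, one column per snippet) and
#'   `sample_period_ms`.
#' @export
generate_cs_waveform <- function(params, seed, n_snippets = 100,
                                 noise_sd = 0.1, sample_period_ms = 0.02) {
  if (!is.list(params) || is.null(params$hmw_ms) || is.null(params$area)) {
    stop_invalid_config("`params` must be a list with hmw_ms and area")
  }
  check_number(n_snippets, "n_snippets", lower = 1)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(seed, "seed")
  tpl <- cs_waveform_template(params$hmw_ms, params$area, sample_period_ms)
  set.seed(as.integer(seed))
  n <- length(tpl$time_ms)
  snips <- matrix(tpl$template, nrow = n, ncol = n_snippets) +
    matrix(rnorm(n * n_snippets, 0, noise_sd), nrow = n)
  structure(list(time_ms = tpl$time_ms, template = tpl$template,
                 snippets = snips, sample_period_ms = tpl$sample_period_ms),
            class = "cs_waveform_set")
}

#' @export
print.cs_waveform_set <- function(x, ...) {
  cat(sprintf("<cs_waveform_set> %d snippets x %d samples, dt = %g ms\n",
              ncol(x$snippets), nrow(x$snippets), x$sample_period_ms))
  invisible(x)
}
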