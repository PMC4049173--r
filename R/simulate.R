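# Point-process generator: gamma-renewal simple spikes, refractory-Poisson
# complex spikes, enforced post-CS pause, multiplicative response kernels.

# Normal draw truncated from below by rejection (truncation points used here
# are several SDs from the mean, so rejection is cheap).
rnorm_trunc <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(max(mean, lower), n))
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lower)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

# Ordinary gamma renewal train on (0, duration]: ISIs ~ Gamma(shape, shape*rate)
# so the mean ISI is 1/rate at every shape.
gamma_renewal_train <- function(rate, shape, duration) {
  if (rate <= 0) return(numeric())
  n0 <- ceiling(rate * duration + 10 * sqrt(rate * duration) + 20)
  times <- cumsum(rgamma(n0, shape = shape, rate = shape * rate))
  while (length(times) && times[length(times)] < duration) {
    times <- c(times, times[length(times)] +
                 cumsum(rgamma(n0, shape = shape, rate = shape * rate)))
  }
  times[times <= duration]
}

# Homogeneous Poisson train with an absolute refractory period. The
# exponential rate is corrected so that the mean ISI (refractory + 1/lambda)
# equals 1/rate.
poisson_refractory_train <- function(rate, duration, refractory = 0.02) {
  if (rate <= 0) return(numeric())
  if (rate >= 1 / refractory) {
    stop_invalid_config(sprintf(
      "CS rate %g Hz is incompatible with a %g ms refractory period",
      rate, 1000 * refractory))
  }
  lambda <- 1 / (1 / rate - refractory)
  n0 <- ceiling(rate * duration + 10 * sqrt(rate * duration) + 20)
  times <- cumsum(refractory + rexp(n0, lambda))
  while (times[length(times)] < duration) {
    times <- c(times, times[length(times)] +
                 cumsum(refractory + rexp(n0, lambda)))
  }
  times[times <= duration]
}

# Multiplicative kernel value at time tp (s) after the end of the pause.
kernel_multiplier <- function(tp, type, kp, cell_rate) {
  switch(type,
    normal = rep(1, length(tp)),
    facilitation = ifelse(tp < kp$facilitation$duration_ms / 1000,
                          1 + kp$facilitation$amplitude, 1),
    suppression = ifelse(tp < kp$suppression$duration_ms / 1000,
                         1 + kp$suppression$amplitude, 1),
    oscillation = {
      f <- kp$oscillation$frequency_hz
      if (is.na(f)) f <- cell_rate
      tau <- kp$oscillation$decay_ms / 1000
      ifelse(tp < kp$oscillation$duration_ms / 1000,
             1 + kp$oscillation$depth * cos(2 * pi * f * tp) * exp(-tp / tau),
             1)
    })
}

kernel_duration_s <- function(type, kp) {
  switch(type,
    normal = 0,
    facilitation = kp$facilitation$duration_ms / 1000,
    suppression = kp$suppression$duration_ms / 1000,
    oscillation = kp$oscillation$duration_ms / 1000)
}

# Remove every SS falling in (cs, cs + pause] for any CS.
enforce_pause <- function(ss, cs, pause) {
  if (!length(ss) || !length(cs) || pause <= 0) return(ss)
  idx <- findInterval(ss, cs)
  drop <- idx > 0 & (ss - cs[pmax(idx, 1L)]) <= pause
  ss[!drop]
}

# Pause deletion followed by multiplicative kernel modulation of the
# post-pause train. Rate reductions (multiplier < 1) are realised by
# thinning; rate increases by superposing a thinned independent Poisson
# train at rate cell_rate * (multiplier - 1).
modulate_around_cs <- function(ss, cs, pause, type, kp, cell_rate, duration) {
  ss <- enforce_pause(ss, cs, pause)
  if (!length(cs) || type == "normal") return(ss)
  dur <- kernel_duration_s(type, kp)
  if (dur <= 0) return(ss)

  idx <- findInterval(ss, cs)
  tp <- ss - (cs[pmax(idx, 1L)] + pause)
  inwin <- idx > 0 & tp >= 0 & tp < dur
  if (any(inwin)) {
    m <- kernel_multiplier(tp[inwin], type, kp, cell_rate)
    keep_prob <- pmin(m, 1)
    keep <- rep(TRUE, length(ss))
    keep[inwin] <- runif(sum(inwin)) < keep_prob
    ss <- ss[keep]
  }

  grid <- seq(0, dur, length.out = 512L)
  mmax <- max(kernel_multiplier(grid, type, kp, cell_rate))
  if (mmax > 1) {
    boost_rate <- cell_rate * (mmax - 1)
    ncand <- rpois(length(cs), boost_rate * dur)
    if (sum(ncand) > 0) {
      tp_cand <- runif(sum(ncand)) * dur
      t_cand <- rep(cs + pause, ncand) + tp_cand
      m_cand <- kernel_multiplier(tp_cand, type, kp, cell_rate)
      accept <- runif(length(t_cand)) < pmax(m_cand - 1, 0) / (mmax - 1)
      extra <- t_cand[accept]
      extra <- extra[extra > 0 & extra <= duration]
      ss <- sort(c(ss, extra))
      ss <- enforce_pause(ss, cs, pause)
    }
  }
  # keep times strictly increasing at the on-disk (1 us) resolution
  if (length(ss) > 1L) ss <- ss[c(TRUE, diff(ss) > 1e-6)]
  ss
}

make_amplitude_series <- function(duration, drift) {
  t <- seq(0, duration, length.out = max(2L, ceiling(duration / 10) + 1L))
  data.frame(time_s = t, amplitude = 1 - drift * t / duration)
}

#' Generate one synthetic Purkinje cell recording
#'
#' Draws a cell from a [cell_preset()] and simulates its labelled spike
#' trains for `duration` seconds. The simple spike train is a gamma renewal
#' process at the cell's drawn rate (sampled once from
#' Normal(`ss_rate_mean`, `ss_rate_sd`) truncated at 1 Hz); the complex
#' spike train is Poisson at the drawn CS rate with a 20 ms refractory
#' period; every SS in `(cs, cs + cf_pause]` is deleted; and the post-pause
#' SS rate is modulated by the kernel of the cell's response type. The
#' drawn rates and the type label are stored as ground truth.
#'
#' @param preset A [cell_preset()].
#' @param duration Recording duration (s), > 0.
#' @param seed Integer seed; the call is deterministic given
#'   `(preset, duration, seed)`.
#' @param cell_id,lobule,context Metadata for the resulting recording.
#' @return A [spike_train_recording()].
#' @examples
#' rec <- generate_cell(zebrin_preset("negative"), duration = 10, seed = 1)
#' firing_rate(rec$ss_times, rec$duration)
#' @export
generate_cell <- function(preset, duration, seed, cell_id = "cell_1",
                          lobule = NA_character_, context = "in_vivo") {
  if (!inherits(preset, "cell_preset")) {
    stop_invalid_config("`preset` must be a cell_preset")
  }
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  check_number(seed, "seed")
  set.seed(as.integer(seed))
  r_ss <- rnorm_trunc(1, preset$ss_rate_mean, preset$ss_rate_sd, lower = 1)
  r_cs <- rnorm_trunc(1, preset$cs_rate, preset$cs_rate_sd, lower = 0.05)
  type <- sample(RESPONSE_TYPES, 1L, prob = preset$response_type_probs)
  cs <- poisson_refractory_train(r_cs, duration)
  ss <- gamma_renewal_train(r_ss, preset$ss_shape, duration)
  ss <- modulate_around_cs(ss, cs, preset$cf_pause_ms / 1000, type,
                           preset$kernel_params, r_ss, duration)
  spike_train_recording(
    cell_id = cell_id, zebrin_identity = preset$zebrin_identity,
    lobule = lobule, context = context, duration = duration,
    ss_times = ss, cs_times = cs,
    amplitude_series = make_amplitude_series(duration, preset$amplitude_drift),
    ground_truth = list(type = type, ss_rate = r_ss, cs_rate = r_cs,
                        seed = as.integer(seed)))
}

#' Generate a synthetic cohort of recordings
#'
#' Generates `n_cells` recordings per preset entry of a
#' [population_config()]. Cell `k` (counted across all presets) uses seed
#' `config$seed + k`, so the cohort is reproducible as a whole and cell by
#' cell. The manifest records every cell's identity, ground-truth type and
#' drawn rates.
#'
#' @param config A [population_config()].
#' @return A list with elements `recordings` (list of
#'   [spike_train_recording()]) and `manifest` (data frame with one row per
#'   cell).
#' @export
generate_population <- function(config) {
  if (!inherits(config, "population_config")) {
    stop_invalid_config("`config` must be a population_config")
  }
  n_total <- sum(vapply(config$presets, function(e) e$n_cells, numeric(1)))
  recordings <- vector("list", n_total)
  rows <- vector("list", n_total)
  k <- 0L
  for (entry in config$presets) {
    for (j in seq_len(entry$n_cells)) {
      k <- k + 1L
      id <- sprintf("cell_%03d", k)
      seed_k <- config$seed + k
      rec <- if (is.null(config$washin)) {
        generate_cell(entry$preset, config$duration, seed_k, cell_id = id,
                      lobule = entry$lobule %||% NA_character_)
      } else {
        generate_washin_series(entry$preset, config$washin, config$duration,
                               seed_k, cell_id = id)
      }
      recordings[[k]] <- rec
      rows[[k]] <- data.frame(
        cell_id = id, zebrin_identity = rec$zebrin_identity,
        lobule = rec$lobule, context = rec$context,
        duration = rec$duration, seed = seed_k,
        true_type = rec$ground_truth$type,
        true_ss_rate = rec$ground_truth$ss_rate,
        true_cs_rate = rec$ground_truth$cs_rate,
        stringsAsFactors = FALSE)
    }
  }
  list(recordings = recordings, manifest = do.call(rbind, rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a drug wash-in recording
#'
#' Simulates a cell whose simple spike rate follows
#' `r(t) = r0 * (1 - effect_fraction * (1 - exp(-(t - onset) / tau)))`
#' after the drug onset, by thinning the baseline renewal train with the
#' time-varying rate ratio. The complex spike train is left at its baseline
#' rate and the pause and response kernel are applied as in
#' [generate_cell()].
#'
#' @param preset A [cell_preset()].
#' @param spec A [washin_spec()].
#' @param duration Recording duration (s); must exceed `spec$drug_onset_s`.
#' @param seed Integer seed.
#' @param cell_id Cell identifier.
#' @return A [spike_train_recording()] with context `"washin"` whose ground
#'   truth records the wash-in parameters.
#' @export
generate_washin_series <- function(preset, spec, duration, seed,
                                   cell_id = "cell_1") {
  if (!inherits(preset, "cell_preset")) {
    stop_invalid_config("`preset` must be a cell_preset")
  }
  if (!inherits(spec, "washin_spec")) {
    stop_invalid_config("`spec` must be a washin_spec")
  }
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  if (duration <= spec$drug_onset_s) {
    stop_invalid_config("`duration` must exceed the drug onset time")
  }
  check_number(seed, "seed")
  set.seed(as.integer(seed))
  r_ss <- rnorm_trunc(1, preset$ss_rate_mean, preset$ss_rate_sd, lower = 1)
  r_cs <- rnorm_trunc(1, preset$cs_rate, preset$cs_rate_sd, lower = 0.05)
  type <- sample(RESPONSE_TYPES, 1L, prob = preset$response_type_probs)
  cs <- poisson_refractory_train(r_cs, duration)
  ss <- gamma_renewal_train(r_ss, preset$ss_shape, duration)
  ss <- modulate_around_cs(ss, cs, preset$cf_pause_ms / 1000, type,
                           preset$kernel_params, r_ss, duration)
  keep_prob <- ifelse(
    ss < spec$drug_onset_s, 1,
    1 - spec$effect_fraction *
      (1 - exp(-(ss - spec$drug_onset_s) / spec$time_constant_s)))
  ss <- ss[runif(length(ss)) < keep_prob]
  spike_train_recording(
    cell_id = cell_id, zebrin_identity = preset$zebrin_identity,
    context = "washin", duration = duration,
    ss_times = ss, cs_times = cs,
    amplitude_series = make_amplitude_series(duration, preset$amplitude_drift),
    ground_truth = list(type = type, ss_rate = r_ss, cs_rate = r_cs,
                        seed = as.integer(seed), washin = unclass(spec)))
}
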