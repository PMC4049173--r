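# Shared fixtures: presets and small cohorts built in code.

RESPONSE_TYPES <- c("normal", "facilitation", "suppression", "oscillation")

# Preset emitting a single response type, at a rate whose oscillation
# frequency (= cell rate) falls inside the classifier's 25-70 Hz band.
type_preset <- function(type, rate = 50, rate_sd = 5, shape = 4) {
  p <- c(normal = 0, facilitation = 0, suppression = 0, oscillation = 0)
  p[type] <- 1
  cell_preset(ss_rate_mean = rate, ss_rate_sd = rate_sd, ss_shape = shape,
              cs_rate = 1.13, cs_rate_sd = 0, cf_pause_ms = 10,
              response_type_probs = p)
}

# Plain renewal preset without pause or CS-locked modulation, for tests of
# the raw renewal statistics.
plain_preset <- function(rate, shape, rate_sd = 0) {
  cell_preset(ss_rate_mean = rate, ss_rate_sd = rate_sd, ss_shape = shape,
              cs_rate = 0.5, cs_rate_sd = 0, cf_pause_ms = 0)
}

# Deterministic regular train: rate hz for dur seconds.
regular_train <- function(rate, dur) seq(1 / rate, dur, by = 1 / rate)

# Brute-force climbing fiber pause oracle: double loop over all CS and all
# later SS, independent of the implementation's vectorized search.
cf_pause_bruteforce <- function(ss, cs) {
  best <- Inf
  for (c in cs) {
    later <- ss[ss > c]
    if (length(later)) best <- min(best, min(later) - c)
  }
  if (!is.finite(best)) NULL else 1000 * best
}
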