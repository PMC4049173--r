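test_that("preset and config invariants are enforced", {
  expect_error(cell_preset(ss_rate_mean = 50, ss_rate_sd = 5, cs_rate = 60),
               class = "zt_invalid_config") # SS rate must exceed CS rate
  expect_error(cell_preset(ss_rate_mean = 50, ss_rate_sd = 5, cs_rate = 1,
                           ss_shape = 0.5),
               class = "zt_invalid_config")
  expect_error(cell_preset(ss_rate_mean = 50, ss_rate_sd = 5, cs_rate = 1,
                           response_type_probs = c(normal = 0.6,
                                                   facilitation = 0.5,
                                                   suppression = 0,
                                                   oscillation = 0)),
               class = "zt_invalid_config")
  expect_error(generate_cell(zebrin_preset("negative"), duration = 0, seed = 1),
               class = "zt_invalid_config")
  expect_error(population_config(list(list(preset = zebrin_preset("negative"),
                                           n_cells = 0))),
               class = "zt_invalid_config")
  expect_error(washin_spec(10, 1.5, 60), class = "zt_invalid_config")
})

test_that("the climbing fiber pause is enforced exactly for every CS", {
  for (seed in 1:5) {
    rec <- generate_cell(type_preset("facilitation"), duration = 30,
                         seed = seed)
    for (cs in rec$cs_times) {
      expect_false(any(rec$ss_times > cs & rec$ss_times <= cs + 0.010))
    }
  }
})

test_that("generation is deterministic given (config, seed)", {
  cfg <- population_config(
    list(list(preset = zebrin_preset("negative"), n_cells = 3),
         list(preset = zebrin_preset("positive"), n_cells = 3)),
    duration = 20, seed = 7)
  a <- generate_population(cfg)
  b <- generate_population(cfg)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$recordings, b$recordings)
  # per-cell seeds allow regenerating any cell in isolation
  solo <- generate_cell(zebrin_preset("negative"), 20, seed = 7 + 2,
                        cell_id = "cell_002")
  expect_identical(solo$ss_times, a$recordings[[2]]$ss_times)
})

test_that("per-cell empirical SS rate recovers the drawn rate (renewal CLT)", {
  for (shape in c(1, 4)) {
    for (seed in 1:5) {
      rec <- generate_cell(plain_preset(80, shape, rate_sd = 10),
                           duration = 120, seed = 100 + seed)
      drawn <- rec$ground_truth$ss_rate
      emp <- firing_rate(rec$ss_times, rec$duration)
      expect_lt(abs(emp - drawn) / drawn, 3 / sqrt(drawn * 120))
    }
  }
})

test_that("mean CV2 decreases with gamma shape (regularity monotonicity)", {
  shapes <- c(1, 2, 4, 8)
  # oracle: plain gamma renewal trains simulated directly, no CS machinery
  mean_cv2_at_shape <- function(shape) {
    mean(vapply(1:20, function(s) {
      set.seed(4000 + s)
      isi <- rgamma(1500, shape = shape, rate = shape * 50)
      mean_cv2(cumsum(isi))
    }, numeric(1)))
  }
  curve <- vapply(shapes, mean_cv2_at_shape, numeric(1))
  expect_true(all(diff(curve) < 0))
  # the generator's trains follow the same ordering
  gen_curve <- vapply(shapes, function(shape) {
    mean(vapply(1:20, function(s) {
      rec <- generate_cell(plain_preset(50, shape), 30, seed = 5000 + s)
      mean_cv2(rec$ss_times)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(gen_curve) < 0))
  # Poisson (shape 1) mean CV2 is near its analytic expectation of 1
  expect_equal(curve[1], 1, tolerance = 0.05)
})

test_that("wash-in series follows the prescribed rate law", {
  preset <- plain_preset(60, 4)
  # effect 1 with a tiny time constant silences the post-onset train
  rec <- generate_washin_series(preset, washin_spec(10, 1, 0.1), 60, seed = 1)
  expect_lt(sum(rec$ss_times > 11) / 49, 0.5)
  # effect 0 is statistically indistinguishable from a plain cell
  red0 <- vapply(1:10, function(s) {
    r <- generate_washin_series(preset, washin_spec(120, 0, 60), 600,
                                seed = 200 + s)
    washin_effect(r, 120)$percent_reduction
  }, numeric(1))
  expect_lt(abs(mean(red0)), 2 * sd(red0) / sqrt(10) + 1e-9)
  expect_error(generate_washin_series(preset, washin_spec(120, 0.5, 60), 100,
                                      seed = 1),
               class = "zt_invalid_config")
})

test_that("synthetic CS waveforms round-trip their target metrics", {
  # zero noise: template metrics match the request by construction
  ws <- generate_cs_waveform(list(hmw_ms = 0.4, area = 0.8), seed = 1,
                             noise_sd = 0)
  wf <- average_waveform(ws)
  expect_equal(half_max_width(wf), 0.4, tolerance = ws$sample_period_ms)
  expect_equal(spike_area(wf), 0.8, tolerance = 0.03)
  # noisy snippets: averaging 100 draws recovers the HMW within 5%
  ws2 <- generate_cs_waveform(list(hmw_ms = 0.3, area = 0.6), seed = 2,
                              n_snippets = 100, noise_sd = 0.1)
  expect_equal(half_max_width(average_waveform(ws2)), 0.3, tolerance = 0.015)
  # infeasible requests are rejected
  expect_error(generate_cs_waveform(list(hmw_ms = 0.4, area = 0), seed = 1),
               class = "zt_invalid_config")
  expect_error(generate_cs_waveform(list(hmw_ms = 0.4, area = 10), seed = 1),
               class = "zt_invalid_config")
})
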