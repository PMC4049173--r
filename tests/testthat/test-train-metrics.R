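test_that("firing rate is count over duration", {
  expect_equal(firing_rate(seq(0.5, 60, by = 0.5), 60), 2)
  expect_equal(firing_rate(numeric(), 30), 0)
  # rate * duration gives back the event count
  t <- sort(runif(137, 0, 45))
  expect_equal(firing_rate(t, 45) * 45, 137)
})

test_that("ISI CV matches hand-computed and analytic values", {
  expect_equal(isi_cv(regular_train(50, 2)), 0)
  # ISIs {1, 3}: sample SD sqrt(2), mean 2
  expect_equal(isi_cv(c(0, 1, 4)), sqrt(2) / 2, tolerance = 1e-12)
  expect_error(isi_cv(c(0, 1)), class = "zt_undefined_metric")
  # exponential ISIs have CV 1
  set.seed(42)
  expect_equal(isi_cv(cumsum(rexp(10000, 80))), 1, tolerance = 0.05)
})

test_that("mean CV2 matches hand values and the uniform-ratio oracle", {
  expect_equal(suppressWarnings(mean_cv2(regular_train(40, 2))), 0)
  # single pair of ISIs {1, 3}: 2*|3-1|/(3+1) = 1
  expect_equal(suppressWarnings(mean_cv2(c(0, 1, 4))), 1)
  expect_error(mean_cv2(c(0, 1)), class = "zt_undefined_metric")
  expect_warning(mean_cv2(c(0, 1, 4)), "terms")
  # Poisson train: E[CV2] = E[2|1-2U|] with U ~ Uniform(0,1), which is 1;
  # cross-check the closed form by direct Monte Carlo on the ratio
  set.seed(43)
  u <- runif(2e5)
  expect_equal(mean(2 * abs(1 - 2 * u)), 1, tolerance = 0.01)
  expect_equal(mean_cv2(cumsum(rexp(10001, 80))), 1, tolerance = 0.05)
})

test_that("mean CV2 is invariant under time rescaling", {
  set.seed(7)
  t <- cumsum(rgamma(500, shape = 3, rate = 150))
  for (c in c(0.2, 5, 1000)) {
    expect_equal(mean_cv2(t * c), mean_cv2(t), tolerance = 1e-12)
  }
})

test_that("climbing fiber pause matches hand values and the brute-force oracle", {
  expect_equal(climbing_fiber_pause(c(0.010, 0.020, 0.030), 0.012), 8)
  expect_equal(climbing_fiber_pause(c(0.010, 0.020, 0.030), c(0.012, 0.025)), 5)
  expect_equal(climbing_fiber_pause(c(0.010, 0.020, 0.030), c(0.012, 0.025),
                                    aggregate = "mean"), mean(c(8, 5)))
  expect_error(climbing_fiber_pause(c(0.1, 0.2), numeric()),
               class = "zt_undefined_metric")
  expect_error(climbing_fiber_pause(c(0.1), 0.2), class = "zt_undefined_metric")
  # 100 random small instances against the double-loop oracle, exactly
  set.seed(99)
  for (i in 1:100) {
    ss <- sort(runif(sample(2:30, 1), 0, 1))
    cs <- sort(runif(sample(1:5, 1), 0, 1))
    oracle <- cf_pause_bruteforce(ss, cs)
    if (is.null(oracle)) {
      expect_error(climbing_fiber_pause(ss, cs), class = "zt_undefined_metric")
    } else {
      expect_identical(climbing_fiber_pause(ss, cs), oracle)
    }
  }
})

test_that("pause floor is respected on generated cells", {
  rec <- generate_cell(type_preset("normal", rate = 60), 120, seed = 21)
  pause <- climbing_fiber_pause(rec$ss_times, rec$cs_times)
  expect_gte(pause, 10)
  # with ~135 CS the minimum overshoot above the floor is small
  expect_lte(pause, 10 + 3000 / rec$ground_truth$ss_rate)
})

test_that("stability profile bins, normalizes and flags", {
  t <- regular_train(50, 120)
  prof <- stability_profile(t, 120)
  expect_identical(nrow(prof), 4L)
  expect_true(all(abs(prof$normalized - 1) < 0.02))
  expect_false(any(prof$flagged))
  # rate doubling halfway is flagged
  t2 <- c(regular_train(30, 60), 60 + regular_train(60, 60))
  prof2 <- stability_profile(t2, 120)
  expect_true(any(prof2$flagged))
  expect_error(stability_profile(t, 45), class = "zt_undefined_metric")
})

test_that("inclusion criteria depend on recording context", {
  short <- spike_train_recording("a", duration = 100,
                                 ss_times = regular_train(50, 100),
                                 context = "in_vivo")
  v <- apply_inclusion_criteria(short)
  expect_false(v$included)
  expect_identical(v$reasons, "duration")

  drifting <- spike_train_recording(
    "b", duration = 130, ss_times = regular_train(50, 130),
    context = "in_vivo",
    amplitude_series = data.frame(time_s = c(0, 65, 130),
                                  amplitude = c(1, 0.9, 0.7)))
  expect_identical(apply_inclusion_criteria(drifting)$reasons, "amplitude")

  # in vitro: CV ~0.25 is excluded for irregularity (gamma shape 16)
  set.seed(5)
  t_irr <- cumsum(rgamma(9000, shape = 16, rate = 50 * 16))
  t_irr <- t_irr[t_irr <= 150]
  irregular <- spike_train_recording("c", duration = 150, ss_times = t_irr,
                                     context = "in_vitro")
  expect_true("cv" %in% apply_inclusion_criteria(irregular)$reasons)

  # in vitro: 30% rate change between first and last 30 s is excluded
  ramp <- spike_train_recording(
    "d", duration = 120,
    ss_times = c(regular_train(50, 30), 30 + regular_train(55, 60),
                 90 + regular_train(65, 30)),
    context = "in_vitro")
  expect_true("rate_drift" %in% apply_inclusion_criteria(ramp)$reasons)

  # drug context only needs 60 s
  drug <- spike_train_recording("e", duration = 80,
                                ss_times = regular_train(40, 80),
                                context = "drug")
  expect_true(apply_inclusion_criteria(drug)$included)
})

test_that("cohort metrics assemble one row per cell with ground truth recovery", {
  pop <- generate_population(population_config(
    list(list(preset = zebrin_preset("negative"), n_cells = 3)),
    duration = 120, seed = 31))
  m <- cohort_metrics(pop)
  expect_identical(nrow(m), 3L)
  expect_true(all(m$included))
  expect_equal(m$ss_rate, pop$manifest$true_ss_rate, tolerance = 0.05)
  expect_true(all(m$cf_pause_ms >= 10))
  expect_true(all(m$ss_mean_cv2 > 0 & m$ss_mean_cv2 < 2))
})
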