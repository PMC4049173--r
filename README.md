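# zebratrain

Cerebellar Purkinje cells fire two classes of action potentials: intrinsic,
high-rate **simple spikes** (SS, tens of Hz) and climbing-fiber-evoked
**complex spikes** (CS, ~1 Hz), each CS followed by a brief SS-free
**climbing fiber pause**. Purkinje cells fall into parasagittal bands defined
by expression of zebrin II (aldolase C), and the two band types operate at
different intrinsic simple spike frequencies — roughly 90–100 Hz in
zebrin-negative (Z−) modules versus ~60 Hz in zebrin-positive (Z+) modules in
the awake mouse, with parallel differences in CS rate, pause duration, CS
waveform and the post-CS response profile.

`zebratrain` is an R package for neurophysiologists analysing such labelled
spike-train recordings. It packages the full analysis chain with which this
kind of module-level comparison is made, together with a point-process
generator of synthetic recordings so that every stage is testable without raw
data:

* **Per-cell statistics** — firing rate; interspike-interval CV
  (`sd(ISI)/mean(ISI)`); mean CV2
  (`mean(2|ISIₙ₊₁ − ISIₙ| / (ISIₙ₊₁ + ISIₙ))`, a short-timescale regularity
  index that is 0 for a clock-like train and 1 for a Poisson train); the
  climbing fiber pause (minimum post-CS first-SS latency); 30-s stability
  profiles; and the context-dependent inclusion filters (minimum duration,
  amplitude stability, in vitro CV < 0.2 and < 20% rate drift).
* **Waveform metrics** — normalized snippet averaging, half-maximum width of
  the first CS peak (FWHM with linear interpolation), and the rectified spike
  area over −0.5 to +3 ms around spike onset.
* **Peri-CS analysis** — CS-triggered SS histograms over [−100, +300] ms and
  a deterministic four-way classification of the post-pause response
  (normal / facilitation / suppression / oscillation).
* **Group statistics** — pooled-variance two-sample t (from raw samples or
  printed `(mean, sd, n)` summaries), paired t, Pearson χ² without
  continuity correction, Spearman/Pearson correlation, one-way ANOVA with
  Tukey or Bonferroni post hoc tests, drug wash-in quantification
  (2-min pre-drug baseline vs the 5–7-min post-drug window), f–I slopes, and
  per-lobule aggregation against zebrin staining intensity.
* **Synthetic data** — simple spikes as a gamma renewal process (one
  parameter for rate, one for regularity), complex spikes as a
  refractory-corrected Poisson process, an enforced post-CS pause,
  per-type post-pause modulation kernels, amplitude drift, drug wash-in rate
  dynamics, and CS waveform snippets with controlled HMW and area.
* **Pipeline** — `run_pipeline()` executes simulate → metrics → peri-CS
  typing → group stats as one seeded, reproducible run;
  `inst/cli/zebratrain.R` is a thin command-line wrapper.

## Worked example

Simulate a small two-group cohort at the published group parameters and run
the comparison:

```r
library(zebratrain)

pop <- generate_population(population_config(
  list(list(preset = zebrin_preset("negative"), n_cells = 10),
       list(preset = zebrin_preset("positive"), n_cells = 10)),
  duration = 120, seed = 42))

m <- cohort_metrics(pop)
aggregate(cbind(ss_rate, cs_rate, cf_pause_ms) ~ zebrin_identity, m, mean)
#>   zebrin_identity ss_rate cs_rate cf_pause_ms
#> 1        negative    98.7   0.962        10.1
#> 2        positive    61.0   0.829        10.2

two_sample_t(m$ss_rate[m$zebrin_identity == "negative"],
             m$ss_rate[m$zebrin_identity == "positive"])
#> <group_comparison> t = 5.175, df = 18, p = 6.365e-05
#>   method: pooled two-sample t, two.sided
```

Even at n = 10 per group the simulated populations separate decisively; the
mean rates recover the generating presets (96.1 and 61.4 Hz) within sampling
error, and every cell respects the 10 ms pause floor.

Peri-CS typing of a single cell:

```r
rec <- pop$recordings[[1]]
classify_response_type(peri_cs_histogram(rec$ss_times, rec$cs_times, rec$duration))
#> <peri_cs_profile> 80 bins x 5 ms over [-100, 300] ms, 89 CS
#>   baseline 95.4 Hz | type: normal
```

Statistics whose inputs are printed summaries work directly from them, e.g.
the facilitation-by-zebrin contingency table (17/47 Z− vs 6/57 Z+
facilitation-type cells):

```r
pearson_chi2(matrix(c(17, 6, 30, 51), nrow = 2))
#> <group_comparison> chi2 = 9.835, df = 1, p = 0.001712
#>   method: Pearson chi-squared, no continuity correction
```

## Layout

| Path | Contents |
| --- | --- |
| `R/simulate.R`, `R/waveform-sim.R` | synthetic spike trains, cohorts, wash-in series, CS waveforms |
| `R/metrics.R` | per-cell statistics and inclusion filters |
| `R/waveform.R` | waveform averaging, HMW, spike area |
| `R/pericomplex.R` | peri-CS histograms and response typing |
| `R/stats.R` | group-level statistics |
| `R/io.R` | spike-time CSV, JSON manifests, intensity tables |
| `R/pipeline.R` | seeded end-to-end runs, YAML configs |
| `vignettes/purkinje-spike-trains.Rmd` | methods: models, parameters, design choices, limitations |
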