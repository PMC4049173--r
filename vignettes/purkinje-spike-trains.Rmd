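---
title: "Methods: simulating and analysing Purkinje cell spike trains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing Purkinje cell spike trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zebratrain)
```

# Scope

`zebratrain` analyses extracellular Purkinje cell recordings in which simple
spikes (SS) and complex spikes (CS) have already been sorted and labelled.
The pipeline starts from labelled event times; spike detection, sorting and
histology are out of scope. This vignette documents the generative model,
the definitions of every statistic, the parameters that matter, and the
design choices made where the underlying analysis conventions are not fully
standardized — so that a user can judge what a passing test suite does and
does not establish about real data.

# The generative model

## Simple spikes: gamma renewal

Within a cell, SS times are a gamma renewal process: interspike intervals
are i.i.d. Gamma(shape $k$, rate $k r$), so the mean ISI is $1/r$ at every
shape. One parameter sets the rate, one the regularity: $k = 1$ is Poisson
(ISI CV $= 1$, mean CV2 $= 1$ in expectation), and CV $= 1/\sqrt{k}$ falls
as $k$ grows. The default $k = 4$ (CV $= 0.5$, mean CV2 $\approx 0.55$)
places synthetic cells in the range typical of awake in vivo recordings;
clock-like in vitro firing corresponds to $k \gtrsim 25$ (CV $< 0.2$). The
process is simulated from $t = 0$ as an ordinary renewal sequence; the
start-up bias in the event count is $O(1)$ events against $\sim 10^4$ per
recording and is ignored.

Across cells, each cell draws its rate once from
Normal(`ss_rate_mean`, `ss_rate_sd`) truncated at 1 Hz. The bundled
`zebrin_preset()` values (96.1 ± 15.4 Hz for zebrin-negative, 61.4 ± 19.3 Hz
for zebrin-positive cells, with CS rates 1.13 ± 0.25 and 0.92 ± 0.28 Hz) are
the published awake-mouse group statistics; truncation at these parameters
is a $> 3\sigma$ event and does not perceptibly shift the mean.

## Complex spikes: refractory Poisson

CS times are homogeneous Poisson with a 20 ms absolute refractory period
(ISI $= 0.02 + \text{Exp}(\lambda)$). Only the mean CS rate is specified by
the data being emulated; the refractory period avoids unphysiological CS
doublets. $\lambda$ is corrected ($1/\lambda = 1/r_{cs} - 0.02$) so the
realized mean rate equals the requested one.

## The climbing fiber pause and post-CS kernels

Every SS in $(t_{cs}, t_{cs} + \text{pause}]$ is deleted (default pause
10 ms), which enforces the hallmark SS-free interval exactly — tests assert
it spike-by-spike, not statistically. After the pause, the SS rate is
multiplied by a response-type kernel:

| type | kernel (time $\tau$ from pause end) | default |
| --- | --- | --- |
| normal | 1 | — |
| facilitation | $1 + a$ on $[0, d)$ | $a = 0.5$, $d = 50$ ms |
| suppression | $1 + a$ on $[0, d)$ | $a = -0.5$, $d = 100$ ms |
| oscillation | $1 + a\cos(2\pi f \tau)\,e^{-\tau/\tau_d}$ | $a = 0.4$, $\tau_d = 100$ ms, $f =$ cell rate |

Only exemplar histograms of the four response classes exist as a reference;
no kernel equations are published. These shapes and amplitudes are therefore
artifact conventions, chosen to be recoverable by the classifier at
realistic CS counts, and all are configurable through
`cell_preset(kernel_params = ...)`. Rate reductions are realized by thinning
the renewal train (exact for any multiplier $\le 1$); rate increases by
superposing a thinned independent Poisson train — an approximation to an
inhomogeneous renewal process that reproduces the target rate profile but
slightly raises local irregularity inside the boosted window. The
oscillation frequency defaults to the cell's own firing rate because the
pause is treated as resetting the cell's intrinsic pacemaker, making the
post-pause modulation phase-locked to the pause end; the classifier exploits
both properties.

## Wash-in series, amplitude drift, waveforms

`generate_washin_series()` thins the SS train by
$1 - e\,(1 - \exp(-(t - t_0)/\tau))$ after drug onset $t_0$ (plateau effect
fraction $e$, time constant $\tau$); the CS train is left at baseline, since
only the SS rate law is being emulated. `amplitude_drift` produces a linear
relative amplitude decline for exercising the amplitude-stability inclusion
filter. `generate_cs_waveform()` builds a CS template on a 50 kHz grid over
$[-0.5, 3]$ ms: a Gaussian first lobe whose FWHM is the requested
half-maximum width, positioned so that the 10%-of-peak rising crossing sits
at $t = 0$ (the onset convention), plus a trough and late bump whose common
scale is solved with `uniroot` so the rectified area of the complete
template matches the requested target exactly (component overlap included).
Requests that would need after-components rivalling the first peak, or an
area below the first lobe's own area, are rejected as infeasible.

## What the generator does not emulate

Spike sorting errors and overlapping waveforms; CS spikelets; slow
non-stationarities other than the linear amplitude drift and the wash-in
rate law; serial ISI correlations beyond renewal; behavioural or sensory
modulation; cell-within-mouse nesting (cells are independent). Passing
recovery tests therefore demonstrates that the analysis chain is correct and
well-calibrated for renewal-like trains, not that it is robust to sorting
artifacts or non-stationary recordings.

# Per-cell statistics

* **Firing rate** = event count / duration.
* **ISI CV** uses the sample ($n-1$) standard deviation; the choice is not
  dictated by the emulated analysis, but matches the small-sample
  conventions of the t statistics used elsewhere. At least 3 events.
* **Mean CV2** = mean of $2|ISI_{n+1} - ISI_n|/(ISI_{n+1} + ISI_n)$ over
  consecutive interval pairs. One term needs 3 spikes; the function accepts
  that minimum and warns below 100 terms. For a Poisson train
  $U = ISI_n/(ISI_n + ISI_{n+1}) \sim \text{Uniform}(0,1)$ and
  $E[2|1-2U|] = 1$, the analytic oracle used in the tests. Mean CV2 is
  dimensionless and invariant under time rescaling (tested).
* **Climbing fiber pause** = the *minimum* over all CS of the latency to
  the next SS, read literally from its definition; CS with no later SS are
  skipped. Because an average of per-CS latencies is also a defensible
  reading, `aggregate = "mean"` is exposed as an option. Tests pin the
  default to a brute-force double-loop oracle, exactly.
* **Stability profile**: rates in half-open 30-s bins $[30k, 30(k+1))$, a
  trailing partial bin dropped, each bin normalized by the whole-recording
  rate and flagged beyond 20% deviation.
* **Inclusion criteria** by context — in vivo: duration ≥ 120 s and no
  amplitude sample deviating more than 20% from the median (the amplitude
  criterion is stated only qualitatively in the emulated protocol; the
  median rule is this package's operationalization); in vitro:
  duration ≥ 120 s, CV < 0.2, first-vs-last-30-s rate change < 20%;
  drug/wash-in: duration ≥ 60 s. All violated criteria are reported, not
  just the first.

SS falling inside a CS pause window in real data (sorting artifacts) are
*not* filtered by the metrics stage; cleaning is the sorter's or the
generator's job.

# Waveform metrics

Averaging assumes onset-aligned snippets on one uniform time axis; the mean
is peak-normalized to unit maximum absolute amplitude. Peak normalization
(rather than area normalization) is a choice — the convention being
emulated says only "normalized average"; half-maximum width is invariant to
it, and spike area is reported on the normalized scale. The *first peak* is
the first local maximum of the positively rectified signal at $t \ge 0$
exceeding half the global maximum, which guards against pre-onset noise;
half-maximum crossings are linearly interpolated between samples. A
monotone tail without a falling crossing is an undefined-metric error, not a
zero. Spike area integrates $|a(t)|$ by the trapezoid rule over exactly
$[-0.5, 3]$ ms, interpolating the endpoints onto the window edges; at 50 kHz
sampling the trapezoid agrees with analytic integrals to well under 1%
(tested against Gaussian, rectangle and half-sine closed forms).

# Peri-CS histograms and response typing

Histograms count SS in 5-ms half-open bins over $[-100, 300]$ ms around
each CS (bin width configurable; it must tile the window exactly, giving 80
bins at the default). CS closer than 100 ms to the recording start or
300 ms to its end are dropped so every window is complete; windows of
neighbouring CS may overlap, matching a plain CS-triggered average. Counts
convert to rates via $c/(n_{cs} \Delta)$, so
$\sum_b \text{rate}_b \cdot \Delta \cdot n_{cs}$ equals the total SS
counted — an exact conservation law used as a test.

The four-way typing is necessarily a package convention: the reference
analysis distinguished the types by visual inspection of the histograms and
published no thresholds. The rule, with all thresholds exposed as
arguments:

1. **Baseline** = mean rate over the pre-CS bins $[-100, 0)$; **pause end**
   = the first post-CS bin whose rate exceeds 50% of baseline. A profile
   whose rate never recovers, or with zero baseline, is an undefined-metric
   error.
2. Per-bin $z = (\text{rate} - b)/\sqrt{b/(n_{cs}\Delta)}$ over the
   post-pause window (Poisson standard error; renewal trains with shape
   $> 1$ are slightly sub-Poisson, making the test mildly conservative in
   the direction of extra sensitivity).
3. **Facilitation**: ≥ 3 consecutive bins with $z > 1.5$;
   **suppression**: the mirror image. The per-bin threshold is deliberately
   moderate because expected counts per 5-ms bin are small
   ($\approx 0.25$ per CS); evidence is accumulated across the run instead.
   With $\sim 135$ CS per 120-s recording, the default ±50% kernels produce
   per-bin $|z| \approx 3$, and a 1.5-threshold run of 3 has a per-cell
   false-positive rate below 1% on null profiles.
4. **Oscillation**: a phase-locked matched filter. A damped cosine
   ($\tau_d$ = 100 ms, phase zero at the pause end) is regressed onto the
   baseline-subtracted post-pause profile at integer frequencies within
   ±6 Hz of the cell's baseline rate, intersected with the 25–70 Hz band,
   against a nested null model containing a piecewise-constant envelope
   (25-ms blocks spanning the first 150 ms). The envelope absorbs monotone
   facilitation/suppression profiles, whose boxcar edges would otherwise
   leak substantial power into the oscillation band; the frequency
   restriction encodes the pacemaker interpretation above and matches the
   observed signature of oscillation-type cells (SS rate 35–60 Hz). The
   profile is oscillatory when the signed t statistic of the cosine term
   exceeds 3. An early design following the common periodogram recipe
   (peak power > 4× median plus sign gates) was measured against the
   generator and discarded: the null distribution of an in-band periodogram
   maximum is too heavy for a 58-bin profile, and cells with strong boxcar
   modulation routinely exceeded any workable power ratio. The matched
   filter reaches per-type recovery above 90% at 20 cells/type (tested),
   with per-type expected accuracy around 95% measured on larger cohorts
   during calibration.
5. Precedence: oscillation over suppression over facilitation, mirroring
   the class definitions (oscillation *is* modulated suppression).

`classify_response_type()` warns below 50 contributing CS. The
oscillation-signature helper (`oscillation_signature_check`) applies the
published bounds literally: rate in $[35, 60]$ Hz and CV strictly below
0.32.

# Group statistics

The unpaired t is the pooled-variance Student form, from raw samples or
from `(mean, sd, n)` summaries — the printed statistics being reproduced are
consistent with pooled rather than Welch degrees of freedom. Two-sided p
values are the default everywhere; a one-sided alternative is an explicit
option because some of the emulated comparisons are reported one-tailed.
χ² is Pearson's without continuity correction (the printed value 9.835 on
the facilitation table matches the uncorrected statistic; the corrected one
would be ≈ 8.5). Correlations delegate to `stats::cor.test` (average-rank
ties, t-approximation p for Spearman); ANOVA delegates to `stats::aov`,
with Tukey HSD or Bonferroni-adjusted pairwise t tests on request — the
post hoc method is always caller-selected, as the emulated analyses mix
both. The wash-in effect is
$100(\text{pre} - \text{post})/\text{pre}$ with pre the mean rate over the
2 min before onset and post over minutes 5–7 after onset, read literally
from the windowing convention. Note that with a 60-s wash-in time constant
the 5–7-min window sits at ≈ 99.7% of plateau, so the recovered reduction
is expected a few tenths of a percentage point below the plateau effect
fraction. f–I slopes are ordinary least squares over the full tested
current range. Lobule aggregation matches labels case-insensitively
against the vermal/hemispheric vocabulary (I–X, HIV&V-Sim, CrI-II, PM,
Cop-PF, Flocc), excluding unmatched cells with a warning.

Where staining intensities are supplied, `normalize_intensity()` divides
soma by background (granule cell layer) intensity per section and averages
the per-section *ratios* per lobule; ratio-then-average was chosen because
the backgrounds of different sections differ, and the alternative
(average-then-ratio) is not what "normalized based on background" most
naturally describes. The convention that high values mean weak staining is
preserved, never inverted.

# Numerical and interface conventions

* Time on disk is seconds with 6 decimals (µs resolution); all millisecond
  quantities are converted explicitly at module boundaries. Event times
  must be strictly increasing per train; the generator enforces a 1-µs
  minimum separation so round-trips through disk are exact.
* Degenerate inputs raise classed conditions (`zt_invalid_config`,
  `zt_validation_error`, `zt_undefined_metric`, `zt_invalid_input`) rather
  than returning sentinels; an empty train has firing rate 0, but CV, CV2,
  pause and classification are errors, not zeros.
* Determinism: `generate_cell(preset, duration, seed)` is a pure function
  of its arguments; cohorts derive cell $k$'s seed as `seed + k`, so a
  single cell can be regenerated without its cohort. The pipeline carries
  one master seed.
* Validation errors from file parsing name the file and the first offending
  row.

# Problem sizes

The test suite and the acceptance script run at the scale of the emulated
study: cohorts of 47 + 57 cells × 120 s for rate recovery, 20 cells per
response type for classifier recovery, 20 seeds × 600 s for wash-in
recovery, $10^4$-ISI trains for the Poisson regularity oracles, and 100
random small instances for the brute-force pause oracle. The full suite
completes in well under a minute on one core.

# Known limitations

* The response-type thresholds are calibrated against this package's own
  generator; applied to real histograms they are a starting point, not a
  validated clinical rule, and the published type assignments they emulate
  were made by inspection.
* The oscillation detector assumes pause-phase-locked modulation near the
  cell's firing rate; oscillations at unrelated frequencies (or in cells
  firing outside 25–70 Hz) are deliberately not claimed.
* Boosted (facilitation) segments are Poisson superpositions, so their
  local CV2 is slightly above that of a true inhomogeneous renewal train.
* The wash-in generator thins SS only; drug effects on CS rate, pause or
  waveform are not modelled.
* `two_sample_t` from summaries cannot check normality or outliers; it
  reproduces printed statistics but inherits their assumptions.
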