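---
title: "Agreement analysis for continuous vital-sign wearables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Agreement analysis for continuous vital-sign wearables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitalval)
```

## The problem

Chest-patch wearables estimate heart rate (HR) and respiratory rate (RR)
continuously, but their accuracy must be demonstrated against gold-standard
monitoring — 3-lead ECG for HR, capnography for RR — before clinical use,
and in particular during patient movement and episodes of low oxygen
saturation, conditions that regulatory standards for cardiac monitors do
not cover. `vitalval` implements the agreement-analysis pipeline used in
that kind of validation study: it pairs a test device reporting every 4
seconds with a reference monitor reporting at 1 Hz, reduces both to
simultaneous 40-second medians, and summarizes their disagreement per
activity and per hypoxia stratum.

## Windowed median pairing

The two devices report at different rates, so raw samples cannot be paired
directly. Instead each stage interval is covered by consecutive,
non-overlapping 40-second windows, and within every window each device is
summarized by the median of its samples: 10 points for the patch, 40 for
the reference, i.e. a 10-point versus a 40-point median centered on the
same interval.

Conventions, all configurable through `windowing_config()`:

* **Windows never cross a stage boundary.** The first window starts at the
  stage start; a trailing partial window is discarded. A stage of duration
  $D$ yields $\lfloor D/40 \rfloor$ windows. For a 40-s window this is
  equivalent to trimming window *centers* by 20 s at each end of the stage.
* **Half-open intervals** $[t_0, t_0 + 40)$ partition time without
  double-counting boundary samples.
* **Even-count medians** use the midpoint of the two central order
  statistics (the standard convention).
* **Missing data are never imputed.** A window is excluded when either
  rate device has fewer than `min_fraction` (default 0.5) of its expected
  in-window samples — at least 5 of 10 patch samples and 20 of 40
  reference samples. The threshold generalizes "windows without data are
  excluded" to a fractional quota; setting `min_fraction` near 0 keeps any
  window with at least one sample per device. Exclusions are counted per
  stage (`exclusion_log()`), because data-quality accounting is a central
  part of the validation narrative.
* During the hypoxia phase the same windows also carry the reference
  SpO2 median, used later for stratification. The hypoxia phase is
  windowed as one continuous interval rather than aligned to plateau
  boundaries; stratification happens afterwards on the windowed SpO2
  median, since plateau timing in a real session is operator-determined.

## Agreement metrics

For windowed differences $d_i = \text{test}_i - \text{ref}_i$:

* $\mathrm{MAE} = \tfrac1n \sum |d_i|$ — the primary accuracy criterion,
  less outlier-sensitive than the mean bias;
* $\mathrm{RMSE} = \sqrt{\tfrac1n \sum d_i^2}$ — combines systematic and
  random error;
* Bland–Altman mean bias $\bar d$ with 95% limits of agreement
  $\bar d \pm 1.96\, s_d$, where $s_d$ is the sample SD (n − 1
  denominator) of the differences;
* Pearson $r$ with the two-sided p-value from
  $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom. A constant
  input makes $r$ undefined; `pearson_cor()` raises a typed error, and
  `analyze_stratum()` converts it to a flagged `NA` so a batch run
  continues.

These quantities satisfy two identities that the test suite asserts on
random inputs: $\mathrm{MAE} \le \mathrm{RMSE}$, and
$\mathrm{RMSE}^2 = \bar d^{\,2} + s_d^2 (n-1)/n$.

### Bootstrap confidence intervals

MAE and RMSE CIs use the percentile bootstrap with 10,000 replicates by
default. Percentile (rather than BCa or normal-theory) intervals are the
minimal-assumption choice and are stated explicitly in
`bootstrap_config()`. Quantiles of the replicate distribution use the
type-7 (linear order-statistic interpolation) definition. Every interval
requires a seed and is exactly reproducible.

Two deliberate extensions:

* **Resampling unit.** The default resamples pooled windows i.i.d.,
  matching the pooled per-stratum "number of data points" convention of
  validation reports. Pooled windows from the same participant are
  autocorrelated, so a participant-level cluster bootstrap
  (`unit = "participant"`) is offered as a sensitivity analysis.
* **Exhaustive mode** enumerates all $n^n$ equally likely resamples for
  tiny $n$, providing an exact reference result against which the Monte
  Carlo path is verified.

Between-subgroup comparisons (`compare_subgroups()`) resample each
subgroup independently and report the percentile CI of the difference in
MAE (and RMSE); "significant" means the CI excludes zero. The underlying
study reported only that subgroup differences were not significant without
naming a test; the bootstrap difference CI is our interpretation, chosen
for consistency with the rest of the machinery, and is labeled as such.

## Clinical acceptance and SpO2 strata

Following ANSI/AAMI-style accuracy criteria, a stratum is *clinically
acceptable* when its MAE is at most 5 bpm (HR) or 3 rpm (RR), inclusive
("within 5 bpm"). `evaluate_acceptance()` also reports whether the entire
bootstrap CI clears the threshold. An unacceptable MAE is a result, not a
pipeline failure.

Hypoxia windows are stratified by their SpO2 median into normoxia
($\ge 90\%$), mild hypoxia ($[85, 90)$) and severe hypoxia ($< 85\%$).
The boundaries are half-open on the continuous scale: descriptions like
"85–89.9%" treat 89.9 as a display artifact of one-decimal reporting, not
a bin edge, so 90 is normoxia and 85 is mild. For per-level accuracy
curves, `assign_spo2_level()` bins windows at the desaturation protocol's
six plateau targets (95, 90, 87, 85, 83, 80%) by nearest-target
assignment within ±1.25% (half the smallest target gap); the binning rule
is a package choice, ties go to the first (higher) target.

## The synthetic session generator

Real validation recordings are rarely shareable, so `vitalval` ships a
generator that emulates the study design with known ground truth:

* **Participant baselines** drawn from Normal(72.9, 11.9) bpm and
  Normal(16.3, 3.6) rpm — a healthy-volunteer cohort — truncated to
  40–150 bpm and 4–31 rpm.
* **Movement protocol**: seven consecutive activities (at rest 180 s,
  sit-to-stand 120 s, tapping 120 s, rubbing 120 s, drinking 90 s,
  turning pages 120 s, tablet 180 s — nominal durations; real sessions
  vary). Sit-to-stand, the one dynamic activity, raises HR by 18 bpm and
  RR by 2 rpm by default; turning pages raises RR by 2 rpm.
* **Hypoxia protocol**: SpO2 descends piecewise linearly from 98% through
  plateaus at 95/90/87/85/83/80% (180-s holds, 60-s transitions, 0.5%
  plateau jitter). HR rises 0.4 bpm per percent SpO2 below 90%, a simple
  linear stand-in for the hypoxic heart-rate response. This is not a
  gas-exchange model; the pipeline only consumes SpO2 medians for
  stratification.
* **Truth wander**: within each stage HR and RR follow a bounded random
  walk (SD 1.5 bpm / 0.8 rpm accumulated over the stage), clipped to the
  physiological bounds.
* **Device observation**: each channel samples the truth on its nominal
  grid, then adds a per-stage additive bias, white Gaussian noise on the
  instantaneous estimates, Poisson-timed artifact bursts (5–15 s of
  zero-mean disturbance, more frequent and larger during sit-to-stand),
  and independent per-sample dropout.

Default biases and noise levels are calibrated once to echo the bias and
LoA magnitudes that chest-patch validation studies report — marginal HR
overestimation that worsens during the dynamic activity, consistent RR
underestimation — but they are configuration, not claims about any
device, and the simulator is not presented as reproducing any published
table.

Because a 40-s median attenuates white noise, instantaneous noise SDs are
not directly comparable with window-level error. The median of $k$ iid
Gaussian estimates has variance $c_k \sigma^2$ with $c_{10} = 0.13833$
and $c_{40} = 0.03793$ (computed by numerical integration of the joint
density of the two central order statistics; `expected_window_sd()`).
The cohort truth ledger records the resulting analytic window-level
difference SD alongside every injected parameter, so parameter-recovery
tests have honest closed-form targets. Artifacts and dropout perturb this
slightly; at the default (low) rates the median filter absorbs almost all
of it.

Determinism: a session spec plus its seed fully determines every output.
Child seeds for channels and cohort members are derived by a fixed
integer congruential mix, keeping streams reproducible yet distinct.

### What passing tests do and do not show

The generator produces plausible multirate streams with known error
structure; it does not model the patch's internal rate-estimation
algorithms, ECG/capnography waveforms, posture effects, sensor detachment
or clock drift (devices are assumed synchronized at source). Passing
recovery tests therefore demonstrates that the *analysis pipeline* is
correct and unbiased under its own assumptions — not that any physical
device meets the clinical thresholds.

## Numerical and design choices

* Timestamps are decimal seconds from session start; CSVs are written
  with 3 decimals, making text round trips exact.
* Unparseable or non-finite sample rows are dropped and counted
  (dropouts are expected); structural file problems are hard errors, as
  are unknown stage labels.
* Stage vocabulary is fixed to the seven movement activities plus
  `hypoxia`.
* Degenerate inputs: an empty window yields an absent median, not an
  error; a single difference yields MAE and bias only; strata with fewer
  than 2 windows are skipped in plots and comparisons with a logged
  reason.
* Per-stratum bootstrap seeds are derived from the run seed, so full
  re-runs reproduce every CSV byte-identically.
* Inputs are never rounded: device value precision is unspecified in
  general, so the toolkit accepts decimals throughout.

## Problem sizes used in the test suite

The suite exercises the pipeline at desk scale: a 29-participant default
cohort (about 1,000 hypoxia windows per variable) for structural and
recovery checks, 1,000-dataset simulations at $n = 500$ with 2,000
replicates per interval for bootstrap coverage, $10^5$ draws for the
closed-form MAE limit ($\sigma\sqrt{2/\pi}$ at zero bias), and exhaustive
$3^3$ enumeration for bootstrap exactness. These sizes were chosen to
give tight statistical checks while keeping a full run of the suite in
the low minutes.

## Known limitations

* The LoA use the classic Bland–Altman form with $z = 1.96$ and a single
  pooled SD; no repeated-measures or within-subject correction is
  applied, mirroring common practice in device validation reports. The
  cluster bootstrap is the provided mitigation.
* Pooled-window resampling understates CI width when windows are strongly
  autocorrelated within participants.
* The hypoxia HR coupling and SpO2 trajectory are deliberately simple;
  per-plateau timing in real sessions is operator-determined and varies.
* No artifact detection or waveform cleaning is attempted — the devices
  under comparison already output rate estimates.
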