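---
title: "Simulating closed-loop MEP neurofeedback: models, calibrations and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating closed-loop MEP neurofeedback: models, calibrations and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meploop)
```

`meploop` simulates an operant neurofeedback paradigm in which participants
learn to volitionally raise ("UP") or lower ("DOWN") their corticomotor
excitability, read out as the peak-to-peak amplitude of motor evoked
potentials (MEPs) elicited by transcranial magnetic stimulation (TMS), and
re-implements the complete offline analysis chain: MEP cleaning, baseline
normalization, pre-stimulus EEG band-power features, linear decoding of the
two brain states, and paired-pulse probes of intracortical inhibition and
disinhibition (SICI, LICI, LCD). No human or hardware data are involved:
every stage is exercised against a generative model of a synthetic
participant whose defaults are calibrated to the trained group effects the
paradigm is known to produce (about +83.8 % and −30.6 % MEP change from
baseline, band-power effect sizes near |d| ≈ 0.7–0.95, single-epoch state
decoding near 81.5 %, and an LCD increase of ≈ 51 percentage points in the
trained UP state).

This vignette is the package's methods account: the generative model and
its assumptions, the closed-loop engine, the analysis conventions, the
numerical calibrations behind the defaults, and what the synthetic data do
*not* capture.

## The synthetic participant

### Corticomotor excitability and MEP generation

A latent excitability multiplier $e$ (1 at rest) acts on the *effective
stimulus intensity* of a sigmoid recruitment curve:

$$\mathrm{E}[\mathrm{MEP}] \;=\; \frac{M}{1 + \exp\{-k\,(I \cdot e - I_{50})\}},$$

with plateau $M$ (`mep_max`, default 4 mV), steepness $k$ and half-max
intensity $I_{50}$ (default 130 % of the resting motor threshold, so that
the calibrated test intensity lands near 130 % RMT, as the paradigm's
post-hoc arithmetic suggests). Placing the excitability inside the
recruitment argument means up-regulation saturates at the physiological
plateau rather than growing without bound. Around this mean, each MEP
carries multiplicative mean-one log-normal noise (`mep_noise_cv`, default
0.15) plus a small zero-mean trial-to-trial excitability jitter
(`excit_jitter_sd`, default 0.01). Because the recruitment curve is steep at
the operating point, the jitter contributes roughly another 10 % of
amplitude variability; the combined per-trial CV of ≈ 0.18 sits at the
clean end of published MEP variability and keeps desk-scale cohort
estimates stable.

### Operant learning

Skill accrues only on veridically rewarded trials: each such trial adds
`learn_rate` (default 0.02) to the trained direction's skill, capped at 1.
Expected excitability is `1 + skill_up * (up_asymptote - 1)` under UP,
`1 - skill_down * (1 - down_asymptote)` under DOWN, and exactly 1 at rest.
Sham reward (the control group) never moves skill, so control cohorts are
null by construction. The linear capped rule is a stand-in — the paradigm
literature describes learning only qualitatively — and its constants are
calibration knobs, not claims about learning dynamics.

### Calibrating the asymptotes

The asymptote defaults are solved, not guessed. At construction the
asymptotes solve for the target percent changes at the ideal operating
point (test intensity $= I_{50}$, baseline at half plateau), integrating
the excitability jitter by Gauss–Hermite quadrature. When a cohort is
simulated through the engine (`simulate_experiment()`), each subject's
asymptotes are additionally re-solved against their *realized* calibration
(`recalibrate_asymptotes()`): the subject's attainable modulation range is
expressed relative to the operating point the calibration actually chose,
which mirrors the fact that the study's group effect is defined on
individually calibrated baselines. This solve also folds in deterministic
corrections for what the offline chain does to a measured mean:

* expected trimmed-mean factors of a log-normal sample (closed-form
  order-statistic integrals) for the 30-trial feedback versus 20-trial
  baseline blocks, and
* the subject-pool interquartile fence, modeled as a five-component
  log-normal mixture over the course's trial composition (resting blocks,
  first-day learning-ramp trials at an average skill of 0.65, and trained
  trials of both directions), which clips the right tail of the
  highest-amplitude condition.

All corrections are numeric integrals with no simulation or seed
dependence. On the UP side the attainable mean is capped just below the
plateau; the cap binds only for subjects whose fitted half-max landed well
above the true one.

### Engine calibration protocol

The resting motor threshold is the lowest grid intensity at which at least
5 of 10 pulses exceed 50 µV. The recruitment curve applies 6 pulses at ten
intensities (90–160, 180, 190 % RMT) in randomized order. The recorded
maximal MEP is the largest per-intensity mean; the *test intensity*,
however, is taken from a sigmoid fitted on the log scale (multiplicative
noise makes log residuals homoscedastic), at the fitted half-plateau
intensity. Reading the half-max off the fitted curve rather than off the
noisy max-of-means matters: the maximum of ten noisy means overestimates
the plateau by several percent, which would push the measured baseline far
enough above half-max that the +83.8 % target becomes unreachable for much
of a cohort (the ceiling is $1/\text{baseline fraction} - 1$). A monotone
interpolation at half the recorded maximum is the fallback when the fit
fails.

## The closed-loop trial engine

A trial begins with the four-muscle EMG gate: the trailing 100 ms rms of
every channel must stay below 7 µV continuously for 500 ms, both before
the fixation cross and throughout the 5.5–8.5 s uniform fixation interval
(the gate re-arms and pauses the trial otherwise). After the pulse, the UP
rule rewards MEPs strictly above the criterion amplitude and the DOWN rule
strictly below (equality is never rewarded). The criterion starts at the
session's 20-trial baseline mean and moves multiplicatively after each
30-trial block: +10 % (UP; −10 % DOWN) above 70 % success, ±20 % above
90 %. Steps compound across blocks; the trial log carries the full audit
trail so the criterion after $k$ blocks equals the baseline mean times the
exact product of step factors. Whether the original paradigm compounded
steps or re-based them on the baseline is not stated; compounding is this
package's documented choice, as is treating each block's staircase
decision as memoryless. The control group receives the deterministic
fixed-rate schedule (cyclic reward–reward–none, 66 %, 20 rewards in 30
trials) regardless of the measured MEP.

Two EMG paths exist. The default statistical path draws gate outcomes and
the logged 110–10 ms pre-pulse rms directly from the relaxed-noise law
(truncated below the gate threshold — exactly the gate's postcondition) and
is used for cohort-scale simulation. The trace path synthesizes raw 2 kHz
4-channel EMG, a stimulus artifact and a Gaussian-windowed ~130 Hz MEP
waveform, and measures it through the offline pipeline; the test suite
shows both paths agree. Session types beyond training days — the
EEG-session day with two half-sessions and per-half baselines, retention
(skill decayed to `retention_frac`), feedback-free (full timing, display
suppressed, no learning) and dual-coil opposite-hemisphere blocks
(spillover `1 + coupling * (e - 1)`) — are scheduler variants of the same
block machinery.

## MEP cleaning

EMG is band-pass filtered 30–800 Hz (4th-order Butterworth, zero-phase),
separately for the pre-pulse segment and the MEP segment so the MEP cannot
smear into the background estimate. Background EMG is the rms over
110–10 ms before the pulse; the MEP is the peak-to-peak amplitude in a
20–45 ms post-pulse window (the conventional hand-muscle latency; the
window is a package choice since no search window is standard) reported in
mV. Cleaning runs per subject in a documented order: block trimming first
(one maximum and one minimum per block, first occurrence on ties), then
three exclusion rules on the post-trim pool — absolute background above
0.01 mV, background above the subject's mean + 2.5 SD over all trials,
and amplitude above Q3 + 1.5 (Q3 − Q1) over the subject's whole trial set,
with quartiles by linear interpolation of order statistics (the R type-7
convention; the fence's outcome depends on it, hence it is pinned).
Each excluded trial carries exactly one reason, the first failing rule.
Whether the original 2.5 SD rule used the pre- or post-trim pool is
unstated; post-trim is the default here and a flag flips the order.
Percent change from baseline and the UP−DOWN modulation difference are
computed on cleaned block means against the same-session baseline block.

## Pre-stimulus EEG

### The epoch generator

Each 1.5 s, 1000 Hz pre-pulse epoch is a randomized-phase $1/f$ background
(fixed spectral moduli, slope 1.5) plus one constant-envelope oscillator
per band (center frequencies 2.5, 6, 9, 12, 17.5, 26, 40, 65 Hz; in-band
oscillator-to-background power ratio 6). The UP/DOWN state shifts each
oscillator's log-amplitude by $\pm\Delta_j/2$, scaled by the learned skill
and attenuated by half on non-hotspot channels. Epoch-to-epoch amplitude
jitter is log-normal with SD `band_sigma` per band, of which a fraction
`band_noise_cor` of the variance is carried by a factor shared across all
bands — an arousal-like global fluctuation that makes band noise
cross-correlated, as in real EEG. Constant-envelope oscillators (rather
than amplitude-modulated narrowband noise) were chosen deliberately: band
power is then an analytic function of the eight log-amplitudes, so the
shift vector realizing prescribed effect sizes can be *solved* instead of
tuned.

### Calibrating the band shifts

`band_d` prescribes the signed standardized UP-vs-DOWN difference of
relative band power at the hotspot (defaults: delta +0.754, theta −0.947,
low alpha −0.805, high alpha −0.714, betas 0, low gamma +0.753, high gamma
+0.712). The calibration (run once per parameter set, cached, under a
private RNG stream) works in four steps:

1. Expected Welch responses are computed exactly: unit-tone profiles by
   phase-averaged probes, the background by convolving its line powers
   with the squared Hann window transfer.
2. First and second moments of relative band power under a candidate shift
   are computed by a fixed-seed antithetic Monte Carlo on the analytic
   power map (exact under the log-normal amplitude law), plus the Welch
   estimation noise measured from a deterministic zero-jitter probe.
3. Compositional closure: the eight bands partition the analyzed 1–80 Hz
   range, so UP−DOWN differences of relative power must sum to zero, while
   prescribed $d_j$ and band SDs $s_j$ need not satisfy
   $\sum_j d_j s_j = 0$. Consistency is restored by scaling the amplitude
   variability of the negative-effect bands (a free realism parameter)
   until the weighted sum vanishes; with the default pattern this leaves
   the beta bands with essentially no effect, matching their absence from
   the prescribed pattern. If a user-supplied sign pattern makes closure
   impossible this way, the residual is spread in least-squares fashion.
4. Newton iteration on the moment map, followed by one empirical
   correction pass through the actual synthesis and Welch pipeline,
   absorbs what the analytic model misses (amplitude-dependent estimation
   noise). Realized epoch-level effect sizes land within a few hundredths
   of the targets.

Between-subject heterogeneity multiplies in via `subject_het` (default
0.2): each subject's target mean-difference vector deviates from the
cohort mean by a Gaussian with SD 0.2 times the epoch SD, mapped back to
log-amplitude space through the calibration Jacobian.

### What the printed effect sizes can and cannot jointly mean

The study-level per-band d values are between-subject paired effect sizes
over 14 subject means, while single-epoch decoding at ≈ 81.5 % requires
epoch-level separations of the same order. An i.i.d.-epoch generator
cannot produce both simultaneously: subject means of 60 independent epochs
are far less variable than real session means (which carry slow
non-stationarities), so matching the subject-level d would require either
enormous between-subject heterogeneity (destroying the tight ±5 %
accuracy spread) or implausibly small epoch effects (destroying the
accuracy). `meploop` resolves this by letting `band_d` parameterize the
*within-subject epoch-level* standardized difference — the quantity
decoding actually sees — and reporting both effect sizes from
`contrast_states()`: `d_epoch` (the generator's recovery target) and
`d_subject` (which, on i.i.d. epochs, is mechanically much larger than the
printed values). `subject_het` is calibrated to the reported ±5 %
across-subject accuracy spread, and `band_noise_cor` (default 0.6) is the
one generator constant calibrated against the printed decoding accuracy
itself, since per-band effect sizes leave the cross-band noise covariance
— which is what decoding accuracy is sensitive to beyond the d's —
unconstrained.

### Spectral conventions

Welch periodograms use 1 s Hann segments with 50 % overlap (two segments
per 1.5 s epoch), giving 1 Hz bins, normalized so the one-sided power sum
equals signal power. The analyzed range is 1–80 Hz; relative power
expresses each bin as a percentage of that range's total, so the eight
bands partition 100 %. Band edges are inclusive integer bins (delta 1–4,
theta 5–7, low alpha 8–10, high alpha 11–13, low beta 14–21, high beta
22–30, low gamma 31–50, high gamma 51–80 Hz); the sub-1 Hz part of the
conventional delta band is unresolvable in a 1.5 s epoch, so delta starts
at 1 Hz. The "1/f transform" used for classifier features multiplies each
bin's relative power by its frequency before band aggregation — the
simplest whitening consistent with the phrase; the exponent is
configurable because the transform is a convention, not a uniquely defined
procedure. The low-gamma:high-alpha ratio is computed on unscaled relative
power. Because the eight raw relative powers sum to exactly 100 %, a joint
regression design containing all of them plus an intercept is singular by
construction; the trial-wise robust regression therefore uses the
1/f-scaled band powers (no linear constraint) as its joint predictors,
with the ratio in a separate single-predictor model. Robust fits are
iteratively reweighted least squares with the Huber loss; per-subject
slopes are aggregated by Wilcoxon signed-rank tests against zero
(normal approximation) with Benjamini–Hochberg correction, the same
testing convention used for the band contrasts.

## State classification

The decoder is a linear support-vector machine with fixed margin parameter
C = 1, evaluated by stratified 10-fold cross-validation on the nine
hotspot features (eight 1/f-scaled band powers plus the ratio), optionally
plus the same nine from the homologous opposite-hemisphere electrode.
Features are z-scored with training-fold statistics only — the permutation
and leak-detector tests verify that shuffled labels yield chance accuracy.
Stratification is justified by the balanced 60/60 design; within-fold
standardization (not stated in the source paradigm) is required for the
margin weights to be comparable across features, which recursive feature
elimination relies on. RFE removes one feature per iteration (smallest
absolute weight, ties toward the later column so earlier columns rank
higher); per-subject rankings aggregate by the modal feature per rank
position with mean-rank tie-breaks. The permutation null re-runs the
identical pipeline on shuffled labels and reports the rank-based p-value
`(1 + #{null >= true}) / (n_perm + 1)`.

## Paired-pulse protocols

Protocol invariants are enforced at construction: SICI uses a 1.97 ms
inter-stimulus interval with a sub-threshold conditioning stimulus, LICI
100 ms with a supra-threshold one, and LCD differs from LICI only by its
220 ms interval. The conditioning-stimulus search scans 50–90 % RMT in 5 %
steps (SICI) or 106–114 % in 2 % steps (LICI), 10 trials per candidate,
and returns the candidate closest to 50 % inhibition, ties toward the
lowest intensity (conservative stimulation); LCD inherits LICI's result.
The generator maps conditioning intensity to inhibition depth through a
logistic whose midpoint sits inside the search range. In the generator,
SICI and LICI ratios are state-independent; LCD multiplies the
single-pulse amplitude by `1 + gain`, with a gain of +50.9 percentage
points at full UP skill and −5.2 at full DOWN skill. The DOWN default is
not zero because the two reported mean differences (UP vs baseline 50.9,
UP vs DOWN 56.1) jointly imply a small, non-significant DOWN deficit of
about −5.2 — the generator encodes both printed numbers as its own
expectations. Interleaved blocks hold exactly a quarter each of
single-pulse, SICI, LICI and LCD trials in seeded random order, with
feedback only on single pulses; state-dependence is summarized per
protocol by the (state − its own baseline) differences and their
interaction, tested by subject-level sign-flip permutation with FDR across
the three protocols.

## Problem sizes, reproducibility and limitations

All randomness flows from one master seed through per-participant derived
seeds; an identical seed reproduces a cohort bit for bit. The calibration
machinery runs under a private RNG stream and never perturbs the user's.
Simulated study sizes mirror the paradigm: 15 experimental and 13 control
participants, four training days of 4 × 30 feedback trials plus 20-trial
baselines and 12-trial post-rest blocks, an EEG day yielding 60 UP and 60
DOWN epochs, 14 subjects in the decoding analyses, and paired-pulse days
with an 80-trial resting baseline plus three 24-trial interleaved blocks
per state. The package's own verification uses replicate-cohort Monte
Carlo at these sizes (up to 100–200 replicates for null-calibration and
effect-size-recovery checks).

What the synthetic data do not capture: artifacts (ocular, muscular,
cardiac — the generator is artifact-free, so the ICA stage of a real
pipeline is a pass-through here), volume conduction and realistic
cross-channel covariance (channels are independent except for the shared
shift), slow non-stationarities within and across sessions (epochs are
i.i.d. given the state — see the effect-size discussion above), biophysics
of I-wave recruitment, and any quantitative model of human learning
trajectories. Passing recovery tests therefore demonstrates that the
analysis chain measures what the generative model encodes at realistic
noise levels — not that it would behave identically on real recordings.
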