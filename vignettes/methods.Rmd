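---
title: "Models and methods behind vanlp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vanlp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`vanlp` analyzes single-trial EEG amplitudes recorded while adaptive
staircases hold a visual stimulus at two awareness thresholds — detection
(experiencing *something* vs. *nothing*; PAS2 vs. PAS1 on a three-level
perceptual awareness scale) and identification (experiencing the stimulus
orientation vs. only something; PAS3 vs. PAS2). This vignette documents the
generative model of the synthetic data, the selection and feature rules, the
statistical model and its sampler, and the numerical and design decisions a
user or reviewer would want spelled out.

## The simulated observer

The observer is a two-probit ordered response model on the 0–100 opacity
scale:

* P(PAS ≥ 2 | x) = fa + (1 − fa) · Φ((x − μ_d)/σ_d)
* P(PAS = 3 | x) = min(P(PAS ≥ 2 | x), Φ((x − μ_i)/σ_i))

with false-alarm rate `fa` at zero opacity and a lapse mixture that replaces
the rating with a uniform draw on {1, 2, 3} at a small rate. The `min`
enforces ordered-response coherence (a clear-orientation report implies at
least a something-report). The source study fits probit psychometric
functions to each staircase but does not state a generative response model;
the two-probit form is the simplest model consistent with those fits.

Defaults place the population detection threshold at μ_d = 1.05 (SD 0.30
across subjects) and the identification threshold at μ_i = 2.85 (SD 1.20,
truncated above μ_d), matching the condition-wise opacity means the design
targets (0.95/1.16 unaware/aware detection, 2.80/2.90 identification) and
their between-subject spreads. The probit scales σ_d = 0.30 and σ_i = 0.45
are calibration choices — no per-subject slopes are available to copy — set
once so that staircase-tracked opacities hover in the printed ranges. The
false-alarm default 0.04 reproduces roughly one false alarm per 23 catch
trials; the lapse default is 0.02. Orientation-report accuracy is a lookup
table by condition and rating, with defaults 0.51/0.53 (unaware/aware
detection), 0.72 (unaware identification) and 0.97 (aware identification).

## Staircases

Both transformed up-down rules target the 50% point of the relevant
psychometric function: 1-up-1-down moves after every response, 2-up-2-down
only after two consecutive identical responses (the counter resets after
each move). A movement-direction change is a reversal; after every second
reversal the step is multiplied by the shrink factor (default 0.5, a
conventional choice — only "decreases at every second reversal" is given)
and never drops below one grid unit. Opacity is quantized to a grid of
`resolution` representable levels on the software scale (default 500; the
configurations with 200,000 and 5,000 levels used for later subjects are
available via the same parameter). When a proposed level falls exactly
halfway between grid points, the tie is rounded *against* the direction of
movement; with a too-coarse grid this prevents the staircase from locking
into a two-level oscillation. Sessions interleave the two staircases with
stimulus-absent catch trials, either per-trial Bernoulli (catch probability
0.05; the default, matching the single-phase design) or in pseudo-random
21-trial sections (10 left, 10 right, 1 catch). A separate no-EEG
calibration pre-phase is not modelled; the probit fit (`fit_probit`) plays
that role when needed and reports `converged = FALSE` rather than erroring
on one-sided or separated data, mirroring the repeat-the-staircase response
to a non-converging calibration.

## Synthetic epochs

Epochs span −100 to 800 ms at 512 Hz (downsampled to 256 Hz in the default
pipeline) over 14 channels. Signal components are raised-cosine bumps,
uniform across their electrode set: a negative VAN bump (180–280 ms over O1,
O2, PO3, PO4, PO7, PO8) and a positive LP bump (350–550 ms over Pz, P1, P2,
CPz, CP1, CP2). Bump time courses are normalized *on the epoch's own sample
grid* so that the window mean equals the programmed amplitude exactly; the
window mean is the only feature the analysis consumes, so the bump shape is
otherwise immaterial. Amplitudes follow the linear trial model

> amplitude = aware · (effect(threshold) + subject deviation)
>             + (opacity − μ_subject,threshold) · slope

with defaults −2.12/−0.46 µV (VAN, detection/identification), +1.83/+0.43 µV
(LP), slopes −3.61/+3.19 µV per opacity unit, and a between-subject effect
SD of 0.8 µV. The opacity term is anchored at the subject's own threshold:
block-centered opacity is an analysis-side quantity (it depends on the block
length, a multiverse setting), so the generator cannot condition on it; the
anchored form is the same linear model up to block-level intercept shifts,
and the block-centered regression recovers the same slope. Noise is white
Gaussian per sample (default SD 25 µV; a 1/f-shaped mode is available), and
with probability 0.04 an epoch receives a 300 µV half-sine drift whose
ground-truth artifact status is recorded, so the artifact flagger's
sensitivity is testable.

What the generator deliberately does *not* emulate: realistic scalp
topography and volume conduction, temporally correlated background EEG (in
the default mode), eye blinks and their ICA removal, bad channels, or
vendor file formats. Passing tests therefore demonstrate that the analysis
machinery is correct and calibrated under the assumed data-generating
process — not that it is robust to every pathology of real recordings. One
practical consequence of white noise: a per-sample SD of 25 µV yields
single-trial window-mean noise of roughly 1.5–2 µV, smaller than typical
real-data trial variability; effect recovery in the tests is accordingly
cleaner than on real EEG.

## Feature extraction

Baseline correction subtracts the per-channel mean over [−100, 0) ms.
Window means average all samples with t in [t_start, t_end] — inclusive on
both ends at the sample grid, a convention the windows' sources leave
unstated — over the window's electrodes. Filtering (the 30-Hz low-pass
before artifact ranges, the anti-alias filter before decimation) uses a
zero-phase symmetric FIR (windowed sinc, order 64, coefficients normalized
to exact unity DC gain) applied with reflection padding; a symmetric FIR has
exactly linear phase, so no forward–backward pass is needed. Artifact
flagging replaces blinded visual inspection with a deterministic rule:
within each subject, an epoch is flagged when its maximum peak-to-peak
channel range (after the 30-Hz low-pass) exceeds median + 5·MAD, with an
absolute 10 µV floor on the MAD term so that degenerate sessions of
identical epochs flag nothing. Per-subject thresholds are retained
deliberately, since range distributions differ strongly across subjects.

## Trial selection

For each subject and staircase, consecutive non-catch trials form blocks of
16 (or 20) trials; a trailing partial block is invalid (the chance criterion
is defined for full blocks, and padding would bias the aware-count test). A
block is valid when its aware count lies in the widest symmetric range
around n/2 whose exact Binomial(n, ½) probability is strictly below the
criterion — (16, .80) → 6–10, (16, .55) → 7–9, (20, .75) → 8–12,
(20, .50) → 9–11. Opacity is mean-centered within valid blocks (drift
removal). Exclusions then proceed in order: bad-EEG trials (unless a
multiverse cell includes them); subject-by-threshold conditions with fewer
than 25 trials in either awareness cell (a subject failing both conditions
drops entirely); and a single-pass 3-SD cut on each amplitude measure
computed once across all retained trials and subjects — single-pass because
no iteration is specified, and separately per measure so a VAN outlier does
not cost an LP trial. The grand mean and SD are computed after the validity
and minimum-trial filters, following the narrative order of the procedure.

## The inference model

Trial amplitudes are modelled as

> y_i = x_i′β + x_i′u_{s(i)} + e_i,  e_i ~ t_ν(0, σ)

with x the un-standardized design (awareness dummy, block-centered opacity,
and for the full model the threshold dummy and its interactions; orientation
optionally), β the fixed effects with independent Normal(0, 2) priors, and
u_s subject-level random coefficients on the same design. The Student-t
likelihood realizes "robust" regression; ν is estimated with a Gamma(2, 0.1)
prior truncated at 1, and a Gaussian likelihood is available behind a flag.

Two deliberate departures from a brms-style default are documented here.
First, random effects are independent across coefficients (diagonal
covariance) with half-t(2) priors on their SDs via the Huang–Wand
inverse-gamma augmentation, rather than a full covariance with an LKJ
prior: the priors on the quantities of scientific interest (the fixed
effects) are exactly the stated Normal(0, 2), the random-effect structure is
an implementer choice, and the diagonal form keeps every conditional
conjugate. Second, sampling uses the package's own blocked Gibbs sampler on
the scale-mixture representation (λ_i ~ Gamma(ν/2, ν/2) mixing weights):
blocked draws of β, of each u_s, of the variances, of λ, and of ν from a
discretized grid (1–30 by 1, 32–100 by 4 — resolution finer than posterior
uncertainty in ν), plus an exact interweaving (translation) move that shifts
mass between β and the subject effects to decorrelate the hyper-means. The
sampler is validated in the test suite against an independent JAGS fit of
the identical model on a small dataset, and runs two chains by default with
split-R̂ (flagged above 1.1) and effective-sample-size diagnostics. All
draws are reproducible from the seed.

Posterior summaries per coefficient: mean, equal-tailed 95% CI, Savage–Dickey
BF10 (prior density at 0 over posterior density at 0; the prior term is
closed-form), pd (fraction of draws sharing the posterior median's sign,
zeros counted with the median), and the ROPE fraction of the full posterior
in ±0.1 µV. The posterior density at zero is estimated by default from a
moment-matched normal: the fixed-effect posteriors of this conjugate
hierarchical model are near-Gaussian, and a kernel estimator is unreliable
precisely where Bayes factors are largest (the null far in the posterior's
tail). A kernel estimator (Sheather–Jones bandwidth) is available as
`method = "kernel"`, and the method and bandwidth are recorded with every
BF. When the posterior density at zero underflows, the BF is flagged as a
lower bound. Verbal labels (moderate/strong/extreme at 3/10/100) are
annotations only.

Orientation-report accuracy uses a Bernoulli-logit mixed model with the same
design and priors on the log-odds scale, sampled with JAGS (the likelihood
is not conjugate); degenerate all-correct/all-incorrect inputs are flagged
as separation and not sampled.

## Multiverse

`run_multiverse()` re-runs selection and the full-interaction models for
VAN and LP under the 2×2×2×2 grid of block length, chance criterion,
bad-EEG inclusion, and orientation predictor. Cell seeds derive
deterministically from the base seed (base + cell index), so results are
invariant to execution order and the main cell (16, liberal, exclude,
no-orientation) reproduces a standalone fit with the same derived seed
bit for bit. A failed cell (for example an empty analysis set) is marked
and the run continues. Fast mode keeps 400 draws per chain after 200
warmup — enough for the sign/CI summaries the robustness table reports —
while full mode keeps 1000 after 500; both share all code.

## Problem sizes and runtime choices

The packaged tests exercise the full pipeline on a synthetic study of 24
subjects × 300 trials (≈ 5,100 analyzed trials after selection), a size at
which all fixed-effect credible intervals comfortably resolve the
programmed effects and a full multiverse completes in a few minutes; unit
tests use smaller fixtures (2–10 subjects) built in code. The acceptance
script uses the same sizes. Between-subject and trial counts can be scaled
up freely; generation is streaming, so memory does not grow with session
length.

## Known limitations

* The epoch container is in-memory, with plain-text CSV/JSON writers for
  the trial table, ground truth and summaries; no binary interchange format
  is written.
* The generator's staircase drift induces small block-level shared offsets
  that the (fixed) model formula does not model; nuisance-intercept
  coverage is therefore marginally below nominal while the programmed
  effects are unaffected.
* Real-data ingestion is limited to the documented trial-table schema; raw
  EEG preprocessing (referencing, ICA, channel interpolation) is out of
  scope and must happen upstream.
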