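---
title: "Statistical methods for subjective sleep depth in serial-awakening hdEEG studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for subjective sleep depth in serial-awakening hdEEG studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dreamdepth)
```

## The scientific problem

In a serial-awakening paradigm, sleepers are repeatedly woken from N2
sleep by an alarm and immediately asked what was going through their
mind, how deep their sleep felt, and how sleepy they are (both on
5-point Likert scales). Each awakening also carries the high-density
EEG recorded in the minutes before the alarm. The analytic questions
this package addresses are: (i) which electrode-level spectral features
of the pre-awakening EEG predict perceived sleep depth and sleepiness;
(ii) whether those brain-behaviour mappings depend on the presence of a
conscious experience (a dream); (iii) how the phenomenology of dreams
relates to perceived depth; and (iv) how all of these evolve across the
night.

The package implements the full statistical machinery for these
questions — spectral band-power extraction, channel-wise mixed-effects
models with cluster-mass permutation correction, report-type contrasts
with FDR, a phenomenology PCA, and polynomial time-of-night models —
together with a synthetic cohort generator that emulates the design of
a two-experiment, 44-participant study, so every stage is testable
without access to recorded data.

## Spectral features

Pre-awakening cortical state is summarised by three per-electrode
indices: delta power (0.5–4 Hz, slow-wave activity, the classical
marker of homeostatic sleep pressure), gamma power (25–50 Hz, wake-like
activation), and the gamma/delta ratio (the high-to-low-frequency
balance; higher values mean a more activated, wake-like cortex).

The extraction path is: robust polynomial detrending (order 2,
iteratively reweighted with Tukey bisquare weights, 3 iterations,
3-robust-SD outlier threshold — the reference implementation's exact
reweighting constants are not published, so these are configurable),
extraction of the 120-s window ending at alarm onset, Welch PSD with
4-s Hamming windows and 90% overlap (0.25 Hz resolution), and
trapezoidal integration over each band. Three numerical choices matter:

* **Density scaling.** The PSD is scaled as power per Hz so that its
  trapezoidal integral over a band approximates the band variance;
  the white-noise integral equals the signal variance (Parseval),
  which the tests verify to 10%.
* **Edge interpolation.** Band edges falling between frequency-grid
  points are included by linear interpolation onto the exact edges, so
  the 0.5–4 Hz integral does not depend on the phase of the grid.
* **Log transform.** Band powers are natural-log transformed. Any
  other base would rescale regression coefficients uniformly; natural
  log makes the gamma/delta log-ratio identically `log gamma − log
  delta`, an identity the tests assert to 1e-9. Nonpositive integrated
  powers (possible only for degenerate synthetic input) are floored at
  a machine-epsilon-scaled constant with a warning rather than
  excluded; real recordings never reach the floor.

Raw segments are carried in memory and serialised as plain-text CSV;
feature tables are CSV matrices (records × electrodes) with a JSON
sidecar recording band edges, Welch parameters and log base.

## The mixed model

Every inferential model is a Gaussian-identity linear mixed model with
a participant random intercept:

`outcome ~ predictor(s) + experiment + night + time + (1 | participant)`

Experiment (2 levels) and night (4 levels) are treatment-coded with
experiment 1 / night 1 as references; time is decimal hours relative to
midnight (negative before midnight). Coefficients are reported from the
REML fit with Wald statistics `W = (β/SE)²`, chi-square(1) p-values and
Wald-normal 95% CIs; likelihood-ratio tests and AIC/BIC comparisons use
ML refits, the standard pairing. Although such models are often run
through "generalized" mixed-model interfaces, the Likert outcomes are
modelled on the identity scale — the symmetric CIs this produces are
what the field reports. (The occasionally seen phrasing "squared fixed
effect estimate divided by its standard error" is implemented as the
standard Wald statistic `(β/SE)²`, not the dimensionally inconsistent
`β²/SE`.)

`fit_lmm()` delegates to `lme4`. The channel-wise and permutation
machinery instead uses a purpose-built profiled-REML fitter (in C++)
specialised for the single-random-intercept case: with an indicator
random-effect matrix, all GLS quantities reduce to per-participant
sums, and the profiled deviance is a smooth 1-D function of the
variance ratio, minimised by golden-section search with an explicit
boundary check at zero. The two routes agree to numerical precision
(asserted in the tests against `lme4`), but the compiled fitter is
roughly three orders of magnitude faster — which is what makes 5,000
whole-array refits per permutation test feasible on one CPU.

## Cluster-mass permutation correction

Channel-wise maps of Wald statistics across 256 electrodes require a
multiplicity correction that respects the spatial correlation of EEG
features. The package uses the max-statistic cluster-mass permutation
approach:

1. electrodes with uncorrected `p < 0.005` and a consistent effect
   sign are grouped into connected components of the electrode
   adjacency graph; components with fewer than 3 electrodes are
   dropped; each cluster's mass is the sum of its Wald statistics;
2. the outcome is shuffled within participant-by-experiment strata
   (Fisher–Yates per stratum) and the entire analysis — every
   electrode's model, the same threshold and minimum-size rules — is
   re-run per permutation, recording the maximum absolute cluster mass
   (0 if no cluster forms);
3. a cluster is significant when its mass exceeds the 95th percentile
   of that null; corrected p-values use the add-one convention
   `(1 + #{null ≥ mass}) / (1 + n_perm)` so they are never exactly 0.

Design choices worth recording: positive and negative clusters are
formed separately but compared against a single max-|mass| null
(two-sided correction); the minimum-size rule is applied identically in
observed and permuted data (the only internally consistent choice);
non-converged electrodes are treated as sub-threshold and logged;
participants are nested in experiment, so the strata reduce to
participants, but the composite participant-by-experiment key is used
regardless. Because the Wald statistic is asymptotically pivotal, the
within-participant shuffle yields a calibrated family-wise error rate
even though it breaks outcome–nuisance relationships; the acceptance
suite measures the realised any-significant-cluster rate on 100
global-null cohorts (16 participants, 32 electrodes, 200 permutations)
and requires 0.05 ± 0.04.

**Adjacency.** Contiguity on a sensor array is not uniquely defined; a
Delaunay triangulation of a 2-D projection is one common choice. The
package defaults to a plainer construction that is easy to reason about
and to test: electrodes closer than a distance threshold (default 1.5×
the median nearest-neighbour distance, which connects regular layouts
without bridging across the cap) are adjacent, with a symmetric
k-nearest-neighbour alternative. The construction parameters are stored
as graph attributes and surface in the pipeline's provenance manifest.
On a regular grid the distance rule reproduces rook adjacency exactly.

## Report taxonomy and contrasts

Reports are classified as conscious experience (CE), conscious
experience without recall of content (CEWR, "white dream"), or no
conscious experience (NCE); follow-ups split CEWR into rich/simple
(rCEWR/sCEWR — did the sleeper have the impression of forgetting a
rich, detailed experience?) and NCE into a contentless sense of
presence (CESP) versus full unconsciousness (UNC). A missing follow-up
leaves the subtype missing while the three-level class is retained;
contradictory states (a CE with a follow-up flag) are rejected.

Report-type effects on the ratings are estimated by one mixed model per
unordered pair of levels rather than a single multi-level model — no
ordinal hierarchy of consciousness levels is assumed. Across the
four-level family {CE, CEWR, CESP, UNC} (6 pairs), Benjamini–Hochberg
q-values are reported; the two-level CE+CEWR vs NCE contrast is
reported unadjusted. Per-participant report-type proportions feed a
Friedman test (the statistic is defined as 0 when all ranks tie), and
Wilcoxon signed-rank tests compare the UNC/CESP and sCEWR/rCEWR shares.

## Phenomenology PCA

Six experiential dimensions of contentful dreams — subjective duration
(seconds, log-transformed with a 1-s clamp), vividness, perceptual vs
thought-like content, bizarreness, emotional intensity, and awareness
of dreaming — are z-scored globally (not per night) and
eigendecomposed. The first two components are retained: "perceptual
immersion" (duration, vividness, perceptual richness, bizarreness,
emotion) and "reflective thought" (thought-like content and
meta-awareness against vividness). Component signs are arbitrary in any
PCA; each component is oriented so that its largest-|loading| feature
loads positively, making directions reproducible across runs. The PCA
is fit on CE records with complete ratings only; scores are not imputed
for other report types. Because all features are z-scored first, scores
are invariant to affine rescaling of the raw scales.

## Time-of-night models

Trajectories of ratings, components and EEG indices are modelled with
raw time powers (linear, quadratic, cubic) plus the standard nuisance
terms; for the two ratings, the other rating enters as a covariate to
absorb shared variance. The polynomial order is chosen by BIC across ML
fits with the identical random-effect structure, and the winning
order's REML coefficients are reported. Raw (non-orthogonalised) powers
keep the linear-term coefficient directly interpretable; a condition
warning is issued if the design becomes ill-conditioned. Orders beyond
cubic are not considered.

The sleepiness peak is the stationary point `−b/(2c)` of the quadratic
fixed-effect polynomial, flagged as a trough if the curvature is
positive and flagged when it falls outside the observed time range. The
post-4AM divergence of depth and sleepiness is tested on long-format
data (two rows per awakening) restricted to `time ≥ 4` h with a
measure-by-time interaction. The random effect for this paired model is
a participant-by-measure intercept rather than a plain participant
intercept: each rating keeps its own participant offset, which matches
the generator's structure (independent offsets per rating) and gives
calibrated interaction CIs; with a single shared intercept the
between-measure half of the participant variance would be pushed into
correlated residuals.

For display, "adjusted" values residualise an outcome against
experiment, night and the participant intercepts (deliberately not
time), then recentre to the raw grand mean. This is a plotting
transform only; all inference adjusts internally.

## The synthetic cohort generator

The generator defines the conditions under which the pipeline is
validated. Defaults mirror the emulated design: 44 participants (split
between two experiments, each participant in exactly one) × 4 nights ×
4–8 retained awakenings per night (~1,050 records, matching a study
that retained ~1,024 N2 awakenings from an 8–12-per-night protocol);
report probabilities follow the published mix (CE 42.2%, CEWR 35.5% of
which 70.4% simple, NCE 22.3% of which 50.2% unconscious); awakening
times are uniform on [−1, +7.5] h relative to midnight; participant
intercept SD 0.5 and residual SD 0.9 rating points; perceived depth
rises linearly at 0.127 points/h while sleepiness follows a quadratic
peaking at 3.3 h; immersion and reflective-thought slopes on depth are
0.277 and −0.195.

Mechanically, a latent per-awakening activation drives the
electrode-level log band powers through a configurable effect
topography (delta down, gamma up, so the log-ratio moves one-for-one
with the latent), and the ratings are assembled from the configured
linear predictor plus Gaussian participant and residual noise. Likert
ratings are produced by rounding and clipping a latent Gaussian to
1–5, which reproduces the discreteness of real scales; generation on
the continuous latent scale is available by flag. Phenomenology
ratings arise from two latent factors with fixed loadings; the depth
outcome uses the *realised* component scores (the scores the analysis
itself computes), so generating slopes are recoverable exactly rather
than attenuated by factor-score estimation error. Per-electrode
regression slopes implied by the topography and feature noise
(errors-in-variables attenuation included) are returned as ground
truth.

Seeding is hierarchical: a single master seed spawns per-stage child
streams via a stable string hash, so identical configurations reproduce
byte-identical datasets and enlarging one stage (say, the electrode
count) never perturbs another (say, the drawn report types).

What the generator does *not* emulate: sleep architecture and
hypnograms, spindles/K-complexes, artifacts, non-Gaussian rating
distributions, spatially correlated feature noise beyond the shared
latent, and any stimulus-evoked structure. Passing tests therefore
demonstrate that the statistical machinery is correct and calibrated
under the assumed generative model — not that the scientific
conclusions transfer to any particular recorded dataset. No
per-electrode effect magnitudes are published for the emulated study;
injected cluster amplitudes are free parameters of the simulations.

## Validation strategy and problem sizes

The test suite validates each primitive against an independent oracle:
closed-form sinusoid/Parseval identities for the spectral path, OLS and
`lme4` for the mixed models, exhaustive connected-component enumeration
for cluster formation, a hand-written step-up rule for
Benjamini–Hochberg, and closed-form peak/rank/taxonomy cases. The
calibration experiments run at deliberately modest sizes chosen to keep
the full suite in the tens of minutes on a single core while leaving
Monte-Carlo error well inside the asserted bands: family-wise error on
100 global-null cohorts of 16 participants × 32 electrodes with 200
permutations; localisation of an injected 8-electrode effect over 20
replicates; CI coverage of five model families over 200 replicates
(run on the continuous latent rating scale, since rounding/clipping is
a deliberate coarsening that biases large effects and would conflate
measurement distortion with CI calibration); BIC order selection and
peak recovery at the full study scale over 20 replicates.

## Known limitations

* Only a single random intercept is supported — no random slopes,
  crossed random effects, or ordinal/logistic families. This matches
  the target analyses but limits reuse.
* The permutation engine shuffles the outcome; designs where the
  *predictor* must be permuted within strata are not covered.
* Cluster inference is spatial only (no time × sensor clustering, no
  TFCE), and reports no cluster-level effect size.
* EDF ingestion is out of scope in this build; segments enter as
  in-memory arrays or plain-text CSV.
* Whether near-zero band powers should be floored or excluded is
  unresolved in the emulated methodology; flooring with a warning was
  chosen so that record counts stay stable across bands.
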