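---
title: "Models and methods behind attnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind attnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

attnet analyses attention-network engagement in task and resting-state
fMRI at the parcel level, and ships a seeded synthetic-data generator so
that every stage of both pipelines can be validated end to end. This
vignette explains the models, the tunable parameters, the numerical
choices, and what the synthetic data do and do not establish about real
data.

## Task model

The multiple-object-tracking (MOT) paradigm probes sustained covert
attention. Each 18.2 s trial (seven 2.6 s TRs) has a 3 s cue phase, a
12.7 s motion phase and a 2.5 s probe phase; a run is 16 trials flanked by
two fixation TRs on either side, 116 timepoints in all. Attend trials
(track four cued discs out of twelve, two per hemifield) strictly
alternate with passive trials (all discs cued; no tracking demand), so the
attend-vs-passive contrast isolates attentional engagement from visual
stimulation. We read the interleaving as strict alternation; the probe is
a tracked target on exactly half of the attend trials (the balanced prior
keeps yes/no response bias uninformative). Disc motion uses a repulsion
algorithm: constant base speed, with pairwise and wall forces inversely
proportional to the gap distance, followed by a hard projection step that
enforces the two invariants — centre distance at least one diameter and
containment in the assigned hemifield rectangle — exactly at every frame.
The force law, base speed (4 deg/s), disc radius (0.6 deg) and rectangle
geometry are display conventions collected in `mot_geometry()`; the
invariants, not particular trajectories, are the contract, and the tests
re-check them frame by frame.

The vivid-novel-oddball (ViNO) spatial-cueing task probes attentional
capture. Each 7.8 s trial jitters the cue duration uniformly on
[1.5, 3.0] s with the inter-stimulus interval filling the orienting phase
to exactly 5.2 s, followed by a 0.5 s target, 0.5 s mask and 1.6 s
inter-trial interval. A run holds 48 trials in six blocks of eight with
exactly 33 valid trials (68.75%) and exactly 8 oddball trials placed
uniformly without replacement, so the 1-in-6 oddball rate is exact per
run. Invalid targets appear at one of the three locations of the uncued
hemifield, drawn uniformly. Oddball trials carry five image identifiers
that never repeat within a session (four runs consume 160 unique ids).
Reaction time is measured from target onset; responses beyond the 2.6 s
window count as misses and are excluded from the scored denominators,
which is also how absent responses are handled.

Behaviour is summarised per subject before any group averaging. Tracking
capacity uses Cowan's k = (hit rate − false-alarm rate) × 4.0 with four
targets; at the group-mean rates 0.64 and 0.33 the formula gives 1.24,
while averaging per-subject k can differ slightly (a property of the
estimator, not an inconsistency).

## Haemodynamic model and GLM

BOLD responses are modelled with a two-parameter gamma response function,
h(t) ∝ ((t − δ)/τ)² exp(−(t − δ)/τ) for t ≥ δ, zero before the onset
delay. Defaults are δ = 2.25 s and τ = 1.25 s, giving a peak at
δ + 2τ = 4.75 s; the function is scaled to unit peak. The exponent 2 is
the convention of the surface-based fitting tools this parameterisation
comes from and is configurable.

Condition regressors are boxcars over event intervals convolved with the
HRF on a grid oversampled tenfold relative to the TR and then sampled at
the acquisition times — necessary because ViNO onsets are not TR-locked.
Regressors are scaled so that a sustained block plateaus at 1, which makes
betas directly interpretable as plateau amplitudes and percent signal
change equal to 100 × beta / baseline. Head motion enters as the first
three left singular vectors of the column-centred six-parameter motion
matrix; numerically null singular values (rank-deficient motion) drop
their eigenvectors with a warning. Fixation is the unmodelled baseline, so
the intercept estimates it and serves as the denominator of percent signal
change. The fit is ordinary least squares per parcel with contrast
t statistics on timepoints − rank degrees of freedom. Temporal
autocorrelation is not modelled (no prewhitening); with ~110-timepoint
runs and long task blocks this mainly widens standard errors slightly, and
is listed under limitations.

Group contrast maps are corrected by sign permutation: a one-sample t per
parcel, cluster formation among parcels beyond the two-sided
cluster-forming threshold (alpha 0.01) on an adjacency graph, and a
max-cluster-size null from random per-subject sign flips. Surface meshes
are out of scope, so adjacency is a 10 × 5 lattice per hemisphere over the
synthetic parcellation; the family-wise error calibration, which the test
suite measures directly against the binomial envelope at alpha = 0.01, is
the testable contract. Cluster p values use the add-one permutation
estimator, so at least 100 permutations are required and scoring is by
cluster size.

## Resting-state pipeline

The preprocessing chain, in order, per subject:

1. **Confound regression** (`nuisance_regress`): per run and per parcel,
   OLS residuals on an intercept plus 15 confounds — global, white-matter
   and ventricle signal analogues, six motion parameters and their six
   temporal derivatives. Collinear columns are dropped with a warning.
2. **Framewise displacement** (`framewise_displacement`): the sum of
   absolute first differences of the six parameters, rotations first
   converted to millimetres as arc length on a 50 mm sphere (the
   convention for this FD definition; the radius is configurable). FD is
   zero at each run start; the censoring threshold defaults to 0.5 mm.
3. **Censor + filter** (`censor_and_filter`): flagged timepoints are
   replaced by linear interpolation between the nearest clean neighbours
   (nearest-value extension at run edges) so artifacts cannot spread
   through the filter; a zero-phase 4th-order Butterworth band-pass
   (0.01–0.08 Hz) runs per parcel and per run; flagged timepoints are then
   deleted. The filter family is a design choice — the contract is the
   property tests: a 0.04 Hz sinusoid passes within 5%, 0.20 Hz is
   attenuated by more than 90%, constants vanish away from the zero-phase
   edge transients.
4. **Harmonisation** (`harmonize_and_concatenate`): each run is z-scored
   per parcel over its retained timepoints ("normalised across time"),
   runs are concatenated, the series is truncated to the first 250
   retained timepoints so every subject contributes identical sample
   counts, and the across-parcel mean signal is regressed out. Both the
   earlier global-signal confound regression and this mean-signal
   regression are retained, in that order; the second can be disabled by
   flag. Truncation counts retained (post-censoring) timepoints.
5. **Connectivity** (`network_connectivity`): within each hemisphere the
   dorsal-attention and default-mode parcels are averaged into one series
   each and Pearson-correlated — one r per subject and hemisphere.

Group comparisons collate hemispheres (each subject contributes left and
right as separate observations): with 13 vs 21 subjects the pooled-variance
t test has 66 degrees of freedom and with 13 vs 168 it has 360, which is
the arithmetic that fixes this convention — averaging hemispheres instead
would give 32 and 179. Student's pooled t is the default (Welch by flag)
and Cohen's d uses the pooled standard deviation. The mixed ANOVA fits
value ~ group × hemisphere with subject random intercepts (lmerTest,
sum-to-zero contrasts, Satterthwaite denominators). With equal group sizes
the split-plot REML optimum has a closed form (the classical ANOVA
variance-component estimator); `mixed_anova()` evaluates the lmer deviance
exactly there, because the REML surface is numerically flat near its
optimum and generic optimisers stall at ~1e-8 relative precision in theta,
which would otherwise propagate into the F statistics. Unequal group sizes
fall back to a tight bobyqa fit. No multiple-testing correction is applied
to ROI tests, matching the reporting convention of the analyses this
package reproduces.

## The synthetic-data generator

`generate_rest_subject()` is the heart of the validation strategy. Per
hemisphere it draws a latent band-limited pair: a dorsal-attention latent
a(t) and a default-mode latent b(t) = r·a + sqrt(1 − r²)·e, where e is
made exactly orthogonal to a in-sample and both are unit-variance, so the
realised sample correlation equals the subject's true r exactly, per run.
The subject-level r is drawn once from Normal(r_mean, r_sd) and used for
both hemispheres (the study found no hemispheric difference), clipped to
(−0.999, 0.999). Latents are band-limited to the analysis passband by
construction (white noise filtered with the same Butterworth family,
generated with padding so edge transients fall outside the window), which
keeps the pipeline's own filtering close to an identity on them.

Three structural choices make the injected correlation recoverable through
the full pipeline, including global-signal regression, and they are the
generator's contract:

* **Network means ride exactly on the latents.** All parcel-level nuisance
  — idiosyncratic noise, drift coefficients, confound-leakage and spike
  artifacts — is centred within each network × hemisphere group, so it
  cancels exactly in the network average.
* **The global mean carries no network latent.** Background-network
  parcels receive latents built from components orthogonal to the (a, e)
  plane whose count-weighted sum equals minus the weighted sum of the DAN
  and DMN latents; the across-parcel mean of the structured signal is
  therefore pure nuisance, and mean-signal regression cannot bias the
  DAN–DMN correlation.
* **Every parcel has unit-variance structured content**, so per-run
  z-scoring rescales parcels uniformly and cannot re-introduce latent
  content into the global mean.

On top of this: low-frequency drift (linear and quadratic trends plus one
slow 0.002–0.008 Hz sinusoid shape per network group, per-parcel
amplitudes), AR(1) global/white-matter/ventricle analogues leaking into
parcels with per-parcel coefficients, smooth random-walk head motion, and
motion spikes — sustained steps of 1.0 mm (above the 0.5 mm threshold) in
a random translation parameter at Bernoulli(0.05) timepoints, with a
coincident high-amplitude BOLD artifact. Spiked timepoints coincide
exactly with FD exceedances because the base motion's framewise increments
are orders of magnitude below threshold.

The three shipped presets encode the study conditions: meditators n = 13,
r ~ N(−0.55, 0.18); in-lab controls n = 21, r ~ N(−0.41, 0.21); HCP-like
controls n = 168, r ~ N(−0.39, 0.19). The in-lab regime is two 139-TR runs
at TR 2.6 s (the stated 278 total timepoints; 6 minutes at this TR is
138.5 TRs, so the run length is rounded to keep the printed total — the
source description is internally ambiguous on this point). The HCP-like
regime is four 346-TR runs, a four-runs-of-fifteen-minutes protocol
expressed at the in-lab TR, since grayordinate-resolution differences are
out of scope and the harmonisation stage reduces every subject to the same
250 samples anyway. Task effects inject attend-vs-passive percent signal
changes of +0.587 (DAN) and −0.194 (DMN) for the meditator preset and
+0.434 / −0.097 for the control preset, i.e. the reported group means,
with programmed hit/false-alarm rates 0.64/0.33 and 0.57/0.39.

**What recovery on synthetic data shows, and what it does not.** The
validation demonstrates that the pipeline is an unbiased, correctly
calibrated estimator of the quantities the generator plants, under the
noise structure the generator emulates. Monte-Carlo recovery is unbiased
to within about ±0.01: the residual wander comes mostly from motion
scrubbing (interpolated neighbourhoods perturb the band-limited latents
after filtering) and per-run z-score weighting noise — a known property of
scrubbing pipelines, visible here because the injected truth is available.
The generator does not emulate spatially structured physiological noise,
vascular or arousal-driven global fluctuations with genuine network
topography, inter-parcel distance-dependent artifacts, or session/scanner
effects; a pipeline that passes these tests can still be confounded by
such structure in real data.

## Numerical choices

* Zero-phase filtering follows the forward–backward scheme with
  end-padding of twice the filter length; it is applied column-wise over
  parcels through a vectorised IIR recursion that is numerically identical
  to filtering each parcel separately. Edge transients are inherent to the
  scheme; amplitude checks in the tests therefore measure central windows.
* Interpolation at run edges extends the nearest clean value rather than
  extrapolating.
* Design matrices are rejected as rank-deficient with the offending
  columns named; confound collinearity drops columns with a warning.
* Cluster connected components use a small breadth-first search on the
  adjacency list: the permutation null evaluates tens of thousands of
  component labellings, so per-call graph-object overhead matters.
* Cohort generation derives per-subject seeds from the master seed via one
  `sample.int` stream; everything downstream is a pure function of the
  preset and the seed, and all derived seeds stay below 2^31.
* Monte-Carlo problem sizes used by the validation suite: 40 master seeds
  for the cohort-recovery checks with the HCP-like cohort at 40 subjects
  per seed (the acceptance script uses 60 seeds); 200 repetitions × 200
  sign permutations for the family-wise-error calibration; 250
  permutation fits for the ANOVA null; 4000 draws for the correlation
  null. Cohen's d between cohorts is computed once over the collated
  observations of all seeds: at 13 subjects per cohort the per-seed d is
  biased upward by several percent (per-seed sample SDs underestimate the
  population spread, and 1/s is convex), whereas the pooled estimator
  mirrors a single d computed on full samples. The two cohorts of each
  seed share one master seed (common random numbers), so the meditator
  subjects' standard-normal draws coincide with those of the first
  HCP-like subjects and cancel in the group difference — the classic
  variance-reduction device for estimating differences by simulation.

## Known limitations

No prewhitening in the GLM; no surface geometry (lattice adjacency stands
in for a cortical mesh); the synthetic "hemispheres" are label conventions
without geometry; motion scrubbing attenuates recovered correlations by up
to ~2% in long-run regimes; the generator's confounds are statistical
analogues, not physiological models.
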