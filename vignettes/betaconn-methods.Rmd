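---
title: "Beta-series connectivity: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beta-series connectivity: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betaconn)
```

## The analysis in one paragraph

Task fMRI usually summarizes a region by its average evoked response.
Beta-series correlation instead estimates one response amplitude *per
trial* and per region, and treats the across-trial covariation of those
amplitudes as task-state functional connectivity: two regions whose
trial-to-trial fluctuations track each other are taken to be functionally
coupled in that condition. `betaconn` implements this analysis for a
2x2 event-related social-interaction paradigm in children — factors
social context (Peer: a live chat partner; Character: a story character)
and mentalizing content (Mental / Non-Mental) — from trial-wise GLM
estimation through motion quality control, network summaries, and
group-level mixed-effects inference, together with a synthetic cohort
generator that plants known effects so every stage can be validated
against ground truth.

## Task model

The default schedule is 4 runs of 24 trials (6 per condition per run,
randomly ordered under the balance constraint). A trial is an 8 s Guess
period and a 2 s Feedback period, separated by a jittered fixation; a
second jittered fixation follows each trial. Runs begin with 10 s and end
with 15 s of fixation. Volumes are acquired at TR = 1.25 s, 352 volumes
(440 s) per run.

Jitters are drawn from a shifted exponential on [2, 6] s whose rate is
solved numerically so the *truncated* mean is 3.5 s. Because a random
draw of 48 jitters never sums exactly to the time the acquisition window
leaves open, the draws are rescaled multiplicatively, clipped to [2, 6],
and the residual is spread over the unclipped jitters until the run
duration equals 352 x 1.25 s to 1e-9 s. The 352-volume default is the
acquisition protocol, not a derived quantity: the schedule is stretched
to fill it, which is why the mean realized jitter (about 3.65 s) sits
slightly above the 3.5 s target of the law itself. Trial order is a
uniformly random balanced permutation; schedule quality is checked post
hoc by `design_collinearity()`, which warns when the aggregate
condition regressors correlate above 0.5.

## Trial-wise GLM (LSS)

Each condition's trial amplitudes are estimated by least-squares-single
(LSS): for a 24-trial condition, 24 separate OLS GLMs, each with two task
columns — the target trial and the sum of the remaining same-condition
trials — plus nuisance regressors: one aggregate column per other
condition's Guess events, one for all Feedback events, the per-run
demeaned motion parameters and their backward-difference derivatives
(first element 0), one indicator column per censored volume (censored
volumes are retained in the fit, not row-deleted), and a per-run Legendre
polynomial baseline of order 3 (configurable; appropriate for 440 s
runs). The target-trial coefficients across the 24 fits form the
condition's beta series.

Guess regressors are duration-modulated: a unit boxcar whose length is
the trial's response time (8 s fallback for missing responses) convolved
with a canonical double-gamma HRF (positive gamma shape 6, scale 1 — peak
at 5 s; undershoot shape 16, ratio 1/6; kernel support 32 s, grid 0.02 s)
and normalized so that a sustained block plateaus at amplitude 1.
Convolution is evaluated analytically as the difference of the kernel's
cumulative integral at `t - onset` and `t - onset - duration`,
interpolated onto the volume grid, which avoids discretizing the stimulus
itself. Feedback events use a fixed 2 s boxcar with the same kernel.

Estimation uses QR least squares (`lm.fit`) with multi-response right-hand
sides, so voxel-level and ROI-level fits share one factorization per
design. Because OLS is linear in the data, the beta series of an ROI
average equals the average of its voxels' beta series; ROI mode is
therefore exact, and the voxel mode (5 mm spheres rasterized on a 2 mm
grid) exists for interface completeness. Rank-deficient designs yield a
missing beta with a warning; a design with more regressors than volumes
is an error.

Two properties worth keeping in mind when reading test output: LSS is
*exactly* unbiased only in the isolated-trial limit (trial responses that
overlap each other, or project onto shared nuisance columns such as the
polynomial baseline, bias single-trial estimates — that is the price LSS
pays for variance stabilization, and the reason the exact-recovery tests
use widely spaced schedules with a matched baseline), and at the default
noise level single-trial recovery correlations sit around 0.3–0.45 per
ROI, which is the realistic regime for event-related designs with 8 s
events and AR(1) noise of the same scale as the trial amplitudes.

## Motion QC

Framewise displacement is the sum of absolute backward differences of the
six rigid-body parameters, rotations converted to arc length on a 50 mm
sphere (the conventional reference radius; a flag accepts degree-valued
rotation files). Volumes with FD > 1 mm are censored. A run is excluded
when fewer than 90% of volumes survive, when mean FD (computed over all
volumes, before censoring) exceeds 0.5 mm, when any condition's accuracy
falls below 50%, or when run accuracy falls below 66.7%; a subject needs
at least three usable runs. All triggered reasons are logged, and the
rules are monotone: censoring more volumes can only move a run toward
exclusion.

## Connectivity summaries

Per condition, the beta series of the 14 default ROIs (two 7-node
networks: mentalizing — dmPFC, vmPFC, precuneus, bilateral TPJ, bilateral
ATL; reward — left OFC, right vmPFC, ACC, bilateral ventral striatum,
bilateral amygdala; 5 mm spheres, pairwise non-overlapping) are
correlated (Pearson), giving four 14x14 matrices per subject.
Within-network connectivity is the mean of the 21 unordered pairs per
network, between-network connectivity the mean of the 49 cross pairs;
21 + 21 + 49 = C(14,2), a complete partition of the edges. Node
strengths are the corresponding per-ROI means. Raw r values are averaged
— group results are reported in r units and a Fisher-z option exists but
is off by default. "Collapsed" Peer/Character matrices are the
element-wise mean of the two matrices of that social level, not a trial
concatenation. Alternative node sets (e.g. salience, mirror, motor
configurations) are supplied as editable tables with the same schema;
coordinates for those networks are deliberately not shipped as defaults.

## Inference suite

Group models are linear mixed models with a single random intercept per
subject, fit by REML through `nlme::lme`, with marginal (drop-one) F
tests. The denominator-df convention is the grouping-level one nlme
implements: terms varying within subject are tested against
`n_obs - n_subjects - p_within` df (200 observations from 50 subjects
with three within-subject terms gives F(1, 147)), between-subject terms
against `n_subjects - p_between - 1`. The network-level model is
`connectivity ~ social + mentalizing + age + social:age` with gender,
mean FD, and IQ as covariates; node-strength models repeat this per ROI
and strength type with Benjamini–Hochberg correction across the 28
node x strength interaction tests. Behavioral models drop mean FD (it is
a scanner-specific covariate); report models are per-measure with FDR
across the six interaction p-values. Brain–behavior models act on the
collapsed Peer/Character summaries (`connectivity ~ social * behavior`
plus covariates), so their within-subject denominator df is
`2n - n - 3 = 47` at n = 50; the convention is applied uniformly.

Continuous covariates are mean-centered before fitting, so marginal
main-effect tests are evaluated at the sample mean of age (etc.) rather
than extrapolated to age zero — with an interaction in the model the
uncentered marginal "social" test would answer a question nobody asks.
Interaction estimates and their F tests are unaffected by centering. A
VIF table (1/(1−R²) per fixed-effect column, flag at 2) accompanies every
fit; the interaction column and its parent factor are expected to exceed
the flag.

Post-hoc machinery mirrors common practice: paired t-tests
(`paired_t`, one- or two-tailed), per-condition OLS regressions with
their own exact dfs, partial Pearson correlations controlling for age,
Wilcoxon signed-rank tests for the ordinal reports (zero differences
dropped, tied ranks averaged; the exact conditional distribution is
computed by dynamic programming over doubled ranks for up to 25 retained
pairs — base R's `wilcox.test` cannot do exact-with-ties — and a
continuity-corrected normal approximation beyond), Spearman correlations
(average ranks, t-approximation), and BH-FDR via `p.adjust`. The
age-quartile contrast recomputes the 25th/75th percentiles from the data
(strict inequalities, linear-interpolation quantiles) instead of
hard-coding any particular sample's boundaries. The low motion–age
subsample utility greedily removes the subject whose removal most
reduces |cor(age, mean FD)| until it falls below 0.05 or a target n is
reached, then refits the network models.

## The synthetic cohort and what it does (not) emulate

`generate_cohort()` draws subjects with ages uniform on 8.18–12.97
years, 60% male, IQ ~ N(112, 12) truncated at 85, and a latent RT
deviation per subject (SD 0.25 s). Reaction times are
`2.08 − 0.12·(age − 10.575) + u_subject − 0.08·1[Peer] + N(0, 0.5)` s,
truncated to (0.2, 8]; these values reproduce a cohort mean RT near
2.04 s (SD ≈ 0.32) with a 0.08 s Peer speed-up. Accuracy is Bernoulli
with base rate 0.9017 and a +0.015/year slope in the Character condition.
Ordinal reports discretize a latent normal whose per-measure locations
and marginal SDs follow the questionnaire's observed Peer/Character
values, plus a shared subject response tendency (SD 0.6) that induces the
within-subject correlation repeated questionnaire measures show; the
residual scale is reduced so the marginal SDs still match.

Trial amplitudes are multivariate normal across the 14 ROIs with unit
mean and SD, and correlation 0.30 within networks versus 0.10 between —
within > between is planted, matching the premise that the two networks
are distinct but coupled. The social manipulation shifts all
off-diagonal correlations by ±delta/2 with
`delta = 0.02·(age − 10.575)` per year (Peer up, Character down), so the
Peer−Character connectivity difference grows with age; the Peer matrix
additionally shifts by `−0.3 · u_subject` (r units per second of RT
deviation), coupling faster Peer responses to stronger Peer
connectivity. Shifts are clamped to [−0.25, 0.6], the range over which
this two-block structure remains positive definite; a configuration that
still fails the eigenvalue check is a parameter error. The magnitudes
were chosen once so that, at n = 50, the interaction tests land in the
small-to-moderate F range a child cohort of this size produces, and were
not revisited afterward.

BOLD is synthesized by the forward model the GLM assumes — amplitudes
times duration-modulated regressors, Feedback at a fixed nuisance
amplitude of 0.5 — plus cubic Legendre drift with random coefficients
(SD 2), AR(1) noise (coefficient 0.3, marginal SD 1), and a
motion-coupled component (0.5 times the mean standardized motion
parameter), with rigid-body motion simulated as random-walk drift, white
jitter, and sparse one-volume spikes. In `"amplitude"` mode the BOLD and
motion stages are skipped and the planted amplitudes serve directly as
beta series with mean FD drawn as a subject covariate
(0.23 ± 0.08 mm, −0.014 mm/year); this is the reduced simulation used
for the statistical calibration and recovery suites, where synthesizing
and re-estimating half a million GLMs would add nothing to the question
being asked.

The generator does **not** emulate anatomical images, distortion, slice
timing, spatial autocorrelation between ROIs' noise, non-Gaussian
amplitude distributions, condition-dependent HRF shape, or any
psychology of the peer illusion. Passing tests therefore demonstrate
that the pipeline's arithmetic, estimators and inference are correct
under its own generative assumptions — not that those assumptions hold
in a given real dataset.

## Numerical choices

* HRF grid 0.02 s; regressors via interpolated cumulative-integral
  differences; plateau normalization by the kernel's maximum cumulative
  integral.
* QR least squares with `lm.fit`'s default rank tolerance; aliased
  target columns produce NA betas with a warning.
* Jitter rescaling iterates clip-and-redistribute to a 1e-9 s fixed
  point; infeasible schedules error before drawing.
* Exact Wilcoxon null distributions by subset-sum DP over `2*rank`
  integers (average ties are half-integers), so exactness survives ties.
* Correlation matrices require >= 3 trials and reject constant series by
  ROI name; planted correlation shifts are clamped as described above.
* Simulation problem sizes in the test suite: 500 null cohorts and 50
  recovery cohorts of n = 50 in amplitude mode; LSS oracle checks on
  12-trial single-run schedules; full-pipeline smoke tests on 12
  subjects with 2 runs x 8 trials.

## Known limitations

* LSS bias under overlap is inherited, not corrected; no AR-prewhitened
  GLS (the estimator contract is iterated OLS), no slice-time modeling,
  no spatial smoothing.
* Accuracy is modeled as a per-cell proportion in a linear mixed model,
  not logistic, and reports are analyzed with linear models plus rank
  post-hocs rather than cumulative-link mixed models.
* No Satterthwaite/Kenward–Roger df; the grouping-level convention is
  simple and documented but approximate, like all df conventions for
  these models.
* The greedy subsample selector is a heuristic; it can stall above the
  correlation threshold when the age–motion relation is structural
  rather than incidental, in which case it stops at the target n.
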