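---
title: "Connectivity neurofeedback: model, simulator and analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity neurofeedback: model, simulator and analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connfeed)
```

## The problem

Connectivity neurofeedback trains people to change the temporal correlation
between two brain regions. During each trial a subject performs motor
imagery for 14 s while BOLD signal is recorded from two target regions —
left primary motor cortex (lM1) and the left lateral parietal node of the
default mode network (lLP) — and a few seconds later receives a score
reflecting how much the inter-regional correlation of that trial exceeded
their own pre-training baseline. The scientific question is whether such
training produces a lasting change in resting-state functional connectivity
between the motor/visuospatial network (MVN) and the default mode network
(DMN), which are normally anticorrelated (around r = −0.3).

`connfeed` implements the full computational apparatus of such an
experiment so that every stage can be exercised and tested on synthetic
data: the online scoring engine, a reward-responsive virtual subject that
closes the training loop, a generator of multi-subject resting-state BOLD
with controllable network correlation structure, and the two offline
evaluation analyses — the ROI-based network analysis with a bootstrap
colored-cell test, and whole-brain degree-of-connectivity mapping with
Monte-Carlo cluster-size correction.

## The feedback score

For trial $i$ with windowed inter-ROI Pearson correlation $r_i$ and
baseline $r_{\text{init}}$ (the mean correlation over the initial block of
day 1, during which no score is shown),

$$\mathrm{score}_i = \frac{r_i - r_{\text{init}}}{1 + |r_{\text{init}}|}
\times 100 .$$

The denominator keeps the score inside $[-100, 100]$; the score is positive
whenever the correlation increases relative to baseline, whether a positive
correlation grows, a negative one turns positive, or a negative one shrinks
in magnitude. A change from $-0.6$ to $-0.2$ scores $25$.

The scored window at the default timing (TR 2 s, 14-s imagery) contains the
last six of the seven imagery-period volumes plus the first feedback-period
volume: discarding the first imagery volume and appending one later volume
partially compensates the hemodynamic delay while keeping feedback fast.
Time courses are high-pass filtered at 0.06 Hz before correlation; the
filter family is not dictated by the procedure itself, so the package uses
a 5th-order Butterworth — standard and analytically checkable — applied
causally during online operation (no future samples) and forward–backward
(zero phase) for offline verification. Whether the original online system
filtered causally or over the accumulated run, and whether ROI means were
taken before or after filtering, are not documented; the package defaults
to causal filtering of ROI-mean series (cheapest in real time; for a linear
filter the mean-then-filter order only changes voxel-noise averaging) and
exposes both choices.

Degenerate trials (zero-variance windows, which short synthetic windows can
produce) are skipped with a logged warning and excluded from block means
rather than silently scored 0; a session aborts if their fraction exceeds a
configurable limit. Block reward credit floors negative block means at zero
— reward is never taken back — but the displayed scores themselves can be
negative.

## The virtual subject

`agent_state()` models the learner as a single latent coupling parameter:
the true imagery-period correlation between the target ROIs, starting at
the resting anticorrelation (−0.3). Each trial the agent perturbs its
coupling by a Gaussian exploration jitter (SD 0.15), the trial's data are
generated at the perturbed coupling, and the received score reinforces the
jitter direction, weighted by the score's *advantage* over the agent's
running-average score:

$$c \leftarrow \mathrm{clip}_{[-1,1]}\!\left(c + \lambda \,
\frac{s - \bar{s}}{100} \, \frac{j}{\sigma_j}\right).$$

Two design points deserve explanation. First, the naive alternative — add
$\lambda s / 100$ plus jitter directly to the coupling
(`simulate_training_trial()`, exported for completeness) — is unstable
around the baseline: because the score is proportional to the deviation of
the measured correlation from a fixed baseline, that rule is a symmetric
unstable autoregression whose direction of divergence is a coin flip, and
it would also "learn" from yoked sham scores, which are positive on average.
A contingency-sensitive learner must gate reward by its own behavior, which
the jitter-weighted rule does: with veridical feedback the expected update
is proportional to the score's slope in coupling (positive), while a yoked
score series, carrying no information about the agent's own jitter, gives a
zero-mean update. Second, the advantage baseline $\bar{s}$ (an exponential
moving average, rate 0.2) removes the growing common level of the score
series; without it a sham-yoked agent performs a high-variance random walk
driven by the donor's large late-training scores. Both are standard
policy-gradient constructions; no cognitive realism is claimed. The
exploration SD was chosen from a signal-to-noise argument: the expected
per-trial coupling drift scales linearly with the exploration SD while the
reinforcement noise (dominated by the 7-sample correlation estimate, SD
about 0.4) does not, so larger exploration learns more reliably; 0.15 keeps
trial-to-trial behavior plausibly variable while giving a comfortable
margin for 4-day learning.

## The synthetic resting-state generator

`simulate_rest_run()` draws ROI latent signals from a multivariate normal
with the target correlation matrix; voxels within an ROI share their ROI's
latent signal plus independent noise (SD 0.6 by default, 12 voxels
materialized per ROI); a shared sinusoidal drift (amplitude 0.2 latent-SDs,
period 100 s) and mild AR(1) temporal smoothing (coefficient 0.3, applied
identically to all series so zero-lag correlations are preserved) stand in
for scanner drift and hemodynamic smoothness. Each run carries a sidecar
confound table — six synthetic motion traces and three tissue-mean
signals — and the tissue means contain the drift, so the nuisance
regression stage genuinely removes it. With these defaults the empirical
ROI-mean correlations recover the target within ±0.05 at long run lengths:
the shared drift contributes at most ~0.02 of common correlation and the
voxel noise attenuates correlations by ~3%, both inside that band. User
matrices that are non-PSD beyond eigenvalue tolerance 1e−6 are rejected;
within tolerance they are repaired by eigenvalue clipping.

`simulate_study()` reproduces the three-group design: 12 neurofeedback, 12
sham-feedback and 9 tapping-imagery subjects, each with rest runs before
training, immediately after, and at two-month follow-up (152 volumes at TR
2 s; the first two are discarded in preprocessing, leaving 150). Target
matrices come from a network factor model — within-network correlation 0.6
for MVN and DMN, 0.4 for the control regions, MVN–DMN cross-correlation
−0.3 pre-training via the factor correlation — which is positive
semidefinite by construction. Training raises the MVN–DMN correlation of
the neurofeedback group by +0.2 in the post and follow-up sessions; control
groups change by 0; the ground-truth table records these deltas exactly.

Two sources of heterogeneity are added because group statistics demand
them. A stable per-subject offset (SD 0.2) on the MVN–DMN block models
trait differences in anticorrelation strength; its size is implied by
published one-sample t statistics for this kind of design (a group-mean
z near −0.3 with t around −5 at n = 12 implies a between-subject SD near
0.2), and being constant across sessions it cancels in post−pre
differences. A per-run pair-level jitter (SD 0.08, PSD-projected) models
the well-documented session-to-session variability of single-pair resting
correlations; without it, all cells of a network pair move in lockstep with
their shared factor, violating the exchangeability that cell-resampling
bootstrap inference relies on and inflating its false-positive rate far
above nominal. With it, the null false-flag rate of the bootstrap test sits
below the nominal alpha.

What the generator does *not* emulate: hemodynamic forward models,
realistic motion artifacts and their spike structure, physiological noise
spectra, spatial autocorrelation beyond applied smoothing, and anatomical
variability. Passing tests therefore show that the analysis chain is
correct and calibrated under a plausible covariance-structured null, not
that it is robust to every artifact of real data.

## ROI registry

The packaged registry holds the 16 analysis regions: 8 MVN (bilateral M1,
SMA, IPS, FEF), 4 DMN (bilateral LP, PCC, MPF), 4 control (bilateral V1,
A1). IPS, FEF, LP, PCC and MPF carry published MNI sphere centers; the
published radius (7.5 mm, stated only for lLP) is applied to all sphere
ROIs and is configurable. M1, SMA, V1 and A1 are anatomically defined
(Brodmann areas); the package accepts such regions as user-supplied mask
volumes and ships no atlas, but the registry includes clearly flagged
*synthetic* sphere centers for them so simulations can voxelize all 16
regions. Sphere voxelization uses the voxel-center-within-radius criterion
(deterministic, matches common ROI tooling); voxel indices are 0-based and
MNI coordinates in mm. The default grid is EPI-like — 61 × 73 × 33 voxels
of 3 × 3 × 3.5 mm (33 axial slices), spanning MNI space so that every
packaged sphere fits; analyses and tests mostly use much smaller custom
grids.

The six network-pair types (MVN-MVN, MVN-DMN, DMN-DMN, MVN-control,
DMN-control, control-control) partition the 120 unordered ROI pairs into
cells of sizes 28, 32, 6, 32, 16 and 6.

## ROI network analysis

Preprocessing discards two volumes, optionally smooths full-volume runs
(6-mm FWHM), and removes nine nuisance regressors (six motion parameters,
gray-matter/white-matter/CSF means) by least squares via the SVD
pseudo-inverse, so rank-deficient confound tables are harmless. Keeping the
gray-matter mean regressor follows the original procedure despite the known
global-signal debate; it is configurable. Residual time courses are
averaged within ROIs; pairwise Pearson correlations are Fisher-z
transformed with |z| capped at atanh(1 − 1e−6) so degenerate perfect
correlations cannot produce infinities; matrix diagonals are NA and never
enter statistics.

Post−pre difference matrices are computed per subject and averaged within
groups. A cell is *colored* when its group-mean increase strictly exceeds
the pooled mean + SD threshold, pooled over all off-diagonal cells of all
group matrices jointly. The bootstrap test draws, for each pair type of
size m in each group, m cells with replacement from the pooled cell
population, counts colored cells, repeats 3000 times, and takes the upper
bound of the two-sided CI at the Bonferroni-corrected level
(alpha / (pair types × groups)); a type is significant when its observed
colored count strictly exceeds that bound. Pooling across the three group
matrices is the reading most consistent with resampling "cells in the three
matrices"; a per-group pool is available via a flag. One-sample negativity
tests are one-sided with Bonferroni correction across the three pair sets
(lM1–lLP, sensorimotor-vs-DMN, MVN-vs-DMN); group score comparisons use
one-way ANOVA on daily group means with pooled-variance post-hoc t tests.

## Degree of connectivity

The degree of a voxel is the number of other in-mask voxels whose
correlation with it satisfies a signed threshold relation; for weakening
anticorrelation the count is of r < −0.25, so a training-induced rise of a
negative correlation appears as a degree *decrease*. Degree maps are
computed blockwise on standardized series (memory bounded by block size,
results independent of the partition; verified against brute-force pairwise
computation). Voxelwise paired t tests of post−pre degree are thresholded
at p < 0.005 one-sided — the voxelwise threshold used with the published
cluster cutoff is not documented, so the liberal exploratory threshold
mentioned alongside it is adopted — and cluster-size correction comes from
Monte-Carlo simulation of smooth Gaussian null fields on the mask (white
noise smoothed at the nominal applied FWHM, standardized, thresholded,
maximum cluster size recorded per iteration). The published 186-voxel
cutoff is treated as dataset-specific and never hard-coded: the minimum
significant cluster size is always recomputed for the current mask and
smoothness. Cluster connectivity defaults to 18 (faces + edges) and is
configurable; residual-smoothness estimation is out of scope.

## Problem sizes and reproducibility

Default analysis sizes are scaled for a single CPU: study simulation uses
ROI-level runs (12 voxels per ROI, 152 volumes) so a full 33-subject,
three-session study simulates and analyzes in roughly a second; the
full-volume degree demonstration uses a 12 × 12 × 8 grid with two 5-mm
ROIs, six subjects per group and a few hundred Monte-Carlo iterations; the
end-to-end report (`run_full_pipeline()`) completes in well under five
minutes. Every stochastic stage takes an explicit integer seed, logs it in
provenance, and regenerates bit-identically from it; the command-line
surface (`inst/cli/connfeed.R`) is a thin wrapper over the same functions.

## Known limitations

The agent is a scalar caricature of human learning; individual learning
dynamics were never characterized and none are claimed. The bootstrap
cell-resampling test assumes approximately exchangeable cells; strongly
factor-structured effects violate this, which is precisely why the
generator includes pair-level heterogeneity, and users applying the test to
real matrices should be aware the same caveat applies there. The
Monte-Carlo cluster null uses nominal rather than estimated smoothness.
Anatomical ROIs require user-supplied masks; spatial normalization is out
of scope. The exact AlphaSim autocorrelation-function variants are not
replicated.
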