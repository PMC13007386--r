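---
title: "Model-based MEG-fMRI fusion of decoding RDMs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based MEG-fMRI fusion of decoding RDMs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsafusion)
```

## The question the package answers

Functional MRI tells you *where* a task feature is encoded; MEG tells you
*when*. Neither alone gives both. Model-based fusion links the two through
representational geometry: if the pattern of pairwise condition
dissimilarities in an fMRI region of interest (ROI) matches the pattern of
dissimilarities in the MEG sensor signal at time *t*, and both match a
hypothesis matrix for one task feature, then that feature is plausibly
encoded in that region at that time. `rsafusion` implements this pipeline
end to end — trial generation, decoding, RDM construction, the commonality
index, and its inference — against synthetic data with planted ground truth,
so every stage is testable without access to recorded neuroimaging data.

The emulated paradigm is a cued stimulus–response mapping task: one of four
stimulus positions (two per visual hemifield, at an inner and an outer
eccentricity) appears together with a coloured cue; one of two memorised
position-to-button rules applies, each rule indicated by two possible cue
colours; responses use four fingers of one hand. Four information types are
analysed: *across*-hemifield position (left vs right), *within*-hemifield
position (inner vs outer), *rule* (1 vs 2), and *response* (inner vs outer
fingers).

## Dissimilarities from decoding

Neural RDMs are built from cross-validated linear-SVM classification
(C = 1, features z-scored with training-fold statistics only):

* **fMRI**: condition-wise beta patterns per block, leave-one-block-out
  cross-validation, voxels as features, all 6 unordered pairs of the
  scheme's 4 conditions.
* **MEG**: sensor patterns at every time sample, stratified k-fold
  (default k = 10) with one fold partition reused across all time points so
  the accuracy trace is temporally comparable; the majority class of each
  training fold is subsampled to the minority count.

Cell values are `1 - accuracy` (accuracy scaled 0..1), so chance maps to 0.5
and perfect separability to 0. Note a consequence of this orientation: a
strongly decodable feature gives *low* neural dissimilarities exactly where
the binary model RDM (1 = conditions differ on the feature, 0.5 = they do
not) has *high* values, so model-consistent neural RDVs are rank
**anti**-correlated with their model. This is harmless for fusion: the
commonality index below is provably invariant to jointly inverting both
neural RDVs, because the two model-correlation signs cancel inside the
partial term (a property asserted by a test).

Each 4x4 RDM is vectorised as its lower triangle in column-major order (6
elements, diagonal excluded); the order is fixed package-wide, and every
correlation between RDVs is rank-based, so any consistent order gives
identical results.

## The commonality index

For an ROI's fMRI RDV `f`, the MEG RDV `g(t)` at time `t`, and a model RDV
`m`, the commonality index is

$$C(t) \;=\; \rho_{f,g(t)} \;-\; \frac{\rho_{f,g(t)} - \rho_{f,m}\,\rho_{g(t),m}}
{\sqrt{1-\rho_{f,m}^2}\,\sqrt{1-\rho_{g(t),m}^2}},$$

all correlations Spearman: the raw correlation between the two neural RDVs
minus their partial correlation given the model. It isolates variance shared
simultaneously by all three — a spatial constraint (the ROI), a temporal
constraint (the time point), and a content constraint (the model). A model
rank-orthogonal to both neural RDVs contributes nothing and the index is 0;
a model rank-identical to a neural RDV makes the partial term undefined, and
the index is reported as missing (with a reason), never clipped to a finite
value — fabricating values there would distort the trace.

With only four conditions an RDV has six elements, so each Spearman
correlation is extremely coarse (the null spread of a 6-point rank
correlation is about 0.45 regardless of how clean the data are). Two design
consequences follow. First, fusion is computed on *group-averaged* RDMs (the
average across participants, and across hemispheres for fMRI), which is also
how the method is used in practice; averaging sharpens the rank ordering of
the true structure even though it cannot reduce the rank noise of truly null
cells. Second, single-dataset commonality traces are noisy by construction,
and the package's recovery tests operate at the group level.

## Inference

Significance is assessed per time point against a permutation null: the
fMRI condition labels are shuffled *within each block* (blocks are the
exchangeability unit of the block-wise beta estimates), the pairwise
decoding is rerun, the fMRI RDM regenerated — for every participant, then
re-averaged — and the full commonality time course recomputed. The MEG RDVs
and the model are held fixed, following the method's published procedure;
whether the MEG side should also be regenerated is an open methodological
question, and the package implements the procedure as stated. One-tailed
p-values use the add-one count estimator `p = (1 + #{null >= obs}) / (1 +
n_perm)`, which cannot return zero. Only positive commonalities can reach
significance; negative values are reported but never flagged, since only
positive commonality is interpretable as shared signal.

Multiple comparisons across time are handled by Storey's adaptive FDR within
each (ROI x model x alignment) trace. The null proportion is estimated with
a fixed `lambda = 0.5` (a vector of lambdas averages the per-lambda
estimates); fixing lambda favours reproducibility over adaptivity. With
fewer than 10 p-values the pi0 estimate is meaningless and the function
falls back to Benjamini-Hochberg with a warning. A time point is significant
when `q < alpha` (default 0.05) *and* the commonality is positive.

Three temporal metrics summarise a tested trace: time to the first
significant commonality (earliest significant point at or after stimulus
onset), time to the maximum commonality, and the time from that maximum to
the response (for stimulus-aligned traces measured against a response
reference, by default the median correct reaction time; for response-aligned
traces, minus the peak time). When a trace never reaches significance the
onset is undefined and the metrics are flagged unreliable rather than
omitted.

Above-chance decoding itself is tested with JZS Bayes-factor t-tests: a
Cauchy prior (scale `sqrt(2)/2`, the conventional default) on the
standardised effect, integrated by adaptive quadrature (relative tolerance
1e-8) of the standard one-dimensional g-mixture representation. Evidence is
categorised at BF10 > 3 (alternative) and < 1/3 (null), boundaries counted
as insufficient. Two-sided tests are the default for condition differences;
a one-sided variant (prior truncated to positive effects) is available for
above-chance tests. The comparator for "above chance" defaults to the
theoretical 50%, with the empirical permutation-null mean available as an
alternative.

## The synthetic-data generator

The generator's defaults mirror the paradigm's own design: 12 blocks of 80
trials, each of the 16 cue-colour x position configurations exactly 5 times
per block in randomised order; group behaviour with accuracy 0.8078,
reaction times log-normal with mean 1692 ms and SD 284 ms (log-normal chosen
because RTs are strictly positive and right-skewed), and a 2.6% omission
rate. Errors press a uniformly random non-target button (the simplest
non-degenerate choice); omitted trials have no response and are excluded
everywhere downstream, like errors. The two stimulus-to-button rules are
configurable bijections (identity and reversal by default), since any real
assignment is arbitrary and counterbalanced.

Planted effects are specified per information type with an `effect_spec`:
an fMRI target ROI and/or an MEG time window, and an effect size defined as
the **Euclidean norm of the latent multivariate pattern in noise-SD units**.
Latent level patterns are i.i.d. Gaussian, orthogonalised between the two
levels of a feature (so planted contrasts are unambiguous) and normalised to
unit norm; the unit-norm convention makes the effect size a multivariate
amplitude comparable across ROI sizes, and keeps moderate effect sizes in
the informative decoding regime instead of saturating every multi-voxel ROI
at 100% accuracy (which would also drive the Eq. denominators degenerate).

fMRI betas are generated at the condition level: latent pattern x effect
size plus i.i.d. Gaussian noise per (condition, block, voxel). A fuller
first-level route exists as well: `build_design_matrix()` models each trial
as an epoch from stimulus onset until the response (duration = RT) convolved
with the canonical double-gamma HRF (peak 6 s, undershoot 16 s, ratio 6, no
derivatives), with block constants; onsets are laid out deterministically
from the paradigm timing (500 ms fixation, then the stimulus/response period
of duration RT, 4.5 s on omissions). `fit_glm()` is ordinary least squares
with a minimum-norm fallback (and warning) for rank-deficient designs.

MEG epochs place a fixed latent sensor topography per condition level inside
the effect's window, scaled by a raised-cosine on/off envelope with 20 ms
ramps (avoiding decoding-onset ringing), on top of i.i.d. Gaussian sensor
noise. Stimulus-aligned epochs span -200..2500 ms and response-aligned
epochs -2500..500 ms by default, at 200 Hz, on closed-interval grids.
Response-aligned epochs shift each trial by its reaction time; with
`alignment = "both"` both frames are cut from one shared per-trial master
series, so a response-aligned sample at time -RT equals the stimulus-aligned
sample at 0 up to linear interpolation.

What the generator deliberately does **not** emulate: forward-modelled MEG
physics (no leadfields or sensor covariance), spatial autocorrelation of
fMRI noise, haemodynamic variability across regions, motion or physiological
confounds, and trial-to-trial amplitude variability. Passing recovery tests
therefore show that the pipeline's statistics behave as designed under
idealised noise — not that the method is robust to the structured artefacts
of real recordings.

## Problem sizes used by the test suite

The test suite exercises the pipeline at reduced scales chosen to keep the
statistical targets meaningful: design-count checks run at the paradigm's
native 12 x 80 size; chance calibration uses 12 blocks and 50 voxels with
1000 label permutations; the group-level recovery test-bed uses 8
participants x (6 blocks x 32 trials), a 6-voxel ROI, 6 sensors, a 40 Hz
grid over 150..800 ms, a planted 300..700 ms window at effect size 2, and
200 permutations; null calibration of the fusion pipeline uses 200
single-participant datasets at 4 blocks with 100 permutations. The
`default_run_config()` demonstration is smaller still (4 blocks x 32 trials,
two ROIs, 20 sensors at 20 Hz) and completes in well under five minutes on
one CPU.

Two power-relevant design notes on the recovery test-bed. The analysis span
150..800 ms concentrates the multiple-comparisons family around the
plausible onset range: adaptive FDR gains its power from the fraction of
time points carrying true effects, and a very long null tail would mask the
planted window at these scales. And eight participants are the point where
the group-averaged fMRI RDV orders reliably under the paradigm's own
block-wise decoding granularity; the published use of the method averaged
over substantially more participants.

## Numerical and degenerate-input choices

* Spearman correlations use average ranks; constant vectors give a missing
  correlation that propagates (never an error mid-pipeline).
* Partial correlations are undefined when either model correlation reaches
  1 in magnitude within 1e-10; the index reports missing with a reason.
* SVM decision ties at exactly zero are assigned to the class with the lower
  label index, making predictions deterministic.
* The SVM is libsvm (via e1071) called through its C entry point with fixed
  arguments (linear kernel, C = 1, no shrinking heuristic changes); a test
  asserts bit-identical decision values against `e1071::svm()`.
* Beta estimation uses QR; designs below full column rank fall back to the
  SVD minimum-norm solution with a warning.
* All generators are deterministic given their seed; the pipeline runner
  writes a manifest (config hash, seed, versions) sufficient to reproduce
  any output byte-identically.

## Known limitations

Six-element RDVs make every rank correlation coarse; commonality traces from
single datasets are correspondingly noisy, and out-of-window false positives
become more likely the closer the fMRI RDV sits to the model's rank ceiling
(the partial term's denominator amplifies MEG rank noise, and the
label-shuffled null cannot reproduce that amplification). This is a property
of the published procedure, not of this implementation; the package
mitigates it by fusing group-averaged RDMs and reports it here rather than
altering the method. The response-scheme condition assignment (two response
regressors plus one cue colour per rule) involves an assumption: trials of
the two designated colours join their colour condition, all others their
response-group condition, and model cells between a response condition and a
colour condition default to 0.5 (exposed as `cross_value`).
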