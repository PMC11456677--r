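---
title: "Methods: individual-level CBTC circuit analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individual-level CBTC circuit analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbtcloops)
```

## The analysis in one paragraph

`cbtcloops` implements a case-control analysis of resting-state functional
connectivity (FC) restricted to the cortico-basal ganglia-thalamo-cortical
(CBTC) circuits, at the individual level. Subcortical structures (caudate,
putamen, pallidum, thalamus) are first subdivided by their structural
connectivity fingerprints: each voxel is assigned to the cortical target
(MPFC, DLPFC, M1, premotor, orbitofrontal) with the highest tractography-derived
connection probability (winner-take-all). FC (Pearson r, Fisher r-to-z) is
then computed edge-wise along two parallel loops -- a "short"
cortico-striato-thalamo-cortical loop (19 edges per hemisphere) and a "long"
cortico-striato-pallido-thalamo-cortical loop (21 edges per hemisphere; 40
in total) -- and, for comparison, over a conventional whole-structure "atlas"
edge set (26 per hemisphere). Downstream, the pipeline runs edge-wise
two-sample t-tests with Benjamini-Hochberg FDR, an F-score-ranked linear SVM
classifier evaluated by leave-one-out cross-validation (LOOCV) with
label-permutation inference, and connectome-based predictive modelling (CPM)
of the Upper Extremity Fugl-Meyer Assessment (UE-FMA, 33 items, 0-66 points),
with behaviour-shuffling permutation inference.

Because the underlying MRI data are not publicly deposited, the package
includes a first-class synthetic cohort generator that emulates the study's
data *structure*; every stage is specified and tested against it.

## Hemisphere convention

To pool left- and right-lesioned patients, volumes of patients with a
left-sided lesion are mirrored across the mid-sagittal plane (`flip_lr()`),
after which the right hemisphere is ipsilesional for every patient. The flip
reverses the voxel order along the axis the NIfTI orientation metadata marks
as left-right; it is an involution and never touches the other axes.
Controls keep their native orientation and the right hemisphere plays the
role of the "affected homologue" in group comparisons; whether the source
study randomly mirrored controls is not stated, so we do not.

## The loop manifest is data

The exact 19- and 21-edge compositions of the two loops were published only
in supplementary material that is not publicly archived, so the shipped
manifest (`inst/extdata/loop_manifest.tsv`) is an explicit, rule-based
reconstruction:

* **short loop** -- for every cortical target `t`: `t-CAU_t`, `CAU_t-THA_t`,
  `THA_t-t` (the striato-thalamic route), plus the putamen branch
  (`t-PUT_t`, `PUT_t-THA_t`) for M1 and DLPFC;
* **long loop** -- for every target: `t-CAU_t`, `CAU_t-PAL_t`,
  `PAL_t-THA_t`, `THA_t-t`, minus the `THA_OFC-OFC` closure, plus the M1
  putamen branch (`M1-PUT_M1`, `PUT_M1-PAL_M1`).

The trimming choices (which targets get a putamen branch; which closure is
dropped) are the documented exclusion list that brings the counts to 19 and
21. Every loop edge the published analyses name -- `caudate_M1-M1`,
`putamen_M1-M1` and `putamen_DLPFC-DLPFC` in the short loop,
`caudate_M1-M1`, `putamen_M1-M1` and `thalamus_DLPFC-DLPFC` in the long
loop, `caudate_MPFC-MPFC` in the short loop -- is present in the loop it is
named in. Users with access to the original edge list can substitute their
own TSV; `load_loop_manifest()` enforces the count, uniqueness and
resolvability invariants on any manifest.

## Winner-take-all parcellation

The segmentation rule is deliberately minimal: a voxel is assigned to the
cortical target with maximal connection probability provided that maximum
reaches `tau` (default 0.01 on the raw probability scale), ties broken
deterministically (first target in the recorded order by default, or left
unassigned). The argmax is invariant to rescaling a voxel's profile; `tau`
is intentionally scale-sensitive, since probabilistic-tractography outputs
are on a calibrated probability scale. No spatial regularisation is applied
by default because the source methods do not mention any; an optional
6-neighbourhood majority filter is available behind a flag. Registration
between diffusion and BOLD grids is out of scope -- inputs are assumed
co-registered -- except for a nearest-neighbour label resampler for grids
differing by an integer factor.

## FC extraction

Edge FC is the Pearson correlation of the two regions' mean time series,
Fisher-transformed with `z = atanh(r)` after clipping `|r|` at `1 - 1e-7` so
that degenerate synthetic inputs cannot produce infinities. Subdivision
regions use their own series; atlas parents use the mean across the
structure's subdivisions (in the synthetic cohort subdivisions are equally
sized, so this equals the voxel mean). Missing edges (an empty subdivision
after parcellation) are an error by default rather than being silently
imputed, because downstream classification requires complete cases. No
nuisance regression, filtering or scrubbing is performed here; preprocessing
is declared upstream.

## Group statistics

Sex is compared with a Pearson chi-square **without** continuity correction
-- the uncorrected statistic is what reproduces the published value
(`chi2_2x2(matrix(c(35, 36, 29, 28), 2))` gives 0.032, p = 0.859; Yates'
correction would give approximately 0). Age uses the Mann-Whitney U with the
tie-corrected normal approximation, matching standard statistical-software
output. Edge-wise comparisons are two-sample t-tests on Fisher-z values --
Welch by default (the pooled Student variant is available; the source does
not specify) -- with Benjamini-Hochberg FDR. The FDR family is all edges of
one scheme across both hemispheres by default, configurable to
per-hemisphere, because the published family is not stated.

## SVM classification

Connections are ranked by the two-class Fisher criterion
`F = ((m+ - m)^2 + (m- - m)^2) / (s+^2 + s-^2)` (unbiased within-class
variances; an exact-separation feature receives an infinite score and ranks
first). For each LOOCV fold, features are standardised with training-fold
statistics only and a linear SVM (libsvm via `e1071`, cost `C = 1` by
default) is trained on the top-k connections; the accuracy curve sweeps k
and `best_k` is the smallest k attaining the maximum. Ranking is
fold-internal by default (leakage-safe); a `global` mode ranks once on the
full sample, mirroring what a single published accuracy-vs-k curve implies,
and is provided with the difference documented. AUC is the Mann-Whitney
statistic of held-out decision values (ties counted 1/2). The permutation
test re-runs the full LOOCV under label permutations and reports the literal
proportion of permuted AUCs at or above the observed one -- this can be
exactly zero; a `(b + 1)/(n + 1)` variant is available.

## CPM

Within each LOOCV fold, edges whose correlation with behaviour in the
training subjects has `p < p_sel` (default 0.05, Pearson; both configurable,
following the originating CPM protocol since the source defers details to
its supplement) are split by correlation sign. Network strength is the
unweighted sum of Fisher-z values over a set. The positive and negative
models regress behaviour on one strength; the combined model uses both
strengths as two regressors (a `sum-diff` single-regressor variant is also
provided, since "a combined model that encompassed all connections" admits
both readings). A fold that selects no edges predicts the training mean and
is flagged. Performance is Spearman's rank correlation between held-out
predictions and observed scores; inference shuffles behaviour and re-runs
the full LOOCV per shuffle. "Well-represented" connections are those
selected in at least `min_frac` of folds (default 1.0), with their sign.

CPM runs on patients only, as behaviour exists only for patients, over the
FC vectors of both hemispheres.

## The synthetic cohort generator

The generator defines the study conditions under which the pipeline is
tested:

* **Region series.** 25 regions per hemisphere (5 cortical + 20
  subdivisions) drawn from a zero-mean unit-variance multivariate normal.
  The correlation matrix has `rho0` (default 0.4) on manifest loop edges and
  0 elsewhere, repaired to the nearest positive semidefinite correlation
  matrix by eigenvalue clipping (floor 1e-8) with diagonal re-normalisation.
  The repair perturbation is recorded and must not exceed 0.05 on any
  targeted entry -- at the shipped manifest and default `rho0` the matrix is
  already PSD and the repair is the identity. Eigenvalue clipping (rather
  than a Higham-style iteration) is sufficient for such sparse targets.
* **Group effect.** Patients carry a correlation decrement `delta` (default
  0.15) on designated ipsilesional edges -- by default the three loop edges
  reported as reduced in patients. The effect is a correlation decrement,
  not a variance change, matching the "decreased FC" phenotype. The source
  reports no effect sizes, so `rho0 = 0.4` and `delta = 0.15` are
  calibration choices: large enough that a 64 + 64 cohort at 200 timepoints
  detects the planted edges, small enough that classification is not
  trivially perfect. A region pair shared by both loops is decremented once
  -- the decrement targets the physical pair.
* **Behaviour.** UE-FMA is `round(offset + scale * sum(w_e z_e) + eps)`
  clipped to [0, 66] (the instrument is integer-valued: 33 items, two points
  each). The default coupled edges are the four loop edges reported as
  predictive, with their reported signs; `offset = -15`, `scale = 60`,
  `noise_sd = 6` put the scores in a clinically plausible moderate-to-severe
  range (median near 25) with both FC-driven and idiosyncratic variance.
  Each patient's score is computed from their own realised edge z-values, so
  CPM has a true signal to find.
* **Voxel profiles.** For each structure, `voxels_per_subdivision` voxels
  per cortical target drawn from a Dirichlet with concentration `kappa` on
  the planted target and 1 elsewhere (default `kappa = 50`: sharp but not
  degenerate). `kappa = 1` is the uninformative control at which recovery
  falls to the 1/5 chance level.
* **Phenotype.** Ages Normal(57, 12) truncated to [30, 80] (the inclusion
  window), sex Bernoulli(0.55 male), and a 15/64 proportion of left-sided
  lesions -- cosmetic except for the demographic tests. Patient series are
  stored post-flip (ipsilesional = R), with `flipped` marking left-lesion
  patients.

What the generator does **not** emulate: haemodynamics, autocorrelated BOLD
noise, motion, lesion-distorted anatomy, scanner effects, or any
interhemispheric coupling. Passing tests therefore demonstrate that the
statistical machinery is correct and calibrated under the stated generative
model, not that the published effect sizes would replicate on real data.

## Numerical and design notes

* All randomness flows from explicit seeds; stage seeds are derived from a
  single master seed, and seeded helpers restore the caller's RNG state.
* Fisher-z clipping at `1e-7` keeps every FC value finite.
* Ties: SVM `best_k` prefers the smallest k; winner-take-all tie-breaking is
  explicit; AUC counts ties as 1/2.
* Permutation p-values use the literal proportion, so p = 0 is possible by
  design; both permutation tests are exchangeable re-runs of the full
  cross-validated procedure, never shortcuts on a fixed model.
* Degenerate CPM folds (no selected edges) predict the training mean. At
  small edge counts this produces predictions exactly anticorrelated with
  the held-out behaviour (predicting the mean of the others is decreasing in
  one's own value), creating an atom of the null statistic at r = -1 and a
  conservative atom of the permutation p at 1. At the analysis's real edge
  counts (80 loop edges) an empty fold has probability about `0.95^80 ~
  0.017` and the effect is negligible; the calibration tests therefore keep
  the real edge count while scaling down subjects and permutation counts.
* Simulation sizes in the test-suite: the null-calibration suite uses 100
  cohorts of 20 + 20 subjects at 200 timepoints; permutation-uniformity
  suites use 100 repetitions of 200 permutations at 12-16 subjects; power
  and recovery checks run at the study scale (64 + 64 subjects, and 64
  patients for CPM). These sizes keep every property sharp while the whole
  suite completes in minutes.

## Known limitations

* The shipped manifest is a reconstruction; analyses that depend on the
  exact published edge lists should substitute the original supplement.
* The tractography itself (PICo/Camino) is consumed, not computed: the
  pipeline starts from per-target connection-probability maps.
* No covariate adjustment in group statistics or CPM (the source used
  none), no kernels beyond linear, no nested hyperparameter search, no
  interhemispheric edges.
* Whether each structure was segmented once globally or per loop is unknown;
  the parcellation API is context-free, so either protocol can be scripted.

## A worked run

```{r, eval = FALSE}
cfg <- run_config(mode = "simulate", outdir = "cbtc_run", seed = 1,
                  n_perm_svm = 200, n_perm_cpm = 200)
summary <- run_pipeline(cfg)
str(summary$classification$loops)
```

The pipeline writes, per run: the phenotype table, parcellation report,
both FC matrices, edge-wise group statistics, SVM accuracy curves and ROC
points, CPM predictions and fold-stability tables, a structured log, and a
`summary.json` that is byte-identical across reruns with the same seed.
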