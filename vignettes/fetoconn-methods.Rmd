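---
title: "Modelling fetal thalamocortical connectivity development with fetoconn"
author: "fetoconn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling fetal thalamocortical connectivity development with fetoconn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetoconn)
```

## The scientific problem

In-utero resting-state fMRI makes it possible to watch the functional
connectome assemble before birth. Between roughly 19 and 40 weeks of
gestation, thalamocortical afferents wait in the subplate, invade the
cortical plate, and begin forming synapses; functional synchrony between the
thalamus and visual cortex is expected to rise steeply in a narrow window
around 29--31 gestational weeks (GW). `fetoconn` provides the analysis chain
needed to quantify that development from region-of-interest (ROI) BOLD
signals: signal cleaning tailored to fetal acquisitions, subject-level
Pearson connectivity, bespoke quality control, a sigmoid growth model per
connection, and hemispheric similarity/laterality statistics.

Because no public fetal cohort accompanies this problem, the package ships a
synthetic-cohort generator with a fully known ground truth. Every
downstream claim the package makes is validated against that ground truth
in the test suite; the generator is first-class, tested code, not a test
fixture.

## The developmental model

For each connection (edge) the trajectory of connectivity $f(t)$ over
gestational age $t$ (decimal weeks) is modelled as

$$ f(t) \;=\; \frac{\beta_1}{1 + \exp\!\left[-\,\frac{t - \beta_3}{\beta_4}\right]} \;+\; \beta_2 , $$

where $\beta_2$ is the initial plateau, $\beta_1 + \beta_2$ the final
plateau, $\beta_4$ (weeks) the growth-rate scale, and $\beta_3$ (weeks) the
inflection point where the derivative peaks --- the age of maximum
connectivity increase. At $t = \beta_3$ the curve passes through
$\beta_2 + \beta_1/2$. The parametrization is sign-degenerate:
$(\beta_1, \beta_2, \beta_3, \beta_4)$ and
$(-\beta_1, \beta_1 + \beta_2, \beta_3, -\beta_4)$ describe the same curve;
the fitter may return either representative.

A linear model (`fitLinear`) is fitted alongside as the natural null
family. Model comparison uses information criteria computed with the same
Gaussian-likelihood convention (4 mean parameters + error variance for the
sigmoid, 2 + 1 for the line). One caveat we document rather than hide: on
data whose truth is linear, the two extra sigmoid parameters buy a roughly
$\chi^2_2$ improvement in fit, which beats AIC's penalty of 2 per parameter
in about a quarter of datasets. AIC therefore selects the sigmoid on purely
linear data more often than a practitioner might expect; BIC's $\log n$
penalty makes the family choice reliable at $n \approx 48$, and we
recommend BIC for the family decision while reporting both.

### Fitting: variable-projection multi-start

The sigmoid is linear in $(\beta_1, \beta_2)$ once $(\beta_3, \beta_4)$ are
fixed. `fitSigmoid` exploits this: $\beta_3$ is scanned over 9 points
spanning the observed age range and $\beta_4$ over
$\pm\{0.25, 0.5, 1, 2, 4, 8, 32, 128\}$ weeks (fast transitions through
near-linear regimes, both orientations), with $(\beta_1,\beta_2)$ profiled
out by closed-form least squares in each cell. The best cells seed a
bounded Levenberg--Marquardt polish ($\beta_3$ restricted to the observed
range $\pm 5$ weeks; $\beta_4$ kept away from zero on the side of its
start). The best residual wins. The grid doubles as a fast fitter that
vectorizes over many responses at once, which is what makes
permutation and bootstrap inference affordable.

Near-linear data drive $|\beta_4|$ to large values; such fits are flagged
`degenerate` when $|\beta_4|$ exceeds the observed age span, but kept ---
published regional fit tables contain growth rates above 100 weeks, so this
regime is a fact of the data, not an error.

### Inference

* **Bootstrap** (`bootstrapParams`): case resampling of subjects, refit per
  replicate, percentile 95% intervals; 1000 replicates by default.
  Non-converged replicates are dropped and counted; the result is flagged
  if more than half fail.
* **Permutation goodness of fit** (`permutationGofTest`): the response is
  permuted against age and the adjusted $R^2$ of the refit compared with
  the observed one, $p = (1 + \#\{\text{perm} \ge \text{obs}\})/(n_{perm}+1)$
  (add-one estimator, so $p \in (0,1]$). Both the observed and permuted
  statistics use the grid fitter, keeping the statistic exchangeable and
  the test exactly calibrated; 999 permutations by default (the permutation
  count is not pinned down by the study this emulates).
* **Multiplicity**: Benjamini--Hochberg FDR at $\alpha = 0.05$.
* **Homolog asymmetry of inflection times**: the published account of this
  comparison is internally ambiguous (a large t statistic reported next to
  a statement of non-significance), so the package treats *equivalence* as
  the primary reading: a TOST (two one-sided tests) of the left/right
  bootstrap distributions of $\beta_3$ with an explicit margin (default
  1 week), with the raw Welch t reported alongside. The same machinery
  tests $\beta_3$ against a reference window of thalamocortical ingrowth
  (default 24--32 GW). Treating bootstrap draws as samples makes these
  t-based summaries approximations; the margin, not the p-value machinery,
  carries the scientific content.
* **Adjusted $R^2$** uses 4 parameters for the sigmoid (the full fitted
  mean function; the source is silent on this choice).

## Preprocessing chain

All steps operate at the ROI/voxel-signal level; image-space operations
(bias-field correction, motion correction, reconstruction, segmentation)
are upstream of this package and enter only through their products: voxel
time series with tissue labels and rigid-body motion traces.

1. **Outlier-volume rejection** (`detectOutlierVolumes`): a voxel is an
   outlier at frame $t$ when the robust $z$ (median/MAD) of its temporal
   first difference exceeds `spikeZ` (default 5) both into and out of the
   frame (single difference at the series edges; using the smaller of the
   two adjacent differences attributes an isolated spike to the spiked
   frame rather than also to its successor). A volume is rejected when
   *strictly more than* `volumeFraction` (default 5%) of voxels are
   outliers --- a frame with exactly 5% is kept.
2. **aCompCor** (`computeACompCor`): top 5 principal components each from
   the white-matter and CSF voxel pools, computed on valid frames after
   per-voxel centring and variance normalization.
3. **Simultaneous high-pass filtering and nuisance regression**
   (`cleanTimeseries`): one joint least-squares projection of every ROI
   series on [intercept, discrete-cosine columns with frequency below
   0.008 Hz, nuisance columns], fitted on valid frames only. A single
   joint projection avoids the reintroduction-of-noise artifact of
   sequential filter-then-regress pipelines. Rejected frames are then
   filled by cubic-spline interpolation of the residuals (nearest valid
   value at the series edges, where spline extrapolation is
   ill-conditioned) and flagged; **interpolated frames are never used in
   correlation analysis** --- they exist only to keep the sampling grid
   regular.
4. **Connectivity** (`computeFC`): Pearson correlation over valid frames,
   unit diagonal, 78 cortical parcels (39 homolog pairs) plus a thalamus
   node. No spatial smoothing exists anywhere in the chain, and no Fisher
   transform is applied. A zero-variance ROI yields zero correlations plus
   a warning rather than an undefined matrix.

## Quality control

* **Subject level** (`dfcFdAssociation`): sliding-window (10 frames,
  step 1) upper-triangle FC vectors; the change between consecutive
  windows is correlated with the framewise displacement (FD) of the frames
  *entering and leaving* the window. We deliberately do not use the whole
  window's mean FD: with step 1, a motion spike spends most window pairs
  strictly inside both windows --- high FD with no FC change --- which
  makes the naive statistic systematically negative under exactly the
  artifact it is meant to flag. Aligning FD with the exchanged frames ties
  each FC change to the motion that can have caused it. Constant FD gives
  a defined statistic of 0 with a `degenerate` flag.
  FD itself is the standard sum of absolute translation differences plus
  head-radius (50 mm) times absolute rotation differences.
* **Group level** (`iterativeAgeConsistencyFilter`): in a homogeneous
  developing cohort, the distance between two subjects' connectomes should
  grow with the distance between their ages. FC matrices are regularized
  to SPD by shrinkage towards the identity (weight 0.1, which guarantees
  positive definiteness for short, censored series), embedded in the
  tangent space at their affine-invariant geometric mean (fixed-point
  iteration, tolerance $10^{-8}$, at most 50 iterations --- the iterative
  reference implies the affine-invariant geometry rather than the
  log-Euclidean one), and each subject's Pearson correlation between
  age gaps and tangent distances to all others is computed. Subjects with
  a negative correlation are removed --- all at once per iteration, which
  matches the plural phrasing of the procedure this implements and
  converges in few iterations --- and the set is re-embedded until no
  negative correlations remain or a floor (`minKeep`) is reached. The
  threshold is exactly 0: no tolerance band is defined for "negative".

## Asymmetry and laterality

* **Mirrored profiles**: the connectivity profile of a parcel is compared
  with the homolog-permuted profile of its contralateral twin; the entries
  belonging to the two parcels and their homologs are excluded (including
  them would inflate homolog similarity trivially). Profiles are
  thresholded first: entries below `tau` (default 0.1, reported across the
  grid {0.05, 0.1, 0.2} because the choice of "weak" is not canonical) are
  zeroed, which removes all negative connections.
* **Homolog test** (`homologSimilarityTest`): per parcel, a one-sided
  one-sample t comparison of the homolog similarity against the mean and
  spread of that parcel's similarities to all non-homolog parcels. The
  test is run per subject, and per-subject statistics are aggregated for
  the cohort (the source is ambiguous about pooling; both views are
  reported).
* **Laterality** (`lateralityIndex`):
  $LI = (L - R)/(L + R)$ on thresholded nodal degrees summed over a
  region's left and right parcels; weighted degrees by default (binary via
  flag --- the choice is not determined by the source). Positive LI means
  left dominance. When $L + R = 0$ the index is undefined (`NA`), never
  silently 0. LI is exactly antisymmetric under a hemisphere swap of the
  input matrix. Cohort-level significance is a two-sided one-sample t test
  of per-subject LI against 0, FDR-corrected across regions, plus an OLS
  of LI on age per region.

## The synthetic cohort generator

The generator emulates the acquisition and phenomena of a mid-gestation
fetal rs-fMRI study: 48 fetuses, ages uniform on 19+5 to 39+2 weeks (the
age distribution of the emulated study is unpublished; uniform is assumed),
96 volumes at TR = 3 s, 78 cortical parcels in left/right homolog pairs
plus one thalamus node, 10 grey-matter voxels per parcel and 50-voxel
WM/CSF pools (small enough for desk scale, large enough for rank-5
nuisance recovery).

**Connectivity ground truth.** Every edge follows the sigmoid above. The
mirror-symmetric base uses: a weak global increase (baseline 0.18,
span 0.12), stronger within-lobe coupling (baseline 0.28) with
lobe-specific inflection weeks (29--31), strong homolog-pair coupling
(baseline 0.38), and thalamus--visual-cortex edges carrying the published
left-hemisphere occipital trajectory parameters on both sides (using the
left-row values bilaterally keeps the base exactly mirror-symmetric; the
inflection weeks 26.9--31.1 are what the recovery studies estimate). Growth
spans are equal across cortical edge classes so that profile variance --
and with it the attenuation of observed profile correlations -- stays
age-stable; the class structure lives in the baselines, and a uniform shift
of a profile does not move Pearson correlations. A static mirror-symmetric
low-rank "topography" component (mirrored factor loadings, rank 10, entry
spread 0.15) gives profiles the stable spatial heterogeneity real
connectomes have; without it, profile correlations are estimation-noise
dominated. The matrix at each age is projected onto the correlation cone
(eigenvalue clipping + renormalization), a projection that is a no-op for
the default symmetric construction, which is verified positive definite
across the whole age range.

**Hemispheric effects.** Two switchable components:

* *Homolog-similarity decay*: the truth matrix is the convex blend
  $(1-w)\,M_{sym}(t) + w\,A$ with $w = 0.02\,(t - 19)$, where $A$ is a
  fixed random correlation matrix (rank-12 factor structure) that is not
  mirror-symmetric. Both ingredients are positive semidefinite, so the
  blend never needs clipping and the planted asymmetry survives intact.
  (An earlier additive mirror-antisymmetric perturbation was discarded:
  it pushed the matrix off the cone and the clipping projection erased
  most of the asymmetry.) With decay 0.02/week the mirrored-profile
  similarity of homolog pairs falls substantially across gestation ---
  the qualitative phenomenon of increasingly diverse, lateralized cortical
  circuitry.
* *Laterality*: temporal parcels (STG, MTG, ITG --- the regions where
  functional laterality is expected) are scaled by $1 \pm g(t)$ with
  $g = 0.03 + 0.025\,(t - 29)$, so the planted LI is about $g$ and grows
  at the published rate of 0.025 per week.

**Forward model.** Latent parcel signals are independent AR(1) noise
(lag-1 coefficient 0.4 by default, configurable to white) mixed through
the symmetric eigen square root of the truth matrix, so their correlation
equals the truth exactly in expectation. Grey-matter voxels add
i.i.d. noise (sd 0.5 per voxel, i.e. $0.5/\sqrt{10}$ after ROI averaging)
and a leak (weight 0.15) of 5 latent WM and 5 latent CSF components; WM and
CSF pools are spanned by those same components (exact rank 5 when tissue
noise is disabled). Motion-corrupted frames occur with probability 0.06 per
frame --- matching the reported average outlier-volume rate of about 6% ---
and receive *both* an intensity spike (amplitude 8 signal-SD, random sign,
on 30% of voxels; large enough that the robust-z statistic must find it) and
a motion-trace spike, so intensity-based censoring and FD-based QC see
consistent evidence. There is no hemodynamic response model and no
image-space geometry; frames are the atomic unit.

**What passing tests do and do not show.** The generator produces
correlation-exact, stationary-noise, label-perfect data. Real fetal fMRI
has spatially structured noise, imperfect segmentations, partial-volume
effects, and residual motion artifacts that survive censoring; a pipeline
that recovers this generator's truth is necessary, not sufficient, for
validity on real data.

**Planted QC anomalies** (`simulateCohortFc(nPlanted = ...)`): subjects
drawn from the outer thirds of the age range are generated at a random age
in the opposite outer third. Mid-range mismatches are only weakly
inconsistent (their distance profile correlates near zero, not negatively,
with the labelled age gaps), and a coherent reversed block would act as a
counter-cohort whose mutual pairs mask each other's inconsistency, so
incoherent extreme mismatches are the anomaly model.

**The statistical null** for trend-calibration checks is a *stationary*
cohort: growth frozen at its reference-age level, decay 0, laterality 0.
Merely setting decay to 0 is not a null for the similarity trend, because
edge growth changes the signal-to-noise of profile correlations with age
and thereby induces a genuine small trend in the observed similarity.

## Numerical choices

* GA notation "W+D" is parsed to $W + D/7$ decimal weeks everywhere.
* Correlation-to-signal construction uses the symmetric eigen square root;
  negative eigenvalues (only possible for non-default configurations) are
  clipped and the matrix renormalized to unit diagonal.
* SPD geometry is eigendecomposition-based throughout; the geometric-mean
  fixed point stops when the mean tangent step has Frobenius norm below
  $10^{-8}$ and errors with the iteration count if 50 iterations do not
  suffice.
* All randomness flows through explicit seeds; per-subject seeds are
  derived from a master seed (`childSeeds`), and helpers restore the
  caller's RNG state. Reruns of the pipeline with the same configuration
  are byte-identical; wall-clock timestamps appear only on stderr, never
  in result files.
* Collinear cleaning designs error naming the offending columns; fewer
  than 8 valid frames flags the subject as unusable for FC.

## Problem sizes in the validation suite

The test suite and the acceptance script run everything at study scale
(cohorts of 48, 96 frames) but keep replicate counts modest by design:
100 cohorts for inflection recovery, 1000 null cohorts (199 permutations
each) for test calibration, 200 replicates (200 bootstrap draws each) for
CI coverage, 20 cohorts for QC anomaly recovery, 100 cohorts per arm for
the similarity trend, and a 12--24-subject cohort for the byte-identity
check of the full pipeline. The fast variable-projection fitter is what
makes these sizes cheap; all bands asserted by the tests are stated in the
tests themselves.

## Known limitations

* Cross-sectional only: one scan per fetus, no mixed-effects or
  longitudinal modelling.
* The bootstrap-distribution t/TOST summaries are approximations, as noted
  above.
* The homolog-similarity statistic depends on the profile threshold
  `tau`; results are therefore reported across a small grid rather than at
  a single value.
* Vertex-level laterality maps and anatomical (Broca/Wernicke) labelling
  are out of scope; regions are parcel groups.
* The generator's voxel counts are desk-scale; it does not emulate
  spatially correlated noise or segmentation error.
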