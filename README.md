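# fetoconn

Modelling the in-utero development of functional thalamocortical and
cortico–cortical connectivity from fetal resting-state fMRI.

Between ~19 and 40 weeks of gestation, thalamocortical afferents leave the
subplate, invade the cortical plate and form the first cortical circuits;
functional synchrony between the thalamus and the visual cortex is expected
to rise steeply around 29–31 gestational weeks (GW). `fetoconn` is an R
package for researchers who want to quantify that development from
ROI-level BOLD signals: it implements the full analysis chain from voxel
time series to developmental growth curves and hemispheric-asymmetry
statistics, together with a synthetic fetal cohort generator with known
ground truth so that every stage can be validated end to end without any
clinical data.

## What it computes

* **Preprocessing** — outlier-volume rejection (robust-z of temporal
  differences, volumes with >5% outlier voxels censored), aCompCor nuisance
  regressors (top-5 WM + top-5 CSF principal components), and simultaneous
  0.008 Hz high-pass filtering + nuisance regression in one least-squares
  projection; censored frames are spline-interpolated but never used in
  correlations.
* **Connectomes** — 78 cortical parcels (39 left/right homolog pairs) plus
  a thalamus node; Pearson correlation over valid frames; thresholded nodal
  degrees.
* **Quality control** — a sliding-window dynamic-FC vs framewise-displacement
  statistic per subject, and a group-level Riemannian filter that embeds FC
  matrices in the tangent space at their geometric mean and iteratively
  removes subjects whose connectome distances correlate negatively with
  their age gaps.
* **Growth models** — per-edge sigmoid trajectories

  $$f(t) = \frac{\beta_1}{1+\exp[-(t-\beta_3)/\beta_4]} + \beta_2,$$

  where β₂/β₁+β₂ are the initial/final plateaus, β₄ the growth-rate scale
  and β₃ the inflection week (peak connectivity increase); fitted by a
  variable-projection multi-start with Levenberg–Marquardt polish, with
  case-bootstrap CIs (1000 draws), permutation tests of adjusted R², FDR
  correction, TOST equivalence tests of homolog inflection times and of β₃
  against the 24–32 GW afferent-ingrowth window, and lobe-level ANOVA.
* **Asymmetry** — mirrored connectivity-profile similarity of homolog
  pairs, per-parcel homolog-vs-others tests, similarity–age trends, and the
  laterality index LI = (Left − Right)/(Left + Right) on thresholded nodal
  degrees with its age regression (positive LI = left dominance).
* **Synthetic cohorts** — `generateCohort()`, `buildGroundTruth()`,
  `simulateSubject()` produce voxel-level BOLD with planted sigmoid edge
  trajectories (thalamo-occipital edges carry published occipital fit
  parameters), age-decaying homolog similarity, temporal-lobe laterality,
  motion-corrupted frames and rank-5 WM/CSF nuisance structure.

## Worked example

Recover the developmental trajectory of the thalamus–middle-occipital
connection from a simulated 48-fetus cohort (ages uniform on 19+5–39+2
weeks, edge values following the planted sigmoid plus noise):

```r
library(fetoconn)

parc   <- defaultParcellation()
truth  <- buildGroundTruth(parc, seed = 1)
cohort <- generateCohort(48, seed = 7)
ga     <- cohort$ga_weeks

set.seed(7)
y   <- sigmoidCurve(ga, c(0.3587, -0.0133, 29.3857, 0.4614)) + rnorm(48, sd = 0.1)
fit <- fitSigmoid(ga, y)
fit
#> SigmoidFit: beta1=-0.3501 beta2=0.3482 beta3=28.63 beta4=-0.1018
#>   adjR2=0.733 AIC=-76.81 BIC=-67.46 n=48

pt <- permutationGofTest(ga, y, nPerm = 999, seed = 7)
bp <- bootstrapParams(ga, y, nBoot = 1000, seed = 7)
#> permutation p = 0.001 (adjusted R2 = 0.71)
#> beta3 95% CI: [28.47, 30.28] weeks

inflectionWindowTost(bp$samples[, "beta3"], window = c(24, 32))$within
#> TRUE
```

The fitted inflection week (β₃ ≈ 28.6, CI 28.5–30.3) recovers the planted
29.39 weeks; the sign-flipped (β₁, β₄) pair is the equivalent
parametrization of the same rising curve (see the methods vignette). The
permutation test rejects the no-development null, and the bootstrap TOST
places the inflection inside the 24–32 GW window of thalamocortical
afferent ingrowth.

Laterality of the inferior-temporal region across the same cohort:

```r
seeds <- childSeeds(7, 48)
li <- vapply(seq_len(48), function(i)
  lateralityIndex(simulateFcMatrix(truth, ga[i], seed = seeds[i]),
                  parc, "ITG", tau = 0.1), numeric(1))
reg <- liAgeRegression(li, ga)
#> ITG laterality: mean LI = 0.047, slope = 0.0275/week (p = 3.1e-12)
```

The cohort is left-dominant on average and laterality increases with
gestation at the planted rate of 0.025/week.

The whole chain — simulate, preprocess, connectomes, QC, fits, asymmetry —
runs as one call (`runPipeline(fetoconnConfig(), outDir = "out")`) or from
the shell via `exec/fetoconn simulate|run`; reruns with the same
configuration and seed produce byte-identical result bundles.

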