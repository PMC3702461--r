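---
title: "Classification-based pseudo-CT synthesis and ion-range error analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classification-based pseudo-CT synthesis and ion-range error analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pction)
```

## The problem

Ion radiotherapy planning needs a map of relative stopping power, which is
routinely derived from X-ray CT numbers through an empirical Hounsfield
lookup table (HLUT).  MRI carries no physical relationship to stopping
power, but it is attractive for adaptive treatment because it adds no dose:
the patient could be imaged before every fraction.  `pction` implements the
two-step conversion that makes MR-only planning testable: (1) predict a
*pseudo CT* (pCT) volume from several co-registered MR contrasts by purely
statistical, voxelwise classification; (2) convert CT numbers to relative
water-equivalent path length (WEPL) through an HLUT and quantify what the
pCT errors do to beam range, via water-equivalent thickness (WET).

The intended user is a medical-physics researcher evaluating whether a set
of MR contrasts carries enough information for range-relevant tissue
discrimination — not a clinical dose engine.

## The classification model

Every masked voxel $j$ contributes an observation vector
$X_j \in \mathbb{R}^p$ built from the selected contrast intensities plus
optional derived features (below).  The CT scale is partitioned into $K$
fixed-width classes — by default 128 classes of 32 HU anchored at
$-1024$ HU, covering $[-1024, 3072)$ — and each learning voxel is labelled
with the class of its reference-CT number.  Labels are therefore free: any
co-registered MR/CT pair is a learning sample.

The classifier is a high-dimensional discriminant analysis in its most
general per-class form.  Class $k$ is Gaussian with mean $\mu_k$ and a
covariance constrained to a $d_k$-dimensional signal subspace with
isotropic residual noise:

$$\Sigma_k = Q_k\,\mathrm{diag}(a_{k1},\dots,a_{kd_k})\,Q_k^{\mathsf T}
  + b_k\,(I - Q_k Q_k^{\mathsf T}),$$

with orthonormal $Q_k \in \mathbb{R}^{p\times d_k}$, subspace variances
$a_{kj} \ge b_k$ and noise variance $b_k > 0$.  Fitting is by per-class
eigendecomposition of the empirical (maximum-likelihood) covariance: the
top $d_k$ eigenvalues become $a_{kj}$, the remaining variance is pooled
into $b_k = (\mathrm{tr}\,\Sigma_k - \sum_{j\le d_k}\lambda_{kj})/(p-d_k)$.
The intrinsic dimension is selected by Cattell's scree rule on eigenvalue
gaps: with $\delta_j = \lambda_j - \lambda_{j+1}$, $d_k$ is the largest $j$
with $\delta_j \ge t\,\max_j \delta_j$ and $t = 0.2$ by default.

Classification uses the cost

$$K_k(x) = \sum_{j\le d_k}\frac{(q_{kj}^{\mathsf T}(x-\mu_k))^2}{a_{kj}}
 + \frac{\lVert (x-\mu_k) - Q_kQ_k^{\mathsf T}(x-\mu_k)\rVert^2}{b_k}
 + \sum_{j\le d_k}\log a_{kj} + (p-d_k)\log b_k - 2\log\pi_k,$$

which is $-2\log(\pi_k\,\phi(x;\mu_k,\Sigma_k))$ up to the
class-independent constant $p\log 2\pi$.  Posteriors follow by softmax over
$-K_k/2$ with max-subtraction; the package pins this implementation to a
dense-Gaussian oracle on the reconstructed $\Sigma_k$ in its test suite, so
the subspace shortcut is verified rather than trusted.

The pseudo CT number is the *soft* reconstruction
$\mathrm{pCT}_j = \sum_k P(C_k \mid X_j)\,\overline{\mathrm{HU}}_k$, the
posterior-weighted average of the per-class mean CT numbers from the
learning set.  With 32 HU classes this reconstruction is quantised: even a
perfect classifier leaves per-class mean errors of up to $\pm 16$ HU, and
that bound is the yardstick the end-to-end tests use for soft tissue.

### Features

Per contrast image the observation vector can include, besides the raw
intensity:

* `box.mean` — mean over the $3\times3\times3$ neighbourhood (26
  neighbours plus the centre); boxes at volume borders use the available
  voxels only (truncation, not zero padding, so no fake air context leaks
  into the statistics).
* `box.sd` — the *population* (n-denominator) standard deviation of the
  same box, **multiplied by the central voxel's intensity**.  The intensity
  weighting is deliberate and kept as the default because it is the variant
  this pipeline is defined with; it amplifies the feature exactly at bright
  boundary voxels where partial-volume misclassification concentrates.  A
  `weight_by_intensity = FALSE` toggle provides the plain box sd.

Globally, coordinate features can be appended: `dist.xyz`, the three
per-axis absolute distances (mm) to the sample centroid, and
`dist.center`, the in-plane (axial $x$–$y$) radial distance (mm).
Coordinates are voxel centres in world millimetres, translated so the mask
centroid sits at the origin — this emulates samples centred in the imaging
volume and makes the features invariant to where the scanner put the
origin.  The centroid is computed per volume (not per slice), and
millimetres (not voxel indices) were chosen as units; both choices are
fixed and documented here because either convention would be defensible.

The dimensionality is $p = n_\text{contrasts}(1 + \text{box.mean} +
\text{box.sd}) + 3\,\text{dist.xyz} + \text{dist.center}$.  The
best-performing combination on the digital phantoms — proton-density TSE
plus the two ultrashort echoes, each with `box.sd`, plus `dist.center` —
spans $p = 7$.

All features are standardised to mean 0, sd 1 on the learning set;
prediction data are transformed with the learning-set parameters, never
rescaled on their own.

### Numerical choices and degenerate inputs

* **Class anchor.**  The HU grid anchor at $-1024$ is configuration: 128
  classes of 32 HU then cover the clinical 140 kVp scale ending at
  $+3072$.  Out-of-range HU values clamp to the end classes instead of
  erroring, so metal-like outliers cannot abort training.
* **Sparse classes.**  Classes with fewer than $5p$ learning voxels
  (configurable) are dropped — covariance estimation needs members — and
  their voxels are relabelled to the retained class with the nearest
  midpoint.  Posteriors are renormalised over retained classes, keeping
  the posterior field a simplex.
* **Singular covariances.**  $b_k$ is floored at $10^{-6}$ (scaled units)
  with a warning; $a_{kj}$ is floored at $b_k$ so the subspace always
  carries the largest variances.
* **Determinism.**  Eigenvector signs are fixed (first non-zero component
  positive); scree-rule ties resolve to the larger dimension (keeps more
  structure); the learning-voxel subsample is seeded.  Training twice on
  identical input serialises byte-identically.
* **Scree rule scope.**  Whether the dimension threshold should act on
  eigenvalue *gaps* or on cumulative variance is a genuinely open choice;
  the gap rule is implemented and isolated behind `select_dimension()` so
  the alternative is a one-function substitution.

## The digital phantom generator

No scanner data ships with the package; `phantom_scene()` +
`render_volumes()` emulate a meat-sample acquisition so that every stage is
testable end to end.  The default scene is a fat shell around a muscle
bulk, one cortical-bone cylinder shell with a yellow-marrow core, a
cartilage band, and an internal air cavity, on a $48\times48\times24$ grid
of 2 mm voxels.  `variant` jitters region centres (up to 3 mm) and sizes
(up to 5 %) deterministically, giving several anatomically similar but
distinct samples for cross-validation — the analogue of scanning three
different pork samples.

The forward model, in order:

1. **Labels** are rasterised at a supersampled resolution (factor 2 by
   default; each target voxel contains 8 fine voxels).
2. **Signals**: per tissue and sequence, standard steady-state closed
   forms — spin echo $S = \mathrm{PD}(1-e^{-TR/T1})e^{-TE/T2}$; spoiled
   gradient echo $S = \mathrm{PD}\sin\alpha\,(1-E_1)/(1-\cos\alpha E_1)\,
   e^{-TE/T2^*}$ with $E_1 = e^{-TR/T1}$; inversion-prepared
   $S = \mathrm{PD}\,|1-2e^{-TI/T1}+e^{-TR/T1}|\,e^{-TE/T2}$.  No Bloch
   simulation: the pipeline needs contrast plausibility, not quantitative
   MR.  Fat saturation is modelled as label-based nulling of fat-like
   tissues.  The tissue table carries literature T1/T2 (T2* for the
   sub-millisecond cortical bone), relative proton and electron densities.
   Note that at the short-TR, low-angle settings of a realistic ultrashort
   echo protocol the steady-state factor suppresses the absolute bone
   signal well below proton density even at $TE = 0.05$ ms — what makes
   bone separable from air is the *ratio* between the two echoes
   ($e^{(4.91-0.05)/0.45} \approx e^{10.8}$), not a large absolute signal.
3. **Partial volume** by block-averaging the fine noiseless volumes to the
   target grid; the block mean preserves the fine-grid mean exactly and
   creates the intermediate boundary voxels that dominate real pCT errors.
   Ground-truth labels are reduced by per-block majority vote.
4. **Bias field**: each MR volume is multiplied by $1 + a\,P(x,y,z)$ with
   $P$ a seeded quadratic polynomial normalised to $\max|P| = 1$, so the
   field lies in $[1-a, 1+a]$ and is strictly positive for $a < 1$.  This
   stands in for inhomogeneous coil illumination without modelling coils.
5. **Noise**: Rician on MR magnitudes (two-channel Gaussian magnitude) and
   additive Gaussian on CT.  Every stream is derived from one root seed by
   a fixed tag-hash derivation, so a scene renders bit-identically.

Nominal CT numbers are bulk assignments (air $-1000$, fat $-100$, marrow
$-80$, muscle $+40$, cartilage $+120$, cortical bone $+1200$) consistent
with a 140 kVp scale; the tissue table gives electron density, not HU, so
these are configurable defaults rather than derived quantities.  MR noise
sigma (0.02 signal units), CT sigma (10 HU) and bias amplitude (0.05) are
free parameters chosen as plausible for a modern 3 T acquisition; nothing
calibrates them to any particular scanner.

What the phantom deliberately does *not* emulate: k-space/radial sampling,
geometric distortion, multi-coil reconstruction, scanner-specific filters,
registration error (volumes are generated co-registered; an integer-voxel
`misalign()` injector exists for sensitivity studies).  Passing tests on
these phantoms therefore demonstrates the statistical machinery — not
robustness to real-scanner artefacts, where registration and resampling
errors are known additional error sources.

## Masking and resampling

All computation is restricted to an air-exclusion mask: CT threshold
($-800$ HU default — the mixture HU of a voxel that is roughly three-quarters
air), morphological closing (radius-1 cube) to seal thin gaps, and removal
of connected components under 27 voxels.  The threshold and morphology are
configuration; no canonical values exist.  Resampling onto the CT grid is
trilinear on voxel centres (world coordinate $= \mathrm{origin} +
(\mathrm{index}+\tfrac12)\,\mathrm{spacing}$ with 0-based indices), exact
for affine fields, with out-of-extent reads returning an air-equivalent
padding value.

## Evaluation and the range proxy

Accuracy is reported as $\mathrm{MAE} = \frac1n\sum_i
|\mathrm{pCT}_i - \mathrm{rCT}_i|$ over masked voxels and as per-class
signed mean errors $\mathrm{ME}_{cl}$, with class membership taken from the
*reference* CT so errors attach to the true tissue class.

For range analysis, HU converts to relative WEPL through a piecewise-linear
HLUT with linear end-segment extrapolation floored at 0.  The shipped
default table (air 0, water 1, cortical-bone range up to 2.4) is
configuration: every WET number is relative to the HLUT in use, and a
site-measured table should be supplied for any quantitative claim.
Per-tissue pCT errors propagate as $\Delta\mathrm{WEPL} =
w(\mathrm{HU}_{rep} + \mathrm{ME}) - w(\mathrm{HU}_{rep})$ at a
representative HU per tissue group (interval midpoint by default; the
right representative value is genuinely underdetermined, so it is
configurable), and $\Delta\mathrm{WET} = \Delta\mathrm{WEPL}\times d$,
exactly linear in the tissue thickness $d$.  Standard errors are offered
in two modes because either correlation assumption is defensible:
`"sqrt"` (independent per-voxel errors accumulating as a random walk along
the path, SE $\propto\sqrt d$) and `"linear"` (fully correlated errors,
SE $\propto d$).  Neither mode is claimed to reproduce any published error
table.

Beam transport is a deliberately honest proxy, not a dose engine: rays are
axis-aligned (matching a lateral irradiation geometry), WET is the running
sum of voxel WEPL times step length, and the planning-relevant quantity is
the per-ray WET from the entry face to the distal PTV surface.  Pencil-beam
optimisation, ripple filters, DVHs and dose prescriptions are out of scope.

The target-shift adaptation experiment shifts the PTV (2 mm in $x$ and
$y$ by default; integer-voxel shifts are exact, fractional ones threshold a
trilinearly interpolated indicator at 0.5) and compares two mean absolute
distal-WET errors: (A) *adapted* — re-planned on the pCT against the
shifted PTV, judged on the reference CT, isolating the classifier's range
error; and (B) *non-adapted* — the original reference-CT plan evaluated
against the shifted target, isolating the geometric miss.  With zero shift
and a perfect pCT both vanish; with zero shift alone B vanishes and A is
the plain pCT range error.  These decomposition identities are asserted in
the tests; the scientific claim mirrored here is that A is of the same
order as B, i.e. planning on MRI-derived CT numbers costs about as much
range accuracy as *not adapting* to a 2 mm target movement.

## Problem sizes and runtime choices

The test suite and the acceptance script run on $48\times48\times24$
phantoms at 2 mm spacing with supersampling 2 (about 16 000 masked voxels
per sample, $p = 7$), three samples in leave-one-out folds; the subspace
fits use all learning voxels (the configurable cap of 200 000 never binds
at this size).  The dense-Gaussian oracle comparisons use 100 random
instances with $p \le 10$, $K \le 8$; parameter recovery uses $n = 10^4$
per class.  These sizes were chosen so a full validation cycle completes
in well under a minute on one core while every statistical claim is still
measurable at its stated tolerance.

## Known limitations

* The 32-HU quantisation floors achievable per-class accuracy at
  $\pm 16$ HU by construction; non-equidistant class schemes are not
  implemented.
* Sparse partial-volume HU bins (boundary mixtures) retain per-class mean
  errors well beyond the quantisation bound even with noiseless data —
  adjacent classes overlap heavily in feature space and the soft
  reconstruction pulls their members toward better-populated neighbours.
  This is intrinsic to voxelwise classification at finite resolution, and
  it is why the end-to-end checks distinguish pure-tissue classes from
  mixture bins.
* Cortical-bone classes are systematically underestimated once the
  ultrashort-echo contrast is removed; the directional test (bone error
  strictly inflates without it) is part of the acceptance suite.
* Rigid/deformable registration is out of scope; synthetic volumes are
  perfectly aligned, so all reported errors exclude registration error.
* The exhaustive contrast/feature enumeration is generic
  (`pct_crossval()` over any spec list); no attempt is made to reproduce
  a specific historical combination count, whose construction rule is not
  public.
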