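---
title: "Methods: R2t* mapping, regional summaries and cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: R2t* mapping, regional summaries and cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(r2tstar)
```

## The signal model and its assumptions

The multi-gradient-echo magnitude signal is modeled as the product of
three factors,

$$S(TE) = S_0\, e^{-R2t^{*}\cdot TE}\; F_{BOLD}(TE)\; F(TE),$$

separating what the decay rate R2\* lumps together: a tissue-specific
mono-exponential component $R2t^{*}$ (s⁻¹), dephasing around deoxygenated
venous blood, and dephasing from macroscopic field inhomogeneity.

**BOLD term.** $F_{BOLD}(TE) = \exp(-\zeta\, f_s(\delta\omega \cdot TE))$
is the static-dephasing-regime attenuation around a randomly oriented
vessel network: $\zeta$ is the deoxygenated-blood volume fraction
(dimensionless, physiologically a few percent) and $\delta\omega$ the
characteristic frequency shift of blood relative to tissue (s⁻¹). The
attenuation exponent is

$$f_s(x) = \frac{1}{3}\int_0^1 (2+u)\sqrt{1-u}\;
\frac{1 - J_0(1.5\,x\,u)}{u^2}\,du,$$

monotone non-decreasing, $\approx 0.3x^2$ as $x \to 0$, asymptotically
linear with unit slope, and always $\le x$. The model is magnitude-only:
the frequency-shift (phase) effects of the blood compartment, multi-
compartment water, and any $T_1$/flip-angle weighting of $S_0$ are out of
scope.

**Macroscopic-field term.** The full voxel-spread-function treatment of
field-inhomogeneity artifacts is replaced by its first-order equivalent: a
linear through-voxel gradient $g$ (Hz/mm) across the slab dimension
$\Delta z$ (mm) dephases the voxel uniformly, giving
$F(TE) = |\mathrm{sinc}(g\,\Delta z\,TE)|$. The gradient is estimated per
voxel from the data (below), and the term can enter the fit either as a
model factor or as a pre-correction dividing the data
(`fit_options(macro_mode = )`); both recover identical parameters on
noiseless data and the model form is the default because it never divides
by a near-zero attenuation.

**Acquisition.** Defaults follow a high-resolution 3D protocol: ten
echoes, first echo 4 ms, spacing 4 ms, TR 50 ms, flip angle 30°, voxels
1×1×2 mm³. All operations also accept an explicit echo-time vector, so
non-uniform echo grids work throughout. Units are seconds, s⁻¹ and Hz/mm
internally; converters live at the I/O boundary.

## Numerical evaluation of $f_s$

Two paths are provided. The reference path integrates by adaptive
quadrature (relative tolerance 1e−10) after the substitution $u = 1-t^2$,
which removes the square-root derivative singularity at $u = 1$; the
removable $u^{-2}$ singularity at the origin is handled by a series-
protected evaluation of $1 - J_0(z)$ (direct computation loses all
precision below $z \approx 10^{-3}$). The voxelwise path precomputes a
dense table on $x \in [0, 100]$ (spacing 0.01) with 256-node
Gauss–Legendre quadrature and interpolates with a monotone Hermite spline;
it agrees with the reference to better than 1e−10 and continues linearly
beyond the table (the asymptotic regime; with the default
$\delta\omega = 70$ s⁻¹ and 40 ms last echo, $x \le 2.8$).

## Voxelwise fitting

Fits are bounded Levenberg–Marquardt least squares (via
`minpack.lm::nls.lm`) of the magnitude model to each voxel's echo series,
initialized from the log-linear estimate of $(S_0, R2t^{*})$ with
$\zeta_0 = 0.01$. Convergence tolerance is 1e−10 on the cost decrease with
at most 200 iterations; non-convergence returns the initialization flagged
`converged = FALSE` rather than an error, and the result is independent of
voxel traversal order.

**Degrees of freedom.** Ten magnitude points constrain a four-parameter
model poorly, so the default mode fixes $\delta\omega$ at 70 s⁻¹ and fits
$(S_0, R2t^{*}, \zeta)$; joint fitting of $\delta\omega \in [10, 300]$ is
available behind `fit_options(mode = "fit_zeta_and_delta_omega")`. In the
fixed mode the $f_s$ vector over echoes is parameter-independent, and the
Jacobian is closed-form — this is the hot path.

**Bounds.** $S_0 \ge 0$, $R2t^{*} \in [0, 100]$ s⁻¹ (bracketing fluid at
about 1 s⁻¹ and tissue at 15–20 s⁻¹), and $\zeta \in [-0.2, 0.2]$. The
symmetric $\zeta$ range is deliberate although the blood volume fraction
is physically non-negative: with a hard floor at zero the estimator's
noise distribution is censored on one side, which at SNR 50 biases
$R2t^{*}$ by about −6% in Monte-Carlo; letting the optimizer explore small
negative $\zeta$ removes the censoring (bias ≈ +1% at SNR 50) at the cost
of a physically loose per-voxel $\zeta$. Regional medians are unaffected
by the widened range's variance, and users needing a strictly physical
$\zeta$ map can restore the floor via `fit_options(bounds = )`.

**Noise model.** Magnitude data with complex Gaussian noise is Rician; no
Rician likelihood is used. Instead the quality mask drops voxels where the
Rician floor matters: expected last-echo SNR below 3 (when the noise level
is known), residual RMS above 3× the noise level, macroscopic attenuation
at the last echo below 0.3, or non-convergence. Voxels with non-finite
input are skipped and flagged.

## Phase processing

**Navigator correction.** Physiological fluctuations add, to first order,
one global phase per excitation. Each excitation acquires one k-space line
along the phase-encode axis, so an uncorrected per-excitation phase ghosts
the magnitude image along that axis. The correction transforms the complex
data to k-space along the phase-encode dimension, removes the recorded
navigator phase per line, and transforms back — exact when the
fluctuation really is zeroth-order (spatially resolved fluctuations
remain, and whether the original acquisitions' correction was spatially
resolved is not known; the zeroth-order model is a labeled
simplification). Magnitude-only data cannot be corrected and raises an
error.

**Field estimation.** The per-voxel field offset is the least-squares
slope of the temporally-unwrapped phase across echoes divided by $2\pi$
(Hz). Unwrapping is temporal only — successive echo differences are
wrapped into $(-\pi, \pi]$ — which is unambiguous for offsets below
$1/(2\Delta TE)$ = 125 Hz at the default spacing; no spatial unwrapping is
needed because each voxel's series is treated independently. The
through-slab gradient is the central finite difference of the field map
along the slab axis divided by the slab voxel size, one-sided at mask
edges, zero for voxels with no in-mask neighbor.

## Regional summaries

Regional R2t\* is the median over a region's labeled voxels intersected
with the fit quality mask: medians damp segmentation errors, and
intersecting the quality mask extends the same robustness logic to fit
artifacts. Volumes deliberately count *all* labeled voxels regardless of
fit quality — atrophy measurement must not depend on the relaxometry fit —
and the normalized volume multiplies by a per-subject skull-size scaling
factor supplied as an input (the scaling computation itself, like
segmentation and registration, is upstream of this package; the label
volume is consumed in FreeSurfer-convention NIfTI + TSV form). The default
region set is eleven limbic regions × two hemispheres. Missing regions
yield missing-value rows plus a warning, never an error.

## Cohort statistics

All tests are complete-case with per-cell n reported.

- **Group comparisons** (`ancova_compare`): linear model
  `value ~ group + age + gender` by least squares; omnibus group effect by
  extra-sum-of-squares F-test against the covariate-only model; pairwise
  contrasts as t-tests on coefficient differences using the full
  coefficient covariance. Hemispheres are analyzed separately (a
  repeated-measures treatment of hemisphere is noted as unimplemented).
  Without covariates the two-group case reduces exactly to the pooled
  t-test.
- **Partial correlations**: `x` and `y` are residualized on
  [intercept, covariates] by QR least squares and the residuals
  correlated; $t = r\sqrt{df/(1-r^2)}$, $df = n - k - 2$. The Spearman
  variant rank-transforms first (average ranks on ties), so it is
  invariant to strictly monotone transforms; its p-value uses the same t
  reference (an approximation standard at these n). Rank-deficient
  covariates raise an error naming the collinear columns.
- **Battery layout**: cognitive scores (PASAT 3s/2s, SDMT) use partial
  Pearson across all regions; the skewed physical scores (EDSS, timed
  25-foot walk, nine-hole peg test) use partial Spearman and are examined
  in the deep structures (hippocampus, amygdala) only. Peg-test rows
  include right-handed subjects only and pair the dominant hand with
  left-hemisphere measures and the non-dominant hand with right-hemisphere
  measures. Covariates are age, a gender dummy, lesion load and a binary
  treatment flag (drug-class-level encoding is out of scope). Correlation
  analyses are MS-only by default.
- **FDR families**: the correction is applied exactly once per family by
  the step-up rule $q_{(i)} = \min_{j\ge i}\min(1, p_{(j)} m/j)$, with
  significance at adjusted p < 0.05. Family definition is a genuine
  design choice (no canonical answer exists): families follow the
  analysis presentation units — per measure, cognitive-deep
  (hippocampus + amygdala), cognitive-cortex (the nine cortical limbic
  regions) and physical. One family per presented table is reproducible
  and keeps unrelated analyses from diluting each other; the report
  header states the family definition.

## Synthetic data: what it emulates, and what it does not

**Phantoms** are piecewise-constant: a bordered grid split into
hemispheres, a CSF slab (R2t\* = 1 s⁻¹), and one box region per
(region, hemisphere) with tissue values of 15–20 s⁻¹. The complex signal
is built exactly from the forward model (so noiseless round-trips are
machine-precision), with a polynomial B0 field whose analytic z-derivative
drives the through-slab attenuation, a sinusoidal per-excitation navigator
drift applied to k-space lines, and complex Gaussian noise specified as
1/SNR of the mean tissue signal (magnitude data therefore Rician — the
standard post-coil-combination approximation; coil-level simulation,
k-space trajectories and realistic anatomy are not emulated). Phantom
tests therefore demonstrate estimator correctness under the model's own
assumptions, not robustness to model misspecification.

**Cohorts** emulate the study design: 31 HC, 32 RRMS, 32 SPMS, 16 PPMS
with the study's group-wise gender composition and age moments; lesion
load (log-normal, MS only), treatment (75% of MS), handedness (73 of 80 MS
right-handed). Regional truths are healthy means plus designed group
deficits (defaults −0.3/−0.9/−0.5 s⁻¹ R2t\* and −3/−9/−5% NV for
RRMS/SPMS/PPMS — the direction and rough magnitude of reported MS
deficits), an age slope, and subject noise (SD 0.6 s⁻¹, 7% NV). Clinical
scores carry designed covariate-adjusted correlations: a score loads on
the empirical covariate-residual of its target cell with weight $\rho$
and on independent noise with weight $\sqrt{1-\rho^2}$, so the partial
correlation is centered on the target by construction (defaults: SDMT ↔
left hippocampus R2t\* at 0.4, PASAT-2s ↔ left amygdala at 0.36, EDSS ↔
right amygdala at −0.29). Skewed scores are monotone transforms of a
latent Gaussian (EDSS additionally rounded to half-points, creating
realistic ties) — chosen to exercise the Pearson/Spearman split, not to
claim the true clinical distributions.

**Fixture SNR.** The end-to-end fixture uses the reduced 16×16×8 grid for
speed, which shrinks regions to 35–70 voxels versus thousands in real
anatomy. Since the regional median's sampling error scales as the
voxelwise error over $\sqrt{n_{voxels}}$, running the reduced grid at the
voxel-level SNR of 50 would inflate the median's error far beyond its
realistic proportion to between-subject variance. The fixture therefore
defaults to SNR 300, the level at which the reduced-grid median error
matches what SNR 50 yields at anatomical region sizes. Voxel-level
recovery checks still run at SNR 20–100.

## Problem sizes and determinism

Every generator is a pure function of its specification and a mandatory
seed (bit-reproducible; the global RNG state is saved and restored). The
test suite uses a 16×16×8 phantom (1176 brain voxels) for volume fits, 500
Monte-Carlo repeats for the SNR-50 bias check and 200 per SNR for the RMSE
curve, 1000 replicates for the ANCOVA type-I calibration and the FDR
oracle comparison, one full 111-subject end-to-end study, and 20 repeated
cohorts for null-cell false-positive calibration. The pipeline skips
stages whose configuration and input checksums are unchanged, and a
subject with missing files is reported and skipped without blocking
others.

## Known limitations

- The BOLD term's functional form and the linear-gradient sinc stand-in
  are first-order models; strong susceptibility interfaces (air/tissue)
  violate the linear-gradient assumption and such voxels are only
  handled by exclusion via the quality floor.
- Per-voxel $\zeta$ at clinical SNR is noisy and best interpreted
  regionally; the default mode does not attempt per-voxel
  $\delta\omega$.
- The Spearman p-value uses the t approximation; exact permutation
  inference is not provided.
- Normalized-volume effects cannot be carried by the fixture's imaging
  path (all subjects share one label geometry), so NV statistics are
  exercised at the cohort-generator level; in the imaging fixture NV
  cells act as additional nulls.
- Real-data inputs are assumed co-registered with the label volume;
  registration, segmentation, coil combination and lesion segmentation
  are upstream of this package.
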