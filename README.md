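# r2tstar

Quantitative mapping of the tissue-specific transverse relaxation rate
R2t\* from multi-gradient-echo MRI, with the regional aggregation and
cohort statistics used in clinical neuroimaging studies of tissue
integrity — for example comparing limbic-system damage between multiple
sclerosis patients and healthy controls and relating it to cognitive and
physical test performance.

## The model

The gradient-echo signal decay rate R2\* mixes a tissue-specific component
with a physiological one: dephasing around deoxygenated venous blood (the
BOLD effect) and macroscopic field inhomogeneity both accelerate the
apparent decay. The package fits the decomposed magnitude model

    S(TE) = S0 · exp(−R2t* · TE) · F_BOLD(TE) · F(TE)

voxel by voxel, where

- `F_BOLD(TE) = exp(−ζ · f_s(δω · TE))` is the static-dephasing-regime
  attenuation from a randomly oriented vessel network, with ζ the
  deoxygenated-blood volume fraction, δω the characteristic frequency
  shift (s⁻¹), and
  `f_s(x) = (1/3)∫₀¹ (2+u)√(1−u) (1 − J₀(1.5xu))/u² du`
  (J₀ the zeroth-order Bessel function; `f_s(x) ≈ 0.3x²` for small x and
  grows with unit slope for large x);
- `F(TE) = |sinc(g·Δz·TE)|` is a first-order model of signal loss from a
  linear through-voxel field gradient `g` (Hz/mm) across the slab
  dimension `Δz` (mm), with `g` estimated per voxel from the phase
  evolution across echoes.

In pure fluid (CSF) R2t\* is about 1 s⁻¹; in normal brain tissue about
15–20 s⁻¹, rising with the density of proteins, lipids and cellular
constituents — which is what makes it a tissue-integrity biomarker.

Around the fit, the package provides:

- **navigator correction** of per-excitation physiological phase
  fluctuations (zeroth-order global phase per acquired k-space line);
- **B0 field and through-slab gradient estimation** from
  temporally-unwrapped phase;
- **ROI summaries**: per-region median R2t\* (medians damp segmentation
  errors) and skull-normalized volumes (NV), from a FreeSurfer-convention
  label volume and a per-subject scaling factor;
- **cohort statistics**: covariate-adjusted ANCOVA group comparisons,
  partial Pearson correlations (cognitive scores) and partial Spearman
  correlations (skewed physical scores) controlled for age, gender,
  lesion load and treatment, with Benjamini–Hochberg FDR per analysis
  family and the lateralized nine-hole-peg-test rule;
- **synthetic data**: phantoms generated from the forward model (known
  ground truth, B0 fields, navigator drift, Rician noise) and cohorts
  with designed group effects and designed score–R2t\* partial
  correlations, so every stage is testable end to end without acquired
  data.

## Worked example

Simulate a phantom, correct and fit it, and summarize by region:

```r
library(r2tstar)

ph    <- make_phantom(phantom_spec(seed = 42, snr = 100))
img   <- navigator_correct(ph$image, ph$nav)
field <- estimate_field(img)
qm    <- fit_volume(img, field, fit_options())
qm
#> qmaps: 16 x 16 x 8 | 1176 fitted voxels, 1176 pass quality
#>   R2t* median: 16.68 s^-1

s <- summarize_subject(qm, ph$label_map, scaling_factor = 1.05,
                       subject_id = "example")
head(s[, c("region_name", "hemisphere", "median_r2t_star",
           "n_voxels", "normalized_volume")], 4)
#>  region_name hemisphere median_r2t_star n_voxels normalized_volume
#>  hippocampus       left        14.83768       35              73.5
#>  hippocampus      right        14.76838       35              73.5
#>     amygdala       left        15.78633       70             147.0
#>     amygdala      right        15.67076       70             147.0

bh_fdr(c(0.005, 0.03, 0.04))
#> [1] 0.015 0.040 0.040
```

The phantom's regional medians land on the generating truths (the default
phantom assigns tissue R2t\* values between 15 and 20 s⁻¹ per region);
`normalized_volume` is voxel count × voxel volume × scaling factor.

A whole synthetic study (111 subjects: 31 HC, 32 RRMS, 32 SPMS, 16 PPMS)
runs through the full pipeline in one call:

```r
cfg <- pipeline_config(input_dir = "study/in", output_dir = "study/out",
                       simulate = list(seed = 1), seed = 1)
run_pipeline(cfg)
```

which writes quantitative maps, a region-summary TSV, tidy statistics
tables and a plain-text report grid of correlation estimates and
FDR-adjusted p-values per region × clinical test. A thin command-line
wrapper with `simulate`/`fit`/`summarize`/`stats`/`run-all`/`report`
subcommands is installed at `inst/exec/r2tstar`.

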