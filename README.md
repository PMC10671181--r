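# petbtv

Quantitative analysis of paired-tracer brain PET in recurrent
glioblastoma: biological tumour volume (BTV) delineation, tumour-to-brain
and tumour-to-organ ratios, inter-tracer overlap and correlation, and
exact nonparametric cohort statistics — with a synthetic phantom
generator so the whole pipeline is testable without patient images.

It is written for imaging scientists comparing an amino-acid tracer
([18F]FET, mapping tumour metabolism) with a PSMA ligand
([68Ga]Ga-PSMA-617, mapping tumour neovasculature) in the same patients,
and for anyone who needs a reproducible, scriptable version of this kind
of dual-tracer PET quantification.

## What it computes

**SUV conversion with decay correction.** Activity `A` (Bq/mL) becomes

    SUV = A * W / (D * exp(-ln2 * dt / t_half))

with body weight `W` (g), injected dose `D` (Bq) and injection-to-scan
interval `dt` (min); dividing by the decayed dose decay-corrects the
image to injection time (`t_half` = 109.77 min for fluorine-18, 67.71 min
for gallium-68). A `decay_to` switch handles scanner-precorrected input.

**Rigid co-registration.** 6-DOF Euler transform maximising normalised
mutual information over a multi-resolution pyramid, with deterministic
global seeding and trilinear resampling (`register_rigid()`,
`resample()`).

**BTV segmentation.** Brain voxels above an initial SUV threshold seed
the tumour component; the contralateral mirror of that component (eroded,
avid voxels removed) is the control VOI; the final BTV is the
connected superlevel set of SUV / control-mean at the tumour-to-brain
ratio (TBR) threshold. Study thresholds: SUV 2.2 / TBR 1.7 (FET), SUV
1.5 / TBR 4.0 (PSMA-617).

**Metrics.** Region volume and SUV/TBR mean/max, Dice coefficient
`2|A∩B|/(|A|+|B|)`, volumetric ratios, tumour-to-liver and
tumour-to-salivary-gland ratios with the therapy-qualification screen
(TLR_max ≥ 1.5 and TSG_max ≥ 1.0), and voxel-wise Pearson correlation
between the two tracers' SUVs inside the BTV overlap.

**Cohort statistics.** An exact Wilcoxon matched-pairs signed-rank test
(dynamic-programming null over the realised rank multiset, midranks for
ties, two-sided `p = min(1, 2 P(W ≤ w))`), Pearson inference, and
descriptives.

The package ships the per-patient summary tables of a ten-patient
dual-tracer cohort (`study_tables()`), so the cohort analysis reproduces
at the desk, plus a phantom generator (`generate_phantom()`) that
emulates the acquisition (doses, timings, uptake levels, inter-session
misalignment, cross-tracer correlation) with known ground truth.

## Worked example

```r
library(petbtv)

# Cohort level: compare TBR_mean between the tracers across 10 patients
tabs <- study_tables()
wilcoxon_exact(tabs$psma_btv$tbr_mean, tabs$fet_btv$tbr_mean)
#> Wilcoxon signed-rank (exact): W = 0, n = 10, p = 0.00195312

sprintf("PSMA TBR_mean: %.1f +/- %.1f; FET TBR_mean: %.1f +/- %.1f",
        mean(tabs$psma_btv$tbr_mean), sd(tabs$psma_btv$tbr_mean),
        mean(tabs$fet_btv$tbr_mean), sd(tabs$fet_btv$tbr_mean))
#> "PSMA TBR_mean: 21.3 +/- 8.4; FET TBR_mean: 2.3 +/- 0.4"
```

Every PSMA-ligand TBR exceeds its FET counterpart, so the exact two-sided
p is the all-same-sign value 2/1024 ≈ 0.002: the PSMA ligand's tumour
uptake stands out against normal brain an order of magnitude more
strongly than the amino-acid tracer's.

```r
# Image level, on a synthetic phantom with known truth
b <- generate_phantom(phantom_spec(rng_seed = 1))
suv <- activity_to_suv(b$activity_a, b$acq_a)     # Bq/mL -> SUV
masked <- apply_brain_mask(suv, b$brain_mask)
seg <- segment_btv(masked, b$brain_mask, default_segmentation_config("fet"))
st <- region_stats(masked, seg$btv, seg$background_suv_mean)
sprintf("BTV: %d voxels, %.0f mm^3, SUV_mean %.2f, TBR_mean %.2f, Dice vs truth %.3f",
        st$n_voxels, st$volume_mm3, st$suv_mean, st$tbr_mean,
        dice(seg$btv, b$tumour_mask))
#> "BTV: 616 voxels, 9625 mm^3, SUV_mean 3.00, TBR_mean 2.34, Dice vs truth 0.999"
```

The segmented BTV recovers the phantom's ellipsoidal tumour almost
exactly (Dice 0.999) and its TBR_mean lands on the generator's target
of 2.3.

## Analysis workflow

Numbered drivers under `analysis/` run the study end to end and write
their tables to `results/`:

1. `01_reproduce_cohort_tables.R` — desk reproduction of the published
   cohort summaries from the packaged tables, with a pass/fail comparison
   at printed precision.
2. `02_simulate_phantom_cohort.R` — simulates a ten-patient phantom
   cohort (NIfTI bundles under `scratch/`).
3. `03_phantom_pipeline.R` — full per-patient pipeline (SUV, registration,
   segmentation, metrics) plus cohort statistics over the simulated
   cohort.
4. `04_method_validation.R` — registration recovery, segmentation
   recovery, copula calibration and exact-test type-I error against
   ground truth.

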