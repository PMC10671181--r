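---
title: "Quantifying paired-tracer brain PET: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying paired-tracer brain PET: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petbtv)
```

## The problem

Recurrent glioblastoma is imaged here with two PET tracers that probe
complementary biology: an amino-acid tracer (O-(2-[18F]-fluoroethyl)-L-tyrosine,
"FET"), which maps tumour metabolic activity, and a gallium-68-labelled
PSMA ligand (PSMA-617), which maps prostate-specific membrane antigen
expressed on tumour neovasculature. Comparing the two per patient asks
three questions: do the tracers delineate the same biological tumour
volume (selectivity); how strongly does each tracer's tumour uptake stand
out against normal brain (specificity, the tumour-to-brain ratio); and is
tumour uptake of the PSMA ligand high enough relative to dose-limiting
organs (liver, salivary glands) to qualify the ligand for radionuclide
therapy (theranostics screening)?

`petbtv` implements the full quantitative chain for such paired-tracer
studies: SUV conversion with decay correction, rigid co-registration,
threshold-based biological-tumour-volume (BTV) segmentation with a
mirrored contralateral control region, per-patient metrics (volumes,
SUV/TBR statistics, Dice overlap, volumetric ratios, tumour-to-organ
ratios, masked voxel-wise correlation) and exact nonparametric cohort
statistics. Because clinical images of this kind are not publicly
shareable, the package also contains a synthetic phantom generator with
known ground truth, and ships the per-patient summary tables of a
ten-patient dual-tracer cohort so the cohort-level analysis is fully
reproducible at the desk.

## SUV conversion

Activity concentration $A$ (Bq/mL) becomes a standardised uptake value

$$\mathrm{SUV} = \frac{A \cdot W}{D \cdot e^{-\lambda \Delta t}},
\qquad \lambda = \ln 2 / t_{1/2},$$

with $W$ the body weight in grams, $D$ the injected dose in Bq and
$\Delta t$ the injection-to-scan interval in minutes. Dividing by the
decayed dose is equivalent to decay-correcting the image activity back to
the injection time. Under the usual 1 g/mL body-density assumption SUV is
unitless. Half-lives: 109.77 min (fluorine-18), 67.71 min (gallium-68).

Two conventions are exposed deliberately. The typeset exponent in source
formulas of this kind is easy to misread, so `activity_to_suv()` has a
`decay_to` switch: `"injection"` (default, as above), `"inverse"` (the
opposite sign, for sensitivity checks) and `"none"`. The latter matters in
practice: many scanners decay-correct reconstructed series to scan start
themselves, and applying the correction twice silently inflates SUV; with
`decay_to = "none"` the package accepts pre-corrected input. Whether the
clinical series behind the packaged tables were scanner-corrected is not
recorded; the phantom encodes activity so that the default convention
recovers the intended scene exactly, making the round-trip testable.

$\Delta t$ is always computed from the sidecar timestamps, never from the
nominal 20/45-minute protocol; the nominal values are only phantom
defaults.

## Rigid registration

The second tracer's acquisition is mapped onto the first tracer's grid by
a 6-degree-of-freedom Euler rigid transform estimated by maximising
normalised mutual information (the entropy ratio
$(H_a + H_b)/H_{ab}$ over a 32-bin joint histogram), with trilinear
resampling. Numerical choices that proved load-bearing:

* **Normalised rather than plain mutual information.** Plain binned MI
  rewards transforms that push constant background out of the overlap
  region (dropping perfectly matched background pairs raises the
  remaining entropy); on phantoms this manifests as a spurious preference
  for epsilon offsets over exact alignment. The entropy-ratio form is
  insensitive to overlap size.
* **1-2-1 pre-smoothing of both volumes at every pyramid level.** An
  acquired (interpolation-smoothed) image compared against a crisp
  reference biases histogram metrics by a fraction of a voxel; smoothing
  both symmetrises the comparison.
* **Deterministic global search.** Block-mean pyramid (never below 16
  voxels per axis); whole-voxel translation scan at the coarsest level;
  at the finest level two rounds of alternating rotation scans
  (±10° in 5° steps, then refined) and translation re-scans with
  Nelder-Mead descent between them; cyclic Brent line searches as the
  final polish. Rotation and translation compensate each other on
  near-symmetric scenes, so neither scan alone suffices. No random
  sampling is used anywhere, so results are bit-reproducible.
* **Optional sampling mask.** High-contrast object edges dominate an
  unmasked metric; restricting sampling to (say) an eroded brain mask
  removes the residual edge bias when the interior carries texture.

On phantom scenes, same-modality recovery of random perturbations up to
10°/10 mm is accurate to under 0.5° and 0.1 mm (see
`analysis/04_method_validation.R`). Cross-tracer registration of the
default phantom recovers translation to well under half a voxel; rotation
is identified only to about a degree, because a sphere-plus-small-ellipsoid
scene carries almost no rotational information about the sphere centre —
a property of the simplified phantom geometry, not of clinical brain
images, which are rich in asymmetric structure. The phantom's brain is a
sphere and its tumour an axis-aligned ellipsoid by design: acceptance of
the downstream metrics never depends on anatomical realism.

## BTV segmentation

The delineation is a concretised five-step version of the semiautomated
threshold method used in such studies, with both printed thresholds
playing the roles their names imply:

1. candidate avid voxels: brain voxels with SUV at or above the initial
   SUV threshold (2.2 for the amino-acid tracer, 1.5 for the PSMA
   ligand);
2. tumour seed component: the 26-connected candidate component containing
   the seed point if one is given, else the largest component (ties by
   voxel count, then SUV maximum, then lowest linear index — fully
   deterministic);
3. control VOI: the seed component mirrored across the mid-sagittal
   plane, eroded by 2 mm, minus any avid voxels — normal contralateral
   brain; a manual control mask overrides;
4. background = mean SUV over the control VOI;
5. BTV: brain voxels with SUV/background at or above the TBR threshold
   (1.7 / 4.0), restricted to components touching the seed component,
   holes filled, components under 10 voxels discarded.

How the original method couples the two thresholds (iterative versus
single-pass) is not determinable from the published description; the
single-pass coupling above is this package's documented choice, and every
step is configuration-exposed (`segmentation_config()`). An image with no
voxel above the initial threshold yields a structured "no avid lesion"
result rather than an error, mirroring enrolment criteria that require
tracer-avid disease.

The mid-sagittal plane is taken as the central grid plane orthogonal to
the left-right axis. Phantoms are constructed symmetric about it;
clinical use would require prior AC-PC/mid-sagittal alignment, a
documented limitation.

One transcription-level caveat: the packaged per-patient TBR values are
not the tabulated SUV_mean divided by the tabulated control-VOI SUV_mean
(e.g. patient 1: 1.61/0.04 is 40, not the printed 17.70), implying the
original TBR background differed from the tabulated control statistic.
The tables are therefore treated as independent printed columns, not as
derivable quantities.

## Metrics and statistics

Region statistics are raw voxel means/maxima (no peak-SUV smoothing);
volume is voxel count times voxel volume. TBR statistics are exactly the
SUV statistics divided by the control background. Dice is
$2|A \cap B| / (|A| + |B|)$. Voxel-wise correlation pairs voxels by grid
index inside the overlap mask (no sub-voxel matching) and reports Pearson
r with the $t$-transform p-value.

The cohort test is an exact Wilcoxon matched-pairs signed-rank test:
zero differences dropped (the convention of the original analysis
software; a Pratt switch is provided), midranks for ties, statistic
$W = \min(W_+, W_-)$, and for $n \le 25$ the exact two-sided
$p = \min(1,\, 2P(W_{\mathrm{null}} \le W))$ computed by dynamic
programming over the realised (possibly tied) rank multiset — equivalent
to enumerating all $2^n$ sign assignments, which the test suite does
independently. Above $n = 25$ a continuity-corrected normal approximation
is used and flagged. The doubled-tail convention is stated because
conventions differ between packages. With all $n$ differences of one sign
this gives $2/2^n$: 0.00195 for $n = 10$, 0.00391 for $n = 9$ — the
structure behind the cohort's TBR and volume comparisons. No
multiple-testing correction is applied, matching the original analysis.

## The phantom generator

`phantom_spec()` defaults define the emulated study conditions:

| parameter | default (tracer A, tracer B) | rationale |
|---|---|---|
| injected dose | 250, 150 MBq | study protocol doses |
| uptake interval | 20, 45 min | study protocol timings |
| half-life | 109.77, 67.71 min | fluorine-18, gallium-68 |
| background mean (SUV) | 1.3, 0.10 | scale of the cohort's control-VOI means |
| background SD | 10% of mean | plausible normal-tissue heterogeneity |
| tumour TBR target | 2.3, 21 | the cohort's mean TBR_mean per tracer |
| cross-tracer rho | 0.51 | the cohort's median voxel-wise r |
| misalignment | ~2°, ~3 mm | plausible inter-session repositioning |
| noise SD | 0 | additive noise is opt-in per experiment |

Tumour voxel values are drawn from a bivariate Gaussian with marginal
means `background_mean * tumour_tbr_target`, marginal SDs
`background_sd * tumour_tbr_target` (uptake heterogeneity scales with
uptake) and correlation `cross_tracer_rho`; with rho = 1 the two tracers
are exactly affinely related. The scene is converted to activity units by
inverting the SUV formula, so the package's own conversion must recover
it — a 1e-6 round-trip property in the tests. The tracer-B grid is the
reference scene observed through the rigid misalignment; tracer A defines
the reference frame, mirroring pipelines that register everything to the
first tracer's acquisition.

What the phantom does *not* emulate — and hence what passing tests do not
establish about clinical data: scanner point-spread and partial-volume
effects, attenuation/scatter, Poisson count statistics (noise is additive
Gaussian on the SUV scale), anatomy (the brain is a sphere, the tumour an
ellipsoid), and spatially smooth biological texture (backgrounds are
voxel-wise independent draws; the registration validation smooths the
scene precisely because real uptake varies smoothly at the voxel scale).

## Problem sizes and reproducibility

The test suite and validation scripts run phantoms at 40–72 voxels per
axis with 2–3.5 mm spacing — volumes of roughly 14–16 cm across, chosen
so the full property suite (segmentation recovery over 20 seeds,
registration recovery over 10 perturbations, copula calibration over 20
seeds, 2000 null cohorts for the exact test's type-I error) completes in
a few minutes on a single CPU. All randomness is seeded: phantoms carry
their seed in the spec and manifest, registration contains no random
sampling, and identical configurations reproduce outputs bit-identically.

## Known limitations

* Rotation recovery in cross-tracer registration is limited by phantom
  geometry (about 1°), as discussed above.
* Two published cohort summaries cannot be reproduced from the printed
  per-patient tables (the PSMA SUV_max cohort mean, printed 7.04 versus
  column mean 7.14; and the BTV volume comparison p-value, printed 0.063
  versus 0.084 from the printed volumes). Both were evidently computed
  from unrounded per-patient values. `reproduce_paper_cohort()` reports
  them with `expect_match = FALSE` rather than forcing agreement.
* Tumour-to-liver ratios require a liver mask from a full-body
  acquisition; the package ingests such masks but cannot validate the
  published TLR values (liver SUVs were not printed).
* The control VOI is constructed by mirroring; strongly midline-crossing
  tumours will produce an empty automatic control region and require a
  manual control mask (the package then demands one explicitly).
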