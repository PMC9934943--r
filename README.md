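# lungqct

Quantitative CT of the ARDS lung, and how precise its measurements are.

In acute respiratory distress syndrome (ARDS), CT is the reference method
for quantifying lung aeration and **alveolar recruitment** — the re-aeration
of non-aerated lung produced by raising PEEP from 5 to 15 cmH₂O. Every one
of these measurements depends on a lung segmentation drawn by a human (or a
machine-learning model), and recruitment is especially fragile because it is
a *difference* between two scans, each with its own segmentation error.
`lungqct` is for researchers who need to (a) compute the standard
quantitative-CT parameters from volumes and masks, (b) quantify how much two
segmentations disagree, and (c) estimate the smallest real difference (SRD)
a measurement pipeline can resolve — plus a synthetic phantom generator so
all of it can be exercised and validated without patient data.

## What it computes

**Aeration quantification** (per CT volume + lung mask):
gas fraction `clamp(HU, −1000, 0)/(−1000)`, tissue fraction `1 − gas`,
tissue weight at 1 g/mL; the four aeration compartments — non-aerated
(+100 to −100 HU), poorly (−101 to −500), normally (−501 to −900) and
hyper-aerated (≤ −901 HU); total and per-compartment weights; EELV;
recruitment PEEP₅₋₁₅, tidal recruitment (% lung weight) and tidal
hyperinflation (mL·kg⁻¹ PBW).

**Segmentation agreement**:
DSC = 2|X∩Y|/(|X|+|Y|); ASSD and MSSD in mm between surface voxel sets
under the 26-neighborhood surface definition, computed exactly via a
separable Euclidean distance transform (with a brute-force all-pairs oracle
for verification).

**Precision statistics** (per parameter, from paired per-patient
measurements): Bland–Altman bias with t-based 95% CI and limits of
agreement; the within-/between-observer SD from duplicates,
S = √(Σdᵢ²/2n); the repeatability / reproducibility coefficient
RC = S·√2·1.96 with BCa bootstrap confidence intervals (patients as the
resampling unit); and sample-size planning
n = z²₁₋α/₂ / (2·precision²·(m−1)).

**Synthetic phantoms**: two-ellipsoid lungs with a gravitational aeration
gradient, programmed recruitment (exact by construction on noiseless
phantoms), per-compartment HU sampling, and an observer model that jitters
mask boundaries by a calibrated, spatially coherent random displacement.

## Worked example

```r
library(lungqct)

# a phantom patient with 10% programmed recruitment, noise-free
spec <- phantomSpec(recruitmentTruth = 10, huMode = "fixed", huNoiseSd = 0)
p5  <- generatePhantom(spec, "EXP_PEEP5")
p15 <- generatePhantom(spec, "EXP_PEEP15")
prof5  <- aerationProfile(p5$volume, p5$mask)
prof15 <- aerationProfile(p15$volume, p15$mask)

prof5
#> AerationProfile 'P01' [EXP_PEEP5]
#>   lung weight 11.2 g, gas volume 4.6 mL, tissue volume 11.2 mL
#>   weight %: non-aerated 63.6, poorly 24.7, normal 11.4, hyper 0.2

recruitmentPeep(prof5, prof15)
#> [1] 9.998868
```

The phantom's lung weighs 11.2 g (it is a desk-scale model, ~15,000 voxels),
with 63.6% of that weight non-aerated at PEEP 5 — the severity profile of a
heavily consolidated lung. The programmed 10% recruitment is recovered to
0.001% through the full quantification path; the residual is voxel-count
rounding.

```r
# a second observer's reading of the same scan, 1 mm boundary jitter
obs2 <- perturbMask(p5$mask, observerModel(1.0, 0, 8, "OBS2"), seed = 3)
agreementMetrics(p5$mask, obs2, comparison = "inter_human_human")
#>          comparison       dsc assd_mm  mssd_mm
#> 1 inter_human_human 0.8220935 1.04361 5.744563

# how many patients to estimate S_W to 40% precision with duplicates?
planSampleSize(0.40, 0.05, 2)
#> [1] 12
```

The jittered "observer 2" lands at an average surface distance of 1.04 mm —
close to its 1.0 mm setting — with a worst-case boundary error of 5.7 mm.
(DSC is lower than on clinical lungs because the phantom is small; overlap
indices scale with object size.)

From there, `generateStudy()` / `simulateMeasurements()` build whole
cohorts, `quantifyCohort()` and `compareMasks()` run manifest-driven over
NIfTI files on disk, and `precisionTables()` produces the bias / RC / RDC
table per parameter and comparison. A command-line wrapper over these
functions is installed at `inst/scripts/lungqct.R`.

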