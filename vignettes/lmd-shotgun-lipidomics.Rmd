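---
title: "Quantitative shotgun lipidomics for laser-microdissected tissue spots: models and methods"
author: "spotlipids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative shotgun lipidomics for laser-microdissected tissue spots: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotlipids)
```

## The problem

Laser microdissection (LMD) excises marked regions of interest (ROIs) from
thin tissue cryosections — spots of 5,000 to 160,000 µm² from 10 µm
sections, i.e. roughly ten to a few hundred cells — which are extracted in
situ together with a set of spiked internal standards and infused directly
into a high-resolution mass spectrometer with polarity switching. The
computational half of that platform, which this package implements, turns
the resulting centroided peak lists into identified, corrected,
internal-standard-quantified lipidomes and ROI-level spatial heterogeneity
analyses. A synthetic-spectrum generator stands in for the instrument so
that every stage — identification, isotopic and adduct corrections,
quantification, QC and clustering — is testable against known ground truth
without any instrument data.

## Chemistry core

Lipids are annotated at *sum-composition* level: class plus total chain
carbons and double bonds, e.g. `PC(38:6)`, with a third hydroxyl index for
sphingolipids, e.g. `SM(36:1:2)`. Each of the 23 supported classes carries
a backbone elemental contribution; a species' composition is

    backbone + C·(CH2) − DB·(H2) + OH·O

so that, for example, `PC(34:2)` resolves to C42H80NO8P. Backbones are
derived from standard condensation chemistry (glycerophosphate + head
group + acyls − waters) and validated in the test-suite against literature
molecular formulas for every class. Isomeric pairs that MS1 cannot
distinguish are stored once and quantified collectively: PC-O(x:y) with
PC-P(x:y−1), PE-P(x:y) with PE-O(x:y+1), and PG with BMP (class
`"PG/BMP"`).

Ion m/z values follow the contract

    m/z = (M + Δm(adduct) − z·m_e) / |z|

with atomic masses embedded as constants from a standard monoisotopic
table, so the arithmetic is bit-stable and independently checkable; the
tests re-derive 50 random species × adduct combinations with a separately
written summation oracle. Chloride adducts use ³⁵Cl for the monoisotopic
peak, per the definition of "monoisotopic"; the ³⁷Cl isotopologue is
carried in the envelope.

Isotope envelopes model ¹³C always (binomial in the carbon count,
abundance 0.0107) and ³⁷Cl when chlorine is present (abundance 0.24229),
with exact isotope mass differences, truncated by default at three nominal
peaks. ³⁴S, ¹⁵N, ¹⁸O and ²H are neglected: for lipid-sized molecules their
combined contribution is below one percent of the envelope and far below
the corrections the pipeline makes. The same truncation is used by the
generator and by the corrections, so the noiseless pipeline closes exactly.

Class-to-polarity routing follows the acquisition design:
glycerophospholipids, their lyso forms and most sphingolipids are
quantified in negative mode ([M−H]⁻, or [M+Cl]⁻ for the choline-bearing
PC/PC-O/LPC which carry no acidic proton; [M−2H]²⁻ for cardiolipin); SM
and the neutral lipids DG/TG/CE in positive mode ([M+H]⁺ / [M+NH4]⁺). PC
is additionally observed in positive mode as [M+H]⁺ and [M+Na]⁺. The
registry, including the quantification adduct of every class and the
internal standard species and amounts, is an editable YAML configuration
(`inst/extdata/lipid_classes.yaml`, `standards.yaml`); the cardiolipin
[M−2H]²⁻ choice and the 10 pmol-per-class default standard amounts are
declared configuration, not measured values.

## Resolution model and centroid merging

The resolving power is modeled Orbitrap-style as R(m) = R₂₀₀·√(200/m) with
R₂₀₀ = 240,000, giving a full width at half maximum FWHM = m/R(m). Two
centroids closer than FWHM/1.18 (the separation below which two Gaussian
peaks of comparable height collapse into a single maximum; implemented as
0.85 × FWHM) are treated as one peak *everywhere*: the generator merges
them into an intensity-weighted centroid, and the corrections use the
identical criterion to decide which predicted interferences need
subtracting. This single rule makes the platform's characteristic
interferences emerge physically rather than by construction:

* the sodiated ion of PC(x:y) and the protonated ion of PC(x+2:y+3) are
  0.0024 m/z units apart — unresolved at any practical resolving power;
* the two-¹³C cluster of a C:DB+1 homolog sits ~0.009/|z| below the
  monoisotopic peak of C:DB — resolved for singly charged lipids over most
  of the mass range at R₂₀₀ = 240,000, but unresolved for doubly charged
  cardiolipins throughout it;
* occasional cross-class coincidences (an A+1 peak of a sphingomyelin next
  to an ammoniated triacylglycerol; ³⁷Cl satellites of chloride adducts on
  doubly-charged candidate positions).

## Identification

Candidate indexes enumerate every admissible (species, adduct) ion on the
per-class sum-composition grids within the m/z 400–1300 window, per
polarity. Matching assigns each candidate to its nearest peak within an
inclusive, symmetric 2 ppm tolerance; a peak claimable by several
candidates goes to the lowest-|ppm| one, which is flagged ambiguous, and
the displaced candidates are recorded in the `contested` attribute rather
than given rows — a row always carries an actually assigned intensity, and
ambiguous assignments are the ones a cautious analyst would not quantify.
Only monoisotopic candidates are indexed — there is no deisotoping at
match time. An isotopologue peak of one species that lands on another
candidate's position is therefore *annotated* and then collapsed to zero
by the isotopic correction; the identification suite asserts both halves
of that contract. Matching is per-sample: direct infusion has no retention
dimension to align across samples.

A centroid fused with a dominating interference is dragged away from the
candidate position; once the displacement exceeds the tolerance the
species is genuinely unidentifiable from centroided MS1 data. The tests
formalize "detectable" through a forward-model oracle: a quantification
ion counts as detectable when its cluster of unresolvable predicted peaks
lies inside the acquisition window, sums above the noise floor, and has a
weighted centroid within 2 ppm of the theoretical position. On noiseless
data, identification achieves precision and recall 1.0 against that
oracle.

## Corrections

**Type-I isotopic correction** divides each matched monoisotopic intensity
by the monoisotopic fraction A₀/ΣA of its ion's truncated envelope,
converting it to a total-species intensity comparable across carbon
numbers.

**Type-II isotopic correction** (default on) reconstructs, from the
annotated ions alone, which predicted envelope peaks are unresolved from
which monoisotopic positions — the same clustering rule as the resolution
model — and subtracts the predicted leak in ascending m/z order, so every
contaminator (always lighter than the ion it leaks into) has already been
corrected when its contribution is predicted. This covers the canonical
same-class double-bond-ladder A+2 overlap and the cross-class
coincidences with one mechanism. Subtractions never produce negative
intensities; results are clipped at zero and flagged.

**Sodiated-PC overlap.** At the low ammonium chloride concentration the
platform uses, sodiated PC reaches about 10% of the protonated form, and
[PC(x:y)+Na]⁺ is isobaric with [PC(x+2:y+3)+H]⁺. The sodiation fraction is
estimated per sample as the median of I(Na)/I(H) over *interference-free*
PC species, where the [PC+Cl]⁻ profile from the negative-mode half of the
same run decides freedom: the +2C/+3DB partner must be absent (clean
sodiated position) *and* the −2C/−3DB partner must be absent (clean
protonated peak). The median is robust to residual interference; with no
usable species the estimator falls back to a configured default with a
warning. The correction then walks the protonated PC ladder in ascending
mass, subtracting f̂·I(H, corrected) of the light partner at each
interfered position, so chains of interference unwind from the light end.
Whether to apply the subtraction is switchable (`na_correction`), since
profile comparison and algebraic correction are alternative uses of the
same chloride reference. A full algebraic deconvolution of all adduct
channels would achieve the same end; the cascade reaches the simulated
ground truth within the tolerances the tests assert, which is why the
simpler rule was kept.

**Quantification** is strictly ratiometric: pmol(species) =
I(species)/I(class standard) × pmol(standard), per class, in the class's
quantification adduct; class response factors cancel by design. Classes
whose standard is missing or unmatched are flagged unquantifiable for that
sample without affecting others. Results are expressed as pmol, as mol% of
membrane lipids — the glycerophospho- plus sphingolipid sum, with DG/TG/CE
excluded from the denominator — and, given the spot geometry, as nmol per
mg wet weight.

## The synthetic generator

The generator emulates the platform's study conditions and is itself
first-class, tested code.

* **Geometry.** Spots are area × thickness × density; density is fixed at
  1 g/cm³, which reproduces both printed wet-weight anchors of the
  platform (a 30,000 µm² × 10 µm spot = 0.3 µg; a 7×7 mm section =
  490 µg), so it is treated as the implicit convention. Cell equivalents
  use the typical mammalian cell volume of 4000 µm³.
* **Ground truth.** `make_lipidome()` draws ~200 species on realistic
  per-class C:DB(:OH) grids with log-normal concentrations around class
  means; default class weights follow a mammalian-tissue composition
  dominated by PC and PE, and membrane concentrations are calibrated to
  15 pmol/µg ww (15 nmol/mg, liver-scale). The cell-culture variant
  expresses ground truth per cell (0.07 pmol membrane lipid per cell, so
  a 5000 µm² spot of about ten cells holds under 1 pmol) and converts
  through the cell volume.
* **Signal model.** Each species contributes its admissible adduct ions
  (response factor 1.0 per class — quantification is ratio-to-standard, so
  factors cancel); sodiated PC ions carry fraction `f_na` (default 0.10)
  of the protonated intensity; each ion spreads over its truncated isotope
  envelope; intensities get multiplicative log-normal noise of the stated
  CV (default 5%, mean-one parameterization — intensities are positive and
  the platform reports CV%), applied per ion; m/z values get Gaussian ppm
  jitter (default SD 0.5 ppm); unresolved centroids merge; peaks below the
  noise floor (default 2·10⁻⁴ on the pmol-equivalent intensity scale) are
  dropped and the window 400–1300 enforced. Internal standards are spiked
  at their configured pmol independent of spot size.
* **Degradation channel.** An optional fraction δ of each diacyl
  glycerophospholipid that has a lyso partner class is re-routed, half to
  the lyso species with half the carbons (rounded to the partner grid) and
  half to PA of the same sum composition — the simplest mass-balanced rule
  producing the class-level lyso + PA signature of laser ablation; total
  pmol is conserved by construction.
* **Determinism.** All randomness flows through a seed-local RNG: the same
  seed gives byte-identical peak lists, and simulations never disturb the
  caller's RNG state.

What the generator does *not* emulate — chromatography-free ion
suppression, matrix effects, acquisition-time drift, profile-mode peak
shapes, fragmentation — bounds what passing tests show about real data:
they validate the computational pipeline against a faithful forward model
of the acquisition geometry and its interference structure, not the
chemistry of extraction or ionization.

## QC statistics

Reproducibility is the coefficient of variation CV% = SD/mean × 100 with
the sample SD (n−1); eligibility is CV% ≤ 30, and CV% ≤ 20 counts as
good-to-excellent. Whether CVs are computed on pmol or mol% is the
caller's choice of input matrix; the examples use mol%. Linearity of
quantification is ordinary least squares of amount versus dissected area
over all replicate points, intercept included (R² as commonly reported;
configurable by fitting through the origin upstream if desired), per
species and for the membrane total, with the eligibility criterion
R² > 0.7. A species counts as quantifiable at an area level when it is
above the floor in at least half of the replicates there — the counting
rule is declared, since published counts rarely state one. Group summaries
report class-level mol% mean ± SEM and the lyso + PA sum used to monitor
ablation-induced degradation.

## Spatial analysis

ROI × species mol% matrices are z-scored per species (column-wise, the
per-lipid color scaling of cluster heatmaps; configurable) and clustered
agglomeratively with Euclidean distance and Ward linkage — `ward.D2`, the
Ward criterion on untransformed Euclidean distances. `stats::hclust` is
deterministic for tied merges (lowest original index first), making
results reproducible and row-order invariant up to that tie-break.
Replicate ROIs are clustered individually rather than averaged, so the
dendrogram displays successive-section reproducibility alongside regional
structure. Dendrograms export to Newick; ROI geometry travels as a JSON
sidecar of centroids (and optionally polygons) in µm, and per-species
spatial maps report per-ROI mean ± SD over successive-section replicates.

## Numerical choices and degenerate inputs

* Tolerances: matching is inclusive and symmetric (|ppm| ≤ 2); envelope
  truncation is consistent across generator and corrections; corrected
  intensities clip at zero with a flag rather than propagate negatives.
* Ties: contested peaks resolve by smallest |ppm|, then lower theoretical
  m/z; merge ties in clustering follow `hclust`'s lowest-index rule.
* Degenerate inputs error early with informative messages: zero-area or
  zero-thickness spots, empty compositions, empty registries, fewer than
  two replicates for CV, fewer than three area levels for linearity,
  all-zero-variance matrices for clustering, zero membrane totals for
  normalization.
* Problem sizes in the tests and the acceptance script — ~200-species
  lipidomes, 24-spot area series, 20-seed medians, 11-ROI region designs
  with 3 successive sections — mirror the platform's own experiment sizes.

## Known limitations

* Sum-composition annotation only; no fragmentation-based isomer
  resolution, so PC-O/PC-P, PE-P/PE-O and PG/BMP stay merged.
* The ³⁷Cl-satellite and A+1 cross-class coincidences are corrected by
  prediction; a species whose quantification ion is *dominated* by such an
  interference loses its centroid and is reported absent rather than
  guessed.
* Neutral lipids (DG/TG/CE) are quantified only where their ammoniated
  ions are simulated or detected; no cross-class response-factor
  calibration is attempted.
* The estimator pool for sodiation needs at least one two-sided
  interference-free PC species; profiles saturated with ladder
  interference fall back to the configured default.

## A worked sketch

```{r example, eval = FALSE}
library(spotlipids)

profile <- make_lipidome(seed = 42)           # ~200-species ground truth
spot    <- spot_spec(area = 30000)            # 0.3 ug wet weight
sim     <- simulate_spot(profile, spot, acq = acquisition_spec(seed = 1))

q <- quantify_spot(sim$negative, sim$positive, spot)
q                                # pmol and mol% per species
attr(q, "f_na")                  # estimated sodiation fraction (~0.10)
attr(q, "membrane_nmol_per_mg")  # membrane density in nmol/mg ww
```
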