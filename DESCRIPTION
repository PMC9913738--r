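Package: spotlipids
Title: Quantitative Shotgun Lipidomics for Laser-Microdissected Tissue Spots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing pipeline for laser-microdissection (LMD)-coupled
    quantitative shotgun lipidomics. Takes high-resolution centroided peak
    lists acquired in polarity-switching direct infusion from micro-dissected
    tissue spots and turns them into identified, isotope- and sodium-adduct-
    corrected, internal-standard-quantified lipidomes, expressed as pmol and
    as mol% of membrane lipids. Includes a sum-composition lipid grammar with
    elemental compositions, adduct m/z and fine isotope envelopes; ppm-based
    peak annotation; type-I/II isotopic correction; a chloride-profile-guided
    estimator and cascade correction for the sodiated-phosphatidylcholine
    isobaric overlap; reproducibility (CV%) and linearity-of-quantification
    QC; hierarchical clustering of ROI lipidome matrices for spatial
    heterogeneity analysis; and a synthetic-spectrum generator that emulates
    LMD spot geometries, spiked internal standards, isotope envelopes, adduct
    formation and instrument noise so every stage is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
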