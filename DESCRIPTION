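Package: lipidmrm
Title: Targeted Lipidomics MRM Panels, Triacylglycerol Composition
    Resolution and Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for targeted lipidomics by scheduled multiple reaction
    monitoring (MRM). Builds precursor/product ion transitions for glycerolipid
    and glycerophospholipid classes from shorthand species names using
    monoisotopic formula arithmetic and class-specific adduct and fragmentation
    rules; enumerates candidate fatty-acid compositions of isobaric
    triacylglycerol (TG) sum compositions and resolves the acyl-chain
    composition of co-eluting TG species by overlaying acyl-loss extracted ion
    chromatograms, with multiplicity-corrected quantifier selection;
    quantifies molecular species against per-class internal standards to
    nmol per mg tissue with class totals and fatty-acid mol%; and computes
    LC-MS method-validation statistics (calibration linearity, LOD/LOQ,
    recovery efficiency, matrix effect). Includes a synthetic XIC generator
    emulating reverse-phase elution of neutral lipids so the whole pipeline is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
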