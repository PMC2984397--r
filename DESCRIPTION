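Package: pseudospec
Title: Correlation-Based Deconvolution of GC/MS and LC/MS Metabolomics Peaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Organizes integrated GC/MS and LC/MS(n) ion peaks from a
    multi-sample metabolomics study into per-metabolite pseudo-spectra.
    Ions are binned across samples by mass and retention index, bins whose
    singlet areas co-vary across samples are grouped by Pearson correlation
    around a normalizer bin, groups are annotated with adduct/multimer
    chemical intelligence to infer monomer masses, MS2 sub-spectra are
    assembled, and spectral-library entries (JSON and MSP) are created and
    matched for known and unknown metabolites. Includes a synthetic peak
    table generator with ground truth for validating every stage, and a
    command-line interface for reproducible pipeline runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
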