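Package: dsmkit
Title: Double-Site Saturation Mutagenesis Library Design and Biosensor
    Characterization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for engineering chemically induced dimerization biosensors
    on protein scaffolds such as the plant abscisic-acid receptor PYR1.
    Covers structure-guided double-site saturation-mutagenesis library design
    (binding-pocket contact analysis, per-position allele sets, exact
    enumeration of single and double variants, proximal/distal partitioning
    for nicking mutagenesis), mutagenic oligo pool generation with
    nearest-neighbor melting-temperature homology arms and an in-silico
    application oracle, amplicon-sequencing library completeness QC,
    quantitative sensor characterization (four-parameter logistic
    dose-response fitting with confidence intervals, immunoassay limits of
    detection by the blank plus three standard deviations rule,
    cross-reactivity/selectivity matrices), ligand-panel Tanimoto similarity
    clustering, and seeded synthetic-data generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ChemmineR,
    ape,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    ChemmineOB,
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
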