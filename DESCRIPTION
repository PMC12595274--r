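Package: msiscreen
Title: Microsatellite Instability Screening from Urine Cell-Free DNA
    Allele Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for amplicon-based microsatellite instability (MSI)
    analysis of urine and tissue cell-free DNA. Implements a per-marker
    naive Bayesian classifier that combines variant-allele-frequency
    evidence across a 14-marker mononucleotide-repeat panel into a single
    MSI score with MSI-high / microsatellite-stable calls and a borderline
    zone with a repeat-testing policy; background-normalised allele
    spectra and cross-sample variant-allele-frequency concordance for
    tumour source attribution; exact Clopper-Pearson binomial diagnostic
    accuracy statistics, ROC/AUC, and binomial study-design probabilities;
    and a synthetic-data generator that emulates stutter-noise allele
    spectra across tumour fractions so the whole pipeline can be exercised
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    ggplot2,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
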