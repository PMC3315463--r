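Package: splicescreen
Title: Quantitative Analysis of Genome-Wide QPCR Splicing Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for high-throughput reverse-genetic QPCR
    screens of pre-mRNA splicing in budding yeast. Converts crossing-point
    (Cp) values to relative quantities through log-linear standard curves,
    applies replicate coefficient-of-variation and low-yield quality
    filters, normalizes each sample by a composite constant built from six
    reference RNAs against per-plate per-primer medians, calls strains
    with significantly altered precursor levels by one-class Significance
    Analysis of Microarrays (sign-flip permutation null, fudge factor,
    delta thresholding, permutation FDR), derives composite rank orders
    across precursor species, computes splicing-efficiency indices, and
    tests gene-set enrichment among top candidates with an exact
    log-space hypergeometric tail. A synthetic-screen generator with
    per-sample yield variation, per-plate batch effects, technical noise
    and spiked splicing-defective strains makes every stage testable at
    desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, grDevices, graphics, yaml
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
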