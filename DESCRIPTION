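Package: clonetrace
Title: Clonal Tracking of DNA-Barcoded Tumour Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis of cellular DNA barcoding experiments that track clonal
    dynamics in spontaneous and experimental metastasis assays. Provides
    amplicon barcode counting from FASTQ reads against a reference barcode
    library, a replicate-aware filtering, pooling and normalisation pipeline
    (read floor, replicate concordance, tumour-piece pooling, virtual-barcode
    collapsing), clonal diversity and dominance statistics (richness, Shannon
    diversity, top-fraction dominant sets, biomass capture), inter-site Pearson
    correlation with hierarchical clustering, a simulation-based neutral
    expectation for the number of tumours in which each clone appears, and a
    synthetic-experiment generator with retained ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
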