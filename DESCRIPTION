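Package: clonetrace
Title: Clonal Tracking of Nucleate and Anucleate Blood Lineages from
    Expressed RNA Barcodes
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for lentiviral RNA cellular-barcoding
    experiments that track hematopoietic clones across platelet, erythroid,
    myeloid and B-cell lineages. Covers simulation of barcode libraries,
    calibration mixtures, amplicon reads, clonal time courses and barcoded
    single cells; anchored mismatch-tolerant barcode extraction from reads;
    per-1000 normalization, dominant-set selection, chimerism correction and
    replicate concordance; Shannon diversity and effective clone counts;
    threshold-based clone lineage-output classification with detection of
    repurposed and newly activated clones across a perturbation; and
    single-cell QC, per-cell barcode assignment and pseudo-bulk aggregation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
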