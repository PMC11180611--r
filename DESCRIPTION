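Package: fragqc
Title: Quality Control, Multiplet Merging and Saturation Economics for
    Single-Cell ATAC-Seq Fragment Files
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for preprocessing and quality control of single-cell
    ATAC-seq "fragments" files: reading and writing the bed-like
    fragments.tsv.gz format, whitelist-based cell barcode error correction
    at Hamming distance one, detection and merging of bead barcode
    multiplets by fragment-coordinate Jaccard similarity with Otsu
    thresholding, per-barcode quality metrics (unique fragments,
    duplication rate, TSS enrichment, fraction of fragments in peaks,
    fragment-length statistics), Otsu-based cell calling, seeded read
    downsampling, sequencing-saturation modelling with Michaelis-Menten
    and Langmuir fits, a per-cell sequencing cost model, and a read-loss
    waterfall decomposition. Includes a fragment-level simulator with
    planted cells, ambient barcodes, bead multiplets and PCR duplication
    so every stage can be validated against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    GenomicRanges,
    IRanges,
    S4Vectors,
    minpack.lm,
    igraph,
    withr,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
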