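Package: ribocodon
Title: Codon-Level Analysis of Ribosome Profiling and tRNA Editing in Stem Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying synonymous codon usage and its readout at the
    ribosome in self-renewing versus differentiating embryonic stem cells.
    Computes per-gene codon frequency vectors and positional GC content from
    coding sequences; codon, amino-acid and stability-class enrichment of
    differentially expressed gene sets; correlation-matrix PCA of GO-term codon
    profiles; ribosome E/P/A-site codon occupancy from ribosome footprints with
    per-read-length reading-frame and P-site offset detection, nine-position
    normalization, and replicate-level differential codon-usage testing (Welch
    t-test with Benjamini-Hochberg correction); wobble-inosine (A34I)
    quantification from tRNA-seq mismatch pileups; and classification of
    translation-efficiency changes for hetADAT-dependent nnC-codon-rich genes.
    Includes seeded generators for every input the pipeline consumes, with
    planted ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
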