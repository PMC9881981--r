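Package: hqalign
Title: Hybrid Quantized Alignment of Noisy Long Reads for Structural Variant Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aligns noisy long (nanopore-style) reads to a reference with a two-stage
    hybrid procedure: a nucleotide minimizer seed-chain-extend pass locates regions of
    interest, which are then re-aligned in a small quantized alphabet derived from the
    pore's Q-mer current model, with the quantized reverse complement aligned as a
    separate query so that inversions are recovered as split alignments. Includes the
    associated alignment-quality metrics (well-aligned classification, normalized edit
    distance and alignment length), a minimal structural-variant caller and a
    Truvari-style benchmarking layer (breakpoint score, length similarity, union model),
    plus generators for repeat-containing genomes, planted variants and reads with
    current-level-confusable errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringi,
    ggplot2,
    generics,
    withr,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    jsonlite
Config/testthat/edition: 3
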