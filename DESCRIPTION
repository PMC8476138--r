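Package: karyofuse
Title: Chromosome Fusion Analysis from Synteny, Diversity and Functional-Element Turnover
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects chromosome fusion points from ortholog synteny anchors,
    splits fused chromosomes into their ancestral homolog segments and
    classifies chromosomes as not-fused, long-fused or short-fused. Profiles
    windowed GC, repeat and coding density in fusion-centred normalized
    coordinates, fits standardized major axis (SMA) scaling relationships
    with permutation-based slope and elevation tests, computes nucleotide
    diversity at 4-fold degenerate third codon positions (pi_4D) in windows
    of a fixed number of sites, models the per-base recombination rate change
    implied by a fixed 50 cM map length per chromosome, and quantifies
    evolutionary turnover of cis-regulatory elements and exons via reciprocal
    best hits. Includes a synthetic two-species genome generator with planted
    fusions, diversity gradients and element-retention models so every stage
    is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
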