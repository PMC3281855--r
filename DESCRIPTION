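Package: barcodegap
Title: Barcode-Gap Analysis and Species Identification from DNA Barcodes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for distance-based and character-based species
    identification from short standardized DNA markers (COI barcodes and
    companion markers such as cytb, 16S and 18S). Computes Kimura
    two-parameter (K2P) and p distances with pairwise deletion, partitions
    pairwise divergences by taxonomic comparison class (conspecific,
    congeneric, confamilial, ...), summarises the barcode gap
    (rank summaries, distance banding by family, nearest-neighbour
    distances, threshold filters, Tukey boxplot statistics), builds
    unrooted neighbour-joining trees and tests per-species monophyly,
    screens protein-coding sequences for nuclear mitochondrial pseudogenes
    (numts) via translation under the vertebrate mitochondrial code, and
    finds pure diagnostic alignment columns per species. A sequence
    simulator with rank-structured divergence and transition-biased
    substitution supports end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    seqinr,
    graphics,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
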