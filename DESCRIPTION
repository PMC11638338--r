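Package: cnphylo
Title: Distance-Based Reconstruction of Single-Cell Copy-Number Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs tumor cell lineage trees from binned single-cell
    copy-number profiles using simple per-bin distance functions (Euclidean,
    Manhattan, square-root and log forms, applied either to copy numbers
    directly or to breakpoint profiles) followed by balanced minimum
    evolution or neighbor joining. Includes a coalescent-based simulator of
    copy-number alteration evolution over hg38-scale genomes with segment
    boundary and per-bin jitter noise models, and evaluation metrics for
    reconstructed trees: normalized Robinson-Foulds distance, clone-detection
    F1, breakpoint precision/recall, clade-induced adjusted Rand index and
    sibling dissimilarity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    mclust,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
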