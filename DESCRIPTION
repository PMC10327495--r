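Package: pancontig
Title: Pangenome Graphs of Complete Bacterial Genomes by Progressive
    Alignment
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Aligns sets of complete (optionally circular) bacterial
    genome assemblies into a pangenome graph of homologous sequence
    blocks (pancontigs).  Each block stores a consensus sequence plus
    per-isolate edits; each genome is an ordered, oriented path over
    blocks.  Construction proceeds by progressive pairwise graph
    alignment along a balanced neighbour-joining guide tree built from
    minimizer Jaccard distances, with candidate mergers ranked by a
    pseudo-energy that balances match length against graph fragmentation
    and alignment divergence.  Includes a Wright-Fisher forward simulator
    of structural variation (inversions, deletions, horizontal transfer)
    with ground-truth graphs, graph marginalization onto strain subsets,
    validation metrics (breakpoint displacement, compression, core
    fraction, partition agreement, divergence-corrected shared k-mers),
    and JSON/GFA/TSV/FASTA exporters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Matrix,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: minimap2 (optional external alignment kernel)
Config/testthat/edition: 3
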