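Package: mitocharter
Title: Characterization Toolkit for Multichromosomal Plant Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for multichromosomal plant mitochondrial genomes:
    simulation of multichromosomal genomes with planted, truth-tracked features;
    iterative seed-extension recruitment of organelle long reads from mixed
    pools; codon-usage statistics (codon counts, positional GC, RSCU, Wright's
    effective number of codons, start/stop tallies); prediction and
    classification of C-to-U RNA editing sites; detection of microsatellites,
    tandem repeats and dispersed repeats; detection of homologous fragments
    between mitochondrial, plastid and nuclear genomes with coverage and gene
    containment reports; and per-gene molecular-evolution statistics
    (Nei-Gojobori Ka/Ks and nucleotide diversity).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
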