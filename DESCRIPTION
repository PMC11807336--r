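Package: fhsketch
Title: Fractional Hitting Set Sketching of k-mer Sets and Multisets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Space-efficient sketching of DNA k-mer sets using fractional
    hitting sets: a near-uniform fraction of the k-mer space is sampled by
    selecting k-mers whose minimizer hash falls below a threshold ("small
    minimizers"), and the sampled k-mers are stored exactly as partitioned
    super-k-mers. Sketches support Jaccard, containment and abundance-weighted
    angular similarity estimation with partition-wise comparison. Includes
    closed-form density, coverage, maximal-super-k-mer and encoding-cost
    theory together with a simulation harness (random sequences, genome
    pairs with controlled overlap, error-prone read simulation) that
    confronts measurements with the theory, plus a command-line interface
    for sketching FASTA/FASTQ inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
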