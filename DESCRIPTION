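Package: chromopaint
Title: Oligo-FISH Probe Design and Cross-Genus Evaluability for Chromosome Painting
Version: 0.1.0
Authors@R: person("chromopaint", "developers", role = c("aut", "cre"),
    email = "chromopaint@example.org")
Description: Design pools of chromosome-painting oligonucleotide probes from a
    reference assembly and evaluate whether they remain usable across genus
    borders.  Implements candidate tiling (43-47 nt), nearest-neighbor melting
    temperature prediction with monovalent-salt correction, a seed-and-extend
    local similarity search with Karlin-Altschul E-values, single-hit homeolog
    filtering, greedy non-overlapping probe selection, the D100 moving-window
    probe density index, microsatellite motif annotation and blocking-oligo
    recommendations, read-based tandem-satellite monomer discovery via k-mer
    graph cycles, a synteny-based cross-genus probe validation workflow, and a
    fully seeded synthetic-data generator (diverged homeologs, chromosome
    fusions, satellite and microsatellite spikes, paired-end reads) for testing
    the whole pipeline without real genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    methods,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
SystemRequirements: C++17
Config/testthat/edition: 3
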