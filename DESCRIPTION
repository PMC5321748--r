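Package: longscaff
Title: Real-Time Hybrid Scaffolding of Short-Read Assemblies with Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Completes fragmented short-read bacterial assemblies with long
    (nanopore-style) reads streamed in generation order. Contigs are classified
    by copy number from depth of coverage, unique contigs are bridged by long
    reads spanning their ends, bridges are committed greedily by score with
    conflict repair, gaps are filled with spanning-read sequence and repetitive
    contigs, and circular replicons (plasmids, chromosomes) are detected.
    Per-batch assembly reports (contig count, N50, circular sequences) support
    stopping a sequencing run as soon as the assembly is complete. Includes a
    synthetic-data generator (multi-replicon genomes with interspersed repeats,
    fragmented assemblies with collapsed-repeat depths, noisy long reads) and an
    evaluation harness against the simulated truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: minimap2 (optional, for built-in long-read alignment)
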