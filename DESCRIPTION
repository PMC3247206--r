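Package: txchar
Title: Post-Assembly Transcriptome Characterization with Ground-Truthed Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes de novo transcriptome assemblies the way early
    454-era coral EST projects did: read trimming and SMART-primer screening,
    completeness/redundancy/gene-count estimation from single-copy ortholog
    hit tables, SNP discovery from padded contig alignments with
    transition/transversion selection screens, microsatellite motif-class
    spectra, reciprocal-best-hit in-paralog grouping, informative-annotation
    selection, and the supporting Fisher-exact and likelihood-ratio-test
    statistics. A ground-truthed synthetic transcriptome generator (reads,
    fragmented contigs, planted SNPs and tandem repeats, two-species paralog
    families with consistent score tables) makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    methods,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
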