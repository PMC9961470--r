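Package: ctga
Title: Contig-to-Chromosome Assignment by Homology Placement and
    Multi-Track Evidence Consensus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Organizes a fragmented genome assembly into chromosomes by
    integrating heterogeneous evidence. Provides readers and writers for
    FASTA, AGP v2.1, GFF3 gene annotations, RepeatMasker output and BLAST
    tabular hit tables; assembly statistics (N50, base composition, contig
    length summaries); a self-contained unique k-mer anchor placer that
    assigns contigs to reference chromosomes with orientation and
    confidence; repeat and gene-biotype composition of placed versus
    unplaced contig partitions; best-hit selection and identity-binned
    summaries of proteome searches; majority-vote integration of evidence
    tracks (scaffolding, protein homology, genetic markers, DArT-seq loci,
    BAC/FISH probes) into per-contig consensus chromosome assignments with
    conflict detection; deterministic HTML/CSV/TSV reporting; and a
    seeded synthetic-data generator with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
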