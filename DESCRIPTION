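Package: symbioscan
Title: Symbiont Contig Triage, Host Association, and Selection-Signature
    Scanning for Endosymbiont Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing bacterial endosymbionts recovered from
    community metagenome assemblies. Provides GC- and coverage-based contig
    triage with two-step best-hit classification, kmer-coverage conversion and
    Spearman midrank co-occurrence screening with Benjamini-Hochberg
    correction, sliding-window Ka/Ks (dN/dS) estimation by the Nei-Gojobori
    (1986) counting method with quantile partitioning of gene scores, Gene
    Ontology enrichment over an is_a DAG (classic Fisher and elim
    decorrelation), presence/absence gene-repertoire set algebra over strain
    groups, branch-transition comparison of enriched functions along an
    ordered chain of strains, and synthetic-data generators that emulate the
    statistical structure of each input so every stage is testable without
    sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
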