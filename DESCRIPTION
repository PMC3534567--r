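Package: annotaudit
Title: Audit Prokaryotic Genome Annotations for Missed Protein-Coding Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects protein-coding genes predicted ab initio but absent from
    a prokaryotic genome annotation. Compares Glimmer-style gene predictions
    against GenBank feature tables by strand-aware 3' end matching, filters
    candidate missed genes by BLAST homology evidence (E-value and subject
    coverage), splits survivors into named versus hypothetical missed genes,
    aggregates knowledgebase evidence into support levels, phenotype
    associations and drug-target flags, flags spurious ORFs from profile-HMM
    hits, and produces per-center annotation-quality reports. Ships a
    synthetic-fixture generator that plants ground truth through every rule
    so the whole pipeline is testable without any downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
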