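# annotaudit

Audit prokaryotic genome annotations for missed protein-coding genes.

## The problem

Public bacterial and archaeal genome annotations disagree surprisingly often
with what an ab initio gene finder predicts on the same sequence. Some of the
disagreement is gene-finder noise — but a substantial fraction is genes the
original annotators simply left out, typically short ORFs below the minimum
gene length their pipeline used. `annotaudit` is for genome annotators,
curators and comparative genomicists who want to quantify that gap: it takes
an annotated chromosome, a set of ab initio gene predictions, and
pre-computed homology evidence, and reports which predictions are genuine
*missed genes*, how trustworthy each one is, and where the annotation came
from.

## The method

The pipeline applies a fixed sequence of rules:

1. **Genome screening.** A record is excluded if it is a plasmid, carries no
   annotation, says "draft" or "nearly complete" in its definition line, or
   contains more than 10 distinct runs of ≥ 5 consecutive ambiguous
   nucleotides.
2. **Annotation diff.** A prediction is *present* in the annotation iff its
   strand-aware 3′ end equals that of some non-pseudo annotated CDS (start
   sites disagree constantly between annotators; stop codons rarely).
   Remaining predictions are dropped if they overlap an RNA feature, a gene
   without a CDS, or a pseudo-CDS by more than 50 % of their own length. The
   survivors are **candidate missed genes**.
3. **Homology filter.** A BLAST hit supports a candidate iff
   E ≤ 10⁻⁶ and the alignment covers ≥ 80 % of the subject protein (the
   P-value of an E-value is P = 1 − e⁻ᴱ, so at these E-values P ≈ E).
   Candidates with a passing hit to a non-hypothetical protein are **named
   missed genes**; those whose passing hits are all hypothetical are
   **hypothetical missed genes**.
4. **Evidence aggregation.** Against a knowledgebase of curated genes
   (evidence and phenotype flags) organised into protein clusters,
   *significant similarity* means E < 10⁻⁵ with ≥ 80 % subject coverage.
   Each missed gene gets a support level — **strong** (conserved: > 50
   significant homologs, or an assigned cluster with > 50 members from ≥ 2
   phyla; or similarity to a gene with experimental function, 3D structure,
   purified protein, protein domain or EC number), **fair** (assigned
   cluster with a computational prediction or ≥ 5 members, or 10–50
   homologs), else **weak** (named) / **insufficient** (hypothetical) — plus
   phenotype associations and a drug-target flag (pathogenic host + ≥
   50-member cluster + similarity to an essential gene).
5. **Spurious flagging.** Missed genes hitting profile-HMM models of known
   spurious ORF families (AntiFam-style) are flagged and tabulated by
   support level.
6. **Reports.** Per-center statistics (missed genes per Mbp, percent of
   annotated genes), rate percentiles, length histograms, top-rate genome
   ranking, and 3′-end-based comparison of two annotations of one
   chromosome (unique genes and 5′ changes).

A synthetic-fixture generator (`make_fixture()`) plants ground truth through
every rule, so the whole pipeline is testable without downloading anything.

## Worked example

```r
library(annotaudit)

dir <- tempfile()
fx <- make_fixture(fixture_config(seed = 7, plant_drug_target = TRUE), dir)
p  <- fx$paths

rep <- run_pipeline(pipeline_config(
  genbank = p[["genbank"]], predictions = p[["predictions"]],
  refseq_hits = p[["refseq_hits"]], kb_hits = p[["kb_hits"]],
  kb_genes = p[["kb_genes"]], kb_clusters = p[["kb_clusters"]],
  hmm_hits = p[["hmm_hits"]], pathogens = p[["pathogens"]],
  centers = p[["centers"]], out_dir = file.path(dir, "out")))
print(rep)
#> <missed_gene_report>
#>   1 record(s), 1 included
#>   13 predictions -> 7 not annotated -> 6 candidates
#>   3 named, 2 hypothetical, 1 without homology; 1 spurious
```

Reading: of 13 predictions, 6 matched an annotated CDS by 3′ end and 1 sat
on a planted RNA/pseudogene, leaving 6 candidate missed genes; homology
evidence names 3 of them, 2 hit only hypothetical proteins, 1 has no passing
hit. One missed gene matches a spurious-family HMM. The per-call tables are
in `rep$calls` and `rep$assignments`:

```r
rep$assignments[, c("pred_id", "category", "support", "phenotypes", "drug_target")]
#>    pred_id     category support phenotypes drug_target
#> 1 orf00011 hypothetical  strong                  FALSE
#> 2 orf00010        named    weak                  FALSE
#> 3 orf00009        named    fair                  FALSE
#> 4 orf00008        named  strong  essential        TRUE
#> 5 orf00012 hypothetical    fair                  FALSE
```

`orf00008` is a potential drug target: its host is on the pathogen list, it
was assigned to a ≥ 50-member protein cluster, and it is significantly
similar to an essential gene. A report directory with the screening,
candidate, missed-gene, evidence, spurious and per-center tables plus a run
manifest is written under `out/`.

There is also a thin CLI over the same functions at
`inst/cli/annotaudit.R` (subcommands `run`, `screen`, `detect`, `classify`,
`make-fixture`).

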