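---
title: "Auditing prokaryotic annotations for missed genes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing prokaryotic annotations for missed genes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annotaudit)
```

## The procedure and its assumptions

`annotaudit` asks a narrow question of an annotated prokaryotic chromosome:
which ab initio gene predictions are *missing* from the official annotation,
and how much external evidence supports each one? It does not run a gene
finder, BLAST or HMMER itself — their outputs are inputs — and it does not
re-annotate anything. Three assumptions shape the design:

* **Stop codons are stable, start codons are not.** Two annotations of the
  same gene almost always agree on the stop codon and frequently disagree on
  the start. Presence of a prediction in an annotation is therefore decided
  by the strand-aware 3′ end alone: a prediction is "annotated" iff some
  non-pseudo CDS on the same strand ends at the same base. A 5′-shifted copy
  of an annotated gene is *not* a missed gene.
* **Overlaps with non-coding features are mis-calls.** A prediction lying
  mostly (> 50 % of its own length) on an rRNA, tRNA, other RNA, a `gene`
  feature with no CDS, or a pseudo-CDS is more plausibly a translation
  artifact of that feature than a missed gene, and is excluded. Non-pseudo
  CDS overlaps never exclude: overlapping genes are common in prokaryotes.
* **Homology is necessary but description quality matters.** A surviving
  candidate only counts as a likely missed gene if a protein alignment
  passes E ≤ 10⁻⁶ with ≥ 80 % subject coverage. The split into *named*
  versus *hypothetical* missed genes encodes that similarity to a protein
  that itself was only ever computationally predicted is weaker evidence
  than similarity to a functionally annotated one.

The evidence-aggregation stage then scores each missed gene against a
knowledgebase of curated genes (with experimental-evidence and phenotype
flags) organised into protein clusters, producing the
strong/fair/weak/insufficient support levels, phenotype associations and
drug-target flags described in the README.

## Coordinates

Internally every interval is 0-based half-open with an explicit strand;
GenBank, Glimmer and GFF3 coordinates (1-based inclusive) are converted
exactly once, at the read/write boundary. This makes overlap arithmetic
(`min(ends) - max(starts)`) and 3′-end arithmetic (`end - 1` forward,
`start` reverse) free of off-by-one case analysis. Exported TSVs print
1-based coordinates again.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `min_length_bp` | 110 | bp | minimum retained prediction length (the g3-iterated default) |
| `candidate_max_evalue` | 1e-6 | — | candidate-stage E-value bound, **inclusive** |
| `candidate_min_coverage` | 0.8 | fraction | subject coverage bound, **inclusive** |
| `kb_max_evalue` | 1e-5 | — | knowledgebase significance, **strict** `<` |
| `kb_min_coverage` | 0.8 | fraction | knowledgebase coverage, inclusive |
| `max_overlap` | 0.5 | fraction | overlap exclusion, strict `>` |
| `big_cluster_min` | 100 | members | cluster assignment: ≥ 100 members hit for big clusters, all members for smaller ones |
| conserved bounds | 50 | genes | strict `>` on homolog count and on cluster size (with ≥ 2 phyla) |
| fair bounds | 5; 10–50 | members; genes | cluster size ≥ 5; homolog band inclusive at both ends |
| `drug_target_min_cluster` | 50 | members | inclusive |
| `max_ambiguous_runs` / `min_ambiguous_run` | 10 / 5 | runs / bp | genome exclusion at `> 10` runs of `≥ 5` ambiguous bases |

The asymmetry between the two E-value bounds (inclusive at the candidate
stage, strict at the knowledgebase stage) is deliberate and pinned by unit
tests; the two stages are defined by different rule sets and we preserve
each one's wording exactly.

## Boundary semantics, ties and degenerate inputs

* Overlap of **exactly** 50 % retains the prediction; coverage of exactly
  80 % passes; E of exactly 10⁻⁶ passes the candidate filter while E of
  exactly 10⁻⁵ fails significance; 51 homologs are conserved, 50 are not;
  a 49-member cluster fails drug-target criterion (ii).
* Best-hit selection orders by E-value, then larger subject coverage, then
  lexicographic subject id — fully deterministic.
* Ranking ties (equal missed-gene rates) break by accession.
* Multiple predictions sharing one 3′ end are evaluated independently.
* In annotation comparison, duplicate (strand, 3′ end) keys within one
  annotation are collapsed to the longest CDS (ties: smallest start) before
  matching; the comparison is symmetric by construction.
* Zero denominators (no annotated genes, empty groups, `0/0` cells) render
  as `NA` or `0/0 (0%)` rather than erroring.
* `P = 1 − e⁻ᴱ` is computed with `expm1`, so it is exact for the tiny
  E-values that matter; for E ≳ 40 the result saturates at 1 in double
  precision, which is irrelevant to any filtering decision.
* Origin-spanning (compound-location) features and predictions are excluded
  with a warning: on circular chromosomes a wrap-around interval has no
  single linear 3′ coordinate, and dropping the handful of such features is
  conservative for an audit (it can only under-count missed genes).
* Percentiles use linear interpolation between closest order statistics
  (`stats::quantile` type 7, R's default), cross-checked against an
  independent sorted-interpolation oracle.

## Design choices where the rules were open

* **Overlap denominator.** "Overlaps by more than 50 %" is read with the
  prediction's own length as denominator — the prediction is the subject of
  the sentence, and it is the object being excluded.
* **Ambiguous nucleotides** are anything outside A/C/G/T case-insensitively
  (N and all IUPAC codes); "distinct locations" are maximal runs, the only
  reading that is oracle-testable without arbitrary window choices.
* **Header line** for the draft-phrase screen is the DEFINITION line.
* **Presence** is restricted to CDS 3′ ends; annotated non-CDS `gene`
  features do not make a prediction "present".
* **Cluster-member evidence** does not trigger the strong level by default
  (direct similarity only); `cluster_evidence_triggers_strong = TRUE`
  enables the cluster path, which some curated examples suggest.
* **Glimmer lengths** count the stated interval as-is (stop codon included
  when the dialect includes it); no codon-multiple check is enforced, since
  dialects differ on whether the stop is part of the reported interval.
* **Spurious denominators.** The summary supports both the
  knowledgebase-similar denominator (calls with ≥ 1 significant homolog)
  and the all-calls denominator; published tallies exist in both
  conventions and neither is "corrected".
* **Pathogen matching** compares the first two whitespace tokens of the
  organism string (genus + species) case-insensitively against a
  user-supplied list; no pathogen database is bundled.

## What the synthetic fixtures emulate — and what they do not

`make_fixture()` builds a complete input set with planted truth: a uniform
random sequence; annotated CDS whose predictions share their 3′ end (half
with shifted starts, exercising the 3′ rule); missed genes with homology
rows constructed to pass the candidate filter against named or hypothetical
subjects (plus deliberately failing rows, so a failing named hit cannot
promote a call); blocker features with > 50 % prediction overlap; HMM hits
for planted spurious genes; and a knowledgebase wired so that each missed
gene's support level is forced by exactly one rule (an evidence flag for
strong; a 12-homolog set or a complete 6-member cluster for fair; 3 plain
homologs for weak/insufficient; a 55-of-60-member essential-bearing cluster
for the drug-target case). Gene placement is rejection sampling with a
minimum inter-feature gap; E-values and coverages are drawn from ranges
straddling each threshold so the boundaries are exercised, including the
inclusive ones exactly.

The fixtures deliberately do **not** model codon statistics, GC bias,
operon structure, overlapping genes, or sequence evolution: they validate
the *rule logic* downstream of gene finding and alignment, not gene-finder
or aligner accuracy. Passing the planted-truth suite therefore shows the
pipeline implements its rules exactly; it says nothing about how often real
annotations miss genes, which depends entirely on the user's predictions
and homology inputs.

## Problem sizes in the test suite

The suite runs 100 seeded fixtures (30 kb genomes, 5–12 planted genes each)
end to end, ≥ 1,000 random instances per brute-force oracle (overlap
fraction, 3′ matching, percentiles, histogram binning, annotation
comparison), and recomputes the bundled 1,574-chromosome per-center and
spurious tallies through the same summary functions the pipeline uses.
These sizes give exhaustive coverage of every rule boundary while keeping
the default test run fast on a single CPU.

## Known limitations

* One predictions file per GenBank record; prediction ids must be unique
  across records fed into one `classify_candidates()` call.
* Circular-chromosome wrap-around features are dropped, not split; a config
  flag to retain them as two sub-intervals is a possible extension.
* The GenBank reader targets the flat-file subset that annotation audits
  need (LOCUS/DEFINITION/SOURCE/FEATURES/ORIGIN, simple and complemented
  spans); it is not a general-purpose GenBank parser.
* No query-side coverage requirement at the candidate stage, and no
  domain-composition comparison in the evidence engine.
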