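## Genome screening: which records enter the analysis. Excludes plasmids,
## unannotated records, drafts (by header phrase), and records with too many
## runs of ambiguous nucleotides.

#' Count runs of ambiguous nucleotides
#'
#' Counts the maximal runs of consecutive ambiguous characters — anything
#' outside A/C/G/T, case-insensitively, which covers N and all IUPAC
#' ambiguity codes — whose length is at least `min_run`. Two runs separated
#' by one or more unambiguous bases are distinct locations.
#'
#' @param sequence nucleotide string.
#' @param min_run minimum run length to count (default 5).
#' @return integer count of qualifying runs.
#' @export
count_ambiguous_runs <- function(sequence, min_run = 5L) {
  if (!nchar(sequence)) return(0L)
  amb <- !strsplit(toupper(sequence), "")[[1]] %in% c("A", "C", "G", "T")
  r <- rle(amb)
  sum(r$values & r$lengths >= min_run)
}

#' Screen a genome record for inclusion
#'
#' A record is excluded if it is a plasmid, carries no annotation features,
#' contains "draft" or "nearly complete" (case-insensitive) in its
#' definition line, or has more than `max_ambiguous_runs` distinct runs of
#' at least `min_run` consecutive ambiguous nucleotides.
#'
#' @param record a [genome_record()].
#' @param max_ambiguous_runs exclusion threshold on the run count (strict
#'   `>`; default 10).
#' @param min_run minimum ambiguous-run length (default 5).
#' @return data.frame with columns `accession`, `included`, `reasons`
#'   (comma-joined subset of `plasmid`, `no_annotation`, `draft_phrase`,
#'   `ambiguous_runs`; empty iff included).
#' @export
screen_genome <- function(record, max_ambiguous_runs = 10L, min_run = 5L) {
  reasons <- character()
  if (record$is_plasmid) reasons <- c(reasons, "plasmid")
  if (!nrow(record$features)) reasons <- c(reasons, "no_annotation")
  if (grepl("draft|nearly complete", record$definition, ignore.case = TRUE)) {
    reasons <- c(reasons, "draft_phrase")
  }
  if (count_ambiguous_runs(record$sequence, min_run) > max_ambiguous_runs) {
    reasons <- c(reasons, "ambiguous_runs")
  }
  data.frame(accession = record$accession, included = !length(reasons),
             reasons = paste(reasons, collapse = ","),
             stringsAsFactors = FALSE)
}

#' @rdname screen_genome
#' @param records list of [genome_record()] objects.
#' @export
screen_genomes <- function(records, max_ambiguous_runs = 10L, min_run = 5L) {
  do.call(rbind, lapply(records, screen_genome,
                        max_ambiguous_runs = max_ambiguous_runs,
                        min_run = min_run))
}
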