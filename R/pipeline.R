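## Pipeline orchestration: screen -> detect -> classify -> evidence
## aggregation -> spurious flagging -> reports, over a set of input files,
## with a run manifest recording configuration, input checksums and the
## record counts at every stage of the funnel.

#' Pipeline configuration
#'
#' Collects all input paths and thresholds. The defaults are the audit's
#' standard settings: minimum prediction length 110 bp; candidate-stage
#' homology filter E <= 1e-6 with subject coverage >= 0.8; knowledgebase
#' significance E < 1e-5 with coverage >= 0.8; overlap exclusion > 0.5;
#' conserved > 50 homologs or a > 50-member multi-phylum cluster; fair at
#' 10-50 homologs or a >= 5-member cluster; big-cluster assignment at 100
#' members; drug-target cluster >= 50 members; genome exclusion at > 10
#' runs of >= 5 ambiguous nucleotides.
#'
#' @param genbank path(s) to GenBank flat files (one record each).
#' @param predictions path(s) to Glimmer `.predict` files, parallel to
#'   `genbank` (or a single file reused for all).
#' @param refseq_hits BLAST tabular hits of predictions vs the reference
#'   protein set.
#' @param kb_hits BLAST tabular hits of predictions vs knowledgebase genes.
#' @param kb_genes,kb_clusters knowledgebase TSVs.
#' @param hmm_hits HMMER table of spurious-family hits (optional).
#' @param pathogens pathogen species list (optional).
#' @param centers accession-to-center metadata TSV (optional).
#' @param out_dir output directory for the report files.
#' @param min_length_bp,candidate_max_evalue,candidate_min_coverage thresholds
#'   for prediction length and the candidate-stage homology filter.
#' @param kb_max_evalue,kb_min_coverage,big_cluster_min,drug_target_min_cluster
#'   thresholds for the knowledgebase evidence rules.
#' @param max_overlap,spurious_max_evalue,max_ambiguous_runs,min_ambiguous_run
#'   overlap-exclusion, spurious-flagging and genome-screening thresholds.
#' @param cluster_evidence_triggers_strong see [assign_support_level()].
#' @param denominator_variant see [spurious_summary()].
#' @param prediction_dialect see [read_predictions()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(genbank, predictions, refseq_hits, kb_hits,
                            kb_genes, kb_clusters, hmm_hits = NULL,
                            pathogens = NULL, centers = NULL,
                            out_dir = tempfile("annotaudit_"),
                            min_length_bp = 110L,
                            candidate_max_evalue = 1e-6,
                            candidate_min_coverage = 0.8,
                            kb_max_evalue = 1e-5,
                            kb_min_coverage = 0.8,
                            max_overlap = 0.5,
                            big_cluster_min = 100L,
                            drug_target_min_cluster = 50L,
                            spurious_max_evalue = 1e-5,
                            max_ambiguous_runs = 10L,
                            min_ambiguous_run = 5L,
                            cluster_evidence_triggers_strong = FALSE,
                            denominator_variant = c("kb_similar", "all"),
                            prediction_dialect = "glimmer_predict") {
  denominator_variant <- match.arg(denominator_variant)
  stopifnot(min_length_bp > 0, candidate_max_evalue > 0,
            candidate_min_coverage > 0, kb_max_evalue > 0,
            kb_min_coverage > 0, max_overlap > 0, big_cluster_min > 0,
            drug_target_min_cluster > 0, max_ambiguous_runs > 0,
            min_ambiguous_run > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full annotation audit
#'
#' Executes every stage over the configured inputs and writes the report
#' files under `config$out_dir`: `screening.tsv`, `candidates.tsv`,
#' `missed_genes.tsv`, `comblast.tsv`, `spurious_flags.tsv`,
#' `spurious_summary.tsv`, `center_stats.tsv`, `per_genome.tsv`,
#' `length_histogram.tsv` and `manifest.json` (configuration, input MD5
#' checksums, and the stage-count funnel). The analysis is deterministic:
#' no randomness is involved past the fixture generator.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list of class `missed_gene_report` holding every
#'   table plus the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config

  records <- unlist(lapply(cfg$genbank, read_genbank), recursive = FALSE)
  if (!is.null(cfg$centers)) {
    records <- assign_centers(records, read_center_metadata(cfg$centers))
  }
  screening <- screen_genomes(records, cfg$max_ambiguous_runs,
                              cfg$min_ambiguous_run)
  included <- which(screening$included)

  pred_paths <- rep_len(cfg$predictions, length(records))
  refseq_hits <- read_blast_tab(cfg$refseq_hits)
  kb_hits <- read_blast_tab(cfg$kb_hits)
  kb <- read_knowledgebase(cfg$kb_genes, cfg$kb_clusters)
  hmm_hits <- if (!is.null(cfg$hmm_hits)) read_hmm_table(cfg$hmm_hits) else
    data.frame(query_id = character(), model_name = character(),
               model_accession = character(), evalue = numeric(),
               stringsAsFactors = FALSE)
  pathogen_species <- if (!is.null(cfg$pathogens))
    read_pathogen_list(cfg$pathogens) else character()

  candidates <- list()
  calls <- list()
  assignments <- list()
  per_genome <- list()
  n_predictions <- 0L
  for (i in included) {
    rec <- records[[i]]
    preds <- read_predictions(pred_paths[i], cfg$prediction_dialect,
                              cfg$min_length_bp,
                              genome_length = rec$length_bp)
    n_predictions <- n_predictions + nrow(preds)
    cand <- detect_candidates(preds, rec$features, rec$accession,
                              cfg$max_overlap)
    cl <- classify_candidates(cand, refseq_hits, cfg$candidate_max_evalue,
                              cfg$candidate_min_coverage)
    asg <- comblast_assign(cl, kb_hits, kb, rec$organism, pathogen_species,
                           cfg$kb_max_evalue, cfg$kb_min_coverage,
                           cfg$big_cluster_min,
                           cfg$cluster_evidence_triggers_strong,
                           cfg$drug_target_min_cluster)
    candidates[[length(candidates) + 1L]] <- cand
    calls[[length(calls) + 1L]] <- cl
    assignments[[length(assignments) + 1L]] <- asg
    per_genome[[length(per_genome) + 1L]] <- data.frame(
      accession = rec$accession, center = rec$center,
      named_missed = sum(cl$category == "named"),
      annotated_genes = sum(rec$features$kind == "CDS" &
                              !rec$features$is_pseudo),
      length_bp = rec$length_bp,
      shortest_annotated = shortest_annotated_length(rec$features),
      pct_short = {
        nl <- cl$length_bp[cl$category == "named"]
        if (length(nl)) round(100 * mean(nl <= 300L), 1) else NA_real_
      },
      stringsAsFactors = FALSE)
  }
  bind <- function(lst, proto) if (length(lst)) do.call(rbind, lst) else proto
  candidates <- bind(candidates, NULL)
  calls <- bind(calls, NULL)
  assignments <- bind(assignments, NULL)
  per_genome <- bind(per_genome, NULL)
  if (is.null(calls)) stop("no genome passed screening; nothing to analyse")

  flags <- flag_spurious(calls, hmm_hits, cfg$spurious_max_evalue)
  spur <- spurious_summary(calls, flags, assignments,
                           cfg$denominator_variant)
  cstats <- center_statistics(per_genome)
  named_lengths <- calls$length_bp[calls$category == "named"]
  hist <- length_histogram(named_lengths)
  ranked <- rank_and_top(per_genome)

  manifest <- list(
    config = cfg[!vapply(cfg, is.null, logical(1))],
    input_md5 = as.list(tools::md5sum(unique(stats::na.omit(c(
      unlist(cfg$genbank), unlist(cfg$predictions), cfg$refseq_hits,
      cfg$kb_hits, cfg$kb_genes, cfg$kb_clusters, cfg$hmm_hits,
      cfg$pathogens, cfg$centers))))),
    stage_counts = list(
      records = length(records),
      records_included = length(included),
      predictions = n_predictions,
      not_annotated = sum(candidates$status != "annotated"),
      candidates = sum(candidates$status == "candidate"),
      named = sum(calls$category == "named"),
      hypothetical = sum(calls$category == "hypothetical"),
      no_homology = sum(calls$category == "no_homology"),
      spurious = sum(flags$spurious)))

  ## write outputs only after every stage succeeded, so a stage error never
  ## leaves partial files behind
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) utils::write.table(
    df, file.path(cfg$out_dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE)
  out_candidates <- candidates
  out_candidates$start <- out_candidates$start + 1L  # 1-based on disk
  w(screening, "screening.tsv")
  w(out_candidates, "candidates.tsv")
  w(calls, "missed_genes.tsv")
  w(assignments, "comblast.tsv")
  w(flags, "spurious_flags.tsv")
  w(spur, "spurious_summary.tsv")
  w(cstats, "center_stats.tsv")
  w(per_genome, "per_genome.tsv")
  w(hist$histogram, "length_histogram.tsv")
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)

  invisible(structure(list(
    screening = screening, candidates = candidates, calls = calls,
    assignments = assignments, spurious_flags = flags,
    spurious_summary = spur, center_stats = cstats,
    per_genome = per_genome, length_histogram = hist,
    top_rates = ranked, manifest = manifest), class = "missed_gene_report"))
}

#' @export
print.missed_gene_report <- function(x, ...) {
  sc <- x$manifest$stage_counts
  cat(sprintf(paste0(
    "<missed_gene_report>\n",
    "  %d record(s), %d included\n",
    "  %d predictions -> %d not annotated -> %d candidates\n",
    "  %d named, %d hypothetical, %d without homology; %d spurious\n"),
    sc$records, sc$records_included, sc$predictions, sc$not_annotated,
    sc$candidates, sc$named, sc$hypothetical, sc$no_homology, sc$spurious))
  invisible(x)
}
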