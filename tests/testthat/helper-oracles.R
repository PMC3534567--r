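# Independent brute-force oracles used to cross-check the vectorised
# implementations, plus small random-data builders. All oracles enumerate
# per-base / per-pair, deliberately ignoring how the package computes things.

# per-base overlap fraction by explicit position membership
oracle_overlap_fraction <- function(ps, pe, fs, fe) {
  p_pos <- seq.int(ps, pe - 1L)
  f_pos <- seq.int(fs, fe - 1L)
  length(intersect(p_pos, f_pos)) / length(p_pos)
}

# all-pairs 3' comparison: is the prediction's stranded last base equal to
# any non-pseudo CDS's stranded last base?
oracle_is_annotated <- function(pred, features) {
  last_base <- function(s, e, st) if (st == "+") e - 1L else s
  p3 <- last_base(pred$start, pred$end, pred$strand)
  for (j in seq_len(nrow(features))) {
    f <- features[j, ]
    if (f$kind != "CDS" || f$is_pseudo) next
    if (f$strand == pred$strand && last_base(f$start, f$end, f$strand) == p3)
      return(TRUE)
  }
  FALSE
}

# maximal-run enumeration by explicit scan
oracle_count_runs <- function(seq, min_run) {
  chars <- strsplit(toupper(seq), "")[[1]]
  amb <- !chars %in% c("A", "C", "G", "T")
  count <- 0L
  run <- 0L
  for (a in c(amb, FALSE)) {
    if (a) {
      run <- run + 1L
    } else {
      if (run >= min_run) count <- count + 1L
      run <- 0L
    }
  }
  count
}

# sorted linear interpolation between closest order statistics
oracle_percentile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  if (n == 1L) return(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[pmin(lo + 1, n)] - s[lo])
}

# explicit per-value binning
oracle_histogram <- function(lengths, w) {
  counts <- list()
  for (l in lengths) {
    b <- as.character((l %/% w) * w)
    counts[[b]] <- (if (is.null(counts[[b]])) 0L else counts[[b]]) + 1L
  }
  counts
}

# brute-force annotation matcher over deduplicated (strand, 3') keys
oracle_compare <- function(fa, fb) {
  prep <- function(f) {
    f <- f[f$kind == "CDS" & !f$is_pseudo, , drop = FALSE]
    out <- list()
    for (j in seq_len(nrow(f))) {
      key <- paste(f$strand[j],
                   if (f$strand[j] == "+") f$end[j] - 1L else f$start[j])
      five <- if (f$strand[j] == "+") f$start[j] else f$end[j] - 1L
      len <- f$end[j] - f$start[j]
      cur <- out[[key]]
      if (is.null(cur) || len > cur$len ||
          (len == cur$len && f$start[j] < cur$start)) {
        out[[key]] <- list(five = five, len = len, start = f$start[j])
      }
    }
    out
  }
  a <- prep(fa); b <- prep(fb)
  common <- intersect(names(a), names(b))
  changes <- sum(vapply(common,
                        function(k) a[[k]]$five != b[[k]]$five, logical(1)))
  list(n_a = length(a), n_b = length(b),
       unique_a = length(a) - length(common),
       unique_b = length(b) - length(common),
       common = length(common), five_prime_changes = changes)
}

# random feature / prediction builders (valid 0-based half-open intervals)
random_features <- function(n, genome_len = 1000L,
                            kinds = c("CDS", "rRNA", "tRNA", "other")) {
  s <- sample.int(genome_len - 60L, n, replace = TRUE) - 1L
  len <- sample(30:60, n, replace = TRUE)
  data.frame(kind = sample(kinds, n, replace = TRUE), start = s,
             end = s + len, strand = sample(c("+", "-"), n, replace = TRUE),
             is_pseudo = sample(c(TRUE, FALSE), n, replace = TRUE,
                                prob = c(0.15, 0.85)),
             product = "", locus_id = sprintf("L%04d", seq_len(n)),
             stringsAsFactors = FALSE)
}

random_predictions <- function(n, genome_len = 1000L) {
  s <- sample.int(genome_len - 60L, n, replace = TRUE) - 1L
  len <- sample(30:60, n, replace = TRUE)
  data.frame(pred_id = sprintf("orf%05d", seq_len(n)), start = s,
             end = s + len, strand = sample(c("+", "-"), n, replace = TRUE),
             length_bp = len, score = rep(1, n),
             genetic_code = rep(11L, n), stringsAsFactors = FALSE)
}

# run a whole fixture through the pipeline stages and return the tables
run_fixture <- function(fx, denominator = "kb_similar") {
  p <- fx$paths
  rec <- read_genbank(p[["genbank"]])[[1]]
  preds <- read_predictions(p[["predictions"]], genome_length = rec$length_bp)
  cand <- detect_candidates(preds, rec$features, rec$accession)
  calls <- classify_candidates(cand, read_blast_tab(p[["refseq_hits"]]))
  kb <- read_knowledgebase(p[["kb_genes"]], p[["kb_clusters"]])
  asg <- comblast_assign(calls, read_blast_tab(p[["kb_hits"]]), kb,
                         rec$organism, read_pathogen_list(p[["pathogens"]]))
  flags <- flag_spurious(calls, read_hmm_table(p[["hmm_hits"]]))
  list(record = rec, candidates = cand, calls = calls, assignments = asg,
       flags = flags, kb = kb)
}

# tiny knowledgebase builder for rule tests: genes_spec is a list of lists
# with fields id, evidence, phenotype, clusters, phylum
build_kb <- function(genes_spec, clusters_spec = list()) {
  g <- do.call(rbind, lapply(genes_spec, function(s) {
    row <- data.frame(gene_id = s$id, length_aa = 100L,
                      phylum = if (is.null(s$phylum)) "Proteobacteria" else
                        s$phylum,
                      stringsAsFactors = FALSE)
    row$evidence_flags <- list(if (is.null(s$evidence)) character() else
      s$evidence)
    row$phenotype_flags <- list(if (is.null(s$phenotype)) character() else
      s$phenotype)
    row$cluster_ids <- list(if (is.null(s$clusters)) character() else
      s$clusters)
    row
  }))
  cl <- if (length(clusters_spec)) {
    do.call(rbind, lapply(clusters_spec, function(s) {
      row <- data.frame(cluster_id = s$id,
                        has_computational_prediction =
                          isTRUE(s$prediction),
                        stringsAsFactors = FALSE)
      row$member_ids <- list(s$members)
      row
    }))
  } else {
    c0 <- data.frame(cluster_id = character(),
                     has_computational_prediction = logical(),
                     stringsAsFactors = FALSE)
    c0$member_ids <- list()
    c0
  }
  knowledge_base(g, cl)
}

# a kb with n plain genes in one phylum, optionally all in one cluster
plain_kb <- function(n, cluster_id = NULL, phyla = "Proteobacteria",
                     prediction = FALSE) {
  ids <- sprintf("G%04d", seq_len(n))
  genes <- lapply(seq_len(n), function(i) {
    list(id = ids[i], phylum = phyla[1L + (i - 1L) %% length(phyla)],
         clusters = if (is.null(cluster_id)) NULL else cluster_id)
  })
  clusters <- if (is.null(cluster_id)) list() else
    list(list(id = cluster_id, members = ids, prediction = prediction))
  build_kb(genes, clusters)
}

blast_row <- function(query, subject, evalue, span, slen, desc = "protein") {
  data.frame(query_id = query, subject_id = subject, evalue = evalue,
             subject_alignment_span = as.integer(span),
             subject_length = as.integer(slen),
             subject_description = desc, stringsAsFactors = FALSE)
}
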