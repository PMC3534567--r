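## Synthetic fixtures with planted ground truth. The generator emulates the
## inputs of a full audit run — an annotated chromosome (GenBank + FASTA),
## ab initio predictions, homology tables against a reference protein set
## and against the knowledgebase, an HMM hit table, the knowledgebase TSVs,
## a pathogen list and a center metadata table — while recording exactly
## which prediction belongs to which outcome class, so the whole pipeline
## can be checked for literal equality against the planted truth.
##
## Random model: uniform base composition; gene placement by rejection
## sampling with a minimum inter-feature gap. No codon statistics are
## modelled: gene finding itself is out of scope, the fixtures validate the
## rule logic downstream of it.

#' Fixture configuration
#'
#' @param n_annotated genes present in both annotation and predictions
#'   (matched by 3' end; about half get a shifted 5' start).
#' @param n_missed_named planted missed genes whose homology hits include a
#'   non-hypothetical protein.
#' @param n_missed_hypothetical planted missed genes hitting only
#'   hypothetical proteins.
#' @param n_no_homology planted candidates with no passing homology hit.
#' @param n_overlap_excluded predictions planted over an RNA/pseudo-CDS
#'   blocker with > 50% overlap.
#' @param n_spurious how many planted missed genes also get an HMM hit
#'   (capped at the number of missed genes).
#' @param support_levels support levels to force for the missed genes, in
#'   order, recycled: `"strong"`, `"fair"`, or `"auto"` (weak for named,
#'   insufficient for hypothetical).
#' @param plant_drug_target if TRUE the first named missed gene is wired to
#'   a 60-member essential-bearing cluster and the organism is put on the
#'   pathogen list, forcing a drug-target flag.
#' @param genome_length chromosome length in bp.
#' @param gene_length_range sampled gene lengths (bp), minimum 110.
#' @param min_gap minimum gap between planted intervals (bp).
#' @param accession,organism,center record metadata.
#' @param seed RNG seed; fixed seed gives byte-identical output files.
#' @return list of class `fixture_config`.
#' @export
fixture_config <- function(n_annotated = 6L, n_missed_named = 3L,
                           n_missed_hypothetical = 2L, n_no_homology = 1L,
                           n_overlap_excluded = 1L, n_spurious = 1L,
                           support_levels = c("strong", "fair", "auto"),
                           plant_drug_target = FALSE,
                           genome_length = 60000L,
                           gene_length_range = c(150L, 900L),
                           min_gap = 30L,
                           accession = "SYN000001",
                           organism = "Synthetica exempli",
                           center = "Other", seed = 1L) {
  stopifnot(n_annotated >= 0, n_missed_named >= 0,
            n_missed_hypothetical >= 0, n_no_homology >= 0,
            n_overlap_excluded >= 0, n_spurious >= 0,
            gene_length_range[1] >= 110L, min_gap >= 1L)
  structure(as.list(environment()), class = "fixture_config")
}

## Rejection sampling of non-overlapping intervals with a minimum gap.
place_intervals <- function(lengths, genome_length, min_gap,
                            max_tries = 200L) {
  placed_start <- integer()
  placed_end <- integer()
  for (len in lengths) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      s <- sample.int(genome_length - len, 1L) - 1L
      e <- s + len
      if (!any(s < placed_end + min_gap & e + min_gap > placed_start)) {
        placed_start <- c(placed_start, s)
        placed_end <- c(placed_end, e)
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("infeasible fixture config: cannot place ", length(lengths),
           " intervals of total length ", sum(lengths), " in ",
           genome_length, " bp")
    }
  }
  data.frame(start = placed_start, end = placed_end)
}

NAMED_PRODUCTS <- c("dimethyladenosine transferase",
                    "adenylate cyclase (EC 4.6.1.1)",
                    "DNA polymerase III subunit alpha",
                    "50S ribosomal protein L33",
                    "ABC transporter ATP-binding protein",
                    "cell division protein FtsZ")
PHYLA <- c("Proteobacteria", "Firmicutes", "Actinobacteria", "Bacteroidetes")

#' Generate a fixture directory with planted ground truth
#'
#' Writes `genome.gbk`, `genome.fasta`, `predictions.predict`,
#' `refseq_hits.tsv`, `kb_hits.tsv`, `kb_genes.tsv`, `kb_clusters.tsv`,
#' `pathogens.txt`, `centers.tsv` and `truth.json` under `dir`. Output is
#' deterministic for a fixed seed. The truth file records the planted
#' outcome class of every prediction, the forced support level, phenotype
#' set and drug-target flag of every missed gene, and the spurious ids.
#'
#' @param config a [fixture_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with `paths` (named file paths) and `truth`.
#' @export
make_fixture <- function(config, dir) {
  stopifnot(inherits(config, "fixture_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  cfg <- config

  n_missed <- cfg$n_missed_named + cfg$n_missed_hypothetical
  n_preds_free <- n_missed + cfg$n_no_homology
  lens <- function(n) {
    if (!n) return(integer())
    ## lengths divisible by 3 (codon-shaped), >= 110
    3L * sample(ceiling(cfg$gene_length_range[1] / 3):
                  floor(cfg$gene_length_range[2] / 3), n, replace = TRUE)
  }
  l_annot <- lens(cfg$n_annotated)
  l_block <- lens(cfg$n_overlap_excluded)
  l_free <- lens(n_preds_free)
  pl <- place_intervals(c(l_annot, l_block, l_free), cfg$genome_length,
                        cfg$min_gap)
  strands <- sample(c("+", "-"), nrow(pl), replace = TRUE)
  i_annot <- seq_len(cfg$n_annotated)
  i_block <- cfg$n_annotated + seq_len(cfg$n_overlap_excluded)
  i_free <- cfg$n_annotated + cfg$n_overlap_excluded + seq_len(n_preds_free)

  ## --- annotation features ---
  feats <- list()
  for (k in seq_along(i_annot)) {
    i <- i_annot[k]
    feats[[length(feats) + 1L]] <- data.frame(
      kind = "CDS", start = pl$start[i], end = pl$end[i],
      strand = strands[i], is_pseudo = FALSE,
      product = NAMED_PRODUCTS[1L + (k - 1L) %% length(NAMED_PRODUCTS)],
      locus_id = sprintf("SYN_%04d", k), stringsAsFactors = FALSE)
  }
  blocker_kinds <- c("tRNA", "rRNA", "other_RNA", "gene_without_CDS", "CDS")
  for (k in seq_along(i_block)) {
    i <- i_block[k]
    kind <- blocker_kinds[1L + (k - 1L) %% length(blocker_kinds)]
    feats[[length(feats) + 1L]] <- data.frame(
      kind = kind, start = pl$start[i], end = pl$end[i],
      strand = strands[i],
      is_pseudo = kind %in% c("CDS", "gene_without_CDS"),  # CDS blocker must be pseudo
      product = if (kind == "CDS") "pseudogene remnant" else "",
      locus_id = sprintf("SYNB_%04d", k), stringsAsFactors = FALSE)
  }
  features <- if (length(feats)) do.call(rbind, feats) else empty_features()

  ## --- predictions ---
  preds <- list()
  pid <- 0L
  next_id <- function() {
    pid <<- pid + 1L
    sprintf("orf%05d", pid)
  }
  planted_annotated <- character()
  for (k in seq_along(i_annot)) {
    i <- i_annot[k]
    s <- pl$start[i]; e <- pl$end[i]; st <- strands[i]
    ## half the matched predictions get a 5'-shifted start (3' unchanged)
    if (k %% 2L == 0L && (e - s) >= 110L + 15L) {
      shift <- 3L * sample.int(5L, 1L)
      if (st == "+") s <- s + shift else e <- e - shift
    }
    id <- next_id()
    planted_annotated <- c(planted_annotated, id)
    preds[[length(preds) + 1L]] <- data.frame(
      pred_id = id, start = s, end = e, strand = st,
      score = round(stats::runif(1, 1, 15), 2), stringsAsFactors = FALSE)
  }
  planted_overlap <- character()
  for (k in seq_along(i_block)) {
    i <- i_block[k]
    L <- pl$end[i] - pl$start[i]
    shift <- min(cfg$min_gap - 1L, floor(0.2 * L))  # keeps overlap >= 0.8
    if (pl$end[i] + shift > cfg$genome_length) {
      shift <- if (pl$start[i] - shift >= 0L) -shift else 0L
    }
    id <- next_id()
    planted_overlap <- c(planted_overlap, id)
    preds[[length(preds) + 1L]] <- data.frame(
      pred_id = id, start = pl$start[i] + shift, end = pl$end[i] + shift,
      strand = strands[i], score = round(stats::runif(1, 1, 15), 2),
      stringsAsFactors = FALSE)
  }
  free_ids <- character(n_preds_free)
  for (k in seq_len(n_preds_free)) {
    i <- i_free[k]
    id <- next_id()
    free_ids[k] <- id
    preds[[length(preds) + 1L]] <- data.frame(
      pred_id = id, start = pl$start[i], end = pl$end[i],
      strand = strands[i], score = round(stats::runif(1, 1, 15), 2),
      stringsAsFactors = FALSE)
  }
  predictions <- if (length(preds)) do.call(rbind, preds) else
    data.frame(pred_id = character(), start = integer(), end = integer(),
               strand = character(), score = numeric(),
               stringsAsFactors = FALSE)
  named_ids <- free_ids[seq_len(cfg$n_missed_named)]
  hypo_ids <- free_ids[cfg$n_missed_named + seq_len(cfg$n_missed_hypothetical)]
  nohom_ids <- free_ids[n_missed + seq_len(cfg$n_no_homology)]

  ## --- reference-set homology hits (candidate-stage filter) ---
  rs <- list()
  pass_hit <- function(qid, sid, desc) {
    slen <- sample(100:400, 1L)
    cov <- stats::runif(1, 0.82, 1)
    if (stats::runif(1) < 0.2) cov <- 0.8   # exercise the inclusive boundary
    ev <- 10^stats::runif(1, -120, -7)
    if (stats::runif(1) < 0.2) ev <- 1e-6   # inclusive boundary
    data.frame(query_id = qid, subject_id = sid, evalue = ev,
               subject_alignment_span = as.integer(ceiling(cov * slen)),
               subject_length = slen, subject_description = desc,
               stringsAsFactors = FALSE)
  }
  fail_hit <- function(qid, sid, desc) {
    slen <- sample(100:400, 1L)
    if (stats::runif(1) < 0.5) {             # fails on E-value
      ev <- 10^stats::runif(1, -5.9, -1)
      cov <- stats::runif(1, 0.85, 1)
    } else {                                 # fails on coverage
      ev <- 10^stats::runif(1, -60, -8)
      cov <- stats::runif(1, 0.3, 0.79)
    }
    data.frame(query_id = qid, subject_id = sid, evalue = ev,
               subject_alignment_span = as.integer(floor(cov * slen)),
               subject_length = slen, subject_description = desc,
               stringsAsFactors = FALSE)
  }
  sid <- 0L
  next_sid <- function() {
    sid <<- sid + 1L
    sprintf("REF_%05d", sid)
  }
  for (q in named_ids) {
    rs[[length(rs) + 1L]] <- pass_hit(q, next_sid(),
                                      sample(NAMED_PRODUCTS, 1L))
    if (stats::runif(1) < 0.5) {
      rs[[length(rs) + 1L]] <- pass_hit(q, next_sid(), "hypothetical protein")
    }
  }
  for (q in hypo_ids) {
    rs[[length(rs) + 1L]] <- pass_hit(q, next_sid(), "hypothetical protein")
    ## a named subject whose hit FAILS the filter must not promote the call
    if (stats::runif(1) < 0.5) {
      rs[[length(rs) + 1L]] <- fail_hit(q, next_sid(),
                                        sample(NAMED_PRODUCTS, 1L))
    }
  }
  for (q in nohom_ids) {
    if (stats::runif(1) < 0.7) {
      rs[[length(rs) + 1L]] <- fail_hit(q, next_sid(), "hypothetical protein")
    }
  }
  refseq_hits <- if (length(rs)) do.call(rbind, rs) else
    data.frame(query_id = character(), subject_id = character(),
               evalue = numeric(), subject_alignment_span = integer(),
               subject_length = integer(), subject_description = character(),
               stringsAsFactors = FALSE)

  ## --- knowledgebase + knowledgebase hits, forcing support levels ---
  missed_ids <- c(named_ids, hypo_ids)
  missed_cat <- c(rep("named", length(named_ids)),
                  rep("hypothetical", length(hypo_ids)))
  levels_forced <- rep_len(cfg$support_levels, length(missed_ids))
  drug_idx <- if (cfg$plant_drug_target && length(named_ids)) 1L else 0L
  if (drug_idx) levels_forced[drug_idx] <- "strong"

  kb_genes <- list()
  kb_clusters <- list()
  kb_rows <- list()
  gid <- 0L
  next_gid <- function() {
    gid <<- gid + 1L
    sprintf("KBG%05d", gid)
  }
  cid <- 0L
  next_cid <- function() {
    cid <<- cid + 1L
    sprintf("CLS%05d", cid)
  }
  add_gene <- function(evidence = character(), phenotype = character(),
                       clusters = character(), phylum = sample(PHYLA, 1L)) {
    g <- next_gid()
    kb_genes[[length(kb_genes) + 1L]] <<- data.frame(
      gene_id = g, length_aa = sample(80:400, 1L), phylum = phylum,
      stringsAsFactors = FALSE)
    kb_genes[[length(kb_genes)]]$evidence_flags <<- list(evidence)
    kb_genes[[length(kb_genes)]]$phenotype_flags <<- list(phenotype)
    kb_genes[[length(kb_genes)]]$cluster_ids <<- list(clusters)
    g
  }
  add_kb_hit <- function(qid, g) {
    slen <- sample(80:400, 1L)
    kb_rows[[length(kb_rows) + 1L]] <<- data.frame(
      query_id = qid, subject_id = g, evalue = 10^stats::runif(1, -60, -8),
      subject_alignment_span = as.integer(ceiling(
        stats::runif(1, 0.82, 1) * slen)),
      subject_length = slen, subject_description = "knowledgebase protein",
      stringsAsFactors = FALSE)
  }
  expected_support <- character(length(missed_ids))
  expected_phenotypes <- stats::setNames(vector("list", length(missed_ids)),
                                         missed_ids)
  expected_drug <- character()
  for (k in seq_along(missed_ids)) {
    q <- missed_ids[k]
    expected_phenotypes[[q]] <- character()
    if (k == drug_idx) {
      ## 60-member, two-phylum cluster; 55 members hit (only cluster touched
      ## -> assigned; > 50 homologs -> conserved -> strong); one hit member
      ## essential -> phenotype + drug-target criterion iii
      cl <- next_cid()
      members <- character(60)
      for (m in seq_len(60)) {
        members[m] <- add_gene(
          phenotype = if (m == 1L) "essential" else character(),
          clusters = cl, phylum = PHYLA[1L + m %% 2L])
      }
      kb_clusters[[length(kb_clusters) + 1L]] <- data.frame(
        cluster_id = cl, has_computational_prediction = FALSE,
        stringsAsFactors = FALSE)
      kb_clusters[[length(kb_clusters)]]$member_ids <- list(members)
      for (m in seq_len(55)) add_kb_hit(q, members[m])
      expected_support[k] <- "strong"
      expected_phenotypes[[q]] <- "essential"
      expected_drug <- c(expected_drug, q)
      next
    }
    lvl <- levels_forced[k]
    if (lvl == "strong") {
      g <- add_gene(evidence = sample(EVIDENCE_FLAGS, 1L))
      add_kb_hit(q, g)
      expected_support[k] <- "strong"
    } else if (lvl == "fair") {
      if (k %% 2L == 0L) {
        ## 10-50 significant homologs, no clusters
        for (m in seq_len(12L)) add_kb_hit(q, add_gene())
      } else {
        ## small 6-member cluster, all members hit -> assigned, >= 5 members
        cl <- next_cid()
        phylum <- sample(PHYLA, 1L)
        members <- vapply(seq_len(6L), function(m)
          add_gene(clusters = cl, phylum = phylum), character(1))
        kb_clusters[[length(kb_clusters) + 1L]] <- data.frame(
          cluster_id = cl, has_computational_prediction = FALSE,
          stringsAsFactors = FALSE)
        kb_clusters[[length(kb_clusters)]]$member_ids <- list(members)
        for (m in members) add_kb_hit(q, m)
      }
      expected_support[k] <- "fair"
    } else {
      ## 'auto': 3 plain homologs -> weak (named) / insufficient (hypothetical)
      for (m in seq_len(3L)) add_kb_hit(q, add_gene())
      expected_support[k] <- if (missed_cat[k] == "named") "weak" else
        "insufficient"
    }
  }
  genes_df <- if (length(kb_genes)) do.call(rbind, kb_genes) else {
    g0 <- data.frame(gene_id = "KBG00000", length_aa = 100L,
                     phylum = PHYLA[1], stringsAsFactors = FALSE)
    g0$evidence_flags <- list(character())
    g0$phenotype_flags <- list(character())
    g0$cluster_ids <- list(character())
    g0
  }
  clusters_df <- if (length(kb_clusters)) do.call(rbind, kb_clusters) else {
    c0 <- data.frame(cluster_id = "CLS00000",
                     has_computational_prediction = FALSE,
                     stringsAsFactors = FALSE)
    c0$member_ids <- list(genes_df$gene_id[1])
    c0
  }
  if (!length(kb_clusters)) {
    genes_df$cluster_ids[[1]] <- "CLS00000"
  }
  kb <- knowledge_base(genes_df, clusters_df)
  kb_hits <- if (length(kb_rows)) do.call(rbind, kb_rows) else
    refseq_hits[0, ]

  ## --- HMM hits for planted spurious genes ---
  n_spur <- min(cfg$n_spurious, length(missed_ids))
  spur_ids <- if (n_spur) missed_ids[seq_len(n_spur)] else character()
  hmm <- if (n_spur) {
    data.frame(query_id = spur_ids,
               model_name = sprintf("Spurious_fam_%02d", seq_len(n_spur)),
               model_accession = sprintf("ANF%05d", seq_len(n_spur)),
               evalue = 10^stats::runif(n_spur, -30, -8),
               stringsAsFactors = FALSE)
  } else {
    data.frame(query_id = character(), model_name = character(),
               model_accession = character(), evalue = numeric(),
               stringsAsFactors = FALSE)
  }

  ## --- sequence + record ---
  sequence <- paste(sample(c("A", "C", "G", "T"), cfg$genome_length,
                           replace = TRUE), collapse = "")
  rec <- genome_record(cfg$accession,
                       sprintf("%s chromosome, complete genome",
                               cfg$organism),
                       cfg$organism, sequence, features,
                       center = cfg$center)

  ## --- write everything ---
  p <- function(f) file.path(dir, f)
  paths <- c(genbank = p("genome.gbk"), fasta = p("genome.fasta"),
             predictions = p("predictions.predict"),
             refseq_hits = p("refseq_hits.tsv"), kb_hits = p("kb_hits.tsv"),
             kb_genes = p("kb_genes.tsv"), kb_clusters = p("kb_clusters.tsv"),
             hmm_hits = p("hmm_hits.tbl"),
             pathogens = p("pathogens.txt"), centers = p("centers.tsv"),
             truth = p("truth.json"))
  write_genbank(list(rec), paths[["genbank"]])
  dna <- Biostrings::DNAStringSet(sequence)
  names(dna) <- cfg$accession
  Biostrings::writeXStringSet(dna, paths[["fasta"]])
  ord <- order(predictions$start)
  write_glimmer_predict(predictions[ord, , drop = FALSE],
                        paths[["predictions"]], tag = cfg$accession)
  write_blast_tab(refseq_hits, paths[["refseq_hits"]])
  write_blast_tab(kb_hits, paths[["kb_hits"]])
  write_knowledgebase(kb, paths[["kb_genes"]], paths[["kb_clusters"]])
  write_hmm_table(hmm, paths[["hmm_hits"]])
  pathogens <- c("Yersinia pestis", "Escherichia coli")
  if (cfg$plant_drug_target) pathogens <- c(pathogens, cfg$organism)
  writeLines(pathogens, paths[["pathogens"]])
  utils::write.table(data.frame(accession = cfg$accession,
                                center = cfg$center),
                     paths[["centers"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- list(seed = cfg$seed,
                planted_annotated = planted_annotated,
                planted_missed_named = named_ids,
                planted_missed_hypothetical = hypo_ids,
                planted_no_homology = nohom_ids,
                planted_overlap_excluded = planted_overlap,
                planted_spurious = spur_ids,
                expected_support = as.list(
                  stats::setNames(expected_support, missed_ids)),
                expected_phenotypes = expected_phenotypes,
                expected_drug_target = expected_drug)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = FALSE,
                       pretty = TRUE)
  invisible(list(paths = paths, truth = truth))
}
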