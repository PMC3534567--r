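## Evidence aggregation against a knowledgebase of curated genes and protein
## clusters: significant similarity, cluster assignment, conservation,
## support levels (strong/fair/weak/insufficient), phenotype association,
## and drug-target flagging.
##
## Boundary semantics follow the ruleset wording exactly: significance is
## E strictly < 1e-5 with coverage >= 0.8; "conserved" needs a cluster with
## MORE than 50 members from >= 2 phyla, or MORE than 50 significant
## homologs; "fair" needs a cluster with >= 5 members, a cluster with a
## computational prediction, or 10-50 significant homologs (inclusive);
## drug targets need a cluster with >= 50 members.

#' Significant similarity to a knowledgebase gene
#'
#' TRUE iff the alignment's E-value is strictly below `max_evalue` (default
#' 1e-5) and it covers at least `min_subject_coverage` of the knowledgebase
#' gene (default 0.8, inclusive). Note the asymmetry with the
#' candidate-stage filter: here the E-value bound is strict.
#'
#' @param hits data.frame from [read_blast_tab()] (vectorised).
#' @param max_evalue strict E-value bound.
#' @param min_subject_coverage inclusive coverage bound.
#' @return logical vector.
#' @export
significant_similarity <- function(hits, max_evalue = 1e-5,
                                   min_subject_coverage = 0.8) {
  hits$evalue < max_evalue &
    hits$subject_alignment_span / hits$subject_length >= min_subject_coverage
}

#' Assign a gene to knowledgebase protein clusters
#'
#' Cluster C is assigned iff (a) the gene has significant similarity to at
#' least `big_cluster_min` members of C, or (b) C has fewer than
#' `big_cluster_min` members and every member is hit, or (c) the hit genes'
#' cluster memberships name only C.
#'
#' @param sig_gene_ids character vector of significantly similar
#'   knowledgebase gene ids.
#' @param kb a [knowledge_base()].
#' @param big_cluster_min the big-cluster membership threshold (default 100).
#' @return character vector of assigned cluster ids (possibly empty).
#' @export
assign_clusters <- function(sig_gene_ids, kb, big_cluster_min = 100L) {
  if (!length(sig_gene_ids)) return(character())
  sig_gene_ids <- unique(sig_gene_ids)
  touched <- unique(unlist(kb$genes[sig_gene_ids, "cluster_ids"]))
  if (!length(touched)) return(character())
  assigned <- character()
  for (cid in touched) {
    members <- kb$clusters[[cid, "member_ids"]]
    n_hit <- sum(members %in% sig_gene_ids)
    m <- length(members)
    if ((m >= big_cluster_min && n_hit >= big_cluster_min) ||
        (m < big_cluster_min && n_hit == m)) {
      assigned <- c(assigned, cid)
    }
  }
  if (!length(assigned) && length(touched) == 1L) assigned <- touched
  sort(unique(assigned))
}

#' Is a gene conserved across organisms?
#'
#' TRUE iff any assigned cluster has more than 50 members drawn from at
#' least 2 phyla, or the gene has significant similarity to more than 50
#' knowledgebase genes.
#'
#' @param sig_gene_ids significant knowledgebase gene ids.
#' @param assigned_cluster_ids cluster ids from [assign_clusters()].
#' @param kb a [knowledge_base()].
#' @param min_cluster_members strict bound on cluster size (default 50).
#' @param min_homologs strict bound on homolog count (default 50).
#' @return logical flag.
#' @export
is_conserved <- function(sig_gene_ids, assigned_cluster_ids, kb,
                         min_cluster_members = 50L, min_homologs = 50L) {
  if (length(unique(sig_gene_ids)) > min_homologs) return(TRUE)
  for (cid in assigned_cluster_ids) {
    if (kb$clusters[cid, "member_count"] > min_cluster_members &&
        length(kb$clusters[[cid, "phyla"]]) >= 2L) {
      return(TRUE)
    }
  }
  FALSE
}

#' Phenotypes associated with a gene
#'
#' Union of the phenotype flags over the significantly similar genes and
#' over all members of the assigned clusters.
#'
#' @inheritParams is_conserved
#' @return character vector, subset of `antibiotic_resistance`,
#'   `antibiotic_sensitivity`, `essential`.
#' @export
phenotype_associations <- function(sig_gene_ids, assigned_cluster_ids, kb) {
  ids <- unique(c(sig_gene_ids,
                  unlist(kb$clusters[assigned_cluster_ids, "member_ids"])))
  if (!length(ids)) return(character())
  sort(unique(unlist(kb$genes[ids, "phenotype_flags"])))
}

#' Assign a support level and evidence summary to one missed gene
#'
#' Strong: conserved, or significant similarity to a gene carrying any
#' evidence flag (experimental function, 3D structure, purified protein,
#' protein domain, EC number). Fair (when not strong): an assigned cluster
#' with a computational prediction, an assigned cluster with 5 or more
#' members, or 10-50 significant homologs. Otherwise weak for named calls,
#' insufficient for hypothetical calls. `strong_reasons` lists every
#' triggering criterion.
#'
#' @param category `"named"` or `"hypothetical"`.
#' @param sig_gene_ids significant knowledgebase gene ids.
#' @param assigned_cluster_ids from [assign_clusters()].
#' @param kb a [knowledge_base()].
#' @param cluster_evidence_triggers_strong if TRUE, evidence flags on
#'   members of assigned clusters also trigger strong (default FALSE:
#'   direct similarity only).
#' @param fair_min_cluster_members,fair_homolog_range fair-level bounds
#'   (defaults 5 and c(10, 50), all inclusive).
#' @return list with `support` and `strong_reasons`.
#' @export
assign_support_level <- function(category, sig_gene_ids, assigned_cluster_ids,
                                 kb, cluster_evidence_triggers_strong = FALSE,
                                 fair_min_cluster_members = 5L,
                                 fair_homolog_range = c(10L, 50L)) {
  sig_gene_ids <- unique(sig_gene_ids)
  reasons <- character()
  if (length(assigned_cluster_ids) &&
      is_conserved(character(), assigned_cluster_ids, kb)) {
    reasons <- c(reasons, "conserved_cluster")
  }
  if (length(sig_gene_ids) > 50L) {
    reasons <- c(reasons, "conserved_many_homologs")
  }
  evidence_pool <- sig_gene_ids
  if (cluster_evidence_triggers_strong && length(assigned_cluster_ids)) {
    evidence_pool <- unique(c(
      evidence_pool,
      unlist(kb$clusters[assigned_cluster_ids, "member_ids"])))
  }
  if (length(evidence_pool)) {
    flags <- unique(unlist(kb$genes[evidence_pool, "evidence_flags"]))
    reasons <- c(reasons, intersect(EVIDENCE_FLAGS, flags))
  }
  if (length(reasons)) {
    return(list(support = "strong", strong_reasons = reasons))
  }
  fair <- FALSE
  if (length(assigned_cluster_ids)) {
    cl <- kb$clusters[assigned_cluster_ids, , drop = FALSE]
    fair <- any(cl$has_computational_prediction) ||
      any(cl$member_count >= fair_min_cluster_members)
  }
  n_sig <- length(sig_gene_ids)
  fair <- fair || (n_sig >= fair_homolog_range[1] &&
                   n_sig <= fair_homolog_range[2])
  if (fair) return(list(support = "fair", strong_reasons = character()))
  list(support = if (category == "named") "weak" else "insufficient",
       strong_reasons = character())
}

#' Drug-target flag
#'
#' TRUE iff the genome's organism matches the pathogen list (case-insensitive
#' genus + species, i.e. the first two whitespace tokens), some assigned
#' cluster has at least `min_cluster_members` members, and some
#' significantly similar knowledgebase gene carries the `essential`
#' phenotype.
#'
#' @param organism organism string of the host genome.
#' @param pathogen_species character vector of pathogen species names.
#' @inheritParams is_conserved
#' @param min_cluster_members inclusive cluster-size bound (default 50).
#' @return logical flag.
#' @export
drug_target_flag <- function(organism, pathogen_species, sig_gene_ids,
                             assigned_cluster_ids, kb,
                             min_cluster_members = 50L) {
  first_two <- function(x) {
    toks <- strsplit(trimws(tolower(x)), "\\s+")[[1]]
    paste(toks[seq_len(min(2L, length(toks)))], collapse = " ")
  }
  if (!length(pathogen_species)) return(FALSE)
  is_pathogen <- first_two(organism) %in%
    vapply(pathogen_species, first_two, character(1))
  if (!is_pathogen || !length(assigned_cluster_ids)) return(FALSE)
  big <- any(kb$clusters[assigned_cluster_ids, "member_count"] >=
               min_cluster_members)
  if (!big || !length(sig_gene_ids)) return(FALSE)
  any(vapply(kb$genes[unique(sig_gene_ids), "phenotype_flags"],
             function(f) "essential" %in% f, logical(1)))
}

#' Run the evidence-aggregation engine over classified missed genes
#'
#' For every named or hypothetical missed gene, computes its significant
#' knowledgebase homologs, assigned clusters, support level, phenotype set
#' and drug-target flag.
#'
#' @param calls data.frame from [classify_candidates()].
#' @param kb_hits data.frame from [read_blast_tab()] of alignments against
#'   knowledgebase genes (`query_id` matches `pred_id`, `subject_id` is a
#'   knowledgebase gene id).
#' @param kb a [knowledge_base()].
#' @param organism organism string of the host genome (for drug targets).
#' @param pathogen_species pathogen list (empty disables drug-target calls).
#' @param max_evalue,min_subject_coverage significance bounds, see
#'   [significant_similarity()].
#' @param big_cluster_min see [assign_clusters()].
#' @param cluster_evidence_triggers_strong see [assign_support_level()].
#' @param drug_target_min_cluster see [drug_target_flag()].
#' @return data.frame: `pred_id`, `category`, `support`, `strong_reasons`,
#'   `n_significant`, `significant_gene_ids`, `assigned_cluster_ids`,
#'   `phenotypes` (semicolon-joined), `drug_target`.
#' @export
comblast_assign <- function(calls, kb_hits, kb, organism = "",
                            pathogen_species = character(),
                            max_evalue = 1e-5, min_subject_coverage = 0.8,
                            big_cluster_min = 100L,
                            cluster_evidence_triggers_strong = FALSE,
                            drug_target_min_cluster = 50L) {
  calls <- calls[calls$category %in% c("named", "hypothetical"), ,
                 drop = FALSE]
  if (nrow(kb_hits)) {
    unknown <- setdiff(unique(kb_hits$subject_id), kb$genes$gene_id)
    if (length(unknown)) {
      warning("ignoring hits to genes absent from the knowledgebase: ",
              paste(utils::head(unknown, 5), collapse = ", "))
      kb_hits <- kb_hits[!kb_hits$subject_id %in% unknown, , drop = FALSE]
    }
    kb_hits <- kb_hits[significant_similarity(kb_hits, max_evalue,
                                              min_subject_coverage), ,
                       drop = FALSE]
    sig_by_query <- lapply(split(kb_hits$subject_id, kb_hits$query_id),
                           unique)
  } else {
    sig_by_query <- list()
  }
  out <- vector("list", nrow(calls))
  for (i in seq_len(nrow(calls))) {
    sig <- sig_by_query[[calls$pred_id[i]]]
    if (is.null(sig)) sig <- character()
    cl <- assign_clusters(sig, kb, big_cluster_min)
    lvl <- assign_support_level(calls$category[i], sig, cl, kb,
                                cluster_evidence_triggers_strong)
    ph <- phenotype_associations(sig, cl, kb)
    dt <- drug_target_flag(organism, pathogen_species, sig, cl, kb,
                           drug_target_min_cluster)
    out[[i]] <- data.frame(
      pred_id = calls$pred_id[i], category = calls$category[i],
      support = lvl$support,
      strong_reasons = paste(lvl$strong_reasons, collapse = ";"),
      n_significant = length(sig),
      significant_gene_ids = paste(sort(sig), collapse = ";"),
      assigned_cluster_ids = paste(cl, collapse = ";"),
      phenotypes = paste(ph, collapse = ";"),
      drug_target = dt, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(pred_id = character(), category = character(),
                      support = character(), strong_reasons = character(),
                      n_significant = integer(),
                      significant_gene_ids = character(),
                      assigned_cluster_ids = character(),
                      phenotypes = character(), drug_target = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
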