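test_that("significant similarity: E strictly below 1e-5, coverage inclusive", {
  expect_true(significant_similarity(blast_row("q", "g", 1e-9, 90, 100)))
  expect_false(significant_similarity(blast_row("q", "g", 1e-5, 100, 100)))
  expect_true(significant_similarity(blast_row("q", "g", 9.9e-6, 80, 100)))
  expect_false(significant_similarity(blast_row("q", "g", 1e-9, 79, 100)))
})

test_that("cluster assignment rules: big, small-complete, only-one-cluster", {
  # 213 significant homologs inside a 218-member cluster -> assigned
  kb <- plain_kb(218, "big", phyla = c("P1", "P2", "P3", "P4", "P5", "P6"))
  expect_identical(assign_clusters(sprintf("G%04d", 1:213), kb), "big")

  # small cluster: all 10 members required
  kb <- plain_kb(10, "small")
  expect_identical(assign_clusters(sprintf("G%04d", 1:10), kb), "small")
  # 3 of 10 members hit, but it is the only cluster touched -> assigned
  expect_identical(assign_clusters(sprintf("G%04d", 1:3), kb), "small")

  # 50 of 120 members of a big cluster, plus hits in a second cluster:
  # the big cluster is NOT assigned, the completed small one is
  ids_big <- sprintf("B%04d", 1:120)
  ids_small <- sprintf("S%04d", 1:4)
  kb <- build_kb(
    c(lapply(ids_big, function(i) list(id = i, clusters = "cbig")),
      lapply(ids_small, function(i) list(id = i, clusters = "csmall"))),
    list(list(id = "cbig", members = ids_big),
         list(id = "csmall", members = ids_small)))
  got <- assign_clusters(c(ids_big[1:50], ids_small), kb)
  expect_identical(got, "csmall")
  # with 100 of the big cluster's members hit, both are assigned
  got <- assign_clusters(c(ids_big[1:100], ids_small), kb)
  expect_setequal(got, c("cbig", "csmall"))
})

test_that("conservation boundaries: > 50 homologs, > 50-member 2-phyla cluster", {
  kb <- plain_kb(60)
  expect_true(is_conserved(sprintf("G%04d", 1:51), character(), kb))
  expect_false(is_conserved(sprintf("G%04d", 1:50), character(), kb))

  # 218-member 6-phyla cluster counts as conserved
  kb6 <- plain_kb(218, "c", phyla = paste0("P", 1:6))
  expect_true(is_conserved(character(), "c", kb6))
  # 50-member single-phylum cluster does not (needs > 50 and >= 2 phyla)
  kb50 <- plain_kb(50, "c")
  expect_false(is_conserved(character(), "c", kb50))
  # 51 members but one phylum: still not conserved via the cluster path
  kb51 <- plain_kb(51, "c")
  expect_false(is_conserved(character(), "c", kb51))
  # 51 members, two phyla: conserved
  kb51b <- plain_kb(51, "c", phyla = c("P1", "P2"))
  expect_true(is_conserved(character(), "c", kb51b))
})

test_that("support levels: strong via evidence, fair rules, weak/insufficient", {
  # similarity to a gene with a known 3D structure -> strong
  kb <- build_kb(list(list(id = "g1", evidence = "structure_3d")))
  lvl <- assign_support_level("hypothetical", "g1", character(), kb)
  expect_identical(lvl$support, "strong")
  expect_identical(lvl$strong_reasons, "structure_3d")

  # named call, 3 homologs, no clusters, no evidence -> weak
  kb <- plain_kb(3)
  lvl <- assign_support_level("named", sprintf("G%04d", 1:3), character(), kb)
  expect_identical(lvl$support, "weak")
  # same evidence picture on a hypothetical call -> insufficient
  lvl <- assign_support_level("hypothetical", sprintf("G%04d", 1:3),
                              character(), kb)
  expect_identical(lvl$support, "insufficient")

  # 10-50 homologs -> fair (both ends inclusive)
  kb <- plain_kb(60)
  for (n in c(10L, 12L, 50L)) {
    lvl <- assign_support_level("hypothetical", sprintf("G%04d", 1:n),
                                character(), kb)
    expect_identical(lvl$support, "fair")
  }
  lvl <- assign_support_level("hypothetical", sprintf("G%04d", 1:9),
                              character(), kb)
  expect_identical(lvl$support, "insufficient")
  # 51 homologs crosses into conserved -> strong
  lvl <- assign_support_level("named", sprintf("G%04d", 1:51), character(), kb)
  expect_identical(lvl$support, "strong")
  expect_identical(lvl$strong_reasons, "conserved_many_homologs")

  # assigned cluster with >= 5 members -> fair
  kb5 <- plain_kb(5, "c")
  lvl <- assign_support_level("named", sprintf("G%04d", 1:5), "c", kb5)
  expect_identical(lvl$support, "fair")
  # 4-member cluster without a computational prediction stays weak
  kb4 <- plain_kb(4, "c")
  lvl <- assign_support_level("named", sprintf("G%04d", 1:4), "c", kb4)
  expect_identical(lvl$support, "weak")
  # ... but with a computational prediction it is fair
  kb4p <- plain_kb(4, "c", prediction = TRUE)
  lvl <- assign_support_level("named", sprintf("G%04d", 1:4), "c", kb4p)
  expect_identical(lvl$support, "fair")
})

test_that("cluster-member evidence triggers strong only when enabled", {
  # cluster with an experimentally validated member; the directly similar
  # genes carry no evidence themselves
  ids <- sprintf("G%04d", 1:6)
  kb <- build_kb(
    lapply(seq_along(ids), function(i)
      list(id = ids[i],
           evidence = if (i == 6L) "experimental_function" else NULL,
           clusters = "c")),
    list(list(id = "c", members = ids)))
  sig <- ids[1:5]
  off <- assign_support_level("hypothetical", sig, "c", kb,
                              cluster_evidence_triggers_strong = FALSE)
  expect_identical(off$support, "fair")   # 6-member cluster
  on <- assign_support_level("hypothetical", sig, "c", kb,
                             cluster_evidence_triggers_strong = TRUE)
  expect_identical(on$support, "strong")
  expect_identical(on$strong_reasons, "experimental_function")
})

test_that("phenotypes pool over significant genes and whole assigned clusters", {
  ids <- sprintf("G%04d", 1:6)
  kb <- build_kb(
    lapply(seq_along(ids), function(i)
      list(id = ids[i],
           phenotype = if (i == 1L) "antibiotic_resistance" else
             if (i == 6L) "essential" else NULL,
           clusters = "c")),
    list(list(id = "c", members = ids)))
  # direct similarity to the resistant gene only
  expect_identical(phenotype_associations("G0001", character(), kb),
                   "antibiotic_resistance")
  # assigned cluster contributes the essential member even if not hit
  expect_setequal(phenotype_associations("G0001", "c", kb),
                  c("antibiotic_resistance", "essential"))
  # no flags anywhere -> empty
  expect_identical(phenotype_associations("G0002", character(), kb),
                   character())
})

test_that("drug-target conjunction and its boundaries", {
  make_dt_kb <- function(n_members) {
    ids <- sprintf("G%04d", seq_len(n_members))
    build_kb(
      lapply(seq_along(ids), function(i)
        list(id = ids[i], phenotype = if (i == 1L) "essential" else NULL,
             clusters = "c")),
      list(list(id = "c", members = ids)))
  }
  pathogens <- c("Yersinia pestis", "Escherichia coli")
  kb60 <- make_dt_kb(60)
  expect_true(drug_target_flag("Yersinia pestis Z176003", pathogens,
                               "G0001", "c", kb60))
  # criterion i: non-pathogen host fails
  expect_false(drug_target_flag("Bacillus subtilis 168", pathogens,
                                "G0001", "c", kb60))
  # criterion ii boundary: 49-member cluster fails, 50 passes
  kb49 <- make_dt_kb(49)
  expect_false(drug_target_flag("Yersinia pestis X", pathogens,
                                "G0001", "c", kb49))
  kb50 <- make_dt_kb(50)
  expect_true(drug_target_flag("Yersinia pestis X", pathogens,
                               "G0001", "c", kb50))
  # criterion iii: no essential similarity fails
  expect_false(drug_target_flag("Yersinia pestis X", pathogens,
                                "G0002", "c", kb60))
  # matching is case-insensitive on genus + species
  expect_true(drug_target_flag("YERSINIA PESTIS biovar X", pathogens,
                               "G0001", "c", kb60))
})

test_that("support levels partition calls; named never insufficient and vice versa", {
  set.seed(51)
  kb <- plain_kb(80, "c", phyla = c("P1", "P2"))
  calls <- data.frame(
    accession = "A", pred_id = sprintf("q%03d", 1:40),
    length_bp = 300L,
    category = sample(c("named", "hypothetical"), 40, replace = TRUE),
    best_hit_id = "", best_evalue = 1e-10, best_subject_coverage = 0.9,
    n_passing_hits = 1L, stringsAsFactors = FALSE)
  m <- 400L
  kb_hits <- blast_row(sample(calls$pred_id, m, replace = TRUE),
                       sample(sprintf("G%04d", 1:80), m, replace = TRUE),
                       10^runif(m, -30, -3),
                       sample(70:100, m, replace = TRUE), 100)
  asg <- comblast_assign(calls, kb_hits, kb)
  expect_setequal(asg$pred_id, calls$pred_id)
  expect_true(all(asg$support %in% c("strong", "fair", "weak",
                                     "insufficient")))
  expect_false(any(asg$support == "insufficient" & asg$category == "named"))
  expect_false(any(asg$support == "weak" & asg$category == "hypothetical"))
  # strong <=> nonempty strong_reasons
  expect_identical(asg$support == "strong", nzchar(asg$strong_reasons))
})

test_that("tightening the significance threshold never promotes support", {
  set.seed(52)
  rank_of <- c(insufficient = 1, weak = 1, fair = 2, strong = 3)
  kb <- plain_kb(80, "c", phyla = c("P1", "P2"))
  calls <- data.frame(
    accession = "A", pred_id = sprintf("q%03d", 1:30), length_bp = 300L,
    category = "hypothetical", best_hit_id = "", best_evalue = 1e-10,
    best_subject_coverage = 0.9, n_passing_hits = 1L,
    stringsAsFactors = FALSE)
  m <- 500L
  kb_hits <- blast_row(sample(calls$pred_id, m, replace = TRUE),
                       sample(sprintf("G%04d", 1:80), m, replace = TRUE),
                       10^runif(m, -12, -3),
                       sample(75:100, m, replace = TRUE), 100)
  loose <- comblast_assign(calls, kb_hits, kb, max_evalue = 1e-5)
  tight <- comblast_assign(calls, kb_hits, kb, max_evalue = 1e-8)
  for (q in calls$pred_id) {
    expect_lte(rank_of[[tight$support[tight$pred_id == q]]],
               rank_of[[loose$support[loose$pred_id == q]]])
  }
})

test_that("with a stripped knowledgebase, < 10 homologs fall through", {
  # evidence/phenotype flags cleared, all clusters below 5 members
  kb <- plain_kb(4, "c")
  for (cat in c("named", "hypothetical")) {
    lvl <- assign_support_level(cat, sprintf("G%04d", 1:4), "c", kb)
    expect_identical(lvl$support, if (cat == "named") "weak" else
      "insufficient")
  }
})
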