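test_that("3' end conventions and 5'-shift invariance", {
  expect_identical(three_prime_end(99L, 201L, "+"), 200L)
  expect_identical(three_prime_end(180L, 300L, "-"), 180L)
  # moving only the 5' coordinate never changes the 3' end
  set.seed(31)
  for (i in 1:50) {
    s <- sample.int(1000, 1); e <- s + sample(110:500, 1)
    expect_identical(three_prime_end(s + 3L, e, "+"),
                     three_prime_end(s, e, "+"))
    expect_identical(three_prime_end(s, e - 3L, "-"),
                     three_prime_end(s, e, "-"))
  }
})

test_that("3' presence rule: shared end, same strand, non-pseudo CDS only", {
  cds <- function(s, e, st, pseudo = FALSE, kind = "CDS") {
    data.frame(kind = kind, start = s, end = e, strand = st,
               is_pseudo = pseudo, product = "", locus_id = "x",
               stringsAsFactors = FALSE)
  }
  pred <- data.frame(start = 99L, end = 201L, strand = "+")
  expect_true(is_annotated(pred, cds(150L, 201L, "+")))   # 5' differs, 3' shared
  expect_false(is_annotated(pred, cds(99L, 201L, "-")))   # opposite strand
  expect_false(is_annotated(pred, cds(150L, 201L, "+", pseudo = TRUE)))
  expect_false(is_annotated(pred, cds(150L, 201L, "+", kind = "rRNA")))
  expect_false(is_annotated(pred, cds(99L, 200L, "+")))   # 3' off by one
})

test_that("3'-matching agrees with brute-force all-pairs comparison", {
  set.seed(32)
  for (rep in 1:10) {
    feats <- random_features(30, 400L)  # dense: frequent shared ends
    preds <- random_predictions(100, 400L)
    for (i in seq_len(nrow(preds))) {
      expect_identical(is_annotated(preds[i, ], feats),
                       oracle_is_annotated(preds[i, ], feats))
    }
  }
})

test_that("overlap fraction matches the per-base oracle", {
  expect_identical(overlap_fraction(0L, 100L, 0L, 100L), 1)    # identity
  expect_identical(overlap_fraction(0L, 100L, 200L, 300L), 0)  # disjoint
  expect_identical(overlap_fraction(0L, 100L, 50L, 200L), 0.5)
  set.seed(33)
  for (i in 1:200) {
    ps <- sample.int(500, 1) - 1L; pe <- ps + sample(10:100, 1)
    fs <- sample.int(500, 1) - 1L; fe <- fs + sample(10:100, 1)
    expect_equal(overlap_fraction(ps, pe, fs, fe),
                 oracle_overlap_fraction(ps, pe, fs, fe))
  }
})

test_that("candidate detection partitions predictions with correct statuses", {
  feats <- data.frame(
    kind = c("CDS", "CDS", "CDS", "tRNA", "CDS"),
    start = c(100L, 400L, 700L, 1000L, 1300L),
    end = c(280L, 580L, 880L, 1120L, 1480L),
    strand = c("+", "-", "+", "+", "+"),
    is_pseudo = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    product = "", locus_id = sprintf("F%d", 1:5), stringsAsFactors = FALSE)
  preds <- data.frame(
    pred_id = sprintf("orf%05d", 1:5),
    start = c(130L, 400L, 700L, 1000L, 2000L),
    end = c(280L, 580L, 880L, 1120L, 2150L),
    strand = c("+", "-", "+", "+", "+"),
    length_bp = 0L, score = 1, genetic_code = 11L, stringsAsFactors = FALSE)
  out <- detect_candidates(preds, feats, "ACC")
  # 3 share a CDS 3' end, 1 covers a tRNA fully, 1 is clean
  expect_identical(out$status, c("annotated", "annotated", "annotated",
                                 "excluded_overlap", "candidate"))
  expect_identical(out$overlapping_feature_id[4], "F4")
  expect_identical(out$overlapping_feature_id[5], "")
  # exactly one status each
  expect_true(all(out$status %in% c("annotated", "excluded_overlap",
                                    "candidate")))
})

test_that("overlap of exactly 50% with a pseudo-CDS is retained (strict >)", {
  feats <- data.frame(kind = "CDS", start = 0L, end = 100L, strand = "+",
                      is_pseudo = TRUE, product = "", locus_id = "P",
                      stringsAsFactors = FALSE)
  pred <- data.frame(pred_id = "orf00001", start = 50L, end = 150L,
                     strand = "+", length_bp = 100L, score = 1,
                     genetic_code = 11L, stringsAsFactors = FALSE)
  out <- detect_candidates(pred, feats)
  expect_identical(out$status, "candidate")         # exactly 0.5 stays
  pred$start <- 49L                                  # 51/101 > 0.5
  out <- detect_candidates(pred, feats)
  expect_identical(out$status, "excluded_overlap")
})

test_that("annotation check takes precedence over overlap exclusion", {
  feats <- data.frame(
    kind = c("CDS", "rRNA"), start = c(0L, 0L), end = c(120L, 120L),
    strand = c("+", "+"), is_pseudo = FALSE, product = "",
    locus_id = c("C", "R"), stringsAsFactors = FALSE)
  pred <- data.frame(pred_id = "o1", start = 0L, end = 120L, strand = "+",
                     length_bp = 120L, score = 1, genetic_code = 11L,
                     stringsAsFactors = FALSE)
  expect_identical(detect_candidates(pred, feats)$status, "annotated")
})

test_that("non-pseudo CDS overlap without 3' match never excludes", {
  feats <- data.frame(kind = "CDS", start = 0L, end = 300L, strand = "+",
                      is_pseudo = FALSE, product = "", locus_id = "C",
                      stringsAsFactors = FALSE)
  pred <- data.frame(pred_id = "o1", start = 50L, end = 250L, strand = "+",
                     length_bp = 200L, score = 1, genetic_code = 11L,
                     stringsAsFactors = FALSE)
  expect_identical(detect_candidates(pred, feats)$status, "candidate")
})

test_that("empty prediction list yields empty output", {
  out <- detect_candidates(random_predictions(0), random_features(3))
  expect_identical(nrow(out), 0L)
})

test_that("removing a CDS never shrinks the candidate set", {
  set.seed(34)
  for (rep in 1:10) {
    feats <- random_features(15, 600L)
    preds <- random_predictions(40, 600L)
    full <- detect_candidates(preds, feats)
    cds_rows <- which(feats$kind == "CDS" & !feats$is_pseudo)
    if (!length(cds_rows)) next
    reduced <- detect_candidates(preds, feats[-cds_rows[1], , drop = FALSE])
    full_c <- full$pred_id[full$status == "candidate"]
    red_c <- reduced$pred_id[reduced$status == "candidate"]
    expect_true(all(full_c %in% red_c))
  }
})
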