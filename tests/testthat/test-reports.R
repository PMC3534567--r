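test_that("per-center derived columns recompute from raw totals", {
  totals <- data.frame(
    center = c("JGI", "TIGR", "JCVI", "Sanger", "Others", "Total"),
    chromosomes = c(563L, 95L, 68L, 67L, 781L, 1574L),
    named_missed = c(1463L, 852L, 190L, 892L, 10205L, 13602L),
    annotated_genes = c(1830805L, 254484L, 179284L, 205667L, 2105188L,
                        4575428L),
    total_mbp = c(2058.6, 273.9, 190.1, 227.7, 2276.6, 5026.9),
    stringsAsFactors = FALSE)
  out <- derive_center_stats(totals)
  expect_equal(out$missed_per_mbp, c(0.71, 3.11, 1.00, 3.92, 4.48, 2.71))
  expect_equal(out$pct_missed_vs_annotated,
               c(0.08, 0.33, 0.11, 0.43, 0.48, 0.30))
  expect_equal(out$avg_missed_per_chromosome,
               c(2.60, 8.97, 2.79, 13.31, 13.07, 8.64))
})

test_that("center statistics aggregate per-genome rows with Others and Total", {
  pg <- data.frame(
    accession = sprintf("A%02d", 1:6),
    center = c("JGI", "JGI", "TIGR", "LabX", "LabY", "LabX"),
    named_missed = c(2L, 4L, 6L, 10L, 0L, 8L),
    annotated_genes = c(2000L, 3000L, 2500L, 1500L, 1000L, 1200L),
    length_bp = c(2e6, 3e6, 2.5e6, 1.5e6, 1e6, 1.2e6),
    stringsAsFactors = FALSE)
  out <- center_statistics(pg)
  expect_identical(out$center, c("JGI", "TIGR", "Others", "Total"))
  jgi <- out[out$center == "JGI", ]
  expect_identical(jgi$chromosomes, 2L)
  expect_equal(jgi$missed_per_mbp, round(6 / 5, 2))
  expect_equal(jgi$avg_missed_per_chromosome, 3)
  oth <- out[out$center == "Others", ]
  expect_identical(oth$named_missed, 18L)
  expect_equal(oth$pct_missed_vs_annotated, round(100 * 18 / 3700, 2))
  tot <- out[out$center == "Total", ]
  expect_identical(tot$chromosomes, 6L)
  expect_equal(tot$missed_per_mbp, round(30 / 11.2, 2))
  # a center with zero missed genes reports clean zeros
  pg0 <- pg
  pg0$named_missed <- 0L
  out0 <- center_statistics(pg0)
  expect_true(all(out0$missed_per_mbp == 0))
  expect_true(all(out0$pct_missed_vs_annotated == 0))
})

test_that("rate percentiles: degenerate groups, uniform grid, random oracle", {
  one <- rate_percentiles(5.5, "g")
  expect_equal(unlist(one[, c("min", "p80", "p95", "max")]),
               c(min = 5.5, p80 = 5.5, p95 = 5.5, max = 5.5))
  grid <- rate_percentiles(0:100, rep("g", 101))
  expect_equal(grid$p80, 80)
  expect_equal(grid$p95, 95)
  set.seed(61)
  for (rep in 1:20) {
    v <- runif(sample(2:40, 1), 0, 120)
    out <- rate_percentiles(v, rep("g", length(v)))
    expect_equal(out$p80, oracle_percentile(v, 0.8))
    expect_equal(out$p95, oracle_percentile(v, 0.95))
    expect_equal(out$min, min(v))
    expect_equal(out$max, max(v))
  }
  # multiple groups are computed independently
  two <- rate_percentiles(c(1, 2, 3, 10, 20), c("a", "a", "a", "b", "b"))
  expect_identical(two$group, c("a", "b"))
  expect_equal(two$max, c(3, 20))
})

test_that("length histogram bins and short-gene count", {
  h <- length_histogram(c(110L, 299L, 300L))
  expect_identical(h$n_below_cutoff, 2L)   # strict <
  expect_identical(sum(h$histogram$count), 3L)
  expect_identical(length_histogram(integer())$histogram$count, integer())
  set.seed(62)
  lens <- sample(110:2000, 1000, replace = TRUE)
  h <- length_histogram(lens, bin_width_bp = 50L)
  oracle <- oracle_histogram(lens, 50L)
  expect_identical(sum(h$histogram$count), 1000L)
  for (i in seq_len(nrow(h$histogram))) {
    expect_identical(h$histogram$count[i],
                     oracle[[as.character(h$histogram$bin_start[i])]])
  }
  expect_identical(h$n_below_cutoff, sum(lens < 300L))
})

test_that("shortest annotated gene ignores pseudo CDS and non-CDS", {
  feats <- data.frame(
    kind = c("CDS", "CDS", "CDS", "tRNA", "CDS"),
    start = c(0L, 1000L, 2000L, 3000L, 4000L),
    end = c(300L, 1452L, 3200L, 3076L, 4108L),
    strand = "+", is_pseudo = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    product = "", locus_id = "", stringsAsFactors = FALSE)
  # pseudo 108 bp CDS and 76 bp tRNA do not count; min is 300
  expect_identical(shortest_annotated_length(feats), 300L)
  feats$is_pseudo[5] <- FALSE   # planted 108 bp CDS now counts
  expect_identical(shortest_annotated_length(feats), 108L)
  expect_true(is.na(shortest_annotated_length(
    feats[feats$kind == "tRNA", ])))
})

test_that("ranking by rate: top table, ties, high-rate threshold count", {
  pg <- data.frame(
    accession = sprintf("A%02d", 1:12),
    center = c(rep("JGI", 4), rep("LabX", 8)),
    named_missed = c(5L, 8L, 232L, 3L, 40L, 36L, 3L, 2L, 50L, 1L, 0L, 4L),
    length_bp = c(rep(4e6, 2), 2.154e6, 4e6, 2e6, 3e6, 4e6, 4e6, 2.5e6,
                  4e6, 4e6, 4e6),
    stringsAsFactors = FALSE)
  out <- rank_and_top(pg, n = 3)
  expect_identical(out$top$accession[1], "A03")     # 232/2.154 = 107.7
  expect_equal(out$top$missed_per_mbp[1], 107.7)
  # rates >= 10: A03 (107.7), A05 (20), A06 (12), A09 (20) -> 4, 3 minor
  expect_identical(out$n_high_rate, 4L)
  expect_identical(out$n_high_rate_minor, 3L)
  # all-equal rates order by accession
  pg$named_missed <- 8L
  pg$length_bp <- 4e6
  tied <- rank_and_top(pg, n = 12)
  expect_identical(tied$top$accession, sort(pg$accession))
})

test_that("annotation comparison: identity, forced 5' change, symmetry", {
  cds <- function(s, e, st = "+") {
    data.frame(kind = "CDS", start = s, end = e, strand = st,
               is_pseudo = FALSE, product = "", locus_id = "",
               stringsAsFactors = FALSE)
  }
  a <- rbind(cds(0L, 300L), cds(500L, 800L, "-"), cds(1000L, 1300L))
  expect_identical(
    compare_annotations(a, a),
    data.frame(n_a = 3L, n_b = 3L, unique_a = 0L, unique_b = 0L,
               common = 3L, five_prime_changes = 0L))
  # 5'-extend one gene in B: still common, one 5' change
  b <- a
  b$start[1] <- 30L
  cmp <- compare_annotations(a, b)
  expect_identical(cmp$common, 3L)
  expect_identical(cmp$five_prime_changes, 1L)
  # symmetry: unique counts swap, common and changes invariant
  b2 <- rbind(b[-2, ], cds(2000L, 2300L), cds(2500L, 2800L))
  ab <- compare_annotations(a, b2)
  ba <- compare_annotations(b2, a)
  expect_identical(ab$unique_a, ba$unique_b)
  expect_identical(ab$unique_b, ba$unique_a)
  expect_identical(ab$common, ba$common)
  expect_identical(ab$five_prime_changes, ba$five_prime_changes)
})

test_that("annotation comparison matches the brute-force matcher", {
  set.seed(63)
  for (rep in 1:20) {
    a <- random_features(25, 2000L, kinds = c("CDS", "tRNA"))
    # B: random edits of A - drop some, add some, shift some 5' ends
    keep <- sample(c(TRUE, FALSE), nrow(a), replace = TRUE, prob = c(.8, .2))
    b <- a[keep, , drop = FALSE]
    shift <- sample(seq_len(nrow(b)), max(1, nrow(b) %/% 4))
    for (j in shift) {
      if (b$strand[j] == "+" && b$end[j] - b$start[j] > 12L) {
        b$start[j] <- b$start[j] + 6L
      } else if (b$end[j] - b$start[j] > 12L) {
        b$end[j] <- b$end[j] - 6L
      }
    }
    b <- rbind(b, random_features(5, 2000L, kinds = "CDS"))
    got <- compare_annotations(a, b)
    want <- oracle_compare(a, b)
    expect_identical(as.list(got), want)
  }
})
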