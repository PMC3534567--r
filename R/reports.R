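## Annotation-quality reports: per-center statistics, missed-gene-rate
## percentiles, length histograms, top-rate genome tables, and comparison
## of two annotations of the same chromosome.

#' Derive per-center summary columns from raw totals
#'
#' Given raw per-center totals, computes the derived columns: average
#' missed genes per chromosome, percent missed vs annotated genes, and
#' missed genes per Mbp, each rounded to 2 decimals. Zero denominators
#' yield `NA` rather than an error.
#'
#' @param totals data.frame with columns `center`, `chromosomes`,
#'   `named_missed`, `annotated_genes`, `total_mbp`.
#' @return the input with columns `avg_missed_per_chromosome`,
#'   `pct_missed_vs_annotated`, `missed_per_mbp` appended.
#' @export
derive_center_stats <- function(totals) {
  safe <- function(num, den) ifelse(den > 0, round(num / den, 2), NA_real_)
  totals$avg_missed_per_chromosome <- safe(totals$named_missed,
                                           totals$chromosomes)
  totals$pct_missed_vs_annotated <- safe(100 * totals$named_missed,
                                         totals$annotated_genes)
  totals$missed_per_mbp <- safe(totals$named_missed, totals$total_mbp)
  totals
}

#' Per-center named-missed-gene statistics
#'
#' Aggregates per-chromosome results by annotation center. Centers outside
#' `major_centers` are pooled into an `Others` bucket, and a `Total` row is
#' appended.
#'
#' @param per_genome data.frame with columns `accession`, `center`,
#'   `named_missed`, `annotated_genes`, `length_bp`.
#' @param major_centers centers reported individually (default JGI, TIGR,
#'   JCVI, Sanger).
#' @return data.frame of [derive_center_stats()] rows, one per major
#'   center present, plus `Others` and `Total`.
#' @export
center_statistics <- function(per_genome,
                              major_centers = c("JGI", "TIGR", "JCVI",
                                                "Sanger")) {
  stopifnot(nrow(per_genome) > 0)
  grp <- ifelse(per_genome$center %in% major_centers, per_genome$center,
                "Others")
  agg <- function(sel, label) {
    data.frame(center = label, chromosomes = sum(sel),
               named_missed = sum(per_genome$named_missed[sel]),
               annotated_genes = sum(per_genome$annotated_genes[sel]),
               total_mbp = sum(per_genome$length_bp[sel]) / 1e6,
               stringsAsFactors = FALSE)
  }
  labels <- c(intersect(major_centers, unique(grp)),
              if ("Others" %in% grp) "Others")
  rows <- lapply(labels, function(l) agg(grp == l, l))
  rows <- c(rows, list(agg(rep(TRUE, nrow(per_genome)), "Total")))
  derive_center_stats(do.call(rbind, rows))
}

#' Missed-gene-rate percentiles per center
#'
#' For each group, reports the minimum, 80th and 95th percentiles, and
#' maximum of the per-chromosome missed-gene rates. Percentiles use linear
#' interpolation between closest order statistics
#' (`stats::quantile(type = 7)`).
#'
#' @param rates numeric vector of per-chromosome rates.
#' @param group character vector of group labels (same length).
#' @return data.frame: `group`, `n`, `min`, `p80`, `p95`, `max`.
#' @export
rate_percentiles <- function(rates, group) {
  stopifnot(length(rates) == length(group), length(rates) > 0)
  do.call(rbind, lapply(split(rates, group), function(v) {
    q <- stats::quantile(v, c(0.8, 0.95), type = 7, names = FALSE)
    data.frame(group = NA_character_, n = length(v), min = min(v),
               p80 = q[1], p95 = q[2], max = max(v),
               stringsAsFactors = FALSE)
  })) -> out
  out$group <- names(split(rates, group))
  rownames(out) <- NULL
  out[, c("group", "n", "min", "p80", "p95", "max")]
}

#' Length histogram of missed genes
#'
#' Bins gene lengths into `[k*w, (k+1)*w)` intervals and reports the count
#' and fraction of genes strictly shorter than `short_cutoff_bp`.
#'
#' @param lengths_bp integer vector of gene lengths.
#' @param bin_width_bp bin width (default 50).
#' @param short_cutoff_bp cutoff for the "short gene" tally (default 300,
#'   strict `<`).
#' @return list with `histogram` (data.frame `bin_start`, `bin_end`,
#'   `count`), `n_below_cutoff`, `frac_below_cutoff`.
#' @export
length_histogram <- function(lengths_bp, bin_width_bp = 50L,
                             short_cutoff_bp = 300L) {
  if (!length(lengths_bp)) {
    return(list(histogram = data.frame(bin_start = integer(),
                                       bin_end = integer(),
                                       count = integer()),
                n_below_cutoff = 0L, frac_below_cutoff = NA_real_))
  }
  k <- lengths_bp %/% bin_width_bp
  tab <- table(k)
  bins <- as.integer(names(tab))
  hist <- data.frame(bin_start = bins * bin_width_bp,
                     bin_end = (bins + 1L) * bin_width_bp,
                     count = as.integer(tab))
  n_short <- sum(lengths_bp < short_cutoff_bp)
  list(histogram = hist, n_below_cutoff = n_short,
       frac_below_cutoff = n_short / length(lengths_bp))
}

#' Shortest annotated gene
#'
#' Minimum length (bp) over the non-pseudo CDS features of a chromosome;
#' `NA` when the annotation has none.
#'
#' @param features feature data.frame.
#' @return integer length or `NA`.
#' @export
shortest_annotated_length <- function(features) {
  cds <- features[features$kind == "CDS" & !features$is_pseudo, ,
                  drop = FALSE]
  if (!nrow(cds)) return(NA_integer_)
  min(cds$end - cds$start)
}

#' Rank chromosomes by missed-gene rate
#'
#' Sorts chromosomes by named missed genes per Mbp (descending; ties broken
#' by accession) and returns the top `n` together with the count of
#' chromosomes at or above `high_rate` missed genes per Mbp and how many of
#' those were annotated outside the major centers.
#'
#' @param per_genome data.frame with columns `accession`, `center`,
#'   `named_missed`, `length_bp`, `pct_short` (percent of missed genes at
#'   most 300 bp) and `shortest_annotated` (optional columns are carried
#'   through).
#' @param n number of rows in the top table (default 10).
#' @param high_rate threshold rate (default 10 per Mbp, inclusive).
#' @param major_centers see [center_statistics()].
#' @return list with `top` (ranked data.frame with `mbp` and
#'   `missed_per_mbp` columns added), `n_high_rate`, `n_high_rate_minor`.
#' @export
rank_and_top <- function(per_genome, n = 10L, high_rate = 10,
                         major_centers = c("JGI", "TIGR", "JCVI",
                                           "Sanger")) {
  pg <- per_genome
  pg$mbp <- pg$length_bp / 1e6
  pg$missed_per_mbp <- round(pg$named_missed / pg$mbp, 1)
  ord <- order(-pg$missed_per_mbp, pg$accession)
  pg <- pg[ord, , drop = FALSE]
  rownames(pg) <- NULL
  high <- pg$missed_per_mbp >= high_rate
  list(top = utils::head(pg, n),
       n_high_rate = sum(high),
       n_high_rate_minor = sum(high & !pg$center %in% major_centers))
}

#' Compare two annotations of one chromosome
#'
#' Genes (non-pseudo CDS) are matched by strand-aware 3' end. Duplicate
#' (strand, 3' end) keys within one annotation are collapsed to the longest
#' gene (ties: smallest start) before matching. Unique counts are the
#' unmatched keys on each side; `five_prime_changes` counts matched pairs
#' whose 5' coordinates differ.
#'
#' @param features_a,features_b feature data.frames from the same
#'   chromosome sequence.
#' @return data.frame: `n_a`, `n_b`, `unique_a`, `unique_b`, `common`,
#'   `five_prime_changes`.
#' @export
compare_annotations <- function(features_a, features_b) {
  keyed <- function(f) {
    cds <- f[f$kind == "CDS" & !f$is_pseudo, , drop = FALSE]
    if (!nrow(cds)) {
      return(data.frame(key = character(), five = integer(),
                        stringsAsFactors = FALSE))
    }
    key <- paste(cds$strand, three_prime_end(cds$start, cds$end, cds$strand))
    five <- ifelse(cds$strand == "+", cds$start, cds$end - 1L)
    len <- cds$end - cds$start
    ord <- order(key, -len, cds$start)
    d <- data.frame(key = key[ord], five = five[ord],
                    stringsAsFactors = FALSE)
    d[!duplicated(d$key), , drop = FALSE]
  }
  a <- keyed(features_a)
  b <- keyed(features_b)
  common_keys <- intersect(a$key, b$key)
  fa <- stats::setNames(a$five, a$key)[common_keys]
  fb <- stats::setNames(b$five, b$key)[common_keys]
  data.frame(n_a = nrow(a), n_b = nrow(b),
             unique_a = nrow(a) - length(common_keys),
             unique_b = nrow(b) - length(common_keys),
             common = length(common_keys),
             five_prime_changes = sum(fa != fb))
}
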