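## The annotation diff: which predictions are genuinely absent from the
## annotation. A prediction counts as present if it shares a strand-aware
## 3' end with any non-pseudo annotated CDS; remaining predictions are
## dropped if they overlap an RNA, a gene-without-CDS, or a pseudo CDS by
## more than half their length; the survivors are candidate missed genes.

#' 3' end of a stranded interval
#'
#' On the forward strand the 3' end is the last base (`end - 1` in 0-based
#' half-open coordinates); on the reverse strand it is `start`. Changing
#' only the 5' coordinate never changes the 3' end, which is what makes the
#' 3' rule robust to start-site disagreement between annotators.
#'
#' @param start,end 0-based half-open coordinates (vectorised).
#' @param strand `"+"` or `"-"` (vectorised).
#' @return integer vector of genomic offsets.
#' @export
three_prime_end <- function(start, end, strand) {
  ifelse(strand == "+", end - 1L, start)
}

#' Is a prediction present in the annotation?
#'
#' TRUE iff some non-pseudo CDS feature has the same strand and the same
#' 3' end as the prediction.
#'
#' @param prediction one-row prediction data.frame (`start`, `end`, `strand`).
#' @param features feature data.frame of the same chromosome.
#' @return logical flag.
#' @export
is_annotated <- function(prediction, features) {
  cds <- features[features$kind == "CDS" & !features$is_pseudo, , drop = FALSE]
  if (!nrow(cds)) return(FALSE)
  p3 <- three_prime_end(prediction$start, prediction$end, prediction$strand)
  f3 <- three_prime_end(cds$start, cds$end, cds$strand)
  any(cds$strand == prediction$strand & f3 == p3)
}

#' Fraction of a prediction covered by a feature
#'
#' Strand-ignored per-base intersection divided by the prediction's length.
#'
#' @param pred_start,pred_end prediction interval (0-based half-open).
#' @param feat_start,feat_end feature interval.
#' @return numeric in `[0, 1]` (vectorised over the feature interval).
#' @export
overlap_fraction <- function(pred_start, pred_end, feat_start, feat_end) {
  inter <- pmax(0L, pmin(pred_end, feat_end) - pmax(pred_start, feat_start))
  inter / (pred_end - pred_start)
}

#' Detect candidate missed genes on one chromosome
#'
#' Each prediction gets exactly one status: `annotated` if its 3' end is
#' shared with a non-pseudo CDS on the same strand (this check takes
#' precedence), `excluded_overlap` if it overlaps an RNA feature, a gene
#' without a CDS, or a pseudo CDS by strictly more than `max_overlap` of its
#' own length, else `candidate`. Non-pseudo CDS features never exclude a
#' prediction by overlap.
#'
#' @param predictions prediction data.frame from [read_predictions()].
#' @param features feature data.frame from the same chromosome.
#' @param accession chromosome accession recorded on each row.
#' @param max_overlap overlap threshold, exclusive (default 0.5).
#' @return data.frame: `accession`, `pred_id`, `start`, `end`, `strand`,
#'   `length_bp`, `status`, `overlapping_feature_id` (non-empty iff
#'   `excluded_overlap`).
#' @export
detect_candidates <- function(predictions, features, accession = "",
                              max_overlap = 0.5) {
  n <- nrow(predictions)
  status <- character(n)
  overlap_id <- character(n)

  cds <- features[features$kind == "CDS" & !features$is_pseudo, , drop = FALSE]
  cds_key <- if (nrow(cds)) {
    paste(cds$strand, three_prime_end(cds$start, cds$end, cds$strand))
  } else character()
  blockers <- features[
    features$kind %in% c("rRNA", "tRNA", "other_RNA", "gene_without_CDS") |
      (features$kind == "CDS" & features$is_pseudo), , drop = FALSE]

  for (i in seq_len(n)) {
    key <- paste(predictions$strand[i],
                 three_prime_end(predictions$start[i], predictions$end[i],
                                 predictions$strand[i]))
    if (key %in% cds_key) {
      status[i] <- "annotated"
      next
    }
    if (nrow(blockers)) {
      fr <- overlap_fraction(predictions$start[i], predictions$end[i],
                             blockers$start, blockers$end)
      hit <- which(fr > max_overlap)
      if (length(hit)) {
        status[i] <- "excluded_overlap"
        j <- hit[which.max(fr[hit])]
        overlap_id[i] <- if (nzchar(blockers$locus_id[j]))
          blockers$locus_id[j] else
            sprintf("%s:%d-%d", blockers$kind[j], blockers$start[j] + 1L,
                    blockers$end[j])
        next
      }
    }
    status[i] <- "candidate"
  }
  data.frame(accession = rep(accession, n),
             pred_id = predictions$pred_id,
             start = predictions$start, end = predictions$end,
             strand = predictions$strand,
             length_bp = predictions$end - predictions$start,
             status = status, overlapping_feature_id = overlap_id,
             stringsAsFactors = FALSE)
}
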