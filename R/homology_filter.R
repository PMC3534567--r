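## Homology filtering of candidate missed genes: keep hits that are both
## statistically significant (E-value) and near-full-length on the subject
## (coverage), then split candidates into named vs hypothetical missed
## genes by the subject descriptions of their surviving hits.

#' Convert a BLAST E-value to a P-value
#'
#' The probability of at least one chance alignment scoring as well is
#' `P = 1 - exp(-E)`; for small E the two are numerically equal (at 1e-6
#' they agree to printed precision). Computed with `expm1` for accuracy at
#' small E.
#'
#' @param evalue non-negative E-value (vectorised).
#' @return P-value in `[0, 1)`.
#' @export
evalue_to_pvalue <- function(evalue) {
  if (any(evalue < 0)) stop("E-value must be non-negative")
  -expm1(-evalue)
}

#' Candidate-stage hit filter
#'
#' A hit passes iff its E-value is at most `max_evalue` (default 1e-6,
#' inclusive) and its alignment covers at least `min_subject_coverage` of
#' the subject protein (default 0.8, inclusive).
#'
#' @param hits data.frame from [read_blast_tab()] (vectorised).
#' @param max_evalue E-value threshold (inclusive).
#' @param min_subject_coverage subject-coverage threshold (inclusive).
#' @return logical vector, one flag per hit.
#' @export
passes_candidate_filter <- function(hits, max_evalue = 1e-6,
                                    min_subject_coverage = 0.8) {
  if (any(hits$subject_length <= 0L)) {
    stop("subject_length must be positive")
  }
  hits$evalue <= max_evalue &
    hits$subject_alignment_span / hits$subject_length >= min_subject_coverage
}

## Default spelling list for "hypothetical" in subject descriptions;
## includes misspellings seen in public annotations. User-extensible.
DEFAULT_HYPOTHETICAL_PATTERNS <- c("hypothetical", "hypothetcial",
                                   "hypotetical", "hypotheical")

#' Does a protein description denote a hypothetical protein?
#'
#' Case-insensitive substring match against a configurable spelling list
#' (the default covers common misspellings of "hypothetical").
#'
#' @param description character vector of subject descriptions.
#' @param patterns spelling list; any match flags the description.
#' @return logical vector.
#' @export
is_hypothetical_description <- function(description,
                                        patterns = DEFAULT_HYPOTHETICAL_PATTERNS) {
  out <- rep(FALSE, length(description))
  for (p in patterns) {
    out <- out | grepl(p, description, ignore.case = TRUE, fixed = FALSE)
  }
  out
}

#' Classify candidate missed genes by homology evidence
#'
#' For each candidate, the hits passing [passes_candidate_filter()] decide
#' the category: `named` if any passing hit's subject is non-hypothetical,
#' `hypothetical` if all passing hits are to hypothetical proteins,
#' `no_homology` if no hit passes. The best hit is the passing hit with the
#' smallest E-value (ties: largest subject coverage, then lexicographically
#' smallest subject id).
#'
#' @param candidates data.frame from [detect_candidates()]; only rows with
#'   `status == "candidate"` are classified.
#' @param hits data.frame from [read_blast_tab()]; `query_id` matches
#'   `pred_id`.
#' @param max_evalue,min_subject_coverage filter thresholds, see
#'   [passes_candidate_filter()].
#' @param hypothetical_patterns spelling list for
#'   [is_hypothetical_description()].
#' @return data.frame: `accession`, `pred_id`, `length_bp`, `category`,
#'   `best_hit_id`, `best_evalue`, `best_subject_coverage`,
#'   `n_passing_hits`.
#' @export
classify_candidates <- function(candidates, hits, max_evalue = 1e-6,
                                min_subject_coverage = 0.8,
                                hypothetical_patterns =
                                  DEFAULT_HYPOTHETICAL_PATTERNS) {
  cand <- candidates[candidates$status == "candidate", , drop = FALSE]
  if (nrow(hits)) {
    hits <- hits[passes_candidate_filter(hits, max_evalue,
                                         min_subject_coverage), , drop = FALSE]
    hits$coverage <- hits$subject_alignment_span / hits$subject_length
    hits$hypo <- is_hypothetical_description(hits$subject_description,
                                             hypothetical_patterns)
    hit_groups <- split(hits, hits$query_id)
  } else {
    hit_groups <- list()
  }
  n <- nrow(cand)
  category <- character(n)
  best_id <- character(n)
  best_ev <- rep(NA_real_, n)
  best_cov <- rep(NA_real_, n)
  n_pass <- integer(n)
  for (i in seq_len(n)) {
    h <- hit_groups[[cand$pred_id[i]]]
    if (is.null(h) || !nrow(h)) {
      category[i] <- "no_homology"
      next
    }
    n_pass[i] <- nrow(h)
    category[i] <- if (any(!h$hypo)) "named" else "hypothetical"
    ord <- order(h$evalue, -h$coverage, h$subject_id)
    b <- h[ord[1], ]
    best_id[i] <- b$subject_id
    best_ev[i] <- b$evalue
    best_cov[i] <- b$coverage
  }
  data.frame(accession = cand$accession, pred_id = cand$pred_id,
             length_bp = cand$length_bp, category = category,
             best_hit_id = best_id, best_evalue = best_ev,
             best_subject_coverage = best_cov, n_passing_hits = n_pass,
             stringsAsFactors = FALSE)
}
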