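## Spurious-ORF flagging from profile-HMM hits (AntiFam-style models of
## commonly mis-annotated families), and the summary table of spurious
## counts by support level and category.

#' Flag spurious missed genes from HMM hits
#'
#' A call is spurious iff it has at least one HMM hit with E-value at most
#' `max_evalue`; the best (smallest-E) model is recorded.
#'
#' @param calls data.frame from [classify_candidates()].
#' @param hmm_hits data.frame from [read_hmm_table()] (`query_id` matches
#'   `pred_id`).
#' @param max_evalue inclusive E-value bound (default 1e-5). Set to `Inf`
#'   to trust the table's own inclusion threshold.
#' @return data.frame: `pred_id`, `spurious`, `model_accession`,
#'   `model_name` (model fields empty unless spurious).
#' @export
flag_spurious <- function(calls, hmm_hits, max_evalue = 1e-5) {
  if (nrow(hmm_hits)) {
    hmm_hits <- hmm_hits[hmm_hits$evalue <= max_evalue, , drop = FALSE]
    groups <- split(hmm_hits, hmm_hits$query_id)
  } else {
    groups <- list()
  }
  n <- nrow(calls)
  spurious <- logical(n)
  acc <- character(n)
  nm <- character(n)
  for (i in seq_len(n)) {
    h <- groups[[calls$pred_id[i]]]
    if (!is.null(h) && nrow(h)) {
      spurious[i] <- TRUE
      b <- h[which.min(h$evalue), ]
      acc[i] <- b$model_accession
      nm[i] <- b$model_name
    }
  }
  data.frame(pred_id = calls$pred_id, spurious = spurious,
             model_accession = acc, model_name = nm,
             stringsAsFactors = FALSE)
}

format_cell <- function(spurious, total) {
  pct <- if (total == 0L || spurious == 0L) "0%" else
    sprintf("%.2f%%", round(100 * spurious / total, 2))
  sprintf("%d/%d (%s)", spurious, total, pct)
}

#' Tabulate spurious genes by support level and category
#'
#' One row per support level (strong, fair, weak, insufficient) plus a
#' totals row; one column pair per category (named, hypothetical). Each cell
#' carries the spurious count, the total count, and the percentage (two
#' decimals; rendered `0%` when the numerator or the denominator is zero).
#'
#' @param calls data.frame from [classify_candidates()].
#' @param flags data.frame from [flag_spurious()].
#' @param assignments data.frame from [comblast_assign()], or `NULL` to
#'   group everything under a single `all` level.
#' @param denominator `"kb_similar"` restricts totals to calls with at
#'   least one significant knowledgebase homolog (the default when
#'   assignments are given); `"all"` counts every named/hypothetical call.
#' @return data.frame: `support`, `named_spurious`, `named_total`,
#'   `named_pct`, `named_cell`, and the same four for `hypothetical`.
#' @export
spurious_summary <- function(calls, flags, assignments = NULL,
                             denominator = c("kb_similar", "all")) {
  denominator <- match.arg(denominator)
  calls <- calls[calls$category %in% c("named", "hypothetical"), ,
                 drop = FALSE]
  orphans <- setdiff(calls$pred_id, flags$pred_id)
  if (length(orphans)) {
    stop("calls without a spurious flag: ", paste(orphans, collapse = ", "))
  }
  spur <- stats::setNames(flags$spurious, flags$pred_id)[calls$pred_id]
  if (!is.null(assignments)) {
    sup_of <- stats::setNames(assignments$support, assignments$pred_id)
    nsig_of <- stats::setNames(assignments$n_significant,
                               assignments$pred_id)
    miss <- setdiff(calls$pred_id, assignments$pred_id)
    if (length(miss)) {
      stop("calls without a support assignment: ",
           paste(miss, collapse = ", "))
    }
    support <- unname(sup_of[calls$pred_id])
    if (denominator == "kb_similar") {
      keep <- unname(nsig_of[calls$pred_id]) >= 1L
      calls <- calls[keep, , drop = FALSE]
      spur <- spur[keep]
      support <- support[keep]
    }
    levels_used <- c("strong", "fair", "weak", "insufficient")
  } else {
    support <- rep("all", nrow(calls))
    levels_used <- "all"
  }
  spurious_counts_row <- function(sel) {
    named <- calls$category[sel] == "named"
    c(named_spurious = sum(spur[sel][named]),
      named_total = sum(named),
      hypothetical_spurious = sum(spur[sel][!named]),
      hypothetical_total = sum(!named))
  }
  rows <- lapply(levels_used, function(lv) spurious_counts_row(support == lv))
  rows <- c(rows, list(spurious_counts_row(rep(TRUE, nrow(calls)))))
  tab <- as.data.frame(do.call(rbind, rows))
  tab$support <- c(levels_used, "total")
  spurious_table(tab)
}

## Derive the percentage/cell columns from raw numerators/denominators.
## Exported separately so printed tables of counts can be re-derived.
#' @rdname spurious_summary
#' @param counts data.frame with columns `support`, `named_spurious`,
#'   `named_total`, `hypothetical_spurious`, `hypothetical_total`.
#' @export
spurious_table <- function(counts) {
  counts$named_pct <- ifelse(counts$named_total > 0,
                             round(100 * counts$named_spurious /
                                     counts$named_total, 2), 0)
  counts$hypothetical_pct <- ifelse(counts$hypothetical_total > 0,
                                    round(100 * counts$hypothetical_spurious /
                                            counts$hypothetical_total, 2), 0)
  counts$named_cell <- mapply(format_cell, counts$named_spurious,
                              counts$named_total)
  counts$hypothetical_cell <- mapply(format_cell,
                                     counts$hypothetical_spurious,
                                     counts$hypothetical_total)
  counts[, c("support", "named_spurious", "named_total", "named_pct",
             "named_cell", "hypothetical_spurious", "hypothetical_total",
             "hypothetical_pct", "hypothetical_cell")]
}
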