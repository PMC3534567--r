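#' Genomic intervals
#'
#' All coordinates inside the package are 0-based half-open with an explicit
#' strand: `start` is the first base (0-based), `end` is one past the last,
#' so `length = end - start`. External 1-based inclusive formats (GenBank,
#' Glimmer, GFF3) are converted at the read/write boundary and nowhere else.
#'
#' @param start 0-based inclusive start offset(s).
#' @param end 0-based exclusive end offset(s).
#' @param strand `"+"` or `"-"`, recycled.
#' @return A data.frame with columns `start`, `end`, `strand`.
#' @export
interval <- function(start, end, strand = "+") {
  start <- as.integer(start)
  end <- as.integer(end)
  strand <- rep_len(as.character(strand), length(start))
  stopifnot(all(strand %in% c("+", "-")))
  if (any(is.na(start)) || any(is.na(end)) || any(start < 0L) ||
      any(start >= end)) {
    stop("invalid interval: require 0 <= start < end")
  }
  data.frame(start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

#' @rdname interval
#' @param x interval data.frame (or anything with `start`/`end` columns).
#' @export
interval_length <- function(x) x$end - x$start

#' Convert between 1-based inclusive and 0-based half-open coordinates
#'
#' `from_onebased()` takes 1-based inclusive (lo, hi) pairs as printed by
#' GenBank/Glimmer/GFF3; `to_onebased()` is its inverse. The two are exact
#' inverses of each other on any valid interval.
#'
#' @param lo,hi 1-based inclusive bounds, `lo <= hi`.
#' @return `from_onebased()`: list with `start`, `end` (0-based half-open);
#'   `to_onebased()`: list with `lo`, `hi` (1-based inclusive).
#' @export
from_onebased <- function(lo, hi) {
  list(start = as.integer(lo) - 1L, end = as.integer(hi))
}

#' @rdname from_onebased
#' @param start,end 0-based half-open bounds.
#' @export
to_onebased <- function(start, end) {
  list(lo = as.integer(start) + 1L, hi = as.integer(end))
}
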