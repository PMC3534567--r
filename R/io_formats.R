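## Readers and writers for the external formats. Everything downstream works
## on the domain types built here: genome_record (S3 list), feature tables,
## prediction tables, homology-hit tables, HMM-hit tables, knowledge_base.

FEATURE_KINDS <- c("CDS", "rRNA", "tRNA", "other_RNA", "gene_without_CDS",
                   "other")

## GenBank feature keys -> internal kinds (configurable via read_genbank()).
DEFAULT_KIND_MAP <- c(
  CDS = "CDS", rRNA = "rRNA", tRNA = "tRNA",
  ncRNA = "other_RNA", tmRNA = "other_RNA", misc_RNA = "other_RNA"
)

empty_features <- function() {
  data.frame(kind = character(), start = integer(), end = integer(),
             strand = character(), is_pseudo = logical(),
             product = character(), locus_id = character(),
             stringsAsFactors = FALSE)
}

#' Construct a genome record
#'
#' @param accession accession string.
#' @param definition the record's definition (header) line.
#' @param organism organism name.
#' @param sequence nucleotide string (IUPAC codes allowed).
#' @param features feature data.frame with columns `kind`, `start`, `end`,
#'   `strand`, `is_pseudo`, `product`, `locus_id` (0-based half-open).
#' @param center annotation-center label; `"Other"` when unknown.
#' @param is_plasmid logical flag.
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(accession, definition = "", organism = "",
                          sequence = "", features = empty_features(),
                          center = "Other", is_plasmid = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  rec <- structure(list(
    accession = accession, definition = definition, organism = organism,
    sequence = toupper(sequence), features = features,
    length_bp = nchar(sequence), center = center, is_plasmid = is_plasmid
  ), class = "genome_record")
  bad <- features$end > rec$length_bp & rec$length_bp > 0L
  if (any(bad)) {
    warning(sprintf("%s: dropping %d feature(s) beyond sequence length",
                    accession, sum(bad)))
    rec$features <- features[!bad, , drop = FALSE]
  }
  rec
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s (%s)\n  %d bp, %d features, center=%s%s\n",
              x$accession, x$organism, x$length_bp, nrow(x$features),
              x$center, if (x$is_plasmid) ", plasmid" else ""))
  invisible(x)
}

## ---- GenBank flat files -----------------------------------------------

## Parse a GenBank location string into (start, end, strand, spans_origin).
## Handles `a..b`, `complement(a..b)`, partial markers `<`/`>`, and flags
## join()/order() locations (treated as origin-spanning/compound).
parse_gb_location <- function(loc) {
  strand <- "+"
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  compound <- grepl("^(join|order)\\(", loc)
  if (compound) loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  parts <- strsplit(loc, ",")[[1]]
  rng <- regmatches(parts[1], regexec("^(\\d+)\\.\\.(\\d+)$", parts[1]))[[1]]
  if (length(rng) != 3L) {
    ## single-base location `n`
    n <- suppressWarnings(as.integer(parts[1]))
    if (is.na(n)) return(NULL)
    rng <- c(parts[1], n, n)
  }
  lo <- as.integer(rng[2]); hi <- as.integer(rng[3])
  if (compound && length(parts) > 1L) {
    last <- regmatches(parts[length(parts)],
                       regexec("^(\\d+)\\.\\.(\\d+)$",
                               parts[length(parts)]))[[1]]
    if (length(last) == 3L) hi <- as.integer(last[3])
  }
  zc <- from_onebased(lo, hi)
  list(start = zc$start, end = zc$end, strand = strand,
       compound = compound || hi < lo)
}

#' Read a GenBank flat file
#'
#' Parses one or more records (LOCUS/DEFINITION/SOURCE/FEATURES/ORIGIN)
#' into [genome_record()] objects. Coordinates are converted to 0-based
#' half-open on read. Feature keys are mapped to the internal kinds:
#' `CDS`, `rRNA`, `tRNA`, `other_RNA` (ncRNA/tmRNA/misc_RNA),
#' `gene_without_CDS` (a `gene` whose locus tag has no CDS), and `other`.
#' `source` features are consumed for plasmid detection only. Compound
#' (join/order, i.e. origin-spanning) locations are excluded with a warning.
#'
#' @param path path to a GenBank flat file with at least one record.
#' @param kind_map named character vector mapping GenBank feature keys to
#'   internal kinds; keys absent from the map become `"other"`.
#' @return A list of [genome_record()] objects.
#' @export
read_genbank <- function(path, kind_map = DEFAULT_KIND_MAP) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^LOCUS", lines[1])) {
    stop(sprintf("%s: line 1: expected LOCUS header in a GenBank flat file",
                 path))
  }
  starts <- grep("^LOCUS", lines)
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(i) {
    parse_genbank_record(lines[starts[i]:ends[i]], kind_map, path)
  })
}

parse_genbank_record <- function(lines, kind_map, path) {
  locus_fields <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(locus_fields) < 2L) {
    stop(sprintf("%s: malformed LOCUS line: '%s'", path, lines[1]))
  }
  accession <- locus_fields[2]

  grab_block <- function(key) {
    i <- grep(paste0("^", key), lines)
    if (!length(i)) return("")
    i <- i[1]
    out <- sub(paste0("^", key, "\\s*"), "", lines[i])
    j <- i + 1L
    while (j <= length(lines) && grepl("^ {4,}\\S", lines[j]) &&
           !grepl("^ {0,11}[A-Z]", lines[j])) {
      out <- paste(out, trimws(lines[j]))
      j <- j + 1L
    }
    out
  }
  definition <- grab_block("DEFINITION")
  org_i <- grep("^  ORGANISM", lines)
  organism <- if (length(org_i)) trimws(sub("^  ORGANISM", "", lines[org_i[1]])) else ""

  ## FEATURES block
  f_i <- grep("^FEATURES", lines)
  o_i <- grep("^ORIGIN", lines)
  feats <- list()
  is_plasmid_src <- FALSE
  if (length(f_i)) {
    f_end <- if (length(o_i)) o_i[1] - 1L else length(lines)
    fl <- lines[(f_i[1] + 1L):f_end]
    ## feature headers start at column 6; qualifiers/continuations at col 22
    hdr <- grepl("^ {5}\\S", fl)
    idx <- which(hdr)
    for (k in seq_along(idx)) {
      block <- fl[idx[k]:(if (k < length(idx)) idx[k + 1L] - 1L else length(fl))]
      key <- sub("^ {5}(\\S+).*$", "\\1", block[1])
      loc <- trimws(substring(block[1], 22))
      ## location continuation lines (no leading '/')
      q <- 2L
      while (q <= length(block) && !grepl("^\\s*/", block[q])) {
        loc <- paste0(loc, trimws(block[q])); q <- q + 1L
      }
      quals <- paste(trimws(block[seq_len(length(block)) >= q]), collapse = " ")
      get_qual <- function(name) {
        m <- regmatches(quals, regexec(sprintf('/%s="([^"]*)"', name), quals))[[1]]
        if (length(m) == 2L) m[2] else ""
      }
      if (key == "source") {
        if (grepl("/plasmid", quals)) is_plasmid_src <- TRUE
        next
      }
      pl <- parse_gb_location(loc)
      if (is.null(pl)) {
        warning(sprintf("%s: unparseable location '%s' for %s; feature dropped",
                        accession, loc, key))
        next
      }
      if (isTRUE(pl$compound)) {
        warning(sprintf(
          "%s: compound/origin-spanning location '%s' for %s; feature excluded",
          accession, loc, key))
        next
      }
      feats[[length(feats) + 1L]] <- data.frame(
        gb_key = key, start = pl$start, end = pl$end, strand = pl$strand,
        is_pseudo = grepl("/pseudo(\\s|$|=)", paste0(quals, " ")),
        product = get_qual("product"),
        locus_id = {
          lt <- get_qual("locus_tag")
          if (nzchar(lt)) lt else get_qual("gene")
        },
        stringsAsFactors = FALSE)
    }
  }
  fdf <- if (length(feats)) do.call(rbind, feats) else
    cbind(empty_features()[0, ], gb_key = character())

  ## kind mapping; `gene` features get gene_without_CDS iff no CDS shares
  ## their locus tag
  kind <- unname(kind_map[fdf$gb_key])
  kind[is.na(kind)] <- "other"
  if (nrow(fdf)) {
    cds_loci <- fdf$locus_id[fdf$gb_key == "CDS" & nzchar(fdf$locus_id)]
    is_gene <- fdf$gb_key == "gene"
    lonely <- is_gene & !(fdf$locus_id %in% cds_loci & nzchar(fdf$locus_id))
    kind[lonely] <- "gene_without_CDS"
  }
  fdf$kind <- kind
  ## pseudo flag only meaningful on CDS / gene_without_CDS
  fdf$is_pseudo <- fdf$is_pseudo & fdf$kind %in% c("CDS", "gene_without_CDS")
  fdf <- fdf[, c("kind", "start", "end", "strand", "is_pseudo", "product",
                 "locus_id")]
  rownames(fdf) <- NULL

  ## ORIGIN sequence
  seq <- ""
  if (length(o_i)) {
    s_end <- grep("^//", lines)
    s_end <- if (length(s_end)) s_end[1] - 1L else length(lines)
    if (s_end > o_i[1]) {
      raw <- lines[(o_i[1] + 1L):s_end]
      seq <- toupper(gsub("[^A-Za-z]", "", paste(raw, collapse = "")))
    }
  }
  genome_record(accession, definition, organism, seq, fdf,
                is_plasmid = is_plasmid_src ||
                  grepl("plasmid", definition, ignore.case = TRUE))
}

## Minimal GenBank writer (used by the fixture generator; read_genbank()
## round-trips its output).
write_genbank <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    writeLines(sprintf("LOCUS       %s %20d bp    DNA     circular BCT",
                       rec$accession, rec$length_bp), con)
    writeLines(sprintf("DEFINITION  %s", rec$definition), con)
    writeLines(sprintf("ACCESSION   %s", rec$accession), con)
    writeLines(sprintf("SOURCE      %s", rec$organism), con)
    writeLines(sprintf("  ORGANISM  %s", rec$organism), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", rec$length_bp), con)
    writeLines(sprintf('                     /organism="%s"', rec$organism), con)
    kind_to_key <- c(CDS = "CDS", rRNA = "rRNA", tRNA = "tRNA",
                     other_RNA = "misc_RNA", gene_without_CDS = "gene",
                     other = "misc_feature")
    f <- rec$features
    for (i in seq_len(nrow(f))) {
      ob <- to_onebased(f$start[i], f$end[i])
      loc <- sprintf("%d..%d", ob$lo, ob$hi)
      if (f$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     %-16s%s", kind_to_key[[f$kind[i]]], loc), con)
      if (nzchar(f$locus_id[i])) {
        writeLines(sprintf('                     /locus_tag="%s"', f$locus_id[i]), con)
      }
      if (f$is_pseudo[i]) writeLines("                     /pseudo", con)
      if (nzchar(f$product[i])) {
        writeLines(sprintf('                     /product="%s"', f$product[i]), con)
      }
    }
    writeLines("ORIGIN", con)
    s <- rec$sequence
    pos <- seq(1L, max(nchar(s), 1L), by = 60L)
    for (p in pos) {
      chunk <- substring(s, p, min(p + 59L, nchar(s)))
      blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                          pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
      writeLines(sprintf("%9d %s", p, paste(blocks, collapse = " ")), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

## ---- Gene predictions --------------------------------------------------

#' Read ab initio gene predictions
#'
#' Supports the Glimmer3 `.predict` dialect (5 whitespace-separated columns:
#' id, start, end, frame, score; `>tag` lines delimit per-chromosome blocks;
#' start > end encodes the reverse strand) and GFF3 (CDS rows only).
#' Predictions shorter than `min_length_bp` are dropped with a message;
#' predictions extending past `genome_length` (when supplied) are treated as
#' origin-spanning and excluded with a warning.
#'
#' @param path path to the predictions file.
#' @param dialect `"glimmer_predict"` or `"gff3"`.
#' @param min_length_bp minimum retained prediction length (default 110 bp,
#'   the Glimmer3 g3-iterated default).
#' @param genome_length optional chromosome length for origin-span checks.
#' @param genetic_code NCBI translation table recorded on each prediction
#'   (11 default; 4 for genomes run with stop codons TAG/TAA only).
#' @return data.frame with columns `pred_id`, `start`, `end`, `strand`,
#'   `length_bp`, `score`, `genetic_code` (0-based half-open coordinates).
#' @export
read_predictions <- function(path, dialect = c("glimmer_predict", "gff3"),
                             min_length_bp = 110L, genome_length = NULL,
                             genetic_code = 11L) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  if (dialect == "glimmer_predict") {
    for (i in seq_along(lines)) {
      ln <- trimws(lines[i])
      if (!nzchar(ln) || startsWith(ln, ">")) next
      f <- strsplit(ln, "\\s+")[[1]]
      if (length(f) < 4L) {
        stop(sprintf("%s: line %d: expected >= 4 columns in .predict line",
                     path, i))
      }
      lo <- suppressWarnings(as.integer(f[2]))
      hi <- suppressWarnings(as.integer(f[3]))
      if (is.na(lo) || is.na(hi)) {
        stop(sprintf("%s: line %d: non-numeric coordinates", path, i))
      }
      strand <- if (lo > hi) "-" else "+"
      zc <- from_onebased(min(lo, hi), max(lo, hi))
      rows[[length(rows) + 1L]] <- data.frame(
        pred_id = f[1], start = zc$start, end = zc$end, strand = strand,
        score = if (length(f) >= 5L) suppressWarnings(as.numeric(f[5])) else NA_real_,
        stringsAsFactors = FALSE)
    }
  } else {
    for (i in seq_along(lines)) {
      ln <- lines[i]
      if (!nzchar(ln) || startsWith(ln, "#")) next
      f <- strsplit(ln, "\t")[[1]]
      if (length(f) < 9L) stop(sprintf("%s: line %d: expected 9 GFF3 columns",
                                       path, i))
      if (f[3] != "CDS") next
      zc <- from_onebased(as.integer(f[4]), as.integer(f[5]))
      id <- sub('^.*ID=([^;]+).*$', "\\1", f[9])
      if (id == f[9]) id <- sprintf("gff_%05d", i)
      rows[[length(rows) + 1L]] <- data.frame(
        pred_id = id, start = zc$start, end = zc$end, strand = f[7],
        score = suppressWarnings(as.numeric(f[6])), stringsAsFactors = FALSE)
    }
  }
  preds <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pred_id = character(), start = integer(), end = integer(),
               strand = character(), score = numeric(),
               stringsAsFactors = FALSE)
  if (!is.null(genome_length) && nrow(preds)) {
    spanning <- preds$end > genome_length
    if (any(spanning)) {
      warning(sprintf("%s: excluding %d origin-spanning prediction(s)",
                      path, sum(spanning)))
      preds <- preds[!spanning, , drop = FALSE]
    }
  }
  preds$length_bp <- preds$end - preds$start
  short <- preds$length_bp < min_length_bp
  if (any(short)) {
    message(sprintf("%s: dropped %d prediction(s) shorter than %d bp",
                    path, sum(short), min_length_bp))
    preds <- preds[!short, , drop = FALSE]
  }
  preds$genetic_code <- as.integer(genetic_code)
  rownames(preds) <- NULL
  preds[, c("pred_id", "start", "end", "strand", "length_bp", "score",
            "genetic_code")]
}

write_glimmer_predict <- function(preds, path, tag = "seq") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", tag), con)
  for (i in seq_len(nrow(preds))) {
    ob <- to_onebased(preds$start[i], preds$end[i])
    if (preds$strand[i] == "+") {
      writeLines(sprintf("%s %8d %8d  +1  %6.2f", preds$pred_id[i],
                         ob$lo, ob$hi,
                         ifelse(is.na(preds$score[i]), 0, preds$score[i])), con)
    } else {
      writeLines(sprintf("%s %8d %8d  -1  %6.2f", preds$pred_id[i],
                         ob$hi, ob$lo,
                         ifelse(is.na(preds$score[i]), 0, preds$score[i])), con)
    }
  }
  invisible(path)
}

## ---- BLAST tabular -----------------------------------------------------

DEFAULT_BLAST_COLUMNS <- c("qseqid", "sseqid", "pident", "length", "qstart",
                           "qend", "sstart", "send", "evalue", "bitscore",
                           "slen", "stitle")

#' Read tabular BLAST hits
#'
#' Reads an outfmt-6-style tab-separated table that carries, in addition to
#' the standard 12 columns, the subject length (`slen`) and subject
#' description (`stitle`). The subject alignment span is computed as
#' `|send - sstart| + 1`.
#'
#' @param path path to the tab-separated file (no header).
#' @param columns character vector naming the columns in file order; must
#'   include `qseqid`, `sseqid`, `sstart`, `send`, `evalue`, `slen`, `stitle`.
#' @return data.frame with columns `query_id`, `subject_id`, `evalue`,
#'   `subject_alignment_span`, `subject_length`, `subject_description`.
#' @export
read_blast_tab <- function(path, columns = DEFAULT_BLAST_COLUMNS) {
  required <- c("qseqid", "sseqid", "sstart", "send", "evalue", "slen",
                "stitle")
  missing_cols <- setdiff(required, columns)
  if (length(missing_cols)) {
    stop("blast column map missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  empty <- data.frame(query_id = character(), subject_id = character(),
                      evalue = numeric(), subject_alignment_span = integer(),
                      subject_length = integer(),
                      subject_description = character(),
                      stringsAsFactors = FALSE)
  if (!file.size(path)) return(empty)
  tab <- utils::read.table(path, sep = "\t", quote = "", comment.char = "",
                           col.names = columns, stringsAsFactors = FALSE,
                           fill = TRUE)
  ev <- suppressWarnings(as.numeric(tab$evalue))
  ss <- suppressWarnings(as.integer(tab$sstart))
  se <- suppressWarnings(as.integer(tab$send))
  sl <- suppressWarnings(as.integer(tab$slen))
  bad <- is.na(ev) | ev < 0 | is.na(ss) | is.na(se) | is.na(sl)
  if (any(bad)) {
    warning(sprintf("%s: rejected %d malformed row(s)", path, sum(bad)))
  }
  keep <- !bad
  data.frame(query_id = as.character(tab$qseqid[keep]),
             subject_id = as.character(tab$sseqid[keep]),
             evalue = ev[keep],
             subject_alignment_span = abs(se[keep] - ss[keep]) + 1L,
             subject_length = sl[keep],
             subject_description = as.character(tab$stitle[keep]),
             stringsAsFactors = FALSE)
}

write_blast_tab <- function(hits, path) {
  ## emits the 12-column layout DEFAULT_BLAST_COLUMNS expects
  n <- nrow(hits)
  tab <- data.frame(
    qseqid = hits$query_id, sseqid = hits$subject_id,
    pident = rep(95, n), length = hits$subject_alignment_span,
    qstart = rep(1L, n), qend = hits$subject_alignment_span,
    sstart = rep(1L, n), send = hits$subject_alignment_span,
    evalue = format(hits$evalue, scientific = TRUE, digits = 3),
    bitscore = rep(200, n), slen = hits$subject_length,
    stitle = hits$subject_description, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---- HMMER per-target tables ------------------------------------------

#' Read an HMMER per-sequence hit table
#'
#' Parses a `hmmscan --tblout`-style table (comment lines start with `#`):
#' column 1 is the model (target) name, column 2 its accession, column 3 the
#' query sequence id, column 5 the full-sequence E-value.
#'
#' @param path path to the table.
#' @return data.frame with columns `query_id`, `model_name`,
#'   `model_accession`, `evalue`.
#' @export
read_hmm_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln)) || startsWith(ln, "#")) next
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 5L) {
      stop(sprintf("%s: line %d: expected >= 5 whitespace-separated fields",
                   path, i))
    }
    ev <- suppressWarnings(as.numeric(f[5]))
    if (is.na(ev)) stop(sprintf("%s: line %d: non-numeric E-value", path, i))
    rows[[length(rows) + 1L]] <- data.frame(
      query_id = f[3], model_name = f[1], model_accession = f[2],
      evalue = ev, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(query_id = character(), model_name = character(),
                      model_accession = character(), evalue = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

write_hmm_table <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#                                query           full sequence",
               "# target name  accession        name       -    E-value  score",
               "#------------- ---------------- ---------- ---- -------- -----"),
             con)
  for (i in seq_len(nrow(hits))) {
    writeLines(sprintf("%s %s %s - %g 42.0", hits$model_name[i],
                       hits$model_accession[i], hits$query_id[i],
                       hits$evalue[i]), con)
  }
  invisible(path)
}

## ---- Knowledgebase -----------------------------------------------------

split_semis <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE), function(v) {
    v <- trimws(v[nzchar(trimws(v))])
    unique(v)
  })
}

EVIDENCE_FLAGS <- c("experimental_function", "structure_3d",
                    "purified_protein", "protein_domain", "ec_number")
PHENOTYPE_FLAGS <- c("antibiotic_resistance", "antibiotic_sensitivity",
                     "essential")

#' Read a knowledgebase of curated genes and protein clusters
#'
#' `genes_path` is a TSV with columns `gene_id`, `length_aa`, `phylum`,
#' `evidence_flags`, `phenotype_flags`, `cluster_ids` (the last three
#' semicolon-separated, possibly empty); `clusters_path` has `cluster_id`,
#' `has_computational_prediction`, `member_ids`. Referential integrity is
#' enforced in both directions, and each cluster's phylum set is derived
#' from its member genes.
#'
#' @param genes_path,clusters_path paths to the two TSV files (with header).
#' @return An object of class `knowledge_base`: a list with data.frames
#'   `genes` and `clusters` (list-columns for the set-valued fields).
#' @export
read_knowledgebase <- function(genes_path, clusters_path) {
  g <- utils::read.table(genes_path, sep = "\t", header = TRUE, quote = "",
                         comment.char = "", stringsAsFactors = FALSE,
                         colClasses = "character")
  cl <- utils::read.table(clusters_path, sep = "\t", header = TRUE,
                          quote = "", comment.char = "",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  genes <- data.frame(gene_id = g$gene_id,
                      length_aa = as.integer(g$length_aa),
                      phylum = g$phylum, stringsAsFactors = FALSE)
  genes$evidence_flags <- split_semis(g$evidence_flags)
  genes$phenotype_flags <- split_semis(g$phenotype_flags)
  genes$cluster_ids <- split_semis(g$cluster_ids)
  clusters <- data.frame(cluster_id = cl$cluster_id,
                         has_computational_prediction =
                           toupper(cl$has_computational_prediction) %in%
                           c("TRUE", "1", "YES"),
                         stringsAsFactors = FALSE)
  clusters$member_ids <- split_semis(cl$member_ids)
  knowledge_base(genes, clusters)
}

#' @rdname read_knowledgebase
#' @param genes,clusters pre-built data.frames in the shapes documented above
#'   (list-columns already split).
#' @export
knowledge_base <- function(genes, clusters) {
  bad_flags <- setdiff(unlist(genes$evidence_flags), EVIDENCE_FLAGS)
  if (length(bad_flags)) {
    stop("unknown evidence flag(s): ", paste(bad_flags, collapse = ", "))
  }
  bad_ph <- setdiff(unlist(genes$phenotype_flags), PHENOTYPE_FLAGS)
  if (length(bad_ph)) {
    stop("unknown phenotype flag(s): ", paste(bad_ph, collapse = ", "))
  }
  dangling_cl <- setdiff(unlist(genes$cluster_ids), clusters$cluster_id)
  if (length(dangling_cl)) {
    stop("gene(s) reference unknown cluster(s): ",
         paste(dangling_cl, collapse = ", "))
  }
  dangling_g <- setdiff(unlist(clusters$member_ids), genes$gene_id)
  if (length(dangling_g)) {
    stop("cluster(s) reference unknown gene(s): ",
         paste(dangling_g, collapse = ", "))
  }
  phylum_of <- stats::setNames(genes$phylum, genes$gene_id)
  clusters$phyla <- lapply(clusters$member_ids,
                           function(m) sort(unique(unname(phylum_of[m]))))
  clusters$member_count <- vapply(clusters$member_ids, length, integer(1))
  if (any(clusters$member_count < 1L)) stop("empty cluster(s) not allowed")
  rownames(genes) <- genes$gene_id
  rownames(clusters) <- clusters$cluster_id
  structure(list(genes = genes, clusters = clusters),
            class = "knowledge_base")
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat(sprintf("<knowledge_base> %d genes, %d clusters\n",
              nrow(x$genes), nrow(x$clusters)))
  invisible(x)
}

join_semis <- function(lst) vapply(lst, paste, character(1), collapse = ";")

write_knowledgebase <- function(kb, genes_path, clusters_path) {
  g <- data.frame(gene_id = kb$genes$gene_id,
                  length_aa = kb$genes$length_aa,
                  phylum = kb$genes$phylum,
                  evidence_flags = join_semis(kb$genes$evidence_flags),
                  phenotype_flags = join_semis(kb$genes$phenotype_flags),
                  cluster_ids = join_semis(kb$genes$cluster_ids),
                  stringsAsFactors = FALSE)
  utils::write.table(g, genes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cl <- data.frame(cluster_id = kb$clusters$cluster_id,
                   has_computational_prediction =
                     kb$clusters$has_computational_prediction,
                   member_ids = join_semis(kb$clusters$member_ids),
                   stringsAsFactors = FALSE)
  utils::write.table(cl, clusters_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(genes_path)
}

## ---- Small auxiliary tables -------------------------------------------

#' Read the pathogen species list (one species per line)
#' @param path plain-text file; blank lines and `#` comments ignored.
#' @return character vector of species names.
#' @export
read_pathogen_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read the accession-to-center metadata table
#' @param path TSV with header columns `accession`, `center`.
#' @return data.frame with those two columns.
#' @export
read_center_metadata <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE, colClasses = "character")
}

#' Assign annotation centers to genome records
#' @param records list of [genome_record()] objects.
#' @param metadata data.frame from [read_center_metadata()].
#' @return the records with `center` filled in (`"Other"` when absent).
#' @export
assign_centers <- function(records, metadata) {
  lut <- stats::setNames(metadata$center, metadata$accession)
  lapply(records, function(r) {
    ctr <- lut[[r$accession]]
    r$center <- if (!is.null(ctr) && nzchar(ctr)) ctr else "Other"
    r
  })
}
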