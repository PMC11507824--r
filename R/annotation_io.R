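# Reading genome annotation into per-chromosome exon-length series.
#
# An "exon series" is the ordered sequence of exon lengths (bp) along one
# chromosome, indexed 1..n by rank of genomic start: the discrete "time
# series" the rest of the package analyses.

#' Parse exon records from GFF3 text
#'
#' Reads a GFF3 annotation (9 tab-separated columns, 1-based inclusive
#' coordinates) and returns one record per line whose feature type is
#' `"exon"`. Coordinates are preserved verbatim; order of appearance is
#' preserved. Strand is retained for provenance but plays no role in series
#' construction.
#'
#' @param path Path to a GFF3 file, or a character vector of GFF3 lines.
#' @param chromosome_filter Optional character vector; keep only exons on
#'   these sequence identifiers.
#' @return A data.frame with columns `chromosome`, `start`, `end`, `strand`,
#'   `gene_id` (NA when no `Parent=`/`gene_id` attribute is present) and
#'   `length` (= end - start + 1).
#' @examples
#' gff <- c("T1\tsrc\texon\t101\t200\t.\t+\t.\tParent=g1",
#'          "T1\tsrc\texon\t301\t450\t.\t+\t.\tParent=g1")
#' parse_exons(gff)
#' @export
parse_exons <- function(path, chromosome_filter = NULL) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  recs <- vector("list", sum(keep))
  j <- 0L
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L)
      abort(sprintf("malformed GFF3 line %d: expected >= 8 tab-separated columns, got %d",
                    i, length(f)), "superexon_parse_error")
    if (tolower(f[3]) != "exon") next
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end))
      abort(sprintf("malformed GFF3 line %d: non-numeric coordinates", i),
            "superexon_parse_error")
    if (end < start)
      abort(sprintf("malformed GFF3 line %d: end (%d) < start (%d)", i, end, start),
            "superexon_parse_error")
    strand <- if (length(f) >= 7L && f[7] %in% c("+", "-")) f[7] else "unknown"
    gene_id <- NA_character_
    if (length(f) >= 9L) {
      m <- regmatches(f[9], regexec("(?:Parent|gene_id)=([^;]+)", f[9]))[[1]]
      if (length(m) == 2L) gene_id <- m[2]
    }
    j <- j + 1L
    recs[[j]] <- data.frame(chromosome = f[1], start = start, end = end,
                            strand = strand, gene_id = gene_id,
                            stringsAsFactors = FALSE)
  }
  out <- if (j == 0L) {
    data.frame(chromosome = character(), start = integer(), end = integer(),
               strand = character(), gene_id = character(),
               stringsAsFactors = FALSE)
  } else do.call(rbind, recs[seq_len(j)])
  if (!is.null(chromosome_filter))
    out <- out[out$chromosome %in% chromosome_filter, , drop = FALSE]
  if (nrow(out) == 0L)
    abort("no exon records after filtering", "superexon_empty_input")
  out$length <- out$end - out$start + 1L
  rownames(out) <- NULL
  out
}

#' Build an exon-length series for one chromosome
#'
#' Orders the exons of `chromosome` (by genomic start by default; ties broken
#' by smaller end, then input order) and returns their lengths indexed
#' 1..n. The index, not the genomic coordinate, is the "time" variable of the
#' series.
#'
#' @param records Data.frame as returned by [parse_exons()].
#' @param chromosome Chromosome identifier to extract.
#' @param ordering `"by_start"` (default) or `"by_file_order"`.
#' @param dedup If `TRUE`, exact-duplicate intervals (same start and end,
#'   e.g. exons shared between transcript isoforms) are collapsed to one.
#'   Default keeps all.
#' @return An object of class `exon_series`: list with `chromosome`,
#'   `lengths` (positive integers) and `indices` (1..n).
#' @export
build_series <- function(records, chromosome,
                         ordering = c("by_start", "by_file_order"),
                         dedup = FALSE) {
  ordering <- match.arg(ordering)
  r <- records[records$chromosome == chromosome, , drop = FALSE]
  if (nrow(r) == 0L)
    abort(sprintf("no exon records for chromosome '%s'", chromosome),
          "superexon_empty_input")
  if (dedup) r <- r[!duplicated(r[, c("start", "end")]), , drop = FALSE]
  if (ordering == "by_start")
    r <- r[order(r$start, r$end), , drop = FALSE]  # stable: input order last
  exon_series(r$end - r$start + 1L, chromosome = chromosome)
}

#' Construct an exon-length series directly from lengths
#'
#' @param lengths Positive integer lengths (bp), in chromosome order.
#' @param chromosome Identifier attached to the series.
#' @return An `exon_series` object.
#' @export
exon_series <- function(lengths, chromosome = "chr") {
  lengths <- as.numeric(lengths)
  if (length(lengths) < 1L)
    abort("series must contain at least one exon", "superexon_empty_input")
  if (any(!is.finite(lengths)) || any(lengths < 1) ||
      any(lengths != round(lengths)))
    abort("exon lengths must be positive integers (bp)",
          "superexon_validation_error")
  structure(list(chromosome = as.character(chromosome),
                 lengths = as.integer(lengths),
                 indices = seq_along(lengths)),
            class = "exon_series")
}

#' @export
print.exon_series <- function(x, ...) {
  cat(sprintf("exon_series: %s, n = %d exons, lengths %d-%d bp (median %g)\n",
              x$chromosome, length(x$lengths), min(x$lengths), max(x$lengths),
              stats::median(x$lengths)))
  invisible(x)
}

#' @export
length.exon_series <- function(x) length(x$lengths)

#' Write / read a series as two-column TSV
#'
#' The plain interchange format: UTF-8, LF endings, header
#' `index<TAB>length_bp`. `read_series` reconstructs the series exactly
#' (round-trip safe).
#'
#' @param series An `exon_series`.
#' @param path File path.
#' @param chromosome Identifier attached on read.
#' @return `write_series` returns `path` invisibly; `read_series` returns an
#'   `exon_series`.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "exon_series"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("index\tlength_bp",
               paste(series$indices, series$lengths, sep = "\t")),
             con, sep = "\n")
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path, chromosome = "chr") {
  d <- utils::read.delim(path, header = TRUE, sep = "\t")
  if (!identical(names(d), c("index", "length_bp")))
    abort(sprintf("series file '%s' must have header 'index\\tlength_bp'", path),
          "superexon_parse_error")
  if (any(d$index != seq_len(nrow(d))))
    abort("series indices must be consecutive integers starting at 1",
          "superexon_validation_error")
  exon_series(d$length_bp, chromosome = chromosome)
}
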