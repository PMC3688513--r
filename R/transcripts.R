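#' Build a set of blocked transcript models
#'
#' The unit flowing through every filter stage: a transcript is a set of
#' sorted, disjoint exons on one chromosome with a strand that may be
#' ambiguous (`"."`). Most de novo assemblies from unstranded libraries
#' carry ambiguous strands, so `"."` is a first-class value here, not
#' missing data. Overlapping or abutting exons within one input transcript
#' are unioned on construction; downstream arithmetic assumes disjoint
#' exons.
#'
#' @param id Character vector of unique transcript ids.
#' @param chrom Chromosome name per transcript.
#' @param strand `"+"`, `"-"` or `"."` per transcript.
#' @param exon_starts,exon_ends Lists of integer vectors (0-based
#'   half-open), one vector per transcript.
#' @param source Optional origin tag (annotation set or dataset).
#' @return A `transcript_set`: a `data.frame` with columns `id`, `chrom`,
#'   `strand`, `start`, `end` (the genomic span) and list columns
#'   `exon_starts`, `exon_ends`, plus `source`.
#' @examples
#' tx <- transcript_set("t1", "chr1", "+", list(c(0L, 800L)),
#'                      list(c(300L, 1100L)))
#' exonic_length(tx)
#' @export
transcript_set <- function(id, chrom, strand, exon_starts, exon_ends,
                           source = NA_character_) {
  n <- length(id)
  stopifnot(length(exon_starts) == n, length(exon_ends) == n)
  if (anyDuplicated(id)) stop("transcript ids must be unique")
  chrom <- rep_len(as.character(chrom), n)
  strand <- rep_len(as.character(strand), n)
  if (!all(strand %in% c("+", "-", "."))) stop("strand must be +, - or .")
  source <- rep_len(source, n)
  es <- vector("list", n); ee <- vector("list", n)
  for (i in seq_len(n)) {
    s <- as.integer(exon_starts[[i]]); e <- as.integer(exon_ends[[i]])
    if (!length(s) || length(s) != length(e) || any(e <= s) || any(s < 0))
      stop("invalid exons for transcript ", id[i])
    r <- IRanges::reduce(ir0(s, e))  # sort + union overlapping/abutting
    es[[i]] <- IRanges::start(r) - 1L
    ee[[i]] <- IRanges::end(r)
  }
  out <- data.frame(id = as.character(id), chrom = as.character(chrom),
                    strand = strand,
                    start = vapply(es, `[`, integer(1), 1L),
                    end = vapply(ee, function(x) x[length(x)], integer(1)),
                    source = source, stringsAsFactors = FALSE)
  out$exon_starts <- es
  out$exon_ends <- ee
  class(out) <- c("transcript_set", "data.frame")
  out
}

#' @export
print.transcript_set <- function(x, ...) {
  cat(sprintf("transcript_set: %d transcript(s) on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  if (nrow(x)) {
    show <- utils::head(data.frame(
      id = x$id, chrom = x$chrom, strand = x$strand, start = x$start,
      end = x$end, n_exons = vapply(x$exon_starts, length, integer(1)),
      exonic_bp = exonic_length(x)), 10)
    print(show)
    if (nrow(x) > 10) cat("...\n")
  }
  invisible(x)
}

# Assemble a transcript_set from parts already known to be valid
# (sorted disjoint exons); skips the per-transcript normalization pass.
new_transcript_set <- function(id, chrom, strand, exon_starts, exon_ends,
                               source = NA_character_) {
  out <- data.frame(id = id, chrom = chrom, strand = strand,
                    start = vapply(exon_starts, `[`, integer(1), 1L),
                    end = vapply(exon_ends, function(x) x[length(x)],
                                 integer(1)),
                    source = rep_len(source, length(id)),
                    stringsAsFactors = FALSE)
  out$exon_starts <- exon_starts
  out$exon_ends <- exon_ends
  class(out) <- c("transcript_set", "data.frame")
  out
}

TX_CORE_COLS <- c("id", "chrom", "strand", "start", "end", "source",
                  "exon_starts", "exon_ends")

# Row-bind transcript sets (core columns only).
bind_transcripts <- function(...) {
  parts <- Filter(function(p) !is.null(p) && nrow(p) > 0, list(...))
  if (!length(parts)) stop("no transcripts to bind")
  out <- do.call(rbind, lapply(parts, function(p) {
    class(p) <- "data.frame"
    p[, TX_CORE_COLS]
  }))
  class(out) <- c("transcript_set", "data.frame")
  rownames(out) <- NULL
  out
}

#' Mature (exonic) length of each transcript
#'
#' The sum of exon lengths: the denominator of FPKM and the operand of the
#' minimum-length filter (lincRNAs are defined by RNA length, not genomic
#' span).
#'
#' @param tx A [transcript_set()].
#' @return Integer vector of exonic lengths in bp.
#' @export
exonic_length <- function(tx) {
  vapply(seq_len(nrow(tx)), function(i) {
    sum(tx$exon_ends[[i]] - tx$exon_starts[[i]])
  }, integer(1))
}

# Flat exon table: one row per exon with the owning transcript row index.
exon_table <- function(tx) {
  n_ex <- vapply(tx$exon_starts, length, integer(1))
  data.frame(tx_row = rep(seq_len(nrow(tx)), n_ex),
             chrom = rep(tx$chrom, n_ex),
             start = unlist(tx$exon_starts, use.names = FALSE) %||% integer(),
             end = unlist(tx$exon_ends, use.names = FALSE) %||% integer())
}

# Span table.
span_table <- function(tx) {
  data.frame(tx_row = seq_len(nrow(tx)), chrom = tx$chrom,
             start = tx$start, end = tx$end)
}

# Extract spliced (exon-concatenated, forward-strand) sequences from
# per-chromosome genome sequences (named character vector of strings).
#' Spliced transcript sequences from genome sequences
#'
#' Concatenates each transcript's exon sequence in genomic order on the
#' forward strand. The large-ORF caller scans all six frames, so the
#' orientation of extraction does not affect filtering.
#'
#' @param tx A [transcript_set()].
#' @param genome_seq Named character vector: one uppercase ACGTN string per
#'   chromosome.
#' @return Named character vector of spliced sequences (names = `tx$id`).
#' @export
transcript_sequences <- function(tx, genome_seq) {
  miss <- setdiff(unique(tx$chrom), names(genome_seq))
  if (length(miss)) stop("no sequence for chromosome(s): ",
                         paste(miss, collapse = ", "))
  out <- vapply(seq_len(nrow(tx)), function(i) {
    s <- tx$exon_starts[[i]]; e <- tx$exon_ends[[i]]
    paste(substring(genome_seq[[tx$chrom[i]]], s + 1L, e), collapse = "")
  }, character(1))
  setNames(out, tx$id)
}
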