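#' Parse BED12 lines into a transcript set
#'
#' A strict BED12 reader for transcript models. Block arithmetic is
#' validated (block count vs. size/start lists, blocks within the span,
#' positive sizes); malformed records raise an error naming the offending
#' line. Strand `"."` maps to ambiguous.
#'
#' @param lines Character vector of tab-separated BED12 records.
#' @param source Source tag stored on the parsed transcripts.
#' @return A [transcript_set()].
#' @examples
#' parse_bed12("chr1\t100\t1100\ttx1\t0\t+\t100\t100\t0\t2\t200,300\t0,700")
#' @export
parse_bed12 <- function(lines, source = NA_character_) {
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(transcript_set(character(0), character(0), character(0),
                          list(), list())[0, ])
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields != 12L))
    stop("line ", which(n_fields != 12L)[1],
         ": expected 12 tab-separated fields, got ", n_fields[n_fields != 12L][1])
  parse_int_list <- function(s) as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
  n <- length(fields)
  id <- character(n); chrom <- character(n); strand <- character(n)
  es <- vector("list", n); ee <- vector("list", n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    chrom[i] <- f[1]
    cs <- suppressWarnings(as.integer(f[2]))
    cn <- suppressWarnings(as.integer(f[3]))
    if (is.na(cs) || is.na(cn) || cn <= cs)
      stop("line ", i, ": invalid chromStart/chromEnd")
    id[i] <- f[4]
    strand[i] <- if (f[6] %in% c("+", "-")) f[6] else "."
    bc <- suppressWarnings(as.integer(f[10]))
    sizes <- suppressWarnings(parse_int_list(f[11]))
    starts <- suppressWarnings(parse_int_list(f[12]))
    if (is.na(bc) || length(sizes) != bc || length(starts) != bc)
      stop("line ", i, ": blockCount does not match blockSizes/blockStarts")
    if (anyNA(sizes) || anyNA(starts) || any(sizes <= 0) || any(starts < 0))
      stop("line ", i, ": negative or non-numeric block sizes/starts")
    s <- cs + starts
    e <- s + sizes
    if (any(e > cn) || starts[1] != 0L || e[bc] != cn)
      stop("line ", i, ": blocks exceed or do not tile the transcript span")
    if (bc > 1 && any(s[-1] < e[-bc]))
      stop("line ", i, ": blocks out of order or overlapping")
    es[[i]] <- s; ee[[i]] <- e
  }
  transcript_set(id, chrom, strand, es, ee, source = source)
}

#' Read a BED12 file of transcript models
#' @param path File path.
#' @param source Source tag stored on the parsed transcripts.
#' @return A [transcript_set()].
#' @export
read_bed12 <- function(path, source = basename(path)) {
  parse_bed12(readLines(path), source = source)
}

#' Format a transcript set as BED12 lines
#' @param tx A [transcript_set()].
#' @param names Record names; defaults to `tx$id`.
#' @param score Score column (recycled).
#' @return Character vector of tab-separated BED12 records.
#' @export
format_bed12 <- function(tx, names = tx$id, score = 0L) {
  score <- rep_len(score, nrow(tx))
  vapply(seq_len(nrow(tx)), function(i) {
    s <- tx$exon_starts[[i]]; e <- tx$exon_ends[[i]]
    paste(tx$chrom[i], tx$start[i], tx$end[i], names[i], score[i],
          tx$strand[i], tx$start[i], tx$end[i], "0", length(s),
          paste0(paste(e - s, collapse = ","), ","),
          paste0(paste(s - tx$start[i], collapse = ","), ","),
          sep = "\t")
  }, character(1))
}

#' Write a transcript set as BED12
#' @inheritParams format_bed12
#' @param path Output file path.
#' @return Invisibly, `path`. Tab-separated, newline-terminated, no header.
#' @export
write_bed12 <- function(tx, path, names = tx$id, score = 0L) {
  writeLines(format_bed12(tx, names = names, score = score), path)
  invisible(path)
}

#' Read a BED3/BED6 interval file
#' @param path File path.
#' @return `data.frame` with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  d <- data.table::fread(path, header = FALSE, sep = "\t",
                         data.table = FALSE)
  names(d)[1:3] <- c("chrom", "start", "end")
  if (ncol(d) >= 6) names(d)[4:6] <- c("name", "score", "strand")
  d
}

#' Write intervals as BED
#' @param intervals `data.frame` with `chrom`, `start`, `end` and
#'   optionally `name`, `score`, `strand`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(intervals))
  data.table::fwrite(intervals[, cols, drop = FALSE], path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Write a depth profile or score track as bedGraph
#' @param track Named list (per chromosome) of numeric vectors or
#'   [S4Vectors::Rle] objects over `[0, chrom length)`.
#' @param path Output file path.
#' @return Invisibly, `path`. Zero runs are omitted, as is conventional.
#' @export
write_bedgraph <- function(track, path) {
  parts <- lapply(names(track), function(ch) {
    r <- track[[ch]]
    if (!methods::is(r, "Rle")) r <- S4Vectors::Rle(r)
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- ends - S4Vectors::runLength(r)
    v <- S4Vectors::runValue(r)
    keep <- !is.na(v) & v != 0
    if (!any(keep)) return(NULL)
    data.frame(chrom = ch, start = starts[keep], end = ends[keep],
               value = v[keep])
  })
  out <- do.call(rbind, parts)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), value = numeric())
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a SNP table
#'
#' Tab-separated columns `snp_id`, `chrom`, `pos`, `platform`,
#' `trait_associated`, `common`. Positions in the file are 1-based (the
#' convention of SNP tables) and are converted to 0-based here.
#'
#' @param path File path.
#' @return `data.frame` with 0-based `pos`.
#' @export
read_snp_table <- function(path) {
  d <- data.table::fread(path, sep = "\t", data.table = FALSE)
  stopifnot(all(c("snp_id", "chrom", "pos", "platform",
                  "trait_associated", "common") %in% names(d)))
  d$pos <- as.integer(d$pos) - 1L
  d$trait_associated <- as.logical(d$trait_associated)
  d$common <- as.logical(d$common)
  d
}

#' Write a SNP table
#' @param snps `data.frame` as produced by the simulator (0-based `pos`).
#' @param path Output file path.
#' @return Invisibly, `path`. Positions are written 1-based.
#' @export
write_snp_table <- function(snps, path) {
  out <- snps
  out$pos <- as.integer(out$pos) + 1L
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
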