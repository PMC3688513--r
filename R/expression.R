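#' Full-assignment read counting
#'
#' Counts reads per transcript with full assignment: a read increments the
#' count of every transcript whose exons its aligned blocks overlap by at
#' least one base. No fractional splitting is done — redundant annotations
#' of the same underlying transcript (repeated de novo assemblies, legacy
#' database entries with slightly different coordinates) each receive the
#' full read. A read whose blocks fall wholly within an intron of a
#' transcript does not count for that transcript; reads overlapping no
#' transcript are ignored.
#'
#' @param reads Read table (`read_id`, `chrom`, `start`, `end`, optionally
#'   `strand`), one row per aligned block.
#' @param tx A [transcript_set()].
#' @param stranded If `TRUE`, a read only counts for a transcript when the
#'   strands are compatible (ambiguous matches both). Defaults to `FALSE`:
#'   most source libraries are unstranded.
#' @return Named integer vector of counts, one per transcript id.
#' @export
count_reads_full_assignment <- function(reads, tx, stranded = FALSE) {
  counts <- count_on_read_index(read_index(reads), tx, stranded = stranded)
  setNames(counts, tx$id)
}

# Pre-split read blocks by chromosome with ready-made IRanges, so many
# transcript batches can be counted against the same dataset cheaply.
read_index <- function(reads) {
  if (is.null(reads) || !nrow(reads)) return(list())
  out <- lapply(split(seq_len(nrow(reads)), reads$chrom), function(i) {
    list(ir = ir0(reads$start[i], reads$end[i]),
         read_id = reads$read_id[i],
         strand = if (!is.null(reads$strand)) reads$strand[i])
  })
  out
}

count_on_read_index <- function(idx, tx, stranded = FALSE) {
  counts <- integer(nrow(tx))
  if (!nrow(tx) || !length(idx)) return(counts)
  ex <- exon_table(tx)
  for (ch in intersect(names(idx), unique(ex$chrom))) {
    e <- ex[ex$chrom == ch, , drop = FALSE]
    ov <- IRanges::findOverlaps(idx[[ch]]$ir, ir0(e$start, e$end))
    if (!length(ov)) next
    rid <- idx[[ch]]$read_id[S4Vectors::queryHits(ov)]
    trow <- e$tx_row[S4Vectors::subjectHits(ov)]
    if (stranded && !is.null(idx[[ch]]$strand)) {
      rs <- idx[[ch]]$strand[S4Vectors::queryHits(ov)]
      ts <- tx$strand[trow]
      keep <- rs == "." | ts == "." | rs == ts
      rid <- rid[keep]; trow <- trow[keep]
    }
    key <- as.numeric(rid) * (nrow(tx) + 1) + trow  # exact below 2^53
    dup <- duplicated(key)
    counts <- counts + tabulate(trow[!dup], nbins = nrow(tx))
  }
  counts
}

#' Convert a read count to FPKM
#'
#' FPKM = count x 10^9 / (exonic length x total mapped reads). The total
#' is the dataset-wide mapped-read count (the library's flagstat total),
#' not the number of reads passed to the counter, so counting a subset
#' region still yields dataset-scale FPKMs.
#'
#' @param count Read count(s).
#' @param length_bp Exonic (mature) length(s) in bp, >= 1.
#' @param total_mapped Total mapped reads in the dataset, >= 1.
#' @return Numeric FPKM value(s).
#' @examples
#' fpkm(100, 1000, 1e7)  # 10
#' @export
fpkm <- function(count, length_bp, total_mapped) {
  if (any(length_bp < 1) || any(total_mapped < 1))
    stop("exonic length and total mapped reads must be >= 1")
  count * 1e9 / (as.numeric(length_bp) * as.numeric(total_mapped))
}

#' Counts and FPKMs for transcripts across datasets
#'
#' @param reads_by_dataset Named list of read tables, one per dataset.
#' @param tx A [transcript_set()].
#' @param dataset_info `data.frame` with `dataset_id` and
#'   `total_mapped_reads` (and optionally `library_type`, `tissue`).
#' @param stranded Passed to [count_reads_full_assignment()].
#' @return An `expression_matrix`: list with integer matrix `counts`,
#'   numeric matrix `fpkm` (rows = transcripts, columns = datasets),
#'   `lengths`, and the `datasets` table.
#' @export
expression_matrix <- function(reads_by_dataset, tx, dataset_info,
                              stranded = FALSE) {
  stopifnot(all(names(reads_by_dataset) %in% dataset_info$dataset_id))
  lens <- setNames(exonic_length(tx), tx$id)
  counts <- sapply(names(reads_by_dataset), function(ds) {
    count_reads_full_assignment(reads_by_dataset[[ds]], tx,
                                stranded = stranded)
  })
  counts <- matrix(counts, nrow = nrow(tx),
                   dimnames = list(tx$id, names(reads_by_dataset)))
  totals <- dataset_info$total_mapped_reads[
    match(colnames(counts), dataset_info$dataset_id)]
  fp <- sweep(counts * 1e9 / as.numeric(lens), 2, as.numeric(totals), "/")
  structure(list(counts = counts, fpkm = fp, lengths = lens,
                 datasets = dataset_info),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d transcripts x %d datasets\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Expression tier of each transcript
#'
#' Tiers are assigned from the maximum FPKM across datasets with strict
#' comparisons: `fail` (never above `tiers[1]`), then one tier per
#' threshold. Tier sets are nested: every transcript above 30 is also in
#' the >10 and >1 sets.
#'
#' @param em An [expression_matrix()].
#' @param tiers Strictly increasing FPKM thresholds (default `c(1, 10,
#'   30)`).
#' @return Named character vector with values `"fail"` or `"fpkm<t>"`.
#' @export
expression_tiers <- function(em, tiers = c(1, 10, 30)) {
  stopifnot(length(tiers) >= 1, all(diff(tiers) > 0))
  mx <- apply(em$fpkm, 1, max)
  labs <- c("fail", paste0("fpkm", tiers))
  idx <- vapply(mx, function(v) sum(v > tiers), integer(1)) + 1L
  setNames(labs[idx], rownames(em$fpkm))
}

#' Write count and FPKM matrices as TSV
#' @param em An [expression_matrix()].
#' @param counts_path,fpkm_path Output paths.
#' @return Invisibly, `NULL`.
#' @export
write_expression_matrix <- function(em, counts_path, fpkm_path) {
  wr <- function(m, path) {
    d <- data.frame(transcript_id = rownames(m), m, check.names = FALSE)
    data.table::fwrite(d, path, sep = "\t")
  }
  wr(em$counts, counts_path)
  wr(em$fpkm, fpkm_path)
  invisible(NULL)
}
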