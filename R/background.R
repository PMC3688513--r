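#' Build the intergenic background space
#'
#' The eligible space for shuffled size-matched annotations: the uniquely
#' mappable genome minus the union of every exclusion set (known genes,
#' the lincRNA catalog itself, UTR extensions, extended gene boundaries,
#' ...). Pieces of 200 bp or less are discarded — background loci must be
#' longer than 200 bp, matching the minimum lincRNA size.
#'
#' @param genome A [genome_spec()].
#' @param exclusions List of interval `data.frame`s or
#'   [transcript_set()]s (spans are excluded).
#' @param min_bp Minimum retained interval width; keep width > `min_bp`
#'   (default 200).
#' @return A `background_space`: interval `data.frame` (`chrom`, `start`,
#'   `end`), disjoint, within the mask, overlapping no exclusion.
#' @export
build_background_space <- function(genome, exclusions, min_bp = 200L) {
  excl <- lapply(exclusions, function(e) {
    if (is.null(e) || !nrow(e)) return(NULL)
    iv <- if (inherits(e, "transcript_set")) span_table(e) else e
    iv[, c("chrom", "start", "end")]
  })
  excl <- do.call(rbind, Filter(Negate(is.null), excl))
  space <- genome$mask
  if (!is.null(excl) && nrow(excl)) space <- subtract_intervals(space, excl)
  space <- space[space$end - space$start > min_bp, , drop = FALSE]
  if (!nrow(space)) stop("background space is empty after exclusions")
  rownames(space) <- NULL
  class(space) <- c("background_space", "data.frame")
  space
}

#' Shuffle an annotation across the background space
#'
#' Places size-matched copies of a transcript uniformly at random over the
#' eligible intergenic space: the exon/intron structure is preserved and
#' translated to a start position chosen uniformly over all positions (on
#' any chromosome) where the full span fits inside one eligible interval.
#'
#' @param t A single-row [transcript_set()].
#' @param space A [build_background_space()] result.
#' @param n Number of placements to draw.
#' @return A [transcript_set()] of `n` placed copies (ids suffixed
#'   `_shuf<i>`). Uses the current RNG state; seed outside for
#'   reproducibility.
#' @export
shuffle_annotation <- function(t, space, n = 1L) {
  span_w <- t$end[1] - t$start[1]
  cap <- pmax(0, (space$end - space$start) - span_w + 1)
  total <- sum(as.numeric(cap))
  if (total <= 0)
    stop("no eligible background interval can contain a span of ", span_w,
         " bp")
  u <- ceiling(runif(n) * total)        # uniform over all valid starts
  cum <- cumsum(as.numeric(cap))
  iv <- findInterval(u - 1, cum) + 1L   # which eligible interval
  offset <- u - c(0, cum)[iv] - 1       # 0-based offset within interval
  new_start <- space$start[iv] + as.integer(offset)
  rel_s <- t$exon_starts[[1]] - t$start[1]
  rel_e <- t$exon_ends[[1]] - t$start[1]
  new_transcript_set(paste0(t$id[1], "_shuf", seq_len(n)),
                     space$chrom[iv], rep(t$strand[1], n),
                     lapply(new_start, function(s) as.integer(s + rel_s)),
                     lapply(new_start, function(s) as.integer(s + rel_e)),
                     source = "shuffled")
}

#' Empirical p-value against a shuffled null
#'
#' Add-one permutation estimator: `p = (1 + #\{null >= observed\}) / (1 +
#' n_shuffles)`. Never returns 0; monotone non-increasing in the observed
#' value.
#'
#' @param observed Observed FPKM (scalar or vector).
#' @param null Numeric vector of null FPKMs from shuffled placements.
#' @return Numeric p-value(s) in `(0, 1]`.
#' @export
empirical_pvalue <- function(observed, null) {
  vapply(observed, function(o) (1 + sum(null >= o)) / (1 + length(null)),
         numeric(1))
}

#' Bonferroni significance across datasets
#'
#' One test per RNA-seq dataset: each empirical p is multiplied by the
#' number of datasets (capped at 1); a transcript is significantly
#' expressed above the intergenic background when its best corrected p is
#' at most `alpha` in at least one dataset.
#'
#' @param p Numeric vector of per-dataset empirical p-values.
#' @param n_datasets Number of datasets tested (defaults to `length(p)`).
#' @param alpha Corrected significance level (default 0.1).
#' @return List: `significant`, `best_p` (corrected), `best_dataset`
#'   (index or name of the minimizing entry).
#' @export
bonferroni_significant <- function(p, n_datasets = length(p), alpha = 0.1) {
  stopifnot(n_datasets >= 1)
  corrected <- pmin(1, p * n_datasets)
  best <- which.min(corrected)
  list(significant = corrected[best] <= alpha,
       best_p = unname(corrected[best]),
       best_dataset = if (!is.null(names(p))) names(p)[best] else best)
}

#' Test a catalog for expression above the intergenic background
#'
#' For every catalog transcript, draws `n_shuffles` size-matched shuffled
#' placements across the background space, scores observed and shuffled
#' placements with full-assignment counting in every dataset, converts to
#' FPKM with each dataset's total, and reports the per-dataset empirical
#' p-values with the Bonferroni decision. Placements are drawn once per
#' transcript and scored against every dataset; the null distribution is
#' dataset-specific through the counts and totals.
#'
#' @param tx Catalog [transcript_set()].
#' @param reads_by_dataset Named list of read tables.
#' @param dataset_info `data.frame` with `dataset_id`,
#'   `total_mapped_reads`.
#' @param space A [build_background_space()] result.
#' @param n_shuffles Null size per transcript (default 10000; reduce for
#'   quick runs).
#' @param alpha Corrected significance level (default 0.1).
#' @param seed Seed for the placement RNG stream.
#' @return `data.frame` per transcript: `id`, `significant`, `best_p`,
#'   `best_dataset`, plus per-dataset observed FPKM and p columns.
#' @export
background_significance <- function(tx, reads_by_dataset, dataset_info,
                                    space, n_shuffles = 10000L, alpha = 0.1,
                                    seed = 1L) {
  ds_ids <- names(reads_by_dataset)
  totals <- setNames(dataset_info$total_mapped_reads[
    match(ds_ids, dataset_info$dataset_id)], ds_ids)
  lens <- exonic_length(tx)
  placements <- with_stream(seed, "background_shuffle", {
    lapply(seq_len(nrow(tx)), function(i) {
      shuffle_annotation(tx[i, , drop = FALSE], space, n = n_shuffles)
    })
  })
  idx <- lapply(reads_by_dataset, read_index)
  out <- vector("list", nrow(tx))
  for (i in seq_len(nrow(tx))) {
    both <- bind_transcripts(tx[i, , drop = FALSE], placements[[i]])
    row <- list(id = tx$id[i])
    p <- setNames(numeric(length(ds_ids)), ds_ids)
    for (ds in ds_ids) {
      cts <- count_on_read_index(idx[[ds]], both)
      fp <- fpkm(cts, lens[i], totals[[ds]])
      p[[ds]] <- empirical_pvalue(fp[1], fp[-1])
      row[[paste0("fpkm_", ds)]] <- unname(fp[1])
      row[[paste0("p_", ds)]] <- unname(p[[ds]])
    }
    dec <- bonferroni_significant(p, length(ds_ids), alpha)
    row$significant <- dec$significant
    row$best_p <- dec$best_p
    row$best_dataset <- dec$best_dataset
    out[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
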