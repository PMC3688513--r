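#' Pool read tables from several datasets
#'
#' Offsets read ids so they stay unique across datasets — required before
#' computing a combined depth profile, where blocks sharing a `read_id`
#' are treated as one (split) read.
#'
#' @param reads_list Named list of read tables.
#' @return One combined read table.
#' @export
pool_reads <- function(reads_list) {
  off <- 0
  parts <- lapply(reads_list, function(r) {
    r$read_id <- r$read_id + off
    off <<- max(r$read_id) + 1
    r
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Per-base read depth profile
#'
#' Computes read depth at every genomic position, stored run-length
#' encoded. Two modes mirror the two ways of treating split (exon-exon
#' junction spanning) reads:
#'
#' * `including_inferred`: each read fills its whole span from the first
#'   block start to the last block end, so the intronic sequence implied by
#'   a junction read is counted as transcribed ("inferred" bases).
#' * `excluding_inferred`: only aligned blocks are filled.
#'
#' The mappability mask is applied at query time by the downstream
#' summaries, not here, so one profile can serve several masks.
#'
#' @param reads A read table: `data.frame` with one row per aligned block
#'   and columns `read_id`, `chrom`, `start`, `end` (0-based half-open).
#' @param genome A [genome_spec()].
#' @param mode `"excluding_inferred"` or `"including_inferred"`.
#' @return A `depth_profile`: named list (per chromosome) of integer
#'   [S4Vectors::Rle] depth vectors covering `[0, chrom length)`, with
#'   attribute `mode`.
#' @export
depth_profile <- function(reads, genome,
                          mode = c("excluding_inferred", "including_inferred")) {
  mode <- match.arg(mode)
  if (!all(reads$chrom %in% names(genome$seqlengths)))
    stop("reads on unknown chromosomes")
  if (any(reads$end > genome$seqlengths[reads$chrom]) || any(reads$start < 0))
    stop("read beyond chromosome end")
  rd <- data.table::as.data.table(reads)
  if (mode == "including_inferred") {
    rd <- rd[, list(start = min(start), end = max(end)),
             by = c("chrom", "read_id")]
  }
  prof <- lapply(names(genome$seqlengths), function(ch) {
    d <- rd[rd$chrom == ch]
    IRanges::coverage(ir0(d$start, d$end), width = genome$seqlengths[[ch]])
  })
  names(prof) <- names(genome$seqlengths)
  structure(prof, mode = mode, class = "depth_profile")
}

# Logical Rle per chromosome: TRUE on mappable positions.
mask_rle <- function(genome) {
  out <- lapply(names(genome$seqlengths), function(ch) {
    IRanges::coverage(mask_ir(genome, ch),
                      width = genome$seqlengths[[ch]]) > 0L
  })
  names(out) <- names(genome$seqlengths)
  out
}

# Logical Rle per chromosome from an interval data.frame.
intervals_rle <- function(intervals, genome) {
  out <- lapply(names(genome$seqlengths), function(ch) {
    d <- intervals[intervals$chrom == ch, , drop = FALSE]
    IRanges::coverage(ir0(d$start, d$end), width = genome$seqlengths[[ch]]) > 0L
  })
  names(out) <- names(genome$seqlengths)
  out
}

#' Fraction of the mappable genome covered at depth thresholds
#'
#' @param profile A [depth_profile()].
#' @param genome A [genome_spec()]; fractions are of its mappable size.
#' @param thresholds Integer vector of minimum read depths (>= 1).
#' @return Named numeric vector: for each threshold `k`, the fraction of
#'   mappable positions with depth >= `k`. Monotone non-increasing in `k`.
#' @export
covered_fraction_at_thresholds <- function(profile, genome, thresholds) {
  stopifnot(all(thresholds >= 1))
  mk <- mask_rle(genome)
  total <- mappable_size(genome)
  if (total == 0) stop("empty mappability mask")
  out <- vapply(thresholds, function(k) {
    sum(vapply(names(profile), function(ch) {
      sum(as.numeric(S4Vectors::runLength(profile[[ch]] >= k & mk[[ch]])[
        S4Vectors::runValue(profile[[ch]] >= k & mk[[ch]])]))
    }, numeric(1))) / total
  }, numeric(1))
  setNames(out, as.character(thresholds))
}

#' Depth-weighted base-call distribution by region label
#'
#' For each region label and read depth `d`, base calls = (number of
#' mappable positions in the label at depth `d`) x `d`: the depth-weighted
#' unit used to show where sequenced bases fall (exon / intron /
#' intergenic).
#'
#' @param profile A [depth_profile()].
#' @param regions Named list of interval `data.frame`s (`chrom`, `start`,
#'   `end`), one per label.
#' @param genome A [genome_spec()]; positions outside the mask are dropped.
#' @return `data.frame` with columns `label`, `depth`, `n_positions`,
#'   `base_calls`. Depth-0 positions are omitted.
#' @export
basecall_depth_distribution <- function(profile, regions, genome) {
  mk <- mask_rle(genome)
  parts <- lapply(names(regions), function(lab) {
    sel <- intervals_rle(regions[[lab]], genome)
    tabs <- lapply(names(profile), function(ch) {
      r <- profile[[ch]][as.vector(sel[[ch]] & mk[[ch]])]
      if (!length(r)) return(NULL)
      data.frame(depth = S4Vectors::runValue(r),
                 n = S4Vectors::runLength(r))
    })
    tab <- do.call(rbind, tabs)
    if (is.null(tab)) return(NULL)
    agg <- stats::aggregate(n ~ depth, tab, sum)
    agg <- agg[agg$depth > 0, , drop = FALSE]
    if (!nrow(agg)) return(NULL)
    data.frame(label = lab, depth = agg$depth, n_positions = agg$n,
               base_calls = agg$depth * agg$n)
  })
  out <- do.call(rbind, parts)
  if (is.null(out))
    out <- data.frame(label = character(), depth = integer(),
                      n_positions = integer(), base_calls = numeric())
  out[order(out$label, out$depth), , drop = FALSE]
}

#' Mappable fraction covered by reads plus annotations
#'
#' The union bookkeeping behind "how much of the genome is transcribed or
#' annotated": the fraction of the mappable genome covered by read-covered
#' bases (depth >= 1 in the supplied profile) unioned with the spans of
#' any number of named annotation sets. Annotation spans include introns.
#'
#' @param profile A [depth_profile()].
#' @param annotations List of interval `data.frame`s (`chrom`, `start`,
#'   `end`); transcript sets are accepted and contribute their spans.
#' @param genome A [genome_spec()].
#' @return Fraction in `[0, 1]`.
#' @export
annotation_union_coverage <- function(profile, annotations, genome) {
  mk <- mask_rle(genome)
  spans <- lapply(annotations, function(a) {
    if (inherits(a, "transcript_set")) span_table(a) else a
  })
  covered <- vapply(names(profile), function(ch) {
    u <- profile[[ch]] >= 1L
    for (a in spans) {
      d <- a[a$chrom == ch, , drop = FALSE]
      u <- u | (IRanges::coverage(ir0(d$start, d$end),
                                  width = genome$seqlengths[[ch]]) > 0L)
    }
    u <- u & mk[[ch]]
    sum(as.numeric(S4Vectors::runLength(u)[S4Vectors::runValue(u)]))
  }, numeric(1))
  sum(covered) / mappable_size(genome)
}

#' Fraction of reads in flattened coding exons, per dataset
#'
#' Library-type quality control: polyA+ libraries are expected to show a
#' higher fraction of reads in protein-coding exons than polyA- or
#' rRNA-depleted libraries; an outlier suggests genomic DNA contamination.
#' Exons of all isoforms are flattened (unioned) before reads are
#' assigned; a read is exonic if any aligned block overlaps a flattened
#' exonic base.
#'
#' @param reads_by_dataset Named list of read tables (see
#'   [depth_profile()]).
#' @param coding_exons Interval `data.frame` or [transcript_set()] whose
#'   exons define the coding-exon space.
#' @return `data.frame` with `dataset`, `exonic_fraction`,
#'   `other_fraction` (fractions sum to 1 per dataset).
#' @export
read_region_distribution <- function(reads_by_dataset, coding_exons) {
  ex <- if (inherits(coding_exons, "transcript_set"))
    exon_table(coding_exons) else coding_exons
  ex <- normalize_intervals(ex)
  parts <- lapply(names(reads_by_dataset), function(ds) {
    rd <- reads_by_dataset[[ds]]
    n_reads <- length(unique(rd$read_id))
    hit_ids <- unlist(lapply(unique(rd$chrom), function(ch) {
      d <- rd[rd$chrom == ch, , drop = FALSE]
      e <- ex[ex$chrom == ch, , drop = FALSE]
      if (!nrow(e)) return(NULL)
      ov <- IRanges::findOverlaps(ir0(d$start, d$end), ir0(e$start, e$end))
      d$read_id[unique(S4Vectors::queryHits(ov))]
    }))
    exonic <- length(unique(hit_ids)) / n_reads
    data.frame(dataset = ds, exonic_fraction = exonic,
               other_fraction = 1 - exonic)
  })
  do.call(rbind, parts)
}
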