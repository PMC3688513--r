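#' Genome specification with a uniquely-mappable mask
#'
#' Bundles chromosome lengths with the uniquely mappable portion of the
#' genome. All coverage fractions and the intergenic background space are
#' computed within the mask, mirroring analyses restricted to the uniquely
#' mappable genome (the regions to which short reads map to one place only).
#'
#' Coordinates throughout the package are 0-based half-open (BED
#' convention); 1-based inputs such as SNP position tables are converted at
#' the reader boundary.
#'
#' @param seqlengths Named integer vector of chromosome lengths (bp).
#' @param mask `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open) giving the uniquely mappable intervals. Intervals are
#'   sorted and unioned per chromosome on construction. Defaults to the
#'   whole genome.
#' @return An object of class `genome_spec`: a list with elements
#'   `seqlengths` and `mask`.
#' @examples
#' g <- genome_spec(c(chr1 = 1000L),
#'                  data.frame(chrom = "chr1", start = 0, end = 900))
#' mappable_size(g)
#' @export
genome_spec <- function(seqlengths, mask = NULL) {
  stopifnot(is.numeric(seqlengths), length(seqlengths) >= 1,
            !is.null(names(seqlengths)), all(seqlengths >= 1))
  seqlengths <- setNames(as.integer(seqlengths), names(seqlengths))
  if (is.null(mask)) {
    mask <- data.frame(chrom = names(seqlengths), start = 0L,
                       end = unname(seqlengths))
  }
  stopifnot(all(c("chrom", "start", "end") %in% names(mask)))
  if (!all(mask$chrom %in% names(seqlengths)))
    stop("mask contains intervals on unknown chromosomes")
  mask <- normalize_intervals(mask)
  bad <- mask$end > seqlengths[mask$chrom] | mask$start < 0
  if (any(bad)) stop("mask intervals outside chromosome bounds")
  structure(list(seqlengths = seqlengths, mask = mask),
            class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("genome_spec: %d chromosome(s), %s bp total, %s bp mappable\n",
              length(x$seqlengths),
              format(sum(as.numeric(x$seqlengths)), big.mark = ","),
              format(mappable_size(x), big.mark = ",")))
  invisible(x)
}

#' Total mappable size of a genome
#' @param genome A [genome_spec()].
#' @return Number of uniquely mappable bases.
#' @export
mappable_size <- function(genome) {
  sum(as.numeric(genome$mask$end - genome$mask$start))
}

# Sort and union (overlapping or abutting) intervals per chromosome.
normalize_intervals <- function(df) {
  stopifnot(all(df$end > df$start))
  parts <- lapply(split(df, df$chrom), function(d) {
    r <- IRanges::reduce(ir0(d$start, d$end))
    cbind(chrom = d$chrom[1], from_ir0(r))
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

# Mask intervals of one chromosome as IRanges.
mask_ir <- function(genome, chrom) {
  m <- genome$mask[genome$mask$chrom == chrom, , drop = FALSE]
  ir0(m$start, m$end)
}

#' Overlap between two intervals in base pairs
#'
#' @param a,b Lists or one-row data.frames with `chrom`, `start`, `end`
#'   (0-based half-open). Vectors of equal length are accepted.
#' @return `max(0, min(ends) - max(starts))` when the chromosomes match;
#'   0 for intervals on different chromosomes (by contract, not an error).
#' @examples
#' exon_overlap_bp(list(chrom = "c", start = 100, end = 300),
#'                 list(chrom = "c", start = 250, end = 400))  # 50
#' @export
exon_overlap_bp <- function(a, b) {
  same <- a$chrom == b$chrom
  ov <- pmax(0, pmin(a$end, b$end) - pmax(a$start, b$start))
  ifelse(same, ov, 0)
}

#' Gap between two genomic spans in base pairs
#'
#' The distance used by the 1 kb proximity filter and by proximity
#' grouping: 0 when the spans overlap, the number of intervening bases
#' otherwise, and `Inf` for spans on different chromosomes.
#'
#' @param a,b Lists or data.frames with `chrom`, `start`, `end`.
#' @return Non-negative distance in bp (possibly `Inf`).
#' @examples
#' gap_distance(list(chrom = "c", start = 0, end = 100),
#'              list(chrom = "c", start = 1100, end = 1200))  # 1000
#' @export
gap_distance <- function(a, b) {
  same <- a$chrom == b$chrom
  d <- pmax(0, pmax(a$start, b$start) - pmin(a$end, b$end))
  ifelse(same, d, Inf)
}

# Subtract interval set b from interval set a (both data.frames with
# chrom/start/end), returning normalized intervals.
subtract_intervals <- function(a, b) {
  a <- normalize_intervals(a)
  parts <- lapply(split(a, a$chrom), function(d) {
    ch <- d$chrom[1]
    bi <- b[b$chrom == ch, , drop = FALSE]
    r <- ir0(d$start, d$end)
    if (nrow(bi)) r <- IRanges::setdiff(r, IRanges::reduce(ir0(bi$start, bi$end)))
    if (!length(r)) return(NULL)
    cbind(chrom = ch, from_ir0(r))
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) out <- data.frame(chrom = character(), start = integer(),
                                      end = integer())
  rownames(out) <- NULL
  out
}
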