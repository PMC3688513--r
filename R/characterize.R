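# Per-window read counts over a transcript's spliced coordinate space.
# Windows of `window` nt tile the concatenated exonic sequence with a 1 nt
# offset; a read counts for a window when any of its aligned blocks,
# intersected with the exons and projected to transcript coordinates,
# overlaps the window by >= 1 nt.
transcript_window_counts <- function(reads, t, window) {
  L <- exonic_length(t)
  nwin <- L - window + 1L
  ex_s <- t$exon_starts[[1]]; ex_e <- t$exon_ends[[1]]
  cum <- cumsum(c(0L, ex_e - ex_s))
  rd <- reads[reads$chrom == t$chrom[1], , drop = FALSE]
  if (!nrow(rd)) return(integer(nwin))
  ov <- IRanges::findOverlaps(ir0(rd$start, rd$end), ir0(ex_s, ex_e))
  if (!length(ov)) return(integer(nwin))
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  ps <- pmax(rd$start[q], ex_s[s]); pe <- pmin(rd$end[q], ex_e[s])
  ts <- cum[s] + (ps - ex_s[s]); te <- cum[s] + (pe - ex_s[s])
  ws <- pmax(0L, ts - window + 1L)       # window starts reached (0-based)
  we <- pmin(nwin - 1L, te - 1L)
  keep <- we >= ws
  if (!any(keep)) return(integer(nwin))
  rid <- rd$read_id[q][keep]
  ir <- IRanges::IRanges(ws[keep] + 1L, we[keep] + 1L)
  per_read <- IRanges::reduce(S4Vectors::split(ir, rid))  # one read, one count
  as.integer(IRanges::coverage(unlist(per_read), width = nwin))
}

#' Maximum windowed ribosome/RNA read ratio
#'
#' Ribosome engagement score: the transcript's spliced sequence is broken
#' into `window`-nt windows with a 1 nt offset; in each window the ratio
#' of ribosome-profiling reads to RNA-seq reads is computed, and the
#' maximum over windows is returned. Windows with zero RNA-seq reads are
#' skipped so the maximum stays finite and comparable across transcripts.
#'
#' @param t Single-row [transcript_set()].
#' @param ribo_reads,rna_reads Read tables.
#' @param window Window size in nt (default 30).
#' @return Maximum ratio, or `NA` (with a `"reason"` attribute) when the
#'   transcript is shorter than one window or no window has RNA-seq reads.
#' @export
max_window_read_ratio <- function(t, ribo_reads, rna_reads, window = 30L) {
  if (exonic_length(t) < window)
    return(structure(NA_real_, reason = "transcript shorter than window"))
  ribo <- transcript_window_counts(ribo_reads, t, window)
  rna <- transcript_window_counts(rna_reads, t, window)
  ok <- rna > 0
  if (!any(ok))
    return(structure(NA_real_, reason = "no window with RNA-seq reads"))
  max(ribo[ok] / rna[ok])
}

#' Maximum mean conservation score in a sliding window
#'
#' Finds the `window`-bp window of the transcript's spliced sequence with
#' the highest mean per-base conservation score. Only windows whose
#' `window` consecutive exonic bases all carry scores qualify; a
#' transcript without `window` contiguously scored exonic bases gets `NA`
#' (such transcripts are reported as unscored, not zero).
#'
#' @param t Single-row [transcript_set()].
#' @param track Score track: named list (per chromosome) of numeric
#'   vectors over `[0, chrom length)` with `NA` at unscored positions.
#' @param window Window size in bp (default 50).
#' @return Maximum window mean, or `NA`.
#' @export
max_conserved_window <- function(t, track, window = 50L) {
  v <- unlist(lapply(seq_along(t$exon_starts[[1]]), function(k) {
    track[[t$chrom[1]]][(t$exon_starts[[1]][k] + 1L):t$exon_ends[[1]][k]]
  }), use.names = FALSE)
  L <- length(v)
  if (L < window) return(NA_real_)
  ok <- !is.na(v)
  v0 <- ifelse(ok, v, 0)
  cs <- cumsum(c(0, v0)); co <- cumsum(c(0L, ok))
  i <- seq_len(L - window + 1L)
  full <- (co[i + window] - co[i]) == window
  if (!any(full)) return(NA_real_)
  max((cs[i + window] - cs[i])[full]) / window
}

# Which SNPs fall inside a region set (interval data.frame or exon table
# of a transcript_set).
snps_in_regions <- function(snps, regions) {
  iv <- if (inherits(regions, "transcript_set")) exon_table(regions)
  else regions
  inside <- rep(FALSE, nrow(snps))
  for (ch in intersect(unique(snps$chrom), unique(iv$chrom))) {
    si <- which(snps$chrom == ch)
    d <- iv[iv$chrom == ch, , drop = FALSE]
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(snps$pos[si] + 1L, snps$pos[si] + 1L),
      ir0(d$start, d$end))
    inside[si[unique(S4Vectors::queryHits(ov))]] <- TRUE
  }
  inside
}

#' Platform-scaled tested-SNP count in a region
#'
#' Genotyping platforms contribute unequally to published GWASs, so raw
#' tested-SNP counts are scaled by each platform's fractional contribution
#' (Illumina 58.6%, Affymetrix 41.4% by default). A SNP present on both
#' platforms contributes to both terms.
#'
#' @param regions Interval `data.frame` or [transcript_set()] (exons).
#' @param snps SNP table (`chrom`, `pos`, `platform` in
#'   `c("illumina", "affymetrix", "both", "none")`, flags).
#' @param w_illumina,w_affymetrix Platform weights (sum to 1).
#' @return Scaled tested-SNP count (real).
#' @export
scaled_tested_snps <- function(regions, snps, w_illumina = 0.586,
                               w_affymetrix = 0.414) {
  stopifnot(abs(w_illumina + w_affymetrix - 1) < 1e-9)
  inside <- snps_in_regions(snps, regions)
  n_i <- sum(inside & snps$platform %in% c("illumina", "both"))
  n_a <- sum(inside & snps$platform %in% c("affymetrix", "both"))
  w_illumina * n_i + w_affymetrix * n_a
}

# Wilson 95% binomial proportion confidence interval.
wilson_ci <- function(k, n, conf = 0.95) {
  if (n <= 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, center - half), min(1, center + half))
}

#' Trait-associated SNP enrichment between two region sets
#'
#' Compares the rate of trait-associated SNPs (TAS) per platform-scaled
#' tested SNP between two region sets (e.g. lincRNA exons vs. nonexpressed
#' intergenic background loci). Reports the rate in each set, the fold
#' enrichment, a Fisher's exact p-value on the 2x2 table of (TAS, non-TAS)
#' counts — scaled tested counts are rounded to integers for the exact
#' test — and Wilson 95% confidence intervals per rate.
#'
#' @param region_a,region_b Interval `data.frame`s or [transcript_set()]s.
#' @param snps SNP table.
#' @param w_illumina,w_affymetrix Platform weights.
#' @return List with `rate_a`, `rate_b`, `fold`, `fisher_p`, `ci_a`,
#'   `ci_b`, `tas_a`, `tas_b`, `tested_a`, `tested_b`.
#' @export
tas_enrichment <- function(region_a, region_b, snps, w_illumina = 0.586,
                           w_affymetrix = 0.414) {
  tested_a <- scaled_tested_snps(region_a, snps, w_illumina, w_affymetrix)
  tested_b <- scaled_tested_snps(region_b, snps, w_illumina, w_affymetrix)
  if (tested_a <= 0) stop("region_a has no tested SNPs")
  if (tested_b <= 0) stop("region_b has no tested SNPs")
  tas <- snps[snps$trait_associated, , drop = FALSE]
  tas_a <- sum(snps_in_regions(tas, region_a))
  tas_b <- sum(snps_in_regions(tas, region_b))
  rate_a <- tas_a / tested_a
  rate_b <- tas_b / tested_b
  na <- round(tested_a); nb <- round(tested_b)
  tab <- matrix(c(tas_a, max(0, na - tas_a), tas_b, max(0, nb - tas_b)),
                nrow = 2, byrow = TRUE)
  p <- stats::fisher.test(tab)$p.value
  list(rate_a = rate_a, rate_b = rate_b,
       fold = if (rate_b > 0) rate_a / rate_b else Inf,
       fisher_p = p,
       ci_a = wilson_ci(tas_a, na), ci_b = wilson_ci(tas_b, nb),
       tas_a = tas_a, tas_b = tas_b, tested_a = tested_a,
       tested_b = tested_b)
}

#' Common-SNP density of a region set
#'
#' @param regions Interval `data.frame` or [transcript_set()] (exons).
#' @param snps SNP table with a `common` flag.
#' @return List with `count`, `bp` (region size after flattening) and
#'   `density` (SNPs per bp).
#' @export
common_snp_density <- function(regions, snps) {
  iv <- if (inherits(regions, "transcript_set")) exon_table(regions)
  else regions
  iv <- normalize_intervals(iv[, c("chrom", "start", "end")])
  bp <- sum(as.numeric(iv$end - iv$start))
  if (bp <= 0) stop("region has zero bases")
  cm <- snps[snps$common, , drop = FALSE]
  count <- sum(snps_in_regions(cm, iv))
  list(count = count, bp = bp, density = count / bp)
}

#' PolyA+/polyA- partitioning of expression
#'
#' For two cell types each measured in polyA-selected (polyA+) and
#' polyA-depleted (polyA-) fractions, computes each feature's
#' FPKM(polyA+)/FPKM(polyA-) ratio per cell type and the cross-cell-type
#' Pearson correlation of log2 ratios per feature class. A consistent
#' ratio across cell types indicates that a transcript's distribution
#' between fractions (polyadenylated, bimorphic, or non-polyadenylated) is
#' an intrinsic property. Features qualify when they have reads in all
#' four datasets and FPKM > 1 in at least one fraction of each cell type.
#'
#' @param em An [expression_matrix()] covering the four datasets.
#' @param dataset_map `data.frame` with `dataset_id`, `cell_type`,
#'   `fraction` (`"polyA+"` / `"polyA-"`); exactly two cell types.
#' @param feature_classes Named list of transcript id vectors (e.g.
#'   `list(lincRNA = ..., coding = ...)`).
#' @param min_fpkm Inclusion threshold (default 1, strict).
#' @return List with `table` (per-feature ratios) and `correlation`
#'   (named per class).
#' @export
polya_ratio_analysis <- function(em, dataset_map, feature_classes,
                                 min_fpkm = 1) {
  cts <- unique(dataset_map$cell_type)
  if (length(cts) != 2) stop("exactly two cell types are required")
  ds_of <- function(ct, fr) {
    id <- dataset_map$dataset_id[dataset_map$cell_type == ct &
                                   dataset_map$fraction == fr]
    if (length(id) != 1) stop("need one dataset per cell type and fraction")
    id
  }
  ids4 <- c(ds_of(cts[1], "polyA+"), ds_of(cts[1], "polyA-"),
            ds_of(cts[2], "polyA+"), ds_of(cts[2], "polyA-"))
  out <- list(); rs <- setNames(numeric(0), character(0))
  for (cl in names(feature_classes)) {
    feats <- intersect(feature_classes[[cl]], rownames(em$fpkm))
    cnt <- em$counts[feats, ids4, drop = FALSE]
    fp <- em$fpkm[feats, ids4, drop = FALSE]
    qual <- rowSums(cnt > 0) == 4 &
      (pmax(fp[, 1], fp[, 2]) > min_fpkm) &
      (pmax(fp[, 3], fp[, 4]) > min_fpkm)
    if (sum(qual) < 3)
      stop("fewer than 3 qualifying features in class ", cl)
    r1 <- fp[qual, 1] / fp[qual, 2]
    r2 <- fp[qual, 3] / fp[qual, 4]
    out[[cl]] <- data.frame(class = cl, id = feats[qual],
                            ratio_ct1 = r1, ratio_ct2 = r2,
                            log2_ratio_ct1 = log2(r1),
                            log2_ratio_ct2 = log2(r2))
    rs[cl] <- stats::cor(log2(r1), log2(r2))
  }
  list(table = do.call(rbind, out), correlation = rs,
       cell_types = cts)
}

#' ChIP signal as an IP/input read ratio
#'
#' Depth-normalized ratio of immunoprecipitated to matched input control
#' reads over a transcript's exons, counted with full assignment:
#' `(ip/ip_total) / (input/input_total)`.
#'
#' @param tx A [transcript_set()].
#' @param ip_reads,input_reads Read tables.
#' @param ip_total,input_total Total mapped reads per library.
#' @return Numeric vector per transcript; `NA` where the input count is
#'   zero (ratio undefined).
#' @export
chip_signal_ratio <- function(tx, ip_reads, input_reads, ip_total,
                              input_total) {
  ip <- count_reads_full_assignment(ip_reads, tx)
  inp <- count_reads_full_assignment(input_reads, tx)
  out <- (ip / ip_total) / (inp / input_total)
  out[inp == 0] <- NA_real_
  setNames(out, tx$id)
}

#' Paired-end ditag (PET) end support for a transcript
#'
#' A transcript end is supported when its terminal base falls inside the
#' corresponding end block (5' or 3', by the cluster's strand) of an
#' overlapping PET cluster. Ambiguous-strand transcripts are tested under
#' both orientations and supported if either matches.
#'
#' @param t Single-row [transcript_set()].
#' @param pet_clusters [transcript_set()] of PET clusters with >= 2 blocks
#'   and definite strands; first/last blocks are the end blocks.
#' @return List with logicals `five_prime_supported`,
#'   `three_prime_supported`.
#' @export
pet_end_support <- function(t, pet_clusters) {
  orientations <- if (t$strand[1] == ".") c("+", "-") else t$strand[1]
  five <- FALSE; three <- FALSE
  cl <- pet_clusters[pet_clusters$chrom == t$chrom[1] &
                       pet_clusters$end > t$start[1] &
                       pet_clusters$start < t$end[1], , drop = FALSE]
  for (o in orientations) {
    t5 <- if (o == "+") t$start[1] else t$end[1] - 1L
    t3 <- if (o == "+") t$end[1] - 1L else t$start[1]
    co <- cl[cl$strand == o, , drop = FALSE]
    for (i in seq_len(nrow(co))) {
      nb <- length(co$exon_starts[[i]])
      b5 <- if (o == "+") 1L else nb
      b3 <- if (o == "+") nb else 1L
      in_block <- function(pos, k) {
        pos >= co$exon_starts[[i]][k] && pos < co$exon_ends[[i]][k]
      }
      if (in_block(t5, b5)) five <- TRUE
      if (in_block(t3, b3)) three <- TRUE
    }
  }
  list(five_prime_supported = five, three_prime_supported = three)
}

#' Cluster samples by expression
#'
#' Filters features to those with FPKM above `min_fpkm` in at least one
#' sample, log2-transforms with a pseudo-count, then iteratively rescales
#' rows and columns until the sum of squares of every row and every column
#' is 1 (within `tol`). Samples are then clustered by Euclidean distance
#' with centroid linkage (on squared distances, as centroid linkage
#' requires).
#'
#' @param fpkm Numeric matrix, features x samples.
#' @param min_fpkm Feature inclusion threshold (default 10, strict).
#' @param eps Pseudo-count added before log2 (default 1, so FPKM 0 maps
#'   to 0).
#' @param tol Convergence tolerance on each sum of squares (default 1e-6).
#' @param max_iter Maximum rescaling iterations (default 100).
#' @return List with `data` (normalized matrix), `dist` (Euclidean sample
#'   distances), `hclust` (centroid-linkage tree), `iterations`,
#'   `converged`.
#' @export
cluster_samples <- function(fpkm, min_fpkm = 10, eps = 1, tol = 1e-6,
                            max_iter = 100L) {
  stopifnot(ncol(fpkm) >= 2)
  keep <- apply(fpkm, 1, max) > min_fpkm
  x <- log2(fpkm[keep, , drop = FALSE] + eps)
  zero <- rowSums(x^2) == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero row(s) dropped before normalization")
    x <- x[!zero, , drop = FALSE]
  }
  if (!nrow(x)) stop("no features left after filtering")
  converged <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    x <- x / sqrt(rowSums(x^2))
    cs <- sqrt(colSums(x^2))
    x <- sweep(x, 2, cs, "/")
    if (max(abs(rowSums(x^2) - 1)) < tol &&
        max(abs(colSums(x^2) - 1)) < tol) { converged <- TRUE; break }
  }
  d <- stats::dist(t(x))
  hc <- stats::hclust(d^2, method = "centroid")
  list(data = x, dist = d, hclust = hc, iterations = it,
       converged = converged)
}
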