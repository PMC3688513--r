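#' Minimum mature-length filter
#'
#' Removes transcripts shorter than `min_length` nucleotides of exonic
#' (mature) sequence — lincRNAs are defined as RNAs longer than 200 nt, so
#' the boundary transcript of exactly 200 nt is kept.
#'
#' @param tx A [transcript_set()].
#' @param min_length Minimum exonic length in nt (default 200).
#' @return Logical vector: `TRUE` = keep.
#' @export
filter_length <- function(tx, min_length = 200L) {
  exonic_length(tx) >= min_length
}

#' Protein-coding gene proximity filter
#'
#' Removes a transcript when it is within `proximity_bp` of a
#' protein-coding gene on the same strand — or, for transcripts of
#' ambiguous strandedness, on either strand. A transcript on the opposite
#' (definite) strand of a gene is removed only if it overlaps the gene
#' span by at least one base. "Within" is inclusive: a gap of exactly
#' `proximity_bp` removes.
#'
#' @param tx Candidate [transcript_set()].
#' @param protein_coding [transcript_set()] (or span `data.frame` with
#'   `chrom`, `start`, `end`, `strand`) of protein-coding genes.
#' @param proximity_bp Distance threshold in bp (default 1000).
#' @return Logical vector: `TRUE` = keep.
#' @export
filter_protein_gene_proximity <- function(tx, protein_coding,
                                          proximity_bp = 1000L) {
  genes <- if (inherits(protein_coding, "transcript_set")) {
    data.frame(chrom = protein_coding$chrom, start = protein_coding$start,
               end = protein_coding$end, strand = protein_coding$strand)
  } else protein_coding
  keep <- rep(TRUE, nrow(tx))
  for (ch in intersect(unique(tx$chrom), unique(genes$chrom))) {
    ti <- which(tx$chrom == ch)
    g <- genes[genes$chrom == ch, , drop = FALSE]
    ov <- IRanges::findOverlaps(ir0(tx$start[ti], tx$end[ti]),
                                ir0(g$start, g$end),
                                maxgap = proximity_bp)
    if (!length(ov)) next
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    ts <- tx$strand[ti[q]]; gs <- g$strand[s]
    strand_match <- ts == "." | gs == "." | ts == gs
    overlap_bp <- pmax(0L, pmin(tx$end[ti[q]], g$end[s]) -
                         pmax(tx$start[ti[q]], g$start[s]))
    remove <- strand_match | overlap_bp >= 1L
    keep[ti[unique(q[remove])]] <- FALSE
  }
  keep
}

#' Annotation overlap filter
#'
#' Removes transcripts whose genomic span overlaps, by at least one base
#' and regardless of strandedness, any interval of the supplied
#' non-lincRNA annotation sets (other-species gene alignments,
#' pseudogenes, non-lincRNA noncoding RNAs, coding sequences, alternative
#' and extended UTRs).
#'
#' @param tx Candidate [transcript_set()].
#' @param ... Interval `data.frame`s (`chrom`, `start`, `end`) or
#'   [transcript_set()]s; spans are used.
#' @return Logical vector: `TRUE` = keep.
#' @export
filter_annotation_overlap <- function(tx, ...) {
  sets <- list(...)
  keep <- rep(TRUE, nrow(tx))
  for (set in sets) {
    if (is.null(set) || !nrow(set)) next
    iv <- if (inherits(set, "transcript_set")) span_table(set) else set
    for (ch in intersect(unique(tx$chrom), unique(iv$chrom))) {
      ti <- which(tx$chrom == ch)
      d <- iv[iv$chrom == ch, , drop = FALSE]
      ov <- IRanges::findOverlaps(ir0(tx$start[ti], tx$end[ti]),
                                  ir0(d$start, d$end))
      keep[ti[unique(S4Vectors::queryHits(ov))]] <- FALSE
    }
  }
  keep
}

#' Large-ORF filter with neighbor removal
#'
#' Two passes mirroring the removal of putative coding transcripts and
#' their unannotated UTRs: (1) transcripts whose spliced sequence contains
#' any large ORF call (see [find_large_orfs()]) are removed; (2) remaining
#' transcripts whose genomic span overlaps (>= 1 bp, strand-blind) a
#' transcript removed in pass 1 are removed as putative UTR fragments of
#' those coding transcripts. Neighbor removal is non-transitive: a
#' transcript overlapping only a pass-2 victim survives.
#'
#' @param tx Candidate [transcript_set()].
#' @param sequences Named character vector of spliced sequences covering
#'   every transcript id.
#' @param max_aa,truncation_nt Passed to [find_large_orfs()].
#' @return List with logical `keep`, character `reason` (`"large_orf"`,
#'   `"orf_neighbor"` or `NA` for kept), and `large_orf_ids` — the
#'   exported catalog of large-ORF-containing transcripts.
#' @export
filter_large_orf_and_neighbors <- function(tx, sequences, max_aa = 100L,
                                           truncation_nt = 300L) {
  miss <- setdiff(tx$id, names(sequences))
  if (length(miss)) stop("missing sequences for: ",
                         paste(head(miss, 5), collapse = ", "))
  has_orf <- vapply(tx$id, function(id) {
    has_large_orf(sequences[[id]], max_aa, truncation_nt)
  }, logical(1))
  reason <- rep(NA_character_, nrow(tx))
  reason[has_orf] <- "large_orf"
  orf_tx <- tx[has_orf, , drop = FALSE]
  rest <- which(!has_orf)
  for (ch in intersect(unique(tx$chrom[rest]), unique(orf_tx$chrom))) {
    ti <- rest[tx$chrom[rest] == ch]
    o <- orf_tx[orf_tx$chrom == ch, , drop = FALSE]
    ov <- IRanges::findOverlaps(ir0(tx$start[ti], tx$end[ti]),
                                ir0(o$start, o$end))
    reason[ti[unique(S4Vectors::queryHits(ov))]] <- "orf_neighbor"
  }
  list(keep = is.na(reason), reason = reason,
       large_orf_ids = tx$id[has_orf])
}

#' Extended gene boundary filter
#'
#' Removes transcripts overlapping, by at least one base and regardless of
#' strandedness, any extended protein-coding gene boundary — gene spans
#' widened by assembly evidence to capture unannotated UTR extensions.
#'
#' @param tx Candidate [transcript_set()].
#' @param extended_gene_boundaries Interval `data.frame` (`chrom`,
#'   `start`, `end`).
#' @return Logical vector: `TRUE` = keep.
#' @export
filter_extended_genes <- function(tx, extended_gene_boundaries) {
  filter_annotation_overlap(tx, extended_gene_boundaries)
}

#' Minimum expression filter with tier assignment
#'
#' Removes transcripts never expressed above the lowest FPKM tier in any
#' dataset (strict comparison: FPKM exactly 1.0 fails an FPKM>1 cutoff).
#'
#' @param tx Candidate [transcript_set()].
#' @param em An [expression_matrix()] covering every transcript.
#' @param tiers Strictly increasing FPKM thresholds.
#' @return List with logical `keep` and the `tier` label per transcript.
#' @export
filter_expression <- function(tx, em, tiers = c(1, 10, 30)) {
  miss <- setdiff(tx$id, rownames(em$fpkm))
  if (length(miss)) stop("transcripts missing from expression matrix: ",
                         paste(head(miss, 5), collapse = ", "))
  tier <- expression_tiers(em, tiers)[tx$id]
  list(keep = tier != "fail", tier = tier)
}

CASCADE_STAGES <- c("length", "proximity", "annotation_overlap", "large_orf",
                    "orf_neighbor", "extended_gene", "expression")

#' Run the lincRNA filter cascade
#'
#' Applies the six filter stages in their fixed order — length, coding
#' gene proximity, annotation overlap, large ORF with neighbor removal,
#' extended gene boundaries, minimum expression — and records per-stage
#' provenance for every removed transcript.
#'
#' @param tx Candidate [transcript_set()].
#' @param catalog Annotation catalog: list with `protein_coding`
#'   (transcript set), `non_lincRNA_other`, `utr_extensions`,
#'   `extended_gene_boundaries` (interval `data.frame`s).
#' @param sequences Named spliced sequences for every candidate.
#' @param em An [expression_matrix()] covering every candidate.
#' @param min_length,proximity_bp,max_aa,truncation_nt,tiers Stage
#'   thresholds (defaults 200 nt, 1000 bp, 100 aa, 300 nt, FPKM 1/10/30).
#' @return List with `kept` (surviving transcript set), `tier` per
#'   survivor, `report` (`data.frame` of `id`, `status`, `reason`),
#'   `stage_counts`, and `large_orf_ids`.
#' @export
run_cascade <- function(tx, catalog, sequences, em, min_length = 200L,
                        proximity_bp = 1000L, max_aa = 100L,
                        truncation_nt = 300L, tiers = c(1, 10, 30)) {
  status <- rep("retained", nrow(tx))
  reason <- rep(NA_character_, nrow(tx))
  alive <- rep(TRUE, nrow(tx))
  mark <- function(alive_idx, keep, stage, why) {
    removed <- alive_idx[!keep]
    status[removed] <<- stage
    reason[removed] <<- why[!keep]
    alive[removed] <<- FALSE
  }

  idx <- which(alive)
  k <- filter_length(tx[idx, , drop = FALSE], min_length)
  mark(idx, k, "length", rep(sprintf("exonic length < %d nt", min_length),
                             length(idx)))

  idx <- which(alive)
  k <- filter_protein_gene_proximity(tx[idx, , drop = FALSE],
                                     catalog$protein_coding, proximity_bp)
  mark(idx, k, "proximity",
       rep(sprintf("within %d bp of (or opposite-strand overlapping) a coding gene",
                   proximity_bp), length(idx)))

  idx <- which(alive)
  k <- filter_annotation_overlap(tx[idx, , drop = FALSE],
                                 catalog$non_lincRNA_other,
                                 catalog$utr_extensions)
  mark(idx, k, "annotation_overlap",
       rep("overlaps non-lincRNA annotation or UTR extension", length(idx)))

  idx <- which(alive)
  orf <- filter_large_orf_and_neighbors(tx[idx, , drop = FALSE], sequences,
                                        max_aa, truncation_nt)
  stage4 <- ifelse(is.na(orf$reason), "retained", orf$reason)
  mark(idx, orf$keep, "large_orf", orf$reason)
  status[idx[stage4 == "orf_neighbor"]] <- "orf_neighbor"

  idx <- which(alive)
  k <- filter_extended_genes(tx[idx, , drop = FALSE],
                             catalog$extended_gene_boundaries)
  mark(idx, k, "extended_gene",
       rep("overlaps extended protein-coding gene boundary", length(idx)))

  idx <- which(alive)
  ex <- filter_expression(tx[idx, , drop = FALSE], em, tiers)
  mark(idx, ex$keep, "expression",
       rep(sprintf("FPKM <= %g in every dataset", tiers[1]), length(idx)))

  kept <- tx[alive, , drop = FALSE]
  report <- data.frame(id = tx$id, status = status, reason = reason,
                       stringsAsFactors = FALSE)
  stage_counts <- setNames(
    vapply(CASCADE_STAGES, function(s) sum(status == s), integer(1)),
    CASCADE_STAGES)
  list(kept = kept, tier = ex$tier[ex$keep], report = report,
       stage_counts = stage_counts, large_orf_ids = orf$large_orf_ids)
}
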