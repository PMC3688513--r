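#' Should two transcripts be merged?
#'
#' The 50% exon overlap rule: merge when some exon of one transcript
#' overlaps some exon of the other by at least half the length of either
#' exon (one direction suffices — a small exon wholly inside a large one
#' merges). The comparison is inclusive at exactly 50%. Transcripts on
#' opposite definite strands never merge; a pair involving an ambiguous
#' strand may.
#'
#' @param a,b Single-row [transcript_set()]s (or rows of one).
#' @param fraction Minimum overlap fraction of either exon (default 0.5).
#' @return Logical scalar.
#' @export
should_merge <- function(a, b, fraction = 0.5) {
  if (a$chrom[1] != b$chrom[1]) return(FALSE)
  if (a$strand[1] != "." && b$strand[1] != "." && a$strand[1] != b$strand[1])
    return(FALSE)
  as <- a$exon_starts[[1]]; ae <- a$exon_ends[[1]]
  bs <- b$exon_starts[[1]]; be <- b$exon_ends[[1]]
  for (i in seq_along(as)) {
    ov <- pmax(0L, pmin(ae[i], be) - pmax(as[i], bs))
    if (any(ov >= fraction * (ae[i] - as[i]) | ov >= fraction * (be - bs)))
      return(TRUE)
  }
  FALSE
}

# Union-find with path compression.
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i); rj <- uf_find(parent, j)
  if (ri != rj) parent[rj] <- ri
  parent
}

#' Merge redundant transcripts into a minimal set
#'
#' Computes connected components under [should_merge()] (transitive
#' closure: if A merges with B and B with C, all three form one merged
#' transcript even if A and C do not meet the criterion pairwise) and
#' replaces each component by the per-chromosome union of its members'
#' exons. The output is a fixed point: no two merged models satisfy the
#' merge predicate.
#'
#' @param tx A [transcript_set()] (one expression tier).
#' @param fraction Passed to [should_merge()].
#' @param id_prefix Prefix for merged transcript ids.
#' @return A [transcript_set()] with one row per merged transcript,
#'   ordered by (chrom, start), carrying a `members` list column of member
#'   ids. Strand is the members' shared definite strand, else ambiguous.
#' @export
merge_closure <- function(tx, fraction = 0.5, id_prefix = "merged") {
  if (!nrow(tx)) return(tx)
  cur <- tx
  if (is.null(cur$members)) cur$members <- as.list(cur$id)
  # exon union inside a merged model can create new 50% overlaps with a
  # neighboring model, so passes are repeated until nothing merges
  repeat {
    nxt <- merge_once(cur, fraction)
    if (nrow(nxt) == nrow(cur)) { cur <- nxt; break }
    cur <- nxt
  }
  cur$id <- paste0(id_prefix, "_", seq_len(nrow(cur)))
  cur
}

merge_once <- function(tx, fraction) {
  n <- nrow(tx)
  parent <- uf_new(n)
  ex <- exon_table(tx)
  for (ch in unique(ex$chrom)) {
    e <- ex[ex$chrom == ch, , drop = FALSE]
    ov <- IRanges::findOverlaps(ir0(e$start, e$end), ir0(e$start, e$end))
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    keep <- q < s & e$tx_row[q] != e$tx_row[s]
    q <- q[keep]; s <- s[keep]
    if (!length(q)) next
    ovbp <- pmax(0L, pmin(e$end[q], e$end[s]) - pmax(e$start[q], e$start[s]))
    meets <- ovbp >= fraction * (e$end[q] - e$start[q]) |
      ovbp >= fraction * (e$end[s] - e$start[s])
    ta <- e$tx_row[q][meets]; tb <- e$tx_row[s][meets]
    sa <- tx$strand[ta]; sb <- tx$strand[tb]
    compat <- sa == "." | sb == "." | sa == sb
    for (k in which(compat)) parent <- uf_union(parent, ta[k], tb[k])
  }
  comp <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  comp_ids <- unique(comp)
  es <- vector("list", length(comp_ids)); ee <- vector("list", length(comp_ids))
  chrom <- character(length(comp_ids)); strand <- character(length(comp_ids))
  members <- vector("list", length(comp_ids))
  for (k in seq_along(comp_ids)) {
    rows <- which(comp == comp_ids[k])
    chrom[k] <- tx$chrom[rows[1]]
    defs <- unique(tx$strand[rows][tx$strand[rows] != "."])
    strand[k] <- if (length(defs) == 1) defs else "."
    u <- IRanges::reduce(ir0(unlist(tx$exon_starts[rows]),
                             unlist(tx$exon_ends[rows])))
    es[[k]] <- IRanges::start(u) - 1L
    ee[[k]] <- IRanges::end(u)
    members[[k]] <- sort(unique(unlist(tx$members[rows])))
  }
  ord <- order(chrom, vapply(es, `[`, integer(1), 1L))
  out <- transcript_set(paste0("m_", seq_along(comp_ids)),
                        chrom[ord], strand[ord], es[ord], ee[ord],
                        source = "merged")
  out$members <- members[ord]
  out
}

#' Group merged transcripts by proximity
#'
#' Merged transcripts within `group_bp` of each other (inclusive,
#' transitively chained) share a group id; they keep distinct transcript
#' numbers within the group. Group ids are dense integers ordered by
#' leftmost coordinate (chromosomes in sorted order).
#'
#' @param merged A [transcript_set()] from [merge_closure()].
#' @param group_bp Grouping distance in bp (default 1000).
#' @return Integer vector of group ids aligned with `merged` rows.
#' @export
group_by_proximity <- function(merged, group_bp = 1000L) {
  n <- nrow(merged)
  group <- integer(n)
  g <- 0L
  for (ch in sort(unique(merged$chrom))) {
    idx <- which(merged$chrom == ch)
    idx <- idx[order(merged$start[idx], merged$end[idx])]
    prev_end <- -Inf
    for (i in idx) {
      if (merged$start[i] - prev_end > group_bp) g <- g + 1L
      group[i] <- g
      prev_end <- max(prev_end, merged$end[i])
    }
  }
  group
}

#' Assign catalog names
#'
#' Names follow the `FPKM<tier>_group_<g>_transcript_<t>` template, with
#' transcript numbers assigned 1..k within each group by leftmost
#' coordinate. Deterministic for a given input.
#'
#' @param merged A [transcript_set()] from [merge_closure()].
#' @param groups Group ids from [group_by_proximity()].
#' @param tier Numeric tier label (e.g. 1, 10, 30).
#' @return Character vector of names aligned with `merged` rows.
#' @export
assign_names <- function(merged, groups, tier) {
  names_out <- character(nrow(merged))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    idx <- idx[order(merged$chrom[idx], merged$start[idx], merged$end[idx],
                     merged$id[idx])]
    names_out[idx] <- sprintf("FPKM%s_group_%d_transcript_%d",
                              format(tier), g, seq_along(idx))
  }
  names_out
}

#' Infer transcript strand from splice junction orientations
#'
#' Splice-site dinucleotides (GT..AG) orient an intron; when every intron
#' of a transcript agrees the transcript inherits that strand, otherwise —
#' single-exon transcripts, junction-free or conflicting evidence — the
#' strand stays ambiguous. This is the conservative, majority-free rule.
#'
#' @param junction_strands Character vector of per-intron orientation
#'   calls (`"+"`, `"-"`, or `NA`); empty for single-exon transcripts.
#' @return `"+"`, `"-"` or `"."`.
#' @export
infer_strand <- function(junction_strands) {
  j <- junction_strands[!is.na(junction_strands)]
  if (!length(j)) return(".")
  u <- unique(j)
  if (length(u) == 1 && u %in% c("+", "-")) u else "."
}

#' Merge, group and name one expression tier
#'
#' Convenience wrapper: [merge_closure()], [group_by_proximity()],
#' [assign_names()] in sequence.
#'
#' @param tx A [transcript_set()] holding all transcripts of one tier.
#' @param tier Numeric tier label.
#' @param fraction,group_bp Rule parameters.
#' @return A [transcript_set()] with `members`, `group` and `name`
#'   columns.
#' @export
build_tier_catalog <- function(tx, tier, fraction = 0.5, group_bp = 1000L) {
  merged <- merge_closure(tx, fraction = fraction,
                          id_prefix = sprintf("FPKM%s", format(tier)))
  merged$group <- group_by_proximity(merged, group_bp)
  merged$name <- assign_names(merged, merged$group, tier)
  merged
}
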