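#' Find large open reading frames in a transcript sequence
#'
#' Scans all six reading frames (three per strand) of a spliced transcript
#' sequence for evidence of protein-coding capacity. Three kinds of calls
#' are made:
#'
#' * `complete`: an ATG-to-stop ORF longer than `max_aa` amino acids
#'   (strictly greater; the stop codon is excluded from `aa_length`). For
#'   each in-frame stop codon the ORF from the first start codon after the
#'   previous in-frame stop is reported; shorter nested ORFs are implied.
#' * `stop_truncated`: a start codon followed by more than `truncation_nt`
#'   nucleotides to the end of the sequence with no in-frame stop — the
#'   stop codon may lie outside the annotated transcript.
#' * `start_truncated`: an in-frame stop codon preceded by more than
#'   `truncation_nt` nucleotides from the start of the sequence with no
#'   prior in-frame start or stop codon — the start codon may lie outside
#'   the annotated transcript.
#'
#' Codons containing `N` never match start or stop codons. Frames 0-2 scan
#' the given sequence at offsets 0-2; frames 3-5 scan its reverse
#' complement, and their offsets are reported in reverse-complement
#' coordinates.
#'
#' @param seq Character scalar over `A`, `C`, `G`, `T`, `N`
#'   (case-insensitive), length >= 3.
#' @param max_aa Calls are returned only when coding length exceeds this
#'   many amino acids (default 100; the truncation rules of 300 nt are the
#'   corresponding nucleotide-scale thresholds).
#' @param truncation_nt Strict nucleotide threshold for both truncation
#'   rules (default 300).
#' @return `data.frame` with columns `frame` (0-5), `start_offset`,
#'   `end_offset` (0-based half-open nt within the scanned strand's
#'   sequence), `aa_length`, `kind`. Zero rows when the sequence has no
#'   large ORF.
#' @examples
#' orf <- paste0("ATG", strrep("GCA", 101), "TAA")
#' find_large_orfs(orf)
#' @export
find_large_orfs <- function(seq, max_aa = 100L, truncation_nt = 300L) {
  stopifnot(is.character(seq), length(seq) == 1)
  s <- toupper(seq)
  if (grepl("[^ACGTN]", s)) stop("sequence contains non-nucleotide characters")
  if (nchar(s) < 3) stop("sequence shorter than one codon")
  fwd <- scan_orf_strand(s, 0L, max_aa, truncation_nt)
  rev <- scan_orf_strand(revcomp(s), 3L, max_aa, truncation_nt)
  out <- rbind(fwd, rev)
  rownames(out) <- NULL
  out
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

scan_orf_strand <- function(s, frame_base, max_aa, truncation_nt) {
  L <- nchar(s)
  acc <- list()
  add <- function(frame, a, b, aa, kind) {
    acc[[length(acc) + 1L]] <<- data.frame(
      frame = frame, start_offset = a, end_offset = b,
      aa_length = as.integer(aa), kind = kind)
  }
  for (f in 0:2) {
    n <- (L - f) %/% 3L
    if (n < 1) next
    p <- f + 3L * (seq_len(n) - 1L)          # 0-based nt offset of codon k
    codons <- substring(s, p + 1L, p + 3L)
    is_start <- codons == "ATG"
    is_stop <- codons %in% STOP_CODONS
    stops <- which(is_stop)

    prev <- 0L
    for (j in stops) {                        # complete ORFs
      if (j - prev >= 2) {
        seg <- which(is_start[(prev + 1L):(j - 1L)])
        if (length(seg)) {
          i <- prev + seg[1]
          aa <- j - i
          if (aa > max_aa)
            add(frame_base + f, p[i], p[j] + 3L, aa, "complete")
        }
      }
      prev <- j
    }

    last_stop <- if (length(stops)) stops[length(stops)] else 0L
    cand <- which(is_start)                   # stop-truncated
    cand <- cand[cand > last_stop]
    if (length(cand)) {
      i <- cand[1]
      d <- L - (p[i] + 3L)                    # nt downstream of the ATG codon
      if (d > truncation_nt)
        add(frame_base + f, p[i], L, d %/% 3L, "stop_truncated")
    }

    if (length(stops)) {                      # start-truncated
      j <- stops[1]
      if (j == 1L || !any(is_start[seq_len(j - 1L)])) {
        u <- p[j]                             # nt upstream of the stop codon
        if (u > truncation_nt)
          add(frame_base + f, f, p[j] + 3L, u %/% 3L, "start_truncated")
      }
    }
  }
  if (!length(acc))
    return(data.frame(frame = integer(), start_offset = integer(),
                      end_offset = integer(), aa_length = integer(),
                      kind = character()))
  do.call(rbind, acc)
}

#' Does a sequence contain any large ORF?
#' @inheritParams find_large_orfs
#' @return Logical scalar.
#' @export
has_large_orf <- function(seq, max_aa = 100L, truncation_nt = 300L) {
  nrow(find_large_orfs(seq, max_aa, truncation_nt)) > 0
}
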