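# Independent brute-force oracles. These deliberately share no code with
# the package implementations they check: plain state machines and
# per-base arrays.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# Six-frame large-ORF scan as a per-codon state machine.
oracle_large_orfs <- function(seq, max_aa = 100, trunc = 300) {
  out <- list()
  scan <- function(s, frame_base) {
    L <- nchar(s)
    for (f in 0:2) {
      n <- (L - f) %/% 3
      if (n < 1) next
      codon <- character(n)
      for (k in seq_len(n)) codon[k] <- substr(s, f + 3 * k - 2, f + 3 * k)
      is_stop <- codon %in% c("TAA", "TAG", "TGA")
      is_atg <- codon == "ATG"
      open <- NA   # codon index of the first ATG since the last stop
      seen_stop <- FALSE
      seen_any_before_first_stop <- FALSE
      for (k in seq_len(n)) {
        if (is_stop[k]) {
          if (!is.na(open) && (k - open) > max_aa) {
            out[[length(out) + 1]] <<- data.frame(
              frame = frame_base + f, start_offset = f + 3 * (open - 1),
              end_offset = f + 3 * k, aa_length = k - open,
              kind = "complete")
          }
          if (!seen_stop && !seen_any_before_first_stop) {
            u <- f + 3 * (k - 1)   # nt before the stop codon
            if (u > trunc) {
              out[[length(out) + 1]] <<- data.frame(
                frame = frame_base + f, start_offset = f,
                end_offset = f + 3 * k, aa_length = u %/% 3,
                kind = "start_truncated")
            }
          }
          seen_stop <- TRUE
          open <- NA
        } else if (is_atg[k]) {
          if (is.na(open)) open <- k
          if (!seen_stop) seen_any_before_first_stop <- TRUE
        }
      }
      if (!is.na(open)) {
        d <- L - (f + 3 * (open - 1)) - 3  # nt after the ATG codon
        if (d > trunc) {
          out[[length(out) + 1]] <<- data.frame(
            frame = frame_base + f, start_offset = f + 3 * (open - 1),
            end_offset = L, aa_length = d %/% 3, kind = "stop_truncated")
        }
      }
    }
  }
  scan(seq, 0)
  scan(oracle_revcomp(seq), 3)
  if (!length(out))
    return(data.frame(frame = integer(), start_offset = integer(),
                      end_offset = integer(), aa_length = integer(),
                      kind = character()))
  do.call(rbind, out)
}

random_seq_gc <- function(len, gc) {
  paste(sample(c("G", "C", "A", "T"), len, replace = TRUE,
               prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
        collapse = "")
}

canon_orfs <- function(d) {
  d <- d[order(d$frame, d$kind, d$start_offset, d$end_offset), ]
  rownames(d) <- NULL
  d[, c("frame", "start_offset", "end_offset", "aa_length", "kind")]
}

# Per-base depth arrays over one small chromosome.
oracle_depth <- function(reads, chrom_len, mode) {
  depth <- integer(chrom_len)
  for (id in unique(reads$read_id)) {
    b <- reads[reads$read_id == id, , drop = FALSE]
    pos <- if (mode == "including_inferred") {
      (min(b$start) + 1):max(b$end)
    } else {
      unlist(lapply(seq_len(nrow(b)), function(k) (b$start[k] + 1):b$end[k]))
    }
    depth[pos] <- depth[pos] + 1L
  }
  depth
}

# Independent 50% exon-overlap pair predicate (plain loops).
oracle_should_merge <- function(a, b) {
  if (a$chrom != b$chrom) return(FALSE)
  if (a$strand != "." && b$strand != "." && a$strand != b$strand)
    return(FALSE)
  for (i in seq_along(a$exon_starts[[1]])) {
    for (j in seq_along(b$exon_starts[[1]])) {
      s1 <- a$exon_starts[[1]][i]; e1 <- a$exon_ends[[1]][i]
      s2 <- b$exon_starts[[1]][j]; e2 <- b$exon_ends[[1]][j]
      ov <- min(e1, e2) - max(s1, s2)
      if (ov > 0 && (ov >= 0.5 * (e1 - s1) || ov >= 0.5 * (e2 - s2)))
        return(TRUE)
    }
  }
  FALSE
}

# Connected components by breadth-first search over an adjacency matrix.
oracle_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (v in seq_len(n)) {
    if (!is.na(comp[v])) next
    cid <- cid + 1
    queue <- v
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[u])) next
      comp[u] <- cid
      queue <- c(queue, which(adj[u, ] & is.na(comp)))
    }
  }
  comp
}

# Brute-force merge partition: repeatedly (a) build the all-pairs
# adjacency with the independent predicate, (b) take BFS components,
# (c) union member exons by a sweep, until no round merges anything.
# Returns the component id of every input transcript.
oracle_merge_partition <- function(tx) {
  models <- lapply(seq_len(nrow(tx)), function(i) {
    list(chrom = tx$chrom[i], strand = tx$strand[i],
         exon_starts = list(tx$exon_starts[[i]]),
         exon_ends = list(tx$exon_ends[[i]]), members = i)
  })
  sweep_union <- function(s, e) {
    o <- order(s)
    s <- s[o]; e <- e[o]
    ks <- s[1]; ke <- e[1]
    rs <- c(); re <- c()
    for (k in seq_along(s)[-1]) {
      if (s[k] <= ke) ke <- max(ke, e[k])
      else { rs <- c(rs, ks); re <- c(re, ke); ks <- s[k]; ke <- e[k] }
    }
    list(starts = c(rs, ks), ends = c(re, ke))
  }
  repeat {
    n <- length(models)
    adj <- matrix(FALSE, n, n)
    flat <- do.call(rbind, lapply(seq_along(models), function(i) {
      data.frame(m = i, chrom = models[[i]]$chrom,
                 strand = models[[i]]$strand,
                 s = models[[i]]$exon_starts[[1]],
                 e = models[[i]]$exon_ends[[1]])
    }))
    for (ch in unique(flat$chrom)) {
      f <- flat[flat$chrom == ch, ]
      E <- nrow(f)
      ii <- rep(seq_len(E), each = E); jj <- rep(seq_len(E), times = E)
      ov <- pmin(f$e[ii], f$e[jj]) - pmax(f$s[ii], f$s[jj])
      ok <- f$m[ii] != f$m[jj] & ov > 0 &
        (ov >= 0.5 * (f$e[ii] - f$s[ii]) |
           ov >= 0.5 * (f$e[jj] - f$s[jj])) &
        (f$strand[ii] == "." | f$strand[jj] == "." |
           f$strand[ii] == f$strand[jj])
      if (any(ok)) adj[cbind(f$m[ii][ok], f$m[jj][ok])] <- TRUE
    }
    comp <- oracle_components(adj)
    if (length(unique(comp)) == n) break
    models <- lapply(unique(comp), function(cid) {
      ms <- models[comp == cid]
      defs <- unique(unlist(lapply(ms, `[[`, "strand")))
      defs <- defs[defs != "."]
      u <- sweep_union(unlist(lapply(ms, function(m) m$exon_starts[[1]])),
                       unlist(lapply(ms, function(m) m$exon_ends[[1]])))
      list(chrom = ms[[1]]$chrom,
           strand = if (length(defs) == 1) defs else ".",
           exon_starts = list(u$starts), exon_ends = list(u$ends),
           members = unlist(lapply(ms, `[[`, "members")))
    })
  }
  out <- integer(nrow(tx))
  for (k in seq_along(models)) out[models[[k]]$members] <- k
  out
}

# Partition equality up to relabeling.
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(tapply(seq_along(a), a, function(i) length(unique(b[i])) == 1)) &&
    length(unique(a)) == length(unique(b))
}

# Exhaustive per-window read counts in transcript coordinates: every
# window a read's bases touch is marked, one hit per read per window.
oracle_window_counts <- function(reads, t, window) {
  gpos <- unlist(lapply(seq_along(t$exon_starts[[1]]), function(k) {
    (t$exon_starts[[1]][k] + 1):t$exon_ends[[1]][k]
  }))
  nwin <- length(gpos) - window + 1
  counts <- integer(nwin)
  for (id in unique(reads$read_id[reads$chrom == t$chrom])) {
    b <- reads[reads$read_id == id & reads$chrom == t$chrom, ,
               drop = FALSE]
    bases <- unlist(lapply(seq_len(nrow(b)),
                           function(k) (b$start[k] + 1):b$end[k]))
    p <- which(gpos %in% bases)
    if (!length(p)) next
    hit <- rep(FALSE, nwin)
    for (q in p) hit[max(1, q - window + 1):min(nwin, q)] <- TRUE
    counts <- counts + hit
  }
  counts
}

oracle_max_window_ratio <- function(t, ribo, rna, window = 30) {
  L <- sum(t$exon_ends[[1]] - t$exon_starts[[1]])
  if (L < window) return(NA_real_)
  nr <- oracle_window_counts(rna, t, window)
  nb <- oracle_window_counts(ribo, t, window)
  if (!any(nr > 0)) return(NA_real_)
  max(nb[nr > 0] / nr[nr > 0])
}

# Exhaustive max 50-bp window mean over scored exonic positions.
oracle_max_conserved <- function(t, track, window = 50) {
  v <- unlist(lapply(seq_along(t$exon_starts[[1]]), function(k) {
    track[[t$chrom]][(t$exon_starts[[1]][k] + 1):t$exon_ends[[1]][k]]
  }))
  if (length(v) < window) return(NA_real_)
  best <- NA_real_
  for (i in 1:(length(v) - window + 1)) {
    w <- v[i:(i + window - 1)]
    if (any(is.na(w))) next
    m <- mean(w)
    if (is.na(best) || m > best) best <- m
  }
  best
}

# Two-sided Fisher p by hypergeometric enumeration on a 2x2 table.
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  x_obs <- tab[1, 1]
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(x_obs, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Uniquely-assigned counting: each read counted for the transcripts whose
# exons it overlaps, via per-read linear scans.
oracle_unique_counts <- function(reads, tx) {
  counts <- setNames(integer(nrow(tx)), tx$id)
  for (id in unique(reads$read_id)) {
    b <- reads[reads$read_id == id, , drop = FALSE]
    for (i in seq_len(nrow(tx))) {
      if (tx$chrom[i] != b$chrom[1]) next
      hit <- FALSE
      for (k in seq_len(nrow(b))) {
        for (e in seq_along(tx$exon_starts[[i]])) {
          if (min(b$end[k], tx$exon_ends[[i]][e]) >
              max(b$start[k], tx$exon_starts[[i]][e])) hit <- TRUE
        }
      }
      if (hit) counts[i] <- counts[i] + 1L
    }
  }
  counts
}

# Random small transcript set for round-trip and merge fixtures.
random_transcripts <- function(n, chroms = c("chr1", "chr2"),
                               chrom_len = 100000) {
  ids <- sprintf("rt%04d", seq_len(n))
  chrom <- sample(chroms, n, replace = TRUE)
  strand <- sample(c("+", "-", "."), n, replace = TRUE)
  es <- list(); ee <- list()
  for (i in seq_len(n)) {
    k <- sample(1:4, 1)
    lens <- sample(50:400, k, replace = TRUE)
    gaps <- if (k > 1) sample(30:500, k - 1, replace = TRUE) else integer()
    s0 <- sample.int(chrom_len - sum(lens) - sum(gaps) - 1, 1)
    st <- s0 + cumsum(c(0, head(lens, -1) + gaps))
    es[[i]] <- as.integer(st)
    ee[[i]] <- as.integer(st + lens)
  }
  transcript_set(ids, chrom, strand, es, ee)
}
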