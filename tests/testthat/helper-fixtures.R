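# Small coverage fixtures shared by the coverage tests and the
# end-to-end acceptance checks.

toy_reads <- function(n = 500, seed = 11, chrom_len = 10000) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n)) {
    if (runif(1) < 0.3) {  # split read: two blocks spanning an intron
      b1 <- sample(20:40, 1); b2 <- sample(20:40, 1)
      gap <- sample(50:2000, 1)
      s <- sample.int(chrom_len - b1 - b2 - gap, 1) - 1L
      rows[[i]] <- data.frame(read_id = i, chrom = "chr1",
                              start = c(s, s + b1 + gap),
                              end = c(s + b1, s + b1 + gap + b2),
                              strand = ".")
    } else {
      w <- sample(30:80, 1)
      s <- sample.int(chrom_len - w, 1) - 1L
      rows[[i]] <- data.frame(read_id = i, chrom = "chr1", start = s,
                              end = s + w, strand = ".")
    }
  }
  do.call(rbind, rows)
}

toy_genome <- function(chrom_len = 10000) {
  genome_spec(c(chr1 = chrom_len),
              data.frame(chrom = "chr1", start = 500, end = 9500))
}
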