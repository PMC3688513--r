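test_that("max window ratio matches a hand-built fixture", {
  t <- transcript_set("t", "chr1", "+", list(0L), list(300L))
  # 10 ribo reads and 2 RNA reads piled at [0,30); RNA-only elsewhere
  ribo <- data.frame(read_id = 1:10, chrom = "chr1", start = 0L, end = 30L,
                     strand = ".")
  rna <- rbind(
    data.frame(read_id = 1:2, chrom = "chr1", start = 0L, end = 30L,
               strand = "."),
    data.frame(read_id = 3:6, chrom = "chr1", start = 200L, end = 240L,
               strand = "."))
  expect_equal(max_window_read_ratio(t[1, ], ribo, rna), 5)
  # zero ribo reads anywhere: ratio 0
  expect_equal(max_window_read_ratio(t[1, ], ribo[0, ], rna), 0)
  # no RNA reads: undefined
  r <- max_window_read_ratio(t[1, ], ribo, rna[0, ])
  expect_true(is.na(r))
  expect_match(attr(r, "reason"), "RNA")
  # transcript shorter than one window: undefined
  short <- transcript_set("s", "chr1", "+", list(0L), list(20L))
  expect_true(is.na(max_window_read_ratio(short[1, ], ribo, rna)))
})

test_that("window operations match exhaustive enumeration on random
           transcripts", {
  set.seed(77)
  for (rep in 1:12) {
    n_ex <- sample(1:3, 1)
    lens <- sample(40:150, n_ex, replace = TRUE)
    gaps <- if (n_ex > 1) sample(50:300, n_ex - 1, replace = TRUE)
            else integer()
    s0 <- sample.int(2000, 1)
    st <- s0 + cumsum(c(0, head(lens, -1) + gaps))
    t <- transcript_set("t", "chr1", ".", list(as.integer(st)),
                        list(as.integer(st + lens)))
    mk_reads <- function(n, w) {
      s <- sample.int(4000, n) - 1L
      data.frame(read_id = seq_len(n), chrom = "chr1", start = s,
                 end = s + w, strand = ".")
    }
    ribo <- mk_reads(25, 25L)
    rna <- mk_reads(25, 40L)
    expect_equal(as.numeric(max_window_read_ratio(t[1, ], ribo, rna)),
                 as.numeric(oracle_max_window_ratio(t[1, ], ribo, rna)),
                 info = paste("ratio rep", rep))
    track <- list(chr1 = rnorm(5000))
    track$chr1[sample(5000, 500)] <- NA
    expect_equal(max_conserved_window(t[1, ], track),
                 oracle_max_conserved(t[1, ], track),
                 info = paste("conservation rep", rep))
  }
})

test_that("conservation windows need 50 contiguous scored exonic bases", {
  t <- transcript_set("t", "chr1", "+", list(0L), list(200L))
  flat <- list(chr1 = rep(1, 300))
  expect_equal(max_conserved_window(t[1, ], flat), 1)
  only49 <- list(chr1 = c(rep(1, 49), rep(NA, 251)))
  expect_true(is.na(max_conserved_window(t[1, ], only49)))
  # a spliced transcript whose exons are each shorter than the window
  spl <- transcript_set("s", "chr1", "+", list(c(0L, 100L)),
                        list(c(40L, 140L)))
  # exonic concatenation is 80 scored bases: window can span the junction
  expect_equal(max_conserved_window(spl[1, ], flat), 1)
  shorty <- transcript_set("x", "chr1", "+", list(0L), list(30L))
  expect_true(is.na(max_conserved_window(shorty[1, ], flat)))
})

test_that("platform scaling weights tested SNPs 58.6/41.4", {
  region <- data.frame(chrom = "chr1", start = 0, end = 1000)
  snp <- function(n, platform) {
    data.frame(snp_id = paste0(platform, seq_len(n)), chrom = "chr1",
               pos = sample.int(1000, n, replace = TRUE) - 1L,
               platform = platform, trait_associated = FALSE,
               common = FALSE)
  }
  set.seed(3)
  even <- rbind(snp(500, "illumina"), snp(500, "affymetrix"))
  expect_equal(scaled_tested_snps(region, even), 500)
  expect_equal(scaled_tested_snps(region, snp(1000, "illumina")), 586)
  expect_equal(scaled_tested_snps(region, snp(1000, "affymetrix")), 414)
  both <- snp(100, "both")
  expect_equal(scaled_tested_snps(region, both), 100)  # counts in both terms
  empty <- data.frame(chrom = "chr2", start = 0, end = 1000)
  expect_equal(scaled_tested_snps(empty, even), 0)
})

test_that("TAS enrichment recovers planted rates and matches the
           hypergeometric oracle", {
  set.seed(17)
  mk_snps <- function(n, chrom, tas_rate) {
    data.frame(snp_id = paste0(chrom, seq_len(n)), chrom = chrom,
               pos = sample.int(100000, n, replace = TRUE) - 1L,
               platform = sample(c("illumina", "affymetrix"), n, TRUE,
                                 prob = c(0.586, 0.414)),
               trait_associated = runif(n) < tas_rate, common = FALSE)
  }
  snps <- rbind(mk_snps(1000, "chrA", 0.2), mk_snps(1000, "chrB", 0.04))
  a <- data.frame(chrom = "chrA", start = 0, end = 100000)
  b <- data.frame(chrom = "chrB", start = 0, end = 100000)
  res <- tas_enrichment(a, b, snps)
  expect_equal(res$rate_a, sum(snps$trait_associated[snps$chrom == "chrA"]) /
                 res$tested_a)
  expect_gt(res$fold, 2.5)
  expect_lt(res$fisher_p, 1e-6)
  expect_true(res$ci_a[1] <= res$rate_a && res$rate_a <= res$ci_a[2])
  # Fisher p equals two-sided hypergeometric enumeration on small tables
  for (tab in list(matrix(c(10, 990, 2, 998), 2, byrow = TRUE),
                   matrix(c(3, 7, 5, 5), 2, byrow = TRUE),
                   matrix(c(0, 20, 8, 12), 2, byrow = TRUE))) {
    expect_equal(stats::fisher.test(tab)$p.value, oracle_fisher_p(tab),
                 tolerance = 1e-12)
  }
  # identical regions: fold 1, p 1
  same <- tas_enrichment(a, a, snps)
  expect_equal(same$fold, 1)
  expect_equal(same$fisher_p, 1)
})

test_that("common SNP density divides count by flattened region size", {
  snps <- data.frame(snp_id = paste0("s", 1:10), chrom = "chr1",
                     pos = seq(0, 9000, 1000), platform = "illumina",
                     trait_associated = FALSE,
                     common = rep(c(TRUE, FALSE), 5))
  region <- data.frame(chrom = "chr1", start = 0, end = 10000)
  d <- common_snp_density(region, snps)
  expect_equal(d$count, 5)
  expect_equal(d$density, 5 / 10000)
  # additive under splitting
  halves <- data.frame(chrom = "chr1", start = c(0, 5000),
                       end = c(5000, 10000))
  expect_equal(common_snp_density(halves, snps)$density, d$density)
  expect_error(common_snp_density(region[0, ], snps), "zero")
})

test_that("polyA ratio analysis applies inclusion rules and correlates
           log ratios", {
  ids <- sprintf("f%02d", 1:10)
  cnt <- matrix(5L, 10, 4, dimnames = list(ids, c("a_p", "a_m", "b_p",
                                                  "b_m")))
  fp <- cbind(a_p = c(4, 8, 2, 16, 4, 6, 10, 3, 0.5, 4),
              a_m = c(2, 2, 2, 2, 2, 2, 2, 2, 0.4, 2),
              b_p = c(4, 8, 2, 16, 4, 6, 10, 3, 0.5, 4),
              b_m = c(2, 2, 2, 2, 2, 2, 2, 2, 0.4, 2))
  rownames(fp) <- ids
  cnt["f05", "a_p"] <- 0L  # no reads in one dataset: excluded
  em <- structure(list(counts = cnt, fpkm = fp,
                       lengths = setNames(rep(1000L, 10), ids),
                       datasets = data.frame(
                         dataset_id = colnames(cnt),
                         total_mapped_reads = 1e7)),
                  class = "expression_matrix")
  dsmap <- data.frame(dataset_id = c("a_p", "a_m", "b_p", "b_m"),
                      cell_type = c("A", "A", "B", "B"),
                      fraction = c("polyA+", "polyA-", "polyA+", "polyA-"))
  res <- polya_ratio_analysis(em, dsmap, list(all = ids))
  expect_false("f05" %in% res$table$id)  # zero-read exclusion
  expect_false("f09" %in% res$table$id)  # never above FPKM 1
  expect_equal(res$table$ratio_ct1[res$table$id == "f01"], 2)
  expect_equal(unname(res$correlation["all"]), 1)  # identical across types
  expect_error(polya_ratio_analysis(em, dsmap, list(few = ids[1:2])),
               "fewer than 3")
})

test_that("ChIP ratio normalizes by totals and guards zero input", {
  tx <- transcript_set(c("t1", "t2"), "chr1", ".", list(0L, 5000L),
                       list(1000L, 6000L))
  ip <- data.frame(read_id = 1:100, chrom = "chr1",
                   start = rep(100L, 100), end = rep(180L, 100),
                   strand = ".")
  input <- data.frame(read_id = 1:50, chrom = "chr1",
                      start = rep(100L, 50), end = rep(180L, 50),
                      strand = ".")
  r <- chip_signal_ratio(tx, ip, input, 1e6, 1e6)
  expect_equal(unname(r["t1"]), 2)
  expect_true(is.na(r["t2"]))  # zero input reads
  # doubling both totals leaves the ratio unchanged
  r2 <- chip_signal_ratio(tx, ip, input, 2e6, 2e6)
  expect_equal(r2["t1"], r["t1"])
})

test_that("PET end support tests terminal bases against oriented end
           blocks", {
  clus <- transcript_set(c("cp", "cm"), "chr1", c("+", "-"),
                         list(c(950L, 2950L), c(4950L, 6950L)),
                         list(c(1050L, 3050L), c(5050L, 7050L)))
  plus_t <- transcript_set("p", "chr1", "+", list(1000L), list(3000L))
  r <- pet_end_support(plus_t[1, ], clus)
  expect_true(r$five_prime_supported)
  expect_true(r$three_prime_supported)
  # minus-strand transcript matching only the minus cluster
  minus_t <- transcript_set("m", "chr1", "-", list(5000L), list(7000L))
  rm_ <- pet_end_support(minus_t[1, ], clus)
  expect_true(rm_$five_prime_supported)   # 5' end = end-1, in last block
  # ambiguous transcript supported under the minus orientation only
  amb <- transcript_set("a", "chr1", ".", list(5000L), list(7000L))
  ra <- pet_end_support(amb[1, ], clus)
  expect_true(ra$five_prime_supported)
  none <- transcript_set("n", "chr1", "+", list(8000L), list(9000L))
  rn <- pet_end_support(none[1, ], clus)
  expect_false(rn$five_prime_supported)
  expect_false(rn$three_prime_supported)
})

test_that("sample clustering normalizes to the attainable fixed point and
           clusters duplicates first", {
  set.seed(55)
  fp <- matrix(2^rnorm(120, 5, 2), 30, 4,
               dimnames = list(sprintf("f%02d", 1:30),
                               c("s1", "s2", "s3", "s4")))
  fp[, 2] <- fp[, 1]  # duplicated sample
  cl <- cluster_samples(fp, min_fpkm = 10)
  # columns reach unit sum of squares; rows reach the common value
  # n_cols/n_rows (both = 1 is attainable only for square matrices)
  expect_true(all(abs(colSums(cl$data^2) - 1) < 1e-6))
  expect_lt(diff(range(rowSums(cl$data^2))), 1e-6)
  expect_equal(as.numeric(stats::as.dist(cl$dist)[1]), 0)  # s1 vs s2
  expect_equal(sort(cl$hclust$merge[1, ]), c(-2, -1))      # merged first
  # square case: both constraints are attainable and converge
  sq <- matrix(2^rnorm(16, 5, 2), 4, 4,
               dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
  cls <- cluster_samples(sq, min_fpkm = 0, eps = 1)
  expect_true(cls$converged)
  expect_true(all(abs(rowSums(cls$data^2) - 1) < 1e-6))
  expect_true(all(abs(colSums(cls$data^2) - 1) < 1e-6))
})
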