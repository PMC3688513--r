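# A reduced configuration shared by generator tests: every category
# present, sized to run in seconds.
small_cfg <- function(seed = 5, ...) {
  sim_config(seed = seed, n_chromosomes = 2L, chrom_length = 300000L,
             counts = c(true_lincRNA = 25L, protein_coding = 12L,
                        pseudogene = 5L, small_ncRNA = 5L,
                        utr_extension_victim = 5L, large_orf_decoy = 8L,
                        orf_neighbor_decoy = 5L, proximity_decoy = 8L,
                        low_expression_decoy = 6L, short_decoy = 6L),
             n_tested_snps = 2000L, ...)
}

# One shared default-seed simulation for the structural checks below.
sim5 <- simulate_all(small_cfg())

test_that("the mappability mask hits its target fraction and is exact at
           zero", {
  cfg <- sim_config(seed = 1, unmappable_fraction = 0.15)
  g <- generate_genome(cfg)
  target <- 0.85 * 2e6
  expect_lt(abs(mappable_size(g) - target), 0.05 * target)
  all_mappable <- generate_genome(sim_config(seed = 1,
                                             unmappable_fraction = 0))
  expect_equal(mappable_size(all_mappable), 2e6)
  # mask intervals are disjoint, sorted, in bounds
  for (ch in names(g$seqlengths)) {
    m <- g$mask[g$mask$chrom == ch, ]
    expect_true(all(diff(m$start) > 0))
    expect_true(all(m$start < m$end))
    expect_true(all(m$end <= g$seqlengths[[ch]]))
    expect_true(all(m$start[-1] > m$end[-nrow(m)]))
  }
})

test_that("generation is byte-identical under a fixed seed and changes
           with the seed", {
  a <- generate_genome(sim_config(seed = 33))
  b <- generate_genome(sim_config(seed = 33))
  expect_identical(a, b)
  c_ <- generate_genome(sim_config(seed = 34))
  expect_false(identical(a$mask, c_$mask))
  s1 <- simulate_all(small_cfg(seed = 12))
  s2 <- simulate_all(small_cfg(seed = 12))
  expect_identical(s1$transcripts, s2$transcripts)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$snps, s2$snps)
  expect_identical(s1$track, s2$track)
})

test_that("truth labels partition the candidates with the requested
           counts", {
  sim <- sim5
  expect_equal(sort(sim$truth$transcript_id), sort(sim$transcripts$id))
  expect_equal(anyDuplicated(sim$truth$transcript_id), 0L)
  got <- table(sim$truth$category)
  want <- small_cfg()$counts
  expect_equal(unname(got[names(want)]), unname(as.table(want)),
               ignore_attr = TRUE)
})

test_that("constructed transcripts satisfy their targeted single
           violation", {
  sim <- sim5
  tx <- sim$transcripts
  truth <- sim$truth
  by_cat <- function(cat) tx[truth$category == cat, , drop = FALSE]

  # planted lincRNAs: ORF-free (oracle), > 1 kb from genes, mappable
  linc <- by_cat("true_lincRNA")
  genes <- by_cat("protein_coding")
  for (i in seq_len(nrow(linc))) {
    expect_equal(nrow(oracle_large_orfs(sim$sequences[[linc$id[i]]])), 0)
    gaps <- vapply(seq_len(nrow(genes)), function(j) {
      gap_distance(linc[i, ], genes[j, ])
    }, numeric(1))
    expect_gt(min(gaps), 1000)
  }
  # every proximity decoy sits within 1 kb of some gene
  prox <- by_cat("proximity_decoy")
  for (i in seq_len(nrow(prox))) {
    gaps <- vapply(seq_len(nrow(genes)), function(j) {
      gap_distance(prox[i, ], genes[j, ])
    }, numeric(1))
    expect_lte(min(gaps), 1000)
  }
  # short decoys are under the length threshold, everything else over
  expect_true(all(exonic_length(by_cat("short_decoy")) < 200))
  expect_true(all(exonic_length(by_cat("true_lincRNA")) >= 200))
  # ORF decoys carry a large ORF per the oracle; neighbors overlap them
  orfd <- by_cat("large_orf_decoy")
  for (i in seq_len(nrow(orfd))) {
    expect_gt(nrow(oracle_large_orfs(sim$sequences[[orfd$id[i]]])), 0)
  }
  nb <- by_cat("orf_neighbor_decoy")
  for (i in seq_len(nrow(nb))) {
    ovl <- vapply(seq_len(nrow(orfd)), function(j) {
      exon_overlap_bp(nb[i, ], orfd[j, ])
    }, numeric(1))
    expect_gt(max(ovl), 0)
    expect_equal(nrow(oracle_large_orfs(sim$sequences[[nb$id[i]]])), 0)
  }
})

test_that("low-expression decoys stay under FPKM 1 in every dataset after
           counting", {
  sim <- sim5
  rna_info <- sim$dataset_info[
    sim$dataset_info$dataset_id %in% names(sim$reads), ]
  em <- expression_matrix(sim$reads, sim$transcripts, rna_info)
  low <- sim$truth$transcript_id[
    sim$truth$category == "low_expression_decoy"]
  expect_true(all(em$fpkm[low, ] < 1))
  # and planted lincRNAs clear the threshold somewhere
  linc <- sim$truth$transcript_id[sim$truth$category == "true_lincRNA"]
  expect_true(all(apply(em$fpkm[linc, , drop = FALSE], 1, max) > 1))
})

test_that("simulated counts are Poisson around the FPKM-implied mean", {
  t <- transcript_set("t", "chr1", "+", list(0L), list(1000L))
  lambda <- 10 * 1000 * 1e6 / 1e9  # FPKM 10, 1 kb, 1M mapped reads
  set.seed(400)
  counts <- replicate(100, {
    r <- lincatlas:::reads_for_transcript(t, lambda, 100L, 1L)
    if (is.null(r)) 0L else length(unique(r$read_id))
  })
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 100))
})

test_that("junction-spanning reads are emitted as split alignments whose
           gap is the intron", {
  t <- transcript_set("t", "chr1", "+", list(c(0L, 2000L)),
                      list(c(100L, 2100L)))
  set.seed(6)
  r <- lincatlas:::reads_for_transcript(t, 50, 80L, 1L)
  split_ids <- names(which(table(r$read_id) == 2))
  expect_gt(length(split_ids), 0)
  for (id in split_ids) {
    b <- r[r$read_id == id, ]
    expect_equal(b$end[1], 100L)    # first block ends at the junction
    expect_equal(b$start[2], 2000L) # second begins after the intron
    expect_equal(sum(b$end - b$start), 80L)
  }
})

test_that("the planted TAS enrichment is recovered from the table", {
  sim <- simulate_all(small_cfg(seed = 44))
  linc <- sim$transcripts[sim$truth$category == "true_lincRNA", ]
  inside <- lincatlas:::snps_in_regions(sim$snps, linc)
  rate_in <- mean(sim$snps$trait_associated[inside])
  rate_out <- mean(sim$snps$trait_associated[!inside])
  fold <- rate_in / rate_out
  n_in <- sum(inside)
  sd_fold <- fold * sqrt((1 - rate_in) / (rate_in * n_in) +
                           (1 - rate_out) / (rate_out * sum(!inside)))
  expect_lt(abs(fold - 5), 3 * sd_fold)
})

test_that("the conservation track elevates planted windows above the
           baseline noise extreme", {
  sim <- simulate_all(small_cfg(seed = 13))
  linc <- sim$transcripts[sim$truth$category == "true_lincRNA", ]
  cons <- vapply(which(linc$id %in% sim$conserved_linc_ids),
                 function(i) max_conserved_window(linc[i, ], sim$track),
                 numeric(1))
  plain <- vapply(which(!linc$id %in% sim$conserved_linc_ids),
                  function(i) max_conserved_window(linc[i, ], sim$track),
                  numeric(1))
  # elevated windows approach mean 2; the max 50-bp mean of N(0,1) noise
  # stays well below that
  expect_gt(min(cons), max(plain))
  expect_lt(max(plain), 1.5)
  expect_gt(min(cons), 1.2)
})

test_that("an infeasible configuration raises a generation error", {
  cfg <- sim_config(seed = 2, n_chromosomes = 1L, chrom_length = 50000L)
  expect_error(generate_annotations_and_transcripts(
    cfg, generate_genome(cfg)), "too small")
})
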