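test_that("length filter removes below 200 nt of mature sequence", {
  tx <- transcript_set(c("a", "b", "c"), "chr1", ".",
                       list(0L, 0L, c(0L, 10000L)),
                       list(199L, 200L, c(5000L, 15000L)))
  expect_equal(unname(filter_length(tx)), c(FALSE, TRUE, TRUE))
})

test_that("proximity filter applies the strand rule table", {
  genes <- transcript_set("nm", "chr1", "+", list(10000L), list(12000L))
  cand <- transcript_set(
    c("amb_near", "opp_near", "opp_touch", "same_near", "amb_far",
      "same_far", "opp_inside"),
    "chr1",
    c(".", "-", "-", "+", ".", "+", "-"),
    list(12500L, 12500L, 11999L, 12900L, 13500L, 13001L, 10500L),
    list(13200L, 13200L, 12500L, 13500L, 14500L, 14000L, 11000L))
  keep <- filter_protein_gene_proximity(cand, genes)
  expect_equal(setNames(keep, cand$id),
               c(amb_near = FALSE,   # ambiguous within 1 kb: either strand
                 opp_near = TRUE,    # opposite strand, no overlap: keep
                 opp_touch = FALSE,  # opposite strand, 1 bp overlap
                 same_near = FALSE,  # same strand within 1 kb
                 amb_far = TRUE,     # > 1 kb away
                 same_far = TRUE,    # exactly 1001 bp away
                 opp_inside = FALSE))
  # inclusive boundary: gap of exactly 1000 removes
  at1000 <- transcript_set("x", "chr1", "+", list(13000L), list(13600L))
  expect_false(filter_protein_gene_proximity(at1000, genes))
})

test_that("annotation overlap filter is strand-blind and one-base strict", {
  tx <- transcript_set(c("hit", "near", "opp"), "chr1", c(".", ".", "-"),
                       list(999L, 2001L, 5000L),
                       list(1500L, 2500L, 5400L))
  pseudo <- data.frame(chrom = "chr1", start = c(500L, 5399L),
                       end = c(1000L, 5600L))
  keep <- filter_annotation_overlap(tx, pseudo)
  expect_equal(unname(keep), c(FALSE, TRUE, FALSE))
  # span overlap counts even when only an intron overlaps the annotation
  spl <- transcript_set("spl", "chr1", ".", list(c(400L, 1200L)),
                        list(c(450L, 1300L)))
  expect_false(filter_annotation_overlap(
    spl, data.frame(chrom = "chr1", start = 600, end = 700)))
})

test_that("large-ORF filter removes carriers and their span neighbors,
           non-transitively", {
  txA <- transcript_set("txA", "chr1", ".", list(c(0L, 2000L)),
                        list(c(700L, 2700L)))
  txB <- transcript_set("txB", "chr1", ".", list(2600L), list(3400L))
  txC <- transcript_set("txC", "chr1", ".", list(3300L), list(3900L))
  txD <- transcript_set("txD", "chr1", ".", list(9000L), list(9600L))
  tx <- lincatlas:::bind_transcripts(txA, txB, txC, txD)
  orf_seq <- paste0(strrep("T", 20), "ATG", strrep("GCA", 120), "TAA",
                    lincatlas:::make_orf_free_sequence(1091))
  set.seed(5)
  seqs <- c(txA = orf_seq,
            txB = lincatlas:::make_orf_free_sequence(800),
            txC = lincatlas:::make_orf_free_sequence(600),
            txD = lincatlas:::make_orf_free_sequence(600))
  res <- filter_large_orf_and_neighbors(tx, seqs)
  expect_equal(res$large_orf_ids, "txA")
  expect_equal(unname(res$keep), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(res$reason[1:2], c("large_orf", "orf_neighbor"))
  # txC overlaps only the pass-2 victim txB and survives (non-transitive)
  expect_true(res$keep[3])
})

test_that("extended-gene filter removes on one-base span overlap", {
  ext <- data.frame(chrom = "chr1", start = 1000L, end = 5000L)
  tx <- transcript_set(c("in_ext", "past", "opp"), "chr1",
                       c(".", ".", "-"),
                       list(4999L, 5001L, 2000L),
                       list(5600L, 5700L, 2400L))
  expect_equal(unname(filter_extended_genes(tx, ext)),
               c(FALSE, TRUE, FALSE))
})

test_that("the cascade applies stages in order, is idempotent, and its
           report counts add up", {
  sim <- simulate_all(sim_config(
    seed = 7, n_chromosomes = 2L, chrom_length = 300000L,
    counts = c(true_lincRNA = 25L, protein_coding = 12L, pseudogene = 5L,
               small_ncRNA = 5L, utr_extension_victim = 5L,
               large_orf_decoy = 8L, orf_neighbor_decoy = 5L,
               proximity_decoy = 8L, low_expression_decoy = 6L,
               short_decoy = 6L),
    n_tested_snps = 2000L))
  rna_info <- sim$dataset_info[
    sim$dataset_info$dataset_id %in% names(sim$reads), ]
  em <- expression_matrix(sim$reads, sim$transcripts, rna_info)
  casc <- run_cascade(sim$transcripts, sim$catalog, sim$sequences, em)
  expect_equal(sum(casc$stage_counts),
               nrow(sim$transcripts) - nrow(casc$kept))
  expect_equal(sort(casc$kept$id),
               sort(sim$truth$transcript_id[
                 sim$truth$category == "true_lincRNA"]))
  # every decoy is removed at its targeted stage
  rep <- merge(casc$report, sim$truth, by.x = "id",
               by.y = "transcript_id")
  expect_equal(rep$status, rep$expected_fate)
  # idempotent: rerunning on the survivors changes nothing
  em2 <- expression_matrix(sim$reads, casc$kept, rna_info)
  casc2 <- run_cascade(casc$kept, sim$catalog,
                       sim$sequences[casc$kept$id], em2)
  expect_equal(casc2$kept$id, casc$kept$id)
  expect_equal(sum(casc2$stage_counts), 0L)
})

test_that("an empty candidate set yields an empty report", {
  tx0 <- transcript_set("x", "chr1", ".", list(0L), list(500L))[0, ]
  catalog <- list(protein_coding = tx0,
                  non_lincRNA_other = data.frame(chrom = character(),
                                                 start = integer(),
                                                 end = integer()),
                  utr_extensions = data.frame(chrom = character(),
                                              start = integer(),
                                              end = integer()),
                  extended_gene_boundaries = data.frame(
                    chrom = character(), start = integer(),
                    end = integer()))
  em <- structure(list(counts = matrix(0L, 0, 1,
                                       dimnames = list(NULL, "d1")),
                       fpkm = matrix(0, 0, 1,
                                     dimnames = list(NULL, "d1")),
                       lengths = integer(0),
                       datasets = data.frame(dataset_id = "d1",
                                             total_mapped_reads = 1e7)),
                  class = "expression_matrix")
  casc <- run_cascade(tx0, catalog, character(0), em)
  expect_equal(nrow(casc$kept), 0L)
  expect_equal(sum(casc$stage_counts), 0L)
})
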