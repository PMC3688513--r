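mk_tx <- function(ids, starts, ends, strand = ".", chrom = "chr1") {
  transcript_set(ids, chrom, strand,
                 lapply(starts, as.integer), lapply(ends, as.integer))
}

test_that("the 50% exon rule is inclusive and one-directional", {
  half <- mk_tx(c("a", "b"), list(0, 500), list(1000, 1500))
  expect_true(should_merge(half[1, ], half[2, ]))    # 500/1000 = 50%
  forty <- mk_tx(c("a", "b"), list(0, 600), list(1000, 1600))
  expect_false(should_merge(forty[1, ], forty[2, ])) # 400/1000 = 40%
  nested <- mk_tx(c("a", "b"), list(0, 200), list(10000, 300))
  expect_true(should_merge(nested[1, ], nested[2, ])) # 100% of small exon
  expect_true(should_merge(nested[2, ], nested[1, ])) # symmetric
})

test_that("strand compatibility gates merging", {
  opp <- mk_tx(c("p", "m"), list(0, 100), list(1000, 1100),
               strand = c("+", "-"))
  expect_false(should_merge(opp[1, ], opp[2, ]))
  ambig <- mk_tx(c("p", "a"), list(0, 100), list(1000, 1100),
                 strand = c("+", "."))
  expect_true(should_merge(ambig[1, ], ambig[2, ]))
  other_chrom <- transcript_set(c("x", "y"), c("chr1", "chr2"), ".",
                                list(0L, 0L), list(1000L, 1000L))
  expect_false(should_merge(other_chrom[1, ], other_chrom[2, ]))
})

test_that("merge closure is transitive and unions member exons", {
  # A-B mergeable (50%), B-C mergeable (50%), A-C do not even overlap
  tx <- mk_tx(c("A", "B", "C"),
              list(0, 500, 1000), list(1000, 1500, 2000))
  expect_true(should_merge(tx[1, ], tx[2, ]))
  expect_true(should_merge(tx[2, ], tx[3, ]))
  expect_false(should_merge(tx[1, ], tx[3, ]))
  merged <- merge_closure(tx)
  expect_equal(nrow(merged), 1)
  expect_equal(sort(merged$members[[1]]), c("A", "B", "C"))
  expect_equal(merged$exon_starts[[1]], 0L)
  expect_equal(merged$exon_ends[[1]], 2000L)
  # pairwise non-mergeable input is returned unchanged in count
  apart <- mk_tx(c("x", "y"), list(0, 5000), list(1000, 6000))
  expect_equal(nrow(merge_closure(apart)), 2)
})

test_that("merge closure output is a fixed point and matches the
           brute-force component oracle", {
  set.seed(411)
  for (rep in 1:8) {
    tx <- random_transcripts(sample(20:80, 1), chrom_len = 30000)
    merged <- merge_closure(tx)
    # fixed point: no pair of outputs merges
    if (nrow(merged) > 1) {
      for (i in 1:(nrow(merged) - 1)) {
        for (j in (i + 1):nrow(merged)) {
          expect_false(should_merge(merged[i, ], merged[j, ]))
        }
      }
    }
    # partition equals the brute-force iterated component oracle
    n <- nrow(tx)
    oc <- oracle_merge_partition(tx)
    got <- integer(n)
    for (k in seq_len(nrow(merged))) {
      got[match(merged$members[[k]], tx$id)] <- k
    }
    expect_true(same_partition(got, oc))
  }
})

test_that("grouping is inclusive at 1 kb and transitively chained", {
  m <- mk_tx(c("a", "b", "c"), list(0, 1999, 10000),
             list(1000, 2500, 11000))
  expect_equal(group_by_proximity(m), c(1L, 1L, 2L))  # 999 bp gap joins
  m2 <- mk_tx(c("a", "b"), list(0, 2001), list(1000, 2500))
  expect_equal(group_by_proximity(m2), c(1L, 2L))     # 1001 bp separates
  m3 <- mk_tx(c("a", "b"), list(0, 2000), list(1000, 2500))
  expect_equal(group_by_proximity(m3), c(1L, 1L))     # exactly 1000 joins
  chain <- mk_tx(c("a", "b", "c"), list(0, 1900, 3800),
                 list(1000, 2900, 4800))
  expect_equal(group_by_proximity(chain), c(1L, 1L, 1L))
})

test_that("names follow the tier/group/transcript template ordered by
           position", {
  m <- mk_tx(c("right", "left"), list(2100, 0), list(2700, 1000))
  m <- m[order(m$start), ]
  g <- group_by_proximity(m)
  nm <- assign_names(m, g, 1)
  expect_equal(nm, c("FPKM1_group_1_transcript_1",
                     "FPKM1_group_2_transcript_1"))
  close_pair <- mk_tx(c("b", "a"), list(500, 0), list(1200, 400))
  gp <- group_by_proximity(close_pair)
  expect_equal(sort(assign_names(close_pair, gp, 10)),
               c("FPKM10_group_1_transcript_1",
                 "FPKM10_group_1_transcript_2"))
  # leftmost transcript gets number 1
  expect_equal(assign_names(close_pair, gp, 10)[close_pair$id == "a"],
               "FPKM10_group_1_transcript_1")
})

test_that("catalogs are invariant to input order", {
  set.seed(99)
  tx <- random_transcripts(60, chrom_len = 40000)
  cat1 <- build_tier_catalog(tx, 1)
  cat2 <- build_tier_catalog(tx[sample(nrow(tx)), ], 1)
  expect_equal(cat1$chrom, cat2$chrom)
  expect_equal(cat1$exon_starts, cat2$exon_starts)
  expect_equal(cat1$name, cat2$name)
  expect_equal(lapply(cat1$members, sort), lapply(cat2$members, sort))
})

test_that("strand inference requires unanimous junction orientations", {
  expect_equal(infer_strand(c("+", "+")), "+")
  expect_equal(infer_strand(c("-", "-", "-")), "-")
  expect_equal(infer_strand(character(0)), ".")   # single exon
  expect_equal(infer_strand(c("+", "-")), ".")    # conflict
  expect_equal(infer_strand(c(NA, "+")), "+")
  expect_equal(infer_strand(NA_character_), ".")
})
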