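#' Default simulated dataset panel
#'
#' Six RNA-seq datasets over three tissues: two tissues measured in both
#' polyA-selected and polyA-depleted fractions, one tissue in replicate
#' rRNA-depleted libraries. Totals are nominal library sizes (the
#' flagstat-style totals used for FPKM); the number of simulated reads is
#' whatever the expression model implies and is smaller, as when counting
#' a region subset of a large library. `background_reads` sets the
#' density of unassigned genomic noise reads per megabase of genome per
#' dataset — higher in polyA- libraries, which carry more non-transcript
#' signal. A density (rather than a count) keeps the noise level
#' comparable across genome sizes.
#'
#' @return `data.frame` with `dataset_id`, `library_type`, `tissue`,
#'   `total_mapped_reads`, `background_reads` (reads per Mb).
#' @export
sim_datasets_default <- function() {
  data.frame(
    dataset_id = paste0("d", 1:6),
    library_type = c("polyA+", "polyA-", "polyA+", "polyA-",
                     "rRNA-depleted", "rRNA-depleted"),
    tissue = c("T1", "T1", "T2", "T2", "T3", "T3"),
    total_mapped_reads = 1e7,
    background_reads = c(125L, 500L, 125L, 500L, 250L, 250L),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' All knobs of the synthetic study: a small multi-chromosome genome with
#' a mappability mask, protein-coding genes carrying real ORFs,
#' pseudogene/small-RNA/UTR decoys, planted lincRNAs, tissue-specific
#' log-normal expression over several library types, a ribosome-profiling
#' dataset concentrated on CDS, ChIP IP/input datasets, a conservation
#' track with elevated windows, SNP tables with a planted trait-associated
#' enrichment, and PET end clusters. One RNG stream per sub-generator is
#' derived from `seed`, so adding a dataset never perturbs annotation
#' placement. Every decoy category violates exactly one filter rule, so
#' per-stage removals are attributable.
#'
#' @param seed Master seed; fixes all randomness.
#' @param n_chromosomes,chrom_length Genome shape (default 2 x 1 Mb).
#' @param unmappable_fraction Fraction of each chromosome excluded from
#'   the mappability mask in random 50-500 bp segments.
#' @param counts Named integer vector of transcripts per truth category.
#' @param datasets RNA-seq dataset panel (see [sim_datasets_default()]).
#' @param read_length RNA-seq read length (bp).
#' @param expression_meanlog,expression_sdlog Log-normal base expression
#'   of active transcripts (FPKM scale).
#' @param min_active_fpkm Floor on an active transcript's tissue FPKM,
#'   keeping planted lincRNAs safely above the FPKM>1 filter.
#' @param coding_meanlog,coding_sdlog Expression of coding genes.
#' @param low_expression_fpkm Expected FPKM of low-expression decoys in
#'   every dataset (well below 1).
#' @param tas_enrichment_fold Trait-associated SNP rate in lincRNA exons
#'   relative to the background rate.
#' @param nm_tas_fold Same for coding exons.
#' @param tas_background_rate Baseline probability that a tested SNP is
#'   trait-associated.
#' @param n_tested_snps Number of tested SNPs scattered over the genome.
#' @param common_snp_rate Probability a tested SNP is common.
#' @param conservation_elevated_mean Mean score in elevated windows
#'   (baseline noise has mean 0, sd 1).
#' @param conserved_lincRNA_fraction Fraction of planted lincRNAs whose
#'   exons get elevated conservation.
#' @param extension_pad_range Extended-gene padding range (bp per side).
#' @param ribo_reads,ribo_read_length,ribo_total Ribosome-profiling
#'   dataset size; reads fall only on coding CDS.
#' @param chip_reads,chip_read_length,chip_total ChIP IP/input dataset
#'   sizes; IP reads are enriched over planted mark intervals.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 42L,
                       n_chromosomes = 2L,
                       chrom_length = 1000000L,
                       unmappable_fraction = 0.1,
                       counts = c(true_lincRNA = 150L, protein_coding = 60L,
                                  pseudogene = 40L, small_ncRNA = 40L,
                                  utr_extension_victim = 40L,
                                  large_orf_decoy = 50L,
                                  orf_neighbor_decoy = 30L,
                                  proximity_decoy = 50L,
                                  low_expression_decoy = 50L,
                                  short_decoy = 50L),
                       datasets = sim_datasets_default(),
                       read_length = 100L,
                       expression_meanlog = log(30),
                       expression_sdlog = 0.8,
                       min_active_fpkm = 20,
                       coding_meanlog = log(50),
                       coding_sdlog = 0.6,
                       low_expression_fpkm = 0.05,
                       tas_enrichment_fold = 5,
                       nm_tas_fold = 3,
                       tas_background_rate = 0.04,
                       n_tested_snps = 10000L,
                       common_snp_rate = 0.3,
                       conservation_elevated_mean = 2,
                       conserved_lincRNA_fraction = 0.3,
                       extension_pad_range = c(500L, 5000L),
                       ribo_reads = 30000L, ribo_read_length = 30L,
                       ribo_total = 1e7,
                       chip_reads = 20000L, chip_read_length = 36L,
                       chip_total = 1e7) {
  stopifnot(all(counts >= 0), unmappable_fraction >= 0,
            unmappable_fraction < 1, n_chromosomes >= 1,
            chrom_length >= 10000, tas_enrichment_fold > 0,
            counts["orf_neighbor_decoy"] <= counts["large_orf_decoy"],
            counts["proximity_decoy"] <= counts["protein_coding"])
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Generate the toy genome and its mappability mask
#'
#' Unmappable segments of 50-500 bp are scattered until they are expected
#' to cover `unmappable_fraction` of each chromosome (segment total is
#' overlap-corrected); the mask is their complement.
#'
#' @param cfg A [sim_config()].
#' @return A [genome_spec()].
#' @export
generate_genome <- function(cfg) {
  with_stream(cfg$seed, "genome", {
    L <- cfg$chrom_length
    chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
    seqlengths <- setNames(rep(L, cfg$n_chromosomes), chroms)
    if (cfg$unmappable_fraction == 0)
      return(genome_spec(seqlengths))
    target <- -L * log(1 - cfg$unmappable_fraction)  # overlap-corrected
    mask_parts <- lapply(chroms, function(ch) {
      widths <- integer(0)
      while (sum(widths) < target)
        widths <- c(widths, sample(50:500, 200, replace = TRUE))
      widths <- widths[cumsum(widths) <= target]
      starts <- sample.int(L, length(widths), replace = TRUE) - 1L
      unmap <- data.frame(chrom = ch, start = starts,
                          end = pmin(starts + widths, L))
      subtract_intervals(data.frame(chrom = ch, start = 0L, end = L), unmap)
    })
    genome_spec(seqlengths, do.call(rbind, mask_parts))
  })
}

# Unmappable intervals (complement of the mask) per chromosome.
unmappable_intervals <- function(genome) {
  whole <- data.frame(chrom = names(genome$seqlengths), start = 0L,
                      end = unname(genome$seqlengths))
  subtract_intervals(whole, genome$mask)
}

# --- placement machinery -----------------------------------------------

# Draw exon geometry for one feature unit. Returns exon starts/ends
# relative to the unit origin, plus satellite features, all 0-based.
unit_geometry <- function(category) {
  runi <- function(a, b) sample(a:b, 1)
  linc_exons <- function() {
    n <- sample(1:3, 1, prob = c(0.4, 0.4, 0.2))
    lens <- sample(250:500, n, replace = TRUE)
    introns <- if (n > 1) sample(250:700, n - 1, replace = TRUE) else integer()
    s <- cumsum(c(0L, head(lens, -1) + introns))
    list(starts = s, ends = s + lens)
  }
  switch(category,
    linc = {
      g <- linc_exons()
      strand <- sample(c(".", "+", "-"), 1, prob = c(0.7, 0.15, 0.15))
      list(main = g, strand = strand, width = max(g$ends))
    },
    lowexpr = {
      # longer mature length: the FPKM>1 cutoff then needs several reads,
      # which background noise essentially never supplies
      n <- sample(1:2, 1)
      lens <- if (n == 1) runi(800, 1000) else
        sample(450:650, 2, replace = TRUE)
      introns <- if (n > 1) runi(300, 600) else integer()
      s <- cumsum(c(0L, head(lens, -1) + introns))
      list(main = list(starts = s, ends = s + lens), strand = ".",
           width = max(s + lens))
    },
    coding = {
      n <- sample(2:3, 1)
      lens <- sample(280:550, n, replace = TRUE)
      introns <- sample(250:700, n - 1, replace = TRUE)
      s <- cumsum(c(0L, head(lens, -1) + introns))
      list(main = list(starts = s, ends = s + lens),
           strand = sample(c("+", "-"), 1), width = max(s + lens))
    },
    orf = {
      lens <- sample(350:650, 2, replace = TRUE)
      intron <- runi(600, 900)
      s <- c(0L, lens[1] + intron)
      list(main = list(starts = s, ends = s + lens), strand = ".",
           width = max(s + lens), intron = c(lens[1], lens[1] + intron))
    },
    anno_pair = NULL,  # built by caller (pseudo / snc / utr variants)
    short = {
      w <- runi(80, 190)
      list(main = list(starts = 0L, ends = w), strand = ".", width = w)
    },
    stop("unknown unit category: ", category)
  )
}

# Geometry for an annotation interval plus an overlapping candidate.
anno_pair_geometry <- function(anno_range) {
  anno_len <- sample(anno_range[1]:anno_range[2], 1)
  cand_len <- sample(300:650, 1)
  # candidate overlaps the annotation's right half by >= 50 bp
  cand_start <- anno_len - sample(50:min(anno_len, cand_len), 1)
  list(anno = c(0L, anno_len),
       main = list(starts = cand_start, ends = cand_start + cand_len),
       strand = ".", width = max(anno_len, cand_start + cand_len))
}

#' Generate annotations, candidate transcripts and ground-truth labels
#'
#' Places every feature unit sequentially along the chromosomes with
#' inter-unit gaps larger than the proximity threshold, avoiding
#' unmappable segments, then writes designed sequences into the genome:
#' protein-coding genes and large-ORF decoys get real ORFs (>= 151
#' codons, resp. 110-180 codons); planted lincRNAs, low-expression decoys
#' and ORF-neighbor decoys get sequences verified free of large ORFs.
#' Each decoy category is constructed to violate exactly one filter rule.
#'
#' @param cfg A [sim_config()].
#' @param genome A [genome_spec()] from [generate_genome()].
#' @return List: `genome_seq` (named character per chromosome),
#'   `transcripts` (candidate [transcript_set()]), `truth`
#'   (`transcript_id`, `category`, `expected_fate`), `catalog` (the
#'   annotation catalog for the cascade), `cds` (transcript-coordinate CDS
#'   per coding id), `gene_tss` (mark anchor points).
#' @export
generate_annotations_and_transcripts <- function(cfg, genome) {
  with_stream(cfg$seed, "annotation", {
    chroms <- names(genome$seqlengths)
    genome_seq <- setNames(
      vapply(chroms, function(ch) random_dna(genome$seqlengths[[ch]]),
             character(1)), chroms)
    unmap <- unmappable_intervals(genome)

    # unit plan: one entry per placed unit; satellites ride along
    n <- cfg$counts
    units <- c(
      rep("true_lincRNA", n["true_lincRNA"]),
      rep("low_expression_decoy", n["low_expression_decoy"]),
      rep("protein_coding_prox", n["proximity_decoy"]),
      rep("protein_coding", n["protein_coding"] - n["proximity_decoy"]),
      rep("pseudogene", n["pseudogene"]),
      rep("small_ncRNA", n["small_ncRNA"]),
      rep("utr_extension_victim", n["utr_extension_victim"]),
      rep("large_orf_neighbor", n["orf_neighbor_decoy"]),
      rep("large_orf", n["large_orf_decoy"] - n["orf_neighbor_decoy"]),
      rep("short_decoy", n["short_decoy"]))
    units <- sample(units)

    tx_rows <- list()       # candidate transcripts
    truth_rows <- list()
    anno_rows <- list()     # non-lincRNA annotation intervals
    utr_rows <- list()
    gene_rows <- list()     # protein-coding annotation (with strand)
    pad_rows <- list()      # extended gene boundaries
    design <- list()        # id -> list(kind, rows)
    counter <- new.env()
    next_id <- function(prefix) {
      k <- if (exists(prefix, envir = counter, inherits = FALSE))
        get(prefix, envir = counter, inherits = FALSE) + 1L else 1L
      assign(prefix, k, envir = counter)
      sprintf("%s_%03d", prefix, k)
    }
    add_tx <- function(id, chrom, strand, starts, ends, category, fate) {
      tx_rows[[length(tx_rows) + 1L]] <<-
        list(id = id, chrom = chrom, strand = strand,
             starts = starts, ends = ends)
      truth_rows[[length(truth_rows) + 1L]] <<-
        data.frame(transcript_id = id, category = category,
                   expected_fate = fate)
    }

    ch_i <- 1L
    cursor <- 0L
    place_width <- function(width, pad_left = 0L, pad_right = 0L) {
      # next position whose core span avoids unmappable segments; the
      # inter-unit gap keeps every pair of features > 1 kb apart
      repeat {
        if (ch_i > length(chroms))
          stop("genome too small to place requested features")
        ch <- chroms[ch_i]
        gap <- sample(1050:1200, 1)
        s <- cursor + gap + pad_left
        repeat {
          u <- unmap[unmap$chrom == ch & unmap$start < s + width &
                       unmap$end > s, , drop = FALSE]
          if (!nrow(u)) break
          s <- max(u$end) + 10L
        }
        if (s + width + pad_right >= genome$seqlengths[[ch]]) {
          ch_i <<- ch_i + 1L
          cursor <<- 0L
          next
        }
        cursor <<- s + width + pad_right
        return(list(chrom = ch, start = s))
      }
    }

    n_padded_target <- max(1L, (n["protein_coding"] - n["proximity_decoy"]) %/% 2)
    n_padded <- 0L

    for (u in units) {
      if (u %in% c("true_lincRNA", "low_expression_decoy")) {
        g <- unit_geometry(if (u == "true_lincRNA") "linc" else "lowexpr")
        at <- place_width(g$width)
        id <- next_id(if (u == "true_lincRNA") "linc" else "lowexpr")
        add_tx(id, at$chrom, g$strand, at$start + g$main$starts,
               at$start + g$main$ends, u,
               if (u == "true_lincRNA") "retained" else "expression")
        design[[id]] <- "orf_free"

      } else if (u %in% c("protein_coding", "protein_coding_prox")) {
        g <- unit_geometry("coding")
        pad <- c(0L, 0L)
        if (u == "protein_coding" && n_padded < n_padded_target) {
          pad <- sample(cfg$extension_pad_range[1]:cfg$extension_pad_range[2],
                        2, replace = TRUE)
          n_padded <- n_padded + 1L
        }
        prox_width <- if (u == "protein_coding_prox") {
          # reserve room for the attached proximity decoy
          700L + 600L
        } else 0L
        at <- place_width(g$width + prox_width, pad_left = pad[1],
                          pad_right = pad[2])
        id <- next_id("gene")
        add_tx(id, at$chrom, g$strand, at$start + g$main$starts,
               at$start + g$main$ends, "protein_coding", "proximity")
        gene_rows[[length(gene_rows) + 1L]] <- data.frame(
          chrom = at$chrom, start = at$start, end = at$start + g$width,
          name = id, score = 0L, strand = g$strand)
        pad_rows[[length(pad_rows) + 1L]] <- data.frame(
          chrom = at$chrom, start = at$start - pad[1],
          end = at$start + g$width + pad[2], name = paste0(id, "_ext"))
        design[[id]] <- "coding"
        if (u == "protein_coding_prox") {
          dgap <- sample(100:700, 1)
          dlen <- sample(300:600, 1)
          dstart <- at$start + g$width + dgap
          did <- next_id("prox")
          add_tx(did, at$chrom, ".", dstart, dstart + dlen,
                 "proximity_decoy", "proximity")
        }

      } else if (u %in% c("pseudogene", "small_ncRNA",
                          "utr_extension_victim")) {
        rng <- switch(u, pseudogene = c(500L, 1500L),
                      small_ncRNA = c(80L, 300L),
                      utr_extension_victim = c(300L, 1000L))
        g <- anno_pair_geometry(rng)
        at <- place_width(g$width)
        pre <- switch(u, pseudogene = "pseudo", small_ncRNA = "sncrna",
                      utr_extension_victim = "utrvic")
        id <- next_id(pre)
        add_tx(id, at$chrom, g$strand, at$start + g$main$starts,
               at$start + g$main$ends, u, "annotation_overlap")
        anno <- data.frame(chrom = at$chrom, start = at$start + g$anno[1],
                           end = at$start + g$anno[2],
                           name = paste0(id, "_anno"))
        if (u == "utr_extension_victim")
          utr_rows[[length(utr_rows) + 1L]] <- anno
        else anno_rows[[length(anno_rows) + 1L]] <- anno

      } else if (u %in% c("large_orf", "large_orf_neighbor")) {
        g <- unit_geometry("orf")
        at <- place_width(g$width)
        id <- next_id("orfdecoy")
        add_tx(id, at$chrom, g$strand, at$start + g$main$starts,
               at$start + g$main$ends, "large_orf_decoy", "large_orf")
        design[[id]] <- "orf"
        if (u == "large_orf_neighbor") {
          nlen <- sample(200:400, 1)
          margin <- (g$intron[2] - g$intron[1] - nlen) %/% 2
          nstart <- at$start + g$intron[1] + margin
          nid <- next_id("orfnb")
          add_tx(nid, at$chrom, ".", nstart, nstart + nlen,
                 "orf_neighbor_decoy", "orf_neighbor")
          design[[nid]] <- "orf_free"
        }

      } else if (u == "short_decoy") {
        g <- unit_geometry("short")
        at <- place_width(g$width)
        id <- next_id("shortd")
        add_tx(id, at$chrom, g$strand, at$start + g$main$starts,
               at$start + g$main$ends, "short_decoy", "length")
      }
    }

    tx <- transcript_set(
      vapply(tx_rows, `[[`, character(1), "id"),
      vapply(tx_rows, `[[`, character(1), "chrom"),
      vapply(tx_rows, `[[`, character(1), "strand"),
      lapply(tx_rows, `[[`, "starts"),
      lapply(tx_rows, `[[`, "ends"),
      source = "candidate")
    truth <- do.call(rbind, truth_rows)

    # --- write designed sequences into the genome ---
    cds <- list()
    for (i in seq_len(nrow(tx))) {
      id <- tx$id[i]
      kind <- design[[id]]
      if (is.null(kind)) next
      L <- exonic_length(tx[i, , drop = FALSE])
      if (kind == "coding" || kind == "orf") {
        ncod <- if (kind == "coding")
          sample(151:min(320, (L - 60) %/% 3 - 2), 1)
        else sample(110:min(180, (L - 30) %/% 3 - 2), 1)
        cds_nt <- 3L * ncod + 6L  # ATG + codons + stop
        utr5 <- sample(10:max(11, (L - cds_nt) %/% 2), 1)
        utr5 <- min(utr5, L - cds_nt)
        body <- paste0(make_orf_free_sequence(utr5), "ATG",
                       random_codons(ncod), "TAA")
        rest <- L - nchar(body)
        seqs <- paste0(body, if (rest > 0) make_orf_free_sequence(rest) else "")
        if (tx$strand[i] == "-") {
          # CDS reads 5'->3' on the minus strand: design on the revcomp
          cds[[id]] <- c(L - (utr5 + cds_nt), L - utr5)
          seqs <- revcomp(seqs)
        } else {
          cds[[id]] <- c(utr5, utr5 + cds_nt)
        }
      } else {
        seqs <- make_orf_free_sequence(L)
      }
      genome_seq[[tx$chrom[i]]] <- write_spliced(
        genome_seq[[tx$chrom[i]]], tx$exon_starts[[i]], tx$exon_ends[[i]],
        seqs)
    }

    genes <- bind_rows_df(gene_rows)
    catalog <- list(
      protein_coding = tx[truth$category == "protein_coding", , drop = FALSE],
      non_lincRNA_other = bind_rows_df(anno_rows),
      utr_extensions = bind_rows_df(utr_rows),
      extended_gene_boundaries = bind_rows_df(pad_rows))
    list(genome_seq = genome_seq, transcripts = tx, truth = truth,
         catalog = catalog, cds = cds, genes = genes)
  })
}

bind_rows_df <- function(rows) {
  if (!length(rows)) return(data.frame(chrom = character(),
                                       start = integer(), end = integer(),
                                       name = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Random sense codons that are neither stop codons nor ATG (keeps designed
# ORF lengths exact).
random_codons <- function(n) {
  bad <- c(STOP_CODONS, "ATG")
  pool <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            c("A", "C", "G", "T")), 1, paste, collapse = "")
  pool <- setdiff(pool, bad)
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

# Random sequence with no large ORF in any of the six frames: offending
# calls are repaired by injecting in-frame stop codons until clean.
make_orf_free_sequence <- function(len, max_iter = 300L) {
  if (len == 0) return("")
  s <- random_dna(len)
  if (len < 3) return(s)
  for (it in seq_len(max_iter)) {
    calls <- find_large_orfs(s)
    if (!nrow(calls)) return(s)
    cl <- calls[1, ]
    mid <- cl$start_offset +
      3L * (((cl$end_offset - cl$start_offset) %/% 2L) %/% 3L)
    mid <- min(max(cl$start_offset, mid), cl$end_offset - 3L)
    if (cl$frame < 3) {
      substr(s, mid + 1L, mid + 3L) <- "TAA"
    } else {
      fwd <- len - mid - 3L  # map revcomp codon position to forward strand
      substr(s, fwd + 1L, fwd + 3L) <- "TTA"
    }
  }
  stop("could not construct an ORF-free sequence of length ", len)
}

# Overwrite genome sequence at exon positions with a spliced sequence.
write_spliced <- function(chrom_seq, exon_starts, exon_ends, spliced) {
  off <- 0L
  for (k in seq_along(exon_starts)) {
    w <- exon_ends[k] - exon_starts[k]
    substr(chrom_seq, exon_starts[k] + 1L, exon_ends[k]) <-
      substr(spliced, off + 1L, off + w)
    off <- off + w
  }
  chrom_seq
}

# --- expression and reads ----------------------------------------------

#' Expected expression (FPKM) of every candidate in every dataset
#'
#' Tissue-specific log-normal model: each transcript is active in a random
#' subset of tissues (coding genes everywhere, lincRNA-like transcripts in
#' one or two tissues most of the time) with a log-normal FPKM floored at
#' `min_active_fpkm`. A polyA weight partitions expression between
#' polyA-selected and polyA-depleted fractions; rRNA-depleted libraries
#' see the total. Low-expression decoys get `low_expression_fpkm`
#' everywhere.
#'
#' @param cfg A [sim_config()].
#' @param tx Candidate [transcript_set()].
#' @param truth Truth table from the annotation generator.
#' @return Numeric matrix of expected FPKM, transcripts x datasets.
#' @export
generate_expression_profiles <- function(cfg, tx, truth) {
  with_stream(cfg$seed, "expression", {
    ds <- cfg$datasets
    tissues <- unique(ds$tissue)
    E <- matrix(0, nrow(tx), nrow(ds), dimnames = list(tx$id, ds$dataset_id))
    cat_of <- setNames(truth$category, truth$transcript_id)
    for (i in seq_len(nrow(tx))) {
      id <- tx$id[i]
      category <- cat_of[[id]]
      if (category == "low_expression_decoy") {
        E[i, ] <- cfg$low_expression_fpkm
        next
      }
      coding <- category == "protein_coding"
      active <- if (coding) tissues else {
        k <- sample(1:3, 1, prob = c(0.6, 0.3, 0.1))
        sample(tissues, min(k, length(tissues)))
      }
      base <- if (coding)
        rlnorm(length(active), cfg$coding_meanlog, cfg$coding_sdlog)
      else pmax(cfg$min_active_fpkm,
                rlnorm(length(active), cfg$expression_meanlog,
                       cfg$expression_sdlog))
      names(base) <- active
      w <- if (coding) {
        if (runif(1) < 0.85) 0.9 else runif(1, 0.4, 0.6)
      } else {
        r <- runif(1)
        if (r < 0.4) 0.9 else if (r < 0.65) 0.1 else runif(1, 0.4, 0.6)
      }
      for (j in seq_len(nrow(ds))) {
        t <- ds$tissue[j]
        if (!t %in% active) next
        E[i, j] <- base[[t]] * switch(ds$library_type[j],
                                      "polyA+" = w, "polyA-" = 1 - w, 1)
      }
    }
    E
  })
}

# Convert transcript-coordinate read intervals to genomic blocks.
# reads: data.frame(read_id, tstart, tend) in [0, L); t: one transcript.
project_reads_to_genome <- function(read_id, tstart, tend, t) {
  ex_s <- t$exon_starts[[1]]; ex_e <- t$exon_ends[[1]]
  cum <- cumsum(c(0L, ex_e - ex_s))
  ov <- IRanges::findOverlaps(ir0(tstart, tend),
                              ir0(cum[-length(cum)], cum[-1]))
  q <- S4Vectors::queryHits(ov); k <- S4Vectors::subjectHits(ov)
  ps <- pmax(tstart[q], cum[k]); pe <- pmin(tend[q], cum[k + 1L])
  data.frame(read_id = read_id[q], chrom = t$chrom[1],
             start = ex_s[k] + (ps - cum[k]), end = ex_s[k] + (pe - cum[k]),
             strand = ".")
}

# Poisson reads along one transcript's spliced coordinates.
reads_for_transcript <- function(t, lambda, read_length, first_id) {
  n <- rpois(1, lambda)
  if (n == 0) return(NULL)
  L <- exonic_length(t)
  rl <- min(read_length, L)
  starts <- sample.int(L - rl + 1L, n, replace = TRUE) - 1L
  project_reads_to_genome(first_id + seq_len(n) - 1L, starts, starts + rl, t)
}

#' Simulate read alignments for every dataset
#'
#' Per-transcript per-dataset counts are Poisson with mean implied by the
#' expected FPKM (`count = FPKM x length_kb x total / 1e6`); reads are
#' placed uniformly along the spliced transcript and emitted as blocked
#' alignments (junction-spanning reads get one block per exon crossed).
#' Uniform genomic background reads model library noise. A
#' ribosome-profiling dataset places reads only within coding CDS, scaled
#' by the matched tissue's mRNA expression; ChIP IP reads are enriched
#' over planted mark intervals around transcription start sites, with a
#' uniform matched input.
#'
#' @param cfg A [sim_config()].
#' @param genome A [genome_spec()].
#' @param tx Candidate [transcript_set()].
#' @param expected_fpkm Matrix from [generate_expression_profiles()].
#' @param cds CDS coordinates per coding transcript id (transcript
#'   coordinates).
#' @param genes Coding-gene span table (for mark placement).
#' @return List: `reads` (named list of read tables for the RNA-seq
#'   datasets), `ribo_reads`, `chip_ip`, `chip_input`, `marks`,
#'   `dataset_info`.
#' @export
simulate_reads <- function(cfg, genome, tx, expected_fpkm, cds, genes) {
  ds <- cfg$datasets
  lens <- exonic_length(tx)
  glens <- genome$seqlengths
  uniform_reads <- function(n, rl, first_id) {
    if (n == 0) return(NULL)
    ch <- sample(names(glens), n, replace = TRUE,
                 prob = as.numeric(glens) / sum(as.numeric(glens)))
    st <- vapply(ch, function(c1) sample.int(glens[[c1]] - rl, 1) - 1L,
                 integer(1))
    data.frame(read_id = first_id + seq_len(n) - 1L, chrom = ch,
               start = st, end = st + rl, strand = ".")
  }

  reads <- with_stream(cfg$seed, "reads", {
    out <- list()
    for (j in seq_len(nrow(ds))) {
      parts <- list()
      nid <- 1L
      for (i in seq_len(nrow(tx))) {
        E <- expected_fpkm[i, j]
        if (E <= 0) next
        lambda <- E * lens[i] * ds$total_mapped_reads[j] / 1e9
        p <- reads_for_transcript(tx[i, , drop = FALSE], lambda,
                                  cfg$read_length, nid)
        if (!is.null(p)) { parts[[length(parts) + 1L]] <- p
          nid <- nid + length(unique(p$read_id)) }
      }
      n_bg <- round(ds$background_reads[j] *
                      sum(as.numeric(glens)) / 1e6)
      bg <- uniform_reads(n_bg, cfg$read_length, nid)
      if (!is.null(bg)) parts[[length(parts) + 1L]] <- bg
      r <- do.call(rbind, parts)
      rownames(r) <- NULL
      out[[ds$dataset_id[j]]] <- r
    }
    out
  })

  ribo <- with_stream(cfg$seed, "ribo", {
    coding_ids <- names(cds)
    # engagement proportional to the matched tissue's expression
    match_ds <- which(ds$library_type == "polyA+")[1]
    lam <- vapply(coding_ids, function(id) {
      i <- match(id, tx$id)
      w <- (cds[[id]][2] - cds[[id]][1]) / lens[i]
      expected_fpkm[i, match_ds] * w * lens[i]
    }, numeric(1))
    lam <- lam / sum(lam) * cfg$ribo_reads
    parts <- list(); nid <- 1L
    for (k in seq_along(coding_ids)) {
      id <- coding_ids[k]
      i <- match(id, tx$id)
      n <- rpois(1, lam[k])
      if (n == 0) next
      lo <- cds[[id]][1]; hi <- cds[[id]][2]
      rl <- min(cfg$ribo_read_length, hi - lo)
      st <- lo + sample.int(hi - lo - rl + 1L, n, replace = TRUE) - 1L
      parts[[length(parts) + 1L]] <- project_reads_to_genome(
        nid + seq_len(n) - 1L, st, st + rl, tx[i, , drop = FALSE])
      nid <- nid + n
    }
    r <- do.call(rbind, parts); rownames(r) <- NULL; r
  })

  chip <- with_stream(cfg$seed, "chip", {
    tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
    marks <- data.frame(chrom = genes$chrom,
                        start = pmax(0L, tss - 500L),
                        end = pmin(unname(glens[genes$chrom]), tss + 500L))
    n_mark <- round(0.7 * cfg$chip_reads)
    mi <- sample(nrow(marks), n_mark, replace = TRUE,
                 prob = marks$end - marks$start)
    st <- marks$start[mi] +
      vapply(marks$end[mi] - marks$start[mi] - cfg$chip_read_length,
             function(w) sample.int(max(1L, w), 1) - 1L, integer(1))
    ip_mark <- data.frame(read_id = seq_len(n_mark), chrom = marks$chrom[mi],
                          start = st, end = st + cfg$chip_read_length,
                          strand = ".")
    ip_bg <- uniform_reads(cfg$chip_reads - n_mark, cfg$chip_read_length,
                           n_mark + 1L)
    input <- uniform_reads(cfg$chip_reads, cfg$chip_read_length, 1L)
    list(ip = rbind(ip_mark, ip_bg), input = input, marks = marks)
  })

  info <- rbind(
    ds[, c("dataset_id", "library_type", "tissue", "total_mapped_reads")],
    data.frame(dataset_id = c("ribo", "chip_ip", "chip_input"),
               library_type = c("ribosome_profiling", "chip_ip",
                                "chip_input"),
               tissue = c(ds$tissue[which(ds$library_type == "polyA+")[1]],
                          "T1", "T1"),
               total_mapped_reads = c(cfg$ribo_total, cfg$chip_total,
                                      cfg$chip_total)))
  list(reads = reads, ribo_reads = ribo, chip_ip = chip$ip,
       chip_input = chip$input, marks = chip$marks, dataset_info = info)
}

#' Simulate the conservation track and SNP tables
#'
#' The conservation track is baseline noise (mean 0, sd 1) over mappable
#' positions (`NA` elsewhere) with elevated windows (mean
#' `conservation_elevated_mean`, sd 1) over coding exons and a fraction of
#' planted lincRNA exons. Tested SNPs are scattered uniformly with
#' platform labels; the trait-associated flag is planted at
#' `tas_background_rate` genome-wide, multiplied by `tas_enrichment_fold`
#' inside lincRNA exons and `nm_tas_fold` inside coding exons. PET end
#' clusters (two end blocks around the 5' and 3' termini) are emitted for
#' coding genes and half of the planted lincRNAs.
#'
#' @param cfg A [sim_config()].
#' @param genome A [genome_spec()].
#' @param tx Candidate [transcript_set()].
#' @param truth Truth table.
#' @return List: `track` (named list of numeric vectors), `snps`
#'   (SNP table with 0-based `pos`), `pet_clusters`
#'   ([transcript_set()]), `conserved_linc_ids`.
#' @export
simulate_tracks_and_snps <- function(cfg, genome, tx, truth) {
  linc <- tx[truth$category == "true_lincRNA", , drop = FALSE]
  coding <- tx[truth$category == "protein_coding", , drop = FALSE]
  track_and_ids <- with_stream(cfg$seed, "track", {
    track <- lapply(names(genome$seqlengths), function(ch) {
      v <- rnorm(genome$seqlengths[[ch]])
      un <- unmappable_intervals(genome)
      un <- un[un$chrom == ch, , drop = FALSE]
      for (k in seq_len(nrow(un))) v[(un$start[k] + 1L):un$end[k]] <- NA
      v
    })
    names(track) <- names(genome$seqlengths)
    elevate <- function(track, regions) {
      for (k in seq_len(nrow(regions))) {
        idx <- (regions$start[k] + 1L):regions$end[k]
        track[[regions$chrom[k]]][idx] <-
          rnorm(length(idx), cfg$conservation_elevated_mean, 1)
      }
      track
    }
    track <- elevate(track, exon_table(coding))
    n_cons <- round(cfg$conserved_lincRNA_fraction * nrow(linc))
    cons_ids <- if (n_cons > 0) sample(linc$id, n_cons) else character()
    if (length(cons_ids))
      track <- elevate(track, exon_table(
        linc[linc$id %in% cons_ids, , drop = FALSE]))
    list(track = track, conserved_linc_ids = cons_ids)
  })

  snps <- with_stream(cfg$seed, "snps", {
    glens <- genome$seqlengths
    ch <- sample(names(glens), cfg$n_tested_snps, replace = TRUE,
                 prob = as.numeric(glens) / sum(as.numeric(glens)))
    pos <- vapply(ch, function(c1) sample.int(glens[[c1]], 1) - 1L,
                  integer(1))
    platform <- sample(c("illumina", "affymetrix", "both"),
                       cfg$n_tested_snps, replace = TRUE,
                       prob = c(0.45, 0.35, 0.20))
    d <- data.frame(snp_id = sprintf("rs%06d", seq_len(cfg$n_tested_snps)),
                    chrom = ch, pos = pos, platform = platform)
    in_linc <- snps_in_regions(d, linc)
    in_nm <- snps_in_regions(d, coding)
    rate <- rep(cfg$tas_background_rate, nrow(d))
    rate[in_nm] <- cfg$tas_background_rate * cfg$nm_tas_fold
    rate[in_linc] <- cfg$tas_background_rate * cfg$tas_enrichment_fold
    d$trait_associated <- runif(nrow(d)) < rate
    d$common <- runif(nrow(d)) < cfg$common_snp_rate
    d
  })

  pet <- with_stream(cfg$seed, "pet", {
    anchors <- rbind(
      data.frame(chrom = coding$chrom, start = coding$start,
                 end = coding$end, strand = coding$strand),
      {
        sel <- sort(sample(nrow(linc), nrow(linc) %/% 2))
        data.frame(chrom = linc$chrom[sel], start = linc$start[sel],
                   end = linc$end[sel],
                   strand = ifelse(linc$strand[sel] == ".",
                                   sample(c("+", "-"), length(sel),
                                          replace = TRUE),
                                   linc$strand[sel]))
      })
    glens <- genome$seqlengths
    transcript_set(sprintf("pet_%03d", seq_len(nrow(anchors))),
                   anchors$chrom, anchors$strand,
                   lapply(seq_len(nrow(anchors)), function(i) {
                     c(max(0L, anchors$start[i] - 50L),
                       min(glens[[anchors$chrom[i]]] - 100L,
                           anchors$end[i] - 50L))
                   }),
                   lapply(seq_len(nrow(anchors)), function(i) {
                     c(anchors$start[i] + 50L,
                       min(glens[[anchors$chrom[i]]] - 50L,
                           anchors$end[i] + 50L))
                   }),
                   source = "pet")
  })

  list(track = track_and_ids$track,
       conserved_linc_ids = track_and_ids$conserved_linc_ids,
       snps = snps, pet_clusters = pet)
}

#' Run the full synthetic-data generator
#'
#' @param cfg A [sim_config()].
#' @return List bundling everything downstream stages consume: `config`,
#'   `genome`, `genome_seq`, `transcripts`, `truth`, `catalog`, `cds`,
#'   `genes`, `expected_fpkm`, `reads`, `ribo_reads`, `chip_ip`,
#'   `chip_input`, `marks`, `dataset_info`, `sequences`, `track`,
#'   `conserved_linc_ids`, `snps`, `pet_clusters`.
#' @export
simulate_all <- function(cfg = sim_config()) {
  genome <- generate_genome(cfg)
  ann <- generate_annotations_and_transcripts(cfg, genome)
  E <- generate_expression_profiles(cfg, ann$transcripts, ann$truth)
  rd <- simulate_reads(cfg, genome, ann$transcripts, E, ann$cds, ann$genes)
  tk <- simulate_tracks_and_snps(cfg, genome, ann$transcripts, ann$truth)
  c(list(config = cfg, genome = genome,
         sequences = transcript_sequences(ann$transcripts, ann$genome_seq),
         expected_fpkm = E),
    ann, rd, tk)
}
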