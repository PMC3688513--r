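#' Pipeline configuration
#'
#' One declarative object carrying the seed, the simulation settings and
#' every filter threshold, each defaulting to its canonical value. A run
#' is fully reproducible from its config.
#'
#' @param seed Master seed for every source of randomness.
#' @param out_dir Output directory (created if needed).
#' @param sim A [sim_config()]; its seed is overridden by `seed`.
#' @param min_length Minimum mature transcript length (nt).
#' @param proximity_bp Coding-gene proximity threshold (bp, inclusive).
#' @param max_orf_aa Large-ORF amino-acid threshold (strict).
#' @param truncation_nt Truncated-ORF nucleotide threshold (strict).
#' @param fpkm_tiers Strictly increasing expression tiers.
#' @param merge_fraction Exon overlap fraction for merging.
#' @param group_bp Grouping distance (bp, inclusive).
#' @param n_shuffles Shuffled placements per transcript for the
#'   expression-above-background test (kept modest by default so a full
#'   run stays interactive; raise for tighter empirical p resolution).
#' @param alpha Bonferroni-corrected significance level.
#' @param coverage_thresholds Depth thresholds for the coverage curve.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 42L, out_dir = "lincatlas_run",
                            sim = sim_config(seed = seed),
                            min_length = 200L, proximity_bp = 1000L,
                            max_orf_aa = 100L, truncation_nt = 300L,
                            fpkm_tiers = c(1, 10, 30),
                            merge_fraction = 0.5, group_bp = 1000L,
                            n_shuffles = 1000L, alpha = 0.1,
                            coverage_thresholds = c(1L, 2L, 3L, 5L, 10L)) {
  stopifnot(min_length > 0, proximity_bp > 0, max_orf_aa > 0,
            truncation_nt > 0, merge_fraction > 0, merge_fraction <= 1,
            group_bp > 0, n_shuffles >= 1, alpha > 0, alpha <= 1)
  if (length(fpkm_tiers) < 1 || any(diff(fpkm_tiers) <= 0))
    stop("fpkm_tiers must be strictly increasing")
  sim$seed <- seed
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys map to [pipeline_config()] arguments; a `sim` block maps
#' to [sim_config()] arguments.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  y$sim <- NULL
  if (!is.null(y$seed)) sim_args$seed <- y$seed
  do.call(pipeline_config, c(y, list(sim = do.call(sim_config, sim_args))))
}

log_msg <- function(stage, fmt, ...) {
  message(sprintf("[lincatlas:%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full discovery and characterization pipeline
#'
#' Simulate -> coverage quantitation -> full-assignment quantification ->
#' filter cascade -> merge/group/name per expression tier ->
#' expression-above-background testing -> characterization (ribosome
#' engagement, conservation, SNP enrichment, polyA partitioning, ChIP
#' ratios, PET end support, sample clustering). Stage outputs are written
#' under `config$out_dir`; a manifest records the config hash, seed,
#' per-stage counts and package version. Reruns with an identical config
#' produce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every stage result and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  log_msg("simulate", "seed %d: generating synthetic study", config$seed)
  sim <- simulate_all(config$sim)
  tx <- sim$transcripts
  write_bed12(tx, out("candidates.bed"))
  data.table::fwrite(sim$truth, out("truth.tsv"), sep = "\t")
  write_bed(sim$genome$mask, out("mappability_mask.bed"))
  write_snp_table(sim$snps, out("snps.tsv"))
  log_msg("simulate", "%d candidates on %d chromosomes, %d datasets",
          nrow(tx), length(sim$genome$seqlengths), nrow(config$sim$datasets))

  log_msg("coverage", "depth profiles and threshold curves")
  all_reads <- pool_reads(sim$reads)
  prof_ex <- depth_profile(all_reads, sim$genome, "excluding_inferred")
  prof_in <- depth_profile(all_reads, sim$genome, "including_inferred")
  cov <- data.frame(
    threshold = config$coverage_thresholds,
    excluding_inferred = unname(covered_fraction_at_thresholds(
      prof_ex, sim$genome, config$coverage_thresholds)),
    including_inferred = unname(covered_fraction_at_thresholds(
      prof_in, sim$genome, config$coverage_thresholds)))
  data.table::fwrite(cov, out("coverage_thresholds.tsv"), sep = "\t")
  coding_tx <- sim$catalog$protein_coding
  exon_iv <- normalize_intervals(exon_table(coding_tx))
  span_iv <- normalize_intervals(span_table(coding_tx))
  intron_iv <- subtract_intervals(span_iv, exon_iv)
  intergenic_iv <- subtract_intervals(
    data.frame(chrom = names(sim$genome$seqlengths), start = 0L,
               end = unname(sim$genome$seqlengths)), span_iv)
  basecalls <- basecall_depth_distribution(
    prof_ex, list(exon = exon_iv, intron = intron_iv,
                  intergenic = intergenic_iv), sim$genome)
  data.table::fwrite(basecalls, out("basecall_distribution.tsv"), sep = "\t")
  union_cov <- annotation_union_coverage(prof_in, list(span_iv), sim$genome)
  region_dist <- read_region_distribution(sim$reads, coding_tx)
  data.table::fwrite(region_dist, out("read_region_distribution.tsv"),
                     sep = "\t")

  log_msg("quantify", "full-assignment counting, %d transcripts", nrow(tx))
  rna_info <- sim$dataset_info[
    sim$dataset_info$dataset_id %in% names(sim$reads), , drop = FALSE]
  em <- expression_matrix(sim$reads, tx, rna_info)
  write_expression_matrix(em, out("counts.tsv"), out("fpkm.tsv"))

  log_msg("filter", "running the cascade")
  casc <- run_cascade(tx, sim$catalog, sim$sequences, em,
                      min_length = config$min_length,
                      proximity_bp = config$proximity_bp,
                      max_aa = config$max_orf_aa,
                      truncation_nt = config$truncation_nt,
                      tiers = config$fpkm_tiers)
  data.table::fwrite(casc$report, out("filter_report.tsv"), sep = "\t")
  writeLines(casc$large_orf_ids, out("large_orf_transcripts.txt"))
  log_msg("filter", "kept %d of %d (%s)", nrow(casc$kept), nrow(tx),
          paste(sprintf("%s=%d", names(casc$stage_counts),
                        casc$stage_counts), collapse = " "))

  log_msg("merge", "merging, grouping, naming per tier")
  catalogs <- list()
  for (tier in config$fpkm_tiers) {
    ids <- names(casc$tier)[vapply(casc$tier, function(t) {
      t != "fail" && as.numeric(sub("fpkm", "", t)) >= tier
    }, logical(1))]
    tier_tx <- casc$kept[casc$kept$id %in% ids, , drop = FALSE]
    cat_t <- build_tier_catalog(tier_tx, tier,
                                fraction = config$merge_fraction,
                                group_bp = config$group_bp)
    # FPKMs are recalculated on the merged models
    em_t <- expression_matrix(sim$reads, cat_t, rna_info)
    cat_t$max_fpkm <- apply(em_t$fpkm, 1, max)
    catalogs[[paste0("fpkm", tier)]] <- cat_t
    write_bed12(cat_t, out(sprintf("catalog_fpkm%s.bed", format(tier))),
                names = cat_t$name)
  }
  main_cat <- catalogs[[1]]
  log_msg("merge", "tier sizes: %s",
          paste(sprintf("%s=%d", names(catalogs),
                        vapply(catalogs, nrow, integer(1))), collapse = " "))

  log_msg("background", "expression above shuffled intergenic null")
  space <- build_background_space(
    sim$genome,
    list(span_iv, main_cat, sim$catalog$non_lincRNA_other,
         sim$catalog$utr_extensions, sim$catalog$extended_gene_boundaries,
         span_table(tx)))
  signif_tab <- background_significance(
    main_cat, sim$reads, rna_info, space,
    n_shuffles = config$n_shuffles, alpha = config$alpha,
    seed = config$seed)
  data.table::fwrite(signif_tab, out("background_significance.tsv"),
                     sep = "\t")
  log_msg("background", "%d/%d significant at corrected p <= %g",
          sum(signif_tab$significant), nrow(signif_tab), config$alpha)

  log_msg("characterize", "ribosome, conservation, SNPs, polyA, ChIP, PET")
  rna_match <- sim$reads[[
    rna_info$dataset_id[rna_info$library_type == "polyA+"][1]]]
  ribo_ratio <- vapply(seq_len(nrow(main_cat)), function(i) {
    max_window_read_ratio(main_cat[i, , drop = FALSE], sim$ribo_reads,
                          rna_match)
  }, numeric(1))
  nm_ribo <- vapply(seq_len(nrow(coding_tx)), function(i) {
    max_window_read_ratio(coding_tx[i, , drop = FALSE], sim$ribo_reads,
                          rna_match)
  }, numeric(1))
  cons <- vapply(seq_len(nrow(main_cat)), function(i) {
    max_conserved_window(main_cat[i, , drop = FALSE], sim$track)
  }, numeric(1))
  nm_cons <- vapply(seq_len(nrow(coding_tx)), function(i) {
    max_conserved_window(coding_tx[i, , drop = FALSE], sim$track)
  }, numeric(1))
  tas_linc <- tas_enrichment(main_cat, space, sim$snps)
  tas_nm <- tas_enrichment(coding_tx, space, sim$snps)
  snp_density <- list(
    lincRNA = common_snp_density(main_cat, sim$snps),
    coding = common_snp_density(coding_tx, sim$snps),
    background = common_snp_density(space, sim$snps))
  polya_map <- rna_info[rna_info$library_type %in% c("polyA+", "polyA-"),
                        c("dataset_id", "tissue", "library_type")]
  names(polya_map) <- c("dataset_id", "cell_type", "fraction")
  polya <- tryCatch(
    polya_ratio_analysis(em, polya_map,
                         list(lincRNA = main_cat$members_flat %||%
                                unlist(main_cat$members),
                              coding = coding_tx$id)),
    error = function(e) {
      log_msg("characterize", "polyA analysis skipped: %s",
              conditionMessage(e))
      NULL
    })
  chip <- chip_signal_ratio(main_cat, sim$chip_ip, sim$chip_input,
                            config$sim$chip_total, config$sim$chip_total)
  pet <- t(vapply(seq_len(nrow(main_cat)), function(i) {
    unlist(pet_end_support(main_cat[i, , drop = FALSE], sim$pet_clusters))
  }, logical(2)))
  char_tab <- data.frame(
    name = main_cat$name, max_ribo_ratio = ribo_ratio,
    max_conserved_window = cons, chip_ratio = unname(chip),
    five_prime_pet = pet[, 1], three_prime_pet = pet[, 2])
  data.table::fwrite(char_tab, out("characterization.tsv"), sep = "\t")

  log_msg("cluster", "tissue clustering on tier-10 lincRNA expression")
  em10 <- expression_matrix(sim$reads, catalogs[[2]] %||% main_cat, rna_info)
  clust <- tryCatch(cluster_samples(em10$fpkm, min_fpkm = 10),
                    error = function(e) {
                      log_msg("cluster", "skipped: %s", conditionMessage(e))
                      NULL
                    })
  if (!is.null(clust))
    data.table::fwrite(as.data.frame(clust$hclust$merge),
                       out("cluster_merges.tsv"), sep = "\t")

  manifest <- list(
    package_version = as.character(utils::packageVersion("lincatlas")),
    seed = config$seed,
    config_hash = config_hash(config),
    n_candidates = nrow(tx),
    stage_counts = as.list(casc$stage_counts),
    tier_sizes = lapply(catalogs, nrow),
    n_significant = sum(signif_tab$significant),
    covered_fraction_k1 = cov$including_inferred[1],
    union_coverage = union_cov,
    tas_fold_lincRNA = tas_linc$fold,
    tas_fold_coding = tas_nm$fold)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(config = config, sim = sim, coverage = cov,
                 basecalls = basecalls, region_dist = region_dist,
                 union_coverage = union_cov, em = em, cascade = casc,
                 catalogs = catalogs, background = signif_tab,
                 space = space,
                 characterization = char_tab,
                 nm_ribo = nm_ribo, nm_cons = nm_cons,
                 tas = list(lincRNA = tas_linc, coding = tas_nm),
                 snp_density = snp_density, polya = polya,
                 cluster = clust, manifest = manifest))
}

# Stable hash of a pipeline config (written to the manifest). The output
# location is not part of the scientific configuration, so two runs of
# the same study into different directories hash identically.
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  writeLines(yaml::as.yaml(rapply(cfg, identity, how = "replace")), tmp)
  unname(tools::md5sum(tmp))
}
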