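# Orchestration: threshold registry, config validation, end-to-end demo
# runs with reproducible manifests.

#' Analysis threshold registry
#'
#' Every numeric constant used by the pipeline stages, with the field's
#' customary defaults: compartment-switch run length (3 bins), strict TAD
#' overlap (0.7), fusion-site flank (5 Mb), long-range cutoff (5 Mb,
#' strict), interaction thresholds (p, q <= 0.01, >= 10 read-pairs),
#' satellite inclusion total (30 bp, strict), satI-telomere juxtaposition
#' split (500 bp), genotype depth range (15-100), SV validation window
#' (1 kb), density window (500 kb), bin-map minimum match (0.85; 0.7 for
#' more diverged pairs), synteny length cutoffs (8/14/35/55 kb by
#' divergence), log10-length window (0.1), ASE minimum sites (2) and
#' alpha (0.05), and working resolutions (100 kb compartments, 40 kb
#' insulation/TADs, 20 kb interactions).
#'
#' @return Named list of thresholds.
#' @export
karyofuse_thresholds <- function() {
  list(
    switch_min_run = 3,
    tad_overlap = 0.7,
    fusion_flank = 5e6,
    long_range = 5e6,
    interaction_p_max = 0.01,
    interaction_q_max = 0.01,
    interaction_min_reads = 10,
    satellite_min_total = 30,
    juxtaposition = 500,
    dp_min = 15,
    dp_max = 100,
    sv_window = 1000,
    density_window = 5e5,
    binmap_min_match = 0.85,
    binmap_min_match_diverged = 0.7,
    synteny_cutoffs = c(8e3, 1.4e4, 3.5e4, 5.5e4),
    log_length_window = 0.1,
    ase_min_sites = 2,
    ase_alpha = 0.05,
    res_compartments = 1e5,
    res_tads = 4e4,
    res_interactions = 2e4
  )
}

#' Validate and normalize a run configuration
#'
#' Missing keys are filled from [karyofuse_thresholds()] plus the
#' simulation defaults; types and ranges are checked; unknown keys are
#' preserved under `$extras` with a warning.
#'
#' @param config Named list of overrides (may be empty).
#' @return The normalized configuration list.
#' @export
validate_config <- function(config = list()) {
  defaults <- c(karyofuse_thresholds(), list(
    seed = 1,
    n_chrom = 6,
    chrom_length = 3e5,
    hic_depth = 4e5,
    n_reads = 100,
    read_mean_len = 8000,
    read_error_rate = 0,
    n_male_specific = 100,
    male_specific_neoY_fraction = 0.66
  ))
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    warn(paste0("unknown config key(s) kept under $extras: ",
                paste(unknown, collapse = ", ")))
  }
  cfg <- defaults
  for (k in intersect(names(config), names(defaults))) cfg[[k]] <- config[[k]]
  cfg$extras <- config[unknown]

  chk <- function(cond, msg) if (!cond) abort(paste0("config: ", msg))
  chk(cfg$switch_min_run >= 1, "switch_min_run must be >= 1")
  chk(cfg$tad_overlap > 0 && cfg$tad_overlap <= 1,
      "tad_overlap must be in (0, 1]")
  chk(cfg$interaction_p_max > 0 && cfg$interaction_p_max <= 1,
      "interaction_p_max must be in (0, 1]")
  chk(cfg$interaction_q_max > 0 && cfg$interaction_q_max <= 1,
      "interaction_q_max must be in (0, 1]")
  chk(cfg$interaction_min_reads >= 1, "interaction_min_reads must be >= 1")
  chk(cfg$binmap_min_match > 0 && cfg$binmap_min_match <= 1,
      "binmap_min_match must be in (0, 1]")
  chk(cfg$ase_alpha > 0 && cfg$ase_alpha < 1, "ase_alpha must be in (0, 1)")
  chk(cfg$ase_min_sites >= 1, "ase_min_sites must be >= 1")
  chk(cfg$dp_min <= cfg$dp_max, "dp_min must not exceed dp_max")
  chk(all(unlist(cfg[c("fusion_flank", "long_range", "satellite_min_total",
                       "juxtaposition", "sv_window", "density_window",
                       "log_length_window", "res_compartments", "res_tads",
                       "res_interactions", "n_chrom", "chrom_length",
                       "hic_depth")]) > 0),
      "all size/threshold values must be positive")
  chk(cfg$male_specific_neoY_fraction >= 0 &&
        cfg$male_specific_neoY_fraction <= 1,
      "male_specific_neoY_fraction must be in [0, 1]")
  cfg
}

demo_fusion_plan <- function(n_chrom) {
  # chain the first ceiling(n/2)+1 chromosomes by tandem fusions with
  # cycling age classes; remaining chromosomes stay unfused
  k <- max(2, ceiling(n_chrom / 2) + 1)
  tibble(
    centromeric_partner = paste0("anc", 2:k),
    distal_partner = "anc1",
    type = "tandem",
    age_class = paste0("C", ((seq_len(k - 1) - 1) %% 5) + 1)
  )
}

#' Run the full pipeline on simulated data
#'
#' Executes simulate -> fusion detection -> bin map -> Hi-C matrix ->
#' compartments/TADs -> interactions -> read patterns -> neo-Y chain in
#' dependency order at demonstration scale, writes every stage output
#' under `out_dir`, and returns a manifest of file digests. Identical
#' config and seed give identical digests.
#'
#' @param config Configuration overrides, see [validate_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `manifest` (tibble `stage, file, md5`),
#'   `config` and the main in-memory results.
#' @export
run_full <- function(config = list(), out_dir = tempfile("karyofuse_run")) {
  cfg <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed
  paths <- character(0)
  stage <- character(0)
  keep <- function(st, p) {
    paths <<- c(paths, p)
    stage <<- c(stage, st)
    p
  }

  # --- simulate genomes -------------------------------------------------
  anc <- build_ancestral_genome(cfg$n_chrom, cfg$chrom_length, seed = seed)
  fused <- apply_fusion_plan(anc, demo_fusion_plan(cfg$n_chrom),
                             seed = seed + 1)
  write_genome_fasta(fused$genome, keep("simulate", file.path(out_dir, "derived.fa")))
  write_bed(fused$genome$features, keep("simulate", file.path(out_dir, "features.bed")))
  write_bed(
    mutate(fused$truth$sites, start = .data$position,
           end = .data$position + 1, label = .data$type),
    keep("simulate", file.path(out_dir, "fusion_sites.bed"))
  )
  blocks <- truth_synteny_blocks(fused$truth)
  write_blocks_tsv(blocks, keep("simulate", file.path(out_dir, "blocks.tsv")))

  # --- fusion detection -------------------------------------------------
  min_len <- min(cfg$synteny_cutoffs)
  events <- detect_fusion_events(filter_blocks(blocks, min_len)) %>%
    classify_fusion_type(
      centromeres = tibble(chrom = names(anc$seqs), centromeric_end = "left"),
      ancestral_lengths = anc$chrom_lengths
    )
  utils::write.table(events, keep("fusions", file.path(out_dir, "events.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- grids, bin map ---------------------------------------------------
  res <- min(cfg$res_interactions, floor(min(fused$genome$chrom_lengths) / 8))
  grid_d <- bin_grid(fused$genome$chrom_lengths, res, genome = "derived")
  grid_a <- bin_grid(anc$chrom_lengths, res, genome = "ancestral")
  bmap <- build_bin_map(blocks, grid_d, grid_a,
                        min_match = cfg$binmap_min_match)
  write_bin_map_tsv(bmap, keep("binmap", file.path(out_dir, "binmap.tsv")))

  # --- Hi-C: simulate, balance, compartments, TADs ----------------------
  nb <- n_bins(grid_d)
  comp_truth <- tibble(
    bin = grid_d$bin,
    label = if_else(((grid_d$bin - 1) %/% 5) %% 2 == 0, "A", "B")
  )
  tad_truth <- grid_d %>% group_by(.data$chrom) %>%
    summarise(lo = min(.data$bin), hi = max(.data$bin), .groups = "drop") %>%
    purrr::pmap(function(chrom, lo, hi) {
      edges <- unique(c(seq(lo, hi, by = 7), hi + 1))
      tibble(start_bin = utils::head(edges, -1), end_bin = utils::tail(edges, -1) - 1)
    }) %>% bind_rows() %>% filter(.data$end_bin >= .data$start_bin)
  m_raw <- simulate_contact_map(
    grid_d, compartments = comp_truth, tads = tad_truth,
    params = hic_sim_params(compartment_boost = 0.3, tad_boost = 0.5,
                            depth = cfg$hic_depth, seed = seed + 2)
  )
  write_matrix_triples(m_raw, keep("matrix", file.path(out_dir, "raw.matrix")))
  m_norm <- ice_normalize(m_raw)
  covar <- simulate_covariates(grid_d, comp_truth, seed = seed + 3)
  comp <- compute_pc1(observed_expected(m_norm), grid_d) %>%
    orient_and_label(covar)
  write_bedgraph(comp, grid_d, keep("compartments",
                                    file.path(out_dir, "eigen.bedgraph")))
  ins <- insulation_score(m_norm, window = 3)
  tads <- call_tads(ins)
  write_bedgraph(ins, grid_d, keep("tads", file.path(out_dir, "insulation.bedgraph")),
                 value = "insulation")

  # --- interactions -----------------------------------------------------
  calls <- call_significant_interactions(
    m_raw, p_max = cfg$interaction_p_max, q_max = cfg$interaction_q_max,
    min_reads = cfg$interaction_min_reads
  )
  write_calls_bedpe(calls, grid_d, keep("interactions",
                                        file.path(out_dir, "calls.bedpe")))
  spanning <- classify_fusion_spanning(calls, grid_d, fused$truth$sites,
                                       fused$truth$segments)
  grad <- tryCatch(age_gradient(spanning, fused$truth$sites),
                   error = function(e) NULL)

  # --- read patterns ----------------------------------------------------
  reads <- simulate_reads(fused$genome, cfg$n_reads, cfg$read_mean_len,
                          cfg$read_error_rate, seed = seed + 4)
  hits <- scan_reads(reads$reads, fused$genome$monomers)
  patterns <- encode_patterns(hits, reads$reads,
                              min_total = cfg$satellite_min_total)
  census <- pattern_census(patterns)
  utils::write.table(census, keep("readpatterns",
                                  file.path(out_dir, "pattern_census.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- neo-Y chain ------------------------------------------------------
  neoy_chrom <- names(fused$genome$seqs)[1]
  neoy_len <- fused$genome$chrom_lengths[[neoy_chrom]]
  vparams <- variant_sim_params(
    neoy_chrom, 0, floor(neoy_len * 0.15 / 100) * 100,
    n_male_specific = cfg$n_male_specific,
    male_specific_neoY_fraction = cfg$male_specific_neoY_fraction,
    depth_min = cfg$dp_min, depth_max = cfg$dp_max, seed = seed + 5
  )
  vt <- simulate_variant_table(fused$genome$chrom_lengths, vparams)
  write_genotypes_tsv(vt$genotypes, keep("neoy", file.path(out_dir, "genotypes.tsv")))
  ms <- call_male_specific_small_variants(vt$genotypes, cfg$dp_min, cfg$dp_max)
  svs <- validate_male_specific_svs(vt$svs, ms, window = cfg$sv_window)
  enr <- neoy_enrichment(
    ms, tibble(chrom = vparams$neoY_chrom, start = vparams$neoY_start,
               end = vparams$neoY_end),
    sum(fused$genome$chrom_lengths)
  )
  ac <- simulate_allele_counts(20, snps_per_gene = 4, imbalance = 1,
                               depth = 40, seed = seed + 6)
  ase <- allele_specific_expression(ac$counts, min_sites = cfg$ase_min_sites,
                                    alpha = cfg$ase_alpha)
  utils::write.table(ase, keep("neoy", file.path(out_dir, "ase.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- tibble(
    stage = stage, file = basename(paths),
    md5 = unname(tools::md5sum(paths))
  )
  invisible(list(
    manifest = manifest, config = cfg, events = events, bin_map = bmap,
    compartments = comp, tads = tads, calls = calls, spanning = spanning,
    age_gradient = grad, patterns = patterns, male_specific = ms,
    svs = svs, enrichment = enr, ase = ase
  ))
}
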