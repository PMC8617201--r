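#' Hi-C simulation parameters
#'
#' The expected count for an intra-chromosomal bin pair (i, j) at
#' separation d = |i - j| is
#' `c * (d + 1)^(-decay_exponent) * (1 + compartment_boost * same_compartment)
#'  * (1 + tad_boost * same_tad) * (loop_fold if (i,j) is a planted loop)`,
#' with `c` chosen so the expected total equals `depth`; observed counts
#' are Poisson draws.
#'
#' @param decay_exponent Power-law distance-decay exponent (> 0).
#' @param compartment_boost Multiplicative plaid enrichment for same-label
#'   bin pairs (>= 0).
#' @param tad_boost Enrichment for pairs inside the same TAD (>= 0).
#' @param loop_fold Fold enrichment at planted loop anchors (>= 1).
#' @param depth Expected total read-pair count.
#' @param seed Integer seed.
#' @return Named list of parameters.
#' @export
hic_sim_params <- function(decay_exponent = 1, compartment_boost = 0,
                           tad_boost = 0, loop_fold = 1, depth = 1e6,
                           seed = 1) {
  stopifnot(decay_exponent > 0, compartment_boost >= 0, tad_boost >= 0,
            loop_fold >= 1, depth > 0)
  list(
    decay_exponent = decay_exponent, compartment_boost = compartment_boost,
    tad_boost = tad_boost, loop_fold = loop_fold, depth = depth, seed = seed
  )
}

#' Simulate a Hi-C contact matrix with planted structure
#'
#' Draws symmetric integer intra-chromosomal counts under the model in
#' [hic_sim_params()]: power-law distance decay, compartment plaid, TAD
#' blocks and loop-anchor enrichments, Poisson-sampled at the requested
#' depth. Reproducible by seed.
#'
#' @param grid A [bin_grid()] with at least 2 bins per chromosome.
#' @param compartments Optional tibble `bin, label` ("A"/"B") defining the
#'   plaid.
#' @param tads Optional tibble `start_bin, end_bin` (global bin indices,
#'   inclusive) of planted TADs.
#' @param loops Optional tibble `bin_i, bin_j` of planted loop anchors.
#' @param params See [hic_sim_params()].
#' @return A raw `contact_matrix`.
#' @export
simulate_contact_map <- function(grid, compartments = NULL, tads = NULL,
                                 loops = NULL, params = hic_sim_params()) {
  withr::local_seed(params$seed)
  lab <- rep(NA_character_, n_bins(grid))
  if (!is.null(compartments)) lab[compartments$bin] <- compartments$label
  tad_id <- rep(NA_integer_, n_bins(grid))
  if (!is.null(tads)) {
    for (k in seq_len(nrow(tads))) {
      tad_id[tads$start_bin[k]:tads$end_bin[k]] <- k
    }
  }

  per_chrom <- grid %>% group_by(.data$chrom) %>%
    summarise(lo = min(.data$bin), hi = max(.data$bin), .groups = "drop")
  cells <- purrr::pmap(per_chrom, function(chrom, lo, hi) {
    idx <- lo:hi
    cmb <- which(upper.tri(diag(length(idx)), diag = TRUE), arr.ind = TRUE)
    tibble(bin_i = idx[cmb[, 1]], bin_j = idx[cmb[, 2]])
  }) %>% bind_rows()

  d <- cells$bin_j - cells$bin_i
  e <- (d + 1)^(-params$decay_exponent)
  same_comp <- !is.na(lab[cells$bin_i]) & !is.na(lab[cells$bin_j]) &
    lab[cells$bin_i] == lab[cells$bin_j]
  e <- e * (1 + params$compartment_boost * same_comp)
  same_tad <- !is.na(tad_id[cells$bin_i]) & !is.na(tad_id[cells$bin_j]) &
    tad_id[cells$bin_i] == tad_id[cells$bin_j]
  e <- e * (1 + params$tad_boost * same_tad)
  if (!is.null(loops) && nrow(loops) > 0) {
    lp <- paste(pmin(loops$bin_i, loops$bin_j), pmax(loops$bin_i, loops$bin_j))
    is_loop <- paste(cells$bin_i, cells$bin_j) %in% lp
    e <- e * ifelse(is_loop, params$loop_fold, 1)
  }
  e <- e * (params$depth / sum(e))
  counts <- rpois(length(e), e)
  keep <- counts > 0
  new_contact_matrix(
    grid,
    tibble(bin_i = cells$bin_i[keep], bin_j = cells$bin_j[keep],
           count = as.numeric(counts[keep])),
    meta = list(sim_params = params)
  )
}

#' Simulate covariate tracks consistent with planted compartments
#'
#' GC fraction and gene density per bin, higher in A-labelled bins, used to
#' orient the compartment eigenvector the way gene-dense GC-rich chromatin
#' anchors compartment A in real genomes.
#'
#' @param grid A [bin_grid()].
#' @param compartments Tibble `bin, label`.
#' @param seed Integer seed.
#' @param gc_contrast Difference in mean GC between A and B bins.
#' @return Tibble `bin, gc, gene_density`.
#' @export
simulate_covariates <- function(grid, compartments, seed = 1,
                                gc_contrast = 0.04) {
  withr::local_seed(seed)
  lab <- rep(NA_character_, n_bins(grid))
  lab[compartments$bin] <- compartments$label
  isA <- !is.na(lab) & lab == "A"
  tibble(
    bin = grid$bin,
    gc = 0.41 + gc_contrast * isA + stats::rnorm(n_bins(grid), 0, 0.01),
    gene_density = pmax(0, round(5 + 6 * isA + stats::rnorm(n_bins(grid), 0, 2)))
  )
}
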