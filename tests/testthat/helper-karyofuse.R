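library(dplyr)
library(tibble)

# small fused genome shared by several tests: 4 acrocentric ancestors,
# the first three chained by tandem fusions
small_fusion_fixture <- function(n_chrom = 4, chrom_length = 2e5,
                                 n_fused = 3, seed = 1) {
  anc <- build_ancestral_genome(n_chrom, chrom_length, seed = seed)
  plan <- tibble(
    centromeric_partner = paste0("anc", seq(2, n_fused)),
    distal_partner = "anc1",
    type = "tandem",
    age_class = paste0("C", seq_len(n_fused - 1))
  )
  fz <- apply_fusion_plan(anc, plan, seed = seed + 1)
  list(anc = anc, plan = plan, fz = fz,
       blocks = truth_synteny_blocks(fz$truth))
}

# the full study-scale plan: 35 acrocentric ancestors joined by 28 tandem
# and 3 Robertsonian fusions into 4 chromosomes (three pairs of 5-chains
# merged head-to-head, plus two free 5-chains... arranged as 3 Rob-merged
# chain pairs and one plain chain)
plan_28t_3r <- function(chrom_names) {
  grp <- split(chrom_names, rep(1:7, each = 5))
  chains <- bind_rows(lapply(grp, function(ids) {
    tibble(centromeric_partner = ids[-1], distal_partner = ids[1],
           type = "tandem")
  }))
  robs <- tibble(
    centromeric_partner = c(grp[[1]][1], grp[[3]][1], grp[[5]][1]),
    distal_partner = c(grp[[2]][1], grp[[4]][1], grp[[6]][1]),
    type = "robertsonian"
  )
  plan <- bind_rows(chains, robs)
  plan$age_class <- rep(paste0("C", 1:5), length.out = nrow(plan))
  plan
}

# truth feature labels -> pattern classes (internal truncated telomeric
# tracts are telomeric sequence)
truth_pattern_hits <- function(truth) {
  truth %>%
    mutate(cls = ifelse(.data$label == "truncated_telomere", "telomere",
                        .data$label)) %>%
    filter(.data$cls %in% c("satI", "satII", "satIV", "telomere"))
}

# collinear whole-chromosome self-alignment blocks for a genome
self_alignment_blocks <- function(chrom_lengths) {
  tibble(
    ref_chrom = names(chrom_lengths), ref_start = 0,
    ref_end = unname(chrom_lengths),
    qry_chrom = names(chrom_lengths), qry_start = 0,
    qry_end = unname(chrom_lengths), orientation = "+"
  )
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# raw contact matrix from an explicit cell table (via the public pair API)
matrix_from_cells <- function(grid, cells) {
  res <- attr(grid, "resolution")
  pairs <- cells[rep(seq_len(nrow(cells)), cells$count), ]
  tibble(
    chrom_a = grid$chrom[pairs$bin_i],
    pos_a = grid$start[pairs$bin_i] + res / 2,
    chrom_b = grid$chrom[pairs$bin_j],
    pos_b = grid$start[pairs$bin_j] + res / 2
  ) %>% bin_pairs(grid)
}

# brute-force binomial oracle: expected probabilities recomputed per
# distance (explicit summation for the tail), independent of the caller's
# vectorized path
oracle_pvalues <- function(m) {
  grid <- m$grid
  chrom_of <- grid$chrom
  cnt <- dplyr::filter(m$counts, chrom_of[bin_i] == chrom_of[bin_j],
                       bin_i != bin_j)
  N <- sum(cnt$count)
  sizes <- table(grid$chrom)
  vapply(seq_len(nrow(cnt)), function(r) {
    d <- cnt$bin_j[r] - cnt$bin_i[r]
    slots <- sum(pmax(0, as.numeric(sizes) - d))
    obs <- sum(cnt$count[cnt$bin_j - cnt$bin_i == d])
    p <- obs / (slots * N)
    sum(dbinom(cnt$count[r]:N, N, p))
  }, 1)
}

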