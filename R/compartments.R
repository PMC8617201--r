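# A/B compartment calling and cross-genome switch detection.

#' Leading eigenvector of the O/E correlation matrix, per chromosome
#'
#' Principal-component analysis of the whole-chromosome
#' observed/expected matrix: the track is the leading eigenvector of the
#' Pearson correlation matrix of the O/E matrix, computed per chromosome
#' over all interaction information on the whole chromosome (never a
#' restricted submatrix). The sign is arbitrary until oriented with
#' [orient_and_label()].
#'
#' @param oe O/E matrix list from [observed_expected()].
#' @param grid The [bin_grid()] the matrices live on.
#' @return Tibble `bin, chrom, eigen` with `NA` for masked bins and for
#'   chromosomes with a degenerate (constant) matrix.
#' @export
compute_pc1 <- function(oe, grid) {
  out <- purrr::imap(oe, function(M, ch) {
    first <- attr(M, "first_bin")
    nb <- nrow(M)
    ev <- rep(NA_real_, nb)
    good <- which(apply(M, 1, function(r) any(is.finite(r))))
    if (length(good) >= 3) {
      sub <- M[good, good, drop = FALSE]
      sds <- apply(sub, 2, sd, na.rm = TRUE)
      if (any(is.finite(sds) & sds > 0)) {
        suppressWarnings(
          C <- cor(sub, use = "pairwise.complete.obs")
        )
        C[!is.finite(C)] <- 0
        C <- (C + t(C)) / 2
        e <- eigen(C, symmetric = TRUE)
        v <- e$vectors[, 1]
        if (e$values[1] > 0 && sd(v) > 0) ev[good] <- v
      }
    }
    tibble(bin = first + seq_len(nb) - 1L, chrom = ch, eigen = ev)
  })
  bind_rows(out)
}

#' Orient the eigenvector and label A/B compartments
#'
#' Per chromosome, the eigenvector sign is flipped if its correlation with
#' GC content is negative (gene density breaks ties when the GC
#' correlation is zero or undefined), so that positive values mark the
#' gene-dense, GC-rich active A compartment. Bins are then labelled by
#' sign; an eigen value of exactly zero gets `NA`.
#'
#' @param track Eigen track from [compute_pc1()].
#' @param covariates Tibble `bin, gc, gene_density` on the same grid.
#' @return Compartment track: `bin, chrom, eigen, label` with `label` in
#'   `{"A", "B", NA}`.
#' @export
orient_and_label <- function(track, covariates) {
  tr <- left_join(track, covariates, by = "bin")
  out <- tr %>% group_by(.data$chrom) %>%
    dplyr::group_modify(function(df, key) {
      ok <- is.finite(df$eigen)
      flip <- 1
      if (sum(ok) >= 3) {
        r <- suppressWarnings(cor(df$eigen[ok], df$gc[ok]))
        if (!is.finite(r) || r == 0) {
          r <- suppressWarnings(cor(df$eigen[ok], df$gene_density[ok]))
        }
        if (!is.finite(r)) {
          warn(sprintf(
            "chromosome %s: zero-variance covariates, orientation unresolved",
            key$chrom
          ))
          df$eigen <- NA_real_
          r <- 1
        }
        if (r < 0) flip <- -1
      }
      df$eigen <- df$eigen * flip
      df$label <- dplyr::case_when(
        !is.finite(df$eigen) ~ NA_character_,
        df$eigen > 0 ~ "A",
        df$eigen < 0 ~ "B",
        TRUE ~ NA_character_
      )
      df
    }) %>% ungroup() %>%
    select("bin", "chrom", "eigen", "label") %>%
    arrange(.data$bin)
  out
}

#' Detect compartment-switch regions between two genomes
#'
#' A switch region is a run of at least `min_run` consecutive focal bins
#' whose homologous partner bins all carry the opposite A/B label.
#' Unmapped bins and bins without a label break runs; discordant runs
#' shorter than `min_run` are categorised `"other"`. Runs never extend
#' across focal chromosome boundaries.
#'
#' @param focal,other Labelled compartment tracks ([orient_and_label()]).
#' @param map [build_bin_map()] result from the focal to the other genome.
#' @param min_run Minimum run length in bins (default 3).
#' @return List with `regions` (tibble `chrom, start_bin, end_bin,
#'   direction, n_bins`; direction `"A->B"` means focal A, partner B) and
#'   `categories` (tibble `bin, chrom, category` with category in
#'   `{stable_A, stable_B, A->B, B->A, other}`).
#' @export
detect_switch_regions <- function(focal, other, map, min_run = 3) {
  partner <- map_bin(map, focal$bin)
  other_lab <- other$label[match(partner, other$bin)]
  df <- focal %>% mutate(partner_label = other_lab)

  discord <- !is.na(df$label) & !is.na(df$partner_label) &
    df$label != df$partner_label
  concord <- !is.na(df$label) & !is.na(df$partner_label) &
    df$label == df$partner_label

  regions <- list()
  cat <- rep("other", nrow(df))
  cat[concord & df$label == "A"] <- "stable_A"
  cat[concord & df$label == "B"] <- "stable_B"

  for (ch in unique(df$chrom)) {
    sel <- which(df$chrom == ch)
    # runs must also be direction-consistent: label changes break them
    key <- ifelse(discord[sel], df$label[sel], NA)
    for (dirlab in c("A", "B")) {
      runs <- true_runs(!is.na(key) & key == dirlab)
      runs <- filter(runs, .data$length >= min_run)
      if (nrow(runs) > 0) {
        for (r in seq_len(nrow(runs))) {
          idx <- sel[runs$start[r]:runs$end[r]]
          cat[idx] <- if (dirlab == "A") "A->B" else "B->A"
          regions[[length(regions) + 1L]] <- tibble(
            chrom = ch,
            start_bin = df$bin[idx[1]],
            end_bin = df$bin[idx[length(idx)]],
            direction = if (dirlab == "A") "A->B" else "B->A",
            n_bins = length(idx)
          )
        }
      }
    }
  }
  list(
    regions = if (length(regions) == 0) {
      tibble(chrom = character(0), start_bin = integer(0),
             end_bin = integer(0), direction = character(0),
             n_bins = integer(0))
    } else {
      bind_rows(regions)
    },
    categories = tibble(bin = df$bin, chrom = df$chrom, category = cat)
  )
}

#' Per-category bin proportions near versus away from fusion sites
#'
#' Partitions focal bins by distance from the bin midpoint to the nearest
#' fusion site (closed interval: a bin exactly at the flank boundary
#' counts as near) and reports category proportions in each partition.
#' Chromosomes can be excluded (e.g. the X, whose dosage-compensated 3D
#' architecture would distort the comparison).
#'
#' @param categories Category tibble from [detect_switch_regions()].
#' @param grid The focal [bin_grid()].
#' @param fusion_sites Tibble `chrom, position` (bp).
#' @param flank Distance threshold in bp (default 5 Mb).
#' @param exclude_chroms Chromosomes to drop before partitioning.
#' @return Tibble `partition, category, n, proportion`.
#' @export
near_fusion_switch_stats <- function(categories, grid, fusion_sites,
                                     flank = 5e6, exclude_chroms = character(0)) {
  df <- categories %>%
    left_join(select(grid, "bin", "start", "end"), by = "bin") %>%
    filter(!.data$chrom %in% exclude_chroms) %>%
    mutate(mid = (.data$start + .data$end) / 2)
  dist_to_site <- function(chrom, mid) {
    s <- fusion_sites$position[fusion_sites$chrom == chrom]
    if (length(s) == 0) return(Inf)
    min(abs(s - mid))
  }
  df$dist <- purrr::map2_dbl(df$chrom, df$mid, dist_to_site)
  df %>%
    mutate(partition = if_else(.data$dist <= flank, "near", "other_regions")) %>%
    group_by(.data$partition, .data$category) %>%
    summarise(n = n(), .groups = "drop_last") %>%
    mutate(proportion = .data$n / sum(.data$n)) %>%
    ungroup()
}

#' Chi-squared test for a difference in switch proportions
#'
#' Pearson chi-squared on the 2x2 table (switched / not) x (region set 1 /
#' region set 2), without continuity correction.
#'
#' @param k1,n1 Switched bins and total bins in region set 1.
#' @param k2,n2 Same for region set 2.
#' @return Tibble `statistic, df, p_value, prop1, prop2`.
#' @export
#' @examples
#' # the neo-Y contrast: 8.9% of 3,310 bins vs 0.7% of 17,640 bins
#' switch_enrichment_test(295, 3310, 123, 17640)
switch_enrichment_test <- function(k1, n1, k2, n2) {
  stopifnot(n1 > 0, n2 > 0, k1 <= n1, k2 <= n2)
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2)
  exp_min <- min(outer(rowSums(tab), colSums(tab)) / sum(tab))
  if (exp_min < 1) warn("expected cell count below 1; test unreliable")
  if (k1 + k2 == 0 || (n1 - k1) + (n2 - k2) == 0) {
    return(tibble(statistic = 0, df = 1L, p_value = 1,
                  prop1 = k1 / n1, prop2 = k2 / n2))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble(
    statistic = unname(ct$statistic), df = 1L,
    p_value = unname(ct$p.value), prop1 = k1 / n1, prop2 = k2 / n2
  )
}

#' Export a per-bin numeric track as bedGraph
#'
#' @param track Tibble with `bin` and a value column.
#' @param grid The [bin_grid()].
#' @param path Output path.
#' @param value Name of the value column.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, grid, path, value = "eigen") {
  df <- track %>% left_join(select(grid, "bin", "start", "end"), by = "bin")
  v <- df[[value]]
  keep <- is.finite(v)
  utils::write.table(
    data.frame(df$chrom[keep],
               format(df$start[keep], scientific = FALSE, trim = TRUE),
               format(df$end[keep], scientific = FALSE, trim = TRUE),
               v[keep]),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
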