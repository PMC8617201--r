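# Distance-stratified significant intra-chromosomal interaction calling
# and fusion-site-centred interaction analyses.

#' Call significant intra-chromosomal interactions
#'
#' Fit-Hi-C-style caller on raw counts: per-pair contact probabilities are
#' estimated in equal-occupancy distance strata and smoothed to be
#' monotone non-increasing in distance (pool-adjacent-violators); each
#' observed pair then receives a binomial upper-tail p-value for seeing at
#' least its count given the total intra-chromosomal count, with BH
#' correction across all tested pairs of the genome. Calls must satisfy
#' `p <= p_max`, `q <= q_max` and `count >= min_reads` (the default 10
#' reads the "more than nine read-pairs" rule literally; set 9 for the
#' inclusive reading).
#'
#' @param m A raw `contact_matrix` (counts at the calling resolution,
#'   typically 20 kb).
#' @param p_max,q_max Significance thresholds (default 0.01 each).
#' @param min_reads Minimum supporting read-pairs (default 10).
#' @param n_strata Target number of equal-occupancy distance strata.
#' @return Tibble of calls: `chrom, bin_i, bin_j, count, expected, p, q,
#'   length` (bp), plus attribute `n_tested`.
#' @export
call_significant_interactions <- function(m, p_max = 0.01, q_max = 0.01,
                                          min_reads = 10, n_strata = 50) {
  grid <- m$grid
  res <- grid_resolution(grid)
  chrom_of <- grid$chrom
  cnt <- m$counts %>%
    filter(chrom_of[.data$bin_i] == chrom_of[.data$bin_j],
           .data$bin_i != .data$bin_j)
  if (nrow(cnt) == 0) abort("no intra-chromosomal off-diagonal counts")
  N <- sum(cnt$count)

  # pair slots per distance over all chromosomes (zeros included)
  sizes <- grid %>% count(.data$chrom, name = "nb")
  dmax <- max(sizes$nb) - 1L
  slots <- vapply(seq_len(dmax), function(d) sum(pmax(0L, sizes$nb - d)), 1)
  obs <- numeric(dmax)
  dpair <- cnt$bin_j - cnt$bin_i
  agg <- tapply(cnt$count, dpair, sum)
  obs[as.integer(names(agg))] <- agg
  present <- which(slots > 0)
  if (length(present) < 2) abort("fewer than 2 distance strata")

  # equal-occupancy strata: consecutive distances grouped so each stratum
  # holds roughly equal total observed counts
  target <- max(1, sum(obs) / n_strata)
  stratum <- integer(dmax)
  acc <- 0
  s <- 1L
  for (d in present) {
    stratum[d] <- s
    acc <- acc + obs[d]
    if (acc >= target) {
      s <- s + 1L
      acc <- 0
    }
  }
  st <- tibble(d = present, stratum = stratum[present],
               obs = obs[present], slots = slots[present]) %>%
    group_by(.data$stratum) %>%
    summarise(d_lo = min(.data$d), obs = sum(.data$obs),
              slots = sum(.data$slots), .groups = "drop") %>%
    arrange(.data$d_lo) %>%
    mutate(prob = .data$obs / (.data$slots * N))
  st$prob <- pava_nonincreasing(st$prob, st$slots)
  prob_of_d <- numeric(dmax)
  prob_of_d[present] <- st$prob[stratum[present]]

  p_pair <- prob_of_d[dpair]
  pval <- pbinom(cnt$count - 1, N, p_pair, lower.tail = FALSE)
  qval <- p.adjust(pval, method = "BH")
  out <- cnt %>%
    mutate(
      chrom = chrom_of[.data$bin_i],
      expected = N * p_pair,
      p = pval, q = qval,
      length = (.data$bin_j - .data$bin_i) * res
    ) %>%
    filter(.data$p <= p_max, .data$q <= q_max, .data$count >= min_reads) %>%
    select("chrom", "bin_i", "bin_j", "count", "expected", "p", "q",
           "length") %>%
    arrange(.data$chrom, .data$bin_i, .data$bin_j)
  attr(out, "n_tested") <- nrow(cnt)
  attr(out, "resolution") <- res
  out
}

#' Normalized interaction-length profile
#'
#' Counts of intra-chromosomal calls in sliding log10(length) windows of
#' width `window`, min-max normalized to `[0, 1]` — invariant under
#' duplicating every call.
#'
#' @param calls Call tibble from [call_significant_interactions()].
#' @param window log10 window width (default 0.1).
#' @return Tibble `window_lo, window_hi, n, normalized`.
#' @export
normalized_length_profile <- function(calls, window = 0.1) {
  if (nrow(calls) == 0) abort("no interaction calls")
  lg <- log10(calls$length)
  lo <- floor(min(lg) / window) * window
  hi <- ceiling((max(lg) + 1e-9) / window) * window
  edges <- seq(lo, hi, by = window)
  idx <- pmin(findInterval(lg, edges), length(edges) - 1)
  n <- tabulate(idx, nbins = length(edges) - 1)
  rng <- range(n)
  normalized <- if (rng[2] > rng[1]) (n - rng[1]) / (rng[2] - rng[1]) else
    rep(1, length(n))
  tibble(
    window_lo = edges[-length(edges)], window_hi = edges[-1],
    n = n, normalized = normalized
  )
}

#' Classify long-range calls by end compartments
#'
#' Calls strictly longer than `min_length` are grouped by the compartment
#' labels of their two anchor bins: `A-A`, `B-B`, `A-B`, or `others` when
#' at least one end has no explicit compartment label.
#'
#' @param calls Call tibble.
#' @param compartments Labelled compartment track on the same grid.
#' @param min_length Length threshold in bp (default 5 Mb, strict).
#' @return Tibble `class, n, proportion` over the four classes.
#' @export
classify_long_range <- function(calls, compartments, min_length = 5e6) {
  lr <- filter(calls, .data$length > min_length)
  la <- compartments$label[match(lr$bin_i, compartments$bin)]
  lb <- compartments$label[match(lr$bin_j, compartments$bin)]
  cls <- dplyr::case_when(
    is.na(la) | is.na(lb) ~ "others",
    la == "A" & lb == "A" ~ "A-A",
    la == "B" & lb == "B" ~ "B-B",
    TRUE ~ "A-B"
  )
  tibble(class = factor(cls, levels = c("A-A", "B-B", "A-B", "others"))) %>%
    count(.data$class, .drop = FALSE, name = "n") %>%
    mutate(proportion = if (sum(.data$n) > 0) .data$n / sum(.data$n) else 0)
}

#' Partition focal calls into shared and specific
#'
#' A focal call is shared when some other-genome call, carried across the
#' homologous bin map, lands with both anchors within `slack` bins of the
#' focal anchors (the "adjacent one upstream or downstream bin"
#' tolerance); otherwise it is specific (newly established in the focal
#' genome).
#'
#' @param calls_focal Focal call tibble.
#' @param calls_other Other-genome call tibble.
#' @param map Bin map from the OTHER genome to the focal grid.
#' @param slack Anchor tolerance in bins (default 1).
#' @return `calls_focal` with a logical `shared` column.
#' @export
map_interactions <- function(calls_focal, calls_other, map, slack = 1) {
  oi <- map_bin(map, calls_other$bin_i)
  oj <- map_bin(map, calls_other$bin_j)
  ok <- !is.na(oi) & !is.na(oj)
  mi <- pmin(oi[ok], oj[ok])
  mj <- pmax(oi[ok], oj[ok])
  shared <- vapply(seq_len(nrow(calls_focal)), function(r) {
    any(abs(mi - calls_focal$bin_i[r]) <= slack &
          abs(mj - calls_focal$bin_j[r]) <= slack)
  }, TRUE)
  mutate(calls_focal, shared = shared)
}

#' Classify calls by the fusion sites they span
#'
#' Counts the fusion sites strictly between a call's two anchors (bin
#' midpoints, same chromosome); calls spanning exactly one site record
#' that site's flanking ancestral chromosomes and age class — the basis
#' of the ancestral-pair contact matrix and the fusion-age gradient.
#'
#' @param calls Call tibble.
#' @param grid The [bin_grid()].
#' @param fusion_sites Tibble `chrom, position, age_class, ...` (e.g.
#'   `truth$sites` or typed events).
#' @param segments Ancestral-segment layout (`chrom, start, end,
#'   ancestral`), used to name the flanking ancestral chromosomes.
#' @return `calls` plus `n_sites_spanned`, `anc_up`, `anc_down`,
#'   `age_class` (the latter three `NA` unless exactly one site spanned).
#' @export
classify_fusion_spanning <- function(calls, grid, fusion_sites, segments) {
  mid <- (grid$start + grid$end) / 2
  pos_i <- mid[calls$bin_i]
  pos_j <- mid[calls$bin_j]
  seg_of <- function(chrom, pos) {
    hit <- segments$ancestral[segments$chrom == chrom &
                                segments$start <= pos & segments$end > pos]
    if (length(hit) == 0) NA_character_ else hit[1]
  }
  res <- purrr::pmap(
    list(calls$chrom, pmin(pos_i, pos_j), pmax(pos_i, pos_j)),
    function(ch, a, b) {
      if (is.na(seg_of(ch, a)) || is.na(seg_of(ch, b))) {
        abort("interaction anchor outside any ancestral segment")
      }
      s <- fusion_sites %>% filter(.data$chrom == ch,
                                   .data$position > a, .data$position < b)
      if (nrow(s) == 1) {
        tibble(n_sites_spanned = 1L,
               anc_up = seg_of(ch, s$position - 1),
               anc_down = seg_of(ch, s$position + 1),
               age_class = s$age_class %||% NA_character_)
      } else {
        tibble(n_sites_spanned = nrow(s), anc_up = NA_character_,
               anc_down = NA_character_, age_class = NA_character_)
      }
    }
  ) %>% bind_rows()
  bind_cols(calls, res)
}

#' Count matrix of single-site spanning calls by ancestral pair
#'
#' @param spanning Output of [classify_fusion_spanning()].
#' @return Tibble `anc_up, anc_down, n` for calls with
#'   `n_sites_spanned == 1`.
#' @export
ancestral_pair_counts <- function(spanning) {
  spanning %>% filter(.data$n_sites_spanned == 1L) %>%
    count(.data$anc_up, .data$anc_down, name = "n")
}

#' Fusion-age gradient of spanning interactions
#'
#' Mean number of single-site spanning calls per fusion site within each
#' age class, and the Pearson correlation of the class age rank (C1 = 1,
#' youngest, through C5 = 5, oldest) with those means: a positive r means
#' interactions across older fusion sites are more numerous.
#'
#' @param spanning Output of [classify_fusion_spanning()].
#' @param fusion_sites Site tibble with `age_class` (defines how many
#'   sites each class holds).
#' @return List with `per_class` (tibble `age_class, n_sites, n_calls,
#'   mean_calls`) and `pearson_r` (`NA` when the means have zero
#'   variance).
#' @export
age_gradient <- function(spanning, fusion_sites) {
  sites <- fusion_sites %>% filter(!is.na(.data$age_class)) %>%
    count(.data$age_class, name = "n_sites")
  if (nrow(sites) < 2) abort("need sites in at least 2 age classes")
  calls <- spanning %>% filter(.data$n_sites_spanned == 1L,
                               !is.na(.data$age_class)) %>%
    count(.data$age_class, name = "n_calls")
  per <- sites %>% left_join(calls, by = "age_class") %>%
    mutate(
      n_calls = tidyr::replace_na(.data$n_calls, 0L),
      mean_calls = .data$n_calls / .data$n_sites,
      rank = as.integer(sub("^C", "", .data$age_class))
    ) %>% arrange(.data$rank)
  r <- if (sd(per$mean_calls) == 0 || sd(per$rank) == 0) NA_real_ else
    cor(per$rank, per$mean_calls)
  list(per_class = select(per, -"rank"), pearson_r = r)
}

#' Transform a contact matrix onto another genome's coordinates
#'
#' Re-addresses every cell through the bin map; cells with an unmapped
#' anchor are dropped, and collisions are summed. Used to build combined
#' focal/other heatmaps around fusion sites.
#'
#' @param m A `contact_matrix` on the map's source grid.
#' @param map Bin map from the matrix's genome to the focal genome.
#' @return A `contact_matrix` on the map's target grid.
#' @export
transform_matrix <- function(m, map) {
  ti <- map_bin(map, m$counts$bin_i)
  tj <- map_bin(map, m$counts$bin_j)
  ok <- !is.na(ti) & !is.na(tj)
  counts <- tibble(
    bin_i = pmin(ti[ok], tj[ok]), bin_j = pmax(ti[ok], tj[ok]),
    count = m$counts$count[ok]
  ) %>%
    group_by(.data$bin_i, .data$bin_j) %>%
    summarise(count = sum(.data$count), .groups = "drop")
  new_contact_matrix(attr(map, "target_grid"), counts,
                     normalized = m$normalized,
                     meta = c(m$meta, list(transformed = TRUE)))
}

#' Export interaction calls as BEDPE
#'
#' @param calls Call tibble.
#' @param grid The [bin_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_bedpe <- function(calls, grid, path) {
  gi <- grid[match(calls$bin_i, grid$bin), ]
  gj <- grid[match(calls$bin_j, grid$bin), ]
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  utils::write.table(
    data.frame(gi$chrom, fmt(gi$start), fmt(gi$end),
               gj$chrom, fmt(gj$start), fmt(gj$end),
               calls$count, calls$expected, calls$p, calls$q),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
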