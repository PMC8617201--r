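# Insulation-score TAD detection and cross-genome conservation.

#' Insulation score along the matrix diagonal
#'
#' For each bin b, the mean contact value inside the `window` x `window`
#' square spanning the bins immediately upstream and downstream of b
#' (rows b-window..b-1, columns b+1..b+window), log2-ratioed to the
#' chromosome mean. `NA` where the window does not fit (the first and last
#' `window` bins of each chromosome) and on masked bins.
#'
#' @param m A normalized `contact_matrix`.
#' @param window Window half-size in bins (>= 1; default 10, i.e. 400 kb
#'   at 40 kb resolution).
#' @return Insulation track: tibble `bin, chrom, insulation`.
#' @export
insulation_score <- function(m, window = 10) {
  stopifnot(window >= 1)
  out <- purrr::map(unique(m$grid$chrom), function(ch) {
    M <- cm_dense_chrom(m, ch)
    first <- attr(M, "first_bin")
    nb <- nrow(M)
    raw <- rep(NA_real_, nb)
    if (nb >= 2 * window + 1) {
      for (b in (window + 1):(nb - window)) {
        sq <- M[(b - window):(b - 1), (b + 1):(b + window), drop = FALSE]
        v <- mean(sq, na.rm = TRUE)
        raw[b] <- if (is.finite(v)) v else NA_real_
      }
    }
    mu <- mean(raw[raw > 0], na.rm = TRUE)
    ins <- ifelse(is.finite(raw) & raw > 0 & is.finite(mu) & mu > 0,
                  log2(raw / mu), NA_real_)
    ins[is.finite(raw) & raw == 0] <- NA_real_
    tibble(bin = first + seq_len(nb) - 1L, chrom = ch, insulation = ins)
  })
  bind_rows(out)
}

# prominence of a local minimum at index i: the smaller of the maxima
# encountered scanning left and right until a value lower than v[i] (or
# the track end) is reached, minus v[i].
min_prominence <- function(v, i) {
  n <- length(v)
  side_max <- function(step) {
    m <- -Inf
    j <- i + step
    while (j >= 1 && j <= n && !is.na(v[j]) && v[j] >= v[i]) {
      m <- max(m, v[j])
      j <- j + step
    }
    if (is.finite(m)) m else NA_real_
  }
  lm <- side_max(-1L)
  rm <- side_max(1L)
  if (is.na(lm) || is.na(rm)) return(NA_real_)
  min(lm, rm) - v[i]
}

#' Call TADs from insulation-score minima
#'
#' Boundaries are local insulation minima with prominence at least
#' `delta` (ties between adjacent equal minima resolve to the leftmost);
#' TADs are the intervals between consecutive boundaries (and chromosome
#' ends), retained when at least `min_size` bins long. A flat track yields
#' one TAD per chromosome.
#'
#' @param track Insulation track from [insulation_score()].
#' @param delta Minimum boundary prominence (log2 units).
#' @param min_size Minimum TAD size in bins.
#' @return TAD set: tibble `chrom, start_bin, end_bin, n_bins` (global bin
#'   indices, inclusive).
#' @export
call_tads <- function(track, delta = 0.1, min_size = 3) {
  out <- purrr::map(unique(track$chrom), function(ch) {
    df <- filter(track, .data$chrom == ch) %>% arrange(.data$bin)
    v <- df$insulation
    n <- length(v)
    is_min <- rep(FALSE, n)
    for (i in seq_len(n)) {
      if (is.na(v[i])) next
      lft <- if (i > 1) v[i - 1] else NA
      rgt <- if (i < n) v[i + 1] else NA
      if (!is.na(lft) && !is.na(rgt) && v[i] < lft && v[i] <= rgt) {
        prom <- min_prominence(v, i)
        if (!is.na(prom) && prom >= delta) is_min[i] <- TRUE
      }
    }
    bnd <- which(is_min)
    # a boundary bin starts the next TAD, keeping TADs non-overlapping
    starts <- c(1L, bnd)
    ends <- c(bnd - 1L, n)
    tads <- tibble(
      chrom = ch,
      start_bin = df$bin[starts],
      end_bin = df$bin[ends]
    ) %>% mutate(n_bins = .data$end_bin - .data$start_bin + 1L)
    filter(tads, .data$n_bins >= min_size)
  })
  bind_rows(out)
}

#' Boundary bins of a TAD set
#'
#' Interior boundaries only (shared edges between adjacent TADs).
#'
#' @param tads A TAD set from [call_tads()].
#' @return Integer vector of boundary bins.
#' @export
tad_boundaries <- function(tads) {
  tads %>% group_by(.data$chrom) %>%
    filter(.data$start_bin > min(.data$start_bin)) %>%
    pull(.data$start_bin)
}

#' Cross-genome TAD conservation
#'
#' A focal TAD is conserved with an other-genome TAD when their mapped
#' overlap covers strictly more than `min_overlap` of BOTH lengths, with
#' missing (unmapped) bins excluded from both denominators: the focal
#' denominator counts focal TAD bins that have a homologous bin at all,
#' the partner denominator counts partner TAD bins present in the map's
#' image. The verdict is symmetric by construction.
#'
#' @param tads_focal,tads_other TAD sets from [call_tads()].
#' @param map [build_bin_map()] from the focal to the other genome.
#' @param min_overlap Strict overlap threshold (default 0.7).
#' @return `tads_focal` with columns `conserved`, `partner` (row index
#'   into `tads_other` or `NA`), `ov_focal`, `ov_other`; the fraction of
#'   conserved focal TADs is attached as attribute `prop_conserved`.
#' @export
compare_tads <- function(tads_focal, tads_other, map, min_overlap = 0.7) {
  tgt_in_map <- unique(map$tgt_bin)
  res <- purrr::pmap(tads_focal, function(chrom, start_bin, end_bin, ...) {
    fb <- start_bin:end_bin
    tg <- map_bin(map, fb)
    mapped <- !is.na(tg)
    deno_f <- sum(mapped)
    best <- tibble(conserved = FALSE, partner = NA_integer_,
                   ov_focal = 0, ov_other = 0)
    if (deno_f == 0) return(best)
    for (r in seq_len(nrow(tads_other))) {
      ob <- tads_other$start_bin[r]:tads_other$end_bin[r]
      ov <- sum(tg[mapped] %in% ob)
      deno_o <- sum(ob %in% tgt_in_map)
      if (deno_o == 0) next
      fo <- ov / deno_f
      oo <- ov / deno_o
      if (fo > min_overlap && oo > min_overlap) {
        return(tibble(conserved = TRUE, partner = r, ov_focal = fo,
                      ov_other = oo))
      }
      if (fo > best$ov_focal) {
        best <- tibble(conserved = FALSE, partner = r, ov_focal = fo,
                       ov_other = oo)
      }
    }
    best
  }) %>% bind_rows()
  out <- bind_cols(tads_focal, res)
  attr(out, "prop_conserved") <-
    if (nrow(out) > 0) mean(out$conserved) else NA_real_
  out
}

#' Genome-specific TADs
#'
#' Focal TADs conserved with every genome in `confirm` and with none in
#' `absent` — e.g. TADs shared between the sexes of the focal species but
#' missing from outgroup genomes.
#'
#' @param tads_focal Focal TAD set.
#' @param confirm,absent Lists of TAD sets.
#' @param confirm_maps,absent_maps Matching lists of bin maps (focal ->
#'   each genome).
#' @param min_overlap Passed to [compare_tads()].
#' @return The subset of `tads_focal` that is specific.
#' @export
find_specific_tads <- function(tads_focal, confirm = list(), absent = list(),
                               confirm_maps = list(), absent_maps = list(),
                               min_overlap = 0.7) {
  keep <- rep(TRUE, nrow(tads_focal))
  for (k in seq_along(confirm)) {
    cc <- compare_tads(tads_focal, confirm[[k]], confirm_maps[[k]], min_overlap)
    keep <- keep & cc$conserved
  }
  for (k in seq_along(absent)) {
    aa <- compare_tads(tads_focal, absent[[k]], absent_maps[[k]], min_overlap)
    keep <- keep & !aa$conserved
  }
  tads_focal[keep, , drop = FALSE]
}

#' Distance from specific-TAD bins to the nearest fusion site
#'
#' @param specific TAD set (e.g. from [find_specific_tads()]).
#' @param grid The [bin_grid()].
#' @param fusion_sites Tibble `chrom, position` (bp); must be non-empty.
#' @return Tibble `bin, chrom, distance` (bp from bin midpoint to the
#'   nearest fusion site on the same chromosome; `Inf` if the chromosome
#'   has no site).
#' @export
specific_tad_fusion_distance <- function(specific, grid, fusion_sites) {
  if (nrow(fusion_sites) == 0) abort("no fusion sites supplied")
  bins <- purrr::pmap(specific, function(chrom, start_bin, end_bin, ...) {
    tibble(chrom = chrom, bin = start_bin:end_bin)
  }) %>% bind_rows()
  df <- bins %>%
    left_join(select(grid, "bin", "start", "end"), by = "bin") %>%
    mutate(mid = (.data$start + .data$end) / 2)
  df$distance <- purrr::map2_dbl(df$chrom, df$mid, function(ch, mid) {
    s <- fusion_sites$position[fusion_sites$chrom == ch]
    if (length(s) == 0) return(Inf)
    min(abs(s - mid))
  })
  select(df, "bin", "chrom", "distance")
}
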