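# Homologous-bin correspondence between two genomes.

#' Construct a bin map from explicit entries
#'
#' Low-level constructor used when a correspondence is known a priori
#' (identity maps, deserialized maps, tests): entries are taken as given.
#' [build_bin_map()] is the standard way to derive a map from alignments.
#'
#' @param entries Tibble `src_bin, tgt_bin, match_fraction` (at most one
#'   target per source bin).
#' @param source_grid,target_grid [bin_grid()]s of the two genomes.
#' @param min_match The threshold the entries satisfy (metadata).
#' @return A `bin_map`.
#' @export
bin_map <- function(entries, source_grid, target_grid, min_match = NA_real_) {
  entries <- as_tibble(entries)
  if (!"match_fraction" %in% names(entries)) entries$match_fraction <- 1
  stopifnot(!anyDuplicated(entries$src_bin))
  attr(entries, "source_grid") <- source_grid
  attr(entries, "target_grid") <- target_grid
  attr(entries, "min_match") <- min_match
  class(entries) <- c("bin_map", class(entries))
  entries
}

#' Identity bin map of a grid onto itself
#'
#' @param grid A [bin_grid()].
#' @return A `bin_map` mapping every bin to itself.
#' @export
identity_bin_map <- function(grid) {
  bin_map(tibble(src_bin = grid$bin, tgt_bin = grid$bin,
                 match_fraction = 1), grid, grid, 1)
}

#' Build a homologous bin map from alignment blocks
#'
#' Projects every source-genome bin base-by-base through the alignment
#' blocks (reference side = source, query side = target;
#' orientation-aware, so inversions project with decreasing offsets) and
#' maps the bin to the target bin receiving the plurality of its bases,
#' provided at least `min_match` of the bin's length lands inside that
#' bin's +-1-bin neighbourhood on a single target chromosome; otherwise
#' the bin is unmapped. Where blocks overlap contradictorily on the
#' reference side, the longer block wins (logged).
#'
#' @param alignments Synteny/alignment blocks (`ref_chrom, ref_start,
#'   ref_end, qry_chrom, qry_start, qry_end, orientation`), reference side
#'   in source-genome coordinates. Ref and qry spans of a block must have
#'   equal length.
#' @param source_grid,target_grid [bin_grid()]s of the two genomes.
#' @param min_match Minimum matched fraction of the source bin in `(0, 1]`.
#' @return A `bin_map`: tibble `src_bin, tgt_bin, match_fraction` with the
#'   two grids and `min_match` stored as attributes.
#' @export
build_bin_map <- function(alignments, source_grid, target_grid,
                          min_match = 0.85) {
  stopifnot(min_match > 0, min_match <= 1)
  res_t <- grid_resolution(target_grid)

  # resolve contradictory overlaps: longer blocks claim reference space
  # first, later (shorter) blocks keep only the uncovered remainder
  pieces <- list()
  n_clipped <- 0L
  for (ch in unique(alignments$ref_chrom)) {
    bl <- alignments %>% filter(.data$ref_chrom == ch) %>%
      arrange(dplyr::desc(.data$ref_end - .data$ref_start))
    covered <- IRanges::IRanges()
    for (r in seq_len(nrow(bl))) {
      want <- IRanges::IRanges(bl$ref_start[r] + 1, bl$ref_end[r])
      avail <- IRanges::setdiff(want, covered)
      if (sum(IRanges::width(avail)) < IRanges::width(want)) {
        n_clipped <- n_clipped + 1L
      }
      covered <- IRanges::union(covered, want)
      if (length(avail) == 0) next
      for (k in seq_along(avail)) {
        a <- IRanges::start(avail)[k] - 1 # back to 0-based
        b <- IRanges::end(avail)[k]
        off0 <- a - bl$ref_start[r]
        off1 <- b - bl$ref_start[r]
        if (bl$orientation[r] == "+") {
          qa <- bl$qry_start[r] + off0
          qb <- bl$qry_start[r] + off1
        } else {
          qa <- bl$qry_end[r] - off1
          qb <- bl$qry_end[r] - off0
        }
        pieces[[length(pieces) + 1L]] <- tibble(
          ref_chrom = ch, a = a, b = b, qry_chrom = bl$qry_chrom[r],
          qa = qa, qb = qb, ori = bl$orientation[r]
        )
      }
    }
  }
  if (n_clipped > 0) {
    inform(sprintf("build_bin_map: clipped %d overlapping block(s)", n_clipped))
  }
  pieces <- bind_rows(pieces)

  grid_cuts <- function(a, b, res) {
    s0 <- ceiling(a / res) * res
    inner <- if (s0 > b) numeric(0) else seq(s0, b, by = res)
    sort(unique(c(a, inner, b)))
  }

  # accumulate projected bases per (source bin, target bin)
  acc <- list()
  if (nrow(pieces) > 0) {
    res_s <- grid_resolution(source_grid)
    for (r in seq_len(nrow(pieces))) {
      p <- pieces[r, ]
      cuts <- grid_cuts(p$a, p$b, res_s)
      for (k in seq_len(length(cuts) - 1)) {
        c0 <- cuts[k]
        c1 <- cuts[k + 1]
        if (c1 <= c0) next
        sb <- locate_bins(source_grid, p$ref_chrom, c0)
        if (p$ori == "+") {
          p0 <- p$qa + (c0 - p$a)
          p1 <- p$qa + (c1 - p$a)
        } else {
          p0 <- p$qb - (c1 - p$a)
          p1 <- p$qb - (c0 - p$a)
        }
        tcuts <- grid_cuts(p0, p1, res_t)
        for (m in seq_len(length(tcuts) - 1)) {
          t0 <- tcuts[m]
          t1 <- tcuts[m + 1]
          if (t1 <= t0) next
          tb <- locate_bins(target_grid, p$qry_chrom, t0)
          if (is.na(sb) || is.na(tb)) next
          acc[[length(acc) + 1L]] <- tibble(src_bin = sb, tgt_bin = tb,
                                            bases = t1 - t0)
        }
      }
    }
  }

  entries <- if (length(acc) == 0) {
    tibble(src_bin = integer(0), tgt_bin = integer(0),
           match_fraction = numeric(0))
  } else {
    bases <- bind_rows(acc) %>%
      group_by(.data$src_bin, .data$tgt_bin) %>%
      summarise(bases = sum(.data$bases), .groups = "drop")
    widths <- source_grid$end - source_grid$start
    tchrom <- target_grid$chrom
    bases %>%
      group_by(.data$src_bin) %>%
      dplyr::group_modify(function(df, key) {
        win <- df$tgt_bin[which.max(df$bases)]
        neigh <- df %>% filter(abs(.data$tgt_bin - win) <= 1,
                               tchrom[.data$tgt_bin] == tchrom[win])
        tibble(tgt_bin = win, matched = sum(neigh$bases))
      }) %>%
      ungroup() %>%
      mutate(match_fraction = .data$matched / widths[.data$src_bin]) %>%
      filter(.data$match_fraction >= min_match) %>%
      select("src_bin", "tgt_bin", "match_fraction")
  }
  attr(entries, "source_grid") <- source_grid
  attr(entries, "target_grid") <- target_grid
  attr(entries, "min_match") <- min_match
  class(entries) <- c("bin_map", class(entries))
  entries
}

#' Look up the target bin of one or more source bins
#'
#' @param map A `bin_map`.
#' @param bins Source bin indices.
#' @return Integer vector of target bins, `NA` where unmapped.
#' @export
map_bin <- function(map, bins) {
  sg <- attr(map, "source_grid")
  if (any(bins < 1 | bins > n_bins(sg))) {
    abort("bin index outside the source grid")
  }
  map$tgt_bin[match(bins, map$src_bin)]
}

#' Fraction of source bins with a homologous target bin
#'
#' @param map A `bin_map`.
#' @return Mapped fraction in `[0, 1]`.
#' @export
mapped_fraction <- function(map) {
  nrow(map) / n_bins(attr(map, "source_grid"))
}

#' Swap the two sides of an alignment-block table
#'
#' @param blocks Block tibble.
#' @return Blocks with ref and qry sides exchanged.
#' @export
invert_blocks <- function(blocks) {
  tibble(
    ref_chrom = blocks$qry_chrom, ref_start = blocks$qry_start,
    ref_end = blocks$qry_end, qry_chrom = blocks$ref_chrom,
    qry_start = blocks$ref_start, qry_end = blocks$ref_end,
    orientation = blocks$orientation
  )
}

#' Serialize / load a bin map as TSV
#'
#' Columns: `src_chrom src_bin tgt_chrom tgt_bin match_fraction`.
#'
#' @param map A `bin_map`.
#' @param path File path.
#' @return `path` invisibly (writer); for the reader, the entry tibble
#'   (grids must be re-attached by the caller via `attr<-` if bin-level
#'   lookups are needed).
#' @export
write_bin_map_tsv <- function(map, path) {
  sg <- attr(map, "source_grid")
  tg <- attr(map, "target_grid")
  out <- data.frame(
    src_chrom = sg$chrom[map$src_bin], src_bin = map$src_bin,
    tgt_chrom = tg$chrom[map$tgt_bin], tgt_bin = map$tgt_bin,
    match_fraction = map$match_fraction
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read alignment blocks from a UCSC chain file
#'
#' Optional interoperability path; requires the `rtracklayer` package.
#' Gapless chain blocks are projected onto the seven-column block schema
#' used everywhere else in the package.
#'
#' @param path Chain file path.
#' @return Block tibble (`ref_chrom, ref_start, ref_end, qry_chrom,
#'   qry_start, qry_end, orientation`).
#' @export
read_chain_blocks <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("read_chain_blocks() requires the rtracklayer package")
  }
  ch <- rtracklayer::import.chain(path)
  out <- list()
  for (ref_chrom in names(ch)) {
    cb <- ch[[ref_chrom]]
    rng <- methods::slot(cb, "ranges")
    off <- methods::slot(cb, "offset")
    spc <- methods::slot(cb, "space")
    rev <- methods::slot(cb, "reversed")
    rs <- IRanges::start(rng) - 1
    re <- IRanges::end(rng)
    qs <- rs - off
    out[[length(out) + 1L]] <- tibble(
      ref_chrom = ref_chrom, ref_start = rs, ref_end = re,
      qry_chrom = as.character(spc), qry_start = qs, qry_end = qs + (re - rs),
      orientation = if_else(rev, "-", "+")
    )
  }
  bind_rows(out)
}
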