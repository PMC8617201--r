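#' Divide a genome into fixed-width bins
#'
#' Builds the bin grid used by all matrix-based analyses: each chromosome is
#' tiled left-to-right with `resolution`-bp bins (the last bin of a
#' chromosome may be short) and bins receive contiguous 1-based global
#' indices across chromosomes.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp, or
#'   a data frame with columns `chrom` and `length`.
#' @param resolution Bin width in bp.
#' @param genome Optional genome identifier stored on the grid.
#'
#' @return A tibble of class `bin_grid` with columns `bin` (global index),
#'   `chrom`, `start`, `end` (0-based half-open bp), and attributes
#'   `resolution` and `genome`.
#' @export
#' @examples
#' bin_grid(c(chr1 = 1e6, chr2 = 5e5), resolution = 1e5)
bin_grid <- function(chrom_lengths, resolution, genome = "genome") {
  if (is.data.frame(chrom_lengths)) {
    chrom_lengths <- setNames(chrom_lengths$length, chrom_lengths$chrom)
  }
  stopifnot(resolution > 0, all(chrom_lengths > 0))
  if (any(chrom_lengths < 2 * resolution)) {
    abort("every chromosome must span at least 2 bins at this resolution")
  }
  per <- purrr::imap(as.list(chrom_lengths), function(len, nm) {
    starts <- seq(0, len - 1, by = resolution)
    tibble(chrom = nm, start = starts, end = pmin(starts + resolution, len))
  })
  g <- bind_rows(per) %>% mutate(bin = row_number()) %>%
    select("bin", "chrom", "start", "end")
  attr(g, "resolution") <- resolution
  attr(g, "genome") <- genome
  class(g) <- c("bin_grid", class(g))
  g
}

grid_resolution <- function(grid) attr(grid, "resolution")

n_bins <- function(grid) nrow(grid)

# Map bp positions to global bin indices; NA for unknown chrom or
# out-of-range position.
locate_bins <- function(grid, chrom, pos) {
  res <- grid_resolution(grid)
  first_bin <- grid %>% group_by(.data$chrom) %>%
    summarise(first = min(.data$bin), len = max(.data$end), .groups = "drop")
  i <- match(chrom, first_bin$chrom)
  off <- floor(pos / res)
  bin <- first_bin$first[i] + off
  bad <- is.na(i) | pos < 0 | pos >= first_bin$len[i]
  bin[bad] <- NA_integer_
  as.integer(bin)
}
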