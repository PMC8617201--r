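# Contact-matrix container and core Hi-C matrix operations.

new_contact_matrix <- function(grid, counts, normalized = FALSE,
                               bad_bins = integer(0), meta = list()) {
  m <- list(
    grid = grid,
    counts = as_tibble(counts),
    normalized = normalized,
    bad_bins = as.integer(bad_bins),
    meta = meta
  )
  class(m) <- "contact_matrix"
  m
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(
    "<contact_matrix> ", n_bins(x$grid), " bins @ ",
    format(grid_resolution(x$grid), big.mark = ","), " bp, ",
    nrow(x$counts), " non-zero cells, ",
    if (x$normalized) "normalized" else "raw",
    ", ", length(x$bad_bins), " masked bins\n",
    sep = ""
  )
  invisible(x)
}

#' @method glance contact_matrix
#' @export
glance.contact_matrix <- function(x, ...) {
  tibble(
    n_bins = n_bins(x$grid),
    resolution = grid_resolution(x$grid),
    n_cells = nrow(x$counts),
    total = sum(x$counts$count),
    normalized = x$normalized,
    n_bad_bins = length(x$bad_bins),
    ice_iterations = x$meta$iterations %||% NA_integer_,
    ice_cv = x$meta$cv %||% NA_real_
  )
}

#' Bin valid read-pairs into a raw contact matrix
#'
#' Each well-formed pair increments exactly one upper-triangle cell
#' (`bin_i <= bin_j`); totals are conserved. Pairs referencing unknown
#' chromosomes or out-of-range positions are skipped and the skip count
#' reported via a message.
#'
#' @param pairs Data frame with columns `chrom_a, pos_a, chrom_b, pos_b`
#'   (bp, 0-based).
#' @param grid A [bin_grid()].
#' @return A raw `contact_matrix`.
#' @export
bin_pairs <- function(pairs, grid) {
  bi <- locate_bins(grid, pairs$chrom_a, pairs$pos_a)
  bj <- locate_bins(grid, pairs$chrom_b, pairs$pos_b)
  ok <- !is.na(bi) & !is.na(bj)
  n_skip <- sum(!ok)
  if (n_skip > 0) inform(sprintf("bin_pairs: skipped %d malformed pair(s)", n_skip))
  i <- pmin(bi[ok], bj[ok])
  j <- pmax(bi[ok], bj[ok])
  counts <- tibble(bin_i = i, bin_j = j) %>%
    count(.data$bin_i, .data$bin_j, name = "count") %>%
    mutate(count = as.numeric(.data$count))
  new_contact_matrix(grid, counts, meta = list(n_skipped = n_skip))
}

# Full symmetric row sums from upper-triangle storage.
cm_row_sums <- function(counts, n) {
  rs <- numeric(n)
  a <- tapply(counts$count, counts$bin_i, sum)
  rs[as.integer(names(a))] <- rs[as.integer(names(a))] + a
  off <- counts[counts$bin_i != counts$bin_j, ]
  if (nrow(off) > 0) {
    b <- tapply(off$count, off$bin_j, sum)
    rs[as.integer(names(b))] <- rs[as.integer(names(b))] + b
  }
  rs
}

#' Balance a contact matrix by iterative correction
#'
#' Masks low-coverage bins (total coverage at or below the
#' `low_coverage_quantile` quantile of non-zero coverages, plus all
#' zero-coverage bins), then iteratively rescales rows and columns until
#' the coefficient of variation of the non-masked row sums drops below
#' `tol`. The total count mass is preserved. Iteration count and final CV
#' are stored in `$meta`.
#'
#' @param m A raw `contact_matrix`.
#' @param tol Convergence threshold on the row-sum CV.
#' @param max_iter Iteration cap.
#' @param low_coverage_quantile Quantile of non-zero bin coverage below
#'   which bins are masked.
#' @return A normalized `contact_matrix` with `bad_bins` set; entries on
#'   masked bins are removed.
#' @export
ice_normalize <- function(m, tol = 1e-6, max_iter = 500,
                          low_coverage_quantile = 0.02) {
  n <- n_bins(m$grid)
  cov <- cm_row_sums(m$counts, n)
  nz <- cov[cov > 0]
  if (length(nz) == 0) abort("ice_normalize: matrix is empty")
  # zero-coverage bins are always masked; the low-coverage tail (bins
  # strictly below the coverage quantile) is assessed on raw input only —
  # a normalized matrix keeps its existing mask, making renormalization
  # idempotent
  bad <- if (m$normalized) {
    union(m$bad_bins, which(cov == 0))
  } else {
    thr <- quantile(nz, low_coverage_quantile)
    union(which(cov == 0), which(cov > 0 & cov < thr))
  }
  if (length(bad) >= n) abort("ice_normalize: all bins masked")

  cnt <- m$counts %>% filter(!.data$bin_i %in% bad, !.data$bin_j %in% bad)
  if (nrow(cnt) == 0) abort("ice_normalize: all entries fall on masked bins")
  total <- sum(m$counts$count)
  good <- setdiff(seq_len(n), bad)
  v <- cnt$count
  it <- 0L
  cv <- Inf
  repeat {
    rs <- numeric(n)
    a <- tapply(v, cnt$bin_i, sum)
    rs[as.integer(names(a))] <- rs[as.integer(names(a))] + a
    offsel <- cnt$bin_i != cnt$bin_j
    if (any(offsel)) {
      b <- tapply(v[offsel], cnt$bin_j[offsel], sum)
      rs[as.integer(names(b))] <- rs[as.integer(names(b))] + b
    }
    g <- rs[good]
    cv <- sd(g) / mean(g)
    if (cv < tol || it >= max_iter) break
    s <- rs / mean(g)
    s[s == 0] <- 1
    v <- v / (s[cnt$bin_i] * s[cnt$bin_j])
    it <- it + 1L
  }
  v <- v * (total / sum(v)) # preserve total mass
  out <- new_contact_matrix(
    m$grid, mutate(cnt, count = v), normalized = TRUE, bad_bins = bad,
    meta = c(m$meta[setdiff(names(m$meta), c("iterations", "cv"))],
             list(iterations = it, cv = cv))
  )
  out
}

# Dense symmetric matrix for one chromosome (local dense block); bins are
# the chromosome's global bin range. Masked bins become NA rows/columns.
cm_dense_chrom <- function(m, chrom) {
  gsub <- filter(m$grid, .data$chrom == !!chrom)
  lo <- min(gsub$bin)
  hi <- max(gsub$bin)
  nb <- hi - lo + 1L
  cnt <- filter(m$counts, .data$bin_i >= lo, .data$bin_i <= hi,
                .data$bin_j >= lo, .data$bin_j <= hi)
  M <- matrix(0, nb, nb)
  if (nrow(cnt) > 0) {
    i <- cnt$bin_i - lo + 1L
    j <- cnt$bin_j - lo + 1L
    M[cbind(i, j)] <- cnt$count
    M[cbind(j, i)] <- cnt$count
  }
  bad <- intersect(m$bad_bins, lo:hi) - lo + 1L
  if (length(bad) > 0) {
    M[bad, ] <- NA_real_
    M[, bad] <- NA_real_
  }
  attr(M, "first_bin") <- lo
  M
}

#' Observed/expected transformation of a normalized matrix
#'
#' Per chromosome, divides each cell by the mean of its diagonal (cells at
#' the same bin separation), the standard precursor to compartment eigen
#' analysis. Diagonals with zero or undefined expectation yield `NA` cells.
#'
#' @param m A normalized `contact_matrix`.
#' @return Named list (one element per chromosome) of dense O/E matrices;
#'   each carries attribute `first_bin`, the global index of its first bin.
#' @export
observed_expected <- function(m) {
  chroms <- unique(m$grid$chrom)
  out <- lapply(chroms, function(ch) {
    M <- cm_dense_chrom(m, ch)
    nb <- nrow(M)
    E <- M
    for (d in 0:(nb - 1)) {
      idx <- cbind(seq_len(nb - d), seq_len(nb - d) + d)
      vals <- M[idx]
      mu <- mean(vals, na.rm = TRUE)
      oe <- if (!is.finite(mu) || mu == 0) rep(NA_real_, nrow(idx)) else vals / mu
      E[idx] <- oe
      E[idx[, c(2, 1), drop = FALSE]] <- oe
    }
    attr(E, "first_bin") <- attr(M, "first_bin")
    E
  })
  setNames(out, chroms)
}

#' Read valid pairs from a TSV file
#'
#' Four whitespace-separated columns: `chrA posA chrB posB`.
#'
#' @param path Input path.
#' @return Tibble with columns `chrom_a, pos_a, chrom_b, pos_b`.
#' @export
read_pairs_tsv <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chrom_a", "pos_a", "chrom_b", "pos_b"),
                          colClasses = c("character", "numeric", "character", "numeric"))
  as_tibble(df)
}

#' Write / read a contact matrix in triple format
#'
#' `bin_i bin_j count` triples plus a companion bin-table BED
#' (`chrom start end bin`), the sparse-matrix dialect used by HiC-Pro-style
#' pipelines.
#'
#' @param m A `contact_matrix`.
#' @param path Triples path; the bin table goes to `paste0(path, ".bins.bed")`.
#' @return `path`, invisibly.
#' @export
write_matrix_triples <- function(m, path) {
  utils::write.table(m$counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_bed(mutate(m$grid, label = .data$bin), paste0(path, ".bins.bed"))
  invisible(path)
}

#' @rdname write_matrix_triples
#' @param grid The [bin_grid()] the triples refer to.
#' @export
read_matrix_triples <- function(path, grid) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("bin_i", "bin_j", "count"))
  new_contact_matrix(grid, as_tibble(df))
}
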