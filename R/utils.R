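# Internal helpers shared across modules.

# Uniform random DNA of length n, drawn from the current RNG stream.
rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Weighted pool-adjacent-violators fit, monotone NON-increasing in the
# given order. Used to smooth the distance-decay expectation; kept tiny and
# explicit because stats::isoreg is unweighted.
pava_nonincreasing <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  if (n == 0L) return(numeric(0))
  # fit non-decreasing on the reversed series, then reverse back
  yr <- rev(y)
  wr <- rev(w)
  val <- yr
  wt <- wr
  idx <- rep(1L, n) # block membership sizes handled via lists
  # classic stack-based PAVA
  vals <- numeric(0)
  wts <- numeric(0)
  lens <- integer(0)
  for (i in seq_len(n)) {
    cv <- yr[i]
    cw <- wr[i]
    cl <- 1L
    while (length(vals) > 0 && tail(vals, 1) > cv) {
      pv <- tail(vals, 1)
      pw <- tail(wts, 1)
      pl <- tail(lens, 1)
      cv <- (pv * pw + cv * cw) / (pw + cw)
      cw <- pw + cw
      cl <- pl + cl
      vals <- vals[-length(vals)]
      wts <- wts[-length(wts)]
      lens <- lens[-length(lens)]
    }
    vals <- c(vals, cv)
    wts <- c(wts, cw)
    lens <- c(lens, cl)
  }
  rev(rep(vals, lens))
}

# Merge integer intervals (1-based, closed) that overlap or lie within
# `gap` of each other; returns a matrix with columns start, end.
merge_intervals <- function(start, end, gap = 0L) {
  if (length(start) == 0L) {
    return(cbind(start = integer(0), end = integer(0)))
  }
  o <- order(start, end)
  start <- start[o]
  end <- end[o]
  ms <- start[1]
  me <- end[1]
  out_s <- integer(0)
  out_e <- integer(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me + gap + 1L) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms)
      out_e <- c(out_e, me)
      ms <- start[i]
      me <- end[i]
    }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

# run-length runs of a logical vector, returning start/end indices of TRUE
# runs (NA treated as FALSE / run breaker).
true_runs <- function(x) {
  x[is.na(x)] <- FALSE
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble(start = starts[keep], end = ends[keep], length = r$lengths[keep])
}
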