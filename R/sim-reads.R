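#' Simulate long reads from a genome with per-read truth annotations
#'
#' Reads are sampled uniformly over chromosomes (weighted by length) and
#' strands, with lengths drawn from a gamma distribution around `mean_len`
#' and a substitution-only error process at `error_rate`. The truth table
#' lists every genome feature interval each read overlaps, projected to
#' read coordinates (orientation-aware for minus-strand reads).
#'
#' @param genome A `sim_genome`.
#' @param n Number of reads (0 allowed).
#' @param mean_len Mean read length in bp; must not exceed the shortest
#'   chromosome.
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return List with `reads` (tibble `read_id, chrom, start, end, strand,
#'   length, sequence`) and `truth` (tibble `read_id, label, read_start,
#'   read_end` with 0-based half-open read coordinates).
#' @export
simulate_reads <- function(genome, n, mean_len = 10000, error_rate = 0,
                           seed = 1) {
  stopifnot(error_rate >= 0, error_rate < 1)
  if (mean_len > min(genome$chrom_lengths)) {
    abort("mean_len exceeds the shortest chromosome")
  }
  withr::local_seed(seed)
  empty <- list(
    reads = tibble(read_id = character(0), chrom = character(0),
                   start = numeric(0), end = numeric(0), strand = character(0),
                   length = numeric(0), sequence = character(0)),
    truth = tibble(read_id = character(0), label = character(0),
                   read_start = numeric(0), read_end = numeric(0))
  )
  if (n == 0) return(empty)

  chroms <- names(genome$seqs)
  lens <- genome$chrom_lengths
  bases <- c("A", "C", "G", "T")

  reads <- vector("list", n)
  truths <- vector("list", n)
  for (r in seq_len(n)) {
    L <- max(200L, round(stats::rgamma(1, shape = 4, scale = mean_len / 4)))
    ch <- sample(chroms, 1, prob = lens)
    L <- min(L, lens[[ch]])
    s <- sample.int(lens[[ch]] - L + 1L, 1) - 1L # 0-based start
    e <- s + L
    strand <- sample(c("+", "-"), 1)
    sq <- substr(genome$seqs[[ch]], s + 1, e)
    if (strand == "-") sq <- revcomp(sq)
    if (error_rate > 0) {
      nerr <- rbinom(1, L, error_rate)
      if (nerr > 0) {
        pos <- sample.int(L, nerr)
        v <- strsplit(sq, "")[[1]]
        v[pos] <- vapply(v[pos], function(b) sample(setdiff(bases, b), 1), "")
        sq <- paste(v, collapse = "")
      }
    }
    id <- sprintf("read%05d", r)
    reads[[r]] <- tibble(
      read_id = id, chrom = ch, start = s, end = e, strand = strand,
      length = L, sequence = sq
    )
    fo <- genome$features %>%
      filter(.data$chrom == ch, .data$end > s, .data$start < e) %>%
      mutate(os = pmax(.data$start, s) - s, oe = pmin(.data$end, e) - s)
    if (strand == "-") {
      fo <- fo %>% mutate(tmp = L - .data$oe, oe = L - .data$os, os = .data$tmp)
    }
    truths[[r]] <- fo %>%
      dplyr::transmute(read_id = id, label = .data$label,
                       read_start = .data$os, read_end = .data$oe) %>%
      arrange(.data$read_start)
  }
  list(reads = bind_rows(reads), truth = bind_rows(truths))
}

#' Write simulated reads to FASTQ
#'
#' @param reads The `reads` tibble from [simulate_reads()].
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  qual <- Biostrings::BStringSet(vapply(reads$length,
                                        function(l) strrep("I", l), ""))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read long reads from FASTA/FASTQ into a tibble
#'
#' @param path Input path.
#' @param format `"fasta"` or `"fastq"` (guessed from the extension by
#'   default).
#' @return Tibble `read_id, length, sequence`.
#' @export
read_reads <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  }
  x <- Biostrings::readDNAStringSet(path, format = format)
  tibble(
    read_id = sub("\\s.*$", "", names(x)),
    length = Biostrings::width(x),
    sequence = unname(as.character(x))
  )
}
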