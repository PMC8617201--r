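# Satellite / telomere / palindrome pattern mining in long reads.

# k-mer set of a tandem monomer: drawn from the doubled monomer so k-mers
# spanning the unit junction are included, plus the reverse complement.
monomer_kmer_dict <- function(monomer, k) {
  double <- paste0(monomer, monomer)
  km <- substring(double, seq_len(nchar(double) - k + 1), seq(k, nchar(double)))
  rc <- revcomp(double)
  km2 <- substring(rc, seq_len(nchar(rc) - k + 1), seq(k, nchar(rc)))
  Biostrings::PDict(Biostrings::DNAStringSet(unique(c(km, km2))))
}

seed_ranges <- function(pdict, subject) {
  m <- Biostrings::matchPDict(pdict, subject)
  IRanges::reduce(unlist(m))
}

# merged seed intervals -> hits with a seed-coverage identity estimate
merged_hits <- function(ranges, merge_gap, min_width, min_identity) {
  if (length(ranges) == 0) {
    return(tibble(read_start = numeric(0), read_end = numeric(0),
                  identity = numeric(0)))
  }
  merged <- IRanges::reduce(ranges, min.gapwidth = merge_gap + 1L)
  ov <- IRanges::findOverlaps(ranges, merged)
  covw <- tapply(IRanges::width(ranges)[S4Vectors::queryHits(ov)],
                 S4Vectors::subjectHits(ov), sum)
  idx <- as.integer(names(covw))
  out <- tibble(
    read_start = IRanges::start(merged)[idx] - 1,
    read_end = as.numeric(IRanges::end(merged)[idx]),
    identity = as.numeric(covw) / IRanges::width(merged)[idx]
  )
  filter(out, .data$read_end - .data$read_start >= min_width,
         .data$identity >= min_identity)
}

#' Scan one read for satellite and telomeric repeat hits
#'
#' Seeded matching of each monomer class against both strands: exact
#' k-mer seeds drawn from the tandem monomer context are matched and
#' merged into hits (gap tolerance `merge_gap`), with identity estimated
#' from seed coverage; hits below `min_identity` or shorter than
#' `min_width` are discarded. Telomeric tracts are found as tandem arrays
#' of the unit (TTAGGG / its reverse complement), merging across
#' occasional disrupted units.
#'
#' @param sequence Read sequence (character).
#' @param monomers Named character vector of monomer sequences (classes
#'   `satI`, `satII`, `satIV`), see [monomer_library()].
#' @param telomere_unit Telomeric repeat unit (default `"TTAGGG"`).
#' @param k Seed length (bp).
#' @param min_identity Minimum seed-coverage identity of a hit.
#' @param merge_gap Maximum gap (bp) bridged when merging seeds.
#' @param min_width Minimum hit width (bp) for satellite classes.
#' @param pdicts Optional precomputed k-mer dictionaries (internal reuse).
#' @return Tibble of hits: `cls, read_start, read_end, identity`
#'   (0-based half-open read coordinates).
#' @export
scan_read <- function(sequence, monomers, telomere_unit = "TTAGGG", k = 12,
                      min_identity = 0.7, merge_gap = 50, min_width = 20,
                      pdicts = NULL) {
  if (nchar(sequence) < k) {
    return(tibble(cls = character(0), read_start = numeric(0),
                  read_end = numeric(0), identity = numeric(0)))
  }
  subject <- Biostrings::DNAString(sequence)
  if (is.null(pdicts)) {
    pdicts <- lapply(monomers, monomer_kmer_dict, k = k)
  }
  sat <- purrr::imap(pdicts, function(pd, cls) {
    h <- merged_hits(seed_ranges(pd, subject), merge_gap, min_width,
                     min_identity)
    if (nrow(h) > 0) mutate(h, cls = cls, .before = 1) else NULL
  })
  # telomere: exact unit matches on both strands, merged across up to two
  # failed units; arrays of >= 3 units retained
  tf <- Biostrings::matchPattern(telomere_unit, subject)
  tr <- Biostrings::matchPattern(revcomp(telomere_unit), subject)
  tel_ranges <- IRanges::reduce(c(IRanges::IRanges(IRanges::start(tf),
                                                   IRanges::end(tf)),
                                  IRanges::IRanges(IRanges::start(tr),
                                                   IRanges::end(tr))))
  tel <- merged_hits(tel_ranges, merge_gap = 12L,
                     min_width = 3L * nchar(telomere_unit),
                     min_identity = min_identity)
  if (nrow(tel) > 0) tel <- mutate(tel, cls = "telomere", .before = 1)
  bind_rows(c(sat, list(tel))) %>% arrange(.data$read_start)
}

#' Scan many reads for repeat hits
#'
#' @param reads Tibble with `read_id` and `sequence` columns.
#' @inheritParams scan_read
#' @return Tibble `read_id, cls, read_start, read_end, identity`.
#' @export
scan_reads <- function(reads, monomers, telomere_unit = "TTAGGG", k = 12,
                       min_identity = 0.7, merge_gap = 50, min_width = 20) {
  pdicts <- lapply(monomers, monomer_kmer_dict, k = k)
  purrr::map2(reads$read_id, reads$sequence, function(id, sq) {
    h <- scan_read(sq, monomers, telomere_unit, k, min_identity, merge_gap,
                   min_width, pdicts = pdicts)
    if (nrow(h) > 0) mutate(h, read_id = id, .before = 1) else NULL
  }) %>% bind_rows()
}

pattern_classes <- c("satI", "satII", "satIV", "telomere")

#' Encode per-read repeat content as a 4-bit pattern
#'
#' Per class, merged hit lengths are summed and the class bit is set when
#' the total exceeds `min_total` (strictly more than 30 bp by default).
#' Bit order, left to right: satI, satII, satIV, telomere — e.g. `"1011"`
#' marks a read carrying satI, satIV and telomeric sequence.
#'
#' @param hits Hit tibble for the reads (from [scan_reads()] or the truth
#'   annotations).
#' @param reads Tibble with `read_id` (and optionally `length`); reads
#'   without hits receive code `"0000"`.
#' @param min_total Per-class inclusion threshold in bp (strict >).
#' @param cls_col,start_col,end_col Column names in `hits`.
#' @return Tibble `read_id, code, len_satI, len_satII, len_satIV,
#'   len_telomere` (one row per read).
#' @export
encode_patterns <- function(hits, reads, min_total = 30,
                            cls_col = "cls", start_col = "read_start",
                            end_col = "read_end") {
  hits <- tibble(
    read_id = hits$read_id, cls = hits[[cls_col]],
    s = hits[[start_col]], e = hits[[end_col]]
  )
  per <- hits %>%
    filter(.data$cls %in% pattern_classes) %>%
    group_by(.data$read_id, .data$cls) %>%
    dplyr::group_modify(function(df, key) {
      mi <- merge_intervals(as.integer(df$s), as.integer(df$e))
      tibble(len = sum(mi[, "end"] - mi[, "start"]))
    }) %>%
    ungroup() %>%
    tidyr::pivot_wider(names_from = "cls", values_from = "len",
                       names_prefix = "len_")
  base <- tibble(read_id = unique(reads$read_id))
  for (cl in pattern_classes) {
    col <- paste0("len_", cl)
    if (!col %in% names(per)) per[[col]] <- 0
  }
  out <- left_join(base, per, by = "read_id") %>%
    mutate(dplyr::across(dplyr::starts_with("len_"),
                         ~ tidyr::replace_na(.x, 0)))
  bits <- vapply(pattern_classes, function(cl) {
    as.integer(out[[paste0("len_", cl)]] > min_total)
  }, integer(nrow(out)))
  if (nrow(out) == 1) bits <- matrix(bits, nrow = 1)
  out$code <- apply(bits, 1, paste, collapse = "")
  select(out, "read_id", "code", "len_satI", "len_satII", "len_satIV",
         "len_telomere")
}

#' Census of 4-bit pattern codes
#'
#' @param patterns Pattern tibble from [encode_patterns()].
#' @return 16-row tibble `code, n, proportion` (proportions sum to 1);
#'   empty input yields an empty tibble.
#' @export
pattern_census <- function(patterns) {
  if (nrow(patterns) == 0) {
    return(tibble(code = character(0), n = integer(0), proportion = numeric(0)))
  }
  all_codes <- apply(expand.grid(0:1, 0:1, 0:1, 0:1)[, 4:1], 1, paste,
                     collapse = "")
  tibble(code = factor(patterns$code, levels = sort(all_codes))) %>%
    count(.data$code, .drop = FALSE, name = "n") %>%
    mutate(code = as.character(.data$code),
           proportion = .data$n / sum(.data$n))
}

#' Distance between satI and telomeric sequence within reads
#'
#' For reads whose pattern code is `"1001"` (satI and telomere only), the
#' distance is the minimum edge-to-edge gap over all satI x telomere hit
#' pairs (0 when hits overlap), split at 500 bp: juxtaposed (`"<500"`,
#' the fused state) versus distant (`">=500"`, the ancestral
#' centromeric-head state).
#'
#' @param patterns Pattern tibble from [encode_patterns()].
#' @param hits Hit tibble.
#' @param code Pattern code to analyse (default `"1001"`).
#' @return Tibble `read_id, distance, category`.
#' @export
sat1_telomere_distance <- function(patterns, hits, code = "1001") {
  ids <- patterns$read_id[patterns$code == code]
  purrr::map(ids, function(id) {
    h <- filter(hits, .data$read_id == id)
    s1 <- filter(h, .data$cls == "satI")
    te <- filter(h, .data$cls == "telomere")
    if (nrow(s1) == 0 || nrow(te) == 0) {
      abort(sprintf("read %s lacks a satI or telomere hit", id))
    }
    d <- min(outer(seq_len(nrow(s1)), seq_len(nrow(te)),
                   Vectorize(function(a, b) {
                     max(0, max(s1$read_start[a], te$read_start[b]) -
                           min(s1$read_end[a], te$read_end[b]))
                   })))
    tibble(read_id = id, distance = d,
           category = if (d < 500) "<500" else ">=500")
  }) %>% bind_rows()
}

#' Per-read telomere totals and hit positions
#'
#' Summarises telomere content for reads in the given pattern-code groups:
#' per-read total telomeric length, and a position class per hit —
#' `"near-end"` if the hit lies within `max(1 kb, 5%)` of either read
#' terminus, else `"middle"` (internal truncated telomeres sit in the
#' middle; genuine chromosome-end telomeres near an end).
#'
#' @param patterns Pattern tibble (must include `read_id, code`).
#' @param hits Hit tibble.
#' @param reads Tibble with `read_id, length`.
#' @param codes Codes to keep; `NULL` keeps every read whose telomere bit
#'   is set.
#' @return List with `read_totals` (`read_id, code, total_telomere`) and
#'   `hit_positions` (`read_id, read_start, read_end, position_class`).
#' @export
telomere_length_summary <- function(patterns, hits, reads,
                                    codes = c("1001", "0011", "1011")) {
  keep <- if (is.null(codes)) {
    patterns$read_id[substr(patterns$code, 4, 4) == "1"]
  } else {
    patterns$read_id[patterns$code %in% codes]
  }
  th <- filter(hits, .data$cls == "telomere", .data$read_id %in% keep)
  totals <- th %>% group_by(.data$read_id) %>%
    summarise(total_telomere = sum(.data$read_end - .data$read_start),
              .groups = "drop") %>%
    left_join(select(patterns, "read_id", "code"), by = "read_id")
  pos <- th %>%
    left_join(select(reads, "read_id", "length"), by = "read_id") %>%
    mutate(
      zone = pmax(1000, 0.05 * .data$length),
      position_class = if_else(
        .data$read_start < .data$zone |
          .data$read_end > .data$length - .data$zone,
        "near-end", "middle"
      )
    ) %>%
    select("read_id", "read_start", "read_end", "position_class")
  list(read_totals = totals, hit_positions = pos)
}

#' Detect palindromes (inverted repeats) within a read
#'
#' Compares the read against its own reverse complement with exact k-mer
#' seeds. Seed pairs belonging to one inverted repeat share a constant
#' anti-diagonal (left position + partner position); clustering on it
#' yields candidate arm pairs, reported when the arm is at least
#' `min_arm` bp, the spacer between arms is at most `max_spacer`, and
#' seed-coverage identity reaches `min_identity`. Overlapping reports are
#' merged keeping the longest arm.
#'
#' @param sequence Read sequence.
#' @param min_arm Minimum arm length (bp).
#' @param max_spacer Maximum spacer between arms (bp).
#' @param min_identity Minimum arm identity (seed coverage).
#' @param k Seed length.
#' @param max_kmer_occ Skip seeds occurring more often than this on either
#'   strand (low-complexity guard).
#' @return Tibble `left_start, left_end, right_start, right_end, arm,
#'   spacer, identity` (0-based half-open read coordinates).
#' @export
detect_palindromes <- function(sequence, min_arm = 30, max_spacer = 2000,
                               min_identity = 0.9, k = 12,
                               max_kmer_occ = 100) {
  empty <- tibble(
    left_start = numeric(0), left_end = numeric(0),
    right_start = numeric(0), right_end = numeric(0),
    arm = numeric(0), spacer = numeric(0), identity = numeric(0)
  )
  L <- nchar(sequence)
  if (L < 2 * k) return(empty)
  rc <- revcomp(sequence)
  starts <- seq_len(L - k + 1)
  km_f <- substring(sequence, starts, starts + k - 1)
  km_r <- substring(rc, starts, starts + k - 1)
  common <- intersect(km_f, km_r)
  common <- common[!grepl("[^ACGT]", common)]
  if (length(common) == 0) return(empty)
  pos_f <- split(starts, factor(km_f, levels = common))
  pos_r <- split(starts, factor(km_r, levels = common))
  pairs <- purrr::map(common, function(w) {
    i <- pos_f[[w]]
    q <- pos_r[[w]]
    if (length(i) == 0 || length(q) == 0) return(NULL)
    if (length(i) > max_kmer_occ || length(q) > max_kmer_occ) return(NULL)
    g <- expand.grid(i = i, q = q)
    g$j <- L - g$q - k + 2 # partner-arm start in read coordinates
    g[g$i < g$j, c("i", "j")]
  }) %>% bind_rows()
  if (nrow(pairs) == 0) return(empty)
  pairs$s <- pairs$i + pairs$j

  hits <- pairs %>% group_by(.data$s) %>%
    dplyr::group_modify(function(df, key) {
      i0 <- min(df$i)
      i1 <- max(df$i) + k - 1 # 1-based inclusive end of left arm
      arm <- i1 - i0 + 1
      j0 <- key$s - max(df$i)
      j1 <- key$s - i0 + k - 1
      segs <- merge_intervals(df$i, df$i + k - 1L)
      covered <- sum(segs[, "end"] - segs[, "start"] + 1)
      tibble(
        left_start = i0 - 1, left_end = i1,
        right_start = j0 - 1, right_end = j1,
        arm = arm, spacer = max(0, j0 - i1 - 1),
        identity = covered / arm
      )
    }) %>% ungroup() %>% select(-"s") %>%
    filter(.data$arm >= min_arm, .data$spacer <= max_spacer,
           .data$identity >= min_identity) %>%
    arrange(dplyr::desc(.data$arm))

  # merge overlapping reports, longest arm wins
  kept <- empty
  for (r in seq_len(nrow(hits))) {
    h <- hits[r, ]
    clash <- nrow(kept) > 0 &&
      any(h$left_start < kept$right_end & h$right_end > kept$left_start)
    if (!clash) kept <- bind_rows(kept, h)
  }
  arrange(kept, .data$left_start)
}

#' Detect palindromes across many reads
#'
#' @param reads Tibble with `read_id, sequence`.
#' @inheritParams detect_palindromes
#' @return Tibble with `read_id` plus the [detect_palindromes()] columns.
#' @export
detect_palindromes_reads <- function(reads, min_arm = 30, max_spacer = 2000,
                                     min_identity = 0.9, k = 12) {
  purrr::map2(reads$read_id, reads$sequence, function(id, sq) {
    h <- detect_palindromes(sq, min_arm, max_spacer, min_identity, k)
    if (nrow(h) > 0) mutate(h, read_id = id, .before = 1) else NULL
  }) %>% bind_rows()
}

#' Fraction of satellite-plus-telomere reads with palindrome-flanked
#' telomeres
#'
#' Among reads whose code sets the telomere bit together with satI or
#' satIV, the fraction whose telomere hit lies inside a detected
#' palindrome spacer (with `flank_tol` bp tolerance at each side).
#'
#' @param patterns Pattern tibble.
#' @param hits Hit tibble.
#' @param palindromes Output of [detect_palindromes_reads()].
#' @param flank_tol Tolerance in bp.
#' @return Tibble `n_reads, n_flanked, fraction`.
#' @export
palindrome_flank_fraction <- function(patterns, hits, palindromes,
                                      flank_tol = 50) {
  sel <- patterns %>%
    filter(substr(.data$code, 4, 4) == "1",
           substr(.data$code, 1, 1) == "1" | substr(.data$code, 3, 3) == "1")
  if (nrow(sel) == 0) abort("no reads with satellite and telomere content")
  flanked <- vapply(sel$read_id, function(id) {
    te <- filter(hits, .data$read_id == id, .data$cls == "telomere")
    pa <- filter(palindromes, .data$read_id == id)
    if (nrow(te) == 0 || nrow(pa) == 0) return(FALSE)
    any(vapply(seq_len(nrow(te)), function(a) {
      any(te$read_start[a] >= pa$left_end - flank_tol &
            te$read_end[a] <= pa$right_start + flank_tol)
    }, TRUE))
  }, TRUE)
  tibble(n_reads = nrow(sel), n_flanked = sum(flanked),
         fraction = mean(flanked))
}
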