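# Male-specific variant calling, SV validation, neo-Y curation and
# allele-specific expression.

#' Call candidate male-specific small variants
#'
#' A site is called male-specific when every one of the six samples has
#' depth within `[dp_min, dp_max]`, both male samples are heterozygous
#' (0/1), and both female and both outgroup samples are
#' homozygous-reference (0/0). Sites with a missing genotype (./.) in any
#' sample are skipped (logged).
#'
#' @param genotypes Genotype tibble (columns `chrom, pos, ref, alt`,
#'   genotypes `F1, F2, M1, M2, O1, O2`, depths `dp_F1..dp_O2`), e.g. from
#'   [simulate_variant_table()] or [read_genotypes_tsv()].
#' @param dp_min,dp_max Depth bounds (inclusive; defaults 15 and 100).
#' @return The subset of `genotypes` passing the full rule, with a
#'   `kind` column (`"SNP"` or `"indel"` by allele length).
#' @export
call_male_specific_small_variants <- function(genotypes, dp_min = 15,
                                              dp_max = 100) {
  gt_cols <- samples_6
  dp_cols <- paste0("dp_", samples_6)
  g <- as.matrix(genotypes[, gt_cols])
  d <- as.matrix(genotypes[, dp_cols])
  missing <- rowSums(g == "./.") > 0
  if (any(missing)) {
    inform(sprintf("skipped %d site(s) with missing genotypes", sum(missing)))
  }
  dp_ok <- rowSums(d >= dp_min & d <= dp_max) == 6
  males_het <- g[, "M1"] == "0/1" & g[, "M2"] == "0/1"
  others_ref <- g[, "F1"] == "0/0" & g[, "F2"] == "0/0" &
    g[, "O1"] == "0/0" & g[, "O2"] == "0/0"
  keep <- !missing & dp_ok & males_het & others_ref
  genotypes[keep, , drop = FALSE] %>%
    mutate(kind = if_else(nchar(.data$ref) == 1 & nchar(.data$alt) == 1,
                          "SNP", "indel"))
}

#' Validate heterozygous SV candidates by nearby reliable SNPs
#'
#' An SV candidate is kept when at least one reliable (male-specific) SNP
#' lies within `window` bp upstream or downstream of its interval
#' (closed: a SNP exactly at the window edge counts).
#'
#' @param svs SV tibble (`sv_id, chrom, start, end, ...`).
#' @param reliable_snps Calls from [call_male_specific_small_variants()]
#'   (needs `chrom, pos`).
#' @param window Search window in bp (default 1 kb).
#' @return `svs` with a logical `validated` column.
#' @export
validate_male_specific_svs <- function(svs, reliable_snps, window = 1000) {
  validated <- purrr::pmap_lgl(
    select(svs, "chrom", "start", "end"),
    function(chrom, start, end) {
      any(reliable_snps$chrom == chrom &
            reliable_snps$pos >= start - window &
            reliable_snps$pos <= end + window)
    }
  )
  mutate(svs, validated = validated)
}

#' Per-window call density
#'
#' Counts calls in non-overlapping tiling windows (default 500 kb).
#'
#' @param calls Call tibble with `chrom, pos`.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param window Window size in bp.
#' @return Tibble `chrom, start, end, n`.
#' @export
window_density <- function(calls, chrom_lengths, window = 5e5) {
  purrr::imap(as.list(chrom_lengths), function(len, ch) {
    starts <- seq(0, len - 1, by = window)
    n <- vapply(starts, function(s) {
      sum(calls$chrom == ch & calls$pos > s & calls$pos <= min(s + window, len))
    }, 1L)
    tibble(chrom = ch, start = starts, end = pmin(starts + window, len), n = n)
  }) %>% bind_rows()
}

#' Neo-Y enrichment of male-specific calls
#'
#' Compares the observed fraction of calls inside the neo-Y intervals
#' with the neo-Y's share of the genome under uniform placement
#' (chi-squared goodness of fit, 1 df).
#'
#' @param calls Call tibble with `chrom, pos` (1-based).
#' @param neoy_intervals Tibble `chrom, start, end` (0-based half-open).
#' @param genome_size Total genome size in bp.
#' @return Tibble `n_calls, n_in, fraction_in, genome_fraction,
#'   statistic, p_value`.
#' @export
neoy_enrichment <- function(calls, neoy_intervals, genome_size) {
  if (nrow(calls) == 0) abort("no calls supplied")
  gf <- sum(neoy_intervals$end - neoy_intervals$start) / genome_size
  if (gf <= 0 || gf >= 1) {
    abort("neo-Y fraction must be strictly between 0 and 1 for the test")
  }
  inside <- purrr::map2_lgl(calls$chrom, calls$pos, function(ch, p) {
    any(neoy_intervals$chrom == ch & p > neoy_intervals$start &
          p <= neoy_intervals$end)
  })
  k <- sum(inside)
  n <- length(inside)
  ct <- suppressWarnings(chisq.test(c(k, n - k), p = c(gf, 1 - gf)))
  tibble(
    n_calls = n, n_in = k, fraction_in = k / n, genome_fraction = gf,
    statistic = unname(ct$statistic), p_value = unname(ct$p.value)
  )
}

#' Curate a neo-Y sequence with male-specific calls
#'
#' At every candidate male-specific site whose neo-Y base (through the
#' neo-X/neo-Y alignment) still equals the neo-X base, the neo-Y base is
#' replaced with the alternate allele; all other positions are untouched,
#' so the operation is idempotent. Sites falling in alignment gaps are
#' skipped (logged).
#'
#' @param neoy_seq Neo-Y sequence (character).
#' @param alignment Collinear block table mapping neo-X to neo-Y
#'   coordinates: tibble `x_start, x_end, y_start, y_end` (0-based
#'   half-open, equal span lengths, plus strand assumed).
#' @param calls SNP calls with `pos` (1-based neo-X coordinate), `ref`
#'   (neo-X base) and `alt`.
#' @return List with `sequence` (curated) and `log` (tibble `pos, y_pos,
#'   action` where action is `replaced`, `already_alt`, `gap` or
#'   `ref_mismatch`).
#' @export
curate_neoy_sequence <- function(neoy_seq, alignment, calls) {
  sq <- strsplit(neoy_seq, "")[[1]]
  log <- vector("list", nrow(calls))
  for (r in seq_len(nrow(calls))) {
    x0 <- calls$pos[r] - 1 # 0-based
    hit <- alignment %>% filter(.data$x_start <= x0, .data$x_end > x0)
    if (nrow(hit) == 0) {
      log[[r]] <- tibble(pos = calls$pos[r], y_pos = NA_real_, action = "gap")
      next
    }
    y1 <- hit$y_start[1] + (x0 - hit$x_start[1]) + 1 # 1-based neo-Y
    cur <- sq[y1]
    if (cur == calls$ref[r]) {
      sq[y1] <- calls$alt[r]
      act <- "replaced"
    } else if (cur == calls$alt[r]) {
      act <- "already_alt"
    } else {
      act <- "ref_mismatch"
    }
    log[[r]] <- tibble(pos = calls$pos[r], y_pos = y1, action = act)
  }
  log <- bind_rows(log)
  n_gap <- sum(log$action == "gap")
  if (n_gap > 0) inform(sprintf("curation: %d site(s) in alignment gaps skipped", n_gap))
  list(sequence = paste(sq, collapse = ""), log = log)
}

#' Classify the coding effect of a variant
#'
#' Minimal four-class effect annotator over toy single-transcript gene
#' models: premature stop, frameshift or splice-site disruption give
#' `HIGH`; missense `MODERATE`; synonymous `LOW`; anything without
#' protein-coding impact (intergenic, intronic away from splice sites)
#' `MODIFIER`.
#'
#' @param call One-row tibble/list with `chrom, pos` (1-based), `ref`,
#'   `alt`.
#' @param models Gene models: tibble `gene, chrom, strand, start, end`
#'   with one row per coding exon (0-based half-open), all exons coding.
#' @param genome_seqs Named character vector of chromosome sequences.
#' @return One of `"HIGH", "MODERATE", "LOW", "MODIFIER"`.
#' @export
annotate_effect <- function(call, models, genome_seqs) {
  pos0 <- call$pos - 1
  gm <- models %>% filter(.data$chrom == call$chrom) %>%
    group_by(.data$gene) %>%
    filter(min(.data$start) <= pos0, max(.data$end) > pos0) %>%
    ungroup()
  if (nrow(gm) == 0) return("MODIFIER")
  gene <- gm$gene[1]
  ex <- gm %>% filter(.data$gene == !!gene) %>% arrange(.data$start)
  in_exon <- any(ex$start <= pos0 & ex$end > pos0)
  if (!in_exon) {
    # the two intronic bases flanking each exon are splice sites
    near_splice <- any((pos0 - ex$end) %in% c(0, 1) |
                         ((ex$start - 1) - pos0) %in% c(0, 1))
    return(if (near_splice) "HIGH" else "MODIFIER")
  }
  indel_shift <- (nchar(call$alt) - nchar(call$ref)) %% 3
  if (nchar(call$ref) != nchar(call$alt)) {
    return(if (indel_shift != 0) "HIGH" else "MODERATE")
  }
  # SNP in CDS: rebuild the codon
  chrom_seq <- genome_seqs[[call$chrom]]
  cds_pos <- 0
  offset <- NA
  for (r in seq_len(nrow(ex))) {
    if (ex$start[r] <= pos0 && ex$end[r] > pos0) {
      offset <- cds_pos + (pos0 - ex$start[r])
      break
    }
    cds_pos <- cds_pos + (ex$end[r] - ex$start[r])
  }
  cds <- paste(purrr::pmap_chr(ex, function(start, end, ...) {
    substr(chrom_seq, start + 1, end)
  }), collapse = "")
  if (identical(ex$strand[1], "-")) {
    cds <- revcomp(cds)
    offset <- nchar(cds) - offset - 1
    sub_base <- revcomp(call$alt)
  } else {
    sub_base <- call$alt
  }
  codon_i <- offset %/% 3
  within <- offset %% 3
  codon <- substr(cds, codon_i * 3 + 1, codon_i * 3 + 3)
  if (nchar(codon) < 3) return("MODIFIER")
  new_codon <- codon
  substr(new_codon, within + 1, within + 1) <- sub_base
  aa_old <- as.character(Biostrings::translate(Biostrings::DNAString(codon)))
  aa_new <- as.character(Biostrings::translate(Biostrings::DNAString(new_codon)))
  if (aa_new == aa_old) return("LOW")
  if (aa_new == "*") return("HIGH")
  "MODERATE"
}

#' Allele-specific expression from per-site allele counts
#'
#' Genes with at least `min_sites` informative male-specific SNP sites are
#' tested with a paired two-sided t-test of neo-X versus neo-Y read
#' counts across sites; the verdict is "different" when p < `alpha`.
#' Zero-variance paired differences with nonzero mean give p = 0 (the
#' limit); genes whose counts are all zero are skipped.
#'
#' @param counts Tibble `gene, site, neoX, neoY`.
#' @param min_sites Minimum informative sites per gene (default 2).
#' @param alpha Significance level (default 0.05).
#' @return Tibble `gene, n_sites, mean_diff, statistic, p_value,
#'   different, direction` (one row per tested gene).
#' @export
allele_specific_expression <- function(counts, min_sites = 2, alpha = 0.05) {
  counts %>% group_by(.data$gene) %>%
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < min_sites) return(tibble())
      if (all(df$neoX == 0 & df$neoY == 0)) return(tibble())
      diffs <- df$neoX - df$neoY
      if (sd(diffs) == 0) {
        if (mean(diffs) == 0) {
          stat <- 0
          p <- 1
        } else {
          stat <- sign(mean(diffs)) * Inf
          p <- 0
        }
      } else {
        tt <- t.test(df$neoX, df$neoY, paired = TRUE)
        stat <- unname(tt$statistic)
        p <- tt$p.value
      }
      tibble(
        n_sites = nrow(df), mean_diff = mean(diffs), statistic = stat,
        p_value = p,
        different = p < alpha,
        direction = dplyr::case_when(
          mean(diffs) > 0 ~ "neoX_higher",
          mean(diffs) < 0 ~ "neoY_higher",
          TRUE ~ "equal"
        )
      )
    }) %>% ungroup()
}

#' Min-max log2 normalization of window coverage
#'
#' Maps per-window mean depths to `[0, 1]`: value v becomes
#' `(log2(v) - min) / (max - min)` with min the log2 of the smallest
#' window coverage and max the log2 of the genome mean depth; values above
#' the genome mean clip to 1. Zero-coverage windows take a 1-read
#' pseudocount before the log, placing them at the scale minimum.
#'
#' @param depths Numeric vector of per-window mean depths (>= 0).
#' @param genome_mean Genome-wide mean depth.
#' @return Numeric vector in `[0, 1]`.
#' @export
normalize_coverage <- function(depths, genome_mean) {
  stopifnot(all(depths >= 0), genome_mean > 0)
  v <- ifelse(depths == 0, 1, depths)
  lv <- log2(v)
  lo <- min(lv)
  hi <- log2(genome_mean)
  if (hi <= lo) return(rep(1, length(depths)))
  pmin(1, pmax(0, (lv - lo) / (hi - lo)))
}
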