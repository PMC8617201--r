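#' Variant-simulation parameters
#'
#' @param neoY_chrom,neoY_start,neoY_end The neo-Y interval (0-based
#'   half-open bp) in which male-specific variants concentrate.
#' @param n_male_specific Number of planted male-specific sites.
#' @param male_specific_neoY_fraction Fraction of planted sites falling
#'   inside the neo-Y interval.
#' @param background_rate Background (non-male-specific) variant rate per
#'   bp; background sites each violate at least one clause of the
#'   male-specific calling rule.
#' @param depth_min,depth_max Per-sample depth bounds for planted sites.
#' @param seed Integer seed.
#' @return Named parameter list.
#' @export
variant_sim_params <- function(neoY_chrom, neoY_start, neoY_end,
                               n_male_specific = 100,
                               male_specific_neoY_fraction = 1,
                               background_rate = 1e-5,
                               depth_min = 15, depth_max = 100, seed = 1) {
  stopifnot(neoY_end > neoY_start, n_male_specific >= 0,
            male_specific_neoY_fraction >= 0,
            male_specific_neoY_fraction <= 1, depth_min <= depth_max)
  list(
    neoY_chrom = neoY_chrom, neoY_start = neoY_start, neoY_end = neoY_end,
    n_male_specific = n_male_specific,
    male_specific_neoY_fraction = male_specific_neoY_fraction,
    background_rate = background_rate,
    depth_min = depth_min, depth_max = depth_max, seed = seed
  )
}

samples_6 <- c("F1", "F2", "M1", "M2", "O1", "O2")

rand_alleles <- function(n) {
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  list(ref = ref, alt = unname(alt))
}

#' Simulate a six-sample genotype table with planted male-specific sites
#'
#' Planted sites are heterozygous in both male samples and
#' homozygous-reference in both female and both outgroup samples, with all
#' depths inside the configured range, so they satisfy the male-specific
#' calling rule by construction. Background sites each violate at least
#' one clause (genotype pattern, depth bound, or missing genotype). SV
#' candidates include validatable events with a planted site within 1 kb
#' and decoys without.
#'
#' @param chrom_lengths Named vector of chromosome lengths (bp), e.g.
#'   `genome$chrom_lengths`.
#' @param params See [variant_sim_params()].
#' @param n_sv Number of SV candidates of each kind (validatable, decoy).
#' @return List with `genotypes` (tibble: `chrom, pos` (1-based),
#'   `ref, alt`, genotype columns `F1..O2`, depth columns `dp_F1..dp_O2`),
#'   `svs` (tibble `sv_id, chrom, start, end, svtype`), and `truth`
#'   (list `sites` — planted male-specific positions with `in_neoy` flag —
#'   and `svs` with `validatable` flag).
#' @export
simulate_variant_table <- function(chrom_lengths, params, n_sv = 5) {
  p <- params
  withr::local_seed(p$seed)
  if (!p$neoY_chrom %in% names(chrom_lengths)) {
    abort("neo-Y chromosome not in genome")
  }
  ylen <- p$neoY_end - p$neoY_start
  n_in <- round(p$n_male_specific * p$male_specific_neoY_fraction)
  n_out <- p$n_male_specific - n_in
  if (n_in > ylen) abort("more male-specific sites requested than neo-Y bp")

  # planted male-specific positions (1-based)
  pos_in <- if (n_in > 0) {
    sort(sample.int(ylen, n_in)) + p$neoY_start
  } else integer(0)
  # outside the neo-Y interval, uniform over the rest of the genome
  out_sites <- if (n_out > 0) {
    tot <- sum(chrom_lengths)
    ch <- sample(names(chrom_lengths), n_out, replace = TRUE,
                 prob = chrom_lengths)
    po <- vapply(ch, function(c0) sample.int(chrom_lengths[[c0]], 1), 1L)
    move <- ch == p$neoY_chrom & po > p$neoY_start & po <= p$neoY_end
    po[move] <- ((po[move] + ylen - 1) %% chrom_lengths[[p$neoY_chrom]]) + 1
    tibble(chrom = ch, pos = as.numeric(po))
  } else tibble(chrom = character(0), pos = numeric(0))

  planted <- bind_rows(
    tibble(chrom = p$neoY_chrom, pos = as.numeric(pos_in)),
    out_sites
  ) %>% distinct(.data$chrom, .data$pos)
  al <- rand_alleles(nrow(planted))
  dp_draw <- function(n) sample(seq(p$depth_min, p$depth_max), n, replace = TRUE)
  gts <- tibble(
    F1 = "0/0", F2 = "0/0", M1 = "0/1", M2 = "0/1", O1 = "0/0", O2 = "0/0"
  )[rep(1, nrow(planted)), ]
  planted_tbl <- bind_cols(
    planted, tibble(ref = al$ref, alt = al$alt), gts,
    setNames(as_tibble(replicate(6, dp_draw(nrow(planted)), simplify = FALSE),
                       .name_repair = "minimal"),
             paste0("dp_", samples_6))
  )

  # background sites, each violating >= 1 clause of the calling rule
  n_bg <- round(p$background_rate * sum(chrom_lengths))
  bg_tbl <- NULL
  if (n_bg > 0) {
    ch <- sample(names(chrom_lengths), n_bg, replace = TRUE, prob = chrom_lengths)
    po <- vapply(ch, function(c0) sample.int(chrom_lengths[[c0]], 1), 1L)
    alb <- rand_alleles(n_bg)
    kind <- sample(c("one_male_only", "female_het", "outgroup_het",
                     "depth_low", "depth_high", "all_het", "missing"),
                   n_bg, replace = TRUE)
    g <- matrix("0/0", n_bg, 6, dimnames = list(NULL, samples_6))
    g[, c("M1", "M2")] <- "0/1"
    d <- matrix(dp_draw(n_bg * 6), n_bg, 6,
                dimnames = list(NULL, paste0("dp_", samples_6)))
    g[kind == "one_male_only", "M2"] <- "0/0"
    g[kind == "female_het", "F1"] <- "0/1"
    g[kind == "outgroup_het", "O2"] <- "0/1"
    g[kind == "all_het", ] <- "0/1"
    g[kind == "missing", "F2"] <- "./."
    d[kind == "depth_low", 1] <- max(0, p$depth_min - 5)
    d[kind == "depth_high", 3] <- p$depth_max + 50
    bg_tbl <- bind_cols(
      tibble(chrom = ch, pos = as.numeric(po), ref = alb$ref, alt = alb$alt),
      as_tibble(g), as_tibble(d)
    )
  }

  # planted rows are listed first, so they win position collisions
  genotypes <- bind_rows(planted_tbl, bg_tbl) %>%
    distinct(.data$chrom, .data$pos, .keep_all = TRUE) %>%
    arrange(.data$chrom, .data$pos)

  truth_sites <- planted %>%
    mutate(in_neoy = .data$chrom == p$neoY_chrom &
             .data$pos > p$neoY_start & .data$pos <= p$neoY_end)

  # SV candidates: validatable ones sit within 1 kb of a planted site
  svs <- NULL
  sv_truth <- NULL
  if (n_sv > 0 && nrow(planted) > 0) {
    anchor <- planted[sample.int(nrow(planted), n_sv, replace = TRUE), ]
    val <- tibble(
      sv_id = sprintf("sv_val%02d", seq_len(n_sv)),
      chrom = anchor$chrom,
      start = pmax(0, anchor$pos + sample(100:800, n_sv, replace = TRUE)),
      svtype = "DEL", validatable = TRUE
    ) %>% mutate(end = .data$start + sample(50:500, n_sv, replace = TRUE))
    # decoys: placed > 1 kb + max SV span away from every planted site
    far_pos <- function(c0) {
      repeat {
        x <- sample.int(chrom_lengths[[c0]] - 600, 1)
        near <- planted %>% filter(.data$chrom == c0,
                                   abs(.data$pos - x) < 3000)
        if (nrow(near) == 0) return(x)
      }
    }
    dch <- sample(names(chrom_lengths), n_sv, replace = TRUE)
    dec <- tibble(
      sv_id = sprintf("sv_dec%02d", seq_len(n_sv)),
      chrom = dch,
      start = vapply(dch, far_pos, 1L),
      svtype = "DEL", validatable = FALSE
    ) %>% mutate(end = .data$start + sample(50:400, n_sv, replace = TRUE))
    sv_truth <- bind_rows(val, dec)
    svs <- select(sv_truth, "sv_id", "chrom", "start", "end", "svtype")
  }

  list(
    genotypes = genotypes,
    svs = svs %||% tibble(sv_id = character(0), chrom = character(0),
                          start = numeric(0), end = numeric(0),
                          svtype = character(0)),
    truth = list(sites = truth_sites, svs = sv_truth)
  )
}

#' Write / read the six-sample genotype table as VCF-like TSV
#'
#' Columns `CHROM POS REF ALT` then one `GT:DP` column per sample
#' (F1, F2, M1, M2, O1, O2); positions 1-based.
#'
#' @param genotypes Genotype tibble from [simulate_variant_table()].
#' @param path Output path.
#' @return `path` (writer) or the genotype tibble (reader).
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  out <- data.frame(
    CHROM = genotypes$chrom, POS = genotypes$pos,
    REF = genotypes$ref, ALT = genotypes$alt
  )
  for (s in samples_6) {
    out[[s]] <- paste0(genotypes[[s]], ":", genotypes[[paste0("dp_", s)]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "", colClasses = "character")
  out <- tibble(
    chrom = df$CHROM, pos = as.numeric(df$POS), ref = df$REF, alt = df$ALT
  )
  for (s in samples_6) {
    sp <- strsplit(df[[s]], ":", fixed = TRUE)
    out[[s]] <- vapply(sp, `[`, "", 1)
    out[[paste0("dp_", s)]] <- as.numeric(vapply(sp, `[`, "", 2))
  }
  out
}

#' Simulate per-site allele counts for allele-specific expression
#'
#' For each gene, `snps_per_gene` informative sites receive a Poisson total
#' read count split binomially between the neo-X and neo-Y alleles with the
#' requested expected ratio.
#'
#' @param genes Character vector of gene ids (or an integer count).
#' @param snps_per_gene Informative sites per gene (>= 1).
#' @param imbalance Expected neo-X:neo-Y ratio (1 = balanced); recycled
#'   over genes.
#' @param depth Mean total reads per site (> 0).
#' @param seed Integer seed.
#' @return List with `counts` (tibble `gene, site, neoX, neoY`) and `truth`
#'   (tibble `gene, imbalance, imbalanced`).
#' @export
simulate_allele_counts <- function(genes, snps_per_gene = 4, imbalance = 1,
                                   depth = 40, seed = 1) {
  stopifnot(snps_per_gene >= 1, depth > 0)
  if (is.numeric(genes) && length(genes) == 1) {
    genes <- sprintf("gene%04d", seq_len(genes))
  }
  withr::local_seed(seed)
  ratio <- rep_len(imbalance, length(genes))
  counts <- purrr::map2(genes, ratio, function(g, r) {
    total <- rpois(snps_per_gene, depth)
    neoX <- rbinom(snps_per_gene, total, r / (1 + r))
    tibble(gene = g, site = seq_len(snps_per_gene),
           neoX = neoX, neoY = total - neoX)
  }) %>% bind_rows()
  list(
    counts = counts,
    truth = tibble(gene = genes, imbalance = ratio, imbalanced = ratio != 1)
  )
}
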