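#' Default repeat-architecture parameters for simulated genomes
#'
#' Lengths (bp) of the repeat arrays placed at the centromeric end of every
#' simulated acrocentric chromosome, ordered from the chromosome tip inward:
#' telomere, satellite II, satellite IV, a truncated telomeric tract flanked
#' by palindrome arms, then satellite I; the opposite end carries a distal
#' telomere. Satellite monomers are pseudo-random sequences of fixed
#' per-class length (satI ~800 bp, satII ~700 bp, satIV ~1000 bp): the
#' analyses only require distinguishable monomer classes, not the real
#' cervid monomers.
#'
#' @param tel_len Telomere array length at each chromosome end (bp,
#'   rounded to whole TTAGGG units).
#' @param satI_monomer,satII_monomer,satIV_monomer Monomer lengths (bp).
#' @param satI_units,satII_units,satIV_units Number of tandem monomer
#'   copies per array.
#' @param trunc_tel_len Target length (bp) of the internal truncated
#'   telomeric tract; the realised length is drawn within one TTAGGG unit
#'   of this value.
#' @param palindrome_arm Length (bp) of each palindrome arm flanking the
#'   truncated telomere.
#' @return A named list of parameters.
#' @export
default_repeat_params <- function(tel_len = 1998,
                                  satI_monomer = 800, satI_units = 6,
                                  satII_monomer = 700, satII_units = 4,
                                  satIV_monomer = 1000, satIV_units = 3,
                                  trunc_tel_len = 38,
                                  palindrome_arm = 200) {
  list(
    tel_len = 6L * round(tel_len / 6),
    satI_monomer = satI_monomer, satI_units = satI_units,
    satII_monomer = satII_monomer, satII_units = satII_units,
    satIV_monomer = satIV_monomer, satIV_units = satIV_units,
    trunc_tel_len = trunc_tel_len,
    palindrome_arm = palindrome_arm
  )
}

#' Generate the satellite monomer library
#'
#' One pseudo-random monomer per satellite class, reproducible from the
#' seed. The same library must be used to build genomes and to scan reads.
#'
#' @param params Repeat parameters, see [default_repeat_params()].
#' @param seed Integer seed.
#' @return Named character vector with elements `satI`, `satII`, `satIV`.
#' @export
monomer_library <- function(params = default_repeat_params(), seed = 1) {
  withr::local_seed(seed)
  c(
    satI = rand_dna(params$satI_monomer),
    satII = rand_dna(params$satII_monomer),
    satIV = rand_dna(params$satIV_monomer)
  )
}

telomere_array <- function(len) {
  units <- floor(len / 6)
  paste(rep("TTAGGG", units), collapse = "")
}

#' Build a simulated ancestral genome of acrocentric chromosomes
#'
#' Every chromosome carries, in order from its centromeric (left) tip
#' inward: a telomere array (TTAGGG)n, a satellite II array, a satellite IV
#' array, a truncated telomeric tract flanked by two palindrome arms
#' (reverse complements of each other), and a satellite I array; the body is
#' unique pseudo-random sequence and the opposite (right) end carries a
#' distal telomere. Deterministic given `seed`.
#'
#' @param n_chrom Number of chromosomes (>= 1).
#' @param chrom_length Length of every chromosome in bp; must accommodate
#'   the repeat arrays.
#' @param repeat_params See [default_repeat_params()].
#' @param seed Integer seed.
#' @return A `sim_genome` object: list with `seqs` (named character vector),
#'   `features` (tibble `chrom,start,end,label`, 0-based half-open),
#'   `ends` (tibble `chrom,left_end,right_end`), `monomers`, and
#'   `chrom_lengths`.
#' @export
build_ancestral_genome <- function(n_chrom, chrom_length,
                                   repeat_params = default_repeat_params(),
                                   seed = 1) {
  stopifnot(n_chrom >= 1)
  p <- repeat_params
  withr::local_seed(seed)
  monomers <- c(
    satI = rand_dna(p$satI_monomer),
    satII = rand_dna(p$satII_monomer),
    satIV = rand_dna(p$satIV_monomer)
  )
  sat <- function(cls, units) paste(rep(monomers[[cls]], units), collapse = "")

  seqs <- character(n_chrom)
  feats <- vector("list", n_chrom)
  names(seqs) <- paste0("anc", seq_len(n_chrom))
  for (i in seq_len(n_chrom)) {
    trunc_units <- max(1L, round(p$trunc_tel_len / 6) + sample(-1:1, 1))
    arm <- rand_dna(p$palindrome_arm)
    parts <- list(
      telomere = telomere_array(p$tel_len),
      satII = sat("satII", p$satII_units),
      satIV = sat("satIV", p$satIV_units),
      palindrome_arm = arm,
      truncated_telomere = telomere_array(6L * trunc_units),
      palindrome_arm = revcomp(arm),
      satI = sat("satI", p$satI_units)
    )
    head_len <- sum(vapply(parts, nchar, 1L))
    unique_len <- chrom_length - head_len - p$tel_len
    if (unique_len < 1) {
      abort("chrom_length too small to hold the repeat arrays")
    }
    parts$unique <- rand_dna(unique_len)
    parts$telomere_distal <- telomere_array(p$tel_len)
    lens <- vapply(parts, nchar, 1L)
    ends <- cumsum(lens)
    labels <- names(parts)
    labels[labels == "telomere_distal"] <- "telomere"
    feats[[i]] <- tibble(
      chrom = names(seqs)[i],
      start = ends - lens, end = ends, label = labels
    )
    seqs[i] <- paste(unlist(parts), collapse = "")
  }
  g <- list(
    seqs = seqs,
    features = bind_rows(feats),
    ends = tibble(
      chrom = names(seqs), left_end = "centromeric", right_end = "distal"
    ),
    monomers = monomers,
    chrom_lengths = setNames(nchar(seqs), names(seqs))
  )
  class(g) <- "sim_genome"
  g
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(
    "<sim_genome> ", length(x$seqs), " chromosomes, ",
    format(sum(x$chrom_lengths), big.mark = ","), " bp total\n",
    sep = ""
  )
  invisible(x)
}

#' Write a simulated genome to FASTA
#'
#' @param genome A `sim_genome`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$seqs), path)
  invisible(path)
}

#' Write genome features or fusion sites to BED
#'
#' @param x Tibble with `chrom`, `start`, `end` (and optionally a name-like
#'   column given by `name_col`).
#' @param path Output path.
#' @param name_col Column used for the BED name field.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, name_col = "label") {
  nm <- if (name_col %in% names(x)) x[[name_col]] else "."
  utils::write.table(
    data.frame(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
               format(x$end, scientific = FALSE, trim = TRUE), nm),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

# Reverse-complement a whole chromosome state (sequence, features,
# segments, end roles, recorded fusion-site positions).
flip_state <- function(st) {
  L <- nchar(st$seq)
  st$seq <- revcomp(st$seq)
  st$features <- st$features %>%
    mutate(
      s2 = L - .data$end, e2 = L - .data$start,
      start = .data$s2, end = .data$e2
    ) %>%
    select(-"s2", -"e2") %>%
    arrange(.data$start)
  st$segments <- st$segments %>%
    mutate(
      s2 = L - .data$end, e2 = L - .data$start,
      start = .data$s2, end = .data$e2,
      orientation = if_else(.data$orientation == "+", "-", "+")
    ) %>%
    select(-"s2", -"e2") %>%
    arrange(.data$start)
  tmp <- st$left_end
  st$left_end <- st$right_end
  st$right_end <- tmp
  if (nrow(st$sites) > 0) st$sites$position <- L - st$sites$position
  st
}

shift_tbl <- function(tb, by) mutate(tb, start = .data$start + by, end = .data$end + by)

#' Apply a fusion plan to a simulated genome
#'
#' Fusions are applied in list order. A tandem fusion joins the centromeric
#' head of `centromeric_partner` to the distal telomere of
#' `distal_partner`: the head repeat arrays of the centromeric partner
#' (telomere, satII, satIV, palindrome arms, truncated telomere) are
#' deleted up to its satI array, and the distal partner's terminal telomere
#' is cut back to a short retained tract (uniform 20-300 bp), so the
#' junction carries a satI array and a partial telomere separated by a
#' remnant gap < 500 bp. A Robertsonian fusion joins two centromeric heads
#' without deletion. Every junction is recorded in the returned truth.
#'
#' @param genome A `sim_genome` (from [build_ancestral_genome()] or a
#'   previous fusion round).
#' @param plan Tibble/data frame with columns `centromeric_partner`,
#'   `distal_partner`, `type` (`"tandem"` or `"robertsonian"`) and
#'   optionally `age_class` (`"C1"`..`"C5"`).
#' @param seed Integer seed (retained-telomere lengths and remnant gaps).
#' @return A list with `genome` (the derived `sim_genome`) and `truth`
#'   (list of `segments` — derived-coordinate layout of ancestral
#'   segments — and `sites` — one row per fusion junction with `chrom`,
#'   `position`, `type`, `age_class`, `gap`, `upstream_ancestral`,
#'   `downstream_ancestral`).
#' @export
apply_fusion_plan <- function(genome, plan, seed = 1) {
  plan <- as_tibble(plan)
  if (nrow(plan) > 0 && !"age_class" %in% names(plan)) plan$age_class <- NA_character_
  withr::local_seed(seed)

  states <- purrr::imap(as.list(genome$seqs), function(s, nm) {
    fe <- filter(genome$features, .data$chrom == nm) %>% select(-"chrom")
    en <- filter(genome$ends, .data$chrom == nm)
    list(
      name = nm, seq = s, features = fe,
      segments = tibble(
        start = 0, end = nchar(s), ancestral = nm,
        anc_start = 0, anc_end = nchar(s), orientation = "+"
      ),
      left_end = en$left_end, right_end = en$right_end,
      sites = tibble(
        position = numeric(0), type = character(0), age_class = character(0),
        gap = numeric(0), upstream_ancestral = character(0),
        downstream_ancestral = character(0)
      )
    )
  })

  for (k in seq_len(nrow(plan))) {
    cen <- plan$centromeric_partner[k]
    dis <- plan$distal_partner[k]
    typ <- plan$type[k]
    if (!cen %in% names(states) || !dis %in% names(states)) {
      abort(sprintf("fusion plan row %d references a missing chromosome", k))
    }
    X <- states[[cen]] # contributes its centromeric head
    Y <- states[[dis]] # contributes distal telomere (tandem) or second head

    if (typ == "tandem") {
      if (Y$right_end != "distal") {
        if (Y$left_end == "distal") Y <- flip_state(Y) else {
          abort(sprintf("plan row %d: '%s' has no free distal end", k, dis))
        }
      }
      if (X$left_end != "centromeric") {
        if (X$right_end == "centromeric") X <- flip_state(X) else {
          abort(sprintf("plan row %d: '%s' has no free centromeric end", k, cen))
        }
      }
      # cut Y's terminal distal telomere back to a short retained tract
      lastf <- dplyr::slice_tail(arrange(Y$features, .data$start), n = 1)
      if (lastf$label != "telomere") {
        abort(sprintf("plan row %d: '%s' does not end in a telomere", k, dis))
      }
      keep <- sample(20:300, 1)
      new_len <- lastf$start + keep
      Y$seq <- substr(Y$seq, 1, new_len)
      Y$features$end[nrow(Y$features)] <- new_len
      Y$segments$end[nrow(Y$segments)] <- new_len
      seg_n <- nrow(Y$segments)
      cut_off <- lastf$end - new_len
      if (Y$segments$orientation[seg_n] == "+") {
        Y$segments$anc_end[seg_n] <- Y$segments$anc_end[seg_n] - cut_off
      } else {
        Y$segments$anc_start[seg_n] <- Y$segments$anc_start[seg_n] + cut_off
      }

      # delete X's head arrays up to (not including) its satI array
      satI_start <- min(filter(X$features, .data$label == "satI")$start)
      X$seq <- substr(X$seq, satI_start + 1, nchar(X$seq))
      X$features <- X$features %>%
        filter(.data$end > satI_start) %>%
        shift_tbl(-satI_start)
      Xseg <- X$segments %>% filter(.data$end > satI_start)
      trim <- pmax(0, satI_start - Xseg$start)
      Xseg$anc_start <- Xseg$anc_start + if_else(Xseg$orientation == "+", trim, 0)
      Xseg$anc_end <- Xseg$anc_end - if_else(Xseg$orientation == "-", trim, 0)
      Xseg <- shift_tbl(mutate(Xseg, start = pmax(.data$start, satI_start)), -satI_start)
      X$segments <- Xseg
      if (nrow(X$sites) > 0) X$sites$position <- X$sites$position - satI_start

      gap <- sample(0:400, 1)
      gap_seq <- if (gap > 0) rand_dna(gap) else ""
      ylen <- nchar(Y$seq)
      new <- list(
        name = Y$name,
        seq = paste0(Y$seq, gap_seq, X$seq),
        features = bind_rows(
          Y$features,
          if (gap > 0) tibble(start = ylen, end = ylen + gap, label = "unique"),
          shift_tbl(X$features, ylen + gap)
        ),
        segments = bind_rows(Y$segments, shift_tbl(X$segments, ylen + gap)),
        left_end = Y$left_end, right_end = X$right_end,
        sites = bind_rows(
          Y$sites,
          mutate(X$sites, position = .data$position + ylen + gap),
          tibble(
            position = ylen + gap %/% 2, type = "tandem",
            age_class = plan$age_class[k], gap = gap,
            upstream_ancestral = Y$segments$ancestral[nrow(Y$segments)],
            downstream_ancestral = X$segments$ancestral[1]
          )
        )
      )
    } else if (typ == "robertsonian") {
      if (Y$right_end != "centromeric") {
        if (Y$left_end == "centromeric") Y <- flip_state(Y) else {
          abort(sprintf("plan row %d: '%s' has no free centromeric end", k, dis))
        }
      }
      if (X$left_end != "centromeric") {
        if (X$right_end == "centromeric") X <- flip_state(X) else {
          abort(sprintf("plan row %d: '%s' has no free centromeric end", k, cen))
        }
      }
      ylen <- nchar(Y$seq)
      new <- list(
        name = Y$name,
        seq = paste0(Y$seq, X$seq),
        features = bind_rows(Y$features, shift_tbl(X$features, ylen)),
        segments = bind_rows(Y$segments, shift_tbl(X$segments, ylen)),
        left_end = Y$left_end, right_end = X$right_end,
        sites = bind_rows(
          Y$sites,
          mutate(X$sites, position = .data$position + ylen),
          tibble(
            position = ylen, type = "robertsonian",
            age_class = plan$age_class[k], gap = 0,
            upstream_ancestral = Y$segments$ancestral[nrow(Y$segments)],
            downstream_ancestral = X$segments$ancestral[1]
          )
        )
      )
    } else {
      abort(sprintf("unknown fusion type '%s'", typ))
    }
    states[[dis]] <- NULL
    states[[cen]] <- NULL
    states[[new$name]] <- new
  }

  seqs <- vapply(states, function(s) s$seq, "")
  names(seqs) <- vapply(states, function(s) s$name, "")
  derived <- list(
    seqs = seqs,
    features = bind_rows(purrr::map(states, function(s) {
      mutate(s$features, chrom = s$name, .before = 1)
    })),
    ends = tibble(
      chrom = names(seqs),
      left_end = vapply(states, function(s) s$left_end, ""),
      right_end = vapply(states, function(s) s$right_end, "")
    ),
    monomers = genome$monomers,
    chrom_lengths = setNames(nchar(seqs), names(seqs))
  )
  class(derived) <- "sim_genome"

  truth <- list(
    segments = bind_rows(purrr::map(states, function(s) {
      mutate(s$segments, chrom = s$name, .before = 1)
    })),
    sites = {
      st <- bind_rows(purrr::map(states, function(s) {
        if (nrow(s$sites) > 0) mutate(s$sites, chrom = s$name, .before = 1)
      }))
      if (nrow(st) == 0) {
        tibble(chrom = character(0), position = numeric(0),
               type = character(0), age_class = character(0),
               gap = numeric(0), upstream_ancestral = character(0),
               downstream_ancestral = character(0))
      } else {
        arrange(st, .data$chrom, .data$position)
      }
    }
  )
  list(genome = derived, truth = truth)
}

#' Synteny blocks implied by a fusion truth
#'
#' Emits one alignment block per ancestral segment of the derived genome
#' (reference side = derived coordinates, query side = ancestral
#' coordinates), the noise-free synteny table that a whole-genome aligner
#' would ideally produce.
#'
#' @param truth The `truth` element returned by [apply_fusion_plan()].
#' @return Tibble with columns `ref_chrom, ref_start, ref_end, qry_chrom,
#'   qry_start, qry_end, orientation`.
#' @export
truth_synteny_blocks <- function(truth) {
  truth$segments %>%
    dplyr::transmute(
      ref_chrom = .data$chrom, ref_start = .data$start, ref_end = .data$end,
      qry_chrom = .data$ancestral, qry_start = .data$anc_start,
      qry_end = .data$anc_end, orientation = .data$orientation
    )
}
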