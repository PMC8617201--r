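#' Filter synteny blocks by reference-side length
#'
#' Short syntenic fragments are discarded before fusion detection so that
#' small interleaved rearrangements do not split a fusion junction into
#' spurious events. Typical per-species-pair cutoffs are 8, 14, 35 and
#' 55 kb depending on divergence (see [karyofuse_thresholds()]).
#'
#' @param blocks Tibble of synteny blocks with columns `ref_chrom,
#'   ref_start, ref_end, qry_chrom, qry_start, qry_end, orientation`
#'   (0-based half-open bp).
#' @param min_len Minimum reference-side block length in bp (>= 0).
#' @return The retained blocks, input order preserved.
#' @export
filter_blocks <- function(blocks, min_len) {
  stopifnot(min_len >= 0)
  filter(blocks, .data$ref_end - .data$ref_start >= min_len)
}

#' Detect fusion events from filtered synteny blocks
#'
#' Scans blocks along each derived (reference-side) chromosome in
#' coordinate order and emits one event per adjacent block pair whose
#' query (ancestral) chromosomes differ. The event position is the
#' midpoint of the inter-block gap — unbiased under symmetric block
#' erosion.
#'
#' @param blocks Filtered synteny blocks (see [filter_blocks()]); reference
#'   side = derived genome, query side = ancestral genome.
#' @return Tibble of events: `derived_chrom, position, upstream_ancestral,
#'   downstream_ancestral, upstream_orientation, downstream_orientation,
#'   upstream_qry_meet, downstream_qry_meet` (ancestral bp coordinate of
#'   each partner's junction-facing end), sorted by derived coordinate.
#'   Type and age class are assigned by [classify_fusion_type()] and
#'   [assign_age_classes()].
#' @export
detect_fusion_events <- function(blocks) {
  if (nrow(blocks) == 0) {
    return(tibble(
      derived_chrom = character(0), position = numeric(0),
      upstream_ancestral = character(0), downstream_ancestral = character(0),
      upstream_orientation = character(0), downstream_orientation = character(0),
      upstream_qry_meet = numeric(0), downstream_qry_meet = numeric(0)
    ))
  }
  blocks %>%
    arrange(.data$ref_chrom, .data$ref_start) %>%
    group_by(.data$ref_chrom) %>%
    mutate(
      nxt_qry = lead(.data$qry_chrom),
      nxt_start = lead(.data$ref_start),
      nxt_ori = lead(.data$orientation),
      nxt_qs = lead(.data$qry_start),
      nxt_qe = lead(.data$qry_end)
    ) %>%
    ungroup() %>%
    filter(!is.na(.data$nxt_qry), .data$nxt_qry != .data$qry_chrom) %>%
    dplyr::transmute(
      derived_chrom = .data$ref_chrom,
      position = floor((.data$ref_end + .data$nxt_start) / 2),
      upstream_ancestral = .data$qry_chrom,
      downstream_ancestral = .data$nxt_qry,
      upstream_orientation = .data$orientation,
      downstream_orientation = .data$nxt_ori,
      # ancestral coordinate of the junction-facing end of each partner
      upstream_qry_meet = if_else(.data$orientation == "+",
                                  .data$qry_end, .data$qry_start),
      downstream_qry_meet = if_else(.data$nxt_ori == "+",
                                    .data$nxt_qs, .data$nxt_qe)
    ) %>%
    arrange(.data$derived_chrom, .data$position)
}

#' Classify fusion events as tandem, Robertsonian or other
#'
#' A junction joining one ancestral chromosome's centromeric (apical) end
#' to the other's distal telomeric end is a tandem fusion; a junction
#' joining two centromeric ends is Robertsonian; two distal ends meeting is
#' reported as `"other"`. Which ancestral end faces the junction is read
#' off the block orientations recorded by [detect_fusion_events()]: the
#' junction-facing ancestral coordinate is compared with the chromosome
#' midpoint and matched against the centromere annotation (acrocentric
#' assumption: the centromere sits at one chromosome end).
#'
#' @param events Tibble from [detect_fusion_events()].
#' @param centromeres Tibble `chrom, centromeric_end` with
#'   `centromeric_end` in `{"left", "right"}` for every ancestral
#'   chromosome.
#' @param ancestral_lengths Named vector of ancestral chromosome lengths.
#' @return `events` with a `type` column in
#'   `{"tandem", "robertsonian", "other"}`.
#' @export
classify_fusion_type <- function(events, centromeres, ancestral_lengths) {
  missing <- setdiff(
    unique(c(events$upstream_ancestral, events$downstream_ancestral)),
    centromeres$chrom
  )
  if (length(missing) > 0) {
    abort(paste0("missing centromere annotation for: ",
                 paste(missing, collapse = ", ")))
  }
  end_kind <- function(anc, meet_pos) {
    cen <- centromeres$centromeric_end[match(anc, centromeres$chrom)]
    len <- ancestral_lengths[anc]
    near_left <- meet_pos < len / 2
    if_else(
      (near_left & cen == "left") | (!near_left & cen == "right"),
      "centromeric", "distal"
    )
  }
  up <- end_kind(events$upstream_ancestral, events$upstream_qry_meet)
  dn <- end_kind(events$downstream_ancestral, events$downstream_qry_meet)
  events %>% mutate(
    type = dplyr::case_when(
      up == "centromeric" & dn == "centromeric" ~ "robertsonian",
      xor(up == "centromeric", dn == "centromeric") ~ "tandem",
      TRUE ~ "other"
    )
  )
}

#' Assign phylogenetic age classes to fusion events
#'
#' Age classes follow nested species sharing along the phylogeny: a fusion
#' shared by all five species is oldest (C5); one shared by all but the
#' earliest-diverging species is C4; and so on down to C1, present only in
#' the focal species. Non-monotone presence patterns (a fusion "absent"
#' in an intermediate species but present in an earlier-diverging one) get
#' `"unassigned"` with a warning.
#'
#' @param events Event tibble with an `event_id` column (added if absent).
#' @param presence Tibble `event_id` x species columns (logical), species
#'   ordered from earliest-diverging to the focal species (the focal
#'   species column last, always TRUE).
#' @return `events` with an `age_class` column `"C1"`..`"C5"` (or
#'   `"unassigned"`).
#' @export
assign_age_classes <- function(events, presence) {
  if (!"event_id" %in% names(events)) {
    events <- mutate(events, event_id = row_number())
  }
  sp_cols <- setdiff(names(presence), "event_id")
  n_sp <- length(sp_cols)
  m <- as.matrix(presence[, sp_cols])
  # presence must be a suffix of the species order (focal species last)
  cls <- character(nrow(presence))
  for (r in seq_len(nrow(presence))) {
    pres <- m[r, ]
    k <- sum(pres)
    ok <- all(pres[(n_sp - k + 1):n_sp]) && (k == n_sp || !any(pres[seq_len(n_sp - k)]))
    if (k == 0 || !ok) {
      cls[r] <- "unassigned"
    } else {
      cls[r] <- paste0("C", k)
    }
  }
  if (any(cls == "unassigned")) {
    warn("non-monotone species-presence pattern(s); age class set to 'unassigned'")
  }
  left_join(events, tibble(event_id = presence$event_id, age_class = cls),
            by = "event_id")
}

#' Fusion rate in events per million years
#'
#' @param n_events Number of fusion events on a branch.
#' @param branch_time Branch duration in million years (> 0).
#' @return Events per million years.
#' @export
#' @examples
#' fusion_rate(10, 2) # 5
fusion_rate <- function(n_events, branch_time) {
  if (branch_time <= 0) abort("branch_time must be positive")
  n_events / branch_time
}

#' Read / write synteny blocks as TSV
#'
#' Seven tab-separated columns: `ref_chrom ref_start ref_end qry_chrom
#' qry_start qry_end strand`.
#'
#' @param path File path.
#' @return Tibble of blocks (reader) or `path` invisibly (writer).
#' @export
read_blocks_tsv <- function(path) {
  df <- utils::read.table(
    path, header = FALSE, sep = "\t",
    col.names = c("ref_chrom", "ref_start", "ref_end",
                  "qry_chrom", "qry_start", "qry_end", "orientation"),
    colClasses = c("character", "numeric", "numeric",
                   "character", "numeric", "numeric", "character")
  )
  as_tibble(df)
}

#' @rdname read_blocks_tsv
#' @param blocks Block tibble.
#' @export
write_blocks_tsv <- function(blocks, path) {
  utils::write.table(
    blocks[, c("ref_chrom", "ref_start", "ref_end",
               "qry_chrom", "qry_start", "qry_end", "orientation")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
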