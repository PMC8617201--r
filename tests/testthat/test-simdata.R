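test_that("ancestral chromosomes carry the centromeric repeat architecture in order", {
  g <- build_ancestral_genome(3, 1e5, seed = 1)
  expect_length(g$seqs, 3)
  for (ch in names(g$seqs)) {
    fe <- dplyr::filter(g$features, chrom == ch)
    expect_equal(
      fe$label,
      c("telomere", "satII", "satIV", "palindrome_arm", "truncated_telomere",
        "palindrome_arm", "satI", "unique", "telomere")
    )
    # non-overlapping, sorted, within bounds
    expect_true(all(fe$start < fe$end))
    expect_true(all(diff(fe$start) > 0))
    expect_true(all(utils::head(fe$end, -1) <= utils::tail(fe$start, -1) + 1e-9))
    expect_true(max(fe$end) == nchar(g$seqs[[ch]]))
    # truncated telomere strictly between satIV and satI
    tt <- fe[fe$label == "truncated_telomere", ]
    expect_true(tt$start > fe$end[fe$label == "satIV"][1] - 1)
    expect_true(tt$end < fe$start[fe$label == "satI"][1] + 1)
    # telomere arrays are tandem TTAGGG
    tel <- fe[fe$label == "telomere", ][1, ]
    tel_seq <- substr(g$seqs[[ch]], tel$start + 1, tel$end)
    expect_equal(tel_seq, strrep("TTAGGG", nchar(tel_seq) / 6))
    # palindrome arms are reverse complements of each other
    arms <- fe[fe$label == "palindrome_arm", ]
    a1 <- substr(g$seqs[[ch]], arms$start[1] + 1, arms$end[1])
    a2 <- substr(g$seqs[[ch]], arms$start[2] + 1, arms$end[2])
    expect_equal(a2, as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(a1))
    ))
  }
})

test_that("genome generation is byte-identical given a seed and errors when too small", {
  g1 <- build_ancestral_genome(2, 5e4, seed = 7)
  g2 <- build_ancestral_genome(2, 5e4, seed = 7)
  f1 <- tempfile(fileext = ".fa")
  f2 <- tempfile(fileext = ".fa")
  write_genome_fasta(g1, f1)
  write_genome_fasta(g2, f2)
  expect_identical(readLines(f1), readLines(f2))
  g3 <- build_ancestral_genome(2, 5e4, seed = 8)
  expect_false(identical(g1$seqs, g3$seqs))
  expect_error(build_ancestral_genome(1, 1e4), "too small")
})

test_that("tandem fusion deletes head arrays and leaves satI near a partial telomere", {
  fx <- small_fusion_fixture(n_chrom = 3, n_fused = 2, seed = 3)
  sites <- fx$fz$truth$sites
  expect_equal(nrow(sites), 1)
  expect_equal(sites$type, "tandem")
  expect_lt(sites$gap, 500)
  # junction-side features on the derived chromosome: a telomere remnant
  # of 20-300 bp then (after the gap) a satI array
  fe <- dplyr::filter(fx$fz$genome$features, chrom == sites$chrom) %>%
    dplyr::arrange(start)
  tel_rem <- fe %>% dplyr::filter(label == "telomere", end <= sites$position + 500) %>%
    dplyr::slice_tail(n = 1)
  expect_true(tel_rem$end - tel_rem$start >= 20 &&
                tel_rem$end - tel_rem$start <= 300)
  nxt <- fe %>% dplyr::filter(start >= tel_rem$end, label != "unique") %>%
    dplyr::slice_head(n = 1)
  expect_equal(nxt$label, "satI")
  expect_lt(nxt$start - tel_rem$end, 500)
  # deleted classes do not appear between the remnant telomere and satI
  between <- fe %>% dplyr::filter(start >= tel_rem$start, end <= nxt$end)
  expect_false(any(between$label %in%
                     c("satII", "satIV", "truncated_telomere", "palindrome_arm")))
})

test_that("fusion plans conserve counts, unique content, and reject bad plans", {
  anc <- build_ancestral_genome(4, 1e5, seed = 2)
  # empty plan: unchanged genome, no sites
  fz0 <- apply_fusion_plan(anc, tibble(centromeric_partner = character(0),
                                       distal_partner = character(0),
                                       type = character(0)), seed = 1)
  expect_identical(fz0$genome$seqs, anc$seqs)
  expect_equal(nrow(fz0$truth$sites), 0)
  # chromosome count bookkeeping: n_sites = n_anc - n_derived
  plan <- tibble(centromeric_partner = c("anc2", "anc4"),
                 distal_partner = c("anc1", "anc3"),
                 type = c("tandem", "robertsonian"))
  fz <- apply_fusion_plan(anc, plan, seed = 1)
  expect_equal(nrow(fz$truth$sites), length(anc$seqs) - length(fz$genome$seqs))
  # unique-sequence conservation (gap insertions only add unique bp)
  uniq <- function(g) sum(with(dplyr::filter(g$features, label == "unique"),
                               end - start))
  expect_gte(uniq(fz$genome), uniq(anc))
  # a consumed chromosome cannot be fused again
  bad <- tibble(centromeric_partner = c("anc2", "anc2"),
                distal_partner = c("anc1", "anc3"), type = "tandem")
  expect_error(apply_fusion_plan(anc, bad, seed = 1), "missing chromosome")
  # a Robertsonian product has no centromeric end left for tandem fusion
  bad2 <- tibble(centromeric_partner = c("anc2", "anc1"),
                 distal_partner = c("anc1", "anc3"),
                 type = c("robertsonian", "tandem"))
  expect_error(apply_fusion_plan(anc, bad2, seed = 1), "centromeric end")
})

test_that("simulated contact maps follow the decay/depth model", {
  grid <- bin_grid(c(chr1 = 4e6), 1e5) # 40 bins
  m <- simulate_contact_map(grid, params = hic_sim_params(depth = 1e6, seed = 4))
  tot <- sum(m$counts$count)
  expect_lt(abs(tot - 1e6), 3 * sqrt(1e6))
  # pure decay: distance-stratified means decrease and match the power law
  d <- m$counts$bin_j - m$counts$bin_i
  mean_d <- vapply(c(1, 4, 16), function(dd) {
    sum(m$counts$count[d == dd]) / (40 - dd)
  }, 1)
  expect_true(all(diff(mean_d) < 0))
  expect_equal(mean_d[1] / mean_d[2], (4 + 1) / (1 + 1), tolerance = 0.1)
})

test_that("planted loops enrich their cell by about the loop fold", {
  grid <- bin_grid(c(chr1 = 2e6), 1e5) # 20 bins
  loop <- tibble(bin_i = 5, bin_j = 15)
  ratios <- vapply(1:100, function(s) {
    m <- simulate_contact_map(grid, loops = loop,
                              params = hic_sim_params(loop_fold = 8,
                                                      depth = 2e5, seed = s))
    d <- m$counts$bin_j - m$counts$bin_i
    loop_count <- sum(m$counts$count[m$counts$bin_i == 5 &
                                       m$counts$bin_j == 15])
    other <- (sum(m$counts$count[d == 10]) - loop_count) / (20 - 10 - 1)
    c(loop_count, other)
  }, c(1, 1))
  expect_equal(mean(ratios[1, ]) / mean(ratios[2, ]), 8, tolerance = 0.15)
})

test_that("simulated reads carry exact truth projections", {
  fx <- small_fusion_fixture(seed = 5)
  rd <- simulate_reads(fx$fz$genome, 50, mean_len = 5000, error_rate = 0,
                       seed = 6)
  expect_equal(nrow(rd$reads), 50)
  expect_equal(rd$reads$length, nchar(rd$reads$sequence))
  # zero reads is not an error
  expect_equal(nrow(simulate_reads(fx$fz$genome, 0, 5000)$reads), 0)
  # a read fully inside a satI array has a single satI truth interval
  satI <- fx$fz$genome$features %>%
    dplyr::filter(label == "satI") %>% dplyr::slice(1)
  sq <- substr(fx$fz$genome$seqs[[satI$chrom]], satI$start + 101,
               satI$start + 600)
  tr <- rd$truth %>% dplyr::filter(read_id == rd$reads$read_id[1])
  expect_true(all(tr$read_end <= rd$reads$length[1]))
  # FASTQ writer emits one record per read
  fq <- tempfile(fileext = ".fq")
  write_reads_fastq(rd$reads, fq)
  expect_equal(length(readLines(fq)), 4 * 50)
  rr <- read_reads(fq)
  expect_equal(rr$sequence, rd$reads$sequence)
})

test_that("reads spanning a tandem junction see the remnant satI-telomere gap", {
  fx <- small_fusion_fixture(n_chrom = 3, n_fused = 2, seed = 9)
  site <- fx$fz$truth$sites[1, ]
  # construct a read centred on the junction via the simulator's genome
  rd <- simulate_reads(fx$fz$genome, 400, mean_len = 6000, error_rate = 0,
                       seed = 10)
  spans <- rd$reads %>%
    dplyr::filter(chrom == site$chrom, start < site$position - 1000,
                  end > site$position + 1000)
  expect_gt(nrow(spans), 0)
  tr <- rd$truth %>% dplyr::filter(read_id == spans$read_id[1])
  expect_true("satI" %in% tr$label && "telomere" %in% tr$label)
  tel <- tr %>% dplyr::filter(label == "telomere")
  s1 <- tr %>% dplyr::filter(label == "satI")
  gap <- min(vapply(seq_len(nrow(tel)), function(a) {
    min(abs(c(tel$read_start[a] - s1$read_end, s1$read_start - tel$read_end[a])))
  }, 1))
  expect_equal(gap, site$gap)
})

test_that("planted male-specific sites pass the filter and backgrounds do not", {
  vp <- variant_sim_params("anc1", 0, 2e4, n_male_specific = 120,
                           male_specific_neoY_fraction = 1,
                           background_rate = 2e-4, seed = 11)
  vt <- simulate_variant_table(c(anc1 = 1e5, anc2 = 1e5), vp)
  expect_true(all(vt$truth$sites$in_neoy))
  ms <- suppressMessages(call_male_specific_small_variants(vt$genotypes))
  key <- function(d) paste(d$chrom, d$pos)
  expect_setequal(key(ms), key(vt$truth$sites))
  # background-only table -> empty call set
  vp0 <- variant_sim_params("anc1", 0, 2e4, n_male_specific = 0,
                            background_rate = 2e-4, seed = 12)
  vt0 <- simulate_variant_table(c(anc1 = 1e5, anc2 = 1e5), vp0)
  expect_equal(nrow(suppressMessages(
    call_male_specific_small_variants(vt0$genotypes)
  )), 0)
  # depths of planted sites within range
  planted <- vt$genotypes %>% dplyr::semi_join(
    tibble(chrom = vt$truth$sites$chrom, pos = vt$truth$sites$pos),
    by = c("chrom", "pos")
  )
  dp <- as.matrix(planted[, paste0("dp_", c("F1", "F2", "M1", "M2", "O1", "O2"))])
  expect_true(all(dp >= 15 & dp <= 100))
})

test_that("allele-count simulation matches its stated ratios", {
  # balanced: pooled totals within 3 sigma binomial
  ac <- simulate_allele_counts(50, snps_per_gene = 4, imbalance = 1,
                               depth = 40, seed = 13)
  tx <- sum(ac$counts$neoX)
  ty <- sum(ac$counts$neoY)
  expect_lt(abs(tx - ty), 3 * sqrt(tx + ty))
  # 3:1 imbalance flagged in >= 90% of 200 seeds
  hits <- vapply(1:200, function(s) {
    one <- simulate_allele_counts(1, snps_per_gene = 4, imbalance = 3,
                                  depth = 40, seed = s)
    res <- allele_specific_expression(one$counts)
    nrow(res) == 1 && res$different
  }, TRUE)
  expect_gte(mean(hits), 0.9)
  # single-SNP genes are excluded downstream regardless of ratio
  one <- simulate_allele_counts(1, snps_per_gene = 1, imbalance = 10,
                                depth = 80, seed = 14)
  expect_equal(nrow(allele_specific_expression(one$counts)), 0)
})
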