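lib <- monomer_library(seed = 99)

test_that("monomer arrays and telomere tracts are recovered as single hits", {
  # exact satI monomer x3 -> one merged satI hit covering the read
  read <- strrep(lib[["satI"]], 3)
  h <- scan_read(read, lib)
  h1 <- dplyr::filter(h, cls == "satI")
  expect_equal(nrow(h1), 1)
  expect_equal(h1$read_start, 0)
  expect_equal(h1$read_end, nchar(read))
  expect_equal(h1$identity, 1)
  # (TTAGGG) x20 -> one 120 bp telomere hit
  tel <- strrep("TTAGGG", 20)
  h2 <- scan_read(tel, lib)
  expect_equal(nrow(h2), 1)
  expect_equal(h2$cls, "telomere")
  expect_equal(h2$read_end - h2$read_start, 120)
  # reverse-complement orientation is found too
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  h3 <- scan_read(rc, lib)
  expect_equal(dplyr::filter(h3, cls == "satI")$read_end, nchar(read))
  expect_equal(nrow(scan_read("", lib)), 0)
})

test_that("pattern codes follow the strict 30 bp rule in the stated bit order", {
  reads <- tibble(read_id = c("r1", "r2", "r3"))
  hits <- dplyr::bind_rows(
    # satI 40 + satIV 35 + telomere 60 -> "1011"
    tibble(read_id = "r1", cls = c("satI", "satIV", "telomere"),
           read_start = c(0, 100, 200), read_end = c(40, 135, 260),
           identity = 1),
    # satI 25 only -> below threshold -> "0000"
    tibble(read_id = "r2", cls = "satI", read_start = 0, read_end = 25,
           identity = 1),
    # telomere 100 only -> "0001"
    tibble(read_id = "r3", cls = "telomere", read_start = 0, read_end = 100,
           identity = 1)
  )
  pat <- encode_patterns(hits, reads)
  expect_equal(pat$code[match(c("r1", "r2", "r3"), pat$read_id)],
               c("1011", "0000", "0001"))
  # exactly 30 bp does not set the bit (strictly more than 30)
  pat30 <- encode_patterns(
    tibble(read_id = "x", cls = "satII", read_start = 0, read_end = 30,
           identity = 1),
    tibble(read_id = "x")
  )
  expect_equal(pat30$code, "0000")
  # hit order does not matter; overlapping same-class hits merge
  shuffled <- hits[c(3, 1, 2, 4, 5), ]
  expect_equal(dplyr::arrange(encode_patterns(shuffled, reads), read_id),
               dplyr::arrange(pat, read_id))
})

test_that("the pattern census covers all 16 codes and sums to one", {
  pat <- tibble(read_id = paste0("r", 1:10), code = "0001")
  cz <- pattern_census(pat)
  expect_equal(nrow(cz), 16)
  expect_equal(cz$proportion[cz$code == "0001"], 1)
  expect_equal(sum(cz$proportion), 1)
  mixed <- tibble(read_id = paste0("r", 1:8),
                  code = c(rep("1001", 3), rep("0000", 4), "1111"))
  expect_equal(sum(pattern_census(mixed)$proportion), 1)
  expect_equal(nrow(pattern_census(pat[0, ])), 0)
})

test_that("satI-telomere distances split exactly at 500 bp", {
  mk <- function(id, gap) {
    dplyr::bind_rows(
      tibble(read_id = id, cls = "satI", read_start = 0, read_end = 1000,
             identity = 1),
      tibble(read_id = id, cls = "telomere", read_start = 1000 + gap,
             read_end = 1100 + gap, identity = 1)
    )
  }
  hits <- dplyr::bind_rows(mk("a", 499), mk("b", 500), mk("c", -50))
  pat <- tibble(read_id = c("a", "b", "c"), code = "1001")
  d <- sat1_telomere_distance(pat, hits)
  expect_equal(d$distance[d$read_id == "a"], 499)
  expect_equal(d$category[d$read_id == "a"], "<500")
  expect_equal(d$category[d$read_id == "b"], ">=500")
  # overlapping hits -> distance 0 -> juxtaposed
  expect_equal(d$distance[d$read_id == "c"], 0)
  expect_equal(d$category[d$read_id == "c"], "<500")
  # a read with the right code but no satI hit errors
  expect_error(
    sat1_telomere_distance(tibble(read_id = "z", code = "1001"),
                           mk("a", 10)),
    "lacks"
  )
})

test_that("telomere totals and end-position classes are computed per read", {
  reads <- tibble(read_id = c("r1", "r2"), length = c(30000, 10000))
  hits <- dplyr::bind_rows(
    tibble(read_id = "r1", cls = "telomere",
           read_start = c(5000, 9000, 15000),
           read_end = c(5020, 9010, 15008), identity = 1),
    tibble(read_id = "r2", cls = "telomere", read_start = 0, read_end = 600,
           identity = 1),
    tibble(read_id = "r1", cls = "satI", read_start = 100, read_end = 400,
           identity = 1)
  )
  pat <- encode_patterns(hits, reads)
  ts <- telomere_length_summary(pat, hits, reads, codes = NULL)
  # 20 + 10 + 8 bp -> total 38
  expect_equal(ts$read_totals$total_telomere[ts$read_totals$read_id == "r1"],
               38)
  # a hit starting at position 0 is near-end; interior hits are middle
  pos <- ts$hit_positions
  expect_equal(pos$position_class[pos$read_id == "r2"], "near-end")
  expect_true(all(pos$position_class[pos$read_id == "r1"] == "middle"))
})

test_that("truncated telomeres in centromeric-head reads sit in the middle", {
  # long reads over the centromeric head: the truncated telomeric tract is
  # flanked by the satIV and satI arrays, so reads carrying both flanks
  # hold it internally, away from the read termini
  g <- build_ancestral_genome(2, 1e5, seed = 101)
  rd <- simulate_reads(g, 600, mean_len = 2e4, error_rate = 0, seed = 102)
  hits <- scan_reads(rd$reads, g$monomers)
  pat <- encode_patterns(hits, rd$reads)
  ts <- telomere_length_summary(pat, hits, rd$reads, codes = NULL)
  short <- ts$hit_positions %>%
    dplyr::semi_join(dplyr::filter(pat, substr(code, 1, 1) == "1" &
                                     substr(code, 3, 3) == "1"),
                     by = "read_id") %>%
    dplyr::filter(read_end - read_start < 100)
  expect_gt(nrow(short), 10)
  expect_gte(mean(short$position_class == "middle"), 0.8)
})

test_that("planted palindromes are found and random reads stay clean", {
  withr::with_seed(103, {
    # planted 50 bp arms with assorted spacers
    hits_found <- vapply(1:30, function(k) {
      X <- rand_seq(50)
      sp <- rand_seq(sample(0:500, 1))
      read <- paste0(rand_seq(400), X, sp,
                     as.character(Biostrings::reverseComplement(
                       Biostrings::DNAString(X))), rand_seq(400))
      h <- detect_palindromes(read, min_arm = 30)
      nrow(h) >= 1 && abs(h$left_start[1] - 400) <= 5 &&
        h$arm[1] >= 45 && h$spacer[1] <= nchar(sp) + 10
    }, TRUE)
    expect_equal(mean(hits_found), 1)
    # seeded uniform-random 10 kb reads: zero hits at min_arm = 30
    clean <- vapply(1:15, function(k) {
      nrow(detect_palindromes(rand_seq(10000), min_arm = 30))
    }, 1L)
    expect_true(all(clean == 0))
  })
})

test_that("simulated truncated-telomere palindromes flank the telomere tract", {
  g <- build_ancestral_genome(2, 1e5, seed = 104)
  rd <- simulate_reads(g, 200, mean_len = 6000, error_rate = 0, seed = 105)
  hits <- scan_reads(rd$reads, g$monomers)
  pat <- encode_patterns(hits, rd$reads)
  pal <- detect_palindromes_reads(rd$reads, min_arm = 30, max_spacer = 2000)
  ff <- palindrome_flank_fraction(pat, hits, pal)
  # reads carrying the full arm-telomere-arm cassette have the telomere
  # inside a palindrome spacer; the planted flanking rate is 1 for reads
  # covering the whole cassette, so the fraction is high but < 1 because
  # partial cassettes also enter the denominator
  expect_gt(ff$fraction, 0.5)
  # all-flanked and none-flanked degenerate cases
  pat1 <- tibble(read_id = "p", code = "1001")
  hit1 <- dplyr::bind_rows(
    tibble(read_id = "p", cls = "satI", read_start = 0, read_end = 500,
           identity = 1),
    tibble(read_id = "p", cls = "telomere", read_start = 700, read_end = 740,
           identity = 1)
  )
  pal1 <- tibble(read_id = "p", left_start = 550, left_end = 650,
                 right_start = 800, right_end = 900, arm = 100, spacer = 150,
                 identity = 1)
  expect_equal(palindrome_flank_fraction(pat1, hit1, pal1)$fraction, 1)
  expect_equal(palindrome_flank_fraction(pat1, hit1, pal1[0, ])$fraction, 0)
  expect_error(palindrome_flank_fraction(pat1[0, ], hit1, pal1), "no reads")
})

test_that("pattern codes agree with truth on simulated reads", {
  fx <- small_fusion_fixture(n_chrom = 3, n_fused = 3, seed = 106)
  # error-free: exact agreement
  rd <- simulate_reads(fx$fz$genome, 150, mean_len = 8000, error_rate = 0,
                       seed = 107)
  pat <- encode_patterns(scan_reads(rd$reads, fx$fz$genome$monomers),
                         rd$reads)
  tru <- encode_patterns(truth_pattern_hits(rd$truth), rd$reads,
                         cls_col = "cls")
  expect_equal(mean(pat$code == tru$code), 1)
  # 5% substitution error: >= 90% agreement
  rd5 <- simulate_reads(fx$fz$genome, 150, mean_len = 8000,
                        error_rate = 0.05, seed = 108)
  pat5 <- encode_patterns(scan_reads(rd5$reads, fx$fz$genome$monomers),
                          rd5$reads)
  tru5 <- encode_patterns(truth_pattern_hits(rd5$truth), rd5$reads,
                          cls_col = "cls")
  expect_gte(mean(pat5$code == tru5$code), 0.9)
})

test_that("fused genomes show more satI-telomere juxtaposition than ancestors", {
  anc <- build_ancestral_genome(3, 2e5, seed = 109)
  plan <- tibble(centromeric_partner = c("anc2", "anc3"),
                 distal_partner = "anc1", type = "tandem")
  fz <- apply_fusion_plan(anc, plan, seed = 110)
  juxta_rate <- function(genome, seed) {
    rd <- simulate_reads(genome, 250, mean_len = 7000, error_rate = 0,
                         seed = seed)
    hits <- scan_reads(rd$reads, genome$monomers)
    pat <- encode_patterns(hits, rd$reads)
    d <- sat1_telomere_distance(pat, hits)
    if (nrow(d) == 0) return(c(0, 0))
    c(sum(d$category == "<500"), nrow(d))
  }
  f <- juxta_rate(fz$genome, 111)
  a <- juxta_rate(anc, 112)
  # fused junctions put satI next to a telomere remnant; the unfused
  # ancestor keeps them far apart (or yields no 1001 reads at all)
  expect_gt(f[1], 0)
  expect_gte(f[1] / max(f[2], 1), a[1] / max(a[2], 1))
})
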