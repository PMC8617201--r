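test_that("binomial p-values match the brute-force oracle on small matrices", {
  grid <- bin_grid(c(chr1 = 30 * 2e4, chr2 = 20 * 2e4), 2e4)
  # dense counts strictly decreasing in distance (plus a small parity
  # wiggle), so per-distance means are monotone and isotonic smoothing is
  # provably a no-op: the expected model reduces to the per-distance mean
  # the oracle recomputes from scratch
  cells <- tidyr::crossing(bin_i = 1:50, bin_j = 1:50) %>%
    dplyr::filter(bin_j > bin_i,
                  grid$chrom[bin_i] == grid$chrom[bin_j]) %>%
    dplyr::mutate(count = 40 - (bin_j - bin_i) + bin_i %% 2)
  m <- matrix_from_cells(grid, cells)
  calls <- call_significant_interactions(m, p_max = 1, q_max = 1,
                                         min_reads = 1, n_strata = 1e6)
  expect_equal(nrow(calls), attr(calls, "n_tested"))
  po <- oracle_pvalues(m)
  cmp <- dplyr::inner_join(
    calls,
    dplyr::filter(m$counts, bin_i != bin_j) %>% dplyr::mutate(po = po),
    by = c("bin_i", "bin_j")
  )
  expect_equal(nrow(cmp), nrow(calls))
  expect_lt(max(abs(cmp$p - cmp$po)), 1e-12)
})

test_that("pairs with nine read-pairs are never called, whatever their p", {
  grid <- bin_grid(c(chr1 = 40 * 2e4), 2e4)
  # flat background of single counts plus one 9-count pair
  cells <- tibble(bin_i = 1:30, bin_j = (1:30) + 9, count = 1) %>%
    dplyr::bind_rows(tibble(bin_i = 2, bin_j = 30, count = 9))
  m <- matrix_from_cells(grid, cells)
  calls <- call_significant_interactions(m, p_max = 1, q_max = 1,
                                         min_reads = 10)
  expect_false(any(calls$count == 9))
  expect_equal(nrow(calls), 0)
  # with the inclusive reading (min_reads = 9) the same pair is reportable
  calls9 <- call_significant_interactions(m, p_max = 1, q_max = 1,
                                          min_reads = 9)
  expect_true(any(calls9$count == 9))
})

test_that("no-signal matrices produce (almost) no q<=0.01 calls", {
  grid <- bin_grid(c(chr1 = 80 * 2e4), 2e4)
  frac <- vapply(1:50, function(s) {
    m <- simulate_contact_map(grid, params = hic_sim_params(depth = 2e5,
                                                            seed = s))
    calls <- call_significant_interactions(m, min_reads = 1)
    nrow(calls) / attr(calls, "n_tested")
  }, 1)
  expect_lte(mean(frac), 0.01)
})

test_that("planted 8x loops are recalled and counts match expectations", {
  grid <- bin_grid(c(chr1 = 200 * 2e4), 2e4)
  withr::with_seed(62, {
    loops <- tibble(bin_i = sample(1:80, 25),
                    bin_j = sample(110:200, 25))
  })
  m <- simulate_contact_map(grid, loops = loops,
                            params = hic_sim_params(loop_fold = 8,
                                                    depth = 1e6, seed = 63))
  calls <- call_significant_interactions(m)
  key <- function(i, j) paste(i, j)
  recall <- mean(key(loops$bin_i, loops$bin_j) %in%
                   key(calls$bin_i, calls$bin_j))
  expect_gte(recall, 0.9)
  expect_true(all(calls$count >= 10 & calls$p <= 0.01 & calls$q <= 0.01))
})

test_that("length profiles bin on log10 windows with min-max scaling", {
  res <- 2e4
  mk_calls <- function(lengths) {
    tibble(chrom = "chr1", bin_i = 1, bin_j = 1 + lengths / res,
           count = 10, expected = 1, p = 0, q = 0, length = lengths)
  }
  # a single 1 Mb call -> all mass in the [6.0, 6.1) window
  pr <- normalized_length_profile(mk_calls(1e6))
  expect_equal(pr$n[pr$window_lo == 6.0], 1)
  expect_equal(sum(pr$n), 1)
  # min-max formula on three windows
  lens <- c(rep(1.0e6, 5), rep(1.35e6, 10), rep(1.65e6, 15))
  pr2 <- normalized_length_profile(mk_calls(lens))
  nz <- pr2 %>% dplyr::filter(n > 0) %>% dplyr::arrange(n)
  expect_equal(nz$normalized, c(0, 0.5, 1))
  # duplicating every call leaves the normalized profile unchanged
  pr3 <- normalized_length_profile(mk_calls(rep(lens, 2)))
  expect_equal(pr3$normalized, pr2$normalized)
  expect_error(normalized_length_profile(mk_calls(1e6)[0, ]), "no interaction")
})

test_that("long-range calls classify by end compartments with strict 5 Mb", {
  labels <- tibble(bin = 1:600, chrom = "chr1",
                   eigen = rep(c(1, -1), 300),
                   label = rep(c("A", "B"), 300))
  labels$label[10] <- NA
  mk <- function(i, j) tibble(chrom = "chr1", bin_i = i, bin_j = j,
                              count = 10, expected = 1, p = 0, q = 0,
                              length = (j - i) * 2e4)
  calls <- dplyr::bind_rows(
    mk(1, 301),  # A end, A end, 6 Mb
    mk(2, 302),  # B-B, 6 Mb
    mk(1, 302),  # A-B, > 5 Mb
    mk(1, 251),  # exactly 5 Mb -> excluded
    mk(10, 311)  # NA end -> others
  )
  cl <- classify_long_range(calls, labels, min_length = 5e6)
  expect_equal(cl$n[cl$class == "A-A"], 1)
  expect_equal(cl$n[cl$class == "B-B"], 1)
  expect_equal(cl$n[cl$class == "A-B"], 1)
  expect_equal(cl$n[cl$class == "others"], 1)
  expect_equal(sum(cl$n), 4)
})

test_that("shared/specific partition matches an all-pairs brute-force oracle", {
  res <- 2e4
  grid <- bin_grid(c(c1 = 25 * res, c2 = 25 * res), res)
  imap <- identity_bin_map(grid)
  mk <- function(i, j) tibble(chrom = grid$chrom[i], bin_i = i, bin_j = j,
                              count = 10, expected = 1, p = 0, q = 0,
                              length = (j - i) * res)
  # worked cases: identical anchors, 1-bin offset, 2-bin offset
  focal <- dplyr::bind_rows(mk(3, 10), mk(5, 15), mk(30, 40))
  other <- dplyr::bind_rows(mk(3, 10), mk(6, 14), mk(30, 43))
  out <- map_interactions(focal, other, imap, slack = 1)
  expect_equal(out$shared, c(TRUE, TRUE, FALSE))
  # randomized instances against a brute-force double loop
  withr::with_seed(71, {
    for (rep in 1:10) {
      fi <- sort(sample(1:49, 8))
      fo <- sort(sample(1:49, 8))
      focal <- dplyr::bind_rows(lapply(1:4, function(k) {
        mk(min(fi[2 * k - 1], fi[2 * k]), max(fi[2 * k - 1], fi[2 * k]) + 1)
      }))
      other <- dplyr::bind_rows(lapply(1:4, function(k) {
        mk(min(fo[2 * k - 1], fo[2 * k]), max(fo[2 * k - 1], fo[2 * k]) + 1)
      }))
      got <- map_interactions(focal, other, imap, slack = 1)$shared
      want <- vapply(seq_len(nrow(focal)), function(a) {
        any(vapply(seq_len(nrow(other)), function(b) {
          abs(focal$bin_i[a] - other$bin_i[b]) <= 1 &&
            abs(focal$bin_j[a] - other$bin_j[b]) <= 1
        }, TRUE))
      }, TRUE)
      expect_equal(got, want)
    }
  })
})

test_that("fusion-spanning classes count junctions between anchors", {
  res <- 2e4
  grid <- bin_grid(c(d1 = 100 * res), res)
  segments <- tibble(chrom = "d1", start = c(0, 7e5, 1.4e6),
                     end = c(7e5, 1.4e6, 2e6),
                     ancestral = c("a1", "a2", "a3"))
  sites <- tibble(chrom = "d1", position = c(7e5, 1.4e6),
                  age_class = c("C1", "C4"))
  mk <- function(i, j) tibble(chrom = "d1", bin_i = i, bin_j = j, count = 10,
                              expected = 1, p = 0, q = 0,
                              length = (j - i) * res)
  calls <- dplyr::bind_rows(mk(5, 20), mk(20, 50), mk(20, 90), mk(40, 80))
  sp <- classify_fusion_spanning(calls, grid, sites, segments)
  expect_equal(sp$n_sites_spanned, c(0L, 1L, 2L, 1L))
  expect_equal(sp$anc_up[2], "a1")
  expect_equal(sp$anc_down[2], "a2")
  expect_equal(sp$age_class[2], "C1")
  expect_equal(sp$age_class[4], "C4")
  pm <- ancestral_pair_counts(sp)
  expect_equal(sum(pm$n), 2)
  # anchors outside any segment error
  short_seg <- segments[1:2, ]
  expect_error(classify_fusion_spanning(mk(20, 90), grid, sites, short_seg),
               "outside any ancestral segment")
})

test_that("the age gradient recovers exact correlations on rank toys", {
  sites <- tibble(chrom = "d1", position = 1:5 * 1e6,
                  age_class = paste0("C", 1:5))
  mk_span <- function(per_class) {
    dplyr::bind_rows(lapply(1:5, function(k) {
      if (per_class[k] == 0) return(NULL)
      tibble(n_sites_spanned = 1L, age_class = paste0("C", k))[
        rep(1, per_class[k]), ]
    }))
  }
  g1 <- age_gradient(mk_span(c(2, 4, 6, 8, 10)), sites)
  expect_equal(g1$pearson_r, 1)
  g2 <- age_gradient(mk_span(c(10, 8, 6, 4, 2)), sites)
  expect_equal(g2$pearson_r, -1)
  g0 <- age_gradient(mk_span(c(3, 3, 3, 3, 3)), sites)
  expect_true(is.na(g0$pearson_r))
  expect_error(age_gradient(mk_span(c(2, 0, 0, 0, 0)),
                            sites[1, ]), "2 age classes")
})

test_that("matrix transformation re-addresses cells and drops unmapped anchors", {
  res <- 2e4
  grid <- bin_grid(c(c1 = 3 * res), res)
  m <- matrix_from_cells(grid, tidyr::crossing(bin_i = 1:3, bin_j = 1:3) %>%
                           dplyr::filter(bin_j >= bin_i) %>%
                           dplyr::mutate(count = bin_i + bin_j))
  # identity map: identical matrix
  t1 <- transform_matrix(m, identity_bin_map(grid))
  expect_equal(as.data.frame(t1$counts), as.data.frame(m$counts))
  # unmapped middle bin: exactly the cells touching bin 2 disappear
  gap <- bin_map(tibble(src_bin = c(1L, 3L), tgt_bin = c(1L, 3L)), grid, grid)
  t2 <- transform_matrix(m, gap)
  expect_false(any(t2$counts$bin_i == 2 | t2$counts$bin_j == 2))
  expect_setequal(paste(t2$counts$bin_i, t2$counts$bin_j),
                  c("1 1", "1 3", "3 3"))
  expect_lte(sum(t2$counts$count), sum(m$counts$count))
})
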