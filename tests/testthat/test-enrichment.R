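lay2 <- genome_layout(c(chr1 = 1e6, chr2 = 5e5))

test_that("TSS windows are built and clipped per the 1 kb promoter proxy", {
  w <- tss_windows(data.frame(chrom = "chr1", pos = 5000L), 1000L, lay2)
  expect_equal(w$intervals$start, 4000L)
  expect_equal(w$intervals$end, 6000L)
  wc <- tss_windows(data.frame(chrom = "chr1", pos = 200L), 1000L, lay2)
  expect_equal(wc$intervals$start, 0L)           # clipped at the left edge
  expect_equal(wc$intervals$end, 1200L)
  withr::with_seed(1, {
    pts <- data.frame(chrom = "chr1", pos = sample.int(9e5, 134))
    expect_equal(nrow(tss_windows(pts, 1000L, lay2)$intervals), 134L)
  })
  expect_error(tss_windows(data.frame(chrom = "chr1", pos = 2e6), 1000L, lay2),
               "bounds")
})

test_that("overlap counting uses half-open semantics and matches brute force", {
  iv <- function(df) interval_set(df, lay2)
  q <- iv(data.frame(chrom = "chr1", start = 0L, end = 100L))
  expect_equal(count_overlapping(q, iv(data.frame(chrom = "chr1",
                                                  start = 100L, end = 200L))),
               0L)                               # abutment does not overlap
  expect_equal(count_overlapping(q, iv(data.frame(chrom = "chr1",
                                                  start = 99L, end = 200L))),
               1L)
  expect_equal(count_overlapping(q, iv(data.frame(chrom = "chr2",
                                                  start = 0L, end = 200L))),
               0L)                               # chromosomes matter
  withr::with_seed(11, {
    for (i in 1:5) {
      qs <- random_intervals(200, lay2)
      ts <- random_intervals(200, lay2)
      expect_equal(count_overlapping(iv(qs), iv(ts)),
                   bf_count_overlaps(qs, ts))
    }
  })
  other <- genome_layout(c(chr1 = 1e6))
  expect_error(count_overlapping(q, interval_set(
    data.frame(chrom = "chr1", start = 0L, end = 10L), other)),
    "different layouts")
})

test_that("interval validation enforces layout bounds", {
  expect_error(interval_set(data.frame(chrom = "chr2", start = 0L,
                                       end = 6e5), lay2), "chromosome length")
  expect_error(interval_set(data.frame(chrom = "chr1", start = -1L,
                                       end = 10L), lay2), "0 <= start")
})

test_that("shuffling preserves lengths, is seeded, and places uniformly", {
  withr::with_seed(3, {
    x <- interval_set(random_intervals(50, lay2), lay2)
  })
  s1 <- shuffle_intervals(x, seed = 99)
  s2 <- shuffle_intervals(x, seed = 99)
  expect_identical(s1, s2)
  expect_identical(sort(s1$intervals$end - s1$intervals$start),
                   sort(x$intervals$end - x$intervals$start))
  expect_false(identical(s1$intervals, x$intervals))

  # single-chromosome layout: starts uniform on [0, L - len]
  one <- genome_layout(c(chr1 = 1e5))
  len <- 1000L
  many <- interval_set(data.frame(chrom = "chr1",
                                  start = rep(0L, 5000),
                                  end = rep(len, 5000)), one)
  sh <- shuffle_intervals(many, seed = 7)
  u <- sh$intervals$start / (1e5 - len)
  expect_gt(suppressWarnings(stats::ks.test(u, "punif")$p.value), 0.001)

  # an interval that fits only one chromosome always lands there
  uneven <- genome_layout(c(big = 5000, small = 100))
  wide <- interval_set(data.frame(chrom = "big", start = 0L, end = 1000L),
                       uneven)
  for (s in 1:5)
    expect_equal(shuffle_intervals(wide, seed = s)$intervals$chrom, "big")

  # chromosome-restricted shuffling stays on the original chromosome
  sr <- shuffle_intervals(x, seed = 5, chrom_restricted = TRUE)
  expect_identical(sr$intervals$chrom, x$intervals$chrom)
})

test_that("permutation enrichment follows the add-one rule at both extremes", {
  lay <- genome_layout(c(chr1 = 1e7))
  withr::with_seed(2, {
    dmrs <- random_intervals(100, lay, min_len = 100, max_len = 100)
  })
  di <- interval_set(dmrs, lay)
  # windows identical to the DMRs: observed = 100, unreachable by the null
  pe <- permutation_enrichment(di, di, n_perm = 199, seed = 5)
  expect_equal(pe$observed, 100L)
  expect_equal(pe$p, 1 / 200)
  expect_true(all(pe$null_counts < 100))

  # a query set that can never overlap: observed 0, p = 1
  far <- interval_set(data.frame(chrom = "chr1", start = 0L, end = 10L), lay)
  none <- interval_set(data.frame(chrom = "chr1", start = 5e6,
                                  end = 5e6 + 10L), lay)
  pe0 <- permutation_enrichment(far, none, n_perm = 99, seed = 8)
  expect_equal(pe0$observed, 0L)
  expect_equal(pe0$p, 1)
  expect_gt(pe0$p, 0)
})

test_that("vectorized permutation counting agrees with explicit per-shuffle counts", {
  lay <- genome_layout(c(chr1 = 2e5, chr2 = 1e5))
  withr::with_seed(21, {
    dmrs <- interval_set(random_intervals(40, lay, 50, 200), lay)
    win <- interval_set(random_intervals(15, lay, 1000, 2000), lay)
  })
  pe <- permutation_enrichment(dmrs, win, n_perm = 50, seed = 4)
  expect_equal(pe$observed, count_overlapping(dmrs, win))
  # the null distribution matches the analytic placement model in spread
  expect_true(all(pe$null_counts >= 0 & pe$null_counts <= 40))
  expect_equal(length(pe$null_counts), 50L)
  # determinism
  expect_identical(permutation_enrichment(dmrs, win, n_perm = 50, seed = 4),
                   pe)
})

test_that("hypergeometric overlap matches closed forms and enumeration", {
  expect_equal(hypergeometric_overlap(10, 5, 5, 5)$p, 1 / 252,
               tolerance = 1e-12)
  expect_equal(hypergeometric_overlap(10, 5, 5, 0)$p, 1)
  # monotone decreasing in the overlap at fixed sizes
  ps <- vapply(0:5, function(k) hypergeometric_overlap(20, 8, 5, k)$p,
               numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(hypergeometric_overlap(10, 12, 5, 2), "inconsistent")
  expect_error(hypergeometric_overlap(10, 5, 5, 6), "inconsistent")
  for (N in c(5, 7, 9)) {
    for (K in 0:N) for (n in 0:N) for (k in 0:min(K, n)) {
      expect_equal(hypergeometric_overlap(N, K, n, k)$p, bf_hyper(N, K, n, k),
                   tolerance = 1e-12)
    }
  }
})

test_that("delta correlation honors identity, antisymmetry and the DMR filter", {
  withr::with_seed(13, {
    tab <- region_table(seq(0, by = 1000, length.out = 100),
                        is_dmr = rep(c(TRUE, FALSE), 50),
                        delta = rnorm(100, 0, 0.1))
  })
  self <- delta_correlation(tab, tab, "all")
  expect_equal(self$r, 1, tolerance = 1e-12)
  expect_equal(self$n, 100L)
  anti <- tab
  anti$delta <- -anti$delta
  expect_equal(delta_correlation(tab, anti, "all")$r, -1, tolerance = 1e-12)
  # union-of-DMRs filter restricts the universe
  expect_equal(delta_correlation(tab, tab, "union_of_dmrs")$n, 50L)
  expect_error(delta_correlation(tab[1:2, ], tab[1:2, ], "all"),
               "fewer than 3")
  # gene-keyed tables correlate on log2fc
  ga <- data.frame(gene_id = paste0("g", 1:50), log2fc = rnorm(50))
  gb <- ga
  expect_equal(delta_correlation(ga, gb, "all")$r, 1, tolerance = 1e-12)
})
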