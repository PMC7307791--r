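test_that("scoreability is a strict per-group coverage threshold", {
  tot <- function(v) matrix(rep(v, each = 1), nrow = 1)
  mat <- make_mat(pos = 100L,
                  meth_c = tot(c(1, 1, 1, 1, 1)), total_c = tot(c(9, 9, 9, 9, 2)),
                  meth_t = tot(c(1, 1, 1, 1, 1)), total_t = tot(c(9, 9, 9, 9, 9)))
  expect_true(flag_scoreable(mat, "control"))   # 4 replicates above 8 reads
  mat8 <- make_mat(pos = 100L,
                   meth_c = tot(rep(1, 5)), total_c = tot(rep(8, 5)),
                   meth_t = tot(rep(1, 5)), total_t = tot(rep(9, 5)))
  expect_false(flag_scoreable(mat8, "control")) # 8 reads is not > 8
  expect_error(flag_scoreable(mat, "nope"), "unknown group")
})

test_that("zero-coverage sites are never scoreable", {
  d <- withr::local_tempdir()
  # 5 replicates of a group whose only site has zero coverage in all of them
  paths <- character(5)
  for (i in 1:5) {
    paths[i] <- file.path(d, sprintf("s%d.cov", i))
    write_coverage_file(data.frame(chrom = "chr1", pos = 0L, meth = 0L,
                                   total = 0L), paths[i])
  }
  mat <- assemble_matrix(data.frame(path = paths,
                                    sample_id = paste0("s", 1:5),
                                    group = "g", stringsAsFactors = FALSE))
  expect_false(flag_scoreable(mat, "g"))
})

test_that("per-CpG differential calls use a strict 5-point rule", {
  mat <- make_mat_fractions(pos = c(100L, 140L, 180L),
                            frac_c = c(0.40, 0.40, 0.40),
                            frac_t = c(0.47, 0.40, 0.45))
  calls <- call_cpg_differential(mat, "control", "treatment")
  expect_equal(calls$delta, c(0.07, 0, 0.05), tolerance = 1e-12)
  expect_identical(calls$differential, c(TRUE, FALSE, FALSE))
  expect_identical(calls$direction, c("gain", "none", "none"))
})

test_that("region binning enforces proximity, CpG count and strict span", {
  p <- filter_params()
  r <- bin_regions(data.frame(chrom = "chr1",
                              pos = c(100L, 130L, 160L, 190L)), p)
  expect_equal(nrow(r), 1L)
  expect_equal(r$span, 92L)           # 190 - 100 + 2, > 50 bp
  expect_equal(r$n_cpgs, 4L)
  expect_equal(r$end, 192L)
  expect_equal(r$cpg_density, 400 / 92)

  # span 42 bp fails the strict > 50 bp rule
  expect_equal(nrow(bin_regions(data.frame(chrom = "chr1",
                                           pos = c(100L, 120L, 140L)), p)), 0L)
  # two CpGs fail the >= 3 rule
  expect_equal(nrow(bin_regions(data.frame(chrom = "chr1",
                                           pos = c(100L, 130L)), p)), 0L)
  # a gap over max_bin_gap splits bins
  r2 <- bin_regions(data.frame(
    chrom = "chr1", pos = c(0L, 30L, 60L, 400L, 430L, 460L)), p)
  expect_equal(nrow(r2), 2L)
  expect_error(bin_regions(data.frame(chrom = "chr1", pos = c(10L, 5L, 60L)),
                           p), "sorted")
})

test_that("regional DMR calls apply the inclusive one-third and strict delta rules", {
  # 3 CpGs, exactly one differential (delta 0.10), regional delta 0.06
  mat <- make_mat_fractions(pos = c(100L, 140L, 180L),
                            frac_c = c(0.40, 0.40, 0.40),
                            frac_t = c(0.50, 0.44, 0.44))
  p <- filter_params()
  cpg <- call_cpg_differential(mat, "control", "treatment", p)
  expect_equal(sum(cpg$differential), 1L)
  reg <- bin_regions(mat$sites, p)
  dmr <- call_dmrs(reg, cpg, mat, "control", "treatment", p)
  expect_true(dmr$is_dmr)             # 1/3 qualifies, |delta| = 0.06 > 0.05
  expect_equal(dmr$delta, 0.06, tolerance = 1e-9)
  expect_equal(dmr$direction, "gain")
  expect_equal(dmr$baseline_class, "intermediate")

  # 6 CpGs, one differential: 1/6 < 1/3, not a DMR despite a large delta
  mat6 <- make_mat_fractions(pos = seq(100L, 350L, by = 50L),
                             frac_c = rep(0.40, 6),
                             frac_t = c(0.90, rep(0.44, 5)))
  cpg6 <- call_cpg_differential(mat6, "control", "treatment", p)
  expect_equal(sum(cpg6$differential), 1L)
  dmr6 <- call_dmrs(bin_regions(mat6$sites, p), cpg6, mat6,
                    "control", "treatment", p)
  expect_false(dmr6$is_dmr)

  # one-third met but regional delta only 0.03: not a DMR
  mat3 <- make_mat_fractions(pos = c(100L, 140L, 180L),
                             frac_c = c(0.40, 0.40, 0.40),
                             frac_t = c(0.49, 0.40, 0.40))
  cpg3 <- call_cpg_differential(mat3, "control", "treatment", p)
  dmr3 <- call_dmrs(bin_regions(mat3$sites, p), cpg3, mat3,
                    "control", "treatment", p)
  expect_equal(dmr3$delta, 0.03, tolerance = 1e-9)
  expect_false(dmr3$is_dmr)
})

test_that("calls match the brute-force oracle exactly on random chromosomes", {
  p <- filter_params()
  for (s in 1:10) {
    mat <- random_mat(n_sites = 150, n_rep = 10, seed = s)
    cpg <- call_cpg_differential(mat, "control", "treatment", p)
    sc <- cpg$scoreable
    tab <- call_dmrs(bin_regions(mat$sites[sc, , drop = FALSE], p),
                     cpg, mat, "control", "treatment", p)
    bf <- bf_dmr_pipeline(mat, "control", "treatment")
    expect_equal(nrow(tab), nrow(bf))
    expect_identical(tab$start, bf$start)
    expect_identical(tab$end, bf$end)
    expect_identical(tab$is_dmr, bf$is_dmr)
    expect_equal(tab$delta, bf$delta, tolerance = 1e-12)
    expect_equal(tab$n_dm_cpgs, as.numeric(bf$n_dm), tolerance = 0)
  }
})

test_that("tightening thresholds is monotone and group swap is symmetric", {
  mat <- random_mat(n_sites = 300, n_rep = 10, seed = 99)
  run <- function(p) {
    cpg <- call_cpg_differential(mat, "control", "treatment", p)
    call_dmrs(bin_regions(mat$sites[cpg$scoreable, , drop = FALSE], p),
              cpg, mat, "control", "treatment", p)
  }
  base <- run(filter_params())
  for (d in c(0.08, 0.12)) {
    expect_lte(sum(run(filter_params(cpg_delta = d))$is_dmr),
               sum(base$is_dmr))
    expect_lte(sum(run(filter_params(region_delta = d))$is_dmr),
               sum(base$is_dmr))
  }
  for (mc in c(10, 14)) {
    expect_lte(sum(flag_scoreable(mat, "control",
                                  filter_params(min_coverage = mc))),
               sum(flag_scoreable(mat, "control", filter_params())))
  }
  # symmetry: swapping groups negates deltas and swaps gain/loss
  p <- filter_params()
  fwd <- run(p)
  cpg_rev <- call_cpg_differential(mat, "treatment", "control", p)
  rev <- call_dmrs(bin_regions(mat$sites[cpg_rev$scoreable, , drop = FALSE], p),
                   cpg_rev, mat, "treatment", "control", p)
  expect_identical(fwd$start, rev$start)
  expect_equal(fwd$delta, -rev$delta, tolerance = 1e-12)
  expect_identical(fwd$is_dmr, rev$is_dmr)
  swap <- c(gain = "loss", loss = "gain", none = "none")
  expect_identical(unname(swap[fwd$direction]), rev$direction)
})

test_that("pooled scoreability mode relaxes the per-group rule", {
  tot <- function(v) matrix(v, nrow = 1)
  # 3 passing replicates per group: fails both_groups, passes all_samples
  mat <- make_mat(pos = 100L,
                  meth_c = tot(rep(1, 5)), total_c = tot(c(9, 9, 9, 2, 2)),
                  meth_t = tot(rep(1, 5)), total_t = tot(c(9, 9, 9, 2, 2)))
  both <- call_cpg_differential(mat, "control", "treatment",
                                filter_params(scoreable_mode = "both_groups"))
  pooled <- call_cpg_differential(mat, "control", "treatment",
                                  filter_params(scoreable_mode = "all_samples"))
  expect_false(both$scoreable)
  expect_true(pooled$scoreable)
})
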