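test_that("landscape generation is deterministic and respects the point process", {
  lay <- genome_layout(c(chrA = 10000))
  cfg <- sim_config(cpg_cluster_rate = 0, background_spacing = 100, seed = 5)
  l1 <- generate_cpg_landscape(lay, cfg)
  l2 <- generate_cpg_landscape(lay, cfg)
  expect_identical(l1, l2)                       # same seed, same positions
  expect_true(all(diff(l1$chrA) >= 2))
  expect_true(is.integer(l1$chrA))

  # background-only process: counts behave like Poisson(L / spacing)
  counts <- vapply(1:1000, function(s) {
    length(generate_cpg_landscape(
      lay, sim_config(cpg_cluster_rate = 0, background_spacing = 100,
                      seed = s))$chrA)
  }, numeric(1))
  expect_true(all(abs(counts - 100) <= 4 * 10))  # each draw within 4 sigma
  expect_lt(abs(mean(counts) - 100), 3)          # dedup loss is small
  expect_gt(sd(counts), 7); expect_lt(sd(counts), 13)

  expect_error(generate_cpg_landscape(genome_layout(c(c1 = 2)), cfg),
               "too small")
})

test_that("clustered landscapes are denser than background-only ones", {
  lay <- genome_layout(c(chr1 = 2e5))
  with_cl <- generate_cpg_landscape(lay, sim_config(seed = 3))
  no_cl <- generate_cpg_landscape(lay, sim_config(cpg_cluster_rate = 0,
                                                  seed = 3))
  expect_gt(length(with_cl$chr1), length(no_cl$chr1))
  expect_gt(sum(diff(with_cl$chr1) <= 30), sum(diff(no_cl$chr1) <= 30))
})

test_that("methylome simulation is deterministic and conserves the truth ledger", {
  lay <- genome_layout(c(chr1 = 8e5))
  cfg <- sim_config(injected_dmr_count = 25, seed = 12)
  s1 <- simulate_methylome(lay, cfg)
  s2 <- simulate_methylome(lay, cfg)
  expect_identical(s1$matrix$meth, s2$matrix$meth)
  expect_identical(s1$matrix$total, s2$matrix$total)
  expect_identical(s1$truth$regions, s2$truth$regions)

  tr <- s1$truth$regions
  expect_equal(nrow(tr), 25L)                    # conservation
  expect_true(all(tr$end <= 8e5))
  expect_true(all(tr$start >= 0))
  o <- order(tr$chrom, tr$start)
  expect_true(all(diff(tr$start[o]) >= 0))
  same_chrom <- tr$chrom[o][-1] == tr$chrom[o][-nrow(tr)]
  expect_true(all(tr$end[o][-nrow(tr)][same_chrom] <=
                    tr$start[o][-1][same_chrom]))  # non-overlapping
  expect_true(all(tr$dynamics %in% c("persist", "decay", "emerge")))

  expect_error(simulate_methylome(lay, sim_config(injected_dmr_count = 1e5,
                                                  seed = 1)),
               "layout too small")
})

test_that("null configuration carries no effects and an empty ledger", {
  lay <- genome_layout(c(chr1 = 2e5))
  cfg <- sim_config(injected_dmr_count = 0, seed = 4)
  sim <- simulate_methylome(lay, cfg)
  expect_equal(nrow(sim$truth$regions), 0L)
  expect_true(all(sim$truth$site_effect == 0))
})

test_that("replicate fractions match the beta-binomial variance within 10%", {
  # baseline pinned at 0.5, rho 0.1, coverage 30
  lay <- genome_layout(c(chr1 = 2.2e6))
  cfg <- sim_config(
    injected_dmr_count = 0, n_replicates = 4, timepoints = 0L,
    mean_coverage = 30, overdispersion = 0.1,
    baseline_mixture = list(
      proportions = c(hypo = 0, intermediate = 1, hyper = 0),
      means = c(hypo = 0.08, intermediate = 0.5, hyper = 0.92)),
    baseline_concentration = 1e7, seed = 21)
  sim <- simulate_methylome(lay, cfg)
  frac <- sim$matrix$meth / sim$matrix$total
  expect_gt(length(frac), 10000)
  v_emp <- var(as.vector(frac))
  # pi (1 - pi) (1 + (n - 1) rho) / n at pi = 0.5, n = 30
  v_theory <- 0.25 * (1 + 29 * 0.1) / 30
  expect_lt(abs(v_emp - v_theory) / v_theory, 0.10)
  expect_lt(abs(mean(as.vector(frac)) - 0.5), 0.01)
})

test_that("group labels are exchangeable under the null configuration", {
  lay <- genome_layout(c(chr1 = 5e4))
  n_runs <- 60
  nonsig <- 0
  for (s in seq_len(n_runs)) {
    cfg <- sim_config(injected_dmr_count = 0, n_replicates = 5,
                      timepoints = 0L, seed = 1000 + s)
    sim <- simulate_methylome(lay, cfg)
    frac <- sim$matrix$meth / sim$matrix$total
    grp <- sim$matrix$samples$group
    stat <- abs(mean(frac[, grp == "control"]) -
                  mean(frac[, grp != "control"]))
    perm <- withr::with_seed(s, {
      vapply(1:99, function(i) {
        sh <- sample(ncol(frac))
        idx <- sh[seq_len(sum(grp == "control"))]
        abs(mean(frac[, idx]) - mean(frac[, -idx]))
      }, numeric(1))
    })
    p <- (1 + sum(perm >= stat)) / 100
    if (p > 0.01) nonsig <- nonsig + 1
  }
  expect_gte(nonsig / n_runs, 0.98)
})

test_that("TSS annotation honors count, width and overlap construction", {
  lay <- genome_layout(c(chr1 = 8e5))
  cfg <- sim_config(injected_dmr_count = 25, tss_count = 134,
                    tss_overlap_fraction = 0, seed = 9)
  sim <- simulate_methylome(lay, cfg)
  tss0 <- make_tss_annotation(lay, sim$truth, cfg)
  expect_equal(nrow(tss0), 134L)
  widths <- tss0$end - tss0$start
  expect_true(all(widths <= 2000 & widths >= 1000))
  tr <- sim$truth$regions
  hits <- vapply(seq_len(nrow(tss0)), function(i) {
    any(tr$chrom == tss0$chrom[i] & tr$start < tss0$end[i] &
          tss0$start[i] < tr$end)
  }, logical(1))
  expect_equal(sum(hits), 0L)                    # overlap fraction 0

  cfg1 <- sim_config(injected_dmr_count = 25, tss_count = 10,
                     tss_overlap_fraction = 1, seed = 9)
  tss1 <- make_tss_annotation(lay, sim$truth, cfg1)
  hits1 <- vapply(seq_len(nrow(tss1)), function(i) {
    any(tr$chrom == tss1$chrom[i] & tr$start < tss1$end[i] &
          tss1$start[i] < tr$end)
  }, logical(1))
  expect_equal(sum(hits1), 10L)                  # all 10 overlap

  expect_identical(make_tss_annotation(lay, sim$truth, cfg1),
                   make_tss_annotation(lay, sim$truth, cfg1))
  null_truth <- list(regions = sim$truth$regions[integer(), ])
  expect_error(make_tss_annotation(lay, null_truth, cfg1), "infeasible")
})

test_that("expression simulation conserves truth and supports null configs", {
  cfg <- sim_config(expression_gene_count = 2000, expression_de_count = 0,
                    dispersion_inflation_factor = 1, seed = 30)
  e <- simulate_expression(cfg)
  expect_equal(nrow(e$counts), 2000L)            # conservation
  expect_equal(nrow(e$truth$de), 0L)
  expect_true(is.na(e$truth$inflated_group))     # exchangeable null
  expect_identical(simulate_expression(cfg)$counts, e$counts)

  cfg2 <- sim_config(expression_de_count = 40, seed = 31,
                     dispersion_inflation_factor = 3)
  e2 <- simulate_expression(cfg2)
  expect_equal(nrow(e2$truth$de), 40L)
  expect_equal(e2$truth$inflated_group, "test")
})

test_that("simulation artifacts round-trip through the on-disk formats", {
  lay <- genome_layout(c(chr1 = 2e5))
  cfg <- sim_config(injected_dmr_count = 5, n_replicates = 4,
                    timepoints = 0L, seed = 17)
  sim <- simulate_methylome(lay, cfg)
  d <- withr::local_tempdir()
  sheet_path <- write_simulation(sim, d)
  sheet <- read_sample_sheet(sheet_path)
  mat <- assemble_matrix(sheet)
  expect_equal(nrow(mat$sites), nrow(sim$matrix$sites))
  expect_equal(mat$total[, sim$matrix$samples$sample_id],
               sim$matrix$total, ignore_attr = TRUE)
  tr <- read.delim(file.path(d, "truth_regions.tsv"))
  expect_equal(nrow(tr), 5L)
})
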