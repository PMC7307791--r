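# Small fixture builders used across test files.

# build a methylation_matrix from per-group count matrices
make_mat <- function(pos, meth_c, total_c, meth_t, total_t,
                     chrom = "chr1") {
  nc <- ncol(total_c); nt <- ncol(total_t)
  samples <- data.frame(
    sample_id = c(sprintf("c%02d", seq_len(nc)), sprintf("t%02d", seq_len(nt))),
    group = c(rep("control", nc), rep("treatment", nt)),
    stringsAsFactors = FALSE)
  methylation_matrix(
    data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE),
    cbind(meth_c, meth_t), cbind(total_c, total_t), samples)
}

# matrix where every replicate of a group has the same fraction at a site
make_mat_fractions <- function(pos, frac_c, frac_t, n_rep = 5, total = 100,
                               chrom = "chr1") {
  ns <- length(pos)
  tc <- matrix(total, ns, n_rep)
  tt <- matrix(total, ns, n_rep)
  make_mat(pos, matrix(round(frac_c * total), ns, n_rep), tc,
           matrix(round(frac_t * total), ns, n_rep), tt, chrom = chrom)
}

# random matrix with clustered sites, heterogeneous coverage and group deltas;
# used for oracle-equivalence and property tests
random_mat <- function(n_sites = 200, n_rep = 10, seed = 1,
                       mean_cov = 15, chrom = "chr1", delta_sd = 0.08) {
  withr::with_seed(seed, {
    pos <- sort(sample.int(n_sites * 60, n_sites))
    pos <- pos[c(TRUE, diff(pos) >= 2)]
    ns <- length(pos)
    base <- rbeta(ns, 0.8, 0.8)
    shift <- rnorm(ns, 0, delta_sd)
    pc <- base
    pt_ <- pmin(1, pmax(0, base + shift))
    tc <- matrix(rpois(ns * n_rep, mean_cov), ns, n_rep)
    tt <- matrix(rpois(ns * n_rep, mean_cov), ns, n_rep)
    mc <- matrix(rbinom(ns * n_rep, tc, pc), ns, n_rep)
    mt <- matrix(rbinom(ns * n_rep, tt, pt_), ns, n_rep)
    make_mat(pos, mc, tc, mt, tt, chrom = chrom)
  })
}

# random interval data.frame within a layout
random_intervals <- function(n, layout, min_len = 50, max_len = 500) {
  ci <- sample.int(nrow(layout), n, replace = TRUE)
  len <- sample.int(max_len - min_len + 1, n, replace = TRUE) + min_len - 1
  start <- floor(runif(n, 0, layout$length[ci] - len))
  data.frame(chrom = layout$chrom[ci], start = as.integer(start),
             end = as.integer(start + len), stringsAsFactors = FALSE)
}

# minimal region table for recovery-classification tests
region_table <- function(start, is_dmr, delta = NULL, chrom = "chr1",
                         width = 100, baseline = 0.5, sd_test = 0.05,
                         density = 5) {
  n <- length(start)
  if (is.null(delta)) delta <- ifelse(is_dmr, 0.2, 0.01)
  data.frame(
    chrom = chrom, start = as.integer(start),
    end = as.integer(start + width), n_cpgs = 5L, span = as.integer(width),
    cpg_density = density, n_scoreable_cpgs = 5, n_dm_cpgs = 5 * is_dmr,
    dm_fraction = as.numeric(is_dmr),
    mean_control = baseline, mean_test = baseline + delta, delta = delta,
    direction = ifelse(delta >= 0, "gain", "loss"),
    baseline_class = ifelse(baseline < 0.25, "hypo",
                            ifelse(baseline > 0.75, "hyper", "intermediate")),
    sd_control = 0.05, sd_test = sd_test, aux_p = 0.5, is_dmr = is_dmr,
    stringsAsFactors = FALSE)
}
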