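#' Run the full recovery analysis on a simulated methylome
#'
#' End-to-end orchestration: simulate (or accept) a multi-timepoint
#' methylome, restrict to CpGs scoreable in every compared group, bin them
#' once into a shared region universe, call DMRs per timepoint against the
#' common control, classify recovery dynamics for each recovery timepoint,
#' and profile the t0-vs-first-recovery comparison by baseline stratum,
#' CpG density and replicate variation.  When simulation truth is
#' available, classification accuracy per dynamics class is scored against
#' it.
#'
#' @param layout a [genome_layout()].
#' @param config a [sim_config()] describing the simulated study.
#' @param params a [filter_params()].
#' @param sim optional pre-built `meth_simulation` (skips simulation).
#' @param outdir optional directory: DMR tables, label tables, BED files
#'   and a JSON report are written there.
#' @return a `recovery_report` list: `counts` (records per stage),
#'   `region_universe`, `tables` (per timepoint), `labels` (per recovery
#'   timepoint), `strata`, `density`, `variation`, `dynamics_accuracy`,
#'   `params`, `seed`.
#' @export
run_recovery_analysis <- function(layout, config = sim_config(),
                                  params = filter_params(), sim = NULL,
                                  outdir = NULL) {
  if (is.null(sim)) sim <- simulate_methylome(layout, config)
  mat <- sim$matrix
  tps <- sort(unique(mat$samples$timepoint[!is.na(mat$samples$timepoint)]))
  if (length(tps) < 2)
    stop("recovery analysis needs an exposure and at least one recovery timepoint")
  t0 <- tps[1L]
  groups <- paste0("treatment_t", tps)

  scoreable <- flag_scoreable(mat, "control", params)
  for (g in groups) scoreable <- scoreable & flag_scoreable(mat, g, params)
  sites <- mat$sites[scoreable, , drop = FALSE]
  regions <- bin_regions(sites, params)

  tables <- setNames(vector("list", length(tps)), paste0("t", tps))
  for (i in seq_along(tps)) {
    cpg <- call_cpg_differential(mat, "control", groups[i], params)
    tables[[i]] <- call_dmrs(regions, cpg, mat, "control", groups[i], params)
  }
  t0_table <- tables[[1L]]

  labels <- setNames(vector("list", length(tps) - 1L),
                     paste0("t", tps[-1L]))
  for (i in seq_along(labels))
    labels[[i]] <- classify_recovery(t0_table, tables[[i + 1L]])
  lab1 <- labels[[1L]]
  t1_table <- tables[[2L]]

  strata <- stratify_recovery(lab1, t0_table)
  density <- density_profile(lab1, t0_table, t1_table)
  variation <- variation_profile(lab1, t0_table, t1_table)
  accuracy <- if (!is.null(sim$truth)) score_dynamics(sim$truth, lab1) else NULL

  counts <- list(
    sites = nrow(mat$sites),
    scoreable_sites = sum(scoreable),
    regions = nrow(regions),
    dmrs = vapply(tables, function(t) sum(t$is_dmr), integer(1)),
    labels = vapply(labels, function(l) {
      c(shared = sum(l$status == "shared"),
        recovered = sum(l$status == "recovered"),
        new = sum(l$status == "new"))
    }, integer(3)))
  report <- structure(
    list(counts = counts, region_universe = regions[, 1:6], tables = tables,
         labels = labels, strata = strata, density = density,
         variation = variation, dynamics_accuracy = accuracy,
         truth = sim$truth$regions, params = params, seed = config$seed),
    class = "recovery_report")
  .check_report_consistency(report)
  if (!is.null(outdir)) .write_recovery_report(report, outdir)
  report
}

.check_report_consistency <- function(report) {
  cn <- report$counts
  stopifnot(cn$scoreable_sites <= cn$sites,
            all(cn$dmrs <= cn$regions))
  t0_dmrs <- cn$dmrs[[1L]]
  for (j in seq_len(ncol(cn$labels))) {
    lc <- cn$labels[, j]
    if (lc[["shared"]] + lc[["recovered"]] != t0_dmrs)
      stop("report inconsistency: shared + recovered != t0 DMR count")
  }
  invisible(report)
}

#' @export
print.recovery_report <- function(x, ...) {
  cn <- x$counts
  cat("recovery analysis report\n")
  cat(sprintf("  CpG sites: %d (%d scoreable in all groups)\n",
              cn$sites, cn$scoreable_sites))
  cat(sprintf("  regions analyzed: %d\n", cn$regions))
  for (nm in names(cn$dmrs))
    cat(sprintf("  DMRs at %s: %d\n", nm, cn$dmrs[[nm]]))
  for (nm in colnames(cn$labels))
    cat(sprintf("  %s: shared %d / recovered %d / new %d\n", nm,
                cn$labels["shared", nm], cn$labels["recovered", nm],
                cn$labels["new", nm]))
  if (!is.null(x$dynamics_accuracy)) {
    cat("  dynamics classification accuracy:\n")
    a <- x$dynamics_accuracy
    for (i in seq_len(nrow(a)))
      cat(sprintf("    %s -> %s: %.1f%% (%d/%d)\n", a$dynamics[i],
                  a$expected_status[i], 100 * a$accuracy[i],
                  a$n_correct[i], a$n[i]))
  }
  invisible(x)
}

.write_recovery_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report$tables)) {
    t <- report$tables[[nm]]
    write.table(t[, setdiff(names(t), "members")],
                file.path(outdir, paste0("regions_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    dmr <- t[t$is_dmr, , drop = FALSE]
    if (nrow(dmr))
      write_bed(data.frame(chrom = dmr$chrom, start = dmr$start,
                           end = dmr$end, name = dmr$direction,
                           score = round(1000 * abs(dmr$delta)),
                           strand = "."),
                file.path(outdir, paste0("dmrs_", nm, ".bed")))
  }
  for (nm in names(report$labels)) {
    l <- report$labels[[nm]]
    write.table(l, file.path(outdir, paste0("labels_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(l))
      write_bed(data.frame(chrom = l$chrom, start = l$start, end = l$end,
                           name = l$status, score = 0, strand = "."),
                file.path(outdir, paste0("labels_", nm, ".bed")))
  }
  write.table(report$strata, file.path(outdir, "strata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  json <- list(counts = report$counts,
               strata = report$strata,
               dynamics_accuracy = report$dynamics_accuracy,
               seed = report$seed)
  jsonlite::write_json(json, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Run the cross-cohort (offspring / genotype) analysis
#'
#' Simulates two cohorts on one shared CpG landscape — e.g. exposed-sire F0
#' sperm and offspring F1 prefrontal cortex, or wild-type and knockout
#' sperm — with either independent injected effects (`f1_mode =
#' "independent"`, the transmission-null scenario) or the same effects
#' (`"shared"`, the concordance scenario).  Calls DMRs per cohort,
#' correlates per-region methylation deltas between cohorts, tests DMR-set
#' overlap hypergeometrically, tests TSS-window enrichment of cohort-B DMRs
#' by interval-shuffle permutation, and runs the expression arm (simulate,
#' normalize, stand-in DE test, DE filter, log2FC correlation, DE-set
#' overlap, variation comparison).
#'
#' @param layout a [genome_layout()].
#' @param config a [sim_config()] (cohort A uses `config$seed`; cohort B
#'   uses a derived seed).
#' @param f1_mode `"independent"` or `"shared"` injected methylation and DE
#'   effects for cohort B.
#' @param params a [filter_params()].
#' @param n_perm permutations for the TSS enrichment test.
#' @param outdir optional output directory for a JSON report.
#' @return an `offspring_report` list with the DMR tables, correlation,
#'   overlap, enrichment and expression results.
#' @export
run_offspring_analysis <- function(layout, config = sim_config(),
                                   f1_mode = c("independent", "shared"),
                                   params = filter_params(),
                                   n_perm = 1000L, outdir = NULL) {
  f1_mode <- match.arg(f1_mode)
  cfg_a <- config
  cfg_a$timepoints <- config$timepoints[1L]
  land <- generate_cpg_landscape(layout, cfg_a)
  sim_a <- simulate_methylome(layout, cfg_a, landscape = land)
  cfg_b <- cfg_a
  cfg_b$seed <- substream_seed(config$seed, "cohort_b")
  sim_b <- simulate_methylome(layout, cfg_b, landscape = land,
                              truth = if (f1_mode == "shared") sim_a$truth)
  g <- paste0("treatment_t", cfg_a$timepoints[1L])

  call_cohort <- function(sim) {
    mat <- sim$matrix
    sc <- flag_scoreable(mat, "control", params) &
      flag_scoreable(mat, g, params)
    regions <- bin_regions(mat$sites[sc, , drop = FALSE], params)
    cpg <- call_cpg_differential(mat, "control", g, params)
    call_dmrs(regions, cpg, mat, "control", g, params)
  }
  tab_a <- call_cohort(sim_a)
  tab_b <- call_cohort(sim_b)

  corr <- tryCatch(delta_correlation(tab_a, tab_b, "union_of_dmrs"),
                   error = function(e) list(r = NA_real_, n = 0L))
  corr_all <- tryCatch(delta_correlation(tab_a, tab_b, "all"),
                       error = function(e) list(r = NA_real_, n = 0L))

  ka <- .region_key(tab_a); kb <- .region_key(tab_b)
  universe <- intersect(ka, kb)
  dmr_a <- intersect(ka[tab_a$is_dmr], universe)
  dmr_b <- intersect(kb[tab_b$is_dmr], universe)
  overlap <- hypergeometric_overlap(length(universe), length(dmr_a),
                                    length(dmr_b),
                                    length(intersect(dmr_a, dmr_b)))

  tssb <- make_tss_annotation(layout, sim_b$truth, cfg_b)
  dmr_iv <- tab_b[tab_b$is_dmr, c("chrom", "start", "end"), drop = FALSE]
  enrichment <- if (nrow(dmr_iv)) {
    permutation_enrichment(interval_set(dmr_iv, layout),
                           interval_set(tssb, layout),
                           n_perm = n_perm,
                           seed = substream_seed(config$seed, "enrich"))
  } else NULL

  exp_a <- simulate_expression(cfg_a)
  exp_b <- simulate_expression(cfg_b,
                               truth = if (f1_mode == "shared") exp_a$truth)
  de_arm <- function(e) {
    nrm <- normalize_counts(e$counts)
    stats <- stand_in_de_test(nrm$normalized, e$groups, "control", "test")
    list(normalized = nrm$normalized, stats = stats,
         de = de_filter(stats))
  }
  arm_a <- de_arm(exp_a)
  arm_b <- de_arm(exp_b)
  expr_corr <- delta_correlation(arm_a$stats, arm_b$stats, "all")
  expr_overlap <- de_overlap(arm_a$de, arm_b$de,
                             intersect(arm_a$stats$gene_id,
                                       arm_b$stats$gene_id))
  variation <- variation_comparison(arm_a$normalized, exp_a$groups,
                                    "test", "control")

  report <- structure(
    list(f1_mode = f1_mode,
         tables = list(cohort_a = tab_a, cohort_b = tab_b),
         dmr_counts = c(cohort_a = sum(tab_a$is_dmr),
                        cohort_b = sum(tab_b$is_dmr)),
         delta_correlation = corr, delta_correlation_all = corr_all,
         dmr_overlap = overlap, tss_enrichment = enrichment,
         de_sets = list(cohort_a = arm_a$de, cohort_b = arm_b$de),
         expression_correlation = expr_corr,
         expression_overlap = expr_overlap,
         expression_variation = variation,
         seed = config$seed),
    class = "offspring_report")
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    json <- list(
      f1_mode = f1_mode, dmr_counts = as.list(report$dmr_counts),
      delta_correlation = corr, dmr_overlap_p = overlap$p,
      tss_enrichment_p = if (!is.null(enrichment)) enrichment$p else NA,
      de_counts = lapply(report$de_sets, length),
      expression_correlation = expr_corr,
      expression_overlap_p = expr_overlap$p,
      expression_variation = list(p = variation$p,
                                  direction = variation$direction),
      seed = config$seed)
    jsonlite::write_json(json, file.path(outdir, "offspring_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.offspring_report <- function(x, ...) {
  cat("cross-cohort analysis report (mode:", x$f1_mode, ")\n")
  cat(sprintf("  DMRs: cohort A %d, cohort B %d\n",
              x$dmr_counts[["cohort_a"]], x$dmr_counts[["cohort_b"]]))
  cat(sprintf("  delta correlation (union of DMRs): r = %.3f (n = %d)\n",
              x$delta_correlation$r, x$delta_correlation$n))
  cat(sprintf("  DMR-set overlap: k = %d, p = %.3g\n",
              x$dmr_overlap$k, x$dmr_overlap$p))
  if (!is.null(x$tss_enrichment))
    cat(sprintf("  TSS enrichment: observed %d, p = %.3g\n",
                x$tss_enrichment$observed, x$tss_enrichment$p))
  cat(sprintf("  DE genes: cohort A %d, cohort B %d; log2FC r = %.3f\n",
              length(x$de_sets$cohort_a), length(x$de_sets$cohort_b),
              x$expression_correlation$r))
  cat(sprintf("  DE-set overlap p = %.3g; variation higher in %s (p = %.3g)\n",
              x$expression_overlap$p, x$expression_variation$direction,
              x$expression_variation$p))
  invisible(x)
}
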