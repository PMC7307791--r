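#' Median-of-ratios normalization of a count table
#'
#' Size factor per sample = median, over genes with a finite log geometric
#' mean across samples, of the ratio count / geometric mean (the median is
#' taken on the log scale).  Normalized counts are raw counts divided by
#' the sample's size factor.  Because the geometric-mean reference involves
#' every sample, multiplying one of `m` samples by a constant `c` scales
#' its size factor by `c^((m-1)/m)` and the others by `c^(-1/m)` — i.e.
#' the scaled sample's factor grows by `c` *relative to the rest*, and the
#' normalized matrix changes only by one global constant.
#'
#' @param counts numeric matrix, genes x samples (non-negative).
#' @return list with `normalized` (matrix) and `size_factors` (named vector).
#' @export
normalize_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need at least 2 samples")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(colSums(counts) == 0)) stop("sample with all-zero counts")
  loggeo <- rowMeans(log(counts))
  sf <- apply(counts, 2, function(cnt) {
    r <- log(cnt) - loggeo
    exp(median(r[is.finite(loggeo) & cnt > 0]))
  })
  list(normalized = sweep(counts, 2, sf, "/"), size_factors = sf)
}

#' Filter differentially expressed genes by fold change and p-value
#'
#' A gene passes when `|log2fc|` strictly exceeds `lfc_threshold` and its
#' (unadjusted) p-value is strictly below `p_threshold`; both boundaries
#' are exclusive, so `log2fc` of exactly 1 does not qualify.  Genes with
#' missing statistics are excluded with a warning.
#'
#' @param stats data.frame with `gene_id`, `log2fc`, `pvalue`.
#' @param lfc_threshold,p_threshold thresholds (defaults 1 and 0.05).
#' @return character vector of DE gene ids.
#' @export
de_filter <- function(stats, lfc_threshold = 1, p_threshold = 0.05) {
  stopifnot(all(c("gene_id", "log2fc", "pvalue") %in% names(stats)))
  miss <- is.na(stats$log2fc) | is.na(stats$pvalue)
  if (any(miss))
    warning(sum(miss), " gene(s) with missing statistics excluded")
  keep <- !miss & abs(stats$log2fc) > lfc_threshold &
    stats$pvalue < p_threshold
  stats$gene_id[keep]
}

#' Simple stand-in differential-expression test
#'
#' A deliberately plain per-gene test so synthetic end-to-end runs need no
#' external DE engine: `log2fc = log2((mean_test + 0.5) /
#' (mean_control + 0.5))` on normalized counts, with a two-sided Welch
#' t-test on `log2(normalized + 1)`.  This is *not* equivalent to a
#' negative-binomial DE method and is intended only for simulated data;
#' real studies should supply an externally computed statistics table.
#'
#' @param normalized normalized count matrix (genes x samples) with gene
#'   ids as rownames.
#' @param groups character/factor of group labels per column.
#' @param control_group,test_group labels to compare.
#' @return data.frame with `gene_id`, `log2fc`, `pvalue`.
#' @export
stand_in_de_test <- function(normalized, groups, control_group, test_group) {
  groups <- as.character(groups)
  ic <- which(groups == control_group)
  it <- which(groups == test_group)
  if (length(ic) < 2 || length(it) < 2)
    stop("need >= 2 replicates per group")
  mc <- rowMeans(normalized[, ic, drop = FALSE])
  mt <- rowMeans(normalized[, it, drop = FALSE])
  lfc <- log2((mt + 0.5) / (mc + 0.5))
  xl <- log2(normalized + 1)
  m1 <- rowMeans(xl[, it, drop = FALSE])
  m2 <- rowMeans(xl[, ic, drop = FALSE])
  v1 <- apply(xl[, it, drop = FALSE], 1, var)
  v2 <- apply(xl[, ic, drop = FALSE], 1, var)
  n1 <- length(it); n2 <- length(ic)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  p[se2 == 0] <- 1  # zero variance in both groups
  data.frame(gene_id = rownames(normalized), log2fc = lfc, pvalue = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare per-gene expression variability between two groups
#'
#' The per-gene spread statistic (default: within-group standard deviation
#' of `log2(normalized + 1)`) is computed for both groups over the same
#' gene universe and compared with a paired two-sided Wilcoxon signed-rank
#' test on the per-gene differences.  The direction reports which group has
#' the higher median spread.
#'
#' @param normalized normalized count matrix (genes x samples).
#' @param groups labels per column.
#' @param group_a,group_b labels to compare.
#' @param spread `"sd"` (default), `"cv"` or `"mad"` on the log scale.
#' @return a `variation_comparison`: per-group median spread, `p`,
#'   `direction` (`group_a`, `group_b` or `none`), and the per-gene spreads.
#' @export
variation_comparison <- function(normalized, groups, group_a, group_b,
                                 spread = c("sd", "cv", "mad")) {
  spread <- match.arg(spread)
  groups <- as.character(groups)
  ia <- which(groups == group_a)
  ib <- which(groups == group_b)
  if (!length(ia) || !length(ib)) stop("unknown group label")
  if (nrow(normalized) < 10) stop("need at least 10 genes")
  xl <- log2(normalized + 1)
  fn <- switch(spread,
               sd = function(m) apply(m, 1, sd),
               mad = function(m) apply(m, 1, mad),
               cv = function(m) apply(m, 1, sd) / (rowMeans(m) + 1e-8))
  sa <- fn(xl[, ia, drop = FALSE])
  sb <- fn(xl[, ib, drop = FALSE])
  d <- sa - sb
  if (all(d == 0)) {
    p <- 1; direction <- "none"
  } else {
    p <- suppressWarnings(wilcox.test(sa, sb, paired = TRUE)$p.value)
    md <- median(d)
    direction <- if (md > 0) group_a else if (md < 0) group_b else "none"
  }
  structure(list(spread = spread, group_a = group_a, group_b = group_b,
                 median_a = median(sa), median_b = median(sb),
                 p = p, direction = direction,
                 spread_a = sa, spread_b = sb),
            class = "variation_comparison")
}

#' @export
print.variation_comparison <- function(x, ...) {
  cat(sprintf(
    "expression variation (%s): %s median %.4f vs %s median %.4f; higher: %s (p = %.3g)\n",
    x$spread, x$group_a, x$median_a, x$group_b, x$median_b, x$direction, x$p))
  invisible(x)
}

#' Hypergeometric overlap of two DE gene sets
#'
#' @param de_set_a,de_set_b character vectors of DE gene ids.
#' @param universe character vector of genes tested in both comparisons.
#' @return an `overlap_test` (see [hypergeometric_overlap()]).
#' @export
de_overlap <- function(de_set_a, de_set_b, universe) {
  a <- intersect(unique(de_set_a), universe)
  b <- intersect(unique(de_set_b), universe)
  hypergeometric_overlap(length(unique(universe)), length(a), length(b),
                         length(intersect(a, b)))
}

#' Simulate a two-group expression experiment
#'
#' Negative-binomial counts with log-normal gene means and per-gene
#' dispersions jittered around `expression_mean_dispersion`.  DE genes
#' (sampled gene ids) have their test-group mean shifted by a true log2
#' fold change drawn from `expression_fold_changes`; one group's dispersion
#' is multiplied by `dispersion_inflation_factor`.
#'
#' @param config a [sim_config()]; uses the expression fields and substream
#'   "expression".
#' @param truth optional truth from a previous call, to re-simulate an
#'   experiment with the same DE genes and fold changes.
#' @return list with `counts` (genes x samples), `groups` (per-column
#'   labels, "control"/"test") and `truth` (list: `de` data.frame with
#'   `gene_id`, `log2fc`; `inflated_group`).
#' @export
simulate_expression <- function(config, truth = NULL) {
  validate_sim_config(config)
  n <- config$n_expression_replicates
  if (n < 2) stop("need >= 2 replicates per expression group")
  G <- config$expression_gene_count
  gene_id <- sprintf("gene_%05d", seq_len(G))
  with_substream(config$seed, "expression", {
    mu <- rlnorm(G, log(100), 1)
    alpha <- config$expression_mean_dispersion * exp(rnorm(G, 0, 0.25))
    if (is.null(truth)) {
      de_idx <- if (config$expression_de_count > 0)
        sort(sample.int(G, config$expression_de_count)) else integer()
      pool <- config$expression_fold_changes
      lfc <- pool[sample.int(length(pool), length(de_idx), replace = TRUE)]
      truth <- list(de = data.frame(gene_id = gene_id[de_idx],
                                    log2fc = lfc,
                                    stringsAsFactors = FALSE),
                    inflated_group = if (config$dispersion_inflation_factor != 1)
                      config$inflated_group else NA_character_)
    } else {
      de_idx <- match(truth$de$gene_id, gene_id)
      if (anyNA(de_idx)) stop("truth DE genes not present in this layout")
      lfc <- truth$de$log2fc
    }
    mu_test <- mu
    mu_test[de_idx] <- mu[de_idx] * 2^lfc
    infl <- config$dispersion_inflation_factor
    alpha_ctrl <- alpha * if (config$inflated_group == "control") infl else 1
    alpha_test <- alpha * if (config$inflated_group == "test") infl else 1
    counts <- matrix(0, G, 2 * n)
    for (j in seq_len(n))
      counts[, j] <- rnbinom(G, mu = mu, size = 1 / alpha_ctrl)
    for (j in seq_len(n))
      counts[, n + j] <- rnbinom(G, mu = mu_test, size = 1 / alpha_test)
    rownames(counts) <- gene_id
    colnames(counts) <- c(sprintf("control_r%02d", seq_len(n)),
                          sprintf("test_r%02d", seq_len(n)))
    list(counts = counts,
         groups = rep(c("control", "test"), each = n),
         truth = truth)
  })
}

#' Read / write a tab-separated expression count table
#'
#' Header row `gene_id` followed by sample ids; one row per gene.
#' @param path file path.
#' @return matrix with gene ids as rownames.
#' @export
read_expression_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "gene_id") stop("first column must be gene_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  m
}

#' @rdname read_expression_table
#' @param counts matrix with gene ids as rownames.
#' @export
write_expression_table <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
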