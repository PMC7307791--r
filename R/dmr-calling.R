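#' Threshold parameters for the DMR-calling cascade
#'
#' The cascade: a CpG is *scoreable* for a group when its read coverage is
#' strictly greater than `min_coverage` in at least `min_replicates`
#' biological replicates; a scoreable CpG is *differentially methylated*
#' when the absolute group-mean difference exceeds `cpg_delta` (strict);
#' scoreable CpGs are binned into regions by proximity (consecutive gaps at
#' most `max_bin_gap`); only regions with at least `region_min_cpgs` CpGs
#' and a span strictly greater than `region_min_span` bp are analyzed; a
#' region is a bona fide DMR when at least `region_dm_fraction` of its CpGs
#' are differentially methylated (inclusive, so 1 of 3 qualifies) and the
#' absolute regional methylation change exceeds `region_delta` (strict).
#'
#' @param min_coverage reads; scoreability requires coverage strictly
#'   greater than this (default 8, i.e. at least 9 reads).
#' @param min_replicates replicates that must pass the coverage rule.
#' @param cpg_delta per-CpG methylation-fraction threshold (strict).
#' @param region_min_span bp; regions must span strictly more than this.
#' @param region_min_cpgs minimum CpGs per region (inclusive).
#' @param region_dm_fraction minimum fraction of differentially methylated
#'   CpGs per region (inclusive).
#' @param region_delta regional methylation-fraction threshold (strict).
#' @param max_bin_gap bp; consecutive scoreable CpGs further apart than this
#'   start a new region.  No canonical value exists for RRBS proximity
#'   binning; 250 bp approximates RRBS fragment clustering and is exposed
#'   here as a parameter.
#' @param scoreable_mode `"both_groups"`: the coverage rule must hold in
#'   each compared group separately (default); `"all_samples"`: the rule is
#'   applied to the pooled samples of both groups.
#' @return a `filter_params` list.
#' @export
filter_params <- function(min_coverage = 8L, min_replicates = 4L,
                          cpg_delta = 0.05, region_min_span = 50L,
                          region_min_cpgs = 3L, region_dm_fraction = 1 / 3,
                          region_delta = 0.05, max_bin_gap = 250L,
                          scoreable_mode = c("both_groups", "all_samples")) {
  scoreable_mode <- match.arg(scoreable_mode)
  p <- list(min_coverage = min_coverage, min_replicates = min_replicates,
            cpg_delta = cpg_delta, region_min_span = region_min_span,
            region_min_cpgs = region_min_cpgs,
            region_dm_fraction = region_dm_fraction,
            region_delta = region_delta, max_bin_gap = max_bin_gap,
            scoreable_mode = scoreable_mode)
  stopifnot(p$min_coverage > 0, p$min_replicates > 0, p$cpg_delta > 0,
            p$region_min_span > 0, p$region_min_cpgs > 0,
            p$region_delta > 0, p$max_bin_gap > 0,
            p$region_dm_fraction > 0, p$region_dm_fraction <= 1)
  class(p) <- "filter_params"
  p
}

#' Flag scoreable CpG sites for one group
#'
#' A site is scoreable when strictly more than `min_coverage` reads are
#' present in at least `min_replicates` replicates of the group.  Missing
#' cells (zero coverage) never pass.
#'
#' @param mat a [methylation_matrix()].
#' @param group a group label present in the sample metadata.
#' @param params a [filter_params()].
#' @return logical vector over `mat$sites`.
#' @export
flag_scoreable <- function(mat, group, params = filter_params()) {
  idx <- .sample_idx(mat, group)
  if (length(idx) < params$min_replicates)
    stop("group '", group, "' has fewer samples (", length(idx),
         ") than min_replicates (", params$min_replicates, ")")
  passing <- mat$total[, idx, drop = FALSE] > params$min_coverage
  rowSums(passing, na.rm = TRUE) >= params$min_replicates
}

#' Call per-CpG differential methylation between two groups
#'
#' For sites scoreable in both groups (or in the pooled samples, per
#' `scoreable_mode`), the group methylation level is the unweighted mean
#' over passing replicates (coverage strictly above `min_coverage`) of the
#' per-replicate methylation fraction.  A site is differentially methylated
#' when `|delta| > cpg_delta` with `delta = test - control` (strict, so a
#' difference of exactly the threshold does not qualify).
#'
#' @param mat a [methylation_matrix()].
#' @param control_group,test_group group labels.
#' @param params a [filter_params()].
#' @return data.frame with one row per site: `chrom`, `pos`, `scoreable`,
#'   `scoreable_control`, `scoreable_test`, `mean_control`, `mean_test`,
#'   `delta`, `differential`, `direction` (gain / loss / none).
#' @export
call_cpg_differential <- function(mat, control_group, test_group,
                                  params = filter_params()) {
  ic <- .sample_idx(mat, control_group)
  it <- .sample_idx(mat, test_group)
  sc_c <- flag_scoreable(mat, control_group, params)
  sc_t <- flag_scoreable(mat, test_group, params)
  scoreable <- if (params$scoreable_mode == "both_groups") {
    sc_c & sc_t
  } else {
    pooled <- mat$total[, c(ic, it), drop = FALSE] > params$min_coverage
    rowSums(pooled, na.rm = TRUE) >= params$min_replicates
  }
  frac <- .fractions(mat)
  group_mean <- function(idx) {
    f <- frac[, idx, drop = FALSE]
    pass <- mat$total[, idx, drop = FALSE] > params$min_coverage
    f[!pass | is.na(pass)] <- NA
    m <- rowMeans(f, na.rm = TRUE)
    m[is.nan(m)] <- NA
    m
  }
  mc <- group_mean(ic)
  mt <- group_mean(it)
  delta <- ifelse(scoreable, mt - mc, NA_real_)
  differential <- !is.na(delta) & abs(delta) > params$cpg_delta
  direction <- ifelse(differential, ifelse(delta > 0, "gain", "loss"), "none")
  data.frame(chrom = mat$sites$chrom, pos = mat$sites$pos,
             scoreable = scoreable, scoreable_control = sc_c,
             scoreable_test = sc_t,
             mean_control = ifelse(scoreable, mc, NA_real_),
             mean_test = ifelse(scoreable, mt, NA_real_),
             delta = delta, differential = differential,
             direction = direction, stringsAsFactors = FALSE)
}

#' Bin scoreable CpGs into proximity regions
#'
#' Greedy single-pass merge: consecutive scoreable CpGs on one chromosome
#' join a bin while their gap is at most `max_bin_gap`.  Bins are emitted
#' only with at least `region_min_cpgs` members and a span strictly greater
#' than `region_min_span` bp, where the span counts the final CpG
#' dinucleotide: `span = last - first + 2` and `end = last + 2` (0-based
#' half-open).
#'
#' @param sites data.frame with `chrom` and `pos`, sorted by position within
#'   chromosome (typically the scoreable subset of a matrix's site list).
#' @param params a [filter_params()].
#' @return data.frame of regions: `chrom`, `start`, `end`, `n_cpgs`, `span`,
#'   `cpg_density` (CpGs per 100 bp of span) and a `members` list-column of
#'   member positions.
#' @export
bin_regions <- function(sites, params = filter_params()) {
  stopifnot(all(c("chrom", "pos") %in% names(sites)))
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_cpgs = integer(), span = integer(),
                      cpg_density = numeric(), stringsAsFactors = FALSE)
  empty$members <- list()
  if (nrow(sites) == 0L) return(empty)
  out <- vector("list", 0L)
  for (chrom in unique(sites$chrom)) {
    pos <- sites$pos[sites$chrom == chrom]
    if (is.unsorted(pos, strictly = TRUE))
      stop("sites must be strictly sorted by position within chromosome")
    grp <- cumsum(c(1L, as.integer(diff(pos) > params$max_bin_gap)))
    for (g in split(pos, grp)) {
      n <- length(g)
      span <- g[n] - g[1L] + 2L
      if (n >= params$region_min_cpgs && span > params$region_min_span) {
        row <- data.frame(chrom = chrom, start = g[1L], end = g[n] + 2L,
                          n_cpgs = n, span = as.integer(span),
                          cpg_density = 100 * n / span,
                          stringsAsFactors = FALSE)
        row$members <- list(g)
        out[[length(out) + 1L]] <- row
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call differentially methylated regions (the full region table)
#'
#' For every binned region, the per-sample regional methylation fraction is
#' the unweighted mean over member CpGs of the per-CpG fraction (cells with
#' coverage contribute; missing cells are skipped), the group level is the
#' mean of those per-sample fractions over replicates, and
#' `delta = test - control`.  A region is a bona fide DMR when at least
#' `region_dm_fraction` of its CpGs are differentially methylated
#' (inclusive) *and* `|delta| > region_delta` (strict).  The baseline class
#' (hypo < 0.25, intermediate, hyper > 0.75) is determined solely by the
#' control-group mean.  `aux_p` is an auxiliary two-sided Welch t-test on
#' the per-sample regional fractions; it is reported for variation
#' profiling and is never used in the calling decision.
#'
#' @param regions output of [bin_regions()] built from the same scoreable
#'   site set as `cpg_calls`.
#' @param cpg_calls output of [call_cpg_differential()].
#' @param mat the [methylation_matrix()].
#' @param control_group,test_group group labels.
#' @param params a [filter_params()].
#' @return data.frame with one row per analyzed region: coordinates,
#'   `n_cpgs`, `span`, `cpg_density`, `n_scoreable_cpgs`, `n_dm_cpgs`,
#'   `dm_fraction`, `mean_control`, `mean_test`, `delta`, `direction`,
#'   `baseline_class`, `sd_control`, `sd_test`, `aux_p`, `is_dmr`.
#' @export
call_dmrs <- function(regions, cpg_calls, mat, control_group, test_group,
                      params = filter_params()) {
  ic <- .sample_idx(mat, control_group)
  it <- .sample_idx(mat, test_group)
  skey <- .site_key(mat$sites$chrom, mat$sites$pos)
  ckey <- .site_key(cpg_calls$chrom, cpg_calls$pos)
  diff_flag <- setNames(cpg_calls$differential, ckey)
  cpg_scoreable <- setNames(cpg_calls$scoreable, ckey)
  frac <- .fractions(mat)
  n <- nrow(regions)
  res <- regions[, c("chrom", "start", "end", "n_cpgs", "span",
                     "cpg_density"), drop = FALSE]
  cols <- c("n_scoreable_cpgs", "n_dm_cpgs", "dm_fraction", "mean_control",
            "mean_test", "delta", "sd_control", "sd_test", "aux_p")
  for (cl in cols) res[[cl]] <- rep(NA_real_, n)
  res$direction <- rep(NA_character_, n)
  res$baseline_class <- rep(NA_character_, n)
  res$is_dmr <- rep(FALSE, n)
  for (i in seq_len(n)) {
    mk <- .site_key(regions$chrom[i], regions$members[[i]])
    ridx <- match(mk, skey)
    if (anyNA(ridx)) stop("region references sites absent from the matrix")
    sc <- cpg_scoreable[mk]
    df <- diff_flag[mk]
    if (anyNA(sc)) stop("region references sites absent from the CpG calls")
    sub <- frac[ridx, , drop = FALSE]
    fr_c <- colMeans(sub[, ic, drop = FALSE], na.rm = TRUE)
    fr_t <- colMeans(sub[, it, drop = FALSE], na.rm = TRUE)
    fr_c <- fr_c[!is.nan(fr_c)]
    fr_t <- fr_t[!is.nan(fr_t)]
    mc <- mean(fr_c); mt <- mean(fr_t)
    delta <- mt - mc
    n_sc <- sum(sc); n_dm <- sum(df[sc])
    dmf <- if (n_sc > 0) n_dm / n_sc else NA_real_
    res$n_scoreable_cpgs[i] <- n_sc
    res$n_dm_cpgs[i] <- n_dm
    res$dm_fraction[i] <- dmf
    res$mean_control[i] <- mc
    res$mean_test[i] <- mt
    res$delta[i] <- delta
    res$sd_control[i] <- sd(fr_c)
    res$sd_test[i] <- sd(fr_t)
    res$aux_p[i] <- tryCatch(t.test(fr_t, fr_c)$p.value,
                             error = function(e) NA_real_)
    res$direction[i] <- if (is.na(delta) || delta == 0) "none"
                        else if (delta > 0) "gain" else "loss"
    res$baseline_class[i] <- baseline_class(mc)
    res$is_dmr[i] <- !is.na(dmf) && !is.na(delta) &&
      (dmf + 1e-12 >= params$region_dm_fraction) &&
      abs(delta) > params$region_delta
  }
  rownames(res) <- NULL
  res
}

.region_key <- function(df) sprintf("%s:%d-%d", df$chrom, df$start, df$end)
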