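#' Classify DMR dynamics between an exposure and a recovery timepoint
#'
#' Given region tables from [call_dmrs()] for the exposure timepoint (t0)
#' and a recovery timepoint (t), both called against the same control on
#' one shared binning, every region that is a DMR in at least one of the
#' two sets receives exactly one status: `shared` (DMR in both),
#' `recovered` (DMR at t0 only) or `new` (DMR at t only).  Status ignores
#' the direction of change, but both directions are recorded and
#' direction-discordant shared regions are flagged.
#'
#' @param table_t0,table_t full region tables (with `is_dmr`) from
#'   [call_dmrs()].  Regions are identified by exact coordinates; tables
#'   whose regions overlap without coinciding indicate different binnings
#'   and raise an error.
#' @return data.frame of labels: `chrom`, `start`, `end`, `status`,
#'   `direction` (at the timepoint where the region is, or was, a DMR:
#'   t0 for shared and recovered, t for new), `direction_t0`, `direction_t`,
#'   `discordant`.
#' @export
classify_recovery <- function(table_t0, table_t) {
  k0 <- .region_key(table_t0)
  kt <- .region_key(table_t)
  # coordinate-compatibility check: overlapping regions must coincide
  g0 <- GenomicRanges::GRanges(table_t0$chrom,
                               IRanges::IRanges(table_t0$start + 1L, table_t0$end))
  gt <- GenomicRanges::GRanges(table_t$chrom,
                               IRanges::IRanges(table_t$start + 1L, table_t$end))
  hits <- GenomicRanges::findOverlaps(g0, gt)
  if (length(hits)) {
    mism <- k0[S4Vectors::queryHits(hits)] != kt[S4Vectors::subjectHits(hits)]
    if (any(mism))
      stop("region universes overlap without coinciding; ",
           "both timepoints must be called on one shared binning")
  }
  dmr0 <- k0[table_t0$is_dmr]
  dmrt <- kt[table_t$is_dmr]
  keys <- union(dmr0, dmrt)
  if (!length(keys)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), status = character(),
                      direction = character(), direction_t0 = character(),
                      direction_t = character(), discordant = logical(),
                      stringsAsFactors = FALSE))
  }
  status <- ifelse(keys %in% dmr0 & keys %in% dmrt, "shared",
                   ifelse(keys %in% dmr0, "recovered", "new"))
  i0 <- match(keys, k0)
  it <- match(keys, kt)
  dir0 <- ifelse(is.na(i0), NA_character_, table_t0$direction[i0])
  dirt <- ifelse(is.na(it), NA_character_, table_t$direction[it])
  chrom <- ifelse(status == "new", table_t$chrom[it], table_t0$chrom[i0])
  start <- ifelse(status == "new", table_t$start[it], table_t0$start[i0])
  end <- ifelse(status == "new", table_t$end[it], table_t0$end[i0])
  direction <- ifelse(status == "new", dirt, dir0)
  discordant <- status == "shared" & !is.na(dir0) & !is.na(dirt) & dir0 != dirt
  out <- data.frame(chrom = chrom, start = as.integer(start),
                    end = as.integer(end), status = status,
                    direction = direction, direction_t0 = dir0,
                    direction_t = dirt, discordant = discordant,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Stratify recovery status by baseline methylation class and direction
#'
#' Cross-tabulates the t0 DMRs (shared + recovered labels) over the six
#' strata baseline class (hypo / intermediate / hyper, from the t0 control
#' mean) x direction (gain / loss), and reports the recovered fraction
#' `recovered / (recovered + shared)` per stratum.  `new` regions are not
#' part of the denominator; their per-stratum counts are reported when they
#' match a region in `table_t0`.
#'
#' @param labels output of [classify_recovery()].
#' @param table_t0 the exposure-timepoint region table (source of baseline
#'   class and direction).
#' @return data.frame with one row per stratum: `baseline_class`,
#'   `direction`, `n_shared`, `n_recovered`, `n_new`, `recovered_fraction`.
#' @export
stratify_recovery <- function(labels, table_t0) {
  k0 <- .region_key(table_t0)
  kl <- .region_key(labels)
  i0 <- match(kl, k0)
  cls <- table_t0$baseline_class[i0]
  dir <- labels$direction
  strata <- expand.grid(baseline_class = c("hypo", "intermediate", "hyper"),
                        direction = c("gain", "loss"),
                        stringsAsFactors = FALSE)
  count <- function(b, d, s)
    sum(!is.na(cls) & cls == b & dir == d & labels$status == s, na.rm = TRUE)
  strata$n_shared <- mapply(count, strata$baseline_class, strata$direction,
                            MoreArgs = list(s = "shared"))
  strata$n_recovered <- mapply(count, strata$baseline_class,
                               strata$direction, MoreArgs = list(s = "recovered"))
  strata$n_new <- mapply(count, strata$baseline_class, strata$direction,
                         MoreArgs = list(s = "new"))
  denom <- strata$n_shared + strata$n_recovered
  strata$recovered_fraction <- ifelse(denom > 0,
                                      strata$n_recovered / denom, NA_real_)
  strata
}

#' CpG-density profile of recovery classes
#'
#' Summarizes the CpG density (members per 100 bp of span) of labeled
#' regions per status x direction class, and compares the densities of
#' recovered gains against recovered losses with a two-sided rank test.
#'
#' @param labels output of [classify_recovery()].
#' @param table_t0,table_t region tables carrying `cpg_density`.
#' @return list with `summary` (per-class n, median and quartiles) and
#'   `test` (Wilcoxon rank-sum of recovered-gain vs recovered-loss density;
#'   `NULL` when either class is empty).
#' @export
density_profile <- function(labels, table_t0, table_t) {
  dens <- .label_metric(labels, table_t0, table_t, "cpg_density")
  classes <- expand.grid(status = c("shared", "recovered", "new"),
                         direction = c("gain", "loss"),
                         stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(seq_len(nrow(classes)), function(i) {
    v <- dens[labels$status == classes$status[i] &
                labels$direction == classes$direction[i]]
    v <- v[!is.na(v)]
    data.frame(status = classes$status[i], direction = classes$direction[i],
               n = length(v),
               median = if (length(v)) median(v) else NA_real_,
               q25 = if (length(v)) unname(quantile(v, 0.25)) else NA_real_,
               q75 = if (length(v)) unname(quantile(v, 0.75)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rg <- dens[labels$status == "recovered" & labels$direction == "gain"]
  rl <- dens[labels$status == "recovered" & labels$direction == "loss"]
  test <- if (length(rg) && length(rl)) .rank_test(rg, rl) else NULL
  list(summary = summ, test = test)
}

#' Replicate-variation profile of recovery classes
#'
#' Summarizes the within-group replicate standard deviation of regional
#' methylation per status and compares shared vs recovered regions with a
#' two-sided rank test.  With an empty class the test is skipped and
#' flagged.
#'
#' @param labels output of [classify_recovery()].
#' @param table_t0,table_t region tables carrying `sd_control`/`sd_test`.
#' @param which_sd use the test-group (`"test"`, default) or control-group
#'   replicate SD.
#' @return list with `summary` (per-status n, median SD), `test` (Wilcoxon
#'   shared vs recovered or `NULL`), and `skipped` flag.
#' @export
variation_profile <- function(labels, table_t0, table_t,
                              which_sd = c("test", "control")) {
  which_sd <- match.arg(which_sd)
  col <- paste0("sd_", which_sd)
  v <- .label_metric(labels, table_t0, table_t, col)
  summ <- do.call(rbind, lapply(c("shared", "recovered", "new"), function(s) {
    x <- v[labels$status == s]
    x <- x[!is.na(x)]
    data.frame(status = s, n = length(x),
               median_sd = if (length(x)) median(x) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  sh <- v[labels$status == "shared"]
  re <- v[labels$status == "recovered"]
  skipped <- !length(sh) || !length(re)
  test <- if (!skipped) .rank_test(sh, re) else NULL
  list(summary = summ, test = test, skipped = skipped)
}

# two-sided rank-sum test; fully tied inputs are degenerate (p = 1)
.rank_test <- function(x, y) {
  ht <- suppressWarnings(wilcox.test(x, y))
  if (is.nan(ht$p.value)) ht$p.value <- 1
  ht
}

# fetch a per-region column for each label row (t0 table for shared and
# recovered, t table for new)
.label_metric <- function(labels, table_t0, table_t, col) {
  k0 <- .region_key(table_t0)
  kt <- .region_key(table_t)
  kl <- .region_key(labels)
  v <- table_t0[[col]][match(kl, k0)]
  isnew <- labels$status == "new"
  v[isnew] <- table_t[[col]][match(kl[isnew], kt)]
  v
}

#' Restrict recovery labels to regions overlapping simulation truth
#'
#' Filters a label table to the regions that overlap an injected truth
#' region, so stratified summaries can be computed over the known effects
#' alone, free of dilution by chance calls at null regions.
#'
#' @param labels output of [classify_recovery()].
#' @param truth a `simulation_truth` (or its `$regions` data.frame).
#' @return the subset of `labels` overlapping a truth region.
#' @export
labels_at_truth <- function(labels, truth) {
  tr <- if (inherits(truth, "simulation_truth")) truth$regions else truth
  if (!nrow(labels) || !nrow(tr)) return(labels[integer(), , drop = FALSE])
  gl <- GenomicRanges::GRanges(labels$chrom,
                               IRanges::IRanges(labels$start + 1L, labels$end))
  gt <- GenomicRanges::GRanges(tr$chrom,
                               IRanges::IRanges(tr$start + 1L, tr$end))
  keep <- GenomicRanges::countOverlaps(gl, gt) > 0L
  labels[keep, , drop = FALSE]
}

#' Score dynamics classification against simulation truth
#'
#' Maps truth dynamics classes onto expected recovery labels (persist ->
#' shared, decay -> recovered, emerge -> new), finds for each truth region
#' the labeled region with maximal coordinate overlap, and reports
#' per-class accuracy.  A truth region with no overlapping label counts as
#' misclassified.
#'
#' @param truth a `simulation_truth` (or its `$regions` data.frame).
#' @param labels output of [classify_recovery()].
#' @return data.frame per dynamics class: `dynamics`, `expected_status`,
#'   `n`, `n_correct`, `accuracy`.
#' @export
score_dynamics <- function(truth, labels) {
  tr <- if (inherits(truth, "simulation_truth")) truth$regions else truth
  map <- c(persist = "shared", decay = "recovered", emerge = "new")
  observed <- rep(NA_character_, nrow(tr))
  if (nrow(labels) && nrow(tr)) {
    gt <- GenomicRanges::GRanges(tr$chrom,
                                 IRanges::IRanges(tr$start + 1L, tr$end))
    gl <- GenomicRanges::GRanges(labels$chrom,
                                 IRanges::IRanges(labels$start + 1L, labels$end))
    hits <- GenomicRanges::findOverlaps(gt, gl)
    if (length(hits)) {
      ov <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(gt)[S4Vectors::queryHits(hits)],
        IRanges::ranges(gl)[S4Vectors::subjectHits(hits)]))
      best <- tapply(seq_along(ov), S4Vectors::queryHits(hits),
                     function(ii) ii[which.max(ov[ii])])
      qh <- as.integer(names(best))
      observed[qh] <- labels$status[S4Vectors::subjectHits(hits)[unlist(best)]]
    }
  }
  do.call(rbind, lapply(names(map), function(d) {
    sel <- tr$dynamics == d
    n <- sum(sel)
    ok <- sum(observed[sel] == map[[d]], na.rm = TRUE)
    data.frame(dynamics = d, expected_status = map[[d]], n = n,
               n_correct = ok,
               accuracy = if (n > 0) ok / n else NA_real_,
               stringsAsFactors = FALSE)
  }))
}
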