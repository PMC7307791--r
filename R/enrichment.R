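#' Construct an interval set over a genome layout
#'
#' Intervals are 0-based half-open and must lie within the layout's
#' chromosome bounds.
#'
#' @param intervals data.frame with `chrom`, `start`, `end`.
#' @param layout a [genome_layout()].
#' @return an `interval_set`.
#' @export
interval_set <- function(intervals, layout) {
  .check_layout(layout)
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (nrow(intervals)) {
    L <- .chrom_length(layout, intervals$chrom)
    if (any(intervals$start < 0) || any(intervals$end > L) ||
        any(intervals$start >= intervals$end))
      stop("intervals must satisfy 0 <= start < end <= chromosome length")
  }
  structure(list(intervals = intervals[, c("chrom", "start", "end"),
                                       drop = FALSE],
                 layout = layout),
            class = "interval_set")
}

.iset_granges <- function(x) {
  GenomicRanges::GRanges(
    factor(x$intervals$chrom, levels = x$layout$chrom),
    IRanges::IRanges(x$intervals$start + 1L, x$intervals$end))
}

#' Build promoter-proxy windows around TSS points
#'
#' Windows `[tss - half_width, tss + half_width)` clipped to chromosome
#' bounds; the default 1 kb half-width yields the usual "within 1 kb of a
#' TSS" promoter proxy.
#'
#' @param tss_points data.frame with `chrom` and `pos` (0-based TSS points).
#' @param half_width bp either side of the TSS.
#' @param layout a [genome_layout()].
#' @return an [interval_set()] of windows.
#' @export
tss_windows <- function(tss_points, half_width = 1000L, layout) {
  .check_layout(layout)
  stopifnot(all(c("chrom", "pos") %in% names(tss_points)))
  L <- .chrom_length(layout, tss_points$chrom)
  if (nrow(tss_points) && (any(tss_points$pos < 0) || any(tss_points$pos >= L)))
    stop("TSS points must lie within chromosome bounds")
  interval_set(data.frame(
    chrom = tss_points$chrom,
    start = as.integer(pmax(0, tss_points$pos - half_width)),
    end = as.integer(pmin(L, tss_points$pos + half_width)),
    stringsAsFactors = FALSE), layout)
}

#' Count query intervals overlapping any target
#'
#' Half-open semantics: abutting intervals (`[0,100)` vs `[100,200)`) do not
#' overlap; a single shared base pair counts.  Each query interval is
#' counted at most once regardless of how many targets it touches.
#'
#' @param query,targets [interval_set()]s over the same layout.
#' @return integer count of distinct query intervals with at least one
#'   overlapping target.
#' @export
count_overlapping <- function(query, targets) {
  stopifnot(inherits(query, "interval_set"), inherits(targets, "interval_set"))
  if (!identical(query$layout, targets$layout))
    stop("query and target interval sets use different layouts")
  if (nrow(query$intervals) == 0L || nrow(targets$intervals) == 0L)
    return(0L)
  sum(GenomicRanges::countOverlaps(.iset_granges(query),
                                   .iset_granges(targets)) > 0L)
}

# vectorized length-preserving uniform re-placement; lens and layout only.
# returns data.frame(chrom, start) for n placements of each length
.shuffle_place <- function(lens, layout) {
  nchr <- nrow(layout)
  chrom <- character(length(lens))
  start <- numeric(length(lens))
  for (i in seq_along(lens)) {
    placeable <- pmax(0, layout$length - lens[i] + 1)
    if (sum(placeable) == 0)
      stop("interval of length ", lens[i],
           " is longer than every chromosome")
    ci <- sample.int(nchr, 1L, prob = placeable)
    chrom[i] <- layout$chrom[ci]
    start[i] <- floor(runif(1, 0, placeable[ci]))
  }
  data.frame(chrom = chrom, start = start, stringsAsFactors = FALSE)
}

#' Shuffle intervals uniformly across the genome (length-preserving)
#'
#' Each interval is re-placed uniformly at random with its length preserved;
#' the chromosome is chosen with probability proportional to the number of
#' placeable start positions, so placement is uniform over all genome-wide
#' positions where the interval fits.  Shuffled intervals may overlap each
#' other.  With `chrom_restricted = TRUE` each interval stays on its
#' original chromosome.
#'
#' @param x an [interval_set()].
#' @param seed integer seed (placement is deterministic given it).
#' @param chrom_restricted keep each interval on its own chromosome.
#' @return a shuffled [interval_set()].
#' @export
shuffle_intervals <- function(x, seed, chrom_restricted = FALSE) {
  stopifnot(inherits(x, "interval_set"))
  lens <- x$intervals$end - x$intervals$start
  withr::with_seed(as.integer(seed), {
    if (chrom_restricted) {
      L <- .chrom_length(x$layout, x$intervals$chrom)
      placeable <- L - lens + 1
      if (any(placeable <= 0))
        stop("interval longer than its chromosome")
      start <- floor(runif(length(lens), 0, placeable))
      df <- data.frame(chrom = x$intervals$chrom, start = start)
    } else {
      df <- .shuffle_place(lens, x$layout)
    }
    interval_set(data.frame(chrom = df$chrom,
                            start = as.integer(df$start),
                            end = as.integer(df$start + lens),
                            stringsAsFactors = FALSE), x$layout)
  })
}

#' Permutation test for interval-set overlap enrichment
#'
#' The observed statistic is the number of distinct `dmrs` intervals
#' overlapping any window ([count_overlapping()]).  Each permutation
#' re-places the window set uniformly at random (length-preserving,
#' genome-wide) and recounts; the empirical p-value uses the add-one rule
#' `p = (1 + #\{null >= observed\}) / (n_perm + 1)`, so p is never exactly
#' zero.  Set `shuffle_set = "dmrs"` to permute the other set instead.
#'
#' @param dmrs,windows [interval_set()]s over the same layout.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed for the permutation stream.
#' @param shuffle_set which set to re-place under the null.
#' @return a `permutation_result`: `observed`, `null_counts`, `p`, `n_perm`,
#'   `seed`.
#' @export
permutation_enrichment <- function(dmrs, windows, n_perm = 1000L, seed = 1L,
                                   shuffle_set = c("windows", "dmrs")) {
  shuffle_set <- match.arg(shuffle_set)
  stopifnot(n_perm >= 1)
  observed <- count_overlapping(dmrs, windows)
  fixed <- if (shuffle_set == "windows") dmrs else windows
  moving <- if (shuffle_set == "windows") windows else dmrs
  layout <- moving$layout
  lens <- moving$intervals$end - moving$intervals$start
  nmov <- length(lens)
  null_counts <- withr::with_seed(substream_seed(seed, "shuffle"), {
    # all permutations placed in one vectorized draw, then one overlap join
    placeable <- outer(layout$length, lens, function(L, l) pmax(0, L - l + 1))
    if (any(colSums(placeable) == 0))
      stop("interval longer than every chromosome")
    total <- n_perm * nmov
    lens_all <- rep(lens, n_perm)
    ci <- integer(total)
    for (j in seq_len(nmov)) {
      idx <- seq.int(j, total, by = nmov)
      ci[idx] <- sample.int(nrow(layout), n_perm, replace = TRUE,
                            prob = placeable[, j])
    }
    start <- floor(runif(total) * placeable[cbind(ci, rep(seq_len(nmov), n_perm))])
    gmov <- GenomicRanges::GRanges(
      factor(layout$chrom[ci], levels = layout$chrom),
      IRanges::IRanges(start + 1L, start + lens_all))
    gfix <- .iset_granges(fixed)
    hits <- GenomicRanges::findOverlaps(gfix, gmov)
    counts <- integer(n_perm)
    if (length(hits)) {
      if (shuffle_set == "windows") {
        # statistic counts distinct DMRs (the fixed set) per permutation
        nfix <- length(gfix)
        perm_of <- (S4Vectors::subjectHits(hits) - 1L) %/% nmov + 1L
        id <- unique((perm_of - 1) * nfix + S4Vectors::queryHits(hits))
        counts <- tabulate((id - 1) %/% nfix + 1, nbins = n_perm)
      } else {
        # statistic counts distinct shuffled DMRs per permutation
        id <- unique(S4Vectors::subjectHits(hits))
        counts <- tabulate((id - 1L) %/% nmov + 1L, nbins = n_perm)
      }
    }
    counts
  })
  p <- (1 + sum(null_counts >= observed)) / (n_perm + 1)
  structure(list(observed = observed, null_counts = null_counts, p = p,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("permutation enrichment: observed =", x$observed,
      "| null mean =", round(mean(x$null_counts), 2),
      "| p =", signif(x$p, 4), sprintf("(%d permutations)\n", x$n_perm))
  invisible(x)
}

#' Upper-tail hypergeometric overlap test
#'
#' Probability of observing at least `overlap` shared items between two sets
#' of sizes `size_a` and `size_b` drawn without replacement from a universe
#' of `universe_size` items.
#'
#' @param universe_size,size_a,size_b,overlap non-negative integers with
#'   `overlap <= min(size_a, size_b)` and `size_a, size_b <= universe_size`.
#' @return an `overlap_test`: `N`, `K`, `n`, `k`, `expected`, `p`.
#' @examples
#' hypergeometric_overlap(10, 5, 5, 5)$p  # 1/252
#' @export
hypergeometric_overlap <- function(universe_size, size_a, size_b, overlap) {
  N <- universe_size; K <- size_a; n <- size_b; k <- overlap
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(K, n))
    stop("inconsistent set sizes for hypergeometric overlap")
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  structure(list(N = N, K = K, n = n, k = k,
                 expected = K * n / max(N, 1), p = p),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "hypergeometric overlap: k = %d (expected %.2f) of K = %d, n = %d in N = %d; p = %.4g\n",
    x$k, x$expected, x$K, x$n, x$N, x$p))
  invisible(x)
}

#' Correlate methylation (or expression) changes between two comparisons
#'
#' Pearson correlation of per-region deltas (or per-gene log2 fold changes)
#' over the items present in both comparisons.  With
#' `region_filter = "union_of_dmrs"` (the default when `is_dmr` flags are
#' available) the correlation is restricted to regions that are a DMR in at
#' least one comparison.
#'
#' @param cmp_a,cmp_b data.frames carrying either region coordinates
#'   (`chrom`, `start`, `end`) or a `gene_id` column, plus a `delta` or
#'   `log2fc` value column and optionally `is_dmr`.
#' @param region_filter `"union_of_dmrs"` or `"all"`.
#' @return list with `r` (Pearson correlation) and `n` (items used).
#' @export
delta_correlation <- function(cmp_a, cmp_b,
                              region_filter = c("union_of_dmrs", "all")) {
  region_filter <- match.arg(region_filter)
  value_col <- function(df) {
    if ("delta" %in% names(df)) "delta"
    else if ("log2fc" %in% names(df)) "log2fc"
    else stop("comparison table needs a 'delta' or 'log2fc' column")
  }
  key <- function(df) {
    if ("gene_id" %in% names(df)) df$gene_id else .region_key(df)
  }
  ka <- key(cmp_a); kb <- key(cmp_b)
  common <- intersect(ka, kb)
  ia <- match(common, ka); ib <- match(common, kb)
  va <- cmp_a[[value_col(cmp_a)]][ia]
  vb <- cmp_b[[value_col(cmp_b)]][ib]
  keep <- !is.na(va) & !is.na(vb)
  if (region_filter == "union_of_dmrs" &&
      all(c("is_dmr") %in% names(cmp_a)) && "is_dmr" %in% names(cmp_b)) {
    keep <- keep & (cmp_a$is_dmr[ia] | cmp_b$is_dmr[ib])
  }
  if (sum(keep) < 3)
    stop("fewer than 3 common regions after filtering; ",
         "cannot compute a correlation")
  list(r = unname(cor(va[keep], vb[keep])), n = sum(keep))
}
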