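# Independent brute-force oracles, written naively and sharing no code with
# the package internals.

# full DMR-calling cascade: plain loops over sites and regions
bf_dmr_pipeline <- function(mat, control, test, min_cov = 8, min_rep = 4,
                            cpg_delta = 0.05, min_span = 50, min_cpgs = 3,
                            dm_frac = 1 / 3, region_delta = 0.05,
                            gap = 250) {
  ic <- which(mat$samples$group == control)
  it <- which(mat$samples$group == test)
  ns <- nrow(mat$sites)
  scoreable <- logical(ns)
  mean_c <- rep(NA_real_, ns)
  mean_t <- rep(NA_real_, ns)
  for (i in seq_len(ns)) {
    nc <- 0; nt <- 0
    for (j in ic) if (!is.na(mat$total[i, j]) && mat$total[i, j] > min_cov)
      nc <- nc + 1
    for (j in it) if (!is.na(mat$total[i, j]) && mat$total[i, j] > min_cov)
      nt <- nt + 1
    scoreable[i] <- nc >= min_rep && nt >= min_rep
    fc <- c(); ft <- c()
    for (j in ic) if (!is.na(mat$total[i, j]) && mat$total[i, j] > min_cov)
      fc <- c(fc, mat$meth[i, j] / mat$total[i, j])
    for (j in it) if (!is.na(mat$total[i, j]) && mat$total[i, j] > min_cov)
      ft <- c(ft, mat$meth[i, j] / mat$total[i, j])
    if (length(fc)) mean_c[i] <- mean(fc)
    if (length(ft)) mean_t[i] <- mean(ft)
  }
  delta <- ifelse(scoreable, mean_t - mean_c, NA)
  differential <- !is.na(delta) & abs(delta) > cpg_delta

  # proximity binning of scoreable sites
  regions <- list()
  for (chrom in unique(mat$sites$chrom)) {
    idx <- which(mat$sites$chrom == chrom & scoreable)
    if (!length(idx)) next
    pos <- mat$sites$pos[idx]
    cur <- idx[1]
    for (k in seq_along(idx)[-1]) {
      if (mat$sites$pos[idx[k]] - mat$sites$pos[cur[length(cur)]] <= gap) {
        cur <- c(cur, idx[k])
      } else {
        regions[[length(regions) + 1]] <- cur
        cur <- idx[k]
      }
    }
    regions[[length(regions) + 1]] <- cur
  }
  out <- NULL
  for (r in regions) {
    pos <- mat$sites$pos[r]
    span <- pos[length(pos)] - pos[1] + 2
    if (length(r) < min_cpgs || span <= min_span) next
    # per-sample regional fraction: mean over member CpGs of covered fractions
    reg_frac <- function(j) {
      f <- c()
      for (i in r) if (!is.na(mat$total[i, j]))
        f <- c(f, mat$meth[i, j] / mat$total[i, j])
      if (length(f)) mean(f) else NA
    }
    fc <- c(); ft <- c()
    for (j in ic) { v <- reg_frac(j); if (!is.na(v)) fc <- c(fc, v) }
    for (j in it) { v <- reg_frac(j); if (!is.na(v)) ft <- c(ft, v) }
    mc <- mean(fc); mt <- mean(ft)
    d <- mt - mc
    ndm <- sum(differential[r])
    is_dmr <- (ndm / length(r) >= dm_frac - 1e-12) && abs(d) > region_delta
    out <- rbind(out, data.frame(
      chrom = mat$sites$chrom[r[1]], start = pos[1],
      end = pos[length(pos)] + 2L, n_cpgs = length(r), n_dm = ndm,
      delta = d, is_dmr = is_dmr, stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_cpgs = integer(), n_dm = integer(),
                      delta = numeric(), is_dmr = logical())
  rownames(out) <- NULL
  out
}

# all-pairs overlap count of distinct query intervals (half-open)
bf_count_overlaps <- function(q, t) {
  cnt <- 0L
  for (i in seq_len(nrow(q))) {
    hit <- FALSE
    for (j in seq_len(nrow(t))) {
      if (q$chrom[i] == t$chrom[j] &&
          q$start[i] < t$end[j] && t$start[j] < q$end[i]) {
        hit <- TRUE
        break
      }
    }
    if (hit) cnt <- cnt + 1L
  }
  cnt
}

# vectorized-per-query variant for larger instances (still all-pairs logic)
bf_count_overlaps_fast <- function(q, t) {
  cnt <- 0L
  for (i in seq_len(nrow(q))) {
    if (any(q$chrom[i] == t$chrom & q$start[i] < t$end & t$start < q$end[i]))
      cnt <- cnt + 1L
  }
  cnt
}

# upper-tail hypergeometric probability by exhaustive enumeration of draws
bf_hyper <- function(N, K, n, k) {
  if (n == 0) return(if (k <= 0) 1 else 0)
  draws <- utils::combn(N, n)
  inA <- seq_len(K)
  ov <- apply(draws, 2, function(d) sum(d %in% inA))
  mean(ov >= k)
}

# independently coded median-of-ratios size factors (median taken on the
# log scale)
bf_size_factors <- function(counts) {
  G <- nrow(counts)
  geo <- numeric(G)
  for (g in seq_len(G)) geo[g] <- exp(mean(log(counts[g, ])))
  sf <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    lr <- c()
    for (g in seq_len(G)) {
      if (is.finite(log(geo[g])) && geo[g] > 0 && counts[g, j] > 0)
        lr <- c(lr, log(counts[g, j] / geo[g]))
    }
    lr <- sort(lr)
    m <- length(lr)
    med <- if (m %% 2 == 1) lr[(m + 1) / 2] else (lr[m / 2] + lr[m / 2 + 1]) / 2
    sf[j] <- exp(med)
  }
  sf
}
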