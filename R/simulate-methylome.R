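#' Generate a clustered CpG landscape
#'
#' CpG positions per chromosome arise from the superposition of a sparse
#' background Poisson point process (mean spacing `background_spacing`) and
#' dense island-like clusters (cluster seeds are a Poisson process of rate
#' `cpg_cluster_rate` per bp; within a cluster, spacings are exponential
#' with mean `within_cluster_spacing`, floored at 2 bp so CpG dinucleotides
#' never overlap).  With `cpg_cluster_rate = 0` all spacings come from the
#' background process alone.
#'
#' @param layout a [genome_layout()].
#' @param config a [sim_config()]; only the landscape fields and `seed`
#'   (substream "landscape") are used.
#' @return a `cpg_landscape`: a named list of strictly increasing 0-based
#'   positions per chromosome, with the layout attached as an attribute.
#' @export
generate_cpg_landscape <- function(layout, config) {
  .check_layout(layout)
  validate_sim_config(config)
  if (any(layout$length < 4))
    stop("layout too small to place CpG features (chromosome shorter than 4 bp)")
  land <- with_substream(config$seed, "landscape", {
    out <- vector("list", nrow(layout))
    names(out) <- layout$chrom
    for (i in seq_len(nrow(layout))) {
      L <- layout$length[i]
      n_bg <- rpois(1L, L / config$background_spacing)
      bg <- if (n_bg > 0)
        sort(sample.int(max(L - 1, 1), min(n_bg, L - 1))) - 1L
      else integer()
      cl <- integer()
      n_cl <- rpois(1L, L * config$cpg_cluster_rate)
      if (n_cl > 0) {
        for (j in seq_len(n_cl)) {
          center <- sample.int(L, 1L) - 1L
          size <- 2L + rpois(1L, max(config$cluster_size_mean - 2, 0))
          gaps <- if (size > 1L)
            pmax(2, round(rexp(size - 1L, 1 / config$within_cluster_spacing)))
          else numeric()
          p <- center + c(0, cumsum(gaps))
          cl <- c(cl, p[p <= L - 2])
        }
      }
      pos <- sort(unique(c(bg, as.integer(cl))))
      pos <- pos[pos >= 0 & pos <= L - 2]
      # enforce a minimum 2 bp gap between CpG starts
      repeat {
        d <- diff(pos)
        bad <- which(d < 2)
        if (!length(bad)) break
        pos <- pos[-(bad + 1L)]
      }
      out[[i]] <- as.integer(pos)
    }
    out
  })
  structure(land, class = "cpg_landscape", layout = layout)
}

.landscape_sites <- function(landscape) {
  data.frame(
    chrom = rep(names(landscape), lengths(landscape)),
    pos = unlist(landscape, use.names = FALSE),
    stringsAsFactors = FALSE)
}

# draw beta-binomial counts: sizes n, mean fraction pi, correlation rho
.rbetabinom <- function(n, pi, rho) {
  stopifnot(length(pi) == length(n))
  p <- pi
  mid <- pi > 0 & pi < 1
  if (rho > 0 && any(mid)) {
    a <- pi[mid] * (1 - rho) / rho
    b <- (1 - pi[mid]) * (1 - rho) / rho
    p[mid] <- rbeta(sum(mid), a, b)
  }
  rbinom(length(n), n, p)
}

# assign baselines, pick truth regions, assign effects + dynamics classes
.make_truth <- function(sites, config) {
  cand <- bin_regions(sites, filter_params())
  if (config$injected_dmr_count > nrow(cand))
    stop("layout too small: ", nrow(cand), " candidate regions but ",
         config$injected_dmr_count, " injected DMRs requested")
  bm <- config$baseline_mixture
  cls_names <- c("hypo", "intermediate", "hyper")
  draw_base <- function(classes) {
    mu <- bm$means[classes]
    conc <- config$baseline_concentration
    rbeta(length(classes), mu * conc, (1 - mu) * conc)
  }
  nbin <- nrow(cand)
  bin_cls <- sample(cls_names, nbin, replace = TRUE,
                    prob = bm$proportions[cls_names])
  bin_base <- draw_base(bin_cls)

  ns <- nrow(sites)
  skey <- .site_key(sites$chrom, sites$pos)
  site_pi0 <- rep(NA_real_, ns)
  site_bin <- rep(NA_integer_, ns)
  for (i in seq_len(nbin)) {
    idx <- match(.site_key(cand$chrom[i], cand$members[[i]]), skey)
    site_pi0[idx] <- bin_base[i]
    site_bin[idx] <- i
  }
  bgidx <- which(is.na(site_pi0))
  if (length(bgidx)) {
    bg_cls <- sample(cls_names, length(bgidx), replace = TRUE,
                     prob = bm$proportions[cls_names])
    site_pi0[bgidx] <- draw_base(bg_cls)
  }

  sel <- if (config$injected_dmr_count > 0)
    sort(sample.int(nbin, config$injected_dmr_count)) else integer()
  base_sel <- bin_base[sel]
  cls_sel <- baseline_class(base_sel)
  sign_sel <- switch(config$effect_direction,
    inward = ifelse(cls_sel == "hypo", 1,
                    ifelse(cls_sel == "hyper", -1,
                           sample(c(-1, 1), length(sel), replace = TRUE))),
    random = sample(c(-1, 1), length(sel), replace = TRUE))
  requested <- sign_sel * config$effect_size
  pi_treat <- pmin(1, pmax(0, base_sel + requested))
  realized <- pi_treat - base_sel
  clipped <- abs(realized - requested) > 1e-12

  # dynamics assignment, with decay preferentially at extreme-baseline
  # regions whose effect points inward (toward intermediate methylation)
  n <- length(sel)
  inward <- (cls_sel == "hypo" & requested > 0) |
    (cls_sel == "hyper" & requested < 0)
  dyn <- rep("persist", n)
  if (n > 0) {
    n_decay <- round(config$dynamics_mix[["decay"]] * n)
    n_emerge <- round(config$dynamics_mix[["emerge"]] * n)
    w <- 1 + 4 * config$dynamics_baseline_coupling * inward
    di <- if (n_decay > 0) sample.int(n, n_decay, prob = w) else integer()
    dyn[di] <- "decay"
    rest <- setdiff(seq_len(n), di)
    ei <- if (n_emerge > 0 && length(rest))
      rest[sample.int(length(rest), min(n_emerge, length(rest)))] else integer()
    dyn[ei] <- "emerge"
  }

  regions <- data.frame(
    chrom = cand$chrom[sel], start = cand$start[sel], end = cand$end[sel],
    n_cpgs = cand$n_cpgs[sel], baseline = base_sel,
    effect = requested, realized_effect = realized, clipped = clipped,
    direction = ifelse(realized > 0, "gain", ifelse(realized < 0, "loss", "none")),
    baseline_class = cls_sel, dynamics = dyn,
    stringsAsFactors = FALSE)

  site_effect <- rep(0, ns)
  site_dynamics <- rep(NA_character_, ns)
  for (r in seq_along(sel)) {
    idx <- which(site_bin == sel[r])
    site_effect[idx] <- realized[r]
    site_dynamics[idx] <- dyn[r]
  }
  structure(list(regions = regions, site_pi0 = site_pi0,
                 site_effect = site_effect, site_dynamics = site_dynamics),
            class = "simulation_truth")
}

#' Simulate a multi-group, multi-timepoint RRBS methylome
#'
#' Generates per-CpG methylated/total read counts for one control group and
#' one treatment group sampled at the configured timepoints.  Total reads
#' per cell follow a shifted Poisson with mean `mean_coverage`; methylated
#' reads follow a beta-binomial with site-level mean fraction and
#' between-replicate correlation `overdispersion`.  Injected truth regions
#' shift the treatment-group fraction by the (possibly clipped) effect,
#' gated by the region's dynamics class: `persist` effects are present at
#' every timepoint, `decay` effects only at the exposure timepoint, and
#' `emerge` effects only at recovery timepoints.  The control group is
#' sampled once and shared across comparisons, matching a design with a
#' single unexposed control cohort.
#'
#' @param layout a [genome_layout()].
#' @param config a [sim_config()].
#' @param landscape optional pre-generated [generate_cpg_landscape()] result
#'   (so two cohorts can share one CpG landscape).
#' @param truth optional pre-built truth (shares injected effects between
#'   cohorts); by default a fresh truth is drawn from substream "truth".
#' @return a `meth_simulation` list: `matrix` (a [methylation_matrix()] whose
#'   sample groups are `"control"` and `"treatment_t<day>"`), `truth` (the
#'   ground-truth ledger with `$regions`), and `landscape`.
#' @examples
#' lay <- genome_layout(c(chr1 = 3e5))
#' sim <- simulate_methylome(lay, sim_config(injected_dmr_count = 5, seed = 7))
#' sim$truth$regions[, c("chrom", "start", "end", "dynamics")]
#' @export
simulate_methylome <- function(layout, config, landscape = NULL, truth = NULL) {
  .check_layout(layout)
  validate_sim_config(config)
  if (config$n_replicates < 1L) stop("zero replicates requested")
  if (is.null(landscape)) landscape <- generate_cpg_landscape(layout, config)
  sites <- .landscape_sites(landscape)
  if (is.null(truth))
    truth <- with_substream(config$seed, "truth", .make_truth(sites, config))
  tps <- sort(config$timepoints)
  t0 <- tps[1L]
  nrep <- config$n_replicates
  groups <- c("control", paste0("treatment_t", tps))
  samples <- do.call(rbind, lapply(groups, function(g) {
    data.frame(sample_id = sprintf("%s_r%02d", g, seq_len(nrep)),
               group = g,
               timepoint = if (g == "control") NA_integer_
                           else as.integer(sub("treatment_t", "", g)),
               replicate = seq_len(nrep), stringsAsFactors = FALSE)
  }))
  ns <- nrow(sites)
  rho <- config$overdispersion
  # per-group site-level mean fractions, computed once
  pi_by_group <- setNames(vector("list", length(groups)), groups)
  pi_by_group[["control"]] <- truth$site_pi0
  for (tp in tps) {
    active <- !is.na(truth$site_dynamics) &
      ((truth$site_dynamics == "persist") |
         (truth$site_dynamics == "decay" & tp == t0) |
         (truth$site_dynamics == "emerge" & tp > t0))
    pi <- truth$site_pi0
    pi[active] <- pmin(1, pmax(0, pi[active] + truth$site_effect[active]))
    pi_by_group[[paste0("treatment_t", tp)]] <- pi
  }
  with_substream(config$seed, "counts", {
    meth <- matrix(NA_real_, ns, nrow(samples))
    total <- matrix(NA_real_, ns, nrow(samples))
    for (j in seq_len(nrow(samples))) {
      tot <- 1L + rpois(ns, config$mean_coverage - 1)
      pi <- pi_by_group[[samples$group[j]]]
      total[, j] <- tot
      meth[, j] <- .rbetabinom(tot, pi, rho)
    }
    mat <- methylation_matrix(sites, meth, total, samples)
    structure(list(matrix = mat, truth = truth, landscape = landscape),
              class = "meth_simulation")
  })
}

#' Generate TSS windows with controllable truth-region overlap
#'
#' Emits `tss_count` promoter-proxy windows of fixed 2 kb width (1 kb either
#' side of a TSS point, clipped to chromosome bounds).  A fraction
#' `tss_overlap_fraction` is placed to overlap injected truth regions; the
#' remainder is placed uniformly while avoiding them.
#'
#' @param layout a [genome_layout()].
#' @param truth a `simulation_truth` (from [simulate_methylome()]).
#' @param config a [sim_config()]; uses `tss_count`, `tss_overlap_fraction`
#'   and substream "annotation".
#' @return BED6-style data.frame of windows, with the TSS points attached as
#'   attribute `"tss"`.
#' @export
make_tss_annotation <- function(layout, truth, config) {
  .check_layout(layout)
  validate_sim_config(config)
  n <- config$tss_count
  n_ov <- round(config$tss_overlap_fraction * n)
  tr <- truth$regions
  if (n_ov > 0 && nrow(tr) == 0)
    stop("tss_overlap_fraction > 0 is infeasible with zero truth regions")
  chr_len <- setNames(layout$length, layout$chrom)
  with_substream(config$seed, "annotation", {
    chrom <- character(n); pos <- numeric(n)
    if (n_ov > 0) {
      pick <- sample.int(nrow(tr), n_ov, replace = n_ov > nrow(tr))
      for (i in seq_len(n_ov)) {
        r <- pick[i]
        L <- chr_len[[tr$chrom[r]]]
        lo <- max(0, tr$start[r] - 900)
        hi <- min(L - 1, tr$end[r] + 900)
        chrom[i] <- tr$chrom[r]
        pos[i] <- lo + floor(runif(1, 0, hi - lo + 1))
      }
    }
    if (n - n_ov > 0) {
      w <- layout$length / sum(layout$length)
      for (i in seq.int(n_ov + 1, n)) {
        ok <- FALSE
        for (try in seq_len(2000L)) {
          ci <- sample.int(nrow(layout), 1L, prob = w)
          L <- layout$length[ci]
          p <- floor(runif(1, 0, L))
          ws <- max(0, p - 1000); we <- min(L, p + 1000)
          hit <- nrow(tr) > 0 && any(tr$chrom == layout$chrom[ci] &
                                       tr$start < we & ws < tr$end)
          if (!hit) { chrom[i] <- layout$chrom[ci]; pos[i] <- p; ok <- TRUE; break }
        }
        if (!ok) stop("could not place a non-overlapping TSS window; ",
                      "truth regions cover too much of the layout")
      }
    }
    L <- chr_len[chrom]
    windows <- data.frame(
      chrom = chrom,
      start = as.integer(pmax(0, pos - 1000)),
      end = as.integer(pmin(L, pos + 1000)),
      name = sprintf("tss_%04d", seq_len(n)),
      score = 0, strand = "+", stringsAsFactors = FALSE)
    attr(windows, "tss") <- data.frame(chrom = chrom, pos = as.integer(pos),
                                       stringsAsFactors = FALSE)
    windows
  })
}

#' Write a simulated methylome to disk
#'
#' Emits one Bismark-dialect coverage file per sample, a YAML sample sheet,
#' and the truth ledger as a tab-separated table.
#'
#' @param sim a `meth_simulation`.
#' @param dir output directory (created if needed).
#' @return the sample-sheet path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mat <- sim$matrix
  entries <- vector("list", nrow(mat$samples))
  for (j in seq_len(nrow(mat$samples))) {
    id <- mat$samples$sample_id[j]
    fn <- file.path(dir, paste0(id, ".cov"))
    keep <- !is.na(mat$total[, j])
    write_coverage_file(data.frame(
      chrom = mat$sites$chrom[keep], pos = mat$sites$pos[keep],
      meth = mat$meth[keep, j], total = mat$total[keep, j]), fn)
    entries[[j]] <- c(list(path = paste0(id, ".cov")),
                      as.list(mat$samples[j, , drop = FALSE]))
  }
  write.table(sim$truth$regions, file.path(dir, "truth_regions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sheet <- file.path(dir, "samples.yaml")
  yaml::write_yaml(list(samples = entries), sheet)
  invisible(sheet)
}
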