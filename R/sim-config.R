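#' Simulation configuration for the synthetic RRBS study
#'
#' Defines the generative model for the synthetic methylome: a clustered CpG
#' landscape, a bimodal baseline methylation mixture, beta-binomial read
#' counts with biological overdispersion, injected group-level methylation
#' differences with timepoint dynamics (persist / decay / emerge), TSS
#' windows with controllable overlap, and a negative-binomial expression
#' experiment with optional dispersion inflation.
#'
#' Defaults describe the emulated study design: 10 replicates per group, an
#' exposure timepoint (day 0 post-exposure) plus one recovery timepoint
#' (day 28, just under one mouse spermatogenic cycle), ~30x mean CpG
#' coverage, beta-binomial rho = 0.1, and a bimodal baseline (most CpG
#' regions near 8% or 92% methylation, a minority intermediate).
#'
#' @param n_replicates biological replicates per group.
#' @param timepoints integer days post-exposure at which the treatment group
#'   is sampled; the first element is the exposure timepoint, later elements
#'   are recovery timepoints.  The control group is sampled once.
#' @param cpg_cluster_rate expected CpG clusters per bp (dense, island-like
#'   clusters).
#' @param cluster_size_mean mean CpGs per cluster.
#' @param within_cluster_spacing mean spacing (bp) between CpGs in a cluster.
#' @param background_spacing mean spacing (bp) of the sparse background CpG
#'   point process.
#' @param baseline_mixture list with `proportions` and `means`, each a named
#'   vector over classes hypo / intermediate / hyper; proportions must sum
#'   to 1 and means must lie in the matching class band (<0.25, 0.25-0.75,
#'   >0.75).
#' @param baseline_concentration beta concentration for per-region baseline
#'   draws around the class mean.
#' @param mean_coverage mean total reads per CpG per sample (shifted Poisson,
#'   so every cell has at least one read).
#' @param overdispersion beta-binomial correlation rho in `[0, 1)`; 0 gives
#'   pure binomial counts.
#' @param injected_dmr_count number of truth regions receiving an effect.
#' @param effect_size methylation-fraction delta injected into the treatment
#'   group (magnitude; sign is set per region via `effect_direction`).
#' @param effect_direction `"inward"` (default): hypomethylated regions gain,
#'   hypermethylated regions lose, intermediate regions get a random sign.
#'   Methylation fractions are bounded, so effects at the extremes can only
#'   move toward the middle; this also mirrors the observed predominance of
#'   gains at hypo- and losses at hyper-methylated regions.  `"random"`
#'   draws the sign uniformly everywhere; effects pushing the fraction
#'   outside `[0, 1]` are clipped and the clipping is recorded in the truth
#'   ledger.
#' @param dynamics_mix named proportions over persist / decay / emerge
#'   classes (must sum to 1).  persist effects are present at every
#'   timepoint, decay effects only at the exposure timepoint, emerge effects
#'   only at recovery timepoints.
#' @param dynamics_baseline_coupling in `[0, 1]`: strength with which the
#'   decay class is preferentially assigned to extreme-baseline regions
#'   whose effect points inward.  0 assigns dynamics classes independently
#'   of baseline.
#' @param tss_count number of TSS windows to generate.
#' @param tss_overlap_fraction fraction of TSS windows placed to overlap
#'   injected truth regions; the rest are placed uniformly avoiding them.
#' @param expression_gene_count,expression_de_count genes simulated and
#'   genes given a true expression effect.
#' @param expression_fold_changes pool of true log2 fold changes sampled for
#'   DE genes.
#' @param expression_mean_dispersion mean NB dispersion (alpha); per-gene
#'   dispersions are jittered around it on the log scale.
#' @param dispersion_inflation_factor multiplier applied to the dispersion of
#'   `inflated_group` (1 = no inflation).
#' @param inflated_group which expression group ("test" or "control")
#'   receives the dispersion inflation.
#' @param n_expression_replicates replicates per expression group.
#' @param seed integer root seed; all stages derive named substreams from it.
#' @return a validated `sim_config` list.
#' @seealso [simulate_methylome()], [simulate_expression()]
#' @export
sim_config <- function(n_replicates = 10L,
                       timepoints = c(0L, 28L),
                       cpg_cluster_rate = 1 / 5000,
                       cluster_size_mean = 8,
                       within_cluster_spacing = 15,
                       background_spacing = 400,
                       baseline_mixture = list(
                         proportions = c(hypo = 0.4, intermediate = 0.2, hyper = 0.4),
                         means = c(hypo = 0.08, intermediate = 0.5, hyper = 0.92)),
                       baseline_concentration = 60,
                       mean_coverage = 30,
                       overdispersion = 0.1,
                       injected_dmr_count = 75L,
                       effect_size = 0.25,
                       effect_direction = c("inward", "random"),
                       dynamics_mix = c(persist = 1 / 3, decay = 1 / 3, emerge = 1 / 3),
                       dynamics_baseline_coupling = 0.8,
                       tss_count = 134L,
                       tss_overlap_fraction = 0.25,
                       expression_gene_count = 2000L,
                       expression_de_count = 50L,
                       expression_fold_changes = c(-2, -1.5, 1.5, 2),
                       expression_mean_dispersion = 0.05,
                       dispersion_inflation_factor = 1,
                       inflated_group = "test",
                       n_expression_replicates = 8L,
                       seed = 1L) {
  effect_direction <- match.arg(effect_direction)
  cfg <- list(
    n_replicates = as.integer(n_replicates),
    timepoints = as.integer(timepoints),
    cpg_cluster_rate = cpg_cluster_rate,
    cluster_size_mean = cluster_size_mean,
    within_cluster_spacing = within_cluster_spacing,
    background_spacing = background_spacing,
    baseline_mixture = baseline_mixture,
    baseline_concentration = baseline_concentration,
    mean_coverage = mean_coverage,
    overdispersion = overdispersion,
    injected_dmr_count = as.integer(injected_dmr_count),
    effect_size = effect_size,
    effect_direction = effect_direction,
    dynamics_mix = dynamics_mix,
    dynamics_baseline_coupling = dynamics_baseline_coupling,
    tss_count = as.integer(tss_count),
    tss_overlap_fraction = tss_overlap_fraction,
    expression_gene_count = as.integer(expression_gene_count),
    expression_de_count = as.integer(expression_de_count),
    expression_fold_changes = expression_fold_changes,
    expression_mean_dispersion = expression_mean_dispersion,
    dispersion_inflation_factor = dispersion_inflation_factor,
    inflated_group = inflated_group,
    n_expression_replicates = as.integer(n_expression_replicates),
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_replicates < 1L) stop("n_replicates must be >= 1")
  if (length(cfg$timepoints) < 1L || anyDuplicated(cfg$timepoints) ||
      any(cfg$timepoints < 0L))
    stop("timepoints must be distinct non-negative days")
  if (cfg$mean_coverage <= 0) stop("mean_coverage must be > 0")
  if (cfg$overdispersion < 0 || cfg$overdispersion >= 1)
    stop("overdispersion rho must lie in [0, 1)")
  bm <- cfg$baseline_mixture
  cls <- c("hypo", "intermediate", "hyper")
  if (!setequal(names(bm$proportions), cls) || !setequal(names(bm$means), cls))
    stop("baseline_mixture needs proportions and means for hypo/intermediate/hyper")
  if (any(bm$proportions < 0) || abs(sum(bm$proportions) - 1) > 1e-8)
    stop("baseline_mixture proportions must be non-negative and sum to 1")
  if (bm$means[["hypo"]] >= 0.25 || bm$means[["hyper"]] <= 0.75 ||
      bm$means[["intermediate"]] < 0.25 || bm$means[["intermediate"]] > 0.75)
    stop("baseline_mixture means must lie in their class bands")
  if (abs(cfg$effect_size) > 1) stop("effect_size must lie in [-1, 1]")
  dm <- cfg$dynamics_mix
  if (!setequal(names(dm), c("persist", "decay", "emerge")) ||
      any(dm < 0) || abs(sum(dm) - 1) > 1e-8)
    stop("dynamics_mix must be proportions over persist/decay/emerge summing to 1")
  if (cfg$dynamics_baseline_coupling < 0 || cfg$dynamics_baseline_coupling > 1)
    stop("dynamics_baseline_coupling must lie in [0, 1]")
  if (cfg$tss_overlap_fraction < 0 || cfg$tss_overlap_fraction > 1)
    stop("tss_overlap_fraction must lie in [0, 1]")
  if (cfg$expression_mean_dispersion <= 0 || cfg$dispersion_inflation_factor <= 0)
    stop("dispersions and inflation factor must be > 0")
  if (cfg$expression_de_count > cfg$expression_gene_count)
    stop("expression_de_count cannot exceed expression_gene_count")
  if (!cfg$inflated_group %in% c("test", "control"))
    stop("inflated_group must be 'test' or 'control'")
  cfg
}

#' Read a simulation configuration from YAML
#'
#' Fields absent from the file keep their [sim_config()] defaults.
#' @param path YAML file whose top-level keys match [sim_config()] arguments.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown sim_config fields: ", paste(unknown, collapse = ", "))
  if (!is.null(raw$baseline_mixture)) {
    raw$baseline_mixture <- lapply(raw$baseline_mixture, unlist)
  }
  if (!is.null(raw$dynamics_mix)) raw$dynamics_mix <- unlist(raw$dynamics_mix)
  do.call(sim_config, raw)
}
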