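#' Construct a multi-sample methylation count matrix
#'
#' The central container: an ordered CpG site list with per-(site, sample)
#' methylated and total read counts plus sample metadata.  Cells with zero
#' total coverage are recorded as missing (`NA`), which is distinct from
#' "covered but failing the scoreability filter".
#'
#' @param sites data.frame with columns `chrom` and `pos` (0-based).
#' @param meth,total numeric matrices, sites x samples.
#' @param samples data.frame of sample metadata with at least `sample_id`
#'   and `group`; ids must be unique.
#' @return a `methylation_matrix` object.
#' @export
methylation_matrix <- function(sites, meth, total, samples) {
  stopifnot(all(c("chrom", "pos") %in% names(sites)),
            all(c("sample_id", "group") %in% names(samples)))
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample id")
  ns <- nrow(sites); k <- nrow(samples)
  stopifnot(nrow(meth) == ns, nrow(total) == ns,
            ncol(meth) == k, ncol(total) == k)
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, c("chrom", "pos"), drop = FALSE]
  if (anyDuplicated(paste(sites$chrom, sites$pos))) stop("duplicate sites")
  meth <- meth[ord, , drop = FALSE]
  total <- total[ord, , drop = FALSE]
  # zero coverage is missing, not zero methylation
  missing <- !is.na(total) & total == 0
  total[missing] <- NA
  meth[missing] <- NA
  meth[is.na(total)] <- NA
  if (any(meth > total, na.rm = TRUE) || any(meth < 0, na.rm = TRUE))
    stop("counts must satisfy 0 <= meth <= total")
  dimnames(meth) <- dimnames(total) <- list(NULL, samples$sample_id)
  rownames(sites) <- NULL
  rownames(samples) <- NULL
  structure(list(sites = sites, meth = meth, total = total,
                 samples = samples),
            class = "methylation_matrix")
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat("methylation_matrix:", nrow(x$sites), "CpG sites x",
      nrow(x$samples), "samples\n")
  cat("groups:", paste(sprintf("%s (n=%d)", names(table(x$samples$group)),
                               table(x$samples$group)), collapse = ", "), "\n")
  invisible(x)
}

# column indices of a group's samples; errors on unknown labels
.sample_idx <- function(mat, group) {
  idx <- which(mat$samples$group == group)
  if (!length(idx)) stop("unknown group label: ", group)
  idx
}

.site_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

#' Assemble per-sample coverage files into a methylation matrix
#'
#' The site list is the union across samples; cells absent from a sample's
#' file are missing.  Input order does not affect the result.
#'
#' @param sheet data.frame with one row per sample: a `path` column naming a
#'   coverage file plus metadata columns (at least `sample_id` and `group`).
#' @return a [methylation_matrix()].
#' @export
assemble_matrix <- function(sheet) {
  stopifnot(is.data.frame(sheet), nrow(sheet) >= 1L,
            all(c("path", "sample_id", "group") %in% names(sheet)))
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample id in sample sheet")
  recs <- lapply(sheet$path, read_coverage_file)
  keys <- lapply(recs, function(r) .site_key(r$chrom, r$pos))
  all_sites <- unique(do.call(rbind, lapply(recs, function(r)
    r[, c("chrom", "pos"), drop = FALSE])))
  all_sites <- all_sites[order(all_sites$chrom, all_sites$pos), , drop = FALSE]
  ukey <- .site_key(all_sites$chrom, all_sites$pos)
  k <- nrow(sheet)
  meth <- matrix(NA_real_, nrow(all_sites), k)
  total <- matrix(NA_real_, nrow(all_sites), k)
  for (j in seq_len(k)) {
    i <- match(keys[[j]], ukey)
    meth[i, j] <- recs[[j]]$meth
    total[i, j] <- recs[[j]]$total
  }
  samples <- sheet[, setdiff(names(sheet), "path"), drop = FALSE]
  methylation_matrix(all_sites, meth, total, samples)
}

#' Read a YAML sample sheet
#'
#' The file holds a top-level `samples:` list whose entries carry `path`,
#' `sample_id`, `group` and optional further metadata (timepoint, tissue,
#' generation, ...).  Relative paths are resolved against the sheet's
#' directory.
#'
#' @param path YAML file.
#' @return data.frame suitable for [assemble_matrix()].
#' @export
read_sample_sheet <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$samples)) stop("sample sheet must contain a 'samples' list")
  rows <- lapply(y$samples, function(s) {
    if (is.null(s$path) || is.null(s$sample_id) || is.null(s$group))
      stop("each sample needs path, sample_id and group")
    as.data.frame(s, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  rel <- !grepl("^/", df$path)
  df$path[rel] <- file.path(dirname(path), df$path[rel])
  df
}

# per-cell methylation fractions (NA where missing)
.fractions <- function(mat) mat$meth / mat$total
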