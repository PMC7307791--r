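#' Read a Bismark-dialect cytosine coverage file
#'
#' Expects six tab-separated columns: chrom, start (1-based), end,
#' methylation percentage, count methylated, count unmethylated.  Positions
#' are converted to the package's internal 0-based convention
#' (`pos = start - 1`) and counts are taken from columns 5 and 6; if the
#' printed methylation percentage disagrees with the counts by more than
#' 0.5 percentage points a warning is raised and the counts win.
#'
#' @param path path to a plain or gzip-compressed coverage file.
#' @return data.frame with columns `chrom`, `pos` (0-based), `meth`, `total`,
#'   sorted by (chrom, pos).
#' @seealso [write_coverage_file()]
#' @export
read_coverage_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      meth = integer(), total = integer(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 6L))
    stop("malformed coverage line ", which(nf != 6L)[1L],
         ": expected 6 tab-separated fields, found ", nf[nf != 6L][1L])
  m <- matrix(unlist(fields), ncol = 6L, byrow = TRUE)
  start <- suppressWarnings(as.numeric(m[, 2]))
  pct <- suppressWarnings(as.numeric(m[, 4]))
  meth <- suppressWarnings(as.numeric(m[, 5]))
  unmeth <- suppressWarnings(as.numeric(m[, 6]))
  bad <- which(is.na(start) | is.na(pct) | is.na(meth) | is.na(unmeth) |
                 start < 1 | meth < 0 | unmeth < 0 |
                 start != floor(start) | meth != floor(meth) |
                 unmeth != floor(unmeth))
  if (length(bad))
    stop("malformed coverage line ", bad[1L],
         ": non-numeric or negative field")
  total <- meth + unmeth
  expected_pct <- ifelse(total > 0, 100 * meth / total, 0)
  off <- abs(pct - expected_pct) > 0.5
  if (any(off))
    warning(sum(off), " line(s) with methylation % inconsistent with counts",
            " by > 0.5 percentage points (first at line ", which(off)[1L],
            "); counts win")
  out <- data.frame(chrom = m[, 1], pos = as.integer(start - 1),
                    meth = as.integer(meth), total = as.integer(total),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write cytosine records in the Bismark coverage dialect
#'
#' Emits chrom, 1-based start, end (= start), methylation percentage
#' (100 * meth / total to 6 significant digits; 0 when total is 0), count
#' methylated and count unmethylated.  Round-trips through
#' [read_coverage_file()] are bit-exact on the counts and coordinates.
#'
#' @param records data.frame with columns `chrom`, `pos` (0-based), `meth`,
#'   `total`.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_coverage_file <- function(records, path) {
  stopifnot(all(c("chrom", "pos", "meth", "total") %in% names(records)))
  if (nrow(records)) {
    if (any(records$meth > records$total) || any(records$meth < 0))
      stop("counts must satisfy 0 <= meth <= total")
    if (any(records$pos < 0)) stop("positions must be >= 0")
  }
  pct <- ifelse(records$total > 0,
                signif(100 * records$meth / records$total, 6), 0)
  lines <- if (nrow(records)) {
    paste(records$chrom, records$pos + 1L, records$pos + 1L,
          format(pct, scientific = FALSE, trim = TRUE, drop0trailing = TRUE),
          records$meth, records$total - records$meth, sep = "\t")
  } else character()
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
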