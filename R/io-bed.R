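#' Read a BED3/BED6 file
#'
#' Intervals are stored exactly as BED defines them: 0-based half-open
#' `[start, end)`.  Three or six columns are accepted.
#'
#' @param path path to a BED file.
#' @return data.frame with columns `chrom`, `start`, `end` and, for BED6,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (!all(nf %in% c(3L, 6L)) || length(unique(nf)) != 1L)
    stop("BED file must be uniformly 3 or 6 columns (line ",
         which(!nf %in% c(3L, 6L) | nf != nf[1L])[1L], ")")
  m <- matrix(unlist(fields), ncol = nf[1L], byrow = TRUE)
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  if (any(is.na(start)) || any(is.na(end)))
    stop("non-numeric BED coordinates")
  if (any(start < 0)) stop("negative BED start")
  if (any(start >= end)) stop("BED requires start < end (line ",
                              which(start >= end)[1L], ")")
  out <- data.frame(chrom = m[, 1], start = as.integer(start),
                    end = as.integer(end), stringsAsFactors = FALSE)
  if (nf[1L] == 6L) {
    out$name <- m[, 4]
    out$score <- suppressWarnings(as.numeric(m[, 5]))
    out$strand <- m[, 6]
  }
  out
}

#' Write intervals as BED3/BED6
#'
#' @param records data.frame with `chrom`, `start`, `end` (0-based
#'   half-open); if `name`, `score` and `strand` are all present a BED6 file
#'   is written.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(records, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(records)))
  if (nrow(records)) {
    if (any(records$start < 0)) stop("negative BED start")
    if (any(records$start >= records$end)) stop("BED requires start < end")
  }
  bed6 <- all(c("name", "score", "strand") %in% names(records))
  lines <- if (nrow(records) == 0L) {
    character()
  } else if (bed6) {
    paste(records$chrom, records$start, records$end, records$name,
          format(records$score, scientific = FALSE, trim = TRUE,
                 drop0trailing = TRUE),
          records$strand, sep = "\t")
  } else {
    paste(records$chrom, records$start, records$end, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}
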