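#' Define a genome layout (chromosome names and lengths)
#'
#' A minimal stand-in for a chromosome-sizes file: unique chromosome names
#' with positive lengths in base pairs.  All coordinates in the package are
#' 0-based half-open and must fall within these bounds.
#'
#' @param lengths named numeric vector of chromosome lengths (bp), names are
#'   chromosome labels.
#' @return a `genome_layout` data.frame with columns `chrom` and `length`.
#' @examples
#' genome_layout(c(chr1 = 1e6, chr2 = 5e5))
#' @export
genome_layout <- function(lengths) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
    stop("chromosome lengths must be named")
  if (anyDuplicated(names(lengths)))
    stop("chromosome names must be unique")
  if (any(!is.finite(lengths)) || any(lengths < 1))
    stop("chromosome lengths must be >= 1")
  structure(
    data.frame(chrom = names(lengths), length = as.numeric(lengths),
               stringsAsFactors = FALSE, row.names = NULL),
    class = c("genome_layout", "data.frame"))
}

#' Read a two-column chromosome-sizes file as a genome layout
#' @param path tab-separated file with columns chrom, length.
#' @return a [genome_layout()].
#' @export
read_genome_layout <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("chrom-sizes file needs two columns")
  genome_layout(setNames(as.numeric(df[[2]]), as.character(df[[1]])))
}

.check_layout <- function(layout) {
  if (!inherits(layout, "genome_layout"))
    stop("`layout` must be a genome_layout")
  invisible(layout)
}

.chrom_length <- function(layout, chrom) {
  i <- match(chrom, layout$chrom)
  if (anyNA(i)) stop("unknown chromosome: ", paste(chrom[is.na(i)], collapse = ", "))
  layout$length[i]
}

# classify a control-group mean methylation fraction; ties go inward to
# intermediate (hypo is strictly < 0.25, hyper strictly > 0.75)
baseline_class <- function(mean_control) {
  ifelse(is.na(mean_control), NA_character_,
         ifelse(mean_control < 0.25, "hypo",
                ifelse(mean_control > 0.75, "hyper", "intermediate")))
}
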