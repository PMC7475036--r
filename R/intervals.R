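#' Construct a set of genomic intervals
#'
#' Intervals are 1-based and fully inclusive on both ends (VCF convention):
#' a single base is `start == end` and has length 1. All interval
#' arithmetic in the package uses this convention; BED input/output is
#' converted at the boundary by [read_bed()] / [write_bed()].
#'
#' @param chrom character vector of chromosome names (compared as exact
#'   strings; no "chr" prefix normalisation unless requested by the caller).
#' @param start,end integer vectors, 1-based inclusive, `start <= end`.
#' @param name optional interval names (recycled; default `"."`).
#' @return A data frame of class `genomic_interval` with columns
#'   `chrom`, `start`, `end`, `name`.
#' @examples
#' genomic_interval("chr13", 16098858, 16099329)
#' @export
genomic_interval <- function(chrom, start, end, name = ".") {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(is.na(chrom)) || any(is.na(start)) || any(is.na(end)))
    stop("interval fields must be non-missing")
  if (any(start < 1)) stop("interval start must be >= 1")
  if (any(end < start)) stop("interval end must be >= start")
  out <- data.frame(chrom = as.character(chrom), start = start, end = end,
                    name = rep_len(as.character(name), length(chrom)),
                    stringsAsFactors = FALSE)
  class(out) <- c("genomic_interval", "data.frame")
  out
}

#' Length of genomic intervals in base pairs
#'
#' @param iv a `genomic_interval` (or any data frame with `start`/`end`
#'   columns, 1-based inclusive).
#' @return Integer-valued vector `end - start + 1`.
#' @examples
#' interval_length(genomic_interval("chr13", 16098858, 16099329)) # 472
#' @export
interval_length <- function(iv) {
  iv$end - iv$start + 1
}

#' Pairwise overlap of two genomic intervals in base pairs
#'
#' Vectorised over rows: `a` and `b` are matched element-wise (recycled).
#' Intervals on different chromosomes overlap by 0.
#'
#' @param a,b `genomic_interval` objects (1-based inclusive).
#' @return Numeric vector of overlapping base pairs (0 if disjoint).
#' @export
interval_overlap <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(numeric(0))
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  ov <- pmax(0, pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi]) + 1)
  ov[a$chrom[ai] != b$chrom[bi]] <- 0
  ov
}

#' Read a BED file as 1-based inclusive intervals
#'
#' Accepts BED3+ (tab-delimited, 0-based half-open); columns beyond the
#' fourth are ignored. Coordinates are converted to the package's 1-based
#' inclusive convention: `start = bed_start + 1`, `end = bed_end`.
#'
#' @param path path to a BED file.
#' @return A `genomic_interval`.
#' @export
read_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "#")
  if (ncol(tab) < 3) stop("BED file must have >= 3 columns: ", path)
  bs <- as.numeric(tab[[2]])
  be <- as.numeric(tab[[3]])
  if (any(is.na(bs)) || any(is.na(be))) stop("non-numeric BED coordinates in ", path)
  if (any(be <= bs))
    stop("BED end must exceed start (0-based half-open) in ", path)
  nm <- if (ncol(tab) >= 4) tab[[4]] else "."
  genomic_interval(tab[[1]], bs + 1, be, name = nm)
}

#' Write intervals as BED (0-based half-open)
#'
#' Inverse of [read_bed()]: writes `start - 1` and `end` so that a
#' read/write round trip is the identity.
#'
#' @param iv a `genomic_interval`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(iv, path) {
  tab <- data.frame(iv$chrom, format(iv$start - 1, scientific = FALSE, trim = TRUE),
                    format(iv$end, scientific = FALSE, trim = TRUE), iv$name)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
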