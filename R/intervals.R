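#' Genomic intervals (0-based, half-open)
#'
#' All coordinates inside the package are 0-based half-open, the BED/SAM
#' convention: an interval covers bases `start .. end - 1` and its length is
#' `end - start`. User-facing text output is printed 1-based inclusive, the
#' convention used in genome browsers and in the literature.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer coordinates, 0-based half-open; `0 <= start < end`.
#' @param ... Further annotation columns recycled to the same length.
#' @return A data frame of class `gintervals` with columns `chrom`, `start`,
#'   `end` plus any annotation columns.
#' @examples
#' dmr <- from_one_based("chr3", 36992300, 36993908)  # the 1.6 kb promoter DMR
#' gi_length(dmr)
#' @export
gintervals <- function(chrom, start, end, ...) {
  start <- suppressWarnings(as.integer(start))
  end <- suppressWarnings(as.integer(end))
  if (anyNA(start) || anyNA(end)) stop("non-integer coordinates")
  if (any(start < 0L)) stop("negative start coordinate")
  if (any(start >= end)) stop("invalid interval: start >= end")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  class(df) <- c("gintervals", "data.frame")
  df
}

#' @rdname gintervals
#' @param x A `gintervals` object.
#' @export
gi_length <- function(x) x$end - x$start

#' Pairwise overlap in base pairs between two interval sets
#'
#' Symmetric: `gi_overlap(x, y) == gi_overlap(y, x)`. Intervals on different
#' chromosomes overlap by 0.
#'
#' @param x,y `gintervals` objects of equal length (or length 1, recycled).
#' @return Integer vector of overlap widths (`max(0, min(ends) - max(starts))`).
#' @export
gi_overlap <- function(x, y) {
  as.integer(ifelse(x$chrom == y$chrom,
                    pmax(0L, pmin(x$end, y$end) - pmax(x$start, y$start)),
                    0L))
}

#' Convert between internal 0-based half-open and printed 1-based inclusive
#'
#' `from_one_based()` takes printed coordinates (e.g. "chr3:36,992,300-36,993,908")
#' and returns the internal representation; `to_one_based()` is its inverse.
#' The two are involutive: `to_one_based(from_one_based(...))` reproduces the
#' printed numbers exactly.
#'
#' @param chrom Chromosome name.
#' @param start1,end1 1-based inclusive coordinates.
#' @export
from_one_based <- function(chrom, start1, end1) {
  gintervals(chrom, as.numeric(start1) - 1, end1)
}

#' @rdname from_one_based
#' @param x A `gintervals` object.
#' @return For `to_one_based()`, a data frame with columns `chrom`, `start1`, `end1`.
#' @export
to_one_based <- function(x) {
  data.frame(chrom = x$chrom, start1 = x$start + 1L, end1 = x$end,
             stringsAsFactors = FALSE)
}

#' Format / parse printed region strings
#'
#' `format_region()` prints an interval 1-based inclusive with thousands
#' separators ("chr3:36,992,300-36,993,908"); `parse_region()` parses that form
#' (commas optional) back into a `gintervals`.
#'
#' @param x A `gintervals` object (`format_region`) or character vector of
#'   region strings (`parse_region`).
#' @export
format_region <- function(x) {
  ob <- to_one_based(x)
  sprintf("%s:%s-%s", ob$chrom,
          formatC(ob$start1, format = "d", big.mark = ","),
          formatC(ob$end1, format = "d", big.mark = ","))
}

#' @rdname format_region
#' @export
parse_region <- function(x) {
  x <- gsub(",", "", x)
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop("malformed region string: ", paste(x[bad], collapse = ", "))
  chrom <- vapply(m, `[`, "", 2L)
  s1 <- as.numeric(vapply(m, `[`, "", 3L))
  e1 <- as.numeric(vapply(m, `[`, "", 4L))
  from_one_based(chrom, s1, e1)
}
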