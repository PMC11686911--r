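#' Burden scan configuration
#'
#' @param af_threshold Population allele frequency below which a variant is
#'   rare (default 0.01, the usual "< 1% in gnomAD" rule).
#' @param window_width,step Sliding-window width and step in bp (defaults
#'   10 kb / 1 kb, resolving a ~800 kb promoter-contacting region into ~800
#'   windows; fully configurable).
#' @export
burden_config <- function(af_threshold = 0.01, window_width = 10000L,
                          step = 1000L) {
  stopifnot(af_threshold > 0, af_threshold < 1, step <= window_width,
            step >= 1, window_width >= 1)
  list(af_threshold = af_threshold, window_width = as.integer(window_width),
       step = as.integer(step))
}

#' Filter variants to the rare set
#'
#' Keeps variants with `af < af_threshold`. Variants with missing AF are kept
#' and flagged (`af_missing = TRUE`): absence from the population database
#' implies a frequency below any common threshold.
#'
#' @param variants A `variant_records` data frame (see [read_variants()]).
#' @param config A [burden_config()].
#' @return The rare subset with an added logical `af_missing` column.
#' @export
filter_rare <- function(variants, config = burden_config()) {
  missing <- is.na(variants$af)
  keep <- missing | variants$af < config$af_threshold
  out <- variants[keep, , drop = FALSE]
  out$af_missing <- missing[keep]
  rownames(out) <- NULL
  out
}

#' Sliding-window rare-variant burden
#'
#' Windows start at `region$start, region$start + step, ...` while
#' `start + width <= region$end`. Each window counts the rare variants whose
#' position falls in `[start, start + width)` and, separately, the subset in
#' phase with the methylation-associated allele (`phase == "IN_PHASE_MAA"`).
#' With `step == window_width` the windows partition the region and counts
#' are conserved.
#'
#' @param variants Rare variants (see [filter_rare()]); only rows on
#'   `region$chrom` are counted.
#' @param region Single-row [gintervals] scan region (e.g. the
#'   promoter-contacting region).
#' @param config A [burden_config()].
#' @return Data frame of class `burden_windows`: `start`, `end`, `n_rare`,
#'   `n_in_phase`.
#' @export
sliding_window_burden <- function(variants, region, config = burden_config()) {
  stopifnot(nrow(region) == 1L)
  if (config$window_width > gi_length(region))
    stop("window width exceeds region length")
  starts <- seq.int(region$start, region$end - config$window_width,
                    by = config$step)
  v <- variants[variants$chrom == region$chrom, , drop = FALSE]
  pos <- v$pos
  inph <- v$phase == "IN_PHASE_MAA"
  n_rare <- vapply(starts, function(s)
    sum(pos >= s & pos < s + config$window_width), 1L)
  n_in_phase <- vapply(starts, function(s)
    sum(inph & pos >= s & pos < s + config$window_width), 1L)
  out <- data.frame(start = starts, end = starts + config$window_width,
                    n_rare = n_rare, n_in_phase = n_in_phase)
  class(out) <- c("burden_windows", "data.frame")
  out
}

#' Argmax burden windows (ties all reported)
#'
#' @param burden A `burden_windows` data frame.
#' @param by Which count to maximise: `"n_rare"` or `"n_in_phase"`.
#' @return The rows achieving the maximum count.
#' @export
burden_argmax <- function(burden, by = c("n_rare", "n_in_phase")) {
  by <- match.arg(by)
  burden[burden[[by]] == max(burden[[by]]), , drop = FALSE]
}
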