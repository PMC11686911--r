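.merge_intervals <- function(x) {
  # maximal non-overlapping blocks of a gintervals set (single chrom at a time)
  out <- NULL
  for (ch in unique(x$chrom)) {
    sub <- x[x$chrom == ch, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(sub$start + 1L, sub$end))
    out <- rbind(out, data.frame(chrom = ch, start = IRanges::start(ir) - 1L,
                                 end = IRanges::end(ir)))
  }
  out[order(out$chrom, out$start), , drop = FALSE]
}

.overlap_vec <- function(starts, widths, peaks, statistic) {
  # per-start statistic against merged, sorted peaks (0-based half-open);
  # returns a vector aligned with `starts`
  ps <- peaks$start; pe <- peaks$end; np <- length(ps)
  if (np == 0L) return(numeric(length(starts)))
  if (statistic == "windows_overlapping_any_peak") {
    j <- findInterval(starts, ps)
    as.numeric((j >= 1L & pe[pmax(j, 1L)] > starts) |
                 (j < np & ps[pmin(j + 1L, np)] < starts + widths))
  } else {
    tot <- numeric(length(starts))
    for (k in seq_len(np))
      tot <- tot + pmax(0, pmin(starts + widths, pe[k]) - pmax(starts, ps[k]))
    tot
  }
}

#' Permutation test for overlap of differential windows with peaks
#'
#' Tests whether differential contact windows overlap accessible/active
#' regions more than expected by chance. Each permutation independently
#' re-places every window uniformly at random within the analysis region,
#' preserving its width (start drawn uniformly from
#' `[region$start, region$end - width]`; permuted windows may overlap each
#' other), and recomputes the same statistic as observed. The empirical
#' p-value uses the add-one correction `(1 + #{null >= observed}) / (n_perm + 1)`
#' and therefore never equals 0.
#'
#' @param windows [gintervals] of differential windows (within `region`).
#' @param peaks [gintervals] of peaks (e.g. consensus accessible regions).
#' @param region Single-row [gintervals] analysis region.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed for a reproducible null.
#' @param statistic `"windows_overlapping_any_peak"` (default) or
#'   `"total_overlap_bp"`.
#' @return List of class `permutation_result`: `observed`, `null` (numeric
#'   vector), `null_mean`, `null_sd`, `p`, `n_perm`, `statistic`.
#' @export
permute_overlap <- function(windows, peaks, region, n_perm = 10000L,
                            seed = NULL,
                            statistic = c("windows_overlapping_any_peak",
                                          "total_overlap_bp")) {
  statistic <- match.arg(statistic)
  stopifnot(nrow(region) == 1L, n_perm >= 1)
  widths <- gi_length(windows)
  if (any(widths > gi_length(region))) stop("window wider than the region")
  mp <- .merge_intervals(peaks[peaks$chrom == region$chrom, , drop = FALSE])
  observed <- sum(.overlap_vec(windows$start, widths, mp, statistic))
  # per window, compute the statistic for all permutations at once
  run_perms <- function() {
    null <- numeric(n_perm)
    for (j in seq_len(nrow(windows))) {
      n_choices <- region$end - widths[j] - region$start + 1L
      s <- region$start + sample.int(n_choices, n_perm, replace = TRUE) - 1L
      null <- null + .overlap_vec(s, rep(widths[j], n_perm), mp, statistic)
    }
    null
  }
  null <- if (is.null(seed)) run_perms() else withr::with_seed(seed, run_perms())
  p <- (1 + sum(null >= observed)) / (n_perm + 1)
  structure(list(observed = observed, null = null,
                 null_mean = mean(null), null_sd = stats::sd(null),
                 p = p, n_perm = n_perm, statistic = statistic),
            class = "permutation_result")
}

#' Consensus peaks by sample voting
#'
#' Merges the union of all peak sets into maximal non-overlapping blocks and
#' keeps a block iff peaks from strictly more than `min_samples` distinct sets
#' overlap it - the interval-vote rule used to build condition consensus
#' peaksets ("present in more than 2 samples within the same condition").
#'
#' @param peak_sets List of [gintervals] objects, one per sample.
#' @param min_samples Strict voting threshold (default 2: a block needs
#'   support from 3 or more samples).
#' @return [gintervals] of retained blocks with a `support` column.
#' @export
consensus_peaks <- function(peak_sets, min_samples = 2L) {
  stopifnot(length(peak_sets) >= 1L)
  all_peaks <- do.call(rbind, lapply(peak_sets, function(x)
    as.data.frame(x)[, c("chrom", "start", "end")]))
  blocks <- .merge_intervals(gintervals(all_peaks$chrom, all_peaks$start, all_peaks$end))
  support <- integer(nrow(blocks))
  for (ch in unique(blocks$chrom)) {
    bsel <- blocks$chrom == ch
    bir <- IRanges::IRanges(blocks$start[bsel] + 1L, blocks$end[bsel])
    for (set in peak_sets) {
      ssub <- set[set$chrom == ch, , drop = FALSE]
      if (nrow(ssub) == 0L) next
      sir <- IRanges::IRanges(ssub$start + 1L, ssub$end)
      support[bsel] <- support[bsel] + as.integer(IRanges::overlapsAny(bir, sir))
    }
  }
  keep <- support > min_samples
  if (!any(keep))
    return(gintervals("chr", 0, 1, support = 0L)[0, , drop = FALSE])
  gintervals(blocks$chrom[keep], blocks$start[keep], blocks$end[keep],
             support = support[keep])
}
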