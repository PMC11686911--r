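#' In silico restriction digestion
#'
#' Cuts a chromosome at every occurrence of the enzyme motif (DpnII "GATC" by
#' default); fragments are the 0-based half-open intervals between consecutive
#' motif starts, tiling the chromosome without gaps or overlaps. Restriction
#' fragments are the native counting unit of 4C-style contact assays.
#'
#' @param genome A `DNAStringSet` genome.
#' @param chrom Chromosome to digest.
#' @param motif Enzyme recognition motif (length >= 1). A motif with no
#'   occurrence yields one fragment spanning the chromosome; a motif starting
#'   at position 0 does not emit an empty fragment.
#' @return Data frame of class `fragment_map` with columns `frag_id` (0-based,
#'   increasing with coordinate), `start`, `end`; attributes `chrom`, `motif`.
#' @export
digest_genome <- function(genome, chrom, motif = "GATC") {
  stopifnot(nchar(motif) >= 1L)
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  len <- length(genome[[chrom]])
  hits <- Biostrings::matchPattern(motif, genome[[chrom]])
  cuts <- IRanges::start(hits) - 1L   # 0-based motif start positions
  bounds <- sort(unique(c(0L, cuts[cuts > 0L], len)))
  map <- data.frame(frag_id = seq_len(length(bounds) - 1L) - 1L,
                    start = bounds[-length(bounds)], end = bounds[-1L])
  attr(map, "chrom") <- chrom
  attr(map, "motif") <- motif
  class(map) <- c("fragment_map", "data.frame")
  map
}

#' Locate the fragment containing a position
#'
#' Binary search for the unique fragment with `start <= pos < end`.
#'
#' @param map A `fragment_map` from [digest_genome()].
#' @param pos 0-based position(s); out-of-range is an error.
#' @return Integer fragment id(s).
#' @export
locate_fragment <- function(map, pos) {
  if (any(pos < map$start[1] | pos >= map$end[nrow(map)]))
    stop("position out of range of the fragment map")
  map$frag_id[findInterval(pos, map$start)]
}

#' Smoothing / profile configuration
#'
#' @param min_win_factor Fraction of the combined molecule total each smoothing
#'   window must reach (default 0.03, i.e. roughly 33 windows across the
#'   analysis region).
#' @param viewpoint_exclusion_fragments Fragments dropped on each side of the
#'   viewpoint fragment to avoid proximity artifacts (default 2).
#' @export
smoothing_config <- function(min_win_factor = 0.03,
                             viewpoint_exclusion_fragments = 2L) {
  stopifnot(min_win_factor > 0, min_win_factor < 1,
            viewpoint_exclusion_fragments >= 0)
  list(min_win_factor = min_win_factor,
       viewpoint_exclusion_fragments = as.integer(viewpoint_exclusion_fragments))
}

.included_fragments <- function(map, viewpoint_frag, region, config) {
  in_region <- map$end > region$start & map$start < region$end
  excl <- abs(map$frag_id - viewpoint_frag) <= config$viewpoint_exclusion_fragments
  map$frag_id[in_region & !excl]
}

#' Build allele-resolved, UMI-deduplicated contact profiles
#'
#' One profile per group key (condition x allele label). Molecules are
#' deduplicated by (contact fragment id, UMI) within a key; contacts outside
#' the analysis region, on the viewpoint fragment or within the viewpoint
#' exclusion zone are dropped; records with allele `"OTHER"` are dropped with
#' a message. The result mirrors separate viewpoint interaction profiles for
#' the methylated and unmethylated haplotypes.
#'
#' @param contacts Contact records: data frame with `group`, `allele`,
#'   `chrom`, `pos`, `umi` (see [read_contacts()]).
#' @param map A `fragment_map` from [digest_genome()].
#' @param viewpoint_pos 0-based viewpoint (bait) position.
#' @param region Analysis region as a [gintervals] row containing the viewpoint.
#' @param config A [smoothing_config()].
#' @return Named list of `contact_profile` objects, keyed `"group.allele"`;
#'   each has `key`, `group`, `allele`, `frag_ids` (included fragments),
#'   `counts` (named unique-molecule counts over `frag_ids`), `total`,
#'   `viewpoint_frag`, `region`.
#' @export
build_profile <- function(contacts, map, viewpoint_pos, region,
                          config = smoothing_config()) {
  stopifnot(region$start <= viewpoint_pos, viewpoint_pos < region$end)
  vp_frag <- locate_fragment(map, viewpoint_pos)
  inc <- .included_fragments(map, vp_frag, region, config)
  other <- contacts$allele == "OTHER"
  if (any(other))
    message(sum(other), " contact record(s) with OTHER allele dropped")
  contacts <- contacts[!other, , drop = FALSE]
  keep <- contacts$chrom == attr(map, "chrom")
  contacts <- contacts[keep, , drop = FALSE]
  frag <- locate_fragment(map, contacts$pos)
  keep <- frag %in% inc
  contacts <- contacts[keep, , drop = FALSE]
  frag <- frag[keep]
  key <- paste(contacts$group, contacts$allele, sep = ".")
  dedup_key <- paste(key, frag, contacts$umi, sep = "\r")
  first <- !duplicated(dedup_key)
  key <- key[first]; frag <- frag[first]
  grp <- contacts$group[first]; al <- contacts$allele[first]
  out <- lapply(unique(key), function(k) {
    sel <- key == k
    counts <- integer(length(inc)); names(counts) <- inc
    tb <- table(frag[sel])
    counts[names(tb)] <- as.integer(tb)
    structure(list(key = k, group = grp[sel][1], allele = al[sel][1],
                   frag_ids = inc, counts = counts, total = sum(counts),
                   viewpoint_frag = vp_frag, region = region),
              class = "contact_profile")
  })
  names(out) <- vapply(out, `[[`, "", "key")
  out
}

#' Count-balanced smoothing windows
#'
#' On each side of the viewpoint, walking away from it, consecutive fragments
#' are accumulated until the combined (all profiles) molecule count reaches
#' `ceil(min_win_factor * T)`, where `T` is the combined total; the window is
#' then closed. A trailing partial window is merged into its predecessor.
#' Windows depend only on combined counts, so every group is tested on
#' identical windows - a requirement for the per-window 2x2 contrast.
#'
#' @param profiles List of `contact_profile`s from [build_profile()] (must
#'   share fragment inclusion).
#' @param map The `fragment_map`.
#' @param config A [smoothing_config()].
#' @return Data frame of class `contact_windows`: `window_id` (genomic order),
#'   `side` ("upstream"/"downstream"), `frag_lo`, `frag_hi`, `start`, `end`,
#'   `n_frags`, `combined` (combined molecule count).
#' @export
build_windows <- function(profiles, map, config = smoothing_config()) {
  stopifnot(length(profiles) >= 1)
  inc <- profiles[[1]]$frag_ids
  for (p in profiles) stopifnot(identical(p$frag_ids, inc))
  combined <- Reduce(`+`, lapply(profiles, `[[`, "counts"))
  total <- sum(combined)
  if (total <= 0) stop("no molecules in any profile; cannot build windows")
  thr <- ceiling(config$min_win_factor * total)
  vp <- profiles[[1]]$viewpoint_frag
  one_side <- function(ids) {   # ids ordered walking away from the viewpoint
    if (length(ids) == 0L) return(NULL)
    cnt <- combined[as.character(ids)]
    runs <- list(); cur <- integer(0); acc <- 0L
    for (i in seq_along(ids)) {
      cur <- c(cur, ids[i]); acc <- acc + cnt[i]
      if (acc >= thr) { runs[[length(runs) + 1L]] <- cur; cur <- integer(0); acc <- 0L }
    }
    if (length(cur) > 0L) {
      if (length(runs) > 0L) runs[[length(runs)]] <- c(runs[[length(runs)]], cur)
      else runs[[1L]] <- cur
    }
    runs
  }
  up <- one_side(sort(inc[inc < vp], decreasing = TRUE))
  down <- one_side(sort(inc[inc > vp]))
  mk <- function(runs, side) {
    if (is.null(runs) || length(runs) == 0L) return(NULL)
    do.call(rbind, lapply(runs, function(r) {
      lo <- min(r); hi <- max(r)
      data.frame(side = side, frag_lo = lo, frag_hi = hi,
                 start = map$start[map$frag_id == lo],
                 end = map$end[map$frag_id == hi],
                 n_frags = length(r),
                 combined = sum(combined[as.character(r)]))
    }))
  }
  out <- rbind(mk(up, "upstream"), mk(down, "downstream"))
  out <- out[order(out$start), , drop = FALSE]
  out$window_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out <- out[, c("window_id", "side", "frag_lo", "frag_hi", "start", "end",
                 "n_frags", "combined")]
  class(out) <- c("contact_windows", "data.frame")
  out
}

#' Per-window molecule counts for one profile
#' @param profile A `contact_profile`.
#' @param windows A `contact_windows` data frame.
#' @return Integer vector of window counts, in `windows` row order.
#' @export
window_counts <- function(profile, windows) {
  ids <- as.integer(names(profile$counts))
  vapply(seq_len(nrow(windows)), function(i) {
    sel <- ids >= windows$frag_lo[i] & ids <= windows$frag_hi[i]
    sum(profile$counts[sel])
  }, 1L)
}

#' Depth-normalised per-window contact trends
#'
#' Window counts of profile B are rescaled by `totalA / totalB` so both trends
#' sit on A's sequencing depth; A's values are unchanged. Total-count scaling
#' is the only depth difference the synthetic generator introduces and is
#' documented so users can substitute another normalisation.
#'
#' @param profileA,profileB `contact_profile`s sharing fragment inclusion.
#' @param windows A `contact_windows` data frame.
#' @return Data frame: `window_id`, `a`, `b` (raw counts), `norm_a`, `norm_b`,
#'   with attribute `scale` = totalA/totalB.
#' @export
normalize_profiles <- function(profileA, profileB, windows) {
  if (profileB$total == 0) stop("profile B has zero molecules; cannot scale")
  a <- window_counts(profileA, windows)
  b <- window_counts(profileB, windows)
  sc <- profileA$total / profileB$total
  out <- data.frame(window_id = windows$window_id, a = a, b = b,
                    norm_a = as.numeric(a), norm_b = b * sc)
  attr(out, "scale") <- sc
  out
}
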