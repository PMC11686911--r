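.BASES <- c("A", "C", "G", "T")

#' Read a JASPAR-style PPM library
#'
#' Parses matrices of the form
#' \preformatted{
#' >MA0001 TF1
#' A [ 10  2  0 ... ]
#' C [ ... ]
#' G [ ... ]
#' T [ ... ]
#' }
#' Counts or probabilities are accepted; each position (column) is normalised
#' to probabilities summing to 1. An optional role table assigns each factor a
#' regulatory role.
#'
#' @param path Path to the matrix file.
#' @param roles Optional data frame (or TSV path) with columns `tf_name`,
#'   `role` (`activator`, `repressor`, `insulator`, `other`).
#' @return List of `ppm` objects: `tf_name`, `mat` (L x 4 matrix, columns
#'   A,C,G,T, rows summing to 1), `role`.
#' @export
read_ppm_library <- function(path, roles = NULL) {
  if (is.character(roles)) roles <- utils::read.table(roles, header = TRUE,
                                                      sep = "\t", stringsAsFactors = FALSE)
  lines <- .read_lines(path)
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (length(heads) == 0L) stop("no matrix headers (>) found in ", path)
  out <- lapply(seq_along(heads), function(i) {
    lo <- heads[i]
    hi <- if (i < length(heads)) heads[i + 1] - 1L else length(lines)
    name <- strsplit(sub("^>\\s*", "", lines[lo]), "\\s+")[[1]][1]
    rows <- lines[(lo + 1L):hi]
    vals <- lapply(.BASES, function(b) {
      r <- rows[startsWith(rows, b)][1]
      if (is.na(r)) stop("matrix ", name, " lacks a row for base ", b)
      x <- strsplit(gsub("[][]", " ", sub("^[ACGT]", "", r)), "\\s+")[[1]]
      as.numeric(x[nzchar(x)])
    })
    L <- unique(vapply(vals, length, 1L))
    if (length(L) != 1L) stop("ragged matrix rows for ", name)
    mat <- t(do.call(rbind, vals))         # L x 4
    colnames(mat) <- .BASES
    mat <- mat / rowSums(mat)
    role <- "other"
    if (!is.null(roles) && name %in% roles$tf_name)
      role <- roles$role[match(name, roles$tf_name)]
    structure(list(tf_name = name, mat = mat, role = role), class = "ppm")
  })
  names(out) <- vapply(out, `[[`, "", "tf_name")
  out
}

#' Convert a position probability matrix to a log-odds PWM
#'
#' Entry for base b at position j is
#' `log2((p_jb + pseudocount * bg_b) / ((1 + pseudocount) * bg_b))`.
#' With `pseudocount = 0`, zero probabilities are an error (they would give
#' -Inf scores). `S_min`/`S_max` (column-wise min/max sums) are precomputed;
#' the relative score of a sequence is `(S - S_min) / (S_max - S_min)`, in
#' `[0, 1]`.
#'
#' @param ppm A `ppm` object (see [read_ppm_library()]).
#' @param background Base composition (A,C,G,T), summing to 1, all > 0.
#' @param pseudocount Non-negative pseudocount (default 0.01).
#' @return A `pwm` object: `tf_name`, `role`, `scores` (L x 4), `smin`,
#'   `smax`, `background`, `pseudocount`.
#' @export
ppm_to_pwm <- function(ppm, background = rep(0.25, 4), pseudocount = 0.01) {
  stopifnot(length(background) == 4, abs(sum(background) - 1) < 1e-6,
            pseudocount >= 0)
  if (any(background <= 0)) stop("zero background frequency")
  if (pseudocount == 0 && any(ppm$mat == 0))
    stop("pseudocount 0 with zero probabilities gives -Inf scores; use pseudocount > 0")
  bg <- matrix(background, nrow = nrow(ppm$mat), ncol = 4, byrow = TRUE)
  scores <- log2((ppm$mat + pseudocount * bg) / ((1 + pseudocount) * bg))
  colnames(scores) <- .BASES
  structure(list(tf_name = ppm$tf_name, role = ppm$role, scores = scores,
                 smin = sum(apply(scores, 1, min)),
                 smax = sum(apply(scores, 1, max)),
                 background = stats::setNames(as.numeric(background), .BASES),
                 pseudocount = pseudocount),
            class = "pwm")
}

#' Reverse-complement of a PWM
#' @param pwm A `pwm` object.
#' @export
reverse_complement_pwm <- function(pwm) {
  sc <- pwm$scores[rev(seq_len(nrow(pwm$scores))), c("T", "G", "C", "A"),
                   drop = FALSE]
  colnames(sc) <- .BASES
  out <- pwm
  out$scores <- sc
  out
}

.seq_codes <- function(seq) {
  match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], .BASES)  # N -> NA
}

.pwm_scores_along <- function(pwm, codes) {
  L <- nrow(pwm$scores)
  n <- length(codes) - L + 1L
  if (n < 1L) return(numeric(0))
  s <- numeric(n)
  for (j in seq_len(L)) s <- s + pwm$scores[j, ][codes[j:(j + n - 1L)]]
  s
}

#' Scan a sequence for PWM matches on both strands
#'
#' The forward strand scores each offset with the PWM; the reverse strand
#' scores the reverse complement of each window (implemented by scanning with
#' the reverse-complement PWM at the same offsets). Offsets containing N are
#' skipped.
#'
#' @param pwm A `pwm` object.
#' @param seq Sequence to scan; shorter than the motif gives zero hits.
#' @param min_rel Minimum relative score in `[0, 1]` to report (default 0.80,
#'   the usual promoter-scan threshold).
#' @return Data frame `pos` (0-based offset), `strand`, `score`, `rel_score`,
#'   sorted by offset then strand.
#' @export
scan_sequence <- function(pwm, seq, min_rel = 0.80) {
  codes <- .seq_codes(seq)
  denom <- pwm$smax - pwm$smin
  one <- function(p, strand) {
    s <- .pwm_scores_along(p, codes)
    # scores live in [smin, smax] by construction; clamp away summation-order
    # rounding so boundary windows keep rel in [0, 1]
    rel <- pmin(1, pmax(0, (s - pwm$smin) / denom))
    keep <- !is.na(rel) & rel >= min_rel
    data.frame(pos = which(keep) - 1L, strand = rep(strand, sum(keep)),
               score = s[keep], rel_score = rel[keep],
               stringsAsFactors = FALSE)
  }
  out <- rbind(one(pwm, "+"), one(reverse_complement_pwm(pwm), "-"))
  out[order(out$pos, out$strand), , drop = FALSE]
}

.score_distribution <- function(pwm, grain) {
  # exact distribution of the integer-grid PWM score under the background model
  r <- round(pwm$scores / grain)           # L x 4 integer matrix
  bg <- pwm$background
  cur <- 1; curlo <- 0
  for (j in seq_len(nrow(r))) {
    rj <- r[j, ]
    newlo <- curlo + min(rj)
    newhi <- curlo + (length(cur) - 1L) + max(rj)
    new <- numeric(newhi - newlo + 1)
    for (b in 1:4) {
      off <- curlo + rj[b] - newlo
      idx <- (off + 1L):(off + length(cur))
      new[idx] <- new[idx] + cur * bg[b]
    }
    cur <- new; curlo <- newlo
  }
  list(probs = cur, lo = curlo, L = nrow(r))
}

#' Exact PWM score p-value by dynamic programming
#'
#' `P(score >= threshold)` for a random sequence drawn from the PWM's
#' background model, computed by exact convolution of per-position score
#' distributions discretised to a fixed grain (default 1e-3 score units).
#' The inclusion comparison carries a `floor(L/2) + 1` grid-cell slack so that
#' no sequence whose true score reaches the threshold is ever excluded by
#' rounding; sequences scoring within about `(L + 2)/2 * grain` below the
#' threshold may be counted as passing, so near exact ties the p-value is a
#' slight over-estimate bounded by the probability mass in that band.
#'
#' @param pwm A `pwm` object.
#' @param threshold Absolute score threshold.
#' @param grain Discretisation grain in score units (default 1e-3).
#' @return The tail probability, in `[0, 1]`.
#' @export
score_pvalue <- function(pwm, threshold, grain = 1e-3) {
  d <- .score_distribution(pwm, grain)
  thr <- round(threshold / grain) - (floor(d$L / 2) + 1L)
  sums <- d$lo + seq_along(d$probs) - 1
  min(1, sum(d$probs[sums >= thr]))
}

#' Score a variant's effect on a transcription-factor motif
#'
#' Builds the reference and alternate local sequences over the variant span
#' plus `L - 1` bp of flank on each side, takes the best relative PWM score of
#' each allele over both strands (indels are scored on the realised alternate
#' sequence; no per-position correspondence is attempted), and classifies the
#' match strength. The motif counts as matched when the exact score p-value of
#' the best absolute score on either allele is at most `p_threshold`; matched
#' variants are `"strong"` when `|delta| >= strong_delta` and `"weak"` when
#' `0 < |delta| < strong_delta`, where `delta = alt_best_rel - ref_best_rel`.
#'
#' @param pwm A `pwm` object.
#' @param genome A `DNAStringSet` genome.
#' @param variant One row of a `variant_records` data frame.
#' @param p_threshold Match p-value threshold (default 1e-4).
#' @param strong_delta Relative-score difference for a "strong" call
#'   (default 0.2).
#' @param grain Discretisation grain passed to [score_pvalue()].
#' @return A one-row data frame of class `disruption_call`: `chrom`, `pos`,
#'   `ref`, `alt`, `tf_name`, `role`, `ref_best_rel`, `alt_best_rel`, `delta`,
#'   `match_p_ref`, `match_p_alt`, `strength`, `partial`.
#' @export
score_variant <- function(pwm, genome, variant, p_threshold = 1e-4,
                          strong_delta = 0.2, grain = 1e-3) {
  L <- nrow(pwm$scores)
  flank <- L - 1L
  chrom_len <- length(genome[[variant$chrom]])
  lo <- variant$pos - flank
  hi <- variant$pos + nchar(variant$ref) + flank
  base <- data.frame(chrom = variant$chrom, pos = variant$pos,
                     ref = variant$ref, alt = variant$alt,
                     tf_name = pwm$tf_name, role = pwm$role,
                     stringsAsFactors = FALSE)
  if (lo < 0 || hi > chrom_len) {
    return(cbind(base, data.frame(ref_best_rel = NA_real_, alt_best_rel = NA_real_,
                                  delta = NA_real_, match_p_ref = NA_real_,
                                  match_p_alt = NA_real_, strength = "none",
                                  partial = TRUE, stringsAsFactors = FALSE)))
  }
  ref_seq <- genome_seq(genome, variant$chrom, lo, hi)
  obs_ref <- substring(ref_seq, flank + 1L, flank + nchar(variant$ref))
  if (obs_ref != variant$ref)
    warning("genome does not match REF at ", variant$chrom, ":", variant$pos + 1L)
  alt_seq <- paste0(substring(ref_seq, 1L, flank), variant$alt,
                    substring(ref_seq, flank + nchar(variant$ref) + 1L))
  best <- function(s) {
    hits <- scan_sequence(pwm, s, min_rel = 0)
    if (nrow(hits) == 0L) return(c(rel = NA_real_, abs = NA_real_))
    i <- which.max(hits$rel_score)
    c(rel = hits$rel_score[i], abs = hits$score[i])
  }
  br <- best(ref_seq); ba <- best(alt_seq)
  p_ref <- if (is.na(br["abs"])) 1 else score_pvalue(pwm, br[["abs"]], grain)
  p_alt <- if (is.na(ba["abs"])) 1 else score_pvalue(pwm, ba[["abs"]], grain)
  matched <- min(p_ref, p_alt) <= p_threshold
  delta <- ba[["rel"]] - br[["rel"]]
  strength <- if (!matched || is.na(delta) || delta == 0) "none"
  else if (abs(delta) >= strong_delta) "strong" else "weak"
  cbind(base, data.frame(ref_best_rel = br[["rel"]], alt_best_rel = ba[["rel"]],
                         delta = delta, match_p_ref = p_ref, match_p_alt = p_alt,
                         strength = strength, partial = FALSE,
                         stringsAsFactors = FALSE))
}

#' Regulatory classification of a motif-disruption call
#'
#' A pure function of (role, sign(delta), strength): a repressor motif whose
#' alternate allele scores higher (`delta > 0`) is a `repressor_gain`; an
#' activator motif whose alternate allele scores lower (`delta < 0`) is an
#' `activator_loss`; a strong hit on an insulator motif is an `insulator_hit`;
#' everything else (including gain of activator binding or loss of repressor
#' binding) is `none`. Calls with strength `"none"` are always `none`.
#'
#' @param call A one-row `disruption_call` (see [score_variant()]).
#' @param role Optional role override; defaults to the call's `role`.
#' @return One of `"repressor_gain"`, `"activator_loss"`, `"insulator_hit"`,
#'   `"none"`.
#' @export
classify_regulatory <- function(call, role = call$role) {
  if (is.na(call$strength) || call$strength == "none") return("none")
  d <- call$delta
  if (role == "repressor" && !is.na(d) && d > 0) return("repressor_gain")
  if (role == "activator" && !is.na(d) && d < 0) return("activator_loss")
  if (role == "insulator" && call$strength == "strong") return("insulator_hit")
  "none"
}

#' Disruption calls for a variant set against a PWM library
#'
#' Convenience wrapper: scores every variant against every motif and attaches
#' the regulatory class.
#'
#' @param variants A `variant_records` data frame.
#' @param ppms List of `ppm` objects (see [read_ppm_library()]).
#' @param genome A `DNAStringSet` genome.
#' @param background,pseudocount Passed to [ppm_to_pwm()].
#' @param ... Passed to [score_variant()].
#' @return Data frame of disruption calls with a `regulatory_class` column.
#' @export
disruption_calls <- function(variants, ppms, genome,
                             background = rep(0.25, 4), pseudocount = 0.01,
                             ...) {
  pwms <- lapply(ppms, ppm_to_pwm, background = background,
                 pseudocount = pseudocount)
  rows <- list()
  for (pw in pwms) {
    for (i in seq_len(nrow(variants))) {
      call <- score_variant(pw, genome, variants[i, , drop = FALSE], ...)
      call$regulatory_class <- classify_regulatory(call)
      rows[[length(rows) + 1L]] <- call
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
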