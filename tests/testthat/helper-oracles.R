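# Independent oracles used across the suite. Each deliberately takes a
# different route from the implementation it checks.

# Exhaustive two-sided Fisher p by direct enumeration of all 2x2 tables with
# the observed margins, probabilities from lchoose (not dhyper).
fisher_enum_oracle <- function(a, b, A, B) {
  K <- a + b
  sup <- max(0, K - B):min(K, A)
  pr <- exp(lchoose(A, sup) + lchoose(B, K - sup) - lchoose(A + B, K))
  min(1, sum(pr[pr <= pr[sup == a] * (1 + 1e-7)]))
}

# Hand-coded BH step-up rule, straight from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  pmin(1, q_sorted)[order(o)]
}

# Naive CIGAR walker: steps one base at a time, builds an explicit map of
# reference position -> read base / "D", plus insertion bookkeeping.
naive_observed <- function(pos, cigar, seq, span_start, span_end) {
  ops <- ciscope::parse_cigar(cigar)
  ref <- pos; q <- 1L
  basemap <- list(); insmap <- list()
  sc <- strsplit(seq, "")[[1]]
  for (i in seq_len(nrow(ops))) {
    for (j in seq_len(ops$len[i])) {
      op <- ops$op[i]
      if (op %in% c("M", "=", "X")) {
        basemap[[as.character(ref)]] <- sc[q]; ref <- ref + 1L; q <- q + 1L
      } else if (op == "I") {
        key <- as.character(ref)
        insmap[[key]] <- c(insmap[[key]], sc[q]); q <- q + 1L
      } else if (op %in% c("D", "N")) {
        basemap[[as.character(ref)]] <- "D"; ref <- ref + 1L
      } else if (op == "S") q <- q + 1L
    }
  }
  cells <- lapply(span_start:(span_end - 1L), function(p) basemap[[as.character(p)]])
  if (any(vapply(cells, is.null, TRUE)))
    return(list(status = "PARTIAL", seq = NA_character_))
  cells <- unlist(cells)
  if (all(cells == "D")) return(list(status = "DELETED", seq = NA_character_))
  if (any(cells == "D")) return(list(status = "PARTIAL", seq = NA_character_))
  out <- character(0)
  for (p in span_start:(span_end - 1L)) {
    out <- c(out, basemap[[as.character(p)]])
    if (p + 1L > span_start && p + 1L < span_end)
      out <- c(out, insmap[[as.character(p + 1L)]])
  }
  list(status = "OK", seq = paste(out, collapse = ""))
}

# Exhaustive PWM tail probability over all 4^L sequences.
pwm_enum_oracle <- function(pwm, threshold) {
  L <- nrow(pwm$scores)
  grids <- rep(list(1:4), L)
  combos <- as.matrix(expand.grid(grids))
  scores <- rowSums(matrix(pwm$scores[cbind(rep(seq_len(L), each = nrow(combos)),
                                            as.vector(combos))],
                           nrow = nrow(combos)))
  probs <- apply(combos, 1, function(cc) prod(pwm$background[cc]))
  list(p = sum(probs[scores >= threshold]), scores = sort(unique(scores)))
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
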