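#' Differential contact configuration
#'
#' @param filter_low Minimum combined window count `a + b` for a window to be
#'   tested (default 30); windows below it are excluded from testing and from
#'   the BH family.
#' @param alpha FDR significance level for calling a direction (default 0.05).
#' @export
differential_config <- function(filter_low = 30L, alpha = 0.05) {
  stopifnot(filter_low >= 0, alpha > 0, alpha < 1)
  list(filter_low = as.integer(filter_low), alpha = alpha)
}

#' Two-sided Fisher exact test for a 2x2 contact table
#'
#' Tests the table `[[a, A-a], [b, B-b]]` (window count vs rest-of-region
#' count in each group). The two-sided p-value is the classical
#' probability-mass definition: the sum of hypergeometric probabilities of all
#' tables with the same margins whose probability does not exceed that of the
#' observed table, with a 1e-7 relative tolerance on the inclusion comparison
#' to avoid floating-point tie instability. The odds ratio is
#' `(a (B-b)) / (b (A-a))`, with 0.5 added to every cell when any cell is zero
#' (Haldane-Anscombe).
#'
#' @param a,b Window counts in groups 1 and 2.
#' @param A,B Group totals in the analysis region (`A, B > 0`).
#' @return List with `p` and `odds_ratio`.
#' @export
fisher_two_sided <- function(a, b, A, B) {
  stopifnot(A > 0, B > 0, a >= 0, b >= 0, a <= A, b <= B)
  K <- a + b
  support <- max(0L, K - B):min(K, A)
  probs <- stats::dhyper(support, A, B, K)
  p_obs <- probs[support == a]
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  cells <- c(a, A - a, b, B - b)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  list(p = p, odds_ratio = or)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_i = min_{p_j >= p_i} (m p_j / rank_j)`, capped
#' at 1 and order-preserving with p.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values; empty input gives empty output.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  stats::p.adjust(pvalues, method = "BH")
}

#' Per-window differential contact test
#'
#' Windows with combined count `a + b < filter_low` are excluded from testing
#' and from the BH family (low-count filtering is independent of the test
#' statistic under the null). Remaining windows get a two-sided Fisher exact
#' p, a BH q, and a direction at `q < alpha`: `"gained"` when group 2 (e.g.
#' the epimutant allele) is enriched, `"lost"` when depleted, by the sign of
#' `b/B - a/A`.
#'
#' @param profileA,profileB `contact_profile`s sharing fragment inclusion.
#' @param windows A `contact_windows` data frame from [build_windows()].
#' @param config A [differential_config()].
#' @return Data frame of class `differential_results`: the window columns plus
#'   `a`, `b`, `A`, `B`, `tested`, `odds_ratio`, `log10_or`, `p`, `q`,
#'   `direction`. Untested windows carry NA statistics and direction "none".
#' @export
test_windows <- function(profileA, profileB, windows,
                         config = differential_config()) {
  a <- window_counts(profileA, windows)
  b <- window_counts(profileB, windows)
  A <- profileA$total; B <- profileB$total
  tested <- (a + b) >= config$filter_low
  if (!any(tested)) warning("no window passes filter_low; empty test family")
  p <- or <- rep(NA_real_, length(a))
  for (i in which(tested)) {
    ft <- fisher_two_sided(a[i], b[i], A, B)
    p[i] <- ft$p; or[i] <- ft$odds_ratio
  }
  q <- rep(NA_real_, length(a))
  q[tested] <- bh_fdr(p[tested])
  direction <- rep("none", length(a))
  sig <- tested & !is.na(q) & q < config$alpha
  delta <- b / B - a / A
  direction[sig & delta > 0] <- "gained"
  direction[sig & delta < 0] <- "lost"
  out <- cbind(as.data.frame(windows),
               data.frame(a = a, b = b, A = A, B = B, tested = tested,
                          odds_ratio = or, log10_or = log10(or), p = p, q = q,
                          direction = direction, stringsAsFactors = FALSE))
  class(out) <- c("differential_results", "data.frame")
  out
}

#' Multi-resolution domainogram of contact fold changes
#'
#' Entry `(k, i)` is the mean over windows `i .. i+k-1` of
#' `log2((norm_b + 1) / (norm_a + 1))` (pseudocount 1 on depth-normalised
#' window counts). Row `k = 1` equals the per-window log2 fold changes; larger
#' `k` trades spatial resolution for stability, the usual way smoothed contact
#' differences are displayed under an interaction profile.
#'
#' @param profileA,profileB `contact_profile`s.
#' @param windows A `contact_windows` data frame.
#' @param K Maximum scale (`1 <= K <=` number of windows).
#' @return A `K x W` matrix with `NA` beyond column `W - k + 1` at scale `k`;
#'   attribute `window_id` gives the column order.
#' @export
domainogram <- function(profileA, profileB, windows, K) {
  W <- nrow(windows)
  stopifnot(K >= 1, K <= W)
  nz <- normalize_profiles(profileA, profileB, windows)
  lfc <- log2((nz$norm_b + 1) / (nz$norm_a + 1))
  out <- matrix(NA_real_, nrow = K, ncol = W,
                dimnames = list(scale = seq_len(K), window = windows$window_id))
  cs <- c(0, cumsum(lfc))
  for (k in seq_len(K)) {
    i <- seq_len(W - k + 1L)
    out[k, i] <- (cs[i + k] - cs[i]) / k
  }
  attr(out, "window_id") <- windows$window_id
  out
}

#' Long-format domainogram table
#' @param dg Matrix from [domainogram()].
#' @return Data frame `scale`, `window_index`, `log2fc` (NA entries dropped).
#' @export
domainogram_long <- function(dg) {
  df <- expand.grid(scale = seq_len(nrow(dg)), window_index = seq_len(ncol(dg)))
  df$log2fc <- dg[cbind(df$scale, df$window_index)]
  df[!is.na(df$log2fc), , drop = FALSE]
}
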