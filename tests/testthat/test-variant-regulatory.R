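variant_row <- function(chrom, pos, ref, alt, af = NA_real_, phase = "UNPHASED") {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             af = af, phase = phase, stringsAsFactors = FALSE)
}

test_that("rare-variant filtering keeps af < 1% and flags missing AF", {
  v <- rbind(variant_row("c", 10, "G", "A", af = 0.005),
             variant_row("c", 20, "G", "A", af = 0.232),  # common reporter-like SNP
             variant_row("c", 30, "G", "A", af = NA),
             variant_row("c", 40, "G", "A", af = 0.01))
  rare <- filter_rare(v)
  expect_equal(rare$pos, c(10L, 30L))
  expect_equal(rare$af_missing, c(FALSE, TRUE))
})

test_that("sliding-window burden matches a brute-force recount", {
  v <- rbind(variant_row("c", 5, "G", "A", af = 0.001, phase = "IN_PHASE_MAA"),
             variant_row("c", 7, "G", "A", af = 0.001),
             variant_row("c", 23, "G", "A", af = 0.001, phase = "IN_PHASE_MAA"))
  region <- gintervals("c", 0, 30)
  bw <- sliding_window_burden(v, region, burden_config(window_width = 10L, step = 5L))
  expect_equal(bw$n_rare, c(2L, 2L, 0L, 1L, 1L))
  expect_equal(bw$n_in_phase, c(1L, 1L, 0L, 1L, 1L))
  am <- burden_argmax(bw, "n_rare")
  expect_equal(am$start, c(0L, 5L))          # ties all reported
  # n_in_phase is always a subset of n_rare
  expect_true(all(bw$n_in_phase <= bw$n_rare))
  # no variants -> all zeros
  bw0 <- sliding_window_burden(v[0, ], region,
                               burden_config(window_width = 10L, step = 5L))
  expect_true(all(bw0$n_rare == 0L))
  expect_error(sliding_window_burden(v, region,
                                     burden_config(window_width = 50L, step = 50L)),
               "width exceeds")
})

test_that("non-overlapping burden windows conserve the total variant count", {
  withr::local_seed(31)
  pos <- sample.int(1000, 80) - 1L
  v <- do.call(rbind, lapply(pos, function(p)
    variant_row("c", p, "G", "A", af = 0.001)))
  region <- gintervals("c", 0, 1000)
  bw <- sliding_window_burden(v, region,
                              burden_config(window_width = 100L, step = 100L))
  expect_equal(sum(bw$n_rare), nrow(v))
})

test_that("PPM to PWM conversion follows the log-odds formula", {
  ppm <- structure(list(tf_name = "toy", role = "other",
                        mat = matrix(c(1, 0, 0, 0,
                                       0.25, 0.25, 0.25, 0.25),
                                     nrow = 2, byrow = TRUE,
                                     dimnames = list(NULL, c("A", "C", "G", "T")))),
                   class = "ppm")
  expect_error(ppm_to_pwm(ppm, pseudocount = 0), "pseudocount")
  pw <- ppm_to_pwm(ppm, pseudocount = 0.01)
  # closed form at position 1: A = log2((1 + .01*.25)/(1.01*.25))
  expect_equal(unname(pw$scores[1, "A"]), log2((1 + 0.01 * 0.25) / (1.01 * 0.25)))
  expect_equal(unname(pw$scores[1, "C"]), log2((0 + 0.01 * 0.25) / (1.01 * 0.25)))
  expect_equal(which.max(pw$scores[1, ]), c(A = 1L))
  # uniform column scores 0 for every base
  expect_equal(unname(pw$scores[2, ]), rep(0, 4))
  expect_equal(pw$smin, sum(apply(pw$scores, 1, min)))
  expect_error(ppm_to_pwm(ppm, background = c(0.5, 0.5, 0, 0)), "zero background")
})

test_that("scanning finds the consensus at rel score 1 and respects min_rel", {
  cfg <- small_config(seed = 2)
  ppms <- make_ppm_library(cfg)
  sharp <- ppms[[1]]                 # odd indices are sharp motifs
  pw <- ppm_to_pwm(sharp)
  consensus <- paste(c("A", "C", "G", "T")[apply(pw$scores, 1, which.max)],
                     collapse = "")
  hits <- scan_sequence(pw, consensus, min_rel = 0.99)
  expect_true(any(hits$pos == 0 & hits$strand == "+" &
                    abs(hits$rel_score - 1) < 1e-12))
  # min_rel = 0 reports every offset on both strands
  seq <- paste(rep("ACGT", 10), collapse = "")
  all_hits <- scan_sequence(pw, seq, min_rel = 0)
  L <- nrow(pw$scores)
  expect_equal(nrow(all_hits), 2 * (nchar(seq) - L + 1))
  # sequence shorter than the motif: no hits
  expect_equal(nrow(scan_sequence(pw, substr(consensus, 1, L - 1))), 0L)
})

test_that("reverse-complement symmetry holds for scanning", {
  # palindromic motif: forward and reverse hits coincide with equal scores
  pal <- structure(list(tf_name = "pal", role = "other",
                        mat = matrix(c(0.9, 0.03, 0.03, 0.04,
                                       0.04, 0.03, 0.03, 0.9),
                                     nrow = 2, byrow = TRUE,
                                     dimnames = list(NULL, c("A", "C", "G", "T")))),
                   class = "ppm")
  pw <- ppm_to_pwm(pal)
  hits <- scan_sequence(pw, "CCATCC", min_rel = 0)
  for (p in unique(hits$pos)) {
    sub <- hits[hits$pos == p, ]
    expect_equal(sub$score[sub$strand == "+"], sub$score[sub$strand == "-"])
  }
  # general invariance: best score on seq equals best score on its revcomp
  cfg <- small_config(seed = 2)
  pw2 <- ppm_to_pwm(make_ppm_library(cfg)[[3]])
  withr::local_seed(17)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = "")
    h1 <- scan_sequence(pw2, s, min_rel = 0)
    h2 <- scan_sequence(pw2, revcomp(s), min_rel = 0)
    expect_equal(max(h1$score), max(h2$score), tolerance = 1e-12)
  }
})

test_that("score p-value: closed-form dinucleotide case and monotonicity", {
  # sharp 2-mer with a unique maximum-scoring dinucleotide -> p(S_max) = 1/16
  ppm <- structure(list(tf_name = "di", role = "other",
                        mat = matrix(c(0.91, 0.03, 0.03, 0.03,
                                       0.03, 0.91, 0.03, 0.03),
                                     nrow = 2, byrow = TRUE,
                                     dimnames = list(NULL, c("A", "C", "G", "T")))),
                   class = "ppm")
  pw <- ppm_to_pwm(ppm, pseudocount = 0.01)
  expect_equal(score_pvalue(pw, pw$smax), 1 / 16)
  expect_equal(score_pvalue(pw, pw$smin), 1)
  thresholds <- seq(pw$smin, pw$smax, length.out = 50)
  ps <- vapply(thresholds, function(t) score_pvalue(pw, t), 0)
  expect_true(all(diff(ps) <= 1e-15))
  expect_true(all(ps >= 0 & ps <= 1))
})

test_that("DP tail probabilities match exhaustive enumeration on small motifs", {
  cfg <- small_config(seed = 13, n_ppms = 6L, ppm_lengths = 3:5)
  ppms <- make_ppm_library(cfg)
  grain <- 1e-3
  for (ppm in ppms) {
    pw <- ppm_to_pwm(ppm)
    enum <- pwm_enum_oracle(pw, pw$smin)
    sc <- enum$scores
    gaps <- which(diff(sc) > 2 * (nrow(pw$scores) + 2) * grain)
    mids <- (sc[gaps] + sc[gaps + 1]) / 2
    expect_gt(length(mids), 0)
    for (thr in mids[unique(round(seq(1, length(mids), length.out = 5)))]) {
      expect_equal(score_pvalue(pw, thr, grain = grain),
                   pwm_enum_oracle(pw, thr)$p, tolerance = 1e-9,
                   info = sprintf("%s thr=%.4f", ppm$tf_name, thr))
    }
  }
})

test_that("variant scoring: disruption direction, indels, and contig edges", {
  # sharp toy motif ACGTA; genome carries its consensus
  mat <- matrix(0.01, nrow = 5, ncol = 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  mat[cbind(1:5, match(c("A", "C", "G", "T", "A"), c("A", "C", "G", "T")))] <- 0.97
  ppm <- structure(list(tf_name = "acgta", role = "activator", mat = mat),
                   class = "ppm")
  pw <- ppm_to_pwm(ppm)
  g <- Biostrings::DNAStringSet(c(chrX = "TTTTTTACGTATTTTTTTTT"))
  # consensus-breaking SNV at the most informative position (the G at pos 8)
  v <- variant_row("chrX", 8, "G", "T")
  call <- score_variant(pw, g, v, p_threshold = 0.01)
  expect_lt(call$alt_best_rel, call$ref_best_rel)
  expect_lt(call$delta, 0)
  expect_false(call$partial)
  # 3-bp deletion: alt sequence is realised and rescanned
  vdel <- variant_row("chrX", 6, "ACGT", "A")
  cdel <- score_variant(pw, g, vdel, p_threshold = 0.01)
  expect_false(cdel$partial)
  expect_lt(cdel$alt_best_rel, cdel$ref_best_rel)
  # variant too close to the contig edge: flagged partial, not scored
  vedge <- variant_row("chrX", 1, "T", "C")
  cedge <- score_variant(pw, g, vedge)
  expect_true(cedge$partial)
  expect_equal(cedge$strength, "none")
})

test_that("a substitution the motif cannot distinguish gives delta 0, strength none", {
  # strand-symmetric motif: A/T columns equal and C/G columns equal at every
  # position, so an A<->T change alters no score on either strand
  mat <- matrix(c(0.40, 0.10, 0.10, 0.40,
                  0.10, 0.40, 0.40, 0.10,
                  0.45, 0.05, 0.05, 0.45,
                  0.05, 0.45, 0.45, 0.05),
                nrow = 4, byrow = TRUE,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  pw <- ppm_to_pwm(structure(list(tf_name = "wsym", role = "other", mat = mat),
                             class = "ppm"))
  g <- Biostrings::DNAStringSet(c(chrX = "CCGGACGTACGTCCGG"))
  v <- data.frame(chrom = "chrX", pos = 8L, ref = "A", alt = "T",
                  af = NA_real_, phase = "UNPHASED", stringsAsFactors = FALSE)
  call <- score_variant(pw, g, v, p_threshold = 0.5)
  expect_equal(call$delta, 0)
  expect_equal(call$strength, "none")
})

test_that("match strength requires a significant motif hit on either allele", {
  mat <- matrix(0.01, nrow = 5, ncol = 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  mat[cbind(1:5, match(c("A", "C", "G", "T", "A"), c("A", "C", "G", "T")))] <- 0.97
  pw <- ppm_to_pwm(structure(list(tf_name = "acgta", role = "repressor",
                                  mat = mat), class = "ppm"))
  # ALT creates the consensus -> strong gain for a repressor motif
  g <- Biostrings::DNAStringSet(c(chrX = "TTTTTTACTTATTTTTTTTT"))
  v <- variant_row("chrX", 8, "T", "G")
  call <- score_variant(pw, g, v, p_threshold = 1e-2)
  expect_equal(call$strength, "strong")
  expect_gt(call$delta, 0)
  expect_equal(classify_regulatory(call), "repressor_gain")
  # with an impossibly strict p threshold the same change is not matched
  call2 <- score_variant(pw, g, v, p_threshold = 1e-12)
  expect_equal(call2$strength, "none")
})

test_that("regulatory classification covers the full rule table", {
  mk_call <- function(delta, strength)
    data.frame(delta = delta, strength = strength, role = NA,
               stringsAsFactors = FALSE)
  cases <- expand.grid(role = c("activator", "repressor", "insulator", "other"),
                       delta = c(-0.3, 0, 0.3),
                       strength = c("none", "weak", "strong"),
                       stringsAsFactors = FALSE)
  want <- function(role, delta, strength) {
    if (strength == "none") return("none")
    if (role == "repressor" && delta > 0) return("repressor_gain")
    if (role == "activator" && delta < 0) return("activator_loss")
    if (role == "insulator" && strength == "strong") return("insulator_hit")
    "none"
  }
  for (i in seq_len(nrow(cases))) {
    got <- classify_regulatory(mk_call(cases$delta[i], cases$strength[i]),
                               role = cases$role[i])
    expect_equal(got, want(cases$role[i], cases$delta[i], cases$strength[i]),
                 info = paste(cases[i, ], collapse = " "))
  }
  # spot checks from the rule statement
  expect_equal(classify_regulatory(mk_call(0.3, "strong"), "repressor"),
               "repressor_gain")
  expect_equal(classify_regulatory(mk_call(0.3, "strong"), "activator"), "none")
  expect_equal(classify_regulatory(mk_call(-0.25, "strong"), "activator"),
               "activator_loss")
})

test_that("an implanted in-phase cluster is the argmax burden window", {
  cfg <- small_config(seed = 19)
  vs <- make_variant_set(cfg)
  rare <- filter_rare(vs$variants)
  bw <- sliding_window_burden(rare, cfg$region,
                              burden_config(window_width = 5000L, step = 500L))
  top <- burden_argmax(bw, "n_in_phase")
  cl <- cfg$cluster_interval
  expect_true(all(top$start < cl$end & top$end > cl$start))
})
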