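test_that("restriction digestion cuts at motif starts and tiles the chromosome", {
  g <- Biostrings::DNAStringSet(c(x = "AAGATCTTGATCAA"))
  map <- digest_genome(g, "x")
  expect_equal(map$start, c(0L, 2L, 8L))
  expect_equal(map$end, c(2L, 8L, 14L))
  expect_equal(map$frag_id, 0:2)
  # motif absent -> single fragment spanning the chromosome
  g2 <- Biostrings::DNAStringSet(c(x = "AAAACCCC"))
  map2 <- digest_genome(g2, "x")
  expect_equal(nrow(map2), 1L)
  expect_equal(c(map2$start, map2$end), c(0L, 8L))
  # motif at position 0 -> no empty leading fragment
  g3 <- Biostrings::DNAStringSet(c(x = "GATCAAGATCAA"))
  map3 <- digest_genome(g3, "x")
  expect_equal(map3$start, c(0L, 6L))
  expect_true(all(map3$end - map3$start > 0))
  # overlapping motif occurrences each produce a cut
  g4 <- Biostrings::DNAStringSet(c(x = "CCAAAACC"))
  map4 <- digest_genome(g4, "x", motif = "AA")
  expect_equal(map4$start, c(0L, 2L, 3L, 4L))
  # fragments always tile: no gaps, no overlaps
  for (m in list(map, map2, map3, map4)) {
    expect_equal(m$start[-1], m$end[-nrow(m)])
  }
})

test_that("fragment lookup is half-open and agrees with a linear scan", {
  gm <- default_genome_map()
  map <- gm$map
  expect_equal(locate_fragment(map, 0L), 0L)
  # boundary position belongs to the fragment starting there
  b <- map$start[10]
  expect_equal(locate_fragment(map, b), map$frag_id[10])
  expect_equal(locate_fragment(map, b - 1L), map$frag_id[9])
  expect_error(locate_fragment(map, max(map$end)), "out of range")
  withr::local_seed(99)
  pos <- sample.int(max(map$end), 1000L) - 1L
  linear <- vapply(pos, function(p)
    map$frag_id[which(map$start <= p & p < map$end)], 1L)
  expect_equal(locate_fragment(map, pos), linear)
})

test_that("profiles deduplicate by (fragment, UMI) and exclude the viewpoint zone", {
  map <- toy_map(21L)
  region <- gintervals("chrT", 0, 2100)
  mk <- function(pos, umi, allele = "MAA")
    data.frame(group = "g", allele = allele, chrom = "chrT", pos = pos,
               umi = umi, stringsAsFactors = FALSE)
  # three records, same fragment, same UMI -> one molecule
  contacts <- rbind(mk(150, "u1"), mk(160, "u1"), mk(199, "u1"))
  p <- build_profile(contacts, map, 1050L, region,
                     smoothing_config(viewpoint_exclusion_fragments = 0L))[["g.MAA"]]
  expect_equal(p$total, 1L)
  # distinct UMIs -> three molecules
  contacts <- rbind(mk(150, "u1"), mk(160, "u2"), mk(199, "u3"))
  p <- build_profile(contacts, map, 1050L, region,
                     smoothing_config(viewpoint_exclusion_fragments = 0L))[["g.MAA"]]
  expect_equal(p$total, 3L)
  expect_equal(unname(p$counts[["1"]]), 3L)
  # viewpoint fragment (10) +- 2 are excluded: record at fragment 9 dropped
  contacts <- rbind(mk(950, "u1"), mk(150, "u2"))
  p <- build_profile(contacts, map, 1050L, region,
                     smoothing_config(viewpoint_exclusion_fragments = 2L))[["g.MAA"]]
  expect_equal(p$total, 1L)
  expect_false("9" %in% names(p$counts))
  # OTHER-allele records are dropped with a message
  contacts <- rbind(mk(150, "u1"), mk(250, "u2", allele = "OTHER"))
  expect_message(
    p <- build_profile(contacts, map, 1050L, region,
                       smoothing_config(viewpoint_exclusion_fragments = 0L))[["g.MAA"]],
    "OTHER")
  expect_equal(p$total, 1L)
})

test_that("deduplication is idempotent", {
  cfg <- small_config(seed = 3, umi_length = 4L)  # short UMIs force collisions
  g <- make_genome(cfg)
  map <- digest_genome(g, cfg$chrom)
  cc <- make_contact_dataset(cfg, map)
  p1 <- build_profile(cc$contacts, map, cfg$viewpoint_pos, cfg$region)
  # rebuild from the deduplicated molecules: counts must not change
  rebuilt <- do.call(rbind, lapply(p1, function(p) {
    df <- data.frame(frag = rep(as.integer(names(p$counts)), p$counts))
    data.frame(group = p$group, allele = p$allele, chrom = cfg$chrom,
               pos = map$start[match(df$frag, map$frag_id)],
               umi = paste0("u", seq_len(nrow(df)), "_", df$frag),
               stringsAsFactors = FALSE)
  }))
  p2 <- build_profile(rebuilt, map, cfg$viewpoint_pos, cfg$region)
  for (k in names(p1)) expect_equal(p2[[k]]$counts, p1[[k]]$counts)
})

test_that("window construction follows the greedy count-balanced rule", {
  # 16 uniform fragments, viewpoint on fragment 10, no exclusion zone.
  # Downstream fragments 11..15 carry counts 1,1,2,0,3; the remaining mass
  # sits upstream so that the combined total is 100 -> threshold ceil(3) = 3.
  map <- toy_map(16L)
  region <- gintervals("chrT", 0, 1600)
  counts <- rep(0L, 16)
  counts[12:16] <- c(1L, 1L, 2L, 0L, 3L)   # fragments 11..15 (0-based ids)
  counts[1:10] <- c(93L, rep(0L, 9))       # fragment 0 upstream holds the rest
  prof <- profile_from_counts(map, counts, 1050L, region)
  w <- build_windows(list(prof), map, smoothing_config(min_win_factor = 0.03,
                                                       viewpoint_exclusion_fragments = 0L))
  down <- w[w$side == "downstream", ]
  expect_equal(nrow(down), 2L)
  expect_equal(down$frag_lo, c(11L, 14L))
  expect_equal(down$frag_hi, c(13L, 15L))      # {f11..f13} sum 4, {f14,f15} sum 3
  expect_equal(down$combined, c(4L, 3L))
  # threshold 1 with all fragments >= 1 -> one window per fragment
  counts2 <- rep(1L, 16)
  prof2 <- profile_from_counts(map, counts2, 1050L, region)
  w2 <- build_windows(list(prof2), map,
                      smoothing_config(min_win_factor = 0.04,
                                       viewpoint_exclusion_fragments = 0L))
  expect_equal(nrow(w2), 15L)                  # 10 upstream + 5 downstream
  expect_true(all(w2$n_frags == 1L))
  # all mass on the first fragment of a side -> single window after merge
  counts3 <- rep(0L, 16)
  counts3[12] <- 50L; counts3[10] <- 50L
  prof3 <- profile_from_counts(map, counts3, 1050L, region)
  w3 <- build_windows(list(prof3), map,
                      smoothing_config(min_win_factor = 0.2,
                                       viewpoint_exclusion_fragments = 0L))
  expect_equal(sum(w3$side == "downstream"), 1L)
  expect_equal(w3$frag_hi[w3$side == "downstream"], 15L)  # trailing merged in
})

test_that("windows partition included fragments, conserve counts, ignore group split", {
  cfg <- default_config()
  cfg$contact_alleles <- "MAA"
  gm <- default_genome_map()
  cc <- make_contact_dataset(cfg, gm$map)
  profs <- build_profile(cc$contacts, gm$map, cfg$viewpoint_pos, cfg$region)
  w <- build_windows(profs, gm$map)
  inc <- profs[[1]]$frag_ids
  covered <- unlist(lapply(seq_len(nrow(w)), function(i)
    inc[inc >= w$frag_lo[i] & inc <= w$frag_hi[i]]))
  expect_setequal(covered, inc)                 # partition: every fragment once
  expect_equal(length(covered), length(inc))
  combined <- Reduce(`+`, lapply(profs, `[[`, "counts"))
  expect_equal(sum(w$combined), sum(combined))  # conservation
  # swapping the groups leaves the windows unchanged
  w_swap <- build_windows(rev(profs), gm$map)
  expect_equal(w_swap, w)
  # all windows except possibly one per side reach the threshold
  thr <- ceiling(0.03 * sum(combined))
  for (s in c("upstream", "downstream")) {
    ws <- w[w$side == s, ]
    expect_lte(sum(ws$combined < thr), 1L)
  }
})

test_that("normalisation rescales to the first profile's depth", {
  map <- toy_map(21L)
  region <- gintervals("chrT", 0, 2100)
  counts <- c(rep(5L, 10), 0L, rep(5L, 10))
  pA <- profile_from_counts(map, counts, 1050L, region, group = "a")
  pB <- profile_from_counts(map, counts, 1050L, region, group = "b")
  w <- build_windows(list(pA, pB), map,
                     smoothing_config(min_win_factor = 0.05,
                                      viewpoint_exclusion_fragments = 0L))
  nz <- normalize_profiles(pA, pB, w)
  expect_equal(nz$norm_a, nz$norm_b)            # identical profiles
  expect_true(all(log2((nz$norm_b + 1) / (nz$norm_a + 1)) == 0))
  # B = 2 x A per fragment -> scale 0.5, trends identical
  pB2 <- profile_from_counts(map, counts * 2L, 1050L, region, group = "b")
  nz2 <- normalize_profiles(pA, pB2, w)
  expect_equal(attr(nz2, "scale"), 0.5)
  expect_equal(nz2$norm_b, nz2$norm_a)
  # totals 1000 vs 500 with b_w = 10 -> normalised 20
  cA <- rep(0L, 21); cA[1] <- 1000L
  cB <- rep(0L, 21); cB[1] <- 490L; cB[15] <- 10L
  pA3 <- profile_from_counts(map, cA, 1050L, region, group = "a")
  pB3 <- profile_from_counts(map, cB, 1050L, region, group = "b")
  w3 <- data.frame(window_id = 1:2, side = c("upstream", "downstream"),
                   frag_lo = c(0L, 11L), frag_hi = c(9L, 20L),
                   start = c(0L, 1100L), end = c(1000L, 2100L),
                   n_frags = c(10L, 10L), combined = c(1490L, 10L))
  nz3 <- normalize_profiles(pA3, pB3, w3)
  expect_equal(nz3$norm_b[2], 20)
  # zero-depth B is an error
  pB0 <- profile_from_counts(map, rep(0L, 21), 1050L, region, group = "b")
  expect_error(normalize_profiles(pA3, pB0, w3), "zero molecules")
})
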