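#' Simulation configuration
#'
#' One seeded configuration drives every generator; each generator is a pure
#' function of the configuration (stage seeds are derived from `seed` by fixed
#' offsets so stages are independently reproducible). The defaults encode the
#' study conditions the package targets: a 1 Mb analysis region centred on a
#' promoter viewpoint carrying a heterozygous G>A reporter whose alternate
#' allele travels with the methylation-associated haplotype (MAA); balanced
#' allele fractions in controls versus 1% MAA / 99% non-MAA accessibility in
#' epimutant samples; distance-decaying viewpoint contacts with eight
#' implanted differential windows (four gained at 2.5x, four lost at 0.4x) on
#' the epimutant MAA; and 99 rare variants of which 34 are in phase with the
#' MAA, with a 10 kb cluster of in-phase variants inside one upstream
#' differential contact.
#'
#' @param seed Integer master seed.
#' @param chrom Simulated chromosome name.
#' @param genome_length Genome length in bp (>= 1000).
#' @param motif Restriction motif (DpnII "GATC").
#' @param min_fragments Minimum number of fragments guaranteed in the region
#'   (motif sites are spiked deterministically if the random sequence falls
#'   short).
#' @param reporter_pos,reporter_ref,reporter_alt Reporter variant (0-based).
#' @param reporter_labels Haplotype labels for REF/ALT.
#' @param viewpoint_pos 0-based viewpoint (bait) position.
#' @param region Analysis region (single-row [gintervals]).
#' @param n_reads Reads per group for the reporter-read generator.
#' @param read_length Read length in bp.
#' @param error_rate Per-base substitution error rate.
#' @param maa_fraction Named vector of MAA allele fractions per group.
#' @param n_molecules UMI-4C molecules per (group, allele).
#' @param decay Contact distance-decay exponent (weights
#'   `(1 + |distance|)^-decay`).
#' @param umi_length UMI length in bases (collisions possible and
#'   truth-tracked).
#' @param contact_groups,contact_alleles Group and allele labels generated.
#' @param implants Data frame `start`, `end`, `multiplier`, `target_group`,
#'   `target_allele`: fragment weights inside each interval are multiplied for
#'   the target group/allele (> 1 gained, < 1 lost).
#' @param n_common,n_rare Variant counts above/below the 1% AF threshold.
#' @param n_in_phase Rare variants labelled in phase with the MAA.
#' @param cluster_interval Single-row [gintervals]: the implanted rare-variant
#'   cluster (inside one promoter-contacting differential window).
#' @param cluster_n In-phase rare variants placed inside the cluster.
#' @param n_ppms,ppm_lengths Motif library size and admissible motif lengths.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              chrom = "chr3sim",
                              genome_length = 1000000L,
                              motif = "GATC",
                              min_fragments = 50L,
                              reporter_pos = 500000L,
                              reporter_ref = "G",
                              reporter_alt = "A",
                              reporter_labels = c(REF = "NON_MAA", ALT = "MAA"),
                              viewpoint_pos = 500000L,
                              region = NULL,
                              n_reads = 10000L,
                              read_length = 75L,
                              error_rate = 0.01,
                              maa_fraction = c(control = 0.5, epimutant = 0.01),
                              n_molecules = 10000L,
                              decay = 1,
                              umi_length = 10L,
                              contact_groups = c("control", "epimutant"),
                              contact_alleles = c("MAA", "NON_MAA"),
                              implants = default_implants(),
                              n_common = 60L,
                              n_rare = 99L,
                              n_in_phase = 34L,
                              cluster_interval = NULL,
                              cluster_n = 12L,
                              n_ppms = 8L,
                              ppm_lengths = 4:10) {
  stopifnot(genome_length >= 1000L, error_rate >= 0, error_rate < 1,
            decay >= 0, umi_length >= 1, n_in_phase <= n_rare,
            cluster_n <= n_in_phase)
  if (is.null(region)) region <- gintervals(chrom, 0, genome_length)
  if (is.null(cluster_interval)) cluster_interval <- gintervals(chrom, 330000, 340000)
  stopifnot(region$start <= viewpoint_pos, viewpoint_pos < region$end,
            cluster_interval$start >= region$start,
            cluster_interval$end <= region$end)
  if (!is.null(implants) && nrow(implants) > 0)
    stopifnot(all(implants$start >= region$start),
              all(implants$end <= region$end), all(implants$multiplier > 0))
  structure(as.list(environment()), class = "simulation_config")
}

#' Default implanted differential windows
#'
#' Eight intervals around a viewpoint at 500 kb: four gained (2.5x) and four
#' lost (0.4x) contacts on the epimutant MAA, spread over both sides and over
#' near/mid/far viewpoint distances, mirroring a profile with both gained and
#' lost interactions. Because molecules are sampled with a fixed count per
#' group, multiplying weights inside implants rescales every other fragment's
#' sampling probability; the implant masses are therefore balanced (extra
#' gained weight ~ removed lost weight under the default distance decay) so
#' that non-implanted fragments stay null. Widths roughly track the local
#' count-balanced smoothing-window width so each implant is detectable at the
#' default depth.
#'
#' @export
default_implants <- function() {
  data.frame(
    start = c(110000L, 280000L, 415000L, 460000L, 508000L, 560000L, 630000L, 780000L),
    end = c(220000L, 380000L, 450000L, 492000L, 534000L, 600000L, 710000L, 890000L),
    multiplier = c(2.5, 0.4, 2.5, 0.4, 0.4, 2.5, 0.4, 2.5),
    target_group = "epimutant",
    target_allele = "MAA",
    stringsAsFactors = FALSE)
}

.rand_seq <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")

#' Generate the simulated genome
#'
#' I.i.d. bases with the reporter REF allele embedded at the reporter
#' position; restriction motif sites are spiked at regular intervals if the
#' random draw yields fewer than `min_fragments` fragments in the region.
#' Deterministic given the configuration.
#'
#' @param config A [simulation_config()].
#' @param path Optional FASTA output path.
#' @return A `DNAStringSet` genome.
#' @export
make_genome <- function(config, path = NULL) {
  gen <- withr::with_seed(config$seed + 11L, {
    s <- .rand_seq(config$genome_length)
    substr(s, config$reporter_pos + 1L,
           config$reporter_pos + nchar(config$reporter_ref)) <- config$reporter_ref
    g <- Biostrings::DNAStringSet(s)
    names(g) <- config$chrom
    map <- digest_genome(g, config$chrom, config$motif)
    if (nrow(map) < config$min_fragments) {
      step <- max(1L, config$genome_length %/% (config$min_fragments + 2L))
      at <- seq.int(step, config$genome_length - nchar(config$motif), by = step)
      at <- at[abs(at - config$reporter_pos) > nchar(config$motif) + 1L]
      for (a in at) substr(s, a + 1L, a + nchar(config$motif)) <- config$motif
      g <- Biostrings::DNAStringSet(s)
      names(g) <- config$chrom
    }
    g
  })
  if (!is.null(path)) write_fasta(gen, path)
  gen
}

.maa_allele <- function(config) {
  # which of REF/ALT carries the MAA label
  names(config$reporter_labels)[config$reporter_labels == "MAA"][1]
}

.apply_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  n_err <- stats::rbinom(length(seqs), nchar(seqs), error_rate)
  for (i in which(n_err > 0L)) {
    at <- sample.int(nchar(seqs[i]), n_err[i])
    for (p in at) {
      cur <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(.BASES, cur), 1L)
    }
  }
  seqs
}

#' Generate reporter-spanning reads (SAM) with per-read allele truth
#'
#' For each group, reads fully spanning the reporter are drawn with the
#' group's MAA allele fraction (balanced in controls, 1%/99% in epimutants,
#' emulating near-monoallelic accessibility), then per-base substitution
#' errors are applied at `error_rate`. SNV-allele reads are plain matches;
#' deletion-allele reads carry a D CIGAR op over exactly the deleted span.
#' A truth table of per-read alleles is produced alongside.
#'
#' @param config A [simulation_config()].
#' @param genome Genome from [make_genome()].
#' @param path Optional SAM output path.
#' @param truth_path Optional truth TSV output path.
#' @return List with `reads` (an `aligned_reads` data frame) and `truth`
#'   (data frame `qname`, `group`, `true_allele`, `true_label`).
#' @export
make_reporter_reads <- function(config, genome, path = NULL, truth_path = NULL) {
  rp <- config$reporter_pos; ref <- config$reporter_ref; alt <- config$reporter_alt
  rl <- config$read_length
  k <- nchar(ref) - nchar(alt)   # deleted bases (0 for an SNV)
  na_ <- nchar(alt)
  maa <- .maa_allele(config)
  chrom_str <- as.character(genome[[config$chrom]])
  out <- withr::with_seed(config$seed + 22L, {
    all_reads <- list(); all_truth <- list()
    for (g in names(config$maa_fraction)) {
      f <- config$maa_fraction[[g]]
      is_maa <- stats::runif(config$n_reads) < f
      allele <- ifelse(is_maa, maa, setdiff(c("REF", "ALT"), maa))
      qname <- sprintf("%s_r%06d", g, seq_len(config$n_reads))
      pos <- integer(config$n_reads); seqs <- character(config$n_reads)
      cigar <- character(config$n_reads)
      for (i in seq_len(config$n_reads)) {
        if (k == 0L) {                      # SNV (or same-length) reporter
          o <- sample.int(rl - nchar(ref), 1L) - 1L   # offset of reporter in read
          rstart <- rp - o
          s <- substr(chrom_str, rstart + 1L, rstart + rl)
          if (allele[i] == "ALT")
            substr(s, o + 1L, o + nchar(alt)) <- alt
          pos[i] <- rstart; seqs[i] <- s; cigar[i] <- paste0(rl, "M")
        } else if (allele[i] == "REF") {    # deletion reporter, reference allele
          o <- sample.int(rl - nchar(ref), 1L) - 1L
          rstart <- rp - o
          pos[i] <- rstart
          seqs[i] <- substr(chrom_str, rstart + 1L, rstart + rl)
          cigar[i] <- paste0(rl, "M")
        } else {                            # deletion allele: xM kD yM
          o <- sample(seq.int(max(na_, 1L), rl - 1L), 1L)  # matched bases before the D
          rstart <- rp + na_ - o
          pos[i] <- rstart
          seqs[i] <- paste0(
            substr(chrom_str, rstart + 1L, rstart + o),
            substr(chrom_str, rp + nchar(ref) + 1L, rp + nchar(ref) + rl - o))
          cigar[i] <- paste0(o, "M", k, "D", rl - o, "M")
        }
      }
      seqs <- .apply_errors(seqs, config$error_rate)
      flag <- sample(c(0L, 16L), config$n_reads, replace = TRUE)
      all_reads[[g]] <- data.frame(qname = qname, flag = flag,
                                   chrom = config$chrom, pos = pos, mapq = 60L,
                                   cigar = cigar, seq = seqs,
                                   umi = NA_character_, group = g,
                                   allele = NA_character_,
                                   stringsAsFactors = FALSE)
      all_truth[[g]] <- data.frame(qname = qname, group = g, true_allele = allele,
                                   true_label = unname(config$reporter_labels[allele]),
                                   stringsAsFactors = FALSE)
    }
    list(reads = do.call(rbind, all_reads), truth = do.call(rbind, all_truth))
  })
  rownames(out$reads) <- rownames(out$truth) <- NULL
  out$reads$strand <- ifelse(bitwAnd(out$reads$flag, 16L) != 0L, "-", "+")
  class(out$reads) <- c("aligned_reads", "data.frame")
  if (!is.null(path))
    write_sam(out$reads, path,
              seqlens = stats::setNames(config$genome_length, config$chrom))
  if (!is.null(truth_path)) write_tsv(out$truth, truth_path)
  out
}

.rand_umis <- function(n, len) {
  m <- matrix(sample(.BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Generate a UMI-4C contact dataset with implanted differential windows
#'
#' Fragment sampling weights decay with distance to the viewpoint as
#' `(1 + |d|)^-decay`; for each implant, weights of fragments whose midpoint
#' falls inside the implanted interval are multiplied by the implant
#' multiplier for the target group/allele only (> 1 gained, < 1 lost contacts
#' on the epimutant allele). Molecules get random UMIs of `umi_length` bases;
#' UMI collisions on the same fragment are possible and recorded in the truth
#' so deduplication undercounting is quantifiable.
#'
#' @param config A [simulation_config()].
#' @param map A `fragment_map` of the simulated genome.
#' @param path Optional contact TSV output path.
#' @param truth_path Optional truth JSON output path.
#' @return List with `contacts` (data frame `group`, `allele`, `chrom`, `pos`,
#'   `umi`) and `truth` (list: `implants`, `n_molecules`, `collisions` per
#'   group.allele key).
#' @export
make_contact_dataset <- function(config, map, path = NULL, truth_path = NULL) {
  mids <- (map$start + map$end) / 2
  w_base <- (1 + abs(mids - config$viewpoint_pos))^(-config$decay)
  in_region <- map$end > config$region$start & map$start < config$region$end
  w_base[!in_region] <- 0
  widths <- map$end - map$start
  out <- withr::with_seed(config$seed + 33L, {
    recs <- list()
    for (g in config$contact_groups) for (al in config$contact_alleles) {
      w <- w_base
      imp <- config$implants
      if (!is.null(imp) && nrow(imp) > 0) {
        for (r in seq_len(nrow(imp))) {
          if (imp$target_group[r] == g && imp$target_allele[r] == al) {
            sel <- mids >= imp$start[r] & mids < imp$end[r]
            w[sel] <- w[sel] * imp$multiplier[r]
          }
        }
      }
      idx <- sample.int(nrow(map), config$n_molecules, replace = TRUE, prob = w)
      pos <- map$start[idx] +
        floor(stats::runif(config$n_molecules) * widths[idx])
      recs[[paste(g, al, sep = ".")]] <-
        data.frame(group = g, allele = al, chrom = config$chrom,
                   pos = as.integer(pos),
                   umi = .rand_umis(config$n_molecules, config$umi_length),
                   frag = map$frag_id[idx], stringsAsFactors = FALSE)
    }
    recs
  })
  collisions <- vapply(out, function(df)
    sum(duplicated(paste(df$frag, df$umi))), 1L)
  contacts <- do.call(rbind, lapply(out, function(df) df[names(df) != "frag"]))
  rownames(contacts) <- NULL
  truth <- list(implants = config$implants, n_molecules = config$n_molecules,
                collisions = as.list(collisions))
  if (!is.null(path)) write_contacts(contacts, path)
  if (!is.null(truth_path))
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  list(contacts = contacts, truth = truth)
}

#' Generate a variant set with an implanted rare in-phase cluster
#'
#' Common variants (AF >= 1%) are uniform over the region; rare variants
#' (AF < 1%) are uniform plus an excess of `cluster_n` in-phase variants
#' inside the cluster interval. `n_in_phase` rare variants in total are
#' labelled in phase with the MAA (the cluster plus uniformly chosen extras);
#' the remaining rare variants are split between the opposite haplotype and
#' unphased.
#'
#' @param config A [simulation_config()].
#' @param genome Optional genome; when supplied, REF alleles are taken from it.
#' @param path Optional VCF output path.
#' @param truth_path Optional truth JSON output path.
#' @return List with `variants` (a `variant_records` data frame, sorted by
#'   position) and `truth` (cluster interval and counts).
#' @export
make_variant_set <- function(config, genome = NULL, path = NULL,
                             truth_path = NULL) {
  reg <- config$region; cl <- config$cluster_interval
  n_bg_rare <- config$n_rare - config$cluster_n
  out <- withr::with_seed(config$seed + 44L, {
    repeat {
      pos_wide <- reg$start + sample.int(gi_length(reg),
                                         config$n_common + n_bg_rare) - 1L
      pos_cl <- cl$start + sample.int(gi_length(cl), config$cluster_n) - 1L
      pos <- c(pos_wide, pos_cl)
      if (!anyDuplicated(pos)) break
    }
    is_rare <- c(rep(c(FALSE, TRUE), c(config$n_common, n_bg_rare)),
                 rep(TRUE, config$cluster_n))
    in_cluster <- c(rep(FALSE, config$n_common + n_bg_rare),
                    rep(TRUE, config$cluster_n))
    af <- numeric(length(pos))
    af[!is_rare] <- stats::runif(config$n_common, 0.01, 0.5)
    af[is_rare] <- stats::runif(config$n_rare, 1e-4, 0.0099)
    phase <- rep("UNPHASED", length(pos))
    extra_inphase <- sample(which(is_rare & !in_cluster),
                            config$n_in_phase - config$cluster_n)
    phase[c(which(in_cluster), extra_inphase)] <- "IN_PHASE_MAA"
    not_in <- which(is_rare & phase != "IN_PHASE_MAA")
    phase[sample(not_in, length(not_in) %/% 2)] <- "OUT_OF_PHASE"
    ref <- if (is.null(genome)) sample(.BASES, length(pos), replace = TRUE)
    else vapply(pos, function(p) genome_seq(genome, reg$chrom, p, p + 1L), "")
    alt <- vapply(ref, function(r) sample(setdiff(.BASES, r), 1L), "")
    data.frame(chrom = reg$chrom, pos = pos, ref = ref, alt = unname(alt),
               af = af, phase = phase, is_rare = is_rare,
               in_cluster = in_cluster, stringsAsFactors = FALSE)
  })
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  variants <- out[, c("chrom", "pos", "ref", "alt", "af", "phase")]
  class(variants) <- c("variant_records", "data.frame")
  truth <- list(cluster = as.data.frame(cl)[, c("chrom", "start", "end")],
                n_common = config$n_common, n_rare = config$n_rare,
                n_in_phase = config$n_in_phase, cluster_n = config$cluster_n)
  if (!is.null(path)) write_variants(variants, path)
  if (!is.null(truth_path))
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  list(variants = variants, truth = truth, detail = out)
}

#' Generate a motif (PPM) library with regulatory roles
#'
#' A mixture of sharp (information-rich, consensus probability 0.8-0.95) and
#' flat (Dirichlet) motifs; roles are assigned round-robin over activator,
#' repressor, insulator, other.
#'
#' @param config A [simulation_config()].
#' @param path Optional JASPAR-style matrix output path.
#' @param roles_path Optional role-table TSV output path.
#' @return List of `ppm` objects with roles set.
#' @export
make_ppm_library <- function(config, path = NULL, roles_path = NULL) {
  roles <- c("activator", "repressor", "insulator", "other")
  ppms <- withr::with_seed(config$seed + 55L, {
    lapply(seq_len(config$n_ppms), function(i) {
      L <- sample(config$ppm_lengths, 1L)
      sharp <- i %% 2L == 1L
      mat <- t(vapply(seq_len(L), function(j) {
        if (sharp) {
          p <- stats::runif(1, 0.8, 0.95)
          v <- rep((1 - p) / 3, 4)
          v[sample.int(4, 1L)] <- p
          v
        } else {
          v <- stats::rgamma(4, shape = 1)
          v / sum(v)
        }
      }, numeric(4)))
      colnames(mat) <- .BASES
      structure(list(tf_name = sprintf("simTF%02d", i), mat = mat,
                     role = roles[(i - 1L) %% 4L + 1L]), class = "ppm")
    })
  })
  names(ppms) <- vapply(ppms, `[[`, "", "tf_name")
  if (!is.null(path)) write_ppm_library(ppms, path)
  if (!is.null(roles_path))
    write_tsv(data.frame(tf_name = names(ppms),
                         role = vapply(ppms, `[[`, "", "role")), roles_path)
  ppms
}

#' @rdname make_ppm_library
#' @param ppms List of `ppm` objects.
#' @export
write_ppm_library <- function(ppms, path) {
  lines <- unlist(lapply(ppms, function(p) {
    c(sprintf(">%s", p$tf_name),
      vapply(.BASES, function(b)
        sprintf("%s [ %s ]", b,
                paste(sprintf("%.6f", p$mat[, b]), collapse = " ")), ""))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Generate per-sample accessible-region peak sets
#'
#' Plumbing for the enrichment stage: each sample's peak set marks the
#' implanted differential windows with accessible regions (peaks at the 1/4,
#' 1/2 and 3/4 points of each implant, so any smoothing window overlapping an
#' implant also touches a peak) plus uniform noise peaks. This gives
#' consensus voting and the overlap permutation test realistic input; it is
#' not part of the study's data model - accessible regions are an input (BED)
#' in real analyses.
#'
#' @param config A [simulation_config()].
#' @param n_samples Number of peak sets (samples).
#' @param peak_width Width of implant-derived peaks in bp.
#' @param n_noise Noise peaks per sample.
#' @param drop_prob Probability that a sample misses an implant peak.
#' @return List of [gintervals] peak sets.
#' @export
make_peak_sets <- function(config, n_samples = 4L, peak_width = 2000L,
                           n_noise = 8L, drop_prob = 0.1) {
  reg <- config$region
  imp <- config$implants
  withr::with_seed(config$seed + 66L, {
    lapply(seq_len(n_samples), function(s) {
      centers <- numeric(0)
      if (!is.null(imp) && nrow(imp) > 0)
        centers <- as.vector(outer(c(0.25, 0.5, 0.75), seq_len(nrow(imp)),
                                   function(q, i) imp$start[i] + q * (imp$end[i] - imp$start[i])))
      keep <- stats::runif(length(centers)) > drop_prob
      centers <- centers[keep] + round(stats::rnorm(sum(keep), 0, peak_width / 4))
      starts <- pmax(reg$start, round(centers - peak_width / 2))
      noise <- reg$start +
        sample.int(gi_length(reg) - peak_width, n_noise)
      starts <- c(starts, noise)
      starts <- pmin(starts, reg$end - peak_width)
      gintervals(reg$chrom, sort(starts), sort(starts) + peak_width)
    })
  })
}
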