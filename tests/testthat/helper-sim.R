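# Shared simulation fixtures, built in code. The default 1 Mb scenario's
# genome and fragment map are cached per session because several test files
# reuse them (contact draws vary by seed; the genome is background).

.fixture_env <- new.env(parent = emptyenv())

default_config <- function(...) simulation_config(seed = 1L, ...)

default_genome_map <- function() {
  if (is.null(.fixture_env$map)) {
    cfg <- default_config()
    .fixture_env$genome <- make_genome(cfg)
    .fixture_env$map <- digest_genome(.fixture_env$genome, cfg$chrom, cfg$motif)
  }
  list(genome = .fixture_env$genome, map = .fixture_env$map)
}

# A small, fast scenario for smoke/unit tests; dots override the defaults.
small_config <- function(seed = 1L, ...) {
  defaults <- list(seed = seed, genome_length = 60000L,
                   reporter_pos = 30000L, viewpoint_pos = 30000L,
                   region = gintervals("chr3sim", 0, 60000),
                   implants = NULL,
                   cluster_interval = gintervals("chr3sim", 40000, 45000),
                   n_reads = 300L, n_molecules = 1000L,
                   n_common = 10L, n_rare = 20L, n_in_phase = 8L,
                   cluster_n = 5L, n_ppms = 4L, ppm_lengths = 4:6)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

# Build a contact_profile with prescribed per-fragment molecule counts by
# synthesising records with distinct UMIs, then running build_profile.
profile_from_counts <- function(map, counts, viewpoint_pos, region,
                                group = "g", allele = "MAA",
                                config = smoothing_config(viewpoint_exclusion_fragments = 0L)) {
  stopifnot(length(counts) == nrow(map))
  if (all(counts == 0)) {
    # zero surviving molecules: an empty profile (downstream must handle)
    vp <- locate_fragment(map, viewpoint_pos)
    inc <- setdiff(map$frag_id[map$end > region$start & map$start < region$end],
                   (vp - config$viewpoint_exclusion_fragments):(vp + config$viewpoint_exclusion_fragments))
    cnt <- integer(length(inc)); names(cnt) <- inc
    return(structure(list(key = paste(group, allele, sep = "."), group = group,
                          allele = allele, frag_ids = inc, counts = cnt,
                          total = 0L, viewpoint_frag = vp, region = region),
                     class = "contact_profile"))
  }
  rows <- which(counts > 0)
  contacts <- do.call(rbind, lapply(rows, function(i) {
    data.frame(group = group, allele = allele, chrom = attr(map, "chrom"),
               pos = map$start[i],
               umi = sprintf("f%d_u%04d", i, seq_len(counts[i])),
               stringsAsFactors = FALSE)
  }))
  if (is.null(contacts))
    contacts <- data.frame(group = character(0), allele = character(0),
                           chrom = character(0), pos = integer(0),
                           umi = character(0))
  build_profile(contacts, map, viewpoint_pos, region, config)[[paste(group, allele, sep = ".")]]
}

# A deterministic toy fragment map: uniform fragment width on one chromosome.
toy_map <- function(n_frags = 21L, width = 100L, chrom = "chrT") {
  map <- data.frame(frag_id = seq_len(n_frags) - 1L,
                    start = (seq_len(n_frags) - 1L) * width,
                    end = seq_len(n_frags) * width)
  attr(map, "chrom") <- chrom
  attr(map, "motif") <- "GATC"
  class(map) <- c("fragment_map", "data.frame")
  map
}

make_read <- function(pos, cigar, seq, chrom = "chrT", qname = "r1",
                      flag = 0L, group = NA_character_) {
  data.frame(qname = qname, flag = flag, chrom = chrom, pos = pos, mapq = 60L,
             cigar = cigar, seq = seq, umi = NA_character_, group = group,
             allele = NA_character_, strand = "+", stringsAsFactors = FALSE)
}
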