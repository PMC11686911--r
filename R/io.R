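#' Read a reference genome from FASTA
#'
#' Sequences are uppercased on input; the alphabet {A,C,G,T,N} is expected.
#' Duplicate record names and empty sequences are errors.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] keyed by record name.
#' @export
read_fasta <- function(path) {
  gen <- Biostrings::readDNAStringSet(path)
  names(gen) <- sub("\\s.*$", "", names(gen))
  if (anyDuplicated(names(gen))) stop("duplicate record names in FASTA: ", path)
  if (any(Biostrings::width(gen) == 0L)) stop("empty sequence in FASTA: ", path)
  Biostrings::DNAStringSet(toupper(as.character(gen)))
}

#' @rdname read_fasta
#' @param genome A `DNAStringSet` genome.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Fetch genome sequence over an interval
#'
#' @param genome A `DNAStringSet` as returned by [read_fasta()].
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open coordinates; out-of-range access errors.
#' @return A character scalar of exactly `end - start` bases.
#' @export
genome_seq <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  len <- length(genome[[chrom]])
  if (start < 0 || end > len || start >= end)
    stop(sprintf("out-of-range access %s:[%d,%d) on sequence of length %d",
                 chrom, start, end, len))
  as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end))
}

.read_lines <- function(path) {
  x <- readLines(path, warn = FALSE)
  sub("[ \t\r]+$", "", x)  # tolerate CRLF and trailing whitespace
}

#' Read a BED3+ file of genomic intervals
#'
#' BED is 0-based half-open, matching the package's internal convention, so
#' coordinates pass through unchanged. Extra columns are kept as annotation
#' columns `V4`, `V5`, ...
#'
#' @param path Path to a BED file (3 or more tab-separated columns).
#' @return A [gintervals] object in file order; empty file gives zero rows.
#' @export
read_bed <- function(path) {
  lines <- .read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (length(lines) == 0L)
    return(gintervals(character(0), integer(0), numeric(0))[0, , drop = FALSE])
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  if (any(nf < 3L)) stop("BED requires at least 3 columns: ", path)
  chrom <- vapply(fields, `[`, "", 1L)
  start <- vapply(fields, `[`, "", 2L)
  end <- vapply(fields, `[`, "", 3L)
  if (!all(grepl("^[0-9]+$", c(start, end)))) stop("non-integer BED coordinates in ", path)
  out <- gintervals(chrom, start, end)
  if (max(nf) > 3L) for (j in 4:max(nf)) {
    v <- vapply(fields, function(f) if (length(f) >= j) f[j] else NA_character_, "")
    out[[paste0("V", j)]] <- utils::type.convert(v, as.is = TRUE)
  }
  out
}

#' @rdname read_bed
#' @param x A `gintervals` object.
#' @export
write_bed <- function(x, path) {
  df <- as.data.frame(x)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.parse_phase <- function(x) {
  out <- rep("UNPHASED", length(x))
  out[!is.na(x) & x == "MAA"] <- "IN_PHASE_MAA"
  out[!is.na(x) & x == "OUT"] <- "OUT_OF_PHASE"
  out
}

#' Read variants from a VCF subset
#'
#' Reads CHROM/POS/REF/ALT plus the INFO keys `AF` (population allele
#' frequency) and `PHASE` (`MAA` = in cis with the methylation-associated
#' allele, `OUT` = on the other haplotype; anything else is `UNPHASED`).
#' Positions are converted from the 1-based VCF convention to the internal
#' 0-based one. Multi-allelic rows (comma in ALT) are an error: such records
#' must be pre-split because a single phase annotation would be ambiguous.
#'
#' @param path Path to an uncompressed VCF.
#' @return A data frame of class `variant_records` with columns `chrom`, `pos`
#'   (0-based), `ref`, `alt`, `af` (NA when absent) and
#'   `phase` in `{IN_PHASE_MAA, OUT_OF_PHASE, UNPHASED}`.
#' @export
read_variants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt, fixed = TRUE)))
    stop("multi-allelic VCF records must be pre-split (comma in ALT)")
  ref <- fix[, "REF"]
  if (any(!nzchar(ref)) || any(!nzchar(alt)) || any(ref == alt))
    stop("REF and ALT must be non-empty and differ")
  af <- suppressWarnings(as.numeric(vcfR::extract.info(v, "AF")))
  phase <- .parse_phase(vcfR::extract.info(v, "PHASE"))
  out <- data.frame(chrom = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]) - 1L,
                    ref = ref, alt = alt, af = af, phase = phase,
                    stringsAsFactors = FALSE)
  class(out) <- c("variant_records", "data.frame")
  out
}

#' @rdname read_variants
#' @param variants A `variant_records` data frame.
#' @export
write_variants <- function(variants, path) {
  info <- mapply(function(af, ph) {
    parts <- character(0)
    if (!is.na(af)) parts <- c(parts, sprintf("AF=%s", format(af, scientific = FALSE)))
    if (ph == "IN_PHASE_MAA") parts <- c(parts, "PHASE=MAA")
    if (ph == "OUT_OF_PHASE") parts <- c(parts, "PHASE=OUT")
    if (length(parts) == 0L) "." else paste(parts, collapse = ";")
  }, variants$af, variants$phase)
  hdr <- c("##fileformat=VCFv4.2",
           '##INFO=<ID=AF,Number=1,Type=Float,Description="Population allele frequency">',
           '##INFO=<ID=PHASE,Number=1,Type=String,Description="MAA = in cis with the methylation-associated allele">',
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s",
                  variants$chrom, variants$pos + 1L, variants$ref, variants$alt, info)
  writeLines(c(hdr, body), path)
  invisible(path)
}

.CIGAR_OPS <- c("M", "=", "X", "I", "D", "S", "H", "N", "P")
.QUERY_OPS <- c("M", "=", "X", "I", "S")
.REF_OPS <- c("M", "=", "X", "D", "N")

#' Parse a CIGAR string into an op/length table
#'
#' @param cigar A CIGAR string, e.g. "10M5D40M".
#' @return Data frame with columns `op` and `len`.
#' @export
parse_cigar <- function(cigar) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  if (length(toks) == 0L || nchar(paste(toks, collapse = "")) != nchar(cigar))
    stop("malformed CIGAR: ", cigar)
  data.frame(op = substring(toks, nchar(toks), nchar(toks)),
             len = as.integer(substring(toks, 1L, nchar(toks) - 1L)),
             stringsAsFactors = FALSE)
}

#' Reference span consumed by a CIGAR string
#' @param cigar CIGAR string.
#' @export
cigar_ref_span <- function(cigar) {
  ops <- parse_cigar(cigar)
  sum(ops$len[ops$op %in% .REF_OPS])
}

.cigar_query_len <- function(cigar) {
  ops <- parse_cigar(cigar)
  sum(ops$len[ops$op %in% .QUERY_OPS])
}

#' Read aligned reads from a SAM text subset
#'
#' Supported columns: QNAME FLAG RNAME POS MAPQ CIGAR SEQ, plus the optional
#' tags `UB:Z:` (UMI), `RG:Z:` (sample/condition group) and `AL:Z:` (allele
#' label). POS is converted from 1-based SAM to 0-based; FLAG bit 0x10 sets
#' strand "-" (SEQ is stored reference-oriented per SAM, so no complementing
#' is performed); unmapped records (FLAG bit 0x4) are skipped with a message.
#' A CIGAR whose query-consuming length disagrees with the SEQ length is an
#' error.
#'
#' @param path Path to a SAM file (header optional).
#' @return Data frame of class `aligned_reads` with columns `qname`, `flag`,
#'   `chrom`, `pos` (0-based), `strand`, `mapq`, `cigar`, `seq`, `umi`,
#'   `group`, `allele`.
#' @export
read_sam <- function(path) {
  lines <- .read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- length(fields)
  get_tag <- function(f, tag) {
    if (length(f) < 12L) return(NA_character_)
    hit <- f[12:length(f)][startsWith(f[12:length(f)], tag)]
    if (length(hit) == 0L) NA_character_ else substring(hit[1], nchar(tag) + 1L)
  }
  out <- data.frame(
    qname = vapply(fields, `[`, "", 1L),
    flag = as.integer(vapply(fields, `[`, "", 2L)),
    chrom = vapply(fields, `[`, "", 3L),
    pos = as.integer(vapply(fields, `[`, "", 4L)) - 1L,
    mapq = as.integer(vapply(fields, `[`, "", 5L)),
    cigar = vapply(fields, `[`, "", 6L),
    seq = toupper(vapply(fields, function(f) f[10L], "")),
    umi = vapply(fields, get_tag, "", "UB:Z:"),
    group = vapply(fields, get_tag, "", "RG:Z:"),
    allele = vapply(fields, get_tag, "", "AL:Z:"),
    stringsAsFactors = FALSE)
  unmapped <- bitwAnd(out$flag, 4L) != 0L
  if (any(unmapped))
    message(sum(unmapped), " unmapped record(s) skipped in ", basename(path))
  out <- out[!unmapped, , drop = FALSE]
  qlen <- vapply(out$cigar, .cigar_query_len, 1L)
  bad <- out$seq != "*" & qlen != nchar(out$seq)
  if (any(bad))
    stop("CIGAR/SEQ length mismatch for read(s): ",
         paste(utils::head(out$qname[bad], 5), collapse = ", "))
  out$strand <- ifelse(bitwAnd(out$flag, 16L) != 0L, "-", "+")
  rownames(out) <- NULL
  class(out) <- c("aligned_reads", "data.frame")
  out
}

#' @rdname read_sam
#' @param reads An `aligned_reads` data frame.
#' @param seqlens Named integer vector of sequence lengths for the @SQ header.
#' @export
write_sam <- function(reads, path, seqlens = NULL) {
  hdr <- "@HD\tVN:1.6\tSO:unknown"
  if (!is.null(seqlens))
    hdr <- c(hdr, sprintf("@SQ\tSN:%s\tLN:%d", names(seqlens), as.integer(seqlens)))
  tags <- rep("", nrow(reads))
  add_tag <- function(tags, vals, tag)
    ifelse(is.na(vals) | !nzchar(vals), tags, paste0(tags, "\t", tag, vals))
  if ("umi" %in% names(reads)) tags <- add_tag(tags, reads$umi, "UB:Z:")
  if ("group" %in% names(reads)) tags <- add_tag(tags, reads$group, "RG:Z:")
  if ("allele" %in% names(reads)) tags <- add_tag(tags, reads$allele, "AL:Z:")
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*%s",
                  reads$qname, reads$flag, reads$chrom, reads$pos + 1L,
                  if ("mapq" %in% names(reads)) reads$mapq else 60L,
                  reads$cigar, reads$seq, tags)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read / write UMI-4C contact records as TSV
#'
#' Columns: `group` (sample/condition), `allele` (reporter allele label),
#' `chrom`, `pos` (0-based contact position), `umi`.
#'
#' @param path Path to a tab-separated contact file with a header row.
#' @export
read_contacts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c(group = "character", allele = "character",
                                         chrom = "character", pos = "integer",
                                         umi = "character"),
                          stringsAsFactors = FALSE)
  need <- c("group", "allele", "chrom", "pos", "umi")
  if (!all(need %in% names(df))) stop("contact TSV must have columns: ",
                                      paste(need, collapse = ", "))
  df
}

#' @rdname read_contacts
#' @param contacts Contact record data frame.
#' @export
write_contacts <- function(contacts, path) {
  utils::write.table(contacts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a result table as TSV
#' @param x Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
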