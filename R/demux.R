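#' Reporter variant for allele demultiplexing
#'
#' A heterozygous variant whose two alleles label the haplotypes, typically
#' the MLH1 promoter SNP c.-93G>A used to separate the methylation-associated
#' allele (MAA) from its unmethylated counterpart, or a small deletion such as
#' c.-234_-236del. For a deletion reporter `alt` must be shorter than `ref`
#' and share the VCF anchor base.
#'
#' @param chrom Chromosome name.
#' @param pos 0-based position (VCF POS - 1).
#' @param ref,alt Reference and alternate alleles (VCF conventions).
#' @param labels Named character vector mapping `REF` and `ALT` to haplotype
#'   labels; the two labels must differ. Default labels follow the common case
#'   where the alternate allele travels with the methylated haplotype.
#' @return A list of class `reporter_variant`.
#' @export
reporter_variant <- function(chrom, pos, ref, alt,
                             labels = c(REF = "NON_MAA", ALT = "MAA")) {
  stopifnot(nzchar(ref), nzchar(alt), ref != alt)
  if (!all(c("REF", "ALT") %in% names(labels)))
    stop("labels must name both REF and ALT")
  if (labels[["REF"]] == labels[["ALT"]]) stop("the two allele labels must differ")
  type <- if (nchar(ref) == nchar(alt)) "snv" else if (nchar(alt) < nchar(ref)) "deletion"
  else stop("insertion reporters are not supported")
  if (type == "deletion" && substring(ref, 1L, nchar(alt)) != alt)
    stop("deletion reporter must share the VCF anchor base(s)")
  structure(list(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                 type = type, labels = labels),
            class = "reporter_variant")
}

#' Span of the reporter on the reference, 0-based half-open
#' @param reporter A [reporter_variant()].
#' @return Integer vector `c(start, end)`. For a deletion this is the full
#'   REF span including the anchor base; the deleted bases themselves occupy
#'   `c(pos + nchar(alt), pos + nchar(ref))`.
#' @export
reporter_span <- function(reporter) {
  c(reporter$pos, reporter$pos + nchar(reporter$ref))
}

.deleted_span <- function(reporter) {
  c(reporter$pos + nchar(reporter$alt), reporter$pos + nchar(reporter$ref))
}

#' Bases a read aligns over a reference span
#'
#' Walks the CIGAR to recover the read sequence aligned over
#' `[span_start, span_end)`. Insertions strictly between reference positions
#' inside the span are appended in place. Soft outcomes instead of errors:
#' `DELETED` when a deletion op covers the entire span, `PARTIAL` when the
#' read covers only part of the span or a deletion covers part of it.
#'
#' @param read One row of an `aligned_reads` data frame (or a list with
#'   `chrom`, `pos`, `cigar`, `seq`).
#' @param span_start,span_end 0-based half-open span on the read's chromosome.
#' @return A list with `status` in `{"OK","DELETED","PARTIAL"}` and `seq`
#'   (the aligned bases for `"OK"`, otherwise `NA`).
#' @export
observed_sequence_at <- function(read, span_start, span_end) {
  stopifnot(span_end > span_start)
  n_span <- span_end - span_start
  at <- rep(NA_character_, n_span)     # per reference position: base or "D"
  ins <- vector("list", n_span)        # insertions following each span position
  ops <- parse_cigar(read$cigar)
  ref <- read$pos
  q <- 1L
  seqc <- strsplit(read$seq, "", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "=", "X")) {
      lo <- max(ref, span_start); hi <- min(ref + len, span_end)
      if (lo < hi) {
        idx <- (lo - span_start + 1L):(hi - span_start)
        at[idx] <- seqc[q + (lo - ref):(hi - ref - 1L)]
      }
      ref <- ref + len; q <- q + len
    } else if (op == "I") {
      # insertion sits between ref-1 and ref; keep it when both flanks in span
      if (ref > span_start && ref < span_end) {
        k <- ref - span_start
        ins[[k]] <- c(ins[[k]], seqc[q:(q + len - 1L)])
      }
      q <- q + len
    } else if (op %in% c("D", "N")) {
      lo <- max(ref, span_start); hi <- min(ref + len, span_end)
      if (lo < hi) at[(lo - span_start + 1L):(hi - span_start)] <- "D"
      ref <- ref + len
    } else if (op == "S") {
      q <- q + len
    } # H, P consume nothing relevant
  }
  if (anyNA(at)) return(list(status = "PARTIAL", seq = NA_character_))
  if (all(at == "D")) return(list(status = "DELETED", seq = NA_character_))
  if (any(at == "D")) return(list(status = "PARTIAL", seq = NA_character_))
  parts <- character(0)
  for (k in seq_len(n_span)) parts <- c(parts, at[k], ins[[k]])
  list(status = "OK", seq = paste(parts, collapse = ""))
}

.read_deletion_spans <- function(read) {
  ops <- parse_cigar(read$cigar)
  ref <- read$pos
  out <- NULL
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("D", "N")) out <- rbind(out, c(ref, ref + len))
    if (op %in% .REF_OPS) ref <- ref + len
  }
  out
}

#' Assign one read to a reporter allele
#'
#' SNV reporter: the observed base(s) over the variant span must equal `ref`
#' (call `REF`) or `alt` (call `ALT`); anything else, including partial
#' deletions, is `OTHER` (the sequencing-error bucket). Deletion reporter:
#' `ALT` requires a deletion op covering the deleted span exactly (same start
#' and end, conservative against misalignment); `REF` requires contiguous
#' bases matching the full REF allele. Reads that do not fully span the
#' reporter (or sit on another chromosome) are `NOT_COVERING`.
#'
#' @param read One row of an `aligned_reads` data frame.
#' @param reporter A [reporter_variant()].
#' @return One of `"REF"`, `"ALT"`, `"OTHER"`, `"NOT_COVERING"`.
#' @export
assign_allele <- function(read, reporter) {
  if (read$chrom != reporter$chrom) return("NOT_COVERING")
  span <- reporter_span(reporter)
  read_end <- read$pos + cigar_ref_span(read$cigar)
  if (read$pos > span[1] || read_end < span[2]) return("NOT_COVERING")
  if (reporter$type == "snv") {
    obs <- observed_sequence_at(read, span[1], span[2])
    if (obs$status != "OK") return("OTHER")
    if (obs$seq == reporter$ref) return("REF")
    if (obs$seq == reporter$alt) return("ALT")
    return("OTHER")
  }
  # deletion reporter
  dspan <- .deleted_span(reporter)
  dels <- .read_deletion_spans(read)
  if (!is.null(dels) &&
      any(dels[, 1] == dspan[1] & dels[, 2] == dspan[2]))
    return("ALT")
  obs <- observed_sequence_at(read, span[1], span[2])
  if (obs$status == "OK" && obs$seq == reporter$ref) return("REF")
  "OTHER"
}

#' Allele-resolved read counts and proportions per group
#'
#' Tallies `REF`/`ALT`/`OTHER`/`NOT_COVERING` calls per sample group and
#' derives allele proportions over the covering `REF + ALT` reads, the
#' statistic behind allele-specific accessibility / histone-mark / expression
#' comparisons (e.g. near-monoallelic accessibility from the unmethylated
#' allele in epimutation carriers versus balanced alleles in controls).
#' Groups with zero covering reads get `NA` proportions, never 0/0.
#'
#' @param reads An `aligned_reads` data frame; a missing/NA `group` column is
#'   treated as a single group `"all"`.
#' @param reporter A [reporter_variant()].
#' @return Data frame of class `allele_count_table` with one row per group:
#'   `group`, `n_ref`, `n_alt`, `n_other`, `n_not_covering`, `prop_ref`,
#'   `prop_alt`, plus `label_ref`/`label_alt` echoing the haplotype labels.
#' @export
count_alleles <- function(reads, reporter) {
  grp <- if ("group" %in% names(reads)) reads$group else rep("all", nrow(reads))
  grp[is.na(grp) | !nzchar(grp)] <- "all"
  calls <- vapply(seq_len(nrow(reads)),
                  function(i) assign_allele(reads[i, , drop = FALSE], reporter), "")
  groups <- sort(unique(grp))
  tab <- lapply(groups, function(g) {
    cg <- calls[grp == g]
    n_ref <- sum(cg == "REF"); n_alt <- sum(cg == "ALT")
    denom <- n_ref + n_alt
    data.frame(group = g, n_ref = n_ref, n_alt = n_alt,
               n_other = sum(cg == "OTHER"),
               n_not_covering = sum(cg == "NOT_COVERING"),
               prop_ref = if (denom > 0) n_ref / denom else NA_real_,
               prop_alt = if (denom > 0) n_alt / denom else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, tab)
  out$label_ref <- reporter$labels[["REF"]]
  out$label_alt <- reporter$labels[["ALT"]]
  class(out) <- c("allele_count_table", "data.frame")
  out
}
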