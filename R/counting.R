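#' Remove presumed PCR duplicates
#'
#' Among mapped reads sharing (chrom, start, strand) exactly one
#' representative is retained: the read with the highest mean base
#' quality, ties broken by lexicographic read id. Unmapped reads pass
#' through untouched.
#'
#' @param alignments an `assnp_alignments` data.frame.
#' @return the deduplicated alignments, attribute `n_duplicates_removed`.
#' @export
deduplicate <- function(alignments) {
  mapped <- !is.na(alignments$chrom)
  al <- alignments[mapped, , drop = FALSE]
  if (nrow(al)) {
    mq <- ifelse(is.na(al$qual), 0, mean_base_quality(
      ifelse(is.na(al$qual), "!", al$qual)))
    ord <- order(al$chrom, al$start0, al$strand, -mq, al$read_id,
                 method = "radix")
    al <- al[ord, , drop = FALSE]
    dup <- duplicated(al[, c("chrom", "start0", "strand")])
    al <- al[!dup, , drop = FALSE]
  }
  out <- rbind(al, alignments[!mapped, , drop = FALSE])
  attr(out, "n_duplicates_removed") <- sum(mapped) - nrow(al)
  class(out) <- c("assnp_alignments", "data.frame")
  out
}

#' Haplotype-resolved allele counts at heterozygous sites
#'
#' For every heterozygous variant and every mapped, haplotype-assigned
#' (non-TIE) read overlapping it, the read's base at the site increments
#' `count_g1` when it equals the haplotype-1 allele, `count_g2` when it
#' equals the haplotype-2 allele, and `count_other` otherwise. Bases
#' below `min_base_quality` are ignored. TIE reads carry no allelic
#' evidence and are never counted.
#'
#' @param alignments an `assnp_alignments` data.frame (one mark).
#' @param variants variant table; only `is_het` rows are counted.
#' @param mark mark label stamped on the output records.
#' @param min_base_quality Phred floor for the base at the SNP column.
#' @return data.frame (chrom, pos, ref, alt, hap1, hap2, mark,
#'   count_g1, count_g2, count_other, total).
#' @export
count_alleles <- function(alignments, variants, mark = "mark",
                          min_base_quality = 20) {
  het <- variants[variants$is_het, , drop = FALSE]
  al <- alignments[!is.na(alignments$chrom) &
                   alignments$assignment %in% c("G1", "G2"), , drop = FALSE]
  n <- nrow(het)
  c1 <- integer(n); c2 <- integer(n); co <- integer(n)
  if (nrow(al) && n) {
    rlen <- nchar(al$seq)
    reads_gr <- GenomicRanges::GRanges(
      al$chrom, IRanges::IRanges(start = al$start0 + 1L,
                                 end = al$start0 + rlen))
    sites_gr <- GenomicRanges::GRanges(
      het$chrom, IRanges::IRanges(start = het$pos, end = het$pos))
    ov <- suppressWarnings(GenomicRanges::findOverlaps(sites_gr, reads_gr))
    si <- S4Vectors::queryHits(ov)
    ri <- S4Vectors::subjectHits(ov)
    if (length(si)) {
      off <- het$pos[si] - al$start0[ri]   # 1-based offset into the read
      base <- substring(al$seq[ri], off, off)
      qual_ok <- rep(TRUE, length(ri))
      has_q <- !is.na(al$qual[ri])
      qual_ok[has_q] <- (utf8ToInt(paste(substring(al$qual[ri][has_q],
                                                   off[has_q], off[has_q]),
                                         collapse = "")) - 33L) >=
        min_base_quality
      keep <- qual_ok
      si <- si[keep]; base <- base[keep]
      is1 <- base == het$hap1[si]
      is2 <- base == het$hap2[si]
      t1 <- table(factor(si[is1], levels = seq_len(n)))
      t2 <- table(factor(si[is2], levels = seq_len(n)))
      to <- table(factor(si[!is1 & !is2], levels = seq_len(n)))
      c1 <- as.integer(t1); c2 <- as.integer(t2); co <- as.integer(to)
    }
  }
  data.frame(chrom = het$chrom, pos = het$pos, ref = het$ref,
             alt = het$alt, hap1 = het$hap1, hap2 = het$hap2, mark = mark,
             count_g1 = c1, count_g2 = c2, count_other = co,
             total = c1 + c2, stringsAsFactors = FALSE)
}

#' Write a per-mark allele-count table
#'
#' @param counts a [count_alleles()] result.
#' @param path output TSV.
#' @export
write_counts <- function(counts, path) {
  write_tsv(counts, path)
}
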