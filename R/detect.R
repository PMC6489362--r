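#' Exact two-sided binomial test for allelic imbalance
#'
#' Tests the haplotype-1 read count `k` out of `n` informative reads
#' against a balanced Binomial(n, 1/2) null. The null proportion is 1/2
#' because realignment to both personal genomes removes reference bias
#' by construction. The two-sided p-value is
#' `min(1, 2 * min(P(X <= k), P(X >= k)))` with exact tail summation.
#' Vectorized over `k` and `n`.
#'
#' @param k haplotype-1 count(s).
#' @param n total informative count(s); `n = 0` yields `NA` (untestable).
#' @return p-value(s) in \[0, 1\].
#' @export
binom_two_sided <- function(k, n) {
  if (any(k < 0 | k > n, na.rm = TRUE))
    stop("k must satisfy 0 <= k <= n", call. = FALSE)
  lower <- stats::pbinom(k, n, 0.5)
  upper <- stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  p <- pmin(1, 2 * pmin(lower, upper))
  p[n == 0] <- NA_real_
  p
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic FDR step-up: with sorted p-values, the adjusted value at rank
#' i is `min over j >= i of m * p_(j) / j`, capped at 1, returned in the
#' input order. `NA` p-values propagate as `NA` and do not count toward
#' m.
#'
#' @param p p-values in \[0, 1\].
#' @return adjusted q-values in input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (!length(ok)) return(out)
  pp <- p[ok]
  if (any(pp < 0 | pp > 1)) stop("p-values must lie in [0, 1]",
                                 call. = FALSE)
  m <- length(pp)
  o <- order(pp)
  q_sorted <- pmin(1, rev(cummin(rev(m * pp[o] / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  out[ok] <- q
  out
}

#' Call allele-specific SNPs from per-mark allele counts
#'
#' The central fit of the package. Per mark, every heterozygous site
#' with at least `min_total` informative reads is tested with
#' [binom_two_sided()]; the genome-wide multiple-testing correction
#' (Benjamini-Hochberg by default) is applied within each mark across
#' all of its tested sites; a site is an AS-SNP when its adjusted value
#' is at or below `fdr` for at least one mark. The returned catalog is
#' unique by (chrom, pos); the reported allelic ratio `count_g1/total`
#' comes from the mark with the smallest q-value.
#'
#' @param counts allele-count data.frame from [count_alleles()] (rows
#'   for several marks may be concatenated; the `mark` column separates
#'   them).
#' @param min_total minimum informative reads for a site to be tested.
#' @param fdr significance level on the adjusted values.
#' @param adjust `"BH"` (default) or `"bonferroni"`.
#' @param pool_marks when `TRUE`, correct across all marks jointly
#'   instead of within mark.
#' @return object of class `assnp_calls`: `sites` (one row per unique
#'   site), `tests` (one row per site x mark test) and `params`.
#'   Methods: `print`, `summary`, `as.data.frame`, `plot`, `coef`.
#' @export
call_as_snps <- function(counts, min_total = 10L, fdr = 0.05,
                         adjust = c("BH", "bonferroni"),
                         pool_marks = FALSE) {
  adjust <- match.arg(adjust)
  tested <- counts[counts$total >= min_total, , drop = FALSE]
  if (nrow(tested) == 0L) {
    warning("no testable sites (all totals below min_total)")
    tested$p <- numeric(0)
    tested$q <- numeric(0)
  } else {
    tested$p <- binom_two_sided(tested$count_g1, tested$total)
    adj <- function(p) if (adjust == "BH") bh_adjust(p) else
      pmin(1, p * length(p))
    tested$q <- if (pool_marks) adj(tested$p) else
      stats::ave(tested$p, tested$mark, FUN = adj)
  }
  tested$allelic_ratio <- ifelse(tested$total > 0,
                                 tested$count_g1 / tested$total, NA_real_)
  tested$significant <- !is.na(tested$q) & tested$q <= fdr

  key <- if (nrow(tested)) paste0(tested$chrom, ":", tested$pos) else
    character(0)
  if (nrow(tested) && !anyDuplicated(key)) {
    # fast path: every site tested in exactly one mark
    sites <- data.frame(chrom = tested$chrom, pos = tested$pos,
                        ref = tested$ref, alt = tested$alt,
                        hap1 = tested$hap1, hap2 = tested$hap2,
                        marks_tested = tested$mark,
                        significant_marks = ifelse(tested$significant,
                                                   tested$mark, ""),
                        p_min = tested$p, q_min = tested$q,
                        allelic_ratio = tested$allelic_ratio,
                        is_as_snp = tested$significant,
                        filtered_reason = "none",
                        stringsAsFactors = FALSE)
    sites <- sites[order(sites$chrom, sites$pos,
                       method = "radix"), , drop = FALSE]
    rownames(sites) <- NULL
    return(structure(list(sites = sites, tests = tested,
                          params = list(min_total = min_total, fdr = fdr,
                                        adjust = adjust,
                                        pool_marks = pool_marks)),
                     class = "assnp_calls"))
  }
  sites <- do.call(rbind, lapply(split(seq_len(nrow(tested)), key),
                                 function(idx) {
    t <- tested[idx, , drop = FALSE]
    best <- idx[which.min(t$q)]
    data.frame(chrom = t$chrom[1], pos = t$pos[1], ref = t$ref[1],
               alt = t$alt[1], hap1 = t$hap1[1], hap2 = t$hap2[1],
               marks_tested = paste(sort(t$mark, method = "radix"),
                                    collapse = ","),
               significant_marks = paste(sort(t$mark[t$significant],
                                              method = "radix"),
                                         collapse = ","),
               p_min = min(t$p), q_min = min(t$q),
               allelic_ratio = tested$allelic_ratio[best],
               is_as_snp = any(t$significant),
               filtered_reason = "none", stringsAsFactors = FALSE)
  }))
  if (is.null(sites))
    sites <- data.frame(chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        hap1 = character(0), hap2 = character(0),
                        marks_tested = character(0),
                        significant_marks = character(0),
                        p_min = numeric(0), q_min = numeric(0),
                        allelic_ratio = numeric(0), is_as_snp = logical(0),
                        filtered_reason = character(0))
  sites <- sites[order(sites$chrom, sites$pos,
                       method = "radix"), , drop = FALSE]
  rownames(sites) <- NULL
  structure(list(sites = sites, tests = tested,
                 params = list(min_total = min_total, fdr = fdr,
                               adjust = adjust, pool_marks = pool_marks)),
            class = "assnp_calls")
}

#' Filter AS-SNP calls against exclusion regions
#'
#' Marks every site whose 0-based position `pos - 1` falls inside a
#' half-open `[start, end)` interval of any exclusion track (ENCODE-style
#' blacklist, centromere/telomere regions). Filtered sites keep their
#' test results but lose AS-SNP status and record the track name in
#' `filtered_reason`.
#'
#' @param calls an `assnp_calls` object (or its `sites` data.frame).
#' @param exclusion_beds named list of BED file paths, data.frames with
#'   chrom/start0/end0, or `GRanges`.
#' @return the input with updated `filtered_reason` / `is_as_snp`.
#' @export
filter_regions <- function(calls, exclusion_beds) {
  is_calls <- inherits(calls, "assnp_calls")
  sites <- if (is_calls) calls$sites else calls
  if (nrow(sites) && length(exclusion_beds)) {
    pos_gr <- GenomicRanges::GRanges(
      sites$chrom, IRanges::IRanges(sites$pos, sites$pos))
    nm <- names(exclusion_beds) %||% paste0("track", seq_along(exclusion_beds))
    for (t in seq_along(exclusion_beds)) {
      gr <- as_granges_track(exclusion_beds[[t]])
      if (length(gr) == 0L) next
      hit <- suppressWarnings(IRanges::overlapsAny(pos_gr, gr))
      newly <- hit & sites$filtered_reason == "none"
      sites$filtered_reason[newly] <- nm[t]
      sites$is_as_snp[hit] <- FALSE
    }
  }
  if (is_calls) {
    calls$sites <- sites
    calls
  } else sites
}

# Accept a BED path, a chrom/start0/end0 data.frame, or a GRanges; BED
# intervals are 0-based half-open, GRanges 1-based closed, and a SNP at
# 1-based pos is inside [start0, end0) iff pos-1 in [start0, end0).
as_granges_track <- function(x) {
  if (methods::is(x, "GRanges")) return(x)
  if (is.character(x)) {
    if (!file.exists(x)) stop("BED file not found: ", x, call. = FALSE)
    x <- read_bed(x)
  }
  if (!nrow(x)) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start0 + 1L,
                                          end = x$end0))
}

#' Read a BED3/BED4 file
#'
#' @param path BED file (0-based half-open intervals).
#' @return data.frame (chrom, start0, end0\[, label\]).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(0), start0 = integer(0),
                      end0 = integer(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L))
    stop("malformed BED line ", which(nf < 3L)[1L], " in ", path,
         call. = FALSE)
  start0 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
  end0 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 3L)))
  if (anyNA(start0) || anyNA(end0))
    stop("malformed BED line ",
         which(is.na(start0) | is.na(end0))[1L], " in ", path,
         call. = FALSE)
  out <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                    start0 = start0, end0 = end0,
                    stringsAsFactors = FALSE)
  if (all(nf >= 4L)) out$label <- vapply(parts, `[`, "", 4L)
  out
}

#' Write AS-SNP calls as TSV, minimal VCF and BED
#'
#' @param calls an `assnp_calls` object.
#' @param prefix output path prefix; writes `<prefix>.tsv`,
#'   `<prefix>.vcf` (q-values in INFO) and `<prefix>.bed` (AS-SNP
#'   positions only).
#' @return named vector of the written paths.
#' @export
write_as_snps <- function(calls, prefix) {
  sites <- calls$sites
  tsv <- paste0(prefix, ".tsv")
  out <- sites
  out$p_min <- sprintf("%.6g", out$p_min)
  out$q_min <- sprintf("%.6g", out$q_min)
  out$allelic_ratio <- sprintf("%.4f", out$allelic_ratio)
  write_tsv(out, tsv)
  vcf <- paste0(prefix, ".vcf")
  con <- file(vcf, "w")
  writeLines(c("##fileformat=VCFv4.2",
               "##source=assnp",
               "##INFO=<ID=Q,Number=1,Type=Float,Description=\"Minimum adjusted p across marks\">",
               "##INFO=<ID=MARKS,Number=1,Type=String,Description=\"Significant marks\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  as <- sites[sites$is_as_snp, , drop = FALSE]
  if (nrow(as))
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\tQ=%.6g;MARKS=%s",
                       as$chrom, as$pos, paste0(as$chrom, ":", as$pos),
                       as$ref, as$alt, as$q_min, as$significant_marks),
               con)
  close(con)
  bed <- paste0(prefix, ".bed")
  write_bed(data.frame(chrom = as$chrom, start0 = as$pos - 1L,
                       end0 = as$pos), bed)
  c(tsv = tsv, vcf = vcf, bed = bed)
}
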