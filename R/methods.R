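# S3 methods for the classed results.

#' @export
print.assnp_calls <- function(x, ...) {
  s <- x$sites
  cat("Allele-specific SNP calls\n")
  cat(sprintf("  %d sites tested (min_total = %d), %s correction at FDR %g%s\n",
              nrow(s), x$params$min_total, x$params$adjust, x$params$fdr,
              if (x$params$pool_marks) ", marks pooled" else ", per mark"))
  cat(sprintf("  %d AS-SNPs, %d filtered by exclusion regions\n",
              sum(s$is_as_snp), sum(s$filtered_reason != "none")))
  marks <- unique(x$tests$mark)
  for (m in marks) {
    t <- x$tests[x$tests$mark == m, ]
    cat(sprintf("  %-10s %5d tested, %4d significant\n", m, nrow(t),
                sum(t$significant)))
  }
  invisible(x)
}

#' @export
summary.assnp_calls <- function(object, ...) {
  s <- object$sites
  as <- s[s$is_as_snp, , drop = FALSE]
  out <- list(
    n_tested = nrow(s),
    n_as_snps = sum(s$is_as_snp),
    n_filtered = sum(s$filtered_reason != "none"),
    per_mark = stats::aggregate(significant ~ mark, object$tests, sum),
    ratio_quartiles = if (nrow(as))
      stats::quantile(as$allelic_ratio, c(0.25, 0.5, 0.75)) else NULL,
    params = object$params)
  class(out) <- "summary.assnp_calls"
  out
}

#' @export
print.summary.assnp_calls <- function(x, ...) {
  cat(sprintf("AS-SNP call summary: %d tested, %d called, %d region-filtered\n",
              x$n_tested, x$n_as_snps, x$n_filtered))
  cat("Significant tests per mark:\n")
  print(x$per_mark, row.names = FALSE)
  if (!is.null(x$ratio_quartiles)) {
    cat("Allelic ratio quartiles of AS-SNPs:\n")
    print(round(x$ratio_quartiles, 3))
  }
  invisible(x)
}

#' @export
as.data.frame.assnp_calls <- function(x, ...) x$sites

#' Coefficients of an AS-SNP call set
#'
#' Returns the per-site allelic ratios (haplotype-1 fraction at the
#' best-supported mark), named `chrom:pos`.
#' @param object an `assnp_calls` object.
#' @param ... unused.
#' @export
coef.assnp_calls <- function(object, ...) {
  stats::setNames(object$sites$allelic_ratio,
                  paste0(object$sites$chrom, ":", object$sites$pos))
}

#' Allelic-imbalance overview plot
#'
#' Haplotype-1 read fraction against -log10 adjusted p per tested site;
#' AS-SNPs are filled, region-filtered sites crossed out.
#' @param x an `assnp_calls` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.assnp_calls <- function(x, ...) {
  s <- x$sites
  if (!nrow(s)) {
    warning("nothing to plot: no tested sites")
    return(invisible(x))
  }
  ql <- -log10(pmax(s$q_min, 1e-300))
  graphics::plot(s$allelic_ratio, ql,
                 xlab = "haplotype-1 read fraction",
                 ylab = expression(-log[10] ~ "adjusted p"),
                 pch = ifelse(s$is_as_snp, 19, 1),
                 col = ifelse(s$filtered_reason != "none", "grey50",
                              ifelse(s$is_as_snp, "firebrick", "black")),
                 ...)
  graphics::abline(v = 0.5, lty = 2, col = "grey70")
  graphics::abline(h = -log10(x$params$fdr), lty = 3, col = "grey70")
  invisible(x)
}

#' @export
print.assnp_simulation <- function(x, ...) {
  cat("Synthetic allele-specific ChIP-seq study\n")
  cat(sprintf("  seed %d: %d chromosome(s) x %d bp, %d variants (%d het)\n",
              x$config$seed, x$config$n_chroms, x$config$chrom_length,
              nrow(x$variants), sum(x$variants$is_het)))
  cat(sprintf("  %d planted AS sites at ratio %.2f over marks %s\n",
              nrow(x$as_sites), x$config$as_ratio,
              paste(x$config$marks, collapse = ", ")))
  nr <- vapply(x$reads, function(r) nrow(r$reads), integer(1))
  cat(sprintf("  reads: %s\n",
              paste(sprintf("%s=%d", names(nr), nr), collapse = ", ")))
  invisible(x)
}

#' @export
print.personal_genome_pair <- function(x, ...) {
  cat(sprintf("Personal genome pair: %d chromosome(s), %d substituted variants (%d het)\n",
              length(x$g1), x$provenance$n_variants, x$provenance$n_het))
  invisible(x)
}
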