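#' Linkage disequilibrium r-squared from haplotype class counts
#'
#' Given counts of the four two-site haplotype classes (AB, Ab, aB, ab),
#' computes `D = p_AB - p_A p_B` and `r2 = D^2 / (p_A(1-p_A) p_B(1-p_B))`.
#' A site monomorphic in the panel makes r2 undefined; `NA` is returned
#' with a warning.
#'
#' @param counts numeric vector of length 4 (AB, Ab, aB, ab) or the four
#'   counts as separate arguments via `...`.
#' @param ... alternative way to pass the four counts.
#' @return r-squared in \[0, 1\], or `NA` if undefined.
#' @export
compute_r2 <- function(counts, ...) {
  counts <- c(counts, ...)
  if (length(counts) != 4L)
    stop("need exactly four haplotype class counts (AB, Ab, aB, ab)",
         call. = FALSE)
  n <- sum(counts)
  if (n < 1L) stop("total haplotypes must be >= 1", call. = FALSE)
  p <- counts / n
  p_ab <- p[1]
  p_a <- p[1] + p[2]
  p_b <- p[1] + p[3]
  denom <- p_a * (1 - p_a) * p_b * (1 - p_b)
  if (denom == 0) {
    warning("monomorphic site: r2 undefined")
    return(NA_real_)
  }
  d <- p_ab - p_a * p_b
  unname(d^2 / denom)
}

#' Read a 0/1 haplotype panel
#'
#' @param path TSV with a `snp_id` column followed by one 0/1 column per
#'   haplotype.
#' @return integer matrix, rownames = snp ids, one column per haplotype.
#' @export
read_haplotype_panel <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$snp_id
  m
}

#' r-squared between two panel SNPs
#'
#' @param panel matrix from [read_haplotype_panel()].
#' @param id_a,id_b snp ids (rownames of the panel).
#' @return r-squared, or `NA` when either site is monomorphic.
#' @export
panel_r2 <- function(panel, id_a, id_b) {
  if (!(id_a %in% rownames(panel)) || !(id_b %in% rownames(panel)))
    return(NA_real_)
  a <- panel[id_a, ]
  b <- panel[id_b, ]
  compute_r2(c(sum(a == 1 & b == 1), sum(a == 1 & b == 0),
               sum(a == 0 & b == 1), sum(a == 0 & b == 0)))
}

#' Expand GWAS top hits to their LD proxies
#'
#' For every GWAS SNP, collects the SNPs in high LD with it — strictly
#' `r2 > threshold`, matching the printed convention — either from a
#' precomputed pair table or by computing r-squared from a haplotype
#' panel. GWAS SNPs absent from the LD source are skipped with a
#' message.
#'
#' @param gwas data.frame (rsid, chrom, pos, trait).
#' @param ld_source either a pair data.frame (snp_a, snp_b, r2) or a
#'   haplotype panel matrix whose rownames include the GWAS rsids.
#' @param threshold proxies require `r2 > threshold` (default 0.8).
#' @return data.frame (gwas_rsid, trait, proxy_id, proxy_chrom,
#'   proxy_pos, r2); proxy coordinates parsed from `chrom:pos`-style ids
#'   when possible, else `NA`.
#' @export
expand_ld <- function(gwas, ld_source, threshold = 0.8) {
  rows <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(gwas))) {
    rs <- gwas$rsid[i]
    if (is.matrix(ld_source)) {
      if (!(rs %in% rownames(ld_source))) { skipped <- c(skipped, rs); next }
      others <- setdiff(rownames(ld_source), rs)
      r2 <- vapply(others, function(o)
        suppressWarnings(panel_r2(ld_source, rs, o)), numeric(1))
      hit <- !is.na(r2) & r2 > threshold
      if (any(hit))
        rows[[length(rows) + 1L]] <- data.frame(
          gwas_rsid = rs, trait = gwas$trait[i], proxy_id = others[hit],
          r2 = unname(r2[hit]), stringsAsFactors = FALSE)
    } else {
      sub <- ld_source[(ld_source$snp_a == rs | ld_source$snp_b == rs), ,
                       drop = FALSE]
      if (!nrow(sub)) { skipped <- c(skipped, rs); next }
      sub <- sub[sub$r2 > threshold, , drop = FALSE]
      if (nrow(sub))
        rows[[length(rows) + 1L]] <- data.frame(
          gwas_rsid = rs, trait = gwas$trait[i],
          proxy_id = ifelse(sub$snp_a == rs, sub$snp_b, sub$snp_a),
          r2 = sub$r2, stringsAsFactors = FALSE)
    }
  }
  if (length(skipped))
    message(length(skipped), " GWAS SNP(s) absent from the LD source: ",
            paste(utils::head(skipped, 5), collapse = ", "))
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gwas_rsid = character(0), trait = character(0),
               proxy_id = character(0), r2 = numeric(0))
  coords <- regmatches(out$proxy_id,
                       regexec("^([^:]+):([0-9]+)$", out$proxy_id))
  out$proxy_chrom <- vapply(coords, function(x)
    if (length(x) == 3L) x[2] else NA_character_, character(1))
  out$proxy_pos <- vapply(coords, function(x)
    if (length(x) == 3L) as.integer(x[3]) else NA_integer_, integer(1))
  out[, c("gwas_rsid", "trait", "proxy_id", "proxy_chrom", "proxy_pos",
          "r2")]
}

#' Annotate AS-SNPs with GWAS links
#'
#' Labels each AS-SNP `direct_hit` when it coincides with a GWAS SNP
#' (by position, or by rsid when coordinates are missing), `ld_proxy`
#' when it matches an LD proxy of one (carrying the source SNP and its
#' r-squared; the strongest link wins), else `unlinked`.
#'
#' @param sites AS-SNP sites data.frame (or an `assnp_calls` object;
#'   only rows with `is_as_snp` are annotated).
#' @param gwas data.frame (rsid, chrom, pos, trait).
#' @param proxy_map an [expand_ld()] result.
#' @return the sites with columns gwas_link, gwas_source_rsid, gwas_r2,
#'   traits appended.
#' @export
annotate_gwas <- function(sites, gwas, proxy_map) {
  if (inherits(sites, "assnp_calls")) sites <- sites$sites
  if (anyDuplicated(gwas$rsid)) {
    d <- gwas[gwas$rsid %in% gwas$rsid[duplicated(gwas$rsid)], ]
    if (nrow(unique(d[, c("rsid", "chrom", "pos")])) > length(unique(d$rsid)))
      stop("duplicate rsid with conflicting positions in GWAS table",
           call. = FALSE)
  }
  key <- paste0(sites$chrom, ":", sites$pos)
  gkey <- paste0(gwas$chrom, ":", gwas$pos)
  sites$gwas_link <- "unlinked"
  sites$gwas_source_rsid <- ""
  sites$gwas_r2 <- NA_real_
  sites$traits <- ""
  direct <- match(key, gkey)
  hit <- !is.na(direct)
  sites$gwas_link[hit] <- "direct_hit"
  sites$gwas_source_rsid[hit] <- gwas$rsid[direct[hit]]
  sites$gwas_r2[hit] <- 1
  for (i in which(hit))
    sites$traits[i] <- paste(sort(unique(gwas$trait[gkey == key[i]]),
                             method = "radix"), collapse = ";")
  if (nrow(proxy_map)) {
    pkey <- ifelse(is.na(proxy_map$proxy_pos), proxy_map$proxy_id,
                   paste0(proxy_map$proxy_chrom, ":", proxy_map$proxy_pos))
    for (i in which(!hit)) {
      rows <- which(pkey == key[i])
      if (!length(rows)) next
      best <- rows[which.max(proxy_map$r2[rows])]
      sites$gwas_link[i] <- "ld_proxy"
      sites$gwas_source_rsid[i] <- proxy_map$gwas_rsid[best]
      sites$gwas_r2[i] <- proxy_map$r2[best]
      sites$traits[i] <- paste(sort(unique(proxy_map$trait[rows]),
                                    method = "radix"), collapse = ";")
    }
  }
  sites
}

#' Annotate AS-SNPs with eQTL target genes
#'
#' Attaches the gene symbols of every eQTL association at each AS-SNP's
#' position (`variant_id` in `chrom:pos` form or explicit chrom/pos
#' columns); sites without a positional match get an empty gene list.
#'
#' @param sites AS-SNP sites data.frame (or `assnp_calls`).
#' @param eqtl data.frame (variant_id, gene, tissue, p).
#' @return sites with `eqtl_genes` (semicolon-joined) appended.
#' @export
annotate_eqtl <- function(sites, eqtl) {
  if (inherits(sites, "assnp_calls")) sites <- sites$sites
  key <- paste0(sites$chrom, ":", sites$pos)
  ekey <- if (all(c("chrom", "pos") %in% names(eqtl)))
    paste0(eqtl$chrom, ":", eqtl$pos) else eqtl$variant_id
  sites$eqtl_genes <- vapply(key, function(k) {
    g <- sort(unique(eqtl$gene[ekey == k]), method = "radix")
    paste(g, collapse = ";")
  }, character(1), USE.NAMES = FALSE)
  sites
}

#' Cluster SNPs into loci by 1-Mb single-linkage chaining
#'
#' Consecutive positions on one chromosome join the same locus when
#' their gap is at most `window`; loci never span chromosomes. With
#' `method = "bin"` fixed genomic bins of width `window` are used
#' instead (sensitivity analysis).
#'
#' @param chrom,pos SNP coordinates (1-based).
#' @param window maximum gap (bp), default 1 Mb.
#' @param method `"chain"` (default) or `"bin"`.
#' @return integer locus ids in input order.
#' @export
cluster_loci <- function(chrom, pos, window = 1e6, method = c("chain",
                                                              "bin")) {
  method <- match.arg(method)
  if (!length(pos)) return(integer(0))
  if (method == "bin") {
    ids <- paste0(chrom, ":", floor((pos - 1) / window))
    return(as.integer(factor(ids, levels = unique(ids))))
  }
  ord <- order(chrom, pos, method = "radix")
  ch <- chrom[ord]
  ps <- pos[ord]
  new_locus <- c(TRUE, ch[-1] != ch[-length(ch)] |
                   diff(ps) > window)
  locus_sorted <- cumsum(new_locus)
  out <- integer(length(pos))
  out[ord] <- locus_sorted
  out
}

#' Per-trait AS-SNP and locus summary
#'
#' Tabulates, per GWAS trait, the number of unique AS-SNPs linked
#' (directly or through LD) and the number of 1-Mb loci they form, with
#' a final Total row counting unique AS-SNPs and loci across all traits.
#'
#' @param annotated output of [annotate_gwas()].
#' @param window locus chaining window (bp).
#' @return data.frame (trait, n_as_snps, n_loci), Total row last, traits
#'   sorted by descending AS-SNP count.
#' @export
summarize_traits <- function(annotated, window = 1e6) {
  linked <- annotated[annotated$gwas_link != "unlinked" &
                      annotated$is_as_snp, , drop = FALSE]
  if (!nrow(linked))
    return(data.frame(trait = "Total", n_as_snps = 0L, n_loci = 0L,
                      stringsAsFactors = FALSE))
  expl <- do.call(rbind, lapply(seq_len(nrow(linked)), function(i) {
    tr <- strsplit(linked$traits[i], ";", fixed = TRUE)[[1]]
    if (!length(tr)) tr <- "(unspecified)"
    data.frame(trait = tr, chrom = linked$chrom[i], pos = linked$pos[i],
               stringsAsFactors = FALSE)
  }))
  per_trait <- do.call(rbind, lapply(split(expl, expl$trait), function(d) {
    u <- unique(d[, c("chrom", "pos")])
    data.frame(trait = d$trait[1], n_as_snps = nrow(u),
               n_loci = length(unique(cluster_loci(u$chrom, u$pos,
                                                   window))),
               stringsAsFactors = FALSE)
  }))
  per_trait <- per_trait[order(-per_trait$n_as_snps, per_trait$trait,
                               method = "radix"), ,
                         drop = FALSE]
  u_all <- unique(linked[, c("chrom", "pos")])
  total <- data.frame(trait = "Total", n_as_snps = nrow(u_all),
                      n_loci = length(unique(cluster_loci(u_all$chrom,
                                                          u_all$pos,
                                                          window))),
                      stringsAsFactors = FALSE)
  out <- rbind(per_trait, total)
  rownames(out) <- NULL
  out
}

#' Expected heterozygosity under Hardy-Weinberg equilibrium
#'
#' The probability that one person is heterozygous at a common
#' polymorphic site: the mean of `2p(1-p)` with the minor allele
#' frequency uniform on (0, 0.5), evaluated by numerical integration.
#' Equals 1/3, i.e. about a third of common polymorphic sites are
#' heterozygous in a single individual — the fraction of regulatory
#' variation one personal genome interrogates.
#'
#' @return the expected heterozygous fraction (scalar in \[0, 1\]).
#' @export
expected_het_fraction <- function() {
  stats::integrate(function(p) 2 * p * (1 - p), 0, 0.5)$value / 0.5
}
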