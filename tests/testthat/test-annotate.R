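# LD, GWAS/eQTL annotation, locus clustering, trait summaries.

test_that("r-squared from haplotype counts matches the worked examples", {
  expect_equal(compute_r2(c(50, 0, 0, 50)), 1.0)
  expect_equal(compute_r2(c(25, 25, 25, 25)), 0.0)
  expect_equal(compute_r2(c(40, 10, 10, 40)), 0.36, tolerance = 1e-12)
  expect_warning(r <- compute_r2(c(50, 50, 0, 0)), "monomorphic")
  expect_true(is.na(r))
  expect_error(compute_r2(c(1, 2, 3)), "four")
})

test_that("r-squared is invariant to allele relabeling and site order", {
  set.seed(12)
  for (i in 1:20) {
    cnt <- as.numeric(rmultinom(1, 200, runif(4, 0.05, 1)))
    r <- suppressWarnings(compute_r2(cnt))
    # swap A <-> a: (AB,Ab,aB,ab) -> (aB,ab,AB,Ab)
    expect_equal(suppressWarnings(compute_r2(cnt[c(3, 4, 1, 2)])), r)
    # swap B <-> b
    expect_equal(suppressWarnings(compute_r2(cnt[c(2, 1, 4, 3)])), r)
    # swap sites: (AB,Ab,aB,ab) -> (AB,aB,Ab,ab)
    expect_equal(suppressWarnings(compute_r2(cnt[c(1, 3, 2, 4)])), r)
  }
})

test_that("panel r-squared equals the squared Pearson correlation", {
  set.seed(13)
  for (i in 1:20) {
    a <- rbinom(100, 1, runif(1, 0.2, 0.8))
    b <- ifelse(runif(100) < 0.7, a, rbinom(100, 1, 0.5))
    panel <- rbind(snpA = a, snpB = b)
    want <- oracle_r2_pearson(a, b)
    got <- suppressWarnings(panel_r2(panel, "snpA", "snpB"))
    if (is.na(want)) expect_true(is.na(got))
    else expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("LD expansion is strict at the threshold", {
  gwas <- data.frame(rsid = c("rs1", "rs2"), chrom = "chr1",
                     pos = c(1000L, 5000L), trait = "Type 2 diabetes",
                     stringsAsFactors = FALSE)
  ld <- data.frame(snp_a = c("rs1", "rs1", "rs2", "rs2", "rs2"),
                   snp_b = c("chr1:1200", "chr1:1300", "chr1:5100",
                             "chr1:5200", "chr1:5300"),
                   r2 = c(0.8, 0.81, 0.95, 0.36, 0.9),
                   stringsAsFactors = FALSE)
  px <- expand_ld(gwas, ld, threshold = 0.8)
  expect_equal(nrow(px), 3L)               # 0.80 excluded, strict >
  expect_false("chr1:1200" %in% px$proxy_id)
  expect_true(all(px$r2 > 0.8))
  expect_equal(px$proxy_pos[px$proxy_id == "chr1:1300"], 1300L)
  # absent GWAS SNP skipped with a message
  gwas2 <- rbind(gwas, data.frame(rsid = "rs3", chrom = "chr1",
                                  pos = 1L, trait = "x"))
  expect_message(expand_ld(gwas2, ld), "absent")
})

as_site_df <- function(chrom, pos, is_as_snp = TRUE) {
  data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G", hap1 = "A",
             hap2 = "G", marks_tested = "CTCF", significant_marks = "CTCF",
             p_min = 1e-6, q_min = 1e-5, allelic_ratio = 0.9,
             is_as_snp = is_as_snp, filtered_reason = "none",
             stringsAsFactors = FALSE)
}

test_that("GWAS annotation distinguishes direct hits, proxies and unlinked", {
  sites <- as_site_df("chr1", c(1000L, 1300L, 9000L))
  gwas <- data.frame(rsid = "rs1", chrom = "chr1", pos = 1000L,
                     trait = "Type 2 diabetes", stringsAsFactors = FALSE)
  px <- data.frame(gwas_rsid = "rs1", trait = "Type 2 diabetes",
                   proxy_id = "chr1:1300", proxy_chrom = "chr1",
                   proxy_pos = 1300L, r2 = 0.9, stringsAsFactors = FALSE)
  ann <- annotate_gwas(sites, gwas, px)
  expect_equal(ann$gwas_link, c("direct_hit", "ld_proxy", "unlinked"))
  expect_equal(ann$gwas_r2[2], 0.9)
  expect_equal(ann$gwas_source_rsid[2], "rs1")
  # conflicting duplicate rsid is a hard error
  gwas_bad <- rbind(gwas, data.frame(rsid = "rs1", chrom = "chr2",
                                     pos = 5L, trait = "y"))
  expect_error(annotate_gwas(sites, gwas_bad, px), "conflicting")
})

test_that("eQTL annotation attaches all genes at a position", {
  sites <- as_site_df("chr1", c(1000L, 2000L))
  eqtl <- data.frame(variant_id = c("chr1:1000", "chr1:1000"),
                     gene = c("APOB", "ALB"), tissue = "liver",
                     p = c(1e-8, 1e-6), stringsAsFactors = FALSE)
  ann <- annotate_eqtl(sites, eqtl)
  expect_equal(ann$eqtl_genes, c("ALB;APOB", ""))
})

test_that("locus chaining follows the 1-Mb gap rule", {
  expect_equal(length(unique(cluster_loci("chr1", 12345L))), 1L)
  # gaps 500 kb (join) and 2.1 Mb (split)
  loci <- cluster_loci(rep("chr1", 3), c(1L, 500001L, 2600001L))
  expect_equal(length(unique(loci)), 2L)
  expect_equal(loci[1], loci[2])
  # same positions on different chromosomes never merge
  loci2 <- cluster_loci(c("chr1", "chr2", "chr3"),
                        c(1L, 500001L, 2600001L))
  expect_equal(length(unique(loci2)), 3L)
  # order invariance
  set.seed(14)
  pos <- sort(sample.int(10000000L, 40))
  chrom <- rep("chr1", 40)
  perm <- sample.int(40)
  l1 <- cluster_loci(chrom, pos)
  l2 <- cluster_loci(chrom[perm], pos[perm])
  expect_equal(length(unique(l1)), length(unique(l2)))
  expect_equal(as.integer(factor(l1[perm], levels = unique(l1[perm]))),
               as.integer(factor(l2, levels = unique(l2))))
  # maximality: merging two adjacent loci requires a gap <= window
  gaps <- diff(pos)
  boundaries <- which(diff(l1) != 0)
  expect_true(all(gaps[boundaries] > 1e6))
  within <- which(diff(l1) == 0)
  expect_true(all(gaps[within] <= 1e6))
  # binning alternative
  expect_equal(length(unique(cluster_loci(rep("chr1", 2),
                                          c(1L, 999999L),
                                          method = "bin"))), 1L)
})

test_that("trait summaries count unique AS-SNPs and loci per trait", {
  sites <- as_site_df("chr1", c(1000L, 2000L, 900000L, 5000000L))
  sites$gwas_link <- c("direct_hit", "ld_proxy", "ld_proxy", "unlinked")
  sites$traits <- c("Type 2 diabetes", "Type 2 diabetes",
                    "Type 2 diabetes;Fibrinogen", "")
  ts <- summarize_traits(sites)
  t2d <- ts[ts$trait == "Type 2 diabetes", ]
  expect_equal(t2d$n_as_snps, 3L)
  expect_equal(t2d$n_loci, 1L)    # all within 1 Mb
  fib <- ts[ts$trait == "Fibrinogen", ]
  expect_equal(fib$n_as_snps, 1L)
  total <- ts[ts$trait == "Total", ]
  expect_equal(total$n_as_snps, 3L)  # shared SNP counted once
  expect_equal(total$n_loci, 1L)
  expect_equal(ts$trait[nrow(ts)], "Total")
  # n_loci never exceeds n_as_snps
  expect_true(all(ts$n_loci <= ts$n_as_snps))
})

test_that("planted GWAS and eQTL links are recovered from a simulated study", {
  study <- simulate_study(tiny_config(seed = 61))
  man <- study$manifest
  sites <- as_site_df(man$as_sites$chrom, man$as_sites$pos)
  px <- expand_ld(study$tables$gwas, study$tables$ld, threshold = 0.8)
  above <- man$gwas_links[man$gwas_links$type == "proxy" &
                          man$gwas_links$r2 > 0.8, ]
  expect_equal(sort(px$proxy_id), sort(above$as_id))
  ann <- annotate_gwas(sites, study$tables$gwas, px)
  ann <- annotate_eqtl(ann, study$tables$eqtl)
  key <- paste0(ann$chrom, ":", ann$pos)
  direct <- man$gwas_links[man$gwas_links$type == "direct", ]
  expect_true(all(ann$gwas_link[key %in% direct$as_id] == "direct_hit"))
  expect_true(all(ann$gwas_link[key %in% above$as_id] == "ld_proxy"))
  planted_r2 <- above$r2[match(key[ann$gwas_link == "ld_proxy"],
                               above$as_id)]
  expect_equal(ann$gwas_r2[ann$gwas_link == "ld_proxy"], planted_r2)
  expect_equal(sum(nzchar(ann$eqtl_genes)),
               nrow(man$eqtl_links))
})

test_that("expected heterozygosity under HWE integrates to one third", {
  expect_equal(expected_het_fraction(), 1 / 3, tolerance = 1e-8)
})
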