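# PWM loading, scanning, allele scoring, functionality calls.

pwm_file <- function() system.file("extdata", "pwms_synthetic.txt",
                                   package = "assnp")

test_that("PWM loading normalizes counts with a pseudocount", {
  p <- tempfile(fileext = ".txt")
  writeLines(c(">M1 TFX",
               "A [ 8 0 0 2 ]",
               "C [ 0 8 0 2 ]",
               "G [ 0 0 8 2 ]",
               "T [ 0 0 0 2 ]"), p)
  pw <- load_pwms(p, pseudocount = 0.01)
  expect_length(pw, 1L)
  m <- pw$M1$mat
  expect_equal(unname(m["A", 1]), 8.01 / 8.04, tolerance = 1e-12)
  expect_equal(unname(m["C", 1]), 0.01 / 8.04, tolerance = 1e-12)
  expect_equal(unname(colSums(m)), rep(1, 4), tolerance = 1e-9)
  # a probability matrix is unchanged up to pseudocount mixing
  p2 <- tempfile(fileext = ".txt")
  writeLines(c(">M2 TFY",
               "A 0.7 0.1 0.25 0.25",
               "C 0.1 0.7 0.25 0.25",
               "G 0.1 0.1 0.25 0.25",
               "T 0.1 0.1 0.25 0.25"), p2)
  m2 <- load_pwms(p2, pseudocount = 0.01)$M2$mat
  expect_equal(unname(m2["A", 1]), 0.71 / 1.04, tolerance = 1e-12)
  # duplicate names are a hard error
  p3 <- tempfile(fileext = ".txt")
  writeLines(rep(c(">M1 TFX", "A 1 1 1 1", "C 1 1 1 1", "G 1 1 1 1",
                   "T 1 1 1 1"), 2), p3)
  expect_error(load_pwms(p3), "duplicate")
  # negative entries are a hard error
  p4 <- tempfile(fileext = ".txt")
  writeLines(c(">M4 T", "A 1 1 1 -1", "C 1 1 1 1", "G 1 1 1 1",
               "T 1 1 1 1"), p4)
  expect_error(load_pwms(p4), "negative")
})

test_that("scan scores are normalized to [0,1] with consensus extremes", {
  pwms <- load_pwms(pwm_file())
  for (pwm in pwms) {
    consensus <- paste(c("A", "C", "G", "T")[apply(pwm$mat, 2,
                                                   which.max)],
                       collapse = "")
    anti <- paste(c("A", "C", "G", "T")[apply(pwm$mat, 2, which.min)],
                  collapse = "")
    sc_c <- scan_scores(consensus, pwm)
    expect_equal(max(sc_c$norm), 1.0, tolerance = 1e-12)
    sc_a <- scan_scores(anti, pwm)
    expect_equal(min(sc_a$norm), 0.0, tolerance = 1e-12)
    expect_true(all(sc_c$norm >= -1e-12 & sc_c$norm <= 1 + 1e-12))
  }
  # ambiguous base placements are skipped
  pwm <- pwms[[1]]
  W <- strrep("A", ncol(pwm$mat) + 3)
  withN <- paste0("N", substr(W, 2, nchar(W)))
  scN <- scan_scores(withN, pwm)
  sc <- scan_scores(W, pwm)
  expect_lt(nrow(scN), nrow(sc))
})

test_that("scanning agrees with the per-position summation oracle", {
  pwms <- load_pwms(pwm_file())
  set.seed(15)
  for (i in 1:10) {
    pwm <- pwms[[1 + (i %% length(pwms))]]
    w <- paste(sample(c("A", "C", "G", "T"), ncol(pwm$mat) + 6,
                      replace = TRUE), collapse = "")
    got <- scan_scores(w, pwm)
    want <- oracle_pwm_scan(w, pwm)
    key <- function(d) d[order(d$strand, d$start0), ]
    g <- key(got); wnt <- key(want)
    expect_equal(g$raw, wnt$raw, tolerance = 1e-9)
    expect_equal(g$norm, wnt$norm, tolerance = 1e-9)
  }
})

test_that("allele scoring reports the disruption and is label-symmetric", {
  pwms <- load_pwms(pwm_file())
  pwm <- pwms$SYN_KLF5
  # consensus planted at position 21 inside an anti-consensus context
  # (the motif's worst-scoring base), heterozygous at the motif's
  # top-information position -- mirrors the generator's planted design,
  # under which the disrupted allele cannot rescue its score in a
  # shifted register
  lo <- log2(pwm$mat / 0.25)
  anti <- c("A", "C", "G", "T")[which.min(rowSums(lo))]
  flank <- strrep(anti, 20)
  consensus <- paste(c("A", "C", "G", "T")[apply(pwm$mat, 2, which.max)],
                     collapse = "")
  j <- which.max(apply(lo, 2, max) - apply(lo, 2, min))
  worst_base <- c("A", "C", "G", "T")[which.min(pwm$mat[, j])]
  g1seq <- paste0(flank, consensus, flank)
  g2seq <- g1seq
  substr(g2seq, 20 + j, 20 + j) <- worst_base
  pair <- structure(list(g1 = c(chr1 = g1seq), g2 = c(chr1 = g2seq),
                         provenance = list()),
                    class = "personal_genome_pair")
  hit <- score_allele_pair("chr1", 20L + j, pwm, pair)
  expect_equal(hit$score_allele1, 1.0, tolerance = 1e-9)
  # hand-computed disruption: lost log-odds at position j over the range
  rng <- sum(apply(lo, 2, max)) - sum(apply(lo, 2, min))
  expected_delta_same_register <-
    (lo[which.max(pwm$mat[, j]), j] - lo[which.min(pwm$mat[, j]), j]) / rng
  expect_lte(hit$delta, expected_delta_same_register + 1e-9)
  expect_gt(hit$delta, 0.3)  # designed to exceed the disruption floor
  # swapping haplotype labels leaves delta unchanged
  swapped <- structure(list(g1 = pair$g2, g2 = pair$g1,
                            provenance = list()),
                       class = "personal_genome_pair")
  hit_sw <- score_allele_pair("chr1", 20L + j, pwm, swapped)
  expect_equal(hit_sw$delta, hit$delta, tolerance = 1e-12)
  # alleles scoring identically give delta 0
  pair_same <- structure(list(g1 = pair$g1, g2 = pair$g1,
                              provenance = list()),
                         class = "personal_genome_pair")
  expect_equal(score_allele_pair("chr1", 20L + j, pwm,
                                 pair_same)$delta, 0)
})

test_that("functionality score sums shipped weights over present annotations", {
  w <- default_functionality_weights()
  none <- list(dnase = FALSE, tf_chip = FALSE, cage = FALSE,
               tf_expressed = FALSE, chromatin_state = "quiescent",
               replication_domain = "late")
  expect_equal(functionality_score(none, w), 0)
  three <- list(dnase = TRUE, tf_chip = TRUE, cage = TRUE,
                tf_expressed = FALSE, chromatin_state = "quiescent",
                replication_domain = "late")
  expect_equal(functionality_score(three, w), 3)
  # dnase + tf_chip + expressed + TSS state with shipped weights
  promo <- list(dnase = TRUE, tf_chip = TRUE, cage = FALSE,
                tf_expressed = TRUE, chromatin_state = "TSS",
                replication_domain = "late")
  expect_equal(functionality_score(promo, w), 1 + 1 + 1 + 1)
  # unknown weight key is a hard error
  expect_error(functionality_score(none, c(w, list(bogus = 1))),
               "unknown annotation")
  expect_error(functionality_score(list(dnase = TRUE,
                                        chromatin_state = "exotic"), w),
               "no weight")
})

test_that("candidate-functional rule enforces its required conjuncts", {
  # DNase is strictly required
  expect_false(call_candidate_functional(FALSE, TRUE, 0.35, TRUE, 9))
  # TF binding satisfies the disjunct even at score 0
  expect_true(call_candidate_functional(TRUE, TRUE, 0.35, TRUE, 0))
  # "no less than 2.55" is inclusive
  expect_true(call_candidate_functional(TRUE, TRUE, 0.35, FALSE, 2.55))
  expect_false(call_candidate_functional(TRUE, TRUE, 0.35, FALSE, 2.54))
  # delta floor at 0.3 is inclusive ("changed at least 0.3")
  expect_true(call_candidate_functional(TRUE, TRUE, 0.3, TRUE, 0))
  expect_false(call_candidate_functional(TRUE, TRUE, 0.29, TRUE, 0))
  # monotone: increasing a satisfied margin never turns true to false
  base <- call_candidate_functional(TRUE, TRUE, 0.31, FALSE, 2.6)
  expect_true(base)
  expect_true(call_candidate_functional(TRUE, TRUE, 0.5, FALSE, 3.5))
})

test_that("planted motif disruptions are recovered as candidate functional", {
  study <- simulate_study(tiny_config(seed = 62,
                                      n_blacklisted_as_sites = 0L))
  man <- study$manifest
  sites <- data.frame(chrom = man$as_sites$chrom,
                      pos = man$as_sites$pos, is_as_snp = TRUE,
                      stringsAsFactors = FALSE)
  pwms <- load_pwms(pwm_file())
  hits <- annotate_motif_hits(sites, pwms, study$pair, study$tracks,
                              study$tracks$expression)
  mp <- man$motif_planted
  for (i in seq_len(nrow(mp))) {
    h <- hits[hits$chrom == mp$chrom[i] & hits$pos == mp$pos[i] &
              hits$pwm == mp$pwm[i], ]
    expect_equal(nrow(h), 1L)
    expect_gte(h$delta, 0.3)
    # planted sign: haplotype 1 carries the consensus
    expect_gt(h$score_allele1, h$score_allele2)
    expect_true(h$candidate_functional)
  }
  smry <- summarize_motifs(hits)
  planted_tfs <- vapply(mp$pwm, function(p) pwms[[p]]$tf, "")
  expect_true(all(planted_tfs %in% smry$tf$tf))
})
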