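# Independent oracles used to cross-check the implementation. These are
# deliberately written as brute-force / first-principles computations on
# small inputs, not calls into the code paths they verify.

# Two-sided balanced binomial p-value by explicit tail summation of
# C(n, j) / 2^n terms.
oracle_binom_enum <- function(k, n) {
  probs <- choose(n, 0:n) / 2^n
  lower <- sum(probs[seq_len(k + 1)])
  upper <- sum(probs[seq(k + 1, n + 1)])
  min(1, 2 * min(lower, upper))
}

# All-positions, all-strands ungapped Hamming scan against both genomes,
# applying the same mapping policy as the aligner but via direct string
# comparison at every single position.
oracle_full_scan <- function(seq, pair, max_mismatches = 3L) {
  len <- nchar(seq)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq)))
  cand <- list()
  for (chrom in names(pair$g1)) {
    L <- nchar(pair$g1[[chrom]])
    for (start1 in seq_len(L - len + 1L)) {
      w1 <- substr(pair$g1[[chrom]], start1, start1 + len - 1L)
      w2 <- substr(pair$g2[[chrom]], start1, start1 + len - 1L)
      for (strand in c("+", "-")) {
        s <- if (strand == "+") seq else rc
        mm1 <- sum(strsplit(s, "")[[1]] != strsplit(w1, "")[[1]])
        mm2 <- sum(strsplit(s, "")[[1]] != strsplit(w2, "")[[1]])
        if (min(mm1, mm2) <= max_mismatches)
          cand[[length(cand) + 1L]] <- data.frame(
            chrom = chrom, start0 = start1 - 1L, strand = strand,
            mm1 = mm1, mm2 = mm2, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(cand))
    return(list(assignment = "UNMAPPED", chrom = NA, start0 = NA,
                mm_g1 = NA, mm_g2 = NA))
  cand <- do.call(rbind, cand)
  for (col in c("mm1", "mm2")) {
    if (min(cand[[col]]) <= max_mismatches &&
        sum(cand[[col]] == min(cand[[col]])) > 1L)
      return(list(assignment = "UNMAPPED", chrom = NA, start0 = NA,
                  mm_g1 = NA, mm_g2 = NA))
  }
  best <- cand[which.min(pmin(cand$mm1, cand$mm2)), ]
  mm1 <- min(cand$mm1); mm2 <- min(cand$mm2)
  list(assignment = if (mm1 < mm2) "G1" else if (mm2 < mm1) "G2"
         else "TIE",
       chrom = best$chrom, start0 = best$start0, mm_g1 = mm1,
       mm_g2 = mm2)
}

# r-squared as the squared Pearson correlation of the two 0/1 haplotype
# indicator vectors.
oracle_r2_pearson <- function(a, b) {
  suppressWarnings(stats::cor(a, b))^2
}

# PWM scan by explicit per-position log-odds summation, with its own
# normalization arithmetic.
oracle_pwm_scan <- function(window, pwm) {
  mat <- pwm$mat
  L <- ncol(mat)
  bases <- c("A", "C", "G", "T")
  lo <- matrix(0, 4, L)
  for (b in 1:4) for (j in 1:L) lo[b, j] <- log2(mat[b, j] / 0.25)
  best <- 0; worst <- 0
  for (j in 1:L) {
    best <- best + max(lo[, j])
    worst <- worst + min(lo[, j])
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  score_one <- function(sub) {
    s <- 0
    ch <- strsplit(sub, "")[[1]]
    for (j in seq_along(ch)) {
      bi <- match(ch[j], bases)
      if (is.na(bi)) return(NA_real_)
      s <- s + lo[bi, j]
    }
    s
  }
  rows <- list()
  W <- nchar(window)
  for (start0 in 0:(W - L)) {
    sub <- substr(window, start0 + 1L, start0 + L)
    raw_f <- score_one(sub)
    rcsub <- paste(rev(comp[strsplit(sub, "")[[1]]]), collapse = "")
    raw_r <- score_one(rcsub)
    rows[[length(rows) + 1L]] <- data.frame(
      start0 = start0, strand = c("+", "-"), raw = c(raw_f, raw_r))
  }
  out <- do.call(rbind, rows)
  out <- out[!is.na(out$raw), ]
  out$norm <- (out$raw - worst) / (best - worst)
  out
}

# tiny deterministic study used by several test files; ... overrides any
# of the small-study defaults
tiny_config <- function(seed = 11L, ...) {
  defaults <- list(seed = seed, n_chroms = 1L, chrom_length = 20000L,
                   variant_spacing = 40L, n_peaks_per_mark = 4L,
                   n_as_sites = 3L, coverage = 200,
                   n_blacklisted_as_sites = 1L, n_motif_planted = 1L,
                   n_eqtl_links = 2L, ld_r2_planted = c(1.0, 0.81))
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}
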