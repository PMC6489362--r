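# k-mer index and haplotype-aware read alignment.

make_tiny_pair <- function(seed = 41, chrom_length = 3000L) {
  cfg <- simulation_config(seed = seed, n_chroms = 1L,
                           chrom_length = chrom_length,
                           variant_spacing = 30L, n_peaks_per_mark = 4L,
                           peak_width = 100L, n_as_sites = 2L,
                           coverage = 30, n_motif_planted = 0L,
                           n_blacklisted_as_sites = 0L,
                           marks = c("CTCF"), n_eqtl_links = 0L,
                           ld_r2_planted = numeric(0))
  ref <- generate_reference(cfg)
  v <- generate_phased_variants(cfg, ref)
  v <- v[v$filter == "PASS", ]
  list(cfg = cfg, ref = ref, variants = v,
       pair = build_personal_genomes(ref, v))
}

test_that("k-mer index stores and retrieves exact positions", {
  g <- c(chr1 = "ACGTACGTACGTACGTACGT")  # 20 bases, period 4
  idx <- build_kmer_index(g, k = 10)
  # n - k + 1 = 11 forward start positions indexed in total
  all_kmers <- substring(g[[1]], 1:11, 10:20)
  expect_equal(sum(lengths(lapply(unique(all_kmers), function(km)
    query_kmer(idx, km)$pos0))), 11L)
  # a repeated k-mer returns all its positions
  hits <- query_kmer(idx, substr(g[[1]], 1, 10))
  expect_equal(sort(hits$pos0), c(0L, 4L, 8L))
  # absent k-mer -> empty
  expect_equal(nrow(query_kmer(idx, strrep("A", 10))), 0L)
  expect_error(build_kmer_index(g, k = 4), "k must be")
  expect_error(build_kmer_index(c(x = "ACGT"), k = 8), "shortest")
})

test_that("reads are assigned to the haplotype they match", {
  tp <- make_tiny_pair()
  idx1 <- build_kmer_index(tp$pair$g1)
  idx2 <- build_kmer_index(tp$pair$g2)
  het <- tp$variants[tp$variants$is_het, ]
  site <- het[5, ]
  # read copied exactly from g2 across the het site
  start <- site$pos - 18L
  r_g2 <- substr(tp$pair$g2[[1]], start, start + 35L)
  al <- align_read(r_g2, strrep("?", 36), idx1, idx2)
  expect_equal(al$assignment, "G2")
  expect_equal(al$mm_g2, 0L)
  expect_equal(al$start0, start - 1L)
  # same window from g1
  r_g1 <- substr(tp$pair$g1[[1]], start, start + 35L)
  expect_equal(align_read(r_g1, NULL, idx1, idx2)$assignment, "G1")
  # a read overlapping no substituted position ties
  far <- max(het$pos) + 50L
  if (far + 35L <= nchar(tp$ref[[1]])) {
    r_tie <- substr(tp$ref[[1]], far, far + 35L)
    hets_in <- any(tp$variants$pos >= far & tp$variants$pos <= far + 35L)
    if (!hets_in)
      expect_equal(align_read(r_tie, NULL, idx1, idx2)$assignment, "TIE")
  }
  # reverse-complement read maps on the minus strand to the same locus
  al_rc <- align_read(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(r_g2))), NULL, idx1, idx2)
  expect_equal(al_rc$assignment, "G2")
  expect_equal(al_rc$strand, "-")
  expect_equal(al_rc$start0, start - 1L)
})

test_that("a read spanning two het sites with one error still resolves", {
  set.seed(7)
  ref <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 400,
                               replace = TRUE), collapse = ""))
  # two phased hets 20 bp apart, hap1 = ref at both
  rb <- substring(ref[[1]], c(100L, 120L), c(100L, 120L))
  ab <- vapply(rb, function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
  v <- data.frame(chrom = "chr1", pos = c(100L, 120L), id = c("a", "b"),
                  ref = rb, alt = ab, hap1 = rb, hap2 = ab, is_het = TRUE,
                  filter = "PASS", phase_set = "", stringsAsFactors = FALSE)
  pair <- build_personal_genomes(ref, v)
  idx1 <- build_kmer_index(pair$g1)
  idx2 <- build_kmer_index(pair$g2)
  read <- substr(pair$g1[[1]], 90, 139)       # covers both hets, hap1
  substr(read, 5, 5) <-                       # one sequencing error
    setdiff(c("A", "C", "G", "T"), substr(read, 5, 5))[1]
  al <- align_read(read, NULL, idx1, idx2)
  expect_equal(al$assignment, "G1")
  expect_equal(al$mm_g1, 1L)
  expect_equal(al$mm_g2, 3L)
})

test_that("swapping the genomes swaps assignments and preserves ties", {
  tp <- make_tiny_pair(seed = 42)
  reads <- simulate_study(tp$cfg)$reads[["CTCF"]]$reads[1:60, ]
  a_fwd <- align_reads(reads, tp$pair)
  swapped <- structure(list(g1 = tp$pair$g2, g2 = tp$pair$g1,
                            provenance = tp$pair$provenance),
                       class = "personal_genome_pair")
  a_swp <- align_reads(reads, swapped)
  map <- c(G1 = "G2", G2 = "G1", TIE = "TIE", UNMAPPED = "UNMAPPED")
  expect_equal(unname(map[a_fwd$assignment]), a_swp$assignment)
  expect_equal(a_fwd$mm_g1, a_swp$mm_g2)
})

test_that("error-free reads recover their haplotype of origin", {
  cfg <- tiny_config(seed = 43, base_error_rate = 0)
  study <- simulate_study(cfg)
  reads <- study$reads[["H3K4me3"]]$reads
  al <- align_reads(reads, study$pair)
  hap_true <- as.integer(sub(".*:h", "", al$read_id))
  het <- study$variants[study$variants$is_het &
                        study$variants$filter == "PASS", ]
  overlaps_het <- vapply(seq_len(nrow(al)), function(i) {
    if (is.na(al$start0[i])) return(NA)
    any(het$chrom == al$chrom[i] & het$pos > al$start0[i] &
        het$pos <= al$start0[i] + nchar(al$seq[i]))
  }, logical(1))
  informative <- al$assignment %in% c("G1", "G2")
  # every informative read carries its true haplotype
  expect_true(all(ifelse(informative,
                         (al$assignment == "G1") == (hap_true == 1L),
                         TRUE)))
  # reads overlapping no het site are ties (unless unmapped)
  no_het <- !is.na(overlaps_het) & !overlaps_het
  expect_true(all(al$assignment[no_het] %in% c("TIE", "UNMAPPED")))
  expect_true(all(al$assignment[no_het] == "TIE"))
})

test_that("low mean base quality reads are screened out before alignment", {
  tp <- make_tiny_pair(seed = 44)
  read <- substr(tp$pair$g1[[1]], 501, 536)
  reads <- data.frame(read_id = c("hi", "lo"), seq = read,
                      qual = c(strrep("?", 36), strrep("+", 36)),
                      stringsAsFactors = FALSE)   # Q30 vs Q10
  al <- align_reads(reads, tp$pair)
  expect_equal(nrow(al), 1L)
  expect_equal(al$read_id, "hi")
  expect_equal(attr(al, "n_quality_filtered"), 1L)
})

test_that("SAM import assigns by edit distance and handles unmapped reads", {
  tp <- make_tiny_pair(seed = 45)
  g1 <- tp$pair$g1[[1]]
  pick <- function(start) substr(g1, start, start + 35L)
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:chr1\tLN:%d", nchar(g1)))
  sam_line <- function(id, flag, pos, seq, nm)
    sprintf("%s\t%d\tchr1\t%d\t60\t36M\t*\t0\t0\t%s\t%s\tNM:i:%d",
            id, flag, pos, seq, strrep("?", 36), nm)
  unmapped_line <- function(id)
    sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t%s", id,
            strrep("A", 36), strrep("?", 36))
  # six reads with hand-chosen NM tags in the two files:
  # r1 (0 vs 1) G1, r2 (1 vs 2) G1, r3 (2 vs 0) G2,
  # r4 (1 vs 1) TIE, r5 (0 vs 0) TIE, r6 unmapped in both
  nm1 <- c(0L, 1L, 2L, 1L, 0L)
  nm2 <- c(1L, 2L, 0L, 1L, 0L)
  s1 <- tempfile(fileext = ".sam"); s2 <- tempfile(fileext = ".sam")
  writeLines(c(hdr, vapply(1:5, function(i)
    sam_line(paste0("r", i), 0L, 100L + 40L * i, pick(100L + 40L * i),
             nm1[i]), ""), unmapped_line("r6")), s1)
  writeLines(c(hdr, vapply(1:5, function(i)
    sam_line(paste0("r", i), 0L, 100L + 40L * i, pick(100L + 40L * i),
             nm2[i]), ""), unmapped_line("r6")), s2)
  al <- import_alignment_pair(s1, s2)
  al <- al[order(al$read_id), ]
  expect_equal(al$assignment,
               c("G1", "G1", "G2", "TIE", "TIE", "UNMAPPED"))
  # a read present in only one file maps to that genome
  writeLines(c(hdr, sam_line("solo", 0L, 200L, pick(200L), 0L)), s1)
  writeLines(hdr, s2)
  al2 <- import_alignment_pair(s1, s2)
  expect_equal(al2$assignment, "G1")
  expect_equal(attr(al2, "n_single_file"), 1L)
})

test_that("aligner agrees with the brute-force all-positions scan", {
  tp <- make_tiny_pair(seed = 46, chrom_length = 2000L)
  idx1 <- build_kmer_index(tp$pair$g1)
  idx2 <- build_kmer_index(tp$pair$g2)
  set.seed(99)
  for (i in 1:25) {
    start <- sample.int(1950, 1)
    src <- if (i %% 2 == 0) tp$pair$g1 else tp$pair$g2
    read <- substr(src[[1]], start, start + 35L)
    if (i %% 3 == 0) {   # inject up to two errors
      p <- sample.int(36, sample(1:2, 1))
      for (e in p) {
        ch <- substr(read, e, e)
        substr(read, e, e) <- setdiff(c("A", "C", "G", "T"), ch)[1]
      }
    }
    if (i %% 5 == 0)
      read <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(read)))
    got <- align_read(read, NULL, idx1, idx2)
    want <- oracle_full_scan(read, tp$pair)
    expect_equal(got$assignment, want$assignment, info = paste("read", i))
    if (want$assignment != "UNMAPPED") {
      expect_equal(got$mm_g1, want$mm_g1, info = paste("read", i))
      expect_equal(got$mm_g2, want$mm_g2, info = paste("read", i))
    }
  }
})
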