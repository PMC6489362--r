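#' Build an exact k-mer index over a genome
#'
#' Maps every forward-strand k-mer to its start positions across all
#' chromosomes. Reads are matched against both strands by also looking
#' up their reverse complement, so only the forward strand is indexed.
#' Positions are stored as 0-based offsets into the concatenated genome
#' for speed; [query_kmer()] converts back to (chrom, pos0).
#'
#' @param genome named character vector of chromosome sequences.
#' @param k k-mer length (>= 8).
#' @return list of class `kmer_index`: hash environment, `k`,
#'   chromosome names/lengths/offsets, and the concatenated sequence as
#'   a raw vector.
#' @export
build_kmer_index <- function(genome, k = 9L) {
  k <- as.integer(k)
  if (k < 8L) stop("k must be >= 8", call. = FALSE)
  lens <- nchar(genome)
  if (any(lens < k))
    stop("k exceeds the shortest chromosome length (", min(lens), ")",
         call. = FALSE)
  offsets <- c(0L, cumsum(lens))[seq_along(lens)]
  names(offsets) <- names(genome)
  kmers <- vector("list", length(genome))
  gpos <- vector("list", length(genome))
  for (ci in seq_along(genome)) {
    n <- lens[[ci]]
    starts <- seq_len(n - k + 1L)
    kmers[[ci]] <- substring(genome[[ci]], starts, starts + k - 1L)
    gpos[[ci]] <- starts - 1L + offsets[[ci]]
  }
  env <- list2env(split(unlist(gpos, use.names = FALSE),
                        unlist(kmers, use.names = FALSE)),
                  hash = TRUE, parent = emptyenv())
  structure(list(env = env, k = k, chrom_names = names(genome),
                 chrom_lengths = lens, offsets = offsets,
                 raw = charToRaw(paste(genome, collapse = ""))),
            class = "kmer_index")
}

# global 0-based offset -> chromosome index (1-based)
global_to_chrom <- function(index, g) {
  findInterval(g, unname(index$offsets))
}

#' Query a k-mer index
#'
#' @param index a [build_kmer_index()] result.
#' @param kmer query string of length `k`.
#' @return data.frame (chrom, pos0); zero rows when absent.
#' @export
query_kmer <- function(index, kmer) {
  hits <- get0(kmer, envir = index$env)
  if (is.null(hits))
    return(data.frame(chrom = character(0), pos0 = integer(0)))
  ci <- global_to_chrom(index, hits)
  data.frame(chrom = index$chrom_names[ci],
             pos0 = hits - unname(index$offsets)[ci],
             stringsAsFactors = FALSE)
}

# complement lookup table over raw byte values
.comp_raw <- local({
  tab <- as.raw(0:255)
  tab[utf8ToInt("A") + 1L] <- charToRaw("T")
  tab[utf8ToInt("C") + 1L] <- charToRaw("G")
  tab[utf8ToInt("G") + 1L] <- charToRaw("C")
  tab[utf8ToInt("T") + 1L] <- charToRaw("A")
  tab
})

revcomp_raw <- function(r) rev(.comp_raw[as.integer(r) + 1L])

# Candidate global starts for one oriented read: seeds at every offset.
# Dense seeding gives a pigeonhole guarantee: e mismatches split a
# length-L read into runs whose longest is >= ceiling((L - e)/(e + 1)),
# so any placement within max_mismatches = 3 of a 36-base read is found
# whenever k <= 9.
candidate_starts <- function(index, seq, len) {
  k <- index$k
  out <- integer(0)
  for (off in seq_len(len - k + 1L)) {
    hits <- get0(substr(seq, off, off + k - 1L), envir = index$env)
    if (!is.null(hits)) out <- c(out, hits - (off - 1L))
  }
  unique(out)
}

# Core ungapped placement against both genomes. Returns a list or NULL
# (no candidate loci at all).
align_core <- function(seq, idx1, idx2, max_mismatches) {
  len <- nchar(seq)
  fwd_raw <- charToRaw(seq)
  rc_raw <- revcomp_raw(fwd_raw)
  rc <- rawToChar(rc_raw)
  starts <- list(); strands <- character(0); reads_raw <- list()
  for (orient in c("+", "-")) {
    s <- if (orient == "+") seq else rc
    g <- unique(c(candidate_starts(idx1, s, len),
                  candidate_starts(idx2, s, len)))
    g <- g[g >= 0L]
    if (!length(g)) next
    # keep placements fully inside one chromosome
    ci <- global_to_chrom(idx1, g)
    ends_ok <-
      (g + len) <= unname(idx1$offsets)[ci] + idx1$chrom_lengths[ci]
    same_chrom <- ci == global_to_chrom(idx1, g + len - 1L)
    g <- g[ends_ok & same_chrom]
    if (!length(g)) next
    starts[[orient]] <- g
    strands <- c(strands, rep(orient, length(g)))
    reads_raw[[orient]] <- if (orient == "+") fwd_raw else rc_raw
  }
  if (!length(starts)) return(NULL)
  g_all <- unlist(starts, use.names = FALSE)
  n <- length(g_all)
  mm1 <- integer(n); mm2 <- integer(n)
  pos <- 0L
  for (orient in names(starts)) {
    rr <- reads_raw[[orient]]
    for (g in starts[[orient]]) {
      pos <- pos + 1L
      w <- (g + 1L):(g + len)
      mm1[pos] <- sum(idx1$raw[w] != rr)
      mm2[pos] <- sum(idx2$raw[w] != rr)
    }
  }
  list(g = g_all, strand = strands, mm1 = mm1, mm2 = mm2)
}

# Shared assignment policy: NULL = unmapped; otherwise index of the best
# candidate plus per-genome minima and the G1/G2/TIE label.
decide_alignment <- function(res, max_mismatches) {
  if (is.null(res)) return(NULL)
  score <- pmin(res$mm1, res$mm2)
  if (min(score) > max_mismatches) return(NULL)
  for (mm in list(res$mm1, res$mm2)) {
    if (min(mm) <= max_mismatches && sum(mm == min(mm)) > 1L)
      return(NULL)   # multiple equally good loci within one genome
  }
  mm1 <- min(res$mm1); mm2 <- min(res$mm2)
  list(j = which.min(score), mm1 = mm1, mm2 = mm2,
       assignment = if (mm1 < mm2) "G1" else if (mm2 < mm1) "G2"
         else "TIE")
}

#' Align one read against both personal genomes
#'
#' Ungapped seed-and-extend: k-mer seeds at every read offset (forward
#' and reverse-complement orientation) propose candidate loci; each
#' locus is scored by full-length Hamming distance against G1 and G2.
#' With the default k = 9 the dense seeding is fully sensitive for
#' 36-base reads within 3 mismatches (pigeonhole over mismatch-free
#' runs).
#' The read is assigned to the genome with the smaller mismatch count at
#' its best locus, `TIE` when equal, and `UNMAPPED` when both exceed
#' `max_mismatches` or multiple equally good loci exist within one
#' genome.
#'
#' @param seq read sequence.
#' @param qual Phred+33 quality string (may be `NULL`).
#' @param index_g1,index_g2 [build_kmer_index()] results for G1 and G2.
#' @param pair unused placeholder kept for call compatibility (the
#'   indexes carry the sequences); may be `NULL`.
#' @param max_mismatches maximum Hamming distance for a mapped read.
#' @return one-row data.frame (chrom, start0, strand, mm_g1, mm_g2,
#'   assignment, seq, qual); `seq`/`qual` are reported in genome-forward
#'   orientation.
#' @export
align_read <- function(seq, qual, index_g1, index_g2, pair = NULL,
                       max_mismatches = 3L) {
  len <- nchar(seq)
  if (len < index_g1$k) stop("read shorter than k", call. = FALSE)
  unmapped <- data.frame(chrom = NA_character_, start0 = NA_integer_,
                         strand = NA_character_, mm_g1 = NA_integer_,
                         mm_g2 = NA_integer_, assignment = "UNMAPPED",
                         seq = seq,
                         qual = if (is.null(qual)) NA_character_ else qual,
                         stringsAsFactors = FALSE)
  res <- align_core(seq, index_g1, index_g2, max_mismatches)
  dec <- decide_alignment(res, max_mismatches)
  if (is.null(dec)) return(unmapped)
  i <- dec$j
  ci <- global_to_chrom(index_g1, res$g[i])
  o_seq <- if (res$strand[i] == "+") seq else
    rawToChar(revcomp_raw(charToRaw(seq)))
  o_qual <- if (is.null(qual)) NA_character_ else
    if (res$strand[i] == "+") qual else intToUtf8(rev(utf8ToInt(qual)))
  data.frame(chrom = index_g1$chrom_names[ci],
             start0 = res$g[i] - unname(index_g1$offsets)[ci],
             strand = res$strand[i], mm_g1 = dec$mm1, mm_g2 = dec$mm2,
             assignment = dec$assignment,
             seq = o_seq, qual = o_qual, stringsAsFactors = FALSE)
}

#' Align a batch of reads to a personal genome pair
#'
#' Applies the read-level quality screen (reads with mean base quality
#' below `min_mean_quality` are discarded before alignment), then aligns
#' every read as in [align_read()].
#'
#' @param reads data.frame (read_id, seq, qual) as written by the
#'   simulator or read with [read_fastq()].
#' @param pair a [build_personal_genomes()] result.
#' @param k seed length.
#' @param max_mismatches maximum Hamming distance for a mapped read.
#' @param min_mean_quality Phred floor on a read's mean base quality.
#' @param indexes optional precomputed `list(g1 = , g2 = )` of
#'   [build_kmer_index()] results, to reuse across several read batches.
#' @return data.frame of class `assnp_alignments` (read_id, chrom,
#'   start0, strand, mm_g1, mm_g2, assignment, seq, qual) with attribute
#'   `n_quality_filtered`.
#' @export
align_reads <- function(reads, pair, k = 9L, max_mismatches = 3L,
                        min_mean_quality = 20, indexes = NULL) {
  mq <- mean_base_quality(reads$qual)
  kept <- mq >= min_mean_quality
  filtered <- sum(!kept)
  reads <- reads[kept, , drop = FALSE]
  idx1 <- if (is.null(indexes)) build_kmer_index(pair$g1, k) else
    indexes$g1
  idx2 <- if (is.null(indexes)) build_kmer_index(pair$g2, k) else
    indexes$g2
  n <- nrow(reads)
  chrom <- character(n); start0 <- integer(n); strand <- character(n)
  mm_g1 <- integer(n); mm_g2 <- integer(n); assignment <- character(n)
  oseq <- reads$seq; oqual <- reads$qual
  offs <- unname(idx1$offsets)
  for (i in seq_len(n)) {
    res <- align_core(reads$seq[i], idx1, idx2, max_mismatches)
    dec <- decide_alignment(res, max_mismatches)
    if (is.null(dec)) {
      chrom[i] <- NA_character_; start0[i] <- NA_integer_
      strand[i] <- NA_character_
      mm_g1[i] <- NA_integer_; mm_g2[i] <- NA_integer_
      assignment[i] <- "UNMAPPED"
      next
    }
    j <- dec$j
    ci <- global_to_chrom(idx1, res$g[j])
    chrom[i] <- idx1$chrom_names[ci]
    start0[i] <- res$g[j] - offs[ci]
    strand[i] <- res$strand[j]
    mm_g1[i] <- dec$mm1; mm_g2[i] <- dec$mm2
    assignment[i] <- dec$assignment
    if (strand[i] == "-") {
      oseq[i] <- rawToChar(revcomp_raw(charToRaw(reads$seq[i])))
      oqual[i] <- intToUtf8(rev(utf8ToInt(reads$qual[i])))
    }
  }
  out <- data.frame(read_id = reads$read_id, chrom = chrom,
                    start0 = start0, strand = strand, mm_g1 = mm_g1,
                    mm_g2 = mm_g2, assignment = assignment, seq = oseq,
                    qual = oqual, stringsAsFactors = FALSE)
  attr(out, "n_quality_filtered") <- filtered
  class(out) <- c("assnp_alignments", "data.frame")
  out
}

#' Read a FASTQ file into the simple read table
#'
#' @param path FASTQ (Phred+33).
#' @return data.frame (read_id, seq, qual).
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ: ", path, call. = FALSE)
  n <- length(lines) %/% 4L
  idx <- seq_len(n)
  data.frame(read_id = sub("^@", "", sub("\\s.*$", "",
                                         lines[(idx - 1L) * 4L + 1L])),
             seq = toupper(lines[(idx - 1L) * 4L + 2L]),
             qual = lines[(idx - 1L) * 4L + 4L],
             stringsAsFactors = FALSE)
}

#' Import a pair of per-genome SAM alignments
#'
#' Entry point for externally produced alignments: the same read set
#' aligned once to G1 and once to G2. Mismatch counts are taken from the
#' NM (edit distance) tag when present, otherwise recomputed against the
#' loaded genomes; assignment follows the same comparison as
#' [align_read()]. Reads below the mapping-quality floor, or unmapped in
#' both files, are `UNMAPPED`.
#'
#' @param sam_g1,sam_g2 SAM files (header required).
#' @param pair personal genome pair for NM recomputation (optional when
#'   every record carries NM).
#' @param min_mapq mapping-quality floor.
#' @return data.frame like [align_reads()] (qual absent from SAM input
#'   is `NA`).
#' @export
import_alignment_pair <- function(sam_g1, sam_g2, pair = NULL,
                                  min_mapq = 0L) {
  read_sam <- function(path) {
    bam <- Rsamtools::asBam(path, destination = tempfile(),
                            overwrite = TRUE, indexDestination = FALSE)
    p <- Rsamtools::ScanBamParam(
      what = c("qname", "rname", "pos", "strand", "mapq", "flag", "seq"),
      tag = "NM")
    b <- Rsamtools::scanBam(bam, param = p)[[1]]
    data.frame(read_id = b$qname,
               chrom = as.character(b$rname),
               pos = b$pos,
               strand = as.character(b$strand),
               mapq = b$mapq,
               unmapped = bitwAnd(b$flag, 4L) != 0L,
               seq = as.character(b$seq),
               nm = if (is.null(b$tag$NM))
                 rep(NA_integer_, length(b$qname)) else b$tag$NM,
               stringsAsFactors = FALSE)
  }
  a1 <- read_sam(sam_g1)
  a2 <- read_sam(sam_g2)
  ids <- union(a1$read_id, a2$read_id)
  i1 <- match(ids, a1$read_id)
  i2 <- match(ids, a2$read_id)
  n_only_one <- sum(is.na(i1)) + sum(is.na(i2))
  mm_of <- function(a, i, genome) {
    if (is.na(i) || a$unmapped[i]) return(NA_integer_)
    if (!is.na(a$nm[i])) return(a$nm[i])
    if (is.null(genome)) stop("NM tag absent and no genomes supplied",
                              call. = FALSE)
    w <- substr(genome[[a$chrom[i]]], a$pos[i],
                a$pos[i] + nchar(a$seq[i]) - 1L)
    hamming(a$seq[i], w)
  }
  rows <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    mm1 <- mm_of(a1, i1[j], if (is.null(pair)) NULL else pair$g1)
    mm2 <- mm_of(a2, i2[j], if (is.null(pair)) NULL else pair$g2)
    mapq <- max(c(if (!is.na(i1[j])) a1$mapq[i1[j]],
                  if (!is.na(i2[j])) a2$mapq[i2[j]], 0L), na.rm = TRUE)
    src <- if (!is.na(i1[j]) && !a1$unmapped[i1[j]]) list(a1, i1[j])
           else if (!is.na(i2[j]) && !a2$unmapped[i2[j]]) list(a2, i2[j])
           else NULL
    assignment <-
      if (is.null(src) || mapq < min_mapq) "UNMAPPED"
      else if (is.na(mm1) && is.na(mm2)) "UNMAPPED"
      else if (is.na(mm2) || (!is.na(mm1) && mm1 < mm2)) "G1"
      else if (is.na(mm1) || mm2 < mm1) "G2"
      else "TIE"
    rows[[j]] <- data.frame(
      read_id = ids[j],
      chrom = if (is.null(src)) NA_character_ else
        src[[1]]$chrom[src[[2]]],
      start0 = if (is.null(src)) NA_integer_ else
        src[[1]]$pos[src[[2]]] - 1L,
      strand = if (is.null(src)) NA_character_ else
        src[[1]]$strand[src[[2]]],
      mm_g1 = mm1, mm_g2 = mm2, assignment = assignment,
      seq = if (is.null(src)) NA_character_ else src[[1]]$seq[src[[2]]],
      qual = NA_character_, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "n_single_file") <- n_only_one
  class(out) <- c("assnp_alignments", "data.frame")
  out
}

#' Write the alignment assignment table
#'
#' @param alignments an `assnp_alignments` data.frame.
#' @param path output TSV.
#' @export
write_assignments <- function(alignments, path) {
  write_tsv(alignments[, c("read_id", "chrom", "start0", "strand",
                           "mm_g1", "mm_g2", "assignment")], path)
}
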