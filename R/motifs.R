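#' Load position weight matrices from JASPAR-style text
#'
#' Parses records of the form
#' ```
#' >MOTIF_ID TF_NAME
#' A [ 4 19 0 ... ]
#' C [ 16 0 20 ... ]
#' G ...
#' T ...
#' ```
#' (brackets optional; count or probability rows). Counts are converted
#' to per-position probabilities after adding a pseudocount to every
#' cell.
#'
#' @param path PWM text file.
#' @param pseudocount additive mass per cell before normalization.
#' @return named list of `pwm` objects: `name`, `tf`, `mat` (4 x L
#'   probability matrix, rows A/C/G/T), `background`, `pseudocount`.
#' @export
load_pwms <- function(path, pseudocount = 0.01) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no PWM records in ", path, call. = FALSE)
  pwms <- list()
  for (s in seq_along(starts)) {
    i <- starts[s]
    hdr <- strsplit(sub("^>", "", lines[i]), "\\s+")[[1]]
    name <- hdr[1]
    tf <- if (length(hdr) >= 2L) hdr[2] else hdr[1]
    rows <- lines[(i + 1):(i + 4)]
    parse_row <- function(r) {
      body <- sub("^[ACGTacgt]\\s*", "", r)
      body <- gsub("[][]", " ", body)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(body),
                                                   "\\s+")[[1]]))
      if (anyNA(vals)) stop("unparseable PWM row in ", name, call. = FALSE)
      vals
    }
    labels <- toupper(substr(rows, 1, 1))
    if (!identical(labels, BASES))
      stop("PWM ", name, " rows must be A, C, G, T in order",
           call. = FALSE)
    vals <- lapply(rows, parse_row)
    if (length(unique(lengths(vals))) != 1L || lengths(vals)[1] < 4L)
      stop("PWM ", name, " rows differ in length or motif shorter than 4",
           call. = FALSE)
    m <- do.call(rbind, vals)
    if (any(m < 0)) stop("negative entries in PWM ", name, call. = FALSE)
    m <- sweep(m + pseudocount, 2, colSums(m + pseudocount), "/")
    rownames(m) <- BASES
    if (name %in% names(pwms))
      stop("duplicate motif name ", name, call. = FALSE)
    pwms[[name]] <- structure(list(name = name, tf = tf, mat = m,
                                   background = rep(0.25, 4),
                                   pseudocount = pseudocount),
                              class = "pwm")
  }
  pwms
}

# Per-position log2 odds against the background.
pwm_log_odds <- function(pwm) {
  log2(pwm$mat / pwm$background)
}

#' Scan a sequence window with a PWM
#'
#' Scores every placement on both strands: the raw score is the summed
#' per-position log2 odds against the background, and the normalized
#' score rescales it to \[0, 1\] between the PWM's worst and best
#' attainable raw scores, so 1 is the consensus and 0 the
#' anti-consensus. The reverse strand scores the reverse complement;
#' placements containing an ambiguous base are skipped.
#'
#' @param window sequence to scan (length >= motif length).
#' @param pwm a `pwm` object.
#' @return data.frame (start0 window-relative, strand, raw, norm).
#' @export
scan_scores <- function(window, pwm) {
  lo <- pwm_log_odds(pwm)
  L <- ncol(lo)
  W <- nchar(window)
  if (W < L) stop("window shorter than motif", call. = FALSE)
  lo_min <- sum(apply(lo, 2, min))
  lo_max <- sum(apply(lo, 2, max))
  score_strand <- function(seq) {
    chars <- strsplit(seq, "")[[1]]
    idx <- match(chars, BASES)
    n_pl <- W - L + 1L
    raw <- rep(NA_real_, n_pl)
    for (j in seq_len(n_pl)) {
      ii <- idx[j:(j + L - 1L)]
      if (anyNA(ii)) next
      raw[j] <- sum(lo[cbind(ii, seq_len(L))])
    }
    raw
  }
  fwd <- score_strand(window)
  rev_raw <- score_strand(revcomp(window))
  # placement j on the reverse complement covers forward window
  # positions (W - L + 1 - j + 1) .. in 0-based start terms:
  n_pl <- W - L + 1L
  rev_start0 <- (n_pl - seq_len(n_pl))
  out <- rbind(
    data.frame(start0 = seq_len(n_pl) - 1L, strand = "+", raw = fwd),
    data.frame(start0 = rev_start0, strand = "-", raw = rev_raw))
  out <- out[!is.na(out$raw), , drop = FALSE]
  out$norm <- (out$raw - lo_min) / (lo_max - lo_min)
  rownames(out) <- NULL
  out
}

#' Score the two alleles of a heterozygous SNP against a PWM
#'
#' Extracts the window `[pos - flank, pos + flank]` from each haplotype
#' genome (default flank L-1, so every placement overlapping the SNP is
#' considered), takes each allele's best normalized score over all
#' placements and strands that overlap the SNP, and reports the absolute
#' normalized score change together with the placement achieving the
#' higher of the two bests.
#'
#' @param chrom,pos SNP coordinates (1-based, heterozygous).
#' @param pwm a `pwm` object.
#' @param pair personal genome pair.
#' @param flank half-window (default motif length - 1).
#' @return one-row data.frame (chrom, pos, pwm, tf, strand,
#'   placement_start0, score_allele1, score_allele2, delta), or `NULL`
#'   when no placement overlaps the SNP.
#' @export
score_allele_pair <- function(chrom, pos, pwm, pair, flank = NULL) {
  L <- ncol(pwm$mat)
  if (is.null(flank)) flank <- L - 1L
  len <- nchar(pair$g1[[chrom]])
  w_start <- max(1L, pos - flank)
  w_end <- min(len, pos + flank)
  if (w_end - w_start + 1L < L) return(NULL)
  snp_off0 <- pos - w_start          # 0-based offset of SNP in window
  best_overlapping <- function(genome) {
    win <- substr(genome[[chrom]], w_start, w_end)
    sc <- scan_scores(win, pwm)
    ov <- sc$start0 <= snp_off0 & snp_off0 <= sc$start0 + L - 1L
    sc <- sc[ov, , drop = FALSE]
    if (!nrow(sc)) return(NULL)
    sc[which.max(sc$norm), ]
  }
  b1 <- best_overlapping(pair$g1)
  b2 <- best_overlapping(pair$g2)
  if (is.null(b1) || is.null(b2)) return(NULL)
  top <- if (b1$norm >= b2$norm) b1 else b2
  data.frame(chrom = chrom, pos = pos, pwm = pwm$name, tf = pwm$tf,
             strand = top$strand,
             placement_start0 = w_start - 1L + top$start0,
             score_allele1 = b1$norm, score_allele2 = b2$norm,
             delta = abs(b1$norm - b2$norm), stringsAsFactors = FALSE)
}

#' Default annotation weights for the functionality score
#'
#' Binary annotations (DNase, TF ChIP, CAGE, TF expressed) weigh 1;
#' active chromatin-state labels weigh 1 and quiescent 0; replication
#' domains weigh 0.25. These shipped defaults make the 2.55
#' candidate-functional threshold exercisable; they are stand-ins, not
#' trained weights.
#'
#' @return nested list of weights.
#' @export
default_functionality_weights <- function() {
  list(dnase = 1, tf_chip = 1, cage = 1, tf_expressed = 1,
       chromatin_state = c(TSS = 1, enhancer = 1, insulator = 1,
                           transcribed = 0.5, quiescent = 0),
       replication_domain = c(early = 0.25, late = 0))
}

#' Weighted functionality score of a motif's annotation bundle
#'
#' Sum of weighted annotations: binary flags contribute their weight
#' when present; chromatin-state and replication-domain labels map to
#' weights through the label tables in `weights`.
#'
#' @param annotations list with logical `dnase`, `tf_chip`, `cage`,
#'   `tf_expressed` and character `chromatin_state`,
#'   `replication_domain`.
#' @param weights a weights list shaped like
#'   [default_functionality_weights()].
#' @return numeric score.
#' @export
functionality_score <- function(annotations,
                                weights = default_functionality_weights()) {
  known <- c("dnase", "tf_chip", "cage", "tf_expressed",
             "chromatin_state", "replication_domain")
  bad <- setdiff(names(weights), known)
  if (length(bad))
    stop("unknown annotation key in weights: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (any(vapply(weights[c("dnase", "tf_chip", "cage", "tf_expressed")],
                 function(w) any(w < 0), logical(1))))
    stop("weights must be nonnegative", call. = FALSE)
  s <- 0
  for (flag in c("dnase", "tf_chip", "cage", "tf_expressed"))
    s <- s + weights[[flag]] * as.numeric(isTRUE(annotations[[flag]]))
  for (lab in c("chromatin_state", "replication_domain")) {
    val <- annotations[[lab]]
    if (is.null(val) || is.na(val) || !nzchar(val)) next
    tbl <- weights[[lab]]
    if (!(val %in% names(tbl)))
      stop("no weight for ", lab, " label '", val, "'", call. = FALSE)
    s <- s + unname(tbl[[val]])
  }
  s
}

#' Candidate-functional call for a scored, annotated motif
#'
#' A motif hit is candidate functional when DNase signal is present on
#' the motif, the TF is expressed, the normalized motif score changes by
#' at least `delta_min` between the alleles, and either the TF binding
#' event is observed or the functionality score is no less than
#' `score_min`.
#'
#' @param dnase,tf_expressed,tf_chip logical annotation flags
#'   (vectorized).
#' @param delta absolute normalized score change.
#' @param score functionality score.
#' @param delta_min minimum score change (default 0.3).
#' @param score_min functionality-score threshold (default 2.55,
#'   inclusive).
#' @return logical flag(s).
#' @export
call_candidate_functional <- function(dnase, tf_expressed, delta, tf_chip,
                                      score, delta_min = 0.3,
                                      score_min = 2.55) {
  dnase & tf_expressed & (delta >= delta_min) &
    (tf_chip | score >= score_min)
}

#' Score and annotate motif disruption at AS-SNPs
#'
#' For every AS-SNP x PWM combination with a placement overlapping the
#' SNP, computes per-allele best normalized scores, overlaps the
#' reported placement interval with the annotation tracks (>= 1 base
#' intersection), looks up TF expression, computes the functionality
#' score and the candidate-functional flag.
#'
#' @param sites AS-SNP sites (an `assnp_calls` object or data.frame);
#'   only `is_as_snp` rows are scanned.
#' @param pwms list from [load_pwms()].
#' @param pair personal genome pair.
#' @param tracks named list with data.frames `dnase`, `tf_chip`, `cage`,
#'   `states`, `repdomains` (chrom/start0/end0, label where relevant).
#' @param expression data.frame (tf, tpm).
#' @param weights functionality weights.
#' @param expression_floor TF expressed when tpm strictly above this.
#' @param delta_min,score_min thresholds for
#'   [call_candidate_functional()].
#' @return data.frame of motif hits, one row per (snp, pwm).
#' @export
annotate_motif_hits <- function(sites, pwms, pair, tracks, expression,
                                weights = default_functionality_weights(),
                                expression_floor = 0, delta_min = 0.3,
                                score_min = 2.55) {
  if (inherits(sites, "assnp_calls")) sites <- sites$sites
  snps <- sites[sites$is_as_snp, , drop = FALSE]
  track_gr <- lapply(tracks[c("dnase", "tf_chip", "cage")],
                     as_granges_track)
  states_df <- tracks$states
  rep_df <- tracks$repdomains
  states_gr <- as_granges_track(states_df)
  rep_gr <- as_granges_track(rep_df)
  rows <- list()
  for (i in seq_len(nrow(snps))) {
    for (pwm in pwms) {
      hit <- score_allele_pair(snps$chrom[i], snps$pos[i], pwm, pair)
      if (is.null(hit)) next
      L <- ncol(pwm$mat)
      pl <- GenomicRanges::GRanges(
        hit$chrom, IRanges::IRanges(hit$placement_start0 + 1L,
                                    hit$placement_start0 + L))
      has <- function(gr) length(gr) > 0L &&
        suppressWarnings(IRanges::overlapsAny(pl, gr))
      label_of <- function(gr, df) {
        if (length(gr) == 0L) return("")
        ov <- suppressWarnings(GenomicRanges::findOverlaps(pl, gr))
        if (!length(ov)) return("")
        df$label[S4Vectors::subjectHits(ov)[1L]]
      }
      tpm <- expression$tpm[match(pwm$tf, expression$tf)]
      ann <- list(dnase = has(track_gr$dnase),
                  tf_chip = has(track_gr$tf_chip),
                  cage = has(track_gr$cage),
                  tf_expressed = !is.na(tpm) && tpm > expression_floor,
                  chromatin_state = label_of(states_gr, states_df),
                  replication_domain = label_of(rep_gr, rep_df))
      fs <- functionality_score(ann, weights)
      rows[[length(rows) + 1L]] <- cbind(
        hit,
        data.frame(dnase = ann$dnase, tf_chip = ann$tf_chip,
                   cage = ann$cage, tf_expressed = ann$tf_expressed,
                   chromatin_state = ann$chromatin_state,
                   replication_domain = ann$replication_domain,
                   functionality_score = fs,
                   candidate_functional = call_candidate_functional(
                     ann$dnase, ann$tf_expressed, hit$delta, ann$tf_chip,
                     fs, delta_min, score_min),
                   stringsAsFactors = FALSE))
    }
  }
  if (!length(rows))
    return(data.frame(chrom = character(0), pos = integer(0),
                      pwm = character(0), tf = character(0),
                      strand = character(0), placement_start0 = integer(0),
                      score_allele1 = numeric(0), score_allele2 = numeric(0),
                      delta = numeric(0), dnase = logical(0),
                      tf_chip = logical(0), cage = logical(0),
                      tf_expressed = logical(0),
                      chromatin_state = character(0),
                      replication_domain = character(0),
                      functionality_score = numeric(0),
                      candidate_functional = logical(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize candidate-functional motif hits
#'
#' @param hits an [annotate_motif_hits()] result.
#' @return list: `tf` (per-TF counts of candidate-functional hits,
#'   descending) and `state` (per chromatin-state counts, descending).
#' @export
summarize_motifs <- function(hits) {
  cf <- hits[hits$candidate_functional, , drop = FALSE]
  count_by <- function(v) {
    if (!length(v))
      return(data.frame(key = character(0), n = integer(0)))
    t <- table(v)
    d <- data.frame(key = names(t), n = as.integer(t),
                    stringsAsFactors = FALSE)
    d[order(-d$n, d$key, method = "radix"), , drop = FALSE]
  }
  tf <- count_by(cf$tf)
  names(tf) <- c("tf", "n")
  st <- count_by(cf$chromatin_state)
  names(st) <- c("chromatin_state", "n")
  list(tf = tf, state = st)
}
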