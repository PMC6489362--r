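#' Configuration for the synthetic allele-specific ChIP-seq study
#'
#' Bundles every knob of the seeded toy-study generator. The defaults
#' describe a small diploid study: a two-chromosome genome, phased SNVs at
#' a mean spacing of 60 bp, three marks (CTCF, H3K4me3, H3K27ac) with
#' enriched peaks, and nine planted allele-specific sites at a
#' haplotype-1 fragment probability of 0.8 against balanced null sites.
#'
#' @param seed master seed; every output file draws from its own RNG
#'   substream derived from it, so outputs are byte-reproducible and
#'   adding a mark does not perturb the other files.
#' @param n_chroms,chrom_length number and length (bp) of chromosomes.
#' @param variant_spacing mean distance (bp) between simulated SNVs.
#' @param het_fraction probability a variant is heterozygous (the rest
#'   are homozygous-alternative).
#' @param non_pass_fraction fraction of variants flagged with a non-PASS
#'   FILTER to exercise VCF filtering.
#' @param n_peaks_per_mark,peak_width ChIP peak count per mark and width (bp).
#' @param n_as_sites total planted allele-specific heterozygous sites,
#'   distributed round-robin over `marks`, one per peak.
#' @param as_ratio probability a fragment at a planted site carries the
#'   haplotype-1 allele (0.5 = balanced, 1 = fully monoallelic).
#' @param coverage mean fragments per peak (Poisson).
#' @param read_length,fragment_length single-end read and fragment size (bp).
#' @param base_error_rate per-base sequencing error probability. Correct
#'   bases get quality Q30, injected errors Q10, so the Phred-20 base
#'   quality filter is exercised deterministically.
#' @param marks ChIP-seq mark names.
#' @param n_blacklisted_as_sites planted AS sites placed inside emitted
#'   blacklist intervals (they must be removed by region filtering).
#' @param n_blacklist_decoys extra blacklist intervals placed away from
#'   peaks.
#' @param n_motif_planted planted AS sites whose flanking reference is
#'   overwritten with a PWM consensus so that haplotype 1 carries the
#'   consensus base and haplotype 2 a disrupting base.
#' @param ld_r2_planted squared-correlation values for planted GWAS
#'   proxy links; values must be exactly realizable from the haplotype
#'   panel (`panel_haplotypes` haplotypes at allele frequency 0.5).
#' @param panel_haplotypes number of haplotypes in the emitted LD panel.
#' @param n_eqtl_links planted AS-SNP to gene expression links.
#'
#' @return A list of class `assnp_sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chroms = 2L,
                              chrom_length = 50000L,
                              variant_spacing = 60L,
                              het_fraction = 0.8,
                              non_pass_fraction = 0.05,
                              n_peaks_per_mark = 10L,
                              peak_width = 200L,
                              n_as_sites = 9L,
                              as_ratio = 0.8,
                              coverage = 300,
                              read_length = 36L,
                              fragment_length = 60L,
                              base_error_rate = 0.001,
                              marks = c("CTCF", "H3K4me3", "H3K27ac"),
                              n_blacklisted_as_sites = 2L,
                              n_blacklist_decoys = 4L,
                              n_motif_planted = 3L,
                              ld_r2_planted = c(1.0, 0.9216, 0.81, 0.36, 0.16),
                              panel_haplotypes = 200L,
                              n_eqtl_links = 3L) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              variant_spacing = as.integer(variant_spacing),
              het_fraction = het_fraction,
              non_pass_fraction = non_pass_fraction,
              n_peaks_per_mark = as.integer(n_peaks_per_mark),
              peak_width = as.integer(peak_width),
              n_as_sites = as.integer(n_as_sites), as_ratio = as_ratio,
              coverage = coverage, read_length = as.integer(read_length),
              fragment_length = as.integer(fragment_length),
              base_error_rate = base_error_rate, marks = marks,
              n_blacklisted_as_sites = as.integer(n_blacklisted_as_sites),
              n_blacklist_decoys = as.integer(n_blacklist_decoys),
              n_motif_planted = as.integer(n_motif_planted),
              ld_r2_planted = ld_r2_planted,
              panel_haplotypes = as.integer(panel_haplotypes),
              n_eqtl_links = as.integer(n_eqtl_links))
  validate_sim_config(cfg)
  structure(cfg, class = "assnp_sim_config")
}

validate_sim_config <- function(cfg) {
  stop_cfg <- function(...) stop("configuration error: ", ..., call. = FALSE)
  if (cfg$chrom_length <= 0L) stop_cfg("chrom_length must be positive")
  if (cfg$n_chroms <= 0L) stop_cfg("n_chroms must be positive")
  if (cfg$variant_spacing < 2L) stop_cfg("variant_spacing must be >= 2")
  if (cfg$as_ratio < 0.5 || cfg$as_ratio > 1)
    stop_cfg("as_ratio must lie in [0.5, 1]")
  if (cfg$read_length > cfg$fragment_length)
    stop_cfg("read_length must not exceed fragment_length")
  if (cfg$fragment_length > cfg$chrom_length)
    stop_cfg("fragment_length must not exceed chrom_length")
  if (cfg$het_fraction < 0 || cfg$het_fraction > 1)
    stop_cfg("het_fraction must lie in [0, 1]")
  if (cfg$base_error_rate < 0 || cfg$base_error_rate > 1)
    stop_cfg("base_error_rate must lie in [0, 1]")
  counts <- c(cfg$n_peaks_per_mark, cfg$peak_width, cfg$read_length,
              cfg$fragment_length, cfg$panel_haplotypes)
  if (any(counts <= 0L)) stop_cfg("all counts must be positive")
  invisible(cfg)
}

#' Generate a random reference genome
#'
#' Uniform i.i.d. bases, one uppercase A/C/G/T sequence per chromosome.
#'
#' @param config an [simulation_config()] object.
#' @return Named character vector of sequences (`chr1`, `chr2`, ...).
#' @export
generate_reference <- function(config) {
  validate_sim_config(config)
  with_stream(config$seed, "reference", {
    seqs <- vapply(seq_len(config$n_chroms), function(i) {
      paste(sample(BASES, config$chrom_length, replace = TRUE),
            collapse = "")
    }, character(1))
    names(seqs) <- paste0("chr", seq_len(config$n_chroms))
    seqs
  })
}

#' Generate phased SNVs over a reference
#'
#' Draws SNV positions with exponential gaps at the configured mean
#' spacing. A `het_fraction` of sites are heterozygous with a random
#' phase orientation (`0|1` or `1|0`); the rest are homozygous-alt
#' (`1|1`). A `non_pass_fraction` receive FILTER `q10`.
#'
#' @param config an [simulation_config()] object.
#' @param reference named character vector from [generate_reference()].
#' @return data.frame with columns chrom, pos (1-based), id, ref, alt,
#'   hap1, hap2, is_het, filter, phase_set.
#' @export
generate_phased_variants <- function(config, reference) {
  validate_sim_config(config)
  with_stream(config$seed, "variants", {
    out <- lapply(names(reference), function(chrom) {
      len <- nchar(reference[[chrom]])
      n_guess <- ceiling(len / config$variant_spacing * 2) + 10L
      gaps <- pmax(2, round(stats::rexp(n_guess, 1 / config$variant_spacing)))
      pos <- cumsum(gaps)
      pos <- pos[pos <= len - 1L]     # keep off the very last base
      n <- length(pos)
      if (n == 0L) return(NULL)
      ref <- substring(reference[[chrom]], pos, pos)
      alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1L),
                    character(1), USE.NAMES = FALSE)
      is_het <- stats::runif(n) < config$het_fraction
      flip <- stats::runif(n) < 0.5   # phase orientation for hets
      hap1 <- ifelse(is_het, ifelse(flip, alt, ref), alt)
      hap2 <- ifelse(is_het, ifelse(flip, ref, alt), alt)
      filt <- ifelse(stats::runif(n) < config$non_pass_fraction, "q10", "PASS")
      data.frame(chrom = chrom, pos = pos,
                 id = paste0(chrom, ":", pos),
                 ref = ref, alt = alt, hap1 = hap1, hap2 = hap2,
                 is_het = is_het, filter = filt, phase_set = "PS1",
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

# Place non-overlapping peaks per mark, at least one fragment length from
# chromosome ends. Deterministic given the stream seed.
place_peaks <- function(config, reference) {
  with_stream(config$seed, "peaks", {
    slot_w <- config$peak_width + config$fragment_length
    rows <- list()
    for (mark in config$marks) {
      per_chrom <- rep(config$n_peaks_per_mark %/% length(reference),
                       length(reference))
      extra <- config$n_peaks_per_mark %% length(reference)
      if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
      for (ci in seq_along(reference)) {
        chrom <- names(reference)[ci]
        len <- nchar(reference[[ci]])
        lo <- config$fragment_length
        hi <- len - config$fragment_length - config$peak_width
        n_slots <- max(0L, (hi - lo) %/% slot_w)
        if (n_slots < per_chrom[ci])
          stop("configuration error: chromosome too short for ",
               per_chrom[ci], " non-overlapping peaks", call. = FALSE)
        slots <- sort(sample.int(n_slots, per_chrom[ci]))
        start0 <- lo + (slots - 1L) * slot_w +
          sample.int(config$fragment_length, per_chrom[ci], replace = TRUE) - 1L
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, start0 = start0,
          end0 = start0 + config$peak_width, mark = mark,
          stringsAsFactors = FALSE)
      }
    }
    pk <- do.call(rbind, rows)
    pk$peak_id <- sprintf("%s_pk%03d", pk$mark, stats::ave(
      seq_len(nrow(pk)), pk$mark, FUN = seq_along))
    pk
  })
}

# Pick planted AS sites: heterozygous PASS variants inside peaks, at most
# one per peak, distributed round-robin over marks.
select_as_sites <- function(config, variants, peaks) {
  with_stream(config$seed, "as_sites", {
    het <- variants[variants$is_het & variants$filter == "PASS", ]
    # plant away from peak edges, where single-end fragment coverage
    # tapers off, mimicking summit-proximal regulatory SNPs
    margin <- min(config$read_length, (config$peak_width - 4L) %/% 3L)
    margin <- max(margin, 1L)
    n_per_mark <- table(factor(rep(config$marks,
                                   length.out = config$n_as_sites),
                               levels = config$marks))
    picked <- list()
    for (mark in config$marks) {
      pk <- peaks[peaks$mark == mark, ]
      pk <- pk[sample.int(nrow(pk)), ]
      need <- n_per_mark[[mark]]
      got <- 0L
      for (i in seq_len(nrow(pk))) {
        if (got >= need) break
        inside <- het$chrom == pk$chrom[i] &
          het$pos > pk$start0[i] + margin & het$pos <= pk$end0[i] - margin
        cand <- het[inside, ]
        if (nrow(cand) == 0L) next
        hit <- cand[sample.int(nrow(cand), 1L), ]
        picked[[length(picked) + 1L]] <- data.frame(
          chrom = hit$chrom, pos = hit$pos, mark = mark,
          true_ratio = config$as_ratio, peak_id = pk$peak_id[i],
          stringsAsFactors = FALSE)
        got <- got + 1L
      }
      if (got < need)
        stop("configuration error: not enough heterozygous PASS sites ",
             "inside ", mark, " peaks; increase variant density",
             call. = FALSE)
    }
    do.call(rbind, picked)
  })
}

# Overwrite the reference around a planted site with a PWM consensus and
# set the variant alleles to consensus (hap1) vs worst base (hap2) at
# the motif's most informative position. The flanking L-1 bases on each
# side are filled with the motif's overall worst-scoring base so that
# the disrupted allele cannot recover a high score in a shifted
# register; the planted score change is then deterministic. Variants
# colliding with the extended window (other than the site itself) are
# dropped.
plant_motif_context <- function(reference, variants, site, pwm) {
  lo <- pwm_log_odds(pwm)
  ranges <- apply(lo, 2, max) - apply(lo, 2, min)
  j <- which.max(ranges)
  L <- ncol(lo)
  w_start <- site$pos - j + 1L
  w_end <- w_start + L - 1L
  f_start <- w_start - (L - 1L)
  f_end <- w_end + (L - 1L)
  len <- nchar(reference[[site$chrom]])
  if (f_start < 1L || f_end > len)
    stop("motif window off chromosome end at ", site$chrom, ":", site$pos)
  consensus <- BASES[apply(pwm$mat, 2, which.max)]
  worst <- BASES[apply(pwm$mat, 2, which.min)]
  anti <- BASES[which.min(rowSums(lo))]
  seq <- reference[[site$chrom]]
  substr(seq, f_start, f_end) <-
    paste0(strrep(anti, L - 1L), paste(consensus, collapse = ""),
           strrep(anti, L - 1L))
  reference[[site$chrom]] <- seq
  drop <- variants$chrom == site$chrom &
    variants$pos >= f_start & variants$pos <= f_end &
    variants$pos != site$pos
  variants <- variants[!drop, ]
  vi <- which(variants$chrom == site$chrom & variants$pos == site$pos)
  variants$ref[vi] <- consensus[j]
  variants$alt[vi] <- worst[j]
  variants$hap1[vi] <- consensus[j]
  variants$hap2[vi] <- worst[j]
  variants$is_het[vi] <- TRUE
  variants$filter[vi] <- "PASS"
  list(reference = reference, variants = variants,
       pwm_name = pwm$name, delta_sign = 1L)
}

#' Simulate ChIP-seq reads with planted allelic imbalance
#'
#' Fragments are sampled around peak centers (midpoint uniform within the
#' peak); each fragment carries one whole haplotype, drawn from haplotype
#' 1 with the planted probability at AS peaks and 0.5 elsewhere, so phase
#' is preserved along the fragment. Single-end reads of `read_length`
#' bases are taken from the fragment 5' end on a random strand.
#'
#' @param config an [simulation_config()] object.
#' @param pair a [build_personal_genomes()] result.
#' @param peaks peak table from the study design.
#' @param as_sites planted site table (chrom, pos, mark, true_ratio,
#'   peak_id).
#' @return list per mark: `reads` (data.frame read_id, seq, qual) and
#'   `site_counts` (realized haplotype-1/2 read counts covering each
#'   planted site).
#' @export
generate_chipseq_reads <- function(config, pair, peaks, as_sites) {
  validate_sim_config(config)
  fl <- config$fragment_length
  rl <- config$read_length
  out <- list()
  for (mark in config$marks) {
    out[[mark]] <- with_stream(config$seed, paste0("reads_", mark), {
      pk <- peaks[peaks$mark == mark, ]
      ids <- character(0); seqs <- character(0); quals <- character(0)
      cov1 <- stats::setNames(integer(nrow(as_sites)),
                              paste0(as_sites$chrom, ":", as_sites$pos))
      cov2 <- cov1
      for (i in seq_len(nrow(pk))) {
        chrom <- pk$chrom[i]
        len <- nchar(pair$g1[[chrom]])
        site <- as_sites[as_sites$mark == mark &
                         as_sites$peak_id == pk$peak_id[i], ]
        p1 <- if (nrow(site) >= 1L) site$true_ratio[1] else 0.5
        n_frag <- stats::rpois(1L, config$coverage)
        if (n_frag == 0L) next
        mid <- stats::runif(n_frag, pk$start0[i] + 1, pk$end0[i])
        fs <- pmin(pmax(1L, as.integer(round(mid - fl / 2))), len - fl + 1L)
        hap <- ifelse(stats::runif(n_frag) < p1, 1L, 2L)
        strand <- ifelse(stats::runif(n_frag) < 0.5, "+", "-")
        rs <- ifelse(strand == "+", fs, fs + fl - rl)  # read start, 1-based
        raw <- character(n_frag)
        h1 <- hap == 1L
        if (any(h1))
          raw[h1] <- substring(pair$g1[[chrom]], rs[h1], rs[h1] + rl - 1L)
        if (any(!h1))
          raw[!h1] <- substring(pair$g2[[chrom]], rs[!h1], rs[!h1] + rl - 1L)
        raw[strand == "-"] <- revcomp(raw[strand == "-"])
        qual <- rep(strrep(phred_to_qual(30L), rl), n_frag)
        if (config$base_error_rate > 0) {
          for (f in seq_len(n_frag)) {
            err <- which(stats::runif(rl) < config$base_error_rate)
            if (length(err) == 0L) next
            s <- strsplit(raw[f], "")[[1]]
            q <- rep(30L, rl)
            for (e in err) {
              s[e] <- sample(setdiff(BASES, s[e]), 1L)
              q[e] <- 10L
            }
            raw[f] <- paste(s, collapse = "")
            qual[f] <- phred_to_qual(q)
          }
        }
        if (nrow(site) >= 1L) {
          key <- paste0(site$chrom[1], ":", site$pos[1])
          covered <- site$pos[1] >= rs & site$pos[1] <= rs + rl - 1L
          cov1[key] <- cov1[key] + sum(covered & hap == 1L)
          cov2[key] <- cov2[key] + sum(covered & hap == 2L)
        }
        ids <- c(ids, sprintf("%s:%s:%d:%d:h%d", mark, chrom, i,
                              seq_len(n_frag), hap))
        seqs <- c(seqs, raw)
        quals <- c(quals, qual)
      }
      sc <- data.frame(site = names(cov1), reads_hap1 = unname(cov1),
                       reads_hap2 = unname(cov2), stringsAsFactors = FALSE)
      sc <- sc[sc$site %in% paste0(as_sites$chrom, ":", as_sites$pos)[
        as_sites$mark == mark], , drop = FALSE]
      list(reads = data.frame(read_id = ids, seq = seqs, qual = quals,
                              stringsAsFactors = FALSE),
           site_counts = sc)
    })
  }
  out
}

#' Generate tissue annotation tracks for the synthetic study
#'
#' Emits 0-based half-open BED intervals: a blacklist covering exactly
#' the planted blacklisted sites plus decoy intervals away from peaks;
#' DNase open chromatin over all peaks; TF ChIP intervals over the CTCF
#' peaks; CAGE tags at H3K4me3 peak centers; a chromatin-state
#' segmentation (TSS / enhancer / insulator over the respective marks'
#' peaks, quiescent elsewhere); replication domains (early first half of
#' each chromosome, late second half); and a TF expression table.
#'
#' @param config an [simulation_config()] object.
#' @param reference reference sequences (for chromosome bounds).
#' @param peaks,as_sites study design tables.
#' @param blacklisted_sites subset of `as_sites` to cover with blacklist
#'   intervals.
#' @param pwms PWM list; their TF names seed the expression table.
#' @return list of data.frames: blacklist, dnase, tf_chip, cage, states
#'   (BED4 label column), repdomains, expression.
#' @export
generate_annotation_tracks <- function(config, reference, peaks, as_sites,
                                       blacklisted_sites, pwms) {
  validate_sim_config(config)
  with_stream(config$seed, "tracks", {
    clip <- function(df) {
      len <- nchar(reference)[df$chrom]
      bad <- df$start0 < 0 | df$end0 > len
      if (any(bad)) {
        warning(sum(bad), " interval(s) clipped to chromosome bounds")
        df$start0 <- pmax(df$start0, 0L)
        df$end0 <- pmin(df$end0, len)
      }
      df[df$start0 < df$end0, , drop = FALSE]
    }
    bl <- NULL
    if (nrow(blacklisted_sites) > 0L)
      bl <- data.frame(chrom = blacklisted_sites$chrom,
                       start0 = blacklisted_sites$pos - 26L,
                       end0 = blacklisted_sites$pos + 25L,
                       stringsAsFactors = FALSE)
    if (config$n_blacklist_decoys > 0L) {
      dk <- lapply(seq_len(config$n_blacklist_decoys), function(i) {
        chrom <- sample(names(reference), 1L)
        len <- nchar(reference[[chrom]])
        repeat {
          s <- sample.int(len - 60L, 1L)
          pk <- peaks[peaks$chrom == chrom, ]
          if (!any(s < pk$end0 + 60L & s + 50L > pk$start0 - 60L)) break
        }
        data.frame(chrom = chrom, start0 = s, end0 = s + 50L,
                   stringsAsFactors = FALSE)
      })
      bl <- rbind(bl, do.call(rbind, dk))
    }
    if (is.null(bl))
      bl <- data.frame(chrom = character(0), start0 = integer(0),
                       end0 = integer(0))
    mark_bed <- function(m, pad = 0L) {
      pk <- peaks[peaks$mark == m, ]
      data.frame(chrom = pk$chrom, start0 = pk$start0 - pad,
                 end0 = pk$end0 + pad, stringsAsFactors = FALSE)
    }
    dnase <- data.frame(chrom = peaks$chrom, start0 = peaks$start0 - 20L,
                        end0 = peaks$end0 + 20L, stringsAsFactors = FALSE)
    tf_chip <- mark_bed("CTCF", pad = 20L)
    k4 <- peaks[peaks$mark == "H3K4me3", ]
    cage <- data.frame(chrom = k4$chrom,
                       start0 = (k4$start0 + k4$end0) %/% 2L - 10L,
                       end0 = (k4$start0 + k4$end0) %/% 2L + 10L,
                       stringsAsFactors = FALSE)
    state_of <- c(CTCF = "insulator", H3K4me3 = "TSS", H3K27ac = "enhancer")
    lab <- peaks
    lab$label <- unname(state_of[lab$mark])
    lab$label[is.na(lab$label)] <- "enhancer"
    states <- do.call(rbind, lapply(names(reference), function(chrom) {
      len <- nchar(reference[[chrom]])
      pk <- lab[lab$chrom == chrom, ]
      pk <- pk[order(pk$start0), ]
      segs <- list(); cur <- 0L
      for (i in seq_len(nrow(pk))) {
        s <- max(pk$start0[i] - 20L, cur); e <- min(pk$end0[i] + 20L, len)
        if (s > cur)
          segs[[length(segs) + 1L]] <- c(cur, s, "quiescent")
        segs[[length(segs) + 1L]] <- c(s, e, pk$label[i])
        cur <- e
      }
      if (cur < len) segs[[length(segs) + 1L]] <- c(cur, len, "quiescent")
      m <- do.call(rbind, segs)
      data.frame(chrom = chrom, start0 = as.integer(m[, 1]),
                 end0 = as.integer(m[, 2]), label = m[, 3],
                 stringsAsFactors = FALSE)
    }))
    repdom <- do.call(rbind, lapply(names(reference), function(chrom) {
      len <- nchar(reference[[chrom]])
      data.frame(chrom = chrom, start0 = c(0L, len %/% 2L),
                 end0 = c(len %/% 2L, len), label = c("early", "late"),
                 stringsAsFactors = FALSE)
    }))
    tfs <- unique(vapply(pwms, function(p) p$tf, character(1)))
    tpm <- round(stats::runif(length(tfs), 5, 100), 2)
    if (length(tpm) > 0L) tpm[length(tpm)] <- 0  # one unexpressed TF
    expression <- data.frame(tf = tfs, tpm = tpm, stringsAsFactors = FALSE)
    list(blacklist = clip(bl), dnase = clip(dnase), tf_chip = clip(tf_chip),
         cage = clip(cage), states = clip(states), repdomains = clip(repdom),
         expression = expression)
  })
}

# Haplotype-class counts realizing an r^2 exactly at allele frequency 0.5.
counts_for_r2 <- function(r2, n_hap) {
  d <- sqrt(r2) * 0.25
  ab <- n_hap * (0.25 + d)
  if (abs(ab - round(ab)) > 1e-9)
    stop("requested r2 = ", r2, " is not exactly realizable with ",
         n_hap, " haplotypes; nearest achievable D grid step is ",
         1 / n_hap, call. = FALSE)
  ab <- as.integer(round(ab))
  c(AB = ab, Ab = as.integer(n_hap / 2) - ab,
    aB = as.integer(n_hap / 2) - ab, ab = ab)
}

#' Generate GWAS, eQTL and LD tables with planted links
#'
#' Plants one direct GWAS hit at the first AS site and proxy links at the
#' following sites, with r-squared values realized exactly by a written
#' haplotype panel (allele frequency 0.5, D chosen on the panel's integer
#' grid). eQTL links attach gene symbols to the first `n_eqtl_links` AS
#' sites.
#'
#' @param config an [simulation_config()] object.
#' @param as_sites planted site table.
#' @return list: gwas, eqtl, ld (pair table), panel (0/1 haplotype
#'   matrix, one row per SNP), gwas_links (the planted truth).
#' @export
generate_gwas_eqtl_ld_tables <- function(config, as_sites) {
  validate_sim_config(config)
  with_stream(config$seed, "tables", {
    sites <- unique(as_sites[, c("chrom", "pos")])
    sites$id <- paste0(sites$chrom, ":", sites$pos)
    n_hap <- config$panel_haplotypes
    traits <- c("Type 2 diabetes", "Blood protein levels",
                "Cholesterol, total", "Fibrinogen", "HDL cholesterol",
                "Serum metabolite levels")
    gwas <- list(); ld <- list(); links <- list(); panel <- list()
    # direct hit: a GWAS SNP at the first AS site itself
    if (nrow(sites) >= 1L) {
      gwas[[1]] <- data.frame(rsid = "rs9000001", chrom = sites$chrom[1],
                              pos = sites$pos[1], trait = traits[1],
                              stringsAsFactors = FALSE)
      links[[1]] <- data.frame(as_id = sites$id[1], gwas_rsid = "rs9000001",
                               r2 = 1.0, trait = traits[1], type = "direct",
                               stringsAsFactors = FALSE)
    }
    n_proxy <- min(length(config$ld_r2_planted), max(0L, nrow(sites) - 1L))
    for (i in seq_len(n_proxy)) {
      site <- sites[i + 1L, ]
      r2 <- config$ld_r2_planted[i]
      rsid <- sprintf("rs90000%02d", i + 1L)
      gpos <- site$pos + 7000L + i * 13L
      gwas[[length(gwas) + 1L]] <- data.frame(
        rsid = rsid, chrom = site$chrom, pos = gpos,
        trait = traits[1L + (i %% length(traits))], stringsAsFactors = FALSE)
      cnt <- counts_for_r2(r2, n_hap)
      a <- c(rep(1L, cnt["AB"] + cnt["Ab"]), rep(0L, cnt["aB"] + cnt["ab"]))
      b <- c(rep(1L, cnt["AB"]), rep(0L, cnt["Ab"]),
             rep(1L, cnt["aB"]), rep(0L, cnt["ab"]))
      panel[[rsid]] <- a
      panel[[site$id]] <- b
      r2_chk <- compute_r2(cnt)
      ld[[length(ld) + 1L]] <- data.frame(snp_a = rsid, snp_b = site$id,
                                          r2 = r2_chk,
                                          stringsAsFactors = FALSE)
      links[[length(links) + 1L]] <- data.frame(
        as_id = site$id, gwas_rsid = rsid, r2 = r2_chk,
        trait = traits[1L + (i %% length(traits))], type = "proxy",
        stringsAsFactors = FALSE)
    }
    gwas <- if (length(gwas)) do.call(rbind, gwas) else
      data.frame(rsid = character(0), chrom = character(0),
                 pos = integer(0), trait = character(0))
    ld <- if (length(ld)) do.call(rbind, ld) else
      data.frame(snp_a = character(0), snp_b = character(0), r2 = numeric(0))
    links <- if (length(links)) do.call(rbind, links) else NULL
    genes <- c("APOB", "HNF4A", "ALB", "SERPINA1", "CYP3A4")
    n_eq <- min(config$n_eqtl_links, nrow(sites))
    eqtl <- if (n_eq > 0L) data.frame(
      variant_id = sites$id[seq_len(n_eq)],
      gene = genes[1L + (seq_len(n_eq) - 1L) %% length(genes)],
      tissue = "liver",
      p = signif(10^stats::runif(n_eq, -12, -4), 3),
      stringsAsFactors = FALSE)
    else data.frame(variant_id = character(0), gene = character(0),
                    tissue = character(0), p = numeric(0))
    pm <- if (length(panel)) do.call(rbind, panel) else
      matrix(integer(0), nrow = 0, ncol = n_hap)
    list(gwas = gwas, eqtl = eqtl, ld = ld, panel = pm, gwas_links = links)
  })
}

#' Direct count-level simulation of heterozygous sites
#'
#' Fast path that skips read simulation: per-site haplotype-1 counts are
#' binomial draws at the given ratio and coverage. Used for calibration
#' and power studies of the detection stage at scales where full read
#' simulation adds nothing.
#'
#' @param n_sites number of heterozygous sites.
#' @param coverage reads per site (fixed).
#' @param ratio haplotype-1 probability (0.5 = null).
#' @param seed RNG seed.
#' @param mark mark label on the records.
#' @return an allele-count data.frame as produced by [count_alleles()].
#' @export
simulate_allele_counts <- function(n_sites, coverage, ratio = 0.5,
                                   seed = 1L, mark = "sim") {
  set.seed(as.integer(seed))
  k <- stats::rbinom(n_sites, coverage, ratio)
  data.frame(chrom = "simchr", pos = seq_len(n_sites) * 1000L,
             ref = "A", alt = "G", hap1 = "A", hap2 = "G", mark = mark,
             count_g1 = k, count_g2 = coverage - k, count_other = 0L,
             total = as.integer(coverage), stringsAsFactors = FALSE)
}

#' Simulate a complete seeded toy study and write all files
#'
#' Orchestrates the generator: reference, phased variants, peak placement
#' and planted AS-site selection, motif-context planting, personal
#' genomes, per-mark FASTQ reads, annotation tracks, GWAS/eQTL/LD tables,
#' PWM file, and a ground-truth manifest (JSON). Every file is derived
#' from its own RNG substream of the master seed, so a fixed seed yields
#' byte-identical outputs.
#'
#' @param config an [simulation_config()] object.
#' @param outdir output directory (created if needed); when `NULL`
#'   nothing is written and only the in-memory study is returned.
#' @return list of class `assnp_simulation`: config, reference, variants,
#'   pair, peaks, as_sites, reads, tracks, tables, manifest, paths.
#' @export
simulate_study <- function(config = simulation_config(), outdir = NULL) {
  validate_sim_config(config)
  reference <- generate_reference(config)
  variants <- generate_phased_variants(config, reference)
  peaks <- place_peaks(config, reference)
  as_sites <- select_as_sites(config, variants, peaks)

  pwm_path <- system.file("extdata", "pwms_synthetic.txt", package = "assnp")
  pwms <- load_pwms(pwm_path)
  motif_planted <- NULL
  n_mp <- min(config$n_motif_planted, nrow(as_sites), length(pwms))
  for (i in seq_len(n_mp)) {
    res <- plant_motif_context(reference, variants, as_sites[i, ], pwms[[i]])
    reference <- res$reference
    variants <- res$variants
    motif_planted <- rbind(motif_planted, data.frame(
      chrom = as_sites$chrom[i], pos = as_sites$pos[i],
      pwm = res$pwm_name, expected_delta_sign = res$delta_sign,
      stringsAsFactors = FALSE))
  }

  n_bl <- min(config$n_blacklisted_as_sites, nrow(as_sites))
  bl_idx <- if (n_bl > 0L) seq(nrow(as_sites), by = -1L,
                               length.out = n_bl) else integer(0)
  blacklisted_sites <- as_sites[bl_idx, , drop = FALSE]

  pair <- build_personal_genomes(reference,
                                 variants[variants$filter == "PASS", ])
  reads <- generate_chipseq_reads(config, pair, peaks, as_sites)
  tracks <- generate_annotation_tracks(config, reference, peaks, as_sites,
                                       blacklisted_sites, pwms)
  tables <- generate_gwas_eqtl_ld_tables(config, as_sites)

  # Fragments carry one whole haplotype, so every het site inside an AS
  # peak shares that peak's imbalance: those are "linked" sites, not
  # nulls. Null sites are het sites inside balanced (non-AS) peaks.
  het <- variants[variants$is_het & variants$filter == "PASS", ]
  in_peak <- rep(FALSE, nrow(het))
  in_as_peak <- rep(FALSE, nrow(het))
  as_peaks <- unique(as_sites$peak_id)
  for (i in seq_len(nrow(peaks))) {
    inside <- het$chrom == peaks$chrom[i] &
      het$pos > peaks$start0[i] & het$pos <= peaks$end0[i]
    in_peak <- in_peak | inside
    if (peaks$peak_id[i] %in% as_peaks)
      in_as_peak <- in_as_peak | inside
  }
  planted_key <- paste0(as_sites$chrom, ":", as_sites$pos)
  het_key <- paste0(het$chrom, ":", het$pos)
  null_het <- het[in_peak & !in_as_peak, c("chrom", "pos")]
  linked_het <- het[in_as_peak & !(het_key %in% planted_key),
                    c("chrom", "pos")]

  site_counts <- do.call(rbind, lapply(names(reads), function(m) {
    sc <- reads[[m]]$site_counts
    if (nrow(sc)) cbind(sc, mark = m, stringsAsFactors = FALSE) else NULL
  }))
  as_key <- paste(paste0(as_sites$chrom, ":", as_sites$pos), as_sites$mark)
  sc_key <- paste(site_counts$site, site_counts$mark)
  as_out <- as_sites
  as_out$reads_hap1 <- site_counts$reads_hap1[match(as_key, sc_key)]
  as_out$reads_hap2 <- site_counts$reads_hap2[match(as_key, sc_key)]
  manifest <- list(
    config = unclass(config),
    as_sites = as_out,
    null_het_sites = null_het,
    linked_het_sites = linked_het,
    blacklisted_planted = blacklisted_sites[, c("chrom", "pos", "mark")],
    motif_planted = motif_planted,
    gwas_links = tables$gwas_links,
    eqtl_links = tables$eqtl)

  study <- structure(list(config = config, reference = reference,
                          variants = variants, pair = pair, peaks = peaks,
                          as_sites = as_sites, reads = reads,
                          tracks = tracks, tables = tables,
                          manifest = manifest, paths = NULL),
                     class = "assnp_simulation")
  if (!is.null(outdir)) study$paths <- write_study(study, outdir, pwm_path)
  study
}

write_study <- function(study, outdir, pwm_path) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- list()
  p$reference <- file.path(outdir, "reference.fa")
  write_fasta(study$reference, p$reference, index = TRUE)
  p$vcf <- file.path(outdir, "variants.vcf")
  write_phased_vcf(study$variants, p$vcf, contigs = nchar(study$reference))
  for (m in names(study$reads)) {
    p[[paste0("fastq_", m)]] <- file.path(outdir, paste0("reads_", m,
                                                         ".fastq"))
    write_fastq(study$reads[[m]]$reads, p[[paste0("fastq_", m)]])
  }
  for (tr in c("blacklist", "dnase", "tf_chip", "cage")) {
    p[[tr]] <- file.path(outdir, paste0(tr, ".bed"))
    write_bed(study$tracks[[tr]], p[[tr]])
  }
  for (tr in c("states", "repdomains")) {
    p[[tr]] <- file.path(outdir, paste0(tr, ".bed"))
    write_bed(study$tracks[[tr]], p[[tr]])
  }
  p$expression <- file.path(outdir, "tf_expression.tsv")
  write_tsv(study$tracks$expression, p$expression)
  p$gwas <- file.path(outdir, "gwas.tsv")
  write_tsv(study$tables$gwas, p$gwas)
  p$eqtl <- file.path(outdir, "eqtl.tsv")
  write_tsv(study$tables$eqtl, p$eqtl)
  p$ld <- file.path(outdir, "ld_pairs.tsv")
  write_tsv(study$tables$ld, p$ld)
  p$panel <- file.path(outdir, "haplotype_panel.tsv")
  pm <- study$tables$panel
  pdf <- data.frame(snp_id = rownames(pm), stringsAsFactors = FALSE)
  if (nrow(pm)) pdf <- cbind(pdf, as.data.frame(pm))
  colnames(pdf) <- c("snp_id", if (ncol(pm)) paste0("h", seq_len(ncol(pm))))
  write_tsv(pdf, p$panel)
  p$pwms <- file.path(outdir, "pwms_synthetic.txt")
  file.copy(pwm_path, p$pwms, overwrite = TRUE)
  p$manifest <- file.path(outdir, "manifest.json")
  jsonlite::write_json(study$manifest, p$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  p
}

# --- plain-text writers for the standard formats -------------------------

write_fasta <- function(seqs, path, index = FALSE) {
  ds <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ds, path, width = 70L)
  if (index) Rsamtools::indexFa(path)
  invisible(path)
}

write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads))
    writeLines(paste0("@", reads$read_id, "\n", reads$seq, "\n+\n",
                      reads$qual), con)
  invisible(path)
}

write_bed <- function(df, path) {
  cols <- c("chrom", "start0", "end0",
            if ("label" %in% names(df)) "label")
  utils::write.table(df[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

write_phased_vcf <- function(variants, path, contigs = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=assnp-simulator",
               if (!is.null(contigs))
                 sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                         contigs),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=PS,Number=1,Type=String,Description=\"Phase set\">",
               paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
                      "\tFORMAT\tsample1")), con)
  if (nrow(variants)) {
    gt_a <- ifelse(variants$hap1 == variants$ref, "0", "1")
    gt_b <- ifelse(variants$hap2 == variants$ref, "0", "1")
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\t%s\t.\tGT:PS\t%s|%s:%s",
                       variants$chrom, variants$pos, variants$id,
                       variants$ref, variants$alt, variants$filter,
                       gt_a, gt_b, variants$phase_set), con)
  }
  invisible(path)
}
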