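#' Load phased SNVs from a VCF
#'
#' Parses a VCF v4.2 with phased genotypes (`a|b`) for one sample and
#' returns the variant table the substitution and counting stages
#' consume. Non-PASS records, non-SNV records and unphased heterozygous
#' genotypes are dropped and tallied in a skip report attached as the
#' `"skip_report"` attribute.
#'
#' @param path VCF file.
#' @param require_pass drop records whose FILTER is not PASS (or `.`).
#' @param snv_only drop records whose REF or ALT is not a single base.
#' @return data.frame (chrom, pos, id, ref, alt, hap1, hap2, is_het,
#'   filter, phase_set) with attribute `skip_report`.
#' @export
load_phased_vcf <- function(path, require_pass = TRUE, snv_only = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt_raw) || ncol(gt_raw) < 1L)
    stop("VCF has no genotype column", call. = FALSE)
  gt <- gt_raw[, 1L]
  ps <- tryCatch(vcfR::extract.gt(v, element = "PS")[, 1L],
                 error = function(e) rep(NA_character_, length(gt)))
  n0 <- nrow(fix)
  filter <- fix$FILTER
  filter[is.na(filter)] <- "."
  skip <- c(non_pass = 0L, non_snv = 0L, unphased_het = 0L, malformed = 0L)

  keep <- rep(TRUE, n0)
  if (require_pass) {
    ok <- filter %in% c("PASS", ".")
    skip["non_pass"] <- sum(!ok)
    keep <- keep & ok
  }
  is_snv <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% BASES & fix$ALT %in% BASES
  if (snv_only) {
    skip["non_snv"] <- sum(keep & !is_snv)
    keep <- keep & is_snv
  }
  m <- regmatches(gt, regexec("^([0-9.])([|/])([0-9.])$", gt))
  bad <- lengths(m) != 4L
  if (any(bad & keep)) {
    first <- which(bad & keep)[1L]
    stop("malformed genotype '", gt[first], "' at record ", first,
         " (", fix$CHROM[first], ":", fix$POS[first], ")", call. = FALSE)
  }
  a1 <- vapply(m, function(x) if (length(x) == 4L) x[2] else NA_character_,
               character(1))
  sep <- vapply(m, function(x) if (length(x) == 4L) x[3] else NA_character_,
                character(1))
  a2 <- vapply(m, function(x) if (length(x) == 4L) x[4] else NA_character_,
               character(1))
  het <- a1 != a2
  unphased_het <- het & sep == "/"
  skip["unphased_het"] <- sum(keep & unphased_het, na.rm = TRUE)
  keep <- keep & !unphased_het
  keep <- keep & !(a1 == "." | a2 == ".")
  keep <- keep & a1 %in% c("0", "1") & a2 %in% c("0", "1")
  keep <- keep & !(a1 == "0" & a2 == "0")   # hom-ref carries no substitution

  fix <- fix[keep, , drop = FALSE]
  if (nrow(fix) == 0L)
    stop("zero usable variants after filtering ", path, call. = FALSE)
  allele <- function(code, ref, alt) ifelse(code == "0", ref, alt)
  out <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    id = ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID),
    ref = fix$REF, alt = fix$ALT,
    hap1 = allele(a1[keep], fix$REF, fix$ALT),
    hap2 = allele(a2[keep], fix$REF, fix$ALT),
    is_het = a1[keep] != a2[keep],
    filter = filter[keep],
    phase_set = ifelse(is.na(ps[keep]), "", ps[keep]),
    stringsAsFactors = FALSE)
  attr(out, "skip_report") <- skip
  out
}

#' Build the two personal haplotype genomes
#'
#' Substitutes the phased alleles of SNVs into the reference: genome G1
#' receives every hap1 allele, genome G2 every hap2 allele;
#' homozygous-alternative sites are substituted into both. Sequence
#' lengths and coordinates are unchanged (SNV-only substitution). Every
#' variant's REF base is checked against the reference; a mismatch or a
#' duplicated position is a hard error.
#'
#' @param reference named character vector of chromosome sequences
#'   (lowercase/soft-masked bases are uppercased on entry).
#' @param variants variant data.frame as from [load_phased_vcf()].
#' @return list of class `personal_genome_pair`: `g1`, `g2` (named
#'   character vectors) and `provenance`.
#' @export
build_personal_genomes <- function(reference, variants) {
  reference <- toupper(reference)
  if (is.null(names(reference)))
    stop("reference sequences must be named", call. = FALSE)
  dup <- duplicated(variants[, c("chrom", "pos")])
  if (any(dup)) {
    d <- variants[dup, ][1L, ]
    stop("duplicate variant position ", d$chrom, ":", d$pos, call. = FALSE)
  }
  g1 <- reference
  g2 <- reference
  for (chrom in unique(variants$chrom)) {
    if (!chrom %in% names(reference))
      stop("variant chromosome ", chrom, " absent from reference",
           call. = FALSE)
    v <- variants[variants$chrom == chrom, ]
    refbase <- substring(reference[[chrom]], v$pos, v$pos)
    bad <- refbase != v$ref
    if (any(bad)) {
      b <- which(bad)[1L]
      stop("REF mismatch at ", chrom, ":", v$pos[b], " (VCF says ",
           v$ref[b], ", reference has ", refbase[b], ")", call. = FALSE)
    }
    s1 <- strsplit(reference[[chrom]], "")[[1]]
    s2 <- s1
    s1[v$pos] <- v$hap1
    s2[v$pos] <- v$hap2
    g1[[chrom]] <- paste(s1, collapse = "")
    g2[[chrom]] <- paste(s2, collapse = "")
  }
  structure(list(g1 = g1, g2 = g2,
                 provenance = list(n_variants = nrow(variants),
                                   n_het = sum(variants$is_het))),
            class = "personal_genome_pair")
}

#' Round-trip validation of a personal genome pair
#'
#' Re-derives the substituted alleles by comparing G1 and G2 against the
#' reference base by base and checks the recovered set against the input
#' variants. Report-only: discrepancies are listed, not raised.
#'
#' @param pair a [build_personal_genomes()] result.
#' @param reference the reference used to build it.
#' @param variants the variant set used to build it.
#' @return list: `ok` flag, `n_checked`, and a `discrepancies`
#'   data.frame (chrom, pos, kind).
#' @export
validate_round_trip <- function(pair, reference, variants) {
  reference <- toupper(reference)
  disc <- list()
  recovered <- list()
  for (chrom in names(reference)) {
    r <- utf8ToInt(reference[[chrom]])
    a <- utf8ToInt(pair$g1[[chrom]])
    b <- utf8ToInt(pair$g2[[chrom]])
    pos <- which(a != r | b != r)
    if (length(pos))
      recovered[[chrom]] <- data.frame(
        chrom = chrom, pos = pos,
        hap1 = intToUtf8(a[pos], multiple = TRUE),
        hap2 = intToUtf8(b[pos], multiple = TRUE),
        stringsAsFactors = FALSE)
  }
  rec <- if (length(recovered)) do.call(rbind, recovered) else
    data.frame(chrom = character(0), pos = integer(0),
               hap1 = character(0), hap2 = character(0))
  key_in <- paste(variants$chrom, variants$pos, variants$hap1,
                  variants$hap2)
  key_rec <- paste(rec$chrom, rec$pos, rec$hap1, rec$hap2)
  missing <- setdiff(key_in, key_rec)
  # sites where hap1 == hap2 == ref are invisible to recovery; not errors
  silent <- paste(variants$chrom, variants$pos, variants$ref, variants$ref)
  missing <- setdiff(missing, silent)
  extra <- setdiff(key_rec, key_in)
  for (k in missing)
    disc[[length(disc) + 1L]] <- data.frame(key = k, kind = "missing",
                                            stringsAsFactors = FALSE)
  for (k in extra)
    disc[[length(disc) + 1L]] <- data.frame(key = k, kind = "unexpected",
                                            stringsAsFactors = FALSE)
  d <- if (length(disc)) do.call(rbind, disc) else
    data.frame(key = character(0), kind = character(0))
  list(ok = nrow(d) == 0L, n_checked = nrow(variants), discrepancies = d)
}

#' Write a personal genome pair as two FASTA files
#'
#' @param pair a [build_personal_genomes()] result.
#' @param prefix output path prefix; writes `<prefix>_G1.fa` and
#'   `<prefix>_G2.fa` with index sidecars.
#' @return named character vector of the two paths.
#' @export
write_personal_genomes <- function(pair, prefix) {
  p1 <- paste0(prefix, "_G1.fa")
  p2 <- paste0(prefix, "_G2.fa")
  write_fasta(pair$g1, p1, index = TRUE)
  write_fasta(pair$g2, p2, index = TRUE)
  c(G1 = p1, G2 = p2)
}

#' Read a genome FASTA into the plain sequence representation
#'
#' @param path FASTA file.
#' @return named uppercase character vector, one element per sequence.
#' @export
read_genome_fasta <- function(path) {
  ds <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ds))
  names(seqs) <- sub("\\s.*$", "", names(ds))
  seqs
}
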