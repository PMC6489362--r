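#' Default pipeline configuration
#'
#' One flat configuration drives every stage. Stage sections:
#' `simulate` (passed to [simulation_config()]), `align` (k,
#' max_mismatches, min_mean_quality), `count` (min_base_quality, dedup),
#' `test` (min_total, fdr, adjust, pool_marks), `annotate`
#' (ld_threshold, window), `motifs` (delta_min, score_min,
#' expression_floor).
#'
#' @param outdir working directory for all stage outputs.
#' @param seed master seed; flows into the simulator and any stage
#'   randomness.
#' @return nested configuration list.
#' @export
default_pipeline_config <- function(outdir, seed = 1L) {
  list(outdir = outdir, seed = as.integer(seed), log_level = "info",
       simulate = list(),
       align = list(k = 9L, max_mismatches = 3L, min_mean_quality = 20),
       count = list(min_base_quality = 20, dedup = TRUE),
       test = list(min_total = 10L, fdr = 0.05, adjust = "BH",
                   pool_marks = FALSE),
       annotate = list(ld_threshold = 0.8, window = 1e6),
       motifs = list(delta_min = 0.3, score_min = 2.55,
                     expression_floor = 0))
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults of
#' [default_pipeline_config()].
#'
#' @param path YAML file; must contain at least `outdir`.
#' @return configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user$outdir)) stop("config must set outdir", call. = FALSE)
  cfg <- default_pipeline_config(user$outdir, user$seed %||% 1L)
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(cfg[[k]])) {
      for (kk in names(user[[k]])) cfg[[k]][[kk]] <- user[[k]][[kk]]
    } else cfg[[k]] <- user[[k]]
  }
  cfg
}

pipeline_stages <- function() {
  c("simulate", "build-genomes", "align", "count", "test", "annotate",
    "motifs", "report")
}

stage_paths <- function(config) {
  o <- config$outdir
  marks <- do.call(simulation_config,
                   c(list(seed = config$seed), config$simulate))$marks
  list(
    sim = file.path(o, "sim"),
    vcf = file.path(o, "sim", "variants.vcf"),
    reference = file.path(o, "sim", "reference.fa"),
    genomes_prefix = file.path(o, "genomes"),
    g1 = file.path(o, "genomes_G1.fa"),
    g2 = file.path(o, "genomes_G2.fa"),
    skip_report = file.path(o, "vcf_skip_report.tsv"),
    fastq = stats::setNames(file.path(o, "sim",
                                      paste0("reads_", marks, ".fastq")),
                            marks),
    assignments = stats::setNames(
      file.path(o, paste0("assignments_", marks, ".tsv")), marks),
    counts = stats::setNames(file.path(o, paste0("counts_", marks,
                                                 ".tsv")), marks),
    as_prefix = file.path(o, "as_snps"),
    as_tsv = file.path(o, "as_snps.tsv"),
    annotated = file.path(o, "as_snps_annotated.tsv"),
    trait_summary = file.path(o, "trait_summary.tsv"),
    locus_bed = file.path(o, "as_loci.bed"),
    motif_hits = file.path(o, "motif_hits.tsv"),
    report = file.path(o, "report.json"),
    marks = marks)
}

# provenance sidecar: stable digests of config and files (no timestamps,
# so identical reruns give identical sidecars)
write_provenance <- function(stage, config, inputs, outputs) {
  cfg_file <- tempfile()
  writeLines(yaml::as.yaml(config), cfg_file)
  digest_of <- function(paths) {
    paths <- paths[file.exists(paths)]
    as.list(tools::md5sum(paths))
  }
  prov <- list(stage = stage,
               tool = paste0("assnp ", as.character(
                 utils::packageVersion("assnp"))),
               seed = config$seed,
               config_md5 = unname(tools::md5sum(cfg_file)),
               inputs = digest_of(inputs), outputs = digest_of(outputs))
  path <- file.path(config$outdir, paste0("provenance_", stage, ".json"))
  jsonlite::write_json(prov, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

require_inputs <- function(paths, stage_hint) {
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing upstream output(s) ", paste(missing, collapse = ", "),
         "; run stage '", stage_hint, "' first", call. = FALSE)
}

format_num_cols <- function(df, digits = 6) {
  for (col in names(df))
    if (is.double(df[[col]])) df[[col]] <- sprintf("%.*g", digits,
                                                   df[[col]])
  df
}

#' Run one pipeline stage
#'
#' Stages (in order): `simulate`, `build-genomes`, `align`, `count`,
#' `test`, `annotate`, `motifs`, `report`. Every stage reads the outputs
#' of its predecessors from `config$outdir`, writes its own outputs
#' there, and records a provenance sidecar (config hash, seed, input and
#' output digests, tool version). A missing upstream output raises an
#' error naming the stage to run first.
#'
#' @param name stage name.
#' @param config configuration list from
#'   [default_pipeline_config()]/[read_pipeline_config()].
#' @return invisible list of the stage's output paths.
#' @export
run_stage <- function(name, config) {
  name <- match.arg(name, pipeline_stages())
  p <- stage_paths(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  msg("stage ", name)
  out <- switch(
    name,
    "simulate" = {
      sc <- do.call(simulation_config,
                    c(list(seed = config$seed), config$simulate))
      study <- simulate_study(sc, p$sim)
      write_provenance(name, config, character(0),
                       unlist(study$paths, use.names = FALSE))
      study$paths
    },
    "build-genomes" = {
      require_inputs(c(p$vcf, p$reference), "simulate")
      variants <- load_phased_vcf(p$vcf, require_pass = TRUE,
                                  snv_only = TRUE)
      skip <- attr(variants, "skip_report")
      write_tsv(data.frame(reason = names(skip), n = as.integer(skip)),
                p$skip_report)
      reference <- read_genome_fasta(p$reference)
      pair <- build_personal_genomes(reference, variants)
      vr <- validate_round_trip(pair, reference, variants)
      if (!vr$ok) stop("personal genome round-trip failed: ",
                       nrow(vr$discrepancies), " discrepancies")
      paths <- write_personal_genomes(pair, p$genomes_prefix)
      write_provenance(name, config, c(p$vcf, p$reference),
                       c(paths, p$skip_report))
      as.list(paths)
    },
    "align" = {
      require_inputs(c(p$g1, p$g2, p$fastq), "build-genomes")
      pair <- structure(list(g1 = read_genome_fasta(p$g1),
                             g2 = read_genome_fasta(p$g2),
                             provenance = list(n_variants = NA,
                                               n_het = NA)),
                        class = "personal_genome_pair")
      a <- config$align
      indexes <- list(g1 = build_kmer_index(pair$g1, a$k),
                      g2 = build_kmer_index(pair$g2, a$k))
      for (m in p$marks) {
        reads <- read_fastq(p$fastq[[m]])
        al <- align_reads(reads, pair, k = a$k,
                          max_mismatches = a$max_mismatches,
                          min_mean_quality = a$min_mean_quality,
                          indexes = indexes)
        write_tsv(al, p$assignments[[m]])
      }
      write_provenance(name, config, c(p$g1, p$g2, p$fastq),
                       p$assignments)
      as.list(p$assignments)
    },
    "count" = {
      require_inputs(c(p$assignments, p$vcf), "align")
      variants <- load_phased_vcf(p$vcf)
      for (m in p$marks) {
        al <- read_tsv(p$assignments[[m]])
        class(al) <- c("assnp_alignments", "data.frame")
        if (isTRUE(config$count$dedup)) al <- deduplicate(al)
        cts <- count_alleles(al, variants, mark = m,
                             min_base_quality =
                               config$count$min_base_quality)
        write_counts(cts, p$counts[[m]])
      }
      write_provenance(name, config, p$assignments, p$counts)
      as.list(p$counts)
    },
    "test" = {
      require_inputs(p$counts, "count")
      counts <- do.call(rbind, lapply(p$counts, read_tsv))
      t <- config$test
      calls <- call_as_snps(counts, min_total = t$min_total, fdr = t$fdr,
                            adjust = t$adjust,
                            pool_marks = isTRUE(t$pool_marks))
      bl <- file.path(p$sim, "blacklist.bed")
      if (file.exists(bl))
        calls <- filter_regions(calls, list(blacklist = bl))
      paths <- write_as_snps(calls, p$as_prefix)
      write_provenance(name, config, c(p$counts, bl), paths)
      as.list(paths)
    },
    "annotate" = {
      require_inputs(p$as_tsv, "test")
      sites <- read_tsv(p$as_tsv)
      an <- config$annotate
      gwas <- read_tsv(file.path(p$sim, "gwas.tsv"))
      ld <- read_tsv(file.path(p$sim, "ld_pairs.tsv"))
      eqtl <- read_tsv(file.path(p$sim, "eqtl.tsv"))
      proxies <- expand_ld(gwas, ld, threshold = an$ld_threshold)
      sites <- annotate_gwas(sites, gwas, proxies)
      sites <- annotate_eqtl(sites, eqtl)
      write_tsv(format_num_cols(sites), p$annotated)
      ts <- summarize_traits(sites, window = an$window)
      write_tsv(ts, p$trait_summary)
      as_sites <- sites[sites$is_as_snp, , drop = FALSE]
      if (nrow(as_sites)) {
        loci <- cluster_loci(as_sites$chrom, as_sites$pos,
                             window = an$window)
        locus_bed <- do.call(rbind, lapply(split(
          seq_along(loci), loci), function(idx) {
            data.frame(chrom = as_sites$chrom[idx][1],
                       start0 = min(as_sites$pos[idx]) - 1L,
                       end0 = max(as_sites$pos[idx]),
                       label = paste0("locus_", loci[idx][1]),
                       stringsAsFactors = FALSE)
          }))
        write_bed(locus_bed, p$locus_bed)
      } else write_bed(data.frame(chrom = character(0),
                                  start0 = integer(0), end0 = integer(0)),
                      p$locus_bed)
      write_provenance(name, config, p$as_tsv,
                       c(p$annotated, p$trait_summary, p$locus_bed))
      list(annotated = p$annotated, trait_summary = p$trait_summary,
           locus_bed = p$locus_bed)
    },
    "motifs" = {
      require_inputs(c(p$annotated, p$g1, p$g2), "annotate")
      sites <- read_tsv(p$annotated)
      pair <- structure(list(g1 = read_genome_fasta(p$g1),
                             g2 = read_genome_fasta(p$g2),
                             provenance = list(n_variants = NA,
                                               n_het = NA)),
                        class = "personal_genome_pair")
      pwms <- load_pwms(file.path(p$sim, "pwms_synthetic.txt"))
      tracks <- list(dnase = read_bed(file.path(p$sim, "dnase.bed")),
                     tf_chip = read_bed(file.path(p$sim, "tf_chip.bed")),
                     cage = read_bed(file.path(p$sim, "cage.bed")),
                     states = read_bed(file.path(p$sim, "states.bed")),
                     repdomains = read_bed(file.path(p$sim,
                                                     "repdomains.bed")))
      expression <- read_tsv(file.path(p$sim, "tf_expression.tsv"))
      mo <- config$motifs
      hits <- annotate_motif_hits(sites, pwms, pair, tracks, expression,
                                  expression_floor = mo$expression_floor,
                                  delta_min = mo$delta_min,
                                  score_min = mo$score_min)
      write_tsv(format_num_cols(hits), p$motif_hits)
      write_provenance(name, config, p$annotated, p$motif_hits)
      list(motif_hits = p$motif_hits)
    },
    "report" = {
      require_inputs(c(p$annotated, p$motif_hits), "motifs")
      rep <- pipeline_report(config)
      jsonlite::write_json(rep, p$report, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      write_provenance(name, config,
                       c(p$annotated, p$motif_hits), p$report)
      list(report = p$report)
    })
  invisible(out)
}

#' Run the whole pipeline
#'
#' Executes every stage in order. Equivalent to calling [run_stage()]
#' for each stage name; outputs depend only on the configuration and
#' inputs, so reruns are idempotent.
#'
#' @param config configuration list.
#' @return invisible named list of per-stage outputs.
#' @export
run_pipeline <- function(config) {
  out <- list()
  for (s in pipeline_stages()) out[[s]] <- run_stage(s, config)
  invisible(out)
}

#' Summary report over a finished pipeline run
#'
#' Collects stage-level counts (variants loaded, reads assigned, sites
#' tested, AS-SNPs, GWAS/eQTL-linked, candidate motifs), the per-trait
#' summary and the per-TF recurrence table.
#'
#' @param config configuration list of the finished run.
#' @return nested list (also written as JSON by the `report` stage).
#' @export
pipeline_report <- function(config) {
  p <- stage_paths(config)
  sites <- read_tsv(p$annotated)
  hits <- read_tsv(p$motif_hits)
  traits <- read_tsv(p$trait_summary)
  assigned <- lapply(p$assignments, function(f)
    if (file.exists(f)) table(read_tsv(f)$assignment) else NULL)
  as_snps <- sites[sites$is_as_snp, , drop = FALSE]
  list(
    n_variants = length(readLines(p$vcf)) -
      sum(startsWith(readLines(p$vcf), "#")),
    reads_assigned = lapply(assigned, function(t)
      if (is.null(t)) NULL else as.list(t)),
    n_sites_tested = nrow(sites),
    n_as_snps = sum(sites$is_as_snp),
    n_filtered = sum(sites$filtered_reason != "none"),
    n_gwas_linked = sum(as_snps$gwas_link != "unlinked"),
    n_eqtl_linked = sum(nzchar(as_snps$eqtl_genes)),
    n_motif_overlapping = length(unique(paste0(hits$chrom, ":",
                                               hits$pos))),
    n_candidate_functional_motifs = sum(hits$candidate_functional),
    n_candidate_functional_snps = length(unique(paste0(
      hits$chrom, ":", hits$pos)[hits$candidate_functional])),
    trait_summary = traits,
    tf_recurrence = summarize_motifs(hits)$tf)
}
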