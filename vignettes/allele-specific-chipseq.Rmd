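---
title: "Detecting allele-specific ChIP-seq signal in a diploid personal genome"
author: "assnp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting allele-specific ChIP-seq signal in a diploid personal genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assnp)
```

## The model

At a heterozygous SNV in one individual, ChIP-seq fragments for a
transcription factor or histone mark are sampled from the two
chromosome copies. Write $n$ for the number of reads that cover the
site, pass the quality screens and unambiguously support one of the two
alleles, and $k$ for those supporting the haplotype-1 allele. Under the
null hypothesis of no allelic preference,

$$K \sim \mathrm{Binomial}(n, \tfrac12),$$

and the evidence against it is the exact two-sided p-value
$p = \min\{1,\, 2\min(P(K \le k),\, P(K \ge k))\}$ computed by tail
summation. The null proportion is exactly $1/2$ — not an empirically
estimated reference/alternative ratio — because reads are aligned to
*both* personal genomes (the reference with each phased haplotype's
alleles substituted in) and assigned to the haplotype they match
better. This construction removes reference bias: at every substituted
position, each haplotype is represented by its own genome, so neither
allele is privileged during alignment.

Sites are tested per mark when $n \ge$ `min_total` (default 10);
within each mark, p-values are adjusted across all tested sites by the
Benjamini–Hochberg step-up (the genome-wide correction), and a site is
an AS-SNP when $q \le$ `fdr` (default 0.05) for at least one mark. The
catalog is the union over marks, unique by position. Calls falling in
exclusion tracks (signal-artifact blacklists, centromere/telomere
regions) are removed afterwards: a 1-based site $x$ is excluded iff
$x - 1$ lies in a 0-based half-open BED interval.

Alternatives are available by configuration: Bonferroni instead of BH,
and pooling the marks before correction instead of per-mark
adjustment. Per-mark BH is the default because the three marks have
very different signal distributions and testable-site sets, and the
union-of-marks definition treats each mark as its own genome-wide
family.

### Assumptions and known limitations

* Reads are independent given the haplotype — no overdispersion. A
  beta-binomial would absorb extra-binomial variance from PCR or
  copy-number changes; it is deliberately out of scope, so q-values on
  real, heavily duplicated libraries will be anticonservative unless
  duplicates are removed (the default).
* Counting is per site; nearby heterozygous SNVs on one haplotype are
  not aggregated into haplotype-level evidence.
* The null assumes equal copy number of the two haplotypes.

## The aligner

The internal aligner is deliberately minimal: ungapped placement with
Hamming scoring, because after substitution the personal genomes differ
from the reads only by SNVs and sequencing errors at desk scale.
Candidate loci come from exact k-mer seeds taken at every read offset
and looked up in forward-strand indexes of both genomes (the reverse
complement of the read is queried for minus-strand placements). Each
candidate is scored against both genomes at the same position; a read
is assigned G1 or G2 by comparing the per-genome minima, TIE when
equal, and UNMAPPED when both exceed `max_mismatches` (default 3) or
when several equally good loci exist within one genome — the latter
mirrors the blacklist-era caution about duplicated regions.

The seed length default is $k = 9$: for a 36-base read with $e$
mismatches, the longest mismatch-free run has at least
$\lceil (36 - e)/(e + 1) \rceil$ bases (pigeonhole), which is $9$ at
$e = 3$; dense seeding at every offset therefore guarantees that every
placement within `max_mismatches` is found, and the aligner is exactly
equivalent to a brute-force all-positions scan. A longer seed would be
faster but loses this guarantee for multi-error reads.

Reads whose *mean* base quality is below 20 are discarded before
alignment. The Phred-20 screen is a standard read-quality cutoff; mean
(rather than per-base) is chosen and configurable, and a separate
per-base Phred-20 floor is applied to the allele-bearing base during
counting. Ties carry no allelic evidence and are excluded from counts;
reads whose base at the SNP matches neither allele are tallied as
`count_other` so sequencing error cannot masquerade as allelic signal.
Externally produced per-genome SAM alignments can be imported instead,
taking mismatch counts from the edit-distance tag.

## Annotation layers

**GWAS and LD.** AS-SNPs are connected to trait associations directly
(same position) or through linkage disequilibrium proxies with
$r^2 > 0.8$, strict inequality. $r^2$ is computed from two-site
haplotype class counts, $D = p_{AB} - p_A p_B$,
$r^2 = D^2 / (p_A(1-p_A)p_B(1-p_B))$, either from a precomputed pair
table or directly from a phased haplotype panel; both paths share the
same function, which is test-verified against the squared Pearson
correlation of the haplotype indicator vectors.

**Loci.** AS-SNPs within 1 Mb are chained into loci by single linkage:
consecutive sorted positions on one chromosome join one locus iff
their gap is at most the window. Chaining, not fixed binning, because
the locus notion is about SNP proximity and chaining is invariant to
the input order and to bin phase; fixed bins are available as a
configuration for sensitivity analysis.

**eQTL.** Sites are linked to the target genes of expression
associations at the same position; the per-site gene list is the union
over associations.

**Motifs.** PWM placements are scored as summed $\log_2$ odds against
a uniform background and normalized to $[0, 1]$ between the worst and
best attainable raw scores of that PWM. A bounded scale makes the
disruption threshold of 0.3 portable across motifs of different length
and information content, which an unbounded log-odds change would not
be. Each allele's score at a SNP is its best normalized score over all
placements and strands overlapping the site (an allele may shift the
optimal register); the allelic score change is the absolute difference
of the two bests. A hit is *candidate functional* iff DNase signal
overlaps the placement AND the TF is expressed AND the change is
$\ge 0.3$ AND (a TF ChIP peak overlaps OR the functionality score is
$\ge 2.55$, inclusive). The functionality score is a weighted sum of
tissue annotations; the shipped weights (binary annotations 1.0,
active chromatin states 1.0, quiescent 0, replication domains 0.25)
are explicit stand-ins that make the 2.55 threshold exercisable — they
are not trained weights, and analyses of real data should supply their
own.

## The synthetic study generator

`simulate_study()` emulates the study design end to end: a uniform
random reference (two chromosomes of 50 kb by default), phased SNVs at
a mean spacing of 60 bp (about 80% heterozygous, 5% non-PASS to
exercise VCF filtering), non-overlapping ChIP peaks for CTCF, H3K4me3
and H3K27ac, planted allele-specific sites, annotation tracks, a GWAS
catalog extract with an exactly-realized LD panel, an eQTL table,
synthetic PWMs and a ground-truth manifest. Every output file draws
from its own RNG substream of the master seed, so outputs are
byte-identical across runs and adding a mark does not perturb the
other files; ordering everywhere uses locale-independent comparisons
so the bytes do not depend on the session locale.

Design choices that matter for interpretation:

* **Fragments carry one whole haplotype.** A fragment in an AS peak is
  drawn from haplotype 1 with probability `as_ratio` (default 0.8) and
  its sequence is lifted intact from that haplotype genome, preserving
  phase across every heterozygous site it covers — as in real
  chromatin. The consequence is that *all* het sites inside an AS peak
  share the peak's imbalance; the manifest records the designated site
  per peak (`as_sites`, with the realized read counts), its imbalanced
  neighbours (`linked_het_sites`), and the balanced-peak sites
  (`null_het_sites`). Tests of calibration use balanced peaks or the
  count-level path only.
* **Planted sites sit away from peak edges** (at least one read length
  inside), where single-end coverage from fragment 5' ends is highest —
  the summit-proximal placement typical of causal regulatory SNPs.
* **Reads are 36-base single-end** from 60-base fragments at ~300
  fragments per peak, giving roughly 40–70 informative reads at a
  planted site. Paired-end adds nothing to the counting logic at this
  scale.
* **Base qualities are constant Q30 with injected errors at Q10**, so
  the Phred-20 base filter has a deterministic effect.
* **The LD panel realizes planted $r^2$ exactly**: at allele frequency
  0.5, haplotype class counts $n(1/4 \pm D)$ with $D = \sqrt{r^2}/4$
  chosen on the panel's integer grid (200 haplotypes), so recomputing
  $r^2$ from the emitted panel reproduces the manifest value to
  numerical precision. Planted values straddle the 0.8 threshold
  (1.0, 0.9216, 0.81 above; 0.36, 0.16 below) to test the strict
  inequality.
* **Planted motif contexts are deterministic.** The consensus of a
  synthetic PWM is embedded at the site with haplotype 1 carrying the
  consensus base and haplotype 2 the worst base at the motif's most
  informative position, inside a flank of the motif's overall
  worst-scoring base. The anti-consensus flank prevents the disrupted
  allele from recovering a high score in a shifted register, so the
  planted normalized score change is a deterministic value above 0.3
  (0.319–0.370 for the shipped matrices). The shipped PWMs have one
  dominant position (97:1:1:1 counts) and moderately informative
  flanking positions (70:10:10:10); they are synthetic and labelled as
  such.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: mappability structure and repeats (the
reference is uniform random, so the blacklist is planted rather than
emergent), overdispersion and PCR duplication families, indels and
structural variants, GC and fragment-length biases, linked-read
phasing errors, and genuinely trained functionality weights.

## Numerical choices

* Exact binomial tails via `pbinom`, not a normal approximation; the
  test is symmetric in $k \mapsto n-k$ and capped at 1.
* BH is implemented as the textbook step-up (cross-checked against
  `p.adjust`); `NA` p-values pass through without counting toward the
  family size.
* Degenerate inputs: $n = 0$ sites are untestable and skipped; an
  empty p-value vector adjusts to an empty vector; a monomorphic site
  makes $r^2$ undefined and returns `NA` with a warning rather than a
  number; an empty blacklist filters nothing; duplicate variant
  positions and reference-base mismatches are hard errors in genome
  construction (silent overwrites would corrupt counts downstream).
* Normalized PWM scores are exactly 1 on the consensus and exactly 0
  on the anti-consensus; placements containing an ambiguous base are
  skipped.
* Homozygous-alternative variants are substituted into both personal
  genomes (so alignment sees the individual's sequence) but only
  heterozygous sites are ever tested.
* Dedup keeps, per (chromosome, start, strand), the read with the
  highest mean base quality, ties broken by read id under
  locale-independent ordering.

## Problem sizes used by the tests

The checks run at sizes chosen to give tight statistical expectations
while remaining quick on one CPU: the oracle equivalences use 2–3 kb
genomes where an all-positions scan is exact and affordable; the FDR
calibration uses 100 replicate seeds of 2000 balanced sites at coverage
30 (200,000 null tests); power recovery uses 300 planted sites at
coverage 50 against 2000 nulls, compared to the exact binomial power at
the realized BH threshold within three standard errors; and the frozen
end-to-end run uses the default two-chromosome, 50 kb study with about
9000 reads. The binomial test is verified against full enumeration for
every $(k, n)$ with $n \le 20$.

## Command-line use

All stages run from R (`run_stage()`, `run_pipeline()`) or from the
thin wrapper `inst/scripts/assnp-pipeline.R` with a single YAML
configuration; every stage writes a provenance sidecar with the config
hash and input/output digests, and reruns are idempotent.
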