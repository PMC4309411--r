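---
title: "Methods: compartment calling, diversity, duplication and the synthetic genome"
author: "pericompart"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compartment calling, diversity, duplication and the synthetic genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pericompart)
```

## The problem

Cereal genomes carry a large pericentromeric compartment in which meiotic
recombination is strongly suppressed. Because recombination is what lets
selection act on individual genes rather than on whole linked blocks
(Hill–Robertson interference), genes resident in that compartment are
expected to show reduced nucleotide diversity, weakened purifying selection
(elevated πa/πs), reduced tandem duplication (which requires unequal
crossing over), and — over tens of millions of years — biased loss of
whole-genome-duplication (WGD) gene pairs. Gene *expression*, by contrast,
need not be affected at all.

`pericompart` implements the full computational chain to test these
predictions on a mapped gene set: compartment calling from a Marey-style
map, π/πa/πs estimation from cDNA-mapped SNP panels of inbred lines,
expression-level and specificity comparisons, WGD ohnolog-pair detection by
collinearity chaining with NG86 Ka/Ks, and local-duplicate calling. A
deterministic simulator generates genomes with all of this structure
planted, so every stage is testable without external data.

## Compartment calling

The input is a gene map: genetic position (cM) against physical position
(bp) for every mapped gene. Processing steps:

1. **Map cleaning** (`clean_genetic_map`): genetic positions are made
   non-decreasing within each chromosome by isotonic clamping
   (cM~i~ := max(cM~i~, cM~i−1~)). Mapping error produces small local
   inversions that would otherwise create negative rates; the number of
   clamped genes is reported so gross map problems are visible.
2. **Windowed rate** (`windowed_rate`): the per-gene recombination rate is
   the cM gained across a centered window of *W* gene intervals divided by
   the intervals spanned, in **cM per gene**. The rate is deliberately per
   gene, not per Mbp: assembly gaps and repeat expansions make physical
   denominators unstable in repeat-rich pericentromeres, while gene-order
   scans match how the per-gene diversity statistics are plotted. The
   default *W* = 50 genes follows the package's rolling-average convention
   throughout; it is a parameter, not a claim about any particular dataset.
3. **Region calling** (`call_lr_regions`): maximal runs of genes with rate
   ≤ (chromosome mean)/`fold` (default 20; a gene exactly at the threshold
   is inside — a deterministic tie rule), merged across high-rate blips
   shorter than `gap_genes` (default 25 = *W*/2), and retained only when
   the physical span exceeds `min_frac` (default 2%) of the chromosome
   length. Chromosome length defaults to the maximum mapped position.
4. **Labelling** (`assign_compartments`): the region containing the
   supplied centromere is the LR-PC region; other retained regions are LR
   flanks; everything else is HR. Two-class analyses pool LR-PC and
   LR-flank as "LR". Labels always partition the mapped gene set.

Boundary resolution is limited by the window: a centered window of *W*
genes cannot localize a rate change more finely than about *W*/2 genes, so
planted-boundary recovery is asserted at that resolution.

## Diversity estimation

The sampled lines are inbred, so each line contributes a single consensus
haplotype: a sample's genotype at a site is its majority allele, a
ref/alt read tie or zero coverage is missing, and per-site sample size
varies accordingly.

* **Filtering** (`filter_variants`): a site is kept iff the minor allele's
  sample-level frequency is ≥ `maf_min` (default 0.1) *and* the minor
  allele has ≥ `min_reads` (default 3) supporting reads in at least one
  sample. Frequency over pooled reads instead of samples is available as a
  switch (`maf_basis = "reads"`); sample-level is the default because the
  panel's per-line coverage is very uneven.
* **ORFs** (`find_orf`): the longest ATG-initiated open reading frame on
  the given strand (cDNAs are oriented), running to the first in-frame stop
  or to the 3′ end truncated at a codon boundary; ties break to the
  smaller start. Genes whose ORF is shorter than 30 codons are excluded
  from coding statistics — micro-ORFs in UTR-like sequence would otherwise
  contribute meaningless πa/πs values.
* **Effect classification** (`classify_snp`): the alternative allele is
  substituted into the reference codon with the other two positions held at
  reference, and amino acids compared under the standard genetic code
  (stop is a 21st symbol). Codons carrying two SNPs have each SNP
  classified independently against the reference codon.
* **π** (`site_pi`, `gene_diversity`): per-site unbiased heterozygosity
  (n/(n−1))(1−Σp²) — the mean pairwise difference among the sampled
  alleles — summed over sites and divided by covered positions. πs and πa
  divide the synonymous and nonsynonymous site sums by fractional NG86
  site counts computed once on the reference ORF (each codon position
  contributes the fraction of its three possible changes that are
  synonymous). Reference-anchored site counts are deterministic;
  sample-averaged counts would change results by well under the noise at
  these diversities. Coverage defaults to every reference position; a
  narrower denominator can be supplied where a real coverage mask exists.

**Aggregation.** A per-gene πa/πs ratio with a handful of SNPs per gene is
a noisy ratio estimator whose mean is biased upward (small-denominator
genes dominate). The compartment-level summary
(`compartment_diversity_summary`) therefore reports the **ratio of
compartment means** (mean πa / mean πs) as the primary aggregate — it is
consistent for the generating ratio — alongside the mean of per-gene
ratios and a two-sample t-test on the per-gene ratios for the
compartment contrast.

## Expression

`summarize_expression` computes each gene's mean level across conditions,
its sample standard deviation, and the specificity quotient mean/sd — the
inverse coefficient of variation, following the quotient definition used
for developmental-specificity scans. Constant genes (sd = 0) have
undefined specificity and are excluded from tests, not imputed.
`compare_compartments` runs one-way ANOVA (HR vs LR) on level and
specificity, genome-wide, per chromosome, and optionally per condition;
for two groups F equals the squared equal-variance t statistic. No log
transform is applied by default; the comparisons are of a null (no
compartment effect), and simulations calibrate the nominal type-I rate.

## WGD ohnologs and local duplicates

Starting from an all-vs-all similarity table (12-column tabular dialect):

1. `best_nonself_hits`: self-hits dropped, best HSP per subject, the best
   non-self subject per query (ties by e-value then subject id);
   `canonical_pairs` stores each unordered pair once.
2. `filter_paralog_pairs`: pairs too similar to be WGD-derived (bit score
   > 8000, or 100% identity over > 200 bp) and pairs too weak to be
   reliable (bit < 300 **and** alignment < 500 bp) are removed.
3. `reorder_by_reference` (optional): where an outgroup genome's gene
   order is available as anchors within synteny blocks, genes are
   reordered by reference order within blocks (anchor-density filter at
   400 reference genes), and `remove_map_outliers` drops genes whose cM
   position deviates from a running median by more than 5 running MADs
   (window 51; a zero MAD removes nothing).
4. `detect_collinear_regions`: dynamic-programming chaining — a chain is
   strictly increasing in one chromosome's gene index, strictly monotone
   in the other's, with at most `max_gap` (default 25) intervening genes
   between consecutive members on either chromosome. Chains are extracted
   greedily by pair count; each pair joins one region; regions need
   ≥ `min_pairs` (default 9) pairs. This replaces external collinearity
   tools and any manual curation of dot plots; an exhaustive
   chain-enumeration oracle verifies optimality on small instances.
5. `ng86_ka_ks`: Nei–Gojobori counting with Jukes–Cantor correction.
   Fractional S/N sites averaged over the two sequences; observed
   differences averaged over all equally weighted shortest pathways within
   each codon (steps through stops counted like any other, stop as a 21st
   amino acid); p ≥ 3/4 saturates to an undefined rate and flags the pair.
   The full maximum-likelihood counting of codon-model tools is out of
   scope: for the one decision Ks feeds here (a Ks ≤ 3 ceiling), pairs
   beyond NG86's validity are saturated under any method.
6. `trim_ohnolog_pairs`, in order, with per-rule counts: Ks > 3 (or
   saturated); genes in more than one pair (all such pairs removed —
   pair-level removal is the conservative, deterministic reading);
   regions left with fewer than `min_pairs` pairs; and where two regions
   overlap in gene-index span on either chromosome, the weaker region
   (fewer pairs; ties to lower mean Ks, then region id).

`call_local_duplicates` implements the second-best-hit rule: the best
same-chromosome non-self hit per query is a **local duplicate** when the
physical distance is at most 2% of the chromosome length (the rule is
"remote by *more than* 2%", so exactly 2% is local) and an
intrachromosomal translocation otherwise.

`ohnolog_compartment_tables` and `local_dup_table` produce the
observed/expected report tables. Expected ohnolog gene counts come from
genome-wide compartment fractions; expected pair classes from
n(p², 2pq, q²) with q the LR gene fraction. The 2×2 depletion test is a
Yates-corrected chi-squared on {locally duplicated genes, all mapped
genes} × {HR, LR} — deliberately *overlapping* categories, because that is
the construction whose p-values match observed/expected depletion tables
of this kind; the disjoint duplicated-vs-not construction is available via
`mode = "disjoint"`.

## The synthetic genome

`sim_config` fixes the emulated study conditions: 14 inbred haplotypes;
two chromosomes of 1000 genes with a central suppressed segment holding
25% of genes; target πs = 0.01 with compartment πa/πs of 0.235 (LR) and
0.170 (HR); WGD pair survival 0.75 / 0.5 / 0 for HR–HR / LR–HR / LR–LR;
tandem duplication probability proportional to the local cM increment;
15 tissues with expression i.i.d. across compartments. One integer seed
determines every output (R's Mersenne–Twister, with fixed sub-seed offsets
per stage so adding a stage never perturbs earlier streams).

Choices worth explaining:

* **Planted suppression is 50-fold** while the *caller's* threshold is
  20-fold-of-average. With a quarter of genes suppressed, the suppressed
  plateau itself lowers the chromosome average; algebraically the planted
  factor must exceed ~26 for the plateau to sit below average/20 at all.
  Real pericentromeres suppress recombination far more strongly than
  20-fold, and 50 leaves the threshold comfortably between the two rates.
* **SNP placement** uses the package's own classifier to select synonymous
  and nonsynonymous positions — deliberate circularity that makes
  estimator recovery exact in expectation; the classifier itself is
  cross-checked against an independent 576-entry genetic-code table, which
  breaks the circle. True SNPs get derived-allele counts uniform on
  2..n−2 (all pass the MAF filter); per-class SNP counts are Poisson with
  mean target·sites/E[site π]. Planted error sites are singletons with at
  most two supporting reads, constructed to fail both filter rules.
* **WGD divergence** plants exactly round(JC(Ks)·S) synonymous and
  round(JC(Ka)·N) nonsynonymous single differences on disjoint codons, so
  pathway counting is unambiguous and the corrected estimate inverts back
  to the target; Ks targets ≥ 3 cannot be represented by counts within the
  correction's range and are realized as fully synonymous-diverged
  (saturated) pairs. Decoys exercise every filter: anciently diverged
  pairs (Ks 6–10) for the Ks ceiling, 100%-identity hits for the
  recent-duplicate rule, short weak hits for the bit/length rule, and
  transposed paralogs that fail chaining.
* **Bit scores** follow a declared monotone formula
  2·len·(id/100)·(1 − 0.9·(1 − id/100)) — not a BLAST emulation — so
  filter behaviour is deterministic and documented.

What the simulator does **not** reproduce: linkage disequilibrium and
coalescent genealogies within genes, read-level errors (FASTQ simulation),
alignment uncertainty and indels in paralog pairs, and the real genome's
gene-density gradients. Passing tests therefore show that the estimators
and calling rules are correct under the assumed sampling model, not that
the model captures every property of real panels.

## Numerical conventions and degenerate inputs

All coordinates are 1-based; intervals closed; physical bp and cM are
never converted inside readers. Ties: a gene exactly at the rate threshold
is low-recombining; a hit at exactly the 2% distance is local; equal bit
scores break by e-value then id. Degenerate inputs have defined behaviour:
monomorphic sites have π = 0, sites with n < 2 are excluded, πa/πs is
undefined when πs = 0, a zero running MAD removes no outliers, zero
covered positions is an error, saturated NG86 pairs are flagged rather
than extrapolated, and identical groups give t = 0/F = 0 with p = 1.

## Problem sizes used in validation

The validation suite uses: the full 2000-gene, 14-haplotype panel
(3 replicates) for πa/πs recovery at ±0.03; 50–100 single-chromosome maps
for boundary recovery at *W*/2; 500 random instances (≤ 15 pairs) for
chaining optimality against exhaustive enumeration; two full WGD genomes
for precision/recall; and 200 null expression replicates for ANOVA
calibration. These sizes were chosen as the smallest that make the
binomial pass criteria meaningful.

## Limitations

* NG86 underestimates Ks relative to codon-model ML when transition/
  transversion bias is strong; here Ks feeds only a ≤ 3 ceiling.
* The chaining score is pair count, not alignment score; very gene-poor
  collinear regions below `min_pairs` are invisible by design.
* The expression module tests mean and mean/sd only; distribution-shape
  differences between compartments would need different statistics.
* With overlapping-category chi-squared tables, cell counts are not
  independent; the construction is retained because it is the reporting
  convention the tables follow, and the disjoint variant is one argument
  away.
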