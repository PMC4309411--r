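# pericompart

Partition a genome into its low-recombining pericentromeric (LR-PC) and
high-recombining (HR) compartments from a Marey-style gene map (genetic cM
vs physical bp per gene), and quantify what compartment residency does to
gene evolution:

* **nucleotide diversity** — per-gene π, πa, πs from cDNA-mapped SNP
  panels of inbred lines, with genome-scan rolling averages;
* **selection efficacy** — the πa/πs contrast between compartments
  (Hill–Robertson interference predicts elevated πa/πs where
  recombination is suppressed);
* **expression** — mean level and developmental specificity (mean/sd),
  compared between compartments by one-way ANOVA;
* **whole-genome-duplication ohnologs** — paralog pairs retained from an
  ancient WGD, detected by best-hit reduction, similarity filtering,
  reference-order correction, dynamic-programming collinearity chaining,
  Nei–Gojobori (1986) Ka/Ks with Jukes–Cantor correction, and
  Ks/uniqueness/region trimming, then classified HR–HR / LR–HR / LR–LR
  against observed-vs-expected counts;
* **local (tandem) duplicates** — the best same-chromosome second hit,
  split at 2% of chromosome length into local duplicates vs
  intrachromosomal translocations, with a Yates-corrected chi-squared
  depletion table per chromosome.

It is aimed at plant comparative genomicists working with mapped gene sets
in large-genome cereals, where the pericentromeric compartment holds a
substantial fraction of all genes. A deterministic synthetic-data
generator (`sim_config()`, `simulate_*()`) emulates an inbreeding cereal
genome — planted suppression segment, 14-haplotype coding panel with
compartment-specific πa/πs, WGD blocks with class-dependent pair survival,
recombination-proportional tandem duplication, compartment-independent
expression — so the whole pipeline runs and is tested without any external
data.

## The statistics at the core

* Per-site diversity: the unbiased estimator
  π = (n/(n−1))(1 − Σᵢ pᵢ²) on the n sampled haploid alleles, i.e. the
  mean pairwise difference. πs and πa divide site sums by fractional NG86
  synonymous/nonsynonymous site counts from the reference ORF.
* Divergence: NG86 counting, ps = Sd/S and pn = Nd/N over all shortest
  within-codon pathways, corrected K = −¾ ln(1 − 4p/3).
* Compartment tables: expected ohnolog genes from compartment gene
  fractions; expected pair classes n(p², 2pq, q²) with q the LR gene
  fraction; depletion tested by χ² = Σ(|O−E|−½)²/E on the 2×2 table, df 1.

## Worked example

Simulate a two-chromosome genome, call compartments, and measure the
diversity and ohnolog consequences:

```r
library(pericompart)

cfg <- sim_config(seed = 42, n_chromosomes = 2, genes_per_chromosome = 600)
sim <- simulate_genome_map(cfg)

map     <- clean_genetic_map(sim$map)
prof    <- windowed_rate(map, window = 50)
regions <- call_lr_regions(prof, fold = 20, min_frac = 0.02)
regions
#>    region_id chromosome start_bp   end_bp start_index end_index n_genes
#> 1 LR_chr01_1      chr01 28288742 39787045         250       350     101
#> 2 LR_chr02_1      chr02 27290190 37780149         249       352     104

ann <- assign_compartments(map, regions, sim$centromeres)
table(ann$label)
#>       HR LR_flank    LR_PC
#>      995        0      205
```

Each chromosome yields one called region containing the centromere
(`LR_PC`); with a 50-gene window the boundaries land within ~25 genes of
the planted segment. Diversity over the simulated 14-line coding panel:

```r
panel <- simulate_coding_panel(cfg, sim$map, sim$labels)
div <- estimate_diversity(Biostrings::DNAStringSet(panel$refs),
                          panel$variants)
cs <- compartment_diversity_summary(div, ann)
cs$LR$ratio_of_means; cs$HR$ratio_of_means
#> [1] 0.2636349
#> [1] 0.1733959
cs$t_test_lr_vs_hr
#> t = 4.797, df = 1182, p = 1.817e-06
```

LR genes show the elevated πa/πs (weakened purifying selection) the
compartment model predicts. Ohnolog pairs, classified by compartment:

```r
w   <- simulate_wgd(cfg, sim$map, sim$labels)
ohn <- find_ohnologs(w$hits, map_ordering(map), w$cds)
tb  <- ohnolog_compartment_tables(ohn$pairs, ann)
tb$pair_classes
#>   class observed   expected
#> 1 HR-HR      254 200.755069
#> 2 LR-HR       38  82.723194
#> 3 LR-LR        0   8.521736
tb$pair_classes_test
#> chi2 = 46.82, df = 2, p = 6.802e-11
```

No LR–LR pair survives where about nine were expected — the generator's
zero LR–LR survival, recovered by the detection chain end to end.
`run_pipeline(out_dir, cfg)` wires all stages together and writes the
fixture files, result tables and a JSON manifest;
`reproduce_tables()` recomputes every derived column of the packaged
observed-count report tables (expected counts, percent-LR ratios, Yates
p-values, the overall depletion percentage).

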