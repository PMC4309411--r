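test_that("every generator output is a pure function of the seed", {
  cfg <- sim_config(seed = 17, n_chromosomes = 2,
                    genes_per_chromosome = 80, orf_codons = c(40, 60))
  a <- simulate_genome_map(cfg)
  b <- simulate_genome_map(cfg)
  expect_identical(a, b)
  pa <- simulate_coding_panel(cfg, a$map, a$labels)
  pb <- simulate_coding_panel(cfg, a$map, a$labels)
  expect_identical(pa, pb)
  wa <- simulate_wgd(cfg, a$map, a$labels)
  wb <- simulate_wgd(cfg, a$map, a$labels)
  expect_identical(wa, wb)
  ta <- simulate_tandem_and_expression(cfg, a$map, a$labels)
  tb <- simulate_tandem_and_expression(cfg, a$map, a$labels)
  expect_identical(ta, tb)
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(pc_fraction = 1.2), "pc_fraction")
  expect_error(sim_config(wgd_pair_survival = c(HR_HR = 1.5, LR_HR = 0.5,
                                                LR_LR = 0)),
               "probabilities")
})

test_that("no planted suppression means no called LR regions", {
  cfg <- sim_config(seed = 31, n_chromosomes = 1,
                    genes_per_chromosome = 600, suppression_fold = 1)
  sim <- simulate_genome_map(cfg)
  prof <- windowed_rate(clean_genetic_map(sim$map), 50)
  expect_equal(nrow(call_lr_regions(prof)), 0L)
})

test_that("generated files parse through the package readers unchanged", {
  cfg <- sim_config(seed = 19, n_chromosomes = 2,
                    genes_per_chromosome = 60, orf_codons = c(40, 60))
  sim <- simulate_genome_map(cfg)
  panel <- simulate_coding_panel(cfg, sim$map, sim$labels)
  wgd <- simulate_wgd(cfg, sim$map, sim$labels)
  dir <- withr::local_tempdir()
  write_gene_map(sim$map, file.path(dir, "map.tsv"))
  expect_equal(read_gene_map(file.path(dir, "map.tsv")), sim$map)
  write_cdna_fasta(panel$refs, file.path(dir, "c.fasta"))
  back <- read_cdna_fasta(file.path(dir, "c.fasta"))
  expect_equal(as.character(back), panel$refs)
  write_variant_vcf(panel$variants, file.path(dir, "v.vcf"))
  vt <- read_variant_table(file.path(dir, "v.vcf"))
  expect_equal(vt$n_skipped, 0L)
  expect_equal(vt$sites, panel$variants$sites)
  write_similarity_table(wgd$hits, file.path(dir, "h.tsv"))
  h <- read_similarity_table(file.path(dir, "h.tsv"))
  expect_equal(nrow(h), nrow(wgd$hits))
})

test_that("planted sequencing-error sites are all removed by filtering", {
  cfg <- sim_config(seed = 23, n_chromosomes = 1,
                    genes_per_chromosome = 150, error_site_rate = 0.5)
  sim <- simulate_genome_map(cfg)
  panel <- simulate_coding_panel(cfg, sim$map, sim$labels)
  err <- panel$truth_sites[panel$truth_sites$class == "error", ]
  expect_gt(nrow(err), 20)  # enough decoys to make the check meaningful
  kept <- filter_variants(panel$variants)
  key <- function(df) paste(df$ref_id, df$pos)
  expect_length(intersect(key(kept$sites), key(err)), 0L)
})

test_that("zero WGD survival yields an empty ohnolog set", {
  cfg <- sim_config(seed = 29, n_chromosomes = 2,
                    genes_per_chromosome = 200,
                    wgd_pair_survival = c(HR_HR = 0, LR_HR = 0, LR_LR = 0),
                    old_decoy_rate = 0)
  sim <- simulate_genome_map(cfg)
  w <- simulate_wgd(cfg, sim$map, sim$labels)
  expect_equal(nrow(w$truth_pairs), 0L)
  ohn <- find_ohnologs(w$hits, map_ordering(sim$map), w$cds)
  expect_equal(nrow(ohn$pairs), 0L)
})

test_that("zero tandem rate yields no local duplicates", {
  cfg <- sim_config(seed = 37, n_chromosomes = 1,
                    genes_per_chromosome = 150, tandem_rate_per_cM = 0)
  sim <- simulate_genome_map(cfg)
  tex <- simulate_tandem_and_expression(cfg, sim$map, sim$labels)
  expect_equal(nrow(tex$truth_tandem), 0L)
  ld <- call_local_duplicates(tex$hits, tex$map_with_dups)
  expect_length(ld$duplicated_genes, 0L)
})
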