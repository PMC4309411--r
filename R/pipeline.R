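# End-to-end wiring: simulate (or read) inputs, call compartments, run the
# diversity / expression / duplication analyses and emit the
# observed-vs-expected report tables, with a manifest for reproducibility.

#' Run the full compartment analysis pipeline on simulated inputs
#'
#' Generates a synthetic dataset from \code{config}, writes the fixture
#' files, reads them back through the package's own readers, and runs every
#' stage: region calling, compartment labels, diversity, expression
#' comparison, ohnolog detection and local-duplicate calling, ending with
#' the compartment report tables. A JSON manifest (parameters, seed, input
#' checksums, package version) is written next to the outputs.
#'
#' @param out_dir output directory (created if missing).
#' @param config a \code{sim_config}.
#' @param window,fold,min_frac region-calling parameters.
#' @param min_pairs,max_gap,ks_max ohnolog parameters.
#' @param frac local-duplicate distance cutoff.
#' @return invisibly, a list with all stage results.
#' @export
run_pipeline <- function(out_dir, config = sim_config(), window = 50,
                         fold = 20, min_frac = 0.02, min_pairs = 9,
                         max_gap = 25, ks_max = 3, frac = 0.02) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genome_map(config)
  panel <- simulate_coding_panel(config, sim$map, sim$labels)
  wgd <- simulate_wgd(config, sim$map, sim$labels)
  tex <- simulate_tandem_and_expression(config, sim$map, sim$labels)

  paths <- list(
    map = file.path(out_dir, "map.tsv"),
    cen = file.path(out_dir, "cen.tsv"),
    cdnas = file.path(out_dir, "cdnas.fasta"),
    calls = file.path(out_dir, "calls.vcf"),
    allvsall = file.path(out_dir, "allvsall.tsv"),
    expr = file.path(out_dir, "expr.tsv")
  )
  write_gene_map(sim$map, paths$map)
  write.table(sim$centromeres, paths$cen, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_cdna_fasta(panel$refs, paths$cdnas)
  write_variant_vcf(panel$variants, paths$calls)
  write_similarity_table(rbind(wgd$hits, tex$hits), paths$allvsall)
  write_expression_matrix(tex$expression, paths$expr)

  map <- clean_genetic_map(read_gene_map(paths$map))
  cen <- read_centromeres(paths$cen)
  refs <- read_cdna_fasta(paths$cdnas)
  vt <- read_variant_table(paths$calls)
  hits <- read_similarity_table(paths$allvsall)
  expr <- read_expression_matrix(paths$expr)

  prof <- windowed_rate(map, window = window)
  regions <- call_lr_regions(prof, fold = fold, min_frac = min_frac)
  ann <- assign_compartments(map, regions, cen)
  write_regions_bed(cbind(regions, label = "LR"),
                    file.path(out_dir, "regions.bed"))

  div <- estimate_diversity(refs, vt)
  div_summary <- compartment_diversity_summary(div, ann)

  es <- summarize_expression(expr)
  expr_tests <- compare_compartments(es, ann)

  ohn <- find_ohnologs(hits, map_ordering(map), wgd$cds,
                       min_pairs = min_pairs, max_gap = max_gap,
                       ks_max = ks_max)
  ohn_tables <- ohnolog_compartment_tables(ohn$pairs, ann)

  # local duplicates on the duplication-bearing map
  map_d <- tex$map_with_dups
  ann_d_lab <- ifelse(map_d$gene_id %in% ann$gene_id[ann$label != "HR"] |
                        sub("_d$", "", map_d$gene_id) %in%
                        ann$gene_id[ann$label != "HR"], "LR_PC", "HR")
  ann_d <- data.frame(gene_id = map_d$gene_id,
                      chromosome = map_d$chromosome,
                      label = factor(ann_d_lab,
                                     levels = c("HR", "LR_flank", "LR_PC")),
                      region_id = NA_character_, stringsAsFactors = FALSE)
  class(ann_d) <- c("compartment_annotation", "data.frame")
  ld <- call_local_duplicates(rbind(wgd$hits, tex$hits), map_d,
                              frac = frac)
  ld_table <- local_dup_table(ld$duplicated_genes, ann_d)

  results <- list(map = map, regions = regions, annotations = ann,
                  diversity = div, diversity_summary = div_summary,
                  expression_tests = expr_tests, ohnologs = ohn,
                  ohnolog_tables = ohn_tables, local_dups = ld,
                  local_dup_table = ld_table, sim = sim,
                  truth = list(panel = panel$truth,
                               wgd = wgd$truth_pairs,
                               tandem = tex$truth_tandem))
  write.table(div, file.path(out_dir, "diversity.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(ohn$pairs, file.path(out_dir, "ohnolog_pairs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(format_local_dup_table(ld_table),
              file.path(out_dir, "local_dup_table.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("pericompart")),
    seed = config$seed,
    parameters = list(window = window, fold = fold, min_frac = min_frac,
                      min_pairs = min_pairs, max_gap = max_gap,
                      ks_max = ks_max, frac = frac),
    config = unclass(config),
    input_md5 = as.list(stats::setNames(tools::md5sum(unlist(paths)),
                                        names(paths)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(results)
}

#' Recompute the published-style report tables from bundled counts
#'
#' The package ships the observed count tables of the barley study
#' (compartment distribution of ohnologs and of locally duplicated genes)
#' as plain-text fixtures, and recomputes every derived column from them:
#' expected ohnolog gene and pair-class counts from compartment gene
#' fractions, the LR ohnolog share, percent-LR columns, ratio of
#' percentages, Yates chi-squared p-values, and the overall depletion
#' percentage.
#'
#' @return a list with \code{ohnolog_genes}, \code{ohnolog_pairs} (observed
#'   and recomputed expected counts with goodness-of-fit tests),
#'   \code{local_dups} (per-chromosome depletion table) and
#'   \code{depletion_pct}.
#' @export
reproduce_tables <- function() {
  t1 <- read.table(system.file("extdata", "ohnolog_counts.tsv",
                               package = "pericompart"),
                   header = TRUE, sep = "\t")
  t2 <- read.table(system.file("extdata", "local_dup_counts.tsv",
                               package = "pericompart"),
                   header = TRUE, sep = "\t")
  all_hr <- sum(t2$all_hr)
  all_lr <- sum(t2$all_lr)
  q <- all_lr / (all_hr + all_lr)
  n_genes <- t1$count[t1$item == "ohnolog_genes_HR"] +
    t1$count[t1$item == "ohnolog_genes_LR"]
  obs_g <- c(HR = t1$count[t1$item == "ohnolog_genes_HR"],
             LR = t1$count[t1$item == "ohnolog_genes_LR"])
  exp_g <- n_genes * c(HR = 1 - q, LR = q)
  n_pairs <- n_genes / 2
  obs_p <- c(`HR-HR` = t1$count[t1$item == "pairs_HR_HR"],
             `LR-HR` = t1$count[t1$item == "pairs_LR_HR"],
             `LR-LR` = t1$count[t1$item == "pairs_LR_LR"])
  exp_p <- n_pairs * c(`HR-HR` = (1 - q)^2, `LR-HR` = 2 * q * (1 - q),
                       `LR-LR` = q^2)
  rows <- lapply(seq_len(nrow(t2)), function(i) {
    r <- t2[i, ]
    pct_dup <- 100 * r$dup_lr / (r$dup_hr + r$dup_lr)
    pct_all <- 100 * r$all_lr / (r$all_hr + r$all_lr)
    p <- chi2_2x2_yates(matrix(c(r$dup_hr, r$dup_lr, r$all_hr, r$all_lr),
                               2, byrow = TRUE))$p
    data.frame(chromosome = r$chromosome, pct_lr_dup = pct_dup,
               pct_lr_all = pct_all, ratio = pct_dup / pct_all, p = p,
               stringsAsFactors = FALSE)
  })
  tot <- data.frame(
    chromosome = "Total",
    pct_lr_dup = 100 * sum(t2$dup_lr) / sum(t2$dup_hr + t2$dup_lr),
    pct_lr_all = 100 * all_lr / (all_hr + all_lr),
    ratio = NA_real_,
    p = chi2_2x2_yates(matrix(c(sum(t2$dup_hr), sum(t2$dup_lr),
                                all_hr, all_lr), 2, byrow = TRUE))$p,
    stringsAsFactors = FALSE)
  tot$ratio <- tot$pct_lr_dup / tot$pct_lr_all
  local <- rbind(do.call(rbind, rows), tot)
  list(
    ohnolog_genes = data.frame(compartment = names(obs_g),
                               observed = unname(obs_g),
                               expected = unname(exp_g)),
    ohnolog_genes_test = chi2_gof(obs_g, exp_g),
    ohnolog_pairs = data.frame(class = names(obs_p),
                               observed = unname(obs_p),
                               expected = unname(exp_p)),
    ohnolog_pairs_test = chi2_gof(obs_p, exp_p),
    lr_gene_share_pct = 100 * obs_g[["LR"]] / n_genes,
    lr_gene_fraction = q,
    local_dups = local,
    depletion_pct = 100 * (1 - tot$ratio)
  )
}
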