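# Deterministic generator for inputs with the statistical structure the
# pipeline assumes: a Marey-style map with a planted pericentromeric
# suppression segment, a coding-sequence haplotype panel with
# compartment-specific pi_a/pi_s, a WGD-duplicated gene complement with
# class-dependent pair survival, tandem duplication proportional to local
# recombination, and compartment-independent expression. Every output is a
# pure function of the config seed (R's default Mersenne-Twister stream,
# with fixed per-stage sub-seed offsets so adding a stage never perturbs
# earlier streams).

#' Simulation configuration
#'
#' Defaults encode the emulated study conditions: 14 inbred haplotypes, a
#' 20-fold recombination suppression around the centromere covering about a
#' quarter of the genes, compartment pi_a/pi_s of 0.235 (LR) vs 0.170 (HR)
#' at pi_s = 0.01, zero LR-LR ohnolog-pair survival, tandem duplication
#' proportional to local cM, and 15 tissues with identically distributed
#' expression in both compartments.
#'
#' @param seed integer seed; fully determines every output.
#' @param n_chromosomes,genes_per_chromosome genome shape (default 2 x
#'   1000 genes).
#' @param pc_fraction fraction of each chromosome's genes in the suppressed
#'   pericentromeric segment (default 0.25).
#' @param suppression_fold recombination suppression factor of the planted segment (default 50, so the segment rate falls clearly below the 20-fold-of-chromosome-average calling threshold).
#' @param cm_per_gene mean high-recombining rate in cM per gene
#'   (default 0.03).
#' @param n_haplotypes sampled inbred lines (default 14).
#' @param target_pi_s synonymous diversity target (default 0.01).
#' @param target_pia_pis_LR,target_pia_pis_HR compartment pi_a/pi_s targets
#'   (defaults 0.235 and 0.170).
#' @param mean_depth mean read depth per sample and site (default 20).
#' @param miss_rate per-sample probability of a missing genotype at a site
#'   (default 0.02).
#' @param error_site_rate sequencing-error decoy sites per true SNP; these
#'   are singletons with at most 2 supporting reads, built to fail the
#'   MAF/min-reads filters (default 0.3).
#' @param orf_codons protein length range in codons (default 150-450).
#' @param utr_len UTR length in bp on each side (default 60).
#' @param wgd_pair_survival named survival probabilities by pair class
#'   (defaults HR_HR 0.75, LR_HR 0.5, LR_LR 0).
#' @param wgd_block_genes ancestral duplication block size in genes
#'   (default 40).
#' @param wgd_cds_codons coding length used for WGD pairs (default 300).
#' @param ks_meanlog,ks_sdlog lognormal synonymous-divergence distribution
#'   of surviving pairs, truncated below 3 (defaults log(1.3), 0.35).
#' @param ka_ks_mean mean Ka/Ks of surviving pairs (default 0.16).
#' @param old_decoy_rate probability that a non-surviving candidate pair is
#'   emitted as an anciently diverged decoy with Ks in (6, 10) (default 0.1).
#' @param tandem_decoy_rate per-gene rate of high-identity recent-duplicate
#'   decoy hits (default 0.01).
#' @param noise_hit_rate per-gene rate of weak random hits (default 0.05).
#' @param tandem_rate_per_cM tandem duplication probability per cM of local
#'   map interval (default 5).
#' @param n_tissues expression conditions (default 15).
#' @return a list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1,
                       n_chromosomes = 2,
                       genes_per_chromosome = 1000,
                       pc_fraction = 0.25,
                       suppression_fold = 50,
                       cm_per_gene = 0.03,
                       n_haplotypes = 14,
                       target_pi_s = 0.01,
                       target_pia_pis_LR = 0.235,
                       target_pia_pis_HR = 0.170,
                       mean_depth = 20,
                       miss_rate = 0.02,
                       error_site_rate = 0.3,
                       orf_codons = c(150, 450),
                       utr_len = 60,
                       wgd_pair_survival = c(HR_HR = 0.75, LR_HR = 0.5,
                                             LR_LR = 0),
                       wgd_block_genes = 40,
                       wgd_cds_codons = 300,
                       ks_meanlog = log(1.3),
                       ks_sdlog = 0.35,
                       ka_ks_mean = 0.16,
                       old_decoy_rate = 0.1,
                       tandem_decoy_rate = 0.01,
                       noise_hit_rate = 0.05,
                       tandem_rate_per_cM = 5,
                       n_tissues = 15) {
  cfg <- as.list(environment())
  if (cfg$pc_fraction >= 1) stop("pc_fraction must be < 1")
  probs <- c(cfg$wgd_pair_survival, cfg$miss_rate, cfg$tandem_decoy_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (cfg$n_haplotypes < 4) stop("need at least 4 haplotypes")
  class(cfg) <- "sim_config"
  cfg
}

# expected per-site diversity when the derived-allele sample count is
# uniform on 2..(n-2) (all planted true SNPs pass the MAF filter)
expected_site_pi <- function(n) {
  k <- 2:(n - 2)
  mean((n / (n - 1)) * 2 * (k / n) * (1 - k / n))
}

#' Simulate a gene map with a planted suppressed segment
#'
#' Physical positions increase uniformly at random; genetic increments are
#' exponential with segment-specific means (pericentromeric rate =
#' high-recombining rate / suppression_fold). The centromere sits at the
#' middle of the planted segment.
#'
#' @param config a \code{sim_config}.
#' @return list: \code{map} (a \code{gene_map}), \code{centromeres},
#'   \code{truth} (planted segment bounds per chromosome) and
#'   \code{labels} (true per-gene HR/LR label, map order).
#' @export
simulate_genome_map <- function(config) {
  set.seed(config$seed + 101L)
  n <- config$genes_per_chromosome
  maps <- list()
  cen <- list()
  truth <- list()
  labels <- list()
  for (c_i in seq_len(config$n_chromosomes)) {
    chr <- sprintf("chr%02d", c_i)
    bp <- cumsum(round(stats::runif(n, 2e4, 2e5)))
    pc_n <- round(n * config$pc_fraction)
    pc_start <- floor((n - pc_n) / 2) + 1L
    pc_end <- pc_start + pc_n - 1L
    rate <- rep(config$cm_per_gene, n)
    rate[pc_start:pc_end] <- config$cm_per_gene / config$suppression_fold
    inc <- stats::rexp(n, rate = 1 / rate)
    cm <- cumsum(inc) - inc[1]
    ids <- sprintf("%s_g%04d", chr, seq_len(n))
    maps[[chr]] <- data.frame(gene_id = ids, chromosome = chr,
                              genetic_pos = cm, physical_pos = bp,
                              stringsAsFactors = FALSE)
    cen_idx <- (pc_start + pc_end) %/% 2
    cen[[chr]] <- data.frame(chromosome = chr, bp = bp[cen_idx],
                             stringsAsFactors = FALSE)
    truth[[chr]] <- data.frame(chromosome = chr, start_index = pc_start,
                               end_index = pc_end, start_bp = bp[pc_start],
                               end_bp = bp[pc_end],
                               centromere_bp = bp[cen_idx],
                               stringsAsFactors = FALSE)
    lab <- rep("HR", n)
    lab[pc_start:pc_end] <- "LR"
    labels[[chr]] <- lab
  }
  all <- do.call(rbind, maps)
  list(map = gene_map(all$gene_id, all$chromosome, all$genetic_pos,
                      all$physical_pos),
       centromeres = do.call(rbind, cen),
       truth = do.call(rbind, truth),
       labels = unlist(labels, use.names = FALSE))
}

# per-codon synonymous/nonsynonymous single-base options, cached
.sim_env <- new.env(parent = emptyenv())

codon_options <- function() {
  if (!is.null(.sim_env$opts)) return(.sim_env$opts)
  tab <- codon_tables()
  stops <- names(tab$aa)[tab$aa == "*"]
  opts <- lapply(names(tab$aa), function(cod) {
    al <- tab$alts[[cod]]
    mk <- function(sel) {
      if (!any(sel)) return(NULL)
      cbind(pos = al$pos[sel], alt = al$alt[sel])
    }
    mut_cod <- vapply(seq_len(nrow(al)), function(r) {
      m <- cod
      substr(m, al$pos[r], al$pos[r]) <- al$alt[r]
      m
    }, character(1))
    list(syn = mk(al$syn),
         nonsyn_nostop = mk(!al$syn & !(mut_cod %in% stops)))
  })
  names(opts) <- names(tab$aa)
  # flat per-codon vectors for fast vectorized candidate expansion
  flat <- lapply(c(syn = "syn", nonsyn_nostop = "nonsyn_nostop"),
                 function(kind) {
    list(pos = lapply(opts, function(o)
           if (is.null(o[[kind]])) integer(0) else
             as.integer(o[[kind]][, "pos"])),
         alt = lapply(opts, function(o)
           if (is.null(o[[kind]])) character(0) else o[[kind]][, "alt"]),
         n = vapply(opts, function(o)
           if (is.null(o[[kind]])) 0L else nrow(o[[kind]]), 0L))
  })
  .sim_env$opts <- opts
  .sim_env$flat <- flat
  opts
}

# vectorized candidate table: cDNA position and alt allele for every
# single-base option of the given effect class over a codon vector
candidate_options <- function(cods, kind, orf_start) {
  codon_options()
  fl <- .sim_env$flat[[kind]]
  counts <- fl$n[cods]
  kvec <- rep(seq_along(cods), counts)
  pos_in_codon <- unlist(fl$pos[cods], use.names = FALSE)
  alt <- unlist(fl$alt[cods], use.names = FALSE)
  list(pos = orf_start + 3L * (kvec - 1L) + pos_in_codon - 1L, alt = alt)
}

random_cds <- function(protein_codons) {
  tab <- codon_tables()
  nonstop <- names(tab$aa)[tab$aa != "*"]
  stops <- names(tab$aa)[tab$aa == "*"]
  paste0("ATG",
         paste(sample(setdiff(nonstop, "ATG"), protein_codons - 1,
                      replace = TRUE), collapse = ""),
         sample(stops, 1))
}

random_utr <- function(len) {
  s <- paste(sample(BASES, len, replace = TRUE), collapse = "")
  gsub("ATG", "ATC", s, fixed = TRUE)
}

#' Simulate a coding-sequence haplotype panel
#'
#' Per gene: an ORF-bearing cDNA (ATG-free UTRs around ATG...stop) and SNPs
#' placed on synonymous, nonsynonymous and UTR positions, with per-class
#' rates tuned so the expected estimator values hit \code{target_pi_s} and
#' the compartment pi_a/pi_s targets. True SNPs have derived-allele sample
#' counts uniform on 2..(n-2) (all pass the MAF filter before missingness);
#' additional sequencing-error decoy sites are singletons with at most 2
#' reads, constructed to fail both filters.
#'
#' @param config a \code{sim_config}.
#' @param map a \code{gene_map} (gives gene ids; from
#'   \code{simulate_genome_map}).
#' @param labels per-gene "HR"/"LR" labels in map order.
#' @return list: \code{refs} (named character cDNAs), \code{variants}
#'   (a \code{variant_table}), \code{truth} (per-gene placement counts and
#'   compartment class) and \code{truth_sites} (per-site effect class,
#'   including the planted error sites).
#' @export
simulate_coding_panel <- function(config, map, labels) {
  set.seed(config$seed + 202L)
  n_hap <- config$n_haplotypes
  e_pi <- expected_site_pi(n_hap)
  opts <- codon_options()
  n_genes <- nrow(map)
  refs <- character(n_genes)
  names(refs) <- map$gene_id
  site_rows <- vector("list", n_genes)
  truth <- vector("list", n_genes)
  samples <- sprintf("hap%02d", seq_len(n_hap))
  for (g in seq_len(n_genes)) {
    lp <- sample(config$orf_codons[1]:config$orf_codons[2], 1)
    cds <- random_cds(lp)
    utr5 <- random_utr(config$utr_len)
    utr3 <- random_utr(config$utr_len)
    seq_g <- paste0(utr5, cds, utr3)
    refs[g] <- seq_g
    orf_start <- config$utr_len + 1L
    cods <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    sc <- ng86_site_counts(cds)
    ratio <- if (labels[g] == "LR") config$target_pia_pis_LR else
      config$target_pia_pis_HR
    m_s <- stats::rpois(1, config$target_pi_s * sc$syn_sites / e_pi)
    m_a <- stats::rpois(1, ratio * config$target_pi_s *
                          sc$nonsyn_sites / e_pi)
    m_nc <- stats::rpois(1, config$target_pi_s * 2 * config$utr_len / e_pi)
    # candidate (pos, alt) options per effect class; one SNP per position
    pick_sites <- function(kind, m, forbidden) {
      if (m == 0) return(NULL)
      cand <- candidate_options(cods, kind, orf_start)
      ok <- !(cand$pos %in% forbidden)
      pos <- cand$pos[ok]
      alt <- cand$alt[ok]
      if (length(pos) == 0) return(NULL)
      # shuffle options, keep one per position, take m positions
      o <- sample.int(length(pos))
      keep <- o[!duplicated(pos[o])]
      keep <- keep[seq_len(min(m, length(keep)))]
      cbind(pos = pos[keep], alt = alt[keep])
    }
    pos_of <- function(x) if (is.null(x)) integer(0) else
      as.integer(x[, "pos"])
    syn_sites <- pick_sites("syn", m_s, integer(0))
    nonsyn_sites <- pick_sites("nonsyn_nostop", m_a, pos_of(syn_sites))
    used <- c(pos_of(syn_sites), pos_of(nonsyn_sites))
    nc_sites <- NULL
    if (m_nc > 0) {
      utr_pos <- c(seq_len(config$utr_len),
                   nchar(seq_g) - config$utr_len + seq_len(config$utr_len))
      sel <- sample(utr_pos, min(m_nc, length(utr_pos)))
      nc_sites <- cbind(pos = sel,
                        alt = vapply(sel, function(p)
                          sample(setdiff(BASES,
                                         substr(seq_g, p, p)), 1),
                          character(1)))
      used <- c(used, sel)
    }
    true_sites <- rbind(syn_sites, nonsyn_sites, nc_sites)
    n_true <- if (is.null(true_sites)) 0L else nrow(true_sites)
    n_err <- stats::rpois(1, config$error_site_rate * max(1, n_true))
    err_sites <- NULL
    if (n_err > 0) {
      free <- setdiff(seq_len(nchar(seq_g)), used)
      sel <- sample(free, min(n_err, length(free)))
      err_sites <- cbind(pos = sel,
                         alt = vapply(sel, function(p)
                           sample(setdiff(BASES,
                                          substr(seq_g, p, p)), 1),
                           character(1)))
    }
    all_sites <- rbind(true_sites, err_sites)
    if (is.null(all_sites) || nrow(all_sites) == 0) {
      truth[[g]] <- data.frame(gene_id = map$gene_id[g], label = labels[g],
                               n_syn = 0L, n_nonsyn = 0L, n_noncoding = 0L,
                               n_error = 0L, stringsAsFactors = FALSE)
      next
    }
    n_site <- nrow(all_sites)
    is_err <- seq_len(n_site) > n_true
    nr0 <- function(x) if (is.null(x)) 0L else nrow(x)
    site_class <- c(rep("synonymous", nr0(syn_sites)),
                    rep("nonsynonymous", nr0(nonsyn_sites)),
                    rep("noncoding", nr0(nc_sites)),
                    rep("error", nr0(err_sites)))
    pos <- as.integer(all_sites[, "pos"])
    refa <- substring(seq_g, pos, pos)
    alta <- all_sites[, "alt"]
    refc <- matrix(0L, n_site, n_hap)
    altc <- matrix(0L, n_site, n_hap)
    for (i in seq_len(n_site)) {
      depth <- 1L + stats::rpois(n_hap, config$mean_depth - 1)
      if (is_err[i]) {
        carrier <- sample(n_hap, 1)
        refc[i, ] <- depth
        refc[i, carrier] <- 0L
        altc[i, carrier] <- sample(2L, 1)
      } else {
        k <- sample(2:(n_hap - 2), 1)
        carriers <- sample(n_hap, k)
        refc[i, ] <- depth
        refc[i, carriers] <- 0L
        altc[i, carriers] <- depth[carriers]
        miss <- stats::runif(n_hap) < config$miss_rate
        refc[i, miss] <- 0L
        altc[i, miss] <- 0L
      }
    }
    colnames(refc) <- samples
    colnames(altc) <- samples
    site_rows[[g]] <- list(
      sites = data.frame(ref_id = map$gene_id[g], pos = pos, ref = refa,
                         alt = alta, stringsAsFactors = FALSE),
      refc = refc, altc = altc,
      truth_sites = data.frame(ref_id = map$gene_id[g], pos = pos,
                               class = site_class,
                               stringsAsFactors = FALSE))
    truth[[g]] <- data.frame(
      gene_id = map$gene_id[g], label = labels[g],
      n_syn = if (is.null(syn_sites)) 0L else nrow(syn_sites),
      n_nonsyn = if (is.null(nonsyn_sites)) 0L else nrow(nonsyn_sites),
      n_noncoding = if (is.null(nc_sites)) 0L else nrow(nc_sites),
      n_error = if (is.null(err_sites)) 0L else nrow(err_sites),
      stringsAsFactors = FALSE)
  }
  site_rows <- site_rows[!vapply(site_rows, is.null, logical(1))]
  if (length(site_rows) > 0) {
    sites <- do.call(rbind, lapply(site_rows, `[[`, "sites"))
    refc <- do.call(rbind, lapply(site_rows, `[[`, "refc"))
    altc <- do.call(rbind, lapply(site_rows, `[[`, "altc"))
    truth_sites <- do.call(rbind, lapply(site_rows, `[[`, "truth_sites"))
  } else {
    sites <- data.frame(ref_id = character(), pos = integer(),
                        ref = character(), alt = character(),
                        stringsAsFactors = FALSE)
    refc <- altc <- matrix(0L, 0, n_hap, dimnames = list(NULL, samples))
    truth_sites <- data.frame(ref_id = character(), pos = integer(),
                              class = character(),
                              stringsAsFactors = FALSE)
  }
  rownames(sites) <- NULL
  rownames(truth_sites) <- NULL
  list(refs = refs, variants = variant_table(sites, refc, altc),
       truth = do.call(rbind, truth), truth_sites = truth_sites)
}

# synthetic bit score: a declared monotone formula of identity and length
# (not a BLAST emulation), so similarity filters are exercised
# deterministically
synthetic_bit_score <- function(aln_length, pct_identity) {
  2 * aln_length * (pct_identity / 100) *
    (1 - 0.9 * (1 - pct_identity / 100))
}

hit_row <- function(q, s, len, ident) {
  bit <- synthetic_bit_score(len, ident)
  data.frame(query_id = q, subject_id = s, pct_identity = round(ident, 2),
             aln_length = len, mismatches = round(len * (1 - ident / 100)),
             gap_opens = 0L, q_start = 1L, q_end = as.integer(len),
             s_start = 1L, s_end = as.integer(len),
             evalue = 2^(-bit / 10), bit_score = round(bit, 1),
             stringsAsFactors = FALSE)
}

# diverge a copy of a CDS to approximately the requested Ks/Ka; one
# substitution per sampled position, stops avoided, final sequence scanned
# for accidental internal stops (reverted)
# diverge a copy to the requested Ks/Ka: the number of observed synonymous
# (nonsynonymous) differences is the Jukes-Cantor forward transform of the
# target rate times the NG86 site count, placed one change per codon on
# disjoint codon sets so the pathway counting is unambiguous and the
# corrected estimate inverts back to the target; targets beyond the
# correction's saturation point yield saturated/undefined estimates by
# construction. Counts are capped by the number of eligible codons (heavy
# nonsynonymous targets are then under-realized, which only lowers Ka).
diverge_cds <- function(cds, ks, ka) {
  codon_options()
  fl <- .sim_env$flat
  sc <- ng86_site_counts(cds)
  cods <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  ncod <- length(cods)
  interior <- seq_len(ncod - 1L)
  jc_fwd <- function(k) 0.75 * (1 - exp(-4 * k / 3))
  m_s <- round(jc_fwd(ks) * sc$syn_sites)
  m_n <- round(jc_fwd(ka) * sc$nonsyn_sites)
  take <- function(pool, m) pool[sample.int(length(pool),
                                            min(m, length(pool)))]
  syn_ok <- interior[fl$syn$n[cods[interior]] > 0]
  # beyond the correction's range a target cannot be realized by counts:
  # saturate every synonymous-capable codon instead
  if (ks >= 3) m_s <- length(syn_ok)
  syn_sel <- take(syn_ok, m_s)
  non_pool <- setdiff(interior, syn_sel)
  non_ok <- non_pool[fl$nonsyn_nostop$n[cods[non_pool]] > 0]
  non_sel <- take(non_ok, m_n)
  mutate_one <- function(cods, k, kind) {
    o <- fl[[kind]]
    cod <- cods[k]
    j <- sample.int(o$n[[cod]], 1)
    substr(cod, o$pos[[cods[k]]][j], o$pos[[cods[k]]][j]) <-
      o$alt[[cods[k]]][j]
    cods[k] <- cod
    cods
  }
  for (k in syn_sel) cods <- mutate_one(cods, k, "syn")
  for (k in non_sel) cods <- mutate_one(cods, k, "nonsyn_nostop")
  paste(cods, collapse = "")
}

#' Simulate a WGD-duplicated gene complement
#'
#' Duplication blocks tile each chromosome and map to permuted block
#' positions on its partner chromosome (random orientation). Candidate
#' pairs survive with class-dependent probabilities; surviving pairs'
#' coding sequences diverge to a lognormal synonymous-divergence target
#' (truncated below 3); non-surviving candidates may appear as anciently
#' diverged decoys (Ks 6-10), plus transposed-paralog decoys, weak noise
#' hits and recent high-identity decoys. All genes receive a coding
#' sequence so Ka/Ks is computable for any chained pair.
#'
#' @param config a \code{sim_config} (needs n_chromosomes >= 2).
#' @param map a \code{gene_map}.
#' @param labels per-gene "HR"/"LR" labels in map order.
#' @return list: \code{hits} (a \code{similarity_table}), \code{cds}
#'   (named character), \code{truth_pairs} (gene_a, gene_b, class, ks).
#' @export
simulate_wgd <- function(config, map, labels) {
  if (config$n_chromosomes < 2) stop("WGD simulation needs >= 2 chromosomes")
  set.seed(config$seed + 303L)
  L <- config$wgd_cds_codons
  chroms <- unique(map$chromosome)
  idx_by_chr <- split(seq_len(nrow(map)), map$chromosome)
  cds <- vapply(seq_len(nrow(map)), function(i) random_cds(L),
                character(1))
  names(cds) <- map$gene_id
  rows <- list()
  truth <- list()
  surv <- config$wgd_pair_survival
  for (p_i in seq_len(length(chroms) %/% 2)) {
    chr_a <- chroms[2 * p_i - 1]
    chr_b <- chroms[2 * p_i]
    ia <- idx_by_chr[[chr_a]]
    ib <- idx_by_chr[[chr_b]]
    n <- min(length(ia), length(ib))
    bs <- config$wgd_block_genes
    starts <- seq(1, n - bs + 1, by = bs + 10)
    n_blocks <- length(starts)
    perm <- sample(n_blocks)
    for (b in seq_len(n_blocks)) {
      a_range <- starts[b]:(starts[b] + bs - 1)
      b_range <- starts[perm[b]]:(starts[perm[b]] + bs - 1)
      if (stats::runif(1) < 0.3) b_range <- rev(b_range)
      for (k in seq_len(bs)) {
        ga <- ia[a_range[k]]
        gb <- ib[b_range[k]]
        cls <- paste(sort(c(labels[ga], labels[gb]), decreasing = TRUE),
                     collapse = "_")  # HR_HR, LR_HR, LR_LR
        alive <- stats::runif(1) < surv[[cls]]
        if (alive) {
          ks <- stats::rlnorm(1, config$ks_meanlog, config$ks_sdlog)
          while (ks >= 3)
            ks <- stats::rlnorm(1, config$ks_meanlog, config$ks_sdlog)
          ka <- ks * stats::runif(1, 0.6, 1.4) * config$ka_ks_mean
          cds[map$gene_id[gb]] <- diverge_cds(cds[[map$gene_id[ga]]],
                                              ks, ka)
          truth[[length(truth) + 1L]] <- data.frame(
            gene_a = min(map$gene_id[ga], map$gene_id[gb]),
            gene_b = max(map$gene_id[ga], map$gene_id[gb]),
            class = gsub("_", "-", cls), ks = ks,
            stringsAsFactors = FALSE)
        } else if (stats::runif(1) < config$old_decoy_rate) {
          ks <- stats::runif(1, 6, 10)
          ka <- ks * stats::runif(1, 0.6, 1.4) * config$ka_ks_mean
          cds[map$gene_id[gb]] <- diverge_cds(cds[[map$gene_id[ga]]],
                                              ks, ka)
        } else next
        sa <- cds[[map$gene_id[ga]]]
        sb <- cds[[map$gene_id[gb]]]
        nd <- sum(strsplit(sa, "")[[1]] != strsplit(sb, "")[[1]])
        ident <- 100 * (1 - nd / nchar(sa))
        rows[[length(rows) + 1L]] <-
          rbind(hit_row(map$gene_id[ga], map$gene_id[gb], nchar(sa), ident),
                hit_row(map$gene_id[gb], map$gene_id[ga], nchar(sa), ident))
      }
    }
  }
  # self hits for every gene
  for (g in map$gene_id)
    rows[[length(rows) + 1L]] <- hit_row(g, g, 3 * L, 100)
  # transposed-paralog decoys: moderate identity between random genes
  n_tp <- round(0.02 * nrow(map))
  if (n_tp > 0) {
    for (i in seq_len(n_tp)) {
      gp <- sample(map$gene_id, 2)
      ident <- stats::runif(1, 60, 72)
      rows[[length(rows) + 1L]] <- hit_row(gp[1], gp[2], 3 * L, ident)
    }
  }
  # weak noise hits (filtered by the bit/length rule)
  n_noise <- round(config$noise_hit_rate * nrow(map))
  if (n_noise > 0) {
    for (i in seq_len(n_noise)) {
      gp <- sample(map$gene_id, 2)
      len <- round(stats::runif(1, 100, 400))
      rows[[length(rows) + 1L]] <- hit_row(gp[1], gp[2], len,
                                           stats::runif(1, 45, 60))
    }
  }
  # recent high-identity decoys (tandem-like; 100% identity over > 200 bp)
  n_td <- stats::rbinom(1, nrow(map), config$tandem_decoy_rate)
  if (n_td > 0) {
    for (g in sample(map$gene_id, n_td)) {
      other <- sample(setdiff(map$gene_id, g), 1)
      rows[[length(rows) + 1L]] <- hit_row(g, other, 600, 100)
    }
  }
  hits <- do.call(rbind, rows)
  rownames(hits) <- NULL
  hits$strand <- "+"
  class(hits) <- c("similarity_table", "data.frame")
  truth <- if (length(truth) > 0) do.call(rbind, truth) else
    data.frame(gene_a = character(), gene_b = character(),
               class = character(), ks = numeric(),
               stringsAsFactors = FALSE)
  list(hits = hits, cds = cds, truth_pairs = truth)
}

#' Simulate tandem duplication and tissue expression
#'
#' Each gene gains an adjacent duplicate with probability
#' \code{tandem_rate_per_cM} times its local genetic-map increment, so
#' duplication tracks recombination; duplicates are placed within the
#' 2-percent physical-distance rule and emitted as high-identity hits.
#' Distant same-chromosome decoy hits model intrachromosomal
#' translocations. Expression values are lognormal i.i.d. across
#' compartments (15 tissues by default).
#'
#' @param config a \code{sim_config}.
#' @param map a \code{gene_map}.
#' @param labels per-gene "HR"/"LR" labels in map order.
#' @return list: \code{map_with_dups} (map plus duplicate entries),
#'   \code{hits}, \code{expression} (genes x tissues matrix),
#'   \code{truth_tandem}, \code{truth_transloc}.
#' @export
simulate_tandem_and_expression <- function(config, map, labels) {
  set.seed(config$seed + 404L)
  rows <- list()
  new_entries <- list()
  truth_t <- list()
  truth_x <- list()
  for (chr in unique(map$chromosome)) {
    i <- which(map$chromosome == chr)
    inc <- c(0, diff(map$genetic_pos[i]))
    p_dup <- pmin(1, config$tandem_rate_per_cM * inc)
    dup <- stats::runif(length(i)) < p_dup
    chr_len <- max(map$physical_pos[i])
    for (k in which(dup)) {
      g <- map$gene_id[i[k]]
      copy <- paste0(g, "_d")
      off <- round(stats::runif(1, 1e3, 1e4))
      new_entries[[copy]] <- data.frame(
        gene_id = copy, chromosome = chr,
        genetic_pos = map$genetic_pos[i[k]],
        physical_pos = map$physical_pos[i[k]] + off,
        stringsAsFactors = FALSE)
      ident <- stats::runif(1, 95, 99.5)
      len <- 900
      rows[[length(rows) + 1L]] <- rbind(hit_row(g, copy, len, ident),
                                         hit_row(copy, g, len, ident))
      truth_t[[length(truth_t) + 1L]] <- data.frame(
        gene_id = g, copy_id = copy, label = labels[i[k]],
        stringsAsFactors = FALSE)
    }
    # intrachromosomal translocation decoys: distant same-chromosome hits
    n_x <- stats::rbinom(1, length(i), 0.02)
    if (n_x > 0) {
      for (k in sample(length(i), n_x)) {
        far <- which(abs(map$physical_pos[i] - map$physical_pos[i[k]]) >
                       0.05 * chr_len)
        if (length(far) == 0) next
        g2 <- map$gene_id[i[sample(far, 1)]]
        g1 <- map$gene_id[i[k]]
        ident <- stats::runif(1, 90, 98)
        rows[[length(rows) + 1L]] <- rbind(hit_row(g1, g2, 900, ident),
                                           hit_row(g2, g1, 900, ident))
        truth_x[[length(truth_x) + 1L]] <- data.frame(
          gene_a = g1, gene_b = g2, stringsAsFactors = FALSE)
      }
    }
  }
  map2 <- map
  if (length(new_entries) > 0) {
    add <- do.call(rbind, new_entries)
    map2 <- gene_map(c(map$gene_id, add$gene_id),
                     c(map$chromosome, add$chromosome),
                     c(map$genetic_pos, add$genetic_pos),
                     c(map$physical_pos, add$physical_pos))
  }
  hits <- if (length(rows) > 0) do.call(rbind, rows) else
    empty_similarity_table()
  rownames(hits) <- NULL
  if (nrow(hits) > 0) hits$strand <- "+"
  class(hits) <- c("similarity_table", "data.frame")
  base <- stats::rlnorm(nrow(map), meanlog = 2, sdlog = 0.8)
  expr <- base * matrix(stats::rlnorm(nrow(map) * config$n_tissues,
                                      0, 0.6),
                        nrow(map), config$n_tissues)
  rownames(expr) <- map$gene_id
  colnames(expr) <- sprintf("tissue%02d", seq_len(config$n_tissues))
  list(map_with_dups = map2, hits = hits, expression = expr,
       truth_tandem = if (length(truth_t)) do.call(rbind, truth_t) else
       data.frame(gene_id = character(), copy_id = character(),
                  label = character(), stringsAsFactors = FALSE),
       truth_transloc = if (length(truth_x)) do.call(rbind, truth_x) else
       data.frame(gene_a = character(), gene_b = character(),
                  stringsAsFactors = FALSE))
}
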