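# Per-gene nucleotide diversity from cDNA-mapped SNP panels of inbred lines:
# each line contributes one (consensus) haplotype, so diversity is computed
# on haploid sample alleles with the unbiased per-site heterozygosity
# estimator, and synonymous/nonsynonymous denominators use fractional
# (Nei-Gojobori) site counts on the reference ORF.

BASES <- c("A", "C", "G", "T")

# cached codon tables (built on first use from the standard genetic code)
.codon_env <- new.env(parent = emptyenv())

codon_tables <- function() {
  if (!is.null(.codon_env$tab)) return(.codon_env$tab)
  gc_tab <- Biostrings::GENETIC_CODE  # stop codons are "*"
  codons <- names(gc_tab)
  syn_sites <- numeric(length(codons))
  names(syn_sites) <- codons
  alts <- vector("list", length(codons))
  names(alts) <- codons
  for (cod in codons) {
    aa <- gc_tab[[cod]]
    ch <- strsplit(cod, "")[[1]]
    rows <- list()
    s <- 0
    for (p in 1:3) {
      for (b in setdiff(BASES, ch[p])) {
        mut <- ch
        mut[p] <- b
        mut_cod <- paste(mut, collapse = "")
        is_syn <- gc_tab[[mut_cod]] == aa
        if (is_syn) s <- s + 1 / 3
        rows[[length(rows) + 1L]] <-
          data.frame(pos = p, alt = b, syn = is_syn,
                     stringsAsFactors = FALSE)
      }
    }
    syn_sites[cod] <- s
    alts[[cod]] <- do.call(rbind, rows)
  }
  .codon_env$tab <- list(aa = gc_tab, syn_sites = syn_sites, alts = alts)
  .codon_env$tab
}

#' Find the longest ATG-initiated open reading frame
#'
#' Among all forward-strand reading frames, returns the longest run from an
#' ATG to the first in-frame stop codon (included) or, if no stop follows,
#' to the sequence 3' end truncated to a codon boundary. Ties are broken by
#' the smaller start position. Regions outside the ORF are UTRs.
#'
#' @param seq a nucleotide string over A/C/G/T/N (oriented cDNA; forward
#'   strand only).
#' @param min_codons minimum ORF length in codons (including any stop) for a
#'   hit to be reported; default 1 reports any ATG-initiated frame.
#' @return a list with \code{orf_start}, \code{orf_end} (1-based inclusive),
#'   \code{n_codons} and \code{protein_codons} (codons excluding a terminal
#'   stop), or \code{NULL} if no qualifying ORF exists.
#' @export
find_orf <- function(seq, min_codons = 1) {
  s <- toupper(as.character(seq))
  n <- nchar(s)
  if (n < 3) return(NULL)
  ch <- strsplit(s, "")[[1]]
  starts <- which(ch == "A")
  starts <- starts[starts + 2 <= n]
  starts <- starts[ch[starts + 1] == "T" & ch[starts + 2] == "G"]
  if (length(starts) == 0) return(NULL)
  first <- ch[seq_len(n - 2)]
  cod3 <- paste0(first, ch[seq_len(n - 2) + 1], ch[seq_len(n - 2) + 2])
  stop_pos <- which(cod3 %in% c("TAA", "TAG", "TGA"))
  best <- NULL
  for (a in starts) {
    sp <- stop_pos[stop_pos >= a + 3 & (stop_pos - a) %% 3 == 0]
    end <- if (length(sp) > 0) sp[1] + 2L else
      a - 1L + 3L * ((n - a + 1L) %/% 3L)
    len <- end - a + 1L
    if (is.null(best) || len > best$len) best <- list(a = a, end = end,
                                                      len = len)
  }
  n_codons <- best$len %/% 3L
  if (n_codons < min_codons) return(NULL)
  has_stop <- substr(s, best$end - 2L, best$end) %in% c("TAA", "TAG", "TGA")
  list(orf_start = best$a, orf_end = best$end, n_codons = n_codons,
       protein_codons = n_codons - as.integer(has_stop))
}

#' Brute-force ORF enumeration (reference oracle)
#'
#' Independently enumerates every ATG...stop/end span in every frame by
#' direct scanning; used to validate \code{find_orf}.
#' @param seq nucleotide string.
#' @return data.frame of all candidate spans (start, end, len).
#' @export
enumerate_orfs <- function(seq) {
  s <- toupper(as.character(seq))
  n <- nchar(s)
  out <- list()
  for (a in seq_len(max(0, n - 2))) {
    if (substr(s, a, a + 2) != "ATG") next
    end <- NA_integer_
    p <- a
    while (p + 2 <= n) {
      if (substr(s, p, p + 2) %in% c("TAA", "TAG", "TGA") && p > a) {
        end <- p + 2L
        break
      }
      p <- p + 3L
    }
    if (is.na(end)) end <- a - 1L + 3L * ((n - a + 1L) %/% 3L)
    out[[length(out) + 1L]] <- data.frame(start = a, end = end,
                                          len = end - a + 1L)
  }
  if (length(out) == 0)
    return(data.frame(start = integer(), end = integer(), len = integer()))
  do.call(rbind, out)
}

#' Classify a SNP as synonymous, nonsynonymous or noncoding
#'
#' Positions outside the ORF are noncoding. Inside, the alternative allele
#' is substituted into the reference codon (the other two positions held at
#' reference) and amino acids compared under the standard genetic code
#' (stop treated as a 21st symbol, so stop-to-stop changes are synonymous).
#'
#' @param pos 1-based position on the cDNA.
#' @param ref,alt reference and alternative single nucleotides; \code{ref}
#'   must match the reference sequence at \code{pos}.
#' @param orf an ORF annotation from \code{find_orf}, or NULL (everything
#'   noncoding).
#' @param ref_seq the reference cDNA string.
#' @return a list with \code{effect} (synonymous/nonsynonymous/noncoding),
#'   \code{codon_index} and \code{codon_pos} (NA when noncoding).
#' @export
classify_snp <- function(pos, ref, alt, orf, ref_seq) {
  s <- toupper(as.character(ref_seq))
  if (pos < 1 || pos > nchar(s)) stop("position outside reference")
  if (substr(s, pos, pos) != ref)
    stop("reference allele mismatch at position ", pos,
         ": sequence has ", substr(s, pos, pos), ", site says ", ref)
  if (is.null(orf) || pos < orf$orf_start || pos > orf$orf_end)
    return(list(effect = "noncoding", codon_index = NA_integer_,
                codon_pos = NA_integer_))
  off <- pos - orf$orf_start
  codon_index <- off %/% 3L + 1L
  codon_pos <- off %% 3L + 1L
  cstart <- orf$orf_start + 3L * (codon_index - 1L)
  cod <- substr(s, cstart, cstart + 2L)
  tab <- codon_tables()
  if (!cod %in% names(tab$aa))
    return(list(effect = NA_character_, codon_index = codon_index,
                codon_pos = codon_pos))
  mut <- cod
  substr(mut, codon_pos, codon_pos) <- alt
  effect <- if (tab$aa[[mut]] == tab$aa[[cod]]) "synonymous" else
    "nonsynonymous"
  list(effect = effect, codon_index = codon_index, codon_pos = codon_pos)
}

#' Fractional synonymous/nonsynonymous site counts (NG86)
#'
#' Each codon position contributes the fraction of its three possible
#' single-base changes that are synonymous; changes creating or destroying a
#' stop are nonsynonymous (stop-to-stop is synonymous).
#'
#' @param cds a coding string whose length is divisible by 3.
#' @return list with \code{syn_sites} and \code{nonsyn_sites}; their sum is
#'   the sequence length (minus codons containing non-ACGT symbols).
#' @export
ng86_site_counts <- function(cds) {
  s <- toupper(as.character(cds))
  if (nchar(s) %% 3 != 0) stop("coding length must be divisible by 3")
  cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  tab <- codon_tables()
  known <- cods %in% names(tab$syn_sites)
  syn <- sum(tab$syn_sites[cods[known]])
  list(syn_sites = syn, nonsyn_sites = 3 * sum(known) - syn)
}

#' Per-sample majority-allele genotype calls
#'
#' A sample's genotype at a site is its majority allele ("R" or "A"); a
#' sample with no reads, or a ref/alt read tie, is missing (NA).
#' @param vt a \code{variant_table}.
#' @return character matrix (sites x samples) of "R"/"A"/NA.
#' @export
genotype_calls <- function(vt) {
  g <- matrix(NA_character_, nrow = nrow(vt$sites),
              ncol = length(vt$sample_ids),
              dimnames = list(NULL, vt$sample_ids))
  g[vt$ref_counts > vt$alt_counts] <- "R"
  g[vt$alt_counts > vt$ref_counts] <- "A"
  g
}

#' Filter variant sites on minor allele frequency and read support
#'
#' A site is retained iff (a) across samples with coverage, the sample-level
#' frequency of the minor allele is at least \code{maf_min}, and (b) the
#' minor allele is supported by at least \code{min_reads} reads in at least
#' one sample. With \code{maf_basis = "reads"} the frequency in (a) is
#' computed over pooled reads instead of sample genotypes.
#'
#' @param vt a \code{variant_table}.
#' @param maf_min minor allele frequency cut-off (default 0.1).
#' @param min_reads minimum read support for the minor allele in at least
#'   one sample (default 3).
#' @param maf_basis "samples" (default) or "reads".
#' @return the filtered \code{variant_table} with attribute
#'   \code{n_removed}.
#' @export
filter_variants <- function(vt, maf_min = 0.1, min_reads = 3,
                            maf_basis = c("samples", "reads")) {
  maf_basis <- match.arg(maf_basis)
  if (nrow(vt$sites) == 0) return(vt)
  g <- genotype_calls(vt)
  n_ref <- rowSums(g == "R", na.rm = TRUE)
  n_alt <- rowSums(g == "A", na.rm = TRUE)
  n_called <- n_ref + n_alt
  minor_is_alt <- n_alt <= n_ref
  if (maf_basis == "samples") {
    maf <- ifelse(n_called > 0, pmin(n_ref, n_alt) / n_called, 0)
  } else {
    tot_ref <- rowSums(vt$ref_counts)
    tot_alt <- rowSums(vt$alt_counts)
    tot <- tot_ref + tot_alt
    maf <- ifelse(tot > 0, pmin(tot_ref, tot_alt) / tot, 0)
    minor_is_alt <- tot_alt <= tot_ref
  }
  minor_max_reads <- ifelse(minor_is_alt,
                            apply(vt$alt_counts, 1, max),
                            apply(vt$ref_counts, 1, max))
  keep <- maf >= maf_min & minor_max_reads >= min_reads
  out <- variant_table(vt$sites[keep, , drop = FALSE],
                       vt$ref_counts[keep, , drop = FALSE],
                       vt$alt_counts[keep, , drop = FALSE],
                       vt$n_skipped)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Per-site nucleotide diversity
#'
#' Unbiased per-site heterozygosity on n sampled alleles:
#' pi = (n/(n-1)) (1 - sum p_i^2), which equals the mean pairwise
#' difference among the alleles.
#'
#' @param counts named or unnamed vector of allele counts at one site.
#' @return pi in [0, 1], or NA if fewer than 2 alleles are sampled.
#' @export
site_pi <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  p <- counts / n
  (n / (n - 1)) * (1 - sum(p^2))
}

#' Exhaustive pairwise-difference diversity (reference oracle)
#'
#' Counts differing pairs among all C(n,2) allele pairs directly; equals
#' \code{site_pi} for any allele multiset.
#' @param alleles character vector of sampled alleles.
#' @return mean pairwise difference.
#' @export
site_pi_bruteforce <- function(alleles) {
  n <- length(alleles)
  if (n < 2) return(NA_real_)
  diff <- 0
  for (i in 1:(n - 1))
    for (j in (i + 1):n)
      diff <- diff + (alleles[i] != alleles[j])
  diff / choose(n, 2)
}

#' Per-gene diversity statistics
#'
#' Computes pi (all covered sites), pi_a and pi_s for one gene from its
#' filtered variant sites. Denominators: pi divides by the number of covered
#' positions; pi_s and pi_a divide by fractional NG86 synonymous and
#' nonsynonymous site counts computed on the reference ORF. Genes whose ORF
#' is absent or shorter than \code{min_codons} get pi only (pi_a/pi_s NA).
#'
#' @param vt_gene a \code{variant_table} restricted to one reference.
#' @param ref_seq the gene's cDNA reference string.
#' @param orf optional precomputed \code{find_orf} result; found if missing.
#' @param n_covered number of covered positions (default: full reference
#'   length, i.e. every position covered in every sample).
#' @param min_codons minimum ORF length in codons for coding statistics
#'   (default 30).
#' @return one-row data.frame: gene-level pi, pi_a, pi_s, pi_a_over_pi_s,
#'   n_sites_total, n_syn_sites, n_nonsyn_sites, n_snps, n_samples_used.
#' @export
gene_diversity <- function(vt_gene, ref_seq, orf = NULL, n_covered = NULL,
                           min_codons = 30) {
  s <- toupper(as.character(ref_seq))
  if (is.null(n_covered)) n_covered <- nchar(s)
  if (n_covered <= 0) stop("zero covered positions")
  if (is.null(orf)) orf <- find_orf(s)
  coding <- !is.null(orf) && orf$n_codons >= min_codons
  nsite <- nrow(vt_gene$sites)
  pis <- numeric(nsite)
  effect <- character(nsite)
  n_used <- integer(nsite)
  if (nsite > 0) {
    g <- genotype_calls(vt_gene)
    for (i in seq_len(nsite)) {
      cnt <- c(sum(g[i, ] == "R", na.rm = TRUE),
               sum(g[i, ] == "A", na.rm = TRUE))
      n_used[i] <- sum(cnt)
      pis[i] <- if (n_used[i] >= 2) site_pi(cnt) else NA_real_
      effect[i] <- if (coding)
        classify_snp(vt_gene$sites$pos[i], vt_gene$sites$ref[i],
                     vt_gene$sites$alt[i], orf, s)$effect
      else "noncoding"
    }
  }
  ok <- !is.na(pis)
  pi <- sum(pis[ok]) / n_covered
  if (coding) {
    orf_seq <- substr(s, orf$orf_start, orf$orf_end)
    sites <- ng86_site_counts(orf_seq)
    syn_s <- sites$syn_sites
    nonsyn_s <- sites$nonsyn_sites
    pi_s <- sum(pis[ok & effect == "synonymous"]) / syn_s
    pi_a <- sum(pis[ok & effect == "nonsynonymous"]) / nonsyn_s
    ratio <- if (pi_s > 0) pi_a / pi_s else NA_real_
  } else {
    syn_s <- nonsyn_s <- NA_real_
    pi_s <- pi_a <- ratio <- NA_real_
  }
  data.frame(pi = pi, pi_a = pi_a, pi_s = pi_s, pi_a_over_pi_s = ratio,
             n_sites_total = n_covered, n_syn_sites = syn_s,
             n_nonsyn_sites = nonsyn_s, n_snps = sum(ok),
             n_samples_used = if (any(ok)) max(n_used[ok]) else 0L)
}

#' Genome-wide diversity estimation
#'
#' Filters the variant table, then computes per-gene pi, pi_a, pi_s for
#' every reference sequence (genes without retained SNPs get zeros).
#'
#' @param refs a named \code{DNAStringSet} (or named character vector) of
#'   cDNA references.
#' @param vt a \code{variant_table} over those references.
#' @param maf_min,min_reads filter settings (see \code{filter_variants}).
#' @param min_codons minimum ORF length for coding statistics.
#' @return data.frame, one row per gene, with gene_id first.
#' @export
estimate_diversity <- function(refs, vt, maf_min = 0.1, min_reads = 3,
                               min_codons = 30) {
  seqs <- as.character(refs)
  fvt <- filter_variants(vt, maf_min = maf_min, min_reads = min_reads)
  idx <- split(seq_len(nrow(fvt$sites)), fvt$sites$ref_id)
  rows <- vector("list", length(seqs))
  for (k in seq_along(seqs)) {
    gid <- names(seqs)[k]
    sel <- idx[[gid]]
    sub <- if (is.null(sel))
      variant_table(fvt$sites[0, , drop = FALSE],
                    fvt$ref_counts[0, , drop = FALSE],
                    fvt$alt_counts[0, , drop = FALSE])
    else
      variant_table(fvt$sites[sel, , drop = FALSE],
                    fvt$ref_counts[sel, , drop = FALSE],
                    fvt$alt_counts[sel, , drop = FALSE])
    rows[[k]] <- cbind(gene_id = gid,
                       gene_diversity(sub, seqs[[k]],
                                      min_codons = min_codons),
                       stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Centered rolling average with NA skipping
#'
#' Moving mean over a centered window truncated at the series ends; missing
#' values are skipped within each window (all-missing windows give NA).
#'
#' @param values numeric vector ordered by map position.
#' @param window window size in elements (default 50); window = 1 is the
#'   identity.
#' @return numeric vector of the same length.
#' @export
rolling_average <- function(values, window = 50) {
  n <- length(values)
  if (n == 0) stop("empty input")
  if (window > n) stop("window larger than series")
  half <- floor(window / 2)
  vapply(seq_len(n), function(i) {
    w <- values[max(1, i - half):min(n, i + (window - 1 - half))]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
}

#' Compartment diversity summary
#'
#' Aggregates per-gene diversity by two-class compartment (HR vs LR). The
#' compartment-level pi_a/pi_s is reported both as the ratio of compartment
#' means (mean pi_a / mean pi_s; the stable aggregate) and as the mean of
#' per-gene ratios (genes with pi_s > 0 only), with a two-sample t-test on
#' the per-gene ratios.
#'
#' @param div output of \code{estimate_diversity}.
#' @param annotations a \code{compartment_annotation} covering the genes.
#' @return list with per-compartment summaries and the t-test.
#' @export
compartment_diversity_summary <- function(div, annotations) {
  lab <- two_class_label(annotations)
  names(lab) <- annotations$gene_id
  cls <- lab[div$gene_id]
  summ <- lapply(c(HR = "HR", LR = "LR"), function(k) {
    d <- div[which(cls == k), , drop = FALSE]
    ratios <- d$pi_a_over_pi_s[is.finite(d$pi_a_over_pi_s)]
    list(n_genes = nrow(d),
         mean_pi = mean(d$pi, na.rm = TRUE),
         mean_pi_a = mean(d$pi_a, na.rm = TRUE),
         mean_pi_s = mean(d$pi_s, na.rm = TRUE),
         ratio_of_means = mean(d$pi_a, na.rm = TRUE) /
           mean(d$pi_s, na.rm = TRUE),
         mean_gene_ratio = if (length(ratios)) mean(ratios) else NA_real_,
         n_ratio_genes = length(ratios))
  })
  rh <- div$pi_a_over_pi_s[which(cls == "HR")]
  rl <- div$pi_a_over_pi_s[which(cls == "LR")]
  rh <- rh[is.finite(rh)]
  rl <- rl[is.finite(rl)]
  tt <- if (length(rh) >= 2 && length(rl) >= 2) t_test_ind(rl, rh) else NULL
  list(HR = summ$HR, LR = summ$LR, t_test_lr_vs_hr = tt)
}
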