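test_that("ORF finder handles the canonical cases", {
  o <- find_orf("AAATGTTTTAAGG")
  expect_equal(o$orf_start, 3L)
  expect_equal(o$orf_end, 11L)
  expect_equal(o$protein_codons, 2L)  # protein MF
  expect_null(find_orf("CCCCCC"))
  # no stop: truncated to codon boundary at the 3' end
  o2 <- find_orf("ATGAAACCCGG")
  expect_equal(o2$orf_start, 1L)
  expect_equal(o2$orf_end, 9L)
  # minimum length rule
  expect_null(find_orf("AAATGTTTTAAGG", min_codons = 30))
})

test_that("ORF finder agrees with brute-force enumeration", {
  cmp_one <- function(s) {
    cand <- enumerate_orfs(s)
    o <- find_orf(s)
    if (nrow(cand) == 0) {
      expect_null(o)
      return(invisible())
    }
    best_len <- max(cand$len)
    best_start <- min(cand$start[cand$len == best_len])
    expect_equal(o$orf_start, best_start)
    expect_equal(o$orf_end - o$orf_start + 1L, best_len)
  }
  cmp_one("ATGAAATGAATGGGGGGGGGGTAA")
  set.seed(101)
  for (i in 1:100)
    cmp_one(paste(sample(c("A", "C", "G", "T"), sample(20:200, 1),
                         replace = TRUE), collapse = ""))
})

test_that("SNP effect classification matches the genetic code", {
  # TTT -> TTC at codon position 3 is Phe -> Phe
  orf <- list(orf_start = 1L, orf_end = 3L, n_codons = 1L)
  expect_equal(classify_snp(3, "T", "C", orf, "TTT")$effect, "synonymous")
  # ATG position 3 G -> A is Met -> Ile
  expect_equal(classify_snp(3, "G", "A", orf, "ATG")$effect,
               "nonsynonymous")
  # outside the ORF: noncoding
  orf2 <- list(orf_start = 1L, orf_end = 3L, n_codons = 1L)
  expect_equal(classify_snp(5, "A", "G", orf2, "TTTGA")$effect,
               "noncoding")
  # corrupt input: stated reference allele disagrees with the sequence
  expect_error(classify_snp(1, "G", "A", orf, "TTT"), "mismatch")
})

test_that("classification is complete over all 576 codon substitutions", {
  # independent oracle: translate both codons directly with the standard
  # genetic code table and compare amino acids
  gc_tab <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  n_checked <- 0L
  for (cod in names(gc_tab)) {
    for (p in 1:3) {
      ref_base <- substr(cod, p, p)
      for (alt in setdiff(bases, ref_base)) {
        mut <- cod
        substr(mut, p, p) <- alt
        want <- if (gc_tab[[mut]] == gc_tab[[cod]]) "synonymous" else
          "nonsynonymous"
        got <- classify_snp(p, ref_base, alt,
                            list(orf_start = 1L, orf_end = 3L,
                                 n_codons = 1L), cod)
        expect_identical(got$effect, want)
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_equal(n_checked, 576L)
})

test_that("site pi equals exhaustive pairwise-difference counting", {
  expect_equal(site_pi(c(A = 2, T = 2)), 2 / 3)
  expect_equal(site_pi(c(A = 14)), 0)
  expect_equal(site_pi(c(A = 1, T = 1)), 1)
  # all allele multisets of size <= 8 over up to 4 alleles
  for (n in 2:8) {
    for (a in 0:n) for (c in 0:(n - a)) for (g in 0:(n - a - c)) {
      t <- n - a - c - g
      counts <- c(a, c, g, t)
      alleles <- rep(c("A", "C", "G", "T"), counts)
      expect_equal(site_pi(counts), site_pi_bruteforce(alleles),
                   tolerance = 1e-12)
    }
  }
})

test_that("pi is invariant to sample order and ref/alt labelling", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(4:14, 1)
    k <- sample(1:(n - 1), 1)
    expect_equal(site_pi(c(k, n - k)), site_pi(c(n - k, k)))
    perm <- sample(n)
    expect_equal(site_pi(table(rep(c("A", "G"), c(k, n - k))[perm])),
                 site_pi(c(k, n - k)))
  }
})

test_that("variant filtering applies MAF and read-support rules", {
  # alt in 2 of 14 samples (MAF 0.143) with 5 reads each: retained
  keep <- filter_variants(vt1(c(rep(10, 12), 0, 0),
                              c(rep(0, 12), 5, 5)))
  expect_equal(nrow(keep$sites), 1L)
  # alt in 1 of 14 (MAF 0.071): removed
  drop1 <- filter_variants(vt1(c(rep(10, 13), 0), c(rep(0, 13), 5)))
  expect_equal(nrow(drop1$sites), 0L)
  # alt in 3 samples but best alt support 2 reads: removed
  drop2 <- filter_variants(vt1(c(rep(10, 11), 0, 0, 0),
                               c(rep(0, 11), 2, 2, 2)))
  expect_equal(nrow(drop2$sites), 0L)
  expect_equal(attr(drop2, "n_removed"), 1L)
})

test_that("gene diversity reproduces the hand-computed NG86 example", {
  ref <- paste0(strrep("GGG", 9), "TTT")
  orf <- list(orf_start = 1L, orf_end = 30L, n_codons = 10L,
              protein_codons = 10L)
  # one synonymous SNP TTT/TTC at frequency 1/2 among n = 4 haplotypes
  vt <- vt1(c(10, 10, 0, 0), c(0, 0, 10, 10), ref_id = "g1", pos = 30L,
            ref = "T", alt = "C")
  gd <- gene_diversity(vt, ref, orf = orf, min_codons = 1)
  expect_equal(gd$n_syn_sites, 9 + 1 / 3, tolerance = 1e-12)
  expect_equal(gd$pi_s, (2 / 3) / (28 / 3), tolerance = 1e-9)
  expect_equal(round(gd$pi_s, 4), 0.0714)
  expect_equal(gd$pi_a, 0)
  expect_equal(gd$pi, (2 / 3) / 30, tolerance = 1e-12)
})

test_that("genes without SNPs and empty coverage behave as specified", {
  ref <- paste0("AA", "ATG", strrep("GGG", 40), "TAA", "CC")
  empty <- variant_table(
    data.frame(ref_id = character(), pos = integer(), ref = character(),
               alt = character(), stringsAsFactors = FALSE),
    matrix(0L, 0, 4, dimnames = list(NULL, paste0("s", 1:4))),
    matrix(0L, 0, 4, dimnames = list(NULL, paste0("s", 1:4))))
  gd <- gene_diversity(empty, ref, min_codons = 30)
  expect_equal(gd$pi, 0)
  expect_equal(gd$pi_a, 0)
  expect_equal(gd$pi_s, 0)
  expect_error(gene_diversity(empty, ref, n_covered = 0), "covered")
})

test_that("rolling average matches direct recomputation and edge rules", {
  expect_equal(rolling_average(rep(3, 40), 10), rep(3, 40))
  x <- c(rep(0, 100), rep(1, 50), rep(0, 100))
  w <- 50
  got <- rolling_average(x, w)
  half <- floor(w / 2)
  brute <- vapply(seq_along(x), function(i)
    mean(x[max(1, i - half):min(length(x), i + (w - 1 - half))]),
    numeric(1))
  expect_equal(got, brute, tolerance = 1e-12)
  expect_equal(rolling_average(c(5, 1, 9), 1), c(5, 1, 9))
  # NA values are skipped within windows
  expect_equal(rolling_average(c(1, NA, 3), 3), c(1, 2, 3))
  expect_error(rolling_average(numeric(0), 5), "empty")
})
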