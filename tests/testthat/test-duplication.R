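test_that("best non-self hit reduction and tie rules", {
  h <- rbind(mk_hit("q", "q", 2000), mk_hit("q", "b", 900),
             mk_hit("q", "c", 500))
  best <- best_nonself_hits(h)
  expect_equal(best$subject_id, "b")
  # equal bit scores: smaller e-value wins, then lexicographic subject
  h2 <- rbind(mk_hit("q", "c", 700, evalue = 1e-60),
              mk_hit("q", "b", 700, evalue = 1e-50))
  expect_equal(best_nonself_hits(h2)$subject_id, "c")
  h3 <- rbind(mk_hit("q", "c", 700, evalue = 1e-50),
              mk_hit("q", "b", 700, evalue = 1e-50))
  expect_equal(best_nonself_hits(h3)$subject_id, "b")
  # only a self-hit: nothing emitted
  expect_equal(nrow(best_nonself_hits(mk_hit("q", "q", 2000))), 0L)
  # rank 2 returns the second-best subject
  expect_equal(best_nonself_hits(h, rank = 2)$subject_id, "c")
  # multiple HSPs per subject are reduced to the best one first
  h4 <- rbind(mk_hit("q", "b", 300), mk_hit("q", "b", 800),
              mk_hit("q", "c", 500))
  expect_equal(best_nonself_hits(h4)$bit_score, 800)
})

test_that("paralog pair similarity filters", {
  pairs <- data.frame(
    gene_a = letters[1:5], gene_b = LETTERS[1:5],
    bit_score = c(8500, 250, 250, 400, 500),
    pct_identity = c(92, 90, 90, 90, 100),
    aln_length = c(900, 400, 600, 400, 250),
    evalue = 1e-50, stringsAsFactors = FALSE)
  out <- filter_paralog_pairs(pairs)
  # removed: bit > 8000; bit < 300 & len < 500; 100% identity over > 200 bp
  expect_setequal(out$gene_a, c("c", "d"))
  expect_equal(attr(out, "n_removed"), 3L)
})

test_that("reference reordering sorts blocks by reference gene order", {
  map <- uniform_map(10, chrom = "1A")
  # one block, barley order a local shuffle of reference order
  anchors <- data.frame(gene_id = map$gene_id, block_id = "B1",
                        ref_order = c(2, 1, 3, 5, 4, 6, 8, 7, 9, 10))
  out <- reorder_by_reference(map, anchors)
  expect_equal(out$gene_id[order(out$order_index)],
               map$gene_id[order(anchors$ref_order)])
  # already-collinear input is unchanged
  anchors2 <- data.frame(gene_id = map$gene_id, block_id = "B1",
                         ref_order = 1:10)
  out2 <- reorder_by_reference(map, anchors2)
  expect_equal(out2$gene_id, map$gene_id)
  # a gene whose anchors are > max_anchor_gap reference genes from both
  # neighbours is dropped
  anchors3 <- anchors2
  anchors3$ref_order[5] <- 600
  out3 <- reorder_by_reference(map, anchors3, max_anchor_gap = 400)
  expect_false(map$gene_id[5] %in% out3$gene_id)
  expect_equal(attr(out3, "n_low_density"), 1L)
  # genes without anchors are dropped and counted
  out4 <- reorder_by_reference(map, anchors2[-3, ])
  expect_equal(attr(out4, "n_no_anchor"), 1L)
})

test_that("map outlier removal uses running median/MAD with a zero guard", {
  m <- uniform_map(101, rate = 1)
  expect_equal(attr(remove_map_outliers(m), "n_removed"), 0L)
  m2 <- m
  m2$genetic_pos[50] <- m2$genetic_pos[50] + 50
  out <- remove_map_outliers(m2)
  expect_equal(attr(out, "n_removed"), 1L)
  expect_false(m$gene_id[50] %in% out$gene_id)
  # all genes at identical cM: MAD 0, nothing removed
  m3 <- gene_map(sprintf("g%03d", 1:60), "1A", rep(2, 60),
                 seq_len(60) * 1e5)
  expect_equal(attr(remove_map_outliers(m3), "n_removed"), 0L)
})

test_that("collinear chaining: diagonals, reroutes and inversions", {
  mk_pairs <- function(a, b) data.frame(
    gene_a = sprintf("a%03d", seq_along(a)),
    gene_b = sprintf("b%03d", seq_along(a)),
    a_chr = "c1", a_idx = a, b_chr = "c2", b_idx = b,
    stringsAsFactors = FALSE)
  # perfect diagonal
  det <- detect_collinear_regions(mk_pairs(1:12, 101:112), min_pairs = 9)
  expect_equal(nrow(det$regions), 1L)
  expect_equal(det$regions$n_pairs, 12L)
  expect_equal(det$regions$orientation, "same")
  # one pair rerouted far away is excluded
  b <- 101:112
  b[6] <- 500
  det2 <- detect_collinear_regions(mk_pairs(1:12, b), min_pairs = 9)
  expect_equal(det2$regions$n_pairs, 11L)
  expect_true(is.na(det2$pairs$region_id[6]))
  # decreasing partner indices: inverted orientation
  det3 <- detect_collinear_regions(mk_pairs(1:12, 112:101), min_pairs = 9)
  expect_equal(det3$regions$n_pairs, 12L)
  expect_equal(det3$regions$orientation, "inverted")
})

test_that("chaining equals brute-force enumeration on random instances", {
  set.seed(123)
  for (i in 1:60) {
    n <- sample(4:12, 1)
    a <- sample(1:30, n)
    b <- sample(1:30, n)
    gap <- sample(c(5, 10, 30), 1)
    pairs <- data.frame(gene_a = sprintf("a%02d", 1:n),
                        gene_b = sprintf("b%02d", 1:n),
                        a_chr = "x", a_idx = a, b_chr = "y", b_idx = b,
                        stringsAsFactors = FALSE)
    det <- detect_collinear_regions(pairs, min_pairs = 2, max_gap = gap)
    got <- if (nrow(det$regions) == 0) 0L else max(det$regions$n_pairs)
    want <- best_chain_bruteforce(a, b, gap)
    if (want < 2) want <- 0L
    expect_equal(got, want,
                 info = sprintf("instance %d (n=%d gap=%d)", i, n, gap))
  }
})

test_that("NG86 Ka/Ks reproduces the hand-computed toy example", {
  a <- paste0(strrep("GGG", 9), "TTT")
  b <- paste0(strrep("GGG", 9), "TTC")
  kk <- ng86_ka_ks(a, b)
  expect_equal(kk$S, 28 / 3, tolerance = 1e-12)
  expect_equal(kk$Sd, 1)
  expect_equal(kk$Nd, 0)
  expect_equal(kk$ks, -0.75 * log(1 - 4 * (3 / 28) / 3), tolerance = 1e-12)
  expect_equal(round(kk$ks, 4), 0.1156)
  expect_equal(kk$ka, 0)
  # identical sequences
  z <- ng86_ka_ks(a, a)
  expect_equal(z$ka, 0)
  expect_equal(z$ks, 0)
  # symmetry
  sw <- ng86_ka_ks(b, a)
  expect_equal(sw$ks, kk$ks)
  expect_equal(sw$ka, kk$ka)
  expect_error(ng86_ka_ks("ATG", "ATGC"), "equal length")
  expect_error(ng86_ka_ks("ATGTAAGGG", "ATGTAAGGG"), "internal stop")
})

test_that("NG86 site counts conserve S + N and pure-synonymous divergence
           gives Ka = 0", {
  set.seed(21)
  for (i in 1:10) {
    cds <- pericompart:::random_cds(sample(50:150, 1))
    sc <- ng86_site_counts(cds)
    expect_equal(sc$syn_sites + sc$nonsyn_sites, nchar(cds),
                 tolerance = 1e-9)
    # apply only synonymous single-base changes (one per codon)
    cods <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    tab <- pericompart:::codon_tables()
    for (k in seq_len(length(cods) - 1)) {
      al <- tab$alts[[cods[k]]]
      al <- al[al$syn, , drop = FALSE]
      if (nrow(al) == 0 || runif(1) < 0.8) next
      j <- sample.int(nrow(al), 1)
      cod <- cods[k]
      substr(cod, al$pos[j], al$pos[j]) <- al$alt[j]
      cods[k] <- cod
    }
    kk <- ng86_ka_ks(cds, paste(cods, collapse = ""))
    expect_equal(kk$ka, 0)
    expect_gte(kk$ks, 0)
  }
})

test_that("ohnolog trimming applies the four rules with counts", {
  pairs <- data.frame(
    gene_a = c("a1", "a2", "a3", "g", "g", "b1"),
    gene_b = c("x1", "x2", "x3", "y1", "y2", "z1"),
    ks = c(3.2, 1.0, NA, 1.2, 1.5, 0.9),
    region_id = c("R1", "R1", "R1", "R1", "R1", "R2"),
    a_chr = "c1", a_idx = c(1:5, 50), b_chr = "c2",
    b_idx = c(101:105, 250), stringsAsFactors = FALSE)
  out <- trim_ohnolog_pairs(pairs, ks_max = 3, min_pairs = 1)
  # Ks 3.2 and saturated (NA) removed; gene g in two pairs: both removed
  expect_equal(out$removed[["ks"]], 2L)
  expect_equal(out$removed[["multi_pair_gene"]], 2L)
  expect_setequal(out$pairs$gene_a, c("a2", "b1"))
  expect_false(anyDuplicated(c(out$pairs$gene_a, out$pairs$gene_b)) > 0)
  # a region left with fewer than min_pairs pairs loses its pairs
  out2 <- trim_ohnolog_pairs(pairs, ks_max = 3, min_pairs = 2)
  expect_equal(nrow(out2$pairs), 0L)
  expect_equal(out2$removed[["weak_region"]], 2L)
})

test_that("overlapping regions resolve to the stronger region", {
  mk <- function(rid, n, a0, b0, ks = 1) data.frame(
    gene_a = sprintf("%s_a%d", rid, 1:n),
    gene_b = sprintf("%s_b%d", rid, 1:n),
    ks = ks, region_id = rid, a_chr = "c1", a_idx = a0 + 1:n,
    b_chr = "c2", b_idx = b0 + 1:n, stringsAsFactors = FALSE)
  pairs <- rbind(mk("R1", 10, 0, 100), mk("R2", 4, 5, 300))
  out <- trim_ohnolog_pairs(pairs, min_pairs = 3)
  # R2 overlaps R1 on chromosome c1 and is weaker: its pairs are removed
  expect_equal(unique(out$pairs$region_id), "R1")
  expect_equal(out$removed[["region_overlap"]], 4L)
  # disjoint regions both survive
  pairs2 <- rbind(mk("R1", 10, 0, 100), mk("R2", 4, 50, 300))
  out2 <- trim_ohnolog_pairs(pairs2, min_pairs = 3)
  expect_setequal(unique(out2$pairs$region_id), c("R1", "R2"))
})

test_that("local duplicates split from translocations at the 2% rule", {
  map <- gene_map(c("q", "near", "edge", "far"), "1A",
                  c(0, 1, 2, 3), c(10e6, 11.5e6, 12e6, 100e6))
  mk <- function(s, bit) mk_hit("q", s, bit)
  # chromosome length is 100 Mbp (max mapped position)
  h <- rbind(mk("near", 900), mk("q", 100))
  ld <- call_local_duplicates(h, map)
  expect_equal(ld$local$subject_id, "near")  # 1.5 Mb <= 2 Mb
  expect_setequal(ld$duplicated_genes, c("q", "near"))
  h2 <- mk_hit("q", "far", 900)
  ld2 <- call_local_duplicates(h2, map)
  expect_equal(nrow(ld2$local), 0L)
  expect_equal(ld2$translocations$subject_id, "far")
  # exactly 2%: the rule is "remote by more than 2%", so still local
  h3 <- mk_hit("q", "edge", 900)
  expect_equal(call_local_duplicates(h3, map)$local$subject_id, "edge")
  # hits to genes missing from the map are skipped and counted
  h4 <- rbind(mk_hit("q", "ghost", 900), mk_hit("q", "near", 800))
  ld4 <- call_local_duplicates(h4, map)
  expect_equal(ld4$n_skipped, 1L)
})

test_that("compartment tables reproduce expected counts from fractions", {
  n_lr <- 8688
  n_hr <- 26445
  ann <- make_annotation(sprintf("g%05d", seq_len(n_lr + n_hr)), "1H",
                         rep(c("LR_PC", "HR"), c(n_lr, n_hr)))
  # 290 pairs: 187 HR-HR, 103 LR-HR, 0 LR-LR
  hr_ids <- ann$gene_id[ann$label == "HR"]
  lr_ids <- ann$gene_id[ann$label == "LR_PC"]
  pairs <- data.frame(
    gene_a = c(hr_ids[1:187], lr_ids[1:103]),
    gene_b = c(hr_ids[188:374], hr_ids[375:477]),
    stringsAsFactors = FALSE)
  tb <- ohnolog_compartment_tables(pairs, ann)
  expect_equal(tb$genes$observed, c(477, 103))
  expect_equal(round(tb$genes$expected), c(437, 143))
  expect_equal(round(tb$pair_classes$expected), c(164, 108, 18))
  expect_equal(tb$pair_classes$observed, c(187, 103, 0))
  expect_equal(round(tb$lr_gene_share_pct), 18)
})

test_that("molecular clock rate follows r = Ks / 2T", {
  expect_equal(clock_rate(1.2, 60e6)$rate, 1e-8)
  expect_equal(clock_rate(0, 60e6)$rate, 0)
  expect_equal(clock_rate(1.290, 60e6)$rate, 1.075e-8)
  expect_error(clock_rate(1, 0), "positive")
  expect_error(clock_rate(-1, 1e6), "non-negative")
})
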