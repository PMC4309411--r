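test_that("windowed rate is constant on a uniform map", {
  m <- uniform_map(n = 200, rate = 0.5)
  prof <- windowed_rate(m, window = 50)
  expect_true(all(abs(prof$rate - 0.5) < 1e-12))
})

test_that("windowed rate is zero strictly inside a cM plateau", {
  m <- segment_map(rates = c(1, 0, 1), sizes = c(100, 200, 100))
  prof <- windowed_rate(m, window = 50)
  inside <- 126:275  # plateau 101..300, clear of window half-width 25
  expect_true(all(prof$rate[inside] == 0))
})

test_that("windowed rate matches brute-force window sums", {
  m <- segment_map(rates = c(1, 0.01, 1), sizes = c(300, 400, 300))
  w <- 50
  prof <- windowed_rate(m, window = w)
  cm <- m$genetic_pos
  n <- nrow(m)
  half <- floor(w / 2)
  brute <- vapply(seq_len(n), function(i) {
    lo <- max(1, i - half)
    hi <- min(n, i + (w - half))
    if (hi == lo) lo <- max(1, hi - 1)
    (cm[hi] - cm[lo]) / (hi - lo)
  }, numeric(1))
  expect_true(all(abs(prof$rate - brute) < 1e-9))
  expect_error(windowed_rate(uniform_map(30), window = 50), "smaller")
})

test_that("LR region calling obeys the fold and span rules", {
  # suppressed middle segment spanning 40% of the chromosome
  m <- segment_map(rates = c(1, 0.01, 1), sizes = c(300, 400, 300))
  prof <- windowed_rate(m, window = 50)
  reg <- call_lr_regions(prof, fold = 20, min_frac = 0.02)
  expect_equal(nrow(reg), 1L)
  expect_lte(abs(reg$start_index - 301), 25)
  expect_lte(abs(reg$end_index - 700), 25)

  # uniform map: no gene is 20-fold below the average
  expect_equal(nrow(call_lr_regions(windowed_rate(uniform_map(200)))), 0L)

  # plateau spanning about 1% of the chromosome fails the span rule
  m2 <- segment_map(rates = c(1, 0, 1), sizes = c(495, 10, 495))
  expect_equal(nrow(call_lr_regions(windowed_rate(m2, 8), fold = 20,
                                    min_frac = 0.02, gap_genes = 4)), 0L)
})

test_that("raising the fold threshold never enlarges called regions", {
  set.seed(42)
  for (rep in 1:5) {
    cfg <- sim_config(seed = rep, n_chromosomes = 1,
                      genes_per_chromosome = 500)
    sim <- simulate_genome_map(cfg)
    prof <- windowed_rate(clean_genetic_map(sim$map), 50)
    covered <- function(fold) {
      reg <- call_lr_regions(prof, fold = fold)
      if (nrow(reg) == 0) return(integer(0))
      unlist(lapply(seq_len(nrow(reg)),
                    function(r) reg$start_index[r]:reg$end_index[r]))
    }
    g10 <- covered(10); g20 <- covered(20); g40 <- covered(40)
    expect_true(all(g20 %in% g10))
    expect_true(all(g40 %in% g20))
  }
})

test_that("compartment labels partition the gene set", {
  cfg <- sim_config(seed = 8, n_chromosomes = 2, genes_per_chromosome = 400)
  sim <- simulate_genome_map(cfg)
  map <- clean_genetic_map(sim$map)
  reg <- call_lr_regions(windowed_rate(map, 50))
  ann <- assign_compartments(map, reg, sim$centromeres)
  expect_equal(nrow(ann), nrow(map))
  expect_false(anyNA(ann$label))
  expect_equal(sum(table(ann$label)), nrow(map))
  # LR_PC genes form one contiguous run per chromosome
  for (chr in unique(ann$chromosome)) {
    idx <- which(ann$chromosome == chr & ann$label == "LR_PC")
    if (length(idx) > 1) expect_equal(idx, seq(min(idx), max(idx)))
  }
})

test_that("centromere decides LR_PC vs LR_flank", {
  m <- segment_map(rates = c(1, 0.001, 1, 0.001, 1),
                   sizes = c(200, 100, 200, 100, 200))
  prof <- windowed_rate(m, window = 20)
  reg <- call_lr_regions(prof, fold = 20, min_frac = 0.02, gap_genes = 10)
  expect_equal(nrow(reg), 2L)
  cen <- data.frame(chromosome = "1A",
                    bp = m$physical_pos[250])  # inside first region
  ann <- assign_compartments(m, reg, cen)
  first <- ann$label[reg$start_index[1]:reg$end_index[1]]
  second <- ann$label[reg$start_index[2]:reg$end_index[2]]
  expect_true(all(first == "LR_PC"))
  expect_true(all(second == "LR_flank"))
  # centromere outside every region: all flank, with a warning
  cen2 <- data.frame(chromosome = "1A", bp = m$physical_pos[10])
  expect_warning(ann2 <- assign_compartments(m, reg, cen2), "centromere")
  expect_true(all(ann2$label[ann2$label != "HR"] == "LR_flank"))
})

test_that("map cleaning clamps non-monotone genetic positions", {
  m <- uniform_map(50, rate = 1)
  m$genetic_pos[10] <- 2  # below its neighbour at 9 cM
  m$genetic_pos[30] <- 5
  cleaned <- clean_genetic_map(m)
  expect_equal(attr(cleaned, "n_clamped"), 2L)
  expect_false(is.unsorted(cleaned$genetic_pos))
  expect_equal(cleaned$genetic_pos[10], m$genetic_pos[9])
})

test_that("compartment shares report the LR fraction", {
  ann <- make_annotation(sprintf("g%05d", 1:35134), "1H",
                         rep(c("LR_PC", "LR_flank", "HR"),
                             c(6285, 2400, 35134 - 6285 - 2400)))
  sh <- compartment_shares(ann)
  expect_equal(sh$total, 35134)
  expect_equal(round(sh$lr_share_pct, 1), 24.7)
})
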