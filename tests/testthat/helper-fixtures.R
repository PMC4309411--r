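# In-code fixture builders shared across test files.

# a map with cM strictly proportional to gene index within each chromosome
uniform_map <- function(n = 120, rate = 0.5, chrom = "1A") {
  gene_map(sprintf("%s_g%03d", chrom, seq_len(n)), chrom,
           rate * (seq_len(n) - 1), seq_len(n) * 1e5)
}

# three-segment map: HR / suppressed / HR with exact per-gene rates
segment_map <- function(rates = c(1, 0.01, 1), sizes = c(300, 400, 300),
                        chrom = "1A", bp_step = 1e5) {
  inc <- rep(rates, sizes)
  n <- length(inc)
  cm <- cumsum(inc) - inc[1]
  gene_map(sprintf("%s_g%04d", chrom, seq_len(n)), chrom, cm,
           seq_len(n) * bp_step)
}

# minimal variant table: one site with given per-sample (ref, alt) counts
vt1 <- function(ref_counts, alt_counts, ref_id = "g1", pos = 1L,
                ref = "A", alt = "G") {
  n <- length(ref_counts)
  samples <- sprintf("s%02d", seq_len(n))
  variant_table(
    data.frame(ref_id = ref_id, pos = pos, ref = ref, alt = alt,
               stringsAsFactors = FALSE),
    matrix(as.integer(ref_counts), 1, n, dimnames = list(NULL, samples)),
    matrix(as.integer(alt_counts), 1, n, dimnames = list(NULL, samples)))
}

# annotation table from a label vector (map order)
make_annotation <- function(gene_id, chromosome, label) {
  ann <- data.frame(gene_id = gene_id, chromosome = chromosome,
                    label = factor(label,
                                   levels = c("HR", "LR_flank", "LR_PC")),
                    region_id = NA_character_, stringsAsFactors = FALSE)
  class(ann) <- c("compartment_annotation", "data.frame")
  ann
}

# similarity hit row for tests
mk_hit <- function(q, s, bit, ident = 90, len = 600, evalue = 1e-50) {
  df <- data.frame(query_id = q, subject_id = s, pct_identity = ident,
                   aln_length = len, mismatches = 0L, gap_opens = 0L,
                   q_start = 1L, q_end = len, s_start = 1L, s_end = len,
                   evalue = evalue, bit_score = bit, strand = "+",
                   stringsAsFactors = FALSE)
  class(df) <- c("similarity_table", "data.frame")
  df
}

# exhaustive monotone-chain oracle: maximum chain size over all subsets of
# pairs that are strictly increasing in a, strictly monotone in b, with
# index gaps <= max_gap on both axes (independent of the DP implementation)
best_chain_bruteforce <- function(a, b, max_gap) {
  n <- length(a)
  ord <- order(a, b)
  a <- a[ord]; b <- b[ord]
  best <- 0L
  check_dir <- function(bb) {
    for (mask in seq_len(2^n) - 1L) {
      sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
      k <- length(sel)
      if (k <= best) next
      av <- a[sel]; bv <- bb[sel]
      if (k > 1) {
        if (any(diff(av) <= 0) || any(diff(bv) <= 0)) next
        if (any(diff(av) > max_gap) || any(diff(bv) > max_gap)) next
      }
      best <<- k
    }
  }
  check_dir(b)
  check_dir(max(b) + 1 - b)  # decreasing chains
  best
}
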