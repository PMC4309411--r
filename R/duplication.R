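# WGD ohnolog-pair detection from all-vs-all similarity tables: best-hit
# reduction, similarity filtering, reference reordering, dynamic-programming
# collinearity chaining (an in-package replacement for external collinearity
# tools), NG86 Ka/Ks with Jukes-Cantor correction, and Ks/uniqueness/region
# trimming. Plus local (tandem) duplicate calling via the second-best-hit
# rule with a physical-distance cutoff.

#' Best non-self hit per query
#'
#' Discards self-hits, keeps the best HSP per (query, subject) by bit score
#' (ties by smaller e-value), ranks subjects per query by bit score (ties by
#' smaller e-value, then lexicographic subject id) and returns the
#' \code{rank}-th subject for each query. With \code{same_chromosome = TRUE}
#' only subjects on the query's chromosome are considered (the second-best
#' hit rule used for local duplicates, since the best overall is self).
#'
#' @param hits a \code{similarity_table}.
#' @param rank which ranked subject to return (default 1 = best non-self).
#' @param same_chromosome restrict subjects to the query's chromosome.
#' @param map a \code{gene_map}; required when \code{same_chromosome}.
#' @return data.frame: query_id, subject_id, bit_score, pct_identity,
#'   aln_length, evalue.
#' @export
best_nonself_hits <- function(hits, rank = 1, same_chromosome = FALSE,
                              map = NULL) {
  h <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  if (same_chromosome) {
    if (is.null(map)) stop("same_chromosome = TRUE requires a gene map")
    chr <- map$chromosome
    names(chr) <- map$gene_id
    keep <- !is.na(chr[h$query_id]) & !is.na(chr[h$subject_id]) &
      chr[h$query_id] == chr[h$subject_id]
    h <- h[keep, , drop = FALSE]
  }
  if (nrow(h) == 0)
    return(data.frame(query_id = character(), subject_id = character(),
                      bit_score = numeric(), pct_identity = numeric(),
                      aln_length = numeric(), evalue = numeric(),
                      stringsAsFactors = FALSE))
  # best HSP per (query, subject), then rank subjects within query
  h <- h[order(h$query_id, h$subject_id, -h$bit_score, h$evalue), ,
         drop = FALSE]
  h <- h[!duplicated(h[, c("query_id", "subject_id")]), , drop = FALSE]
  h <- h[order(h$query_id, -h$bit_score, h$evalue, h$subject_id), ,
         drop = FALSE]
  pos <- stats::ave(seq_len(nrow(h)), h$query_id, FUN = seq_along)
  h <- h[pos == rank, , drop = FALSE]
  out <- h[, c("query_id", "subject_id", "bit_score", "pct_identity",
               "aln_length", "evalue")]
  rownames(out) <- NULL
  out
}

#' Canonicalize paralog pairs
#'
#' Stores each unordered pair once with gene_a < gene_b lexicographically;
#' duplicates (the same pair reached from both queries) keep the higher
#' bit score.
#'
#' @param pairs output of \code{best_nonself_hits}.
#' @return data.frame with gene_a, gene_b and the similarity columns.
#' @export
canonical_pairs <- function(pairs) {
  ga <- pmin(pairs$query_id, pairs$subject_id)
  gb <- pmax(pairs$query_id, pairs$subject_id)
  df <- data.frame(gene_a = ga, gene_b = gb,
                   bit_score = pairs$bit_score,
                   pct_identity = pairs$pct_identity,
                   aln_length = pairs$aln_length, evalue = pairs$evalue,
                   stringsAsFactors = FALSE)
  df <- df[order(df$gene_a, df$gene_b, -df$bit_score), , drop = FALSE]
  df <- df[!duplicated(df[, c("gene_a", "gene_b")]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Filter paralog pairs on similarity bounds
#'
#' Removes pairs much too similar to be WGD-derived (bit score above
#' \code{bit_max}, or 100 percent identity over more than
#' \code{ident_len}) and very weakly related pairs (bit score below
#' \code{bit_min} AND alignment length below \code{len_min}).
#'
#' @param pairs canonical pair table with bit_score, pct_identity,
#'   aln_length.
#' @param bit_max,ident_len,bit_min,len_min filter thresholds (defaults
#'   8000, 200 bp, 300, 500 bp).
#' @return the filtered pairs with attribute \code{n_removed}.
#' @export
filter_paralog_pairs <- function(pairs, bit_max = 8000, ident_len = 200,
                                 bit_min = 300, len_min = 500) {
  too_similar <- pairs$bit_score > bit_max |
    (pairs$pct_identity == 100 & pairs$aln_length > ident_len)
  too_weak <- pairs$bit_score < bit_min & pairs$aln_length < len_min
  out <- pairs[!too_similar & !too_weak, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(too_similar | too_weak)
  out
}

#' Reorder genes by reference (outgroup) gene order within synteny blocks
#'
#' Replaces map order by the reference genome's gene order within each
#' collinear synteny block: genes without a reference anchor are dropped
#' (counted), genes in regions of low anchor density (nearest anchored
#' neighbours more than \code{max_anchor_gap} reference genes away) are
#' dropped, then genes are sorted by reference order within blocks while
#' block order along the chromosome is preserved.
#'
#' @param map a \code{gene_map}.
#' @param anchors data.frame with columns gene_id, block_id, ref_order
#'   (the gene's position in the reference genome's order).
#' @param max_anchor_gap density cutoff in reference genes (default 400).
#' @return data.frame gene_id, chromosome, order_index (1-based per
#'   chromosome); attributes n_no_anchor, n_low_density.
#' @export
reorder_by_reference <- function(map, anchors, max_anchor_gap = 400) {
  a <- anchors[match(map$gene_id, anchors$gene_id), , drop = FALSE]
  anchored <- !is.na(a$gene_id)
  n_no_anchor <- sum(!anchored)
  df <- cbind(map[anchored, , drop = FALSE],
              block_id = a$block_id[anchored],
              ref_order = a$ref_order[anchored])
  # density filter along map order within chromosomes
  keep <- rep(TRUE, nrow(df))
  for (chr in unique(df$chromosome)) {
    i <- which(df$chromosome == chr)
    r <- df$ref_order[i]
    n <- length(i)
    if (n < 2) next
    gap_prev <- c(Inf, abs(diff(r)))
    gap_next <- c(abs(diff(r)), Inf)
    keep[i] <- pmin(gap_prev, gap_next) <= max_anchor_gap
  }
  n_low_density <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  out <- list()
  for (chr in unique(df$chromosome)) {
    i <- which(df$chromosome == chr)
    sub <- df[i, , drop = FALSE]
    # block order along the chromosome = order of first appearance
    blocks <- unique(sub$block_id)
    ord <- unlist(lapply(blocks, function(b) {
      j <- which(sub$block_id == b)
      j[order(sub$ref_order[j])]
    }))
    out[[chr]] <- data.frame(gene_id = sub$gene_id[ord], chromosome = chr,
                             order_index = seq_along(ord),
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_no_anchor") <- n_no_anchor
  attr(res, "n_low_density") <- n_low_density
  res
}

#' Remove genes with anomalous genetic map positions
#'
#' A gene is removed when its cM position deviates from the running median
#' (window of \code{window} genes along map order) by more than
#' \code{z_max} running MADs. A zero running MAD (locally constant map)
#' removes nothing.
#'
#' @param map a \code{gene_map}.
#' @param window odd window size for the running median (default 51).
#' @param z_max deviation threshold in MAD units (default 5).
#' @return the filtered \code{gene_map} with attribute \code{n_removed}.
#' @export
remove_map_outliers <- function(map, window = 51, z_max = 5) {
  if (window %% 2 == 0) window <- window + 1
  drop <- rep(FALSE, nrow(map))
  for (chr in unique(map$chromosome)) {
    i <- which(map$chromosome == chr)
    cm <- map$genetic_pos[i]
    k <- min(window, if (length(cm) %% 2 == 0) length(cm) - 1 else
      length(cm))
    if (k < 3) next
    med <- stats::runmed(cm, k, endrule = "med")
    dev <- abs(cm - med)
    mad_run <- stats::runmed(dev, k, endrule = "med") * 1.4826
    drop[i] <- mad_run > 0 & dev > z_max * mad_run
  }
  out <- map[!drop, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(map)
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Attach per-chromosome gene-index positions to pairs
#'
#' @param pairs canonical pair table.
#' @param ordering data.frame gene_id, chromosome, order_index (e.g. from
#'   \code{reorder_by_reference}, or map order via \code{map_ordering}).
#' @return pairs with a_chr, a_idx, b_chr, b_idx columns; pairs with a gene
#'   absent from the ordering are dropped (attribute \code{n_unplaced}).
#' @export
attach_pair_indices <- function(pairs, ordering) {
  ia <- match(pairs$gene_a, ordering$gene_id)
  ib <- match(pairs$gene_b, ordering$gene_id)
  ok <- !is.na(ia) & !is.na(ib)
  out <- pairs[ok, , drop = FALSE]
  out$a_chr <- ordering$chromosome[ia[ok]]
  out$a_idx <- ordering$order_index[ia[ok]]
  out$b_chr <- ordering$chromosome[ib[ok]]
  out$b_idx <- ordering$order_index[ib[ok]]
  # canonical chromosome orientation for grouping
  swap <- out$b_chr < out$a_chr
  tmp_chr <- out$a_chr[swap]; tmp_idx <- out$a_idx[swap]
  out$a_chr[swap] <- out$b_chr[swap]; out$a_idx[swap] <- out$b_idx[swap]
  out$b_chr[swap] <- tmp_chr; out$b_idx[swap] <- tmp_idx
  rownames(out) <- NULL
  attr(out, "n_unplaced") <- sum(!ok)
  out
}

#' Gene-map order as an ordering table
#' @param map a \code{gene_map}.
#' @return data.frame gene_id, chromosome, order_index.
#' @export
map_ordering <- function(map) {
  idx <- stats::ave(seq_len(nrow(map)), map$chromosome, FUN = seq_along)
  data.frame(gene_id = map$gene_id, chromosome = map$chromosome,
             order_index = as.integer(idx), stringsAsFactors = FALSE)
}

# longest chain strictly increasing in a and b with index gaps <= max_gap;
# returns indices into (a, b) of the best chain
chain_dp <- function(a, b, max_gap) {
  n <- length(a)
  ord <- order(a, b)
  a <- a[ord]; b <- b[ord]
  len <- rep(1L, n)
  par <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (a[j] < a[i] && b[j] < b[i] &&
          a[i] - a[j] <= max_gap && b[i] - b[j] <= max_gap &&
          len[j] + 1L > len[i]) {
        len[i] <- len[j] + 1L
        par[i] <- j
      }
    }
  }
  best <- which.max(len)
  chain <- integer(0)
  k <- best
  while (k != 0L) {
    chain <- c(k, chain)
    k <- par[k]
  }
  list(members = ord[chain], length = len[best])
}

#' Detect collinear (ohnologous) regions by monotone chaining
#'
#' Dynamic-programming chaining of paralog pairs: a chain is strictly
#' increasing in one chromosome's gene index and strictly monotone
#' (increasing or decreasing) in the other's, with index gaps of at most
#' \code{max_gap} on both chromosomes between consecutive members. Chains
#' are extracted greedily by score (pair count) per chromosome pair; each
#' pair joins at most one region; chains shorter than \code{min_pairs} are
#' not reported.
#'
#' @param pairs pair table with a_chr, a_idx, b_chr, b_idx (see
#'   \code{attach_pair_indices}).
#' @param min_pairs minimum pairs per region (default 9).
#' @param max_gap maximum intervening gene gap (default 25).
#' @return list with \code{regions} (region_id, a_chr, b_chr, n_pairs,
#'   orientation) and \code{pairs} (input rows with a \code{region_id}
#'   column, NA for unassigned pairs).
#' @export
detect_collinear_regions <- function(pairs, min_pairs = 9, max_gap = 25) {
  pairs$region_id <- NA_character_
  regions <- list()
  grp <- paste(pairs$a_chr, pairs$b_chr, sep = "|")
  rn <- 0L
  for (g in unique(grp)) {
    avail <- which(grp == g & is.na(pairs$region_id))
    repeat {
      if (length(avail) == 0 || length(avail) < min_pairs) break
      fwd <- chain_dp(pairs$a_idx[avail], pairs$b_idx[avail], max_gap)
      rev <- chain_dp(pairs$a_idx[avail], -pairs$b_idx[avail], max_gap)
      use <- if (fwd$length >= rev$length) fwd else rev
      orientation <- if (fwd$length >= rev$length) "same" else "inverted"
      if (use$length < min_pairs) break
      rn <- rn + 1L
      rid <- sprintf("R%03d", rn)
      sel <- avail[use$members]
      pairs$region_id[sel] <- rid
      regions[[rid]] <- data.frame(
        region_id = rid, a_chr = pairs$a_chr[sel[1]],
        b_chr = pairs$b_chr[sel[1]], n_pairs = use$length,
        orientation = orientation, stringsAsFactors = FALSE)
      avail <- setdiff(avail, sel)
    }
  }
  reg <- if (length(regions) > 0) do.call(rbind, regions) else
    data.frame(region_id = character(), a_chr = character(),
               b_chr = character(), n_pairs = integer(),
               orientation = character(), stringsAsFactors = FALSE)
  rownames(reg) <- NULL
  list(regions = reg, pairs = pairs)
}

#' NG86 Ka/Ks with Jukes-Cantor correction
#'
#' Nei-Gojobori (1986) counting on a pair of aligned coding sequences:
#' fractional synonymous (S) and nonsynonymous (N) site counts averaged
#' over the two sequences; observed synonymous (Sd) and nonsynonymous (Nd)
#' differences averaged over all shortest substitution pathways within each
#' codon (all pathways weighted equally, steps through stop codons counted
#' like any other; stop is treated as a 21st amino acid). Proportions are
#' Jukes-Cantor corrected: K = -3/4 ln(1 - 4p/3). A proportion >= 0.75
#' saturates: the corresponding rate is NA and the pair is flagged.
#'
#' @param cds_a,cds_b aligned coding sequences: equal length, divisible by
#'   3, no internal stop codons; codons containing a gap ("-") are skipped.
#' @return list with ka, ks, ka_ks, S, N, Sd, Nd and \code{saturated}.
#' @export
ng86_ka_ks <- function(cds_a, cds_b) {
  a <- toupper(as.character(cds_a))
  b <- toupper(as.character(cds_b))
  if (nchar(a) != nchar(b)) stop("sequences must be aligned (equal length)")
  if (nchar(a) %% 3 != 0) stop("alignment length must be divisible by 3")
  starts <- seq(1, nchar(a), 3)
  cod_a <- substring(a, starts, starts + 2)
  cod_b <- substring(b, starts, starts + 2)
  gap <- grepl("-", cod_a) | grepl("-", cod_b)
  cod_a <- cod_a[!gap]; cod_b <- cod_b[!gap]
  tab <- codon_tables()
  stops <- names(tab$aa)[tab$aa == "*"]
  ncod <- length(cod_a)
  if (ncod > 1) {
    if (any(cod_a[-ncod] %in% stops) || any(cod_b[-ncod] %in% stops))
      stop("internal stop codon in input")
  }
  s_a <- sum(tab$syn_sites[cod_a])
  s_b <- sum(tab$syn_sites[cod_b])
  S <- (s_a + s_b) / 2
  N <- 3 * ncod - S
  Sd <- 0; Nd <- 0
  for (k in seq_len(ncod)) {
    d <- codon_path_counts(cod_a[k], cod_b[k], tab)
    Sd <- Sd + d[1]; Nd <- Nd + d[2]
  }
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  ks <- jc(ps); ka <- jc(pn)
  saturated <- ps >= 0.75 || pn >= 0.75
  ka_ks <- if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks else NA_real_
  list(ka = ka, ks = ks, ka_ks = ka_ks, S = S, N = N, Sd = Sd, Nd = Nd,
       saturated = saturated)
}

# average (syn, nonsyn) difference counts over all orderings of the
# differing positions between two codons
codon_path_counts <- function(ca, cb, tab) {
  if (ca == cb) return(c(0, 0))
  cha <- strsplit(ca, "")[[1]]
  chb <- strsplit(cb, "")[[1]]
  diffp <- which(cha != chb)
  d <- length(diffp)
  perms <- if (d == 1) list(diffp) else
    if (d == 2) list(diffp, rev(diffp)) else
      lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2),
                  c(3,2,1)), function(o) diffp[o])
  syn <- 0; nonsyn <- 0
  for (path in perms) {
    cur <- cha
    for (p in path) {
      nxt <- cur
      nxt[p] <- chb[p]
      aa1 <- tab$aa[[paste(cur, collapse = "")]]
      aa2 <- tab$aa[[paste(nxt, collapse = "")]]
      if (identical(aa1, aa2)) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
  }
  c(syn, nonsyn) / length(perms)
}

#' Trim candidate ohnolog pairs
#'
#' Applies the post-chaining trims in order, reporting counts per rule:
#' (1) pairs with Ks above \code{ks_max} (or saturated/undefined Ks);
#' (2) every pair containing a gene that appears in more than one pair
#' (all such pairs removed, not best-kept); (3) pairs whose region, after
#' the previous removals, holds fewer than \code{min_pairs} pairs (pairs
#' without a region are removed here too); (4) where two regions overlap in
#' gene-index span on either chromosome, the pairs of the weaker region
#' (fewer pairs; ties broken by lower mean Ks, then region id).
#'
#' @param pairs pair table with gene_a, gene_b, ks, region_id and index
#'   columns (a_chr, a_idx, b_chr, b_idx).
#' @param ks_max Ks ceiling (default 3).
#' @param min_pairs minimum region strength (default 9).
#' @return list with \code{pairs} (final table) and \code{removed}
#'   (named counts per rule).
#' @export
trim_ohnolog_pairs <- function(pairs, ks_max = 3, min_pairs = 9) {
  removed <- c(ks = 0L, multi_pair_gene = 0L, weak_region = 0L,
               region_overlap = 0L)
  keep <- !is.na(pairs$ks) & pairs$ks <= ks_max
  removed["ks"] <- sum(!keep)
  pairs <- pairs[keep, , drop = FALSE]
  genes <- c(pairs$gene_a, pairs$gene_b)
  dup_genes <- unique(genes[duplicated(genes)])
  bad <- pairs$gene_a %in% dup_genes | pairs$gene_b %in% dup_genes
  removed["multi_pair_gene"] <- sum(bad)
  pairs <- pairs[!bad, , drop = FALSE]
  strength <- table(pairs$region_id[!is.na(pairs$region_id)])
  st <- rep(0L, nrow(pairs))
  has_reg <- !is.na(pairs$region_id)
  st[has_reg] <- as.integer(strength[pairs$region_id[has_reg]])
  weak <- !has_reg | st < min_pairs
  removed["weak_region"] <- sum(weak)
  pairs <- pairs[!weak, , drop = FALSE]
  # region overlap resolution on gene-index spans
  if (nrow(pairs) > 0) {
    rids <- unique(pairs$region_id)
    spans <- do.call(rbind, lapply(rids, function(r) {
      p <- pairs[pairs$region_id == r, , drop = FALSE]
      rbind(
        data.frame(region_id = r, chrom = p$a_chr[1], lo = min(p$a_idx),
                   hi = max(p$a_idx), stringsAsFactors = FALSE),
        data.frame(region_id = r, chrom = p$b_chr[1], lo = min(p$b_idx),
                   hi = max(p$b_idx), stringsAsFactors = FALSE))
    }))
    info <- data.frame(
      region_id = rids,
      strength = as.integer(table(pairs$region_id)[rids]),
      mean_ks = vapply(rids, function(r)
        mean(pairs$ks[pairs$region_id == r]), numeric(1)),
      stringsAsFactors = FALSE)
    info <- info[order(-info$strength, info$mean_ks, info$region_id), ,
                 drop = FALSE]
    kept <- character(0)
    for (r in info$region_id) {
      sp_r <- spans[spans$region_id == r, , drop = FALSE]
      sp_k <- spans[spans$region_id %in% kept, , drop = FALSE]
      clash <- FALSE
      for (i in seq_len(nrow(sp_r))) {
        same <- sp_k[sp_k$chrom == sp_r$chrom[i], , drop = FALSE]
        if (any(same$lo <= sp_r$hi[i] & sp_r$lo[i] <= same$hi)) {
          clash <- TRUE
          break
        }
      }
      if (!clash) kept <- c(kept, r)
    }
    drop <- !(pairs$region_id %in% kept)
    removed["region_overlap"] <- sum(drop)
    pairs <- pairs[!drop, , drop = FALSE]
  }
  rownames(pairs) <- NULL
  stopifnot(!anyDuplicated(c(pairs$gene_a, pairs$gene_b)))
  list(pairs = pairs, removed = removed)
}

#' End-to-end ohnolog pair detection
#'
#' Wires the full chain: best non-self hits, canonical pairs, similarity
#' filtering, index attachment on the supplied gene ordering, collinearity
#' chaining, NG86 Ka/Ks on each chained pair, and trimming.
#'
#' @param hits a \code{similarity_table} (all-vs-all).
#' @param ordering gene ordering table (gene_id, chromosome, order_index),
#'   typically \code{map_ordering(map)} or \code{reorder_by_reference}.
#' @param cds named character vector (or DNAStringSet) of coding sequences
#'   used for Ka/Ks; pairs are compared over their common codon length.
#' @param min_pairs,max_gap,ks_max pipeline parameters (defaults 9, 25, 3).
#' @param bit_max,ident_len,bit_min,len_min similarity filters (see
#'   \code{filter_paralog_pairs}).
#' @return list: pairs (final OhnologPair table with ka, ks, ka_ks,
#'   region_id), regions, removed counts, n_candidates.
#' @export
find_ohnologs <- function(hits, ordering, cds, min_pairs = 9, max_gap = 25,
                          ks_max = 3, bit_max = 8000, ident_len = 200,
                          bit_min = 300, len_min = 500) {
  nm <- names(cds)
  cds <- toupper(as.character(cds))
  names(cds) <- nm
  if (is.null(nm)) stop("cds must be named by gene id")
  best <- best_nonself_hits(hits)
  cand <- canonical_pairs(best)
  cand <- filter_paralog_pairs(cand, bit_max, ident_len, bit_min, len_min)
  cand <- attach_pair_indices(cand, ordering)
  det <- detect_collinear_regions(cand, min_pairs = min_pairs,
                                  max_gap = max_gap)
  pr <- det$pairs
  chained <- !is.na(pr$region_id)
  pr$ka <- NA_real_; pr$ks <- NA_real_; pr$ka_ks <- NA_real_
  for (i in which(chained)) {
    if (!(pr$gene_a[i] %in% names(cds)) ||
        !(pr$gene_b[i] %in% names(cds))) next
    sa <- cds[[pr$gene_a[i]]]
    sb <- cds[[pr$gene_b[i]]]
    len <- 3 * (min(nchar(sa), nchar(sb)) %/% 3)
    kk <- ng86_ka_ks(substr(sa, 1, len), substr(sb, 1, len))
    pr$ka[i] <- kk$ka; pr$ks[i] <- kk$ks; pr$ka_ks[i] <- kk$ka_ks
  }
  trim <- trim_ohnolog_pairs(pr[chained, , drop = FALSE], ks_max = ks_max,
                             min_pairs = min_pairs)
  regions <- det$regions[det$regions$region_id %in%
                           unique(trim$pairs$region_id), , drop = FALSE]
  list(pairs = trim$pairs, regions = regions, removed = trim$removed,
       n_candidates = nrow(cand))
}

#' Call local (tandem) gene duplicates
#'
#' For each query the best same-chromosome non-self hit is classified by
#' physical distance: within \code{frac} of the chromosome length (rule is
#' "remote by more than frac", so a distance of exactly frac x length is
#' local) it is a local duplicate, beyond it an intrachromosomal
#' translocation. A gene is locally duplicated if it is query or subject of
#' at least one local pair.
#'
#' @param hits a \code{similarity_table}.
#' @param map a \code{gene_map}.
#' @param frac distance cutoff as fraction of chromosome length
#'   (default 0.02).
#' @param chrom_lengths optional named bp lengths; defaults to the maximum
#'   mapped position per chromosome.
#' @return list: local (pair table with distance), translocations,
#'   duplicated_genes (character), n_skipped (hits with unmapped genes).
#' @export
call_local_duplicates <- function(hits, map, frac = 0.02,
                                  chrom_lengths = NULL) {
  chr <- map$chromosome; names(chr) <- map$gene_id
  bp <- map$physical_pos; names(bp) <- map$gene_id
  h <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  mapped <- !is.na(chr[h$query_id]) & !is.na(chr[h$subject_id])
  n_skipped <- sum(!mapped)
  best <- best_nonself_hits(h[mapped, , drop = FALSE],
                            same_chromosome = TRUE, map = map)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(map$physical_pos, map$chromosome, max)
  }
  if (nrow(best) == 0)
    return(list(local = best, translocations = best,
                duplicated_genes = character(), n_skipped = n_skipped))
  best$chromosome <- unname(chr[best$query_id])
  best$distance <- abs(bp[best$query_id] - bp[best$subject_id])
  cutoff <- frac * unlist(chrom_lengths)[best$chromosome]
  is_local <- best$distance <= cutoff
  local <- best[is_local, , drop = FALSE]
  rownames(local) <- NULL
  trans <- best[!is_local, , drop = FALSE]
  rownames(trans) <- NULL
  list(local = local, translocations = trans,
       duplicated_genes = sort(unique(c(local$query_id,
                                        local$subject_id))),
       n_skipped = n_skipped)
}

#' Ohnolog pair compartment class
#'
#' @param pairs pair table with gene_a, gene_b.
#' @param annotations a \code{compartment_annotation}.
#' @return factor with levels HR-HR, LR-HR, LR-LR.
#' @export
ohnolog_pair_class <- function(pairs, annotations) {
  lab <- as.character(two_class_label(annotations))
  names(lab) <- annotations$gene_id
  la <- lab[pairs$gene_a]
  lb <- lab[pairs$gene_b]
  cls <- ifelse(la == "LR" & lb == "LR", "LR-LR",
                ifelse(la == "HR" & lb == "HR", "HR-HR", "LR-HR"))
  factor(cls, levels = c("HR-HR", "LR-HR", "LR-LR"))
}

#' Observed vs expected ohnolog distribution by compartment
#'
#' (a) Gene level: observed HR/LR counts among ohnolog genes against
#' expectations from the genome-wide compartment gene fractions;
#' (b) pair level: observed HR-HR / LR-HR / LR-LR counts against
#' n_pairs x (p^2, 2pq, q^2) with q the LR gene fraction. Both come with a
#' goodness-of-fit chi-squared.
#'
#' @param pairs final ohnolog pair table.
#' @param annotations a \code{compartment_annotation} of all mapped genes.
#' @return list with \code{genes} and \code{pair_classes} tables (observed,
#'   expected) and their \code{compartment_test}s, plus
#'   \code{lr_gene_share_pct} (percent of ohnolog genes in LR).
#' @export
ohnolog_compartment_tables <- function(pairs, annotations) {
  lab_all <- two_class_label(annotations)
  q <- mean(lab_all == "LR")
  genes <- c(pairs$gene_a, pairs$gene_b)
  lab <- as.character(lab_all)
  names(lab) <- annotations$gene_id
  gl <- lab[genes]
  obs_g <- c(HR = sum(gl == "HR"), LR = sum(gl == "LR"))
  exp_g <- length(genes) * c(HR = 1 - q, LR = q)
  cls <- ohnolog_pair_class(pairs, annotations)
  obs_p <- c(`HR-HR` = sum(cls == "HR-HR"), `LR-HR` = sum(cls == "LR-HR"),
             `LR-LR` = sum(cls == "LR-LR"))
  exp_p <- nrow(pairs) * c(`HR-HR` = (1 - q)^2, `LR-HR` = 2 * q * (1 - q),
                           `LR-LR` = q^2)
  list(
    genes = data.frame(compartment = names(obs_g), observed = unname(obs_g),
                       expected = unname(exp_g), stringsAsFactors = FALSE),
    genes_test = chi2_gof(obs_g, exp_g),
    pair_classes = data.frame(class = names(obs_p),
                              observed = unname(obs_p),
                              expected = unname(exp_p),
                              stringsAsFactors = FALSE),
    pair_classes_test = chi2_gof(obs_p, exp_p),
    lr_gene_fraction = q,
    lr_gene_share_pct = 100 * obs_g[["LR"]] / length(genes)
  )
}

#' Local-duplication depletion table by chromosome
#'
#' Per chromosome and in total: HR/LR counts among locally duplicated genes
#' and among all mapped genes, the percent-LR of each, their ratio, and a
#' two-tailed Yates chi-squared p-value. By default the 2x2 table is
#' {locally duplicated genes, all mapped genes} x {HR, LR} (overlapping
#' categories, the construction that reproduces observed/expected report
#' tables); \code{mode = "disjoint"} uses duplicated vs non-duplicated.
#'
#' @param duplicated_genes character vector of locally duplicated gene ids.
#' @param annotations a \code{compartment_annotation} of all mapped genes.
#' @param mode "overlapping" (default) or "disjoint".
#' @return data.frame with one row per chromosome plus a Total row;
#'   attribute \code{depletion_pct} = 100 x (1 - total ratio).
#' @export
local_dup_table <- function(duplicated_genes, annotations,
                            mode = c("overlapping", "disjoint")) {
  mode <- match.arg(mode)
  lab <- two_class_label(annotations)
  is_dup <- annotations$gene_id %in% duplicated_genes
  mk_row <- function(sel, name) {
    dup_hr <- sum(sel & is_dup & lab == "HR")
    dup_lr <- sum(sel & is_dup & lab == "LR")
    all_hr <- sum(sel & lab == "HR")
    all_lr <- sum(sel & lab == "LR")
    pct_dup <- 100 * dup_lr / (dup_hr + dup_lr)
    pct_all <- 100 * all_lr / (all_hr + all_lr)
    tab <- if (mode == "overlapping")
      matrix(c(dup_hr, dup_lr, all_hr, all_lr), 2, byrow = TRUE)
    else
      matrix(c(dup_hr, dup_lr, all_hr - dup_hr, all_lr - dup_lr), 2,
             byrow = TRUE)
    p <- if (all(rowSums(tab) > 0) && all(colSums(tab) > 0))
      chi2_2x2_yates(tab)$p else NA_real_
    data.frame(chromosome = name, dup_hr = dup_hr, dup_lr = dup_lr,
               dup_total = dup_hr + dup_lr, pct_lr_dup = pct_dup,
               all_hr = all_hr, all_lr = all_lr,
               all_total = all_hr + all_lr, pct_lr_all = pct_all,
               ratio = pct_dup / pct_all, p = p, stringsAsFactors = FALSE)
  }
  rows <- lapply(sort(unique(annotations$chromosome)), function(chr)
    mk_row(annotations$chromosome == chr, chr))
  rows[[length(rows) + 1L]] <- mk_row(rep(TRUE, nrow(annotations)), "Total")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "depletion_pct") <-
    100 * (1 - out$ratio[out$chromosome == "Total"])
  out
}

#' Round a depletion table to report precision
#'
#' Ratios to 2 decimals and p-values to 4 decimals, matching the printed
#' table convention.
#' @param tab output of \code{local_dup_table}.
#' @return the table with rounded ratio, p and percent columns.
#' @export
format_local_dup_table <- function(tab) {
  tab$pct_lr_dup <- round(tab$pct_lr_dup, 1)
  tab$pct_lr_all <- round(tab$pct_lr_all, 1)
  tab$ratio <- round(tab$ratio, 2)
  tab$p <- round(tab$p, 4)
  tab
}

#' Molecular clock rate from mean Ks
#'
#' r = mean Ks / (2 T): substitutions per site per year given a divergence
#' time T in years.
#' @param ks_mean mean synonymous divergence (substitutions/site).
#' @param t_years divergence time in years (> 0).
#' @return list with ks_mean, t_years, rate.
#' @export
clock_rate <- function(ks_mean, t_years) {
  if (ks_mean < 0) stop("ks_mean must be non-negative")
  if (t_years <= 0) stop("t_years must be positive")
  list(ks_mean = ks_mean, t_years = t_years,
       rate = ks_mean / (2 * t_years))
}
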