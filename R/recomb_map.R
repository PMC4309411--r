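# Compartment calling from a Marey-style map (genetic cM vs physical bp per
# gene). Rate unit is cM per gene along map order, as plotted in per-gene
# genome scans; physical length enters only through the minimum-span rule.

#' Make genetic positions non-decreasing within chromosomes
#'
#' Raw maps can contain small inversions from mapping error that would
#' produce negative local rates. Positions are clamped isotonically
#' (cM_i := max(cM_i, cM_{i-1}) along physical order); the number of clamped
#' genes is recorded in attribute \code{n_clamped}.
#'
#' @param map a \code{gene_map}.
#' @return the cleaned \code{gene_map} with attribute \code{n_clamped}.
#' @export
clean_genetic_map <- function(map) {
  n_clamped <- 0L
  for (chr in unique(map$chromosome)) {
    i <- which(map$chromosome == chr)
    cm <- cummax(map$genetic_pos[i])
    n_clamped <- n_clamped + sum(cm != map$genetic_pos[i])
    map$genetic_pos[i] <- cm
  }
  attr(map, "n_clamped") <- n_clamped
  map
}

#' Windowed recombination rate per gene
#'
#' For gene i on a chromosome the rate is the cM gained across a centered
#' window of \code{window} gene intervals, divided by the number of
#' intervals actually spanned (windows are clamped at chromosome ends):
#' R_i = (cM[hi] - cM[lo]) / (hi - lo) with lo = max(1, i - w/2),
#' hi = min(n, i + w/2). The chromosome mean rate is total cM / gene count.
#'
#' @param map a \code{gene_map}, genetic positions non-decreasing per
#'   chromosome (see \code{clean_genetic_map}).
#' @param window window size in gene intervals (default 50, the package's
#'   rolling-average convention).
#' @return a data.frame of class \code{rate_profile} with columns
#'   \code{gene_id}, \code{chromosome}, \code{physical_pos}, \code{rate};
#'   attributes \code{chrom_mean} (named vector) and \code{window}.
#' @export
windowed_rate <- function(map, window = 50) {
  if (window < 1) stop("window must be >= 1")
  half <- floor(window / 2)
  out <- vector("list", length(unique(map$chromosome)))
  chroms <- unique(map$chromosome)
  chrom_mean <- numeric(length(chroms))
  names(chrom_mean) <- chroms
  for (k in seq_along(chroms)) {
    i <- which(map$chromosome == chroms[k])
    n <- length(i)
    if (n < window + 1)
      stop("chromosome ", chroms[k], " has ", n, " genes; need > window (",
           window, ") - use a smaller window")
    cm <- map$genetic_pos[i]
    if (is.unsorted(cm)) stop("genetic positions must be non-decreasing; ",
                              "run clean_genetic_map() first")
    idx <- seq_len(n)
    lo <- pmax(1L, idx - half)
    hi <- pmin(n, idx + (window - half))
    lo[hi == lo] <- pmax(1L, hi[hi == lo] - 1L)  # degenerate end window
    rate <- (cm[hi] - cm[lo]) / (hi - lo)
    chrom_mean[k] <- (cm[n] - cm[1]) / n
    out[[k]] <- data.frame(gene_id = map$gene_id[i],
                           chromosome = chroms[k],
                           physical_pos = map$physical_pos[i],
                           rate = rate, stringsAsFactors = FALSE)
  }
  prof <- do.call(rbind, out)
  rownames(prof) <- NULL
  attr(prof, "chrom_mean") <- chrom_mean
  attr(prof, "window") <- window
  class(prof) <- c("rate_profile", "data.frame")
  prof
}

#' Call low-recombining (LR) regions
#'
#' Maximal runs of consecutive genes whose windowed rate is at or below the
#' chromosome mean divided by \code{fold} (a gene exactly at the threshold is
#' inside the run). Runs separated by fewer than \code{gap_genes} high-rate
#' genes are merged, then runs are retained only if their physical span
#' exceeds \code{min_frac} of the chromosome's physical length (taken as the
#' maximum mapped physical position unless \code{chrom_lengths} is given).
#'
#' @param profile a \code{rate_profile} from \code{windowed_rate}.
#' @param fold suppression threshold relative to the chromosome mean
#'   (default 20).
#' @param min_frac minimum physical span as a fraction of chromosome length
#'   (default 0.02).
#' @param gap_genes runs separated by fewer than this many high-rate genes
#'   are merged before the span test (default 25).
#' @param chrom_lengths optional named vector of chromosome lengths in bp.
#' @return a data.frame of class \code{lr_regions}: \code{region_id},
#'   \code{chromosome}, \code{start_bp}, \code{end_bp}, \code{start_index},
#'   \code{end_index}, \code{n_genes}.
#' @export
call_lr_regions <- function(profile, fold = 20, min_frac = 0.02,
                            gap_genes = 25, chrom_lengths = NULL) {
  chrom_mean <- attr(profile, "chrom_mean")
  res <- list()
  for (chr in unique(profile$chromosome)) {
    i <- which(profile$chromosome == chr)
    rate <- profile$rate[i]
    bp <- profile$physical_pos[i]
    thr <- chrom_mean[[chr]] / fold
    low <- rate <= thr
    runs <- run_bounds(low)
    if (nrow(runs) == 0) next
    # merge runs separated by short high-rate gaps
    merged <- runs[1, , drop = FALSE]
    if (nrow(runs) > 1) {
      for (r in 2:nrow(runs)) {
        gap <- runs$start[r] - merged$end[nrow(merged)] - 1L
        if (gap < gap_genes) {
          merged$end[nrow(merged)] <- runs$end[r]
        } else {
          merged <- rbind(merged, runs[r, , drop = FALSE])
        }
      }
    }
    len <- if (!is.null(chrom_lengths)) chrom_lengths[[chr]] else max(bp)
    span <- bp[merged$end] - bp[merged$start]
    keep <- span > min_frac * len
    merged <- merged[keep, , drop = FALSE]
    if (nrow(merged) == 0) next
    res[[chr]] <- data.frame(
      chromosome = chr,
      start_bp = bp[merged$start], end_bp = bp[merged$end],
      start_index = merged$start, end_index = merged$end,
      n_genes = merged$end - merged$start + 1L,
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(res) > 0) do.call(rbind, res) else
    data.frame(chromosome = character(), start_bp = numeric(),
               end_bp = numeric(), start_index = integer(),
               end_index = integer(), n_genes = integer(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (nrow(out) > 0)
    out <- cbind(region_id = paste0("LR_", out$chromosome, "_",
                                    stats::ave(seq_len(nrow(out)),
                                               out$chromosome,
                                               FUN = seq_along)),
                 out, stringsAsFactors = FALSE)
  else out <- cbind(region_id = character(), out)
  class(out) <- c("lr_regions", "data.frame")
  out
}

run_bounds <- function(flag) {
  r <- rle(flag)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  data.frame(start = start[r$values], end = end[r$values])
}

#' Assign compartment labels to mapped genes
#'
#' Genes inside the LR region containing the chromosome's centromere are
#' labelled \code{LR_PC}; genes in other LR regions \code{LR_flank}; the
#' remainder \code{HR}. For two-class analyses LR = LR_PC + LR_flank.
#' If no region on a chromosome contains the centromere, all its LR regions
#' are labelled LR_flank with a warning.
#'
#' @param map a \code{gene_map} (same order the profile was computed on).
#' @param regions an \code{lr_regions} table.
#' @param centromeres data.frame with columns \code{chromosome}, \code{bp}.
#' @return a data.frame of class \code{compartment_annotation} with columns
#'   \code{gene_id}, \code{chromosome}, \code{label} (HR/LR_flank/LR_PC) and
#'   \code{region_id} (NA for HR genes).
#' @export
assign_compartments <- function(map, regions, centromeres) {
  label <- rep("HR", nrow(map))
  region_id <- rep(NA_character_, nrow(map))
  for (chr in unique(map$chromosome)) {
    gi <- which(map$chromosome == chr)
    reg <- regions[regions$chromosome == chr, , drop = FALSE]
    if (nrow(reg) == 0) next
    cen <- centromeres$bp[centromeres$chromosome == chr]
    has_cen <- logical(nrow(reg))
    if (length(cen) == 1) {
      has_cen <- reg$start_bp <= cen & cen <= reg$end_bp
    }
    if (!any(has_cen))
      warning("no LR region contains the centromere on chromosome ", chr,
              "; all its LR regions labelled LR_flank")
    for (r in seq_len(nrow(reg))) {
      sel <- gi[reg$start_index[r]:reg$end_index[r]]
      label[sel] <- if (has_cen[r]) "LR_PC" else "LR_flank"
      region_id[sel] <- reg$region_id[r]
    }
  }
  out <- data.frame(gene_id = map$gene_id, chromosome = map$chromosome,
                    label = factor(label,
                                   levels = c("HR", "LR_flank", "LR_PC")),
                    region_id = region_id, stringsAsFactors = FALSE)
  class(out) <- c("compartment_annotation", "data.frame")
  out
}

#' Two-class compartment label (HR vs LR)
#' @param annotations a \code{compartment_annotation}.
#' @return factor with levels HR, LR (LR = LR_PC + LR_flank).
#' @export
two_class_label <- function(annotations) {
  factor(ifelse(annotations$label == "HR", "HR", "LR"),
         levels = c("HR", "LR"))
}

#' Compartment share summary
#'
#' Gene counts and percentage shares per compartment label, plus the
#' combined LR share.
#' @param annotations a \code{compartment_annotation}.
#' @return a list with \code{counts} (named), \code{total} and
#'   \code{lr_share_pct}.
#' @export
compartment_shares <- function(annotations) {
  counts <- table(annotations$label)
  total <- sum(counts)
  lr <- sum(counts[c("LR_flank", "LR_PC")])
  list(counts = counts, total = total,
       lr_share_pct = 100 * lr / total)
}

#' Plot a recombination-rate genome scan
#'
#' Per-gene windowed recombination rate along map order for one chromosome,
#' with called LR regions shaded.
#' @param profile a \code{rate_profile}.
#' @param regions optional \code{lr_regions}.
#' @param chromosome chromosome to plot (default: first).
#' @export
plot_rate_scan <- function(profile, regions = NULL, chromosome = NULL) {
  if (is.null(chromosome)) chromosome <- profile$chromosome[1]
  i <- which(profile$chromosome == chromosome)
  graphics::plot(seq_along(i), profile$rate[i], type = "l", col = "darkgreen",
                 xlab = "gene order", ylab = "recombination rate (cM/gene)",
                 main = chromosome)
  if (!is.null(regions)) {
    reg <- regions[regions$chromosome == chromosome, , drop = FALSE]
    for (r in seq_len(nrow(reg)))
      graphics::rect(reg$start_index[r], 0, reg$end_index[r],
                     max(profile$rate[i]), col = grDevices::grey(0.85, 0.5),
                     border = NA)
  }
  invisible(NULL)
}
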