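# Expression level and developmental specificity per gene, with
# compartment comparisons by one-way ANOVA. Specificity is the quotient
# mean/sd across conditions (an inverse noise-to-signal measure); it is
# undefined for constant genes, which are excluded from tests rather than
# imputed.

#' Reads per kilobase of reference per million mapped reads
#'
#' @param read_count mapped read count for the gene.
#' @param ref_length reference length in bp (> 0).
#' @param library_total total mapped reads in the library (> 0).
#' @return RPKM value.
#' @export
rpkm <- function(read_count, ref_length, library_total) {
  if (any(ref_length <= 0)) stop("ref_length must be positive")
  if (any(library_total <= 0)) stop("library_total must be positive")
  read_count / (ref_length / 1000) / (library_total / 1e6)
}

#' Per-gene expression summary
#'
#' Mean and sample standard deviation (n - 1 denominator) across conditions,
#' and the specificity quotient mean/sd (NA when sd = 0). Invariant to
#' condition column order.
#'
#' @param mat genes x conditions matrix (>= 2 conditions), non-negative.
#' @return data.frame with gene_id, mean_level, sd_level, specificity_q.
#' @export
summarize_expression <- function(mat) {
  if (ncol(mat) < 2) stop("need at least 2 conditions")
  m <- rowMeans(mat, na.rm = TRUE)
  s <- apply(mat, 1, stats::sd, na.rm = TRUE)
  q <- ifelse(s > 0, m / s, NA_real_)
  data.frame(gene_id = rownames(mat), mean_level = m, sd_level = s,
             specificity_q = q, row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare expression between genome compartments
#'
#' One-way ANOVA of HR vs LR genes on mean expression level and on the
#' specificity quotient, genome-wide and per chromosome; optionally per
#' condition on the raw matrix. Genes with undefined specificity are
#' excluded from the quotient test and counted.
#'
#' @param summaries output of \code{summarize_expression}.
#' @param annotations a \code{compartment_annotation}.
#' @param mat optional raw expression matrix for per-condition tests.
#' @return a data.frame with one row per test: scope, variable, F, df1,
#'   df2, p, n_hr, n_lr, n_excluded.
#' @export
compare_compartments <- function(summaries, annotations, mat = NULL) {
  lab <- two_class_label(annotations)
  names(lab) <- annotations$gene_id
  chrom <- annotations$chromosome
  names(chrom) <- annotations$gene_id
  cls <- lab[summaries$gene_id]
  rows <- list()
  add_test <- function(scope, variable, hr, lr) {
    hr <- hr[is.finite(hr)]
    lr <- lr[is.finite(lr)]
    if (length(hr) < 2 || length(lr) < 2) {
      warning("compartment with < 2 values for ", variable, " in ", scope,
              "; test skipped")
      return(NULL)
    }
    tst <- anova_oneway(list(hr, lr))
    data.frame(scope = scope, variable = variable, F = tst$value,
               df1 = tst$df[1], df2 = tst$df[2], p = tst$p,
               n_hr = length(hr), n_lr = length(lr),
               stringsAsFactors = FALSE)
  }
  scopes <- c("genome", unique(annotations$chromosome))
  for (sc in scopes) {
    in_scope <- if (sc == "genome") rep(TRUE, nrow(summaries)) else
      chrom[summaries$gene_id] == sc
    for (v in c("mean_level", "specificity_q")) {
      x <- summaries[[v]]
      rows[[length(rows) + 1L]] <-
        add_test(sc, v, x[in_scope & cls == "HR" & !is.na(cls)],
                 x[in_scope & cls == "LR" & !is.na(cls)])
    }
  }
  if (!is.null(mat)) {
    mcls <- lab[rownames(mat)]
    for (cond in colnames(mat)) {
      x <- mat[, cond]
      rows[[length(rows) + 1L]] <-
        add_test(paste0("condition:", cond), "level",
                 x[mcls == "HR" & !is.na(mcls)],
                 x[mcls == "LR" & !is.na(mcls)])
    }
  }
  out <- do.call(rbind, rows)
  n_und <- sum(!is.finite(summaries$specificity_q))
  attr(out, "n_specificity_excluded") <- n_und
  out
}
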