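#' @importFrom utils read.table write.table count.fields
NULL

# All coordinates are 1-based; physical positions in bp, genetic in cM.
# Region intervals are closed [start, end].

#' Read a gene map table
#'
#' Reads a TSV with header columns \code{gene_id}, \code{chromosome},
#' \code{cM}, \code{bp}: one row per mapped gene with its genetic (cM) and
#' physical (bp) position. Entries are returned sorted by (chromosome,
#' physical position); duplicate gene ids are an error.
#'
#' @param path path to a tab-separated file.
#' @return a data.frame of class \code{gene_map} with columns \code{gene_id},
#'   \code{chromosome}, \code{genetic_pos}, \code{physical_pos}.
#' @export
read_gene_map <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", colClasses = "character",
                   quote = "", comment.char = "")
  need <- c("gene_id", "chromosome", "cM", "bp")
  if (!all(need %in% names(df)))
    stop("gene map must have header columns: ", paste(need, collapse = ", "))
  cm <- suppressWarnings(as.numeric(df$cM))
  bp <- suppressWarnings(as.numeric(df$bp))
  bad <- which(is.na(cm) | is.na(bp) | cm < 0 | bp < 0)
  if (length(bad) > 0)
    stop("malformed gene map row at line ", bad[1] + 1L,
         " (non-numeric or negative position)")
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in map: ",
         df$gene_id[duplicated(df$gene_id)][1])
  gene_map(df$gene_id, df$chromosome, cm, bp)
}

#' Construct a gene map from vectors
#'
#' @param gene_id character gene identifiers (unique).
#' @param chromosome character chromosome names.
#' @param genetic_pos numeric genetic positions (cM, non-negative).
#' @param physical_pos numeric physical positions (bp, non-negative).
#' @return a \code{gene_map} data.frame sorted by (chromosome, physical_pos).
#' @export
gene_map <- function(gene_id, chromosome, genetic_pos, physical_pos) {
  if (anyDuplicated(gene_id)) stop("gene_id must be unique")
  df <- data.frame(
    gene_id = as.character(gene_id),
    chromosome = as.character(chromosome),
    genetic_pos = as.numeric(genetic_pos),
    physical_pos = as.numeric(physical_pos),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$chromosome, df$physical_pos), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gene_map", "data.frame")
  df
}

#' Write a gene map table
#'
#' Inverse of \code{read_gene_map}; round-trips exactly.
#' @param map a \code{gene_map}.
#' @param path output path.
#' @export
write_gene_map <- function(map, path) {
  out <- data.frame(gene_id = map$gene_id, chromosome = map$chromosome,
                    cM = map$genetic_pos, bp = map$physical_pos)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 12-column BLAST tabular similarity table
#'
#' Standard tabular dialect: qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore. No filtering is performed;
#' minus-strand hits (sstart > send) are retained with a derived
#' \code{strand} flag.
#'
#' @param path path to the tab-separated file (no header).
#' @return a data.frame of class \code{similarity_table}.
#' @export
read_similarity_table <- function(path) {
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) == 0) {
    df <- empty_similarity_table()
    return(df)
  }
  bad <- which(nf != 12L)
  if (length(bad) > 0)
    stop("similarity table line ", bad[1], " has ", nf[bad[1]],
         " columns; expected 12")
  df <- read.table(path, sep = "\t", quote = "", comment.char = "",
                   col.names = similarity_cols(),
                   colClasses = c("character", "character", rep("numeric", 4),
                                  rep("integer", 4), "numeric", "numeric"))
  df$strand <- ifelse(df$s_start > df$s_end, "-", "+")
  class(df) <- c("similarity_table", "data.frame")
  df
}

similarity_cols <- function() {
  c("query_id", "subject_id", "pct_identity", "aln_length", "mismatches",
    "gap_opens", "q_start", "q_end", "s_start", "s_end", "evalue",
    "bit_score")
}

empty_similarity_table <- function() {
  df <- data.frame(query_id = character(), subject_id = character(),
                   pct_identity = numeric(), aln_length = numeric(),
                   mismatches = numeric(), gap_opens = numeric(),
                   q_start = integer(), q_end = integer(),
                   s_start = integer(), s_end = integer(),
                   evalue = numeric(), bit_score = numeric(),
                   strand = character(), stringsAsFactors = FALSE)
  class(df) <- c("similarity_table", "data.frame")
  df
}

#' Write a similarity table in the 12-column tabular dialect
#' @param hits a \code{similarity_table} (the derived strand column is not
#'   written; it is re-derived on read).
#' @param path output path.
#' @export
write_similarity_table <- function(hits, path) {
  write.table(hits[, similarity_cols()], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Variant table container
#'
#' Biallelic SNVs over cDNA coordinates with per-sample allele read counts.
#' A sample with zero reads for both alleles is missing at that site.
#'
#' @param sites data.frame with columns \code{ref_id}, \code{pos},
#'   \code{ref}, \code{alt} (single A/C/G/T nucleotides, ref != alt).
#' @param ref_counts,alt_counts integer matrices, one row per site and one
#'   column per sample (column names are sample ids).
#' @param n_skipped count of records skipped on input (indels,
#'   multi-allelic).
#' @return an object of class \code{variant_table}.
#' @export
variant_table <- function(sites, ref_counts, alt_counts, n_skipped = 0L) {
  stopifnot(nrow(sites) == nrow(ref_counts),
            nrow(sites) == nrow(alt_counts),
            ncol(ref_counts) == ncol(alt_counts))
  nt <- c("A", "C", "G", "T")
  if (nrow(sites) > 0) {
    if (!all(sites$ref %in% nt) || !all(sites$alt %in% nt))
      stop("ref/alt alleles must be single A/C/G/T nucleotides")
    if (any(sites$ref == sites$alt)) stop("ref and alt alleles must differ")
    if (any(ref_counts < 0) || any(alt_counts < 0))
      stop("read counts must be non-negative")
  }
  rownames(sites) <- NULL
  rownames(ref_counts) <- NULL
  rownames(alt_counts) <- NULL
  structure(
    list(sites = sites, ref_counts = ref_counts, alt_counts = alt_counts,
         sample_ids = colnames(ref_counts), n_skipped = as.integer(n_skipped)),
    class = "variant_table"
  )
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d sites x %d samples (%d records skipped)\n",
              nrow(x$sites), length(x$sample_ids), x$n_skipped))
  invisible(x)
}

#' Read per-sample variant calls (minimal VCF or flat TSV)
#'
#' Accepts either a minimal VCF 4.x subset (CHROM = cDNA id, POS, REF, ALT,
#' per-sample AD-style ref,alt read counts) or a flat TSV with header
#' \code{ref_id pos ref alt} followed by \code{<sample>_ref <sample>_alt}
#' column pairs. Indel and multi-allelic records are skipped and counted.
#'
#' @param path input path; VCF is detected from a \code{##fileformat} first
#'   line or a \code{.vcf} extension.
#' @param sample_ids optional character vector restricting/ordering samples.
#' @return a \code{variant_table}.
#' @export
read_variant_table <- function(path, sample_ids = NULL) {
  first <- readLines(path, n = 1L)
  is_vcf <- grepl("^##fileformat", first) || grepl("\\.vcf$", path)
  vt <- if (is_vcf) read_variants_vcf(path) else read_variants_tsv(path)
  if (!is.null(sample_ids)) {
    if (!all(sample_ids %in% vt$sample_ids))
      stop("sample ids not present in variant file: ",
           paste(setdiff(sample_ids, vt$sample_ids), collapse = ", "))
    vt$ref_counts <- vt$ref_counts[, sample_ids, drop = FALSE]
    vt$alt_counts <- vt$alt_counts[, sample_ids, drop = FALSE]
    vt$sample_ids <- sample_ids
  }
  vt
}

read_variants_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))  # single-record files come back as a vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snv <- nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!snv)
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(ad)) stop("VCF has no per-sample AD field")
  ad <- ad[snv, , drop = FALSE]
  split_counts <- function(idx) {
    x <- sub(sprintf("^(?:[^,]*,){%d}", idx - 1L), "", ad, perl = TRUE)
    x <- sub(",.*$", "", x)
    ok <- is.na(ad) | ad == "." | grepl("^[0-9]+(,[0-9]+)*$", ad)
    if (!all(ok)) stop("unreadable AD counts in VCF")
    cnt <- suppressWarnings(matrix(as.integer(x), nrow = nrow(ad),
                                   dimnames = dimnames(ad)))
    cnt[is.na(cnt)] <- 0L
    cnt
  }
  refc <- split_counts(1L)
  altc <- split_counts(2L)
  sites <- data.frame(
    ref_id = unname(fix[snv, "CHROM"]),
    pos = as.integer(fix[snv, "POS"]),
    ref = unname(ref[snv]), alt = unname(alt[snv]),
    stringsAsFactors = FALSE
  )
  variant_table(sites, refc, altc, n_skipped)
}

read_variants_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", quote = "",
                   comment.char = "", colClasses = "character")
  need <- c("ref_id", "pos", "ref", "alt")
  if (!all(need %in% names(df)))
    stop("variant TSV must start with columns: ", paste(need, collapse = ", "))
  cc <- setdiff(names(df), need)
  refcols <- grep("_ref$", cc, value = TRUE)
  samples <- sub("_ref$", "", refcols)
  altcols <- paste0(samples, "_alt")
  if (!all(altcols %in% cc))
    stop("each sample needs paired <sample>_ref and <sample>_alt columns")
  snv <- nchar(df$ref) == 1L & nchar(df$alt) == 1L &
    df$ref %in% c("A", "C", "G", "T") & df$alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!snv)
  df2 <- df[snv, , drop = FALSE]
  tocounts <- function(cols) {
    m <- suppressWarnings(vapply(df2[cols], as.integer,
                                 integer(nrow(df2))))
    m <- matrix(m, nrow = nrow(df2))
    if (anyNA(m)) stop("unreadable read counts in variant TSV")
    colnames(m) <- samples
    m
  }
  sites <- data.frame(ref_id = df2$ref_id, pos = as.integer(df2$pos),
                      ref = df2$ref, alt = df2$alt, stringsAsFactors = FALSE)
  variant_table(sites, tocounts(refcols), tocounts(altcols), n_skipped)
}

#' Write a variant table as flat TSV
#' @param vt a \code{variant_table}.
#' @param path output path.
#' @export
write_variant_table <- function(vt, path) {
  out <- vt$sites
  for (s in vt$sample_ids) {
    out[[paste0(s, "_ref")]] <- vt$ref_counts[, s]
    out[[paste0(s, "_alt")]] <- vt$alt_counts[, s]
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a variant table as minimal VCF
#'
#' Emits a VCF 4.2 subset: CHROM/POS/ID/REF/ALT/QUAL/FILTER/INFO plus a
#' per-sample AD genotype field (ref,alt read counts).
#' @param vt a \code{variant_table}.
#' @param path output path.
#' @export
write_variant_vcf <- function(vt, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vt$sample_ids), collapse = "\t")
  )
  n <- nrow(vt$sites)
  if (n > 0) {
    gt <- matrix(paste(vt$ref_counts, vt$alt_counts, sep = ","), nrow = n)
    body <- paste(vt$sites$ref_id, vt$sites$pos, ".", vt$sites$ref,
                  vt$sites$alt, ".", "PASS", ".", "AD",
                  apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  } else body <- character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an expression matrix (genes x conditions)
#'
#' TSV with a header; the first column holds gene ids, remaining columns are
#' non-negative expression values (arbitrary units or RPKM). Missing values
#' are encoded as NA.
#'
#' @param path input path.
#' @return a numeric matrix with gene ids as rownames.
#' @export
read_expression_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", quote = "",
                   comment.char = "", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("expression values must be numeric")
  if (any(m < 0, na.rm = TRUE)) stop("expression values must be non-negative")
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write an expression matrix
#' @param mat numeric matrix with gene ids as rownames.
#' @param path output path.
#' @export
write_expression_matrix <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read centromere positions
#' @param path TSV with header columns \code{chromosome}, \code{bp}.
#' @return data.frame with columns chromosome, bp.
#' @export
read_centromeres <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", quote = "",
                   comment.char = "")
  if (!all(c("chromosome", "bp") %in% names(df)))
    stop("centromere table needs columns chromosome, bp")
  df$chromosome <- as.character(df$chromosome)
  df$bp <- as.numeric(df$bp)
  df
}

#' Write called regions as BED-like TSV
#'
#' Columns: chrom, start, end (closed 1-based bp interval), label.
#' @param regions a data.frame with chromosome, start_bp, end_bp and a label
#'   column (e.g. from \code{assign_compartments} region summaries).
#' @param path output path.
#' @export
write_regions_bed <- function(regions, path) {
  lab <- if ("label" %in% names(regions)) regions$label else
    ifelse(isTRUE(regions$contains_centromere), "LR_PC", "LR")
  out <- data.frame(chrom = regions$chromosome, start = regions$start_bp,
                    end = regions$end_bp, label = lab)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read cDNA reference sequences
#' @param path FASTA file.
#' @return a \code{Biostrings::DNAStringSet}.
#' @export
read_cdna_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write cDNA reference sequences
#' @param seqs a named \code{DNAStringSet} or named character vector.
#' @param path output path.
#' @export
write_cdna_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
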