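#' Gene models with strand and exon structure
#'
#' A light-weight container for gene models used in SNP proximity annotation.
#' Coordinates are stored 1-based inclusive (the R/Bioconductor convention);
#' on-disk BED is 0-based half-open and GFF3 1-based inclusive, with the
#' conversions handled by the readers/writers. Exons are kept in transcription
#' order: the first exon is the 5'-most, so for minus-strand genes exon 1 has
#' the largest genomic coordinates.
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors, 1-based inclusive gene spans.
#' @param strand Character vector, `"+"` or `"-"`.
#' @param exons List of two-column matrices (`start`, `end`; 1-based
#'   inclusive), one per gene, rows in transcription order. `NULL` entries are
#'   replaced by a single exon covering the whole span.
#' @param family Optional character vector of gene-family tags
#'   (`"Vmn1r"`, `"Vmn2r"`, `"Fpr"` or `"other"`); inferred from the gene id
#'   prefix when `NULL`.
#'
#' @return An object of class `gene_models`: a data.frame with columns
#'   `gene_id`, `chrom`, `start`, `end`, `strand`, `family` and a list column
#'   `exons`.
#' @export
gene_models <- function(gene_id, chrom, start, end, strand,
                        exons = NULL, family = NULL) {
  n <- length(gene_id)
  start <- as.integer(start); end <- as.integer(end)
  if (anyDuplicated(gene_id)) stop("duplicate gene_id", call. = FALSE)
  if (any(start < 1L) || any(end < start))
    stop("invalid gene span (need 1 <= start <= end)", call. = FALSE)
  if (!all(strand %in% c("+", "-")))
    stop("unknown strand symbol: ",
         paste(unique(setdiff(strand, c("+", "-"))), collapse = ", "),
         call. = FALSE)
  if (is.null(exons)) exons <- vector("list", n)
  if (length(exons) != n) stop("need one exon set per gene", call. = FALSE)
  for (i in seq_len(n)) {
    ex <- exons[[i]]
    if (is.null(ex)) ex <- cbind(start = start[i], end = end[i])
    ex <- matrix(as.integer(ex), ncol = 2L,
                 dimnames = list(NULL, c("start", "end")))
    if (any(ex[, 1L] > ex[, 2L]))
      stop("exon with start > end in gene ", gene_id[i], call. = FALSE)
    if (any(ex[, 1L] < start[i]) || any(ex[, 2L] > end[i]))
      stop("exon outside gene span in gene ", gene_id[i], call. = FALSE)
    ex <- ex[order(ex[, 1L]), , drop = FALSE]
    if (nrow(ex) > 1L && any(ex[-1L, 1L] <= ex[-nrow(ex), 2L]))
      stop("overlapping exons in gene ", gene_id[i], call. = FALSE)
    # transcription order: 5'-most first
    if (strand[i] == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
    exons[[i]] <- ex
  }
  if (is.null(family)) family <- infer_gene_family(gene_id)
  df <- data.frame(gene_id = as.character(gene_id),
                   chrom = as.character(chrom),
                   start = start, end = end,
                   strand = as.character(strand),
                   family = as.character(family),
                   stringsAsFactors = FALSE)
  df$exons <- exons
  df <- df[order(df$chrom, df$start, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("gene_models", "data.frame"))
}

#' Infer receptor-family tag from a gene name
#'
#' Vomeronasal type-1 (`Vmn1r*`), type-2 (`Vmn2r*`) and formyl peptide
#' receptor (`Fpr*`) genes are recognised by name prefix; everything else is
#' `"other"`.
#'
#' @param gene_id Character vector of gene names.
#' @return Character vector of family tags.
#' @export
infer_gene_family <- function(gene_id) {
  fam <- rep("other", length(gene_id))
  fam[grepl("^Vmn1r", gene_id, ignore.case = TRUE)] <- "Vmn1r"
  fam[grepl("^Vmn2r", gene_id, ignore.case = TRUE)] <- "Vmn2r"
  fam[grepl("^Fpr",  gene_id, ignore.case = TRUE)] <- "Fpr"
  fam
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  fam <- table(x$family)
  cat("  families:", paste(names(fam), fam, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

n_exons <- function(models) vapply(models$exons, nrow, integer(1))
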