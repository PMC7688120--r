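#' Annotate one SNP against nearby gene models
#'
#' Reports every gene whose span lies within `window` bp of the SNP
#' position. A SNP inside the gene span is assigned `exon k` or `intron k`
#' (1-based, counted in transcription order, so exon 1 is the 5'-most exon
#' regardless of strand) with distance 0. An intergenic SNP is `upstream`
#' when it lies on the 5' side of the gene and `downstream` on the 3' side
#' (strand-aware), with distance the absolute coordinate difference to the
#' nearest gene boundary (a SNP adjacent to the gene has distance 1).
#' Results are sorted by distance.
#'
#' @param snp A list or single-row data.frame with fields `snp_id`, `chrom`,
#'   `pos`.
#' @param genes A [gene_models()] object.
#' @param window Search window in bp around the SNP (default 50 kb).
#' @return Data.frame with columns `snp_id`, `gene_id`, `strand`,
#'   `relation`, `distance_bp`.
#' @examples
#' g <- gene_models("Vmn2r110", "chr17", 5001L, 8000L, "-")
#' annotate_snp(list(snp_id = "rs1", chrom = "chr17", pos = 4477L), g)
#' # -> downstream of the minus-strand gene, 524 bp
#' @export
annotate_snp <- function(snp, genes, window = 50000L) {
  pos <- as.integer(snp[["pos"]])
  chrom <- as.character(snp[["chrom"]])
  hits <- which(genes$chrom == chrom &
                genes$start - window <= pos &
                genes$end + window >= pos)
  if (!length(hits)) {
    return(data.frame(snp_id = character(0), gene_id = character(0),
                      strand = character(0), relation = character(0),
                      distance_bp = integer(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(hits, function(i) {
    gstart <- genes$start[i]; gend <- genes$end[i]
    strand <- genes$strand[i]
    if (pos >= gstart && pos <= gend) {
      rel <- intragenic_relation(pos, genes$exons[[i]], strand)
      dist <- 0L
    } else if (pos < gstart) {
      dist <- gstart - pos
      rel <- if (strand == "+") "upstream" else "downstream"
    } else {
      dist <- pos - gend
      rel <- if (strand == "+") "downstream" else "upstream"
    }
    data.frame(snp_id = as.character(snp[["snp_id"]]),
               gene_id = genes$gene_id[i], strand = strand,
               relation = rel, distance_bp = dist,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$distance_bp, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# exon/intron call for a position inside the gene span; exons are in
# transcription order (5'-most first)
intragenic_relation <- function(pos, exons, strand) {
  k <- nrow(exons)
  for (j in seq_len(k)) {
    if (pos >= exons[j, 1L] && pos <= exons[j, 2L])
      return(sprintf("exon %d", j))
  }
  # between exon j and exon j+1 in transcription order
  for (j in seq_len(k - 1L)) {
    lo <- min(exons[j, ], exons[j + 1L, ])
    hi <- max(exons[j, ], exons[j + 1L, ])
    if (pos > lo && pos < hi &&
        ((strand == "+" && pos > exons[j, 2L] && pos < exons[j + 1L, 1L]) ||
         (strand == "-" && pos < exons[j, 1L] && pos > exons[j + 1L, 2L])))
      return(sprintf("intron %d", j))
  }
  # inside the span but before the first / after the last exon (possible
  # when the span exceeds the exon extent); treat as nearest-end intron call
  if (strand == "+") {
    if (pos < exons[1L, 1L]) return("intron 0") else return(sprintf("intron %d", k))
  } else {
    if (pos > exons[1L, 2L]) return("intron 0") else return(sprintf("intron %d", k))
  }
}

#' Annotate every SNP of a panel
#'
#' Concatenates per-SNP annotations in a stable order (SNP coordinate, then
#' distance) and adds the report columns used by
#' [write_annotation_table()]: `snp_location` (the SNP position) and
#' `alleles` — the `"<group-fixed base> / <opposite base>"` pair, oriented
#' selected-first, filled in when a `classified` panel is supplied and the
#' SNP is all-or-none.
#'
#' @param panel A [snp_panel()].
#' @param genes A [gene_models()] object.
#' @param window Search window in bp (default 50 kb).
#' @param classified Optional `classified_panel` from [classify_panel()]
#'   used to fill the `alleles` column.
#' @return Data.frame with columns `snp_id`, `snp_location`, `alleles`,
#'   `gene`, `strand`, `relation`, `distance_bp`.
#' @export
annotate_panel <- function(panel, genes, window = 50000L, classified = NULL) {
  alleles <- rep(NA_character_, nrow(panel))
  if (!is.null(classified)) {
    m <- match(panel$snp_id, classified$snp_id)
    for (i in seq_len(nrow(panel))) {
      j <- m[i]
      if (!is.na(j) && classified$is_all_or_none[j]) {
        fixed <- classified$fixed_base[j]
        other <- if (fixed == panel$focal_allele[i]) panel$other_allele[i]
                 else panel$focal_allele[i]
        alleles[i] <- if (classified$fixed_linetype[j] == "selected")
          paste(fixed, "/", other) else paste(other, "/", fixed)
      }
    }
  }
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    ann <- annotate_snp(panel[i, ], genes, window = window)
    if (nrow(ann) == 0L) return(NULL)
    data.frame(snp_id = ann$snp_id,
               snp_location = panel$pos[i],
               alleles = alleles[i],
               gene = ann$gene_id,
               strand = ann$strand,
               relation = ann$relation,
               distance_bp = ann$distance_bp,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(snp_id = character(0), snp_location = integer(0),
                      alleles = character(0), gene = character(0),
                      strand = character(0), relation = character(0),
                      distance_bp = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Overlap DE genes with SNP clusters
#'
#' Counts, for each padded SNP cluster, the differentially expressed genes
#' whose gene span intersects the cluster interval, split by receptor
#' family, plus genome-wide totals. DE status is `qvalue < alpha`.
#'
#' @param clusters A `snp_cluster_set` from [cluster_snps()].
#' @param de_genes DE table (data.frame with `gene_id`, `log2fc`, `qvalue`,
#'   optionally `family`).
#' @param genes A [gene_models()] object providing gene coordinates.
#' @param alpha DE q-value threshold (default 0.05).
#' @return An object of class `de_overlap`: list with `table` (one row per
#'   cluster: `cluster_id`, `n_de`, `n_de_Vmn1r`, `n_de_Vmn2r`, `n_de_Fpr`,
#'   `n_de_other`, `de_gene_ids` list column), `totals` (list:
#'   `n_de_genes`, `n_de_in_clusters`), and `missing` (DE gene ids absent
#'   from the gene models; also raised as a warning).
#' @export
overlap_de_with_clusters <- function(clusters, de_genes, genes,
                                     alpha = 0.05) {
  de <- de_genes[de_genes$qvalue < alpha, , drop = FALSE]
  missing <- setdiff(de$gene_id, genes$gene_id)
  if (length(missing))
    warning("DE gene id(s) absent from gene models: ",
            paste(missing, collapse = ", "), call. = FALSE)
  de <- de[de$gene_id %in% genes$gene_id, , drop = FALSE]
  idx <- match(de$gene_id, genes$gene_id)
  tab <- clusters$clusters
  fam_levels <- c("Vmn1r", "Vmn2r", "Fpr", "other")

  if (nrow(de) && nrow(tab)) {
    de_gr <- GenomicRanges::GRanges(
      genes$chrom[idx], IRanges::IRanges(genes$start[idx], genes$end[idx]))
    cl_gr <- GenomicRanges::GRanges(
      tab$chrom, IRanges::IRanges(tab$start, tab$end))
    ov <- GenomicRanges::findOverlaps(cl_gr, de_gr)
    hits_by_cluster <- split(S4Vectors::subjectHits(ov),
                             factor(S4Vectors::queryHits(ov),
                                    levels = seq_len(nrow(tab))))
  } else {
    hits_by_cluster <- rep(list(integer(0)), nrow(tab))
  }
  fam <- infer_or_take_family(de, genes, idx)
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    h <- hits_by_cluster[[i]]
    counts <- vapply(fam_levels, function(fv) sum(fam[h] == fv), integer(1))
    data.frame(cluster_id = tab$cluster_id[i],
               n_de = length(h),
               n_de_Vmn1r = counts[["Vmn1r"]],
               n_de_Vmn2r = counts[["Vmn2r"]],
               n_de_Fpr = counts[["Fpr"]],
               n_de_other = counts[["other"]],
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = character(0), n_de = integer(0),
               n_de_Vmn1r = integer(0), n_de_Vmn2r = integer(0),
               n_de_Fpr = integer(0), n_de_other = integer(0),
               stringsAsFactors = FALSE)
  out$de_gene_ids <- lapply(hits_by_cluster, function(h) sort(de$gene_id[h]))
  in_any <- if (nrow(out)) length(unique(unlist(out$de_gene_ids))) else 0L
  structure(
    list(table = out,
         totals = list(n_de_genes = nrow(de), n_de_in_clusters = in_any),
         missing = missing),
    class = "de_overlap"
  )
}

infer_or_take_family <- function(de, genes, idx) {
  if ("family" %in% names(de) && !all(is.na(de$family))) de$family
  else genes$family[idx]
}

#' @export
print.de_overlap <- function(x, ...) {
  cat(sprintf("DE genes vs SNP clusters: %d of %d DE genes fall in a cluster\n",
              x$totals$n_de_in_clusters, x$totals$n_de_genes))
  if (nrow(x$table))
    print.data.frame(x$table[, setdiff(names(x$table), "de_gene_ids")])
  if (length(x$missing))
    cat("  (", length(x$missing), "DE ids missing from gene models )\n")
  invisible(x)
}
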