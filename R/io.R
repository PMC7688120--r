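#' Read a replicate-line design file
#'
#' The design file is a TSV with columns `line_id` and `linetype`
#' (`selected`/`control`), and optionally constant columns `ne` and
#' `generations`; absent parameters fall back to the defaults of the breeding
#' design (Ne = 35, 88 generations).
#'
#' @param path Path to the design TSV.
#' @param ne,generations Override values; `NULL` means "take from file or
#'   default".
#' @return A [line_design()].
#' @export
read_line_design <- function(path, ne = NULL, generations = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("line_id", "linetype"))
    if (!col %in% names(df))
      stop("design file missing column `", col, "`", call. = FALSE)
  if (is.null(ne)) ne <- if ("ne" %in% names(df)) df$ne[1] else 35L
  if (is.null(generations))
    generations <- if ("generations" %in% names(df)) df$generations[1] else 88L
  line_design(df$line_id, df$linetype, ne = ne, generations = generations)
}

#' Write a replicate-line design file
#' @param design A [line_design()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_line_design <- function(design, path) {
  stopifnot_line_design(design)
  df <- design$lines
  df$ne <- design$ne
  df$generations <- design$generations
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an allele-frequency panel
#'
#' Expects a TSV with header columns `snp_id`, `chrom`, `pos`,
#' `focal_allele`, `other_allele` followed by one focal-allele frequency
#' column per line of the design. Frequencies must be in `[0, 1]`; records
#' are returned sorted by `(chrom, pos)`.
#'
#' @param path Path to the panel TSV.
#' @param design_path Path to the companion design TSV, or a [line_design()]
#'   object directly.
#' @return A [snp_panel()].
#' @export
read_snp_panel <- function(path, design_path) {
  design <- if (inherits(design_path, "line_design")) design_path
            else read_line_design(design_path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(snp_id = "character",
                                         chrom = "character"))
  need <- c("snp_id", "chrom", "pos", "focal_allele", "other_allele")
  for (col in need)
    if (!col %in% names(df))
      stop("panel file missing column `", col, "`", call. = FALSE)
  miss <- setdiff(design$lines$line_id, names(df))
  if (length(miss))
    stop("design mismatch: panel file has no column for line(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(df), c(need, design$lines$line_id))
  if (length(extra))
    stop("design mismatch: unknown line_id column(s) ",
         paste(extra, collapse = ", "), call. = FALSE)
  snp_panel(df$snp_id, df$chrom, df$pos, df$focal_allele, df$other_allele,
            freqs = df[, design$lines$line_id, drop = FALSE],
            design = design)
}

#' Write an allele-frequency panel
#'
#' Output is sorted by coordinate with fixed column order so that repeated
#' runs are byte-identical.
#'
#' @param panel A [snp_panel()].
#' @param path Output TSV path.
#' @param design_path Optional path to also write the companion design TSV.
#' @return Invisibly, `path`.
#' @export
write_snp_panel <- function(panel, path, design_path = NULL) {
  design <- panel_design(panel)
  df <- as.data.frame(panel)
  df <- df[, c("snp_id", "chrom", "pos", "focal_allele", "other_allele",
               design$lines$line_id)]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(design_path)) write_line_design(design, design_path)
  invisible(path)
}

#' Read gene models from GFF3 or BED12
#'
#' GFF3 files must carry `gene` features (with `ID`) and optionally `exon`
#' children (`Parent` pointing at the gene or at an intermediate transcript);
#' genes without exon children are treated as single-exon. An optional
#' `family` attribute on the gene row overrides the name-prefix family
#' inference. BED12 blocks become exons.
#'
#' @param path Path to a `.gff3`/`.gff` or `.bed` file.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @return A [gene_models()] object.
#' @export
read_gene_models <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  if (format == "bed") read_gene_models_bed(path) else read_gene_models_gff3(path)
}

read_gene_models_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) == 0L)
    return(gene_models(character(), character(), integer(), integer(),
                       character()))
  if (any(GenomicRanges::strand(gr) == "*"))
    stop("unknown strand symbol in BED record", call. = FALSE)
  bl <- rtracklayer::blocks(gr)  # absolute coordinates, 1-based
  exons <- lapply(seq_along(gr), function(i) {
    b <- bl[[i]]
    cbind(start = GenomicRanges::start(b), end = GenomicRanges::end(b))
  })
  gene_models(gene_id = gr$name,
              chrom = as.character(GenomicRanges::seqnames(gr)),
              start = GenomicRanges::start(gr),
              end = GenomicRanges::end(gr),
              strand = as.character(GenomicRanges::strand(gr)),
              exons = exons)
}

read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  is_gene <- type == "gene"
  if (!any(is_gene))
    return(gene_models(character(), character(), integer(), integer(),
                       character()))
  genes <- gr[is_gene]
  if (any(GenomicRanges::strand(genes) == "*"))
    stop("unknown strand symbol for gene record", call. = FALSE)
  gene_ids <- genes$ID
  # map any feature ID to its owning gene, following Parent one level up
  id2gene <- stats::setNames(gene_ids, gene_ids)
  non_gene <- gr[!is_gene & type != "exon"]
  if (length(non_gene)) {
    par <- vapply(non_gene$Parent,
                  function(p) if (length(p)) p[[1]] else NA_character_,
                  character(1))
    ok <- !is.na(non_gene$ID) & par %in% names(id2gene)
    id2gene <- c(id2gene, stats::setNames(id2gene[par[ok]], non_gene$ID[ok]))
  }
  exon_gr <- gr[type == "exon"]
  exon_parent <- vapply(exon_gr$Parent,
                        function(p) if (length(p)) p[[1]] else NA_character_,
                        character(1))
  exon_gene <- unname(id2gene[exon_parent])
  exons <- lapply(seq_along(genes), function(i) {
    ex <- exon_gr[!is.na(exon_gene) & exon_gene == gene_ids[i]]
    if (length(ex) == 0L) return(NULL)
    cbind(start = GenomicRanges::start(ex), end = GenomicRanges::end(ex))
  })
  fam <- if ("family" %in% names(S4Vectors::mcols(genes))) genes$family else NULL
  if (!is.null(fam) && all(is.na(fam))) fam <- NULL
  gene_models(gene_id = gene_ids,
              chrom = as.character(GenomicRanges::seqnames(genes)),
              start = GenomicRanges::start(genes),
              end = GenomicRanges::end(genes),
              strand = as.character(GenomicRanges::strand(genes)),
              exons = exons, family = fam)
}

#' Write gene models to GFF3 or BED12
#'
#' GFF3 output carries one `gene` row per gene (attributes `ID` and `family`)
#' and one `exon` row per exon with `Parent`; BED12 output encodes exons as
#' blocks (family is not representable in BED and is re-inferred from the
#' gene name on reading).
#'
#' @param models A [gene_models()] object.
#' @param path Output path.
#' @param format `"gff3"` or `"bed"`.
#' @return Invisibly, `path`.
#' @export
write_gene_models <- function(models, path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  if (format == "bed") {
    blocks <- IRanges::IRangesList(lapply(seq_len(nrow(models)), function(i) {
      ex <- models$exons[[i]]
      ex <- ex[order(ex[, 1L]), , drop = FALSE]
      IRanges::IRanges(start = ex[, 1L] - models$start[i] + 1L,
                       end = ex[, 2L] - models$start[i] + 1L)
    }))
    gr <- GenomicRanges::GRanges(
      models$chrom,
      IRanges::IRanges(models$start, models$end),
      strand = models$strand,
      name = models$gene_id,
      score = 0L,
      thick = IRanges::IRanges(models$start, models$end),
      blocks = blocks
    )
    rtracklayer::export(gr, path, format = "bed")
    return(invisible(path))
  }
  rows <- lapply(seq_len(nrow(models)), function(i) {
    ex <- models$exons[[i]]
    ex <- ex[order(ex[, 1L]), , drop = FALSE]
    k <- nrow(ex)
    GenomicRanges::GRanges(
      models$chrom[i],
      IRanges::IRanges(c(models$start[i], ex[, 1L]),
                       c(models$end[i],   ex[, 2L])),
      strand = models$strand[i],
      type = c("gene", rep("exon", k)),
      ID = c(models$gene_id[i], rep(NA_character_, k)),
      family = c(models$family[i], rep(NA_character_, k)),
      Parent = IRanges::CharacterList(
        c(list(character()), rep(list(models$gene_id[i]), k)))
    )
  })
  gr <- do.call(c, rows)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a differential-expression gene table
#'
#' TSV with columns `gene_id`, `log2fc`, `qvalue` and optionally `family`
#' (inferred from the gene name when absent). Q-values must be in `[0, 1]`.
#'
#' @param path Path to the DE TSV.
#' @return A data.frame with columns `gene_id`, `log2fc`, `qvalue`, `family`.
#' @export
read_de_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("gene_id", "log2fc", "qvalue"))
    if (!col %in% names(df))
      stop("DE table missing column `", col, "`", call. = FALSE)
  bad <- is.na(df$qvalue) | df$qvalue < 0 | df$qvalue > 1
  if (any(bad))
    stop("qvalue outside [0, 1] for gene ", df$gene_id[which(bad)[1]],
         call. = FALSE)
  if (!"family" %in% names(df)) df$family <- infer_gene_family(df$gene_id)
  df[, c("gene_id", "log2fc", "qvalue", "family")]
}

#' Write a differential-expression gene table
#' @param de A data.frame as returned by [read_de_table()] or
#'   [generate_de_table()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_de_table <- function(de, path) {
  df <- de[order(de$gene_id), c("gene_id", "log2fc", "qvalue", "family")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a SNP-to-gene annotation table
#'
#' One row per (SNP, gene) pair with the fixed column order `snp_id`,
#' `snp_location`, `alleles`, `gene`, `strand`, `relation`, `distance_bp`
#' (the schema of a proximity-annotation report: gene within the window,
#' strand, upstream/downstream/exon/intron relation, distance in bp). Rows
#' are written in the stable order produced by [annotate_panel()], so the
#' file is byte-identical across runs on the same input.
#'
#' @param annotations Data.frame from [annotate_panel()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_annotation_table <- function(annotations, path) {
  cols <- c("snp_id", "snp_location", "alleles", "gene", "strand",
            "relation", "distance_bp")
  df <- as.data.frame(annotations)
  if (nrow(df) == 0L) {
    df <- as.data.frame(stats::setNames(replicate(length(cols),
                                                  character(0),
                                                  simplify = FALSE), cols))
  } else {
    df <- df[, cols]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Write SNP clusters as BED6
#'
#' BED6 with the padded cluster interval (0-based half-open on disk), the
#' cluster id as name and the member count as score.
#'
#' @param clusters A cluster set from [cluster_snps()].
#' @param path Output BED path.
#' @return Invisibly, `path`.
#' @export
write_clusters_bed <- function(clusters, path) {
  df <- clusters$clusters
  bed <- data.frame(chrom = df$chrom,
                    start = df$start - 1L,
                    end = df$end,
                    name = df$cluster_id,
                    score = df$n_snps,
                    strand = rep(".", nrow(df)))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read SNP cluster intervals from BED6
#'
#' Inverse of [write_clusters_bed()] for the interval fields (member SNP
#' lists are not representable in BED6 and come back as counts only).
#'
#' @param path BED6 path.
#' @return Data.frame with columns `cluster_id`, `chrom`, `start`, `end`,
#'   `n_snps` (1-based inclusive coordinates).
#' @export
read_clusters_bed <- function(path) {
  empty <- data.frame(cluster_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_snps = integer(0), stringsAsFactors = FALSE)
  if (length(readLines(path, n = 1L)) == 0L) return(empty)
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 5L) stop("expected BED6 cluster file", call. = FALSE)
  data.frame(cluster_id = as.character(bed[[4L]]),
             chrom = as.character(bed[[1L]]),
             start = as.integer(bed[[2L]]) + 1L,
             end = as.integer(bed[[3L]]),
             n_snps = as.integer(bed[[5L]]),
             stringsAsFactors = FALSE)
}
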