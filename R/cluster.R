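#' Group SNPs into genomic clusters
#'
#' Single-linkage grouping along each chromosome: SNPs are sorted by
#' position and a new group starts whenever the gap to the previous SNP
#' exceeds `max_gap`. Groups with at least `min_size` members become
#' clusters whose interval runs from `pad` bp before the first member to
#' `pad` bp after the last (clamped at position 1, and at the chromosome
#' length when `chrom_sizes` is supplied); members of smaller groups are
#' reported as singletons rather than silently dropped.
#'
#' Defaults: `min_size = 3` (groups of 3 or more), `pad` = 0.1 Mb on each
#' side, and `max_gap` = 1.5 Mb — the smallest round threshold under which
#' the 8 printed chromosome-17 positions of the motivating data set (largest
#' internal gap 1,192,272 bp) form a single cluster.
#'
#' @param snps A data.frame with columns `chrom`, `pos`, `snp_id` (a
#'   [snp_panel()], a `classified_panel`, or the output of [aon_loci()]).
#' @param max_gap Maximum within-group gap in bp (> 0).
#' @param min_size Minimum group size to report as a cluster (>= 1).
#' @param pad Interval padding in bp (>= 0) added on both sides.
#' @param chrom_sizes Optional named vector of chromosome lengths for
#'   clamping the padded intervals.
#' @return An object of class `snp_cluster_set`: a list with
#'   `clusters` (data.frame: `cluster_id`, `chrom`, `start`, `end`,
#'   `n_snps`, list column `members` in position order),
#'   `singletons` (character vector of snp_ids in ungrouped/small groups),
#'   and `params`.
#' @examples
#' pos <- c(18001459, 18210739, 19403011, 19424358,
#'          19616228, 20573305, 20587484, 20779567)
#' cs <- cluster_snps(data.frame(chrom = "chr17", pos = pos,
#'                               snp_id = paste0("s", 1:8)))
#' cs$clusters[, c("chrom", "start", "end", "n_snps")]
#' @export
cluster_snps <- function(snps, max_gap = 1.5e6, min_size = 3L, pad = 1e5,
                         chrom_sizes = NULL) {
  if (max_gap <= 0) stop("`max_gap` must be > 0", call. = FALSE)
  if (pad < 0) stop("`pad` must be >= 0", call. = FALSE)
  if (min_size < 1L) stop("`min_size` must be >= 1", call. = FALSE)
  df <- as.data.frame(snps)[, c("chrom", "pos", "snp_id")]
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df <- df[order(df$chrom, df$pos, df$snp_id), , drop = FALSE]

  clusters <- list()
  singletons <- character(0)
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    gaps <- diff(sub$pos)
    grp <- cumsum(c(1L, as.integer(gaps > max_gap)))
    for (g in unique(grp)) {
      m <- sub[grp == g, , drop = FALSE]
      if (nrow(m) >= min_size) {
        start <- max(1L, min(m$pos) - as.integer(pad))
        end <- max(m$pos) + as.integer(pad)
        if (!is.null(chrom_sizes) && ch %in% names(chrom_sizes))
          end <- min(end, as.integer(chrom_sizes[[ch]]))
        clusters[[length(clusters) + 1L]] <- list(
          chrom = ch, start = start, end = end,
          members = m$snp_id, n_snps = nrow(m))
      } else {
        singletons <- c(singletons, m$snp_id)
      }
    }
  }
  if (length(clusters)) {
    tab <- data.frame(
      chrom = vapply(clusters, `[[`, character(1), "chrom"),
      start = vapply(clusters, `[[`, integer(1), "start"),
      end = vapply(clusters, `[[`, integer(1), "end"),
      n_snps = vapply(clusters, `[[`, integer(1), "n_snps"),
      stringsAsFactors = FALSE
    )
    ord <- order(tab$chrom, tab$start)
    tab <- tab[ord, , drop = FALSE]
    tab$members <- lapply(clusters, `[[`, "members")[ord]
    tab$cluster_id <- sprintf("%s_c%02d", tab$chrom,
                              stats::ave(seq_len(nrow(tab)), tab$chrom,
                                         FUN = seq_along))
    tab <- tab[, c("cluster_id", "chrom", "start", "end", "n_snps", "members")]
    rownames(tab) <- NULL
  } else {
    tab <- data.frame(cluster_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_snps = integer(0), stringsAsFactors = FALSE)
    tab$members <- list()
  }
  structure(
    list(clusters = tab, singletons = singletons,
         params = list(max_gap = max_gap, min_size = as.integer(min_size),
                       pad = pad)),
    class = "snp_cluster_set"
  )
}

#' @export
print.snp_cluster_set <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "SNP clusters: %d cluster(s), %d clustered loci, %d singleton(s)\n",
    nrow(x$clusters), sum(x$clusters$n_snps), length(x$singletons)))
  cat(sprintf("  (max_gap = %g bp, min_size = %d, pad = %g bp)\n",
              p$max_gap, p$min_size, p$pad))
  if (nrow(x$clusters))
    print.data.frame(x$clusters[, c("cluster_id", "chrom", "start", "end",
                                    "n_snps")])
  invisible(x)
}

#' Summary table of a cluster set
#'
#' One row per cluster with its chromosome, padded interval, interval length
#' (`end - start`, i.e. the padded span in bp) and member count, plus totals.
#'
#' @param clusters A `snp_cluster_set` from [cluster_snps()].
#' @return An object of class `cluster_summary`: list with `table`
#'   (data.frame: `cluster_id`, `chrom`, `start`, `end`, `length`,
#'   `n_snps`) and `totals` (list: `n_clusters`, `n_clustered_snps`,
#'   `n_singletons`).
#' @export
cluster_summary <- function(clusters) {
  tab <- clusters$clusters
  out <- data.frame(cluster_id = tab$cluster_id,
                    chrom = tab$chrom,
                    start = tab$start,
                    end = tab$end,
                    length = tab$end - tab$start,
                    n_snps = tab$n_snps,
                    stringsAsFactors = FALSE)
  structure(
    list(table = out,
         totals = list(n_clusters = nrow(tab),
                       n_clustered_snps = sum(tab$n_snps),
                       n_singletons = length(clusters$singletons))),
    class = "cluster_summary"
  )
}

#' @export
print.cluster_summary <- function(x, ...) {
  t <- x$totals
  cat(sprintf("%d cluster(s), %d clustered loci, %d singleton(s)\n",
              t$n_clusters, t$n_clustered_snps, t$n_singletons))
  if (nrow(x$table)) print.data.frame(x$table)
  invisible(x)
}
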