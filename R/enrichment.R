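#' Permutation test for genomic clustering of labeled SNPs
#'
#' Tests whether a labeled subset of a SNP panel (e.g. the all-or-none
#' loci) is more clustered along the genome than a random subset of the
#' same size. The null preserves the panel's own positions and spatial
#' density: each permutation redraws which loci carry the label, uniformly
#' without replacement. One-sided upper test with the add-one estimator
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`, so p is never zero.
#'
#' Statistics (computed on the labeled loci via [cluster_snps()] with
#' `cluster_params`):
#' * `frac_in_groups_ge3`: fraction of labeled loci that fall in groups of
#'   at least `min_size` members (default 3);
#' * `n_clusters`: number of groups of at least `min_size` members;
#' * `max_cluster_size`: size of the largest group (regardless of
#'   `min_size`).
#'
#' @param panel A [snp_panel()] (or any data.frame with `snp_id`, `chrom`,
#'   `pos`) giving the background of variable loci.
#' @param labels Character vector of labeled snp_ids (subset of the panel).
#' @param statistic One of `"frac_in_groups_ge3"`, `"n_clusters"`,
#'   `"max_cluster_size"`.
#' @param n_perm Number of permutations (>= 1; default 10000).
#' @param seed Integer seed (results are bit-identical for a fixed seed).
#' @param cluster_params List of [cluster_snps()] parameters
#'   (`max_gap`, `min_size`, `pad`).
#' @return An object of class `perm_test`: list with `statistic_name`,
#'   `observed`, `null_samples`, `p_value`, `n_perm`, `seed`.
#' @export
permute_labels_cluster_test <- function(panel, labels,
                                        statistic = c("frac_in_groups_ge3",
                                                      "n_clusters",
                                                      "max_cluster_size"),
                                        n_perm = 10000L, seed = 1L,
                                        cluster_params = list()) {
  statistic <- match.arg(statistic)
  if (n_perm < 1L) stop("`n_perm` must be >= 1", call. = FALSE)
  df <- as.data.frame(panel)[, c("snp_id", "chrom", "pos")]
  if (!all(labels %in% df$snp_id))
    stop("labels not in panel: ",
         paste(utils::head(setdiff(labels, df$snp_id)), collapse = ", "),
         call. = FALSE)
  k <- length(labels)
  if (k > nrow(df)) stop("more labels than panel loci", call. = FALSE)
  cp <- utils::modifyList(list(max_gap = 1.5e6, min_size = 3L, pad = 1e5),
                          cluster_params)
  stat_fun <- function(ids) {
    sub <- df[df$snp_id %in% ids, , drop = FALSE]
    cs <- cluster_snps(sub, max_gap = cp$max_gap, min_size = cp$min_size,
                       pad = cp$pad)
    switch(statistic,
           frac_in_groups_ge3 =
             if (k == 0L) 0 else sum(cs$clusters$n_snps) / k,
           n_clusters = nrow(cs$clusters),
           max_cluster_size = {
             all_groups <- cluster_snps(sub, max_gap = cp$max_gap,
                                        min_size = 1L, pad = cp$pad)
             if (nrow(all_groups$clusters)) max(all_groups$clusters$n_snps)
             else 0L
           })
  }
  observed <- stat_fun(labels)
  set.seed(seed)
  null_samples <- vapply(seq_len(n_perm), function(i)
    stat_fun(sample(df$snp_id, k)), numeric(1))
  p <- (1 + sum(null_samples >= observed)) / (1 + n_perm)
  structure(
    list(statistic_name = statistic, observed = observed,
         null_samples = null_samples, p_value = p,
         n_perm = as.integer(n_perm), seed = as.integer(seed)),
    class = "perm_test"
  )
}

#' Permutation test for DE-gene enrichment in SNP clusters
#'
#' Observed statistic: the number of DE genes whose gene span intersects
#' any padded SNP cluster. The null permutes which genes carry the DE
#' label while preserving every gene's position, redrawing `|de|` genes
#' uniformly without replacement from `all_genes`. One-sided upper add-one
#' p-value.
#'
#' @param clusters A `snp_cluster_set` from [cluster_snps()].
#' @param de_genes DE table (rows with `qvalue < alpha` count as DE), or a
#'   character vector of DE gene ids.
#' @param all_genes A [gene_models()] object (the label-permutation
#'   universe; must contain the DE genes).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param alpha DE q-value threshold when `de_genes` is a table.
#' @return A `perm_test` object (see [permute_labels_cluster_test()]).
#' @export
de_in_cluster_enrichment <- function(clusters, de_genes, all_genes,
                                     n_perm = 10000L, seed = 1L,
                                     alpha = 0.05) {
  if (n_perm < 1L) stop("`n_perm` must be >= 1", call. = FALSE)
  de_ids <- if (is.character(de_genes)) de_genes
            else de_genes$gene_id[de_genes$qvalue < alpha]
  if (!all(de_ids %in% all_genes$gene_id))
    stop("DE gene id(s) absent from `all_genes`: ",
         paste(utils::head(setdiff(de_ids, all_genes$gene_id)),
               collapse = ", "), call. = FALSE)
  tab <- clusters$clusters
  in_cluster <- rep(FALSE, nrow(all_genes))
  if (nrow(tab)) {
    for (i in seq_len(nrow(tab))) {
      in_cluster <- in_cluster |
        (all_genes$chrom == tab$chrom[i] &
           all_genes$start <= tab$end[i] &
           all_genes$end >= tab$start[i])
    }
  }
  names(in_cluster) <- all_genes$gene_id
  k <- length(de_ids)
  observed <- sum(in_cluster[de_ids])
  set.seed(seed)
  null_samples <- vapply(seq_len(n_perm), function(i)
    sum(in_cluster[sample.int(nrow(all_genes), k)]), numeric(1))
  p <- (1 + sum(null_samples >= observed)) / (1 + n_perm)
  structure(
    list(statistic_name = "n_de_in_clusters", observed = observed,
         null_samples = null_samples, p_value = p,
         n_perm = as.integer(n_perm), seed = as.integer(seed)),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Permutation test: %s\n", x$statistic_name))
  cat(sprintf("  observed = %g; null mean = %.4g (n_perm = %d)\n",
              x$observed, mean(x$null_samples), x$n_perm))
  cat(sprintf("  one-sided p = %.4g (add-one estimator, seed = %d)\n",
              x$p_value, x$seed))
  invisible(x)
}
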