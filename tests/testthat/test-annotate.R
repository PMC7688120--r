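test_that("intergenic relations are strand-aware with boundary distances", {
  plus <- one_gene("gA", "chr1", 5001, 8000, "+")
  minus <- one_gene("gB", "chr1", 5001, 8000, "-")
  snp <- function(pos) list(snp_id = "s1", chrom = "chr1", pos = pos)

  a <- annotate_snp(snp(4501), plus)
  expect_equal(a$relation, "upstream")
  expect_equal(a$distance_bp, 500L)

  # mirrors a SNP 524 bp downstream of a minus-strand receptor gene
  b <- annotate_snp(snp(4477), minus)
  expect_equal(b$relation, "downstream")
  expect_equal(b$distance_bp, 524L)

  # 3' side of each strand
  expect_equal(annotate_snp(snp(8100), plus)$relation, "downstream")
  expect_equal(annotate_snp(snp(8100), minus)$relation, "upstream")
  expect_equal(annotate_snp(snp(8100), plus)$distance_bp, 100L)

  # adjacent base -> distance 1
  expect_equal(annotate_snp(snp(5000), plus)$distance_bp, 1L)

  # beyond the window -> no annotation
  expect_equal(nrow(annotate_snp(snp(70000), plus)), 0L)
  expect_equal(nrow(annotate_snp(list(snp_id = "s", chrom = "chr2",
                                      pos = 5500), plus)), 0L)
})

test_that("intragenic SNPs get transcription-ordered exon/intron calls", {
  # minus-strand 2-exon gene: exon 1 is the rightmost
  ex <- cbind(start = c(5001L, 7001L), end = c(5500L, 8000L))
  minus <- one_gene("Vmn2r110", "chr17", 5001, 8000, "-", exons = ex)
  snp <- function(pos) list(snp_id = "s1", chrom = "chr17", pos = pos)

  mid <- annotate_snp(snp(6000), minus)  # between the exons
  expect_equal(mid$relation, "intron 1")
  expect_equal(mid$distance_bp, 0L)
  expect_equal(annotate_snp(snp(7500), minus)$relation, "exon 1")
  expect_equal(annotate_snp(snp(5200), minus)$relation, "exon 2")

  plus <- one_gene("Vmn2r99", "chr17", 5001, 8000, "+", exons = ex)
  expect_equal(annotate_snp(snp(6000), plus)$relation, "intron 1")
  expect_equal(annotate_snp(snp(5200), plus)$relation, "exon 1")
  expect_equal(annotate_snp(snp(7500), plus)$relation, "exon 2")
})

test_that("strand flip swaps up/downstream and reverses intron numbering", {
  set.seed(31)
  ex <- cbind(start = c(10001L, 12001L, 15001L),
              end = c(10500L, 12800L, 16000L))
  for (rep in 1:20) {
    pos <- sample.int(30000, 1)
    plus <- one_gene("g", "chr1", 10001, 16000, "+", exons = ex)
    minus <- one_gene("g", "chr1", 10001, 16000, "-", exons = ex)
    a <- annotate_snp(list(snp_id = "s", chrom = "chr1", pos = pos), plus)
    b <- annotate_snp(list(snp_id = "s", chrom = "chr1", pos = pos), minus)
    expect_equal(nrow(a), nrow(b))
    if (nrow(a) == 0) next
    expect_equal(a$distance_bp, b$distance_bp)
    flip <- c(upstream = "downstream", downstream = "upstream")
    if (a$relation %in% names(flip)) {
      expect_equal(b$relation, flip[[a$relation]])
    } else {
      k <- 3L  # exons
      num <- as.integer(sub(".* ", "", a$relation))
      if (startsWith(a$relation, "exon"))
        expect_equal(b$relation, sprintf("exon %d", k + 1L - num))
      else
        expect_equal(b$relation, sprintf("intron %d", k - num))
    }
  }
})

test_that("shifting an intergenic SNP shifts its distance equally", {
  g <- one_gene("g", "chr1", 100001, 120000, "+")
  d0 <- annotate_snp(list(snp_id = "s", chrom = "chr1", pos = 95000), g)$distance_bp
  for (k in c(1, 10, 1000)) {
    dk <- annotate_snp(list(snp_id = "s", chrom = "chr1",
                            pos = 95000 - k), g)$distance_bp
    expect_equal(dk, d0 + k)
  }
})

test_that("panel annotation composes per-SNP results within the window", {
  genes <- generate_gene_models(
    data.frame(chrom = "chr17", start = 18e6, end = 21e6, n_genes = 12,
               family = "Vmn2r"), seed = 5)
  p <- make_panel(matrix(0.5, 8, 8), chrom = rep("chr17", 8),
                  pos = chr17_cluster_positions)
  ann <- annotate_panel(p, genes)
  # equals the union of per-SNP annotation
  per_snp <- do.call(rbind, lapply(seq_len(nrow(p)), function(i)
    annotate_snp(p[i, ], genes)))
  expect_equal(nrow(ann), nrow(per_snp))
  expect_equal(ann$gene, per_snp$gene_id)
  expect_equal(ann$distance_bp, per_snp$distance_bp)
  expect_true(all(ann$distance_bp <= 50000))
  # snp_location column carries the SNP position
  expect_true(all(ann$snp_location %in% p$pos))
  # empty panel -> empty annotation
  empty <- make_panel(matrix(numeric(0), 0, 8))
  expect_equal(nrow(annotate_panel(empty, genes)), 0L)
})

test_that("alleles column reports group-fixed over opposite base", {
  d <- design44()
  f <- rbind(c(1, 1, 1, 1, 0.2, 0.3, 0.1, 0.6),   # selected fixed focal
             c(0.5, 0.2, 0.7, 0.3, 0, 0, 0, 0))   # control fixed other
  p <- snp_panel(c("a", "b"), c("chr1", "chr1"), c(1000L, 2000L),
                 c("C", "T"), c("A", "G"),
                 matrix(f, 2, 8, dimnames = list(NULL, d$lines$line_id)), d)
  cl <- classify_panel(p)
  g <- one_gene("g", "chr1", 1500, 1600, "+")
  ann <- annotate_panel(p, g, classified = cl)
  expect_equal(ann$alleles[ann$snp_id == "a"], "C / A")
  # control-fixed SNP: selected-group allele printed first
  expect_equal(ann$alleles[ann$snp_id == "b"], "T / G")
})

test_that("DE-cluster overlap counts match all-pairs intersection", {
  set.seed(61)
  genes <- generate_gene_models(
    data.frame(chrom = rep(c("chr1", "chr2"), each = 2),
               start = c(1e6, 8e6, 2e6, 9e6),
               end = c(4e6, 11e6, 5e6, 12e6),
               n_genes = c(10, 8, 9, 7)), seed = 61)
  de <- generate_de_table(genes, p_de = 0.4, seed = 62)
  snps <- data.frame(chrom = sample(c("chr1", "chr2"), 40, replace = TRUE),
                     pos = sample.int(12e6, 40),
                     snp_id = sprintf("s%02d", 1:40))
  cs <- cluster_snps(snps, min_size = 2)
  ov <- overlap_de_with_clusters(cs, de, genes)
  de_ids <- de$gene_id[de$qvalue < 0.05]
  expect_equal(ov$table$n_de,
               oracle_overlap_counts(cs$clusters, de_ids, genes))
  # family split sums to the total
  expect_equal(ov$table$n_de,
               ov$table$n_de_Vmn1r + ov$table$n_de_Vmn2r +
                 ov$table$n_de_Fpr + ov$table$n_de_other)
  # no DE genes -> all zeros; missing ids are warned about and flagged
  ov0 <- overlap_de_with_clusters(cs, de[0, ], genes)
  expect_true(all(ov0$table$n_de == 0))
  de_bad <- rbind(de, data.frame(gene_id = "ghost", log2fc = 2,
                                 qvalue = 0.001, family = "other"))
  expect_warning(ovb <- overlap_de_with_clusters(cs, de_bad, genes), "ghost")
  expect_equal(ovb$missing, "ghost")
})

test_that("a DE gene inside a cluster is counted once for that cluster", {
  g <- one_gene("Vmn2r1", "chr5", 2e6, 2.01e6, "+")
  cs <- cluster_snps(data.frame(chrom = "chr5", pos = c(1.9e6, 2e6, 2.1e6),
                                snp_id = c("a", "b", "c")))
  de <- data.frame(gene_id = "Vmn2r1", log2fc = 1.5, qvalue = 0.01,
                   family = "Vmn2r")
  ov <- overlap_de_with_clusters(cs, de, g)
  expect_equal(ov$table$n_de, 1L)
  expect_equal(ov$table$n_de_Vmn2r, 1L)
  expect_equal(ov$totals$n_de_in_clusters, 1L)
  expect_equal(ov$table$de_gene_ids[[1]], "Vmn2r1")
})
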