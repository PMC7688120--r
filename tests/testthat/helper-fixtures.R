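# shared builders for small in-code fixtures

design44 <- function(ne = 35L, generations = 88L) default_line_design(ne, generations)

# panel from a loci x 8 frequency matrix (HR1..HR4, C1..C4)
make_panel <- function(freqs, chrom = NULL, pos = NULL, design = design44()) {
  n <- nrow(freqs)
  if (is.null(chrom)) chrom <- rep("chr1", n)
  if (is.null(pos)) pos <- seq(1e6, by = 2e6, length.out = n)
  colnames(freqs) <- design$lines$line_id
  snp_panel(sprintf("s%03d", seq_len(n)), chrom, as.integer(pos),
            rep("A", n), rep("G", n), freqs, design)
}

# random panel of n loci with frequencies on a grid (includes exact 0/1)
random_panel <- function(n, seed, design = design44()) {
  set.seed(seed)
  grid <- c(0, 0, 0, 1, 1, 1, 0.1, 0.25, 0.5, 0.75, 0.9)
  f <- matrix(sample(grid, n * 8L, replace = TRUE), nrow = n)
  chrom <- sample(paste0("chr", 1:3), n, replace = TRUE)
  pos <- sample.int(60e6, n)
  make_panel(f, chrom = chrom, pos = pos, design = design)
}

# single-gene model helper (1-based inclusive coords)
one_gene <- function(gene_id, chrom, start, end, strand, exons = NULL,
                     family = NULL) {
  gene_models(gene_id, chrom, as.integer(start), as.integer(end), strand,
              exons = if (is.null(exons)) NULL else list(exons),
              family = family)
}

chr17_cluster_positions <- c(18001459L, 18210739L, 19403011L, 19424358L,
                      19616228L, 20573305L, 20587484L, 20779567L)

extdata <- function(f) system.file("extdata", f, package = "aonsnp")
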