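# aonsnp

Analysis of **all-or-none SNPs** in replicated selection experiments:
loci fixed for the same allele in every replicate line of one selection
group while fixed in no replicate line of the other group (or vice
versa). Such loci are the sharpest genomic signature of a response to
selective breeding, because independent replicate lines agree.

The package is written for experimental-evolution studies of the classic
4 + 4 design — four lines selectively bred for a trait (e.g. high
voluntary wheel running in mice) and four unselected control lines from
the same base population, with effective population size Ne ≈ 35 per line
and on the order of 88 generations — but all parameters are configurable.

It provides, as composable functions with a thin CLI
(`inst/cli/aonsnp.R`):

* **Classification** (`classify_panel`): per-locus all-or-none calls from
  an allele-frequency panel, with two readings of "not fixed" and a
  fixation tolerance δ.
* **Clustering** (`cluster_snps`): single-linkage genomic grouping
  (default gap threshold 1.5 Mb, minimum group size 3) with ±0.1 Mb
  interval padding; BED6 output.
* **Annotation** (`annotate_panel`): strand-aware gene proximity within
  50 kb — upstream/downstream with boundary distances, exon/intron calls
  numbered in transcription order; GFF3/BED12 gene models.
* **DE co-localization** (`overlap_de_with_clusters`): differentially
  expressed genes intersecting SNP clusters, split by receptor family
  (Vmn1r / Vmn2r / Fpr / other).
* **Drift null** (`p_all_or_none_neutral`): the exact Wright–Fisher
  Markov chain over 2N gametes, giving the neutral probability of the
  all-or-none pattern per locus and its expectation over a panel, with a
  Monte-Carlo cross-route. Under drift the next-generation allele count is
  Binomial(2N, p(1+s)/(1+ps)); s = 0 is pure drift.
* **Permutation tests** (`permute_labels_cluster_test`,
  `de_in_cluster_enrichment`): position-preserving label permutation for
  non-random genomic distribution and DE enrichment, one-sided with the
  add-one estimator.
* **Synthetic data** (`generate_panel`, `generate_gene_models`,
  `generate_de_table`): a generator emulating the whole breeding design,
  including selected loci placed in a genomic window, used throughout the
  tests.

## Worked example

Eight all-or-none SNPs on mouse chromosome 17 (positions from a published
table) cluster into a single padded interval:

```r
library(aonsnp)
snps <- read.delim(system.file("extdata", "chr17_receptor_cluster_snps.tsv",
                               package = "aonsnp"))
cs <- cluster_snps(data.frame(chrom = snps$chrom, pos = snps$pos,
                              snp_id = snps$snp_id))
cluster_summary(cs)
#> 1 cluster(s), 8 clustered loci, 0 singleton(s)
#>   cluster_id chrom    start      end  length n_snps
#> 1  chr17_c01 chr17 17901459 20879567 2978108      8
```

All 8 loci merge into one cluster (every internal gap is below the 1.5 Mb
threshold) spanning 2,978,108 bp after ±0.1 Mb padding — the "~3 Mb"
vomeronasal-receptor-cluster interval.

How likely is such a locus under pure drift? For a neutral locus starting
at frequency 0.5:

```r
p_all_or_none_neutral(0.5)   # Ne = 35, 88 generations, 4 + 4 lines
#> Neutral drift null (2N = 70, 88 generations, p0 = 0.5, mode = not_fixed_for_focal)
#>   per line: P(fix focal) = 0.294, P(fix other) = 0.294, P(segregating) = 0.412
#>   P(all-or-none pattern | 4 + 4 lines) = 0.007313
```

So after 88 generations each line has a 29% chance of fixing either
allele, but the coordinated pattern — all four selected lines fixed for
the same allele with no control line fixed for it — arises in only ~0.7%
of neutral loci, and the probability falls steeply toward 0 as the
starting frequency approaches 0 or 1 (`expected_all_or_none_count()`
reports the panel-wide expectation as a function of per-locus starting
frequencies, which are rarely known). Coordinated fixation *in the
selected group specifically*, at many loci concentrated in one genomic
interval next to a receptor-gene cluster, is the signature the
permutation and recovery analyses quantify.

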