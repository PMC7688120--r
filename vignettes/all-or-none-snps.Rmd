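---
title: "All-or-none SNPs in replicated selection lines: methods and design"
author: "aonsnp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{All-or-none SNPs in replicated selection lines: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aonsnp)
```

## The problem

Replicated selection experiments breed several independent lines toward a
trait while maintaining unselected control lines from the same base
population. After many generations, a locus whose allele frequencies have
diverged *consistently* between the two groups — in every selected replicate
the same way, in no control replicate — is a strong candidate for having
responded to selection, because independent replicates agree. The sharpest
version of this signal is the **all-or-none SNP**: a locus fixed for the
same allele in all selected lines while fixed in none of the control lines,
or vice versa.

`aonsnp` implements the analysis pipeline around this concept for a design
with 4 selected and 4 control mouse lines, effective population size
Ne ≈ 35 per line, and 88 generations of breeding: classification of
all-or-none SNPs from per-line allele-frequency panels, genomic clustering
of the classified loci, strand-aware gene-proximity annotation,
co-localization with differentially expressed (DE) genes, an explicit
Wright–Fisher neutral-drift null, and permutation tests for non-random
genomic distribution. A synthetic-data generator emulates the whole design
so that every stage is testable without any external data.

## Classification

Let $f_{ij}$ be the focal-allele frequency of SNP $i$ in line $j$. A line
is *fixed* for the focal allele when $f \ge 1 - \delta$ and for the other
allele when $f \le \delta$; the default $\delta = 0$ reads "fixed"
literally, and a small positive $\delta$ accommodates sample-based
frequency estimates.

"Not fixed in any line of the other group" admits two readings, both
implemented:

* **`not_fixed_for_focal`** (default): a line of the other group fails the
  criterion when its frequency of the group-fixed allele is below
  $1 - \delta$. A control line fixed for the *opposite* allele still
  counts as "not fixed" for the group allele. This is the literal reading
  of the definition.
* **`strict_polymorphic`**: a line fails only when it is strictly
  segregating ($\delta < f < 1 - \delta$). Opposite-fixed lines
  disqualify the locus.

The two modes differ only for loci where some line of the non-fixed group
is itself fixed for the opposite allele. When *both* groups are fully
fixed, for opposite alleles, the default mode accepts the locus in either
direction; the classifier then reports the direction deterministically
(selected-fixed first). This double-fixed configuration is the one place
where a single reported direction cannot satisfy both label-swap
antisymmetry and relabeling invariance simultaneously; the `is_all_or_none`
call itself is invariant under both operations in both modes.

## Clustering

All-or-none SNPs are grouped per chromosome by single-linkage on position:
sort, then cut wherever the gap to the previous SNP exceeds `max_gap`.
Groups with at least `min_size` members become clusters; the cluster
interval is padded by 0.1 Mb beyond the first and last member SNP
(clamped at position 1 and, when chromosome sizes are supplied, at the
chromosome end). Members of smaller groups are reported as singletons
rather than dropped.

Defaults and their rationale:

* `min_size = 3`: a "group" means 3 or more loci in proximity.
* `pad = 1e5` (0.1 Mb per side): the cluster-interval definition.
* `max_gap = 1.5e6`: no proximity threshold is canonical. The worked
  example of 8 SNPs on chromosome 17 (positions 18,001,459–20,779,567,
  largest internal gap 1,192,272 bp) must form a single cluster, which
  requires `max_gap` > 1.19 Mb; 1.5 Mb is the smallest round value with
  margin, and the parameter is exposed. With the defaults that cluster
  spans 2,978,108 bp after padding — the "~3 Mb interval". Cluster
  *length* is reported as `end - start` of the padded interval.

Since reported group censuses are ambiguous about whether pairs and
singletons count as "clusters", `cluster_snps` supports both conventions
(`min_size = 3` vs `min_size = 1`) instead of guessing.

## Annotation

Gene proximity is assessed within a 50 kb window from the SNP to the
nearest gene-span boundary (not TSS-only, since both upstream and
downstream genes are reported with boundary distances). Conventions,
documented rather than asserted as universal:

* Distance is the absolute coordinate difference between the SNP base and
  the nearest gene boundary; a SNP adjacent to the gene has distance 1;
  intragenic SNPs have distance 0.
* Upstream/downstream is strand-aware: on the minus strand a SNP at lower
  genomic coordinate than the gene is *downstream*.
* Exon/intron numbering is 1-based in transcription order (exon 1 is the
  5′-most exon; for minus-strand genes it has the largest coordinates).
* A SNP may annotate to several genes; no best-gene selection is done.

Internally all intervals are 1-based inclusive — the R/Bioconductor
(IRanges) convention; on disk BED is 0-based half-open and GFF3 1-based
inclusive, with conversions delegated to `rtracklayer`. SNP positions are
1-based throughout. Coordinates are assumed to come from one consistent
genome build supplied by the user; no liftover is attempted.

## The Wright–Fisher drift null

Whether all-or-none loci can be explained by drift alone is quantified
with an explicit neutral model rather than intuition. Each line is an
independent Wright–Fisher population of $2N = 70$ gametes: the
focal-allele count follows
$X_{t+1} \mid X_t \sim \mathrm{Binomial}\!\left(2N,\; \frac{p(1+s)}{1+ps}\right),
\quad p = X_t / 2N,$
with genic selection coefficient $s$ ($s = 0$ is pure drift; 0 and $2N$
are absorbing). The chain is evaluated exactly by dense matrix–vector
propagation for $2N \le 200$ (beyond that the functions direct the user to
Monte Carlo); the initial count is the nearest integer to $p_0 \cdot 2N$,
with an optional two-point mixture over the adjacent counts that preserves
the exact mean for fractional $p_0 \cdot 2N$.

From the final-generation distribution, let $a$ and $b$ be the per-line
probabilities of fixing the focal and the other allele. With $n$ selected
and $m$ control lines, the neutral probability of the all-or-none pattern
under the default mode is, by inclusion–exclusion,

$$P = a^n(1-a)^m + b^n(1-b)^m + a^m(1-a)^n + b^m(1-b)^n - a^n b^m - a^m b^n,$$

where the subtracted terms remove the doubly-counted configurations in
which the groups are fixed for opposite alleles. Under
`strict_polymorphic` the failure factor is the segregating probability and
no correction is needed. A naive four-term sum without the correction
over-counts; the implementation is cross-checked in the tests against an
independent Monte-Carlo route (simulate trajectories, apply the
classification predicate).

At the design parameters ($p_0 = 0.5$, $2N = 70$, 88 generations) a single
neutral locus produces the pattern with probability ≈ 0.0073, and the
probability vanishes at $p_0 \in \{0, 1\}$ and peaks at intermediate
frequencies. Because base-population starting frequencies are generally
unknown, `expected_all_or_none_count()` reports the expectation as a sum
over user-supplied per-locus $p_0$ values rather than a single headline
number, with a 95% interval obtained by sampling each locus's indicator
from its exact probability (loci are unlinked and independent, so this is
distributionally identical to re-simulating trajectories and classifying
them, at a fraction of the cost).

## Permutation tests

The claim that all-or-none loci are "not randomly distributed" is made
checkable with a label-permutation test: the background is the full
variable-SNP panel, and the null redraws *which* loci carry the label,
uniformly without replacement, preserving every position — so the null
respects the panel's own spatial density rather than assuming genome-wide
uniformity. Statistics: fraction of labeled loci in groups of ≥ 3, number
of clusters, or largest group size. DE-gene enrichment inside clusters is
tested the same way over gene labels. Tests are one-sided upper
(clustering and enrichment are directional hypotheses) and use the add-one
estimator $p = (1 + \#\{T_{\mathrm{null}} \ge T_{\mathrm{obs}}\}) / (1 +
n_{\mathrm{perm}})$, which can never return 0. Results are bit-identical
for a fixed seed. Because the statistics are discrete, p-values are
slightly conservative (super-uniform), which the calibration test's
acceptance band accounts for.

## The synthetic-data generator

The generator emulates the breeding design: 4 + 4 replicate lines, Ne = 35,
88 generations, loci simulated independently in every line from a shared
per-locus $p_0$, with optional genic selection at chosen loci *in the
selected lines only* and placement of those loci inside one contiguous
window (a selected gene cluster). Gene models are drawn as non-overlapping,
strand-alternating genes with 2–5 exons and a family tag per window;
DE tables flag genes with configurable probability, raised inside target
windows.

Default and experiment parameter choices, made once:

* Background loci draw $p_0 \sim U(0.05, 0.95)$: a variable-SNP panel is
  ascertained to be segregating, so extreme starting frequencies are
  under-represented.
* The parameter-recovery experiment uses $p_0 = 0.1$ with $s = 0.5$ at the
  10 selected loci: beneficial variants typically segregate at low
  frequency in an outbred base population, and low $p_0$ keeps the control
  lines from fixing the favored allele by drift (neutral fixation
  probability equals $p_0$), which is what makes the all-or-none signature
  of selection detectable in the first place.
* Ne is a direct input; the inflation of effective size by within-family
  selection is not modeled mechanistically.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: linkage and hitchhiking (loci are independent,
whereas real all-or-none SNP groups likely reflect LD with a selected
site), mutation, dominance (selection is genic, one parameter), shared
pedigree structure within lines, and genotyping/frequency-estimation
error. The clustering of synthetic selected loci arises purely from their
placement in one window.

Reproducibility: each generated panel is fully determined by its config
seed. The panel simulation runs generation-major over a single RNG stream
(one vectorised binomial draw per generation across all loci and lines),
which keeps the generator fast in R; per-locus streams keyed by
(seed, line, locus) were considered and rejected as they would force
scalar sampling loops.

## Numerical and scale choices

* Exact chain: dense matrix powers up to $2N = 200$; probability mass is
  conserved to 1e−12 and the neutral absorption probability matches the
  martingale value $p_0$ to 1e−6 at long horizons (5,000 generations).
* Verification scales: Monte-Carlo cross-checks use 100,000 replicate
  lines; martingale/variance checks use 1,000 loci × 8 lines; calibration
  uses 20 seeded panels of 300 loci and 200 permutation runs of a
  400-locus panel; parameter recovery uses 20 seeds of 1,010 loci. These
  sizes give 3-standard-error resolution on every quantity checked while
  keeping the whole suite fast on one CPU.
* Output tables are written sorted with fixed column order, so repeated
  runs are byte-identical.

## Known limitations

* The fixation tolerance $\delta$ treats all lines symmetrically; designs
  with line-specific sample sizes would need per-line tolerances.
* The drift null assumes identical, independent lines with a shared
  $p_0$; correlated founder frequencies across lines would require a
  hierarchical extension.
* The proximity annotation is gene-span based; promoter- or TSS-anchored
  conventions will give different distances for upstream genes, and the
  base-counting convention (coordinate difference) is one of several in
  use. The choice is documented so users can convert.
* `max_gap` has no canonical value; conclusions about cluster *counts*
  should be checked for robustness across a range of thresholds.
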