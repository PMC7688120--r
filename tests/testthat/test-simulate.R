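test_that("boundary states are absorbing and parameters validated", {
  expect_error(simulate_wf_line(0.5, 0, 10), "ne")
  expect_error(simulate_wf_line(1.5, 10, 10), "p0")
  set.seed(1)
  expect_equal(simulate_wf_line(0, 35, 88, s = 0.5, keep_trajectory = TRUE),
               rep(0, 89))
  expect_equal(simulate_wf_line(1, 35, 88, keep_trajectory = TRUE),
               rep(1, 89))
})

test_that("one-generation transition matches the closed-form binomial", {
  # ne = 1 (2N = 2), p0 = 0.5, s = 0: next count ~ Binomial(2, 0.5)
  set.seed(99)
  reps <- 20000
  finals <- vapply(seq_len(reps), function(i) simulate_wf_line(0.5, 1, 1),
                   numeric(1))
  counts <- table(factor(finals * 2, levels = 0:2)) / reps
  expected <- dbinom(0:2, 2, 0.5)
  se <- sqrt(expected * (1 - expected) / reps)
  expect_true(all(abs(as.numeric(counts) - expected) <= 3 * se))
})

test_that("panel generation is deterministic given the seed", {
  cfg <- simulation_config(5, c(chr1 = 1e7), seed = 77)
  p1 <- generate_panel(cfg)
  p2 <- generate_panel(cfg)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  expect_identical(attr(p1, "truth"), attr(p2, "truth"))
})

test_that("neutral drift preserves the mean and matches the WF variance", {
  cfg <- simulation_config(1000, c(chr1 = 1e8), p0 = 0.5, seed = 101)
  panel <- generate_panel(cfg)
  f <- as.vector(panel_freqs(panel))   # 1000 loci x 8 lines
  n <- length(f)
  # martingale: E[p_t] = p0
  expect_lt(abs(mean(f) - 0.5), 3 * stats::sd(f) / sqrt(n))
  # Var[p_t] = p0 (1 - p0) (1 - (1 - 1/2N)^t)
  v_expected <- 0.5 * 0.5 * (1 - (1 - 1 / 70)^88)
  v_obs <- mean((f - 0.5)^2)
  m4 <- mean((f - 0.5)^4)
  se_v <- sqrt((m4 - v_obs^2) / n)
  expect_lt(abs(v_obs - v_expected), 3 * se_v)
})

test_that("strong selection fixes the favored allele almost surely", {
  # exact chain benchmark with the selection-adjusted transition
  v <- exact_state_distribution(0.5, 70, 88, s = 1.0)
  p_fix_exact <- min(v[71], 1)
  expect_gt(p_fix_exact, 0.99)
  cfg <- simulation_config(
    120, c(chr1 = 1e8), p0 = 0.5, seed = 55,
    selected_loci = data.frame(locus = 1:120, s = 1.0))
  panel <- generate_panel(cfg)
  sel_f <- panel_freqs(panel)[, selected_lines(panel_design(panel))]
  rate <- mean(sel_f == 1)
  se <- sqrt(p_fix_exact * (1 - p_fix_exact) / length(sel_f))
  expect_lt(abs(rate - p_fix_exact), 3 * se + 0.005)
})

test_that("selection acts only in the selected lines", {
  cfg <- simulation_config(
    200, c(chr1 = 1e8), p0 = 0.5, seed = 56,
    selected_loci = data.frame(locus = 1:200, s = 1.0))
  panel <- generate_panel(cfg)
  ctrl_f <- panel_freqs(panel)[, control_lines(panel_design(panel))]
  # control lines drift neutrally: mean stays near p0
  expect_lt(abs(mean(ctrl_f) - 0.5), 3 * stats::sd(as.vector(ctrl_f)) /
              sqrt(length(ctrl_f)))
})

test_that("favoring the other allele mirrors focal-allele selection", {
  cfg <- simulation_config(
    100, c(chr1 = 1e8), p0 = 0.5, seed = 57,
    selected_loci = data.frame(locus = 1:100, s = 1.0, favored = "other"))
  panel <- generate_panel(cfg)
  sel_f <- panel_freqs(panel)[, selected_lines(panel_design(panel))]
  expect_gt(mean(sel_f == 0), 0.98)   # focal allele lost
})

test_that("selected loci land inside the configured window", {
  cfg <- simulation_config(
    50, c(chr1 = 5e7, chr2 = 5e7), seed = 58,
    selected_loci = data.frame(locus = 1:10, s = 0.5),
    cluster_spec = list(chrom = "chr2", start = 10e6, end = 11e6))
  panel <- generate_panel(cfg)
  truth <- attr(panel, "truth")
  sel <- truth[truth$selected, ]
  expect_equal(nrow(sel), 10L)
  expect_true(all(sel$chrom == "chr2"))
  expect_true(all(sel$pos >= 10e6 & sel$pos <= 11e6))
  expect_error(simulation_config(5, c(chr1 = 1e6),
                                 selected_loci = data.frame(locus = 9, s = 1)),
               "out of range")
})

test_that("gene-window and DE generators respect their configuration", {
  g0 <- generate_gene_models(
    data.frame(chrom = "chr1", start = 1, end = 1e6, n_genes = 0))
  expect_equal(nrow(g0), 0L)
  g <- generate_gene_models(
    data.frame(chrom = "chr1", start = 1e6, end = 2e6, n_genes = 10,
               family = "Vmn1r"), seed = 31)
  expect_equal(nrow(g), 10L)
  expect_true(all(g$start >= 1e6 & g$end <= 2e6))
  expect_true(all(g$family == "Vmn1r"))
  o <- order(g$start)
  expect_true(all(g$start[o][-1] > g$end[o][-10]))  # disjoint
  expect_true(all(n_exons(g) >= 2 & n_exons(g) <= 5))
  expect_true(all(g$strand %in% c("+", "-")))
  expect_error(generate_gene_models(
    data.frame(chrom = "chr1", start = 1, end = 1e4, n_genes = 10)),
    "too small")

  # all-DE window, nothing elsewhere
  g2 <- generate_gene_models(
    data.frame(chrom = c("chr1", "chr2"), start = c(1e6, 1e6),
               end = c(3e6, 3e6), n_genes = c(15, 15)), seed = 32)
  win <- data.frame(chrom = "chr1", start = 1e6, end = 3e6)
  de <- generate_de_table(g2, p_de = 0, window_p_de = 1, windows = win,
                          seed = 33)
  is_de <- de$qvalue < 0.05
  on_chr1 <- g2$chrom == "chr1"
  expect_true(all(is_de[on_chr1]))
  expect_false(any(is_de[!on_chr1]))

  # DE fraction inside the window concentrates on the configured value
  g3 <- generate_gene_models(
    data.frame(chrom = "chr1", start = 1e6, end = 60e6, n_genes = 500),
    seed = 34)
  de3 <- generate_de_table(g3, p_de = 0.4, seed = 35)
  frac <- mean(de3$qvalue < 0.05)
  expect_lt(abs(frac - 0.4), 3 * sqrt(0.4 * 0.6 / 500))
})
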