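#' Simulation configuration for a replicated selection experiment
#'
#' Bundles the parameters of the synthetic breeding design: loci count,
#' chromosome sizes, initial-frequency distribution, per-line effective
#' population size and generation count, replicate structure, and an
#' optional set of selected loci (with genic selection coefficients) that
#' can be placed inside a contiguous genomic window to emulate a selected
#' gene cluster.
#'
#' @param n_loci Number of loci (>= 1).
#' @param chrom_sizes Named integer vector of chromosome lengths in bp.
#' @param p0 Initial focal-allele frequency specification: a single number
#'   (all loci share it) or a length-2 vector `c(min, max)` for a uniform
#'   draw per locus.
#' @param ne Effective population size per line (default 35).
#' @param generations Number of generations (default 88).
#' @param n_selected,n_control Replicate lines per group (default 4 + 4).
#' @param selected_loci Optional data.frame with columns `locus` (index in
#'   `1..n_loci`), `s` (genic selection coefficient, >= -1, applied in the
#'   selected lines only) and optionally `favored` (`"focal"` or
#'   `"other"`, default focal) and `p0` (per-locus initial frequency
#'   override).
#' @param cluster_spec Optional list `(chrom, start, end)`: the selected
#'   loci are placed uniformly inside this window instead of genome-wide.
#' @param seed Integer seed making the generated panel reproducible.
#' @return An object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_loci,
                              chrom_sizes,
                              p0 = c(0.05, 0.95),
                              ne = 35L,
                              generations = 88L,
                              n_selected = 4L,
                              n_control = 4L,
                              selected_loci = NULL,
                              cluster_spec = NULL,
                              seed = 1L) {
  n_loci <- as.integer(n_loci)
  if (is.na(n_loci) || n_loci < 1L) stop("`n_loci` must be >= 1", call. = FALSE)
  if (is.null(names(chrom_sizes)) || any(chrom_sizes < 1))
    stop("`chrom_sizes` must be a named vector of lengths >= 1", call. = FALSE)
  if (!length(p0) %in% 1:2 || any(p0 < 0) || any(p0 > 1))
    stop("`p0` must be one frequency or a [min, max] range in [0, 1]",
         call. = FALSE)
  if (ne < 1L) stop("`ne` must be >= 1", call. = FALSE)
  if (generations < 0L) stop("`generations` must be >= 0", call. = FALSE)
  if (!is.null(selected_loci)) {
    if (!all(c("locus", "s") %in% names(selected_loci)))
      stop("`selected_loci` needs columns `locus` and `s`", call. = FALSE)
    if (any(selected_loci$locus < 1L) || any(selected_loci$locus > n_loci))
      stop("selected locus index out of range", call. = FALSE)
    if (any(selected_loci$s < -1))
      stop("selection coefficient must be >= -1", call. = FALSE)
    if (!"favored" %in% names(selected_loci))
      selected_loci$favored <- "focal"
    if (!all(selected_loci$favored %in% c("focal", "other")))
      stop("`favored` must be \"focal\" or \"other\"", call. = FALSE)
  }
  if (!is.null(cluster_spec)) {
    if (!all(c("chrom", "start", "end") %in% names(cluster_spec)) ||
        !cluster_spec$chrom %in% names(chrom_sizes))
      stop("`cluster_spec` needs chrom/start/end on a known chromosome",
           call. = FALSE)
  }
  structure(
    list(n_loci = n_loci, chrom_sizes = chrom_sizes, p0 = p0,
         ne = as.integer(ne), generations = as.integer(generations),
         n_selected = as.integer(n_selected),
         n_control = as.integer(n_control),
         selected_loci = selected_loci, cluster_spec = cluster_spec,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# genic selection: next-generation sampling probability of the focal allele
wf_selection_prob <- function(p, s) p * (1 + s) / (1 + p * s)

#' Simulate one Wright-Fisher line
#'
#' Discrete-generation Wright-Fisher sampling of `2 * ne` gametes: each
#' generation the focal-allele count is drawn binomially with success
#' probability `p (1 + s) / (1 + p s)` (genic selection; `s = 0` is pure
#' drift). The boundaries 0 and 1 are absorbing. Uses the current RNG
#' state; call [set.seed()] beforehand for reproducibility.
#'
#' @param p0 Initial focal-allele frequency in `[0, 1]`.
#' @param ne Effective population size (>= 1).
#' @param generations Number of generations (>= 0).
#' @param s Genic selection coefficient (>= -1).
#' @param keep_trajectory Return the whole trajectory instead of the final
#'   frequency.
#' @return Final frequency, or (with `keep_trajectory = TRUE`) a numeric
#'   vector of length `generations + 1` starting at `p0`.
#' @export
simulate_wf_line <- function(p0, ne, generations, s = 0,
                             keep_trajectory = FALSE) {
  if (ne < 1) stop("`ne` must be >= 1", call. = FALSE)
  if (p0 < 0 || p0 > 1) stop("`p0` must be in [0, 1]", call. = FALSE)
  if (s < -1) stop("`s` must be >= -1", call. = FALSE)
  two_n <- 2L * as.integer(ne)
  p <- p0
  traj <- if (keep_trajectory) numeric(generations + 1L) else NULL
  if (keep_trajectory) traj[1L] <- p
  for (g in seq_len(generations)) {
    if (p > 0 && p < 1)
      p <- stats::rbinom(1L, two_n, wf_selection_prob(p, s)) / two_n
    if (keep_trajectory) traj[g + 1L] <- p
  }
  if (keep_trajectory) traj else p
}

# vectorised final-frequency simulation: one trajectory per element of p0
# (all with the same two_n/generations; s may be scalar or vector)
wf_simulate_final <- function(p0, two_n, generations, s = 0) {
  p <- p0
  if (length(s) == 1L) s <- rep(s, length(p0))
  for (g in seq_len(generations)) {
    live <- which(p > 0 & p < 1)
    if (!length(live)) break
    pr <- wf_selection_prob(p[live], s[live])
    p[live] <- stats::rbinom(length(live), two_n, pr) / two_n
  }
  p
}

#' Generate a synthetic allele-frequency panel
#'
#' Simulates every locus independently in each replicate line from a shared
#' per-locus initial frequency. Selection (from `selected_loci`) acts in the
#' selected lines only; control lines always drift neutrally. Positions are
#' drawn uniformly within the configured chromosomes (length-weighted), with
#' selected loci placed inside `cluster_spec` when given. Deterministic
#' given the config seed.
#'
#' @param config A [simulation_config()].
#' @return A [snp_panel()] with a truth table in `attr(, "truth")`
#'   (data.frame: `snp_id`, `p0`, `s`, `favored`, `selected` flag).
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_loci
  # initial frequencies
  p0 <- if (length(config$p0) == 1L) rep(config$p0, n)
        else stats::runif(n, config$p0[1L], config$p0[2L])
  s_sel <- rep(0, n)       # selection coefficient in selected lines
  favored <- rep("focal", n)
  is_sel_locus <- rep(FALSE, n)
  if (!is.null(config$selected_loci)) {
    sl <- config$selected_loci
    s_sel[sl$locus] <- sl$s
    favored[sl$locus] <- sl$favored
    is_sel_locus[sl$locus] <- TRUE
    if ("p0" %in% names(sl)) p0[sl$locus] <- sl$p0
  }
  # positions
  chroms <- names(config$chrom_sizes)
  chrom <- sample(chroms, n, replace = TRUE,
                  prob = as.numeric(config$chrom_sizes))
  pos <- vapply(chrom, function(ch)
    sample.int(as.integer(config$chrom_sizes[[ch]]), 1L), integer(1))
  if (!is.null(config$cluster_spec) && any(is_sel_locus)) {
    cs <- config$cluster_spec
    k <- sum(is_sel_locus)
    chrom[is_sel_locus] <- cs$chrom
    pos[is_sel_locus] <- sort(sample(seq.int(cs$start, cs$end), k))
  }
  # alleles
  bases <- c("A", "C", "G", "T")
  focal <- sample(bases, n, replace = TRUE)
  other <- vapply(focal, function(b) sample(setdiff(bases, b), 1L),
                  character(1))
  # drift/selection, generation-major and vectorised over (locus, line)
  design <- line_design(
    c(paste0("HR", seq_len(config$n_selected)),
      paste0("C", seq_len(config$n_control))),
    rep(c("selected", "control"), c(config$n_selected, config$n_control)),
    ne = config$ne, generations = config$generations)
  n_lines <- nrow(design$lines)
  two_n <- 2L * config$ne
  # frequency of the *favored* allele, flipped back afterwards
  q0 <- ifelse(favored == "focal", p0, 1 - p0)
  Q0 <- matrix(rep(q0, n_lines), nrow = n, ncol = n_lines)
  S <- matrix(0, nrow = n, ncol = n_lines)
  sel_cols <- which(design$lines$linetype == "selected")
  S[, sel_cols] <- s_sel
  qf <- wf_simulate_final(as.vector(Q0), two_n, config$generations,
                          as.vector(S))
  Qf <- matrix(qf, nrow = n, ncol = n_lines)
  Pf <- ifelse(matrix(favored == "focal", n, n_lines), Qf, 1 - Qf)
  colnames(Pf) <- design$lines$line_id
  snp_id <- sprintf("snp%06d", seq_len(n))
  panel <- snp_panel(snp_id, chrom, pos, focal, other, Pf, design)
  truth <- data.frame(snp_id = snp_id, chrom = chrom, pos = pos, p0 = p0,
                      s = s_sel, favored = favored, selected = is_sel_locus,
                      stringsAsFactors = FALSE)
  truth <- truth[match(panel$snp_id, truth$snp_id), , drop = FALSE]
  rownames(truth) <- NULL
  attr(panel, "truth") <- truth
  panel
}

#' Generate synthetic gene models in cluster windows
#'
#' Places the requested number of non-overlapping genes inside each window,
#' with alternating strands, 2-5 exons each, and a per-window family tag —
#' emulating receptor-family gene clusters (e.g. vomeronasal `Vmn1r`,
#' `Vmn2r`, `Fpr` clusters).
#'
#' @param windows Data.frame with columns `chrom`, `start`, `end`,
#'   `n_genes`, and optionally `family` (default `"other"`) and `prefix`
#'   for gene names.
#' @param gene_length Approximate gene length in bp (genes are drawn
#'   between 50% and 100% of this value).
#' @param seed Integer seed.
#' @return A [gene_models()] object.
#' @export
generate_gene_models <- function(windows, gene_length = 20000L, seed = 1L) {
  set.seed(seed)
  if (!all(c("chrom", "start", "end", "n_genes") %in% names(windows)))
    stop("`windows` needs columns chrom, start, end, n_genes", call. = FALSE)
  windows$start <- as.integer(windows$start)
  windows$end <- as.integer(windows$end)
  windows$n_genes <- as.integer(windows$n_genes)
  if (!"family" %in% names(windows)) windows$family <- "other"
  if (!"prefix" %in% names(windows))
    windows$prefix <- ifelse(windows$family == "other", "Gene",
                             windows$family)
  all_rows <- list()
  for (w in seq_len(nrow(windows))) {
    k <- windows$n_genes[w]
    if (k == 0L) next
    width <- windows$end[w] - windows$start[w] + 1L
    slot <- width %/% k
    if (slot < gene_length + 2L)
      stop("window too small for ", k, " genes of ~", gene_length, " bp",
           call. = FALSE)
    for (i in seq_len(k)) {
      slot_start <- windows$start[w] + (i - 1L) * slot
      glen <- as.integer(stats::runif(1, 0.5, 1) * gene_length)
      gstart <- slot_start +
        sample.int(max(1L, slot - glen - 1L), 1L) - 1L
      gend <- gstart + glen - 1L
      nex <- sample(2:5, 1L)
      # cut the gene into 2*nex-1 alternating exon/intron pieces
      cuts <- sort(sample(seq.int(gstart + 1L, gend - 1L), 2L * nex - 2L))
      bounds <- c(gstart, cuts, gend)
      ex <- cbind(start = bounds[seq(1L, 2L * nex - 1L, by = 2L)],
                  end = bounds[seq(2L, 2L * nex, by = 2L)])
      all_rows[[length(all_rows) + 1L]] <- list(
        gene_id = sprintf("%s%d_%d", windows$prefix[w], w, i),
        chrom = windows$chrom[w], start = gstart, end = gend,
        strand = if (i %% 2L == 1L) "+" else "-",
        exons = ex, family = windows$family[w])
    }
  }
  if (!length(all_rows))
    return(gene_models(character(), character(), integer(), integer(),
                       character()))
  gene_models(
    gene_id = vapply(all_rows, `[[`, character(1), "gene_id"),
    chrom = vapply(all_rows, `[[`, character(1), "chrom"),
    start = vapply(all_rows, `[[`, integer(1), "start"),
    end = vapply(all_rows, `[[`, integer(1), "end"),
    strand = vapply(all_rows, `[[`, character(1), "strand"),
    exons = lapply(all_rows, `[[`, "exons"),
    family = vapply(all_rows, `[[`, character(1), "family"))
}

#' Generate a synthetic differential-expression table
#'
#' Flags each gene DE (q-value below 0.05) with probability `p_de`, raised
#' to `window_p_de` for genes whose span intersects any of the given
#' windows — emulating DE-gene enrichment inside a receptor cluster. DE
#' genes get q ~ U(0, 0.05) and |log2 fold change| ~ U(0.5, 3.3) with
#' random sign; non-DE genes q ~ U(0.05, 1) and small fold changes.
#'
#' @param genes A [gene_models()] object.
#' @param p_de Baseline DE probability per gene.
#' @param window_p_de DE probability inside `windows` (defaults to `p_de`).
#' @param windows Optional data.frame with `chrom`, `start`, `end`.
#' @param seed Integer seed.
#' @return Data.frame with columns `gene_id`, `log2fc`, `qvalue`, `family`.
#' @export
generate_de_table <- function(genes, p_de = 0.1, window_p_de = p_de,
                              windows = NULL, seed = 1L) {
  set.seed(seed)
  n <- nrow(genes)
  in_window <- rep(FALSE, n)
  if (!is.null(windows) && nrow(windows)) {
    for (w in seq_len(nrow(windows))) {
      in_window <- in_window |
        (genes$chrom == windows$chrom[w] &
           genes$start <= windows$end[w] &
           genes$end >= windows$start[w])
    }
  }
  prob <- ifelse(in_window, window_p_de, p_de)
  de <- stats::runif(n) < prob
  q <- ifelse(de, stats::runif(n, 0, 0.05), stats::runif(n, 0.05, 1))
  fc <- ifelse(de,
               sample(c(-1, 1), n, replace = TRUE) * stats::runif(n, 0.5, 3.3),
               stats::rnorm(n, 0, 0.2))
  data.frame(gene_id = genes$gene_id, log2fc = fc, qvalue = q,
             family = genes$family, stringsAsFactors = FALSE)
}
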