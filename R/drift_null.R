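#' Wright-Fisher transition matrix
#'
#' Dense `(two_n + 1) x (two_n + 1)` transition matrix of the focal-allele
#' gamete count under binomial resampling with genic selection: from count
#' `i` (frequency `p = i / two_n`) the next count is
#' `Binomial(two_n, p (1 + s) / (1 + p s))`. Rows sum to 1; 0 and `two_n`
#' are absorbing.
#'
#' @param two_n Gamete count `2 * Ne` (<= 200 for dense evaluation).
#' @param s Genic selection coefficient.
#' @return Numeric matrix, rows = current count `0..two_n`.
#' @export
wf_transition_matrix <- function(two_n, s = 0) {
  if (two_n < 1) stop("`two_n` must be >= 1", call. = FALSE)
  if (two_n > 200)
    stop("two_n > 200: dense transition matrix not supported; ",
         "use Monte Carlo (wf_simulate or simulate_wf_line)", call. = FALSE)
  p <- (0:two_n) / two_n
  pp <- wf_selection_prob(p, s)
  t(vapply(pp, function(q) stats::dbinom(0:two_n, two_n, q),
           numeric(two_n + 1L)))
}

#' Exact allele-count distribution after drift
#'
#' Propagates the Wright-Fisher Markov chain for a given number of
#' generations and returns the full probability vector over allele counts
#' `0..two_n`. The initial count is the integer nearest to `p0 * two_n`
#' (`init = "round"`), or a two-point mixture over the adjacent counts with
#' weights preserving the exact mean (`init = "mixture"`) for fractional
#' `p0 * two_n`.
#'
#' @param p0 Initial focal-allele frequency.
#' @param two_n Gamete count `2 * Ne` (<= 200).
#' @param generations Number of generations (>= 0).
#' @param s Genic selection coefficient (default 0, pure drift).
#' @param init `"round"` or `"mixture"`.
#' @return Numeric probability vector of length `two_n + 1` (sums to 1).
#' @export
exact_state_distribution <- function(p0, two_n, generations, s = 0,
                                     init = c("round", "mixture")) {
  init <- match.arg(init)
  if (p0 < 0 || p0 > 1) stop("`p0` must be in [0, 1]", call. = FALSE)
  if (generations < 0) stop("`generations` must be >= 0", call. = FALSE)
  v <- numeric(two_n + 1L)
  x <- p0 * two_n
  if (init == "round" || x == round(x)) {
    v[round(x) + 1L] <- 1
  } else {
    lo <- floor(x)
    w <- x - lo
    v[lo + 1L] <- 1 - w
    v[lo + 2L] <- w
  }
  if (generations == 0L) return(v)
  T <- wf_transition_matrix(two_n, s)
  for (g in seq_len(generations)) v <- as.vector(v %*% T)
  v
}

# per-line fixation probabilities under the exact chain, with a fixation
# tolerance delta applied to the final frequency
wf_line_probs <- function(p0, two_n, generations, s = 0, delta = 0,
                          init = "round") {
  v <- exact_state_distribution(p0, two_n, generations, s, init = init)
  counts <- 0:two_n
  a <- sum(v[counts / two_n >= 1 - delta])  # fixed for focal
  b <- sum(v[counts / two_n <= delta])      # fixed for other
  list(p_fix_focal = a, p_fix_other = b,
       p_segregating = max(0, 1 - a - b), dist = v)
}

#' Neutral-drift probability of the all-or-none pattern
#'
#' Computes, from the exact Wright-Fisher chain, the probability that a
#' neutral locus with initial frequency `p0` produces the all-or-none
#' pattern across `n_selected + n_control` independent replicate lines:
#' every line of one group fixed for one allele while every line of the
#' other group fails the fixation criterion for that allele (both group
#' directions and both alleles counted, overlap-corrected). This quantifies
#' how much of the observed between-group differentiation pure drift can
#' explain.
#'
#' Writing `a` and `b` for the per-line probabilities of fixing the focal
#' and the other allele, and `n`, `m` for the group sizes, the pattern
#' probability under the default mode is
#' `a^n (1-a)^m + b^n (1-b)^m + a^m (1-a)^n + b^m (1-b)^n - a^n b^m - a^m b^n`
#' (the subtracted terms remove the doubly-counted configurations in which
#' the two groups are fixed for opposite alleles); under
#' `strict_polymorphic` the failure factor is the segregating probability
#' and no overlap correction is needed.
#'
#' @param p0 Initial focal-allele frequency.
#' @param ne Effective population size per line (default 35).
#' @param generations Number of generations (default 88).
#' @param n_selected,n_control Replicate lines per group (default 4 + 4).
#' @param mode `"not_fixed_for_focal"` or `"strict_polymorphic"` (see
#'   [classify_all_or_none()]).
#' @param delta Fixation tolerance.
#' @param init Initial-count convention (see [exact_state_distribution()]).
#' @param mc_reps When > 0, also estimate the pattern probability by Monte
#'   Carlo (simulating `mc_reps` independent loci across the replicate
#'   lines and applying the classification predicate) and report a 95%
#'   binomial confidence interval.
#' @param seed Optional seed for the Monte Carlo run.
#' @return An object of class `drift_null`: list with `p0`, `two_n`,
#'   `generations`, `mode`, `delta`, `p_fix_focal`, `p_fix_other`,
#'   `p_segregating`, `p_all_or_none`, and (when requested) `mc_estimate`
#'   and `mc_ci`.
#' @export
p_all_or_none_neutral <- function(p0, ne = 35L, generations = 88L,
                                  n_selected = 4L, n_control = 4L,
                                  mode = c("not_fixed_for_focal",
                                           "strict_polymorphic"),
                                  delta = 0, init = "round",
                                  mc_reps = 0L, seed = NULL) {
  mode <- match.arg(mode)
  if (delta < 0 || delta >= 0.5)
    stop("`delta` must satisfy 0 <= delta < 0.5", call. = FALSE)
  two_n <- 2L * as.integer(ne)
  pr <- wf_line_probs(p0, two_n, generations, s = 0, delta = delta,
                      init = init)
  p_aon <- aon_pattern_prob(pr$p_fix_focal, pr$p_fix_other,
                            n_selected, n_control, mode)
  res <- list(p0 = p0, two_n = two_n, generations = as.integer(generations),
              n_selected = as.integer(n_selected),
              n_control = as.integer(n_control),
              mode = mode, delta = delta,
              p_fix_focal = pr$p_fix_focal,
              p_fix_other = pr$p_fix_other,
              p_segregating = pr$p_segregating,
              p_all_or_none = p_aon)
  if (mc_reps > 0L) {
    if (!is.null(seed)) set.seed(seed)
    hits <- mc_aon_hits(p0, two_n, generations, n_selected, n_control,
                        mode, delta, mc_reps)
    est <- mean(hits)
    se <- sqrt(est * (1 - est) / mc_reps)
    res$mc_estimate <- est
    res$mc_reps <- as.integer(mc_reps)
    res$mc_ci <- c(max(0, est - 1.96 * se), min(1, est + 1.96 * se))
  }
  structure(res, class = "drift_null")
}

# inclusion-exclusion over (fixed group, fixed allele) configurations
aon_pattern_prob <- function(a, b, n, m, mode) {
  if (mode == "not_fixed_for_focal") {
    fail_a <- 1 - a
    fail_b <- 1 - b
    p <- a^n * fail_a^m + b^n * fail_b^m +
         a^m * fail_a^n + b^m * fail_b^n -
         a^n * b^m - a^m * b^n
  } else {
    s <- max(0, 1 - a - b)
    p <- (a^n + b^n) * s^m + (a^m + b^m) * s^n
  }
  min(1, max(0, p))
}

# Monte-Carlo all-or-none indicator per replicate locus (vectorised)
mc_aon_hits <- function(p0, two_n, generations, n_sel, n_ctrl, mode, delta,
                        reps) {
  n_lines <- n_sel + n_ctrl
  finals <- wf_simulate_final(rep(p0, reps * n_lines), two_n, generations)
  F <- matrix(finals, nrow = reps, ncol = n_lines)
  sel <- F[, seq_len(n_sel), drop = FALSE]
  ctrl <- F[, n_sel + seq_len(n_ctrl), drop = FALSE]
  aon_indicator(sel, ctrl, mode, delta)
}

# vectorised all-or-none predicate over rows of two frequency matrices
aon_indicator <- function(sel, ctrl, mode, delta) {
  fixF <- function(M) rowSums(M >= 1 - delta) == ncol(M)
  fixO <- function(M) rowSums(M <= delta) == ncol(M)
  if (mode == "not_fixed_for_focal") {
    failF <- function(M) rowSums(M < 1 - delta) == ncol(M)
    failO <- function(M) rowSums(M > delta) == ncol(M)
  } else {
    failF <- failO <- function(M)
      rowSums(M > delta & M < 1 - delta) == ncol(M)
  }
  (fixF(sel) & failF(ctrl)) | (fixO(sel) & failO(ctrl)) |
    (fixF(ctrl) & failF(sel)) | (fixO(ctrl) & failO(sel))
}

#' @export
print.drift_null <- function(x, ...) {
  cat(sprintf(
    "Neutral drift null (2N = %d, %d generations, p0 = %g, mode = %s)\n",
    x$two_n, x$generations, x$p0, x$mode))
  cat(sprintf("  per line: P(fix focal) = %.4g, P(fix other) = %.4g, P(segregating) = %.4g\n",
              x$p_fix_focal, x$p_fix_other, x$p_segregating))
  cat(sprintf("  P(all-or-none pattern | %d + %d lines) = %.4g\n",
              x$n_selected, x$n_control, x$p_all_or_none))
  if (!is.null(x$mc_estimate))
    cat(sprintf("  Monte Carlo (%d reps): %.4g [%.4g, %.4g]\n",
                x$mc_reps, x$mc_estimate, x$mc_ci[1], x$mc_ci[2]))
  invisible(x)
}

#' Expected all-or-none count over a panel under neutrality
#'
#' Sums the exact per-locus pattern probabilities over the panel's initial
#' frequencies, and attaches a simulation-based 95% interval for the
#' realized count under neutral drift (each locus's all-or-none indicator
#' is an independent Bernoulli draw with its exact probability; loci are
#' unlinked, so this is distributionally identical to re-simulating
#' trajectories and classifying them).
#'
#' @param panel_p0s Numeric vector of per-locus initial frequencies.
#' @param ne,generations,n_selected,n_control,mode,delta,init As in
#'   [p_all_or_none_neutral()].
#' @param ci_reps Number of simulated panels for the interval (default
#'   2000; 0 disables).
#' @param seed Optional seed.
#' @return List with `expected` (sum of per-locus probabilities),
#'   `per_locus_p`, and `ci` (named numeric `lower`/`upper` 95% count
#'   interval, `NULL` when `ci_reps = 0` or the panel is empty).
#' @export
expected_all_or_none_count <- function(panel_p0s, ne = 35L,
                                       generations = 88L,
                                       n_selected = 4L, n_control = 4L,
                                       mode = c("not_fixed_for_focal",
                                                "strict_polymorphic"),
                                       delta = 0, init = "round",
                                       ci_reps = 2000L, seed = NULL) {
  mode <- match.arg(mode)
  if (!length(panel_p0s))
    return(list(expected = 0, per_locus_p = numeric(0), ci = NULL))
  two_n <- 2L * as.integer(ne)
  # exact per-locus probabilities, computed once per distinct p0
  upo <- unique(panel_p0s)
  pmap <- vapply(upo, function(p0)
    p_all_or_none_neutral(p0, ne, generations, n_selected, n_control,
                          mode, delta, init)$p_all_or_none, numeric(1))
  per_locus <- pmap[match(panel_p0s, upo)]
  expected <- sum(per_locus)
  ci <- NULL
  if (ci_reps > 0L) {
    if (!is.null(seed)) set.seed(seed)
    # Poisson-binomial sample: sum of independent Bernoulli(per_locus)
    U <- matrix(stats::runif(ci_reps * length(per_locus)), nrow = ci_reps)
    counts <- rowSums(U < matrix(per_locus, nrow = ci_reps,
                                 ncol = length(per_locus), byrow = TRUE))
    ci <- stats::quantile(counts, c(0.025, 0.975), names = FALSE)
    names(ci) <- c("lower", "upper")
  }
  list(expected = expected, per_locus_p = per_locus, ci = ci)
}
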