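# Independent brute-force oracles. These re-derive each result from the
# literal definitions, deliberately taking a different computational path
# than the package implementation.

# literal all-or-none definition applied to one locus: enumerate per-line
# fixation states, then check the four (group, allele) configurations
oracle_aon <- function(sel, ctrl, mode = "not_fixed_for_focal", delta = 0) {
  state <- function(f) {
    ifelse(f >= 1 - delta, "F", ifelse(f <= delta, "O", "S"))
  }
  ss <- state(sel); cs <- state(ctrl)
  ok_fail <- function(states, allele) {
    if (mode == "not_fixed_for_focal") {
      # fails fixation for `allele` iff its state is not the allele's fixed state
      target <- if (allele == "focal") "F" else "O"
      !any(states == target)
    } else {
      all(states == "S")
    }
  }
  hit <- FALSE
  for (cfg in list(list(ss, cs, "selected"), list(cs, ss, "control"))) {
    for (allele in c("focal", "other")) {
      target <- if (allele == "focal") "F" else "O"
      if (all(cfg[[1]] == target) && ok_fail(cfg[[2]], allele)) hit <- TRUE
    }
  }
  hit
}

# connected components of the "within max_gap on the same chromosome"
# graph, via boolean matrix transitive closure
oracle_cluster_groups <- function(chrom, pos, max_gap) {
  n <- length(pos)
  adj <- outer(seq_len(n), seq_len(n), function(i, j)
    chrom[i] == chrom[j] & abs(pos[i] - pos[j]) <= max_gap)
  reach <- adj | diag(TRUE, n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[reach[i, ]] <- cid
    }
  }
  comp
}

# all-pairs interval intersection count of DE genes per cluster interval
oracle_overlap_counts <- function(cl_tab, de_ids, genes) {
  vapply(seq_len(nrow(cl_tab)), function(i) {
    hits <- 0L
    for (g in de_ids) {
      j <- which(genes$gene_id == g)
      if (length(j) == 1L &&
          genes$chrom[j] == cl_tab$chrom[i] &&
          genes$start[j] <= cl_tab$end[i] &&
          genes$end[j] >= cl_tab$start[i]) hits <- hits + 1L
    }
    hits
  }, integer(1))
}

# exhaustive label-permutation p-value: proportion of all size-k subsets
# whose statistic is >= the observed one (the observed subset included)
oracle_exhaustive_p <- function(ids, k, stat_fun, observed) {
  subsets <- utils::combn(ids, k, simplify = FALSE)
  stats <- vapply(subsets, stat_fun, numeric(1))
  mean(stats >= observed)
}
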