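test_that("fixation predicate follows the tolerance convention", {
  expect_equal(is_fixed(1.0, 0), "fixed_focal")
  expect_equal(is_fixed(0.0, 0), "fixed_other")
  expect_equal(is_fixed(0.96, 0.05), "fixed_focal")
  expect_equal(is_fixed(0.96, 0), "segregating")
  expect_equal(is_fixed(0.04, 0.05), "fixed_other")
  expect_error(is_fixed(0.5, 0.5), "delta")
  expect_error(is_fixed(1.2), "\\[0, 1\\]")
})

test_that("single-locus classification covers both modes and directions", {
  d <- design44()
  mk <- function(sel, ctrl) {
    f <- matrix(c(sel, ctrl), nrow = 1)
    as.list(make_panel(f)[1, ])
  }
  # selected fixed focal, one control line fixed-opposite: mode-dependent
  snp <- mk(c(1, 1, 1, 1), c(0.2, 0.0, 0.5, 0.9))
  r1 <- classify_all_or_none(snp, d, mode = "not_fixed_for_focal")
  expect_true(r1$is_all_or_none)
  expect_equal(r1$fixed_linetype, "selected")
  expect_equal(r1$fixed_allele, "focal")
  expect_equal(r1$fixed_base, "A")
  r2 <- classify_all_or_none(snp, d, mode = "strict_polymorphic")
  expect_false(r2$is_all_or_none)

  # one selected line segregating disqualifies
  r3 <- classify_all_or_none(mk(c(1, 1, 1, 0.9), c(0.2, 0.3, 0.4, 0.5)), d)
  expect_false(r3$is_all_or_none)
  expect_equal(r3$fixed_linetype, "none")
  expect_equal(r3$fixed_allele, "none")

  # control-fixed direction, other allele
  r4 <- classify_all_or_none(mk(c(0.3, 0.6, 0.2, 0.8), c(0, 0, 0, 0)), d)
  expect_true(r4$is_all_or_none)
  expect_equal(r4$fixed_linetype, "control")
  expect_equal(r4$fixed_allele, "other")
  expect_equal(r4$fixed_base, "G")

  # tolerance re-admits near-fixed lines
  r5 <- classify_all_or_none(mk(c(1, 1, 1, 0.96), c(0.2, 0.3, 0.4, 0.5)), d,
                             delta = 0.05)
  expect_true(r5$is_all_or_none)
})

test_that("a published-table-style record classifies as selected-fixed", {
  # rs29503987: HR lines fixed for C, control allele A
  d <- design44()
  snp <- list(snp_id = "rs29503987", focal_allele = "C", other_allele = "A",
              HR1 = 1, HR2 = 1, HR3 = 1, HR4 = 1,
              C1 = 0.4, C2 = 0.1, C3 = 0.7, C4 = 0.55)
  r <- classify_all_or_none(snp, d)
  expect_true(r$is_all_or_none)
  expect_equal(r$fixed_linetype, "selected")
  expect_equal(r$fixed_base, "C")
})

test_that("panel classification preserves order and reports counts", {
  empty <- make_panel(matrix(numeric(0), nrow = 0, ncol = 8))
  ce <- classify_panel(empty)
  expect_equal(nrow(ce), 0L)
  expect_equal(sum(attr(ce, "counts")), 0L)

  # all 8 lines fixed for the same allele at every locus -> zero all-or-none
  allfix <- make_panel(matrix(1, nrow = 5, ncol = 8))
  expect_equal(sum(classify_panel(allfix)$is_all_or_none), 0L)

  p <- random_panel(40, seed = 11)
  cl <- classify_panel(p)
  expect_equal(cl$snp_id, p$snp_id)   # input order preserved
  expect_true(all(cl$fixed_linetype[!cl$is_all_or_none] == "none"))
  expect_true(all(cl$fixed_allele[cl$is_all_or_none] != "none"))
})

test_that("classifier matches the brute-force definition on random panels", {
  d <- design44()
  for (seed in c(1, 2, 3)) {
    p <- random_panel(200, seed = seed)
    f <- panel_freqs(p)
    sel <- f[, selected_lines(d), drop = FALSE]
    ctrl <- f[, control_lines(d), drop = FALSE]
    for (mode in c("not_fixed_for_focal", "strict_polymorphic")) {
      cl <- classify_panel(p, mode = mode)
      oracle <- vapply(seq_len(nrow(p)), function(i)
        oracle_aon(sel[i, ], ctrl[i, ], mode = mode), logical(1))
      expect_equal(cl$is_all_or_none, oracle)
    }
  }
})

test_that("allele relabeling flips the fixed allele but not the call", {
  d <- design44()
  set.seed(42)
  for (rep in 1:40) {
    grid <- c(0, 1, 0.2, 0.5, 0.8)
    sel <- sample(grid, 4, replace = TRUE)
    ctrl <- sample(grid, 4, replace = TRUE)
    for (mode in c("not_fixed_for_focal", "strict_polymorphic")) {
      a <- classify_freqs(sel, ctrl, mode = mode)
      b <- classify_freqs(1 - sel, 1 - ctrl, mode = mode)
      expect_equal(a$is_aon, b$is_aon)
      if (a$is_aon) {
        expect_equal(a$fixed_linetype, b$fixed_linetype)
        expect_equal(b$fixed_allele,
                     c(focal = "other", other = "focal")[[a$fixed_allele]])
      }
    }
  }
})

test_that("swapping group labels flips the fixed linetype", {
  set.seed(43)
  for (rep in 1:40) {
    grid <- c(0, 1, 0.2, 0.5, 0.8)
    sel <- sample(grid, 4, replace = TRUE)
    ctrl <- sample(grid, 4, replace = TRUE)
    # strict mode: the both-groups-fixed-for-opposite-alleles configuration
    # cannot qualify, so the direction is unambiguous
    a <- classify_freqs(sel, ctrl, mode = "strict_polymorphic")
    b <- classify_freqs(ctrl, sel, mode = "strict_polymorphic")
    expect_equal(a$is_aon, b$is_aon)
    if (a$is_aon)
      expect_equal(b$fixed_linetype,
                   c(selected = "control", control = "selected")[[a$fixed_linetype]])
  }
  # under the default mode the call itself is still swap-invariant
  set.seed(44)
  for (rep in 1:40) {
    sel <- sample(c(0, 1, 0.5), 4, replace = TRUE)
    ctrl <- sample(c(0, 1, 0.5), 4, replace = TRUE)
    expect_equal(classify_freqs(sel, ctrl)$is_aon,
                 classify_freqs(ctrl, sel)$is_aon)
  }
})

test_that("widening the fixation tolerance only adds all-or-none calls", {
  # monotonicity on the fixation side: delta = 0 calls survive any larger
  # delta applied to the fixation criterion only
  fixed_side_aon <- function(sel, ctrl, delta) {
    fix <- function(f) all(f >= 1 - delta) || all(f <= delta)
    not_fixed0 <- function(f, hi) if (hi) all(f < 1) else all(f > 0)
    (all(sel >= 1 - delta) && not_fixed0(ctrl, TRUE)) ||
      (all(sel <= delta) && not_fixed0(ctrl, FALSE)) ||
      (all(ctrl >= 1 - delta) && not_fixed0(sel, TRUE)) ||
      (all(ctrl <= delta) && not_fixed0(sel, FALSE))
  }
  set.seed(7)
  hits <- 0L
  for (rep in 1:1000) {
    sel <- sample(c(0, 0, 1, 1, 0.02, 0.5, 0.98), 4, replace = TRUE)
    ctrl <- sample(c(0, 0, 1, 1, 0.02, 0.5, 0.98), 4, replace = TRUE)
    if (classify_freqs(sel, ctrl, delta = 0)$is_aon) {
      hits <- hits + 1L
      expect_true(fixed_side_aon(sel, ctrl, 0.05))
    }
  }
  expect_gt(hits, 0)
})
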