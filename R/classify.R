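#' Fixation status of a single allele frequency
#'
#' A line is "fixed" for the focal allele when its frequency is at least
#' `1 - delta`, and fixed for the other allele when at most `delta`; anything
#' in between is segregating. The default `delta = 0` is exact fixation;
#' a small positive tolerance accommodates sample-based frequency estimates.
#'
#' @param freq Numeric vector of focal-allele frequencies in `[0, 1]`.
#' @param delta Fixation tolerance, `0 <= delta < 0.5`.
#' @return Character vector: `"fixed_focal"`, `"fixed_other"` or
#'   `"segregating"`.
#' @examples
#' is_fixed(c(1, 0, 0.96), delta = 0)     # fixed_focal, fixed_other, segregating
#' is_fixed(0.96, delta = 0.05)           # fixed_focal
#' @export
is_fixed <- function(freq, delta = 0) {
  if (delta < 0 || delta >= 0.5)
    stop("`delta` must satisfy 0 <= delta < 0.5", call. = FALSE)
  if (any(is.na(freq)) || any(freq < 0) || any(freq > 1))
    stop("frequencies must be in [0, 1]", call. = FALSE)
  out <- rep("segregating", length(freq))
  out[freq >= 1 - delta] <- "fixed_focal"
  out[freq <= delta] <- "fixed_other"
  out
}

# Core predicate on the two frequency vectors of one locus.
# Returns list(is_aon, fixed_linetype, fixed_allele); direction precedence
# when both directions hold (one group fixed focal, the other fixed other,
# possible only under mode "not_fixed_for_focal") is selected-focal,
# selected-other, control-focal, control-other.
classify_freqs <- function(sel, ctrl,
                           mode = c("not_fixed_for_focal",
                                    "strict_polymorphic"),
                           delta = 0) {
  mode <- match.arg(mode)
  if (delta < 0 || delta >= 0.5)
    stop("`delta` must satisfy 0 <= delta < 0.5", call. = FALSE)
  fixed_for <- function(f, allele) {
    if (allele == "focal") all(f >= 1 - delta) else all(f <= delta)
  }
  fails_for <- function(f, allele) {
    # every line must fail the fixation criterion for `allele`
    if (mode == "not_fixed_for_focal") {
      if (allele == "focal") all(f < 1 - delta) else all(f > delta)
    } else {
      all(f > delta & f < 1 - delta)
    }
  }
  for (linetype in c("selected", "control")) {
    fx <- if (linetype == "selected") sel else ctrl
    other <- if (linetype == "selected") ctrl else sel
    for (allele in c("focal", "other")) {
      if (fixed_for(fx, allele) && fails_for(other, allele)) {
        return(list(is_aon = TRUE, fixed_linetype = linetype,
                    fixed_allele = allele))
      }
    }
  }
  list(is_aon = FALSE, fixed_linetype = "none", fixed_allele = "none")
}

#' Classify one SNP as all-or-none
#'
#' A SNP is *all-or-none* when it is fixed for the same allele in every
#' replicate line of one group (selected or control) while every replicate
#' line of the other group fails the fixation criterion for that allele —
#' in either direction. Two readings of "not fixed" are supported:
#'
#' * `not_fixed_for_focal` (default): a line of the other group fails when
#'   its frequency of the group-fixed allele is below `1 - delta`. Lines
#'   fixed for the *opposite* allele still count as "not fixed".
#' * `strict_polymorphic`: a line fails only when it is segregating
#'   (strictly between `delta` and `1 - delta`); lines fixed for the
#'   opposite allele disqualify the SNP.
#'
#' @param snp A single-row [snp_panel()] slice, or a list with fields
#'   `snp_id`, `focal_allele`, `other_allele` and one frequency per line.
#' @param design A [line_design()].
#' @param mode `"not_fixed_for_focal"` or `"strict_polymorphic"`.
#' @param delta Fixation tolerance (see [is_fixed()]).
#' @return A list with `snp_id`, `is_all_or_none`, `fixed_linetype`
#'   (`"selected"`, `"control"` or `"none"`), `fixed_allele` (`"focal"`,
#'   `"other"` or `"none"`), and `fixed_base` (the nucleotide, or `NA`).
#' @export
classify_all_or_none <- function(snp, design,
                                 mode = c("not_fixed_for_focal",
                                          "strict_polymorphic"),
                                 delta = 0) {
  mode <- match.arg(mode)
  stopifnot_line_design(design)
  get_freq <- function(ids) {
    f <- vapply(ids, function(id) {
      v <- snp[[id]]
      if (is.null(v) || length(v) != 1L || is.na(v))
        stop("missing frequency for line ", id, " at SNP ", snp[["snp_id"]],
             call. = FALSE)
      as.numeric(v)
    }, numeric(1))
    if (any(f < 0) || any(f > 1))
      stop("frequency outside [0, 1] at SNP ", snp[["snp_id"]], call. = FALSE)
    f
  }
  sel <- get_freq(selected_lines(design))
  ctrl <- get_freq(control_lines(design))
  res <- classify_freqs(sel, ctrl, mode = mode, delta = delta)
  base <- NA_character_
  if (res$is_aon) {
    base <- if (res$fixed_allele == "focal") snp[["focal_allele"]]
            else snp[["other_allele"]]
  }
  list(snp_id = snp[["snp_id"]],
       is_all_or_none = res$is_aon,
       fixed_linetype = res$fixed_linetype,
       fixed_allele = res$fixed_allele,
       fixed_base = base)
}

#' Classify every SNP of a panel
#'
#' Applies [classify_all_or_none()] to each record, preserving input order,
#' and attaches summary counts by `(fixed_linetype, fixed_allele)`.
#'
#' @param panel A [snp_panel()].
#' @inheritParams classify_all_or_none
#' @return An object of class `classified_panel`: a data.frame with columns
#'   `snp_id`, `chrom`, `pos`, `is_all_or_none`, `fixed_linetype`,
#'   `fixed_allele`, `fixed_base`; summary counts in `attr(, "counts")`, the
#'   classification parameters in `attr(, "params")`.
#' @export
classify_panel <- function(panel,
                           mode = c("not_fixed_for_focal",
                                    "strict_polymorphic"),
                           delta = 0) {
  mode <- match.arg(mode)
  design <- panel_design(panel)
  n <- nrow(panel)
  sel_m <- panel_freqs(panel)[, selected_lines(design), drop = FALSE]
  ctrl_m <- panel_freqs(panel)[, control_lines(design), drop = FALSE]
  out <- data.frame(
    snp_id = panel$snp_id, chrom = panel$chrom, pos = panel$pos,
    is_all_or_none = logical(n),
    fixed_linetype = character(n),
    fixed_allele = character(n),
    fixed_base = rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    r <- classify_freqs(sel_m[i, ], ctrl_m[i, ], mode = mode, delta = delta)
    out$is_all_or_none[i] <- r$is_aon
    out$fixed_linetype[i] <- r$fixed_linetype
    out$fixed_allele[i] <- r$fixed_allele
    if (r$is_aon)
      out$fixed_base[i] <- if (r$fixed_allele == "focal")
        panel$focal_allele[i] else panel$other_allele[i]
  }
  counts <- table(fixed_linetype = out$fixed_linetype,
                  fixed_allele = out$fixed_allele)
  structure(out,
            counts = counts,
            params = list(mode = mode, delta = delta),
            class = c("classified_panel", "data.frame"))
}

#' @export
print.classified_panel <- function(x, ...) {
  p <- attr(x, "params")
  n_aon <- sum(x$is_all_or_none)
  cat(sprintf("Classified panel: %d loci, %d all-or-none (mode=%s, delta=%g)\n",
              nrow(x), n_aon, p$mode, p$delta))
  if (n_aon > 0) {
    cat("  by direction:\n")
    tab <- table(x$fixed_linetype[x$is_all_or_none])
    for (nm in names(tab))
      cat(sprintf("    fixed in %s lines: %d\n", nm, tab[[nm]]))
  }
  invisible(x)
}

#' All-or-none loci of a classified panel
#' @param classified A `classified_panel` from [classify_panel()].
#' @return The subset data.frame of all-or-none loci (columns `snp_id`,
#'   `chrom`, `pos`, direction fields), ordinary data.frame.
#' @export
aon_loci <- function(classified) {
  df <- as.data.frame(classified)[classified$is_all_or_none, , drop = FALSE]
  rownames(df) <- NULL
  df
}
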