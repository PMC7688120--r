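#' SNP allele-frequency panel
#'
#' A panel holds, for every SNP, the frequency of its focal allele in each
#' replicate line of a [line_design()]. Records are kept sorted by
#' `(chrom, pos)` and SNP ids are unique. Positions are 1-based.
#'
#' @param snp_id Character vector of unique SNP identifiers.
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 1-based positions.
#' @param focal_allele,other_allele Single-character nucleotides per SNP;
#'   must differ within a SNP.
#' @param freqs Numeric matrix (or data.frame) of focal-allele frequencies,
#'   one column per line of `design` (column names = line ids), values in
#'   `[0, 1]`.
#' @param design A [line_design()].
#'
#' @return An object of class `snp_panel`: a data.frame with columns
#'   `snp_id`, `chrom`, `pos`, `focal_allele`, `other_allele` and one
#'   frequency column per line, sorted by `(chrom, pos)`, with the design in
#'   `attr(, "design")`.
#' @export
snp_panel <- function(snp_id, chrom, pos, focal_allele, other_allele,
                      freqs, design) {
  stopifnot_line_design(design)
  freqs <- as.matrix(freqs)
  n <- length(snp_id)
  if (!all(lengths(list(chrom, pos, focal_allele, other_allele)) == n) ||
      nrow(freqs) != n)
    stop("panel fields must have one entry per SNP", call. = FALSE)
  df <- data.frame(
    snp_id = as.character(snp_id),
    chrom = as.character(chrom),
    pos = as.integer(pos),
    focal_allele = as.character(focal_allele),
    other_allele = as.character(other_allele),
    stringsAsFactors = FALSE
  )
  want <- design$lines$line_id
  if (is.null(colnames(freqs))) colnames(freqs) <- want
  missing <- setdiff(want, colnames(freqs))
  if (length(missing))
    stop("design mismatch: no frequency column for line(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  extra <- setdiff(colnames(freqs), want)
  if (length(extra))
    stop("design mismatch: unknown line_id column(s) ",
         paste(extra, collapse = ", "), call. = FALSE)
  df <- cbind(df, as.data.frame(freqs)[, want, drop = FALSE])
  validate_snp_panel_df(df, design)
  df <- df[order(df$chrom, df$pos, df$snp_id), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, design = design, class = c("snp_panel", "data.frame"))
}

validate_snp_panel_df <- function(df, design) {
  if (anyDuplicated(df$snp_id))
    stop("duplicate snp_id in panel", call. = FALSE)
  if (any(is.na(df$pos)) || any(df$pos < 1L))
    stop("SNP positions must be integers >= 1", call. = FALSE)
  same <- df$focal_allele == df$other_allele
  if (any(same))
    stop("focal and other allele identical for SNP ",
         df$snp_id[which(same)[1]], call. = FALSE)
  for (id in design$lines$line_id) {
    f <- df[[id]]
    bad <- is.na(f) | f < 0 | f > 1
    if (any(bad))
      stop(sprintf("frequency outside [0, 1] for SNP %s in line %s",
                   df$snp_id[which(bad)[1]], id), call. = FALSE)
  }
  invisible(df)
}

#' @export
print.snp_panel <- function(x, ...) {
  d <- panel_design(x)
  cat(sprintf("SNP panel: %d loci x %d lines (%d selected, %d control)\n",
              nrow(x), nrow(d$lines),
              length(selected_lines(d)), length(control_lines(d))))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("... and", nrow(x) - 6L, "more loci\n")
  invisible(x)
}

#' Design attached to a panel
#' @param panel A [snp_panel()].
#' @return The [line_design()] stored in the panel.
#' @export
panel_design <- function(panel) {
  d <- attr(panel, "design")
  stopifnot_line_design(d)
  d
}

#' Frequency matrix of a panel
#' @param panel A [snp_panel()].
#' @return Numeric matrix, loci x lines, of focal-allele frequencies.
#' @export
panel_freqs <- function(panel) {
  d <- panel_design(panel)
  m <- as.matrix(as.data.frame(panel)[, d$lines$line_id, drop = FALSE])
  rownames(m) <- panel$snp_id
  m
}
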