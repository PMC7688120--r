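#' Replicate-line study design
#'
#' Describes the replicated selection experiment: which replicate lines belong
#' to the selected group and which to the unselected control group, together
#' with the population-genetic parameters that govern drift within each line.
#'
#' @param line_ids Character vector of line identifiers (unique).
#' @param linetypes Character vector, same length, each `"selected"` or
#'   `"control"`.
#' @param ne Effective population size per line (integer, >= 1). The default
#'   of 35 reflects a within-family selection regimen that minimises
#'   inbreeding in lines of 10 breeding pairs.
#' @param generations Number of discrete generations of breeding (>= 0).
#'
#' @return An object of class `line_design`: a list with elements `lines`
#'   (data.frame with columns `line_id`, `linetype`), `ne`, `generations`.
#'
#' @examples
#' d <- line_design(c("HR1","HR2","HR3","HR4","C1","C2","C3","C4"),
#'                  rep(c("selected","control"), each = 4))
#' d
#' @export
line_design <- function(line_ids,
                        linetypes,
                        ne = 35L,
                        generations = 88L) {
  if (length(line_ids) != length(linetypes))
    stop("`line_ids` and `linetypes` must have the same length", call. = FALSE)
  if (anyDuplicated(line_ids))
    stop("duplicate line_id in design", call. = FALSE)
  linetypes <- match.arg(linetypes, c("selected", "control"), several.ok = TRUE)
  if (!all(c("selected", "control") %in% linetypes))
    stop("design needs at least one selected and one control line", call. = FALSE)
  ne <- as.integer(ne)
  generations <- as.integer(generations)
  if (is.na(ne) || ne < 1L) stop("`ne` must be an integer >= 1", call. = FALSE)
  if (is.na(generations) || generations < 0L)
    stop("`generations` must be an integer >= 0", call. = FALSE)
  structure(
    list(
      lines = data.frame(line_id = as.character(line_ids),
                         linetype = linetypes,
                         stringsAsFactors = FALSE),
      ne = ne,
      generations = generations
    ),
    class = "line_design"
  )
}

#' Default 4 + 4 replicate design
#'
#' The canonical design of the breeding experiment: 4 selected ("high runner")
#' lines and 4 control lines, Ne = 35 per line, 88 generations.
#'
#' @inheritParams line_design
#' @return A [line_design()] object with lines `HR1..HR4` and `C1..C4`.
#' @export
default_line_design <- function(ne = 35L, generations = 88L) {
  line_design(c(paste0("HR", 1:4), paste0("C", 1:4)),
              rep(c("selected", "control"), each = 4L),
              ne = ne, generations = generations)
}

#' @export
print.line_design <- function(x, ...) {
  n_sel <- sum(x$lines$linetype == "selected")
  n_ctl <- sum(x$lines$linetype == "control")
  cat(sprintf("Replicate-line design: %d selected + %d control lines\n",
              n_sel, n_ctl))
  cat(sprintf("  Ne = %d per line, %d generations\n", x$ne, x$generations))
  cat("  selected:", paste(selected_lines(x), collapse = ", "), "\n")
  cat("  control: ", paste(control_lines(x), collapse = ", "), "\n")
  invisible(x)
}

selected_lines <- function(design) {
  design$lines$line_id[design$lines$linetype == "selected"]
}

control_lines <- function(design) {
  design$lines$line_id[design$lines$linetype == "control"]
}

stopifnot_line_design <- function(design) {
  if (!inherits(design, "line_design"))
    stop("expected a `line_design` object", call. = FALSE)
  invisible(design)
}
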