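#' Round half away from zero
#'
#' Reported percentages use commercial (half-up) rounding rather than the
#' IEEE half-to-even rule of [base::round()], so that e.g. 24.245 reports as
#' 24.25 regardless of binary representation quirks.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` places, halves away from zero.
#' @keywords internal
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The seven exclusive regions of a three-set decomposition
#'
#' Region labels are fixed so that exported tables are machine-comparable:
#' three "only" regions, three pairwise-exclusive regions and the triple
#' intersection of the MG (metagenome), MT (metatranscriptome) and simMG
#' (simulated metagenome) feature sets.
#'
#' @return character vector of the 7 region names, in canonical order.
#' @export
region_names <- function() {
  c("MG_only", "MT_only", "sim_only",
    "MG_MT", "MG_sim", "MT_sim", "MG_MT_sim")
}

#' Supported method labels
#' @return character vector `c("MG", "MT", "simMG")`.
#' @export
method_labels <- function() c("MG", "MT", "simMG")

#' Supported pairwise and three-way comparisons
#' @return character vector of comparison keys.
#' @export
comparison_names <- function() c("simMG:MG", "simMG:MT", "MG:MT", "simMG:MG:MT")

.assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                  integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("'%s' must be in [%s, %s], got %s", name,
                 format(lower), format(upper), format(x)), call. = FALSE)
  if (integer && x != floor(x))
    stop(sprintf("'%s' must be an integer, got %s", name, format(x)),
         call. = FALSE)
  invisible(x)
}
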