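#' Binarize a functional profile into a presence/absence matrix
#'
#' A feature is present in a sample iff its abundance is strictly greater
#' than zero. Features absent everywhere keep their rows (all `FALSE`) and
#' contribute to no region of any decomposition.
#'
#' @param profile a [functional_profile()].
#' @return an object of class `presence_matrix`: a logical feature-by-sample
#'   matrix with attributes `method_label` and `level`.
#' @export
binarize <- function(profile) {
  m <- profile$abundance > 0
  structure(m, method_label = profile$method_label, level = profile$level,
            class = c("presence_matrix", class(m)))
}

.align_presence <- function(mg, mt, sim) {
  mats <- list(MG = unclass(mg), MT = unclass(mt), simMG = unclass(sim))
  samp <- lapply(mats, colnames)
  if (!all(vapply(samp[-1], identical, TRUE, samp[[1]])))
    stop("sample mismatch: the three presence matrices must share the same ",
         "samples in the same order", call. = FALSE)
  features <- sort(unique(unlist(lapply(mats, rownames))))
  lapply(mats, function(m) {
    out <- matrix(FALSE, length(features), ncol(m),
                  dimnames = list(features, colnames(m)))
    out[rownames(m), ] <- m
    out
  })
}

#' Decompose three per-sample feature sets into their 7 exclusive regions
#'
#' For every sample, the features present in the MG, MT and simMG methods are
#' partitioned into the 7 mutually exclusive regions of the three-set
#' diagram (the quantities behind an UpSet plot): three single-method
#' regions, three pairwise-exclusive regions, and the triple intersection.
#' Cross-sample arithmetic means are attached — repertoire comparisons are
#' made on region counts averaged over samples first.
#'
#' @param mg,mt,sim presence matrices (see [binarize()]) with identical
#'   sample ordering; feature universes are aligned on their union.
#' @return an object of class `intersection_decomposition` with `per_sample`
#'   (7 x n count matrix, rows named by [region_names()]) and `averaged`
#'   (named numeric length 7).
#' @export
decompose_sets <- function(mg, mt, sim) {
  mats <- .align_presence(mg, mt, sim)
  # membership code 1..7 = MG + 2*MT + 4*simMG; 0 = absent everywhere
  code <- mats$MG + 2L * mats$MT + 4L * mats$simMG
  per_sample <- apply(code, 2L, function(v) tabulate(v, nbins = 7L))
  if (is.null(dim(per_sample)))
    per_sample <- matrix(per_sample, nrow = 7L,
                         dimnames = list(NULL, colnames(code)))
  # codes: 1 MG_only, 2 MT_only, 3 MG_MT, 4 sim_only, 5 MG_sim, 6 MT_sim, 7 all
  ord <- c(1L, 2L, 4L, 3L, 5L, 6L, 7L)
  per_sample <- per_sample[ord, , drop = FALSE]
  rownames(per_sample) <- region_names()
  structure(list(per_sample = per_sample, averaged = rowMeans(per_sample)),
            class = "intersection_decomposition")
}

#' @export
print.intersection_decomposition <- function(x, ...) {
  cat("<intersection_decomposition>", ncol(x$per_sample), "samples\n")
  print(round(x$averaged, 2))
  invisible(x)
}

.comparison_regions <- function(comparison, universe = c("pair", "all")) {
  universe <- match.arg(universe)
  r <- region_names()
  in_set <- list(
    MG = c("MG_only", "MG_MT", "MG_sim", "MG_MT_sim"),
    MT = c("MT_only", "MG_MT", "MT_sim", "MG_MT_sim"),
    simMG = c("sim_only", "MG_sim", "MT_sim", "MG_MT_sim"))
  if (comparison == "simMG:MG:MT")
    return(list(intersection = "MG_MT_sim",
                remaining = setdiff(r, "MG_MT_sim")))
  pair <- switch(comparison,
                 "simMG:MG" = c("simMG", "MG"),
                 "simMG:MT" = c("simMG", "MT"),
                 "MG:MT" = c("MG", "MT"),
                 stop("unknown comparison '", comparison, "'", call. = FALSE))
  a <- in_set[[pair[1]]]; b <- in_set[[pair[2]]]
  inter <- intersect(a, b)
  remaining <- union(setdiff(a, b), setdiff(b, a))
  if (universe == "all") # also penalize features unique to the third method
    remaining <- union(remaining, setdiff(r, union(a, b)))
  list(intersection = inter, remaining = remaining)
}

#' Percent similarity of shared repertoires
#'
#' The study's similarity statistic on a region decomposition:
#' `2 * I / (2 * I + R) * 100`, where for a pairwise comparison `X:Y` the
#' intersection `I` is the full two-set intersection (the exclusive pair
#' region plus the triple region) and the remainder `R` counts features in
#' exactly one of the pair — identically the Sorensen-Dice coefficient
#' scaled to a percentage. For the three-way comparison `I` is the triple
#' region and `R` the sum of the other six regions.
#'
#' By default `R` is restricted to the pair's two-set universe, so a
#' pairwise value is independent of the third method; set
#' `universe = "all"` to additionally penalize third-method-only features
#' (a documented sensitivity option, not the default reading).
#'
#' @param decomp an [decompose_sets()] result, or a named numeric vector of
#'   the 7 region counts (names as in [region_names()]).
#' @param comparison one of [comparison_names()].
#' @param per_sample compute per-sample similarities and average those,
#'   instead of applying the formula once to the averaged region counts
#'   (default: averaged-counts-first, the study's convention).
#' @param universe `"pair"` (default) or `"all"`; see Details.
#' @return similarity in percent, or `NA` (with a warning) when every
#'   relevant region is empty.
#' @export
percent_similarity <- function(decomp, comparison = comparison_names(),
                               per_sample = FALSE,
                               universe = c("pair", "all")) {
  comparison <- match.arg(comparison)
  universe <- match.arg(universe)
  reg <- .comparison_regions(comparison, universe)
  dice <- function(counts) {
    i <- sum(counts[reg$intersection])
    r <- sum(counts[reg$remaining])
    if (i + r == 0) {
      warning("all region counts are zero: similarity undefined")
      return(NA_real_)
    }
    2 * i / (2 * i + r) * 100
  }
  if (inherits(decomp, "intersection_decomposition")) {
    if (per_sample)
      return(mean(apply(decomp$per_sample, 2L, dice)))
    return(dice(decomp$averaged))
  }
  stopifnot(is.numeric(decomp), all(region_names() %in% names(decomp)))
  dice(decomp)
}

#' Full similarity summary (all four comparisons)
#'
#' @inheritParams percent_similarity
#' @return named numeric vector over [comparison_names()], in percent.
#' @export
similarity_summary <- function(decomp, per_sample = FALSE,
                               universe = c("pair", "all")) {
  universe <- match.arg(universe)
  vapply(comparison_names(), function(cmp)
    percent_similarity(decomp, cmp, per_sample = per_sample,
                       universe = universe),
    numeric(1))
}

#' Change in percent similarity after prokaryote-only filtering
#'
#' Signed difference (prokaryote-only minus total), in percentage points,
#' reported to two decimals — the quantity used to measure how much the
#' non-prokaryotic content of the sequenced data depresses the apparent
#' concordance with the simulated metagenomes.
#'
#' @param total,prok_only named numeric similarity summaries (percent) with
#'   matching comparison names, e.g. from [similarity_summary()].
#' @return named numeric vector of deltas, percentage points, two decimals.
#' @export
similarity_change <- function(total, prok_only) {
  missing <- setdiff(names(total), names(prok_only))
  if (length(missing) || is.null(names(total)))
    stop("comparison(s) missing from prok_only summary: ",
         paste(missing, collapse = ", "), call. = FALSE)
  round_half_up(prok_only[names(total)] - total, 2)
}
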