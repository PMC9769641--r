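#' Per-method sample prevalence of a curated gene set
#'
#' For every feature of a gene set, counts in how many samples it is present
#' in each method — the table behind prevalence heat maps. Features absent
#' from every method keep a zero row so accuracy statements like "x of the N
#' reference genes were recovered" stay well defined.
#'
#' @param presence named list of presence matrices (one per method, same
#'   samples; see [binarize()]).
#' @param set a [gene_set()].
#' @return integer matrix, gene-set features x methods, with attributes
#'   `n_samples` and `classes` (the per-feature class labels); class
#'   `prevalence_table`.
#' @export
prevalence <- function(presence, set) {
  stopifnot(length(presence) >= 1L)
  n <- ncol(presence[[1L]])
  feats <- set$members$feature_id
  if (length(feats) == 0L) {
    warning("empty gene set: empty prevalence table")
    return(structure(matrix(integer(0), 0L, length(presence),
                            dimnames = list(NULL, names(presence))),
                     n_samples = n, classes = character(0),
                     class = c("prevalence_table", "matrix", "array")))
  }
  tab <- sapply(presence, function(m) {
    counts <- integer(length(feats))
    have <- feats %in% rownames(m)
    counts[have] <- rowSums(m[feats[have], , drop = FALSE])
    counts
  })
  tab <- matrix(as.integer(tab), nrow = length(feats),
                dimnames = list(feats, names(presence)))
  structure(tab, n_samples = n,
            classes = stats::setNames(set$members$class, feats),
            class = c("prevalence_table", "matrix", "array"))
}

#' Keep gene-set features present in at least `threshold` samples
#'
#' Implements the "found in five or more samples" rule used for prevalence
#' heat maps: with `scope = "any"` (default) a feature survives iff it
#' reaches the threshold in at least one method; with `scope = "per_method"`
#' the rule is applied within a single named method.
#'
#' @param table a [prevalence()] result.
#' @param threshold integer in `[1, n_samples]` (default 5).
#' @param scope `"any"` or `"per_method"`.
#' @param method method name, required when `scope = "per_method"`.
#' @return the filtered `prevalence_table` subset.
#' @export
majority_filter <- function(table, threshold = 5,
                            scope = c("any", "per_method"), method = NULL) {
  scope <- match.arg(scope)
  n <- attr(table, "n_samples")
  .assert_scalar_number(threshold, "threshold", lower = 1, upper = n,
                        integer = TRUE)
  keep <- if (scope == "any") {
    apply(table, 1L, max) >= threshold
  } else {
    stopifnot(!is.null(method), method %in% colnames(table))
    table[, method] >= threshold
  }
  out <- table[keep, , drop = FALSE]
  structure(out, n_samples = n, classes = attr(table, "classes")[keep],
            class = class(table))
}

#' Percent more features identified by one method than another
#'
#' `(count_a - count_b) / count_b * 100`, reported to two decimals; negative
#' when method A identified fewer features. Distinct from
#' [coverage_fraction()]: this is a relative excess, not a recovery rate.
#'
#' @param count_a nonnegative count for the method of interest.
#' @param count_b positive reference count.
#' @return percent, two decimals.
#' @export
percent_more <- function(count_a, count_b) {
  .assert_scalar_number(count_a, "count_a", lower = 0)
  .assert_scalar_number(count_b, "count_b")
  if (count_b <= 0)
    stop("'count_b' must be positive: percent_more is undefined",
         call. = FALSE)
  round_half_up((count_a - count_b) / count_b * 100, 2)
}

#' Fraction of a reference repertoire that was recovered
#'
#' `n_shared / n_reference * 100`, to two decimals: e.g. the share of the
#' fiber-degrading enzymes found in the metagenomes that the simulated
#' metagenomes also identified.
#'
#' @param n_shared nonnegative count of recovered features
#'   (`<= n_reference`).
#' @param n_reference positive size of the reference repertoire.
#' @return percent in `[0, 100]`, two decimals.
#' @export
coverage_fraction <- function(n_shared, n_reference) {
  .assert_scalar_number(n_shared, "n_shared", lower = 0)
  .assert_scalar_number(n_reference, "n_reference")
  if (n_reference <= 0) stop("'n_reference' must be positive", call. = FALSE)
  if (n_shared > n_reference)
    stop("'n_shared' cannot exceed 'n_reference'", call. = FALSE)
  round_half_up(n_shared / n_reference * 100, 2)
}

#' SCFA pathway presence table and per-product rollup
#'
#' Short-chain fatty acid (acetate, butyrate, lactate, propionate) pathway
#' prevalence across methods. "Present" means the pipeline-reported pathway
#' abundance is greater than zero — completeness scoring is the upstream
#' profiler's concern. The rollup counts, per product and method, how many
#' pathways were seen in at least one sample; a pathway producing several
#' SCFAs counts toward each of its products.
#'
#' @param presence named list of pathway-level presence matrices per method.
#' @param scfa_set a [gene_set()] whose class labels are `;`-separated
#'   fermentation products.
#' @return list with `table` (a [prevalence()] result) and `rollup`
#'   (data frame: product, method, n_pathways_detected).
#' @export
scfa_presence <- function(presence, scfa_set) {
  lv <- unique(unlist(lapply(presence, attr, "level")))
  if (length(lv) && !all(lv == "pathway"))
    stop("scfa_presence expects pathway-level profiles", call. = FALSE)
  tab <- prevalence(presence, scfa_set)
  classes <- strsplit(scfa_set$members$class, ";", fixed = TRUE)
  products <- sort(unique(unlist(classes)))
  rollup <- do.call(rbind, lapply(products, function(pr) {
    rows <- vapply(classes, function(cl) pr %in% cl, TRUE)
    data.frame(product = pr, method = colnames(tab),
               n_pathways_detected =
                 as.integer(colSums(tab[rows, , drop = FALSE] > 0)),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  list(table = tab, rollup = rollup)
}
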