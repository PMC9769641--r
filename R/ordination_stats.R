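#' Jaccard distances between sample presence profiles
#'
#' Classic binary Jaccard dissimilarity, `1 - |A n B| / |A u B|`, between
#' every pair of sample profiles, computed with [vegan::vegdist()]. The
#' usual input is the column-bound presence matrices of all three methods,
#' so each point is one sample under one method and the grouping factor for
#' downstream PERMANOVA is the method label.
#'
#' @param presence either a named list of presence matrices (features x
#'   samples, one per method; feature universes are aligned on their union
#'   and points are labelled `method.sample`), or a single binary matrix
#'   with points in rows and features in columns.
#' @return a `dist` object with attribute `groups` (method per point when a
#'   list was supplied). Pairs of empty profiles get distance 0 with a
#'   warning.
#' @export
jaccard_distances <- function(presence) {
  if (is.list(presence) && !is.data.frame(presence)) {
    features <- sort(unique(unlist(lapply(presence, rownames))))
    rows <- lapply(names(presence), function(mth) {
      m <- matrix(FALSE, length(features), ncol(presence[[mth]]),
                  dimnames = list(features, colnames(presence[[mth]])))
      m[rownames(presence[[mth]]), ] <- unclass(presence[[mth]])
      t(m)
    })
    groups <- rep(names(presence), vapply(rows, nrow, 0L))
    mat <- do.call(rbind, rows)
    rownames(mat) <- paste(groups, rownames(mat), sep = ".")
  } else {
    mat <- as.matrix(presence)
    groups <- NULL
  }
  storage.mode(mat) <- "numeric"
  empty <- rowSums(mat) == 0
  if (any(empty))
    warning("all-absent profile(s) found: pairwise distances between empty ",
            "profiles are set to 0 by convention")
  # vegdist warns about empty rows itself and returns NaN for empty pairs;
  # the convention here (flagged above) is distance 0
  d <- suppressWarnings(vegan::vegdist(mat, method = "jaccard",
                                       binary = TRUE))
  d[is.na(d)] <- 0
  attr(d, "groups") <- groups
  d
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Classical scaling of a distance matrix via the double-centered `-D^2/2`
#' eigendecomposition ([stats::cmdscale()]). Negative eigenvalues — common
#' for Jaccard matrices — are reported as-is, with no Cailliez/Lingoes
#' correction; `proportion_explained` is computed on the positive part of
#' the spectrum. For a Euclidean-embeddable matrix the pairwise distances
#' among the returned coordinates reproduce the input.
#'
#' @param d a `dist` object or symmetric distance matrix.
#' @param n_axes number of axes to return (default: all, `n - 1`).
#' @return list of class `pcoa_result`: `coordinates` (points x axes),
#'   `eigenvalues`, `proportion_explained` (both per retained axis).
#' @export
pcoa_ordination <- function(d, n_axes = NULL) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d), tol = 1e-10))
      stop("distance matrix must be symmetric", call. = FALSE)
    d <- stats::as.dist(d)
  }
  n <- attr(d, "Size")
  k <- min(n_axes %||% (n - 1L), n - 1L)
  fit <- suppressWarnings(stats::cmdscale(d, k = k, eig = TRUE))
  coords <- fit$points
  if (is.null(coords) || ncol(coords) < k) {
    # degenerate case (e.g. all-zero distances): pad with zero axes
    pad <- matrix(0, n, k - (if (is.null(coords)) 0L else ncol(coords)))
    coords <- cbind(coords, pad)
    rownames(coords) <- attr(d, "Labels") %||% seq_len(n)
  }
  eig <- fit$eig
  pos <- pmax(eig, 0)
  prop <- if (sum(pos) > 0) pos / sum(pos) else rep(0, length(eig))
  structure(list(coordinates = coords,
                 eigenvalues = eig[seq_len(k)],
                 proportion_explained = prop[seq_len(k)]),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("<pcoa_result> %d points, %d axes; first axes explain %s\n",
              nrow(x$coordinates), ncol(x$coordinates),
              paste(sprintf("%.1f%%", 100 * utils::head(
                x$proportion_explained, 3)), collapse = ", ")))
  invisible(x)
}

.permanova_f <- function(d2, groups, sst) {
  n <- nrow(d2)
  a <- length(unique(groups))
  ssw <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ssa <- sst - ssw
  f <- (ssa / (a - 1)) / (ssw / (n - a))
  c(f = f, ssa = ssa, ssw = ssw)
}

#' Distance-based one-way PERMANOVA
#'
#' Permutational multivariate analysis of variance computed directly from
#' the distance matrix (no coordinates needed): total and within-group sums
#' of squared interpoint distances give the pseudo-F statistic
#' `F = (SSA / (a - 1)) / (SSW / (N - a))`, and the p-value is estimated by
#' permuting the group labels:
#' `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_permutations)`.
#' `R^2 = SSA / SST` is the fraction of distance-based variance explained by
#' the grouping. A fixed seed makes the p-value reproducible.
#'
#' @param d `dist` object or symmetric distance matrix.
#' @param groups group label per point; at least 2 groups of at least 2
#'   points each.
#' @param n_permutations number of label permutations (default 999).
#' @param seed optional integer seed for the permutation stream.
#' @return list of class `permanova_result`: `pseudo_F`, `r_squared`,
#'   `p_value`, `n_permutations`, `seed`.
#' @export
permanova <- function(d, groups, n_permutations = 999, seed = NULL) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  groups <- as.character(groups)
  stopifnot(length(groups) == n)
  sizes <- table(groups)
  if (length(sizes) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  if (any(sizes < 2L))
    stop("every group needs at least 2 points", call. = FALSE)
  sst <- sum(d2) / (2 * n)
  if (sst <= .Machine$double.eps)
    warning("constant distances: pseudo-F is degenerate")
  obs <- .permanova_f(d2, groups, sst)
  if (!is.null(seed)) set.seed(seed)
  exceed <- 0L
  for (i in seq_len(n_permutations)) {
    fp <- .permanova_f(d2, groups[sample.int(n)], sst)["f"]
    if (!is.na(fp) && fp >= obs["f"]) exceed <- exceed + 1L
  }
  structure(list(pseudo_F = unname(obs["f"]),
                 r_squared = unname(obs["ssa"] / sst),
                 p_value = (1 + exceed) / (1 + n_permutations),
                 n_permutations = n_permutations,
                 seed = seed),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "<permanova_result> pseudo-F = %.4f, R2 = %.4f, p = %.4g (%d permutations)\n",
    x$pseudo_F, x$r_squared, x$p_value, x$n_permutations))
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum test on per-sample feature counts
#'
#' Wrapper around [stats::wilcox.test()] following the usage for comparing
#' the number of features identified per sample between methods: exact
#' distribution when both samples have at most 10 observations and no ties,
#' otherwise the normal approximation with tie and continuity corrections.
#'
#' @param x,y numeric vectors (non-empty).
#' @return list with `statistic` (rank-sum W) and `p_value`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  if (length(unique(c(x, y))) == 1L) {
    warning("all values identical across both samples: p = 1")
    return(list(statistic = length(x) * length(y) / 2, p_value = 1))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) <= 10 && length(y) <= 10
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}
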