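test_that("Jaccard distances match hand enumeration", {
  sets <- list(MG = list(S1 = c("f1", "f2"), S2 = c("f2", "f3"),
                         S3 = c("f1", "f2")))
  d <- as.matrix(jaccard_distances(list(MG = presence_from_sets(sets$MG))))
  expect_equal(d["MG.S1", "MG.S2"], 1 - 1 / 3, tolerance = 1e-12)
  expect_equal(d["MG.S1", "MG.S3"], 0)
  disjoint <- list(MG = list(A = "f1", B = "f2"))
  d2 <- as.matrix(jaccard_distances(list(MG = presence_from_sets(disjoint$MG))))
  expect_equal(d2["MG.A", "MG.B"], 1)
})

test_that("Jaccard is a metric on random binary profiles; empty pairs flagged", {
  set.seed(501)
  m <- matrix(runif(300) > 0.5, 20, 15)
  rownames(m) <- sprintf("p%02d", 1:20)
  d <- as.matrix(jaccard_distances(m))
  expect_true(isSymmetric(unname(d)))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
  for (i in 1:60) {
    ijk <- sample(20, 3)
    expect_lte(d[ijk[1], ijk[3]],
               d[ijk[1], ijk[2]] + d[ijk[2], ijk[3]] + 1e-12)
  }
  m[1:2, ] <- FALSE
  expect_warning(d0 <- jaccard_distances(m), "all-absent")
  expect_equal(as.matrix(d0)[1, 2], 0)
})

test_that("PCoA reproduces distances from Euclidean configurations", {
  set.seed(502)
  pts <- matrix(rnorm(12 * 5), 12, 5)
  d <- dist(pts)
  ord <- pcoa_ordination(d)
  expect_lt(max(abs(dist(ord$coordinates) - d)), 1e-8)
  expect_true(all(diff(ord$proportion_explained) <= 1e-12))
  expect_equal(sum(ord$proportion_explained), 1, tolerance = 1e-8)

  # three collinear points, d = (1, 1, 2): a perfect 1-axis embedding
  d3 <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3)
  ord3 <- pcoa_ordination(d3, n_axes = 2)
  expect_lt(max(abs(as.matrix(dist(ord3$coordinates)) - d3)), 1e-8)
  expect_lt(sum(abs(ord3$coordinates[, 2])), 1e-6)

  zero <- matrix(0, 4, 4)
  ordz <- pcoa_ordination(zero)
  expect_true(all(ordz$coordinates == 0))

  asym <- matrix(c(0, 1, 2, 0), 2)
  expect_error(pcoa_ordination(asym), "symmetric")
})

test_that("PCoA recovers known coordinates up to rotation (Procrustes)", {
  skip_if_not_installed("vegan")
  set.seed(503)
  pts <- scale(matrix(rnorm(10 * 3), 10, 3), scale = FALSE)
  ord <- pcoa_ordination(dist(pts), n_axes = 3)
  proc <- vegan::procrustes(pts, ord$coordinates, symmetric = FALSE)
  expect_lt(max(abs(stats::residuals(proc))), 1e-6)
})

test_that("PERMANOVA agrees with the adonis2 oracle and honours its contract", {
  set.seed(504)
  pts <- rbind(matrix(rnorm(12, 0), 6, 2), matrix(rnorm(12, 3), 6, 2))
  d <- dist(pts)
  groups <- rep(c("a", "b"), each = 6)
  res <- permanova(d, groups, n_permutations = 999, seed = 99)
  df <- data.frame(groups = groups)
  or <- vegan::adonis2(d ~ groups, data = df, permutations = 499)
  expect_equal(res$pseudo_F, or$F[1], tolerance = 1e-10)
  expect_equal(res$r_squared, or$R2[1], tolerance = 1e-10)
  # strong separation: p is tiny (permutations reproducing the partition
  # tie the observed F, so the exact enumeration floor need not be hit)
  expect_lte(res$p_value, 0.01)
  # reproducible under a fixed seed
  res2 <- permanova(d, groups, n_permutations = 999, seed = 99)
  expect_identical(res$p_value, res2$p_value)

  expect_error(permanova(d, rep("a", 12)), "2 groups")
  expect_error(permanova(d, c("a", rep("b", 11))), "at least 2 points")
})

test_that("PERMANOVA R2 and F are invariant to relabeling and scaling", {
  set.seed(505)
  pts <- matrix(rnorm(18 * 2), 18, 2)
  d <- dist(pts)
  groups <- rep(c("x", "y", "z"), each = 6)
  r1 <- permanova(d, groups, n_permutations = 49, seed = 1)
  relabel <- c(x = "q", y = "r", z = "s")[groups]
  r2 <- permanova(d, relabel, n_permutations = 49, seed = 1)
  r3 <- permanova(d * 7.3, groups, n_permutations = 49, seed = 1)
  expect_equal(r1$pseudo_F, r2$pseudo_F)
  expect_equal(r1$pseudo_F, r3$pseudo_F, tolerance = 1e-12)
  expect_equal(r1$r_squared, r3$r_squared, tolerance = 1e-12)
})

test_that("permutation p matches the exhaustive exact p at n = 6", {
  set.seed(506)
  pts <- matrix(rnorm(12), 6, 2)
  d2 <- as.matrix(dist(pts))^2
  groups <- rep(c("a", "b"), each = 3)
  # exhaustive oracle over all C(6,3) = 20 label assignments
  f_stat <- function(g) {
    sst <- sum(d2) / (2 * 6)
    ssw <- 0
    for (gr in unique(g)) {
      idx <- which(g == gr)
      ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
    }
    ((sst - ssw) / 1) / (ssw / 4)
  }
  obs <- f_stat(groups)
  combos <- combn(6, 3)
  fs <- apply(combos, 2, function(idx) {
    g <- rep("b", 6); g[idx] <- "a"; f_stat(g)
  })
  exact_p <- mean(fs >= obs - 1e-12)
  res <- permanova(dist(pts), groups, n_permutations = 999, seed = 7)
  expect_lt(abs(res$p_value - exact_p), 0.02)
})

test_that("Wilcoxon rank-sum: exact enumeration, identity, and shift power", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$p_value, 0.1) # 2/20 assignments as extreme, two-sided
  expect_warning(w2 <- wilcoxon_rank_sum(c(2, 2), c(2, 2)), "identical")
  expect_equal(w2$p_value, 1)
  set.seed(507)
  x <- rnorm(30); y <- rnorm(30, 3)
  expect_lt(wilcoxon_rank_sum(x, y)$p_value, 1e-3)
  # oracle agreement on a tied, large-sample case
  x2 <- c(rep(1, 8), rnorm(12)); y2 <- c(rep(1, 5), rnorm(15, 0.8))
  expect_equal(wilcoxon_rank_sum(x2, y2)$p_value,
               suppressWarnings(stats::wilcox.test(x2, y2)$p.value))
})
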