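test_that("binarize uses strict positivity and keeps all-absent features", {
  m <- matrix(c(0, 1e-12, 0, 3), 2, 2,
              dimnames = list(c("a", "b"), c("S1", "S2")))
  pm <- binarize(make_profile(m))
  expect_identical(unclass(pm)[, "S1"], c(a = FALSE, b = TRUE))
  expect_identical(unclass(pm)[, "S2"], c(a = FALSE, b = TRUE))

  zero <- binarize(make_profile(matrix(0, 2, 1, dimnames = list(c("a", "b"), "S1"))))
  expect_false(any(zero))
  expect_equal(nrow(zero), 2L)
})

test_that("decompose_sets matches hand-enumerated regions", {
  sets <- function(a, b, c)
    lapply(list(MG = a, MT = b, simMG = c), function(s) list(S1 = s))
  s <- sets(c("a", "b", "c"), c("b", "c", "d"), c("c", "d", "e"))
  dc <- decompose_sets(presence_from_sets(s$MG, "MG"),
                       presence_from_sets(s$MT, "MT"),
                       presence_from_sets(s$simMG, "simMG"))
  expect_equal(dc$averaged,
               c(MG_only = 1, MT_only = 0, sim_only = 1, MG_MT = 1,
                 MG_sim = 0, MT_sim = 1, MG_MT_sim = 1))

  ident <- list(S1 = letters[1:5])
  dci <- decompose_sets(presence_from_sets(ident, "MG"),
                        presence_from_sets(ident, "MT"),
                        presence_from_sets(ident, "simMG"))
  expect_equal(unname(dci$averaged), c(0, 0, 0, 0, 0, 0, 5))
})

test_that("decompose_sets equals brute-force enumeration on random triples", {
  set.seed(401)
  universe <- sprintf("K%05d", 1:20)
  for (i in 1:300) {
    a <- sample(universe, min(rpois(1, 6), 20))
    b <- sample(universe, min(rpois(1, 6), 20))
    c_ <- sample(universe, min(rpois(1, 6), 20))
    expected <- brute_force_regions(a, b, c_)
    dc <- decompose_sets(presence_from_sets(list(S1 = a), "MG"),
                         presence_from_sets(list(S1 = b), "MT"),
                         presence_from_sets(list(S1 = c_), "simMG"))
    expect_equal(dc$averaged, expected)
    # region conservation: the 7 counts partition the union
    expect_equal(sum(dc$averaged), length(union(union(a, b), c_)))
  }
})

test_that("decompose_sets refuses mismatched samples and averages over samples", {
  p1 <- presence_from_sets(list(S1 = "a"), "MG")
  p2 <- presence_from_sets(list(S2 = "a"), "MT")
  expect_error(decompose_sets(p1, p2, p1), "sample mismatch")

  two <- list(MG = list(S1 = c("a", "b"), S2 = "a"),
              MT = list(S1 = "b", S2 = character(0)),
              sim = list(S1 = "b", S2 = "a"))
  dc <- decompose_sets(presence_from_sets(two$MG, "MG"),
                       presence_from_sets(two$MT, "MT"),
                       presence_from_sets(two$sim, "simMG"))
  expect_equal(dc$per_sample["MG_only", ], c(S1 = 1, S2 = 0))
  expect_equal(dc$averaged, rowMeans(dc$per_sample))
})

test_that("pairwise percent similarity is the Dice coefficient", {
  counts <- c(MG_only = 1, MT_only = 0, sim_only = 1, MG_MT = 0,
              MG_sim = 3, MT_sim = 0, MG_MT_sim = 0)
  # |A n B| = 3, |A only| = 1, |B only| = 1 -> 2*3/(6+2)*100
  expect_equal(percent_similarity(counts, "simMG:MG"), 75)

  ident <- c(MG_only = 0, MT_only = 0, sim_only = 0, MG_MT = 0,
             MG_sim = 0, MT_sim = 0, MG_MT_sim = 7)
  expect_equal(percent_similarity(ident, "simMG:MG"), 100)
  expect_equal(percent_similarity(ident, "simMG:MG:MT"), 100)

  disjoint <- c(MG_only = 3, MT_only = 0, sim_only = 2, MG_MT = 0,
                MG_sim = 0, MT_sim = 0, MG_MT_sim = 0)
  expect_equal(percent_similarity(disjoint, "simMG:MG"), 0)

  empty <- setNames(rep(0, 7), names(ident))
  expect_warning(v <- percent_similarity(empty, "MG:MT"), "undefined")
  expect_true(is.na(v))
})

test_that("percent similarity matches a raw-set Dice oracle and is symmetric", {
  set.seed(402)
  universe <- sprintf("K%05d", 1:18)
  for (i in 1:200) {
    a <- sample(universe, sample(0:10, 1))
    b <- sample(universe, sample(1:10, 1))
    c_ <- sample(universe, sample(0:10, 1))
    dc <- decompose_sets(presence_from_sets(list(S1 = a), "MG"),
                         presence_from_sets(list(S1 = b), "MT"),
                         presence_from_sets(list(S1 = c_), "simMG"))
    expect_equal(suppressWarnings(percent_similarity(dc, "MG:MT")),
                 brute_force_dice(a, b))
    expect_equal(suppressWarnings(percent_similarity(dc, "simMG:MG")),
                 brute_force_dice(c_, a))
    expect_equal(suppressWarnings(percent_similarity(dc, "simMG:MT")),
                 brute_force_dice(c_, b))
  }
})

test_that("the alternate pairwise universe penalizes third-method features", {
  counts <- c(MG_only = 0, MT_only = 4, sim_only = 0, MG_MT = 0,
              MG_sim = 3, MT_sim = 0, MG_MT_sim = 0)
  expect_equal(percent_similarity(counts, "simMG:MG", universe = "pair"), 100)
  expect_equal(percent_similarity(counts, "simMG:MG", universe = "all"),
               2 * 3 / (2 * 3 + 4) * 100)
})

test_that("similarity_change reproduces published deltas and handles errors", {
  expect_equal(unname(similarity_change(c(`simMG:MG` = 76.21),
                                        c(`simMG:MG` = 81.05))), 4.84)
  expect_equal(unname(similarity_change(c(`MG:MT` = 68.13),
                                        c(`MG:MT` = 67.73))), -0.40)
  x <- c(`simMG:MG` = 50, `MG:MT` = 60)
  expect_equal(unname(similarity_change(x, x)), c(0, 0))
  expect_error(similarity_change(x, c(`simMG:MG` = 50)), "MG:MT")
})

test_that("per-sample-then-average is a distinct, sane averaging order", {
  st <- quiet_study(presence_noise = 0.3, seed = 21)
  m <- lapply(merge_profiles(st$profiles), binarize)
  dc <- decompose_sets(m$MG, m$MT, m$simMG)
  avg_first <- percent_similarity(dc, "simMG:MG")
  per_sample <- percent_similarity(dc, "simMG:MG", per_sample = TRUE)
  expect_true(abs(avg_first - per_sample) < 10)
  expect_false(identical(avg_first, per_sample))
})
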