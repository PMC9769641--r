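test_that("gene-set fixtures carry the curated structure", {
  sets <- generate_geneset_fixtures()

  scfa <- sets$scfa
  expect_equal(nrow(scfa$members), 16L)
  products <- strsplit(scfa$members$class, ";", fixed = TRUE)
  tally <- table(unlist(products))
  expect_equal(tally[["acetate"]], 6L)
  expect_equal(tally[["butyrate"]], 7L)
  expect_equal(tally[["lactate"]], 5L)
  expect_equal(tally[["propionate"]], 3L)
  # total product assignments minus pathways = dual-product pathways
  expect_equal(sum(lengths(products)) - nrow(scfa$members), 5L)
  expect_true(all(c("P161-PWY", "P162-PWY", "P163-PWY", "P124-PWY",
                    "P461-PWY", "PWY-5100", "GLUDEG-II-PWY", "PWY-5677",
                    "PROPFERM-PWY", "ANAEROFRUCAT-PWY") %in%
                    scfa$members$feature_id))

  expect_equal(length(gene_set_classes(sets$amr)), 11L)
  expect_equal(nrow(sets$amr$members), 162L)
  expect_equal(sort(gene_set_classes(sets$cazy)), c("GH5", "GH6", "GH7"))
  expect_equal(nrow(sets$cazy$members), 102L)
})

test_that("prevalence counts samples per method and keeps absent features", {
  sets <- list(MG = list(S1 = c("K98001", "K98002"), S2 = "K98001",
                         S3 = "K98001"),
               MT = list(S1 = character(0), S2 = "K98002", S3 = character(0)),
               simMG = list(S1 = "K98001", S2 = "K98001", S3 = "K98001"))
  presence <- lapply(names(sets), function(m)
    presence_from_sets(sets[[m]], m))
  names(presence) <- names(sets)
  gs <- gene_set("demo", data.frame(feature_id = c("K98001", "K98002",
                                                   "K98003"),
                                    class = "x"))
  tab <- prevalence(presence, gs)
  expect_equal(unname(tab["K98001", ]), c(3L, 0L, 3L))
  expect_equal(unname(tab["K98002", ]), c(1L, 1L, 0L))
  expect_equal(unname(tab["K98003", ]), c(0L, 0L, 0L))
  expect_equal(attr(tab, "n_samples"), 3L)

  expect_warning(empty <- prevalence(presence,
                                     gene_set("none", data.frame(
                                       feature_id = character(0),
                                       class = character(0)))),
                 "empty gene set")
  expect_equal(nrow(empty), 0L)
})

test_that("prevalence recovers planted per-method sample counts", {
  amr <- generate_geneset_fixtures()$amr
  st <- quiet_study(presence_noise = 0, contaminant_count = 0, seed = 31,
                    seed_features = amr$members$feature_id)
  presence <- lapply(merge_profiles(st$profiles), binarize)
  tab <- prevalence(presence, amr)
  n <- st$config$n_samples
  member <- matrix(
    c(1, 0, 0, 1, 1, 0, 1, 0, 1, 0, 1, 0, 1, 1, 0, 0, 1, 0, 1, 1, 1), 7,
    dimnames = list(region_names(), method_labels()))
  planted <- st$truth[match(rownames(tab), st$truth$feature_id), "region"]
  for (m in method_labels()) {
    expected <- ifelse(is.na(planted), 0L, member[planted, m] * n)
    expect_equal(unname(tab[, m]), unname(expected))
  }
})

test_that("majority_filter applies the at-least-threshold rule", {
  tab <- structure(matrix(c(5L, 4L, 0L, 4L, 0L, 4L), 2,
                          dimnames = list(c("f1", "f2"),
                                          c("MG", "MT", "simMG"))),
                   n_samples = 9L, classes = c(f1 = "x", f2 = "x"),
                   class = c("prevalence_table", "matrix", "array"))
  kept <- majority_filter(tab, threshold = 5)
  expect_equal(rownames(kept), "f1") # boundary: "five or more"
  expect_equal(nrow(majority_filter(tab, threshold = 4)), 2L)
  expect_equal(rownames(majority_filter(tab, threshold = 4,
                                        scope = "per_method",
                                        method = "MT")), "f2")
  expect_error(majority_filter(tab, threshold = 10), "threshold")
})

test_that("majority_filter extremes: threshold 1 and threshold n", {
  amr <- generate_geneset_fixtures()$amr
  st <- quiet_study(presence_noise = 0.4, contaminant_count = 0, seed = 32,
                    seed_features = amr$members$feature_id)
  presence <- lapply(merge_profiles(st$profiles), binarize)
  tab <- prevalence(presence, amr)
  anywhere <- majority_filter(tab, threshold = 1)
  expect_setequal(rownames(anywhere),
                  rownames(tab)[apply(tab, 1, max) >= 1])
  everywhere <- majority_filter(tab, threshold = attr(tab, "n_samples"))
  expect_true(all(apply(everywhere, 1, max) == attr(tab, "n_samples")))
})

test_that("percent_more and coverage_fraction reproduce printed arithmetic", {
  expect_equal(percent_more(82, 66), 24.24)
  expect_equal(percent_more(82, 20), 310)
  expect_equal(percent_more(5, 5), 0)
  expect_equal(percent_more(10, 20), -50)
  expect_error(percent_more(5, 0), "positive")

  expect_equal(coverage_fraction(44, 73), 60.27)
  expect_equal(coverage_fraction(0, 10), 0)
  expect_equal(coverage_fraction(7, 8), 87.5)
  expect_error(coverage_fraction(9, 8), "exceed")
  expect_error(coverage_fraction(1, 0), "positive")

  # excess and recovery are different statistics, not interchangeable
  expect_false(isTRUE(all.equal(percent_more(82, 66),
                                coverage_fraction(66, 82))))
})

test_that("scfa_presence builds the heat-map table and product rollup", {
  scfa <- generate_geneset_fixtures()$scfa
  ids <- scfa$members$feature_id
  n <- 9
  samples <- sprintf("S%d", 1:n)
  full <- matrix(1, length(ids), n, dimnames = list(ids, samples))
  mg <- full
  mg["PWY-5677", 1] <- 0        # one metagenome misses this butyrate pathway
  mg["PROPFERM-PWY", 1:2] <- 0
  sim <- full
  sim[c("GLUDEG-II-PWY", "PROPFERM-PWY"), ] <- 0 # absent from all simMGs
  mt <- full
  mt[c("P162-PWY", "P163-PWY", "GLUDEG-II-PWY", "PWY-5677",
       "PROPFERM-PWY"), ] <- 0
  presence <- list(MG = binarize(make_profile(mg, "MG", "pathway")),
                   MT = binarize(make_profile(mt, "MT", "pathway")),
                   simMG = binarize(make_profile(sim, "simMG", "pathway")))
  res <- scfa_presence(presence, scfa)
  expect_equal(unname(res$table["P161-PWY", ]), c(9L, 9L, 9L))
  expect_equal(unname(res$table["GLUDEG-II-PWY", c("MT", "simMG")]),
               c(0L, 0L))
  # simMG recovers 14 of the 16 pathways the MGs identified
  mg_found <- sum(res$table[, "MG"] > 0)
  sim_found <- sum(res$table[, "MG"] > 0 & res$table[, "simMG"] > 0)
  expect_equal(mg_found, 16L)
  expect_equal(sim_found, 14L)
  expect_equal(coverage_fraction(sim_found, mg_found), 87.5)

  rollup <- res$rollup
  expect_equal(rollup$n_pathways_detected[rollup$product == "butyrate" &
                                            rollup$method == "MG"], 7L)
  expect_equal(rollup$n_pathways_detected[rollup$product == "propionate" &
                                            rollup$method == "simMG"], 2L)
  expect_error(scfa_presence(list(MG = presence_from_sets(list(S1 = "x"))),
                             scfa),
               "pathway-level")
})

test_that("prevalence is invariant to abundance scaling", {
  st <- quiet_study(seed = 33, presence_noise = 0.2)
  amr <- generate_geneset_fixtures()$amr
  m <- merge_profiles(st$profiles)
  scaled <- lapply(m, function(p)
    functional_profile(p$abundance * 1e6, p$method_label, p$level))
  t1 <- prevalence(lapply(m, binarize), amr)
  t2 <- prevalence(lapply(scaled, binarize), amr)
  expect_equal(unclass(t1), unclass(t2), ignore_attr = TRUE)
})
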