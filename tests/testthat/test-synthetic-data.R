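test_that("configuration validation names the offending field", {
  expect_error(synthetic_config(presence_noise = 1.5), "presence_noise")
  expect_error(synthetic_config(contaminant_count = -1), "contaminant_count")
  expect_error(synthetic_config(region_counts = c(MG_only = 5)),
               "region_counts")
  expect_error(synthetic_config(genus_pool = c(A = 0.5, B = 0.6)),
               "genus_pool")
  expect_error(synthetic_config(n_samples = 0), "n_samples")
})

test_that("degenerate configs: all-zero regions, and a forced triple core", {
  zero <- setNames(rep(0, 7), region_names())
  st <- quiet_study(region_counts = zero, contaminant_count = 0,
                    n_asvs = 0, n_high_nsti = 0, seed = 1)
  expect_equal(nrow(st$profiles$MG$abundance), 0L)
  expect_equal(nrow(st$profiles$MT$abundance), 0L)
  expect_equal(nrow(st$profiles$simMG$abundance), 0L)

  core <- zero; core["MG_MT_sim"] <- 10
  st2 <- quiet_study(region_counts = core, presence_noise = 0,
                     contaminant_count = 0, seed = 2)
  pres <- lapply(st2$profiles, binarize)
  expect_true(all(unclass(pres$MG)))
  expect_equal(unclass(pres$MG) > 0, unclass(pres$MT) > 0)
  expect_equal(unclass(pres$MG) > 0, unclass(pres$simMG) > 0)
  expect_equal(nrow(st2$profiles$MG$abundance), 10L)
})

test_that("identical seeds give byte-identical serialized studies", {
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  write_study(quiet_study(seed = 42), d1)
  write_study(quiet_study(seed = 42), d2)
  write_study(quiet_study(seed = 43), d3)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  expect_false(identical(readLines(file.path(d1, "MG_KO.tsv")),
                         readLines(file.path(d3, "MG_KO.tsv"))))
})

test_that("generated IDs are syntactically valid per level", {
  for (lv in c("KO", "EC", "pathway")) {
    st <- quiet_study(level = lv, contaminant_count = 3, seed = 8)
    ids <- st$truth$feature_id
    pat <- switch(lv, KO = "^K\\d{5}$", EC = "^9\\.\\d+\\.\\d+\\.\\d+$",
                  pathway = "^SYN-PWY-\\d+$")
    expect_true(all(grepl(pat, ids)))
    expect_false(anyDuplicated(ids) > 0)
  }
})

test_that("truth covers every feature once; contaminant lineages lack prokaryote tokens", {
  st <- quiet_study(contaminant_count = 15, seed = 9)
  expect_setequal(st$truth$feature_id,
                  unique(unlist(lapply(st$profiles,
                                       function(p) rownames(p$abundance)))))
  cont <- st$truth$feature_id[st$truth$contaminant]
  expect_equal(length(cont), 15L)
  expect_false(any(grepl("Bacteria|Archaea", st$lineage_map[cont])))
  # contaminants are never planted in the simulated table
  expect_true(all(rowSums(st$profiles$simMG$abundance[cont, , drop = FALSE])
                  == 0))
  expect_equal(classify_lineage(st$lineage_map[cont]),
               rep("nonprokaryotic", 15))
})

test_that("noiseless decomposition returns the planted region counts per sample", {
  rc <- setNames(c(5, 4, 3, 2, 2, 2, 10), region_names())
  st <- quiet_study(region_counts = rc, presence_noise = 0,
                    contaminant_count = 0, seed = 10)
  pres <- lapply(merge_profiles(st$profiles), binarize)
  dc <- decompose_sets(pres$MG, pres$MT, pres$simMG)
  for (s in colnames(dc$per_sample))
    expect_equal(dc$per_sample[, s], rc)
})

test_that("noisy region counts match the thinning expectation (200 replicates)", {
  rc <- setNames(c(5, 4, 3, 2, 2, 2, 10), region_names())
  p <- 0.1
  # transition law: a feature planted with membership v is observed with
  # membership w <= v with probability prod over methods of (1-p)^w * p^(v-w)
  member <- matrix(c(1, 0, 0, 1, 1, 0, 1,
                     0, 1, 0, 1, 0, 1, 1,
                     0, 0, 1, 0, 1, 1, 1), 7,
                   dimnames = list(region_names(), method_labels()))
  trans <- matrix(0, 7, 7, dimnames = list(region_names(), region_names()))
  for (r in region_names()) for (w in region_names()) {
    v <- member[r, ]; u <- member[w, ]
    if (any(u > v)) next
    trans[r, w] <- prod(((1 - p)^u * p^(v - u))[v == 1])
  }
  expected <- as.vector(rc %*% trans)
  reps <- 200L
  obs <- matrix(NA_real_, reps, 7)
  for (i in seq_len(reps)) {
    st <- quiet_study(region_counts = rc, presence_noise = p,
                      contaminant_count = 0, n_samples = 3,
                      n_asvs = 0, n_high_nsti = 0, seed = 7000 + i)
    pres <- lapply(st$profiles, binarize)
    dc <- decompose_sets(pres$MG, pres$MT, pres$simMG)
    obs[i, ] <- dc$averaged
  }
  se <- apply(obs, 2, sd) / sqrt(reps)
  expect_true(all(abs(colMeans(obs) - expected) <= 3 * se + 1e-9))
})

test_that("the ASV fixture has the configured NSTI composition", {
  st <- quiet_study(seed = 3)
  expect_equal(nrow(st$asv_table), 1129L)
  expect_equal(sum(st$asv_table$nsti > 2), 71L)
  expect_true(all(st$asv_table$read_count >= 1))
})

test_that("seed_features are planted into shared regions first", {
  ids <- c("P161-PWY", "PWY-5100", "ANAEROFRUCAT-PWY")
  rc <- setNames(c(1, 1, 1, 0, 0, 0, 3), region_names())
  st <- quiet_study(level = "pathway", region_counts = rc,
                    presence_noise = 0, contaminant_count = 0,
                    seed_features = ids, seed = 4)
  expect_equal(st$truth$region[match(ids, st$truth$feature_id)],
               rep("MG_MT_sim", 3))
})

test_that("config round trips through YAML and key=value files", {
  y <- tempfile(fileext = ".yml")
  writeLines(c("n_samples: 5", "presence_noise: 0.2", "seed: 77",
               "contaminant_count: 3"), y)
  cfg <- read_synthetic_config(y)
  expect_equal(cfg$n_samples, 5L)
  expect_equal(cfg$presence_noise, 0.2)
  expect_equal(cfg$seed, 77L)

  kv <- tempfile(fileext = ".cfg")
  writeLines(c("n_samples = 4", "presence_noise = 0.05", "seed = 3"), kv)
  cfg2 <- read_synthetic_config(kv)
  expect_equal(cfg2$n_samples, 4L)
  expect_equal(cfg2$presence_noise, 0.05)
})
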