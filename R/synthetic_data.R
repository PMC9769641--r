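#' Default genus pool for synthetic studies
#'
#' Seventeen gut-associated genera with relative-abundance weights. The
#' first nine are the genera that a stratified gene-family table typically
#' resolves (and are the ones used for attribution in generated studies);
#' the rest pad the pool to the seventeen abundant genera a 16S survey of a
#' wild folivore plausibly yields. Weights sum to 1.
#'
#' @return named numeric vector of 17 weights.
#' @export
default_genus_pool <- function() {
  g <- c(Bacteroides = 0.12, Campylobacter = 0.08, Curtobacterium = 0.05,
         Escherichia = 0.09, Faecalibacterium = 0.10, Helicobacter = 0.05,
         Megamonas = 0.07, Subdoligranulum = 0.09, Turicibacter = 0.05,
         Clostridium = 0.05, Lactobacillus = 0.05, Streptococcus = 0.04,
         Enterococcus = 0.04, Pseudomonas = 0.03, Prevotella = 0.03,
         Ruminococcus = 0.03, Rothia = 0.03)
  g / sum(g)
}

.default_region_counts <- function() {
  # qualitative copy of the averaged KO overlap structure: the triple
  # intersection dominates, MG-simMG is the second largest region, and on
  # average only ~23 features are unique to the metatranscriptomes
  c(MG_only = 120, MT_only = 23, sim_only = 80,
    MG_MT = 60, MG_sim = 200, MT_sim = 15, MG_MT_sim = 400)
}

#' Configuration for a synthetic multiomics study
#'
#' Defines the planted structure of a coupled MG/MT/simMG study: how many
#' features sit in each of the 7 overlap regions, how often a planted
#' presence is dropped in an individual sample, how many non-prokaryotic
#' contaminant features pollute the sequenced (MG/MT) tables, and which
#' genera attribute the stratified rows. Defaults mirror the study design
#' the package evaluates: 9 paired samples, a KO-level overlap structure
#' dominated by the triple intersection, and an ASV table of 1,129 variants
#' of which 71 exceed the NSTI cutoff of 2.
#'
#' @param n_samples number of paired samples (default 9).
#' @param region_counts named nonnegative counts over [region_names()].
#' @param presence_noise probability in `[0, 1]` that a planted-present
#'   feature is dropped in an individual sample, independently per
#'   feature, sample and method (default 0.1).
#' @param contaminant_count number of non-prokaryotic (viral/eukaryotic)
#'   features injected into MG and MT only; never into simMG (default 25).
#' @param genus_pool named weights (must sum to 1 within 1e-9) for the
#'   genus pool; the first 9 entries are usable for stratified attribution.
#' @param stratified_fraction fraction of MG features whose occurrences are
#'   attributed to a named genus (default 0.6).
#' @param mt_dropout probability that a feature planted in an MT-containing
#'   region is silenced in the metatranscriptome entirely (transcription
#'   dropout); the planted truth records the post-dropout region. Default 0.
#' @param level functional level of the generated profiles.
#' @param n_asvs,n_high_nsti size of the companion ASV table and how many
#'   of its variants draw an NSTI above 2 (defaults 1129 and 71).
#' @param seed_features optional feature IDs to use (in order) instead of
#'   generated IDs, assigned to regions starting from the triple
#'   intersection — use to plant curated gene-set members into a study.
#' @param seed integer seed for the pseudo-random stream.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 9,
                             region_counts = .default_region_counts(),
                             presence_noise = 0.1,
                             contaminant_count = 25,
                             genus_pool = default_genus_pool(),
                             stratified_fraction = 0.6,
                             mt_dropout = 0,
                             level = c("KO", "EC", "pathway"),
                             n_asvs = 1129, n_high_nsti = 71,
                             seed_features = NULL,
                             seed = 1L) {
  level <- match.arg(level)
  .assert_scalar_number(n_samples, "n_samples", lower = 1, integer = TRUE)
  if (!all(region_names() %in% names(region_counts)))
    stop("'region_counts' must name all 7 regions: ",
         paste(region_names(), collapse = ", "), call. = FALSE)
  region_counts <- region_counts[region_names()]
  if (any(region_counts < 0) || any(region_counts != floor(region_counts)))
    stop("'region_counts' must be nonnegative integers", call. = FALSE)
  .assert_scalar_number(presence_noise, "presence_noise", 0, 1)
  .assert_scalar_number(mt_dropout, "mt_dropout", 0, 1)
  .assert_scalar_number(contaminant_count, "contaminant_count", lower = 0,
                        integer = TRUE)
  .assert_scalar_number(stratified_fraction, "stratified_fraction", 0, 1)
  .assert_scalar_number(n_asvs, "n_asvs", lower = 0, integer = TRUE)
  .assert_scalar_number(n_high_nsti, "n_high_nsti", lower = 0,
                        upper = n_asvs, integer = TRUE)
  .assert_scalar_number(seed, "seed", integer = TRUE)
  if (is.null(names(genus_pool)) || anyDuplicated(names(genus_pool)))
    stop("'genus_pool' must be a uniquely named weight vector", call. = FALSE)
  if (any(genus_pool < 0) || abs(sum(genus_pool) - 1) > 1e-9)
    stop("'genus_pool' weights must be nonnegative and sum to 1",
         call. = FALSE)
  structure(list(n_samples = as.integer(n_samples),
                 region_counts = region_counts,
                 presence_noise = presence_noise,
                 contaminant_count = as.integer(contaminant_count),
                 genus_pool = genus_pool,
                 stratified_fraction = stratified_fraction,
                 mt_dropout = mt_dropout, level = level,
                 n_asvs = as.integer(n_asvs),
                 n_high_nsti = as.integer(n_high_nsti),
                 seed_features = seed_features, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Read a synthetic-study configuration from YAML or key=value text
#' @param path a YAML file, or a flat file of `key = value` lines.
#' @return a [synthetic_config()].
#' @export
read_synthetic_config <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vals <- if (any(grepl(":", txt, fixed = TRUE)))
    yaml::read_yaml(path)
  else {
    kv <- txt[grepl("=", txt, fixed = TRUE)]
    parts <- strsplit(kv, "=", fixed = TRUE)
    stats::setNames(lapply(parts, function(p) {
      v <- trimws(p[2])
      num <- suppressWarnings(as.numeric(v))
      if (is.na(num)) v else num
    }), trimws(vapply(parts, `[`, "", 1)))
  }
  if (!is.null(vals$region_counts))
    vals$region_counts <- unlist(vals$region_counts)
  if (!is.null(vals$genus_pool)) vals$genus_pool <- unlist(vals$genus_pool)
  do.call(synthetic_config, vals)
}

.feature_ids <- function(level, n, offset = 0L) {
  idx <- offset + seq_len(n)
  switch(level,
         KO = sprintf("K9%04d", idx),
         EC = sprintf("9.%d.%d.%d", (idx - 1) %/% 2500 + 1,
                      ((idx - 1) %/% 50) %% 50 + 1, (idx - 1) %% 50 + 1),
         pathway = sprintf("SYN-PWY-%d", idx))
}

.region_membership <- function() {
  # method membership of each region
  matrix(c(1, 0, 0, 1, 1, 0, 1,
           0, 1, 0, 1, 0, 1, 1,
           0, 0, 1, 0, 1, 1, 1),
         nrow = 7, dimnames = list(region_names(), method_labels()))
}

.synthetic_phyla <- c("Firmicutes", "Proteobacteria", "Actinobacteria",
                      "Bacteroidetes")
.contaminant_lineages <- c(
  "Viruses; Riboviria; Bromoviridae",
  "Viruses; Retroviridae",
  "Eukaryota; Viridiplantae; Streptophyta",
  "Eukaryota; Metazoa; Chordata",
  "Eukaryota; Fungi; Ascomycota")

#' Generate a coupled synthetic MG/MT/simMG study
#'
#' Builds three method-labelled functional profiles over a shared feature
#' pool with *planted, recoverable* structure: every feature is assigned to
#' one of the 7 overlap regions, non-prokaryotic contaminants are injected
#' into the sequenced tables only, per-sample presence noise thins the
#' planted patterns, a fraction of metagenome occurrences is attributed to
#' genera, and companion fixtures (lineage map, ASV/NSTI table, genus
#' relative abundances) are produced alongside. With `presence_noise = 0`
#' the per-sample presence pattern of every feature equals its planted
#' region, so every downstream statistic has a closed-form expected value.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_study`: `profiles` (named list of
#'   [functional_profile()]s), `lineage_map`, `truth` (data frame:
#'   feature_id, region, contaminant, genus), `asv_table`,
#'   `genus_abundance`, `config`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_samples
  samples <- sprintf("ZD%02d", seq_len(n))
  rc <- config$region_counts
  n_planted <- sum(rc)
  n_total <- n_planted + config$contaminant_count

  # assign IDs region by region, triple intersection first, so that
  # seed_features land in shared regions
  region_order <- c("MG_MT_sim", "MG_sim", "MG_MT", "MT_sim",
                    "MG_only", "MT_only", "sim_only")
  ids <- .feature_ids(config$level, n_total)
  if (!is.null(config$seed_features)) {
    k <- min(length(config$seed_features), n_total)
    ids[seq_len(k)] <- config$seed_features[seq_len(k)]
  }
  region <- rep(region_order, rc[region_order])
  contaminant <- rep(c(FALSE, TRUE), c(n_planted, config$contaminant_count))
  region <- c(region, rep("MG_MT", config$contaminant_count))
  feature_id <- ids

  # transcription dropout reassigns MT-containing regions; the truth table
  # records the post-dropout region so planted-truth recovery stays exact
  if (config$mt_dropout > 0) {
    drop_map <- c(MT_only = NA, MG_MT = "MG_only", MT_sim = "sim_only",
                  MG_MT_sim = "MG_sim")
    in_mt <- region %in% names(drop_map) & !contaminant
    hit <- in_mt & stats::runif(length(region)) < config$mt_dropout
    region[hit] <- drop_map[region[hit]]
    keep <- !is.na(region)
    region <- region[keep]; contaminant <- contaminant[keep]
    feature_id <- feature_id[keep]
  }

  membership <- .region_membership()[region, , drop = FALSE]
  genus_names <- names(config$genus_pool)
  strat_pool <- genus_names[seq_len(min(9L, length(genus_names)))]
  strat_w <- config$genus_pool[strat_pool] / sum(config$genus_pool[strat_pool])

  # per-feature genus attribution (MG members only, non-contaminant)
  genus <- rep(NA_character_, length(feature_id))
  mg_member <- membership[, "MG"] == 1 & !contaminant
  attributed <- mg_member &
    stats::runif(length(feature_id)) < config$stratified_fraction
  genus[attributed] <- sample(strat_pool, sum(attributed), replace = TRUE,
                              prob = strat_w)

  truth <- data.frame(feature_id = feature_id, region = region,
                      contaminant = contaminant, genus = genus,
                      stringsAsFactors = FALSE)

  make_abund <- function(mth) {
    planted <- matrix(rep(membership[, mth], n), ncol = n,
                      dimnames = list(feature_id, samples))
    if (config$presence_noise > 0) {
      keep <- matrix(stats::runif(length(planted)) >= config$presence_noise,
                     ncol = n)
      planted <- planted * keep
    }
    vals <- matrix(stats::rlnorm(length(planted), meanlog = 5, sdlog = 1),
                   ncol = n)
    planted * vals
  }
  ab <- lapply(method_labels(), make_abund)
  names(ab) <- method_labels()

  # stratified rows for the MG table: attributed features donate a fixed
  # share of their abundance to their genus wherever they are present
  stratified <- NULL
  attr_idx <- which(!is.na(genus))
  if (length(attr_idx)) {
    share <- stats::runif(length(attr_idx), 0.4, 0.9)
    smat <- ab$MG[attr_idx, , drop = FALSE] * share
    stratified <- cbind(
      data.frame(feature = feature_id[attr_idx], genus = genus[attr_idx],
                 species = paste0(genus[attr_idx], "_sp"),
                 stringsAsFactors = FALSE),
      as.data.frame(smat, row.names = NULL))
    names(stratified)[-(1:3)] <- samples
  }

  profiles <- list(
    MG = functional_profile(ab$MG, "MG", config$level,
                            stratified = stratified),
    MT = functional_profile(ab$MT, "MT", config$level),
    simMG = functional_profile(ab$simMG, "simMG", config$level))

  # lineage map: planted features are bacterial/archaeal, contaminants viral
  # or eukaryotic (never containing the prokaryote tokens)
  lineage <- ifelse(
    contaminant,
    sample(.contaminant_lineages, length(feature_id), replace = TRUE),
    paste0("cellular organisms; Bacteria; ",
           sample(.synthetic_phyla, length(feature_id), replace = TRUE)))
  lineage_map <- stats::setNames(lineage, feature_id)

  asv_table <- .generate_asv_table(config$n_asvs, config$n_high_nsti)
  genus_abundance <- .generate_genus_abundance(config$genus_pool, samples)

  structure(list(profiles = profiles, lineage_map = lineage_map,
                 truth = truth, asv_table = asv_table,
                 genus_abundance = genus_abundance, config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_study> level %s, %d samples, %d features ",
                     "(%d contaminants), noise %.2g\n"),
              x$config$level, x$config$n_samples, nrow(x$truth),
              sum(x$truth$contaminant), x$config$presence_noise))
  invisible(x)
}

.generate_asv_table <- function(n_asvs, n_high) {
  if (n_asvs == 0L)
    return(data.frame(asv_id = character(0), read_count = numeric(0),
                      nsti = numeric(0)))
  nsti <- c(stats::runif(n_asvs - n_high, 0, 2),
            stats::runif(n_high, 2 + 1e-6, 8))
  data.frame(asv_id = sprintf("ASV%04d", seq_len(n_asvs)),
             read_count = stats::rnbinom(n_asvs, mu = 2000, size = 0.8) + 1,
             nsti = nsti[sample.int(n_asvs)], stringsAsFactors = FALSE)
}

.generate_genus_abundance <- function(pool, samples) {
  # every pool genus is dominant (>5%) in at least one sample when
  # 2 * n_samples >= |pool|; three perennially rare genera stay below 5%
  n <- length(samples)
  genera <- names(pool)
  minors <- c("Sutterella", "Akkermansia", "Dialister")
  m <- matrix(0, length(genera) + length(minors), n,
              dimnames = list(c(genera, minors), samples))
  for (j in seq_len(n)) {
    dom <- ((2 * (j - 1) + 0:1) %% length(genera)) + 1
    dom <- unique(dom)
    m[minors, j] <- 0.01
    m[genera[dom], j] <- c(0.25, 0.20)[seq_along(dom)]
    rest <- setdiff(seq_along(genera), dom)
    w <- pool[rest] * stats::rgamma(length(rest), shape = 4, rate = 4)
    m[genera[rest], j] <- (1 - sum(m[, j])) * w / sum(w)
  }
  m
}

.scfa_products <- function() {
  list("P161-PWY" = "acetate",
       "P162-PWY" = "acetate;butyrate",
       "P163-PWY" = "acetate;butyrate",
       "P124-PWY" = "acetate;lactate",
       "P461-PWY" = "acetate;lactate",
       "PWY-5100" = "acetate;lactate",
       "GLUDEG-II-PWY" = "butyrate",
       "PWY-5677" = "butyrate",
       "PROPFERM-PWY" = "propionate",
       "ANAEROFRUCAT-PWY" = "lactate",
       # the curated catalog names only 10 of the 16 fermentation pathways;
       # synthetic IDs fill the remainder with the products needed to reach
       # the 6/7/5/3 acetate/butyrate/lactate/propionate multiplicities
       "SYN-SCFA-PWY-1" = "butyrate",
       "SYN-SCFA-PWY-2" = "butyrate",
       "SYN-SCFA-PWY-3" = "butyrate",
       "SYN-SCFA-PWY-4" = "lactate",
       "SYN-SCFA-PWY-5" = "propionate",
       "SYN-SCFA-PWY-6" = "propionate")
}

.amr_class_sizes <- function() {
  c(aminoglycosides = 39, fosfomycin = 5,
    `macrolide-lincosamide-streptogramin` = 19, penicillin = 47,
    phenicol = 8, quinolone = 2, rifamycin = 4, sulfonamide = 3,
    tetracycline = 11, trimethoprim = 6, vancomycin = 18)
}

#' Curated gene-set fixtures
#'
#' Three editable gene sets for the focused analyses:
#'
#' * `scfa` — 16 short-chain fatty acid fermentation pathways with product
#'   labels; 6 produce acetate, 7 butyrate, 5 lactate and 3 propionate
#'   (5 pathways carry two products). Ten carry their catalog IDs; six are
#'   synthetic placeholders (`SYN-SCFA-PWY-*`) because the full list is a
#'   versioned catalog resource — supply your own via [read_geneset()] for
#'   real analyses.
#' * `amr` — 162 synthetic antimicrobial-resistance KOs spread over the 11
#'   antimicrobial classes (aminoglycosides through vancomycin).
#' * `cazy` — 102 synthetic cellulolytic/hemicellulolytic EC placeholders
#'   labelled by glycoside hydrolase family (GH5/GH6/GH7).
#'
#' AMR and CAZy member IDs are drawn from namespaces (`K98xxx`, `9.9.x.x`)
#' that generated study features do not reach at realistic study sizes, so
#' collisions are always intentional (via `seed_features`).
#'
#' @return named list of three [gene_set()] objects.
#' @export
generate_geneset_fixtures <- function() {
  scfa <- .scfa_products()
  scfa_set <- gene_set("SCFA_pathways",
                       data.frame(feature_id = names(scfa),
                                  class = unlist(scfa, use.names = FALSE),
                                  stringsAsFactors = FALSE))
  sizes <- .amr_class_sizes()
  amr_set <- gene_set("AMR_KOs",
                      data.frame(feature_id = sprintf("K98%03d",
                                                      seq_len(sum(sizes))),
                                 class = rep(names(sizes), sizes),
                                 stringsAsFactors = FALSE))
  cazy_set <- gene_set("CAZy_GH_ECs",
                       data.frame(feature_id = sprintf("9.9.%d.%d",
                                                       rep(1:3, each = 34),
                                                       rep(1:34, times = 3)),
                                  class = rep(c("GH5", "GH6", "GH7"),
                                              each = 34),
                                  stringsAsFactors = FALSE))
  list(scfa = scfa_set, amr = amr_set, cazy = cazy_set)
}

#' Write every fixture of a synthetic study to a directory
#'
#' Serializes the three profiles, lineage map, ASV table, genus abundances
#' and planted truth as the TSV dialects the readers in this package
#' consume; byte-identical for identical configs.
#'
#' @param study a [generate_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in names(study$profiles))
    write_profile(study$profiles[[m]],
                  file.path(dir, sprintf("%s_%s.tsv", m,
                                         study$profiles[[m]]$level)))
  write_lineage_map(study$lineage_map, file.path(dir, "lineage_map.tsv"))
  utils::write.table(study$asv_table, file.path(dir, "asv_nsti.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_genus_abundance(study$genus_abundance,
                        file.path(dir, "genus_abundance.tsv"))
  utils::write.table(study$truth, file.path(dir, "planted_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
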