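# Small in-code fixtures shared across test files.

make_profile <- function(abund, method = "MG", level = "KO", ...) {
  functional_profile(abund, method, level, ...)
}

# a profile from an explicit list of per-sample feature sets
profile_from_sets <- function(sets, method = "MG", level = "KO") {
  features <- sort(unique(unlist(sets)))
  m <- matrix(0, nrow = length(features), ncol = length(sets),
              dimnames = list(features, names(sets)))
  for (j in seq_along(sets)) m[features %in% sets[[j]], j] <- 1
  functional_profile(m, method, level)
}

presence_from_sets <- function(sets, method = "MG", level = "KO") {
  binarize(profile_from_sets(sets, method, level))
}

# independent brute-force 7-region decomposition via explicit set algebra
brute_force_regions <- function(a, b, c) {
  c(MG_only = length(setdiff(setdiff(a, b), c)),
    MT_only = length(setdiff(setdiff(b, a), c)),
    sim_only = length(setdiff(setdiff(c, a), b)),
    MG_MT = length(setdiff(intersect(a, b), c)),
    MG_sim = length(setdiff(intersect(a, c), b)),
    MT_sim = length(setdiff(intersect(b, c), a)),
    MG_MT_sim = length(intersect(intersect(a, b), c)))
}

# direct Dice coefficient (x100) from two raw sets
brute_force_dice <- function(x, y) {
  i <- length(intersect(x, y))
  r <- length(setdiff(x, y)) + length(setdiff(y, x))
  2 * i / (2 * i + r) * 100
}

# tiny HUMAnN2-style table written to a temp file
write_profile_text <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

quiet_study <- function(...) {
  suppressMessages(generate_study(synthetic_config(...)))
}

quiet_pipeline <- function(study, ...) {
  suppressMessages(run_pipeline(study, ...))
}

# published averaged percent-similarity reference values (percent)
published_similarity <- function() {
  read.delim(system.file("extdata", "published_similarity_summary.tsv",
                         package = "simmgeval"),
             stringsAsFactors = FALSE)
}
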