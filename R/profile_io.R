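#' Functional abundance profile
#'
#' Container for a feature-by-sample abundance table at one functional level
#' (KEGG orthologies, enzyme commission numbers, or MetaCyc pathways) produced
#' by one method: shotgun metagenome (`MG`), metatranscriptome (`MT`) or a
#' 16S-derived simulated metagenome (`simMG`). Stratified rows — abundance
#' attributed to a contributing taxon, as written by HUMAnN2-style tools with
#' the `FEATURE|g__Genus.s__species` convention — are kept alongside the
#' unstratified totals.
#'
#' @param abundance numeric matrix, features in rows (rownames = feature IDs),
#'   samples in columns (colnames = sample IDs); all values must be >= 0.
#' @param method_label one of `"MG"`, `"MT"`, `"simMG"`.
#' @param level one of `"KO"`, `"EC"`, `"pathway"`.
#' @param stratified optional data frame with columns `feature`, `genus`,
#'   `species`, followed by one numeric column per sample (same sample IDs as
#'   `abundance`). Taxon-attributed abundance for a feature may not exceed the
#'   feature's unstratified total (tolerance 1e-6 relative).
#' @param unmapped_mass optional named numeric vector (per sample) holding the
#'   summed mass of UNMAPPED/UNGROUPED/UNINTEGRATED rows excluded from the
#'   feature set; kept as a diagnostic.
#' @return an object of class `functional_profile`.
#' @export
functional_profile <- function(abundance, method_label, level,
                               stratified = NULL, unmapped_mass = NULL) {
  method_label <- match.arg(method_label, method_labels())
  level <- match.arg(level, c("KO", "EC", "pathway"))
  if (!is.matrix(abundance) || !is.numeric(abundance))
    stop("'abundance' must be a numeric matrix", call. = FALSE)
  if (is.null(colnames(abundance)))
    stop("'abundance' must have sample IDs as column names", call. = FALSE)
  if (anyDuplicated(colnames(abundance)))
    stop("sample IDs must be unique", call. = FALSE)
  if (nrow(abundance) > 0 && is.null(rownames(abundance)))
    stop("'abundance' must have feature IDs as row names", call. = FALSE)
  if (anyDuplicated(rownames(abundance)))
    stop("feature IDs must be unique (sum duplicates before construction)",
         call. = FALSE)
  if (any(abundance < 0, na.rm = TRUE))
    stop("abundances must be nonnegative", call. = FALSE)
  if (anyNA(abundance))
    stop("abundances must not contain NA", call. = FALSE)
  samples <- colnames(abundance)
  if (is.null(unmapped_mass)) {
    unmapped_mass <- stats::setNames(numeric(length(samples)), samples)
  } else {
    unmapped_mass <- unmapped_mass[samples]
    unmapped_mass[is.na(unmapped_mass)] <- 0
    names(unmapped_mass) <- samples
  }
  if (!is.null(stratified)) {
    need <- c("feature", "genus", "species", samples)
    if (!all(need %in% names(stratified)))
      stop("stratified table must have columns feature, genus, species and ",
           "one column per sample", call. = FALSE)
    stratified <- stratified[, need, drop = FALSE]
    # taxon sums must not exceed the unstratified total for the feature
    strat_tot <- rowsum(as.matrix(stratified[, samples, drop = FALSE]),
                        group = stratified$feature)
    common <- intersect(rownames(strat_tot), rownames(abundance))
    if (length(common)) {
      excess <- strat_tot[common, , drop = FALSE] -
        abundance[common, , drop = FALSE]
      tol <- 1e-6 * pmax(1, abundance[common, , drop = FALSE])
      if (any(excess > tol))
        stop("stratified taxon sums exceed the unstratified totals",
             call. = FALSE)
    }
  }
  structure(
    list(method_label = method_label, level = level, abundance = abundance,
         stratified = stratified, unmapped_mass = unmapped_mass,
         sample_ids = samples),
    class = "functional_profile"
  )
}

#' @export
print.functional_profile <- function(x, ...) {
  cat(sprintf("<functional_profile> %s / %s: %d features x %d samples\n",
              x$method_label, x$level, nrow(x$abundance), ncol(x$abundance)))
  if (!is.null(x$stratified))
    cat(sprintf("  stratified rows: %d (%d genera)\n", nrow(x$stratified),
                length(unique(x$stratified$genus))))
  if (any(x$unmapped_mass > 0))
    cat(sprintf("  unmapped/ungrouped diagnostic mass: %.4g (total)\n",
                sum(x$unmapped_mass)))
  invisible(x)
}

#' Number of samples in a profile
#' @param profile a `functional_profile`.
#' @return integer.
#' @export
n_samples <- function(profile) length(profile$sample_ids)

.unmapped_ids <- c("UNMAPPED", "UNGROUPED", "UNINTEGRATED")

.parse_taxon <- function(taxon) {
  # "g__Escherichia.s__Escherichia_coli" or "unclassified"
  genus <- rep("unclassified", length(taxon))
  species <- rep(NA_character_, length(taxon))
  hit <- regmatches(taxon, regexec("g__([^.|]+)", taxon))
  has_g <- lengths(hit) == 2L
  genus[has_g] <- vapply(hit[has_g], `[`, "", 2L)
  hit <- regmatches(taxon, regexec("s__([^.|]+)", taxon))
  has_s <- lengths(hit) == 2L
  species[has_s] <- vapply(hit[has_s], `[`, "", 2L)
  data.frame(genus = genus, species = species, stringsAsFactors = FALSE)
}

#' Read a tab-delimited functional abundance table
#'
#' Reads HUMAnN2/PICRUSt2-style output: first column is the feature ID
#' (header `# Gene Family`, `# Pathway` or plain), remaining columns are
#' samples. `UNMAPPED`, `UNGROUPED` and `UNINTEGRATED` rows (stratified or
#' not) are excluded from the feature set but their per-sample mass is kept
#' as a diagnostic. Rows of the form `FEATURE|g__Genus.s__species` are split
#' into the stratified table; the genus token is parsed from the `g__`
#' prefix. Duplicate unstratified feature rows are summed.
#'
#' @param path path to a UTF-8, tab-delimited file.
#' @param method_label,level as in [functional_profile()].
#' @return a [functional_profile()].
#' @export
read_profile <- function(path, method_label, level) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, comment.char = "",
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L)
    stop(sprintf("empty profile: '%s' contains no data rows", path),
         call. = FALSE)
  ids <- raw[[1L]]
  samples <- names(raw)[-1L]
  num <- as.matrix(raw[, -1L, drop = FALSE])
  suppressWarnings(storage <- matrix(as.numeric(num), nrow = nrow(num),
                                     dimnames = list(NULL, samples)))
  bad <- which(is.na(storage) & !is.na(num) & nzchar(num), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric cell at row %d, column '%s' of '%s'",
                 bad[1, 1], samples[bad[1, 2]], path), call. = FALSE)
  storage[is.na(storage)] <- 0

  base_id <- sub("\\|.*$", "", ids)
  is_strat <- grepl("|", ids, fixed = TRUE)
  is_unmapped <- base_id %in% .unmapped_ids

  unmapped_mass <- colSums(storage[is_unmapped, , drop = FALSE])
  names(unmapped_mass) <- samples

  un_rows <- !is_strat & !is_unmapped
  abundance <- rowsum(storage[un_rows, , drop = FALSE],
                      group = ids[un_rows], reorder = FALSE)

  strat_rows <- is_strat & !is_unmapped
  stratified <- NULL
  if (any(strat_rows)) {
    taxon <- sub("^[^|]*\\|", "", ids[strat_rows])
    tax <- .parse_taxon(taxon)
    stratified <- cbind(
      data.frame(feature = base_id[strat_rows], stringsAsFactors = FALSE),
      tax,
      as.data.frame(storage[strat_rows, , drop = FALSE])
    )
    rownames(stratified) <- NULL
    # a stratified feature lacking a total row gets one, totalled from strata
    missing <- setdiff(unique(stratified$feature), rownames(abundance))
    if (length(missing)) {
      add <- rowsum(as.matrix(stratified[stratified$feature %in% missing,
                                         samples, drop = FALSE]),
                    group = stratified$feature[stratified$feature %in% missing])
      abundance <- rbind(abundance, add[missing, , drop = FALSE])
    }
  }
  functional_profile(abundance, method_label, level,
                     stratified = stratified, unmapped_mass = unmapped_mass)
}

#' Write a functional profile as a tab-delimited table
#'
#' Inverse of [read_profile()]: unstratified rows first, then stratified rows
#' in the `FEATURE|g__Genus.s__species` form, then an `UNMAPPED` row if the
#' profile carries diagnostic mass. `read_profile(write_profile(p))` restores
#' the data model exactly (within numeric print precision).
#'
#' @param profile a [functional_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  header <- if (profile$level == "pathway") "# Pathway" else "# Gene Family"
  samples <- profile$sample_ids
  lines <- paste(c(header, samples), collapse = "\t")
  fmt_row <- function(id, vals)
    paste(c(id, format(vals, digits = 15, scientific = FALSE, trim = TRUE)),
          collapse = "\t")
  for (i in seq_len(nrow(profile$abundance)))
    lines <- c(lines, fmt_row(rownames(profile$abundance)[i],
                              profile$abundance[i, ]))
  if (!is.null(profile$stratified)) {
    st <- profile$stratified
    for (i in seq_len(nrow(st))) {
      taxon <- if (st$genus[i] == "unclassified" && is.na(st$species[i]))
        "unclassified"
      else if (is.na(st$species[i]))
        paste0("g__", st$genus[i])
      else
        paste0("g__", st$genus[i], ".s__", st$species[i])
      lines <- c(lines, fmt_row(paste0(st$feature[i], "|", taxon),
                                unlist(st[i, samples])))
    }
  }
  if (any(profile$unmapped_mass > 0))
    lines <- c(lines, fmt_row("UNMAPPED", profile$unmapped_mass))
  writeLines(lines, path)
  invisible(path)
}

#' Align profiles on the union feature set and the shared samples
#'
#' Merges one profile per method onto the union of their feature sets
#' (missing features filled with 0) and the intersection of their sample
#' sets, preserving paired-sample alignment. Samples without a counterpart
#' in every method are dropped with a message — simulated metagenomes are
#' typically predicted for more extracts than were shotgun-sequenced.
#'
#' @param profiles list of [functional_profile()] objects, one per method,
#'   all at the same functional level.
#' @return named list of aligned profiles (names = method labels), with
#'   attribute `dropped_samples` naming any removed samples.
#' @export
merge_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 2L)
  levels <- unique(vapply(profiles, `[[`, "", "level"))
  if (length(levels) != 1L)
    stop(sprintf("level mismatch: cannot merge profiles at levels %s",
                 paste(levels, collapse = ", ")), call. = FALSE)
  methods <- vapply(profiles, `[[`, "", "method_label")
  if (anyDuplicated(methods))
    stop("at most one profile per method label", call. = FALSE)
  names(profiles) <- methods
  features <- sort(unique(unlist(lapply(profiles,
                                        function(p) rownames(p$abundance)))))
  common <- Reduce(intersect, lapply(profiles, `[[`, "sample_ids"))
  if (length(common) == 0L)
    stop("no samples are shared by all methods", call. = FALSE)
  all_samples <- unique(unlist(lapply(profiles, `[[`, "sample_ids")))
  dropped <- setdiff(all_samples, common)
  if (length(dropped))
    message("dropping ", length(dropped), " unpaired sample(s): ",
            paste(dropped, collapse = ", "))
  # keep the sample order of the first profile
  common <- profiles[[1L]]$sample_ids[profiles[[1L]]$sample_ids %in% common]
  out <- lapply(profiles, function(p) {
    m <- matrix(0, nrow = length(features), ncol = length(common),
                dimnames = list(features, common))
    have <- intersect(rownames(p$abundance), features)
    m[have, ] <- p$abundance[have, common, drop = FALSE]
    st <- p$stratified
    if (!is.null(st))
      st <- st[, c("feature", "genus", "species", common), drop = FALSE]
    functional_profile(m, p$method_label, p$level, stratified = st,
                       unmapped_mass = p$unmapped_mass[common])
  })
  attr(out, "dropped_samples") <- dropped
  out
}

#' Discard amplicon sequence variants by NSTI
#'
#' The nearest-sequenced taxon index (NSTI) measures how far an ASV sits from
#' any reference genome; predictions for highly divergent ASVs are unreliable
#' and are discarded when NSTI is *strictly* greater than the cutoff.
#'
#' @param records data frame with columns `asv_id`, `read_count`, `nsti`.
#' @param cutoff nonnegative NSTI cutoff (default 2).
#' @return list with `retained`, `discarded` (row subsets), `n_discarded`,
#'   `asv_fraction_discarded` and `read_fraction_discarded` (the latter
#'   weighted by `read_count`). Fractions are `NA` with a warning on empty
#'   input.
#' @export
filter_by_nsti <- function(records, cutoff = 2) {
  .assert_scalar_number(cutoff, "cutoff", lower = 0)
  stopifnot(all(c("asv_id", "read_count", "nsti") %in% names(records)))
  if (nrow(records) == 0L) {
    warning("empty ASV table: discard fractions are undefined")
    return(list(retained = records, discarded = records, n_discarded = 0L,
                asv_fraction_discarded = NA_real_,
                read_fraction_discarded = NA_real_))
  }
  if (any(records$nsti < 0)) stop("NSTI values must be nonnegative")
  drop <- records$nsti > cutoff
  list(
    retained = records[!drop, , drop = FALSE],
    discarded = records[drop, , drop = FALSE],
    n_discarded = sum(drop),
    asv_fraction_discarded = mean(drop),
    read_fraction_discarded = sum(records$read_count[drop]) /
      sum(records$read_count)
  )
}

#' Curated gene set
#'
#' A named list of feature IDs with class labels: antimicrobial groups for
#' AMR KOs, glycoside hydrolase family origins for CAZy ECs, or fermentation
#' products for SCFA pathways. A member carrying several class labels (e.g. a
#' pathway producing both acetate and lactate) stores them separated by `;`.
#'
#' @param name set name.
#' @param members data frame with columns `feature_id` (unique) and `class`
#'   (non-empty; multiple labels `;`-separated).
#' @return an object of class `gene_set`.
#' @export
gene_set <- function(name, members) {
  stopifnot(is.character(name), length(name) == 1L,
            all(c("feature_id", "class") %in% names(members)))
  if (anyDuplicated(members$feature_id))
    stop("feature_ids must be unique within a gene set", call. = FALSE)
  if (any(!nzchar(members$class) | is.na(members$class)))
    stop("every member needs at least one class label", call. = FALSE)
  structure(list(name = name,
                 members = members[, c("feature_id", "class"), drop = FALSE]),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d members, %d classes\n", x$name,
              nrow(x$members), length(gene_set_classes(x))))
  invisible(x)
}

#' Distinct class labels of a gene set
#' @param set a [gene_set()].
#' @return character vector of class labels (multi-label members split).
#' @export
gene_set_classes <- function(set) {
  sort(unique(unlist(strsplit(set$members$class, ";", fixed = TRUE))))
}

#' Read a gene-set TSV (feature_id, set_name, optional class label)
#' @param path 2-3 column tab-delimited file, no header required; a header
#'   line starting with `feature_id` is tolerated.
#' @param name overrides the set name (defaults to the file's `set_name`).
#' @return a [gene_set()].
#' @export
read_geneset <- function(path, name = NULL) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (identical(df[1, 1], "feature_id")) df <- df[-1, , drop = FALSE]
  if (ncol(df) == 2L) df$V3 <- df$V2
  names(df)[1:3] <- c("feature_id", "set_name", "class")
  gene_set(name %||% df$set_name[1],
           data.frame(feature_id = df$feature_id, class = df$class,
                      stringsAsFactors = FALSE))
}

#' Write a gene set as a 3-column TSV
#' @param set a [gene_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_geneset <- function(set, path) {
  utils::write.table(
    data.frame(feature_id = set$members$feature_id, set_name = set$name,
               class = set$members$class),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a feature-to-lineage map (2-column TSV)
#' @param path tab-delimited file: feature ID, lineage text.
#' @return named character vector (names = feature IDs).
#' @export
read_lineage_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  stats::setNames(as.character(df[[2L]]), df[[1L]])
}

#' Write a lineage map
#' @param map named character vector as returned by [read_lineage_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lineage_map <- function(map, path) {
  utils::write.table(data.frame(names(map), unname(map)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ASV table (asv_id, read_count, NSTI)
#' @param path 3-column tab-delimited file; header tolerated.
#' @return data frame with columns `asv_id`, `read_count`, `nsti`.
#' @export
read_asv_table <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (is.na(suppressWarnings(as.numeric(df[1, 2])))) df <- df[-1, , drop = FALSE]
  data.frame(asv_id = as.character(df[[1L]]),
             read_count = as.numeric(df[[2L]]),
             nsti = as.numeric(df[[3L]]), stringsAsFactors = FALSE)
}

#' Read a genus-by-sample relative-abundance table
#' @param path tab-delimited file, genus rows, sample columns, header row.
#' @return numeric matrix (genus x sample) of proportions.
#' @export
read_genus_abundance <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  as.matrix(df)
}

#' Write a genus-by-sample relative-abundance table
#' @param abund numeric matrix, genus rows, sample columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genus_abundance <- function(abund, path) {
  utils::write.table(cbind(genus = rownames(abund), as.data.frame(abund)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
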