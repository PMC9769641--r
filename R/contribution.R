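#' Genera exceeding a relative-abundance threshold
#'
#' Selects the genera whose 16S relative abundance strictly exceeds the
#' threshold in at least one sample (default 5%), ordered by their maximum
#' abundance, descending. These "abundant" genera are the candidates for the
#' taxon-specific contribution analysis.
#'
#' @param abund numeric matrix, genus rows, sample columns, proportions in
#'   `[0, 1]`.
#' @param threshold strict lower bound on relative abundance, in `(0, 1)`.
#' @return character vector of selected genus names (possibly empty).
#' @export
abundant_genera <- function(abund, threshold = 0.05) {
  .assert_scalar_number(threshold, "threshold", lower = 0, upper = 1)
  if (threshold == 0 || threshold == 1)
    stop("'threshold' must be strictly inside (0, 1)", call. = FALSE)
  if (is.null(dim(abund)) || nrow(abund) == 0L) return(character(0))
  mx <- apply(abund, 1L, max)
  sel <- mx > threshold
  names(sort(mx[sel], decreasing = TRUE))
}

#' Genus-level contribution to the KO repertoire
#'
#' From a taxon-stratified functional profile, quantifies what share of the
#' detected feature repertoire each genus accounts for in each sample:
#' `sum(genus-specific KOs) / sum(all KOs)`, where both sums count
#' *distinct* feature identifiers (an abundance-weighted variant is
#' available via `weighted = TRUE`). A feature is genus-specific in a sample
#' when any stratified row attributes positive abundance to that genus; the
#' denominator is every feature with positive unstratified abundance.
#' Features stratified only to `unclassified` count in the denominator but
#' in no genus's numerator. The combined fraction counts features attributed
#' to at least one *selected* genus, so overlapping attributions are not
#' double counted.
#'
#' @param profile a [functional_profile()] carrying stratified rows.
#' @param genera character vector of genus names (a `g__` prefix is
#'   stripped; matching is case-sensitive thereafter), e.g. from
#'   [abundant_genera()].
#' @param weighted use abundance sums instead of distinct-feature counts.
#' @return list of class `contribution_report`: `per_genus` (data frame:
#'   sample, genus, n_features, fraction) and `per_sample` (data frame:
#'   sample, total_features, combined_features, combined_fraction).
#' @export
genus_contribution <- function(profile, genera, weighted = FALSE) {
  genera <- sub("^g__", "", genera)
  samples <- profile$sample_ids
  st <- profile$stratified
  if (is.null(st) || nrow(st) == 0L) {
    warning("profile has no stratified rows: all genus fractions are 0")
    st <- data.frame(feature = character(0), genus = character(0),
                     species = character(0))
    for (s in samples) st[[s]] <- numeric(0)
  }
  missing <- setdiff(genera, unique(st$genus))
  if (length(missing))
    message("genus(es) absent from the stratified vocabulary (reported 0): ",
            paste(missing, collapse = ", "))

  per_genus <- list(); per_sample <- list()
  for (s in samples) {
    ab <- profile$abundance[, s]
    if (weighted) {
      total <- sum(ab)
      g_val <- vapply(genera, function(g)
        sum(st[st$genus == g, s]), numeric(1))
      sel <- st$genus %in% genera
      combined <- sum(st[sel, s])
      n_comb <- combined
    } else {
      total <- sum(ab > 0)
      g_val <- vapply(genera, function(g)
        length(unique(st$feature[st$genus == g & st[[s]] > 0])), numeric(1))
      comb_feats <- unique(st$feature[st$genus %in% genera & st[[s]] > 0])
      n_comb <- length(comb_feats)
      combined <- n_comb
    }
    frac <- if (total > 0) g_val / total else rep(0, length(genera))
    per_genus[[s]] <- data.frame(sample = s, genus = genera,
                                 n_features = unname(g_val),
                                 fraction = unname(frac),
                                 stringsAsFactors = FALSE, row.names = NULL)
    per_sample[[s]] <- data.frame(
      sample = s, total_features = total, combined_features = n_comb,
      combined_fraction = if (total > 0) combined / total else 0,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  structure(list(per_genus = do.call(rbind, per_genus),
                 per_sample = do.call(rbind, per_sample)),
            class = "contribution_report")
}

#' @export
print.contribution_report <- function(x, ...) {
  rng <- range(x$per_sample$combined_fraction)
  cat(sprintf(paste0("<contribution_report> %d samples, %d genera; combined",
                     " contribution %.1f%% to %.1f%% (mean %.1f%%)\n"),
              nrow(x$per_sample), length(unique(x$per_genus$genus)),
              100 * rng[1], 100 * rng[2],
              100 * mean(x$per_sample$combined_fraction)))
  invisible(x)
}
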