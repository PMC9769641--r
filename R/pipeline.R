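.id_pattern <- function(level) {
  switch(level,
         KO = "^K\\d{5}$",
         EC = "^\\d+\\.[0-9-]+\\.[0-9-]+\\.[0-9n-]+$",
         pathway = NULL)
}

#' Validate pipeline inputs before running
#'
#' Non-destructive checks on a set of profiles and companion inputs:
#' paired-sample alignment (naming the unpaired samples that a merge would
#' drop), feature-ID syntax against the declared functional level, and
#' lineage-map coverage of the sequenced features when prokaryote filtering
#' is requested. Warnings are advisory; `error` rows would abort a run.
#'
#' @param profiles list of [functional_profile()] objects.
#' @param lineage_map optional named lineage vector.
#' @param require_lineage is prokaryote filtering requested?
#' @return data frame with columns `severity` (`"warning"`/`"error"`),
#'   `check`, `message`; zero rows when everything is clean.
#' @export
validate_inputs <- function(profiles, lineage_map = NULL,
                            require_lineage = FALSE) {
  out <- list()
  note <- function(severity, check, message)
    out[[length(out) + 1L]] <<- data.frame(severity = severity,
                                           check = check, message = message,
                                           stringsAsFactors = FALSE)
  levels <- vapply(profiles, `[[`, "", "level")
  if (length(unique(levels)) != 1L)
    note("error", "level", paste("profiles mix levels:",
                                 paste(unique(levels), collapse = ", ")))
  common <- Reduce(intersect, lapply(profiles, `[[`, "sample_ids"))
  for (p in profiles) {
    extra <- setdiff(p$sample_ids, common)
    if (length(extra))
      note("warning", "sample_pairing",
           sprintf("%s sample(s) without a complementary sample will be dropped: %s",
                   p$method_label, paste(extra, collapse = ", ")))
    pat <- .id_pattern(p$level)
    if (!is.null(pat)) {
      feats <- rownames(p$abundance)
      bad <- feats[!grepl(pat, feats)]
      # a KO identifier inside an EC table (or vice versa) signals a
      # mislabelled level
      if (length(bad))
        note("warning", "id_syntax",
             sprintf("%s/%s table: %d feature ID(s) do not look like %s IDs (e.g. %s)",
                     p$method_label, p$level, length(bad), p$level, bad[1]))
    }
  }
  if (require_lineage) {
    if (is.null(lineage_map)) {
      note("error", "lineage_map",
           "prokaryote filtering requested but no lineage map supplied")
    } else {
      methods <- vapply(profiles, `[[`, "", "method_label")
      seq_feats <- unique(unlist(lapply(profiles[methods != "simMG"],
                                        function(p) rownames(p$abundance))))
      misses <- setdiff(seq_feats, names(lineage_map))
      if (length(misses))
        note("warning", "lineage_coverage",
             sprintf("%d feature(s) missing from the lineage map (will be 'unknown')",
                     length(misses)))
    }
  }
  if (length(out) == 0L)
    return(data.frame(severity = character(0), check = character(0),
                      message = character(0)))
  do.call(rbind, out)
}

#' Run the full concordance analysis
#'
#' Executes the whole comparative workflow on a study: align the three
#' profiles, compute per-sample repertoire sizes and their pairwise
#' Wilcoxon comparisons, decompose the presence sets into the 7 overlap
#' regions and derive percent similarities, apply the prokaryote filter and
#' repeat (reporting the per-comparison similarity change), run the
#' NSTI discard rule on the companion ASV table, cross-reference any
#' level-matching curated gene sets, compute Jaccard distances with PCoA
#' and PERMANOVA across the pooled sample-by-method points, and quantify
#' genus contributions from the stratified metagenome rows. Identical
#' study + parameters + seed give an identical bundle.
#'
#' @param study a [generate_study()] result, or any list with the same
#'   shape (`profiles`, and optionally `lineage_map`, `asv_table`,
#'   `genus_abundance`).
#' @param genesets optional named list of [gene_set()]s; defaults to
#'   [generate_geneset_fixtures()]. Only sets whose members match the
#'   study's level contribute (AMR for KO, CAZy for EC, SCFA for pathway).
#' @param nsti_cutoff NSTI discard cutoff (default 2).
#' @param prevalence_threshold majority-prevalence threshold (default 5).
#' @param genus_threshold relative-abundance cutoff for abundant genera
#'   (default 0.05).
#' @param n_permutations PERMANOVA permutations (default 999).
#' @param seed single seed governing every stochastic stage.
#' @param keep_unknown passed to [filter_prokaryotic()].
#' @param per_sample_similarity,pairwise_universe passed to
#'   [similarity_summary()].
#' @param output_dir if non-NULL, the bundle is also written there via
#'   [write_bundle()].
#' @return a list of class `simmg_bundle` with the per-stage results and a
#'   run `manifest`.
#' @export
run_pipeline <- function(study, genesets = generate_geneset_fixtures(),
                         nsti_cutoff = 2, prevalence_threshold = 5,
                         genus_threshold = 0.05, n_permutations = 999,
                         seed = 1L, keep_unknown = FALSE,
                         per_sample_similarity = FALSE,
                         pairwise_universe = "pair",
                         output_dir = NULL) {
  stage <- "align"
  result <- tryCatch({
    merged <- merge_profiles(study$profiles)
    level <- merged[[1L]]$level

    stage <- "counts"
    presence_total <- lapply(merged, binarize)
    counts <- sapply(presence_total, colSums)

    stage <- "set_comparison_total"
    decomp_total <- decompose_sets(presence_total$MG, presence_total$MT,
                                   presence_total$simMG)
    sim_total <- similarity_summary(decomp_total,
                                    per_sample = per_sample_similarity,
                                    universe = pairwise_universe)

    stage <- "prokaryote_filter"
    filt <- filter_prokaryotic(merged, study$lineage_map %||% character(),
                               keep_unknown = keep_unknown)
    presence_prok <- lapply(filt$profiles, binarize)
    counts_prok <- sapply(presence_prok, colSums)
    decomp_prok <- decompose_sets(presence_prok$MG, presence_prok$MT,
                                  presence_prok$simMG)
    sim_prok <- similarity_summary(decomp_prok,
                                   per_sample = per_sample_similarity,
                                   universe = pairwise_universe)
    deltas <- similarity_change(sim_total, sim_prok)

    stage <- "nsti_filter"
    nsti <- if (!is.null(study$asv_table))
      filter_by_nsti(study$asv_table, cutoff = nsti_cutoff)

    stage <- "gene_sets"
    set_for_level <- list(KO = "amr", EC = "cazy", pathway = "scfa")[[level]]
    geneset_results <- list()
    if (!is.null(genesets) && set_for_level %in% names(genesets)) {
      set <- genesets[[set_for_level]]
      tab <- prevalence(presence_total, set)
      geneset_results[[set$name]] <- list(
        prevalence = tab,
        majority = majority_filter(tab, threshold = prevalence_threshold))
      if (level == "pathway")
        geneset_results[[set$name]]$scfa <-
          scfa_presence(presence_total, set)
    }

    stage <- "ordination"
    d <- jaccard_distances(presence_total)
    ord <- pcoa_ordination(d)
    perm <- permanova(d, attr(d, "groups"),
                      n_permutations = n_permutations, seed = seed)

    stage <- "wilcoxon"
    pairs <- list(c("simMG", "MG"), c("simMG", "MT"), c("MG", "MT"))
    wilcox <- do.call(rbind, lapply(pairs, function(pr) {
      scopes <- list(total = counts, prok_only = counts_prok)
      do.call(rbind, lapply(names(scopes), function(sc) {
        w <- wilcoxon_rank_sum(scopes[[sc]][, pr[1]], scopes[[sc]][, pr[2]])
        data.frame(comparison = paste(pr, collapse = ":"), scope = sc,
                   statistic = w$statistic, p_value = w$p_value,
                   stringsAsFactors = FALSE)
      }))
    }))

    stage <- "contribution"
    contribution <- NULL
    selected_genera <- character(0)
    if (!is.null(study$genus_abundance) &&
        !is.null(merged$MG$stratified)) {
      selected_genera <- abundant_genera(study$genus_abundance,
                                         threshold = genus_threshold)
      contribution <- genus_contribution(merged$MG, selected_genera)
    }

    manifest <- list(
      package = "simmgeval",
      version = as.character(utils::packageVersion("simmgeval")),
      level = level, seed = seed,
      params = list(nsti_cutoff = nsti_cutoff,
                    prevalence_threshold = prevalence_threshold,
                    genus_threshold = genus_threshold,
                    n_permutations = n_permutations,
                    keep_unknown = keep_unknown,
                    per_sample_similarity = per_sample_similarity,
                    pairwise_universe = pairwise_universe),
      n_samples = nrow(counts))

    structure(list(level = level, counts = counts, counts_prok = counts_prok,
                   decomposition_total = decomp_total,
                   decomposition_prok = decomp_prok,
                   similarity_total = sim_total, similarity_prok = sim_prok,
                   similarity_change = deltas, filter_audit = filt$audit,
                   nsti = nsti, gene_sets = geneset_results,
                   distances = d, ordination = ord, permanova = perm,
                   wilcoxon = wilcox, selected_genera = selected_genera,
                   contribution = contribution, manifest = manifest),
              class = "simmg_bundle")
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  if (!is.null(output_dir)) write_bundle(result, output_dir)
  result
}

#' @export
print.simmg_bundle <- function(x, ...) {
  cat(sprintf("<simmg_bundle> level %s, %d samples\n", x$level,
              x$manifest$n_samples))
  cat("  percent similarity (total | prokaryote-only | delta):\n")
  for (cmp in names(x$similarity_total))
    cat(sprintf("    %-13s %6.2f | %6.2f | %+5.2f\n", cmp,
                x$similarity_total[cmp], x$similarity_prok[cmp],
                x$similarity_change[cmp]))
  cat(sprintf("  PERMANOVA: pseudo-F = %.3f, R2 = %.4f, p = %.4g\n",
              x$permanova$pseudo_F, x$permanova$r_squared,
              x$permanova$p_value))
  invisible(x)
}

.write_tsv <- function(df, path)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)

#' Write a result bundle as TSV tables plus a JSON manifest
#'
#' Exports every table of a [run_pipeline()] bundle under `dir`. On any
#' write failure the partially written directory content from this call is
#' removed before the error propagates.
#'
#' @param bundle a `simmg_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  put <- function(df, name) {
    path <- file.path(dir, name)
    .write_tsv(df, path)
    written <<- c(written, path)
  }
  tryCatch({
    put(data.frame(sample = rownames(bundle$counts), bundle$counts,
                   check.names = FALSE), "feature_counts_total.tsv")
    put(data.frame(sample = rownames(bundle$counts_prok), bundle$counts_prok,
                   check.names = FALSE), "feature_counts_prok.tsv")
    for (sc in c("total", "prok")) {
      dc <- bundle[[paste0("decomposition_", sc)]]
      put(data.frame(region = region_names(), dc$per_sample,
                     averaged = dc$averaged, check.names = FALSE),
          sprintf("decomposition_%s.tsv", sc))
    }
    put(data.frame(comparison = names(bundle$similarity_total),
                   total = unname(bundle$similarity_total),
                   prok_only = unname(bundle$similarity_prok),
                   delta = unname(bundle$similarity_change)),
        "similarity_summary.tsv")
    put(bundle$filter_audit, "prokaryote_filter_audit.tsv")
    if (!is.null(bundle$nsti))
      put(data.frame(n_retained = nrow(bundle$nsti$retained),
                     n_discarded = bundle$nsti$n_discarded,
                     asv_fraction_discarded =
                       bundle$nsti$asv_fraction_discarded,
                     read_fraction_discarded =
                       bundle$nsti$read_fraction_discarded),
          "nsti_filter.tsv")
    for (nm in names(bundle$gene_sets)) {
      gs <- bundle$gene_sets[[nm]]
      put(data.frame(feature_id = rownames(gs$prevalence),
                     class = attr(gs$prevalence, "classes"),
                     gs$prevalence, check.names = FALSE),
          sprintf("geneset_%s_prevalence.tsv", nm))
      if (!is.null(gs$scfa))
        put(gs$scfa$rollup, sprintf("geneset_%s_product_rollup.tsv", nm))
    }
    dm <- as.matrix(bundle$distances)
    put(data.frame(point = rownames(dm), dm, check.names = FALSE),
        "jaccard_distances.tsv")
    put(data.frame(point = rownames(bundle$ordination$coordinates),
                   bundle$ordination$coordinates, check.names = FALSE),
        "pcoa_coordinates.tsv")
    put(data.frame(pseudo_F = bundle$permanova$pseudo_F,
                   r_squared = bundle$permanova$r_squared,
                   p_value = bundle$permanova$p_value,
                   n_permutations = bundle$permanova$n_permutations,
                   seed = bundle$permanova$seed %||% NA),
        "permanova.tsv")
    put(bundle$wilcoxon, "wilcoxon_tests.tsv")
    if (!is.null(bundle$contribution)) {
      put(bundle$contribution$per_genus, "contribution_per_genus.tsv")
      put(bundle$contribution$per_sample, "contribution_per_sample.tsv")
    }
    jsonlite::write_json(bundle$manifest,
                         file.path(dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }, error = function(e) {
    unlink(c(written, file.path(dir, "run_manifest.json")))
    stop("write_bundle failed: ", conditionMessage(e), call. = FALSE)
  })
  invisible(dir)
}
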