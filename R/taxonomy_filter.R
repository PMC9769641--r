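.prok_tokens <- c("Bacteria", "Archaea")
.nonprok_tokens <- c("Viruses", "Viroids", "Riboviria", "Eukaryota",
                     "Viridiplantae", "Metazoa", "Fungi")

#' Classify lineage text as prokaryotic or not
#'
#' A lineage string is called `prokaryotic` iff it contains the rank token
#' `Bacteria` or `Archaea` (case-sensitive whole-token match). The rule is
#' deliberately liberal: text naming both prokaryotic and eukaryotic or viral
#' taxa is still prokaryotic, because a feature found in both domains is
#' retained with the prokaryote-only data. Text with recognized
#' eukaryotic/viral tokens only is `nonprokaryotic`; text with no recognized
#' rank token at all is `unknown`.
#'
#' Case sensitivity is intentional: it matches capitalized rank names while
#' passing over free text such as "bacterial host"; the residual risk of a
#' capitalized incidental mention is recorded in the filter audit.
#'
#' @param lineage_text character vector of lineage strings.
#' @return character vector over `{"prokaryotic", "nonprokaryotic", "unknown"}`.
#' @export
classify_lineage <- function(lineage_text) {
  has_any <- function(tokens, x) {
    hit <- rep(FALSE, length(x))
    for (tk in tokens)
      hit <- hit | grepl(paste0("\\b", tk, "\\b"), x, perl = TRUE)
    hit
  }
  x <- as.character(lineage_text)
  x[is.na(x)] <- ""
  out <- rep("unknown", length(x))
  out[has_any(.nonprok_tokens, x)] <- "nonprokaryotic"
  out[has_any(.prok_tokens, x)] <- "prokaryotic" # liberal rule: wins on both
  out
}

#' Extract lineage text from a saved database record
#'
#' Offline replacement for scraping pathway/protein record pages: pulls every
#' line whose label matches one of the configurable taxonomic-rank keywords
#' and concatenates the text after the label. Deterministic for fixed
#' patterns; records with no matching line yield an empty string (classified
#' `unknown` downstream).
#'
#' @param record_text character scalar, the saved textual content of a record.
#' @param rank_keywords labels whose lines carry taxonomy (defaults follow
#'   the MetaCyc/UniProt page vocabulary).
#' @return a single lineage string (possibly `""`).
#' @export
extract_lineage <- function(record_text,
                            rank_keywords = c("Superclasses",
                                              "Taxonomic Range",
                                              "Organism", "Taxonomy")) {
  stopifnot(length(record_text) == 1L)
  lines <- strsplit(record_text, "\n", fixed = TRUE)[[1L]]
  spans <- character(0)
  for (kw in rank_keywords) {
    pat <- paste0("^\\s*", kw, "\\s*:\\s*(.*)$")
    hit <- grepl(pat, lines)
    spans <- c(spans, sub(pat, "\\1", lines[hit]))
  }
  paste(spans[nzchar(spans)], collapse = "; ")
}

#' Remove non-prokaryotic features from MG and MT profiles
#'
#' Simulated metagenomes are predicted from 16S amplicons and therefore only
#' contain bacteria and archaea; a fair comparison removes eukaryotic and
#' viral features from the sequenced data. Two-step rule, in order of
#' precedence:
#'
#' 1. every MG/MT feature that also occurs in the simulated metagenome is
#'    called prokaryotic (`shared_with_simulated`), regardless of lineage;
#' 2. remaining MG/MT features are classified from the offline lineage map
#'    via [classify_lineage()].
#'
#' Non-prokaryotic features are dropped from MG and MT (including their
#' stratified rows); the simMG profile is returned unchanged. Features absent
#' from the lineage map get call `unknown`; by default these are removed too
#' (they cannot be certified prokaryotic), controllable via `keep_unknown`.
#'
#' @param profiles named list of aligned profiles as returned by
#'   [merge_profiles()] (must contain `MG`, `MT` and `simMG`).
#' @param lineage_map named character vector, feature ID -> lineage text.
#' @param keep_unknown keep features whose domain cannot be resolved?
#' @return list with `profiles` (filtered MG/MT, untouched simMG) and
#'   `audit`, a data frame (`feature_id`, `call`, `evidence`) recording every
#'   decision over the MG/MT feature universe.
#' @export
filter_prokaryotic <- function(profiles, lineage_map = character(),
                               keep_unknown = FALSE) {
  stopifnot(all(c("MG", "MT", "simMG") %in% names(profiles)))
  present <- function(p) rownames(p$abundance)[rowSums(p$abundance) > 0]
  sim_feats <- present(profiles$simMG)
  mgmt_feats <- sort(union(present(profiles$MG), present(profiles$MT)))

  call <- rep(NA_character_, length(mgmt_feats))
  evidence <- rep(NA_character_, length(mgmt_feats))
  shared <- mgmt_feats %in% sim_feats
  call[shared] <- "prokaryotic"
  evidence[shared] <- "shared_with_simulated"

  rest <- !shared
  in_map <- mgmt_feats %in% names(lineage_map)
  idx <- rest & in_map
  call[idx] <- classify_lineage(lineage_map[mgmt_feats[idx]])
  evidence[idx] <- "lineage_text"
  idx <- rest & !in_map
  call[idx] <- "unknown"
  evidence[idx] <- "unresolvable"

  audit <- data.frame(feature_id = mgmt_feats, call = call,
                      evidence = evidence, stringsAsFactors = FALSE)
  drop_calls <- if (keep_unknown) "nonprokaryotic" else
    c("nonprokaryotic", "unknown")
  drop <- audit$feature_id[audit$call %in% drop_calls]

  strip <- function(p) {
    keep <- setdiff(rownames(p$abundance), drop)
    st <- p$stratified
    if (!is.null(st)) {
      st <- st[!(st$feature %in% drop), , drop = FALSE]
      if (nrow(st) == 0L) st <- NULL
    }
    functional_profile(p$abundance[keep, , drop = FALSE], p$method_label,
                       p$level, stratified = st,
                       unmapped_mass = p$unmapped_mass)
  }
  out <- profiles
  out$MG <- strip(profiles$MG)
  out$MT <- strip(profiles$MT)
  list(profiles = out, audit = audit)
}
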