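#!/usr/bin/env Rscript
# Stage 4: beta diversity and count comparisons. Pools the 27 sample-method
# points on Jaccard distances, ordinates them with PCoA, tests the method
# effect with PERMANOVA, and compares per-sample repertoire sizes with
# Wilcoxon rank-sum tests — total data versus prokaryote-only.

suppressPackageStartupMessages(library(simmgeval))
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)

profiles <- list(
  read_profile("results/synthetic/MG_KO.tsv", "MG", "KO"),
  read_profile("results/synthetic/MT_KO.tsv", "MT", "KO"),
  read_profile("results/synthetic/simMG_KO.tsv", "simMG", "KO"))
lineage <- read_lineage_map("results/synthetic/lineage_map.tsv")
merged <- merge_profiles(profiles)

analyse <- function(presence, label) {
  d <- jaccard_distances(presence)
  ord <- pcoa_ordination(d, n_axes = 2)
  perm <- permanova(d, attr(d, "groups"), n_permutations = 999, seed = 42)
  cat(sprintf("%s data: PERMANOVA pseudo-F = %.2f, R2 = %.4f, p = %.4g\n",
              label, perm$pseudo_F, perm$r_squared, perm$p_value))
  cat(sprintf("  PCoA axes 1-2 explain %.1f%% + %.1f%% of the positive spectrum\n",
              100 * ord$proportion_explained[1],
              100 * ord$proportion_explained[2]))
  write.table(data.frame(point = rownames(ord$coordinates),
                         method = attr(d, "groups"), ord$coordinates),
              sprintf("results/tables/04_pcoa_%s.tsv", label), sep = "\t",
              quote = FALSE, row.names = FALSE)
  perm
}

pres_total <- lapply(merged, binarize)
perm_total <- analyse(pres_total, "total")
filt <- filter_prokaryotic(merged, lineage)
pres_prok <- lapply(filt$profiles, binarize)
perm_prok <- analyse(pres_prok, "prok")

counts <- sapply(pres_total, colSums)
counts_prok <- sapply(pres_prok, colSums)
pairs <- list(c("simMG", "MG"), c("simMG", "MT"), c("MG", "MT"))
rows <- list()
for (pr in pairs) for (sc in c("total", "prok_only")) {
  m <- if (sc == "total") counts else counts_prok
  w <- wilcoxon_rank_sum(m[, pr[1]], m[, pr[2]])
  rows[[length(rows) + 1]] <- data.frame(
    comparison = paste(pr, collapse = ":"), scope = sc,
    statistic = w$statistic, p_value = w$p_value)
}
wil <- do.call(rbind, rows)
write.table(wil, "results/tables/04_wilcoxon.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(scope = c("total", "prok_only"),
                       pseudo_F = c(perm_total$pseudo_F, perm_prok$pseudo_F),
                       r_squared = c(perm_total$r_squared,
                                     perm_prok$r_squared),
                       p_value = c(perm_total$p_value, perm_prok$p_value),
                       n_permutations = 999, seed = 42),
            "results/tables/04_permanova.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("\nper-sample repertoire size comparisons (Wilcoxon rank-sum):\n")
print(wil, row.names = FALSE)
cat("\nthe three methods remain separated before and after filtering,\n")
cat("mirroring the planted design: method explains most of the variance.\n")
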