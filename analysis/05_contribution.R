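#!/usr/bin/env Rscript
# Stage 5: taxon-specific contributions. Selects the genera above 5%
# relative abundance in the 16S table, then quantifies each genus's share
# of the distinct KO repertoire from the stratified metagenome rows.

suppressPackageStartupMessages(library(simmgeval))
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)

mg <- read_profile("results/synthetic/MG_KO.tsv", "MG", "KO")
ga <- read_genus_abundance("results/synthetic/genus_abundance.tsv")

selected <- abundant_genera(ga, threshold = 0.05)
cat(sprintf("genera above 5%% relative abundance in >=1 sample: %d\n",
            length(selected)))
resolved <- intersect(selected, unique(mg$stratified$genus))
cat(sprintf("of those, resolved in the stratified KO table: %d (%s)\n",
            length(resolved), paste(resolved, collapse = ", ")))

report <- suppressMessages(genus_contribution(mg, selected))
print(report)

write.table(report$per_genus, "results/tables/05_contribution_per_genus.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(report$per_sample,
            "results/tables/05_contribution_per_sample.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

rng <- range(report$per_sample$combined_fraction)
cat(sprintf("combined contribution of the selected genera: %.1f%%-%.1f%% (mean %.1f%%)\n",
            100 * rng[1], 100 * rng[2],
            100 * mean(report$per_sample$combined_fraction)))
cat("a handful of genera accounts for a large share of the repertoire,\n")
cat("as planted through the stratified-attribution fraction.\n")
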