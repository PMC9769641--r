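---
title: "Evaluating 16S-derived simulated metagenomes against shotgun multiomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating 16S-derived simulated metagenomes against shotgun multiomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simmgeval)
```

## The problem

Amplicon sequencing of the 16S rRNA gene identifies who is in a microbiome
but not what genes it carries. Tools such as PICRUSt2 bridge the gap by
matching amplicon sequence variants (ASVs) to reference genomes and
predicting a "simulated metagenome" (simMG): a table of gene families the
community should contain. How trustworthy those predictions are in
non-model hosts — wild birds, say, rather than humans or mice — is an
empirical question that must be answered by comparing predictions against
paired shotgun metagenomes (MG, the functional potential) and
metatranscriptomes (MT, the expressed functions).

`simmgeval` implements that comparison as a reusable, tested workflow over
functional profiles at three levels: KEGG orthologies (KO), enzyme
commission numbers (EC) and MetaCyc pathways. Its statistics are simple by
design — presence/absence set algebra, a Dice-type similarity, Jaccard
distances, permutation tests — because the scientific question is about
repertoire recovery, not abundance estimation.

## The comparison model

**Presence.** A feature is present in a sample iff its reported abundance
is strictly positive. Presence is the only information used downstream;
all repertoire statistics are therefore invariant to abundance scaling and
to the (tool-specific) units of the input tables.

**Set decomposition.** For each sample, the three per-method feature sets
are partitioned into the 7 exclusive regions of the three-set diagram
(three single-method regions, three pairwise-exclusive regions, the triple
intersection). Region counts are averaged across samples *first*, then
summary statistics are applied once to the averaged counts. A
per-sample-then-average variant exists behind `per_sample = TRUE` for
sensitivity analysis; the two agree closely unless presence noise is
severe.

**Percent similarity.** For a pair of methods $X\!:\!Y$ with intersection
$I = |X \cap Y|$ and disagreement $R = |X \setminus Y| + |Y \setminus X|$,

$$\%\,\text{similarity} = \frac{2I}{2I + R} \times 100,$$

identically the Sørensen–Dice coefficient. On the 7-region decomposition,
the pairwise $I$ is the exclusive-pair region *plus* the triple region:
treating the triple region as "outside the intersection" would make every
pairwise value smaller than the three-way value, which contradicts the
structure of real repertoire data where the triple region dominates. By
default the remainder is restricted to the pair's two-set universe, so a
pairwise similarity does not depend on the third method;
`universe = "all"` additionally penalizes third-method-only features, a
documented alternative reading. For the three-way comparison $I$ is the
triple region and $R$ the sum of the other six.

**Similarity change.** Filtering to prokaryote-only data changes each
similarity; the delta is reported signed, in percentage points, to two
decimals (half-up rounding, matching how such values are conventionally
printed).

## The prokaryote filter

Simulated metagenomes contain only bacteria and archaea, so a fair
comparison removes eukaryotic and viral features from the sequenced data.
Two rules, in order of precedence:

1. **Shared with the simulation.** Any MG/MT feature also present in the
   simMG table is accepted as prokaryotic outright. This shortcut encodes
   the design assumption that the simulation can only have produced
   prokaryotic content. (The source protocol can also be read as accepting
   features shared between MG and MT alone; we follow the
   shared-with-simulated reading and note the alternative here.)
2. **Lineage text.** Remaining features are classified from an offline
   feature-to-lineage map: a lineage is prokaryotic iff it contains the
   token `Bacteria` or `Archaea` (case-sensitive, whole token). The rule is
   *liberal*: text naming both domains stays prokaryotic. Tokens such as
   `Viruses`, `Eukaryota`, `Viridiplantae`, `Metazoa` and `Fungi` mark a
   feature non-prokaryotic; text with no recognized rank token is
   `unknown`.

Features with `unknown` calls are removed by default — they cannot be
certified prokaryotic — with `keep_unknown = TRUE` as the override; the
disposition is a genuine judgment call, recorded per feature in the filter
audit. Case-sensitivity is deliberate (it avoids matching phrases like
"bacterial host"), at the cost that an incidental capitalized mention
would mis-classify; the audit table makes such cases inspectable.
`extract_lineage()` provides the companion text-mining step for saved
database records (lines labelled `Superclasses`, `Taxonomic Range`,
`Organism`, `Taxonomy` by default), replacing live page retrieval with a
deterministic offline operation.

## The ASV discard rule

Predictions are unreliable for ASVs far from any sequenced genome.
`filter_by_nsti()` discards records with nearest-sequenced-taxon index
*strictly* greater than the cutoff (default 2), reporting both the ASV
fraction and the read-weighted fraction discarded. The fraction is
reported as computed, not re-rounded to match any particular printed
precision.

## Gene-set statistics

Curated repertoires are cross-referenced by presence: `prevalence()`
counts, per feature and method, the samples containing it;
`majority_filter()` applies the "at least 5 of 9 samples" rule;
`percent_more()` reports relative excess ($(a-b)/b \times 100$) and
`coverage_fraction()` reports recovery ($a/b \times 100$), both to two
decimals. The shipped fixtures (`generate_geneset_fixtures()`) carry the
curated *structure* — 16 SCFA pathways whose product labels multiply to 6
acetate / 7 butyrate / 5 lactate / 3 propionate with 5 dual-product
pathways, 162 AMR KOs over 11 antimicrobial classes, 102 CAZy
glycoside-hydrolase ECs — but the AMR and CAZy member IDs are synthetic
placeholders: the real lists are versioned database resources that users
should supply via `read_geneset()`. Only 10 of the 16 SCFA pathway IDs are
fixed by the catalog names used here; the remaining 6 are synthetic
(`SYN-SCFA-PWY-*`) and carry the products required by the multiplicities.
The per-class AMR counts follow the published per-antimicrobial breakdown
where available, adjusted so the total is the stated 162 unique KOs (the
source breakdown is internally inconsistent by a small margin); exact
membership is intentionally user-editable.

"Present" for a pathway means the profiling pipeline reported positive
abundance; pathway completeness is the upstream tool's responsibility and
is not re-derived here.

## Ordination and testing

Beta diversity pools all sample-method points on binary Jaccard distances
(`vegan::vegdist`). PCoA is classical metric scaling of the
double-centered $-D^2/2$ matrix; negative eigenvalues, common for Jaccard
matrices, are reported without Cailliez/Lingoes correction, and explained
proportions are computed on the positive spectrum. Two all-empty profiles
get distance 0 by convention, with a warning.

PERMANOVA is implemented directly from the distance matrix (Anderson's
formulation: within- and between-group sums of squared distances, no
coordinates), with
$p = (1 + \#\{F_{\text{perm}} \ge F_{\text{obs}}\})/(1 + n_{\text{perm}})$
over label permutations and a required seed for reproducibility. The
default 999 permutations support the conventional $p < 0.001$ floor. The
implementation is cross-checked in the test suite against
`vegan::adonis2` (identical pseudo-F and $R^2$ to $10^{-10}$), against
exhaustive enumeration at $n = 6$, and against a 500-replicate null
calibration of the type-I error. Note that with very strong separation the
$1/(n_{\text{perm}}+1)$ floor need not be attained exactly: permutations
that reproduce the group partition tie the observed F.

Count comparisons use the two-sided Wilcoxon rank-sum test
(`stats::wilcox.test`): exact when both groups have at most 10
observations without ties, otherwise normal approximation with tie and
continuity corrections. No multiplicity adjustment is applied across the
three pairwise comparisons by default, matching common reporting practice;
`p.adjust` can be applied downstream.

## Genus contributions

From a taxon-stratified table, a genus's contribution in a sample is the
number of *distinct* features attributed to it divided by the number of
distinct features detected — a repertoire share, not an abundance share
(an abundance-weighted variant exists behind `weighted = TRUE`; the
distinct-count reading follows the "total number of KOs detected"
phrasing of such analyses, and whether unattributed features belong in
the denominator is a documented judgment call — here they do).
Features stratified only to `unclassified` count in the denominator but in
no numerator. Candidate genera come from the companion 16S table: strictly
above 5% relative abundance in at least one sample. The combined fraction
de-duplicates features attributed to several selected genera, so it equals
the per-genus sum exactly when attributions are disjoint and is otherwise
smaller.

## What the synthetic generator emulates

`generate_study()` plants a fully known structure so that every statistic
above has a closed-form expected value:

* **Overlap structure** — each feature belongs to one of the 7 regions;
  the default counts (120, 23, 80, 60, 200, 15, 400 for MG-only through
  the triple region) qualitatively copy the averaged KO structure of a
  paired goose-microbiome comparison: triple region dominant, MG∩simMG
  second, on the order of twenty features unique to the MTs.
* **Presence noise** — each planted occurrence is dropped independently
  per feature, sample and method with probability 0.1 (default). This is
  the simplest exchangeable thinning model; it yields the closed-form
  region-transition law used by the recovery tests.
* **Contaminants** — 25 viral/eukaryotic features (default) injected into
  MG and MT only, with lineage text lacking the prokaryote tokens; the
  prokaryote filter must remove exactly these.
* **Stratification** — 60% of metagenome features (default) are attributed
  to one of nine genera; each attributed feature donates a fixed share of
  its abundance wherever present, so contribution fractions are exactly
  recoverable at zero noise.
* **Companions** — an ASV table of 1,129 variants with 71 drawing NSTI in
  (2, 8] (the study-scale composition), and a 16S genus table in which
  each of the 17 pool genera exceeds 5% in at least one sample (guaranteed
  when `2 * n_samples >= |pool|`) while three perennially rare genera
  stay below threshold.

Abundances for present cells are log-normal (meanlog 5, sdlog 1) — an
arbitrary positive scale, since everything downstream is presence-based.
Feature IDs come from synthetic namespaces (`K9xxxx`, `9.x.x.x`,
`SYN-PWY-n`) so fixtures cannot be mistaken for real catalog entries;
`seed_features` lets a caller plant real gene-set IDs, which are assigned
to regions starting from the triple intersection.

What the generator does **not** emulate: read-level sequencing error,
abundance dynamics or compositionality, correlated (phylogenetically
structured) dropout, and real lineage texts. Passing tests therefore
certify the *statistical machinery* — region algebra, filter logic,
estimator calibration — not the biological accuracy of any particular
prediction tool on real data.

## Numerical choices and problem sizes

* Half-up rounding to two decimals for reported percentages; raw values
  are retained internally.
* Strict inequalities throughout the decision rules: abundance > 0 for
  presence, NSTI > cutoff for discard, relative abundance > threshold for
  genus selection — boundary cases are tested explicitly.
* Degenerate inputs are total-function cases, not crashes: empty ASV
  tables report `NA` fractions with a warning, all-zero region counts make
  the similarity `NA` with a warning, all-identical Wilcoxon inputs give
  p = 1, all-zero distance matrices embed at the origin.
* The test suite and acceptance script size their simulations to run on a
  single CPU in minutes: 1,000 random triples for the set-algebra oracle,
  500 replicates at 999 permutations for the PERMANOVA null calibration,
  200 replicates for the noisy-recovery check. These sizes give Monte
  Carlo standard errors comfortably inside the asserted tolerances
  (e.g. ±0.01 on a 0.05 type-I rate at 500 replicates).

## Known limitations

* The lineage classifier is token-based; it does not consult a taxonomy
  database and inherits any ambiguity of the source text.
* Pathway presence is taken from the upstream profiler verbatim; no
  completeness re-scoring.
* The pairwise-similarity universe convention (third method ignored) is a
  modelling choice; both conventions are implemented, and analyses should
  state which was used.
* Contribution analysis keys on genus names only; reconciling 16S genus
  calls with shotgun taxonomy beyond name identity is out of scope.
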