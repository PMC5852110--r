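---
title: "Associating gut taxa with brain substructures through shared ontologies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Associating gut taxa with brain substructures through shared ontologies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2bsgo)
library(dplyr)
```

## The problem

A growing body of work on the microbiota-gut-brain axis suggests that gut
bacteria can influence brain physiology, but very few analyses connect
*specific taxa* to *specific brain regions* at the level of molecular
function. `t2bsgo` implements an in-silico association strategy built on a
simple idea: a taxon and a brain substructure are functionally linked when
the Gene Ontology (GO) terms over-represented among the taxon's human
protein homologs coincide with the GO terms enriched among the genes
differentially expressed in that substructure. Each shared term yields a
taxon-to-brain-substructure (T2BS) record — a (taxon, substructure, GO)
triple with its supporting genes.

The pipeline has five stages, each usable on its own:

1. **Expression filtering and differential expression** of a gene-by-sample
   brain count matrix with replicated substructures.
2. **Homology ingestion**: per-taxon protein hit tables (BLAST tabular,
   the last PSI-BLAST iteration) resolved to non-redundant human gene sets.
3. **GO enrichment** of both gene-list families by Fisher's exact test
   with Bonferroni control.
4. **Association**: intersection of the significant term sets, Sorensen-Dice
   similarity matrices, and a Pearson diagnostic against metaproteome size.
5. **Slims**: a-posteriori grouping of the shared terms by hierarchical
   clustering of shortest-path semantic distances on the GO graph.

Because the original data sources (reference metaproteomes, a donor brain
RNA-seq atlas, a protein reference database and a PSI-BLAST run over them)
are large external downloads, the package ships a seeded synthetic-data
generator that emulates all five inputs with planted associations, so every
stage — and the end-to-end recovery behaviour — is testable offline.

## Differential expression model

Counts for gene $g$ in sample $s$ are modelled as negative binomial,
$y_{gs} \sim \mathrm{NB}(\mu_{gs}, \phi_g)$ with
$\mathrm{Var}(y) = \mu + \phi\mu^2$, and a log-link GLM with one
coefficient per substructure and an offset for library size. Fitting and
testing use the quasi-likelihood machinery of edgeR (`estimateDisp`,
`glmQLFit`, `glmQLFTest`), which shrinks gene-wise quasi-dispersions and
refers the contrast statistic to an F distribution — the rigid error-rate
control that motivates this test family.

The tested contrast for substructure $k$ is the one-vs-grand-mean
comparison under a sum-to-zero view of the design,
$\beta_k - \tfrac{1}{K}\sum_j \beta_j$, i.e. "this substructure's CPM
against the mean CPM of all samples". P-values are Bonferroni-corrected
over the whole gene-by-substructure family by default (a per-substructure
family is available), and a gene is *selected* for a substructure when
$p_{adj} \le 0.05$ and $|\log_2 FC| \ge 1.5$.

Before testing, the count matrix is filtered: genes outside the annotated
universe go, genes with zero counts everywhere go, and lowly expressed
genes go by a CPM rule with two readings. The *standard* reading (default)
keeps a gene with CPM $> 0.5$ in at least `min_replicates` samples of at
least one substructure — the keep-rule documented for NB DE toolchains,
which preserves tissue-specific genes. The *literal* reading ("eliminate
genes with CPM $\le 0.5$ in at least two replicates of one substructure")
drops any gene weakly expressed anywhere; it is available as
`rule = "literal"` because the phrasing of the rule in the methodology this
package operationalises is genuinely ambiguous, and we did not want to
assert one reading silently. The two readings differ exactly on
tissue-specific genes; the default follows the toolchain convention.

CPM uses raw library sizes (column sums) — no TMM — because the intended
count input arrives pre-normalised upstream, and log-CPM for sample
distances uses a prior count of 2 to avoid logs of zero. Sample distances
follow the *leading fold change* convention: for each pair of samples, the
root-mean-square of the `n_top = 500` largest absolute log2-CPM
differences, embedded in 2-D by classical metric MDS.

## Enrichment model

For a study list $S$ drawn from a population $P$, each GO term $t$ with at
least one study-gene annotation is tested on the 2x2 table splitting
$P$ by membership in $S$ and by carrying $t$, with the two-sided Fisher's
exact test. Annotations are propagated to `is_a` ancestors before counting
by default (switchable — the counting convention of the enrichment tool
family this mirrors), the Bonferroni family is the set of terms actually
tested for that list, and only terms with $p_{adj} \le \alpha = 0.05$ are
returned. Per-term *direction* compares study and population frequencies;
underrepresented terms are discarded from taxon lists (they reflect what a
metaproteome lacks, not what it does), while substructure lists keep both
directions by default.

The population is the enclosing universe of each list: the post-filter
gene universe for substructure lists, and all annotated genes for taxon
lists. Neither choice is forced — the method we operationalise names no
population — but both are the smallest universes from which the study
lists are actually drawn.

## Semantic similarity and slims

The similarity of two GO terms is the reciprocal of the minimal number of
`is_a` edges between them, treating edges as undirected, so that sibling
terms are at finite distance through their shared parent; `sim(a, a) = 1`
(the measure's supremum) and disconnected pairs (different namespaces)
get similarity 0. An alternative directed reading — paths restricted to
ancestor lines — is exposed via `directed = TRUE`, since "minimal number
of branches" does not by itself fix the edge orientation; the undirected
reading is the default because without it sibling terms would be
infinitely far apart and slims would collapse to ancestor chains. Only
`is_a` edges enter the graph; `part_of` and `regulates` are ignored.

Slims are built by average-linkage agglomerative clustering of the
all-pairs branch-distance matrix, cut at a requested number of groups
(`n_slims = 14` by default, mirroring the slim count of the curated
analysis this replaces). Disconnected pairs receive a finite penalty
distance (graph diameter + 1) so clustering stays defined. Term ids are
sorted before clustering and dendrogram ties therefore resolve
identically for any input order; the exact membership of a manually
curated slim set is *not* reproduced — the cut parameter replaces the
manual regrouping step.

## Association statistics

For taxon set $A$ and substructure set $B$ (of GO terms, or of genes), the
Sorensen-Dice coefficient is $2|A \cap B| / (|A| + |B|)$, with the
two-empty-sets case defined as 0 to avoid 0/0. The Pearson diagnostic
correlates each taxon's metaprotein count with its matched-GO count; a
value near zero or negative indicates the association counts are not a
trivial artefact of metaproteome size. The psychobiotic report restricts
records to a configurable focus list of genera (default: the twelve
genera with reported mental-health or neurotransmitter evidence, including
the family-level label *Enterobacteriaceae* kept verbatim) and ranks the
shared terms by mention count.

## The synthetic generator

`synthetic_config()` fixes the reference study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_terms` | 300 | ontology size (one namespace, single root) |
| `n_genes` | 2000 | annotated genes |
| `n_substructures` x `replicates_per_substructure` | 6 x 4 | count-matrix design |
| `n_taxa` | 10 | genus labels |
| `n_planted` | 5 | planted (taxon, substructure, GO) triples |
| `effect_log2fc` | 3.0 | planted expression effect |
| `n_signal_genes` | 20 | dedicated genes per planted term |
| `nb_dispersion` | 0.05 | NB dispersion (Var $= \mu + \phi\mu^2$) |
| `baseline_mean` | 100 | median per-gene baseline mean |
| `annotation_mean_terms` | 3 | mean direct terms per background gene |
| `frac_silent` | 0.05 | background genes rendered near-silent (filtered by the CPM rule) |
| `hit_noise` | 0.1 | off-target homology-hit fraction |

Design choices worth knowing:

* **Branch-separated ontology.** The generated DAG grows a handful of
  top-level branches under one root, and both parents of a two-parent term
  stay inside one branch. Planted terms are leaves of *distinct* branches,
  so their ancestor sets share only the root — planted associations are
  separated functional modules, the situation the real analysis assumes
  when it interprets shared terms as specific functions. Annotation draws
  are biased toward leaves and deep terms, which yields heavy-tailed
  propagated term sizes as in real GO corpora.
* **Signal genes are annotated directly to the planted term**, so that
  recovery does not hinge on whether propagation is switched on.
* **Library sizes are jittered by +/-20%** to exercise CPM normalisation;
  with 6 substructures an effect of $\log_2 FC = 3$ in one substructure
  shifts the contrast-against-grand-mean estimate to about
  $\log_2(8/2.17) \approx 1.9$, comfortably above the 1.5 selection gate.
* **Determinism**: each generator stage derives its stream from the single
  config seed, and identical configs produce byte-identical files.

What the generator does *not* emulate: real sequence homology (hits are
drawn, not aligned), phylogenetic correlation between taxa, multi-donor
designs, batch structure, and the extreme term-size skew of the full GO.
Passing tests therefore demonstrate that the statistical machinery behaves
as specified under controlled conditions — not that any particular
biological association in external data is correct.

## Numerical choices and degenerate inputs

* Bonferroni is applied as $p_{adj} = \min(1, p \cdot m)$; monotone in $p$
  by construction.
* Fisher p-values come from `stats::fisher.test` (p-value only); the test
  suite verifies them against exhaustive hypergeometric enumeration for
  every table with population size up to 60.
* `fit_nbql` requires at least two substructures with two replicates each;
  constant-count genes yield zero fold changes and are never selected.
* Empty post-filter count matrices, studies outside their population,
  unknown term or substructure labels, and cyclic ontologies raise
  immediate errors naming the offenders; unresolvable annotation ids and
  unmapped accessions are reported, not fatal.
* Hit tables with more than 10% malformed rows are rejected; accession
  version suffixes are stripped before gene lookup (switchable).
* The e-value threshold is inclusive ($\le 0.05$) and applied once, at
  extraction; multi-iteration PSI-BLAST files are supported through an
  `# Iteration:` sentinel splitter.

## Problem sizes used by the test-suite

The acceptance-style checks run at the generator's reference conditions:
the exhaustive Fisher enumeration covers all tables with population size
up to 60; the type-I study uses 200 seeded null replicates at 300 genes
plus one 2000-gene replicate for the uniformity check; effect-size
recovery uses 20 seeds at 400 genes; and the end-to-end recovery uses 20
seeds at the full default configuration. These sizes were chosen to give
stable Monte-Carlo estimates (binomial SE below 2 percentage points on
the error-rate checks) at desk-scale runtimes.

## A small worked example

```{r example}
cfg <- synthetic_config(seed = 20180308, n_terms = 120, n_genes = 600,
                        n_substructures = 4, replicates_per_substructure = 3,
                        n_taxa = 6, n_planted = 3, n_signal_genes = 12)
study <- simulate_t2bs_study(cfg)
result <- run_t2bs_pipeline(study$ontology, study$annotations, study$counts,
                            study$samples, study$hits, study$accession_map)
result
association_recovery(result$records, study$planted,
                     taxa = names(study$hits),
                     substructures = unique(study$samples$substructure))
result$slim_summary
```

The heatmap and stacked-bar data behind the association tables are
available as tidy tibbles (`tidy(result$sd_gos)`,
`result$slim_stacked`) and as ggplot builders (`autoplot()` on the
Sorensen-Dice matrices and sample distances, `plot_slim_counts()`).

## Known limitations

* The package consumes homology hit tables; it does not run PSI-BLAST,
  and bitscore-based filtering is out of scope.
* Numerical identity with any particular enrichment tool's output is not
  a contract; the contract is the Fisher/Bonferroni specification above.
* Information-content similarity measures (Resnik, Lin) are deliberately
  not implemented; the shortest-path measure is the one this pipeline is
  defined around.
* FDR-style control is not offered as the primary correction; Bonferroni
  is the named method of the procedure this package operationalises, even
  though the stronger FWER control costs sensitivity.
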