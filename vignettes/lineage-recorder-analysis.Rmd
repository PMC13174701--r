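---
title: "Lineage-recorder analysis with lintrace: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lineage-recorder analysis with lintrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lintrace)
```

# The problem

Prime-editing lineage recorders install heritable, irreversible marks at
genomically integrated cassettes as cells divide. Reading the cassettes out
together with the transcriptome in single cells makes it possible to
reconstruct, for a whole embryo, which cells are clonally related, when
their ancestors divided, and when each lineage became committed to a fate.
`lintrace` implements the full analysis chain for such data: quality
control of the raw allele tables, character-matrix tree reconstruction,
maximum-likelihood branch-length dating, and a suite of fate-restriction
statistics. Because public recorder datasets at embryo scale are not
generally available, the package also ships a first-class synthetic-embryo
generator so that every stage can be exercised against known ground truth.

# The recorder model

The recorder consists of `n_cassettes` (default 35) integrated cassettes,
each with `sites_per_cassette` (default 3) editable sites, giving 105
independent characters per cell. Each site can acquire one of 8 predefined
lineage marks; once installed a mark never changes and is inherited by all
descendants. A character's state is therefore *unedited* (`UE`), one of the
marks (`M1`–`M8`), or *missing* (`ND`, silenced or undetected).

Editing is modelled as an independent exponential process per character:
along a branch of duration $\Delta t$ days a character that is still
unedited acquires a mark with probability $1 - e^{-r_c \Delta t}$, where
$r_c$ is the per-character rate. Rates cycle over the values
$(0.3, 0.4, 1.2) \times s$ across sites, reflecting designed kinetic
heterogeneity; the scale $s$ (`site_rate_scale`) is the single knob that
sets overall recorder speed.

# The synthetic embryo generator

`simulate_recorder_experiment()` chains four stages, all seeded from one
integer:

* **Division tree** — a pure-birth process with a piecewise-constant
  division-rate schedule. The default (0.5 divisions/day before embryonic
  day 4.5, 1.4/day after, founder seeded at E2.0, sampling at E9.5)
  reproduces the qualitative slow-then-fast growth of the early mouse
  embryo; the values are defaults, not biological claims.
* **Editing and silencing** — exponential editing as above, plus heritable
  per-cassette silencing (Poisson per cassette per day, default
  0.002/cassette/day, a placeholder in the absence of a published rate):
  a silenced cassette is missing in every descendant.
* **Fate map** — nested commitments: at each requested day one extant
  branch is chosen (optionally an exact node) and all of its sampled
  descendants receive the fate, with a per-leaf `leakage` probability of
  flipping to a sibling fate. Uncommitted leaves keep the root
  ("progenitor") label.
* **Allele table** — capture subsampling of leaves (default 50%, matching
  roughly half-of-all-cells dissociative sampling), UMI and read support
  for true alleles from shifted negative binomials whose floors (5 UMIs, 4
  reads/UMI) sit above the QC thresholds, support drawn per cassette (all
  sites of one cassette share a transcript) so true alleles respect the
  within-cassette relative filters, ambient alleles with reads-per-UMI
  ≤ 3 (below the filter floor by construction), donor–donor doublets
  formed by merging two cells' alleles under one barcode, and host cells
  that carry no cassettes but a high host-signal score.

The default `site_rate_scale = 0.06` was calibrated once so that the
fraction of branches in the *reconstructed* trees supported by at least one
edit — observed edges over observed plus hidden branches, the quantity the
collapsed multifurcating trees expose — is about 75–80%, the regime an
intermediate-kinetics recorder line operates in.

What the generator does *not* emulate: real transcriptomes (expression is
simulated separately where needed), spatial geometry (spatial positions
are modelled as heritable scalar traits), sequencing-depth variation
across captures, and cell death. Passing tests on synthetic data therefore
demonstrates correctness of the algorithms under the stated generative
model, not robustness to every artefact of real data.

# Quality control

QC follows an adaptive-threshold philosophy: wherever a data-driven cutoff
is needed, a two-component Gaussian mixture is fitted per capture and the
lower peak removed (`gmm_threshold()`). A fit is declared *degenerate* —
and no filtering is implied — when the Bayesian information criterion
prefers a single component or the component means are closer than half a
pooled standard deviation. The BIC condition is this package's design
choice: expectation–maximization splits even a unimodal sample into two
separated half-components, so a separation rule alone cannot recognize a
single-population input.

The fixed thresholds are: minimum 5,000 total UMIs per cell (a lower
floor, e.g. 100, can be passed for shallow captures), mitochondrial
fraction below 2%, alleles with at least 5 UMIs and 4 reads per UMI,
within-cell/cassette relative support of at least 25% of the maximum
(rescued at ≥ 10 reads/UMI), and a donor–donor doublet call when the
allele-conflict fraction — reads on non-dominant alleles, computed over
integrations whose background conflict is below 1% — strictly exceeds 3%.
Dominant-allele ties are broken by read count, then mark ID, so the
pipeline is deterministic. The host–host doublet rolling window is 501
cells.

# Tree reconstruction

`reconstruct_tree()` combines greedy high-confidence splits with classic
neighbor joining:

1. **Greedy partition** (`greedy_partition()`): mutations are ranked by
   prevalence; the seed's carrier set is expanded by mutations with
   Jaccard similarity > 0.9, refined to mutations present in > 90% of the
   provisional clade (missing compatible), and cells matching the refined
   set are assigned. Splits need ≥ 3 shared edits and ≥ 1% of cells;
   recursion stops at depth 3. Top-level cells matching no clade are
   reported as likely doublets, never silently dropped.
2. **Neighbor joining** (`nj_subtree()`): characters detected in > 50% of
   the clade with no mark above 95% frequency; pairwise distance is the
   fraction of co-observed characters with differing states; exact
   O(n³) NJ via `ape::nj`. Pairs with no co-observed characters get the
   matrix maximum + 1 and are flagged.
3. **Rooting** (`root_subtree()`): cells carrying the globally most
   frequent edited state act as a proxy outgroup; the tree is rooted on
   the edge whose side maximizes Jaccard overlap with that set, with
   deterministic tie-breaks (smaller side, then smallest leaf label).
4. **Assembly** (`assemble_and_split()`): one subtree per top-level clade
   under a single root; the root's children are the clone trees.

By default NJ runs across each *top-level* clade's full cell set
(`nj_scope = "top"`). The alternative, NJ only within the deepest greedy
clades with hierarchical assembly (`nj_scope = "leaf"`), is the scalable
choice for very large embryos, but flattening nested-clade residuals into
multifurcations measurably lowers triplet accuracy at desk scale
(about 0.70 versus 0.82 on 375-leaf simulations), so the exact mode is
the default.

# Ancestral states and branch lengths

`sankoff_ancestral()` reconstructs minimum-cost ancestral states under the
irreversible model: unedited→mark costs 1, mark→anything-else is
forbidden, missing leaves impose no cost, the root is forced unedited and
ties resolve toward unedited — one consistent convention that pushes edits
tipward. The implementation is verified against exhaustive minimum-cost
enumeration on all small trees.

Edges without any inferred mutation are collapsed
(`collapse_mutationless()`), producing multifurcations; a node with $k$
children implies $k - 2$ hidden (unmarked) divisions, which is how
`marked_fraction()` accounts for unresolved branches. Hidden branches are
assigned midpoints evenly spaced between the node's day and the median of
its children's days — the implied-ordering spread made concrete.

Branch lengths maximize the exponential-editing likelihood
$\sum_{\text{edited}} \log(1 - e^{-r_c t}) - \sum_{\text{survived}} r_c t$
per edge, with a pseudocount of 1 edit per edge for stability. A character
is at risk on an edge only if unedited at the parent and observed in at
least one leaf below, which is how missing data is excluded from both
terms. Two estimators are provided:

* `ml_branch_lengths()` — independent per-edge optima (safeguarded
  Newton); exposes the one-edge closed form
  $\hat t = -\ln(1 - m/S)$ used as an analytic anchor in the tests.
* `ml_node_times()` — the joint optimum over node times with the root at
  depth 0 and all leaves fixed at a common depth (coordinate ascent; the
  objective is concave in each coordinate). This is `date_tree()`'s
  default (`method = "ultrametric"`): constraining leaves to a common
  depth pools information across paths, and on 800–1,400-leaf simulations
  raises the correlation between true and inferred internal-node days from
  roughly 0.8 (free edges, single global rescaling) to 0.93–0.98.

`calibrate_times()` then applies one global scale so the tree's depth
matches the known sampling day; leaves shallower than the maximum are
reported, not stretched. Degenerate edges with no at-risk characters get a
pseudocount-based length and are flagged.

# Fate statistics

All statistics operate on a dated, possibly multifurcating tree plus
per-cell annotations:

* **Fate bias**: $1 - H(p)/H(q)$ with plug-in entropies and the root
  distribution $q$ as reference, clipped to $[0, 1]$ (a node can be more
  even than the root on categories the root lacks; entropies are computed
  on the union support). Node values expand over half-open time bins —
  a node contributes from its parent's time (inclusive) to its own
  (exclusive) — and per-bin summaries weight nodes by descendant counts.
  The permutation null redraws each node's fate counts multinomially from
  the root distribution, preserving descendant counts, with add-one
  p-values.
* **Fate-restricted clades**: two-pass selection of the highest node with
  ≥ 90% single-fate descendants, descendants excluded per fate once an
  ancestor is selected; at multifurcations where several children qualify
  jointly, the parent is selected once (`via_multifurcation`), its day
  serving as the restriction day (the most parsimonious single event).
  Single leaves are trivially pure, so reported clades need at least 2
  descendants by default.
* **Sibling outputs**: the parent's non-focal descendants (same-node
  non-focal descendants for multifurcation clades), excluding siblings
  more than 10× the focal size — the cap is exposed because the source
  analyses state only "substantially larger".
* **Ancestral linkage**: raw score = day of the deepest MRCA with the
  nearest target-category cell; background = mean raw score when the
  target label set is repositioned uniformly over all leaves (size
  preserved), 100 permutations, applied globally per permutation. This
  reading is the one that yields a nonzero-variance background for every
  source cell. Pairwise category matrices are symmetrized by averaging
  reciprocal directions.
* **Co-occurrence**: pointwise mutual information over the clade ×
  category presence matrix, with $-\infty$ for never-co-occurring pairs
  and flagged `NA` rows for absent categories.
* **Bipotency**: per restriction-day bin, the fraction of clades
  containing each of two outputs and both, against the independence
  product; empty bins are missing, not zero.
* **Motifs**: fate-distribution vectors of early, well-populated nodes
  (≥ 50 descendants) on a k-NN graph (k = 20), Leiden communities at
  resolution 0.5 with the modularity objective.
* **Scores on trees**: ancestral score imputation (descendant means),
  centered rolling-mean (window 2 bins) two-point slopes for rates of
  change, nearest-neighbor clade heritability ($R^2$ of paired values,
  path-distance neighbors, ties by node ID), transcriptional divergence
  (mean embedding distance to leaves within a lineage-distance cap of 3
  collapsed-tree edges, or a day window — both modes provided since the
  edge-to-day conversion is data-dependent), proliferation scores (close
  relatives within 24 h), and within-clade cosine similarity against a
  subtype-stratified resampling null with Benjamini–Hochberg correction.

# Gene programs

`tree_kernel()` builds a row-stochastic kernel over each cell's 5 nearest
leaves by tree distance in days with weights $e^{-d^2/\sigma^2}$,
$\sigma = 2$ days — the bandwidth is on the same day scale as the tree.
`local_autocorrelation()` computes, per gene, a correlation-like local
covariance $C = \tfrac1n \sum_i \sum_j w_{ij} z_i z_j$ on standardized
expression, with significance from cell-permutation nulls shared across
genes. Genes with $C > 0.1$ are retained; pairwise permutation Z-scores
feed `group_programs()`, which cuts an average-linkage dendrogram coarsely
and then merges greedily (always the best pair) while the merged group's
mean pairwise Z stays above the threshold — greedy-maximum merging makes
the partition order-independent on block-structured inputs. Programs need
at least 4 genes. Scoring subtracts expression-matched controls drawn from
25 mean-expression bins, excluding the program's own genes from the pools.

One deliberate substitution: the published normal-model analytic Z of the
Hotspot approach is replaced by a permutation Z with the same decision
semantics, because the closed form's derivation lives outside the scope of
this package. Consequences: the default grouping threshold of 80 matches
the published scale, which was computed on data three orders of magnitude
larger; on desk-scale data (hundreds of cells) the permutation Z spans
roughly 0–40 and a threshold near 10 separates planted programs from noise
cleanly, which is what the package's own recovery experiments use.

# Numerical choices and degenerate inputs

* Sankoff ties → unedited; dominant-allele ties → read count, then mark;
  rooting ties → smaller side, then smallest leaf label. Everything is
  reproducible under a fixed seed.
* Pairwise distances with zero co-observed characters → matrix max + 1,
  flagged.
* ML dating: per-coordinate tolerance 1e-8 (free) / 1e-6 (ultrametric),
  at most 200 sweeps; edges with no at-risk characters get
  pseudocount-based lengths and a flag; zero-depth trees refuse to
  calibrate.
* Empty captures, empty allele tables, and simulations whose founder
  never divides all return well-formed empty or single-leaf objects.

# Problem sizes used in the validation experiments

The package validates itself on simulations of 250–1,400 captured cells
with the full 105-character recorder — large enough for embryo-like clonal
structure and stable statistics, small enough that the exhaustive oracles
(exhaustive Sankoff labelings, all-pairs MRCA scans, brute-force interval
and neighbor searches) remain feasible alongside. Permutation counts
follow the source analyses (100 for fate bias and linkage; up to 1,000 for
within-clade similarity).

# Known limitations

* Exact NJ is O(n³); beyond ~20,000 cells use `nj_scope = "leaf"` or an
  external FastTree-compatible export (marks map onto 20 amino-acid
  letters, so more than 19 marks per site are unsupported there).
* Branch-length estimates inherit the molecular-clock assumption;
  per-character rates are taken as known relative values, not estimated.
* The fate-map generator plants hard commitments; gradual or reversible
  fate acquisition is outside its model.
* Clades whose stem branch carries no edit are invisible in principle to
  any character-based reconstruction; recovery guarantees apply to clades
  whose founding branch is supported by edits (the same reason the
  reconstruction treats only multi-edit splits as high-confidence).
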