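# lintrace

Analysis of prime-editing lineage recorders in developing embryos: from raw
allele tables to time-calibrated cell lineage trees and fate-restriction
statistics.

Engineered recorder cassettes accumulate irreversible lineage marks as cells
divide; reading them out by single-cell sequencing, together with each
cell's transcriptome, makes it possible to reconstruct an embryo's division
history and ask when each lineage became committed to a fate. `lintrace`
provides the complete downstream toolchain for such experiments, plus a
ground-truth simulator so every stage can be validated without access to
sequencing data.

## What the package computes

* **Synthetic embryos** (`sim_config()`, `simulate_recorder_experiment()`):
  pure-birth division trees with a slow-then-fast division schedule,
  irreversible per-site exponential editing across 35 cassettes × 3 sites
  (8 marks per site), heritable cassette silencing, planted fate
  commitments, capture subsampling, ambient alleles, doublets and host
  cells.
* **Quality control** (`filter_cells()`, `filter_alleles()`,
  `classify_cells()`): adaptive two-component Gaussian-mixture thresholds
  per capture, allele-support filters (≥ 5 UMIs, ≥ 4 reads/UMI, 25%
  relative support with a 10 reads/UMI rescue), and donor / host /
  doublet classification from LTC content, host signal and allele
  conflict (> 3% → donor–donor doublet).
* **Tree reconstruction** (`build_character_matrix()`,
  `reconstruct_tree()`): character matrices over (cassette, site) with
  a > 75% detection filter, greedy high-confidence splits (≥ 3 shared
  edits, Jaccard > 0.9, ≥ 1% of cells, depth ≤ 3), exact neighbor joining
  on a custom edit distance, character-based outgroup rooting, and clone
  splitting at the root.
* **Dating** (`date_tree()`): Sankoff ancestral states under the
  irreversible editing model, collapse of mutationless edges into
  multifurcations, maximum-likelihood branch lengths under an exponential
  editing model — relative site rates (0.3, 0.4, 1.2), pseudocount 1 —
  jointly optimized over node times, and calibration so tree depth matches
  the sampling day. Derived quantities: extant-cell curves and the percent
  of branches marked by an edit, with k − 2 hidden branches per
  k-multifurcation.
* **Fate statistics** (`fate_bias()`, `bias_permutation_test()`,
  `find_restricted_clades()`, `sibling_outputs()`, `ancestral_linkage()`,
  `pairwise_linkage()`, `pmi_cooccurrence()`, `bipotency_curves()`,
  `fate_bias_motifs()`, `impute_ancestral_scores()`, `rate_of_change()`,
  `clade_heritability()`, `transcriptional_divergence()`,
  `proliferation_score()`, `within_clade_similarity()`): the fate bias
  score 1 − H(p)/H(q) with multinomial permutation nulls, ≥ 90%-purity
  fate-restricted clades with explicit multifurcation handling, MRCA-based
  ancestral linkage against permuted backgrounds, PMI co-occurrence,
  bipotency versus independence, and tree-based score analyses.
* **Gene programs** (`tree_kernel()`, `local_autocorrelation()`,
  `group_programs()`, `score_programs()`): lineage-kernel local
  autocorrelation (5 neighbors, σ = 2 days), permutation Z-scores,
  agglomerative program grouping and bin-matched program scoring.

## Worked example

Simulate an embryo sampled at E8.0, run QC, reconstruct and date its
lineage trees:

```r
library(lintrace)

cfg <- sim_config(seed = 42, sampling_day = 8.0)
sim <- simulate_recorder_experiment(cfg)
nrow(sim$reads$qc)
#> [1] 590                                  # captured barcodes

tab    <- filter_alleles(sim$reads$allele_table)
labels <- classify_cells(tab, sim$reads$qc)
table(labels$label)
#>               donor donor_donor_doublet                host
#>                 436                  15                 139

donors <- labels$cell_id[labels$label == "donor"]
M <- build_character_matrix(tab[tab$cell_id %in% donors, ],
                            sprintf("BC%02d", 1:35))
dim(M)
#> [1] 435 105                              # cells x characters

rec <- reconstruct_tree(M)
length(rec$clones)
#> [1] 3                                    # independently seeded clones

dt <- date_tree(rec$embryo, M, sampling_day = 8.0, origin_day = 2.0)
marked_fraction(dt$tree)$overall
#> [1] 0.801                                # ~80% of branches carry an edit

extant_cells(dt$tree, c(4, 5, 6, 7, 8))
#> [1]   3   3  23  86 433                  # inferred extant cells per day
```

The 590 barcodes split into donor singlets (used for trees), flagged
doublets, and host cells; 435 donors pass the 75% cassette-detection
filter; the dated tree resolves ~80% of divisions with an edit, and the
extant-cell curve recovers the embryo's exponential growth. Fate
statistics run on the dated tree plus any per-cell annotation, e.g.
`find_restricted_clades(dt$tree, labels_by_cell)`.

A thin command-line wrapper over the same functions is installed at
`inst/cli/lintrace.R` with `simulate`, `qc`, `reconstruct` and `date`
subcommands.

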