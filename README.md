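# rnacoloc

Object-based RNA co-localization, pulldown enrichment, and gene-locus
apposition analysis.

## The problem

Do distinct mRNAs travel together? Multi-transcript RNP granules
("transperons") are probed with three kinds of measurements, and this
package implements the quantitative side of each for anyone analyzing
or simulating such experiments:

* **Two-channel smFISH co-localization.** Single mRNAs appear as
  diffraction-limited spots. After spot detection and assignment to
  cells, co-localization is scored per cell as a distance-gated optimal
  pairing between channels — a linear assignment problem solved with
  the Hungarian algorithm. For reference-channel spots
  $a_i$ and partner spots $b_j$, the pairing $M$ maximizes cardinality
  and then minimizes $\sum_{(i,j)\in M}\lVert a_i-b_j\rVert$ subject to
  $\lVert a_i-b_j\rVert \le r$ (gate $r$, default 0.3 µm); the per-cell
  statistic is $|M|/n_\mathrm{ref}$, summarized as mean ± SEM across
  cells with a nuclear/cytoplasmic split.
* **Pulldown (RaPID-style) enrichment.** Genes enriched in an
  aptamer-tagged pulldown versus control are scored with a
  fixed-dispersion negative-binomial exact test
  (variance $=\mu+\phi\mu^2$, default $\phi = 0.1$), BH FDR, and the
  "at least fourfold, FDR < 0.001" filter; heatmap values are
  `log2(TPM+1)` minus the control.
* **Locus apposition.** Pairs of chromosomally tagged loci (lacO/tetO
  arrays) are classified per nucleus as co-localized (fully overlapping
  signals), adjacent (partially overlapping), or not co-localized,
  using intersection-over-smaller-signal.

Every stage is backed by a ground-truthed synthetic-data generator
(spot fields with a controllable true pairing fraction, rendered 3D
stacks with PSF blur and shot noise, NB count matrices with planted
enrichment, locus-pair images with controlled overlap), so the whole
pipeline is testable without external data. See
`vignettes/rnacoloc-methods.Rmd` for the models, defaults, and
limitations.

## Worked example

```r
library(rnacoloc)

# a cohort of 50 cells, 30 spots/cell/channel, 65% true co-localization
cfg <- sim_config(n_cells = 50, spots_per_cell_mean = 30, true_rho = 0.65,
                  jitter_sigma = 0.1, rng_seed = 42)
cohort <- simulate_cohort(cfg)
coloc_cohort(cohort$fields, gate_radius = 0.3, reference = "a")$summary
#> coloc_summary: 63.4% +/- 0.5% (mean +/- SEM, n = 50 cells)
```

The estimate (63.4 %) recovers the generating fraction (ground truth
65.0 % in this draw) to within the expected bias: ~3 % of true pairs
jitter beyond the 0.3 µm gate, partially offset by chance pairings
(`chance_coloc_expectation()` quantifies the latter).

```r
# pulldown enrichment: 5 genes planted at fold 8 among 2000, 3 replicates
em <- simulate_count_matrix(2000, enriched_ids = sprintf("gene%05d", 1:5),
                            fold = 8, dispersion = 0.1, rng_seed = 42,
                            n_reps = 3)
tab <- score_enrichment(em, dispersion = 0.1)
head(tab[order(tab$fdr), ], 6)
#>           gene fold_change  p_value      fdr enriched
#> 4    gene00004      10.029 6.85e-16 1.37e-12     TRUE
#> 1    gene00001       9.637 1.57e-15 1.57e-12     TRUE
#> 3    gene00003      11.984 1.22e-14 8.13e-12     TRUE
#> 2    gene00002       7.431 7.61e-13 3.81e-10     TRUE
#> 5    gene00005       5.806 2.92e-10 1.17e-07     TRUE
#> 1222 gene01222       0.359 2.67e-04 8.90e-02    FALSE
```

Exactly the five planted genes pass the fourfold / FDR < 0.001 filter.

```r
# locus apposition: 200 nuclei with class probabilities (0.1, 0.7, 0.2)
loci <- simulate_locus_cohort(200, class_probs = c(0.1, 0.7, 0.2),
                              rng_seed = 42)
score_locus_cohort(loci)$table
#>              label percent   n
#> 1     co-localized    13.0  26
#> 2         adjacent    64.5 129
#> 3 not co-localized    22.5  45
```

The tabulated percentages recover the generating probabilities within
binomial sampling error at n = 200.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/rnacoloc", package = "rnacoloc"))')
Rscript "$CLI" end-to-end --seed 3 --out run1 --gate-um 0.3
Rscript "$CLI" enrich     --seed 2 --out run2 --dispersion 0.1
Rscript "$CLI" report     --out run1     # figures from the tables
```

Commands are driven by a JSON config (`--config`) with per-module
blocks; flags override the config. Outputs carry the hash of the run
parameters, and re-running an unchanged config + seed reproduces
byte-identical tables.

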