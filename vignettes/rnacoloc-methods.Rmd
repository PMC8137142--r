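---
title: "Models and methods behind rnacoloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rnacoloc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnacoloc)
```

# Scope

`rnacoloc` implements three quantitative procedures used to ask whether
distinct mRNAs travel together in multi-transcript RNP granules:

1. object-based two-channel **smFISH co-localization** — spot detection,
   per-cell distance-gated optimal pairing, and mean ± SEM summaries;
2. **RNA pulldown enrichment scoring** — a fixed-dispersion
   negative-binomial exact test with BH FDR control and a fold/FDR
   filter, plus the `log2(TPM+1)` control-subtracted heatmap transform;
3. **gene-locus apposition classification** — co-localized / adjacent /
   not co-localized calls for pairs of chromosomally tagged loci.

Because raw microscopy and sequencing data of this kind are rarely
released, the package ships a ground-truthed synthetic-data generator;
every claim the test suite makes is a claim about parameter recovery on
that generator, not about any particular biological dataset.

# The co-localization model

## Matching as a gated linear assignment

Within one cell, let $a_1,\dots,a_{n_A}$ and $b_1,\dots,b_{n_B}$ be spot
positions (µm) in the two channels. A pairing $M$ is admissible when
every matched pair satisfies $\lVert a_i - b_j\rVert \le r$, the gate
radius. Among admissible pairings, `match_spots()` returns the one that
first maximizes $|M|$ and then minimizes $\sum_{(i,j)\in M}
\lVert a_i-b_j \rVert$. The per-cell co-localized fraction is
$|M| / n_{\mathrm{ref}}$, with the reference channel as the denominator
("X co-localized with Y" counts the fraction of X spots with a Y
partner), and the cohort summary is the across-cell mean ± SEM. Cells
without reference spots are excluded.

The solver is a Jonker–Volgenant shortest-augmenting-path assignment
(`src/lap.cpp`, $O(n^3)$) on a padded square matrix: each spot gets a
private "unmatched" dummy slot. A subtlety worth recording: padding at
cost $= r$ (the obvious choice) does **not** yield maximum cardinality —
three pairs at distance $\approx r$ cost more than two zero-distance
pairs plus two dummies, so the min-cost solution would drop a pair. The
dummy cost is therefore $(\min(n_A, n_B) + 1)\, r$, which makes every
gained pair strictly cheaper than any total distance a
maximum-cardinality pairing can accumulate; within a fixed cardinality
all pairings carry the same number of dummies, so the distance ordering
is untouched. The test suite checks this against exhaustive enumeration
of all gated sub-assignments for up to 6 spots per channel.

## Choices the procedure description leaves open

The underlying experimental protocol does not state a gate distance, a
cost function, or a denominator convention. This package uses Euclidean
(not squared) distance, a default gate of 0.3 µm (about one PSF width;
configurable), and a user-designated reference channel. Matching is
always per cell, never across cell boundaries. Ties in the optimum are
broken deterministically by the solver's fixed scan order and the pairs
table is sorted by ascending reference index.

## Chance co-localization

Unrelated spots still pair at a rate set by the partner-spot density
$\lambda$ (spots/µm³): a reference spot has at least one background
partner within the gate with probability
$p_c = 1 - \exp(-\lambda \tfrac{4}{3}\pi r^3)$
(`chance_coloc_expectation()`). At 50 spots in a ~115 µm³ cell and
$r = 0.3$ µm this is ≈ 0.05 — not negligible, which is why the
zero-co-localization control is asserted *relative to* $p_c$ rather
than to zero.

# The synthetic spot world

`sim_config()` states the simulated world once; the defaults are the
conditions the analysis is meant to face:

* **Spot counts**: Poisson across cells with mean 50 per channel,
  matching a highly expressed heat-shock transcript (~50 spots/cell);
  lowly expressed transcripts (~7/cell) are one parameter away.
* **Pairing**: a fraction `true_rho` of channel-A spots is duplicated
  into channel B with isotropic Gaussian jitter (default σ = 0.1 µm) —
  physical localization error is frame-independent, so jitter is drawn
  in µm and only then lands on anisotropic voxels. The pair count is
  `round()`ed half-up (deterministic, testable). Remaining spots in
  both channels are uniform over the cell mask.
* **Geometry**: ellipsoidal cells (semi-axes 3.5 × 3.5 × 2.25 µm,
  ≈ 115 µm³) with a 1.2 × 1.2 × 0.9 µm nucleus, rasterized at
  0.1 × 0.1 µm pixels and 0.2 µm z-steps. The volume was fixed *a
  priori* from the chance model above: recovering `true_rho` to ±0.05
  at 50 spots/channel and a 0.3 µm gate requires an unpaired-partner
  density below ≈ 0.4 µm⁻³, i.e. a cell of at least ~115 µm³ — the
  "low background density" regime. In a smaller (25–40 µm³) yeast
  mother cell at the same counts, chance pairing alone reaches
  15–20 % and an uncorrected estimator would be visibly biased; users
  analyzing dense real data should compare their estimates against
  `chance_coloc_expectation()` at their measured densities.
* **Optics**: spots render as 3D Gaussians (PSF σ = 0.13 µm lateral,
  0.3 µm axial, a 100×/1.4 NA confocal), peak 200 photons over a
  background of 10, Poisson and/or Gaussian read noise. The integrated
  intensity of a rendered spot equals
  $A\,(2\pi)^{3/2}\sigma_z\sigma_y\sigma_x / v$ (with $v$ the voxel
  volume) within 5 % in the noise-free limit, which the suite asserts.
* **Reproducibility**: each cell consumes a private RNG stream spawned
  from the top-level seed, so results are independent of the order in
  which cells are processed.

What the generator deliberately does not emulate: optical aberrations
beyond a Gaussian PSF, camera gain/offset, chromatic shift between
channels, cell-to-cell expression heterogeneity, clustered or
ER-enriched spot placement (uniform placement is the stated default; a
`nuclear_fraction` override exists but claims no fidelity to any
measured compartment split). A green recovery test therefore
establishes that the estimator is unbiased *under these assumptions*,
not that any particular biological number is correct.

# Spot detection

Candidates are local maxima of a difference-of-Gaussians band-pass
(σ and 1.6σ, separable filtering with replicate borders), thresholded
at `median + 5 × MAD` of the response (robust to the mostly-background
voxel population), and separated greedily by at least `min_separation`
(default 0.3 µm). Each candidate is refined by least-squares fitting of
a 3D Gaussian (background, amplitude, centre, per-axis σ) in a 7³-voxel
window; the fit quality is a clamped $R^2$ and fits below 0.5 are
dropped. Positions are voxel-centre micrometres with 0-based indices
and z listed first, so array, table, and physical coordinates
round-trip exactly.

On the stated world (SNR ≈ 14, separation ≥ 3 PSF widths) the suite
measures recall and precision of 1.0 and a noise-free localization RMS
around 3 × 10⁻⁴ voxel; the acceptance bands (≥ 0.95, < 0.2 voxel) leave
room for harder regimes, not for this one.

Compartment calls use the nucleus mask with an inclusive convention:
a spot whose voxel is on the mask (boundary included) is nuclear.

# Enrichment scoring

Two deliberately separate paths mirror the two computations done on
pulldown sequencing data:

* the **heatmap path**: `log2(TPM + 1)` per sample minus the control's
  (controls averaged on the log scale); identically zero when sample
  equals control, antisymmetric under swapping sample and control;
* the **differential path**: a from-scratch exact test on counts with
  the dispersion fixed at φ = 0.1 (variance $= \mu + \phi\mu^2$).

For counts $A$, $B$ scaled to a common effective library size, the test
conditions on $s = A + B$: under the null the conditional law of $A$ is
a Pólya (beta-binomial-type) distribution free of the unknown mean, and
the two-sided p-value sums all splits at most as probable as the one
observed. With φ = 0 this collapses to the conditional binomial
(Poisson) exact test. With $n$ replicate libraries per group, group
sums are NB with dispersion φ/n, so the conditional law uses size
$n/\phi$ per group — replication enters the test exactly as in the
standard count-based DE tools. During development the implementation
was checked against the installed edgeR: single-library p-values agree
to machine precision and replicated designs to ~1e-5 (their
quantile-adjustment rounding); the shipped tests use an independent
log-gamma closed-form oracle instead, to 1e-10.

**A power fact worth knowing**: with *single* libraries and φ = 0.1,
the p-value for a fold-8 change plateaus near 2 × 10⁻⁵ as counts grow —
the fixed biological CV ($\sqrt{0.1} \approx 0.32$) dominates, and no
sequencing depth helps. An FDR < 0.001 filter over 10,000 genes
(BH threshold ≈ 10⁻⁵) is then unreachable by construction. The
acceptance power scenario therefore runs the three-biological-replicate
design that such studies actually use, where recovery of fold-8 genes
is ≈ 96–99 % with no false positives; the type-I rate under the global
null is ≈ 0.04 in either design.

Fold changes use size-factor-normalized counts with a prior count of
0.5 per group (never the +1 pseudo-count of the log path); the filter
keeps genes with fold ≥ 4 (inclusive — "at least fourfold") and
FDR < 0.001 (strict). The FDR procedure is Benjamini–Hochberg; the
upstream description says only "FDR", so the choice is flagged here.

# Locus apposition

Each channel of a nucleus image is segmented by threshold and the
brightest connected component is kept (one tagged locus expected per
channel). The overlap statistic is intersection area over the *smaller*
signal's area — the description says only "overlapping", and the
smaller-denominator convention makes the statistic symmetric and
insensitive to unequal blob sizes. Labels: overlap ≥ 0.9 →
co-localized; zero intersection → not co-localized; otherwise adjacent.
The 0.9 default (rather than a literal 1.0 for "fully overlapping")
absorbs single-pixel rasterization effects; both thresholds are
configurable. Centroid distance is reported as auxiliary output only.
Cells where either tag is undetectable are excluded and counted
(`n_excluded`) rather than being called "not co-localized" — with one
signal missing, apposition is simply unobservable.

The cohort simulator draws classes from stated probabilities and
realizes them as equal-radius disks whose centre distance is solved in
closed form from the circle-lens area: co-localized → overlap 1,
adjacent → overlap uniform in 0.10–0.25 (the reported partial-overlap
band), not co-localized → disjoint. Rasterized overlap lands within one
pixel's area (±0.02 at radius 10 px) of the target.

# Orchestration and reproducibility

`run_pipeline()` executes simulate → match / enrich / loci from a
single JSON configuration (the environment provides no YAML parser, so
the config format is JSON with the same field names); the CLI in
`inst/cli/rnacoloc` exposes the same commands with flag overrides.
Every output table carries the MD5 hash of the run parameters
(excluding the output path), and re-running an unchanged configuration
and seed reproduces byte-identical tables — asserted in the acceptance
suite. Figures (PNG) are exempt from byte-identity; their underlying
tables are not.

# Known limitations

* Images are exchanged as in-memory arrays / CSV spot tables, not TIFF:
  no TIFF codec is available in the target environment, and
  hand-rolling one was out of scope.
* The detector does not decompose dense spot clusters or transcription
  sites; recall guarantees hold at ≥ 3 PSF-width separations.
* The exact test reimplements the fixed-dispersion computation but not
  the quantile-adjusted ("qCML") pseudo-count machinery of edgeR;
  p-values can differ in the 5th decimal for unequal library sizes.
* `chance_coloc_expectation()` assumes spatially uniform background
  spots; clustered backgrounds would need an empirical
  (scrambled-channel) control instead.
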