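---
title: "Quantifying the living skin microbiome: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the living skin microbiome: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`liveabund` estimates absolute live and total cell densities of microbial
taxa on the skin by fusing three measurements made on paired swabs — one
untreated ("raw"), one treated with propidium monoazide (PMA) to deplete
relic (dead-cell and extracellular) DNA: bead-calibrated flow cytometry of
both aliquots, genome-length-normalized shotgun metagenomics of both
aliquots, and the per-site swabbed area. This vignette explains the
underlying measurement model, the synthetic cohort the package uses to
validate itself, and the design decisions taken where the methodology is
genuinely open.

## The measurement model

### Flow cytometry

An aliquot of volume $V$ (µL) is stained with a DNA dye, spiked with $B$
counting beads, and acquired. Events are gated in sequence:

1. **DNA-positive**: $FL1_A \ge$ `fl1_min` and $FL4_A \le$ `fl4_max`
   (stain-specific emission high, background emission low);
2. **singlets**: $|FL1_A - s \cdot FL1_H| \le t \cdot FL1_A$ — aggregates
   carry roughly twice the integrated area per pulse height and fall off
   the linear band of slope $s$;
3. **size**: $FSC_A \le$ `fsc_max`, $BSC_A \le$ `bsc_max` — removes large
   (e.g. residual human-cell) events.

Beads are counted in a high-$FL1 \times$ high-$FL4$ rectangle that the
configuration is required to keep disjoint from the cell quadrant. With
$c$ gated cells and $b$ gated beads, the concentration is
$\hat{C} = (c/b)(B/V)$ cells/µL and the areal density
$\hat{D} = \hat{C} \cdot V \cdot k / A$ cells/cm², where $A$ is the
swabbed area and $k \ge 1$ (`extract_scale`) maps the run aliquot back to
the whole swab extract. The acquisition fraction (the portion of the
aliquot actually read out) cancels from the bead ratio, which is the point
of spiking beads. Both $c$ and $b$ are Poisson, so
$\mathrm{SE}(\hat{D})/D \approx \sqrt{1/\mathbb{E}c + 1/\mathbb{E}b}$;
the test suite holds estimates to 3 of these standard errors.

A sample with no detected beads cannot be quantified; the package flags it
(`no_beads`) rather than reporting zero, and downstream paired analyses
drop the affected volunteer-site unit with a manifest entry.

The **per-sample live fraction** is $100 \times \hat{D}_{pma} /
\hat{D}_{raw}$ percent. It is deliberately *not* clamped at 100: counting
noise can push it above, and clamping would bias per-site medians.

### Abundance and fusion

Counts $n_{is}$ of taxon $i$ in sample $s$ with genome length $g_i$ are
normalized as

$$\mathrm{RPKM}_{is} = \frac{n_{is} \cdot 10^9}{g_i \sum_j n_{js}},$$

which removes both sequencing depth and the fact that a longer genome
sheds proportionally more fragments per cell. Two filters follow: a taxon
is kept in a sample only if its genome coverage there is at least 60%
(inclusive boundary — exactly 0.60 is retained), and a taxon enters
displayed/fused panels only if its median relative abundance exceeds
0.05%. Relative abundances are re-closed after every filter.

Fusion distributes the flow-cytometry density over taxa:
$\mathrm{abs}_{is} = \mathrm{rel}_{is} \cdot \hat{D}_s$, so per-taxon
absolute abundances sum to the sample density by construction. Derived
quantities:

- per-taxon live fraction $100 \cdot \mathrm{abs}^{pma} /
  \mathrm{abs}^{raw}$, unclamped, `NA` when the total is zero;
- PMA index $\mathrm{rel}^{pma} / (\mathrm{rel}^{pma} +
  \mathrm{rel}^{raw})$, with fixed point 0.5 when treatment does not
  change a taxon's share. The orientation is chosen so that values above
  0.5 mean the taxon is *underestimated* by total-DNA sequencing. The
  complementary orientation would flip values around 0.5 but leaves the
  fixed point invariant; only the chosen orientation is emitted.
  Site-level tables compute the index from site-median relative
  abundances of the top taxa ranked by median RPKM;
- relic portion $\max(\mathrm{abs}^{raw} - \mathrm{abs}^{pma}, 0)$. The
  floor at zero is a deliberate bias–variance trade: negative relic mass
  is unphysical and would destabilize the log-ratio analysis of the relic
  composition. When a taxon passes filters in only one member of a pair,
  the missing side is treated as 0.

### Compositional statistics

Zeros in sparse low-biomass tables are treated as *unobserved*, not as
vanishing abundance. The RCLR transform logs only positive entries and
centers each sample by the mean of its observed logs; a sample with fewer
than two observed taxa has no ratio information and is dropped with a
warning. The robust Aitchison ordination completes the missing entries by
alternating truncated SVD: missing cells start at 0 (the row-centered
null), are repeatedly replaced by the rank-$r$ reconstruction, and
iteration stops when the relative Frobenius change falls below `tol`
(default 1e-7, `max_iter` 200; non-convergence is flagged, never hidden).
Sample scores are $U \Sigma$, so Euclidean score distances are the robust
Aitchison distances of the rank-reduced data. Rank 3 is the default,
consistent with common robust-Aitchison practice; the completion is exact
on complete low-rank input and the test suite verifies masked-entry
recovery (RMSE < 1e-3 on a rank-2 oracle).

PERMANOVA is the one-way, distance-based formulation: with
$SS_T = \sum_{i<j} d_{ij}^2 / n$ and
$SS_W = \sum_g \sum_{i<j \in g} d_{ij}^2 / n_g$,
$F = \frac{(SS_T - SS_W)/(k-1)}{SS_W/(n-k)}$, and
$p = (1 + \#\{F^* \ge F\})/(1 + N_{perm})$ under label permutation
(999 by default, seeded), so the smallest attainable p is
$1/(N_{perm}+1)$. Factors are tested separately (one-way), matching how
cohort metadata factors are usually reported for this design. The
implementation is cross-checked against `vegan::adonis2` in the tests.

Alpha diversity uses `vegan`: Shannon $H = -\sum p_i \ln p_i$ and Simpson
$1 - \sum p_i^2$. Because "Simpson evenness" is ambiguous in the
literature, the package emits both `simpson` ($1-\sum p_i^2$) and
`simpson_evenness` ($(1/\sum p_i^2)/S$), labeled. Correlations follow the
sparse-data convention of using jointly nonzero pairs only, and both $r$
and $r^2$ are reported since either convention appears in practice.
Dunn's post-hoc test (rank-based $z$ with tie correction) is implemented
in-package and BH-adjusted, consistent with the global FDR policy;
Levene's test uses the median-centered (Brown–Forsythe) form via `car`.

## The synthetic cohort

### What it emulates

The generator plants a known truth with the statistical structure the
analysis assumes, so that every downstream stage can be validated against
it:

- **Study design**: 12 volunteers × 6 sites (forehead, upper back =
  sebaceous; antecubital and popliteal creases = moist; forearm, abdomen
  = dry), every unit sampled in parallel as raw + PMA.
- **Biomass**: per-site log10-normal total densities whose location
  parameters follow published median total cell counts for these sites
  (3.4e4 cells/cm² forehead down to 2.5e3 popliteal crease), sd 0.55
  decades.
- **Viability**: per-unit live fractions drawn logit-normally around site
  means (0.877 sebaceous forehead … 0.063 dry forearm). The logit-normal
  keeps the per-site *median* at the configured mean, which is what the
  recovery tests measure. The default spread (0.15 logit units) is
  deliberately modest so that a 12-volunteer median is a sharp estimate
  of the site mean; real cohorts show wider interquartile ranges, which
  can be emulated by raising `live_fraction_logit_sd`.
- **Live composition**: site-preference weights perturbed per volunteer
  by a log-normal taxon-wise signature (sd 1.5), the planted
  personalization of the living community.
- **Relic composition**: one Dirichlet draw per site (concentration 200)
  around a *site-agnostic* base (the cross-microenvironment mean of the
  preference weights), shared by all volunteers. This encodes two
  modelling commitments: relic DNA is not personalized, and — being
  dominated by environmental deposition and accumulated shedding — it is
  far less site-structured than the living community.
- **Sequencing**: multinomial reads with probability ∝ cell density ×
  genome length (raw: live + relic; PMA: live only), 3e6 fragments per
  sample with an effective 200 bp of genome coverage each; a 2% read
  contamination fraction split across three flagged reagent-contaminant
  taxa; genome coverage follows the saturating Lander–Waterman form
  $1 - e^{-N L / g}$, so low-abundance assignments are removed by the
  coverage filter exactly as fragmentary alignments are in practice.
- **Cytometry events**: class-wise channel centers in arbitrary linear
  units with log-normal jitter (CV 0.15; the area/height relation jitters
  at CV/3 so true singlets stay inside the band), Poisson bead counts
  (30,000 beads spiked, 2% of the aliquot acquired → ≈ 600 bead events,
  matching the few-percent bead CVs of real counting-bead runs), plus
  debris (low FL1), doublets (area ≈ 2 × slope × height) and
  human-cell-like large events at configurable rates.

Determinism: the whole cohort is a pure function of the configuration;
per-sample event and count streams are seeded by sample index, so
regeneration is byte-identical and independent of call order.

### What it does not emulate

No read-level sequences, no alignment or classification errors (taxon
assignments are taken as correct), no PMA chemistry biases between cell
envelopes, no cytometer spillover/compensation or binary FCS encoding, no
day/batch effects. Passing the recovery tests therefore demonstrates that
the *pipeline arithmetic and inference* are correct under the stated
generative assumptions — not that those assumptions exhaust real skin
data.

### A structural property worth knowing

In this generator the volunteer signature lives only in the live
compartment, and raw samples see it diluted by the shared relic pool
(heavily, at sites where <15% of cells are alive). Consequently
PMA-treated samples cluster *more* strongly by volunteer than raw samples
do, and intra-individual distances shrink when the analysis is restricted
to the live signal. Real cohorts have shown the opposite ordering (raw
more volunteer-clustered than PMA) — a pattern that cannot arise when
relic DNA carries no volunteer signal at all, and which suggests real
relic pools retain a personal imprint even when a relic-only ordination
fails to detect one. The package takes the conservative generative
stance (relic fully shared) and verifies the contrast that follows from
it: the volunteer factor is significant on raw-sample distances (it
enters through the live share) and null on relic-only distances.
Relatedly, with a strong planted volunteer effect the PMA-sample
ordination is dominated by volunteer axes, so skin-type separation there
is established by PERMANOVA (which conditions on group labels) rather
than by unsupervised cluster-quality scores; under moderate
personalization (volunteer sd ≈ 0.5) skin types separate cleanly.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `beads_added` | 30,000 | beads | 30 µL spike of a counting-bead reagent; with 2% acquisition ≈ 600 bead events → bead CV ≈ 4% |
| `run_volume` | 250 | µL | stained aliquot volume |
| `extract_scale` | 1 | — | whole pooled extract equals the run aliquot; pooling/aliquot arithmetic is one multiplier because back-calculation conventions differ between labs |
| `acquisition_fraction` | 0.02 | — | timed-acquisition fraction; cancels from the bead ratio |
| `event_noise` | 0.15 | CV | realistic channel spread while keeping class populations inside their gates at zero noise |
| `min_coverage` | 0.60 | fraction | coverage filter, inclusive boundary |
| `min_rel` | 5e-4 | fraction | median relative-abundance threshold (0.05%) |
| `seq_depth` | 3e6 | fragments | post-filter mapped depth typical of skin shotgun runs; with 200 bp fragments the coverage filter then admits taxa down to ≈ 0.4% relative abundance |
| `rank` | 3 | — | robust-Aitchison completion rank |
| `n_permutations` | 999 | — | PERMANOVA permutations; p resolution 0.001 |
| areas | 25–50 | cm² | per-site swabbed areas are free design parameters (set by the sampling template, not the method) |

## Numerical choices and degenerate inputs

- Coverage boundary inclusive (≥ 0.60); abundance threshold strict
  (> 0.05%).
- RCLR never imputes `log 0`; zeros stay missing through ordination.
- Completion initializes missing entries at 0; observed entries are
  re-imposed every iteration (hard constraint).
- PERMANOVA on a degenerate distance matrix (no within-group variation)
  returns `NA` with a warning instead of an unbounded F.
- The distance contrast flags all-zero distance sets as `degenerate` and
  too-small pair populations as `insufficient`.
- Empty event tables gate to zero counts with an `empty` flag; zero raw
  density makes the live fraction `NA` (flagged), never `Inf`.
- Wilcoxon tests use the normal approximation (`exact = FALSE`)
  uniformly, so ties cannot silently switch the null distribution.
- Classical PCoA (eigendecomposition of the Gower-centered squared
  distance matrix) is provided as the deterministic ordination for
  relic-only views; non-metric MDS is intentionally not used because its
  stress optimization is initialization-dependent and untestable against
  fixed references.

## Problem sizes used by the validation suite

The shipped tests run the full default cohort (144 samples) for the
live-fraction and planted-contrast checks, 100 simulated aliquots for the
counting-recovery check, 1,000 label-shuffling replicates at 199
permutations (24 samples, 3 groups) for PERMANOVA calibration, and a
50 × 20 rank-2 oracle for the completion accuracy bound. These sizes give
the Monte-Carlo margins stated in each test while keeping the suite quick
to run on a laptop.

## Limitations

- Absolute abundances inherit any taxon-assignment bias of the upstream
  classifier; the package starts from count tables.
- The bead formula assumes beads and cells are acquired with equal
  probability; differential settling or clogging is not modeled.
- `extract_scale` must be supplied by the user when the run aliquot is
  not the whole extract; densities scale linearly in it.
- The gemelli-style ordination here is "low-rank completion of the RCLR
  matrix"; scores are not numerically identical to any particular
  external implementation, and only the geometry (distances, recovered
  structure) is asserted.
- PERMANOVA is one-way; crossed or nested designs are out of scope.
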