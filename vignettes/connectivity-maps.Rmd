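---
title: "Semantic connectivity maps with the Auto-Contractive Map"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic connectivity maps with the Auto-Contractive Map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(autocmap)
```

## The problem

Prenatal exposures — heavy metals and dioxin-like organics accumulating in
the placenta, maternal stress, smoking, infections — act in concert on the
epigenome of the mother–foetus dyad. A cohort that measures gene-specific
DNA methylation in several tissues together with exposure concentrations
and questionnaire classes yields a mixed-type table of a few dozen records
and a comparable number of variables. Pairwise tests on such a table are
underpowered and blind to the joint, nonlinear organisation of the system.
The Auto-Contractive Map (Auto-CM) takes the opposite route: it trains an
unsupervised network on all variables simultaneously and reads the
*learned weights* as association strengths, which a spanning-tree filter
then reduces to a legible map of the main connections.

`autocmap` implements that pipeline end to end: a validated cohort data
model, the \[0,1\] encoding, the Auto-CM itself, the translation of
weights into strengths of association (SA) and the filtered map with hub
detection, plus a seeded synthetic-cohort generator (the study data are
not publicly deposited) and an MS-HRM standard-curve module for the
upstream methylation quantification.

## Encoding mixed-type records onto [0, 1]

Each questionnaire parameter is stratified into its two classes and
binary-coded: 0 if the class is absent, 1 if present. Both outcomes are
kept as complementary nodes by default (`binary_mode = "both_levels"`),
because a map node should name a specific class ("suboptimal birth
weight", not "birth weight"); `first_level_only` halves the
dimensionality when desired.

Continuous assays (methylation %, concentrations) are min–max scaled on
their **observed** range: `x -> (x - min) / (max - min)`. A methylation
column observed from 40.7% to 76.1% therefore maps 40.7 to exactly 0 and
76.1 to exactly 1. The observed range — not the theoretical 0–100 —
defines the scale, so every node uses its full \[0,1\] span and
contributes comparable signal to the network. The per-node min/max is
recorded as provenance for back-transformation.

Constant columns carry no information and would sit as isolated
uninformative nodes; the packaged exposure set contains one (vanadium,
never detected: 0 ± 0). They are dropped with a warning by default, or
kept as a constant 0.5 node via `constant = "midpoint"`. Missing values
are rejected by default; `missing = "impute"` substitutes the variable
median (continuous) or mode (binary).

## The Auto-Contractive Map

The network has three layers of the same width N. A contraction constant
`C > 0` bounds all weights; each node `s` carries a hidden-contraction
weight `v_s` and each ordered pair `(i, s)` an output-contraction weight
`w_is`. For one record `m` (entries in \[0,1\]):

    hidden_s = m_s (1 - v_s / C)
    net_i    = sum_s hidden_s (1 - w_is / C)
    out_i    = hidden_i (1 - net_i / C)

and the online updates, applied record by record with learning factor
`alpha`:

    v_s  += alpha (m_s - hidden_s) (1 - v_s / C)
    w_is += alpha (hidden_i - out_i) (1 - w_is / C) hidden_s

Every increment is nonnegative for inputs in \[0,1\], so all weights grow
monotonically and saturate below `C` (a floating-point guard clamps them
to `[0, C]`). The `w` increment is proportional to the co-activation
`hidden_i · hidden_s`: variable pairs that are systematically high
together accumulate weight faster, which is what makes the trained `w`
matrix an association measure. As `v -> C` the hidden layer contracts the
signal to zero, the epoch mean `|out|` (the training trace) vanishes, and
learning stops by itself.

### Parameters and defaults

* `C = "auto"` sets `C = N`. Since `net_i <= sum_s hidden_s <= N`, this
  guarantees every contraction factor `1 - net/C` stays in \[0,1\] without
  clipping. Any `C >= N` behaves equivalently up to a monotone rescaling
  of the final weights; the map's edge set is insensitive to it.
* `alpha = 0.1`. The updates are self-limiting, so `alpha` sets the time
  scale, not the fixed point: in the slow-dynamics limit it cancels out
  of the final weight ordering. Moderate values keep the discrete steps
  well below the saturation bound (`alpha / C << 4`).
* `init = 0.01` — initial weights `v = w = init · C`. The initialisation
  must be strictly positive: the `v` update is proportional to
  `m_s - hidden_s = m_s v_s / C`, so `v = 0` is an exactly absorbing
  state in which the hidden layer never engages, the output never
  contracts and training cannot converge. A small uniform positive value
  is deterministic, breaks no symmetry it shouldn't, and adds only a
  constant `init` floor to every SA.
* `tol = 1e-6` on the epoch mean `|out|`, `max_epochs = 5000`. Small
  matrices converge in tens of epochs; the full 75-node cohort needs a
  few thousand because nodes with low mean activation contract slowly.
  A run that hits `max_epochs` still yields a usable map (`converged`
  reports the distinction); the edge ordering is established long before
  the tail of the contraction.
* `record_order = "dataset"` makes training bit-reproducible;
  `"shuffled"` is available behind an explicit seed.

### The trace and its burn-in

The epoch trace of mean `|out|` is *not* monotone from epoch one: early
in training `w` grows quickly (its increment is proportional to the
not-yet-contracted co-activation) which lifts `1 - net/C` and with it the
output, while `v` — whose growth rate is proportional to `v` itself —
is still leaving its small initial value. The trace therefore rises for
a short burn-in (typically well under a hundred epochs), peaks, and then
decreases monotonically to zero as the hidden contraction takes over.
The test suite asserts exactly this shape: unimodal, nonincreasing after
its peak.

## From weights to the map

At the end of training, `w` is symmetrised by its arithmetic mean with
its transpose (it is near-symmetric at convergence; the map is
undirected) and normalised by `C`:

    SA_ij = (w_ij + w_ji) / (2C),   d_ij = 1 - SA_ij.

Normalising by `C` rather than by the maximum weight keeps SA an absolute
contraction fraction — a saturated association prints as 0.99, not as a
forced 1.00. The map of main connections is the minimum spanning tree of
`d` (equivalently the maximum-SA spanning tree), computed with Kruskal's
algorithm over edges sorted by distance and then lexicographically by
node labels, so equal-weight ties resolve identically on every platform.
An MST depends on distances only through their order, so any monotone
re-normalisation of SA leaves the map unchanged. **Hubs** are the nodes
of maximal tree degree, ties included.

Exports: edge CSV (SA rounded to two decimals as on printed maps, plus a
full-precision column), GraphML and Graphviz DOT, with hub flags as node
attributes.

## The synthetic cohort generator

No public accession exists for the study data, so the generator is a
first-class module. Its defaults are the cohort's printed summary
statistics: 28 subjects; 8 questionnaire prevalences; 15 genes × 3
tissues plus global 5-mC/5-hmC methylation means ± SD on \[0,100\]%; 8
placental metal concentrations and a dioxin/PCB-TEQ concentration on
\[0,∞).

Dependence is a Gaussian copula: a latent multivariate standard normal
with a block correlation matrix (validated positive semi-definite),
transformed coordinate-wise. Binary coordinates threshold the latent
normal at the prevalence quantile; continuous coordinates pass through a
quantile transform of a *moment-matched* family:

* **Truncated normal** wherever feasible: `(mu, sigma)` are solved
  (multi-start Nelder–Mead on the truncated-moment equations) so that the
  *truncated* distribution on the valid range has exactly the target mean
  and sd. Naive truncation would visibly bias high-sd marginals near a
  bound (placental LEP, 65.62 ± 17.96 on \[0,100\], shifts by over a unit).
* **Gamma / scaled beta fallback**: a truncated normal cannot exceed the
  coefficient of variation of its exponential tail limit (cv = 1), yet
  several near-zero marginals have cv up to 3 (maternal HSD11B2
  0.99 ± 2.62; arsenic 0.001 ± 0.003). Those draw from a moment-matched
  gamma (half-open ranges) or scaled beta (bounded ranges), which match
  both moments exactly inside the range. Only a marginal no bounded
  family can attain raises an error naming it.
* `sd = 0` marginals generate the constant value — vanadium exists to
  exercise the constant-column policy downstream.

What the generator emulates is the *marginal* structure of the cohort
plus a plantable latent dependence; what it does not emulate is the
study's actual joint distribution, its cross-tissue correlation pattern,
or any instrument noise. Tests that pass on synthetic cohorts therefore
validate the pipeline's mechanics and its ability to recover *planted*
structure — they say nothing about which biological associations are
real.

## Numerical choices

* All encoding and training in double precision; no rounding until
  export (edge labels round to two decimals, full precision alongside).
* Cohort CSVs write numerics with 17 significant digits so read–write
  round-trips are exact cell for cell.
* MST ties: lexicographic on (distance, node_a, node_b); training:
  record order fixed; simulation: one seed drives everything, and the
  generator restores the caller's RNG state.
* The copula adds a `1e-10` ridge before Cholesky for boundary-PSD
  matrices and rescales to unit latent variance.
* Degenerate inputs: all-zero matrices converge at epoch 1 with weights
  at their initial value; untrained models produce an all-zero SA with a
  warning; a response beyond the calibration standards clamps to the
  extreme level and is flagged rather than extrapolated.

## Problem sizes used by the tests

The suite trains hundreds of small instances (up to 10 nodes, 50
records), twenty 12-node planted-block cohorts at n = 200, and the full
75-node cohort at study size; marginal-recovery checks simulate up to
100,000 subjects. These sizes keep the whole suite around a minute on a
single core while leaving every property with comfortable statistical
margin.

## Known limitations

* The Auto-CM's weight saturation compresses SA contrast: with a dozen
  identically-distributed nodes and latent block correlation 0.9, SA
  separates within- from between-block pairs by only a few hundredths.
  Block recovery as connected subtrees succeeds in roughly nine of ten
  cohorts at n = 200 — an unlucky between-block sample correlation can
  displace a single tree edge. A plain correlation MST would separate
  these blocks more sharply; the Auto-CM's value is its uniform handling
  of mixed types and nonlinear co-activation, not maximal power on
  Gaussian blocks.
* SA values depend on the stopping point for runs that reach
  `max_epochs`; edge *ordering* stabilises much earlier than SA
  magnitudes.
* Only the spanning tree is produced; associations just below a tree
  edge's SA are visible in the all-pairs export but not in the map.
* The calibration module consumes an already-reduced melt response; it
  is deliberately agnostic to how HRM software derives that statistic.
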