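---
title: "Methods: multiobjective Bayesian optimization of glycosylation conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiobjective Bayesian optimization of glycosylation conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycobo)
```

## The problem and the model

Glycosylation couples an activated glycosyl donor to an acceptor alcohol;
the two products (α- and β-anomers) differ only in the configuration of the
new glycosidic bond, and which one forms depends on a mechanism too
entangled to design against directly. `glycobo` therefore treats the
reaction class as a black box and optimizes two objectives at once — yield
(%) and anomeric selectivity (%) — over a space of reaction conditions,
with a human (or the bundled virtual lab) executing the experiments.

Each objective is modeled by its own Gaussian-process regression over the
encoded condition vector. The optimizer is a minimizer, so a percentage
objective $v$ is fitted as the loss $\ell = 100 - v$; values above 100 %
(possible through NMR integration error against an internal standard) are
deliberately not clamped, so losses may be negative. Predictions are
back-transformed for all reporting.

For selectivity the two anomer percentages are complements,
$\alpha\% = 100 - \beta\%$, **except** at zero yield: a failed reaction
forms no product of either anomer, and scoring it as "100 % α-selective"
would teach the surrogate that the least productive conditions are the most
selective ones. `objective_values()` therefore assigns both selectivity
objectives the value 0 whenever the yield is exactly 0. Hypervolume metrics
are unaffected (a zero-yield rectangle has zero area); only surrogate
fitting and partial dependence see the difference.

## The reaction space and its encoding

Ten direct parameters are declared in `build_default_space()`; an eleventh,
the DCM solvent fraction, is derived as $1 - \mathrm{Et_2O} -
\mathrm{MeCN}$ under the constraint $\mathrm{Et_2O} + \mathrm{MeCN} \le 1$.
Discrete parameters carry registered integer codes: donor configuration
α = 0 / β = 1; acids ordered by increasing strength (none = 0, acetic
(p$K_a$ 4.76) = 1, formic (3.75) = 2, oxalic (1.25) = 3, TFA (0.23) = 4);
molecular sieves by pore size (none = 0, 3 Å = 1, 4 Å = 2, 5 Å = 3);
temperature as its two stations {0, 25} °C; and the lithium salts by their
PCA rank (below). Continuous bounds are fixed from the envelope of the
bundled campaign data with small margins — salt equivalents [0.5, 5],
acceptor equivalents [0.8, 3], concentration [0.03, 0.31] mol L⁻¹, solvent
fractions [0, 1] — because the exact optimizer bounds of the reference
campaigns are not recoverable; every bundled campaign row validates against
them. `encode_conditions()` min–max scales every axis to $[0,1]$, and
`decode_conditions()` inverts exactly (labels exactly, continuous values to
1 × 10⁻⁹). Reaction time is deliberately not a variable, and no unit
conversion is attempted.

Uniform sampling under the solvent constraint uses rejection sampling of
the two fractions on the unit square (≈50 % acceptance), which is exactly
uniform on the constrained triangle; a two-sample test against an
independent rejection oracle guards this in the suite.

## Salt encoding from descriptors

Categorical reagents enter the GP as ordinal integers. `pca_rank_encode()`
standardizes a descriptor table (zero mean, unit variance — so the encoding
is invariant to units and column rescaling), takes the first principal
component, orients its arbitrary sign so that a designated anchor reagent
receives rank 1, and returns the rank order of the scores. Ties are an
error (the caller must add a discriminating descriptor).

The descriptor set used for the published salt ranking is not public. The
bundled table (`salt_descriptors_synthetic.csv`) is a *synthetic
reconstruction*: three plausible anion properties (donor ability,
coordinating basicity, ion-pair dissociation) whose values were calibrated
so the PC1 ranks reproduce the four externally fixed anchors LiI = 1,
LiBF₄ = 2, LiNTf₂ = 5, LiPF₆ = 6. The remaining salts occupy ranks
LiClO₄ = 3, LiOTf = 4, LiB(C₆F₅)₄ = 7; these three are a modeling choice,
configurable by supplying another table, and no claim is made that they
match the original descriptor analysis.

## Surrogate model

`fit_surrogate()` fits a zero-mean GP on standardized losses with a
Matérn-5/2 kernel, ARD (per-axis) length scales, a signal variance and a
fitted white-noise variance. A single isotropic length scale was tried
first and discarded: with ten heterogeneous axes it collapses to a
noise-only model on the selectivity objective, whereas ARD recovers
out-of-sample correlations above 0.94 on virtual-lab data. Ordinal
parameters are treated as continuous after integer encoding, which is what
makes partial-dependence curves over discrete axes meaningful as
interpolations. Heteroscedastic noise is not modeled — the campaigns carry
no replicates to estimate it from.

Hyperparameters maximize the log marginal likelihood by L-BFGS-B on log
parameters from a fixed default start plus two seeded random restarts
(length scales in [0.05, 20] on the unit cube, noise variance in
[10⁻⁶, 10]). Refitting identical data with the same seed is exactly
deterministic; permuting training rows changes floating-point summation
order and reproduces predictions only to optimizer precision (~10⁻⁵).

## Acquisition

`ask()` proposes the initiation batch (10 uniform random conditions) when
the campaign is empty, otherwise a batch of 5 in which **each experiment
independently** is exploratory with probability 0.25 — per-experiment
rather than per-batch assignment, since published batches mix both modes.

*Exploitation* (`pareto_exploit()`): draw a candidate pool (default 2000),
predict both objective means, clamp them into the objective square, keep
the model-estimated Pareto set, and return the member maximizing the total
hypervolume gain over the *observed* front; ties break by predicted
rectangle area, then by the seeded RNG. There is no gradient-based inner
optimization — a pool argmax keeps every proposal a valid, decodable
condition by construction.

*Exploration* (`steinerberger_sample()`): from a random pool, return the
candidate minimizing the repulsive energy
$E(x) = \sum_i \lVert x - x_i \rVert^{-4}$ against everything already
observed or proposed, in the encoded cube. The steep inverse-power kernel
is dominated by the nearest existing point, making the argmin an
approximate maximin (space-filling) pick; a logarithmic kernel was tried
and rejected because it optimizes the distance *product* and visibly
under-weights the nearest neighbor. The exponent is configurable.

Batches are proposed sequentially: exploration sees earlier proposals of
the same batch as occupied space; exploitation proposals do not fantasize
results, so near-duplicate exploitation picks within a batch are possible
(different pools make them rare).

`tell()` appends *executed* conditions — which may deviate from the
proposals, as lab measurement granularity dictates — and marks the
surrogates stale; they are refit lazily on the next `ask()`. Duplicates are
allowed. `dual_ask()`/`dual_tell()` implement the two-optimizer protocol:
2 exploitation proposals from the β-campaign and 3 from the α-campaign per
batch, all 5 results broadcast to both states, exploration off.

## Hypervolume conventions

All analytics live in the (yield, selectivity) maximization plane with
reference point (0, 0) and the 100 × 100 square as 100 %. A single
experiment's printed contribution is its rectangle area
$y \times s / 100$ — *not* the exclusive (marginal) contribution, which is
provided separately as `exclusive_hypervolume()`. Yields above 100 are used
as-is. `total_hypervolume()` computes the exact union area by the
descending-yield sweep; `pareto_front()` flags weakly non-dominated points,
keeping one representative among exact duplicates. When comparing with
printed integer columns, rounding is half-away-from-zero
(`round_half_up()`), matching how the source tables appear to have been
produced; residual ±1 discrepancies trace to the printed columns having been
rounded from unrounded raw data, and the suite pins the measured agreement instead of
pretending exactness.

## Partial dependence

`partial_dependence()` sweeps one parameter over a grid (25 points for
continuous axes, the registered levels for discrete ones), sets it in every
row of a background sample, averages the predicted loss and
back-transforms. The background is the campaign's own observed conditions —
an empirical average, chosen over uniform sampling because the intent is to
read trends *from the obtained data*; with a uniform background the curves
answer a subtly different question. When the swept parameter is a solvent
fraction, the complementary fraction is shrunk where needed to keep the
background rows feasible. PDP is linear in the model predictions, which the
suite checks by direct construction.

## The virtual lab

`lab_scenario()` defines a synthetic response surface used to exercise the
closed loop; it is a benchmark, not a chemical prediction model. Additive
logit-scale trend terms with two explicit interactions (salt × sieves,
salt × solvent for LiPF₆) are squashed through a logistic into the valid
ranges, reproducing the qualitative structure of the campaign data as hard
guarantees at zero noise: LiI gives β% < 25 everywhere; LiBF₄ and LiNTf₂
give β% > 55 everywhere; LiPF₆ is β-selective with sieves or
acetonitrile-rich solvent and α-selective without sieves in ether-rich
conditions; without acid the yield is capped at 60 %. The yield scale and
weights were set so the noiseless optimum sits near the best observed
experiments (~90 %) rather than at a saturated ceiling — an early draft
saturated both strategies and made benchmarking meaningless. Observation
noise is additive Gaussian with σ = 5 % per objective (the few-percent
error scale suggested by single NMR measurements occasionally exceeding
100 % yield), clipped to yield ∈ [0, 105] and β ∈ [0, 100].

What passing closed-loop tests on this oracle shows: the machinery — space,
encoding, surrogates, acquisition, bookkeeping — extracts structure faster
than uniform random sampling when such structure exists. What it does not
show: anything about real glycosylation chemistry, whose noise is not
Gaussian, whose interactions are not two-term, and whose failure modes
(decomposition, no conversion) are only caricatured by the yield cap.

## Problem sizes and determinism

The suite and the acceptance script use the bundled 75-experiment tables
for all data-driven checks; Monte-Carlo hypervolume cross-checks use 10⁶
samples per instance over 100 random instances; the closed-loop benchmark
runs 20 replicate seeds of a 55-experiment budget (10 random + 9 × 5
proposed) per strategy at σ = 5 noise, the same campaign shape as the
published study. Every stochastic step takes an explicit seed: campaign
states derive one sub-seed per operation from their base seed, so an entire
campaign is reproducible from a single integer, and the virtual lab is a
pure function of (scenario, conditions, seed).

## Known limitations

* The GP treats ordinal axes as continuous; no categorical kernel is
  offered, so unordered structure among salts must be carried by the
  descriptor ranking.
* Exploitation cannot propose outside its random candidate pool; very
  narrow optima could be missed at the default pool size.
* Two printed α-contribution values in the bundled tables (experiments 72
  and 73) are internally inconsistent with their own rows and are treated
  as source typos by the integrity tests.
* The three non-anchored salt ranks are a convention, not a reconstruction
  of the unpublished descriptor analysis.
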