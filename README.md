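# glycobo

Multiobjective, human-in-the-loop Bayesian optimization for glycosylation
reaction discovery.

Controlling the anomeric selectivity of glycosylations is hard because the
mechanism — a web of competing S<sub>N</sub>1/S<sub>N</sub>2 pathways,
counter-ion adducts and solvent-bound intermediates — resists rational
design. `glycobo` treats the reaction class as a black-box function
*f*(conditions) → (yield %, β-anomer %) and searches a constrained, mixed
discrete/continuous condition space with a pair of Gaussian-process
surrogates, one per objective. The package covers the full campaign
workflow:

* **Reaction space** — ten direct parameters (donor anomeric configuration
  α/β; lithium salt; salt equivalents; acid; acceptor equivalents;
  concentration; Et₂O and MeCN solvent fractions with
  Et₂O + MeCN ≤ 1 and DCM as the derived remainder; molecular sieves;
  temperature ∈ {0, 25} °C), with validation, uniform constrained sampling
  and a normalized `[0, 1]` encoding for the surrogates.
* **Descriptor encoding** — categorical reagents (the seven lithium salts)
  are mapped to ordinal integers by the rank of their first-principal-
  component score over a standardized anion-descriptor table
  (`pca_rank_encode()`).
* **Surrogates** — Matérn-5/2 Gaussian processes with ARD length scales and
  a fitted noise term, trained on the minimizer transform
  `loss = 100 − objective(%)`.
* **Acquisition** — the ask/tell loop: a 10-experiment random initiation
  batch, then batches of 5 proposed by Pareto-front exploitation
  (hypervolume-gain pick from the model-estimated front of a candidate
  pool) or repulsive-energy exploration, each experiment independently
  exploratory with probability 0.25. A dual protocol runs β- and
  α-selectivity campaigns side by side (2 + 3 proposals per batch, all
  results shared).
* **Analytics** — exact 2-D hypervolume (reference point (0, 0), 100 % =
  100 % yield × 100 % selectivity), per-experiment contributions, Pareto
  fronts, batch-wise convergence, and partial-dependence curves for reading
  per-parameter trends off the surrogates.
* **Virtual lab** — a synthetic response surface encoding the discovered
  qualitative structure (LiI → α; LiBF₄/LiNTf₂ → β; LiPF₆ flips with
  sieves/solvent; yields capped without acid) for closed-loop benchmarking.
* **Fixture** — the 75 experiments of the two published campaigns as
  plain-CSV validation data (`glyco_fixture()`).

## Worked example

```r
library(glycobo)

space <- build_default_space()
c1 <- glyco_fixture(1)                       # campaign 1: 55 experiments

an <- analyze_campaign(c1, "beta_selectivity")
an
#> Campaign analysis (beta_selectivity): 55 experiments
#>   total hypervolume: 82.57%
#>   Pareto front: 4 points
#>   batches: 10 (final batch HV 82.57%)

round(an$table$HVContr[1:3])                 # per-experiment contributions
#> [1] 60 12  8

analyze_campaign(c1, "alpha_selectivity")$total_hv
#> [1] 88.96                                  # (yield, alpha) total HV

# propose the next batch for a fresh campaign
st <- new_campaign(space, seed = 1)
out <- ask(st)                               # 10 random initiation rows
res <- simulate_reaction(lab_scenario(), out$proposals, seed = 1)
st <- tell(out$state, res)
ask(st)$proposals$Mode                       # 5 proposals, mostly exploitation
#> [1] "pareto_exploit" "pareto_exploit" "steinerberger_explore" ...
```

The total hypervolume is the area of objective space dominated by the
campaign (82.6 % for yield/β-selectivity; 89.0 % for yield/α-selectivity
computed from the same 55 experiments), and each experiment's contribution
is its own rectangle `yield × selectivity / 100` — e.g. experiment 1
(87 % yield, 69 % β) contributes 60 %.

A shell entry point for the lab loop is installed at
`system.file("scripts", "glycoopt.R", package = "glycobo")` with verbs
`init`, `suggest`, `tell`, `analyze`, `pdp`, `simulate` and `benchmark`.

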