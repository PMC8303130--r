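---
title: "Methods: a Bayesian-network model of flood interventions and mental health"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Bayesian-network model of flood interventions and mental health}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floodbn)
```

## The problem

Flooding damages mental health through pathways that are hard to price.
Beyond the direct experience of being flooded, *secondary stressors* — here,
the loss of items of sentimental value (LOSI) — raise the risk of probable
depression among flooded households. An agency deciding whether to fund an
intervention such as an early-warning system needs that pathway expressed in
the currency of health economics: quality-adjusted life years (QALYs) and
pounds at a stated willingness-to-pay threshold.

`floodbn` implements that evaluation as a discrete Bayesian network (BN)
plus a QALY valuation layer, together with the machinery needed to test
every stage without access to the underlying survey data: exact inference,
parameter and structure learning, forward simulation of synthetic survey
records, and probabilistic sensitivity analysis (PSA) with an expected
value of perfect information (EVPI) estimator.

## The model

A BN over categorical variables $X_1,\dots,X_n$ is a DAG $G$ plus one
conditional probability table (CPT) per variable; the joint distribution
factorizes as

$$P(X_1,\dots,X_n) \;=\; \prod_{i=1}^{n} P(X_i \mid \mathrm{pa}_i).$$

The packaged flood model has five probabilistic nodes, all binary with
states `present`/`absent`:

* `Flood` — the household was flooded;
* `LOSI` — sentimental items were lost (the secondary stressor);
* `PPD` — probable depression;
* `Lsever`, `Msever` — less / more severe depression. These are modeled as
  two separate binary children of `PPD` rather than one three-state node,
  because the two severity states can overlap in practice.

The default arc set is the chain-and-fan
`Flood -> LOSI -> PPD`, `PPD -> Lsever`, `PPD -> Msever`; it is
configuration-overridable. The change-in-utility (CU) and change-in-QALY
(CQALY) quantities drawn downstream of the severity nodes are deterministic
arithmetic on posteriors and the utility table; they carry no CPTs and live
outside the probabilistic core.

### Calibrating conditionals to elicited marginals

The elicited evidence arrives as *marginal* prevalences: 20.1% flooded, 62%
losing sentimental items, 18.6% probable depression, 48.3% less severe and
21.1% more severe depression. Marginals do not determine conditionals: for
a child with target marginal $m$ and a single parent with marginal $p$, any
pair $(q_1, q_0)$ with $p\,q_1 + (1-p)\,q_0 = m$ reproduces $m$. We fix the
residual degree of freedom with an exposed-vs-unexposed risk ratio
$r = q_1/q_0$, default 2 — the outcome is taken to be twice as likely when
the parent condition is present, a conservative mid-range choice for
stressor effects of this kind, and one number that is easy to challenge and
change in `flood_config()`.

The requested ratio is not always feasible: $q_1 = r\,q_0 \le 1$ bounds
$r$ by $(1-p)/(m-p)$ when $m > p$. Under the default marginals the `LOSI`
node (target 0.62, parent marginal 0.201) admits at most $r \approx 1.907$,
so the builder clamps the ratio to the feasible maximum with a message; at
the clamp the exposed probability reaches 1 ("every flooded household loses
some sentimental item"), which is the extreme reading the elicited marginals
force once any larger ratio is requested. Marginals are honored to machine
precision either way, and `validate_network()` enforces row-normalization to
`1e-9` afterwards.

Calibration by a single risk ratio is only well-posed for nodes with at
most one parent; configurations that give a calibrated node several parents
are rejected rather than silently resolved.

## Inference

Posterior queries use exact variable elimination with a min-degree
elimination ordering — at seven nodes nothing heavier (junction trees,
conditioning) earns its complexity. The posterior is invariant to the
elimination order, and the test suite checks every query against an
independent oracle that conditions the brute-force joint table from
`enumerate_joint()`. Evidence with probability zero raises a dedicated
error (`floodbn_inconsistent_evidence`) rather than producing NaNs.

`backpropagate_to_roots()` implements the reverse question — given an
observed outcome, which root causes move the most? No standard influence
metric exists for this capability, so the package defines the shift of a
root as the maximum over its states of the absolute prior-to-posterior
change, ranks roots by it and breaks ties by variable name. The metric is
simple, bounded in $[0,1]$ and symmetric in the states of binary nodes;
alternatives (KL divergence, likelihood ratios) would rank identically on
binary roots in all but contrived cases.

## QALY valuation

The three mental-health states carry utilities elicited as Beta
distributions: remission $\mathrm{Be}(923,163)$ (mean 0.85), less severe
depression $\mathrm{Be}(182,122)$ (mean 0.60), more severe depression
$\mathrm{Be}(54,75)$ (mean 0.42); a stated mean drifting more than 0.005
from its Beta mean is rejected at construction. The change in utility of a
state is the remission utility minus the state utility (0.25 and 0.43 for
the two severity states); over a one-year monitoring horizon a change in
utility converts one-for-one into a change in QALYs.

`compute_cqaly()` offers one defensible pathway reading:

$$\mathrm{CQALY}_s = P(s=\text{present},\ \mathrm{LOSI}=\text{present}
  \mid \mathrm{Flood}=\text{present}) \times \mathrm{CU}_s \times
  \text{horizon}.$$

The published before/after CQALY values for the early-warning-system
scenario (0.055/0.062 before, 0.033/0.038 after) are **not** derivable from
the elicited tables by any formula stated with them, and the default
pathway formula above does not reproduce them either. They are therefore
packaged as authoritative inputs (`scenario_ews.json`) and passed through
an explicit override path; the pathway formula is documented as the
package's reading of the CQALY node, never as a derivation of those four
numbers. Everything downstream of the stated inputs is exact: incremental
QALYs of 0.022 (`Msever`) and 0.024 (`Lsever`), valued at the lower NICE
threshold of £20,000 per QALY as £440 and £480, scaling linearly to £660
and £720 at the £30,000 upper bound. Monetary values are reported to the
nearest pound, half away from zero; full precision is kept internally.

How an intervention changes the network (which probabilities an early
warning alters) is not specified by the elicited inputs, so scenarios
accept explicit before/after states — either CQALY values or whole
networks — rather than hard-coding a mechanism.

## Probabilistic sensitivity analysis and EVPI

`run_psa()` propagates utility uncertainty by Monte Carlo: each draw
samples all three utilities from their Beta distributions (state-major
order from a single seeded generator, so summaries are bit-reproducible),
recomputes each severity state's CU against the drawn remission utility,
and scales the scenario's QALY changes by `CU_draw / CU_mean` with
`CU_mean` the Beta-implied mean CU. The scaling choice matters twice: the
change in QALY is linear in CU, so for model-form scenarios it is exact,
and centering on the Beta-implied mean makes the PSA mean converge to the
deterministic valuation as the Beta variances shrink — the package's main
internal consistency check for the sampler. For value-form scenarios the
multiplicative perturbation is an assumption, made necessary because the
formula behind the stated CQALY values is unknown; it is the weakest link
in the PSA and is flagged as such.

EVPI uses the textbook common-draw estimator
$\mathrm{EVPI} = \mathbb{E}[\max_d \mathrm{NB}_d] - \max_d
\mathbb{E}[\mathrm{NB}_d]$, nonnegative by construction. No decision set
is stated for the underlying analysis, so the package defaults to
{intervene, do nothing} with the net benefit of intervening equal to the
total monetary QALY gain minus an optional per-person cost (default 0).
With zero cost, intervening dominates in every draw and EVPI is exactly 0
— an honest statement that decision uncertainty only appears once a cost
comparable to the benefit enters. EVPI is per person; population scaling
needs a population and a decision horizon, neither of which is specified.

## Learning

* `fit_cpts()` — maximum a posteriori estimation with a symmetric
  Dirichlet prior: entry $= (\text{count} + c) / (\text{total} + c\,K)$
  for pseudocount $c$ and child cardinality $K$. Pseudocount 1 (Laplace)
  is the learning default; 0 gives exact relative frequencies for
  hand-count tests, with unobserved parent configurations falling back to
  uniform under a warning.
* `bic_score()` — maximized log-likelihood minus $(k/2)\ln N$. The BIC is
  used because a search-and-score learner needs *some* score and the BIC
  has no hyperparameters, decomposes over node families (which makes local
  moves cheap) and selects consistently as $N$ grows.
* `hill_climb_structure()` — greedy add/delete/reverse moves until no move
  improves the BIC, acyclicity checked per move, ties broken
  lexicographically on the move description so runs are deterministic.
* `count_dags()` — the number of labeled DAGs on $p$ nodes via the
  alternating-sum recurrence
  $a(p) = \sum_{k=1}^{p} (-1)^{k+1}\binom{p}{k} 2^{k(p-k)} a(p-k)$,
  verified against brute-force enumeration for $p \le 4$. Counts overflow
  double precision from $p = 10$, so the recurrence runs on a small exact
  big-integer representation (signed base-$10^7$ limbs) written for this
  purpose; results return as numerics while exactly representable and as
  digit strings beyond that.

Learning is complete-data only. BNs can in principle absorb records with
missing cells via EM, but no missingness mechanism is specified for this
application, so none is modeled.

## Synthetic survey data

The study's individual-level records are not deposited, so
`forward_sample()` / `make_survey_fixture()` generate stand-in cohorts by
ancestral sampling: variables are drawn in topological order from their CPT
rows, giving records whose joint distribution *is* the model's. The
generator's defaults are the packaged network itself — samples match the
five elicited prevalences, and parameter recovery from 50,000 records
returns every CPT entry to within 0.02.

What the synthetic cohorts do **not** emulate: covariates (age, sex,
income, prior mental health), survey weights and sampling design,
measurement error in depression screening, and item missingness. Tests
passing on these cohorts therefore demonstrate that the algorithms are
correct *given the model*, not that the model captures real survey
heterogeneity.

## Numerical choices

* CPT rows must sum to 1 within `1e-9`; loaders renormalize rows off by at
  most `1e-6` (elicited tables are printed to 1–3 significant figures) and
  reject anything worse.
* Zero probabilities are permitted; the PSA's `0/0` scaling guard maps a
  zero-mean-CU state to zero contribution with a warning.
* Parent-configuration rows are ordered lexicographically over the
  declared parent order and each parent's declared state order, and JSON
  serialization writes 17 significant digits, so save/load round-trips are
  value-identical and serialized networks are stable.
* All randomized paths (sampling, PSA) take explicit seeds and restore the
  session RNG state.

Test problem sizes were chosen to make statistical assertions sharp but
cheap: 100 random networks of up to 8 binary nodes for the
inference-vs-enumeration property, 100,000 samples for marginal-convergence
checks (3 standard errors), 50,000 records for parameter recovery, and
4,000–20,000 PSA draws. Each is stated in the corresponding test.

## Known limitations

* The marginal-to-conditional calibration is one-parameter; richer
  elicitation (conditional probabilities, multi-parent interactions) would
  make the network less underdetermined.
* The pathway CQALY formula is a documented reading, not a validated
  derivation; the published CQALY values are inputs.
* PSA covers utility uncertainty only — the elicited probabilities are
  treated as fixed. Extending the Beta treatment to the CPT entries is the
  natural next step and the EVPI machinery already accepts arbitrary
  net-benefit tables.
* The one-year horizon means no discounting; multi-year horizons would
  need it.
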