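---
title: "GA-MLR QSAR modelling for steroidal AR antagonists: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GA-MLR QSAR modelling for steroidal AR antagonists: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arqsar)
```

`arqsar` implements a complete linear QSAR workflow for the 7α-substituted
dihydrotestosterone series of androgen-receptor antagonists: descriptor
curation, genetic-algorithm subset selection scored by the Friedman
lack-of-fit, internal and external validation, a leverage applicability
domain, virtual screening with a frozen model, and MM/GBSA energy
bookkeeping. This vignette explains the model and its assumptions, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the numerical and design choices made where the published
workflow left them open.

## The model

Activity is the negative decadic logarithm of the molar IC50 (pIC50; higher
is more potent). The model is ordinary multiple linear regression on a small
subset of molecular descriptors,

$$\widehat{\mathrm{pIC50}} = b_0 + \sum_{j=1}^{p} b_j x_j,$$

with $p$ fixed in advance (the reference antagonist model uses $p = 4$:
IC5, GATS5e, DISPp, HATS3u). MLR assumes numeric, complete, full-rank
descriptors and approximately homoscedastic Gaussian errors; nothing in the
pipeline imputes data — a missing descriptor value is a load-time error,
because descriptor generators emit complete tables and silent imputation
would corrupt the leverage geometry downstream.

Subset selection is the scientific crux: with a few hundred curated
descriptors and ~30 compounds, exhaustive search over 4-subsets is
infeasible and stepwise selection is unstable. A genetic algorithm over
fixed-size chromosomes (descriptor index sets) is used instead, with the
Friedman lack-of-fit fitness

$$\mathrm{LOF} = \frac{\mathrm{SSE}}{\bigl(1 - (c + d\,p)/n\bigr)^2},$$

where SSE is the training sum of squared errors, $c$ the number of basis
functions, $d$ a smoothness factor and $n$ the training size. We take
$c = p + 1$ (descriptors plus the always-included intercept) and $d = 0.5$.
At fixed subset size the penalty is constant, so LOF ranks same-size models
identically to SSE — the penalty matters when comparing sizes, which is done
by sweeping `model_size` across separate runs rather than inside one GA, so
that each search is a clean fixed-dimension problem.

## Descriptor curation

Two pre-selection rules run before any search:

* **Constant and near-constant removal.** Zero-variance columns carry no
  information; "near constant" is not quantified in standard descriptor
  pipelines, so we expose it as a relative threshold: a column is
  near-constant when its standard deviation is below a fraction
  (default $10^{-4}$) of the largest column standard deviation. The default
  is deliberately conservative — it only drops columns that are flat to
  within numerical noise on the scale of the most informative column.
* **Correlation pruning.** While any pair of surviving columns has
  |Pearson r| > 0.98, the worst pair is located and the member with the
  larger mean absolute correlation against all other surviving columns is
  dropped; ties drop the later column in table order. The rule is applied
  *iteratively* (each drop changes the mean correlations) rather than in a
  single pass; a single pass can leave super-cutoff pairs behind, which
  would defeat the rule's purpose, and the iterative variant is what the
  post-condition (no surviving pair above the cutoff) requires. Pearson
  correlation is used, the standard choice in QSAR curation.

Both operations are deterministic and order-preserving, so curation is
reproducible across platforms by construction.

## The genetic algorithm

Published GA-MLR protocols typically state population size, generation cap
and mutation rate but not the operator suite. The defaults here are
population 200, at most 10000 generations and per-gene mutation probability
0.05, with the remaining operators chosen as the minimal standard GA
consistent with that description:

* binary tournament selection;
* subset crossover drawing the child uniformly from the union of the two
  parents' genes (crossover probability 0.9), which cannot create duplicate
  genes and therefore needs no repair step;
* per-gene mutation replacing an index with a random unused one;
* elitism of 2, which makes the best LOF non-increasing across generations;
* early stopping after 500 generations without improvement of the best LOF
  (`stagnation_patience`), which makes the 10000-generation cap affordable:
  on the planted-signal benchmark the optimum is typically found within the
  first few hundred generations and the run then terminates at the patience
  bound.

All randomness flows from one integer seed; identical data, configuration
and seed give an identical best-fitness trajectory. Chromosome fitness is
memoized, so converged populations cost little. Singular subsets (e.g.
near-duplicate columns that escaped curation) score `+Inf` rather than
aborting the search. On tables small enough to enumerate
(≤ 12 columns, subsets of ≤ 3) the GA's winner is tested against brute-force
enumeration.

## Validation battery

* **R² and RMSE** on the training fit; RMSE uses the $1/n$ convention (not
  $1/(n - p - 1)$), which is the convention under which the reference
  training statistics reproduce from the published activity table.
* **Q²(LOO)** uses the exact hat-matrix identity
  $e_{(i)} = e_i/(1 - h_{ii})$ for deleted residuals. This is algebraically
  identical to explicitly refitting $n$ times for OLS, and the test suite
  holds the two routes together to $10^{-10}$ on random instances. A row
  with $h_{ii} = 1$ makes LOO degenerate and is reported as such.
* **Q²(LMO)** leaves out a random 30% for 1000 iterations by default; both
  settings are unstated in typical workflow descriptions, so they follow the
  common leave-30%-out convention, are seeded, and are echoed into the
  report so a reader can always see what was run.
* **External predictivity** is reported as all three conventions
  (Q²F1 against the training mean, Q²F2 against the external mean, Q²F3 as
  per-compound MSE over per-compound training variance) plus Lin's
  concordance correlation coefficient, since the three Q² variants answer
  differently when the external set's spread differs from the training
  set's.
* **Y-scrambling** permutes the response, refits the same subset and
  records R²/Q² per iteration (5000 by default). A genuine
  structure–activity relationship shows the unscrambled R² far above the
  scrambled distribution.

## Applicability domain

The leverage of a query row $x$ is $h = \tilde{x}(\tilde{X}^\top
\tilde{X})^{-1}\tilde{x}^\top$ where the tilde denotes augmentation with the
intercept column. Including the intercept makes the training leverages sum
to $p + 1$ and matches the $p + 1$ in the cutoff $h^* = 3(p+1)/n$; for the
four-descriptor reference model on 29 compounds, $h^* = 0.517$. (Workflow
write-ups sometimes print the leverage formula without the matrix inverse;
that form is not dimensionally meaningful, and the standard inverse form is
what reproduces the published cutoff.) Standardized residuals divide by the
*sample* standard deviation (n − 1 normalization) of the training residuals
— also when standardizing external compounds, so that both sets are judged
on the training error scale — and are flagged beyond 2.5. Williams-plot
records (labelled data) and Insubria-graph records (unlabelled screening
data) share the same $h^*$.

## Virtual screening and MM/GBSA bookkeeping

Screening applies a frozen `model_spec` to a descriptor table by exact
column-name match, attaches leverages and Y/N domain flags, and ranks by
descending prediction with ties broken by ascending compound id (a
deterministic, diff-able report ordering). The descriptor values of the 110
published screening compounds were never released, so the packaged screening
table stores their predictions and flags as printed; ranking and reporting
logic run on it, while prediction and leverage computation are exercised on
synthetic data. This boundary is deliberate and documented — the package
does not pretend to recompute numbers whose inputs are unavailable.

The MM/GBSA module is bookkeeping over precomputed per-complex terms
(kcal/mol): $\Delta E_{MM} = \Delta E_{val} + \Delta E_{ele} + \Delta
E_{vdw}$, $\Delta G_{sol} = \Delta G_p + \Delta G_{np}$, $\Delta E_{bind} =
\Delta E_{MM} + \Delta G_{sol}$, $\Delta G_{bind} = \Delta E_{bind} +
(-T\Delta S)$. The entropy column is stored as $-T\Delta S$ so composition
is pure addition and no sign is ever flipped twice. $\Delta E_{val}$
defaults to 0 — the single-trajectory convention, under which the internal
terms cancel between complex, receptor and ligand. When a table already
carries $\Delta E_{MM}$ or $\Delta G_{sol}$ (as printed tables do, rounded
independently), those values are honoured rather than recomputed, so that
composed binding energies match the table they came from; recomputation from
parts agrees within 0.015 kcal/mol (2-dp rounding) on the packaged table.
The nonpolar solvation helper uses $\Delta G_{np} = \gamma\,\mathrm{SASA} +
\beta$ with $\gamma = 0.0072$ and $\beta = 0.92$ kcal mol⁻¹ Å⁻². Per-residue
decompositions are filtered at |total| ≥ 1.5 kcal/mol, the conventional bar
for a key binding-site residue.

## The synthetic-data generator

`generate_synthetic()` emulates the *statistical* structure the workflow
assumes, not steroid chemistry. Its defaults are the study conditions:
29 training, 7 external and 110 screening compounds; 358 descriptor columns
(the curated count of the reference workflow); a planted linear signal in 4
columns with coefficients (0.6, −0.5, 0.8, −0.7) and intercept 6.5, chosen
so activities span roughly the observed pIC50 range (5–8) with every
coefficient magnitude ≥ 0.5; Gaussian noise with sd 0.2 pIC50 units (about
the training RMSE of the reference model); 5 near-duplicate descriptor pairs
(partner = column + N(0, 0.05), |r| ≈ 0.999) to exercise pruning; and 26 of
the 110 screening rows constructed beyond the training leverage cutoff,
mirroring the published screen's 84-inside/26-outside composition.
Descriptor marginals are standard Gaussians. Non-outlier screening rows are
resampled (in the signal columns) until they sit inside the domain, so the
planted inside/outside split is exact by construction.

What this does **not** emulate: the heterogeneous scales and discreteness of
real topological/autocorrelation descriptors, their block-correlation
structure beyond the planted pairs, activity cliffs, or any relationship
between descriptor identity and chemistry. Passing tests on synthetic data
therefore demonstrate that the *algorithms* behave correctly under the
assumed statistical model — recovery of a known subset, correct domain
flags, calibrated validation metrics — not that a four-descriptor model is
the right description of any particular chemical series.

Ground truth (indices, coefficients, pair layout, outlier ids) is returned
with the data and written as a sidecar JSON by the pipeline, so recovery
tests read it rather than re-deriving it.

## Numerical choices and degenerate inputs

* OLS goes through base R's QR path (`.lm.fit`); the normal-equations solve
  appears only as an independent oracle in tests. Rank deficiency is a
  classed error (`arqsar_singular_fit_error`), not a silent pseudo-inverse.
* Leverages use a Cholesky inverse of $\tilde{X}^\top\tilde{X}$; a singular
  cross-product is an error rather than a regularized approximation.
* Curation tie-breaks (equal mean absolute correlation within $10^{-12}$)
  drop the later column; GA improvement requires a decrease larger than
  $10^{-12}$ so floating-point jitter cannot reset the stagnation counter.
* Model JSON stores coefficients as 17-significant-digit decimal strings,
  which uniquely identify a double, making the round trip bit-exact.
* Degenerate requests fail loudly with typed conditions: empty tables,
  unknown split labels, LOF penalty $(c + d\,p) \ge n$, leverage-1 rows in
  LOO, zero residual variance in standardization, infeasible synthetic
  specifications.

## Problem sizes used in the shipped checks

The test suite runs the planted-subset recovery at full study scale
(358 descriptors, 29 training rows, population 200, patience 500) over 20
seeds, expecting at least 18 exact recoveries — a property chosen because
the real selection outcome cannot be reproduced without the unpublished
descriptor values. Metric cross-checks (LOO vs refit oracle, leverage trace,
scrambling separation, pruning post-conditions) run on small random
instances where brute force is exact. Y-scrambling property checks use 200
iterations rather than the 5000-iteration reporting default; the
separation being tested (scrambled mean R² at least 0.3 below the
unscrambled R²) is insensitive to the iteration count at that scale.

## Known limitations

* Fixed `model_size` per search: model-size selection is an outer sweep,
  not a GA degree of freedom.
* The leverage domain is the only applicability criterion; distance-to-model
  and kNN domains are out of scope.
* MLR only — no PLS/ridge fallback for collinear regimes; curation is
  expected to have removed them.
* The MM/GBSA module neither runs simulations nor computes GB/SASA terms;
  it is a ledger over exported tables.
* The published screening predictions cannot be recomputed (descriptors
  unavailable); they are consumed as data, exactly as printed.
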