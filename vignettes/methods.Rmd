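---
title: "Classifying NDD cases from de novo coding variation at very low false-positive rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying NDD cases from de novo coding variation at very low false-positive rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(denovoSNN)
```

## The problem

Individuals affected by neurodevelopmental disorders (NDDs — autism spectrum
disorder, intellectual disability, developmental delay, epilepsy) carry de
novo likely gene-disruptive (LGD) coding mutations at roughly twice the rate
of unaffected individuals (about 0.21 versus 0.12 events per person in
simplex-family cohorts), and a milder excess of de novo missense mutation.
Because the excess concentrates in a limited set of constraint-intolerant
genes, a classifier that sees *which* gene is hit, together with gene-level
constraint and conservation metrics, can identify a subset of cases with a
false-positive rate (FPR) near zero. Operating at near-zero FPR is the
design goal: a screening context where falsely flagging an unaffected
individual is far more costly than missing an affected one.

`denovoSNN` implements that classifier and its evaluation protocol:

1. **Feature construction** — variant-class-specific matrices. For LGD
   variation: samples × gene 0/1 indicators, plus four per-sample gene-score
   features (pLI, LOEUF, RVIS, mean phastCons element score). For missense
   variation: the cell for (sample, gene) holds the maximum per-variant
   pathogenicity score (PrimateAI-style, in [0, 1]) and no gene-score
   features are appended.
2. **A shallow neural network (SNN)** — one ReLU hidden layer, sigmoid
   output — trained with the loss
   `loss = 1 − (TP − λ₁·FP)`,
   where TP and FP are *soft counts*: the summed predicted probability over
   true cases and true controls respectively. λ₁ prices one false positive
   in units of true positives; large λ₁ drives control scores toward zero
   before case scores rise, which is exactly the low-FPR trade the method
   wants. An L2 penalty with weight λ₂ applies to the output layer.
3. **Hyperparameter selection** — stratified three-fold cross-validation on
   the training partition, scoring each candidate by the fraction of
   validation cases whose predicted probability is *strictly greater than
   every* validation control (the FPR = 0 operating point). Ties break by
   grid order.
4. **Baselines, combination, ensembling** — random forest, linear SVM and
   ridge logistic regression trained on identical splits; a *combined*
   prediction takes the per-sample maximum of the LGD-specific and
   missense-specific model probabilities; an *ensemble* averages all model
   probabilities; the ensemble-without-SNN variant isolates the SNN's
   contribution.
5. **Evaluation** — repeated stratified 75/25 splits (default 100); per
   split: TPR at FPR < 0.01, ROC-AUC, PR-AUC; aggregated as mean, percentile
   95% CI, and a z-score against a uniform-random reference model.
6. **Gene ranking** — one artificial sample per gene carrying a single
   variant in that gene, scored by the trained per-iteration models; the
   mean predicted probability orders genes by apparent NDD relevance.

## Numerical and design choices

Where the source protocol left details open, the package makes these
choices (each is visible in code and overridable):

* **Soft TP/FP counts, full batch.** Hard counts are non-differentiable;
  the soft versions recover them when predictions saturate. Training is
  full-batch so the loss keeps raw-count semantics — consequently λ₁'s
  effective scale grows with cohort size, which is why it sits in the
  search grid rather than being fixed.
* **Cross-validation comparison is strict** (`>` against the maximum
  control score, never `>=`), and the TPR@FPR metric keeps FPR *strictly*
  below the bound: with `m` controls the threshold is the `(k+1)`-th
  largest control score for the largest `k` with `k/m < fpr_max`. At
  `fpr_max = 0.01` and `m < 100` this reduces to "above every control".
* **Per-sample gene-score aggregation** for multi-gene LGD carriers takes
  the most deleterious value per score (max pLI, min LOEUF, min RVIS, max
  phastCons). With a single mutated gene — the common case, and every
  artificial sample — aggregation is the identity.
* **Missing data.** Genes absent from a score table are imputed with
  least-constrained defaults (pLI 0, LOEUF 2, RVIS 0, phastCons 0) so an
  unknown gene cannot masquerade as constrained. A missense variant without
  a pathogenicity score is filled with the scale midpoint 0.5 (with a
  warning); if *no* missense variant has a score the build errors rather
  than silently inventing a cohort.
* **SVM probabilities.** Linear-SVM decision values are min-max rescaled to
  [0, 1] within each prediction batch. Ranking metrics and the max/mean
  combinations only need order-preserving comparability, which this
  provides at zero calibration cost.
* **CI and z-score.** 95% intervals are percentile intervals over the
  per-iteration metric values (no distributional assumption); the z-score
  denominator is the standard deviation (n−1) of the randomized model's
  per-iteration values. Both formulas of the source protocol live in an
  unavailable supplement; these substitutes are recorded in the report
  metadata.
* **Enrichment difference proxy.** The published per-gene enrichment
  statistic is likewise in an unavailable supplement. The package computes
  `e_diff(g) = c_g/C − u_g/U` (the gene's share of case variants of a class
  minus its share of control variants), which sums to zero over a complete
  ranking and is labelled a proxy in every output.
* **Untuned harness default.** `run_experiment()` uses fixed per-model
  hyperparameters unless `tune = TRUE`; per-split grid search over the full
  default grid (λ₁ ∈ {0.5, 1, 2, 5, 10} × hidden ∈ {8, 16, 32, 64} × λ₂ ∈
  {0, 1e-4, 1e-3, 1e-2} × lr ∈ {1e-3, 1e-2}) times 100 iterations is a
  cluster-scale computation, not a desk-scale one.
* **Determinism.** Every stochastic path (weight initialization, fold and
  split assignment, bootstrap resampling, the cohort simulator, randomized
  predictions) draws from an explicit seed and restores the caller's RNG
  state. Two runs with identical inputs are bit-identical, and serialized
  SNN models (`write_snn()`/`read_snn()`) reproduce predictions exactly.

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` produces a cohort in the package's own input dialect:
per-sample variant counts are Poisson with class-specific rates (defaults
0.21/0.12 LGD and 1.2/1.0 missense per sample, case/control); control
variants land on genes uniformly; a configurable share of the *case excess*
is routed into a planted risk-gene set; risk genes draw high pLI
(Beta(5, 1)) and low LOEUF (2·Beta(1, 5)), background genes the reverse;
RVIS and phastCons are noisy monotone transforms of LOEUF and pLI so the
constraint metrics are collinear, as in real annotation; missense
pathogenicity is Beta(2, 2), mean-shifted upward for case variants in risk
genes.

Two sizing choices matter and are deliberate:

* **The gene universe is genome-scale relative to the cohort**
  (`n_genes = 2000` by default). Real de novo databases spread a few
  thousand LGD events over thousands of genes, so most mutated genes are
  hit once and *recurrence* concentrates in the risk set. Compressing the
  universe makes uniformly-placed control variants recur inside risk genes
  at a density real cohorts never show, which mechanically destroys the
  near-zero-FPR operating regime the method targets — a property of the
  simulation, not of the method.
* **Null-calibration cohorts must be dense.** A finite cohort has a fixed,
  chance alignment between features and labels that does *not* average out
  over repeated splits of the same cohort. For sparse cohorts (a few
  hundred carriers) this dataset-level tilt leaves any learner's mean test
  AUC several points away from 0.5 even with no planted signal. The
  acceptance suite's null cohort is sized (1000+1000 samples, 400 genes,
  LGD rate 0.5) so the tilt's across-dataset standard deviation is ~0.015.

A green test on synthetic data establishes that the implementation
recovers planted signal with the designed operating characteristics. It
does not establish clinical performance: the generator has no mutability
differences between genes, no ascertainment structure, no relatedness, no
diagnostic-category heterogeneity, and its case:control ratio is balanced
whereas real de novo databases are heavily case-dominated (which is why
published PR-AUC values there exceed 0.85 even for a random classifier).

## Gene ranking notes

Artificial samples are built for *every* gene of interest — including
genes never mutated in the training cohort. With an LGD-type schema those
genes carry no indicator weight and are ranked purely from their score
features; they are flagged `extrapolated` in the output. This genome-wide
ranking is the protocol's intent ("a single variant in a unique gene"),
and it matters quantitatively: restricting the ranking to training-schema
genes dilutes the correlation between predicted probability and constraint
scores, because within the mutated-gene subset the model's gene-identity
evidence competes with its score evidence. Missense-type artificial
samples default to pathogenicity 1.0 — the gene's ceiling effect under the
trained model.

The ranking averages per-gene probabilities over the models from repeated
split iterations. The average converges well before 100 iterations; the
acceptance suite uses 20.

## Known limitations

* λ₁'s scale couples to cohort size (unnormalized loss); grids must be
  revisited for cohorts far from the 10³–10⁴ range.
* The linear SVM's probability rescaling depends on the prediction batch;
  two batches containing the same sample can assign it different rescaled
  scores (rankings within a batch are unaffected). Platt-style calibration
  would remove this at the cost of an extra fitted map.
* `optimize_hyperparams()` scores a candidate by a strict-max criterion
  that is noisy in small validation folds; with very few controls per fold
  the selection degenerates toward grid order (stratified folding keeps
  this observable rather than silent, by erroring on control-free folds).
* The enrichment statistic and the z-score/CI constructions are documented
  substitutes for formulas in an unavailable supplement; comparisons
  against published absolute values should treat them as such.
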