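---
title: "Meta-prediction of amyloid hot spots: model, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-prediction of amyloid hot spots: model, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(amylometa)
```

## The problem and the model

Amyloid fibril formation is seeded by short sequence segments — hot spots —
and a hexapeptide is experimentally sufficient to drive the conversion of a
protein domain into fibrils.  Many sliding-window hot-spot predictors exist,
each encoding a partial view of aggregation: hydrophobicity, beta-sheet
propensity, position-specific packing preferences, trained discriminative
models.  Their errors are only partly overlapping, which is exactly the
situation in which stacking helps.

amylometa models the probability that a hexapeptide $x$ is a hot spot as a
logistic combination of $k$ component scorer outputs $S_1(x),\dots,S_k(x)$:

$$
P(Y = 1 \mid x) \;=\;
\operatorname{logit}^{-1}\!\Big(\beta_0 + \sum_{j=1}^{k} \beta_j S_j(x)\Big).
$$

The $\beta$ vector is estimated by maximum likelihood on a labelled
hexapeptide training set (`amylometa()`), and the component set itself can
be chosen by a bidirectional stepwise search minimizing BIC
(`stepwise_bic()`), reflecting the fact that candidate scorers are often
strongly correlated families whose redundant members should be removed
rather than averaged.  The logistic stacking is the core contribution of
the package and is implemented in full here (IRLS with step-halving); the
generic `stats::glm` fit is used only as an independent cross-check in the
test suite.

### Component scorers

Two generic families cover the common window predictors:

* **residue scales** (`scale_scorer()`): a value per amino acid, aggregated
  over the six window residues.  The default aggregation is the *mean*,
  which keeps scores on a per-residue scale and comparable across scales;
  `sum` is provided and equals $6\times$ the mean.
* **position-specific matrices** (`pssm_scorer()`): a $6\times 20$ matrix
  $M$ scoring a window as $\sum_{p=1}^{6} M[p, x_p]$.

Predictors that are neither (e.g. an externally trained SVM) plug in as
precomputed hexapeptide score tables (`table_scorer()`,
`read_score_table()`).  The built-in registry (`builtin_scorers()`) ships
four *generic* configurations — Kyte–Doolittle hydropathy, Chou–Fasman
beta propensity, a simple charge scale, and a synthetic position matrix
weighting a combined hydropathy/beta axis more strongly in the window core.
These are deliberately not re-derivations of any published predictor's
trained parameters; they exist so the whole pipeline runs self-contained,
and users substitute real scorer parameter files via `read_scale()` /
`read_pssm()`.

The full hexapeptide space has $20^6 = 64{,}000{,}000$ members
(`hexapeptide_space_size()`); `precompute_scorer()` offers the
corresponding table memoization for repeated screening, as an optional
optimization rather than a required enumeration.

### Profiles, hot spots, TA and NHSA

`compute_profile()` slides a fixed 6-residue window along the protein and
assigns each window probability to the window's **third residue**; residues
1–2 and $L\!-\!2..L$ therefore carry no score and are reported as `NA`, not
0.  A **hot spot** (`call_hotspots()`) is a maximal run of consecutive
windows with score at or above the threshold ("above" is implemented as
$\geq$ everywhere, so ties count positive).  Its residue span is the union
of the run's windows, i.e. `first_window .. last_window + 5`; spans of hot
spots separated by fewer than six below-threshold windows can overlap in
residue space even though their window ranges never do.

Two AGGRESCAN-style summary statistics quantify amyloidogenicity:

* **TA (Total Area)** = the sum of all window scores of the sequence;
  threshold-independent by construction.
* **NHSA (Normalized Hot Spot Area)** = the area between the profile and
  the threshold over a hot spot's windows, divided by the hot spot's
  *residue* length (window count + 5).  The per-residue denominator is the
  design choice here: a single window at threshold$+0.3$ has NHSA
  $0.3/6 = 0.05$.

### Thresholds

`select_threshold()` implements four cut-off rules on the ROC curve:
minimal Euclidean distance to the upper-left corner $(0,1)$ (the
"best global accuracy" rule — described in the hot-spot literature as
*maximizing the distance to the upper-left corner*, but the quantity being
optimized is conventionally the minimum of
$\sqrt{(1-\text{sens})^2+(1-\text{spec})^2}$, and that minimization is what
is implemented); Youden's $J = \text{sens}+\text{spec}-1$; and
high-sensitivity / high-specificity rules that return the most stringent
threshold meeting a user target.  The two optimality criteria often agree
on real data but are not equivalent; the test suite contains a constructed
instance where they disagree and each matches its own exhaustive optimum.
Thresholds should be selected on *cross-validated* scores (`cv_scores()`),
since in-sample scores are optimistically biased.

### Evaluation machinery

The evaluation functions follow the conventions used throughout the
hot-spot literature:

* `classification_metrics()` — accuracy, sensitivity, specificity, MCC,
  $Q = (\text{sens}+\text{spec})/2$ and F1 from a confusion matrix.
  Zero-denominator metrics return `NA` (a tagged undefined value) rather
  than 0; note that specificity $TN/(TN+FP)$ is perfectly well defined
  (and equal to 0) when $TN=0$ but $FP>0$.
* `roc_curve()` / `auc()` — one operating point per distinct score (ties
  grouped), trapezoidal area.  `auc_concordance()` is the independent
  rank-based (Mann–Whitney) estimator of the same quantity; the two agree
  to $10^{-12}$ and both routes are kept deliberately.
* `partial_auc()` — area over an FPR band, **unnormalized**: the 0–20%
  band of a perfect classifier is 0.2 and of an uninformative one 0.02.
  McClish normalization is intentionally not applied, so values are
  directly comparable to published partial-AUC tables on that scale.
* `delong_test()` — DeLong's placement-value test for the difference of
  two correlated AUCs, two-sided.  It agrees with `pROC::roc.test` to
  machine precision when the ROC direction is pinned.
* `bootstrap_ci()` — percentile intervals over class-stratified resamples
  (2000 replicates by default), so no replicate ever loses a class.
  BCa corrections are out of scope.
* `per_residue_confusion()` — region-level predictions scored residue by
  residue against validated regions; counts always sum to the sequence
  length, and the result is invariant to splitting regions into adjacent
  pieces.

### Variant effects

`mutation_effect()` compares a mutant against its wild type over a fixed
analysis region (1-based inclusive; windows are attributed to the region by
their start residue, which makes region-restricted TA unambiguous).  It
reports both $\Delta$NHSA (summed over hot-spot contributions inside the
region) and $\Delta$TA, because either is a reasonable single-number
summary of a variant's effect on local aggregation propensity and the
choice between them is a reporting convention, not a modelling one.  A
single substitution can alter at most the six windows covering the mutated
position — a property the tests verify exhaustively — so substitution
effects are local by construction; frameshifts are handled by clipping the
region to each sequence's length.

## Numerical choices

* **IRLS**: relative log-likelihood tolerance $10^{-8}$, at most 100
  iterations, with step-halving so the log-likelihood trace is monotone
  (asserted in tests).  Complete or quasi-complete separation is *flagged*
  (`converged = FALSE`, `separation = TRUE`), not penalized away: the
  meta-model operates on noisy continuous scores where separation signals a
  degenerate input rather than a fitting choice.
* **Collinearity** is a hard error naming the dependent columns.
* **Stepwise ties** are broken toward fewer parameters (deletions before
  additions), then lexicographic scorer name, making the search
  deterministic.
* **Standardization** of component scores before fitting is optional and
  off by default (it changes coefficient interpretability, not
  predictions); when used, the transform is recorded in the model and
  replayed on new data.
* **Nonstandard residues**: policy `reject` (default), `map-to-nearest`
  (B→D, Z→E, J→L, U→C, O→K; X unmappable), or `skip-window`, which accepts
  the sequence and marks every window covering the residue unscoreable
  (`NA` in the profile, excluded from TA with a warning, interrupting
  hot-spot runs).

## The synthetic-data generators

Real benchmark compendia (experimentally labelled hexapeptide sets,
amylome proteins with validated regions, scrambled-peptide panels) cannot
be bundled here, so `gen_labelled_hexapeptides()`,
`gen_features_from_logistic()` and `gen_annotated_protein()` emulate their
*structure*:

* labelled hexapeptides default to 116 positives / 162 negatives — the
  class composition of the classic training compendium — with positives
  drawn from a background distribution tilted by
  $\exp(\text{separation}\cdot z/2)$ along the standardized
  hydropathy/beta axis $z$.  `separation = 0` is an exact null;
  the default 2 makes single component scores strongly informative
  (AUC $> 0.8$), a realistic regime for published scorers.
* feature matrices are drawn from a known logistic model
  ($\beta_0 = -1$, slopes $(0.8, -0.5, 0.6, 0.9)$ in the validation
  simulations), optionally with redundant copies correlated $r = 0.8$
  with their parents — the regime in which stepwise BIC should keep the
  four signal carriers and drop the copies, mirroring the 11-to-4
  predictor reduction that motivates selection in the first place.
* annotated proteins plant 6–12-residue high-propensity segments
  (tilt 3) on uniform background with $\geq 6$-residue gaps, recording
  coordinates for per-residue evaluation; a scramble mode permutes a
  sequence uniformly.

Every generator threads a single seeded RNG and restores the caller's RNG
state, so outputs are bit-reproducible from (seed, configuration).

What the generators do **not** emulate: real amyloid sequence statistics
beyond a one-axis propensity tilt, position-dependent composition,
homology structure between peptides, or the label noise of heterogeneous
experimental assays.  Passing the simulation suites therefore demonstrates
the correctness and calibration of the machinery, not field performance on
real proteomes.

## Validation summary

The test suite and `scripts/acceptance.R` recompute, among others: the
published per-residue and per-peptide benchmark metrics from their printed
contingency counts; the $20^6$ combinatorial identity; dual-route AUC
agreement at $10^{-12}$ over 500 random tied instances; coefficient
recovery at $n = 5000$ over 50 seeds (mean bias $< 0.05$); exact stepwise
recovery of 4 signal carriers among 11 correlated candidates in $\geq 90\%$
of 100 replicates at $n = 2000$; DeLong null rejection at the 5% level
within (0.03, 0.07) over 1000 simulations; and 95% bootstrap AUC interval
coverage within (0.90, 0.99) over 200 replications with 2000 resamples.
Simulation sizes are chosen to make each check sharp while keeping a full
run of the suite around a minute on one core.

## A compact worked example

```{r example}
# a synthetic training set with the classic 116/162 class design
train <- gen_labelled_hexapeptides(seed = 1)
feats <- as.data.frame(compute_features(train))
feats$label <- train$label

fit <- amylometa(label ~ ., feats, select = "stepwise")
summary(fit)

loo <- cv_scores(label ~ ., feats)
auc(loo, train$label)
thr <- select_threshold(loo, train$label, "upper-left")

protein <- gen_annotated_protein(120, n_hotspots = 2, seed = 9)
prof <- compute_profile(protein$seq, fit)
call_hotspots(prof, thr)
protein$regions
```

## Known limitations

* The built-in scorers are generic surrogates; meaningful biological
  screening requires plugging in real published scorer parameters.
* Stepwise-BIC selection is greedy; with heavily correlated candidates it
  returns *one* well-supported subset, not all equivalent ones.
* No regularized or Bayesian fitting; separation is reported, not
  resolved.
* Percentile bootstrap intervals can undercover slightly for extreme AUCs
  with small class counts.
* Clinical interpretation of variant deltas is out of scope: the package
  scores aggregation propensity, not disease phenotype.
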