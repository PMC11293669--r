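---
title: "Neural-network prediction intervals for pain-intensity estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural-network prediction intervals for pain-intensity estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intervalnet)
```

## The problem

Objective pain assessment from physiological signals is usually framed as
point regression: predict a continuous pain-intensity score (0–4) from
features extracted from electrodermal activity (EDA). A point estimate
hides both the irreducible noise in self-reported pain and the model's own
uncertainty. This package instead estimates *prediction intervals* (PIs):
per-observation pairs $(L(x_i), U(x_i))$ meant to contain the unknown
target $y_i$ with a chosen probability $1-\alpha$.

Two properties define PI quality and trade off against each other:

* **PICP** (prediction interval coverage probability),
  $\mathrm{PICP} = \frac{1}{n}\sum_i k_i$ with
  $k_i = \mathbf{1}\{L(x_i) \le y_i \le U(x_i)\}$ (inclusive at both ends);
* **MPIW** (mean prediction interval width),
  $\frac{1}{n}\sum_i (U(x_i) - L(x_i))$, reported also as
  **NMPIW** $= \mathrm{MPIW}/R$ with $R = \max y - \min y$ (4 on the pain
  scale).

A wide interval trivially covers; a useful method maximizes coverage while
minimizing width.

## The three interval constructions

All three share the data interface: a feature table (22 features per
observation in the motivating application), min-max normalized on the
training split, with the continuous label left on its original scale.

**Bootstrap baseline.** $B$ single-output regression networks
(`nnet::nnet`) are trained on bootstrap resamples. The ensemble mean
estimates the regression function; the ensemble variance estimates model
(epistemic) uncertainty $\sigma^2_{model}$. Noise (aleatoric) variance is
the mean squared held-in residual of the ensemble mean minus the mean
model variance, floored at zero, so that
$\sigma^2_y = \sigma^2_{model} + \sigma^2_{noise}$. Bounds are the
Gaussian band $\hat\mu(x) \pm z_{1-\alpha/2}\,\sigma_y(x)$ — symmetric by
construction and exactly right when the residuals are Gaussian.

**LUBE loss trained by a genetic algorithm.** The interval network has
two free linear outputs (lower, upper). The lower–upper-bound estimation
loss couples width and coverage multiplicatively,

$$\mathrm{Loss}_L = \frac{\mathrm{MPIW}}{R}\,
  \bigl(1 + \gamma\, e^{-\eta\,(\mathrm{PICP} - \mu)}\bigr),$$

with $\gamma = 1$ during training ($\gamma = 0$ at evaluation when
$\mathrm{PICP} \ge \mu$). The hard indicator makes it non-differentiable,
so the flattened weight vector is evolved by a genetic algorithm:
rank selection of the top parents, single-point crossover, random-reset
mutation of a fixed percentage of genes, elitism of one (which makes the
best-loss trace non-increasing — a tested invariant). Coverage is
computed on the full training set each generation; there are no
minibatches in the GA.

**Soft loss trained by gradient descent.** The differentiable variant
replaces the indicator with a product of logistic sigmoids,

$$\mathrm{PICP}_S = \frac{1}{n} \sum_i \sigma\!\bigl(s\,(y_i - L_i)\bigr)\,
  \sigma\!\bigl(s\,(U_i - y_i)\bigr),$$

restricts the width term to captured points
($\mathrm{MPIW}_S$, hard $k_i$ selector), and penalizes coverage
shortfall quadratically:

$$\mathrm{Loss}_S = \mathrm{MPIW}_S + \lambda\,
  \frac{\eta}{\alpha(1-\alpha)}\,
  \max\bigl(0,\ (1-\alpha) - \mathrm{PICP}_S\bigr)^2 .$$

$\eta$ is a free constant hyperparameter (searched in [35, 240]
independently of the minibatch length); $s$ controls how closely the soft
coverage approximates the hard indicator; $\lambda$ weighs coverage
against width. Training is minibatch Adam on the analytic gradient
(`loss_soft_grad()` for $\partial/\partial L_i, \partial/\partial U_i$,
then ordinary backpropagation), verified against central finite
differences to below $10^{-4}$ relative error.

### Numerical choices in the gradient-descent trainer

These are implementation details of this package, documented because each
one was forced by an observed failure mode of the plain recipe:

* **Output-bias initialization at the 25%/75% target quantiles** (weights
  remain small uniform, seed-controlled). With all-small initialization
  both bounds start near zero while targets span [0, 4]; at searched
  softening factors the coverage sigmoids are saturated and the gradient
  vanishes before training can start.
* **Softening-factor warmup** (`s_warmup`): $s$ is annealed geometrically
  from $\min(5, s)$ to its target over the first half of the step budget.
  At large $s$ a cold-started network has no points inside the sigmoid
  band, the coverage gradient underflows to numerical zero, and runs
  stall at their initial coverage.
* **Gradient-norm clipping** (default global norm 5). The quadratic
  penalty's scale $\lambda\eta/(\alpha(1-\alpha))$ reaches $10^4$; when
  coverage dips below nominal the gradient spike, amplified by Adam
  momentum, can undo hundreds of width-shrinking steps and lock training
  into wide-interval cycles.
* **Zero-capture guard**: a minibatch capturing no point would make
  $\mathrm{MPIW}_S$ undefined; the width term falls back to the plain
  mean width for that batch and the event is counted (`guard_events`).
* **Crossed bounds** ($U < L$) are legal throughout training and metrics
  — the loss never reorders them — and are swapped into canonical order
  only in `predict()`, with the pre-swap crossing fraction reported.
* **Infeasible GA candidates**: a chromosome with non-positive *mean*
  width would make $\mathrm{Loss}_L$ unboundedly negative (negative width
  times the exponential penalty) and the GA exploits that immediately;
  such candidates are assigned infinite loss. Metrics still report
  crossed bounds unclipped.

## Model-building regimes

* **Generalized**: one model for the whole cohort.
* **Personalized**: one model per subject, trained on that subject's rows
  only (subjects under a row threshold are skipped with a warning).
* **Hybrid**: subjects are summarized by 110-dimensional vectors (22
  feature means × 5 pain levels, normalized, fixed level order), grouped
  by k-means with $k = 4$, and one model is trained per cluster. A new
  subject is routed to the nearest centroid (Euclidean distance, ties to
  the lowest index). Hybrid with $k = 1$ reduces exactly to the
  generalized regime (a tested identity).

k-means is an explicit Lloyd loop (random subject rows as initial
centroids, assignment stabilization as convergence, empty clusters
re-seeded at the farthest point, best of 10 seeded restarts) because the
regime needs its internals observable: the per-iteration inertia trace is
asserted non-increasing, and `stats::kmeans` serves as an independent
cross-check of the attained objective in the test suite. Clustering runs
on all subjects before any train/test split, matching a design where
clusters are fixed subject groupings.

Evaluation uses stratified cross-validation. Folds for regime comparisons
are stratified on the subject × level interaction so every subject
retains observations at every pain level in each training split — the
subject-vector construction requires it. Fold metrics aggregate by their
unweighted mean.

## What the synthetic cohort emulates

`simulate_cohort()` draws feature tables with the statistical structure
the analysis assumes:

* **latent subject clusters** — cluster centroids in feature space
  (`cluster_sd`), and, importantly, *cluster-specific response loadings*:
  feature $j$ of a subject in cluster $c$ shifts by
  `effect_size * level * w[c, j]` with $w_{cj} \sim N(1,
  \texttt{cluster\_response\_sd})$. With a single shared loading the
  feature-to-pain mapping would be identical in every cluster and
  cluster-specific models could never help; heterogeneous response
  expression is precisely the phenomenon that motivates the hybrid
  regime.
* **subject random effects** (`subject_sd`) added to every feature;
* **heteroscedastic sensor noise** — sd
  `noise_sd_base * (1 + heteroscedasticity * level)`;
* **label noise** — off by default (integer levels 0–4); optionally
  uniform jitter or heavy-tailed Student-$t$ jitter (`label_noise = "t"`,
  3 df), emulating occasional large self-report errors in pain ratings;
* **row-level missingness** (`missing_rate`, one blanked cell per hit
  row), removed by `clean_cohort()`. At the default 87 subjects × 5
  levels × 20 observations and 1% missingness, cleaning leaves about
  8,613 of 8,700 rows.

`simulate_known_quantiles()` provides the coverage oracle: $y = x +
\varepsilon$ with fully known noise, so the true conditional
$\alpha/2$ and $1-\alpha/2$ quantiles are available in closed form
(constant width $2 z_{1-\alpha/2}\sigma$ in the Gaussian case).

What the generator does **not** emulate: raw EDA waveforms, the
distributions of real catch22 features, within-subject nonstationarity
(habituation, drift), or any dependence between observations beyond the
subject/cluster random effects. Observations are iid within each
subject-level cell. Passing tests therefore demonstrate correctness of
the machinery and reproduction of the qualitative phenomena *that the
generator can express* — not performance on real EDA data.

## Frozen study conditions

The cohort-level comparisons in the tests and the acceptance script use
one fixed set of conditions, chosen once as a realistic scaled-down
cohort: 24 subjects × 5 levels × 20 observations, 4 latent clusters
(`cluster_sd = 1`, `cluster_response_sd = 0.5`), `subject_sd = 0.3`,
sensor noise 0.15 (heteroscedasticity 0.15), heavy-tailed label noise
($t_3$, scale 0.5), no missingness. Training budgets: soft — hidden
layer 24, 250–300 epochs; LUBE GA — hidden 8, 300 generations; bootstrap
— 20 size-6 regressors. The coverage-recovery benchmark uses n = 1000
train/test, hidden 16, 1000 epochs. These sizes keep a full run of the
suite in minutes on one CPU while leaving each phenomenon measurable.

Under heavy-tailed label noise the Gaussian $z\sigma$ bootstrap band is
wider than the true central quantile band (the variance is inflated by
the tails), which is where direct quantile-style interval learning earns
its narrower widths. Under purely Gaussian noise the bootstrap is
near-oracle and the methods are practically indistinguishable — a useful
reminder of what the comparison does and does not show.

## Known limitations

* **Personalized models in an iid world.** With ~50 training rows per
  subject and networks of ≥250 parameters, per-subject training
  memorizes: test intervals come out *narrow and undercovering*
  (coverage ~0.55–0.6 at nominal 0.85). The regime comparison therefore
  reproduces hybrid < generalized in width robustly, but not the
  "personalized widest" ordering reported on real data, which plausibly
  rests on within-subject nonstationarity the generator cannot express.
  The corresponding assertion is kept in the acceptance tests and fails
  honestly rather than being weakened.
* **Softening-factor sweep is budget-dependent.** The advantage of large
  $s$ (higher soft coverage at matched width) shows under limited
  per-configuration budgets, where the estimation property of $s$
  dominates; at full convergence every configuration sits at the penalty
  equilibrium $\mathrm{PICP}_S \approx 1-\alpha$ and the trend flattens.
  The sweep in the tests uses a 25-epoch budget and a fixed seed and
  grid, and is deterministic.
* The GA evolves hundreds of weights by random-reset mutation; it
  reliably reaches covering intervals but converges slowly in width,
  remaining far wider than gradient-trained soft intervals — consistent
  with the motivation for the differentiable loss.
* Min-max scaling is fitted per training split and never clipped;
  out-of-range test values extrapolate linearly.

## A small worked run

```{r example, eval = FALSE}
d_train <- simulate_known_quantiles(1000, "gaussian", level = 0.9, seed = 1)
d_test  <- simulate_known_quantiles(1000, "gaussian", level = 0.9, seed = 2)
fit <- pinet(d_train["x"], d_train$y, method = "soft", level = 0.9,
             hidden = 16, control = list(epochs = 1000), seed = 3)
p <- predict(fit, d_test["x"])
b <- interval_batch(p$lower, p$upper, d_test$y)
c(picp = picp(b), mpiw = mpiw(b), oracle = 2 * qnorm(0.95))
```

On this benchmark the soft-loss network recovers close to nominal
coverage with a width near the oracle band; `scripts/acceptance.R`
recomputes this and the cohort-level quantities end to end.
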