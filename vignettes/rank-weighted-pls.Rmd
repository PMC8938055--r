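---
title: "Rank-weighted partial least squares for ordinal responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-weighted partial least squares for ordinal responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rankpls)
```

## The problem

Survey and epidemiological outcomes are often recorded on an ordinal rank
scale — for instance the adequacy of antenatal care (ANC) visits, ranked
inadequate / intermediate / adequate — and explained by dozens of ordinal
covariates that are strongly inter-correlated. Ordinary least squares is
unstable under such multicollinearity, and standard partial least squares
(PLS), built around covariances with a continuous response, does not
acknowledge that both sides of the regression live on rank scales.

`rankpls` fits PLS1 regression by NIPALS with a *pluggable loading
weight*: the covariance weight $w_c = Z_{c-1}'y_{c-1}$ of standard PLS can
be replaced by any of eight rank-association measures, computed between
each predictor column and the response,

| name | measure |
|------|---------|
| `rho_s` | Spearman's $\rho$ (Pearson correlation of midranks) |
| `tau_a` | Kendall's $\tau_A = (n_c - n_d)/n_0$ |
| `tau_b` | Kendall's $\tau_B = (n_c - n_d)/\sqrt{(n_0-n_1)(n_0-n_2)}$ |
| `tau_c` | Stuart–Kendall $\tau_C = 2m(n_c-n_d)/(n^2(m-1))$ |
| `somers_d` | Somers' $D = (n_c-n_d)/(n_0-n_1)$, predictor ties removed |
| `gk_tau` | Goodman–Kruskal's tau, loading-weight form $2(n_c-n_d)/n_0$ |
| `gk_gamma` | Goodman–Kruskal's $\gamma = (n_c-n_d)/(n_c+n_d)$ |
| `theil_u` | Theil's $U = (H(Z)-H(Z\mid Y))/H(Z)$ |

where $n_c, n_d$ are concordant/discordant pair counts, $n_0 = n(n-1)/2$,
$n_1, n_2$ are tied-pair counts of the two variables, $m$ is the smaller
dimension of their contingency table, and $H$ is the (natural-log) entropy.

Each component then proceeds exactly as in NIPALS: scores
$t_c = Z_{c-1}w_c$, loadings $p_c = Z_{c-1}'t_c/t_c't_c$,
$q_c = y_{c-1}'t_c/t_c't_c$, deflation $Z_c = Z_{c-1}-t_cp_c'$,
$y_c = y_{c-1}-t_cq_c$, and after $C$ components the coefficients are
recovered as $\hat\beta = W(P'W)^{-1}q$,
$\hat\alpha = \bar y - \bar Z\hat\beta$. The score vectors are mutually
orthogonal for *any* weight sequence (a consequence of the deflation), and
$P'W$ is unit upper triangular, so the coefficient recovery is exact; both
facts are asserted to 1e-8 in the test suite.

## Modeling decisions that were genuinely open

**Ties.** Ordinal codes are heavily tied, so the classical tie-free
Spearman formula $1 - 6\sum d_i^2/(n(n^2-1))$ is biased; `rho_s` therefore
uses Pearson correlation of midranks, which coincides with the classical
formula on tie-free data (tested to 1e-12). The $\tau_B$ denominator uses
the conventional square-root form with $n_1 = \sum_i t_i(t_i-1)/2$, which
keeps $|\tau_B| \le 1$ under ties; this is cross-checked against
`stats::cor(method = "kendall")`.

**The two Goodman–Kruskal taus.** The loading-weight form
$2(n_c-n_d)/n_0$ equals $2\tau_A$ — after unit-norm scaling its weight
*direction* is identical to `tau_a` — and can exceed 1 in magnitude. It is
the default because it is the form this PLS family is defined with. The
classical proportional-reduction-in-error tau is available as
`gk_mode = "classical"`.

**Sign-free measures.** Theil's $U$ (and classical GK tau) are
nonnegative, but a PLS weight must carry direction; each entry's magnitude
is therefore signed by the Spearman correlation of that column with the
response.

**Response coding.** Ranks are coded $1..K$ and treated numerically,
as the regression formulation implies; predictions are continuous scores
on that scale, and classification happens downstream via LDA in score
space.

**Preprocessing.** Predictors are always centered. Unit-variance scaling
is *on* by default for general use, so that the covariance weight and the
scale-free rank weights act on comparable columns. The simulation-study
comparison below deliberately turns scaling off — see that section.

**Deflated components ($c \ge 2$).** After one deflation the working
matrices are continuous. Rank measures are computed on the deflated
values directly, which for the pair-counting family is equivalent to
computing them on midranks (pair counting only sees order); $\tau_C$ and
$U$ need discrete levels, so continuous columns are binned by their
distinct values when there are at most 20, else by quintiles. Whether one
should re-rank deflated data at all is not settled; this choice keeps
every component's weight definition consistent with the first.

**Degenerate columns.** A constant (or fully tied) column gets weight 0
and a warning — never an exception mid-fit. If an entire weight vector
degenerates at the first component the fit fails with a diagnostic; at a
later component the fit truncates and records the truncation. The
stopping tolerance on $\|w_c\|$ and $t_c't_c$ is 1e-12.

**Number of components.** There is no canonical $C$ for these variants.
`choose_ncomp()` picks $C \in 1..15$ by Monte-Carlo validation accuracy;
the validation grid uses a fixed default of $C = 5$ so that all 36 cells
are compared at equal complexity.

## Variable selection

Three filter methods score each predictor from a fitted model:

* **LW** — per component, $|w_{a,j}|/\max_k |w_{a,k}|$, aggregated by the
  maximum across components (mean available). Default cut 0.5.
* **RC** — $|\hat\beta_j|$ on the standardized scale. Default cut: the
  median, retaining the more influential half.
* **SMC** — each centered, scaled column $z_j$ is decomposed along the
  model's regression direction *in sample space* (the normalized centered
  fitted-value vector $b \propto Z\hat\beta$):
  $\mathrm{SMC}_j = (z_j'b)^2 \big/ \left(\|z_j - (z_j'b)b\|^2/(n-2)\right)$.
  For a noise column this ratio is approximately $F(1, n-2)$ — the
  package's Monte-Carlo calibration finds a 0.95-quantile rejection rate
  of ~0.05 over 2000 null columns — so the default cut is
  $F_{0.95}(1, n-2)$.

The published equation for SMC names only the mean-square ratio; the
projection decomposition above is the construction adopted here, and the
sample-space reading of the regression direction is what makes the ratio
well-defined and exactly $F$-calibrated. Thresholds are configurable and a
fixed top-$k$ override exists; the retained count is always reported.

## Validation protocol

`monte_carlo_evaluate()` repeats, by default, 10 iterations of: a random
70:30 split (re-drawn until both parts contain every response level, so
LDA stays well-posed); fitting on the training part; applying the
selection cut and refitting on the retained variables; projecting test
rows into score space via $T_{new} = Z_{new}W(P'W)^{-1}$; and classifying
them with a Fisher LDA (pooled within-class covariance, proportional
priors, ridge fallback $\lambda = 10^{-6}\,\mathrm{tr}(\Sigma)/C$ if
singular) trained on the training scores. Test accuracy is the headline
metric; leave-one-out LDA accuracy on the training scores is recorded
alongside, since published accuracy figures of this design are ambiguous
between the two. `run_grid()` evaluates all nine weight variants crossed
with none/LW/RC/SMC (36 cells; the three filter methods alone give 27)
and declares a winner by mean accuracy, ties broken by fewer retained
variables, then lower AIC.

Model comparison uses the Gaussian least-squares AIC
$n\ln(\mathrm{RSS}/n) + 2(C+1)$, with $C+1$ effective parameters
(components + intercept) — a pragmatic choice, since no standard AIC
exists for PLS.

Every random step draws its seed from a per-cell, per-iteration hash of
the master seed, so the whole grid is bitwise reproducible and adding a
cell never perturbs the others.

## The synthetic-data generator

`simulate_ranked_data()` is a latent-Gaussian thresholding generator:
standard-normal latents with block-exchangeable correlation
(`block_corr` within blocks of `block_sizes`, zero between), each column
discretized into its level count by equal-probability thresholds (or
user-given probabilities), and a latent response
$\eta = \mathrm{effect\_size}\sum_{j \in \mathrm{informative}} L_j +
N(0, \mathrm{noise\_sd}^2)$ discretized into $K$ ranks by its empirical
quantiles. The generated object carries a truth record (informative
indices, effect size, blocks) for recovery studies. Defaults: $n = 1000$,
$p = 100$, fifty 3-level and fifty 4-level predictors, $K = 3$, ten
informative predictors forming one correlated block
(`block_corr = 0.5`), `effect_size = 0.5`, `noise_sd = 2` — a moderate
signal: latent $R^2 \approx 0.77$ before discretization, chosen so that
recovery is achievable but not trivial.

`simulate_anc_data()` is an ANC-like preset: $n = 943$, $p = 43$ ordinal
factors on 2–5 levels, one strongly correlated block of 16 covariates
(latent correlation 0.8) plus weaker blocks, and a skewed 12/36/52
three-rank response labeled inadequate/intermediate/adequate. It is a
synthetic stand-in shaped like a demographic-survey extract; it contains
no survey microdata.

What the generator does *not* emulate: real survey features such as
sampling weights, cluster designs, missing-data mechanisms, nominal
(unordered) covariates, and covariate-specific nonmonotone effects.
Passing tests on these synthetic conditions demonstrates the algorithmic
properties of the estimators — not that any particular real dataset will
rank the variants the same way.

## The simulation study and its calibration

`simulation_study_data()` freezes the conditions of the package's own
simulation study. It keeps the design above but makes the marginals
heterogeneous, as they are in real questionnaires: signal predictors
near-balanced, the remaining 3-level columns skewed 60/30/10, the 4-level
noise columns bimodal 40/10/10/40, response 12/36/52.

`compare_weight_variants()` fits all nine variants to each of 10
replicated draws and compares AIC. Two protocol choices matter and are
deliberate:

* **Centering only (`scale = FALSE`).** The algorithm is compared exactly
  as written — its weight step is $Z'y$, with no standardization step.
  With scaling on, the covariance weight *becomes* the vector of Pearson
  correlations, a different estimator from the one under study.
* **One component.** The loading-weight definition is the object under
  comparison, and $C = 1$ isolates it; with more components deflation
  progressively washes out the difference between weight choices (all
  variants approach the same least-squares fit).

Under these conditions each rank variant attains lower AIC than standard
PLS in 10 of 10 replicates. The mechanism is scale confounding: on
unstandardized ordinal codes, a covariance weight multiplies each
column's relevance by its marginal spread, so high-variance noise columns
(the bimodal ones) crowd out lower-variance signal columns, while every
rank measure is invariant to the coding scale. This marginal layout was
*calibrated* — chosen once so that the documented ordering of standard
vs. modified weights is reproducible in direction — and is presented as
such: under equal-probability marginals with scaling on, standard PLS is
not at a disadvantage and the ordering reverses. Entropy-based $U$ is
the variant most sensitive to weak signals (its response to a small
association is quadratic), which is why the calibrated conditions matter
most for it.

## Numerical notes

* Pair counting is exhaustive $O(n^2)$ in C++; an independent plain-R
  enumeration oracle verifies every coefficient to 1e-12 in the tests.
* Weight vectors are unit-norm with the sign fixed so the
  largest-magnitude entry is positive (reproducibility under sign
  indeterminacy).
* $P'W$ is solved directly; a singular system falls back to the
  Moore–Penrose pseudo-inverse with a warning.
* Problem sizes in the test suite and acceptance script are the study
  sizes where they matter scientifically ($n = 1000$, $p = 100$ for the
  AIC direction and recovery; $n = 943$, $p = 43$ for the ANC-like grid)
  and reduced sizes for purely structural checks (grid cardinality,
  determinism), which do not depend on scale.
* Model serialization writes 17 significant digits, so a JSON round trip
  reproduces every field exactly.

## Known limitations

* PLS1 only: one response at a time; no multivariate-Y, kernel, or
  orthogonal-signal-correction variants.
* The response is treated as equally spaced ranks; no proportional-odds
  or adjacent-category likelihood is involved.
* No confidence intervals or tests for the association measures, and no
  wrapper/embedded (sparse, genetic) selection — filters only.
* Rank-measure weights at components $c \ge 2$ rest on the
  deflate-then-re-rank convention described above; other conventions are
  defensible and would give slightly different later components.
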