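---
title: "Methods: chemometric authentication from elemental profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemometric authentication from elemental profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemauth)
```

## The problem

Certified regional foods — the bundled case study is three Italian
Pecorino cheese varieties (PF, PS, PR) — command premium prices and are
therefore targets for origin fraud. Multi-elemental composition measured
by ICP-OES is a convenient authenticity marker: it reflects soil and
process (salting mode, rennet, ripening), survives sample preparation,
and eight elements (Ba, Ca, Fe, K, Mg, Na, P, Zn) can be read in one
run. `chemauth` implements the complete chemometric workflow that turns
such profiles into a validated variety classifier, along with the
analytical figures of merit that establish the measurements themselves
are trustworthy.

## Method validation arithmetic

Calibration is an ordinary least-squares line of emission intensity on
standard concentration; linearity is summarised by
$R^2 = 1 - SS_{res}/SS_{tot}$. Sensitivity rests on the background
equivalent concentration: the concentration whose total signal is twice
the background, operationalised on the fitted line as
$BEC = (2\,\bar I_{blank} - b_0)/b_1$, which reduces to
$\bar I_{blank}/b_1$ when the fitted intercept equals the blank. We use
the general form so a non-zero fitted intercept is handled gracefully.
Detection and quantification limits follow

$$LOD = 3\,\cdot RSD_{blank}\cdot BEC/100, \qquad
  LOQ = 10\,\cdot RSD_{blank}\cdot BEC/100,$$

so $LOQ/LOD = 10/3$ identically — a dilution-invariant property the
tests assert for any input. LOD/LOQ are reported on a dry-mass basis via
an explicit dilution factor (mL of digest per g of dry sample; 25 mL or
100 mL from a 0.3 g aliquot in the bundled scenario) because solution
limits are not directly comparable to native sample levels. Accuracy is
spike recovery, $R\% = 100\,(c_{fortified}-c_{genuine})/c_{spike}$;
precision is the relative standard deviation of procedural replicates
with the $n-1$ denominator (standard analytical practice). Drift and
matrix effects are modelled only as a multiplicative internal-standard
ratio correction; spectral interferences and multi-point drift schemes
are out of scope.

## Univariate screen

Each element is screened by one-way ANOVA. The summary-statistics path
reconstructs the decomposition from per-class mean/SD/n alone
($SSB = \sum_i n_i(\bar x_i - \bar x)^2$,
$SSW = \sum_i (n_i - 1) s_i^2$), so a printed summary table can be
screened without raw data; on raw data the two paths agree to machine
precision (a tested invariant). Pairwise structure comes from Fisher's
LSD with the pooled within-group mean square on $N-k$ degrees of
freedom. The LSD is *unconditional* by default — pairs are tested
whether or not the overall ANOVA rejects — with `protected = TRUE`
available; the unconditional default matches screening tables that list
pairs for elements whose overall ANOVA p-value is above 0.05. No
multiple-testing correction is applied across elements, and all tests
are two-sided at a default $\alpha = 0.05$.

## Multivariate model

All multivariate steps operate on autoscaled data (per-variable mean 0,
SD 1, $n-1$ denominator) because the eight elements span three orders of
magnitude and two units; a log10 pretreatment can precede autoscaling.
Scalers are always fitted on training rows only and stored, so held-out
and external samples are projected with training statistics — a leakage
guard that is mutation-tested.

**PCA** is the decomposition $X = TP^\top + E$ computed by SVD, with
components ordered by explained variance and each component's sign fixed
by making its largest-magnitude loading positive, so repeated runs are
bit-identical.

**Duplex splitting** selects a representative external test set
per class: the two mutually farthest points seed the training set, the
two farthest remaining seed the test set, and the sets then alternate,
each taking the remaining point with the largest minimum distance to
its current members. The test set's quota is the class remainder; once
either set is full the other absorbs what is left (with a 16-sample
class and a training quota of 9 this yields the 9/7 division). Ties are
broken by the lowest row index; for tie-free data the split is
invariant to row permutation, and the greedy choices are verified
against an exhaustive max–min re-walk in the tests.

**PLS-DA** encodes membership of $C$ classes as a dummy matrix (class
one of three is $[1\;0\;0]$), centres it (variance-scaling a 0/1 dummy
would distort class priors — the "auto-scaled data" convention is read
as applying to the X block), and fits a single NIPALS PLS2 model rather
than $C$ separate PLS1 models, which is what the dummy-matrix notation
implies. The NIPALS iteration runs to a $10^{-12}$ relative tolerance;
scores are mutually orthogonal and, at full rank, predictions coincide
with ordinary least squares (both are tested against independent
oracles). Regression coefficients are assembled as
$B = W(P^\top W)^{-1}Q^\top$ for every truncation $1..A$, so one fit
serves the whole error curve.

**Latent-variable selection** is stratified 5-fold cross-validation:
within each class, samples ordered by id are dealt round-robin into
folds ("venetian blinds"), a deterministic scheme chosen for
reproducibility; a seeded random stratified scheme is available. Within
each fold the scaler and PLS fit see the training folds only; the
assignment rule is calibrated on the training folds' calculated
responses and applied to the held-out fold's predicted responses. The
selected $A$ minimises the misclassification rate, taking the smallest
$A$ on ties (parsimony).

**Class assignment** from the continuous predicted responses
$\hat y$ is config-selectable:

* `lda` — classic linear discriminant analysis in predicted-response
  space with pooled covariance and frequency priors (used for the CV
  error curve by default). The dummy responses sum to one across
  classes, so the last response column is dropped before the fit to
  keep the pooled covariance non-singular.
* `bayes` — per class, univariate Gaussians are fitted to the
  cross-validated $\hat y$ of the in-class and out-of-class groups; a
  sample's posterior membership probability follows from Bayes' theorem
  and it is assigned to the class of maximal posterior (the default for
  final assignment). For symmetric equal-variance, equal-prior
  Gaussians the implied threshold is the midpoint, and the two rules
  coincide — a tested closed form. Posterior ties break by the larger
  raw response margin, then the lower class index.

**Variable selection** uses VIP scores,
$VIP_j = \sqrt{V \sum_a SSY_a (w_{ja}/\lVert w_a\rVert)^2 / \sum_a SSY_a}$,
whose mean square is 1 by construction; variables with $VIP > 1$ are
retained ("greater-than-one" criterion). The reduced model is refit by
the *identical* code path (shared helper, including a fresh CV
latent-variable selection), so selection cannot silently change the
procedure.

## The synthetic generator

No raw sample-level data ships with the package; the generator draws
concentration tables from per-class summary statistics
(`pecorino_class_stats()` holds the bundled case study: mean, SD and n
for 16 PF, 20 PS and 17 PR samples over eight elements, micro-elements
in µg/g and macro-elements in mg/g dry weight, never silently
converted). Defaults are deliberate:

* **Family** — zero-truncated normal with the stated mean/SD as parent
  parameters (rejection sampling). All but two class/element rows sit
  ≥ 1.4 SD above zero, so truncation bias is small; the tests compare
  large-n means against the analytic truncated mean. A log-normal
  family whose log-scale parameters are solved to match the arithmetic
  mean and SD is offered for the positive skew real concentrations
  show.
* **Covariance** — diagonal by default: the summaries report only
  marginal SDs, and inventing dependence they do not support would be
  unverifiable. A per-class correlation matrix can be supplied
  (validated for symmetry, unit diagonal and positive
  semi-definiteness) and is recovered empirically to ±0.02 at n = 10⁵
  in the tests.
* **Seeding** — every generator call takes an explicit seed and runs
  under a private RNG state, restoring the caller's state afterwards;
  identical seeds give bit-identical tables.

What passing tests on this generator do **not** show: real cheese data
have inter-element correlations (e.g. the K–Fe anti-correlation that
salting mode induces), batch structure from manufacturing cycles and
ripening categories, and non-Gaussian tails. Synthetic accuracy figures
therefore characterise the algorithmic pipeline under the published
location/scale structure, not the method's field performance; on
independently drawn classes the CV error correctly converges to the
no-information rate (a tested property).

## Numerical choices and degenerate inputs

Tail probabilities come from R's `pf`/`pt`. Singular cases raise
informative errors rather than propagating NaN: constant columns in
autoscaling (named), identical calibration concentrations, zero pooled
within-group variance in LSD, zero-variance Bayes calibration groups,
non-PSD correlation matrices. Sign conventions (largest-|loading| or
largest-|weight| entry positive) make PCA and PLS runs reproducible to
the bit. The study-sized problems here (tens to hundreds of samples,
eight variables) run in seconds; the packaged analyses use n = 200 per
class for the large synthetic study and n = 10⁵ draws for moment
checks, sizes at which Monte-Carlo error is far below the asserted
tolerances.

## Worked run

```{r run, eval = FALSE}
rep <- run_discrimination(
  class_stats = pecorino_class_stats(),
  train_per_class = c(PF = 9, PS = 12, PR = 9),
  rule = "bayes", seed = 11)
rep
plot_error_curve(rep)
plot_vip(rep)
```

At the published class sizes the Duplex bookkeeping gives 30 training
and 23 test samples (7 PF, 8 PS, 8 PR held out). At n = 200 per class
the VIP criterion stably selects Na, K and Ba — the same three
predictors the univariate screen flags as highly significant — and
cross-validated accuracy sits far above the 33% no-information
baseline.

## Known limitations

* Marginal summaries cannot constrain dependence; synthetic realism
  beyond the marginals is unverifiable by construction.
* The Bayesian assignment uses one-vs-rest univariate Gaussians on the
  response columns; a full multivariate posterior in response space is
  not offered.
* LDA optimisation operates on predicted-Y responses, not
  latent-variable scores.
* The log10 pretreatment transforms all elements or none.
* Kernel/sparse PLS, PLS1 mode, SIMCA and soft (ambiguity-class)
  assignment are out of scope.
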