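---
title: "Discriminating coffee production environments from multi-trait phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating coffee production environments from multi-trait phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Arabica coffee grown in the Matas de Minas region (Minas Gerais, Brazil)
expresses its production site and its post-harvest processing in many traits
at once: plant architecture, disease scores, bean production, sieve and
defect profiles of the processed beans, and sensory cupping attributes.
`coffeeDiscrim` asks the multivariate question directly: given 31
morpho-agronomic, post-harvest and sensory traits measured on individual
genotype observations, can a classifier recover which of four environments —
three sites, with the highest-altitude site (Araponga) split into pulped and
natural processing — an observation came from, and which traits carry that
signal?

Two features make the problem interesting as a classification benchmark.
First, the two Araponga environments are the *same plants* whose fruit was
split between two processing routes, so every pre-harvest trait is literally
identical between them; they can only be told apart through post-harvest and
sensory traits. Second, the trait panel mixes continuous measurements,
bounded percentages and small ordinal scales, which strains the multivariate
normality and common-covariance assumptions behind classical discriminant
rules.

## The synthetic generator

The original field data are not public; what is published are per-environment
means and standard deviations for every trait, the design constants (4
environments, 88 observations, balanced), and the constancy of three sensory
attributes (clean cup, sweetness, uniformity, all pinned at the maximum score
of 10). The generator in `generate_phenotypes()` reproduces exactly these
published study conditions:

* **Independent truncated normals per trait and environment.** No covariance
  structure is published, so independence is the minimal assumption. This is
  a real limitation: correlated trait blocks (e.g. the sieve percentages,
  which sum to ~100 in real samples) are generated without their sum
  constraint, and no genotype or block structure is modelled. Tests passing
  on this generator demonstrate correctness of the pipeline under the
  published first and second moments, not performance on real field data.
* **Moment fidelity for continuous and percentage traits.** Where a bound
  truncates the distribution appreciably (e.g. the S19 sieve percentage,
  mean 4.0, sd 3.3, bounded below by 0), the latent (mu, sigma) are solved
  numerically so the *truncated* distribution has exactly the published mean
  and sd. Bounds further than 6 sd away are left alone (truncation is then
  numerically irrelevant).
* **Ordinal scores** (vigor 1–10; maturation cycle 1–5; maturity uniformity
  1–4; fruit size; cercosporiosis and rust severity 1–5) are drawn as
  truncated normals with the published moments, then rounded to the nearest
  integer in range. Rounding and truncation bias the realized mean; the bias
  is computed in closed form (`ordinal_expected_mean()`) and stays below 0.4
  score points for every trait (the worst case is rust severity in Araponga,
  published mean 2.17 with sd 1.21 truncated at 1). The published fruit-size
  mean in Araponga (3.18) exceeds the nominal 3-point scale, so the fixture
  admits a fourth level.
* **Araponga redundancy.** Pre-harvest values (including bean production,
  which is measured per plot before the processing split and is published
  with identical moments for both Araponga entries) are drawn once per
  individual and copied to the matched row of the other Araponga
  environment.
* **Defaults are the study design:** 22 individuals per environment. The
  trait inventory is 31 specs: the 28 primary per-environment rows of the
  published moment table (the derived aggregates — total cupping score,
  total moca percentage, raw defect count alongside the defect percentage —
  are excluded) plus the three constant sensory attributes.

## The comparison pipeline

`env_discrim()` is the package's central fitting function. It removes
zero-variance traits (by design the three constant sensory scores, mirroring
their exclusion in the original analysis), builds a repeated proportional
stratified k-fold plan (default 4 folds x 10 repeats: individuals of every
environment are shuffled and dealt round-robin, so per-environment test
counts are 5 or 6 and average 5.5), and runs every requested classifier on
identical folds. Traits are rescaled to [0, 1] with training-fold min/max by
default; test values extrapolate without clipping. A `"global"` mode
normalizes once on the full data for literal replication of pipelines that
normalize before cross-validation — the original description does not say
which was done; per-fold is the default because it avoids information
leakage.

The eight supervised methods:

* **Fisher** — canonical discriminant axes from the within/between scatter
  eigenproblem (solved by Cholesky whitening; a small ridge enters only if
  the within scatter is numerically singular, which happens when an ordinal
  trait is constant within every training class), nearest class centroid in
  the canonical space.
* **Anderson** — the multivariate-normal equal-covariance linear scores with
  pooled covariance and frequency priors; ties go to the lowest class index.
* **Classification tree** — entropy splits (`entropy_impurity()`, natural
  log; deviance splitting is the same criterion scaled by 2n), grown to
  purity or node size < 2, no pruning.
* **Bagging** — 500 unpruned entropy trees on bootstrap resamples, plurality
  vote. With `B = 1` and the bootstrap disabled it reduces exactly to the
  single tree.
* **Random forest** — 500 trees with floor(sqrt(p)) candidate traits per
  split.
* **Boosting** — 500 sequential depth-2 trees, multinomial deviance,
  shrinkage 0.01 (gradient boosting, not AdaBoost, matching that
  parameterization).
* **MLP** — two hidden tanh layers, linear outputs against one-hot targets,
  Nguyen-Widrow initialization (weight vectors scaled to 0.7·H^(1/I), biases
  spaced across the active region), full-batch gradient descent with
  momentum 0.9 and a bold-driver step (grow 2% on improvement, halve on a
  rejected step), 5000 epochs, L2 weight penalty.
* **RBF** — K-means with K = 4 places the first centers; additional hidden
  units up to the configured count sit at the training points farthest from
  their cluster center (deterministic); Gaussian units
  phi(x) = exp(-||x-c||²/2r²); output weights by ridge least squares on
  one-hot targets (ridge 1e-4; the intercept is unpenalized).

An unsupervised **Kohonen map** (`fit_ksom()`, 4 units, 1000 online
iterations) is provided for the pattern-recognition question. Its
"standardized average Euclidean distance" is implemented as squared
Euclidean distance on range-standardized traits divided by the trait count —
the phrase has no canonical definition, so this reading is a documented
choice, not an assertion about the original software. On generated fixture
data the map's clusters do *not* align with the four environments (the
Araponga pair is unsupervised-indistinguishable), while four well-separated
clusters are recovered exactly.

### Architecture selection and regularization

Network capacity is chosen by inner validation inside every training fold: a
stratified 75/25 split, apparent error rate on the held-out quarter, ties to
the smaller network. Two package-level choices deserve explanation:

* The MLP's candidate grid crosses the architecture list (default one
  two-layer shape, 20+10 units, within the study's 5–40 range; widen via
  `discrim_control()`) with the L2 penalty (default {0.003, 0.01, 0.03}).
  The original training used Levenberg-Marquardt with *Bayesian*
  regularization, whose entire point is to set the effective weight penalty
  adaptively; a fixed penalty with plain gradient descent reproduces the
  model family but not that adaptivity, so the penalty is selected by the
  same inner-validation criterion that selects the architecture.
* The RBF's grid (hidden units 10–50, radius 5–15) is selected on the
  *average* inner AER over three stratified splits rather than one: the
  output stage is a closed-form ridge solve, so repeated refits cost little,
  and a single 17-point validation split is too coarse (one observation =
  5.9 percentage points of AER) to rank 15 candidates stably.

### Evaluation

Per fold, a confusion matrix (rows = true environment) and its apparent
error rate AER(%) = 100 x off-diagonal / total; per repeat, the mean over
the 4 folds (equal to pooling, since folds are equal-sized under the
balanced design); per method, the final AER is the mean of the 10 repeat
values, and the 40 fold matrices average element-wise into a matrix whose
rows total 5.5. The per-repeat AERs feed the Scott-Knott test: methods are
sorted by mean, the contiguous binary partition maximizing the between-group
sum of squares B0 is tested with lambda = pi/(2(pi-2)) · B0/sigma0², where
sigma0² blends the maximum-likelihood variance of the group's means with the
replicate-level error variance (classical formulation), against chi-squared
with k/(pi-2) degrees of freedom at alpha = 0.05; significant splits recurse.
Groups are therefore contiguous letter intervals. When replicate noise is
exactly zero, any mean difference separates — the test degenerates to
splitting, which is the correct limit.

### Trait importance

For the two networks, two disturbance techniques run on every test fold:

* **Zeroing**: all first-layer weights fed by trait j are set to zero (for
  the RBF the first-layer weights are the hidden-unit center coordinates).
  The model copy is discarded afterwards; the fitted model is never mutated.
* **Randomization**: trait j's column in the *test* inputs is permuted
  (seeded; one draw per test set by default, `n_draws` to average several).
  Test-input permutation is used because the forecast of the already-trained
  network is what is being disturbed. Unlike zeroing, permuted values stay
  inside the trait's biological range.

Each yields Delta = AER_modified - AER_complete per (trait, test set).
Per-trait sums over all 40 test sets are floored at zero and normalized to
relative importances summing to 100% (raw signed sums are kept alongside);
a trait is *selected* when its mean RI across the four technique x network
quadrants exceeds 15%. Two honest caveats: RBF center-zeroing perturbs the
flat Gaussian kernels only weakly and can leave all predictions unchanged
(its quadrant then contributes near-uniform or degenerate RI), and with 28
informative traits the 15% cutoff is a high bar — on generated fixture data
the RI mass spreads more evenly than on the real trial, so typically only
the strongest separator (bean production) clears it.

## Numerical choices and degenerate inputs

* Entropy uses the natural logarithm; zero proportions contribute zero.
* Argmax decoding breaks ties toward the lowest class index, everywhere.
* Empty K-means clusters are handled by re-seeding (up to 5 attempts).
* Non-finite MLP loss aborts with an error rather than returning garbage;
  the bold-driver rollback makes this unreachable in practice.
* All randomness flows from one master seed through a deterministic
  child-seed derivation per (method, repeat, fold), so adding a method to a
  configuration does not perturb any other method's stream, and rerunning a
  configuration reproduces the report byte-for-byte.
* CSV round trips write doubles as `%.17g`, so written datasets re-read
  bit-identically.

## Problem sizes used in the shipped checks

The package's own test suite runs the full eight-method comparison at the
study design (22 per environment, 4 folds x 10 repeats) with the default
control settings; generator moment-recovery checks use 5,000–10,000
individuals per environment; importance-recovery checks use a constructed
dataset in which four planted traits fully determine four classes among
noise traits, where the dual procedure must select exactly those four.
These sizes were chosen as the smallest that make the stochastic claims
sharp.

## Limitations

* Independence across traits and exchangeability within environment are
  simplifications; real data have genotype structure, block effects and
  strong trait correlations. One measurable consequence: independent
  axis-aligned features suit tree ensembles unusually well, and on generated
  fixture data the random forest can outperform both networks even while the
  networks beat the linear discriminant rules — a ranking the original
  correlated field data did not produce.
* The MLP optimizer is not Levenberg-Marquardt; with small networks the
  reachable minima are comparable, but step-for-step replication of
  `trainbr` is out of scope.
* The Kohonen map's distance and the RBF's zeroing semantics are reasoned
  reconstructions of underspecified descriptions, flagged as such above.
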