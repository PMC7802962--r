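# coffeeDiscrim

Multi-trait environment discrimination for *Coffea arabica* phenotypes.

Coffee grown at different sites and processed by different post-harvest
routes (pulped vs natural) expresses those factors across many traits at
once — plant height, fruit size, bean production, sieve and defect profiles,
sensory cupping scores. This package treats environment identification as a
supervised multivariate classification problem on such trait panels, for
plant-breeding and coffee-quality researchers who want to know (a) whether
environments leave a recoverable multi-trait signature and (b) which traits
carry it.

It implements, end to end:

* a **synthetic phenotype generator** parameterized by the published
  per-environment trait means and standard deviations of a four-environment
  Matas de Minas trial (three sites; the Araponga site split into pulped and
  natural processing, sharing identical pre-harvest values between the two);
* **repeated proportional stratified k-fold cross-validation** (4 folds x 10
  repeats; 5–6 test individuals per environment per fold, mean 5.5);
* **eight classifiers** behind one fit/predict contract: Fisher and Anderson
  discriminant rules, an entropy classification tree, bagging (500 trees),
  random forest (500 trees, sqrt(p) candidates per split), multinomial
  gradient boosting (500 depth-2 trees, 1% shrinkage), a two-hidden-layer
  tanh MLP with Nguyen–Widrow initialization, and a K-means/Gaussian RBF
  network — plus an unsupervised Kohonen self-organizing map;
* **evaluation** by the apparent error rate,
  `AER(%) = 100 · Σ off-diagonal / Σ total` of the test-fold confusion
  matrix, with fold-averaged confusion matrices and **Scott-Knott** grouping
  of the per-repeat method means at α = 0.05
  (λ = π/(2(π−2)) · B₀/σ̂₀² against χ² with k/(π−2) df);
* **dual trait importance** for the networks: weight-zeroing
  (first-layer weights of one input set to 0) and input-randomization
  (test-column permutation), each summarized as relative importance
  `RI_j(%) = 100 · Σ_i (AER_mod(j) − AER_com)_i / Σ_j Σ_i (…)`, with traits
  selected when their mean RI over the four technique × network quadrants
  exceeds 15%.

See `vignette("environment-discrimination")` for the models, assumptions and
design choices.

## Worked example

```r
library(coffeeDiscrim)

ds  <- generate_phenotypes(n_per_env = 22, seed = 42)   # 88 x 31 + labels
fit <- env_discrim(ds, methods = c("fisher", "anderson", "tree", "mlp"),
                   n_repeats = 5, seed = 7)
print(fit)
```

```
Multi-environment discrimination comparison
   28 traits, 4 environments, 4 folds x 5 repeats
  zero-variance traits removed: CleanCup, Sweetness, Uniformity
   method AER(%) group
   fisher   4.77     a
 anderson   4.77     a
     tree  10.45     b
      mlp   3.86     a
Important traits (mean RI > 15 %): Prod, Body, Overall
```

The three constant sensory attributes (clean cup, sweetness, uniformity, all
at the maximum score of 10) carry no information and are removed up front,
leaving 28 traits. The per-method numbers are final apparent error rates —
each the mean over 5 repeats of 4-fold cross-validation — and the letters
are Scott-Knott groups (methods sharing a letter do not differ at the 5%
level): here the MLP and the two discriminant rules are statistically
indistinguishable and all beat the single tree. `fit$confusion$mlp` shows
*where* the residual error lives:

```
fold-averaged MLP confusion matrix:
                        assigned
true                     PaulaCandido.Pulped SenhoraOliveira.Pulped Araponga.Pulped Araponga.Natural
  PaulaCandido.Pulped                   5.50                   0.00            0.00             0.00
  SenhoraOliveira.Pulped                0.00                   5.50            0.00             0.00
  Araponga.Pulped                       0.00                   0.00            4.90             0.60
  Araponga.Natural                      0.00                   0.00            0.25             5.25
```

Rows total 5.5 (the average per-environment test count) and the grand total
is 22 (one test fold). The two production sites with distinct climates are
classified perfectly; essentially all confusion sits between the two
Araponga environments, which are the same plants split by post-harvest
processing and differ only in post-harvest and sensory traits.
`plot(fit)` draws the AER boxplot with the group letters;
`plot(fit, "importance")` the four relative-importance quadrants.

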