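---
title: "Coreferentiality: model, test, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coreferentiality: model, test, and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coref)
```

## The statistic and its null hypothesis

Given two test variables $X_1, X_2$ and a reference set
$\mathbf{Y} = \{Y_1, \dots, Y_k\}$ measured on the same $N$ samples, the
coefficient of coreferentiality is the Pearson correlation of the two
correlation profiles,

$$
R_C \;=\; \mathrm{cor}\big(\,(\rho(X_1, Y_i))_{i=1..k},\;
                             (\rho(X_2, Y_i))_{i=1..k}\,\big).
$$

It measures whether the two variables parallel each other in their
relatedness to the reference data — an *indirect* relation that is
deliberately distinct from their direct correlation $R = \rho(X_1, X_2)$:
correlated variables need not be coreferential (if neither relates to
$\mathbf{Y}$), and coreferential variables need not be correlated.

The null hypothesis is that $R_C$ equals its no-association expectation
$R_{C0}$. Crucially, $R_{C0} \ne 0$ in general: when $X_1$ and $X_2$ are
directly correlated, even reference data independent of both produce
profiles whose sampling errors correlate, and $R_{C0} \approx R$. The test
must therefore compare the observed $R_C$ against a null distribution that
*preserves* $R$ and the internal correlation structure of $\mathbf{Y}$.

## The permutation test

`coref_test()` generates the null by **parallel reshuffling**: each of
`n_perm` uniform random permutations of the sample indices is applied
jointly to $X_1$ and $X_2$ (the same permutation for both) while
$\mathbf{Y}$ stays in place. This breaks any $X$–$\mathbf{Y}$ association
while leaving $R$ and the $\mathbf{Y}$ structure intact. The two-tailed
empirical p-value counts permutations whose $|R_C|$ reaches the observed
value.

Numerical and procedural choices:

* **Counting rule.** The default is the add-one randomization correction
  $p = (1 + \#\{|R_C^{perm}| \ge |R_C^{obs}|\}) / (n_{perm} + 1)$, which
  guarantees $p > 0$; `p_rule = "strict"` gives the plain
  strict-exceedance proportion. For continuous data ties have measure
  zero and the two differ only by the correction.
* **Tie tolerance.** $|R_C|$ comparisons use a $10^{-12}$ tolerance so
  that last-ulp recomputation noise cannot decide whether a permutation
  counts as reaching the observed statistic. This matters only for
  exactly tied (e.g. rank-structured) inputs.
* **Exhaustive mode.** For $N \le 6$ (`exhaustive = "auto"`) or on request
  up to $N = 8$, all $N!$ permutations are enumerated and the exact
  proportion (identity included, hence $p > 0$) is reported. The test
  suite verifies Monte-Carlo/exhaustive agreement against an
  independently coded enumeration oracle.
* **Permutation sampling.** Uniform with replacement across draws; the
  identity permutation may be drawn. Every stochastic operation takes an
  explicit seed and is bit-reproducible.
* **Correlation kind.** Pearson throughout ("linear correlations");
  `method = "spearman"` rank-transforms everything first but is never the
  default. Only the two-tailed test is offered.
* **Minimum dimensions.** $N \ge 4$ and $k \ge 3$ are hard errors (with
  $k = 2$ the profile correlation is always $\pm 1$). Missing values are
  hard errors, not silently deleted: the permutation scheme assumes
  complete rows.

## The bystander control

A significant $R_C$ can arise when only $X_1$ drives $\mathbf{Y}$ and
$X_2$ merely correlates with $X_1$. `bystander_control()` quantifies this:
it simulates artificial secondary variables
$X_2' = r z_1 + \sqrt{1 - r^2}\,\varepsilon$ with $r = \hat\rho(X_1, X_2)$,
$z_1$ the standardized $X_1$ and fresh Gaussian $\varepsilon$, and reports
the (add-one corrected) fraction of replicates whose $|R_C|$ reaches the
observed one. Under datasets where $X_2$ really is a pure bystander this
p-value is approximately uniform (verified in the test suite); genuinely
both-informative data push it far below 0.05.

## The synthetic-data generator

`simulate_coref_data()` reproduces the generative model of the power
study. Test pairs are Gaussian with standard deviation $\sigma = 10$
(immaterial: every statistic in the package is affine-invariant, which the
suite checks by comparing $\sigma = 1$ against $\sigma = 10$), correlated
at an exact population value $r_x$ via
$X_2 = r_x X_1 + \sqrt{1 - r_x^2}\, e$. Each reference variable mixes the
test variables and fresh noise with a weight $w_i$ taken from a linear
gradient $-2\delta, \dots, +2\delta$ (so the average absolute weight is
$\delta$, the "average degree of determination"):

* `both_informative`: $Y_i = w_i X_1 + w_i X_2 + (1 - 2|w_i|) E_i$
* `bystander`: $Y_i = w_i X_1 + (1 - |w_i|) E_i$
* `null`: $Y_i = E_i$

Design choices where the verbal model description left room:

* **Aligned gradients.** The *same* $w_i$ multiplies both test variables
  in `both_informative` mode. If the two weight gradients were ordered
  independently, the expected profile correlation would be zero and no
  coreferentiality could exist at any $\delta$; alignment is the only
  reading consistent with the method having power at all.
* **Complementary noise weight.** The noise coefficient is one minus the
  summed absolute signal weights, by analogy with the explicit bivariate
  mixture $X_2 = \delta X_1 + (1 - \delta) E$ used for the regression
  baseline. This restricts $\delta \le 0.25$; a $\delta$ that makes any
  noise coefficient non-positive is a hard error.
* **Per-column noise.** Each $E_i$ is drawn independently per column; a
  noise vector shared across columns would make both profiles
  near-deterministic functions of the gradient and drive power to 100%
  even at $\delta = 0.01$, contradicting the intended low-information
  regime.
* **Index-ordered gradient.** Weights are assigned to columns in index
  order; column order never enters $R_C$, so a shuffled assignment would
  change nothing.
* **Contamination.** Noninformative contamination columns are i.i.d.
  Gaussian, independent of everything; `include_x1_in_y` /
  `include_x2_in_y` append the test variables verbatim, creating the
  correlation outlier that degrades power.

The generator emulates Gaussian, linearly mixed, homoscedastic data. Real
phenotype panels are heavier-tailed, heteroscedastic, block-correlated and
occasionally missing; passing tests on these simulations therefore
demonstrate the statistic's operating characteristics under its own
generative model, not robustness to those features (Spearman mode and the
hard missing-data errors are the package's concessions to them).

## The power study

`run_power_condition()` simulates `n_sims` independent datasets per
condition, applies the chosen test, and reports the rejection fraction at
$\alpha$ plus the median $R_C$; `run_power_grid()` maps this over a tidy
condition table. Two deterministic seed streams (data and permutations)
are derived per condition from the master seed, so any single replicate is
reproducible in isolation and results are independent of evaluation order.

The comparison baselines follow the stated procedures: PCA-score multiple
regression (`pca_regression_test()`, correlation-matrix PCA of the
standardized reference columns — their variances differ along the
gradient — with $x$ regressed on the leading 10 or 50 score vectors and
the overall F-test p reported; the two-variable bookkeeping uses the first
test variable's own regression, as no combining rule is stated and the
construction is symmetric), and simple bivariate regression
(`bivariate_regression_test()`) on pairs generated by the literal mixture
$X_2 = \delta X_1 + (1 - \delta) E$.

Default study scales follow the source conditions throughout: 100
simulated datasets per condition, 1000 permutations per test,
$\alpha = 0.05$, $k = 130$ reference variables, sample sizes 50–500. The
acceptance script and the acceptance test file run at exactly these
scales; a few supporting calibration checks in the unit suite use 50–500
replicates with proportionally reduced permutation counts, chosen to keep
each check's Monte-Carlo error well inside the asserted band.

## Known limitations

* Under the generative convention above, simulated power at
  small-$N$/large-$\delta$ conditions (e.g. $N = 100$, $\delta = 0.05$)
  plateaus 10–20 points below the strongest published claims for this
  design, while specificity, the $R_{C0} \approx R$ behaviour,
  contamination orderings and large-$N$ power reproduce well. Because all
  involved statistics are scale-invariant, the only free parameter of the
  mixture family is an effective $\delta$ multiplier, and no single value
  reconciles all published anchors simultaneously; the package keeps the
  literal convention rather than tuning toward any one of them. The
  acceptance suite asserts the published bounds faithfully and lets the
  unattainable ones fail.
* The permutation test's smallest reportable p is $1/(n_{perm}+1)$;
  studies needing smaller p must raise `n_perm`.
* No multiple-testing correction across many variable pairs is provided;
  the intended use is single, hypothesis-defined pairs.
* Canonical correlation and PLS are out of scope (they address dependency
  modeling, not profile parallelism).
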