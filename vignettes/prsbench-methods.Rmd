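---
title: "Simulating and benchmarking genetic disease prediction with prsbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and benchmarking genetic disease prediction with prsbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the package addresses

Polygenic risk scores (PRS) and machine-learning classifiers are both used
to predict a binary disease phenotype from panels of susceptibility SNPs,
but their behaviour under controlled genetic architectures — mode of
inheritance, effect-size distribution, fraction of null markers — is hard
to study on real data, where the truth is unknown. `prsbench` builds the
controlled setting: it simulates case/control multilocus genotypes from an
explicit penetrance model, scores individuals with the standard
log-odds-ratio PRS, benchmarks four classifier families by test-set ROC
AUC, and evaluates two closed-form approximations that predict AUC from
PRS summary statistics alone.

## The disease model

Each biallelic site carries a risk allele with population frequency $p$
and genotype penetrances $f_{11} \le f_{12} \le f_{22}$, the probabilities
of disease given 0, 1 or 2 risk alleles. Penetrances are built from a
wild-type baseline $f_{11}$ and an absolute increment $\delta \ge 0$:

| mode      | $f_{12}$           | $f_{22}$            |
|-----------|--------------------|---------------------|
| recessive | $f_{11}$           | $f_{11} + \delta$   |
| dominant  | $f_{11} + \delta$  | $f_{11} + \delta$   |
| additive  | $f_{11} + \delta$  | $f_{11} + 2\delta$  |
| null      | $f_{11}$           | $f_{11}$            |

Writing the genotypic relative risk as $\gamma = 1 + \delta/f_{11}$, these
are the classical relations $f_{22} = \gamma f_{12}$ (recessive),
$f_{22} = f_{12} = \gamma f_{11}$ (dominant) and $f_{12} = \gamma f_{11}$,
$f_{22} = (2\gamma - 1) f_{11}$ (additive). We parameterize by the
absolute increment rather than by $\gamma$ because it makes the simulated
risk range transparent: with the default baseline $f_{11} = 0.01$ and the
top of the default grid ($\hat\delta = 0.0075$, below), a dominant or
recessive site's maximal penetrance is uniform on $[0.01,\, 0.025]$.
Note that an additive site's homozygote reaches $f_{11} + 2\delta$ — up to
0.04 at the top of the grid — so at equal $\hat\delta$ the additive
architecture carries *more* per-site information than the dominant one
(the heterozygote gains the same $\delta$ while the homozygote gains
twice as much, and it raises the site prevalence by $2p\delta$ versus
$(1-(1-p)^2)\delta < 2p\delta$). This matters when comparing
mode-specific results: in this parameterization additive architectures
reach a given AUC at *smaller* $\hat\delta$ than dominant ones, while
dominant architectures still produce the largest case/control PRS
separation. Constructors reject any combination with $f_{22} > 1$ rather
than clipping; an invalid model should fail loudly.

Under Hardy–Weinberg equilibrium, Bayes inversion gives the genotype
distribution conditional on status at one site,

$$P(g \mid \text{case}) = \frac{f(g)\,P(g)}{K}, \qquad
  P(g \mid \text{control}) = \frac{(1 - f(g))\,P(g)}{1 - K},$$

with $K = \sum_g f(g) P(g)$ the site's marginal prevalence. Mixing the two
conditionals with weights $(K, 1-K)$ recovers the Hardy–Weinberg marginal
exactly; the test suite asserts this identity to $10^{-12}$ over random
penetrance models.

## What the generator emulates — and what it does not

`sample_architecture()` draws, independently per site, a risk-allele
frequency $p \sim \mathrm{Beta}(1.9195,\ 5.6067)$ (mean 0.255, variance
0.0223 — a method-of-moments fit to the site-frequency spectrum of
genome-wide-significant GWAS SNPs) and, for risk sites, an increment
$\delta \sim \mathrm{Uniform}[0,\ 2\hat\delta]$, so $\hat\delta$ is the
expected per-site perturbation and the natural grid parameter. The default
panel is 500 risk sites plus 50 null sites: the setting emulated is a
*post-GWAS* panel in which most markers are true positives and roughly
10% are false positives, not an exploratory scan where nulls dominate.

`simulate_cohort()` assigns disease status first (balanced groups, default
2000 cases + 2000 controls for both a training and a test cohort) and then
draws every genotype independently from the site's conditional
distribution. Consequences worth keeping in mind when extrapolating to
real data:

* **Linkage equilibrium.** Sites are independent by construction. Real
  panels have residual LD; PRS methods that clump or shrink for LD are out
  of scope.
* **No epistasis, no gene–environment interaction.** Site effects combine
  only through the per-site conditionals; the baseline $f_{11}$ absorbs
  environmental risk.
* **No population structure.** Individuals are exchangeable draws from one
  ancestry with one allele-frequency distribution; no relatedness, no
  genotyping error, no missingness.
* **Per-site prevalence.** Because sampling is conditional on status,
  no genome-wide prevalence is imposed; each site uses its own marginal
  prevalence in the inversion. This matches the independence assumption
  but means "prevalence" is a per-site quantity, not a cohort property.

Passing tests therefore certify the machinery under these idealized
conditions; they do not certify performance on structured, LD-rich data.

By default a *fresh* architecture (new $p$ and $\delta$ draws) is sampled
for every replicate, so replicate-to-replicate spread includes
architecture variation as well as sampling noise; set
`fresh_architecture = FALSE` in `grid_config()` to hold one architecture
fixed per grid cell.

## The polygenic risk score

Weights are estimated on the training cohort only: per site, the risk
allele frequencies in cases and controls ($f_{cs}$, $f_{ct}$, computed as
risk-allele count over $2 \times$ group size) give the allelic odds ratio
$\mathrm{OR} = f_{cs}(1-f_{ct}) / (f_{ct}(1-f_{cs}))$, and an individual
with risk-allele counts $X_i$ scores

$$\mathrm{PRS} = \frac{1}{2n} \sum_{i=1}^{n} \ln(\mathrm{OR}_i)\, X_i,$$

with $n$ the number of sites (all 550 by default — the same panel the
classifiers see; a feature mask can restrict it). The $1/(2n)$ convention
normalizes by the maximal allele count, so the score is a per-allele
average; all reported PRS quantities (case/control means, their difference
$\Delta\mathrm{PRS}$, variances) are on this scale, and any comparison
with scores normalized differently (e.g. $1/n$) must rescale first —
$\Delta\mathrm{PRS}$ scales linearly and variances quadratically with the
convention. When a training allele count is 0 or $2n_\text{group}$ the
Haldane–Anscombe correction (add 0.5 to all four cells of that site's
allele table) keeps the weight finite; corrected sites are flagged.
Scores and summaries are computed out-of-sample on the test cohort,
avoiding the optimism of scoring the cohort that produced the weights.
The $R^2$ reported with each summary is the squared Pearson correlation
of score with the 0/1 phenotype, identical to the $R^2$ of the simple
linear regression of score on phenotype.

## Classifiers and the AUC

Four families, each behind one interface (`fit_predict()`), all consuming
the additive 0/1/2 encoding:

* **LR** — logistic regression via glmnet with a minimal ridge penalty
  ($\lambda = 10^{-4}$). At the top of the $\hat\delta$ grid the classes
  become quasi-separable and an unpenalized IRLS fit can fail or return
  unstable coefficients; the tiny ridge stabilizes the fit and changes
  measured AUC by well under $10^{-3}$.
* **NB** — Gaussian naive Bayes on the numeric genotype counts, fitted
  with e1071. Scoring is vectorized from the fitted class-conditional
  tables (the reference `predict()` loops over rows at R level, which is
  prohibitive at $4000 \times 550$); the test suite pins our scores to the
  reference predictions at $10^{-10}$.
* **RF** — probability random forest via ranger: 500 trees,
  $\lfloor\sqrt{L}\rfloor$ candidate features per split, single-threaded
  and seeded so runs are reproducible.
* **NN** — a single-hidden-layer feed-forward network (nnet): 4 logistic
  hidden units, weight decay $10^{-3}$, at most 100 BFGS iterations. The
  size is deliberately small: nnet's optimizer stores an
  $O(W^2)$ quasi-Newton matrix, and $W$ grows with
  $L \times \text{units}$, so a few hundred units over 550 inputs is not
  tractable here. The family reproduces the qualitative benchmark finding
  (the network underperforms the other three families at moderate signal)
  and all sizes are configurable through `classifier_spec()`. Reaching
  the iteration cap is recorded in the `converged` flag and the replicate
  is kept, never silently dropped.

Optional LASSO feature selection (`lasso_select()`) fits the L1 logistic
path over penalties $\{0, 0.01, \ldots, 0.05\}$ and enforces a retention
floor: a penalty qualifies only if it keeps at least 10% of sites. The
floor is applied per candidate penalty, with the replicate falling back to
no selection (flagged `fs_failed`) if nothing qualifies. Among qualifying
penalties we pick the one minimizing 5-fold cross-validated deviance —
the selection rule was an open design choice, and cross-validated deviance
is the standard, auditable one. Note that the unpenalized grid point
retains everything and often wins the deviance comparison at strong
signal, which is exactly why feature selection barely moves the AUC in
this regime. The selection path uses a looser coordinate-descent
tolerance ($10^{-5}$) than glmnet's default; only the support set and the
fold-level deviance ordering matter for selection, and both are stable at
this tolerance while unpenalized fits become dramatically cheaper.

AUC is computed by the rank-sum (Mann–Whitney) identity with mid-ranks for
ties — the probability that a random case outscores a random control,
ties counting one half — and `auc_empirical()` also returns the
tie-grouped ROC curve, whose trapezoidal area equals the rank-sum value
(asserted to $10^{-12}$; also cross-checked against pROC).

## Closed-form AUC predictions

Two standard approximations map PRS summaries to an expected AUC:

* **Liability threshold** (`auc_liability()`):
  $\Phi\!\left((\mu_\text{case} - \mu_\text{ctrl}) /
  \sqrt{\sigma^2_\text{case} + \sigma^2_\text{ctrl}}\right)$, the
  two-normal concordance probability with plug-in test-cohort moments.
* **Log-risk** (`auc_log_risk()`):
  $\Phi\!\left(\sqrt{R^2 (1-K)^2 / (2P(1-P))}\right)$ with population
  prevalence $K = 0.01$ (the simulated wild-type baseline) and sample
  prevalence $P = 0.5$ (balanced design). At these defaults the argument
  is capped at $R^2 = 1$, so the prediction cannot exceed
  $\Phi(1.4001) \approx 0.919$ — the model saturates below 1 by
  construction.

Both were derived for additive risk; `compare_analytic_empirical()`
nevertheless tabulates them for every inheritance mode, labeled, so the
quality of the approximation can be contrasted across modes. The liability
prediction is validated in the tests against a brute-force two-normal
Monte Carlo concordance oracle.

## Randomness and reproducibility

Every stochastic step takes a seed derived with `derive_seed()` — an
exact 32-bit hash of a master seed plus named labels (architecture,
delta-hat, replicate, cohort role, classifier family). A grid run is a
pure function of `(config, master_seed)`: the suite asserts that two runs
produce byte-identical records, and any single replicate can be
regenerated in isolation from its labels.

## Numerical and degenerate-input conventions

* Penetrance models with $f_{11} + 2\delta > 1$ and grid points with
  $f_{11} + 4\hat\delta > 1$ are rejected at construction.
* Sites with prevalence 0 or 1 make the conditional distributions
  undefined and are rejected.
* Constant PRS scores define $R^2 = 0$ (and the normality checks return
  `NA`).
* Gaussian NB class-conditional standard deviations are floored at
  $10^{-6}$ so a within-class-constant feature cannot produce infinite
  scores.
* Correlations over degenerate (constant) columns are reported as `NA`
  with a warning rather than an error.
* All-equal scores give AUC exactly 0.5 under the mid-rank convention.

## Problem sizes used by the shipped checks

The default test suite exercises the full study conditions (550 sites,
2000 + 2000 genomes per cohort) wherever a published operating
characteristic is asserted — null calibration, the dominant high-signal
check, the AUC-versus-$\Delta$PRS correlations (16 grid values with 10
replicates each per mode), PRS normality, and the feature-selection
neutrality check — and desk-scale cohorts (tens of sites, hundreds of
genomes) for the structural and property-based tests. The full
publication-scale design (100 replicates, four classifiers, both
feature-selection arms, all five architectures) is available as a
configuration (`grid_config(replicates = 100, ...)`) and is sized for an
overnight run; `scripts/acceptance.R` reruns the headline quantities at
the 10-replicate scale.

## Known limitations

* The NN family is a deliberately small single-hidden-layer network; it
  stands in for "a default feed-forward network" and its absolute AUC
  should not be read as the ceiling of neural approaches.
* PRS magnitudes depend on the $1/(2n)$ normalization; compare across
  conventions only after rescaling ($\times 2$ for means, $\times 4$ for
  variances against a $1/n$ convention).
* The log-risk approximation assumes a rare disease and equal
  case/control PRS variances; at the top of the grid the variances
  diverge and the approximation saturates below 1.
* Mixed architectures are supported end to end, but the analytic AUC
  formulas remain additive-model approximations there.
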