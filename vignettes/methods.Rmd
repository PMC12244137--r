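---
title: "Latent-variable modelling of regional PET binding with a left-censored hormone covariate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-variable modelling of regional PET binding with a left-censored hormone covariate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petlvm)
```

## The scientific problem

Serotonin-4 receptor (5-HT4R) availability can be quantified by PET as the
non-displaceable binding potential (BP\_ND) in individual brain regions. In
studies of depression, four regions are of particular interest — neostriatum
(high binding), hippocampus and amygdala (intermediate), and prefrontal
cortex (low binding) — and the scientific questions concern a *global*
receptor level: does it differ between men with major depressive disorder
(MDD) and healthy controls (HC), and how does it relate to plasma
testosterone and estradiol, given that estradiol in men derives largely from
aromatisation of testosterone?

Two features make off-the-shelf regression unsuitable. First, the four
regional outcomes are noisy indicators of one latent quantity, so effects
should be estimated on a common factor rather than region by region. Second,
plasma estradiol is measured with an assay whose lower limit of
quantification (LOQ) is 0.09 nM; a substantial fraction of samples fall at
or below it and are *left-censored* — known only to be at most 0.09 nM.
`petlvm` implements the full analysis chain: a linear latent-variable model
(LVM) with a closed-form censored-likelihood contribution, mediation
decomposition of the testosterone effect with delta-method inference,
score-test-driven refinement of the residual covariance structure, Gehan's
generalized Wilcoxon test for censored group comparisons, and a regularized
partial-correlation network over symptoms, hormones and neostriatal binding.

## The two models

**Group-difference model.** For subject $i$ with group indicator $G_i$
(0 = HC, 1 = MDD) and covariates $x_i$ (age in years, injected tracer mass
per kg, PET scanner HRRT/GE):

$$Y_{ri} = \nu_r + \lambda_r \eta_i + \beta_r' x_i + \epsilon_{ri}, \qquad
  \eta_i = \gamma_G G_i + \zeta_i,$$

with $\zeta_i \sim N(0, \sigma_\zeta^2)$ independent of
$\epsilon_i \sim N(0, \Psi)$. $\Psi$ is diagonal, optionally extended by
free residual covariances added by the diagnostic refinement (in practice
the hippocampus–amygdala pair). Covariates enter the measurement equations
only; group enters the structural equation only. The first loading
($\lambda_{\text{neostriatum}}$) is fixed at 1 for identification with
$\sigma_\zeta$ free; a variance normalization ($\sigma_\zeta = 1$, all
loadings free) is available behind a flag and implies identical fitted
moments.

**Hormone model.** Testosterone $T$ and estradiol $E$ (nM) act on the latent
factor with group-specific slopes, and estradiol is linearly coupled to
testosterone with a slope shared across groups:

$$\eta_i = \gamma_G G_i + (\gamma_1 + \Delta\gamma_1 G_i)\,T_i
  + (\gamma_2 + \Delta\gamma_2 G_i)\,E_i + \zeta_i, \qquad
  E_i = \alpha_E + \gamma_3 T_i + \epsilon_{E,i}.$$

The group main effect is retained alongside the hormone terms. Within each
group the model is linear-Gaussian given $(T, G, x)$, so the observable
vector (four regions plus estradiol) is exactly multivariate normal — the
fact every likelihood computation below exploits.

## Left-censored estradiol

A subject whose estradiol is at or below the LOQ contributes the likelihood
integrated over the unobserved concentration:

$$\int_{-\infty}^{LOQ} f(y, e)\,de \;=\;
  \phi_Y(y)\,\Phi\!\left(\frac{LOQ - \mu_{E|Y}}{\sigma_{E|Y}}\right),$$

the marginal Gaussian density of the regional outcomes times the
conditional-Gaussian probability that estradiol lies below the limit. This
closed form is exact per group because the model is linear-Gaussian per
group; the test suite verifies it against adaptive numerical quadrature of
the joint density to $10^{-8}$ on random parameter draws.

Three censoring modes are exposed:

* `integrate_main_only` (default): the integration runs through the main
  estradiol effect only, and the estradiol-by-group interaction covariate is
  plugged in at the LOQ for censored rows. This reproduces the
  simplification that stabilizes estimation when the fully interacted
  censored model is fragile at small n; for HC subjects it coincides with
  the exact treatment.
* `integrate_full`: exact per-group integration. This is the mode used in
  all parameter-recovery simulations, since it is unbiased by construction.
* `plugin`: censored values treated as observed at the LOQ (for sensitivity
  comparisons only).

## Estimation and inference

`fit_lvm()` maximizes the log-likelihood by BFGS from moment-based starting
values: per-region least squares gives intercepts and covariate slopes,
triad ratios of the residual covariance give loadings, and a least-squares
pass of the first region's residual on the structural predictors gives the
structural slopes. SD parameters are log-parameterized (a raw-SD
parameterization is available and reaches the same maximum). The optimizer
runs at relative tolerance $10^{-8}$ with up to 500 iterations and restarts
from its own solution until no further gain, which guards against early
line-search termination on strongly correlated parameters. Standard errors
come from the inverse observed information (central-difference Hessian at
the optimum); every free parameter is reported with a Wald two-sided p-value
and a 95% confidence interval, unadjusted for multiplicity. Fits that do not
converge refuse to report estimates.

Rows missing any model variable are dropped listwise with a logged count.
Group is coded 0 = HC / 1 = MDD (so $\gamma_G$ is MDD−HC) and scanner
0 = HRRT / 1 = GE.

## Mediation decomposition

Within group $g$, the direct effect of testosterone on the latent factor is
$\gamma_1(g)$, the estradiol-mediated indirect effect is
$\gamma_2(g)\,\gamma_3$, and the total effect is their sum. Group contrasts
subtract the HC functional from the MDD one; because $\gamma_3$ is shared,
the total-effect contrast reduces to
$\Delta\gamma_1 + \Delta\gamma_2\,\gamma_3$. Standard errors use the
first-order delta method with the joint estimated covariance of
$(\gamma_1, \Delta\gamma_1, \gamma_2, \Delta\gamma_2, \gamma_3)$, including
cross-covariances; the tests check these against a 2000-draw parametric
bootstrap (within 10%). A second-order correction is deliberately omitted:
it is what standard latent-variable software reports, and the worked
confidence intervals are symmetric.

## Residual-covariance diagnostics

`score_tests()` computes a Rao score statistic for every region pair without
a free residual covariance: the extended model's gradient is evaluated
numerically at the restricted MLE (candidate fixed at 0) and combined with
the **expected** (Fisher) information, assembled from numerical derivatives
of the model-implied moments for Gaussian blocks and from per-subject
outer-product gradients for censored rows. The expected information is used
deliberately: at a restricted MLE under strong misspecification the observed
Hessian of the extended model can be indefinite along the candidate
direction (the restricted optimum is a saddle of the extended likelihood),
which produces negative "statistics"; the expected information is positive
semi-definite at any evaluation point and keeps the statistic a proper
chi-square(1) quantity. On large simulated cohorts the statistic agrees with
the likelihood-ratio statistic within 10% for the leading candidate.

`refine_covariance()` implements the stepwise loop: fit, score-test all
candidates, Holm–Bonferroni-adjust within the current round's family (the
family shrinks as parameters are added; whether adjustment should span
rounds is not determined by the source procedure, and per-round adjustment
is the choice documented here), add the smallest-p candidate if its adjusted
p-value is below $\alpha = 0.05$, and repeat. Ties break by region-pair
lexicographic order. The loop terminates because the candidate set strictly
shrinks.

**A structural caveat.** With four indicators on a single factor, the
measurement covariance has 10 moments against 8 parameters. An omitted
residual covariance on (hippocampus, amygdala) violates exactly one tetrad
constraint — and freeing the complementary pair (neostriatum, prefrontal)
satisfies the same constraint exactly. The two extended models fit the true
covariance equally well, so their score statistics share one asymptotic
noncentrality and which pair attains the smallest p-value is decided by
sampling noise (roughly 60/40 in favour of the true pair at n = 2000 in our
simulations). The refinement therefore reliably detects *that* a covariance
is missing (and the implied covariance, and hence all structural estimates,
are identical whichever of the two is added), but the identity of the pair
is not asymptotically recoverable from four indicators alone. Substantive
knowledge — the anatomical adjacency of hippocampus and amygdala — is what
selects between them.

## Censored group comparisons

`gehan_test()` scores every between-group pair +1/−1/0. Under
left-censoring, a censored value at $c$ means "at most $c$": observation $i$
is unambiguously greater than $j$ only when $i$ is uncensored and its value
exceeds $j$'s value or bound; two censored values never separate; ties score
0. The statistic is the sum of scores, equal to the Mann–Whitney
$U_1 - U_2$ difference when no value is censored. Inference is by label
permutation — exhaustive enumeration up to n = 10, seeded Monte-Carlo with
10,000 draws by default — or by the asymptotic normal approximation with the
permutation variance $\frac{n_A n_B}{n(n-1)} \sum_i h_i^2$ on the pair-score
row sums $h_i$. Welch's t-test (Satterthwaite df) covers the uncensored
testosterone comparison.

## The symptom–hormone–receptor network

`mdd_symptom_network()` builds nine nodes from the MDD subjects: neostriatal
BP\_ND residualized on age and tracer dose, testosterone and a binary
above/below-LOQ estradiol indicator residualized on age (ordinary
least-squares residualization throughout — for the binary node these are
linear-probability residuals, which keeps the Pearson correlation matrix
well defined), the six-item HAMD6 core-depression subscale (items 1, 2, 7,
8, 10, 13), and the five vegetative HAMD items (initial/middle/delayed
insomnia, gastrointestinal symptoms, weight loss) individually.

`ebic_glasso()` estimates a sparse precision matrix by graphical lasso
(block coordinate descent, off-diagonal L1 penalty) over a logarithmic grid
of 100 penalties spanning [0.01, 1] times the largest absolute off-diagonal
correlation. The penalty is selected by the extended Bayesian information
criterion with $\gamma = 0.5$,
$EBIC = -2\ell + k\log n + 4k\gamma\log p$, where $k$ counts nonzero
upper-triangle precision entries and $\ell$ is the log-likelihood of the
**support-restricted unpenalized MLE** (each distinct support along the path
is refit once without shrinkage). This refit convention matters: computing
EBIC on the penalized likelihood lets shrinkage of genuine edges dominate
the fit term and drags in weak spurious edges — in our chain-recovery
simulations exact support recovery at n = 500 was 27% under the penalized
convention and 99% under the refit convention. Reported edge weights are
nonetheless the penalized partial correlations
$-\omega_{ij}/\sqrt{\omega_{ii}\omega_{jj}}$ at the selected penalty, the
convention of psychometric network software. Non-positive-definite input
correlations (possible at small n) are repaired by eigenvalue clipping with
a logged warning.

Centrality: strength is the sum of absolute incident weights; betweenness
counts weighted shortest paths through a node with edge length
$1/|w|$; both are also z-scored across nodes. With nine nodes, fewer than
three observations per node is refused unless explicitly acknowledged
(`small_sample_ack = TRUE`) — at a typical exploratory cohort size of a few
dozen subjects the network is unstable, which is precisely why the
generator-based simulations in the tests use larger cohorts.

## The synthetic cohort generator

`generate_cohort()` draws cohorts in which the structural model is *literally
true*: covariates, then per-group testosterone (left-truncated normal at 0),
then uncensored estradiol $E^* = \alpha_E + \gamma_3 T + \epsilon_E$, then
the latent factor $\eta = \gamma_G G + \gamma_1(G) T + \gamma_2(G) E^* +
\zeta$ using the *uncensored* estradiol, then the regional outcomes with the
full residual covariance (including the extra hippocampus–amygdala term),
and only then the censoring (value set to the LOQ, flag raised; the
uncensored draw is kept in `estradiol_true` for oracle tests). One master
seed drives deterministic per-stage child streams, so identical seeds give
bit-identical tables.

Defaults and their provenance:

* Published values: group effect −0.07; testosterone→latent slopes −0.0074
  (HC) and 0.0001 (MDD); estradiol→latent slopes 1.74 (HC) and 0.64 (MDD);
  testosterone→estradiol slope 0.003; LOQ 0.09 nM; per-group testosterone
  moments 17.9 (5.7) for HC and 16.7 (7.4) nM for MDD; cohort sizes 25 MDD /
  52 HC; GE-scanner fraction 6/52 among controls only; per-group age and
  dose distributions from the cohort table (doses 0.019 vs 0.012 μg/kg).
* Free choices (regional intercepts, loadings, residual SDs and the latent
  disturbance SD are not published numerically): intercepts (3.60, 1.10,
  1.00, 0.65) and loadings (1, 0.45, 0.40, 0.30) follow the high /
  intermediate / low binding ordering of this tracer; $\sigma_\zeta = 0.35$
  with residual SDs (0.30, 0.15, 0.15, 0.10) implies a neostriatal
  between-subject SD of about 0.46 and inter-regional correlations of
  0.45–0.6, the range typical of global-binding PET data (an earlier draft
  value of 0.10 implied correlations near 0.2 and a weakly identified
  factor, and was revised once on realism grounds). The extra
  hippocampus–amygdala residual covariance defaults to 0.006 (≈ 0.27 extra
  residual correlation). The estradiol intercept 0.05 nM and residual SD
  0.02 nM put the marginal censoring fraction at ≈ 30–35%, between the
  published 8% (HC) and 56% (MDD); the published group gap partly reflects
  assay differences that printed values do not allow reconstructing.
* HAMD items are drawn by thresholding latent standard-normal scores at
  binomial-quantile cut points (success probability 0.42 over each item's
  0–2 or 0–4 range, giving a mean total near the published 21.9); the five
  vegetative items share a configurable loading (default 0.4) on
  standardized testosterone, and the HAMD6 core items are independent of
  hormones.

What passing tests on these cohorts do **not** show: robustness to
non-Gaussian binding distributions, assay changes mid-study, nonlinear
hormone effects, or informative missingness — none of which the generator
emulates.

## Numerical choices and problem sizes

Simulation-based checks in the test suite use sizes chosen as a compromise
between asymptotic validity and a single-CPU run: parameter recovery and
coverage at n = 2000 with 200 replicates per model; score-test type-I
calibration at n = 300 with 400 replicates; misspecification power at
n = 2000 with 50 replicates; chain support recovery at n = 500 with 100
replicates; censored-likelihood quadrature checks on 100 random parameter
draws. Degenerate inputs are handled explicitly: non-positive-definite
implied covariances yield a −∞ log-likelihood rather than a crash, singular
information matrices mark SEs unavailable, constant covariates are dropped
with a message, and constant residual vectors in QQ computations warn.

## Known limitations

* The interaction-with-censoring simplification (`integrate_main_only`)
  plugs the LOQ into the interaction covariate for censored MDD rows; it is
  exact for controls but mildly biased for the MDD interaction when
  censoring is heavy. `integrate_full` is the clean alternative and the one
  used for recovery simulations.
* Which of the two tetrad-equivalent residual covariances the refinement
  adds is not identifiable from four indicators (see above).
* No robust/sandwich variances, no FIML for general missingness, single
  latent factor only, no bootstrapped edge-stability analysis for the
  network.
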