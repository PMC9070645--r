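---
title: "Models and methods behind diallelGP"
author: "diallelGP authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind diallelGP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

diallelGP implements an across-population genomic-prediction workflow for
bi-parental families connected in a half-diallel: estimate genotypic values
from field records, train penalized marker-effect models within or outside
the design, score predictive ability for cross means and for
Mendelian-sampling deviations, optimize training sets, and regress
predictive ability on its drivers. This vignette records the models, the
defaults, the numerical choices, and the design decisions that were
genuinely open.

## The field model and genotypic values

Plot records $y_{ijkl}$ (genotype $i$ of cross $j$, block $k$, year $l$)
are modelled as

$$y = \mu + B + Y + B{:}Y + G + C + G{:}Y + C{:}Y + x + y + x{:}y
      + x{:}Y + y{:}Y + \epsilon,$$

with fixed block and year terms and i.i.d. Gaussian random terms for
genotype-within-cross ($G$), cross ($C$), their year interactions, and
categorical row/column field coordinates. Field coordinates are treated as
unordered factors — no spatial kernel — because the replicated complete
blocks make row/column effects estimable as plain contrasts, and an
autoregressive surface would add parameters the desk-scale designs cannot
support. Fixed effects are coded sum-to-zero, so BLUPs of every random
term sum to approximately zero.

Variance components are estimated by EM iterations on Henderson's
mixed-model equations, in ML or REML flavor. Each iteration solves the
dense symmetric system once (Cholesky), updates
$\sigma_k^2 \leftarrow (u_k'u_k + \sigma_e^2\,\mathrm{tr}\,C^{kk})/q_k$
and the residual from the weighted residual sum of squares, and floors
components at $10^{-10}\,\mathrm{var}(y)$. Plain EM is safe but slow in two
regimes, and both are handled with moves that are accepted only when the
(restricted) log-likelihood does not decrease, so the likelihood is
monotone by construction:

* **interior slow-down** — every fourth iteration an Aitken-style
  extrapolation on the log-variances (componentwise ratio capped at 0.995)
  is attempted;
* **boundary components** — EM approaches a zero variance only
  sublinearly, so every tenth iteration any small, shrinking component is
  tentatively snapped to the floor.

Convergence is declared when the largest relative component change falls
below `tol` (default $10^{-6}$) or the likelihood plateaus below
$10^{-8}$ after 30 iterations; `maxIter` defaults to 1000. The estimates
match the balanced one-way ANOVA closed form to $10^{-6}$ and lme4 to five
digits on unbalanced two-factor designs (both are enforced in the test
suite; lme4 is never used in the fitting path).

Backward elimination of random terms uses REML likelihood-ratio tests
against the boundary mixture $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$,
dropping the largest $p \ge \alpha$ one at a time; $G$ and $C$ are never
dropped. Fixed effects are always retained: their selection would change
no downstream quantity, since predictions use only the random-term BLUPs.

Total genotypic values are the BLUP sums $C + G$, scaled to unit sample
variance per population so traits are comparable; Pearson correlations are
invariant to this scaling.

**Heritability** on a genotype-entry-mean basis divides year-interaction
components by the mean number of years per genotype and plot-level
components by years times replicates per year:

$$H^2 = \frac{\sigma_C^2+\sigma_G^2}
 {\sigma_C^2+\sigma_G^2
  + \frac{\sigma_{C:Y}^2+\sigma_{G:Y}^2+\sigma_{x:Y}^2+\sigma_{y:Y}^2}{n_{year}}
  + \frac{\sigma_x^2+\sigma_y^2+\sigma_{x:y}^2+\sigma_\epsilon^2}
         {n_{year}\, n_{rep.year}}}.$$

Per-cross $H^2$ refits the globally selected model within one cross with
all cross terms removed. Whether per-cross refits should re-select their
terms was open; the global selection is reused so that per-cross values
are comparable across crosses.

Raw phenotypes are transformed before fitting when skewed: identity for
$|g_1| \le 1$, square root for $g_1 \in (1, 2]$ on non-negative data, log
(shifted if needed) beyond. The thresholds stand in for an unspecified
normality screen; the choice and the skewness are returned so users can
override.

## Penalized marker-effect models

Markers are centered and scaled to unit population sd (denominator $n$)
with training-set statistics only; monomorphic training markers are zeroed
and flagged. The objective

$$\tfrac{1}{2n}\lVert y-\beta_0-X\beta\rVert^2 + \lambda P(\beta),\qquad
P=\tfrac12\lVert\beta\rVert^2 \;(\text{RR})\ \text{or}\
\lVert\beta\rVert_1\ (\text{LASSO}),$$

is minimized by cyclic coordinate descent with covariance updates
(compiled; convergence when the largest coefficient change is below
$10^{-7}$ for final fits). The $1/(2n)$ scaling gives the standard
$\lambda_{max} = \max_j |x_j'(y-\bar y)|/n$, the top of the
cross-validation grid. $\lambda$ is chosen at the minimum mean squared
prediction error of a seeded $k$-fold (default 5) inner cross-validation
over a log-spaced grid from $\lambda_{max}$ down to
$10^{-4}\lambda_{max}$; ties go to the larger $\lambda$. The minimum-CV
rule (not the 1-SE rule) was chosen as the most direct reading of
"calibrated"; folds are plain random, not stratified by cross.

Two numerical notes. Ridge coordinate descent on $p > n$ designs converges
very slowly at the smallest grid values, so the path fits inside
cross-validation are capped (50 sweeps at tolerance $10^{-4}$) — they only
score prediction error, which is insensitive at that tolerance — while
final fits keep the strict tolerance and can optionally warn instead of
erroring when a pathological small-$\lambda$ fit is requested by the
calibration. Standardizing markers inside the fit mirrors the reference
ridge/LASSO tooling's default; the standardization is recorded in the
model object so predictions are exactly reproducible.

Prediction is the affine map $\beta_0 + X\beta$ after applying the
training standardization; fractional dosages are accepted, and by
linearity the prediction at a parental-average genotype
$(d_1+d_2)/2$ equals the segregation-weighted mean over offspring
classes — the identity behind both cross-mean modalities and the all-pairs
enumeration ($n(n-1)/2$ rows; 38 781 for 279 panel genotypes).

## Scenarios and predictive ability

* **1a** — random 10-fold cross-validation over all phenotyped offspring,
  replicated (default 10 times); every individual is predicted once per
  replicate. Folds are simple random; shrinkage is re-calibrated within
  every outer training set with a seed derived from (trait, replicate,
  fold).
* **1b** — for each focal cross and each of its parents, training on the
  union of that parent's other crosses (three half-sib families in a
  complete 5-parent half-diallel); each cross is predicted twice and the
  two results are reported separately, never averaged.
* **2** — training on the diversity panel (values scaled within the
  panel), predicting every cross; optionally restricted to one
  subpopulation.

Predictive ability is the Pearson correlation between observed and
predicted total genotypic values. Mendelian-sampling PA is computed within
each (trait, cross) cell; per-trait and overall figures are means over
cells (with, in 1a, the per-cross values computed within each replicate
and averaged with their standard error). Cross-mean PA correlates observed
cross means (phenotyped offspring only; parents excluded) with predicted
means across crosses (per trait), across traits (per cross), or pooled.
Cells with fewer than three pairs, or zero variance, are reported missing
rather than zero. Cross means are predicted both as replicate-averaged
offspring predictions and at the parental-average genotype; the PA rows
use the parental modality, and the table keeps both columns so their
agreement (typically $r > 0.98$ at realistic family sizes) can be checked.
Both RR and LASSO are run; `bestMethod()` keeps the larger PA with ties to
RR.

Per-trait bias of predicted cross means (mean of predicted minus observed
over crosses) can be estimated and subtracted, which is how the all-pairs
ranking of candidate crosses is corrected.

## Training-set optimization

For a validation cross with genotyped offspring, candidate training sets
are scored on a VanRaden relationship matrix
$A = ZZ'/(2\sum_m p_m(1-p_m))$ (frequencies from the matrix itself by
default, from the panel when panel and progenies are related; fixed
markers are excluded with a logged count):

* `PEVmean` — mean Gaussian conditional variance
  $A_{VV} - A_{VT}(A_{TT}+\lambda_r I)^{-1}A_{TV}$ (lower is better),
  with $\lambda_r = (1-h^2)/h^2$, default $h^2 = 0.5$;
* `CDmean` — mean of $1 - PEV_{ii}/A_{ii}$ (higher is better);
* `MeanRel` — mean training-validation relationship (higher is better).

The search is greedy forward construction followed by steepest-ascent
single-swap exchanges, deterministic given the seed, with ties broken by
id order; MeanRel is separable over members, so its exact optimum is the
top-$k$ candidates by mean relationship. A deterministic local search
replaces the genetic-algorithm package used historically for these
criteria: the criteria, not the metaheuristic, are the scientific content,
and at a few hundred candidates the swap search reaches criterion values
that dominate all seeded random baselines (asserted in the tests). The
PEV/CD formulas here are the plain conditional-variance forms without
fixed-effect contrasts.

## Determinants of predictive ability

One row per (trait, cross) with Mendelian-sampling PA as response and six
common predictors — non-segregating marker proportion (both parents
homozygous, same or opposite alleles: zero offspring variance), overall
and per-cross $H^2$, the cross-variance share
$\sigma_C^2/(\sigma_C^2+\sigma_G^2)$, the parents' additive relationship,
and their Euclidean distance on the first two panel-PCA axes — plus the
mean training-validation relationship (1b, 2) and panel $H^2$ and
subpopulation $R^2$ (2). The panel PCA centers markers by panel means,
never scales, and projects parents and progenies with the panel loadings,
so the parental-average genotype projects to the parents' midpoint.

Predictors are standardized, exact collinears dropped (later-listed
first), and the model selected by forward-backward stepwise search under
AIC (`stats::step`). The selected model's $R^2$ is decomposed by **lmg**
(sequential increments averaged uniformly over orderings, computed from a
cached subset-$R^2$ table) and **pmvd** (ordering weights proportional to
$\prod_i (R^2_{full} - R^2(\text{first } i))^{-1}$, so zero-marginal
variables get exactly zero share; such variables are detected and placed
last analytically, which is the weighting's limit). Orderings are
enumerated exhaustively, hence the 10-predictor cap. Shares summing to
$R^2$ and the zero-share property are asserted.

## The synthetic-data generator

The generator emulates the statistical skeleton of a structured perennial
diversity panel plus half-diallel:

* **panel** — Balding–Nichols subpopulation frequencies around uniform
  ancestral frequencies (differentiation `fst`, default 0.05, three
  subpopulations labelled WW/WE/TE), binomial dosages, phased haplotypes;
  markers on 19 chromosomes, ~70 cM each, uniform positions;
* **meiosis** — Haldane model: per-chromosome Poisson crossover counts
  (mean = length in Morgans), uniform positions, no interference;
* **half-diallel** — every unordered pair of parents once; parents are
  panel members (by default four from one subpopulation, one from
  another);
* **phenotypes** — plot values from exactly the field model above, every
  random term i.i.d. with its architecture's sd (defaults 0.3 for all
  year interactions, 0.2 for spatial terms, 0.7 residual, on the
  unit-additive-variance scale); perennial layout (each genotype-block
  plot keeps its position across years); defaults 2 years x 2 blocks.

Trait architectures carry QTL positions and effects (oligogenic <= 10,
polygenic >= 100 QTLs), rescaled so the additive variance in a reference
population is 1. Calibration works from two dials:

* `targetH2` — the genetic side is rescaled by one factor so that the
  *true* simulated components plugged into the entry-mean $H^2$ formula
  hit the target exactly; the non-genetic sds are taken as fixed, and an
  unattainable target (all non-genetic sds zero) errors with the implied
  $H^2$ of 1.
* the cross-variance share — under pure additivity with effectively
  unrelated parents, the between-cross share of genetic variance sits
  near one half (midparent variance ~ Mendelian-sampling variance), so
  shares below that cannot be reached by *adding* a cross deviation.
  `calibrateCrossShare()` therefore adds an i.i.d. cross deviation when
  the target exceeds the additive share, and otherwise shrinks the
  additive cross-mean component (`crossMeanScale` < 1), emulating the
  non-additive and scale effects that depress fitted cross variance below
  its additive expectation in real data. This gives the generator the
  documented <10%–50% range of shares.

What the generator does **not** emulate: linkage disequilibrium decay
calibrated to any real genome, dominance or epistasis, missing genotypes
or imputation error, selection, assortative mating, or spatial
autocorrelation beyond i.i.d. row/column/cell effects. Passing tests
therefore demonstrate internal consistency of the estimators and the
pipeline under the assumed model, not performance on real grapevine data;
none of the simulation distributions are estimates of the real process.

## Problem sizes and identifiability

The package's own experiments run at desk scale: a default configuration
of 300 panel individuals, 2 000 markers on 19 chromosomes, 10 crosses of
65 offspring and 5 traits; the acceptance run uses 180 panel individuals,
800 markers, 10 x 18 offspring and 3 traits, with 5-fold outer
cross-validation replicated twice and a 20-point shrinkage grid. Two
identifiability-driven choices at these scales are worth recording:

* with one plot per (row, column, year) cell and two years, the
  per-plot `x:y` term and the position-by-year terms are nearly
  indistinguishable from the residual; the acceptance run and the
  parameter-recovery experiment therefore fit the identifiable subset
  (`G`, `C`, `G:Y`, `C:Y`, plus row/column main effects where
  simulated), and the recovery experiment simulates with spatial sds of
  zero so the fitted model is exactly the generating model;
* with 10 crosses, the cross variance has nine degrees of freedom: its
  REML estimate is noisy per trait, and recovery statements are made as
  means over seeds.

## Known limitations

* Random terms are i.i.d.: no genomic covariance in the phenotype model
  (GBLUP-style variance estimation is out of scope); the marker models
  carry all genomic information.
* The EM solver builds one dense symmetric system; it is comfortable to a
  few thousand mixed-model equations, not more.
* pmvd/lmg enumerate orderings exhaustively (<= 10 predictors).
* The transformation rule is a skewness heuristic, not a test.
* Scenario functions assume complete dosage matrices; filtering and
  imputation happen upstream.
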