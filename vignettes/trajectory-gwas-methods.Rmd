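---
title: "Modelling childhood BMI trajectories for GWAS: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling childhood BMI trajectories for GWAS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajgwas)
```

This vignette is the package's own account of its statistical machinery:
the growth model and its assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the numerical
choices made where the design was genuinely open.

## The problem

Childhood BMI does not change linearly: it rises steeply through infancy to
an *adiposity peak* (AP) before age one, declines to a nadir — the
*adiposity rebound* (AR) — around four to six years, and rises again
through adolescence. Cross-sectional GWAS at a single age cannot separate
genetic effects on the level of BMI from effects on its change, and cohorts
measure children at incompatible ages. The approach implemented here fits a
subject-level nonlinear growth model per cohort and sex, summarises each
child's fitted curve by a dozen interpretable phenotypes, and meta-analyses
the per-cohort GWAS of those phenotypes. Because each phenotype comes from
the fitted curve rather than a raw measurement, cohorts need not share
visit schedules.

## The mixed model

For child $i$ at age $t$ (years), log BMI is modelled as

$$\log \mathrm{BMI}_{it} = X(t)\beta + Z(t) b_i + \varepsilon_{it},
\qquad b_i \sim \mathcal{N}(0, G),$$

where $X(t)$ is a spline basis in age and $Z(t)$ a (usually reduced)
random-effect basis. Three fixed-effect families are supported — cubic
polynomial ("cubic slope"), linear smoothing spline, and cubic smoothing
spline with truncated power terms $(t-\kappa_k)_+^3$ — with knots for the
preferred cubic spline at 1, 8 and 12 years: roughly the AP--AR descent,
the pre-pubertal rise, and the pubertal inflection. Residuals are either
independent or follow continuous-time AR(1), $\mathrm{corr} =
\phi^{|\Delta t|}$, which absorbs short-range dependence between closely
spaced visits.

The natural log of BMI is modelled because BMI is right-skewed and
heteroskedastic; on the log scale measurement error is approximately
multiplicative-symmetric and a slope $s$ converts to a percentage change,
$100(e^{s\,\Delta t}-1)$, via `slope_to_change()`.

Estimation is maximum likelihood by default so that AIC/BIC comparisons
across fixed-effect structures are valid; REML is available by flag. Two
engines sit behind `fit_lmm()`: for independent residuals, a standard
profiled-deviance mixed-model fit; for CAR(1), an authored quasi-Newton
optimiser on the unconstrained parameters (log-Cholesky factor of $G$,
$\log\sigma^2$, $\mathrm{logit}\,\phi$) with $\beta$ profiled out by GLS
within the per-subject block structure. The CAR(1) optimiser warm-starts
from the independent-residual optimum and always evaluates the $\phi = 0$
boundary candidate, so its log-likelihood can never fall below the nested
model — a property the tests assert. All basis columns are rescaled to
$[-1,1]$ internally (the cubic terms span four orders of magnitude over
0–18 years and stall optimisers unscaled); estimates are mapped back to the
natural scale, so users never see the scaling.

Convergence problems are data, not exceptions: each fit carries a status
(`ok`/`warning`/`error`) with the captured message, and the model-grid
runner (`run_model_grid()`) records failures per cell. `select_preferred()`
only accepts specifications that fitted cleanly in *every* cohort and sex,
choosing by summed AIC with BIC and parameter count as tie-breaks, and
reports the better-AIC specifications that were excluded — those are the
natural sensitivity models.

`lmm_loglik()` evaluates the marginal likelihood independently of either
engine (block formula or naive full matrix); the tests use it to
cross-check both engines and the block/naive agreement.

## Quality control of raw anthropometry

`flag_records()` implements a transparent, deterministic version of the
standard paediatric implausible-value taxonomy: missing components,
same-day duplicates (first record kept, by file order), carried-forward
values (height *and* weight identical to the previous visit), weight unit
switches (robust z collapses from $>5$ to $<2$ after multiplying or
dividing by 2.2046), extreme values ($|z| > 25$), sequential height
decreases beyond 3 cm, single-measurement height/weight z mismatch,
moderate outliers against an exponentially weighted moving average
(half-life 0.5 y, cutoff 3 robust SD), and finally error load (subjects
with more than half their records flagged lose all of them).

Two normalisations proved essential rather than cosmetic. Robust z-scores
are computed against the cohort median/MAD within sex and age bins
(quarter-years in infancy, half-years to age 2, years after), and bins with
fewer than 20 records yield no z-based flags — a sparse bin at the age
extremes otherwise produces clustered false flags that measurably bias the
late-age spline coefficients. The moderate-outlier EWMA runs on
*log-scale, age-adjusted* values, with the cohort median curve
interpolated at the exact age: anthropometric error is multiplicative (a
kg-scale threshold tuned on infants misflags essentially every adolescent
record), and raw growth curves trend upward, so at a subject's first or
last visit an EWMA of their remaining visits is one-sided and would flag
the trajectory tails wholesale. With these defaults about 3–4% of clean
synthetic records are flagged, comfortably inside the 4–16% overall
exclusion range typical of real paediatric cleaning.

The thresholds live in `qc_config()` and are deliberate package decisions,
not published constants: the EWMA half-life (0.5 y), moderate-outlier
cutoff (3 robust SD) and error-load threshold (0.5) have no canonical
published values.

## Derived phenotypes

Each child's curve — fixed part plus BLUP, covariates at reference — is
predicted at 0.01-year steps from two weeks to 17 years (16 for cohorts
without later data). The BLUP is computed directly as
$\hat b_i = G Z_i' V_i^{-1}(y_i - X_i\hat\beta)$, so it works identically
for both engines and for fits restored from JSON.

* **AP/AR**: first interior local maximum of predicted log BMI in
  [0.25, 10] years (strict sign change of the discrete derivative), then
  the first interior minimum after it; if either is absent or the AP does
  not precede the AR, all four values are missing. A boundary extremum at
  the 0.25-year grid edge is *not* accepted — an interior turning point is
  required, which avoids calling a monotone segment a peak.
* **Window slopes** over infancy (2 weeks–0.5 y, labelled "0–6 months"),
  early childhood (1.5–3.5 y), late childhood (6.5–10 y) and adolescence
  (12–17 y): exact endpoint differences evaluated from the coefficients,
  so they are independent of the grid step.
* **Window AUCs**: closed-form integrals using the antiderivatives of the
  monomial and truncated power terms (exact across interior knots), in
  log-BMI·years. Tests verify agreement with adaptive quadrature to
  1e-8 and additivity across window splits to 1e-10.

Subjects outside $[Q_1 - 2\,\mathrm{IQR},\ Q_3 + 2\,\mathrm{IQR}]$ on
*any* phenotype are excluded from all downstream analyses (one aberrant
phenotype usually means the whole curve is suspect). Quartiles use linear
interpolation (R type 7); the rule is configurable since no canonical
quantile convention exists for this filter. Missingness is per-phenotype:
a child without a detected AP keeps their slopes and AUCs.

## GWAS and meta-analysis

`run_gwas()` regresses each phenotype on allelic dosage plus covariates by
OLS, using one Frisch–Waugh–Lovell projection of the covariates so the
per-variant pass is numerically identical to a full per-SNP refit (tests
assert equality with `lm()` to 1e-10). Constant dosages are flagged
monomorphic rather than failing. Per-cohort pre-filters remove
monomorphic/multiallelic/indel variants, $n < 20$, minor allele count
$\le 3$, $|\beta|$ or SE $\ge 10$ (boundary inclusive) and INFO $< 0.4$,
with a per-rule ledger. `harmonize()` aligns effect alleles to the first
cohort (flipping $\beta$ and EAF on swaps), drops strand-ambiguous A/T and
C/G variants with EAF within 0.08 of 0.5, and flags cross-cohort EAF
differences above 0.2 — the ambiguity window and difference threshold are
package defaults, as the published harmonisation pipelines do not print
theirs. `ivw_meta()` is the textbook inverse-variance fixed-effects pool
with Cochran's Q, I² and a per-cohort direction string;
`post_meta_filters()` applies the ≥50%-of-cohorts rule (ceiling), the
MAF ≥ 0.005 filter, genome-wide significance at $5\times10^{-8}$, and
±500 kb distance clumping.

A deliberate simplification: GWAS is plain OLS, not a relatedness-aware
mixed model — related individuals are assumed removed upstream, and
modelling family structure is out of scope.

## The synthetic-cohort generator

`sim_config()`/`simulate_cohort()` define the study conditions under which
the framework is validated. Defaults emulate a population birth cohort:
18 scheduled visits from two weeks to 18 years with Normal age jitter
(SD 0.08 y, truncated to the age range), giving 8–20 usable measures per
child; a fixed-effect cubic spline (knots 1, 8, 12) whose implied BMI curve
has its peak near 0.73 years at ~17.9 kg/m², its rebound near 5.5 years at
~15.5 kg/m², and reaches ~22 kg/m² at 18; a random cubic slope covariance
chosen so subject-level spread is ~5% of BMI in infancy, ~1 kg/m² SD at
the AP, and rebound-age SD slightly above one year; residual SD 0.05 on
the log scale; girls shifted down by 0.025 log units. Height follows a
monotone logistic-in-age curve with small subject and measurement
variation, and weight is back-derived so that weight/height² reproduces
the simulated BMI exactly — height exists so the height-based QC rules
have something to act on, not as a modelled trait. SNP dosages are
Binomial(2, MAF) with an index-keyed allele panel shared across cohorts,
and configured SNP effects add `dosage × effect` to a named random
coefficient before curves are formed, so slope/AUC GWAS has known truth.

Per-subject randomness uses sub-streams whose seeds come from one
well-mixed global stream keyed by the master seed; subject $i$'s data
depend only on the master seed and $i$, so subsetting a cohort does not
change the retained subjects. (Seeding sub-streams by a linear formula in
$i$ — the obvious shortcut — leaves cross-stream correlation strong enough
to inflate the sampling variance of cohort-level estimates by ~40%, which
the parameter-recovery tests caught.)

`inject_errors()` plants the five fault types the QC must catch, with a
complete ledger for sensitivity scoring. What the generator does *not*
emulate: secular trends, relatedness/twins, informative dropout,
cohort-specific measurement devices, or real LD structure (variants are
independent). Passing tests therefore demonstrate internal consistency of
the framework under its own assumptions, not performance on real data.

## Numerical choices and known limitations

* Problem sizes in the test-suite simulations — e.g. 20 replicates of
  500-subject cohorts for parameter recovery, 2,000 subjects × 10,000 null
  SNPs for GWAS calibration, three 400-subject cohorts for the end-to-end
  planted-SNP run — were chosen as the smallest designs at which the
  corresponding checks are statistically meaningful.
* BLUP shrinkage biases subject phenotypes toward the cohort mean, more
  for children with few visits; a SNP effect planted on a random
  coefficient is therefore recovered attenuated (the end-to-end tests
  assert sign, significance and magnitude within ±50%, not exact
  recovery). Debiasing the GWAS for shrinkage is future work.
* ICC is reported from the random-intercept variance only (age-zero
  formula) — a single-number diagnostic, documented as such.
* Marginal/conditional R² follow the variance-partition convention with
  the random-effect contribution averaged over the observed design
  (`mean diag(Z G Z')`).
* With true $\phi = 0$ and dense early-life visits, the CAR(1) likelihood
  is very flat in $\phi$ near zero and can prefer spiky short-range
  correlation; the boundary candidate keeps such fits honest but $\phi$
  itself is weakly identified when visit gaps are long relative to
  $-1/\log\phi$.
* Age is used uncentred (knots on the natural scale); centring is a
  common convergence aid and can be emulated by shifting the data, but is
  not needed by either engine here thanks to the internal column scaling.
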