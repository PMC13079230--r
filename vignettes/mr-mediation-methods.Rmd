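---
title: "Methods: two-sample MR estimation, diagnostics and two-step mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR estimation, diagnostics and two-step mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

This vignette is the package's account of the statistical machinery it
implements: the models and their assumptions, the tunable parameters and
why their defaults are what they are, what the synthetic-data generator
does and does not emulate, and the numerical and design choices made where
the literature leaves them open.

## The model

Two-sample Mendelian randomization treats each genetic variant $j$ as an
instrument: its per-allele association $\hat\beta_{Xj}$ (s.e.
$\sigma_{Xj}$) with the exposure comes from one GWAS, its association
$\hat\beta_{Yj}$ (s.e. $\sigma_{Yj}$) with the outcome from another, and
under the instrumental-variable assumptions (relevance, independence of
confounders, no effect on $Y$ except through $X$) each ratio
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ estimates the same causal
effect. All traits are analysed in SD units, so effects read as SD of
outcome per SD of exposure.

**IVW.** The headline estimator pools the ratios with inverse-variance
weights $w_j = 1/\sigma_{Yj}^2$, equivalently weighted least squares of
$\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ through the origin. Its
fixed-effect standard error is $1/\sqrt{\sum_j w_j \hat\beta_{Xj}^2}$;
the default *multiplicative random-effects* model inflates it by
$\max\{1, \sqrt{Q/(L-1)}\}$, where $Q$ is Cochran's statistic, so
balanced heterogeneity widens the interval without moving the point
estimate. The floor at 1 guarantees the random-effects interval never
undercuts the fixed-effect one. Inference is normal-theory; intervals use
the conventional $\pm 1.96\,\mathrm{se}$.

**Robust estimators.** Each relaxes the exclusion restriction
differently:

* *MR-Egger* regresses $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ *with* an
  intercept after orienting all exposure effects positive (joint sign
  flips of $(\hat\beta_{Xj},\hat\beta_{Yj})$, to which every estimator
  here is invariant). The slope is consistent under InSIDE (instrument
  strength independent of direct effects); the intercept estimates the
  mean directional pleiotropic effect, and its $t_{L-2}$ test is the
  pleiotropy diagnostic. Standard errors carry the same multiplicative
  inflation, here $\max\{1, \sqrt{\mathrm{RSS}_w/(L-2)}\}$.
* *Weighted median*: the 50% point of the inverse-variance-weighted
  empirical CDF of the ratios, interpolated linearly between the
  cumulative-weight midpoints $s_j = \sum_{k\le j} w'_k - w'_j/2$;
  consistent while valid instruments hold a majority of the weight.
* *Mode-based estimators*: the argmax of a normal-kernel smoothed density
  of the ratios (uniform or inverse-variance weights), consistent when
  the largest homogeneous cluster of instruments is valid.

The weighted-median and mode standard errors come from a parametric
bootstrap that resamples $\hat\beta_{Xj}$ and $\hat\beta_{Yj}$ from
normal distributions centred on the observed values — the same
data-generating assumption the estimators themselves make.

**Multivariable IVW** regresses the outcome effects on several columns of
exposure effects jointly (no intercept, weights $1/\sigma_{Yj}^2$),
giving each predictor's *direct* effect conditional on the others. With
exposure and mediator columns this supplies the direct effect $c'$ needed
by the difference method. A predictor column that is identically zero is
unidentifiable and is dropped with an `NA` coefficient (the remaining fit
then reduces exactly to univariable IVW); genuinely collinear non-zero
columns raise an error instead, since silently dropping one would change
the estimand.

## Diagnostics

* **Cochran's Q** over the ratio estimates with first-order weights
  $(\hat\beta_{Xj}/\sigma_{Yj})^2$; $\chi^2_{L-1}$ under homogeneity.
* **Egger intercept test** at $\alpha = 0.05$.
* **Global pleiotropy / outlier test** (MR-PRESSO style): observed
  statistic $\mathrm{RSS} = \sum_j w_j(\hat\beta_{Yj} -
  \hat\theta_{(-j)}\hat\beta_{Xj})^2$ with leave-one-out IVW estimates
  $\hat\theta_{(-j)}$; its null distribution is rebuilt by `n_sim`
  parametric simulations (default 1000), and empirical p-values use the
  $(1+k)/(n_\mathrm{sim}+1)$ convention so they are never exactly zero.
  Per-variant outlier p-values are Bonferroni-adjusted by $L$; note the
  resulting resolution floor $L/(n_\mathrm{sim}+1)$ — with 50 instruments,
  1000 simulations is the minimum at which an outlier can be flagged at
  0.05, which is why `n_sim` defaults there and should be raised for
  larger panels. The distortion test of the original proposal is not
  implemented; outlier-corrected re-estimation is available simply by
  refitting without the flagged variants.
* **Analytic power** for a continuous outcome:
  $\Phi(-z_{1-\alpha/2} + |\beta|\sqrt{n r^2}) + \Phi(-z_{1-\alpha/2} -
  |\beta|\sqrt{n r^2})$, with $r^2$ defaulting naturally to the selected
  instruments' explained variance. At $\beta = 0$ this returns exactly
  $\alpha$.

## Instrument selection

Thresholds follow the strict convention and are all overridable:
genome-wide significance $P < 5\times10^{-8}$ (strict inequality), MAF
$\ge 0.01$, greedy clumping at $r^2 < 0.001$ within a 10,000 kb window
(lowest-p variant claims its window; ties broken by rsID so the result is
order-invariant), and a per-variant $F = (\hat\beta/\mathrm{se})^2 \ge
10$ screen. The overall instrument strength
$F = \frac{n-L-1}{L}\,\frac{R^2}{1-R^2}$ with $R^2 = \sum_j
2\,\mathrm{eaf}_j(1-\mathrm{eaf}_j)\hat\beta_j^2$ is reported alongside;
filtering uses the per-variant F (the overall F is also available, and
which of the two a published analysis used is rarely stated — both are
surfaced so either rule can be applied).

LD comes from a pluggable source: a sparse pair table (absent pair =
below reporting floor = 0, the usual sparse-export semantics), a
reference dosage matrix (r² = squared Pearson correlation of dosages), or
an explicit no-LD source for panels known to be pre-pruned. Running with
no LD information at all either errors or — only on request — falls back
to distance-only clumping with a loud warning, because that genuinely
changes results.

Harmonization matches variants by rsID only (the common case for GWAS
exports; chrom:pos matching would add liftover concerns), aligns each
table to the exposure's effect allele via sign flips and strand flips,
drops irreconcilable allele pairs with reason codes, and seeks no
proxies. Palindromic (A/T, C/G) variants default to frequency inference:
kept only when both frequencies are outside (0.42, 0.58), aligned by
frequency side; `drop_all` is available for strictness. The 0.42 band is
the conservative end of common practice; published pipelines rarely state
their choice, which is why it is a policy argument rather than a constant.

## Two-step mediation

For a pathway $X \to M \to Y$: $a$ (exposure→mediator) and the total
effect $c$ (exposure→outcome) use the exposure's instruments; $b$
(mediator→outcome) uses the mediator's own instruments, univariable by
default with an MVMR-adjusted option (`b_method = "mvmr"`) since
published two-step analyses are usually silent on which was used.
The indirect effect is the product $a\,b$ and the proportion mediated
$a\,b/c$. Its 95% CI is the Monte-Carlo distribution-of-product interval
(default $10^6$ seeded draws): drawing $A \sim N(a, se_a^2)$, $B \sim
N(b, se_b^2)$ and taking percentiles of $AB$ is the sampling analogue of
the analytic product-normal method and correctly reproduces its
asymmetry; $10^6$ draws give interval endpoints stable to well under the
reporting precision, and the count is configurable.

The *difference method* cross-check computes $c - c'$ with $c'$ from
multivariable IVW over the union of the two instrument sets, and the
corresponding proportion $(c-c')/c$. Under the linear structural model
with valid instruments the two decompositions estimate the same quantity.
Variants appearing in both instrument sets are reported but kept — there
is no established removal rule, and removing them would silently change
$b$. Proportions outside $[0,1]$, or an indirect effect whose sign
contradicts the total effect, are reported verbatim with an
`inconsistent_mediation` flag, never truncated.

## The synthetic-data generator

`simulate_gwas_triplet()` draws a three-trait summary-statistic study
from a known linear structural model: standardized instrument effects
$g_j$ on the exposure (rescaled so $\sum 2\,\mathrm{maf}_j(1-
\mathrm{maf}_j)\gamma_j^2 = h^2_X$ exactly), optional mediator-specific
effects $\delta_j$, true associations $\gamma_j$, $a\gamma_j + \delta_j$
and $(d + ab)\gamma_j + b\delta_j + \alpha_j$ for exposure, mediator and
outcome, and independent sampling noise with the standardized-trait
closed form $\mathrm{se} = 1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})\,n}$
(non-overlapping samples, the clean two-sample setting).

Defaults encode the calibrated mediation scenario the package validates
against: $L = 80$ exposure instruments, 80 mediator-specific instruments,
$n = 5\times10^5$ per trait, MAF $\sim U(0.05, 0.5)$, $a = -0.125$,
$b = 0.080$, $d = -0.0247$ (total $c = -0.0347$, true proportion
mediated 28.8%). Heritabilities are not dictated by the scenario; both
default to $h^2 = 0.10$, chosen so that instruments are strong (per-SNP
$F \approx 625$, comfortably in the $F > 10$ regime of large GWAS
meta-analyses) and the total-effect estimate has coefficient of variation
$\approx 0.13$ at these sample sizes. Giving the mediator its own
instrument set mirrors real two-step designs, where the mediator GWAS
contributes its own genome-wide hits for step 2.

Pleiotropy options: a fraction `rho_invalid` of exposure instruments
receives direct outcome effects $\alpha_j \sim N(\mu_\alpha,
\sigma_\alpha^2)$. Directional pleiotropy is applied *relative to the
exposure-increasing allele* (the sign of $\gamma_j$): with symmetric
$\gamma_j$, a sign-agnostic $\alpha$ would be balanced by construction
and directional pleiotropy would be unsimulatable. `inside_violation`
correlates $\alpha_j$ with $|\gamma_j|$ (correlation 0.7) to break
InSIDE. `inject_outliers()` adds specified direct effects to chosen
variants, with the truth updated, to exercise outlier detection.

Optional LD: each instrument can be expanded into an AR(1) block; non-lead
variants carry the LD-attenuated marginal effects
($\rho^{\mathrm{dist}}$ on the standardized scale), and
`make_ld_reference()` generates a matching reference panel of Gaussian
dosages (mean $2\,\mathrm{maf}$, variance
$2\,\mathrm{maf}(1-\mathrm{maf})$, AR(1) within blocks). The panel is
synthetic and exists only to carry the correlation structure; values are
not integer genotypes and may stray outside $[0,2]$.

All randomness flows from the single `seed` through one RNG stream with a
fixed draw order (frequencies, effects, pleiotropy, then per-trait
noise), so identical configs are bit-identical; the reference panel uses
`seed + 1` so that it is reproducible independently of the study draw.

What the generator does *not* emulate — and hence what passing recovery
tests do not certify about real data: genome-scale LD beyond block-AR(1),
sample overlap between the trait GWAS (an option correlating sampling
errors exists but real biobank overlap structure is richer), binary
traits and liability scales, imputation uncertainty, population
stratification, and winner's-curse-inducing discovery pipelines beyond
the significance screen itself.

## Known behaviour of the recovery pipeline

Two small, well-understood biases affect the mean estimated proportion
mediated under the default scenario, both visible in the validation
suite: the noisy total effect in the denominator contributes ratio bias
of roughly $+\mathrm{prop}\cdot \mathrm{cv}(c)^2$ (about half a point
here), and a handful of exposure instruments that also reach genome-wide
significance for the mediator enter step 2 carrying ratio $c/a$ rather
than $b$, nudging $b$ upward by a couple of percent. Both are properties
of the faithful two-step procedure, not implementation artefacts, and
both shrink with larger mediator heritability or sample size.

## Multistage orchestration

`run_multistage()` runs the three analysis families (exposure→outcome,
exposure→mediator, mediator→outcome) with explicit Bonferroni family
sizes — explicit because published reports often state "Bonferroni
corrected" without printing $m$; defaults are the number of tests
actually run, and any configured $m$ smaller than that is raised with a
warning. Mediators enter the mediation stage only with a
Bonferroni-significant exposure→mediator estimate, alongside significant
total and mediator→outcome effects. Every estimate carries its
sensitivity report; `render_report()` writes deterministic TSVs and a
JSON manifest (thresholds, seeds, families, drop accounting), and
identical config plus seed reproduces byte-identical outputs.

## Problem sizes used in validation

The shipped validation suite runs entirely on generated data: 2000
replicates for null calibration of the IVW z-test and Cochran's Q
($L = 50$, $n = 5\times10^5$), 300 replicates per calibrated mediation
scenario for proportion/indirect recovery, 200 replicates each for the
directional-pleiotropy robustness comparison ($L = 100$, 30% invalid,
$\mu_\alpha = 0.02$, $\sigma_\alpha = 0.005$), outlier detection
($10\times$ typical outcome effect against 1000-simulation null
distributions) and product-vs-difference concordance. These sizes were
chosen so that Monte-Carlo error is well below each assertion's
tolerance. Reproduction of the published real-data estimates requires the
full deposited GWAS summary statistics and runs only when those files are
supplied locally.

## Limitations

No proxy-variant lookup, no liftover, no VCF ingestion, no Steiger
directionality filtering, no binary-outcome (liability) power formula,
and none of the mixture-model estimators (MRMix, contamination mixture);
the LD machinery targets panels of hundreds to thousands of candidate
variants, not genome-scale binary genotype formats.
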