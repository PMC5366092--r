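---
title: "Age-at-onset informed association testing with liabilityGWAS"
author: "liabilityGWAS maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-at-onset informed association testing with liabilityGWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liabilityGWAS)
```

# The model

Case/control GWAS ordinarily discards a highly informative covariate: the
age at which cases fell ill and the age to which controls have stayed
healthy.  For diseases whose cumulative risk rises steeply with age, a
young case must carry an unusually large dose of risk factors to have
crossed the disease threshold already, while an old, still-healthy control
is evidence of unusually low risk.  `liabilityGWAS` implements an
association workflow that encodes this intuition through the classical
liability threshold model.

Each individual has a latent, standard-normal *liability*
$\varphi = c\,(t - \bar t) + m + \varepsilon$, where $t$ is age, $\bar t$
a fixed reference age, $c$ the per-year liability trend, $m$ the offset at
the reference age, and $\varepsilon = \gamma g + e$ the residual liability
carrying the genetic effect $\gamma$ of genotype $g$ plus standard-normal
noise $e$.  A person is a case iff $\varphi \ge 0$, i.e. iff
$\varepsilon$ exceeds the age-dependent threshold
$$\tau(t) = -c\,(t - \bar t) - m ,$$
so the implied prevalence at age $t$ is $P(\text{case}\mid t) =
1 - \Phi(\tau(t)) = \Phi(c\,(t-\bar t) + m)$.

## Calibration from risk-by-age schedules

`calibrateLiability()` estimates $(c, m)$ per sex from a published
cumulative risk schedule.  Each cumulative risk $R_k$ quoted at age $a_k$
is multiplied by the subtype fraction $s$ (0.20 by default for a stroke
subtype analysis, 1 for the whole disease), probit-transformed,
$y_k = \Phi^{-1}(s R_k)$, and regressed on age by ordinary least squares;
$c$ is the slope and $m$ the fitted value at the index age
$\bar t = 55$.  The shipped schedules are the population-based ischemic
stroke risks from an index age of 55 (women: 1.8%, 5.4%, 12.1% before
65, 75, 85; men: 2.4%, 7.3%, 12.6%).

Two modelling choices deserve comment:

* **Sign convention.**  We parameterise the offset so that
  $P(\text{case}\mid\bar t) = \Phi(m)$, i.e. $m = \Phi^{-1}(p)$ is
  *negative* for a rare disease and the threshold $\tau(\bar t) = -m$ is
  large and positive.  The occasionally seen convention
  $\Phi(-m) = p$ would place more than half the population above the
  case threshold for a rare disease; the present form preserves every
  downstream formula and the qualitative behaviour (younger cases carry
  larger posterior liability).
* **Risks as prevalences.**  Each printed cumulative risk is treated as
  $P(\text{affected by age } a)$ and fitted on the probit scale.  With
  two schedule points the fit is exact; with three or more, small probit
  nonlinearity is absorbed into OLS residuals, and
  `caseProbability()` reproduces the schedule up to those residuals.

With no sex record, the average of the per-sex thresholds is used.

## Posterior mean liabilities

Given status $z$ and age $t$, the expected residual liability is a
truncated-normal mean,
$$E(\varepsilon \mid z = 1, t) = \frac{\phi(\tau)}{1 - \Phi(\tau)},
\qquad
E(\varepsilon \mid z = 0, t) = -\frac{\phi(\tau)}{\Phi(\tau)},$$
the upper- and lower-tail inverse Mills ratios at $\tau = \tau(t)$.
Young cases take the largest positive values; old controls the most
negative.  Both are evaluated on the log scale
(`dnorm(log = TRUE) - pnorm(log.p = TRUE)`), not as a naive pdf/cdf
quotient, and remain accurate and finite for $|\tau|$ well beyond 38;
tests verify agreement with adaptive quadrature to far better than
$10^{-8}$ across $\tau \in [-8, 8]$ and the exact zero-mean identity
$P(\text{case})\,E(\varepsilon\mid\text{case}) +
P(\text{control})\,E(\varepsilon\mid\text{control}) = 0$.

Missing ages (typically well under 1% of samples) are median-imputed
within the cohort and status group — cases receive the case median —
before posterior computation (`imputeMissingAge()`).

## The score test

`liabilityScoreTest()` residualizes both the dosage and the posterior
liability on an intercept plus any ancestry principal components
(EIGENSTRAT-style; both sides are adjusted, which makes the statistic
invariant to which side the confounder enters), and forms
$$\chi^2 = N r^2,$$
with $r$ the Pearson correlation of the residuals, referred to
$\chi^2_1$; $Z = \mathrm{sign}(r)\sqrt{\chi^2}$ is oriented to the
counted allele.  $N$ is the number of samples complete for dosage,
posterior and covariates (listwise).  A dosage constant after
residualization yields a flagged untestable record rather than a silent
drop.  `logisticAssoc()` and `linearQtlAssoc()` provide the conventional
case/control and quantitative (cis-QTL) analyses via `glm()`/`lm()`,
with Wald statistics from the observed information.

## Filters, genomic control, FDR

`snpFilter()` applies the conventional exclusions — imputation info
score below 0.7 or minor allele frequency below 0.01 — with *inclusive*
thresholds (info exactly 0.7 is kept) and an itemised exclusion report.
`genomicControl()` estimates $\lambda$ as the median $\chi^2$ over its
null median 0.4549364 and divides statistics by $\lambda$ only when
$\lambda > 1$; deflation is never applied in reverse, and correction is
per cohort, before meta-analysis.  `lambda1000()` rescales an inflation
factor to the canonical 1,000-case/1,000-control study.  `bhFdr()` is
the Benjamini–Hochberg step-up with the "equivalent p threshold"
reported alongside the flags.

## Meta-analysis and the three-stage design

`stoufferMeta()` combines signed per-cohort Z scores with weights
$w_i = \sqrt{N_i}$; the default uses the effective sample size
$4/(1/n_{\text{case}} + 1/n_{\text{ctrl}})$, the METAL convention for
case/control studies, falling back to raw $N$ where the split is
unavailable (`weights = "raw"` forces raw $N$).  METAL-style direction
strings (`+`/`-`/`?`) are emitted.  `ivwMeta()` and `cochranQ()` supply
fixed-effects inverse-variance pooling and heterogeneity.

`clumpSelect()` reduces a summary-statistics set to loci: greedily take
the smallest-p unassigned SNP as index, claim ±500 kb (configurable),
and keep up to two additional SNPs per locus by smallest p, restricted
to $r^2 \ge 0.5$ with the index when an LD matrix is supplied.  Ties
break deterministically by (p, chromosome, position, allele).
`runStages()` chains the three-stage design: top-25-loci selection in
stage I, Stouffer meta of stages I+II gated at $5\times10^{-7}$,
survivors meta-analysed across all three stages and flagged at
$5\times10^{-8}$, with a full audit trail.  The final statistic is the
ungated Stouffer combination over all stages — gating affects selection
only.  `quartileAnalysis()` splits cases into onset-age quartiles
(type-7 quantiles, boundary ties to the lower quartile), fits each
quartile against all controls by logistic regression, and pools across
cohorts by inverse variance.

## Colocalization

`colocPosterior()` asks whether a disease signal and a molecular-QTL
signal in a window (default ±50 kb around the lead SNP, inclusive)
share one causal variant.  Per-SNP Wakefield log approximate Bayes
factors,
$$\log ABF = \tfrac12\log\frac{v}{v+w} + \tfrac12 z^2 \frac{w}{v+w},$$
are combined over the five hypotheses (no association; trait 1 only;
trait 2 only; both, two SNPs; both, one shared SNP) with per-SNP priors
$p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$ — the field's customary
defaults — and prior effect variance $w = 0.15^2$ for case/control
traits and $0.2^2$ for quantitative traits, all configurable.  All
configuration sums use log-sum-exp arithmetic and stay finite for log
Bayes factors up to several hundred; a single-SNP window yields
$PP_3 = 0$ exactly, as no two-SNP configuration exists.  When only Z,
N and allele frequency are available, the sampling variance is
approximated by $1/(2f(1-f)N)$ (divided by $s(1-s)$ for a case
fraction $s$), and the output flags the approximation.

# The synthetic-data generator

Because the consortium genotypes behind any real analysis of this kind
are not redistributable, the package carries a first-class generator so
every stage is testable offline.

* **Population.**  Ages uniform on 35–85 years, sexes balanced, one
  individual per draw; liability
  $\varphi = c(t-\bar t) + m + \gamma (g - 2f) + N(0,1)$ with the
  genetic term centred so the marginal age-specific case rate stays
  exactly on the calibrated schedule (the uncentred form differs only
  by an intercept shift).
* **Genotypes.**  Haplotypes come from a latent Gaussian AR(1) process
  within consecutive LD blocks (default 10 SNPs per block,
  $\rho = 0.8$), thresholded at each SNP's target frequency and summed
  — a seedable Gaussian-copula model that is adequate for exercising
  clumping and colocalization without coalescent machinery.  Blocks
  are laid out 2 Mb apart, ten per chromosome.
* **Ascertainment.**  Cases are rare, so the generator draws source
  batches until the quotas are reachable, then samples controls
  uniformly and cases with weight $\exp(-0.08\,(t - t_{\min}))$ per
  year in the young-onset-enriched design (a threefold surplus of
  affected individuals is drawn first).  The 0.08/year rate was chosen
  so that about 45% of sampled cases are younger than 70, matching the
  published discovery composition in which 1,012 of 2,275 small-vessel
  cases came from a younger-onset (<70) cohort; `caseAgeWeight = 0`
  gives population-proportional cases, which — because risk rises with
  age — are *older* than controls on average.
* **Efficiency.**  Only the causal SNP is generated at the population
  stage (its marginal law is Binomial(2, MAF)); after selection its LD
  block is completed by exact conditional AR(1) reconstruction
  (truncated-normal latent given the allele, Markov chain outward),
  and all other blocks — independent of the phenotype given the causal
  genotype — are generated directly for the selected samples.  This is
  exact under the generator's own model and keeps source pools of
  several hundred thousand cheap.
* **Imputation quality.**  `degradeToDosage()` models lossy imputation
  per haplotype: each allele is retained with probability equal to the
  target info score and otherwise replaced by the population frequency.
  The dosage variance is then exactly $k \cdot 2f(1-f)$, the estimated
  info score is unbiased for the target, and dosages never leave
  $[0,2]$.
* **Molecular traits.**  `simulateMolecularTrait()` adds
  $b \cdot \text{dosage} + N(0, \sigma^2)$ with $b$ derived from a
  target variance explained (default 6%, the middle of the 5–8%
  cis-mQTL design range used in the validation suite).

What the generator does *not* emulate: realistic human LD maps and
frequency spectra, competing mortality, secular trends in incidence,
genotyping batch structure, or population stratification (PCs enter the
tests as covariates but the generator draws a homogeneous population).
Passing the suite therefore demonstrates the statistical machinery is
correct under the stated model, not that any particular real-data result
is reproduced.

One structural simplification is inherited from the cross-sectional
threshold model itself: a case's age-at-onset is approximated by the age
at which the individual is sampled.  A survival/competing-risk treatment
of incidence is out of scope by design.

# Numerical choices

* Mills ratios via log-scale `dnorm`/`pnorm`, finite past $|\tau|=38$.
* Log-sum-exp for every colocalization configuration sum;
  $PP_3$ computed as $\log(e^{S_1+S_2} - e^{S_4})$ via `log1p`, with an
  exact $-\infty$ guard for the single-SNP case.
* Residualization through QR (`qr.resid`), with rank-deficiency errors
  naming the collinear column; the vectorised genome-wide scan and the
  per-SNP path agree to $10^{-12}$ and idempotence holds to $10^{-10}$.
* Logistic fits: `glm` with tolerance $10^{-10}$, 100 iterations;
  perfect separation yields a flagged record with missing SE (no Firth
  correction).
* Deterministic tie-breaks everywhere a selection is made (clumping:
  p, chromosome, position, allele).
* All generators take an integer seed and restore the caller's RNG
  state (`withSeed`); equal seeds give bitwise-identical output.

# Validation problem sizes

The test suite and the acceptance script exercise, as this package's
chosen validation conditions: the staged count reconciliation and
$\lambda_{1000}$ arithmetic on the shipped study table; the quadrature
oracle on a $\tau$ grid over $[-8, 8]$; null size on one cohort of
1,000 cases / 1,000 controls $\times$ 5,000 independent SNPs; the
liability-vs-logistic power comparison and the three-cohort
(1,500/1,500 each, 60 SNPs, $\gamma = 0.15$, MAF 0.3) staged recovery
over 50 seeds each; colocalization against exhaustive enumeration for
regions of up to 25 SNPs and a shared-causal simulation at 20 SNPs.

# Known limitations

* The score test assumes the liability model's residual normality;
  gross miscalibration of the risk schedule biases posterior means,
  though the null size is protected by the permutation-like structure
  of the correlation statistic.
* Raw $N$ versus effective $N$ in $\chi^2 = N r^2$ matters under heavy
  case/control imbalance; raw $N$ is used for the per-cohort statistic,
  while meta-weights default to effective $N$.
* X-chromosome dosage compensation, mixed-model association,
  random-effects meta-analysis and multi-causal colocalization are out
  of scope.
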