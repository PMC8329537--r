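---
title: "Models and methods: maternal crossover plasticity in cattle pedigrees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: maternal crossover plasticity in cattle pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recombinr)
```

## The scientific problem

Meiotic recombination is phenotypically plastic: how many crossovers a
female meiosis produces depends not only on the dam's genotype but also on
her age and, in several taxa, on environmental temperature. In genotyped
dairy-cattle populations the phenotype is observable at scale without any
molecular assay: inside a *three-generation family* — a genotyped
offspring, its genotyped dam, and at least one genotyped grandparent — the
dam's two haplotypes can be assigned to grandparental origin, and every
switch of origin along the gamete she transmitted is one maternal
crossover.

`recombinr` implements that observation chain and the downstream
plasticity analysis as a tested pipeline:

1. **family extraction** — find every (dam, offspring) meiosis with the
   required genotyping pattern, applying the panel-density rule (all
   genotyped members on chips of at least 50,000 markers);
2. **crossover calling** — Mendelian trio phasing of the dam,
   informative-site detection, origin tracing, and interval-resolved event
   calling, followed by the genome-wide cap of 45 crossovers per meiosis;
3. **covariates** — maternal age in complete months (`A`), dam birth year
   (`B`), and hot/cold/normal temperature categories for the month
   preceding the offspring's birth (`T1`, fetal development of the
   offspring) and the month preceding the dam's own birth (`T2`, fetal
   development of the dam, when female meiosis arrests);
4. **mixed model** — the full model
   $$Y = \alpha + T_1 + T_2 + A + A^2 + B + B^2 + g + \epsilon,
     \qquad g \sim N(0,\, \sigma^2_g \mathbf{G}),$$
   where $Y$ is the crossover count residualized on chip class and
   informative-marker count, $\mathbf{G}$ is the VanRaden method-1 genomic
   relationship matrix of the dams, and heritability is
   $h^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_e)$.

Because national evaluation databases are proprietary, the package ships a
synthetic-data module that generates pedigrees, genotypes, meioses, and
farm temperature series with known truth, so every stage is verifiable end
to end.

## The crossover caller

**Phasing.** The dam's phase is deduced site by site from her parents'
genotypes only (single-pass Mendelian deduction, no statistical or
population phasing). A grandparent with dosage 0 or 2 can only have
transmitted that allele; a heterozygous or ungenotyped grandparent can
have transmitted either. At a heterozygous dam site the ordered assignment
(grandpaternal, grandmaternal) is fixed when exactly one of the two
orderings is compatible; when both are, the site stays phase-unknown, and
when neither is, it is a Mendelian inconsistency — counted, logged, and
excluded, never fatal. Only unambiguous sites ever become informative, so
no probabilistic phasing error can propagate into an event call.

**Informative sites and tracing.** A site is informative when the dam is
heterozygous with known phase *and* the transmitted allele is
determinable: offspring homozygous, or offspring heterozygous with a
homozygous sire. (Whether the study required the sire genotyped is not
stated in the source literature; here the sire is optional and used only
for this disambiguation.) Each informative site is labelled with the
grandparental haplotype carrying the transmitted allele; one crossover is
called per adjacent pair of informative sites with different labels,
localized to the 0-based half-open interval between them.

**What calling can and cannot see.** An even number of true crossovers
between two adjacent informative sites cancels; crossovers before the
first or after the last informative site are invisible. The caller is
therefore validated not against raw truth counts but against the exact
estimand: on error-free data the called count per chromosome equals the
number of *parity changes* of true crossovers between consecutive
informative markers, and every odd-parity interval is covered by exactly
one called event. The test suite checks this equivalence exactly over 500
simulated meioses on a 5 x 2,000-marker genome.

**Quality filters.** All constants are surfaced in the run configuration
with their conventional defaults: panel density 50,000; genome-wide cap
45; per-family Mendelian-inconsistency tolerance 0.02 (the threshold is
ours — the source analyses do not state one); an optional BED mask of
problematic regions applied before phasing; autosomes only. A
short-window double-crossover artifact filter is deliberately not applied
by default, since no window is stated in the literature; the interval
output makes it easy to add downstream.

## The synthetic-data generator

The generator's defaults are the study conditions the analysis assumes;
they are fixed once and are not tuning knobs.

**Counts.** Genome-wide maternal crossover counts are Poisson conditional
on a Gaussian latent rate
$$\lambda_i = \mu + x_i'\beta + g_i + e_i,$$
floored at 0.5. The published empirical distribution is "close to normal"
with mean 23.2 and variance 98.3, with no generative form given; the
Poisson–Gaussian mixture is our choice, flagged as such. It yields the
required overdispersion (law of total variance:
$\mathrm{var}(R) = E\lambda + \mathrm{var}\,\lambda$) and a well-defined
heritability on the count scale. With default effect sizes the marginal
moments are matched *exactly* by solving, after the covariates are
realized, $$\sigma^2_g = h^2\,(V - v_f), \qquad
\sigma^2_{lat} = (1 - h^2)(V - v_f) - \mu,$$ where $V = 98.3$ is the
target variance, $v_f$ the realized variance of the centered fixed-effect
contribution, and $\mu = 23.2$. The Poisson noise $\mu$ lands in the
model's residual, so `h2_true = 0.10` is *exactly* the estimand of the
GRM-REML fit — this is what makes the heritability-recovery experiment a
calibration-free test.

**Fixed effects.** Default generative effect sizes are the published
eight-factor estimates: cold/hot during offspring fetal development
$-0.194$ / $+0.167$; cold/hot during the dam's own fetal development
$+0.139$ / $+0.093$; maternal age $-0.082$ per month with quadratic
$+4.69\times10^{-4}$; birth year $+5.02\times10^{-3}$ with quadratic
$-4.41\times10^{-7}$. Note an internal tension in the source estimates:
the age betas place the parabola vertex near 87 months while the spline
analyses report the minimum at 65 months; the generator uses the
published betas as-is, and the spline-recovery experiment generates its
own quadratic minimized at 65 months.

**Genetics.** $g_i = \sum_j a_j (x_{ij} - 2p_j)$ with marker effects
$a_j \sim N(0, \sigma^2_g / 2\sum_j p_j(1-p_j))$, so
$\mathrm{cov}(g) = \sigma^2_g \mathbf{G}$ for the VanRaden matrix computed
from the same genotypes — the realized GRM explains the simulated genetic
values by construction. Founder haplotypes are drawn in linkage
equilibrium with allele frequencies uniform on (0.05, 0.5); realistic LD
from a coalescent is a stated non-goal.

**Meioses.** The desk-scale genome is 5 chromosomes; per-chromosome map
length defaults to $\mu / 5$ Morgans so the map implies the configured
expected genome-wide count. Given a count, crossovers are allocated to
chromosomes proportionally to map length and placed uniformly on genetic
distance (no interference — the analysis uses only counts and interval
positions; a gamma-interference hook can be added without touching the
caller). Each chromosome starts from a random grandparental strand.
Gametes are transmitted exactly, so before error injection offspring
genotypes are Mendelian-perfect; genotyping errors (default 0.001) and
missingness (default 0.005) are then injected per call.

**Pedigree and environment.** Founders split evenly by sex across 6
farms; each dam produces on average 3 calves per generation step with
first calving near 26 months and ~13-month intervals, which spans the
maternal-age range the analyses use. Monthly farm temperatures follow a
sinusoid peaking in July (annual mean 12 °C, amplitude 15 °C, month-level
noise 2 °C, between-farm spread 3 °C), which yields realistic shares of
hot (> 26.67 °C) and cold (< 4.44 °C) month-prior exposures for a
temperate dairy region.

**What the simulator does not emulate.** Real LD and allele-frequency
spectra, chip-specific marker panels (chip class is metadata driving the
density filter, not a separate marker set), selection and culling,
pedigree errors, and the conception-to-birth gestation offset. Passing
tests therefore demonstrate correctness of the algorithms under the
stated generative assumptions, not robustness to every artifact of
national evaluation data.

## Covariate conventions

* **Month prior to birth.** The temperature covariate is the stored
  monthly average for the full calendar month preceding the birth month.
  The source text is ambiguous between this reading (its methods) and
  temperatures "when the calves were conceived" (its results); the
  month-prior reading is the default here, and since covariates flow
  through one lookup function, the alternative is a one-line change.
  Missing months flag the record for exclusion from temperature analyses
  rather than erroring.
* **Strict thresholds.** "Above 26.67 °C" and "below 4.44 °C" are read as
  strict inequalities; boundary values are normal.
* **Age groups.** Ten bins from 20 months in 10-month increments, the
  last bin open-ended (everything over 110, including the published
  "over 120 months" records); ages under 20 months are excluded from
  grouped displays only — ungrouped analyses use all ages.
* **Residualization.** `Y` is the residual of the count on chip-class
  indicators plus the continuous informative-marker count. The functional
  form is not stated in the source; categorical-plus-continuous is our
  choice. With a single chip class and constant marker count this
  degrades gracefully to centering.

## The mixed model and REML

The variance structure is
$V = \sigma^2_e I + \sigma^2_g Z \mathbf{G} Z'$, with $Z$ the
meiosis-to-dam incidence matrix (meioses of one dam share her $g$; the
one-record-per-family layout is the special case $Z = I$).

**Algorithm.** Rather than average-information Newton updates (which can
step outside the parameter space and need EM safeguarding), the fit is
exact: eigendecompose $\mathbf{G}$ once, form $W = Z U D^{1/2}$, and take
the spectrum of $W'W$, which diagonalizes $V$ in a rotated basis. For a
fixed ratio $\gamma = \sigma^2_g/\sigma^2_e$ the REML residual variance
has the closed form $\hat\sigma^2_e(\gamma) = y'P_1y/(n-f)$, and the
profiled restricted likelihood is maximized over $\log\gamma \in
[-14, 14]$ by Brent's method (tolerance $10^{-9}$), which cannot diverge;
the $\gamma = 0$ boundary is evaluated explicitly and wins ties, so
$\hat\sigma^2_g = 0$ is reported cleanly rather than as a failed
iteration. After the one-off $O(p^3)$ decomposition each likelihood
evaluation costs $O(k f^2)$, so the 400-replicate null-calibration
experiment is feasible on one core. The optimum is the exact REML
maximum — the test suite verifies it dominates a 50 x 50 grid over
$(\sigma^2_g, \sigma^2_e)$ on a toy dataset.

**Inference.** Fixed effects are GLS at the REML variances with standard
errors from $(X'V^{-1}X)^{-1}$ and two-sided Wald $z$-tests, significance
at $P < 0.05$ with no multiple-testing correction (matching the source
convention). Variance-component sampling covariance comes from the
numerically differentiated Hessian of the unprofiled restricted
log-likelihood at the optimum (`stats::optimHess`); $SE(h^2)$ follows by
the delta method — how the published $SE(h^2) = 0.03$ was obtained is not
stated, and the delta method is our choice. At the $\sigma^2_g = 0$
boundary the Hessian is one-sided and the SE is reported as `NA` rather
than a fabricated number.

**Conditioning.** `A`, `B` enter the reported model uncentered (months
and calendar years, matching the published coefficient scales), but an
uncentered design with $B \approx 2000$ and $B^2 \approx 4\times10^6$ has
condition number around $10^{13}$. Internally the quadratics are built
from centered variables and the estimates mapped back with the exact
affine transform (covariances included); the reported coefficients are
identical to the raw-basis fit at full precision, which the OLS
equivalence test checks to $10^{-6}$.

**Degenerate inputs.** Rank-deficient designs error naming the aliased
column; temperature dummies are built only for categories observed in the
data; fits need at least 30 complete rows; a GRM not covering every dam
errors naming the missing ids.

## Smoothing spline and group summaries

The maternal-age trend uses `stats::smooth.spline` with
generalized-cross-validated smoothing, evaluated on a 400-point age grid;
the reported turning point is the grid argmin. Age-group summaries report
mean and $sd/\sqrt{n}$ per bin (empty bins kept with $n = 0$);
temperature-category summaries report medians, quartiles, and 1.5 x IQR
whiskers via `grDevices::boxplot.stats`, omitting absent categories with
a warning.

## Verification experiments and problem sizes

The package's verification experiments (in `tests/testthat/`, mirrored by
`scripts/acceptance.R` for the calibration quantities) use these desk
scales, chosen once as a balance of statistical resolution and single-core
runtime:

* caller oracle equivalence: 500 error-free meioses, 5 x 2,000 markers —
  exact equality required;
* simulator calibration: 10,000 meioses (2,500 dams x 4), sample mean and
  variance within 3 Monte-Carlo standard errors of 23.2 and 98.3;
* heritability recovery: 10 replicates of 1,000 dams x 3 meioses, mean
  REML $\hat h^2$ within ±0.04 of the generating 0.10;
* fixed-effect recovery: 20 replicates of 500 dams x 10 meioses; at
  least 90% of the per-replicate estimates of
  $\beta_{hot}, \beta_{cold}, \beta_A, \beta_{A^2}$ fall within 2
  standard errors of their generating values;
* spline recovery: 10 replicates, n = 4,000, curvature 0.004 per month²
  and residual sd 3 around a 65-month minimum (a signal-to-noise chosen
  to carry roughly the information the full-scale study's record count
  provides), argmin within ±10 months;
* null calibration: 400 replicates of 200 dams x 2 meioses with both
  parent-stage temperature effects set to zero; the pooled Wald rejection
  rate of the two terms at $\alpha = 0.05$ must fall in a binomial band
  around 0.05.

The headline results of the motivating full-scale analysis (hundreds of
thousands of families, millions of events) derive from a proprietary
national database and are deliberately out of reach at desk scale;
nothing in this package asserts them.

## Known limitations

* Phasing is family-local; sites that population phasing could rescue
  stay uninformative, so informative density — and thus resolution — is
  below what the full-scale studies achieve with dedicated phasing
  pipelines.
* The exact informative-site and error-handling rules of the pipelines
  cited by the source literature are not published in it; the rule set
  here is a documented stand-in validated against its own truth model.
* One genetic variance component only: no dominance, no
  permanent-environment effect separate from $g$ (with repeated meioses
  per dam these would be confounded with $\sigma^2_g$ in part), no THI or
  humidity handling, no X chromosome, and paternal meioses are out of
  scope.

## A minimal run

```{r example, eval = FALSE}
run <- run_pipeline(pipeline_config(list(
  seed = 91,
  sim = list(n_founders = 36, n_generations = 3, markers_per_chrom = 150,
             genotyping_error_rate = 0, missing_rate = 0,
             seasonal_temp = c(mean = 16, amplitude = 16, noise_sd = 2)))))
make_report(run)       # eight-factor table, h2, spline argmin
tidy(run$fit)          # broom-style coefficients
glance(run$fit)        # variance components and h2
plot_age_spline(run$spline)
```
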