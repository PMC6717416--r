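---
title: "Methods: probabilistic dermal risk assessment for metals in hair dyes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probabilistic dermal risk assessment for metals in hair dyes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermrisk)
```

## The model

`dermrisk` estimates the chronic daily dose of a metal absorbed through
the scalp during hair-dye use,

$$D_\mathrm{dermal} = \frac{C \cdot SA \cdot SL \cdot ABS \cdot EF \cdot ED}{BW \cdot AT} \times 10^{-6}
\quad \left[\mathrm{mg\,kg^{-1}\,day^{-1}}\right],$$

with averaging time $AT = ED \times 365$ days. The symbols, units and
defaults:

| symbol | meaning | unit | default |
|---|---|---|---|
| $C$ | metal concentration in the product | mg/kg | fitted distribution |
| $SA$ | exposed scalp area | cm² | 580 (fixed) |
| $SL$ | product adherence to skin | mg/cm² | 1.45 (fixed) |
| $ABS$ | absorbed fraction | — | 0.001 (fixed) |
| $EF$ | applications per year | day/yr | lognormal, mean 12, SD 4 |
| $ED$ | years of use | yr | lognormal, mean 20, SD 8 |
| $BW$ | body weight | kg | lognormal, mean 60, SD 8 |

The $10^{-6}$ factor converts the mg-of-product basis of
$C \cdot SL \cdot SA$ to kg, exactly as the dose equation is
conventionally printed. Because $AT \propto ED$, the dose is
*algebraically invariant to $ED$*; the package keeps $ED$ in the
interface and the sensitivity report (its rank correlation is ≈ 0 by
construction, with an explanatory note) rather than silently removing
it.

Risk is characterized per metal by the hazard quotient
$HQ = D_\mathrm{dermal}/RfD$ using dermally-adjusted reference doses by
default (the ingestion column is retained and selectable), and per
stratum by the chronic hazard index $HI = \sum_k HQ_k$. The
classification threshold is strict: values **greater than** 1 are
"significant", 1 or below "not-probable". When the censoring policy has
excluded metals, $HI$ is reported as an explicit lower bound and the
exclusions are listed — never folded in as zero.

No exposure-factor values were fixed by the study this design emulates,
so all defaults above are package choices: $SA$, $SL$ and $ABS$ are
conventional screening values for scalp application of a rinse-off
product, and the stochastic $EF$, $ED$, $BW$ are lognormals centered on
the fixed fallbacks (12 applications/yr, 20 yr, 60 kg) with spreads a
questionnaire of adult consumers would plausibly produce (e.g. most
users dye between 6 and 20 times a year). Every run echoes the factor
configuration in its manifest, and each one can be replaced by a fixed
value or any `dist_spec()`.

## Censored concentrations

Measurements below the limit of detection are left-censored. The policy
is two-branched, applied per metal, all-or-nothing:

* censored fraction ≥ 20 % (configurable): the metal is **excluded**
  from assessment and the decision is recorded with the observed
  fraction;
* otherwise censored values are **substituted** (half-LOD by default;
  zero and full-LOD available) and flagged `imputed`.

The threshold fires at exactly 20 % (the comparison is ≥). Censored
likelihood fitting is deliberately out of scope — substitution happens
upstream of all fitting, which keeps every downstream stage oblivious to
censoring mechanics.

## Distribution fitting and selection

Concentrations are modelled by one of eight families. The five used for
the packaged reference models are lognormal, log-gamma
($\ln X \sim \Gamma(\alpha, \beta)$, support $x > 1$, optional location
shift disabled by default), Weibull, Pareto type I, and log-Laplace
($\ln X \sim \mathrm{Laplace}(\mu, b)$); normal, gamma and exponential
are generic alternates. Parameterizations follow the common conventions
of commercial fitting tools and are recorded in output metadata.

Fitting is maximum likelihood: closed forms where they exist
(lognormal, normal, exponential, log-Laplace via the Laplace MLE on
logs, Pareto with $x_\min$ at the sample minimum and
$\hat\alpha = n/\sum \ln(x_i/x_\min)$), Nelder–Mead on log-transformed
parameters for gamma, Weibull and log-gamma with moment-based starting
values. Candidates that cannot be fitted (support violations — e.g.
log-gamma on data with values ≤ 1 — or degenerate samples) are retained
in the ranking with their failure message.

Selection ranks successful fits by the Kolmogorov–Smirnov statistic
ascending, with Anderson–Darling then chi-square as deterministic
tie-breaks; the chi-square uses $\lceil 1 + \log_2 n \rceil$
equal-probability bins under the fitted cdf. At the study's sample size
($n = 32$) selection power is limited — in simulation the generating
family lands in the top 2 for most but not all metals — which is the
expected behaviour, not a defect; fitted parameters are validated by
parameter-recovery properties rather than against published values,
since none were published.

## Monte Carlo engine

`simulate_dose()` draws each distributional input from its **own named
RNG stream**, derived deterministically from the run seed. This gives
bit-identical reproducibility and stream independence, which the
rank-correlation sensitivity analysis requires. Inputs are sampled
independently; no correlation structure is modelled (a deliberate
scope decision).

Realized values outside an input's support — possible only for
user-supplied unbounded families such as a normal body weight — are
rejected and redrawn from the same stream, with the rejection count
reported; redrawing is capped at 10× `n_iter` attempts so a severely
misspecified input fails loudly instead of looping. Silent truncation
would bias summaries invisibly, which is why rejection is counted and
surfaced in the manifest.

The default iteration count is 20,000 (the value governing the reported
figures); 2,000 is a recognized light preset. The risk point estimate
defaults to the **median** of the simulated dose — the simulated dose is
strongly right-skewed, and the median is robust to the upper tail (the
mean is available).

Stratified risk (per brand, per color) feeds each stratum's
concentration point estimate (median over its measurements) through the
same dose pipeline as a fixed concentration, sharing exposure-factor
draws across metals and strata so that between-stratum contrasts
reflect concentrations only. Full distribution fitting inside a stratum
of 4 samples would be unstable, which is why strata use point estimates
while the pooled analysis (n = 32) fits distributions.

## The synthetic-data generator

The generator emulates the study design the analysis assumes:

* 8 brands (annotated Iran/Spain/Italy/Germany) × 4 colors (black,
  blonde, light brown, dark brown) × 1 replicate = 32 samples per metal;
* six assessed metals (Al, Ba, Cd, Cu, Fe, Pb) drawn per brand cell from
  lognormals moment-matched to the packaged per-brand mean/SD reference
  cells ($\sigma^2 = \ln(1 + sd^2/\mathrm{mean}^2)$,
  $\mu = \ln(\mathrm{mean}) - \sigma^2/2$; SD 0 degenerates to a point
  mass); a per-color parameterization ships as an alternate design;
* reference cells flagged as heavily censored (one Ba and one Cd brand
  cell) generated from a lognormal with mean = SD = LOD, so most of
  their draws censor without pushing the whole metal over the exclusion
  threshold;
* four censoring-prone metals (Ag, Co, Cr, Mn) generated with 25 %
  sub-LOD probability, so the exclusion branch of the censoring policy
  is exercised end-to-end — deterministically in expectation, stochastic
  per seed;
* draws below the metal's LOD are stored as censored with the LOD.

A companion survey generator emits questionnaire-like populations
(dye-use prevalence 92.19 %, chemical-dye share 49.5 %, color-preference
weights 33.6/27.4/19.6/14 %, lognormal starting age, application
frequency and body weight).

What the generator does **not** emulate: correlation between metals
within a sample, between-color structure within a brand (the per-brand
design determines colors only marginally — the per-brand and per-color
reference tables are marginal summaries of the same 32 samples and
cannot both be matched by independent cell-wise generation, so they are
treated as alternative parameterizations), measurement error, or batch
effects. Passing tests therefore demonstrate the *pipeline's*
correctness under a faithful rendering of the study's design and
summary statistics, not fidelity to the unpublished raw measurements.

## Numerical choices

* Canonical concentration unit is mg/kg (ppm); ppb inputs are divided by
  1000 at ingest and LODs are converted alongside.
* Percentiles use linear interpolation between order statistics
  (quantile type 7), recorded in the summary metadata.
* Quantile/cdf inverse identity holds to 1e-8 on interior
  probabilities for every family (closed-form quantiles throughout).
* Dose linearity in concentration is exact draw-by-draw; ED-invariance
  holds to 1e-15 relative.
* Spearman correlation uses average ranks for ties; influence ordering
  is by absolute correlation with the sign reported separately (body
  weight influences negatively); ties in ordering are broken
  alphabetically and flagged.
* A constant input's rank correlation is undefined and reported
  not-applicable, never as zero; a simulation run without input
  retention produces an explicit error instructing a rerun.

Simulation-heavy checks in the test suite use 2,000–20,000 iterations
and 20–100 seed replicates; parameter-recovery checks use 50 replicates
of n = 10,000. Standardized-bias assertions allow 3 Monte Carlo SEs per
parameter because roughly ten parameters are checked jointly — under a
true bias of zero each standardized ratio is approximately standard
normal, so a per-parameter 2-SE rule would false-alarm on more than a
third of seed sets.

## Known limitations

* Dermal pathway only; no ingestion or inhalation, no carcinogenic
  (slope-factor) metrics, no age-segmented lifetime averaging.
* The hazard index is summed across metals within a stratum; when
  exclusions exist it is a lower bound and is labelled as such.
* Absolute dose and hazard values depend entirely on the exposure-factor
  configuration; with the defaults they are screening-level values whose
  rank structure (which metal, which brand) is far more robust than
  their magnitudes.
* The log-gamma family without a location shift requires observations
  above 1 in the working unit; fits on sub-unity data are recorded
  failures. Reference models affected by this are parameterized in
  µg/kg.
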