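---
title: "Methods: ethnic-specific BMI adjustment for child weight-status surveillance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ethnic-specific BMI adjustment for child weight-status surveillance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmiadjust)
```

## The problem

School-based surveillance programmes such as England's National Child
Measurement Programme (NCMP) measure the height and weight of two school
cohorts (reception year, 4–5 years; Year 6, 10–11 years), convert each
child's BMI to a centile of an age- and sex-specific growth reference, and
classify weight status from centile cut-offs. BMI is an imperfect proxy for
body fatness, and the BMI–fatness relationship differs across ethnic groups:
at equal body fatness, South Asian children carry a *lower* BMI than White
children and Black children of African origin a *higher* one. Unadjusted BMI
therefore understates overweight-obesity in South Asian children and
overstates it in Black children.

The remedy implemented here adds an ethnic-specific correction to measured
BMI so that adjusted BMI bears the same relationship to a reference measure
of fatness — the fat mass index, FMI = fat mass / height$^5$ (kg m$^{-5}$),
estimated by deuterium dilution in calibration studies — in every group as it
does in the White reference group. Classification then proceeds exactly as
before, but on adjusted BMI.

## Centiles: the LMS engine

A growth reference is stored as $(L, M, S)$ triples on an age grid per sex:
$M$ the median BMI (kg m$^{-2}$), $S$ the coefficient of variation, and $L$
the Box–Cox power that symmetrises the skewed BMI distribution. A
measurement maps to a normal-equivalent z-score

$$z = \frac{(\mathrm{BMI}/M)^L - 1}{L\,S} \quad (L \neq 0), \qquad
  z = \frac{\log(\mathrm{BMI}/M)}{S} \quad (L = 0),$$

and the centile is $100\,\Phi(z)$. Numerical choices:

* the log form is used whenever $|L| < 10^{-7}$, keeping the transform
  continuous across $L \to 0$;
* $L$, $M$, $S$ are interpolated piecewise-linearly in age, separately per
  parameter — adequate at the fine age grids growth references use, and
  exact at the knots;
* ages outside the reference span are a hard error; silent extrapolation
  corrupts centiles;
* $z$ is clamped to $\pm 8$ before the normal CDF so centiles stay strictly
  inside $(0, 100)$ in double precision, which keeps the classification
  domain well-defined for physiologically extreme inputs;
* decimal age is used exactly as supplied; whether a surveillance programme
  rounds age to months is not observable from outside, so the package
  declares the exact-age convention rather than inferring one.

The inverse map (centile → BMI) is used by the synthetic generator and
round-trips through the forward map to well below $10^{-9}$ centile points
(verified in the tests at $10^4$ random draws).

## Classification

Two named threshold schemes are built in. *Population* (surveillance)
thresholds: underweight at or below the 2nd centile, overweight at or above
the 85th and below the 95th, obese at or above the 95th. *Clinical*
(parent-feedback) thresholds: overweight at or above the 91st, obese at or
above the 98th. "Overweight-obese" is everything at or above the overweight
cut. Boundary direction matters — "or below" versus "on or above" — so the
semantics are encoded once in the scheme object and unit-tested at every
printed threshold.

Exclusion filtering applies, in order: unparseable fields, plausibility
bounds, the cohort age windows, flagged local authorities (LAs); each record
is counted once under its first triggered reason. The programme's own
plausibility rules are not published, so the defaults — height 80–200 cm,
weight 8–150 kg, BMI 8–60 kg m$^{-2}$ — are documented, configurable
choices wide enough never to exclude genuine children. Cohort windows
default to $[4, 6)$ and $[10, 12)$ years, consistent with school-year
cohorts whose mean ages are about 5.0 and 10.9 years. Severe obesity can be
flagged against a sex–age-indexed BMI cut-off table (linearly interpolated
in age, flag at or above the cut-off) in the style of the extended IOTF
thresholds; the published cut-off values are proprietary to their source, so
the shipped table is synthetic and any real table can be supplied as
delimited text.

## The adjustment model

A model holds one rule per sex × broad ethnic group:

* **identity** — White and unknown-ethnicity children are never adjusted,
  and groups without calibration data cannot be;
* **additive constant** — BMI + $\delta$, independent of age and BMI. The
  published South Asian adjustments have this form: $+1.12$ kg m$^{-2}$ for
  boys and $+1.07$ kg m$^{-2}$ for girls, applicable at all ages and
  fatness levels;
* **banded linear** — per 3-year age band $[lo, hi)$,
  $\mathrm{adjusted} = \mathrm{intercept} + (1 + \mathrm{slope}) \times
  \mathrm{BMI}$, with slope $> -1$ enforced at validation so adjustment
  preserves BMI ordering within a stratum. The published Black adjustments
  are negative and grow in magnitude with age and fatness; their exact
  coefficients appear only in supplementary material of the source studies,
  so the package's default encodes the documented *structure* with
  illustrative values (intercepts $-0.30/-0.40/-0.50$, slopes
  $-0.040/-0.050/-0.060$ across bands 4.0–6.9, 7.0–9.9, 10.0–12.9 years)
  and real coefficients are supplied as JSON configuration.

Fatness dependence is expressed through unadjusted BMI because surveillance
records contain nothing else: height and weight are the only anthropometry
collected. Sub-ethnic groups (Black African, Indian, …) inherit their broad
group's rule.

## Deriving adjustments from calibration data

Given calibration records (sex, 3-year age band, ethnic group, height, fat
mass, BMI), the derivation fits, per sex,

$$\mathrm{BMI} \sim \mathrm{FMI} + \mathrm{group} + \mathrm{band}$$

and then enters the three two-way interactions (FMI×group, FMI×band,
group×band) stepwise-forwards at the 5% level, judged by partial $F$-tests
on nested fits — the standard choice for multi-level factor terms. Among
eligible terms the smallest $p$ below 0.05 enters first; ties break by the
fixed order just listed, since "stepwise forwards" alone does not determine
an order. The three-way interaction is considered only when all three
two-ways entered. A joint partial-$F$ test of every group-involving term
guards the null case: when ethnicity explains nothing at the 5% level, the
emitted rule is the identity.

The adjustment for group $g$ is the *negation* of the fitted expected BMI
difference from White at equal FMI and band:
$\mathrm{adjusted} = \mathrm{BMI} - (\hat E[\mathrm{BMI} \mid \mathrm{FMI},
g, b] - \hat E[\mathrm{BMI} \mid \mathrm{FMI}, \mathrm{White}, b])$.
If the difference is constant across bands and the observed FMI range (to
within 0.01 kg m$^{-2}$, the rule-collapse tolerance), the rule collapses to
an additive constant. An FMI-dependent difference is re-expressed in
unadjusted BMI by substituting the White fitted relation
$\mathrm{FMI} = (\mathrm{BMI} - a_b)/b_b$, yielding one (intercept, slope)
pair per band. The collapse tolerance also absorbs the numerically
meaningless interaction terms that can enter when calibration data are
noiseless (zero residual variance makes partial-$F$ $p$-values 0/0), which
is why noiseless constant offsets are recovered to machine precision
regardless of the stepwise path.

The fit report carries, per group, an offset estimate defined as the
group-vs-White contrast at mean FMI averaged over bands, with its standard
error from the coefficient covariance ($c^\top \hat\Sigma\, c$). This
definition is well-posed whatever interaction terms entered, so its 95% CI
has close-to-nominal coverage in the parameter-recovery simulations (200
seeded replicates at roughly 500 children per group, checked in the
acceptance suite).

## Summaries, tests, LA rankings

Child BMI is positively skewed, so strata are summarised by the median and
quartiles (linear interpolation between order statistics, `quantile`
type 7 — a declared convention; the source reporting does not state one).
Prevalences carry Wilson score 95% intervals, chosen over Wald because small
minority strata sit at extreme prevalences where Wald intervals degenerate;
whether the original tables used Wilson or Wald is not determinable from
printed intervals, and the interval is clamped to contain the point
estimate against floating-point edge effects at 0 and 100%.

Distributions are compared with Mann–Whitney $U$ (midrank ties; two-sided
$p$ from the tie-corrected, continuity-corrected normal approximation;
exact enumeration of all $\binom{n_1+n_2}{n_1}$ assignments when both
$n \le 8$). Prevalences are compared with the pooled two-proportion
$z$-test. Both are two-sided with no multiplicity correction, matching raw
$p$-value reporting practice. A caveat established by the package's own
exhaustive scan: the normal approximation and exact enumeration can disagree
by up to 0.088 at $n_1 = n_2 = 2$ (and far more under heavy ties), though
they agree within 0.04 for all untied problems with both $n \ge 3$ — exact
enumeration is therefore the route actually used at small $n$.

Per-LA overweight-obesity prevalence uses the population threshold. LAs
below a minimum participant count (default 1000, counted on the LA's total
included records) are dropped to avoid imprecise rates. Ranks are dense by
descending prevalence with ties broken deterministically by LA code — a
reproducibility requirement the source conventions leave open — so ranks
are always a permutation of $1..K$. Each LA is classed by its within-LA
South Asian and Black proportions against a 20% threshold (configurable),
computed across the whole LA because composition is an LA attribute, not a
cohort one. Spearman's $\rho$ (Pearson on midranks) and top-$k$ set overlap
quantify how much adjustment reorders the league table; $\rho$ is computed
on all included LAs.

## What the synthetic generator emulates — and what it does not

`generate_population()` emulates: two school cohorts with sizes scaled
down 100× from the national survey (2979/2850 and 2488/2366 boys/girls);
the national ethnic mixture (~65% White, ~4.9% Black, ~7.8% South Asian
with the published sub-group splits, ~14% unknown); LA clustering with 30
LAs of which four are high-South-Asian (35% SA), three high-Black (30%
Black) and one high-both, baseline LAs absorbing the residual so the
national marginal is preserved exactly; ethnic BMI differences injected on
the z-score scale (Black $+0.25$ SD; South Asian $+0.10$ SD with scale
1.15, widening both tails as the unadjusted data show: more underweight
*and* more obesity); and cohort-specific normal height models
(110.0/109.0 cm, SD 5.1; 144.7/145.4 cm, SD 7.0/7.5). Injecting shifts on
the z-scale rather than in raw kg m$^{-2}$ keeps the age-dependence
realistic and makes expected category prevalences analytically computable:
with zero shifts every category's prevalence equals its scheme gap width,
which the acceptance suite verifies at $n = 50\,000$ within three binomial
standard errors. Sampled z-scores are clamped at $\pm 4$ SD so generated
records always pass the default plausibility screen.

It does **not** emulate: secular trends, school-level clustering,
measurement error, missingness beyond an unknown-ethnicity share, regional
geography, or any real LA's identity. The single per-group z-shift is also
deliberately simpler than reality — the real South Asian pattern reverses
between cohorts (lower unadjusted prevalence at 4–5, higher at 10–11) —
so passing tests demonstrate mechanical correctness of the pipeline and the
*direction* of adjustment effects, not calibration to any survey year.
Likewise the LMS fixture is a smooth synthetic surface (M rising 15.3–17.6
kg m$^{-2}$ over ages 4–13, $L$ negative so BMI is right-skewed, $S$
0.085–0.121), not the official UK90 coefficients, which are licensed
separately; all reported centiles are relative to this fixture.

`generate_calibration()` draws FMI log-normally per band, height normally,
and BMI from a White law $a + b\,\mathrm{FMI} + \text{band effect} +
N(0, \sigma)$ plus a configurable group offset (constant, or
band-and-FMI-dependent for a Black-like pattern). The true offsets travel
with the dataset so recovery is testable; with $\sigma = 0$ recovery is
exact by construction.

## Problem sizes and runtime

Defaults were chosen so the full test suite runs in well under a minute and
the acceptance script in seconds: populations of $10^4$–$5 \times 10^4$
children, 200-replicate recovery simulations at ~1000 calibration records
each, and $10^4$-draw property checks. These sizes give Monte-Carlo errors
comfortably inside the asserted tolerances (binomial SEs of ~0.1–0.2
percentage points at $n = 50\,000$).

## Known limitations

* The default Black rule is structurally faithful but numerically
  illustrative; analyses of real data must supply the published
  coefficients as configuration.
* Adjustments are standardised to total body fatness; standardising to
  visceral fat, potentially more relevant to metabolic risk in South Asian
  children, would need different calibration data.
* Groups absent from calibration data (Other Asian, mixed/other, unknown)
  remain unadjusted; if South Asian adjustments in fact transfer to Other
  Asian children, their burden is understated here.
* The derivation models band as categorical (as the calibration design
  dictates), so adjusted BMI can step discontinuously at band boundaries
  under banded rules.
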