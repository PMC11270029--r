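---
title: "Temperature and speech complexity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temperature and speech complexity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parlheat)
```

# The scientific question

Heat stress degrades cognitive performance. `parlheat` provides the
statistical machinery to ask whether that shows up in a high-stakes,
professionally produced text corpus: parliamentary speeches. The unit of
analysis is one speech by one politician in one city on one calendar
day; the outcome is a readability-based complexity score; the exposure
is the daily mean temperature of the city hosting the parliament,
discretised into bins around a 12–18 °C comfort zone.

# Outcome: readability scores

Speech complexity is measured by the Flesch reading ease,

$$\mathrm{Flesch} = 206.835 - 1.015\,\frac{\text{words}}{\text{sentences}}
  - 84.6\,\frac{\text{syllables}}{\text{words}},$$

its grade-level transform, the Flesch–Kincaid score

$$\mathrm{FK} = 0.39\,\frac{\text{words}}{\text{sentences}}
  + 11.8\,\frac{\text{syllables}}{\text{words}} - 15.59,$$

and the RIX index, long words (strictly more than 6 letters) per
sentence. FK is the default outcome; Flesch, RIX and the two component
ratios (average sentence length, average syllables per word) are
alternative outcomes so that one can ask *which* component of
complexity reacts to heat. Both formulas are affine in the two ratios,
so all scores are invariant to replicating a text.

Because no standard defines sentence segmentation or syllabification,
the package fixes deterministic rules and documents them:

* sentences end at `.`, `!`, `?` or `;` followed by whitespace and a
  capital letter (or end of text); a fixed abbreviation list (`Dr.`,
  `Mr.`, `Mrs.`, `St.`, `No.`, `etc.`) suppresses splits;
* words are alphanumeric runs with internal apostrophes/hyphens;
  numerals count as one-syllable words;
* syllables are maximal vowel groups (`aeiouy`), minus one for a
  terminal silent `e` — an `e` preceded by a consonant, except in
  consonant-`le` endings (`table`) — floored at one. An `e` preceded by
  another vowel (`agree`) is not silent under this rule, as it does not
  form its own vowel group.

The heuristic is English-oriented; scoring other languages with it is
approximate and cross-language levels should not be compared, only
within-language variation. Sample filters mirror the study design:
speeches by parliamentary chairs and speeches shorter than 25 words
(strictly) are dropped, each with a logged reason; unscorable speeches
(empty after tokenisation) are excluded rather than scored zero, so
they cannot distort the outcome distribution.

# Exposure and meteorological controls

Daily mean temperature is discretised into 10 bins
(`<0, 0–3, 3–6, 6–9, 9–12, 12–18, 18–21, 21–24, 24–27, >27` °C), with
the comfort zone 12–18 °C as the omitted reference; a 9-bin variant for
milder climates merges everything above 24 °C. The bin labels share
endpoints, so a boundary convention is mandatory: bins are uniformly
lower-closed/upper-open, `[lower, upper)`, hence 27.0 °C falls in
`>27`. Results for observations exactly on a boundary depend on this
convention.

Controls are precipitation (pass-through, untransformed), wind speed
$\sqrt{u^2+v^2}$ from the two wind components, and relative humidity
computed from air and dew-point temperature via the Magnus-type
saturation vapor pressure formula

$$E(T) = 6.11 \times 10^{\,7.5\,T/(237.7+T)} \text{ hPa},\qquad
  \mathrm{RH} = 100\,E(T_{dew})/E(T_{air}).$$

Inputs must arrive in °C and m/s; no unit conversion is attempted.
Lagged and lead exposures (bins of the days around the speech) support
displacement analyses; a missing neighbour day yields a missing value,
never a silently dropped row. Arbitrary extra covariates (a precomputed
topic label, a binary pollution flag from strict threshold exceedance)
enter as additional controls; fitting a topic model is out of scope.

# The panel model

The estimating equation regresses the outcome for speech $i$ of
politician $p$ in city $c$ on date $t$ on the bin dummies and controls,

$$Y_{ipct} = \sum_j \beta_j\,\mathrm{TEMP}^j_{ct} + X_{ct}\gamma
  + \delta_{mc} + \upsilon_d + \mu_p + \varepsilon_{ipct},$$

with politician ($\mu_p$), month-by-city ($\delta_{mc}$) and
day-of-week ($\upsilon_d$) fixed effects. Each $\beta_j$ is the effect
of a day in bin $j$ relative to a comfort-zone day, within politician,
net of location-specific seasonality and weekday patterns.

Estimation absorbs the fixed effects by alternating-projections
demeaning: group means are subtracted per dimension, sweeping in
declared order until the largest absolute group mean falls below
`1e-10` (at most 10,000 sweeps; non-convergence is an error carrying
the residual norm). Coefficients are then OLS on the demeaned data and
equal, to numerical precision, a dense regression with an explicit
dummy per fixed-effect level — the test suite verifies this on random
panels. Collinear columns are pruned by pivoted QR and reported.
Singleton groups are retained; they demean to zero and are counted in
the fit metadata.

Inference is cluster-robust (CR1): the sandwich estimator with
within-cluster score sums and small-sample factor
$\frac{G}{G-1}\frac{N-1}{N-K}$, where $K$ counts slope columns plus
absorbed fixed-effect levels minus redundancies (mirroring the dense
regression, which makes the standard errors match it too). With every
observation its own cluster this reduces exactly to HC1. Confidence
intervals use the normal 1.96 critical value: the model is built for
samples with many clusters, where the t/normal distinction is
immaterial. The default cluster is city × calendar month of the sample
(year-month), the level at which weather-driven error correlation
plausibly lives; politician-level clustering is the alternative, the
usual choice for demographic interaction analyses. Because the original
design is ambiguous between month-of-year × city and year-month × city
for both the fixed effect and the cluster, both conventions are
exposed; the defaults are month-of-year × city fixed effects (a
seasonality control) with year-month × city clusters.

## Demographic interactions

For heterogeneity by age quartile (19–44, 45–50, 51–56, 57+ — integer
ages, with 57 and above in the top quartile), gender, or study period
(1950–1967, 1968–1985, 1986–2003, 2004–2019, closed ranges), every bin
dummy is interacted with every demographic level. Each coefficient is
then directly the marginal effect of that bin for that level, with its
clustered standard error — no delta-method combination is needed
beyond reading off the coefficient. Speaker-constant demographics
(gender) need no level main effect (the politician fixed effect absorbs
it); time-varying ones (age quartile, period) get automatic level
main-effect dummies. Empty bin-level cells are reported as missing rows
with a zero cell count, never dropped silently.

# The synthetic data generator

Because the real multi-country corpus is not redistributable, every
stage is validated on synthetic panels whose truth is known and stored.
The generator emulates:

* **Weather**: per city, daily mean temperature is a seasonal sinusoid
  (base level 9–13 °C across cities, amplitude 12 °C, peak around
  mid-July) plus an AR(1) deviation (coefficient 0.7, innovation SD
  3.2 °C) — chosen so a temperate city occupies all 10 bins over a
  multi-year panel, which the tests assert by direct tally. Dew point
  sits a folded-normal deficit below air temperature (so RH ≤ 100);
  wind components are Gaussian; precipitation is zero-inflated
  exponential.
* **Sittings**: weekdays sit with probability 0.8, weekends 0.05, so
  the day-of-week effect is estimable; speeches per sitting city-day
  are Poisson.
* **Outcome**: built additively per the estimating equation — baseline
  11.1 FK grade years, injected bin effects (default 0 on cold bins and
  −0.02, −0.03, −0.04, −0.05 on the four warmest bins, the graded
  pattern with the headline −0.05 heat magnitude), small control
  effects, Gaussian politician / month-by-city / day-of-week effects
  (SDs 1, 0.3, 0.05), and noise of total SD 2 of which a share
  `intra_cluster_rho = 0.25` is a draw shared by all speeches of the
  same city and calendar month. Every draw is stored in the truth
  record, and `reconstruct_outcome()` rebuilds the outcome from it to
  machine precision.
* **Demographics**: uniform ages 25–70 at panel start (spanning all
  four age quartiles) and a 30% female share, echoing the
  underrepresentation of women in parliaments — which is what makes
  minority-level confidence intervals visibly wider in the interaction
  tests.

All randomness flows from one integer seed through a fixed generator
(Mersenne-Twister, inversion normals), so output is bit-reproducible
across platforms. The default scale — 200 politicians, 2 cities, 10
years, ~26,000 speeches — keeps a 250-replicate recovery study in the
low minutes on one CPU; it is a deliberately reduced model of a
corpus three orders of magnitude larger, so absolute standard errors
are much larger than the real study's, while unbiasedness, coverage
and test size are scale-free properties that transfer.

Optionally, speeches get generated text at controlled complexity: a
lexicon annotated by the package's own syllable counter is arranged
into sentences hitting target words-per-sentence exactly and target
syllables-per-word to integer rounding, so re-scoring generated text
recovers the targets by construction. That closes the loop from raw
text to estimate. The generated text is lexically meaningless; it
exercises counting, not semantics — so passing round-trip tests says
nothing about segmentation quality on real multilingual transcripts.

## What the validation shows — and does not

The Monte-Carlo suite establishes, under the generator's conditions:
coefficient equality with dense OLS (50 random panels, `1e-8` relative
tolerance), unbiased recovery of the injected effects (mean estimate
within 2 Monte-Carlo SEs over 250 replicates), 95% clustered-CI
coverage inside [0.90, 0.98], and permutation of bins within
city-month driving rejection to the nominal level. A 1,000-replicate
null study (all injected effects zero, default scale) measures per-bin
type-I error at the 5% level: the suite requires every bin inside
[3%, 7%], and the measured rates run slightly above nominal
(roughly 5–6.5%), most visibly for seasonally concentrated bins. This
mild over-rejection is the expected finite-sample behaviour of
cluster-robust inference when a coefficient is identified by a small
subset of the clusters — at 2 cities a rare bin draws on a few dozen
effective month-clusters — and it shrinks with more cities or years.
Users testing rare-bin hypotheses at small cluster counts should treat
borderline p-values near 0.05 with caution. None of this validates the *identifying assumption* on real
data — that daily temperature is as-good-as-random within politician,
city-month and weekday — nor the realism of the noise law; the
generator's clustered-Gaussian errors are the simplest structure
matching the clustering assumption, not an empirical model of speech
data.

# Numerical choices and edge cases

* Demeaning tolerance `1e-10`, max 10,000 sweeps, deterministic sweep
  order (dimensions as declared).
* QR with column pivoting prunes collinear regressors; dropped names
  are reported, and rank deficiency that survives pruning is an error
  naming the columns.
* Degenerate inputs fail loudly: empty texts are "unscorable", an
  all-rows-dropped design is an error, a single cluster is an error,
  ages below 18 and years outside 1950–2019 are errors.
* The week index for trend controls is whole weeks since the earliest
  date in the run; trend powers are standardised to mean 0 / SD 1 for
  conditioning.
* Pipeline CSV output formats numbers with 15 significant digits so
  repeated runs are byte-identical.

# Known limitations

Syllabification is heuristic and English-oriented; RIX is provided as
the syllabification-robust alternative. The estimator supports one-way
clustering only (no two-way, no wild bootstrap). The binning convention
at shared endpoints is a package choice that may differ from other
implementations at exact boundary values. Paralinguistic channels of
speech complexity (pacing, intonation) are unmeasured by construction.
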