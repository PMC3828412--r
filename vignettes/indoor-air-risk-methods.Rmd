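---
title: "Modelling indoor air-toxics exposure and cancer risk with iaqrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling indoor air-toxics exposure and cancer risk with iaqrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iaqrisk)
```

## The problem

Freshly remodeled buildings emit formaldehyde and benzene from boards,
adhesives, paints and furniture, and occupants of such spaces in dense
Chinese cities spend most of their day inside them. `iaqrisk` turns a
building survey of indoor concentrations — or, when raw records are not
available, only its printed per-stratum summary statistics — into two kinds
of health-risk statements:

1. **Non-carcinogenic screening**: what fraction of buildings exceeds a
   reference concentration, and what is the hazard index of a given
   exposure?
2. **Carcinogenic assessment**: what lifetime excess cancer risk does
   time-weighted indoor personal exposure imply under published inhalation
   unit risks?

The packaged default scenario is a survey of recently remodeled Beijing
dwellings and offices with four strata (building type x compound):
formaldehyde 131±90 (median 100) µg/m³ in dwellings and 85±56 (74) in
offices; benzene 17±16 (11) in dwellings and 30±34 (16) in offices, with
stratum sizes 383/406/379/375.

## Concentration model

Emission-driven indoor concentrations are strictly positive and right-
skewed; a lognormal law is the standard generative model and fits these
data well. Because the survey is available only as arithmetic mean $m$ and
SD $s$ per stratum, the default estimator is the **method of moments**:

$$\sigma^2 = \log\!\left(1 + (s/m)^2\right), \qquad
  \mu = \log m - \sigma^2/2,$$

which reproduces $m$ and $s$ exactly (a property the tests assert to
machine precision; `log1p` keeps the degenerate $s \to 0$ limit stable).
Maximum likelihood (`fit_lognormal_mle()`, the closed-form log-moment
estimator) is offered when raw records exist, but MoM stays the default so
that every downstream number is reproducible from the printed summaries
alone.

**Adequacy check.** When a reported median accompanies the moments, the
fitted geometric mean $e^\mu$ is compared with it; a deviation beyond 15%
raises a warning. Three of the four default strata pass; office benzene
does not ($e^\mu \approx 19.9$ vs a reported 16, a 24% gap), which signals
that this stratum is more skewed than a single lognormal — the warning is
deliberate and visible on every default run, not an error, because the
moments (which drive exposure and risk means) are matched regardless.

Guideline exceedance is the analytic upper tail
$P(X > t) = 1 - \Phi((\log t - \mu)/\sigma)$, with an empirical strict-
inequality counterpart for raw records (ties count as compliant). Whether
the original survey computed its percentages on raw data or fitted tails is
unknowable from the summaries; the two agree to a couple of percentage
points at these sample sizes, which is why the package reports both.

## Guideline and toxicity registries

Reference values ship as plain CSV (editable, versioned with the package):
GB/T 18883-2002 indoor standards (0.10 / 0.11 mg/m³, converted to µg/m³ at
load — the internal unit everywhere), OEHHA acute (55 / 1,300 µg/m³) and
chronic (9 / 60 µg/m³) RELs, and the IRIS chronic benzene RfC (30 µg/m³;
IRIS publishes no chronic formaldehyde RfC, and asking for one is a named
error). IURs: IRIS 1.3×10⁻⁵ (formaldehyde) and 7.8×10⁻⁶ (benzene, with the
lower 2.2×10⁻⁶ kept as an explicit alternate — the upper value is the
default to bound the risk from above), OEHHA 6.0×10⁻⁶ and 2.9×10⁻⁵, all
stored as lifetime risk per µg/m³. The per-million scaling happens exactly
once, in `cancer_risk()`.

## Time-use model and synthetic data

Per-person indoor exposure weights home and office concentrations by the
fractions of **total** time spent there:
$E_i = C_{i,\mathrm{home}} f_{i,\mathrm{home}} +
       C_{i,\mathrm{office}} f_{i,\mathrm{office}}$.
The fractions include all other microenvironments in their denominator, so
$f_\mathrm{home} + f_\mathrm{office} < 1$ and $E$ is deliberately the
indoor share of total exposure — never renormalized.

The national time-use tabulations behind the original survey are not
printed anywhere recoverable, so the default fractions are calibrated from
the survey's own arithmetic: mean home exposure / mean home concentration
gives $\bar f_\mathrm{home} = 86/131 \approx 0.657$ and
$\bar f_\mathrm{office} = 15/85 \approx 0.176$ (the benzene strata give
0.647/0.167, reassuringly close). Defaults are truncated normals with SDs
0.05 and 0.04, truncated to [0, 1] and rejection-sampled to a joint cap of
0.95. The SDs are the one genuinely free choice: they are set small so that
exposure spread stays concentration-dominated, consistent with the
reported exposure SDs being slightly *below* the point-mass-fraction value
(52 vs 0.657×90 ≈ 59 for home formaldehyde). Both SDs, the cap and the
means are plain `time_use_model()` arguments; an SD of 0 gives point-mass
fractions.

Home and office concentrations for one simulated person are drawn
**independently** from the fitted stratum lognormals; nothing in the survey
reports a within-person correlation. The generator (`scenario_config()` +
`generate_building_records()` + `sample_time_use()`) emulates stratum
moments, lognormal shape and time-budget structure — it does not emulate
seasonality, air-exchange-rate dynamics, within-building room correlation
or the occupant self-selection of the original survey, so passing tests
demonstrate internal consistency of the method, not field accuracy of any
particular building stock.

## Risk, disaggregation, decay

Per-draw risk is $E \times \mathrm{IUR} \times 10^6$ excess cases per
million (70-year lifetime basis; no exposure-duration adjustment is
applied, matching the "live and work there over a lifetime" scenario).
Summaries report mean, SD, median and the 95th **percentile** of the
simulated distribution (a Monte Carlo output convention; it is not a
confidence bound). Quantiles use linear interpolation between order
statistics (type 7) — stated because medians are compared at 10–15%
tolerances. Cumulative risk splits into home and office shares as ratios of
means, which always sum to one.

Because risk is linear in concentration, the post-remodeling decay
scenario (long-term retention of ~35% for formaldehyde, ~25% for benzene)
multiplies draws or summary statistics by the retained fraction rather than
re-simulating; the tests assert that the two routes commute to machine
precision.

## Numerical and design choices

- **Problem sizes.** The package default is 5,000 Monte Carlo trials, the
  survey's own setting. The shipped acceptance script and the end-to-end
  tests use 50,000 persons per compound, which puts the Monte Carlo error
  of a median well below the 15% comparison band while still running in
  seconds; convergence-style property tests use up to 10⁵ draws.
- **Seeds.** A root seed is mandatory everywhere randomness appears (no
  wall-clock default); per-stage seeds are split deterministically from it,
  so a config re-runs to byte-identical CSV/JSON outputs. The output
  manifest stores the seed and a content hash of the config.
- **Degenerate inputs.** Zero or negative concentrations are hard errors
  (physically impossible and log-undefined); no detection-limit imputation
  is attempted because the survey reports none. Empty draws, all-zero
  total risk, infeasible time budgets (mean fractions above the cap) and
  missing strata abort with named errors, the last with the failing
  pipeline stage in the message.
- **Reported precision.** Exceedance percentages print to one decimal,
  risk statistics as integers with thousands separators, matching the
  field's reporting convention.

## Known limitations

- A single lognormal per stratum understates the upper tail where the
  adequacy warning fires (office benzene); a mixture or censored model is
  out of scope.
- Only home and office microenvironments are modelled; outdoor and
  transport exposure, inhalation-rate or body-weight dosimetry, and
  compound synergies are not.
- The abstract-level medians of the original survey differ slightly from
  its own summary table (1,150 vs 1,160 per million for formaldehyde); the
  package's comparisons use bands wide enough to cover both readings.
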