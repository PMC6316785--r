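---
title: "Comparing butterfly survey methods: models, statistics and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing butterfly survey methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lepisurv)
```

## The problem

Urban biodiversity is routinely surveyed by three very different kinds of
citizen-science effort: structured transect counts by trained volunteers
(Pollard walks), passive Malaise traps sorted by experts, and opportunistic
presence-only records submitted to platforms such as iNaturalist. The three
produce data of different granularity — per-site abundances for the structured
methods, a stream of individual observations for the incidental one — so naive
comparisons of species richness conflate method effectiveness with sampling
design. `lepisurv` implements the statistics that make the comparison
meaningful, the record-filtering plumbing the incidental stream requires, and a
generative simulator that makes every stage testable against known truth.

## Data model

The package's containers are tibbles with light classes:

* a **survey table**: one row per (site, method, species) with a pooled
  non-negative integer count. Duplicate keys on input are pooled additively and
  pooling is order-independent, so a table is a well-defined function of its
  rows.
* an **occurrence table**: one Darwin Core style record per row — reported
  name, point coordinate, event date, optional coordinate uncertainty in
  metres, quality flag. Missing uncertainty stays missing; it is never coerced
  to zero, because zero asserts perfect precision.
* an **incidence summary**: one row per species with the number of sites (out
  of `n_sites`) where each structured method recorded it, and the number of
  incidental observations. Site incidence deliberately discards abundance: a
  species at 2 sites with counts {1, 7} has incidence 2. The packaged
  `load_incidence_summary()` table (30 species, 16 sites) carries exactly this
  granularity.

## Filtering incidental records

`filter_records()` applies five predicates in a fixed order — quality flag,
family membership, inclusive date window, closed bounding box, coordinate
uncertainty — and logs records in/out and removed ids per stage. Because every
stage is a record-wise predicate, the final set is invariant to stage order and
the whole filter is idempotent; the fixed order only structures the audit
trail. Conventions worth stating:

* **Date window endpoints are inclusive** and the **bounding box is closed**
  (a record on the boundary is kept). "Between" two dates is ambiguous;
  inclusivity is the least surprising reading and is applied consistently.
* **Records with missing uncertainty are kept**, with a warning. The
  uncertainty filter exists to remove continental-scale blunders (the default
  threshold is 2,500,000 m); silently discarding records that merely omit the
  field would bias against older uploads. `keep_missing_uncertainty = FALSE`
  inverts the policy.
* **Taxonomy reconciliation** (`reconcile_taxonomy()`) maps platform synonyms
  to accepted binomials before filtering; accepted names must be fixed points
  of the map, so chained or cyclic maps are rejected outright rather than
  resolved. The reported name is always preserved alongside.

## Richness and diversity statistics

Shannon's *H* is computed in natural-log units over species with positive
counts; `per_site_stats()` reports a site with zero individuals as richness 0
with *H* missing, since evenness is undefined without individuals. *H* of a
single species is 0, and the uniform composition maximises *H* for a given
support — both properties are enforced by tests (the latter by enumeration
over small integer compositions).

Mean per-site richness is recoverable from incidence alone:
sum of site-incidences / number of sites. The identity holds exactly because
each species contributes one unit of richness at exactly as many sites as its
incidence, and it is property-tested against per-site statistics on simulated
worlds. This is what lets the packaged incidence table yield 11.31 (walks) and
5.94 (traps) species per site without the unpublished per-site records.

Between-method comparisons use the **paired** *t*-test on site-wise
differences. Survey write-ups sometimes describe this design as a paired test
"assuming equal variance"; that phrase is internally inconsistent (the paired
test is a one-sample test on differences and carries no equal-variance
assumption), so the package implements the standard paired test and documents
the choice here. All p-values are two-sided. Zero-variance differences raise a
classed degenerate-input error instead of returning NaN.

## Bootstrapping pooled richness across designs

Sixteen fixed-effort site surveys and a stream of 104 one-off observations
cannot be compared with a mean-per-unit statistic. The package instead
bootstraps **pooled richness** — the size of the species union across the
study — with the resampling unit matched to each design: whole sites (with
replacement, n = number of sites) for the structured methods, individual
observations (n = number of records) for the incidental stream. The
per-pseudoreplicate statistic is pooled richness rather than mean per-unit
richness, because pooled richness is the quantity with observed values at the
whole-area scale (27/18/22 in the packaged study).

Two properties follow structurally and are tested: pseudoreplicates conserve
the observed species pool, and the bootstrap mean never exceeds observed
pooled richness (a union over a resample cannot beat the full union; equality
only with a single unit). Distributions are compared with a pooled-variance
two-sample *t*-test (Welch behind `var_equal = FALSE`); a one-sample mode
against a fixed observed value is also provided, with
distribution-vs-distribution the default. Every result carries an explicit
note that these p-values are **anti-conservative** — 1000 pseudoreplicates are
not 1000 independent samples — mirroring a procedure common in the field
rather than endorsing its calibration.

Reproducibility contract: all bootstrap draws use R's Mersenne-Twister,
seeded per call; the seed is recorded in the result and the caller's RNG
state is restored afterwards. Identical (inputs, `n_boot`, seed) give
identical distributions across platforms.

## The synthetic-data generator

`simulate_world()` draws from a standard occupancy–detection structure:

1. **Occupancy**: site *s* holds species *i* with probability ψ<sub>i</sub>
   (Bernoulli, independent across sites).
2. **Abundance**: occupied sites receive a zero-truncated Poisson(λ<sub>i</sub>)
   abundance. Truncation is deliberate: "occupied" means at least one
   individual is present, and it guarantees that perfect detection recovers
   the full community — a degenerate case the tests rely on.
3. **Detection**: each of *K* survey events per site detects each present
   species with the method's per-event probability p<sub>im</sub>; a detection
   contributes at least one counted individual, with further individuals seen
   at the same rate, and counts pool across events. The per-site detection
   frequency is therefore ψ<sub>i</sub>(1 − (1 − p<sub>im</sub>)<sup>K</sup>),
   which the parameter-recovery tests verify over 200 simulated worlds within
   a 4-standard-error binomial band.
4. **Incidental records**: n multinomial draws with probability proportional
   to (reporting weight × total true abundance). Unequal weights express a
   "photogenic species" reporting bias; the default is neutral weights.
   Each record gets a uniform point in the study box, a uniform date in the
   window, log-normal coordinate uncertainty with an optional outlier mass at
   2,600,000 m, and — at the synonym noise rate — a platform-synonym name.

Randomness flows from a single seed through eight named substreams
(occupancy, abundance, per-method detection, per-method counts, incidental,
corruption), so stages are independently reproducible. Detection uniforms are
consumed in fixed blocks of 64 per present (site, species) cell, site-major.
This is a common-random-numbers device: matched-seed worlds stay coupled
across ladders of detection probability, survey effort (up to the 64-event
cap) and site count, which turns the monotonicity of observed richness in
those parameters into an exact, per-seed testable property instead of a
statistical one.

Default parameters describe the study design the package ships data for: 30
species, 16 sites, 8 survey events per site (biweekly trap services over four
months), a logistic common-to-rare occupancy gradient (≈0.92 down to ≈0.08),
log-spaced mean abundances (8 down to 0.5), per-event detection 0.4 for walks
and 0.15 for traps (walks detect butterflies far more reliably than passive
flight-interception traps), and 104 incidental records in a Los Angeles Basin
scale bounding box over 15 March – 15 July 2015.

What the generator does **not** emulate: spatial autocorrelation between
sites, within-season phenology (detection is date-stationary), observer
heterogeneity within a method, and abundance overdispersion beyond Poisson.
Passing tests on simulated worlds therefore demonstrate correctness of the
statistical machinery under the stated model, not robustness of the field
protocols to these real-data features.

## The calibrated benchmark world

`simulate_benchmark_world()` is the integration fixture: a deterministic world
whose pipeline output reproduces the packaged incidence table exactly — not
just its margins. Site identities, abundances, points and dates come from the
seed; the incidence structure is fixed by construction. It builds in three
realistic defects: a 105th incidental record with a 2,600,000 m uncertainty
(so the staged filter removes exactly one record, at the uncertainty stage),
and two platform-synonym names (*Paratrytone melane* for *Poanes melane*,
*Zerynthia rumina* for *Papilio rumiko*) that reconciliation must repair
before the species totals come out right. End-to-end tests assert the
105 → 104 filter structure and the 27/18/22 source richness after the full
chain.

## Numerical and design notes

* Counts are integers; fractional counts are rejected at validation with the
  offending row named. Dates are strict ISO 8601.
* The butterfly family set defaults to the six Papilionoidea families
  (Hesperiidae, Papilionidae, Pieridae, Nymphalidae, Lycaenidae, Riodinidae).
* Classed conditions separate configuration errors, data validation errors
  and degenerate statistical inputs, so pipelines can react differently to
  "your config is wrong" and "your data are pathological".
* Problem sizes in the test suite are chosen to make Monte-Carlo bands tight
  at desk scale: 200 replicate worlds for parameter recovery and
  goodness-of-fit, 20 worlds × 1000 pseudoreplicates for the
  ordering-recovery check, 4000 pseudoreplicates against the exact
  two-unit enumeration oracles.
* Per-site Shannon *H* and the paired *t* statistics of the original study are
  functions of per-site abundances that were never published; the package
  computes them for any user- or simulator-supplied survey table, and its
  tests validate them against independent oracles (direct formula; vegan's
  `diversity()`), but no attempt is made to reproduce those published values
  from the incidence table, which cannot determine them.

## Known limitations

No richness extrapolation (Chao, ACE, rarefaction) is provided — the
comparison framework here is about observed pooled richness under matched
resampling. The bootstrap *t* p-values inherit the anti-conservatism noted
above and should be read as effect-ordering evidence, not calibrated error
rates. Incidental data support no diversity index, since presence-only
streams carry no abundance structure per sampling unit.
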