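---
title: "Methods: context matching and the scattar layout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: context matching and the scattar layout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scattar)
```

## The problem

Evidence on domestic health financing in low- and middle-income
countries is broad, heterogeneous and hard for policy makers to
navigate. This package implements the engine behind a visual
evidence-navigation tool: a database of studies, each scored
qualitatively for the impact of seven financing mechanisms (equity
funds/discount cards, tax funding, private health insurance, user-fee
implementation, user-fee removal, community-based health insurance,
national health insurance) on five health-system goals (promote
equity, reduce poverty, improve quality, generate revenue, increase
use); a *context-matching* metric scoring how closely the countries in
each study resemble the user's country; and a *scattar* layout — a
hybrid scatter/radar display that places every study as one dot per
addressed mechanism inside a seven-sector ring.

## The evidence model

Each study carries a six-state qualitative impact score per
(mechanism, goal) pair: an ordered five-point scale from
`evidence_against` to `evidence_for`, plus an explicit
`not_considered` state. The explicit state matters: a mechanism a
study addresses without assessing a given goal is an *evidence gap*,
shown as a grey dot, and is distinct from a study that does not
address the mechanism at all (which contributes no dot to that sector
and is excluded from that mechanism's tallies). At construction time
every addressed mechanism is normalised to carry all five goal
scores, with unstated goals stored as `not_considered`.

Studies are either literature `review`s or primary `evaluation`s.
Reviews are differentiated to reduce the risk of double-counting
evidence and may legitimately lack a country list (a warning, not an
error, in `validate_evidence()`); evaluations must name at least one
country, identified throughout by ISO 3166-1 alpha-3 code.

A study that addresses several mechanisms is stored once and
contributes one dot per addressed mechanism. This is the only reading
consistent with a database whose per-mechanism study counts
(2 + 2 + 4 + 21 + 10 + 24 + 25 = 88) exceed its number of distinct
studies (78): some studies must appear in more than one sector.

## Context matching

Country context is summarised by eleven indicators: health
expenditure per capita, maternal mortality ratio, under-5 mortality,
HIV prevalence, malaria incidence, education index, GDP, life
expectancy, urban population share, the share living on under
$1.25/day, and population. Population enters as its base-10
logarithm — a country of 10 million and one of 100 million differ as
much, for policy purposes, as one of 100 million and one of a
billion — and the log is taken at load time, before bounds are
computed.

Each raw indicator value $I_j$ is transformed to
$T(I_j) = (I_j - \min_j) / (\max_j - \min_j)$, with the minima and
maxima taken over the countries in the loaded table, so every country
becomes a point $\{T(I)_j\}_{j=1}^{11}$ in the unit hypercube. The
match between countries $Y$ and $Z$ is the Euclidean distance

$$d_{YZ} = \sqrt{\textstyle\sum_{j=1}^{11}\bigl(T(I)_j^Y - T(I)_j^Z\bigr)^2}
  \in [0, \sqrt{11}].$$

Linear min-max scaling and the Euclidean form are design choices —
the simplest forms consistent with a transform "between 0 and 1" and
an "11-dimensional distance between two points" — and both are
isolated behind `transform_indicator()` and `context_distance()` so
either could be swapped without touching anything else. The measure
is a visual sorting aid, not a validated statistic: exact ranks are
not meant to carry weight, and `rank_matches()` exists for
exploration only.

Numerical edge cases, decided once:

* **Out-of-range values** clamp to $[0, 1]$ rather than extrapolate,
  keeping the codomain contract when a user's country lies outside the
  reference bounds.
* **Degenerate indicators** ($\min = \max$) map every country to 0.5,
  so an uninformative dimension contributes zero to every distance.
* **Missing values**: the distance is computed over the $k \le 11$
  dimensions present in both profiles and rescaled by
  $\sqrt{11/k}$, keeping partial- and full-coverage distances on one
  $[0, \sqrt{11}]$ scale. A pair sharing no dimension has no defined
  distance and errors.
* **No direction inversion** (higher-is-better vs worse) is applied:
  the distance is symmetric in the sign of differences, so none is
  needed.
* A **study's** distance is the *minimum* over its countries — the
  best-matching study country decides relevance — so adding a country
  to a study can only move its dot inward. Bounds are recomputed from
  whatever table is loaded rather than frozen to any reference year;
  a consequence, tested as an invariant, is that adding a country
  strictly inside the existing bounds changes no existing distance.

## The scattar layout

`layout_scattar()` is a pure geometry engine, renderer-agnostic and
free of randomness. Its rules:

* Seven equal sectors in a fixed legend order (equity funds, tax,
  private insurance, fee implementation, fee removal, CBHI, NHI),
  clockwise from 12 o'clock.
* One dot per (study, mechanism) pair, so every plot of the same
  database has the same number of dots regardless of country or goal.
* **Radius** encodes context mismatch: `radius_norm = d / sqrt(11)`,
  normalised by the theoretical maximum rather than the observed one
  so layouts stay comparable across databases. Dots at radius 0 are
  exactly the reviews (squares on the inner ring, their country lists
  ignored) and the evaluations that studied the chosen country
  itself.
* **Colour** encodes the study's score for the chosen goal: green
  (`evidence_for`) through light green, orange (`no_evidence_of_impact`
  — definite evidence of *no* impact), light red, red
  (`evidence_against`), and grey for `not_considered`. A five-step
  palette distinguishing "some" from full evidence is assumed.
* Positions therefore depend only on the country, colours only on the
  goal — switching goal recolours without moving anything, which is
  what makes the five thumbnail plots comparable at a glance.
* **Angles** are a convention of this implementation (no published
  rule exists): within each sector, dots are sorted by
  `(radius_norm, study_id)` and spread evenly across the sector minus
  a small gap. This is deterministic — identical inputs give
  byte-identical layouts and SVG — and co-located dots receive
  successive angular slots instead of overplotting, so every study
  stays individually addressable downstream via its `data-study-id`
  attribute.

SVG output is produced by deterministic string templating with fixed
two-decimal coordinate formatting; the test suite parses the emitted
documents and reconciles every marker's tag, fill and identity
against the layout.

## The synthetic generators

No real evidence database or indicator table ships with the package;
seeded generators stand in for both. `generate_indicator_table()`
draws values uniformly within hard-coded plausible ranges (life
expectancy 40–80 years, under-5 mortality 5–200 per 1,000, GDP and
population log-uniform over $5\times10^8$–$5\times10^{12}$ and
$10^5$–$10^9$, and so on — collected in one internal table). The
ranges need only be ordinally sensible: no statistical claim depends
on them. `generate_evidence_db()` produces exactly the configured
number of studies per mechanism, samples study countries from the
supplied table, gates each (mechanism, goal) pair through a coverage
probability (default 0.5, giving the visibly large grey-dot share
characteristic of this literature) and draws scores from a mildly
positive-skewed weight vector. Reviews (default 15% of studies) get
empty country lists, consistent with their inner-ring placement.

`paper_shaped_fixture()` fixes the published shape: 30 countries,
per-mechanism counts of 2/2/4/21/10/24/25, and ten two-mechanism
merges so that 78 distinct studies carry the 88 assessment pairs.

What the generators do *not* emulate: real-world correlations between
indicators (synthetic dimensions are independent), the actual
bibliography's content, and any association between a study's
mechanism and its scores. Passing tests therefore demonstrate the
correctness of the mechanics — transforms, distances, layout rules,
serialisation — on realistic shapes, not any substantive conclusion
about health financing.

## Problem sizes and tolerances

The test suite runs on the 78-study/30-country fixture for layout and
integration properties, 1,000 random vector pairs for the metric
oracle (agreement within $10^{-12}$; the implementation and the
brute-force loop differ only by floating-point summation order), and
200 random triples for the triangle inequality with a $10^{-12}$
slack for rounding. Exact (`identical`) assertions are used wherever
the quantity is discrete: dot counts, colours, shapes, sort orders,
byte-level determinism of files and SVG.

## Known limitations

* The context measure is unvalidated by construction; it orders
  evidence visually and nothing more.
* `query_studies(goal=)` filters to studies that assessed the goal,
  which is the useful reading but means grey-dot studies drop out of
  goal-filtered tables while remaining on every plot.
* Reviews always sit at radius 0 even when they list countries; their
  geographic scope is not reflected in the display.
* The CSV dialect is lossy for abstracts (the schema has no abstract
  column); JSON is the canonical form.
* Angular position carries no information; only sector, radius,
  colour and shape are meaningful.
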