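---
title: "Methods: building a pregnancy register from linked EHR sources"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building a pregnancy register from linked EHR sources}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pregreg)
```

## The problem

Linked electronic health records describe the same pregnancy from several
vantage points: a GP may code the delivery or the miscarriage weeks after
the event, the hospital admission carries an ICD-10 diagnosis, the
maternity record carries a gestational age in whole weeks, and a
procedure table may hold the caesarean or the surgical management of a
loss. A pregnancy *register* collapses this redundancy into one row per
pregnancy, with an outcome, an end date and an estimated date of
conception (EDC). The hard parts are (a) deciding when two records
describe the same pregnancy versus two pregnancies, (b) resolving
contradictory coding, and (c) dating a pregnancy when nothing records its
start. This vignette documents how `pregreg` does each, which knobs
exist, and which choices were genuinely open.

## Data model and units

All dates are calendar dates; every duration is an exact whole-day
difference (`date B - date A`). Gestational age from hospital maternity
records arrives in completed weeks and is converted as weeks × 7. Four
source datasets are modelled — `GP` (SNOMED CT), `HES_MAT` (ICD-10, plus
the gestation field), `HES_APC` (ICD-10), `HES_OPCS` (OPCS-4) — each with
its own coverage window; in the shipped defaults GP data end on
2022-02-11 while hospital data run to the study end, 2022-09-30, which is
what makes the `--cutoff` sensitivity analysis in the CLI meaningful.
Events dated before the study start are kept as *anchors*: they
constrain gaps and dating but can never terminate a register episode.

## Rule constants

All thresholds live in one configurable record, `register_params()`:

| parameter | default | meaning |
|---|---|---|
| `delivery_gap_min` | 175 d | minimum days since the previous outcome record for a new delivery episode |
| `loss_gap_min` | 56 d | same for a new loss episode |
| `livebirth_gestation_min` | 154 d | viability floor; HES_MAT livebirths recorded below it are dropped |
| `stillbirth_gestation_min` | 168 d | stillbirth floor; below it the outcome is reclassified a miscarriage |
| `loss_gestation_min/max` | 35 / 167 d | legal gestation range for losses |
| `inter_episode_gap` | 21 d | minimum days between one pregnancy's end and the next conception |
| `fullterm_imputed_gestation` | 275 d | imputed gestation, undated full-term delivery |
| `preterm_imputed_gestation` | 259 d | undated pre-term delivery (qualifying indicator code) |
| `multiple_imputed_gestation` | 259 d | undated multiple-birth delivery |
| `loss_imputed_gestation` | 83 d | undated non-ectopic loss |
| `ectopic_imputed_gestation` | 63 d | undated ectopic pregnancy |
| `edd_offset` | 280 d | EDD = LMP + 280, so EDC = EDD − 280 |
| `postnatal_window` | 175 d | postnatal GP linkage window after delivery |
| `ppv_windows` | 0, 2, 7 d | cross-source linkage windows |

The constructor asserts the identities the rule set relies on:
35 + 21 = 56 and 154 + 21 = 175 (a gestation floor plus the inter-episode
minimum equals the corresponding episode gap), and 167 < 168 (the loss
ceiling sits directly under the stillbirth floor).

## Boundary conventions

Three boundaries are stated in prose ambiguously enough that a convention
had to be fixed; each was resolved in favour of the arithmetically
coherent reading and is pinned by tests:

* a later **delivery** starts a new episode iff the gap is **≥ 175** days
  ("at least"); a later **loss** iff the gap is **≥ 56** days (so 55 days
  merges and 56 splits, coherent with 56 = 35 + 21);
* a livebirth is retained iff recorded gestation is **≥ 154** days (the
  drop rule "less than 154" wins over "more than 154", coherent with
  175 = 154 + 21);
* linkage windows ±k are closed on both sides; the postnatal window is
  half-open `(end, end + 175]` so the delivery record itself never counts
  as postnatal follow-up.

## The gap clock: chaining from the last retained record

When a record is absorbed into an open episode, does the next gap measure
from the episode's end or from that absorbed record? We chain from the
**most recent retained record** of any kind. Three miscarriage records at
days 0, 40 and 80 therefore form one episode (each is within 56 days of
its predecessor) even though the outer pair are 80 days apart. Besides
matching the natural reading of "within 56 days of a previous record",
chaining has a structural benefit: when a higher-priority loss absorbed
into an episode later re-represents it (below), the episode's end can
only move to a date the clock has already passed, so the inter-episode
gap invariants cannot be violated retroactively.

## Phases and the maternity spine

Patients are routed to exactly one phase: any HES Maternity outcome
record → phase 1; else any delivery record → phase 2; else phase 3
(losses only). In phase 1 the maternity records are segmented first (gap
rules, viability floors, gestation-consistency) and become fixed *spine*
episodes. Records from other sources are then merged in date order; one
may open its own episode only if it respects the gap from the last
retained record **and** does not conflict with the next spine episode —
either by sitting closer to it than that episode's gap threshold, or by
implying a conception (from the spine's recorded gestation) less than 21
days after itself. Conflicting records are absorbed as corroborating
evidence. This realises "spine priority" concretely: a record is absorbed
iff it cannot legally start an episode given the spine.

Gestation-consistency: a maternity record whose recorded gestation
implies conception before the previous spine episode's end + 21 days is
rejected outright (logged `rejected_gestation_conflict`) — it is treated
as erroneous and does not advance the gap clock, unlike absorbed records.

Within an episode terminated by a loss, all loss records absorbed at or
after the terminating date compete in the loss hierarchy; the
highest-priority one re-represents the episode (its date, source and
subtype), and the displaced codes are logged as dropped. Records absorbed
from the *future* side of a spine episode (spine-conflict absorptions)
do not compete — the spine's priority over other sources would otherwise
be undone by a GP code predating it.

## Conception dating

The hierarchy is strict: recorded gestation (HES preferred — in the
shipped schema gestation only exists on HES_MAT records, so the
`gp_gestation` method is reserved but can never fire), then EDD − 280,
then LMP, then scans, then imputation. Two subtleties:

* **Legality, not clamping.** A rung whose implied gestation falls
  outside the outcome's legal range, or whose conception sits closer than
  21 days to the prior pregnancy event, is skipped entirely and the next
  rung consulted. An LMP 168 days before a miscarriage is simply not
  believed (losses max out at 167 days); the episode is imputed at 83
  days instead.
* **Attribution.** EDD/LMP/scan records belong to an episode if the
  conception they imply (for EDD) or their own date (LMP, scans) lies
  between the prior event + 21 days and the episode end. Among several
  EDDs the earliest legal one wins; among LMPs the latest (the freshest
  re-recording before conception); scans prefer the earliest date with
  hospital records beating GP on ties.

Imputation picks the outcome's constant (275/259/83/63), selecting 259
for deliveries that are multiples or carry a pre-term indicator code from
the maternity dataset (the O60.1/O60.3 stubs in the bundled map; an
undated delivery with no indicator is treated as full-term). If the
window since the prior event is shorter than the constant + 21, gestation
becomes window − 21 (`imputed_window_capped`), floored at the outcome's
minimum. For losses the 35-day floor is absolute and may override the
21-day spacing; such episodes carry `floor_exception = TRUE`. The episode
builder guarantees the window is at least the class gap, so the floor can
bind only at equality — a non-positive window is an assertion failure
signalling a builder bug, not a data condition.

An undated **stillbirth** has no published constant of its own; it is
imputed like other deliveries (275, or 259 with an indicator) and floored
at 168 days.

## Sequencing of the unspecified-loss rule

Unspecified-loss codes both (a) rank sixth in the loss hierarchy and
(b) end up reported as terminations. The order of those two operations is
not uniquely determined, so both are implemented behind
`register_params(unspecified_relabel=)`: the default `"after_priority"`
lets unspecified losses compete at rank 6 and relabels only survivors;
`"before_priority"` relabels first, so they compete at termination's
rank 2. The default keeps the hierarchy's printed ranks meaningful.

## The synthetic cohort generator

`generate_truth()` draws patients (age ~ Normal(30, 5.7) truncated to
15–50; ethnicity, deprivation quintile and region in proportions matching
a large English primary-care pregnancy cohort) and per-patient episode
counts (95.6% one, 4.2% two, the rest three or four). Episode outcomes
are 83.4% deliveries (99.5% livebirths, 1.5% of them multiples, 0.5%
stillbirths) and 16.6% losses with a subtype mix echoing the published
register composition. Gestations are drawn uniformly within each
outcome's legal range — the rules bound the ranges but no distribution is
published, and uniform sampling exercises the boundaries hardest.
Spacings respect the builder's gaps by construction, so a noise-free
rendering must be recovered exactly (and the test suite requires it, with
100% PPV at ±2 days).

`render_source_events()` records each episode in each source with
independent per-class probabilities and bounded integer date lags, writes
GESTAT as ⌊gestation/7⌋ on maternity delivery records, and adds GP dating
records (EDD = conception + 280, LMP = conception, scans at exact
completed weeks), postnatal records, same-day duplicates, injected
conflicting loss codes and unspecified-loss coding. Independence across
sources is the simplest model producing the partial-overlap structure of
real linked data, and it makes the PPV calibration exact: for episodes
derived from a given source, the probability of corroboration is
1 − (1 − p)³, which the suite verifies at p = 0.7 on 10,000
single-episode patients within Monte-Carlo error.

What the generator does **not** emulate: correlated recording across
sources (a hospitalised loss is in reality more likely to reach the GP
record too), realistic code-frequency distributions, transfers between
practices, and mother–baby linkage. Passing tests on this generator
therefore demonstrate algorithmic correctness under controlled
conditions, not performance on real data.

## Verification strategy and problem sizes

* **Brute-force oracle.** An independent enumerator checks all 2^n
  terminator/absorbed labelings of a patient's records against the rules
  stated declaratively and demands a unique legal labeling. The suite
  compares the builder against it exhaustively over all 2- and 3-event
  category layouts at boundary-straddling gap combinations, and over
  seeded random 4–6-event layouts on a 7-day grid spanning 400 days with
  all four sources mixed in. These sizes keep the check minutes-cheap
  while covering every rule boundary; the full cross-product of dates and
  categories grows combinatorially without adding new boundary cases.
* **Recovery and calibration cohorts** use 1,000 and 10,000 patients
  respectively; property checks (PPV monotonicity over window widths) run
  over 20 seeds at 60 patients each.
* **Standardisation** is checked against a hand example
  (0.25·10 + 0.75·30 = 25 per 1000), the equal-rates identity, and random
  weighted-sum recomputations. Confidence intervals use the gamma
  (Fay–Feuer) approximation for standardised rates and Wilson intervals
  for proportions; the method choice is a convention, stated here because
  rate CIs are often reported without one.

## Known limitations

The bundled code map is a stub (a handful of codes per category), so
classification coverage on real data is out of scope. Cross-source
same-day ties are broken maternity-first then by canonical sort — real
registers may prefer other tie-breaks. Multiple births stay one row; the
register does not split per baby. The external comparison values shipped
in `external_reference_rates.csv` (ONS/CPRD) are footnote context only
and are never recomputed. The synthetic standard population table is
labelled synthetic: it has the shape, not the values, of a national
mid-year estimate.
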