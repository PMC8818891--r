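---
title: "Cost-utility analysis of rapid genome sequencing in the PICU"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-utility analysis of rapid genome sequencing in the PICU}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwgscea)
```

## The problem

When a critically ill child receives a molecular diagnosis from rapid
whole genome sequencing (rWGS), clinical management often changes: a
planned biopsy is cancelled, an escalation of care is avoided, a
prophylactic therapy is started earlier. Valuing those changes is hard
because matched historical controls rarely exist for ultra-rare disease.
The approach implemented here replaces controls with *counterfactual
trajectories* — the care each patient would plausibly have received
without the diagnosis — validated by an independent expert panel, and then
prices and scores those trajectories.

## Delphi consensus scoring

Each counterfactual is phrased as a statement and scored by panelists on
the five-point Likert scale (strongly disagree = 1, disagree = 2, neutral
= 3, agree = 4, strongly agree = 5; "unable to comment" is excluded from
both numerator and denominator of the mean). A question reaches consensus
when the panel mean is at least 4 or at most 2 — both thresholds
inclusive, compared at full precision with an absolute tolerance of 1e-9
against binary-float artifacts. Questions missing consensus are returned
once, with the prior round's mean shown to panelists; the stop criterion
is hard-coded at two rounds, after which unresolved questions are
discarded and contribute nothing downstream. A panelist who answered round
one but not round two is simply absent from round two's mean. Panel size
is data, not a constant — the engine accepts any panel of at least one and
records the size per question; the reference cohort uses panels of ten
intensivists and, for one hematology question, five hematologists. Round
means are stored at full precision and formatted to two decimals only for
display.

## The cost ledger

Every monetary effect is one line item with an unsigned amount and an
explicit direction (`avoided` or `incurred`); carrying sign in a separate
field prevents silent double negation. A patient's net effect is
`savings − incurred`, and the cohort total is the exact sum of patient
nets. Items linked to a Delphi question count only when that question
reached consensus; excluded items are logged, and re-including them
restores the original totals exactly.

Two standard valuation helpers are provided. An avoided hospital day is
priced at the mean charge over the patient's last three procedure-free
inpatient days (`estimate_daily_cost()` insists on exactly three values —
the rule is specific to three days); professional fees are a published
ratio times accrued hospital charges, and that ratio is a required
configuration input rather than a constant, because the applicable
published value depends on setting and year. The reference cohort carries
professional fees inside its pre-computed line items, and its
hospital-vs-professional split ($156,575 / $28,271) is recorded only as
cohort metadata: the per-patient split was never itemized, so the package
treats it as unverifiable at patient level. All amounts are nominal USD
with no inflation adjustment and no cost-to-charge conversion; reports
round to whole dollars, ties away from zero.

## QALY decision trees

Outcomes are a finite, acyclic, one-shot decision tree: internal nodes
split probability mass over mutually exclusive outcomes (each node's
branch probabilities must sum to 1 within 1e-9), and leaves carry a
quality-of-life weight `Q` in `[0, 1]` and a duration in years. A leaf is
worth `Q × years`; expected QALYs are the probability-weighted sum over
root-to-leaf paths, and an intervention's gain is the difference between
the with- and without-intervention trees. `outcome_paths()` emits the full
audit trail — every path, its probability and its contribution.

The default discount rate is 0: the bundled per-patient components
(0.12 and 9.08 + 2.90) sum to the recorded totals only undiscounted, and
the underlying model is a one-shot tree, not a Markov cycle, so no
half-cycle correction applies. An annual discount rate is available for
standard health-technology-assessment practice; year `t` is discounted by
`(1 + r)^-t` and a fractional final year is prorated linearly at the next
year's factor, which makes the discounted value converge continuously to
the undiscounted one as `r -> 0`.

Condition-specific quality weights and life expectancies are inputs
(`life_expectancy()` interpolates a sex-by-age life table linearly,
clamping outside the tabulated range), never constants. For the Factor
XIII deficiency case the published risk inputs — a 12% mortality risk
given a second CNS bleed and neurologic complications in 72.6% of its
survivors — are kept as metadata, and `factor13_example_trees()` rebuilds
an *illustrative* with/without-prophylaxis tree pair from them. The
quality weights and durations in that pair are placeholders: the exact
parameterization behind the recorded 9.08 and 2.9 QALY components was not
published, so the illustrative trees demonstrate structure and are never
asserted against those components.

## Aggregation and classification

Net cost is sequencing spend minus ledger savings; the ICER divides it by
the QALY gain of consensus-modeled patients only. The reported ICER is
rounded to whole dollars, ties away from zero (54,554 / 12.1 = 4,508.595…
reports as 4,509); yields are rounded to the nearest integer percent
(17/38 → 45, 13/17 → 76 — both published yields are consistent with
nearest-integer rounding, which is therefore used). Value classes bracket
the willingness-to-pay thresholds ($20k / $50k / $100k per QALY by
default) with strict inequality below the conservative and standard
thresholds and an inclusive upper bound; the boundary convention is a
documented package choice, since thresholds are conventionally quoted as
ranges without comparison operators. An intervention that both saves
money and gains QALYs is *dominant* and gets no finite ICER; positive net
cost with zero QALY gain classifies as low value.

## The reference cohort

`reference_cohort()` bundles a 38-proband PICU cohort: 17 diagnosed, 13
management changes, 8 Delphi questions, 7 reaching consensus, six
per-patient cost effects (9,795; 74,556; 8,108; −9,856; 134,538; −32,295
USD), QALY components 0.12 and 9.08 + 2.90, and a cohort sequencing spend
of $239,400. Two reconciliations deserve note. First, the quoted per-trio
sequencing price ($7,400) times 38 does not equal the cohort total, which
implies mixed, unitemized family configurations; the cohort total is
treated as authoritative and spread evenly across families, with the
per-trio figure kept as reference metadata. Second, panelist-level Likert
responses were never published, so the bundled responses are synthesized
to be consistent with the recorded per-question statuses only (seven
round-one agreements; the question for patient 6052 scores 3.3 then 3.5
and is discarded) and are flagged as synthetic in the metadata.

## The synthetic generator

`generate_cohort()` draws cohorts from the structure the analysis
assumes: a Bernoulli chain diagnosis → management change → modelable
counterfactual (defaults 0.45, 0.76, 8/13, matching the reference
cohort's observed rates); log-normal avoided costs (`meanlog = log 25,000`,
`sdlog = 1.1`, spanning roughly the $8k–$135k spread of the reference
effects) with rarer, smaller log-normal incurred costs for about a
quarter of modeled patients; QALY gains for about 2 in 7 modeled
patients, produced by actually drawing with/without outcome trees within
configured probability, quality and duration ranges; per-family
sequencing costs by configuration; and panel responses drawn from a
normal distribution centered on each question's true effect with standard
deviation `1/concentration`, rounded and clamped onto the 1–5 scale. The
distributional families are generator choices — no distributions were
published — selected for the right qualitative shape (heavy right tail in
costs, sparse QALY gains, concentration-monotone consensus). One in eight
questions draws a mid-scale true effect where consensus is unlikely,
mirroring the one discarded question in eight. A single integer seed
drives fixed per-table sub-streams, so the same configuration regenerates
the same bundle table by table.

What the generator does *not* emulate: clinical phenotypes, correlation
between cost size and QALY gain, panelist-specific response styles, or
calibration to external cost databases. Passing tests on synthetic
cohorts therefore demonstrate the pipeline's arithmetic and gating, not
external validity of any particular cost distribution.

## Numerical choices and test scale

Probability sums and consensus thresholds use an absolute tolerance of
1e-9; monetary aggregation is plain double-precision summation, tested
permutation-invariant to 1e-6 absolute on cohort-scale ledgers. Tree
evaluation is checked against an independent brute-force path-enumeration
oracle (closed-form geometric discounting) on hundreds of random trees of
depth up to four. Parameter-recovery tests generate 10,000-proband
cohorts and require empirical yields and mean savings within three
standard errors of the generating truth — a size chosen to make
three-standard-error bands tight (about ±1.5 percentage points on the
diagnostic yield) while generating in seconds.

## Limitations

The pipeline deliberately omits probabilistic sensitivity analysis and
acceptability curves, payer-vs-societal perspectives, cascade testing of
relatives, Markov/microsimulation disease models, utility elicitation,
cost-to-charge conversion and inflation adjustment. Charges are used as
cost proxies throughout, and avoided-procedure valuations arrive as
single line items rather than being re-derived from comparable cases.
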