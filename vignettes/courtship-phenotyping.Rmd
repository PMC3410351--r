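---
title: "Courtship-based behavioral phenotyping of Parkinson's-model flies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Courtship-based behavioral phenotyping of Parkinson's-model flies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flycourt)
```

## The assay and why it exists

Flies expressing mutant human alpha-synuclein (A30P) pan-neurally are a
standard *Drosophila* model of Parkinson's disease. The classical behavioral
readout, the negative-geotaxis climbing assay, is convenient but coarse: it
is binary per fly and the deficit only becomes measurable at around three
weeks of age. Courtship is a far richer behavior — a stereotyped ritual of
orientation, wing vibration (song), licking, and attempted copulation that
demands coordination across visual, chemosensory, auditory and motor
systems — so deficits of neural function should surface in it earlier and in
more dimensions. This package implements that idea as a reproducible
pipeline: bout-level event logs in, per-couple parameters, group
comparisons, a composite score, and a rule-learned Boolean diagnostic out.

## Data model

A *session* is one male paired with one virgin female for up to
`observation_cap_s` seconds (default 600), ending early if copulation
occurs; the session's total time is the copulation start time in that case.
Behavior is a list of bouts `(element, start_s, end_s)` over six elements:
`orientation`, `vibration`, `licking`, `attempted_copulation`, `copulation`
and `nse`. A non-sexual encounter (NSE) is a male-female encounter not
followed by any sexual activity and is recorded as an instantaneous event.

Two validation rules are worth stating because the field's conventions do
not force them: bouts of *different* elements may overlap (a male orients
while singing), while bouts of the *same* element may not — this keeps every
per-element duration sum well-defined and bounded by the total time.
Touching bout endpoints do not count as overlap. Times are carried at 0.01 s
resolution and written with two decimals, so CSV round trips are exact.

One published quantity, "total ritual time", is never defined precisely in
the source material. We identify it with the (copulation-truncated)
observation time, which is consistent with every printed value falling in
350–520 s under a 600 s cap; `total_time(session, from_first_act = TRUE)`
exposes the alternative reading (time from the first courtship act) for
sensitivity analyses, but nothing downstream uses it by default.

## Per-couple parameters and group arithmetic

Each couple reduces to eight features: summed orientation and vibration bout
durations, licking/ATC/NSE bout counts, the copulation indicator, total
time, and the sexual focus index

$$\mathrm{SFI} = \frac{1}{\mathrm{NSE} + 1} \in (0, 1],$$

which is 1 for a male whose every encounter leads to courtship and decays as
unfocused encounters accumulate.

Because fast-copulating males have short sessions, durations and counts are
time-normalized before averaging: orientation and vibration as
$100\,t/T$ percent of session time, licking and ATC as counts per 100 s
($100\,k/T$). NSE (and hence SFI) is deliberately **not** divided by total
time: NSEs concentrate before any sexual activity begins, so dividing by a
copulation-truncated denominator would reward rather than penalize
distraction. Copulation is binary per couple, so groups are compared on the
summed copulation count, not a mean.

Group comparisons set the control group to 100%: each trait's relative
activity is $100\,\bar{x}_{\mathrm{PD}}/\bar{x}_{\mathrm{ctrl}}$, reported
rounded to whole percents alongside the unrounded value. The composite
courtship score averages the six relative activities (orientation,
vibration, licking, ATC, copulation, SFI), so a group identical to control
scores 100 and uniform impairment to half of control scores 50. SFI, not
raw NSE, serves as the sixth trait so that every component is
monotone-increasing in courtship quality. Note the published "36% better"
figure for SFI is not reproducible from group mean NSEs (1/22 vs 1/34 gives
a ~54% ratio); we average per-fly SFIs and report that ratio without
asserting any particular value.

The climbing assay is scored as the pooled pass fraction (total flies that
climbed ≥ 1 cm in 18 s over total flies assayed); with equal vial sizes this
equals the mean per-vial fraction, and pooling makes the score invariant to
how flies are partitioned into vials. The deficit is again reported
control-relative: $100(1 - s_{\mathrm{PD}}/s_{\mathrm{ctrl}})$.

## The rule-based diagnostic

The diagnostic layer treats health (wild-type vs A30P) as a Boolean
dependent variable and searches for interval conditions on the eight
features. A *condition* is an inclusive interval $[l, h]$ on one feature
(inclusive at both ends — "3 to 5 times" includes 3 and 5; nothing in the
published ranges indicates open endpoints). A *rule* is a conjunction of
one or more conditions on distinct features; two intervals on the same
feature would reduce to their intersection, which is itself an enumerated
candidate, so same-feature conjunctions are excluded. A *rule set* is a
disjunction of healthy-predicting rules read as necessary and sufficient:
satisfy at least one rule and the fly is called healthy, satisfy none and it
is called sick.

`evaluate_ruleset()` reports the empirical conditional probabilities
P(healthy | ≥ 1 rule fires) and P(sick | none fires), the two-sided success
rate $s$, and the improvement factor over chance,

$$\mathrm{IF} = \frac{\min(p, 1-p)}{1 - s},$$

with prior $p$ defaulting to 0.5 — i.e. the error rate of guessing under the
prior divided by the observed error rate, reported as `Inf` when
classification is perfect. The shipped seven-condition rule set
(`table1_rules()`) reproduces the published statistics on a synthetic
56-couple cohort (`synthetic_table1_cohort()`) constructed to have the
published confusion structure — 23/28 correct in each class. The original
per-fly recordings are unpublished, so that cohort is a labelled synthetic
stand-in: it validates the evaluation arithmetic, not the original data.
The within-interval "average" annotations attached to some published
conditions are carried as metadata only; several are mutually inconsistent
and none affect classification.

## Mining: enumeration, thresholds, pruning, selection

`mine_rules()` re-implements the association-rule search as an exhaustive,
fully deterministic enumeration:

* **Candidates.** For count and Boolean features, every contiguous run of
  observed values (a Boolean yields exactly its two point conditions). For
  continuous features, every interval whose endpoints are observed values
  when the dataset has ≤ 64 rows, otherwise every interval over
  equal-frequency 8-bin boundaries. On 56 couples this is ~4,000 candidate
  conditions.
* **Thresholds.** A conjunction qualifies for a label when its empirical
  P(label | conjunction) ≥ `min_probability` (default 0.8, chosen to
  bracket the published 0.821) and its support ≥ `min_support` (default 2,
  an absolute count). Both labels are mined. The default `max_conjunction`
  is 2 because no published rule uses more than two conditions.
* **Pruning.** A rule whose condition set strictly contains that of an
  equally-or-more-probable shorter rule for the same label is dropped; the
  shorter rule explains at least as much with less.
* **Scale.** Even after pruning, exhaustive enumeration on 56 rows leaves
  on the order of $10^6$ qualifying rules, so the mined set is returned as
  a columnar `rule_table` (condition indices plus statistics) rather than a
  million S3 objects; `as_rule_list()` materializes any subset.

`select_iff_ruleset()` assembles the necessary-and-sufficient set by greedy
forward selection over the healthy-predicting rules, maximizing the
two-sided success rate of the disjunction; ties prefer higher support, then
fewer conditions, then canonical lexical order, and selection stops when no
single addition strictly improves the success rate. Greedy selection is
deliberate — the subset lattice over $10^6$ rules is not searchable — but it
inherits the classic set-cover caveat: it can stall below the exhaustive
optimum when every individually neutral addition would only pay off in
combination. The test suite demonstrates both regimes on ≤ 8-row datasets
against a brute-force subset oracle. The mined probabilities and supports
are audited against the data (`audit_rules()`), and mining is invariant
under row permutation.

We make no claim of bit-compatibility with the proprietary mining tool used
originally; the contract is the procedure above, and reproducing the exact
published intervals is impossible without the unpublished raw data.

## The synthetic generator

`generate_sessions()` emulates the study design so the whole pipeline is
testable without the original recordings: per couple, copulation ~
Bernoulli(p), with session length Uniform(300 s, 600 s) when copulation
occurs (the published ritual times, 354.95–519.91 s, fall in this range)
and 600 s otherwise; orientation and vibration time fractions ~ Beta with
the group's target mean and concentration 50; licking and ATC counts ~
Poisson(rate × total/100); NSE ~ Poisson(group mean). Group means default
to the published values (orientation 56.6% vs 41.3%, vibration 21.5% vs
17.2%, licking 3.4 vs 2.0 and ATC 0.4 vs 0.2 per 100 s, copulation 11/28 vs
8/28, NSE 21 vs 33). No dispersion information is published anywhere, so
all second moments (Beta concentration 50, Poisson counts, the uniform
latency) are this package's own choices, made once for plausibility — a
concentration of 50 gives orientation-fraction SDs of about 7 percentage
points, a realistic couple-to-couple spread for a 10-minute assay.

Bout streams realize the drawn totals: durations of 2–20 s placed
non-overlapping with random gaps, all on the 0.01 s grid. The generator
emulates summary statistics only; it does not model the sequential
structure of the ritual (orientation preceding song preceding licking),
within-session nonstationarity, or correlations between traits beyond their
shared dependence on session length. Passing parameter-recovery tests
therefore demonstrates that the pipeline measures what the generator
encodes — not that the generator is a biophysical model of courtship.

Problem sizes used in the checks are chosen for tight Monte-Carlo error at
interactive run times: 2,000 couples per group for mean recovery (relative
tolerance 2%) and 500 vials of 10 flies per group for the climbing
reduction (±2 percentage points around the configured 28%).

## Numerical and degenerate-input choices

* Interval membership is inclusive at both endpoints everywhere.
* Bout times live on a centisecond integer grid internally; CSV writes two
  decimals, making `write_sessions()` ∘ `read_sessions()` the identity.
* Sessions read from CSV are ordered by couple id, events by start time;
  all iteration orders in mining are fixed, and the generator's output is a
  pure function of its seed.
* An empty event list is a valid session (all counts zero, SFI 1). A
  session may contain at most one copulation event and nothing after it.
* `evaluate_ruleset()` reports `NA` conditional probabilities when a side
  of the split is empty, and `Inf` improvement factor at success rate 1.
* `group_summary()` and `climbing_score()` refuse empty groups rather than
  returning NaNs.

## Limitations

* The evaluation cohort for the published classifier statistics is
  synthetic by necessity; only the arithmetic, not the original data, is
  reproduced.
* Greedy rule-set selection is not globally optimal (see above).
* Binned-mode mining (> 64 rows) trades completeness for tractability; the
  exhaustive guarantee holds only in exhaustive mode.
* The generator draws traits independently given session length; real
  courtship traits are correlated, so mined rule sets on synthetic cohorts
  are illustrative, not biological findings.
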