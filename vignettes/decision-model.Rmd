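---
title: "The COPD advance-directive decision model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The COPD advance-directive decision model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copdAD)
```

## The decision problem

A patient with chronic obstructive pulmonary disease (COPD) choosing an
advance directive faces two options for the event of respiratory failure
during an exacerbation: **Full Code** (invasive mechanical ventilation via
endotracheal tube, ETT, is allowed) or **Do Not Intubate** (**DNI**;
noninvasive ventilation and medical treatment only). copdAD values each
option as the expected quality-adjusted life years (QALYs) of a decision
tree covering a single index hospitalization, and recommends the directive
with the higher expected value. The comparison is deliberately
preference-sensitive: how the patient values a month of intubation
complications and permanent nursing-home residence enters the payoffs
directly and can reverse the recommendation.

## Tree structure

Both strategy trees share one skeleton, built by `build_strategy_tree()`
and checked programmatically by `audit_strategy()`:

1. The exacerbation presents **severely ill** (pH < 7.29) with probability
   `exacerbation_mix`, otherwise **moderately ill**.
2. Admission to **ICU** or **ward**, with directive- and
   illness-severity-specific probabilities.
3. Treatment intensity: **ETT** is offered only in the ICU and only under
   Full Code; **NIMV** (noninvasive ventilation) in either location and
   under either directive; treatment **without mechanical ventilation**
   only on the ward (an absorbing arm — no later escalation).
4. Short-term outcome: in-hospital death, or survival with or without a
   ventilation complication. ETT complications are end-organ damage,
   infection, or inability to discontinue ventilation; the NIMV
   complication is failure to wean. Patients failing ventilation may
   choose **Comfort Measures Only** (CMO); under Full Code a failed NIMV
   course may instead escalate — modelled as an ICU transfer followed by
   intubation, so the ETT-only-in-ICU constraint holds by construction —
   while under DNI the alternative is continued medical treatment, with a
   dedicated (and clinically much higher) mortality than the general
   non-ventilated ward population.
5. Disposition: death; discharge home; **short-term** extended-care
   facility (ECF) rehabilitation followed by home; or **long-term ECF**
   (permanent institutionalization), the latter reachable only after
   ventilation complications, failure to wean, or CMO survival.

A terminal payoff is `terminal_qaly()`: zero for death; utility x life
expectancy for the discharge states, with short-term ECF valued as home
(it is temporary rehabilitation; no separate utility exists for it, and an
optional transient-disutility hook defaults off). A complicated course
adds `complication_months/12 * u_complication` and deducts the same
duration from the post-discharge term, floored at zero. The complication
period defaults to 1 month, matching the time-tradeoff scenario used to
value it; it is configurable through the parameter file. Life expectancy
and home utility after discharge are assumed equal to their
pre-exacerbation baseline. No discounting is applied (a no-op hook exists
on `rollback()`).

The tree is a one-shot model of a single hospitalization: no state
transitions, no repeat exacerbations within a year. Re-evaluating the tree
at an annual advance-directive discussion is the intended usage pattern.
An optional root chance node for exacerbation-versus-stable-year is not
built by default because the single-hospitalization structure is the
published convention for this decision.

## Inputs

* **Probabilities** are `parameter_estimate()` objects: point, plausible
  range, provenance. They can be produced from study tables by
  `choose_estimate()`, which pools with the DerSimonian–Laird
  random-effects estimator (`pool_dl()`) when the studies are homogeneous
  — declared when the Q-test p-value exceeds 0.10 *and* I² is below 25%
  (informal statements of this rule sometimes mix the Q statistic with its
  p-value; the implemented criterion is the standard one consistent with
  those thresholds) — and otherwise falls back to the median estimate with
  the range spanning the lowest and highest reported study CI bounds.
  Expert-opinion values carry explicitly wide ranges. Sibling sets at a
  chance node are closed by `back_calculate_complement()` or, inside a
  tree, by a single `"complement"` edge resolved at validation time.
* **Life expectancies** come from survival fractions through the DEALE
  (declining exponential approximation: rate = −ln S/t, LE = 1/rate),
  converted at load time with a logged record, or are given directly.
* **Utilities**: baseline COPD utility per GOLD severity stratum in
  (0, 1]; the complication and long-term-ECF utilities derive from linear
  time-tradeoff (TTO) responses, `u = (d − t)/d` for `t` months traded
  against a state of duration `d`. The complication state is referenced
  against its 1-month duration; the chronic ECF state against the
  severity-specific COPD life expectancy (in months) — the natural
  chronic-state horizon; referencing against ECF life expectancy instead
  is a defensible alternative the file format could support, but the
  severity-specific choice keeps the two grid axes on the same scale of
  "months of one's own remaining life". Utilities are *not* floored at −1:
  trading more time than the state lasts legitimately encodes states worse
  than death, and a floor would destroy the tradeoff-ladder semantics
  (`floor_utility()` is available as an opt-in transform). Tradeoff units
  accepted: weeks, months, years (1 year = 12 months, 1 month = 4.345
  weeks).

## Sensitivity analyses

`one_way()` evaluates the QALY difference at both ends of one parameter's
plausible range with everything else at base case; because each
probability enters every root-to-leaf path product at most once, the
difference is affine in any single parameter, and a sign change is
bracketed and located by plain bisection (`find_threshold()`, stopping at
|ΔQALY| < 1e-9 or a bracket narrower than 1e-6 in parameter units —
derivative-free on purpose, since continuity is all the model guarantees).
Probabilities are swept jointly with their complement edge, keeping
sibling sums at 1. `tornado()` sorts the one-way bars by width;
the two TTO-derived utilities are swept over the utilities generated by
the default tradeoff ladder (0, 1 week, 1, 2, 3, 6 months, 1 year).
`two_way_preference_grid()` re-evaluates the recommendation over a grid of
ECF-versus-complication tradeoffs. Ties at decision nodes resolve to the
first-listed child with a logged notice, and `recommend()` reports
`"indifferent"` within a configurable tolerance (default 1e-9 QALYs — a
float-safe strict comparison, not a clinical equivalence margin).

## The synthetic fixture

The published base-case parameter table for this decision is not
reproduced here, so `generate_fixture()` emits a complete synthetic
stand-in: clinically plausible magnitudes (ICU admission, intubation and
NIMV rates stratified by illness severity, treatment-arm mortalities,
complication and disposition probabilities), BODE-quartile-like 4-year
survival fractions (0.80 / 0.60 / 0.35 for mild / moderate / severe COPD)
and a nursing-home 1-year survival of 0.69, all DEALE-converted, plus
neutral (zero-tradeoff) TTO responses. Points are jittered around these
anchors by a seeded generator, within their plausible ranges; the severity
ordering survives any seed, and a given seed reproduces the file
byte-for-byte. Every value is labelled a stand-in in the file itself.

What passing tests on this fixture do show: the engine equals exhaustive
path enumeration; the structural constraints hold; the recommendation
responds in the clinically expected directions (less favorable to Full
Code as complications become likelier or as complication/ECF aversion
grows, and a Full Code advantage that shrinks with COPD severity). What
they do not show: agreement with any published base-case numbers — the
fixture is more robust to preferences than a calibrated parameter set
would be (on the default tradeoff ladder its severe-COPD grid stays Full
Code; flips appear only at more extreme tradeoffs), and its thresholds
are properties of the stand-in values only. Problem sizes were chosen
for thorough yet quick checking: 200 random trees for the rollback
oracle, three seeds by three severities for the structural audit, a 7x7
preference grid.

## Known limitations

Single hospitalization only (no Markov extension, no repeat
exacerbations); no cost outcomes; no age/sex/comorbidity adjustment of
life expectancy; the exact interleaving of admission location and
ventilation choice is one defensible reading of the clinical pathway;
"no significant outliers on the forest plot" is left to visual inspection
of `forest_data()` output rather than automated.
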