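---
title: "Methods: auditing written versus calculated opioid prescription durations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: auditing written versus calculated opioid prescription durations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxaudit)
```

## The problem and the model

An outpatient opioid order carries four sig elements — per-administration
dose, frequency, a prescriber-documented duration, and the tablet quantity to
dispense — that most order-entry systems do not reconcile. `rxaudit`
recomputes, for every oral opioid tablet prescription, the number of days the
dispensed quantity would actually last:

$$
d_{calc} \;=\; \frac{(q \times s)\,/\,m}{a}
$$

where $q$ is the tablet quantity dispensed, $s$ the per-tablet strength (mg),
$m$ the maximum dose per administration (mg) and $a$ the administrations per
24-hour day. Equivalently, $q$ divided by the daily tablet consumption. Two
conventions bias this *downward*, i.e. toward the shortest defensible
duration:

* a ranged discrete dose (e.g. "20–30 mg") resolves to its maximum, so
  $m = 30$ and a 15 mg tablet gives 2 tablets per administration;
* a PRN sig is scored at its maximum allowed frequency ("twice a day PRN" is
  $a = 2$; "every other day" is $a = 0.5$).

The audit therefore *understates* how often the dispensed supply outlasts the
documented duration: any patient taking less than the maximum stretches the
supply further. The comparison classifies each prescription with both
durations available as `equal`, `calc_greater` ($d_{calc} > d_{written}$, the
discrepancy of interest) or `calc_less`, and compares the category mix before
and after an order-entry intervention.

Prescriptions are treated as independent observations; within-patient
correlation across prescriptions is not modeled (the per-patient utilization
analysis is reported separately), and no adherence or pharmacy-fill behavior
is modeled — the audit is about what the order itself represents.

## Sig normalization

**Frequency lexicon.** Frequency labels map to administrations per day
through an editable lookup table ([default_frequency_lexicon()]): daily
synonyms = 1, BID/twice a day = 2, TID = 3, QID = 4, every $N$ hours
= $24/N$ for $N \in \{3,4,6,8,12\}$, every other day = 0.5, nightly = 1,
weekly = 1/7. Lookups are case- and whitespace-insensitive, and PRN / "as
needed" qualifiers are stripped before lookup, so the PRN-maximum convention
is structural: `rate(label) == rate(label + " PRN")` for every entry. Real
EHR vocabularies differ between sites, so site labels merge over the built-in
table (`frequency_lexicon(path=, extra=)`) and win collisions. A label not in
the lexicon is never guessed: the record becomes uncomputable, is counted,
and the label lands in the unmapped-labels log.

**Dose grammar.** Discrete doses must match `"A mg"` or `"A-B mg"` (en dash
accepted, decimals and loose whitespace allowed, $0 < A \le B$). Anything
else — inverted ranges, zero doses, free text — is a parse failure: a silent
misparse would corrupt the headline discrepancy rate, so failures are counted
instead. Tablets per administration ($m/s$) may be fractional (half tablets);
no rounding is applied at this layer.

**Written-duration units.** Durations documented in non-day units convert to
days with factors week = 7, month = 30, hour = 1/24, and doses ÷
administrations-per-day. These factors are configuration, not discoveries,
and every converted record carries a flag so the share of unit-converted
records is reportable. Where the unit is unknown (or a doses-unit record has
no computable rate) the record is excluded and counted separately from
records missing a written duration altogether — the convert-versus-exclude
boundary is genuinely ambiguous in practice, so the pipeline reports both
counters and lets the analyst draw the line.

## The cohort cascade

Exclusions are applied in a fixed order, and each record leaves the cascade
exactly once, so `n_total` always equals `n_final` plus the sum of the
exclusion counters:

1. route not oral, or formulation not a tablet (missing route/formulation
   fails here too — counted, never silently dropped);
2. drug name contains an excluded substring (default: buprenorphine and
   methadone, which are dosed for opioid-use-disorder maintenance, not
   analgesia; the list is configurable);
3. no written duration documented;
4. written duration documented in a non-convertible unit;
5. calculated duration uncomputable (unmapped frequency, unparseable dose,
   missing quantity or strength);
6. ordered outside the configured study window.

The order matters because a doubly-defective record lands in the first bucket
that catches it; the chosen order follows the narrative order in which the
filters are naturally described (population definition first, then
field availability). Refill orders are *not* exempt from any filter — they
simply tend to lack written durations, which the generator emulates.

The pre/post split is strict-before: `ordered_at < intervention_datetime` is
preintervention. The default window is 2017-10-01 to 2019-08-01 (22 calendar
months) with the boundary at 2018-09-01, giving two 11-month periods around
an August-2018 intervention; all three timestamps are configuration.

## Statistical layer

* **Proportions** use the Wald interval on the percent scale,
  $\hat p \pm z\sqrt{\hat p(1-\hat p)/n}$, clipped to $[0,100]$. Wald is the
  default because it is the interval the audit's cohort-scale reference
  values follow exactly; its boundary degeneracy (zero-width at
  $\hat p \in \{0,1\}$) is documented and the Wilson score interval is
  available via `ci_method = "wilson"` for small or boundary-heavy cohorts.
  Display rounds half-up to 2 decimals; stored values are unrounded.
* **Two-proportion comparisons** use the Pearson chi-square on the 2×2 table
  without continuity correction (immaterial at cohort-scale counts; Yates
  available via `chisq_correct`). The statistic equals the squared
  two-proportion z statistic, which the tests assert numerically. Per
  category this yields three 2×2 tests; since it is ambiguous whether a
  three-category pre/post comparison should instead be one omnibus test, the
  report emits both (`category_*` rows and `category_omnibus`).
* **Monthly volumes** are compared with a Welch t test by default
  (`t_var_equal = TRUE` for pooled variance) over calendar-month order
  counts.
* **Per-patient-per-month counts** are compared with a Wilcoxon rank-sum
  test. These counts are heavily tied (median 1, IQR 1–2), so the test is
  written tie-aware: for combined samples of 12 or fewer the null
  distribution of the rank sum is enumerated exactly over all group
  assignments of the observed midranks; above that, the tie-corrected normal
  approximation
  $z = (W - \mu)/\sigma$, $\sigma^2 = \frac{n_1 n_2}{N(N-1)}\left(\sum r_i^2
  - \frac{N(N+1)^2}{4}\right)$, is used. An all-tied sample carries no
  ordering information and returns $p = 1$ with a warning.

No multiple-testing adjustment is applied: the audit reports a small, fixed
family of pre-registered-style comparisons, and consumers should interpret
the p values jointly.

## Classification tolerance and rounding

Equality means $|d_{written} - d_{calc}| \le$ `tolerance_days`, default
$10^{-9}$ — effectively exact comparison on rational inputs while absorbing
floating-point dust from the division chain. Consequently a fractional days
supply (2.5 days) never classifies `equal` against an integer written
duration. Whether calculated durations should be rounded to whole days
before classification is a genuinely open design point; the default is no
rounding (the formula is purely algebraic and the reference sig examples
divide evenly), with `round_calculated = TRUE` available for sensitivity
analysis.

The day-by-day consumption oracle (`consumption_duration()`) exists to keep
the formula honest: it simulates taking tablets administration by
administration and must agree with the algebraic formula to $10^{-9}$ days on
randomized sigs, which the test suite asserts on over a thousand cases.
Partial final administrations count pro rata in both, the continuous
extension consistent with the algebraic formula.

## The synthetic generator

`generate_prescriptions()` emulates the EHR extract the audit consumes —
never any real data. Per calendar month (months anchored at the intervention
boundary) it draws an order count (normal, truncated at zero, rounded),
assigns orders to patients in blocks of $1 + \mathrm{Geom}(0.6)$ so the
per-patient-per-month distribution has median 1 and IQR 1–2, samples
drug/strength and frequency from catalogs of common oral opioid tablets, and
*solves the dispense quantity from a target relationship category*
(`quantity_for_category()`): exact product for `equal`, inflated by
$U(1.1,3)$ and rounded up for `calc_greater`, deflated by $U(0.3,0.9)$ and
rounded down (floor one tablet) for `calc_less`, re-drawing when rounding
would flip the category. Corruptions are then applied per period: missing
written durations (three-fold odds weighting toward refills, calibrated so
the marginal period rate matches the configured probability), unmappable
frequency text, non-day duration units (expressed so the converted value is
consistent), and non-oral / excluded-drug contaminant records.

Default rates are pinned to the audited system's observed magnitudes: missing
written durations 33.54% pre / 9.45% post, uncomputable sigs 6.01% / 3.61%,
ranged doses 4.5%, refills 10%, category mixes (equal, calc_greater,
calc_less) = (0.3886, 0.1795, 0.4319) pre and (0.4435, 0.1621, 0.3944) post.
The written-duration support {1, 2, 3, 5, 7, 10, 14, 30} days is weighted
toward 3–7 days, the typical acute-pain range. Volume defaults are a ~1/20
scale-down (monthly means 214.2 pre / 206.1 post, SD 10.2, ~1,500 patients)
so a full default run finishes in well under a second;
`generator_config(profile = "study")` pins the full-scale magnitudes
(monthly means 4284.64 / 4121.00, SDs ~200/181, ~30,000 patients, ~92,000
records over 22 months). A single seeded stream is consumed in a fixed,
documented order, so identical configs are byte-identical.

What the generator does **not** emulate: realistic drug-name frequencies or
indications, temporal trends beyond the pre/post step change, within-patient
autocorrelation of sigs, or free-text sig noise beyond the structured
grammar. Passing closed-loop tests therefore demonstrates that the pipeline
is arithmetically and statistically faithful to its own model of the extract
— not that any particular real EHR export is clean enough to audit without
inspecting the unmapped-labels log and flow counters first.

## Problem sizes in the test suite

The suite exercises the formula/oracle equivalence on 1,200+ randomized
sigs; parameter-recovery runs the pipeline on a two-period extract of roughly
31,000 and 41,000 computable prescriptions (the cohort-scale condition);
type-I calibration uses 1,000 simulated null replicates at $n = 500$ per arm
and expects 5% ± 2% rejections at $\alpha = .05$; and the generate–audit
round trip is fuzzed over 50 random configurations. The full suite runs in
about half a minute.

## Known limitations

* Wald intervals degenerate at the boundaries; use Wilson for tiny cohorts.
* The chi-square tests assume adequate expected cell counts; the report
  suppresses (rather than fails on) the small-sample approximation warning,
  so very small periods deserve a look at the raw counts.
* Drug exclusion is a case-insensitive substring match on the drug name —
  formulary-code matching would be stricter but codes are site-specific.
* Month = 30 days and the other unit factors are conventions, not facts
  about any prescription.
* The audit measures what orders *say*, not what patients take or pharmacies
  fill.
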