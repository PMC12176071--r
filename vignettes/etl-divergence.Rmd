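---
title: "How ETL choices move primary-care research outcomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How ETL choices move primary-care research outcomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Research registries that reuse general-practice electronic health records
do not analyze the raw EHR: a data processor extracts, transforms and
loads (ETL) the records into a research dataset, and different registries
make different choices at every step. Two registries fed by the *same*
practices can therefore report different patient counts, utilization
levels and even prevalences. Because the original care data are
confidential, the consequence of each choice is hard to isolate on real
data.

`ehretl` makes the whole chain observable on synthetic data. It simulates
raw care-zone tables for a group of practices, processes them through two
configurable ETL rule-sets modeled on real Dutch registry practice, links
the resulting research datasets per patient, and quantifies the
divergence with the three-step comparison used in registry benchmarking:
demographics, paired per-patient indicators of concordant patients, and
diagnosis-group rates with standardized differences.

## The two rule-sets

Every database-zone rule is a field of `pipeline_config()`; the shipped
`ahon_style()` and `nivel_style()` configurations bundle the two contrasted
philosophies:

| rule | `ahon_style()` (minimal processing) | `nivel_style()` (extensive processing) |
|---|---|---|
| registration quarters | from the enrollment date; only fully covered quarters; mid-quarter enrollment starts next quarter | from quarterly capitation fee records; gaps between first and last fee imputed |
| pseudonym | keyed hash of (3-digit postal prefix, birth year, sex) | keyed hash of the social security number |
| claims codes | all retained | filtered to a study-relevant selection |
| prescriptions | GP-recorded only, incl. repeats | GP + pharmacy feedback, deduplicated within 8 days |
| episodes | as recorded in the EHR | episode-of-care construct over a 2-year lookback |

Patient-years are always `0.25 ×` the number of registration quarters, so
each retained patient contributes 0.25-1 patient-year; a patient with no
registered quarter is excluded. Contacts are patient-days with at least
one retained claims code (at most one contact per patient per day), and
the regular consultation/visit subset `{12001, 12002, 12003, 12010,
12011}` is processed identically by both rule-sets — deliberately, as the
benchmark for what coordinated variable definitions achieve.

### The episode construct

For each patient and ICPC code the construct pools encounter dates —
ICPC-coded journal contacts, prescriptions carrying that indication, and
the start dates of recorded episodes — over the analysis year and
`lookback_years = 2` prior years. Sorted encounters split into episodes
wherever the gap exceeds the code's contact-free interval `L`; an episode
runs from its first encounter to its last encounter plus `floor(L / 2)`
days, and codes in `chronic_codes` yield a single never-closing episode.
Defaults: `L = 90` days with `U71 = 28`, and `T90`/`K86` chronic.

Three readings of the construct were genuinely open:

* *"half of the contact-free interval"* is read as half of the configured
  per-code interval, not half of an observed gap — the latter is undefined
  for single-encounter episodes.
* recorded episode **end** dates do not participate: the construct exists
  precisely because recorded end dates are unreliable, so it overrides
  them for non-chronic codes and uses recorded episodes only to seed
  start dates.
* a symptom contact filed under an episode with a different code takes the
  episode's code (`apply_symptom_overrule()`) before pooling.

### Deduplication

The 8-day prescription dedup is a greedy scan within each (patient, ATC)
group in date order: a record is dropped when it falls within
`dedup_window_days` (boundary inclusive) of the **last kept** record. This
keeps the first record of a burst, allows a new record once more than the
window has passed, and is idempotent. At pipeline level
`dedup_window_days = 0` disables the stage; the operation itself, called
with window 0, still collapses exact same-day duplicates of one ATC.

### Pseudonym collisions

The postal-prefix scheme can assign one pseudonym to several patients.
The pipeline's default (`collision_policy = "drop"`) removes all patients
with an ambiguous pseudonym: ambiguity is unrelated to morbidity, so
population rates are unaffected, which mirrors how such patients also
fail platform linkage ("loss of coverage"). The alternative
(`"collapse"`) merges them into one patient with the union of events and
quarters; it is offered because some registries do exactly that, but it
halves the patient-year denominator of the merged mass and therefore
inflates per-patient and per-patient-year rates — the reason it is not
the default.

## What the generator emulates

`generator_config()` defaults encode the study conditions the package
replays: 8 practices × 5,750 (SD 1,300) enrolled patients; age bands
0-4/5-17/18-64/65+ at 4.7/15.5/57.9/21.9% and 50.6% female; a
2017-2019 window with 2019 as analysis year; 8.6 GP contact days per
patient-year with the regular consultation codes at about half the claims
catalog weight; annual diagnosis prevalences T90 0.065 (chronic), U71
0.065, R05 0.055 plus chronic hypertension and acute background codes;
and the imperfections that make the rule-sets diverge — 7% missing social
security numbers, a 1% per-quarter capitation gap (calibrated to the
~0.3-0.5% patient-year deficit a capitation-based quarter rule shows
against an enrollment-based one), 15% pharmacy-sourced prescriptions with
a 50% chance of an 8-day cross-source re-record and a 15% chance of a
same-source repeat burst, and episodes of care recorded for only a
quarter of coded contact days while 45% of routine contact days carry a
loose ICPC journal line.

Disease case probabilities are scaled by the patient's within-year
enrollment exposure, and every case is guaranteed at least one coded
contact per active year inside its enrollment span. This makes a
configured annual prevalence `p` recoverable as `1000 p` cases per 1000
patient-years by *both* pipelines — the package's central calibration
property, tested at registry scale over 20 replicates.

What the generator does **not** model, and what passing tests therefore
do not show about real data: GP-specific recording habits and EHR-vendor
export dialects, free-text, seasonality, age- or sex-dependent morbidity
and utilization, mis-linkage (a pseudonym collision here never links the
*wrong* person, it only loses people), and realistic postal-code
geography. Utilization magnitudes are calibrated only loosely to the
order of magnitude seen in practice-registry tables (means of roughly
4-9 events per patient-year) and are documented as illustrative.

One emulation limit is structural: a 3-digit postal prefix offers at most
900 values, so at ~46,000 patients roughly a fifth of the population
shares a (prefix, birth year, sex) triple with someone else. The
synthetic concordant fraction (~0.75) therefore sits below the ~0.84 that
real registries with richer linkage achieve, and the postal-pseudonym
dataset ends up *smaller* than the social-security one rather than
larger. The package treats the real-world fraction as worked-example
arithmetic on published totals, not as a simulation target.

## Statistics

Step 2 uses the classical paired t test on dataset-A-minus-B differences
over concordant patients (`stats::t.test` underneath), reporting the mean
difference with its confidence interval. The confidence level is a
parameter with default 0.95; methods sections in this literature
sometimes state 99% while tables print 95%, so the level is always echoed
in the output rather than hard-coded. With identical inputs the
differences are exactly zero; that degenerate case is reported as t = 0,
p = 1 with a zero-width interval and a `degenerate` flag instead of an
error, because the identity null is a meaningful pipeline check. No
multiple-testing correction is applied, and the report says so.

Step 3 compares each diagnosis-group rate per 1000 patient-years as a
proportion through the standardized difference

SD = (p_A − p_B) / sqrt[(p_A(1−p_A) + p_B(1−p_B)) / 2],

antisymmetric in its arguments, banded at 0.2/0.5/0.8
(small/medium/large) with |SD| > 0.2 flagged as significant. When both
proportions are exactly 0 or 1 the denominator vanishes and the function
signals an error rather than fabricating a value. Prevalence always uses
the whole population's patient-years as denominator (`n_cases /
total patient-years × 1000`, one case per patient); for the prescription
and consultation rates the denominator is configurable (`total_py`,
default, or `group_py`) because published tables are ambiguous on this
point — rate magnitudes under `total_py` are consistent with the
published ones. Group consultations count all regular consultations of
the group's patients, not only same-day diagnosis-linked ones; the
alternative attribution is deliberately out of scope.

An episode counts toward the step-2 indicator when it overlaps the
analysis year (rather than only when it starts in it): an open chronic
episode is ongoing care, and the construct's half-interval tails are part
of its definition. Disease cases for step 3 are counted on the ICPC-coded
journal table, not on the claims table, so that a claims filter cannot
silently change a prevalence.

## Numerical choices and degenerate inputs

Dates are day-granular and all intervals closed. Quarter membership is
exact date arithmetic (a quarter counts iff enrollment is on or before
its first day and disenrollment, if any, on or after its last day).
`floor(L/2)` keeps episode tails whole days. Empty inputs (no capitation
records, empty claims filter, zero-patient extracts, no concordant
patients) return empty results or a flagged skip rather than errors; an
explicit empty claims filter warns. All randomness flows from a single
integer seed; identical configuration and seed reproduce extracts
byte-identically.

## Problem sizes used by the shipped checks

The test-suite replicates run at two scales, chosen as the package's own
trade-off between fidelity and turnaround: property and oracle checks on
hand-built micro-fixtures and ~800-patient extracts, and the calibration
checks at the full study scale (8 × 5,750 patients, 20 replicates for the
prevalence-recovery and directional-effect properties). The acceptance
script performs one full-scale replay plus the worked-example arithmetic.

## Known limitations

* ICPC and ATC codes are plain strings with prefix matching; no
  vocabulary validation beyond format, because the rules use codes only
  as match keys.
* The synthetic concordant fraction understates real platform linkage
  (see above); mis-linkage is not modeled at all.
* Recorded-episode behavior is vendor-dependent in reality; here it is a
  single probabilistic recording model.
* Which episodes a minimal-processing registry counts ("active in" vs
  "opened in" the year) is not settled in the field; the package uses
  overlap and documents it.
* The factorial attribution of the total divergence to individual ETL
  steps is out of scope; the directional single-step checks in the test
  suite are sign-only.
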