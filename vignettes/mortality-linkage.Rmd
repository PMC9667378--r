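---
title: "Deterministic mortality-file record linkage: method and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deterministic mortality-file record linkage: method and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mortlink)
```

## The problem

Hospital registries rarely know what happens to patients after discharge.
France's national mortality file publishes nominative records of every
registered death — surname at birth, given names, birth date, sex, birth
place, death date — but shares no unique identifier with any hospital
system. Linking the two means deciding, for each (patient, death record)
pair, whether both rows describe the same person, in the presence of
married-name changes, compound given names, clerical typos, partially
missing birth dates, and tens of millions of candidate rows.

`mortlink` implements a deterministic strategy built on the restricted
Damerau-Levenshtein distance (DLD; insertions, deletions, substitutions
and adjacent transpositions, each substring edited at most once — the
optimal string alignment variant), together with the data-cleaning and
blocking machinery that makes it correct and tractable, a direct
exact-matching reference strategy, a stratified evaluation layer, and a
synthetic cohort generator used to validate all of it.

## The matching rule

Both sides are first normalised: accents stripped (the mortality file
carries none), letters lowercased, non-letters removed. Birth dates are
repaired into valid `YYYYMMDD` strings: a day/month recorded as `00-00`
becomes January 1; an invalid date is retried with day and month swapped;
if still invalid, January 1 is used. City names lose district mentions
("Paris, 13ème arrondissement" → "paris"), and on the registry side an
abbreviation table rewrites particles ("St-Martin-sr-Ocre" →
"saintmartinsurocre").

Because given names are recorded inconsistently, three mortality-side
first-name variants are compared and the smallest distance kept: the first
element of the first name ("pierre"), the whole cleaned first name
("pierreolivier"), and the first name concatenated with the first middle
name ("pierreolivierchristian"). The surname distance is likewise the
minimum over the registry's birth and current surnames against the
mortality-file surname — this is what absorbs married-name changes when
the birth surname is on file.

A candidate pair is accepted when every field distance and their sum stay
within the learned bounds:

| bound | default |
|---|---|
| first name | 2 |
| surname | 1 |
| birth date (on the 8-digit string) | 1 |
| sex (0 = equal, 1 = different) | 1 |
| total (sum of the four) | 2 |

The defaults are the values learned on a stratified hospital training
sample; `dld_thresholds()` exposes all five. The city distance (minimum
over raw and abbreviation-expanded registry city against the mortality
city) never participates in validation — it is a tie-breaker only.

When one patient validates against several death records, the pair with
the smallest total distance is kept; ties break on the smallest city
distance (missing city distance sorts last); anything still tied is kept
and flagged `ambiguous`, with a deterministic `selected` representative by
(death date, record id) order. No authoritative selection procedure is
publicly documented for this design, so this rule is the package's own
construction, anchored on the fact that the city distance is computed
precisely as an option for pertinent-pair selection; ambiguity is
surfaced rather than silently resolved. Many registry patients may legitimately link to the same death
record (registry duplicates), so many-to-one links are allowed and visible
in the output.

## Blocking and scale

Comparing every pair is quadratic and infeasible at national scale. Two
successive simple blocking passes restrict comparison to pairs agreeing
exactly on (1) the repaired birth date, or (2) the concatenation of the
first 4 letters of the first name and the first 4 letters of the preferred
surname (shorter names contribute what they have). A pair can survive a
mismatch in either key but not both; the candidate set is the union of the
two passes, deduplicated before any distance is computed.

The engine partitions the mortality file into chunks (`chunk_size` rows,
default 50,000; equal blocking keys never split), scores chunks on
parallel workers (`workers = "auto"` uses available cores minus one), and
removes all scheduling nondeterminism with a final sort: the pair file is
byte-identical for any worker count and chunk size — a property the test
suite asserts.

## The direct reference strategy

To quantify what the cleaning and the distance tolerance buy, a reference
strategy links records only when surname (birth surname if present,
otherwise current), first name, birth date and sex are exactly equal after
minimal cleaning (lowercase, accents stripped — no non-letter removal, no
date repair, no name variants). Every direct match is also a distance
match at the default bounds.

## Evaluation design

Sensitivity is measured on patients whose death between 2001-01-01 and
2020-12-31 is registry-documented: detected means at least one selected
link with a death date in that window. Specificity is measured on patients
provably alive on the index date 2016-01-01 (encounters on both sides of
it): only links to deaths *before* the index date count as false
positives, because a link to a later death is a patient who genuinely died
after the index date.

Strata are sex × birth country (in/outside the home country). The overall
estimate is the stratified-sampling-proportion estimator
\(\hat p = \sum_s w_s \hat p_s\) with the sexes weighted ½ each and the
born-outside share taken from census data (`census_weight()`; the 2012
published counts give 4.5% for Nantes, 4.3% for Rennes, 8.4% for Lille).
The interval is Wald on that estimator,
\(\operatorname{Var} = \sum_s w_s^2 \hat p_s (1-\hat p_s)/n_s\), clipped
to [0, 1] — the standard form for the stratified estimator, stated here
explicitly because reported intervals in this field rarely name their
method. Strategies are compared on the same records with
McNemar's test: continuity-corrected chi-square
\((|b-c|-1)^2/(b+c)\), exact binomial when fewer than 25 discordant
pairs; zero discordance is reported as degenerate with p = 1.

## The synthetic cohort generator

No real registry can ship with the package, so validation runs on
generated cohorts (`simulate_cohort()`) with exact stratum design (half
deceased / half living-at-index, sexes split evenly, an exact born-outside
count per sex) and a fully explicit error model (`error_model()`)
emulating each documented corruption: single-edit typos per name field,
digit typos in dates, day/month inversion (injected only when the true day
exceeds 12, i.e. when the inversion is detectably invalid), `00-00`
day/month, married surnames with the birth surname sometimes unrecorded,
compound and concatenated given names, district suffixes on big-city
births, accents on the registry side only, plus controlled adversaries for
specificity: decoys sharing one blocking key, near-twins one edit away
with a pre-index death, and exact homonym twins.

Two design points deserve emphasis:

* **Identifiability.** Distinct generated persons are rejection-sampled so
  that no two sit within the validation budget of each other (birth dates
  within one edit *and* names within the per-field bounds). Without this,
  a finite name pool occasionally produces coincidental near-homonyms that
  no algorithm could tell apart, and "specificity = 1 on error-free data"
  — which is exactly what the generator must certify — would be
  unattainable in principle. All near-match stress is therefore injected
  explicitly and tunably (decoy and twin rates), never accidentally.
* **Calibration of defaults.** The default rates were chosen analytically
  (before any benchmark run) so that the direct strategy loses roughly ten
  sensitivity points to the distance strategy, the qualitative gap
  reported for real hospital data: a direct match requires *every* field
  to be exact, so its expected sensitivity is the product of the per-field
  no-error probabilities (≈ 0.91 × 0.93 × 0.96 × 0.997 ≈ 0.81 at the
  defaults), while the distance strategy only misses the events that
  exceed its budget (`00-00` dates with a non-January birth month,
  omitted birth surnames, multi-error records: ≈ 0.93–0.95). On the
  packaged 10,000-patient benchmark this yields roughly 95% vs 79%
  sensitivity and 99.3% vs 99.9% specificity.

What the generator does **not** emulate: realistic national name
frequencies (pools are ~120–200 names each, which *overstates* blocking
collisions relative to real data), transcription phonetics, and
correlated within-family errors. Passing the synthetic benchmark
therefore demonstrates correctness of the machinery and the qualitative
strategy ordering, not the real-data performance figures, which were
measured on private hospital registries and are not reproducible here.

## Numerical and degenerate-input choices

* Restricted (OSA) rather than unrestricted Damerau-Levenshtein: it
  matches the published operation list and standard implementations, and
  the two differ only beyond the distances used here. Note OSA is not
  compositional: a chain of k single edits that includes transpositions
  can land at distance > k; the generator's per-edit postcondition
  (distance exactly 1 per edit) is what the tests assert.
* The date distance is computed on the 8-digit digit string; separators
  never differ after repair and would only dilute the distance.
* A missing sex on either side scores 0 rather than consuming the small
  total budget; a missing city yields an undefined city distance, which
  sorts last in tie-breaking. Both are this package's decisions — the
  source work does not state them.
* A partially zeroed day (`1970-05-00`) falls through the same cascade to
  January 1. A record with no surname at all is a data error, not a
  silent skip.
* Worker auto-selection caps at available cores − 1 and at the chunk
  count; chunk boundaries never split a blocking key.

## Problem sizes used in the packaged checks

The shipped test suite and acceptance script run, by design, at desk
scale: the distance kernel is verified exhaustively against an
independent brute-force recursion over every pair of strings of length
≤ 8 from a 3-letter alphabet (≈ 9.7 × 10⁷ ordered pairs) plus 10,000
random pairs of length ≤ 12 against an R-level oracle; engine equivalence
against an all-pairs reference uses 500 × ~2,400 records; the benchmark
cohorts use 10,000 patients. These sizes were chosen to exercise every
code path (including chunking and parallelism) while keeping a full run
in minutes on one core.
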