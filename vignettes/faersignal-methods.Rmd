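---
title: "Curating spontaneous adverse-event reports and computing disproportionality signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating spontaneous adverse-event reports and computing disproportionality signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

The FDA's spontaneous reporting system collects voluntary adverse-event
reports. Used raw, the quarterly files are treacherous: the archive switched
dialects in 2012 (legacy files key rows by `ISR`/`CASE`, current ones by
`primaryid`/`caseid`), a single case accumulates follow-up versions and may
exist in both distributions, demographic fields are patchily populated, drug
names are free text (brands, dose suffixes, misspellings, NDA numbers), and
reactions/indications are MedDRA preferred terms that most downstream
vocabularies do not speak. Any disproportionality statistic computed on the
raw feed double-counts versions and fragments drugs across spelling
variants.

`faersignal` implements the complete curation chain — merge, impute,
de-duplicate, map, count, score — and emits the eight `standard_*`
tab-delimited tables that drug-safety analysts expect, with both case
identifiers retained everywhere so results can be traced back to the source
files.

## The procedure and its assumptions

**Merging.** Legacy and current versions are concatenated into one
case-version table carrying both key fields; nothing is dropped at this
stage. Demographics are normalized first: ages to years via the unit code
(`DEC` ×10, `YR` ×1, `MON` /12, `WK` /52, `DY` /365, `HR` /8760), reporter
countries through a bundled name→code table so that a spelled-out legacy
country and a coded current one compare equal, and event dates to
`YYYYMMDD`.

**Single missing-value imputation.** The four demographic key fields (event
date, age, sex, reporter country) drive de-duplication, so missingness is
repaired first — but conservatively. If at least one version of a case is
fully populated, a donor key is formed from the per-field maxima over the
fully populated versions (date by calendar order, age numerically, sex and
country lexicographically), and any version missing *exactly one* field has
that field filled. Versions missing two or more fields are left alone, and a
populated field is never overwritten. The per-field-maxima reading is a
design choice: "maximum key values" could also mean "the values of the
single maximal version"; the plural, field-wise phrasing favours the former,
and on realistic data the two rarely differ because sibling versions of a
case usually agree on populated fields.

**De-duplication, step 1 (latest version).** Versions of a case are ranked
by a precedence key: current data set beats legacy, then the unique case key
descending (numeric comparison when fully numeric, lexicographic otherwise),
then file year/quarter descending. The top-ranked version survives. Versions
with identical signatures (demographic key plus the `|`-joined,
alphabetically sorted upper-case drug-name and reaction lists) are thereby
collapsed to the most recent submission; for versions with *differing*
signatures the same precedence order decides, because no content-based
recency rule exists — submission order is exactly what the key encodes. A
case present in both data sets always keeps its current-data version.

**De-duplication, step 2 (demographic collapse).** Among surviving cases
whose four demographic fields are all populated and pairwise equal, only
the highest-precedence one is kept, regardless of assigned case number. A
missing field always protects a case from collapse: null never matches null.
Collapsing on missing data would merge unrelated cases, and the imputation
step exists precisely to populate these fields first. Probabilistic or fuzzy
duplicate detection is deliberately out of scope.

**Drug mapping.** Verbatim drug strings are mapped to standard vocabulary
concepts by a stepwise, first-hit-wins procedure: (1) exact lookup of the
normalized name; (2) the same lookup on the separate active-ingredient
field; (3) NDA-number lookup in an orange-book-style table; (4) an optional
user-supplied manual map keyed on the raw string (a two-column file replaces
interactive mapping tools). Non-standard hits (brands, combination products)
are resolved through the relationship table to their unique standard
concept; a non-standard concept with zero or several standard targets is
reported unmapped with a warning rather than resolved arbitrarily, because a
silent wrong mapping corrupts every count downstream. The normalization
chain (case fold, whitespace collapse, quote stripping, parenthesized-suffix
removal, trailing dose/form token removal, trailing punctuation removal) is
this package's own, documented rule set — the historical regexes behind
published coverage figures were never released, so reproducibility was
preferred over guesswork.

**Reaction and indication mapping.** Preferred terms are looked up,
upper-cased and trimmed, in a simplified PT→SNOMED table. Misses are
retained downstream with null concept identifiers. Indications are mapped
only for the surviving (latest) case versions.

**Pairs and statistics.** Every mapped drug of a surviving case — all roles,
concomitant included — is crossed with every mapped outcome of the case,
yielding the distinct triple universe of (case, drug concept, outcome
concept) combinations. For each observed pair, the 2×2 table over that
universe is

|                          | outcome        | other outcomes |
|--------------------------|----------------|----------------|
| reports with the drug    | a              | b              |
| all other reports        | c              | d              |

and the two classical disproportionality measures are

$$\mathrm{PRR} = \frac{a/(a+b)}{c/(c+d)},\qquad
\mathrm{CI}_{95} = \exp\!\Big(\ln \mathrm{PRR} \pm 1.96\sqrt{\tfrac1a - \tfrac1{a+b} + \tfrac1c - \tfrac1{c+d}}\Big)$$

$$\mathrm{ROR} = \frac{ad}{bc},\qquad
\mathrm{CI}_{95} = \exp\!\Big(\ln \mathrm{ROR} \pm 1.96\sqrt{\tfrac1a + \tfrac1b + \tfrac1c + \tfrac1d}\Big)$$

The counting unit is the triple universe, not unique cases: historical
published pair counts (tens of millions from ~5M cases) and the cell
magnitudes of the canonical worked example are only consistent with
triple-level counting. Case-level counting is available via
`counting_unit = "case"` for analysts who want case-denominated tables.

## Numerical choices and degenerate inputs

- Zero cells yield `NA` statistics; there is no silent continuity
  correction. The Haldane–Anscombe +0.5 correction is available behind
  `haldane = TRUE`, off by default.
- The PRR interval uses the standard error form
  $\sqrt{1/a - 1/(a+b) + 1/c - 1/(c+d)}$; the ROR interval uses
  $\sqrt{1/a + 1/b + 1/c + 1/d}$. Both implementations were verified to
  nine decimal places of relative error against an independent 50-digit
  arbitrary-precision implementation on 1,000 random tables, and the test
  suite repeats that check on every run.
- Partial event dates (`YYYY`, `YYYYMM`) are padded with `01` components so
  calendar ordering works, and count as populated; discarding them would
  inflate missingness for no benefit.
- Case keys are compared numerically when fully numeric so that `"9" <
  "10"`; otherwise lexicographically.
- List signatures join sorted, upper-cased, trimmed names with `"|"`, a
  character that does not occur in names, so concatenation is injective.
- Malformed source rows (wrong field count) are skipped and counted, not
  fatal; the historical handling of such rows was never documented, so
  skip-and-log is this package's choice. Files are read as Latin-1 (legacy
  files contain non-UTF-8 bytes) and written as UTF-8.
- No multiple-testing adjustment is applied: the output publishes raw
  PRR/ROR with their confidence intervals, as the field's reference
  datasets do.

## The worked example

The canonical published example for these formulas is the 2×2 table for
etanercept × injection site pain with cells a = 30,793, b = 647,134,
c = 140,853, d = 61,815,244. Exact arithmetic on those cells gives
PRR = 19.9796 (95% CI 19.7394–20.2227) and ROR = 20.8827 (95% CI
20.6219–21.1469). The statistics printed alongside that table in the
literature (PRR 21.11113, ROR 22.1693) do **not** follow from the printed
cells under the stated formulas — they were evidently computed from a
different intermediate dataset. This package documents and asserts the
oracle-verified values for the printed cells and makes no attempt to
reproduce the inconsistent printed statistics.

## What the synthetic generator emulates

`synth_config()` / `synth_vocabulary()` / `synth_corpus()` produce a
miniature corpus with a known answer for every stage: multi-version cases
(initial `I` plus geometric follow-up `F` versions), cases present in both
dialects, versions with exactly one or exactly two demographic fields
blanked, orphan duplicates (a second case number with an identical fully
populated demographic key), drug strings drawn from a fixture vocabulary
through brand, dose-suffix, misspelling and NDA-number variants, and
reaction/indication PTs of which a configured fraction has a SNOMED
mapping. The surviving-case ground truth is computed inside the generator
by a plain-loop application of the selection rules — a code path that shares
nothing with the dplyr-based dedup module — so the two act as independent
oracle and subject in the tests.

Default study conditions: 1,000 cases; 30% of cases gain follow-ups; 10%
appear in both data sets; 15%/5% of versions miss one/two demographic
fields; 3% orphan duplicates; 20 ingredients; drug-string variants 25%
brand, 20% dose-suffixed, 7% misspelled (the injected unmappable fraction),
10% NDA-number strings; 30 PTs with 80% SNOMED coverage. These are round
values chosen once to be representative of the regimes the pipeline must
handle — substantial multi-versioning and missingness, a realistic mapped
fraction for PTs (published reaction coverage sits near 80%), and enough
unmappable drug text to exercise the unmapped path — not estimates of any
particular quarter's marginals.

What the generator does *not* emulate, and what passing tests therefore do
not show: realistic marginal frequencies of real drugs and events (no
signal structure is planted; observed PRR/ROR values scatter around 1),
free-text noise beyond the four documented variant classes (real FAERS
contains dose text in many more shapes), therapy dates and report-source
records (parsed but unused, as in the published pipeline), and the actual
RxNorm/MedDRA/SNOMED content, which cannot be redistributed. Coverage
fractions on synthetic corpora are exact by construction, whereas the
published coverage figures (93% of drug names, 80%/64% of reaction/
indication PTs) depend on a specific vocabulary release and the full
archive, and are not reproducible at desk scale.

## Problem sizes used by the tests

The checked-in suite runs entirely from generated data: 200 randomized
corpora of 30–1,000 cases for the de-duplication oracle comparison, six
corpora of 50–500 cases for brute-force contingency verification, a
500-case fixture for mapping recovery, 1,000 random tables for the
arbitrary-precision statistics comparison, and a 120-case corpus for
byte-identity of the full pipeline across reruns and input permutations.
These sizes give every scenario class (cross-dataset cases, orphan
duplicates, two-field missingness) double-digit expected counts per run
while keeping the whole suite in the minutes range.

## Known limitations

- Step-2 collapse treats imputed and originally populated fields alike;
  whether the historical pipeline distinguished them is undocumented.
- The drug-name normalizer is deliberately conservative: it will not strip
  dose tokens embedded mid-name ("VITAMIN B12 COMPLEX" is left intact) and
  performs no spelling correction, so misspellings stay unmapped unless a
  manual map entry supplies them.
- `standard_case_outcome_category` crosses each OUTC category code with the
  case's mapped SNOMED outcomes; cases without mapped outcomes contribute
  no category rows.
- The PT→SNOMED table is a simplified one-hop mapping; PT misses propagate
  as nulls rather than falling back to broader MedDRA levels.
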