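---
title: "Disproportionality analysis of ICI pericardial toxicities: methods and design"
author: "perivig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality analysis of ICI pericardial toxicities: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perivig)
```

## The problem and the data model

Spontaneous reporting systems such as FAERS accumulate adverse-event
reports with demographics, drugs (with role codes: primary suspect PS,
secondary suspect SS, concomitant C, interacting I), reactions coded as
MedDRA preferred terms (PTs), outcome codes, therapy dates and
indications, distributed as quarterly "$"-delimited ASCII tables. Such
data support *disproportionality analysis* — comparing how often a
drug–event pair is reported against a comparator frame — but not
incidence estimation: there is no denominator of exposed patients,
reporting is voluntary and biased, and cases arrive as evolving
versions of the same report.

`perivig` implements the full analysis path for pericardial toxicities
under immune checkpoint inhibitors (ICIs): anti-PD-1 (nivolumab,
pembrolizumab, cemiplimab), anti-PD-L1 (atezolizumab, avelumab,
durvalumab) and anti-CTLA-4 (ipilimumab, tremelimumab) antibodies.

## Case definition and cohort construction

A *case* is a deduplicated report with

1. at least one reaction among the 15 pericardial-disorder preferred
   terms (autoimmune pericarditis, pericarditis, pericarditis adhesive,
   pericarditis constrictive, pleuropericarditis, cardiac tamponade,
   pericardial calcification, pericardial disease, pericardial
   effusion, pericardial fibrosis, pericardial hemorrhage, pericardial
   mass, pericardial rub, pneumopericardium, pericardial drainage),
   matched by lower-cased name or 8-digit MedDRA code; and
2. at least one ICI among its **suspect** drugs (role PS or SS) —
   concomitant ICIs never qualify a case.

Both the PT list and the drug dictionary (generic plus brand names,
with target class) ship as plain-text assets under `inst/extdata/` so
they can be audited or extended. A report with several pericardial PTs
counts once.

Deduplication keeps, per case id, the highest case version, breaking
ties by latest receipt date and then highest primaryid; drop counts are
logged. The unit of counting everywhere is the deduplicated report.

**Regimen.** The set of distinct suspect ICI generics defines the
regimen: one generic is that monotherapy; the pairs
ipilimumab+nivolumab, ipilimumab+pembrolizumab and
tremelimumab+durvalumab are the named combinations; any other multi-ICI
set is "other-multi-ICI". Strategy follows from the label (anti-PD-1 /
anti-PD-L1 / anti-CTLA-4 monotherapy, combination, other), so
monotherapy strategies, combination and other partition every cohort.

**Fatality.** A case is fatal iff its outcome set contains DE,
regardless of other codes; for display the mutually exclusive outcome
rows use the precedence death > life-threatening > disability >
hospitalization > other serious. Reports with no outcome code form an
explicit unknown-outcome stratum.

**Time to onset (TTO)** is the whole-day interval from the earliest
*day-precision* therapy start date among suspect ICI drugs to the event
date. Date tokens parse as 8-digit (day), 6-digit (month) or 4-digit
(year) precision; day-level arithmetic requires day precision on both
operands, so a TTO is never fabricated from a month- or year-anchored
date. Negative intervals are treated as incorrect records: they become
missing and are counted in the provenance. When several therapy records
exist for a drug, the earliest start is used — the most conservative
onset. Bins are 0–30, 31–60, 61–90, 91–180 and >180 days, closed at the
printed endpoints.

**Other conventions.** Ages convert to years with a 365-day year
(so whole-year ages stated in days convert exactly), decades ×10, and
implausible results (>120 years or negative) become missing with a
warning. Occurrence country maps to a five-region scheme in which
"America" pools North and South America; the shipped ISO-3166 table
makes the mapping total — anything unmapped is missing, never an error.
Indication terms map onto twelve reporting groups through a shipped
keyword table; a report's group is the most specific match among its
terms.

## Disproportionality statistics

For a comparison design the pipeline classifies every deduplicated
report into exactly one cell of the 2×2 table (a = target and event,
b = target only, c = comparator and event, d = comparator only). With
the full-database comparator, b/c/d are drawn from all non-target
reports; a named comparator restricts the frame to the two disjoint
groups.

The **reporting odds ratio** is ROR = (a·d)/(b·c) with the Woolf
log-normal interval exp(ln ROR ± z·√(1/a+1/b+1/c+1/d)), z = 1.959964.
The interval method is a deliberate design choice: the convention is
standard, cheap and matches published pharmacovigilance practice. When
any cell is zero the Haldane–Anscombe correction adds 0.5 to *all*
cells (estimate and interval) and the row is flagged `corrected` rather
than dropped; rows with zero observed cases are emitted with empty
statistics, never zeros.

The **information component** is the shrunken log2 observed/expected
ratio IC = log₂((N_obs+0.5)/(N_exp+0.5)) with
N_exp = N_drug·N_event/N_total; the built-in +0.5 keeps zero counts
well defined without further correction. For its credibility lower
bound the package adopts the analytic approximation

IC₀₂₅ = IC − 3.3(N_obs+0.5)^−1/2 − 2(N_obs+0.5)^−3/2,

isolated in `icLowerBound()` so a posterior-simulation alternative can
be swapped in. Published IC₀₂₅ values in this field vary with the
(often unstated) posterior method; this approximation is conservative
for small counts.

**Signal criteria**: IC₀₂₅ > 0 for the IC; ROR₀₂₅ > 1 *and* at least 3
observed cases for the ROR. IC is computed for full-database designs
only — a subgroup frame has no database-wide expected count, so
regimen-vs-regimen comparisons carry ROR alone. The default design set
mirrors the published layout: one total-ICI row, three class rows,
eight per-drug rows, three combination rows (ROR and IC), and four
subgroup comparisons (anti-PD-1 vs anti-CTLA-4, anti-PD-L1 vs
anti-CTLA-4, anti-PD-1 vs anti-PD-L1, combination vs monotherapy; ROR
only). Subgroup comparisons condition on the two compared regimens'
reports only; whether published analyses conditioned this way is
usually unstated, and this choice is the defensible two-group reading.

## Clinical comparisons

Categorical characteristics compare fatal vs non-fatal cases with the
chi-square test, no continuity correction, after dropping
unknown/missing categories and unknown-outcome reports; expected-count
adequacy (cells below 5) is reported but does not switch the test,
since the analysis convention names only chi-square. TTO uses
Mann-Whitney for two groups and Kruskal-Wallis across regimens.
Continuous age uses the t test only when a Shapiro-Wilk pre-check
(alpha 0.05) accepts normality in both groups, otherwise Mann-Whitney.
Degenerate tables (a zero margin after exclusions, fewer than two
groups) yield an explicit `untestable` result, not an error.
Significance is 0.05; the plain-text rendering prints "NS" above that
threshold.

Two percentage denominators coexist *by design*: characteristics-table
percentages use the cohort size including unknown rows (the published
convention), while the "within 30 days" share uses the documented-TTO
count. Both are exposed and named — `buildCharacteristicsTable()`
percentages versus `summarizeTto()` bin counts. Quantiles use linear
interpolation (`stats::quantile` type 7); published IQRs cannot
adjudicate the convention, so the package states its own.

## The synthetic generator

`generateDatabase()` emulates what the pipeline must survive:
case/version duplication (duplicates mutate only version and receipt
date, so deduplication correctness is observable), drug records with
role codes, brand names and dose-text noise, reactions as preferred
terms, outcome codes, demographics with realistic missingness, therapy
dates with mixed precision, and a configurable drug–event association.
The association is injected on the *odds* scale — a multiplier m
inflates the pericardial event odds of reports where the drug is
suspect — so the true reporting odds ratio of the injected pair equals
m, making parameter recovery a well-posed check. Every emitted report
has a ledger row with its ground truth (suspect set, event flag, true
TTO and fatality, duplicate flag), and `ledgerContingency()` recomputes
any registered design's 2×2 cells from the ledger; the tests require
exact agreement with the pipeline's cells up to 200,000-report
databases.

Generator defaults describe one realistic study condition and are not
tuned per test: age N(63, 10) truncated to [0, 120] with 20%
missingness, sex about 36/54/10 female/male/missing, regions dominated
by Europe/America/Asia, 78% health-professional reporters, log-normal
TTO with meanlog 3.6 and sdlog 1.0 (median ≈ 37 days), 17% fatality
among pericardial ICI cases, 5% duplicate injection, and a 1% baseline
pericardial-term probability. The simulation suites use 50,000-report
databases with 5% exposure to the target drug (200 null seeds, 100
recovery seeds at multiplier 5, observed counts around 100–120), and
the type-I-error and power studies use 500 and 100 replicates of
120–400-case cohorts; these sizes make the operating characteristics
stable while keeping the default test run fast.

What the generator does *not* emulate — free-text drug-name typos
beyond simple suffixing, MedDRA hierarchy effects, true FAERS scale
(~10⁷ reports), correlated exposures, indication-channeling bias —
bounds what passing tests show: the pipeline is correct and calibrated
on data with the declared structure, which is not evidence about
confounding or reporting bias in real spontaneous data.

## The deterministic fixture cohort

`buildTable2Fixture()` constructs 705 case records (123 fatal, 580
non-fatal, 2 unknown-outcome) whose fatal-by-characteristic cross
counts match a published characteristics table exactly, from a shipped
machine-readable copy of its counts. The published table constrains
only the per-characteristic×fatality two-way margins, not the joint
distribution, so the fixture assigns each characteristic independently
within outcome stratum by deterministic in-order repetition:
margin-exact but not unique. TTO values are bin-representative
integers (15, 45, 75, 120, 240 days) — bin membership, not medians, is
the reproducible surface. A self-audit re-derives all nine blocks on
every construction and errors citing the first mismatching block.

Every percentage that is arithmetic over the table's counts is then
exactly recomputable: gender/region/indication/outcome shares, the
within-30-days share among documented TTO (184/413 = 44.55%),
stratified fatality rates (Asia 45/201 = 22.39%, anti-CTLA-4 7/22 =
31.82%). Test statistics computed *through* the joint distribution
(the region chi-square, the TTO Mann-Whitney) depend on the
non-unique joint fill and on bin representatives, so the tests assert
their direction and significance, not exact published p-values.

## Numerical and degenerate-input choices

- Dates: invalid calendar tokens (e.g. a 30th of February) are counted
  as unparseable and become missing with a warning, never an abort.
- Empty cohorts are valid: the characteristics table renders zero
  counts without division errors, and the pipeline writes a bundle of
  empty tables with a prominent warning and success status.
- `expectedCount()` rejects a zero-size frame and margins exceeding it
  as explicit errors; `computeIc()` accepts zero observed/expected.
- Deduplication tie-breaks are total (version, then receipt date, then
  primaryid), so the retained report is unique and runs are
  byte-reproducible; all generator randomness flows from one seed.
- The command-line wrapper maps condition classes to exit codes:
  0 success (including empty results), 2 configuration error, 3 input
  error.

## Known limitations

Disproportionality is qualitative: a signal is not an incidence, and
no multiple-testing adjustment is applied (matching field practice for
this design). The MedDRA case definition is the verbatim 15-term list —
no SMQ expansion or hierarchy handling. The IC₀₂₅ approximation is one
of several published conventions and small-count values differ between
them. Occurrence country (not reporter country) defines the reporting
region. XML-dialect FAERS files and download automation are out of
scope.
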