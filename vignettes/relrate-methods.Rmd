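---
title: "Collecting expert relevance ratings of medical-record items: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collecting expert relevance ratings of medical-record items: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relrate)
```

## The problem

Clinical EMR search tools tailored to a task — say, a radiologist reading an
abdominal CT for abdominal pain — need ground truth about which record items
practitioners actually consider relevant to that task. `relrate` implements
the data-collection machinery for acquiring that ground truth: de-identified
patient *scenarios* are disassembled into individual medical-record items,
each item is shown to expert raters under the hypothetical clinical context,
and the raters' 0–3 relevance scores are collected and pooled per item.

The pipeline is deliberately organized around a strict privacy contract:
scenarios leave the extraction stage carrying no identifying information and
no path back to their source record.

## Extraction and de-identification

### The window

An index radiology exam anchors each scenario. Items of the six supported
categories (radiology reports, operative notes, laboratory results,
pathology reports, endoscopy reports, microbiology results) are retained if
their date `d` satisfies `index − w ≤ d ≤ index + w` with `w = 2` years by
default (`window_years`, whole years). Two numerical choices were open and
are fixed here:

* **Boundary inclusive at both ends.** An item dated exactly two years from
  the index exam is retained. Inclusivity is the conservative reading of a
  window stated in years, and it makes the window test exact rather than
  dependent on day-count conventions.
* **Calendar-year arithmetic.** `index ± w` is computed by shifting the year
  component (with the usual normalisation of Feb 29 targets), not by adding
  `365·w` days, so the window respects calendar anniversaries across leap
  years. Items are then compared by whole calendar dates.

Selected items are sorted ascending by date; ties keep source order (a
stable sort), giving a deterministic presentation order.

### Redaction

Redaction is an ordered list of pattern rules over exactly eight identifier
kinds: patient name, physician name, date, MRN, accession number, phone/fax,
zip, and a catch-all *other identifying number*. Matches are replaced by
bracketed kind tokens — `[NAME]`, `[DATE]`, `[ID]` — chosen so that no token
can itself match a rule, which makes redaction **idempotent** (a property
the test suite checks on generated text).

Three decisions deserve note:

* **Conservative number rule.** Any digit run of five or more characters is
  treated as an identifying number, labelled or not. Over-redaction of an
  occasional lab value is accepted as the safer failure mode; privacy is
  prioritized over fidelity of the narrative.
* **Vocabulary-based name rules.** Person names cannot be matched reliably
  by shape alone. The default rule set therefore builds its name matchers
  from the package's closed name vocabularies (the same lists the synthetic
  generator samples from) plus a physician-title pattern (`Dr. …`). On
  generated records this makes redaction provably complete; for external
  text, `redact_text()` additionally accepts a PHI manifest whose literals
  are removed as fixed strings.
* **Dates are dropped entirely; order survives.** Raters still need temporal
  sense, and chronological order is the minimal non-identifying surrogate
  for it. Relative timing beyond order (e.g. "11 months before the index
  exam") is deliberately not preserved.

### Demographics and identity

Demographics are reduced to sex and age at the index exam, with ages of 90
or more reported as 89 (`reduce_demographics()`); ages are validated into
[0, 130]. The scenario and every item receive fresh random version-4 UUIDs
at build time, and **no lookup table from UUIDs to source identifiers is
ever created** — two builds of the same record give identical texts but
disjoint UUIDs. This forecloses later enrichment of a scenario, a loss
accepted in exchange for making re-identification impossible.

`phi_audit()` is an automated stand-in for a manual residual-PHI review: it
re-scans a finished scenario against the name vocabularies and conservative
date/number patterns and reports every suspicious span deterministically. A
clean scenario yields an empty report; the CLI `audit` command exits
non-zero otherwise.

## The synthetic EMR generator

Real records cannot ship with a package, so the generator is first-class,
tested code rather than a fixture. For a fixed `(seed, params)` it produces
a byte-identical patient: demographics and identifiers (name, MRN, phone,
zip, birth date), an index abdominal-CT exam whose clinical-history string
instantiates the scenario template, and per category 2–4 additional dated
items (defaults) whose texts embed planted PHI — the patient's name, a
physician name, the item date in one of three dialects (`MM/DD/YYYY`,
`Month D, YYYY`, `YYYY-MM-DD`), an accession number, and sometimes a phone
number or zip code. Every planted literal is recorded in a manifest with its
kind and location.

Default generation parameters and their rationale:

| parameter | default | why |
|---|---|---|
| `items_per_category` | 2–4 | small but non-trivial records; 13–25 items per patient |
| `date_spread_years` | ±3 years, uniform | straddles the ±2-year window so both retained and excluded items occur; the two extreme offsets are always planted so the spread (and an out-of-window item) is guaranteed, not merely probable |
| `age_years` | 64 | typical abdominal-CT demographic; any value in [0, 130] is accepted, letting tests exercise the age cap |

Families are seeded per patient from `(seed, ordinal)` so fixtures are
reproducible item by item, and MRNs are forced distinct within a family.

**What the generator does and does not emulate.** It reproduces the
*structure* that matters to this pipeline — categories, dates around an
index exam, PHI embedded in free text, a shared clinical context — with
deliberately minimal narrative realism. PHI is drawn from closed
vocabularies; real text contains names and formats outside any list.
Passing the zero-leak suite therefore demonstrates that the redaction
machinery removes everything it can *know about*; it does not certify
performance on real clinical text, where the manifest-hint path and a human
review would still be warranted. PHI classes outside the redactor's scope
(emails, device identifiers, biometrics) are not planted and not claimed.

## Interchange schemas

Two XML formats are frozen by packaged XSD files (`inst/extdata/`), each
carrying a `schema-version` attribute: the *scenario* document (context,
sex, age ≤ 89, ordered items with UUID and category) and the *ratings*
document (one element per current rating with rater/scenario/item UUIDs,
score 0–3, its canonical label, and an ISO 8601 UTC timestamp). Reading
validates against the schema — unknown elements, out-of-domain ages or
categories, malformed UUIDs and out-of-range scores are rejected with the
offending element named — and writing validates before emitting any bytes.
Both formats round-trip exactly (`parse ∘ serialize = id`), which the test
suite checks over randomized valid documents and single-field mutations.

Scores are stored with both number and label for auditability; the label
must match the score's canonical name (0 = irrelevant, 1 = unlikely
relevant, 2 = probably relevant, 3 = certainly relevant). Exports identify
raters by UUID only.

## The rating workflow

The data model links a `ScenarioFamily` (one clinical context) to its
`Scenario`s and their items; raters (`User`) connect to families through
`RatingAssignment`s, per-scenario progress is tracked by
`RaterScenarioStatus` counters, and scores live in `ItemRating` rows —
at most one current rating per (rater, item).

Traversal is the core contract: `next_item()` serves the first unrated item
in (scenario import order, chronological item order); after a scenario's
last item the walk continues into the next scenario, and when nothing
remains a completion signal routes the rater back to their task list. The
suite checks this against an independent brute-force enumeration under
randomized rating orders, along with the coverage property: completion
appears exactly when every (rater, item) pair has a current rating.

Open design points were resolved as follows:

* **Re-rating is allowed**, last-write-wins, with the revision timestamp
  retained — annotation tools conventionally permit correction. A
  replacement never changes the items-rated count.
* **Progress is never cached stale**: `progress()` and `task_list()`
  recompute from the ratings table; the maintained status rows are checked
  against that recount in tests.
* **Persistence** is a single-file JSON store (`store_save()` /
  `store_load()`), written atomically via a rename, with one writer per
  rater session assumed. Interleaved submissions by different raters touch
  disjoint rows and cannot affect each other's status.
* **Authentication is out of scope**: raters are addressed by UUID from the
  CLI/API.
* Admin overviews abbreviate scenario UUIDs to their first 8 hex characters
  and order rows by (family name, rater name) for stable display.
* The index exam itself **is** a ratable item: it falls inside the window by
  definition, and its report is a record item like any other; its redacted
  clinical history additionally serves as the scenario context. Inclusion
  of a fuller index report in the context is left off by default.

## Pooling

`pool_ratings()` emits one row per item with ≥ 1 rating: number of raters,
mean, median, and the full 0–3 histogram. No single pooling statistic is
imposed — the downstream consumer (search-strategy design) may weight a
bimodal item differently from a uniformly "probably relevant" one, so all
three are reported. Items with zero ratings are listed separately (the
`unrated` attribute) rather than dropped silently: "unrated" must never be
conflated with "rated irrelevant". Because a shared clinical context could
also be summarized per item *kind*, `pool_by_category()` emits the
secondary per-category table. Ranking (`rank_items()`) is a stable
descending sort with ties resolved by (scenario order, item order).

Pooling is permutation-invariant in rating order and conserves histogram
marginals; both are tested against independent recomputation from the raw
tuples.

## Problem sizes and verification

The shipped suites run on sizes chosen to exercise every boundary while
staying quick to verify: the zero-leak property is quantified over 100
seeded patients (about 2,000 planted literals), traversal and pooling
oracles over randomized families of 1–3 scenarios × 1–5 items with 2–3
raters, and round-trips over dozens of randomized documents.
`scripts/acceptance.R` recomputes the headline quantities (age cap output,
number of rating levels, maximum retained window offset, leak count over
120 patients, traversal/round-trip/pooling error counts) from scratch
against the installed package.

## Known limitations

* Rule-based redaction with closed vocabularies is not a general clinical
  de-identifier; no statistical NER is attempted, and scanned documents and
  images are out of scope.
* Inter-rater reliability statistics (e.g. κ) and search-strategy learning
  are downstream of this package and deliberately excluded.
* The store targets single-site studies; multi-site federation and secure
  exchange are not implemented.
* Assignment revocation is not modelled; an assignment, once made, persists.
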