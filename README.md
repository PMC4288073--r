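# relrate

Task-specific EMR search tools and user interfaces have to be designed from
data about what practitioners actually need: which parts of a patient's
electronic medical record (EMR) matter for a given clinical task. `relrate`
implements a complete pipeline for collecting that data from expert raters —
without ever touching a real EMR — for clinical informaticists building
relevance-rating studies and the search strategies downstream of them.

The pipeline has three stages:

1. **Extraction and de-identification.** Around an *index* radiology exam
   (e.g. an abdominal CT for abdominal pain), record items of six kinds —
   radiology reports, operative notes, laboratory results, pathology reports,
   endoscopy reports, microbiology results — are selected within a window of
   ±2 years of the index exam, boundary inclusive. Every item text is
   rule-redacted: patient and physician names, any dates (three dialects),
   and all identifying numbers (MRNs, accession numbers, phone/fax numbers,
   zip codes, any digit run ≥ 5) are replaced by `[NAME]` / `[DATE]` / `[ID]`
   tokens. Demographics are reduced to sex and age, with ages ≥ 90 reported
   as 89. The scenario and each item receive fresh random version-4 UUIDs and
   no lookup table is kept, so re-identification is impossible by
   construction. The result is a *scenario* XML document validating against a
   packaged schema.
2. **Rating collection.** Scenarios are grouped into *scenario families*
   (one shared clinical context). Registered raters are assigned to families;
   the workflow serves each rater the next unrated item (scenario order, then
   chronological item order), records 0–3 relevance scores — *irrelevant*,
   *unlikely relevant*, *probably relevant*, *certainly relevant* — with
   auto-advance and completion routing, tracks per-scenario progress, and
   exports the collected scores as a *ratings* XML document.
3. **Pooling.** Per-item ratings are pooled across raters into mean, median,
   and the full 0–3 score histogram (plus a per-category table), ranked for
   downstream search-strategy design.

Because real records cannot be shared, the package includes a first-class
synthetic-EMR generator: seeded, deterministic patients whose texts embed
planted PHI drawn from closed vocabularies, every literal recorded in a
ground-truth *manifest*. The manifest makes the redactor's zero-leak property
testable, item by item, seed by seed.

## Worked example

```r
library(relrate)
set.seed(2026)

# Two synthetic patients sharing one clinical context
srcs <- generate_family_sources(2, seed = 7)

sc1 <- build_scenario(srcs[[1]]$record)
sc1$age_years
#> [1] 64
strwrap(sc1$context, 78)[1:3]
#> Patient: [NAME]. MRN: [ID]. Date of service: [DATE]. Accession: [ID].
#> Abdominal CT ordered for a 64-year-old patient with abdominal pain. Questions
#> to the office at [ID]. Electronically signed by Dr. [NAME].
nrow(phi_audit(sc1))   # residual PHI-like spans after redaction
#> [1] 0

# Import into the rating store, register a rater, assign, and rate
store <- rating_store()
for (g in srcs)
  import_scenario(store, "abdominal CT for abdominal pain",
                  scenario_document(build_scenario(g$record)))
fam <- store$families$family_uuid[1]
u <- register_rater(store, "Dr. Example")
assign_rater(store, u$user_uuid, fam)

nx <- next_item(store, u$user_uuid, fam)
nx$item$category; nx$item_position; nx$n_items
#> [1] "radiology_report"
#> [1] 1
#> [1] 12
while (!is_complete(nx)) {
  record_rating(store, u$user_uuid, nx$item$item_uuid, sample(0:3, 1))
  nx <- next_item(store, u$user_uuid, fam)
}
task_list(store, u$user_uuid)[, c("scenarios_complete", "scenarios_total",
                                  "items_rated", "items_total")]
#>   scenarios_complete scenarios_total items_rated items_total
#> 1                  2               2          25          25

# Export and pool
doc <- export_ratings(store, fam)
pooled <- pool_ratings(doc, scenario_family(store, fam))
head(rank_items(pooled, by = "mean")[, c("category", "n_raters",
                                         "mean_score", "median_score")], 2)
#>            category n_raters mean_score median_score
#> 1 laboratory_result        1          3            3
#> 2    operative_note        1          3            3
```

The `age_years` of 64 is the patient's age at the index exam; ages of 90 or
more would print as 89. The context shows every planted identifier replaced
by its redaction token. The task list confirms both scenarios (25 items
total) are fully rated, and the pooled table ranks items by mean relevance.

A command-line front end wraps the same functions
(`Rscript $(Rscript -e 'cat(system.file("cli", "relrate.R", package="relrate"))') synth --n-patients 2 --seed 7 --out sources/`,
then `extract`, `audit`, `validate`, `import`, `register`, `assign`,
`tasks`, `rate`, `status`, `export`, `pool`; see `?relrate_main`).

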