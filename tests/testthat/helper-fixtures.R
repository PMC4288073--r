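# Fixtures are built in code: hand-assembled records with known date offsets,
# small scenario families, and randomized valid documents for round-trip and
# oracle checks.

source_item <- function(category, date, text, accession = "00000000") {
  structure(list(category = category, date = as.Date(date), text = text,
                 source_accession = accession), class = "source_item")
}

# A record whose non-index items sit at whole-year offsets from the index
# exam; item text carries its offset so selections can be identified later.
make_offset_record <- function(offsets_years,
                               index_date = as.Date("2013-06-15"),
                               age = 60L, sex = "M") {
  items <- list(source_item("radiology_report", index_date,
                            "index exam clinical history"))
  for (k in seq_along(offsets_years)) {
    d <- relrate:::add_years(index_date, offsets_years[k])
    items[[k + 1L]] <- source_item("laboratory_result", d,
                                   sprintf("offset %+d years", offsets_years[k]))
  }
  structure(list(
    format_version = "1", patient_name = "Test Patient", sex = sex,
    birth_date = relrate:::add_years(index_date, -age), mrn = "9999999",
    phone = "(617) 555-0000", zip = "02114", index_item = 1L, items = items
  ), class = "source_patient_record")
}

make_scenario <- function(n_items = 3L, age = 45L, sex = "F") {
  items <- lapply(seq_len(n_items), function(j) {
    relrate:::new_deid_item(uuid4(),
                            item_categories()[(j - 1L) %% 6L + 1L],
                            sprintf("redacted item text %d", j))
  })
  relrate:::new_scenario(uuid4(), "context: abdominal CT, abdominal pain",
                         sex, age, items)
}

# Store preloaded with one family of n_scenarios x n_items and n_raters
# assigned raters.
make_test_store <- function(n_scenarios = 2L, n_items = 3L, n_raters = 1L,
                            family_name = "abdominal CT for abdominal pain") {
  store <- rating_store()
  for (k in seq_len(n_scenarios)) {
    import_scenario(store, family_name,
                    scenario_document(make_scenario(n_items)))
  }
  raters <- lapply(seq_len(n_raters), function(i) {
    register_rater(store, sprintf("Rater %d", i))
  })
  fam <- store$families$family_uuid[1L]
  for (u in raters) assign_rater(store, u$user_uuid, fam)
  list(store = store, family_uuid = fam,
       raters = vapply(raters, `[[`, "", "user_uuid"))
}

# Independent traversal oracle for next_item: first unrated item in
# (scenario import order, item order), read straight off the store tables.
brute_force_next <- function(store, user_uuid, family_uuid) {
  sc <- store$scenarios[store$scenarios$family_uuid == family_uuid, ,
                        drop = FALSE]
  sc <- sc[order(sc$scenario_order), , drop = FALSE]
  rated <- store$ratings$item_uuid[store$ratings$user_uuid == user_uuid]
  for (su in sc$scenario_uuid) {
    it <- store$items[store$items$scenario_uuid == su, , drop = FALSE]
    it <- it[order(it$item_order), , drop = FALSE]
    for (iu in it$item_uuid) if (!(iu %in% rated)) return(iu)
  }
  NULL
}

all_family_item_uuids <- function(store, family_uuid) {
  sc <- store$scenarios[store$scenarios$family_uuid == family_uuid, ,
                        drop = FALSE]
  sc <- sc[order(sc$scenario_order), , drop = FALSE]
  unlist(lapply(sc$scenario_uuid, function(su) {
    it <- store$items[store$items$scenario_uuid == su, , drop = FALSE]
    it$item_uuid[order(it$item_order)]
  }))
}

random_scenario_document <- function(with_family = runif(1) < 0.5) {
  s <- make_scenario(n_items = sample(0:5, 1L),
                     age = sample(0:89, 1L),
                     sex = sample(c("M", "F"), 1L))
  scenario_document(s, family_uuid = if (with_family) uuid4())
}

random_ratings_document <- function(n_raters = sample(1:3, 1L),
                                    n_items = sample(1:6, 1L)) {
  raters <- uuid4(n_raters)
  scenario <- uuid4()
  items <- uuid4(n_items)
  grid <- expand.grid(r = raters, i = items, stringsAsFactors = FALSE)
  grid <- grid[runif(nrow(grid)) < 0.8, , drop = FALSE]
  scores <- sample(0:3, nrow(grid), replace = TRUE)
  ratings <- data.frame(
    rater_uuid = grid$r, scenario_uuid = scenario, item_uuid = grid$i,
    score = as.integer(scores), label = score_label(scores),
    recorded_at = format(as.POSIXct("2026-01-01", tz = "UTC") +
                           sample(0:1e6, nrow(grid)),
                         "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    stringsAsFactors = FALSE)
  ratings_document(uuid4(), "randomized family", ratings)
}

scan_for_leaks <- function(scenario, manifest) {
  texts <- c(scenario$context,
             vapply(scenario$items, `[[`, "", "text"))
  manifest$literal[vapply(manifest$literal,
                          function(l) any(grepl(l, texts, fixed = TRUE)),
                          logical(1))]
}
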