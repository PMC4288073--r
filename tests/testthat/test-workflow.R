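test_that("imports create families, preserve order, and reject duplicates", {
  store <- rating_store()
  d1 <- scenario_document(make_scenario())
  d2 <- scenario_document(make_scenario())
  import_scenario(store, "fam A", d1)
  fam <- import_scenario(store, "fam A", d2)
  expect_identical(fam$n_scenarios, 2L)
  sc <- relrate:::family_scenarios(store, fam$family_uuid)
  expect_identical(sc$scenario_uuid,
                   c(d1$scenario$scenario_uuid, d2$scenario$scenario_uuid))

  expect_error(import_scenario(store, "fam A", d1),
               class = "relrate_conflict")
  expect_error(import_scenario(store, "fam B", d1),
               class = "relrate_conflict")

  before <- nrow(store$scenarios)
  import_scenario(store, "fam A", scenario_document(make_scenario()))
  expect_identical(nrow(store$scenarios), before + 1L)
})

test_that("rater registration issues fresh retrievable UUIDs", {
  store <- rating_store()
  u1 <- register_rater(store, "Same Name")
  u2 <- register_rater(store, "Same Name")
  expect_false(u1$user_uuid == u2$user_uuid)
  expect_identical(nrow(store$users), 2L)
  expect_identical(
    store$users$display_name[match(u1$user_uuid, store$users$user_uuid)],
    "Same Name")
  expect_error(register_rater(store, ""), class = "relrate_param_error")
})

test_that("assignment is idempotent and validated", {
  tf <- make_test_store(n_raters = 1L)
  store <- tf$store
  u <- tf$raters[1L]
  a1 <- assign_rater(store, u, tf$family_uuid)
  expect_identical(sum(store$assignments$user_uuid == u), 1L)
  expect_identical(a1$family_uuid, tf$family_uuid)

  import_scenario(store, "second family", scenario_document(make_scenario()))
  fam2 <- store$families$family_uuid[2L]
  assign_rater(store, u, fam2)
  expect_identical(nrow(task_list(store, u)), 2L)

  expect_error(assign_rater(store, u, uuid4()), class = "relrate_not_found")
  expect_error(assign_rater(store, uuid4(), tf$family_uuid),
               class = "relrate_not_found")
})

test_that("the task list reflects live progress", {
  tf <- make_test_store(n_scenarios = 2L, n_items = 3L, n_raters = 1L)
  store <- tf$store
  u <- tf$raters[1L]
  tl <- task_list(store, u)
  expect_identical(tl$items_rated, 0L)
  expect_identical(tl$items_total, 6L)
  expect_false(tl$complete)

  for (iu in all_family_item_uuids(store, tf$family_uuid)) {
    record_rating(store, u, iu, 2L)
  }
  tl <- task_list(store, u)
  expect_identical(tl$items_rated, 6L)
  expect_identical(tl$scenarios_complete, 2L)
  expect_true(tl$complete)

  other <- register_rater(store, "Unassigned")
  expect_identical(nrow(task_list(store, other$user_uuid)), 0L)
})

test_that("next_item auto-advances across scenarios and signals completion", {
  tf <- make_test_store(n_scenarios = 2L, n_items = 3L, n_raters = 1L)
  store <- tf$store
  u <- tf$raters[1L]
  # rate the whole first scenario: the walk moves to scenario 2, item 1
  for (k in 1:3) {
    nx <- next_item(store, u, tf$family_uuid)
    expect_identical(nx$scenario_position, 1L)
    record_rating(store, u, nx$item$item_uuid, 1L)
  }
  nx <- next_item(store, u, tf$family_uuid)
  expect_identical(nx$scenario_position, 2L)
  expect_identical(nx$item_position, 1L)
  expect_identical(nx$items_rated_family, 3L)
  expect_identical(nx$items_total_family, 6L)

  for (k in 1:3) {
    nx <- next_item(store, u, tf$family_uuid)
    record_rating(store, u, nx$item$item_uuid, 3L)
  }
  expect_true(is_complete(next_item(store, u, tf$family_uuid)))

  stranger <- register_rater(store, "No Assignment")
  expect_error(next_item(store, stranger$user_uuid, tf$family_uuid),
               class = "relrate_auth_error")
})

test_that("next_item equals the brute-force first-unrated oracle on random subsets", {
  withr::with_seed(41, {
    for (rep in 1:8) {
      tf <- make_test_store(n_scenarios = sample(1:3, 1L),
                            n_items = sample(1:4, 1L), n_raters = 1L)
      store <- tf$store
      u <- tf$raters[1L]
      all_items <- all_family_item_uuids(store, tf$family_uuid)
      subset <- sample(all_items, sample(0:length(all_items), 1L))
      for (iu in subset) record_rating(store, u, iu, sample(0:3, 1L))
      expected <- brute_force_next(store, u, tf$family_uuid)
      got <- next_item(store, u, tf$family_uuid)
      if (is.null(expected)) {
        expect_true(is_complete(got))
      } else {
        expect_identical(got$item$item_uuid, expected)
      }
    }
  })
})

test_that("ratings are validated, counted once, and replaced on re-rating", {
  tf <- make_test_store(n_scenarios = 1L, n_items = 3L, n_raters = 1L)
  store <- tf$store
  u <- tf$raters[1L]
  items <- all_family_item_uuids(store, tf$family_uuid)

  expect_error(record_rating(store, u, items[1L], 4L),
               class = "relrate_domain_error")
  expect_error(record_rating(store, u, items[1L], -1L),
               class = "relrate_domain_error")
  expect_error(record_rating(store, u, uuid4(), 2L),
               class = "relrate_not_found")

  r1 <- record_rating(store, u, items[1L], 1L, at = "2026-01-01T00:00:00Z")
  expect_identical(r1$label, "unlikely relevant")
  st <- store$status[store$status$user_uuid == u, ]
  expect_identical(st$items_rated, 1L)

  r2 <- record_rating(store, u, items[1L], 3L, at = "2026-01-02T00:00:00Z")
  expect_identical(r2$score, 3L)
  st <- store$status[store$status$user_uuid == u, ]
  expect_identical(st$items_rated, 1L)  # replacement does not recount
  row <- store$ratings[store$ratings$item_uuid == items[1L], ]
  expect_identical(nrow(row), 1L)
  expect_identical(row$score, 3L)
  expect_identical(row$revised_at, "2026-01-02T00:00:00Z")

  # items_rated increments by exactly one per fresh rating until complete
  for (k in 2:3) {
    record_rating(store, u, items[k], 0L)
    st <- store$status[store$status$user_uuid == u, ]
    expect_identical(st$items_rated, k)
  }
  expect_true(st$complete)

  outsider <- register_rater(store, "Outsider")
  expect_error(record_rating(store, outsider$user_uuid, items[1L], 1L),
               class = "relrate_auth_error")
})

test_that("progress is recomputed from the rating store and matches a recount", {
  withr::with_seed(43, {
    tf <- make_test_store(n_scenarios = 3L, n_items = 4L, n_raters = 1L)
    store <- tf$store
    u <- tf$raters[1L]
    p0 <- progress(store, u, tf$family_uuid)
    expect_identical(sum(p0$per_scenario$items_rated), 0L)
    expect_identical(p0$overall_fraction, 0)

    items <- all_family_item_uuids(store, tf$family_uuid)
    subset <- sample(items, 7L)
    for (iu in subset) record_rating(store, u, iu, sample(0:3, 1L))
    p <- progress(store, u, tf$family_uuid)
    # oracle: full scan of the ratings table
    for (k in seq_len(nrow(p$per_scenario))) {
      su <- p$per_scenario$scenario_uuid[k]
      in_scenario <- store$items$item_uuid[store$items$scenario_uuid == su]
      rated <- store$ratings$item_uuid[store$ratings$user_uuid == u]
      expect_identical(p$per_scenario$items_rated[k],
                       sum(in_scenario %in% rated))
    }
    expect_identical(p$overall_fraction, 7 / 12)
    # the maintained status rows agree with the recount
    for (k in seq_len(nrow(p$per_scenario))) {
      st <- store$status[store$status$user_uuid == u &
                           store$status$scenario_uuid ==
                             p$per_scenario$scenario_uuid[k], ]
      if (nrow(st) > 0L) {
        expect_identical(st$items_rated, p$per_scenario$items_rated[k])
      }
    }

    for (iu in setdiff(items, subset)) record_rating(store, u, iu, 1L)
    expect_identical(progress(store, u, tf$family_uuid)$overall_fraction, 1)
  })
})

test_that("interleaved raters never affect each other's progress", {
  withr::with_seed(44, {
    tf <- make_test_store(n_scenarios = 2L, n_items = 3L, n_raters = 2L)
    store <- tf$store
    items <- all_family_item_uuids(store, tf$family_uuid)
    plan <- data.frame(u = sample(rep(tf$raters, each = length(items))),
                       stringsAsFactors = FALSE)
    cursor <- c(0L, 0L)
    names(cursor) <- tf$raters
    for (u in plan$u) {
      cursor[u] <- cursor[u] + 1L
      record_rating(store, u, items[cursor[u]], sample(0:3, 1L))
    }
    for (u in tf$raters) {
      expect_identical(progress(store, u, tf$family_uuid)$overall_fraction, 1)
    }
    # exactly one current rating per (rater, item)
    expect_identical(anyDuplicated(store$ratings[c("user_uuid", "item_uuid")]),
                     0L)
  })
})

test_that("a rate-then-advance session visits every item exactly once", {
  tf <- make_test_store(n_scenarios = 3L, n_items = 3L, n_raters = 1L)
  store <- tf$store
  u <- tf$raters[1L]
  seen <- character(0)
  repeat {
    nx <- next_item(store, u, tf$family_uuid)
    if (is_complete(nx)) break
    seen <- c(seen, nx$item$item_uuid)
    record_rating(store, u, nx$item$item_uuid, 2L)
  }
  expect_identical(seen, all_family_item_uuids(store, tf$family_uuid))
  expect_identical(anyDuplicated(seen), 0L)
})

test_that("the admin overview lists families, raters, and abbreviated UUIDs", {
  expect_identical(nrow(admin_overview(rating_store())), 0L)

  tf <- make_test_store(n_scenarios = 2L, n_items = 2L, n_raters = 2L)
  store <- tf$store
  ov <- admin_overview(store)
  expect_identical(nrow(ov), 2L)
  expect_identical(ov$rater_name, sort(ov$rater_name))
  abbrevs <- strsplit(ov$scenarios[1L], ",")[[1]]
  expect_identical(nchar(abbrevs), rep(8L, 2L))
  expect_true(all(vapply(seq_along(abbrevs), function(k) {
    startsWith(relrate:::family_scenarios(store, tf$family_uuid)$scenario_uuid[k],
               abbrevs[k])
  }, logical(1))))

  record_rating(store, tf$raters[1L],
                all_family_item_uuids(store, tf$family_uuid)[1L], 3L)
  ov <- admin_overview(store)
  expect_identical(sort(ov$items_rated), c(0L, 1L))
  expect_identical(ov$items_total, c(4L, 4L))
})

test_that("exports carry one current rating per pair and round-trip scores", {
  tf <- make_test_store(n_scenarios = 2L, n_items = 3L, n_raters = 2L)
  store <- tf$store
  expect_identical(nrow(export_ratings(store, tf$family_uuid)$ratings), 0L)
  expect_error(export_ratings(store, uuid4()), class = "relrate_not_found")

  items <- all_family_item_uuids(store, tf$family_uuid)
  scores <- list()
  withr::with_seed(45, {
    for (u in tf$raters) for (iu in items) {
      s <- sample(0:3, 1L)
      scores[[paste(u, iu)]] <- s
      record_rating(store, u, iu, s)
    }
  })
  # re-rate one item; the export must carry exactly the latest score
  record_rating(store, tf$raters[1L], items[2L], 3L)
  scores[[paste(tf$raters[1L], items[2L])]] <- 3L

  doc <- export_ratings(store, tf$family_uuid)
  expect_identical(nrow(doc$ratings), 2L * 6L)
  for (k in seq_len(nrow(doc$ratings))) {
    key <- paste(doc$ratings$rater_uuid[k], doc$ratings$item_uuid[k])
    expect_identical(doc$ratings$score[k], as.integer(scores[[key]]))
  }

  path <- withr::local_tempfile(fileext = ".ratings.xml")
  write_ratings_xml(doc, path)
  expect_identical(read_ratings_xml(path), doc)
})

test_that("the store persists losslessly through its JSON file", {
  tf <- make_test_store(n_scenarios = 2L, n_items = 2L, n_raters = 2L)
  store <- tf$store
  items <- all_family_item_uuids(store, tf$family_uuid)
  record_rating(store, tf$raters[1L], items[1L], 2L)
  path <- withr::local_tempfile(fileext = ".json")
  store_save(store, path)
  store2 <- store_load(path)
  for (nm in c("families", "scenarios", "items", "users", "assignments",
               "ratings", "status")) {
    expect_identical(get(nm, store2), get(nm, store), label = nm)
  }
  expect_identical(export_ratings(store2, tf$family_uuid),
                   export_ratings(store, tf$family_uuid))
})
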