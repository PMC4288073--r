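## Rating-collection workflow: the data model links ScenarioFamily ->
## Scenario -> MedicalRecordItem, raters (User) to families via
## RatingAssignment, per-rater progress via RaterScenarioStatus, and scores
## via ItemRating. The store is an in-memory set of tables with whole-store
## save/load to a single JSON file; every operation leaves the store
## consistent, and one writer per rater session is assumed.

store_tables <- function() {
  list(
    families = data.frame(family_uuid = character(0), name = character(0),
                          stringsAsFactors = FALSE),
    scenarios = data.frame(family_uuid = character(0),
                           scenario_uuid = character(0),
                           scenario_order = integer(0),
                           context = character(0), sex = character(0),
                           age_years = integer(0), stringsAsFactors = FALSE),
    items = data.frame(scenario_uuid = character(0), item_uuid = character(0),
                       item_order = integer(0), category = character(0),
                       text = character(0), stringsAsFactors = FALSE),
    users = data.frame(user_uuid = character(0), display_name = character(0),
                       registration_info = character(0),
                       stringsAsFactors = FALSE),
    assignments = data.frame(user_uuid = character(0),
                             family_uuid = character(0),
                             assigned_at = character(0),
                             stringsAsFactors = FALSE),
    ratings = data.frame(user_uuid = character(0), item_uuid = character(0),
                         score = integer(0), label = character(0),
                         recorded_at = character(0), revised_at = character(0),
                         seq = integer(0), stringsAsFactors = FALSE),
    status = data.frame(user_uuid = character(0), scenario_uuid = character(0),
                        items_rated = integer(0), complete = logical(0),
                        stringsAsFactors = FALSE)
  )
}

#' Create a rating-collection store
#'
#' An empty store holding scenario families, scenarios, items, raters,
#' assignments, ratings and per-rater scenario progress. Use
#' [store_save()] / [store_load()] to persist it as a single JSON file.
#'
#' @return A `rating_store` object.
#' @export
#' @examples
#' store <- rating_store()
rating_store <- function() {
  env <- new.env(parent = emptyenv())
  for (nm in names(store_tables())) assign(nm, store_tables()[[nm]], env)
  env$seq <- 0L
  structure(env, class = "rating_store")
}

#' @export
print.rating_store <- function(x, ...) {
  cat(sprintf(
    "<rating_store> %d families, %d scenarios, %d items, %d raters, %d ratings\n",
    nrow(x$families), nrow(x$scenarios), nrow(x$items), nrow(x$users),
    nrow(x$ratings)))
  invisible(x)
}

#' Save / load a rating store as a single JSON file
#'
#' The whole store is written atomically (to a temporary file, then renamed
#' into place), so a reader never observes a partial write.
#'
#' @param store A `rating_store`.
#' @param path File path.
#' @return `store_save()` returns `path` invisibly; `store_load()` returns a
#'   `rating_store`.
#' @export
store_save <- function(store, path) {
  payload <- c(lapply(names(store_tables()),
                      function(nm) as.data.frame(get(nm, store))),
               list(store$seq))
  names(payload) <- c(names(store_tables()), "seq")
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(payload, tmp, auto_unbox = FALSE, digits = NA,
                       dataframe = "rows", na = "null")
  file.rename(tmp, path)
  invisible(path)
}

#' @rdname store_save
#' @export
store_load <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  store <- rating_store()
  templates <- store_tables()
  for (nm in names(templates)) {
    tab <- raw[[nm]]
    if (is.null(tab) || length(tab) == 0L || NROW(tab) == 0L) next
    tmpl <- templates[[nm]]
    for (col in names(tmpl)) {
      tab[[col]] <- if (is.integer(tmpl[[col]])) as.integer(tab[[col]])
      else if (is.logical(tmpl[[col]])) as.logical(tab[[col]])
      else as.character(tab[[col]])
    }
    assign(nm, tab[names(tmpl)], store)
  }
  store$seq <- as.integer(raw$seq %||% 0L)
  store
}

find_family <- function(store, family_uuid, required = TRUE) {
  i <- match(family_uuid, store$families$family_uuid)
  if (is.na(i) && required) {
    relrate_abort(sprintf("unknown scenario family '%s'", family_uuid),
                  "relrate_not_found")
  }
  i
}

find_user <- function(store, user_uuid, required = TRUE) {
  i <- match(user_uuid, store$users$user_uuid)
  if (is.na(i) && required) {
    relrate_abort(sprintf("unknown user '%s'", user_uuid),
                  "relrate_not_found")
  }
  i
}

## Family scenarios in import order; their items in item order.
family_scenarios <- function(store, family_uuid) {
  sc <- store$scenarios[store$scenarios$family_uuid == family_uuid, ,
                        drop = FALSE]
  sc[order(sc$scenario_order), , drop = FALSE]
}

scenario_items <- function(store, scenario_uuid) {
  it <- store$items[store$items$scenario_uuid == scenario_uuid, ,
                    drop = FALSE]
  it[order(it$item_order), , drop = FALSE]
}

family_items <- function(store, family_uuid) {
  sc <- family_scenarios(store, family_uuid)
  do.call(rbind, c(lapply(sc$scenario_uuid,
                          function(u) scenario_items(store, u)),
                   list(store$items[0, , drop = FALSE])))
}

#' Import a scenario document into a family
#'
#' De-identified scenario documents are imported into the store under a named
#' scenario family (the shared clinical context). The family is created with
#' a fresh UUID on first use; subsequent imports under the same name append,
#' preserving import order as scenario order. Re-importing a scenario UUID
#' already present anywhere in the store is a conflict.
#'
#' @param store A `rating_store`.
#' @param family_name Family display name, e.g. "abdominal CT for abdominal
#'   pain".
#' @param doc A `scenario_document`.
#' @return The family's row (list with `family_uuid`, `name`,
#'   `n_scenarios`), invisibly.
#' @export
import_scenario <- function(store, family_name, doc) {
  validate_scenario_document(doc)
  s <- doc$scenario
  if (s$scenario_uuid %in% store$scenarios$scenario_uuid) {
    relrate_abort(sprintf("scenario '%s' already imported", s$scenario_uuid),
                  "relrate_conflict")
  }
  i <- match(family_name, store$families$name)
  if (is.na(i)) {
    family_uuid <- doc$family_uuid %||% uuid4()
    store$families <- rbind(store$families,
                            data.frame(family_uuid = family_uuid,
                                       name = family_name,
                                       stringsAsFactors = FALSE))
  } else {
    family_uuid <- store$families$family_uuid[i]
  }
  ord <- sum(store$scenarios$family_uuid == family_uuid) + 1L
  store$scenarios <- rbind(store$scenarios, data.frame(
    family_uuid = family_uuid, scenario_uuid = s$scenario_uuid,
    scenario_order = ord, context = s$context, sex = s$sex,
    age_years = as.integer(s$age_years), stringsAsFactors = FALSE))
  if (length(s$items) > 0L) {
    store$items <- rbind(store$items, data.frame(
      scenario_uuid = s$scenario_uuid,
      item_uuid = vapply(s$items, `[[`, "", "item_uuid"),
      item_order = seq_along(s$items),
      category = vapply(s$items, `[[`, "", "category"),
      text = vapply(s$items, `[[`, "", "text"),
      stringsAsFactors = FALSE))
  }
  invisible(list(family_uuid = family_uuid, name = family_name,
                 n_scenarios = ord))
}

#' Register an expert rater
#'
#' Creates a User with a fresh UUID. Display names need not be unique; the
#' UUID is the identity.
#'
#' @param store A `rating_store`.
#' @param display_name Non-empty rater name.
#' @param registration_info Free-text registration details.
#' @return List with `user_uuid`, `display_name`, `registration_info`.
#' @export
register_rater <- function(store, display_name, registration_info = "") {
  if (!is.character(display_name) || length(display_name) != 1L ||
      !nzchar(display_name)) {
    relrate_abort("display_name must be non-empty", "relrate_param_error")
  }
  user <- list(user_uuid = uuid4(), display_name = display_name,
               registration_info = registration_info)
  store$users <- rbind(store$users,
                       data.frame(user, stringsAsFactors = FALSE))
  user
}

#' Assign a rater to a scenario family
#'
#' Idempotent: re-assigning returns the existing assignment.
#'
#' @param store A `rating_store`.
#' @param user_uuid Rater UUID.
#' @param family_uuid Family UUID.
#' @param at Assignment timestamp (ISO 8601 UTC; defaults to now).
#' @return List with `user_uuid`, `family_uuid`, `assigned_at`.
#' @export
assign_rater <- function(store, user_uuid, family_uuid, at = NULL) {
  find_user(store, user_uuid)
  find_family(store, family_uuid)
  hit <- store$assignments$user_uuid == user_uuid &
    store$assignments$family_uuid == family_uuid
  if (any(hit)) {
    a <- store$assignments[which(hit)[1L], ]
    return(list(user_uuid = a$user_uuid, family_uuid = a$family_uuid,
                assigned_at = a$assigned_at))
  }
  a <- list(user_uuid = user_uuid, family_uuid = family_uuid,
            assigned_at = at %||% iso_utc_now())
  store$assignments <- rbind(store$assignments,
                             data.frame(a, stringsAsFactors = FALSE))
  a
}

is_assigned <- function(store, user_uuid, family_uuid) {
  any(store$assignments$user_uuid == user_uuid &
        store$assignments$family_uuid == family_uuid)
}

user_rated_items <- function(store, user_uuid) {
  store$ratings$item_uuid[store$ratings$user_uuid == user_uuid]
}

family_progress_counts <- function(store, user_uuid, family_uuid) {
  sc <- family_scenarios(store, family_uuid)
  rated <- user_rated_items(store, user_uuid)
  per <- lapply(sc$scenario_uuid, function(u) {
    it <- scenario_items(store, u)
    n_rated <- sum(it$item_uuid %in% rated)
    data.frame(scenario_uuid = u, items_rated = n_rated,
               items_total = nrow(it),
               complete = n_rated == nrow(it) & nrow(it) > 0L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(per, list(data.frame(scenario_uuid = character(0),
                                        items_rated = integer(0),
                                        items_total = integer(0),
                                        complete = logical(0)))))
}

#' A rater's task list
#'
#' One row per family assignment, in assignment order, with progress:
#' scenarios completed / total and items rated / total, recomputed from the
#' rating store (never cached).
#'
#' @param store A `rating_store`.
#' @param user_uuid Rater UUID.
#' @return Data frame with columns family_uuid, family_name,
#'   scenarios_complete, scenarios_total, items_rated, items_total, complete.
#' @export
task_list <- function(store, user_uuid) {
  find_user(store, user_uuid)
  a <- store$assignments[store$assignments$user_uuid == user_uuid, ,
                         drop = FALSE]
  rows <- lapply(a$family_uuid, function(fu) {
    per <- family_progress_counts(store, user_uuid, fu)
    data.frame(
      family_uuid = fu,
      family_name = store$families$name[find_family(store, fu)],
      scenarios_complete = sum(per$complete),
      scenarios_total = nrow(per),
      items_rated = sum(per$items_rated),
      items_total = sum(per$items_total),
      complete = nrow(per) > 0L && all(per$complete),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, list(data.frame(
    family_uuid = character(0), family_name = character(0),
    scenarios_complete = integer(0), scenarios_total = integer(0),
    items_rated = integer(0), items_total = integer(0),
    complete = logical(0)))))
}

#' Serve the next unrated item for a rater
#'
#' Returns the first item the rater has not yet rated, walking scenarios in
#' import order and items in presentation (chronological) order; after a
#' scenario's last item the walk continues with the first unrated item of the
#' next scenario. When every item in the family has been rated, a completion
#' signal (`relrate_completion`) is returned instead — the rater is done with
#' this assignment. Position indicators report progress within the current
#' scenario and across the family.
#'
#' @param store A `rating_store`.
#' @param user_uuid Rater UUID (must be assigned to the family).
#' @param family_uuid Family UUID.
#' @return A `relrate_next_item` list (`context`, `item`, position fields) or
#'   a `relrate_completion` object; test with [is_complete()].
#' @export
next_item <- function(store, user_uuid, family_uuid) {
  find_user(store, user_uuid)
  find_family(store, family_uuid)
  if (!is_assigned(store, user_uuid, family_uuid)) {
    relrate_abort("user is not assigned to this scenario family",
                  "relrate_auth_error")
  }
  sc <- family_scenarios(store, family_uuid)
  rated <- user_rated_items(store, user_uuid)
  fam_it <- family_items(store, family_uuid)
  n_family <- nrow(fam_it)
  rated_family <- sum(fam_it$item_uuid %in% rated)
  for (k in seq_len(nrow(sc))) {
    it <- scenario_items(store, sc$scenario_uuid[k])
    unrated <- which(!(it$item_uuid %in% rated))
    if (length(unrated) > 0L) {
      j <- unrated[1L]
      return(structure(list(
        family_uuid = family_uuid,
        scenario_uuid = sc$scenario_uuid[k],
        context = sc$context[k],
        sex = sc$sex[k], age_years = sc$age_years[k],
        item = list(item_uuid = it$item_uuid[j], category = it$category[j],
                    text = it$text[j]),
        scenario_position = k, n_scenarios = nrow(sc),
        item_position = j, n_items = nrow(it),
        items_rated_scenario = j - 1L,
        items_rated_family = rated_family,
        items_total_family = n_family
      ), class = "relrate_next_item"))
    }
  }
  structure(list(family_uuid = family_uuid, complete = TRUE),
            class = "relrate_completion")
}

#' Test for the completion signal
#'
#' @param x Result of [next_item()].
#' @return `TRUE` if `x` is a completion signal.
#' @export
is_complete <- function(x) inherits(x, "relrate_completion")

update_status <- function(store, user_uuid, scenario_uuid) {
  it <- scenario_items(store, scenario_uuid)
  n_rated <- sum(it$item_uuid %in% user_rated_items(store, user_uuid))
  hit <- store$status$user_uuid == user_uuid &
    store$status$scenario_uuid == scenario_uuid
  row <- data.frame(user_uuid = user_uuid, scenario_uuid = scenario_uuid,
                    items_rated = n_rated,
                    complete = n_rated == nrow(it) & nrow(it) > 0L,
                    stringsAsFactors = FALSE)
  if (any(hit)) store$status[which(hit)[1L], ] <- row
  else store$status <- rbind(store$status, row)
  invisible(row)
}

#' Record (or revise) a relevance rating
#'
#' Persists one rater's 0-3 relevance score for one item, with its canonical
#' label and an ISO 8601 UTC timestamp, and updates the rater's per-scenario
#' progress. Re-rating an already-rated item replaces the current score
#' (last write wins) and retains the revision timestamp; the rater's
#' items-rated count is unchanged by a replacement.
#'
#' @param store A `rating_store`.
#' @param user_uuid Rater UUID; must be assigned to the family containing the
#'   item.
#' @param item_uuid Item UUID.
#' @param score Integer in 0..3.
#' @param at Timestamp override (ISO 8601 UTC; defaults to now).
#' @return The stored rating as a list (`user_uuid`, `item_uuid`, `score`,
#'   `label`, `recorded_at`), invisibly.
#' @export
record_rating <- function(store, user_uuid, item_uuid, score, at = NULL) {
  find_user(store, user_uuid)
  if (length(score) != 1L || is.na(score) || !(score %in% 0:3)) {
    relrate_abort("score must be a single integer in 0..3",
                  "relrate_domain_error")
  }
  i <- match(item_uuid, store$items$item_uuid)
  if (is.na(i)) {
    relrate_abort(sprintf("unknown item '%s'", item_uuid),
                  "relrate_not_found")
  }
  scenario_uuid <- store$items$scenario_uuid[i]
  family_uuid <- store$scenarios$family_uuid[
    match(scenario_uuid, store$scenarios$scenario_uuid)]
  if (!is_assigned(store, user_uuid, family_uuid)) {
    relrate_abort("item is not in any family assigned to this user",
                  "relrate_auth_error")
  }
  now <- at %||% iso_utc_now()
  store$seq <- store$seq + 1L
  hit <- which(store$ratings$user_uuid == user_uuid &
                 store$ratings$item_uuid == item_uuid)
  if (length(hit) > 0L) {
    ## last write wins (by recorded_at, seq as tie-break); keep when revised
    store$ratings$score[hit[1L]] <- as.integer(score)
    store$ratings$label[hit[1L]] <- score_label(score)
    store$ratings$revised_at[hit[1L]] <- now
    store$ratings$recorded_at[hit[1L]] <- now
    store$ratings$seq[hit[1L]] <- store$seq
  } else {
    store$ratings <- rbind(store$ratings, data.frame(
      user_uuid = user_uuid, item_uuid = item_uuid,
      score = as.integer(score), label = score_label(score),
      recorded_at = now, revised_at = NA_character_, seq = store$seq,
      stringsAsFactors = FALSE))
  }
  update_status(store, user_uuid, scenario_uuid)
  invisible(list(user_uuid = user_uuid, item_uuid = item_uuid,
                 score = as.integer(score), label = score_label(score),
                 recorded_at = now))
}

#' A rater's progress through a family
#'
#' Per-scenario items rated / total plus the overall rated fraction, always
#' recomputed from the rating store.
#'
#' @param store A `rating_store`.
#' @param user_uuid Rater UUID.
#' @param family_uuid Family UUID.
#' @return List with `per_scenario` (data frame) and `overall_fraction`.
#' @export
progress <- function(store, user_uuid, family_uuid) {
  find_user(store, user_uuid)
  find_family(store, family_uuid)
  if (!is_assigned(store, user_uuid, family_uuid)) {
    relrate_abort("no assignment for this user and family",
                  "relrate_not_found")
  }
  per <- family_progress_counts(store, user_uuid, family_uuid)
  total <- sum(per$items_total)
  list(per_scenario = per,
       overall_fraction = if (total == 0L) 0 else sum(per$items_rated) / total)
}

#' Administrative overview of all families and raters
#'
#' One row per (family, assigned rater), ordered by family name then rater
#' name, with the family's scenarios listed as UUIDs abbreviated to their
#' first 8 hexadecimal characters and the rater's items rated / total.
#' Families with no assigned raters appear with an NA rater.
#'
#' @param store A `rating_store`.
#' @return Data frame with columns family_name, family_uuid, scenarios,
#'   rater_name, rater_uuid, items_rated, items_total, complete.
#' @export
admin_overview <- function(store) {
  empty <- data.frame(family_name = character(0), family_uuid = character(0),
                      scenarios = character(0), rater_name = character(0),
                      rater_uuid = character(0), items_rated = integer(0),
                      items_total = integer(0), complete = logical(0),
                      stringsAsFactors = FALSE)
  if (nrow(store$families) == 0L) return(empty)
  rows <- lapply(seq_len(nrow(store$families)), function(i) {
    fu <- store$families$family_uuid[i]
    sc <- family_scenarios(store, fu)
    abbrev <- paste(abbrev_uuid(sc$scenario_uuid), collapse = ",")
    n_total <- nrow(family_items(store, fu))
    raters <- store$assignments$user_uuid[store$assignments$family_uuid == fu]
    if (length(raters) == 0L) {
      return(data.frame(family_name = store$families$name[i],
                        family_uuid = fu, scenarios = abbrev,
                        rater_name = NA_character_,
                        rater_uuid = NA_character_,
                        items_rated = NA_integer_, items_total = n_total,
                        complete = NA, stringsAsFactors = FALSE))
    }
    do.call(rbind, lapply(raters, function(ru) {
      per <- family_progress_counts(store, ru, fu)
      data.frame(family_name = store$families$name[i], family_uuid = fu,
                 scenarios = abbrev,
                 rater_name = store$users$display_name[find_user(store, ru)],
                 rater_uuid = ru,
                 items_rated = sum(per$items_rated), items_total = n_total,
                 complete = n_total > 0L && sum(per$items_rated) == n_total,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, c(rows, list(empty)))
  out <- out[order(out$family_name, out$rater_name, na.last = TRUE), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a family's current ratings as a ratings document
#'
#' One entry per current rating by any assigned rater on any item in the
#' family, ordered by rater UUID, then scenario order, then item order.
#' Re-rated items contribute exactly one entry carrying the latest score.
#'
#' @param store A `rating_store`.
#' @param family_uuid Family UUID.
#' @return A `ratings_document`.
#' @export
export_ratings <- function(store, family_uuid) {
  i <- find_family(store, family_uuid)
  fam_it <- family_items(store, family_uuid)
  raters <- sort(unique(
    store$assignments$user_uuid[store$assignments$family_uuid == family_uuid]))
  item_scenario <- store$items$scenario_uuid[
    match(fam_it$item_uuid, store$items$item_uuid)]
  rows <- lapply(raters, function(ru) {
    r <- store$ratings[store$ratings$user_uuid == ru, , drop = FALSE]
    keep <- match(fam_it$item_uuid, r$item_uuid)  # family item order
    found <- which(!is.na(keep))
    if (length(found) == 0L) return(NULL)
    data.frame(rater_uuid = ru,
               scenario_uuid = item_scenario[found],
               item_uuid = fam_it$item_uuid[found],
               score = r$score[keep[found]],
               label = r$label[keep[found]],
               recorded_at = r$recorded_at[keep[found]],
               stringsAsFactors = FALSE)
  })
  ratings <- do.call(rbind, c(rows, list(empty_ratings_frame())))
  ratings_document(family_uuid, store$families$name[i], ratings)
}

#' Retrieve a scenario family with its scenarios and items
#'
#' @param store A `rating_store`.
#' @param family_uuid Family UUID.
#' @return A `scenario_family` list: `family_uuid`, `name`, `scenarios`
#'   (each a `scenario` object in import order).
#' @export
scenario_family <- function(store, family_uuid) {
  i <- find_family(store, family_uuid)
  sc <- family_scenarios(store, family_uuid)
  scenarios <- lapply(seq_len(nrow(sc)), function(k) {
    it <- scenario_items(store, sc$scenario_uuid[k])
    items <- lapply(seq_len(nrow(it)), function(j) {
      new_deid_item(it$item_uuid[j], it$category[j], it$text[j])
    })
    new_scenario(sc$scenario_uuid[k], sc$context[k], sc$sex[k],
                 sc$age_years[k], items)
  })
  structure(list(family_uuid = family_uuid, name = store$families$name[i],
                 scenarios = scenarios),
            class = "scenario_family")
}
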