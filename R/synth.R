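## Synthetic patient-record generator with a ground-truth PHI manifest.
##
## Every identifying string planted in generated text is drawn from closed,
## package-internal vocabularies (names, number formats, date dialects) and
## recorded in a manifest, so the redactor can be tested for provable
## completeness instead of relying on manual review.

phi_first_names <- function() {
  c("Alice", "Brian", "Carmen", "Daniel", "Elena", "Frank", "Grace", "Hector",
    "Irene", "James", "Karen", "Liam", "Marisol", "Nathan", "Olivia", "Peter",
    "Quinn", "Rosa", "Samuel", "Teresa", "Victor", "Wendy")
}

phi_last_names <- function() {
  c("Abbott", "Barnes", "Castillo", "Donovan", "Ellison", "Fuentes", "Grady",
    "Holloway", "Ibarra", "Jennings", "Kowalski", "Lindqvist", "Moreau",
    "Novak", "Okafor", "Pemberton", "Quigley", "Rutherford", "Santos",
    "Thornton", "Ulrich", "Vasquez", "Whitfield")
}

## Three date dialects are planted to exercise the redactor.
phi_date_dialects <- function() c("mdy", "long", "iso")

format_phi_date <- function(date, dialect) {
  lt <- as.POSIXlt(date)
  switch(dialect,
    mdy  = format(date, "%m/%d/%Y"),
    long = sprintf("%s %d, %d", month.name[lt$mon + 1L], lt$mday,
                   lt$year + 1900L),
    iso  = format(date, "%Y-%m-%d"),
    relrate_abort("unknown date dialect", "relrate_param_error")
  )
}

random_person_name <- function() {
  paste(sample(phi_first_names(), 1L), sample(phi_last_names(), 1L))
}

random_mrn <- function() {
  paste0(sample(1:9, 1L), paste(sample(0:9, 6L, replace = TRUE), collapse = ""))
}

random_accession <- function() {
  paste(sample(0:9, 8L, replace = TRUE), collapse = "")
}

random_phone <- function() {
  sprintf("(%d) %d-%04d", sample(c(617L, 508L, 781L, 413L, 978L), 1L),
          sample(200:999, 1L), sample(0:9999, 1L))
}

random_zip <- function() sprintf("%05d", sample(1000:99999, 1L))

## Per-category narrative bodies: deliberately free of names, dates and
## digit runs >= 5 so every identifying string in an item is a planted one.
category_bodies <- function() {
  list(
    radiology_report = c(
      "EXAM: CT abdomen and pelvis with intravenous contrast. FINDINGS: No acute intra-abdominal abnormality. IMPRESSION: Stable examination.",
      "EXAM: Abdominal ultrasound. FINDINGS: Normal liver echotexture, no biliary dilation. IMPRESSION: Unremarkable study."),
    operative_note = c(
      "PROCEDURE: Laparoscopic appendectomy. The appendix was identified, ligated and removed without complication. Estimated blood loss minimal.",
      "PROCEDURE: Laparoscopic cholecystectomy. Critical view of safety obtained. The gallbladder was dissected free and removed intact."),
    laboratory_result = c(
      "CBC: WBC 8.2, HGB 13.1, HCT 39.4, PLT 240. Differential within normal limits.",
      "BMP: Na 139, K 4.1, Cl 103, CO2 25, BUN 14, Cr 0.9, Glu 98."),
    pathology_report = c(
      "SPECIMEN: Appendix. DIAGNOSIS: Acute appendicitis with periappendicitis. No evidence of malignancy.",
      "SPECIMEN: Gallbladder. DIAGNOSIS: Chronic cholecystitis with cholelithiasis."),
    endoscopy_report = c(
      "Colonoscopy advanced to the cecum. Mucosa normal throughout. No polyps or masses identified. Recommend routine surveillance.",
      "Upper endoscopy to the second portion of the duodenum. Mild antral gastritis. Biopsies obtained."),
    microbiology_result = c(
      "Blood culture: no growth at five days. Final report.",
      "Urine culture: mixed flora, likely contamination. Repeat if clinically indicated.")
  )
}

#' Parameters for synthetic patient generation
#'
#' @param items_per_category Integer length-2 range; each of the six categories
#'   receives a uniformly drawn number of items in this range (the index exam is
#'   additional). Default 2-4.
#' @param date_spread_years Positive number; non-index item dates are uniform
#'   over the index date +/- this many years. The default 3 straddles the
#'   +/- 2-year selection window so both retained and excluded items occur, and
#'   the two extreme offsets (-spread, +spread) are always planted.
#' @param age_years Patient age in completed years at the index exam, 0-130.
#' @return An object of class `generation_params`.
#' @export
#' @examples
#' generation_params(age_years = 93)
generation_params <- function(items_per_category = c(2L, 4L),
                              date_spread_years = 3,
                              age_years = 64L) {
  if (length(items_per_category) != 2L || any(is.na(items_per_category)) ||
      any(items_per_category < 1L) ||
      items_per_category[2L] < items_per_category[1L]) {
    relrate_abort("items_per_category must be a positive low-high range",
                  "relrate_param_error")
  }
  if (!is.numeric(date_spread_years) || is.na(date_spread_years) ||
      date_spread_years <= 0) {
    relrate_abort("date_spread_years must be > 0", "relrate_param_error")
  }
  if (!is.numeric(age_years) || is.na(age_years) ||
      age_years < 0 || age_years > 130) {
    relrate_abort("age_years must lie in [0, 130]", "relrate_param_error")
  }
  structure(list(items_per_category = as.integer(items_per_category),
                 date_spread_years = as.numeric(date_spread_years),
                 age_years = as.integer(age_years)),
            class = "generation_params")
}

default_scenario_template <- function() {
  "Abdominal CT ordered for a {age}-year-old patient with abdominal pain."
}

instantiate_template <- function(template, age, sex) {
  out <- gsub("{age}", as.character(age), template, fixed = TRUE)
  gsub("{sex}", sex, out, fixed = TRUE)
}

new_manifest_env <- function() {
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  env
}

manifest_add <- function(env, kind, literal, location) {
  env$rows[[length(env$rows) + 1L]] <-
    data.frame(kind = kind, literal = literal, location = location,
               stringsAsFactors = FALSE)
  invisible(env)
}

manifest_collect <- function(env) {
  if (length(env$rows) == 0L) {
    man <- data.frame(kind = character(0), literal = character(0),
                      location = character(0), stringsAsFactors = FALSE)
  } else {
    man <- do.call(rbind, env$rows)
    man <- unique(man)
    rownames(man) <- NULL
  }
  structure(man, class = c("phi_manifest", "data.frame"))
}

## Build one item's text, planting PHI and recording it in the manifest.
## `location` is "item:<ordinal>" within the record.
compose_item_text <- function(body, date, patient_name, mrn, env, location,
                              with_phone = FALSE, with_zip = FALSE) {
  dialect <- sample(phi_date_dialects(), 1L)
  date_str <- format_phi_date(date, dialect)
  accession <- random_accession()
  physician <- random_person_name()
  header <- sprintf("Patient: %s. MRN: %s. Date of service: %s. Accession: %s.",
                    patient_name, mrn, date_str, accession)
  footer <- sprintf("Electronically signed by Dr. %s.", physician)
  extra <- character(0)
  if (with_phone) {
    phone <- random_phone()
    extra <- c(extra, sprintf("Questions to the office at %s.", phone))
    manifest_add(env, "phone_fax", phone, location)
  }
  if (with_zip) {
    zip <- random_zip()
    extra <- c(extra, sprintf("Clinic zip: %s.", zip))
    manifest_add(env, "zip", zip, location)
  }
  manifest_add(env, "patient_name", patient_name, location)
  manifest_add(env, "mrn", mrn, location)
  manifest_add(env, "date", date_str, location)
  manifest_add(env, "accession", accession, location)
  manifest_add(env, "physician_name", physician, location)
  list(text = paste(c(header, body, extra, footer), collapse = " "),
       accession = accession)
}

new_source_item <- function(category, date, text, source_accession) {
  structure(list(category = category, date = date, text = text,
                 source_accession = source_accession),
            class = "source_item")
}

## Core generator; consumes the current RNG stream (callers seed it).
gen_patient_impl <- function(params, scenario_template) {
  env <- new_manifest_env()
  sex <- sample(c("M", "F"), 1L)
  patient_name <- random_person_name()
  mrn <- random_mrn()
  phone <- random_phone()
  zip <- random_zip()
  index_date <- as.Date("2012-01-01") + sample(0:1460, 1L)
  birth_date <- add_years(index_date, -params$age_years) - sample(0:300, 1L)
  stopifnot(age_at(birth_date, index_date) == params$age_years)

  manifest_add(env, "patient_name", patient_name, "demographics")
  manifest_add(env, "mrn", mrn, "demographics")
  manifest_add(env, "phone_fax", phone, "demographics")
  manifest_add(env, "zip", zip, "demographics")
  manifest_add(env, "date", format(birth_date, "%Y-%m-%d"), "demographics")

  ## Draw all non-index item (category, offset-day) pairs first, then force
  ## the two extremes so the configured spread is always covered and at least
  ## one item falls outside the +/- 2-year selection window by construction.
  cats <- item_categories()
  lo <- params$items_per_category[1L]
  hi <- params$items_per_category[2L]
  counts <- vapply(cats, function(cat) {
    lo + sample.int(hi - lo + 1L, 1L) - 1L
  }, integer(1))
  spread_days <- round(params$date_spread_years * 365.25)
  plan <- data.frame(
    category = rep(cats, counts),
    offset = sample(seq(-spread_days, spread_days),
                    sum(counts), replace = TRUE),
    stringsAsFactors = FALSE
  )
  plan$offset[1L] <- -spread_days
  plan$offset[min(2L, nrow(plan))] <- spread_days

  bodies <- category_bodies()
  items <- vector("list", nrow(plan) + 1L)

  ## Item 1 is the index exam; its text is the clinical-history string that
  ## becomes the scenario context after redaction.
  idx_body <- instantiate_template(scenario_template, params$age_years, sex)
  idx <- compose_item_text(idx_body, index_date, patient_name, mrn, env,
                           "item:1", with_phone = TRUE)
  items[[1L]] <- new_source_item("radiology_report", index_date,
                                 idx$text, idx$accession)

  for (i in seq_len(nrow(plan))) {
    cat_i <- plan$category[i]
    date_i <- index_date + plan$offset[i]
    body_i <- sample(bodies[[cat_i]], 1L)
    made <- compose_item_text(body_i, date_i, patient_name, mrn, env,
                              sprintf("item:%d", i + 1L),
                              with_phone = runif(1) < 0.3,
                              with_zip = runif(1) < 0.3)
    items[[i + 1L]] <- new_source_item(cat_i, date_i, made$text,
                                       made$accession)
  }

  record <- structure(list(
    format_version = "1",
    patient_name = patient_name,
    sex = sex,
    birth_date = birth_date,
    mrn = mrn,
    phone = phone,
    zip = zip,
    index_item = 1L,
    items = items
  ), class = "source_patient_record")
  list(record = record, manifest = manifest_collect(env))
}

#' Generate one synthetic patient record with a PHI manifest
#'
#' Produces a seeded, fully synthetic patient record: demographics and
#' identifiers, an index radiology exam carrying a clinical-history string, and
#' dated free-text items in the six record categories whose dates span the
#' configured spread around the index exam. Every identifying string planted in
#' any text is recorded in the returned manifest, the ground truth against
#' which redaction is audited.
#'
#' @param seed Integer seed; output is byte-identical for a fixed
#'   `(seed, params)`. The caller's RNG state is untouched.
#' @param params A [generation_params()] object.
#' @param scenario_template Clinical-history template for the index exam;
#'   `{age}` and `{sex}` placeholders are substituted.
#' @return A list with elements `record` (a `source_patient_record`) and
#'   `manifest` (a `phi_manifest` data frame with columns kind, literal,
#'   location).
#' @export
#' @examples
#' gp <- generate_patient(seed = 1)
#' gp$record$mrn
#' head(gp$manifest)
generate_patient <- function(seed, params = generation_params(),
                             scenario_template = default_scenario_template()) {
  if (!inherits(params, "generation_params")) {
    params <- do.call(generation_params, params)
  }
  withr::with_seed(as.integer(seed),
                   gen_patient_impl(params, scenario_template))
}

#' Generate source records for one scenario family
#'
#' Generates `n_patients` independent synthetic patients sharing one clinical
#' context: each patient's index-exam clinical history instantiates
#' `scenario_template`. Patient `i` is seeded deterministically from
#' `(seed, i)`, and MRNs are guaranteed distinct across the family.
#'
#' @param n_patients Number of patients (>= 1).
#' @param scenario_template Shared clinical-context template.
#' @param seed Master integer seed.
#' @param params A [generation_params()] object applied to every patient.
#' @return List of `n_patients` lists, each with `record` and `manifest`.
#' @export
generate_family_sources <- function(n_patients,
                                    scenario_template = default_scenario_template(),
                                    seed = 1L,
                                    params = generation_params()) {
  if (!is.numeric(n_patients) || is.na(n_patients) || n_patients < 1) {
    relrate_abort("n_patients must be >= 1", "relrate_param_error")
  }
  n_patients <- as.integer(n_patients)
  child_seed <- function(i, bump = 0L) {
    as.integer((as.numeric(seed) + 104729 * i + bump) %% 2147483647)
  }
  out <- vector("list", n_patients)
  seen_mrn <- character(0)
  for (i in seq_len(n_patients)) {
    bump <- 0L
    repeat {
      gp <- generate_patient(child_seed(i, bump), params, scenario_template)
      if (!(gp$record$mrn %in% seen_mrn)) break
      bump <- bump + 1L  # deterministic regeneration on MRN collision
    }
    seen_mrn <- c(seen_mrn, gp$record$mrn)
    out[[i]] <- gp
  }
  out
}

record_to_list <- function(record) {
  list(
    format_version = record$format_version,
    patient_name = record$patient_name,
    sex = record$sex,
    birth_date = format(record$birth_date, "%Y-%m-%d"),
    mrn = record$mrn,
    phone = record$phone,
    zip = record$zip,
    index_item = record$index_item,
    items = lapply(record$items, function(it) {
      list(category = it$category, date = format(it$date, "%Y-%m-%d"),
           text = it$text, source_accession = it$source_accession)
    })
  )
}

list_to_record <- function(x) {
  if (!identical(x$format_version, "1")) {
    relrate_abort("unsupported source-record format_version",
                  "relrate_validation_error")
  }
  items <- lapply(x$items, function(it) {
    new_source_item(it$category, as.Date(it$date), it$text,
                    it$source_accession)
  })
  structure(list(
    format_version = x$format_version, patient_name = x$patient_name,
    sex = x$sex, birth_date = as.Date(x$birth_date), mrn = x$mrn,
    phone = x$phone, zip = x$zip, index_item = as.integer(x$index_item),
    items = items
  ), class = "source_patient_record")
}

#' Serialize a source record to its JSON fixture form
#'
#' @param record A `source_patient_record`.
#' @return A single JSON string.
#' @export
serialize_source_record <- function(record) {
  as.character(jsonlite::toJSON(record_to_list(record), auto_unbox = TRUE,
                                pretty = TRUE))
}

#' Write / read a source record as a JSON fixture file
#'
#' The JSON fixture format is internal and versioned with a `format_version`
#' field; it stands in for a real EMR export.
#'
#' @param record A `source_patient_record`.
#' @param path Destination / source file path.
#' @return `write_source_record()` returns `path` invisibly;
#'   `read_source_record()` returns a `source_patient_record`.
#' @export
write_source_record <- function(record, path) {
  writeLines(serialize_source_record(record), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_source_record
#' @export
read_source_record <- function(path) {
  list_to_record(jsonlite::fromJSON(path, simplifyVector = FALSE))
}

#' Write / read a PHI manifest as JSON
#'
#' @param manifest A `phi_manifest` data frame.
#' @param path Destination / source file path.
#' @export
write_phi_manifest <- function(manifest, path) {
  jsonlite::write_json(as.data.frame(manifest), path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_phi_manifest
#' @export
read_phi_manifest <- function(path) {
  man <- jsonlite::fromJSON(path)
  if (length(man) == 0L || nrow(man) == 0L) {
    man <- data.frame(kind = character(0), literal = character(0),
                      location = character(0), stringsAsFactors = FALSE)
  }
  structure(man, class = c("phi_manifest", "data.frame"))
}
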