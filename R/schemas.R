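## The two XML interchange formats: scenario documents (de-identified cases)
## and scenario-family ratings documents (exported scores). Both are frozen by
## packaged XSD files carrying a schema_version attribute; serialization is
## UTF-8 with deterministic element order, and both formats round-trip.

SCHEMA_VERSION <- "1.0"

schema_path <- function(kind) {
  system.file("extdata", paste0(kind, ".xsd"), package = "relrate",
              mustWork = TRUE)
}

read_schema <- function(kind) xml2::read_xml(schema_path(kind))

empty_ratings_frame <- function() {
  data.frame(rater_uuid = character(0), scenario_uuid = character(0),
             item_uuid = character(0), score = integer(0),
             label = character(0), recorded_at = character(0),
             stringsAsFactors = FALSE)
}

#' Construct a scenario document
#'
#' Wraps a de-identified [build_scenario()] result, optionally tagged with the
#' UUID of the scenario family it belongs to, for XML interchange.
#'
#' @param scenario A `scenario` object.
#' @param family_uuid Optional family UUID.
#' @param schema_version Schema version string (default `"1.0"`).
#' @return A `scenario_document` object.
#' @export
scenario_document <- function(scenario, family_uuid = NULL,
                              schema_version = SCHEMA_VERSION) {
  doc <- structure(list(schema_version = schema_version,
                        family_uuid = family_uuid,
                        scenario = scenario),
                   class = "scenario_document")
  validate_scenario_document(doc)
  doc
}

#' Validate a scenario document's invariants
#'
#' Checks UUID formats and uniqueness, the M/F sex domain, the 0-89 age
#' domain, the six-category domain, and non-empty item texts. Errors name the
#' offending element.
#'
#' @param doc A `scenario_document`.
#' @return `doc`, invisibly.
#' @export
validate_scenario_document <- function(doc) {
  fail <- function(msg) relrate_abort(msg, "relrate_validation_error")
  s <- doc$scenario
  if (!is.character(doc$schema_version)) fail("schema-version: missing")
  if (!is.null(doc$family_uuid) && !is_uuid(doc$family_uuid)) {
    fail("family/@uuid: not a valid UUID")
  }
  if (!is_uuid(s$scenario_uuid)) fail("scenario/@uuid: not a valid UUID")
  if (!is.character(s$context) || length(s$context) != 1L) {
    fail("context: must be a single string")
  }
  if (!s$sex %in% c("M", "F")) fail("demographics/sex: must be M or F")
  if (!is.numeric(s$age_years) || is.na(s$age_years) ||
      s$age_years < 0 || s$age_years > 89) {
    fail("demographics/age: must lie in [0, 89]")
  }
  uuids <- vapply(s$items, `[[`, "", "item_uuid")
  if (anyDuplicated(uuids)) fail("items/item/@uuid: duplicated within scenario")
  for (it in s$items) {
    if (!is_uuid(it$item_uuid)) fail("items/item/@uuid: not a valid UUID")
    if (!it$category %in% item_categories()) {
      fail(sprintf("items/item/@category: unknown category '%s'", it$category))
    }
    if (!is.character(it$text) || length(it$text) != 1L || !nzchar(it$text)) {
      fail("items/item: text must be non-empty")
    }
  }
  invisible(doc)
}

#' Write a scenario document as XML
#'
#' Emits well-formed UTF-8 XML that validates against the packaged scenario
#' schema, with deterministic element order (context, demographics, items in
#' scenario item order). The document is validated before anything is
#' written.
#'
#' @param doc A `scenario_document`.
#' @param path Destination file path.
#' @return Number of bytes written, invisibly.
#' @export
write_scenario_xml <- function(doc, path) {
  validate_scenario_document(doc)
  s <- doc$scenario
  x <- xml2::xml_new_root("scenario-document", "schema-version" = doc$schema_version)
  if (!is.null(doc$family_uuid)) {
    xml2::xml_add_child(x, "family", uuid = doc$family_uuid)
  }
  sc <- xml2::xml_add_child(x, "scenario", uuid = s$scenario_uuid)
  xml2::xml_add_child(sc, "context", s$context)
  demo <- xml2::xml_add_child(sc, "demographics")
  xml2::xml_add_child(demo, "sex", s$sex)
  xml2::xml_add_child(demo, "age", as.character(s$age_years))
  items <- xml2::xml_add_child(sc, "items")
  for (it in s$items) {
    xml2::xml_add_child(items, "item", it$text, uuid = it$item_uuid,
                        category = it$category)
  }
  if (!xml2::xml_validate(x, read_schema("scenario"))) {
    relrate_abort("scenario document does not validate against the schema",
                  "relrate_validation_error")
  }
  xml2::write_xml(x, path)
  invisible(file.size(path))
}

xsd_check <- function(x, kind) {
  ok <- xml2::xml_validate(x, read_schema(kind))
  if (!ok) {
    relrate_abort(paste0("schema violation: ",
                         paste(attr(ok, "errors"), collapse = "; ")),
                  "relrate_validation_error")
  }
  invisible(TRUE)
}

#' Read and validate a scenario XML document
#'
#' Parses the file, validates it against the packaged scenario schema
#' (unknown elements, out-of-domain ages or categories and malformed UUIDs
#' are rejected with the offending element named), and returns the
#' reconstructed document.
#'
#' @param path Source file path.
#' @return A `scenario_document`.
#' @export
read_scenario_xml <- function(path) {
  x <- tryCatch(xml2::read_xml(path),
                error = function(e) {
                  relrate_abort(paste0("malformed XML: ", conditionMessage(e)),
                                "relrate_parse_error")
                })
  if (xml2::xml_name(x) != "scenario-document") {
    relrate_abort("root element is not scenario-document",
                  "relrate_validation_error")
  }
  xsd_check(x, "scenario")
  fam <- xml2::xml_find_first(x, "./family")
  family_uuid <- if (inherits(fam, "xml_missing")) NULL else
    xml2::xml_attr(fam, "uuid")
  sc <- xml2::xml_find_first(x, "./scenario")
  item_nodes <- xml2::xml_find_all(sc, "./items/item")
  items <- lapply(item_nodes, function(node) {
    new_deid_item(xml2::xml_attr(node, "uuid"),
                  xml2::xml_attr(node, "category"),
                  xml2::xml_text(node))
  })
  scenario <- new_scenario(
    xml2::xml_attr(sc, "uuid"),
    xml2::xml_text(xml2::xml_find_first(sc, "./context")),
    xml2::xml_text(xml2::xml_find_first(sc, "./demographics/sex")),
    as.integer(xml2::xml_text(xml2::xml_find_first(sc, "./demographics/age"))),
    items
  )
  scenario_document(scenario, family_uuid, xml2::xml_attr(x, "schema-version"))
}

#' Construct a ratings document
#'
#' The export form of a scenario family's collected ratings: one row per
#' current (rater, item) rating, each with the 0-3 score, its canonical
#' label, and an ISO 8601 UTC timestamp.
#'
#' @param family_uuid Family UUID.
#' @param family_name Family display name (the clinical context).
#' @param ratings Data frame with columns rater_uuid, scenario_uuid,
#'   item_uuid, score, label, recorded_at.
#' @param schema_version Schema version string.
#' @return A `ratings_document` object.
#' @export
ratings_document <- function(family_uuid, family_name,
                             ratings = empty_ratings_frame(),
                             schema_version = SCHEMA_VERSION) {
  ratings <- as.data.frame(ratings, stringsAsFactors = FALSE)
  if (nrow(ratings) > 0L) ratings$score <- as.integer(ratings$score)
  doc <- structure(list(schema_version = schema_version,
                        family_uuid = family_uuid,
                        family_name = family_name,
                        ratings = ratings),
                   class = "ratings_document")
  validate_ratings_document(doc)
  doc
}

#' Validate a ratings document's invariants
#'
#' Checks that every score lies in \{0,1,2,3\} with its canonical label, that
#' (rater, item) pairs are unique, that UUIDs are well-formed and timestamps
#' ISO 8601 UTC.
#'
#' @param doc A `ratings_document`.
#' @return `doc`, invisibly.
#' @export
validate_ratings_document <- function(doc) {
  fail <- function(msg) relrate_abort(msg, "relrate_validation_error")
  if (!is_uuid(doc$family_uuid)) fail("family/@uuid: not a valid UUID")
  if (!is.character(doc$family_name) || !nzchar(doc$family_name)) {
    fail("family/@name: must be non-empty")
  }
  r <- doc$ratings
  needed <- c("rater_uuid", "scenario_uuid", "item_uuid", "score", "label",
              "recorded_at")
  if (!all(needed %in% names(r))) fail("ratings: missing columns")
  if (nrow(r) == 0L) return(invisible(doc))
  if (!all(r$score %in% 0:3)) fail("rating/@score: must lie in 0..3")
  if (!identical(r$label, score_label(r$score))) {
    fail("rating/@label: label does not match its score's canonical name")
  }
  if (anyDuplicated(r[c("rater_uuid", "item_uuid")])) {
    fail("rating: duplicate (rater-uuid, item-uuid) pair")
  }
  for (col in c("rater_uuid", "scenario_uuid", "item_uuid")) {
    if (!all(is_uuid(r[[col]]))) fail(sprintf("rating/@%s: invalid UUID", col))
  }
  if (!all(is_iso_utc(r$recorded_at))) {
    fail("rating/@recorded-at: must be an ISO 8601 UTC timestamp")
  }
  invisible(doc)
}

#' Write a ratings document as XML
#'
#' One `rating` element per item rating, in the row order of the document
#' (exports produced by [export_ratings()] are ordered by rater, then
#' scenario order, then item order). The document is validated before any
#' bytes are written.
#'
#' @param doc A `ratings_document`.
#' @param path Destination file path.
#' @return Number of bytes written, invisibly.
#' @export
write_ratings_xml <- function(doc, path) {
  validate_ratings_document(doc)
  x <- xml2::xml_new_root("ratings-document",
                          "schema-version" = doc$schema_version)
  xml2::xml_add_child(x, "family", uuid = doc$family_uuid,
                      name = doc$family_name)
  container <- xml2::xml_add_child(x, "ratings")
  r <- doc$ratings
  for (i in seq_len(nrow(r))) {
    xml2::xml_add_child(container, "rating",
                        "rater-uuid" = r$rater_uuid[i],
                        "scenario-uuid" = r$scenario_uuid[i],
                        "item-uuid" = r$item_uuid[i],
                        score = as.character(r$score[i]),
                        label = r$label[i],
                        "recorded-at" = r$recorded_at[i])
  }
  if (!xml2::xml_validate(x, read_schema("ratings"))) {
    relrate_abort("ratings document does not validate against the schema",
                  "relrate_validation_error")
  }
  xml2::write_xml(x, path)
  invisible(file.size(path))
}

#' Read and validate a ratings XML document
#'
#' @param path Source file path.
#' @return A `ratings_document`.
#' @export
read_ratings_xml <- function(path) {
  x <- tryCatch(xml2::read_xml(path),
                error = function(e) {
                  relrate_abort(paste0("malformed XML: ", conditionMessage(e)),
                                "relrate_parse_error")
                })
  if (xml2::xml_name(x) != "ratings-document") {
    relrate_abort("root element is not ratings-document",
                  "relrate_validation_error")
  }
  xsd_check(x, "ratings")
  fam <- xml2::xml_find_first(x, "./family")
  nodes <- xml2::xml_find_all(x, "./ratings/rating")
  ratings <- if (length(nodes) == 0L) empty_ratings_frame() else data.frame(
    rater_uuid = xml2::xml_attr(nodes, "rater-uuid"),
    scenario_uuid = xml2::xml_attr(nodes, "scenario-uuid"),
    item_uuid = xml2::xml_attr(nodes, "item-uuid"),
    score = as.integer(xml2::xml_attr(nodes, "score")),
    label = xml2::xml_attr(nodes, "label"),
    recorded_at = xml2::xml_attr(nodes, "recorded-at"),
    stringsAsFactors = FALSE
  )
  ratings_document(xml2::xml_attr(fam, "uuid"), xml2::xml_attr(fam, "name"),
                   ratings, xml2::xml_attr(x, "schema-version"))
}

#' Validate an XML file of either interchange kind
#'
#' Auto-detects the document kind from the root element and validates it.
#'
#' @param path File path.
#' @return List with `kind` ("scenario" or "ratings") and the parsed document.
#' @export
validate_xml_file <- function(path) {
  root <- xml2::xml_name(xml2::read_xml(path))
  switch(root,
    "scenario-document" = list(kind = "scenario",
                               doc = read_scenario_xml(path)),
    "ratings-document" = list(kind = "ratings", doc = read_ratings_xml(path)),
    relrate_abort(sprintf("unknown document root '%s'", root),
                  "relrate_validation_error")
  )
}
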