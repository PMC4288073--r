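## Window selection, rule-based PHI redaction, demographic reduction, and
## scenario assembly.
##
## Redaction is deliberately conservative: any digit run of five or more
## characters is treated as an identifying number even when it carries no
## label, because over-redaction is the safer failure mode for patient
## privacy.

name_alternation <- function() {
  sprintf("\\b(?:%s)\\s+(?:%s)\\b",
          paste(phi_first_names(), collapse = "|"),
          paste(phi_last_names(), collapse = "|"))
}

month_alternation <- function() paste(month.name, collapse = "|")

#' The default redaction rule set
#'
#' An ordered list of pattern rules covering exactly the eight identifier
#' kinds removed during de-identification: patient names, physician names,
#' dates (three dialects), medical record numbers, accession numbers,
#' phone/fax numbers, zip codes, and any other identifying number (digit run
#' of 5+ characters). Matches are replaced by bracketed kind tokens:
#' `[NAME]`, `[DATE]`, `[ID]`.
#'
#' Name rules are built from the package's closed name vocabularies (the same
#' lists the synthetic generator draws from), which makes redaction provably
#' complete on generated records; on external text the physician-title,
#' date, and number rules still apply, and a PHI manifest can be passed to
#' [redact_text()] to remove known literals directly.
#'
#' @return A `redaction_rules` object (fields `version`, `rules`).
#' @export
#' @examples
#' vapply(redaction_rules()$rules, `[[`, "", "kind")
redaction_rules <- function() {
  rule <- function(kind, pattern, token) {
    list(kind = kind, pattern = pattern, token = token)
  }
  structure(list(
    version = "1.0",
    rules = list(
      rule("physician_name",
           "(?<=Dr\\. )[[:upper:]][[:alpha:]'-]+(?: [[:upper:]][[:alpha:]'-]+)?",
           "[NAME]"),
      rule("patient_name", name_alternation(), "[NAME]"),
      rule("date", "\\b\\d{1,2}/\\d{1,2}/\\d{4}\\b", "[DATE]"),
      rule("date", sprintf("\\b(?:%s)\\s+\\d{1,2},\\s+\\d{4}\\b",
                           month_alternation()), "[DATE]"),
      rule("date", "\\b\\d{4}-\\d{2}-\\d{2}\\b", "[DATE]"),
      rule("phone_fax",
           "\\(\\d{3}\\)\\s*\\d{3}[- ]\\d{4}|\\b\\d{3}[-.]\\d{3}[-.]\\d{4}\\b",
           "[ID]"),
      rule("mrn", "(?<=MRN: )\\d+", "[ID]"),
      rule("accession", "(?<=Accession: )\\d+", "[ID]"),
      rule("zip", "(?<=zip: )\\d{5}\\b", "[ID]"),
      rule("other_id", "\\b\\d{5,}\\b", "[ID]")
    )
  ), class = "redaction_rules")
}

redaction_token <- function(kind) {
  switch(kind,
         patient_name = , physician_name = "[NAME]",
         date = "[DATE]",
         "[ID]")
}

#' Select record items inside the extraction window
#'
#' Returns the items of all six categories whose date lies within
#' `window_years` calendar years of the index radiology exam, boundary
#' inclusive at both ends, sorted ascending by date (ties keep source order).
#' The index exam itself is always within the window and is included.
#'
#' @param record A `source_patient_record`.
#' @param window_years Non-negative integer half-width of the window; the
#'   default 2 gives the period from 2 years before to 2 years after the
#'   index exam.
#' @return Ordered list of `source_item`s.
#' @export
select_items <- function(record, window_years = 2L) {
  if (is.null(record$index_item) ||
      record$index_item > length(record$items)) {
    relrate_abort("record has no index exam", "relrate_structure_error")
  }
  if (!is.numeric(window_years) || is.na(window_years) || window_years < 0) {
    relrate_abort("window_years must be >= 0", "relrate_param_error")
  }
  index_item <- record$items[[record$index_item]]
  if (is.null(index_item$date) || is.na(index_item$date)) {
    relrate_abort("index exam has no date", "relrate_structure_error")
  }
  if (!identical(index_item$category, "radiology_report")) {
    relrate_abort("index exam is not a radiology report",
                  "relrate_structure_error")
  }
  lower <- add_years(index_item$date, -as.integer(window_years))
  upper <- add_years(index_item$date, as.integer(window_years))
  dates <- as.Date(vapply(record$items, function(it) format(it$date),
                          character(1)))
  keep <- which(dates >= lower & dates <= upper)
  keep <- keep[order(dates[keep])]  # stable: ties keep source order
  record$items[keep]
}

apply_rule <- function(text, rule) {
  gsub(rule$pattern, rule$token, text, perl = TRUE)
}

#' Redact identifying information from free text
#'
#' Applies each rule of the rule set in order, replacing every match with the
#' rule's token; non-matching content is byte-preserved. If a PHI manifest is
#' supplied, its literals are additionally removed as fixed strings (with the
#' token of their recorded kind) even where no generic rule fires. Redaction
#' is idempotent: the replacement tokens match no rule.
#'
#' @param text Character vector of free text.
#' @param rules A [redaction_rules()] object.
#' @param manifest_hint Optional `phi_manifest` whose literals are removed
#'   unconditionally.
#' @return Redacted character vector, same length as `text`.
#' @export
#' @examples
#' redact_text("Seen on 03/04/2013, MRN: 1234567.")
redact_text <- function(text, rules = redaction_rules(),
                        manifest_hint = NULL) {
  for (rule in rules$rules) text <- apply_rule(text, rule)
  if (!is.null(manifest_hint) && nrow(manifest_hint) > 0L) {
    for (i in seq_len(nrow(manifest_hint))) {
      text <- gsub(manifest_hint$literal[i],
                   redaction_token(manifest_hint$kind[i]),
                   text, fixed = TRUE)
    }
  }
  text
}

#' Reduce demographics to sex and capped age
#'
#' Demographic data are reduced to sex and age in years, with ages of 90 or
#' more reported as 89 to reduce identifiability.
#'
#' @param sex "M" or "F".
#' @param age_years Integer age in completed years, 0-130.
#' @return List with `sex` and `age_years` (capped at 89).
#' @export
#' @examples
#' reduce_demographics("F", 93)  # age reported as 89
reduce_demographics <- function(sex, age_years) {
  if (!sex %in% c("M", "F")) {
    relrate_abort("sex must be 'M' or 'F'", "relrate_param_error")
  }
  if (!is.numeric(age_years) || is.na(age_years) ||
      age_years < 0 || age_years > 130) {
    relrate_abort("age_years must lie in [0, 130]", "relrate_param_error")
  }
  list(sex = sex, age_years = min(as.integer(age_years), 89L))
}

new_deid_item <- function(item_uuid, category, text) {
  structure(list(item_uuid = item_uuid, category = category, text = text),
            class = "deid_item")
}

new_scenario <- function(scenario_uuid, context, sex, age_years, items) {
  structure(list(scenario_uuid = scenario_uuid, context = context, sex = sex,
                 age_years = age_years, items = items),
            class = "scenario")
}

#' Build a de-identified scenario from a source record
#'
#' Composes the de-identification pipeline: select the items within the
#' extraction window, redact every item text, reduce demographics to sex and
#' capped age, and assign fresh random UUIDs to the scenario and each item.
#' Item dates are dropped entirely; chronological order is preserved as the
#' item order. The scenario context is the redacted clinical-history text of
#' the index exam. No mapping from the new UUIDs back to source identifiers
#' (MRN, accession numbers) is retained anywhere, so the source record cannot
#' be re-identified from the scenario.
#'
#' @param record A `source_patient_record`.
#' @param rules A [redaction_rules()] object.
#' @param window_years Window half-width in years (default 2).
#' @param manifest_hint Optional `phi_manifest` passed to [redact_text()].
#' @return A `scenario` object.
#' @export
build_scenario <- function(record, rules = redaction_rules(),
                           window_years = 2L, manifest_hint = NULL) {
  selected <- select_items(record, window_years)
  index_item <- record$items[[record$index_item]]
  age <- age_at(record$birth_date, index_item$date)
  demo <- reduce_demographics(record$sex, age)
  items <- lapply(selected, function(it) {
    new_deid_item(uuid4(), it$category,
                  redact_text(it$text, rules, manifest_hint))
  })
  new_scenario(uuid4(), redact_text(index_item$text, rules, manifest_hint),
               demo$sex, demo$age_years, items)
}

default_audit_patterns <- function() {
  list(
    patient_name = name_alternation(),
    physician_name = "\\bDr\\. [[:upper:]][[:alpha:]'-]+",
    date = sprintf(
      "\\b\\d{1,2}/\\d{1,2}/\\d{4}\\b|\\b(?:%s)\\s+\\d{1,2},\\s+\\d{4}\\b|\\b\\d{4}-\\d{2}-\\d{2}\\b",
      month_alternation()),
    phone_fax = "\\(\\d{3}\\)\\s*\\d{3}[- ]\\d{4}|\\b\\d{3}[-.]\\d{3}[-.]\\d{4}\\b",
    other_id = "\\b\\d{5,}\\b"
  )
}

#' Audit a scenario for residual PHI-like spans
#'
#' Automated stand-in for a manual residual-PHI review: scans the scenario
#' context and every item text against name vocabularies and date/number
#' patterns and reports any suspicious span. A clean scenario yields an empty
#' report. The audit is deterministic.
#'
#' @param scenario A `scenario` object.
#' @param patterns Named list of perl regular expressions (default:
#'   the package vocabularies and conservative date/number patterns).
#' @return Data frame with columns `item_uuid` (or `"context"`), `span`, and
#'   `kind`; zero rows when clean.
#' @export
phi_audit <- function(scenario, patterns = default_audit_patterns()) {
  scan_one <- function(id, text) {
    hits <- lapply(names(patterns), function(kind) {
      m <- gregexpr(patterns[[kind]], text, perl = TRUE)[[1]]
      if (m[1] == -1L) return(NULL)
      data.frame(item_uuid = id,
                 span = unlist(regmatches(text, list(m))),
                 kind = kind, stringsAsFactors = FALSE)
    })
    do.call(rbind, hits)
  }
  reports <- c(list(scan_one("context", scenario$context)),
               lapply(scenario$items,
                      function(it) scan_one(it$item_uuid, it$text)))
  reports <- reports[!vapply(reports, is.null, logical(1))]
  if (length(reports) == 0L) {
    return(data.frame(item_uuid = character(0), span = character(0),
                      kind = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, reports)
  rownames(out) <- NULL
  out
}
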