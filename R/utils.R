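`%||%` <- function(x, y) if (is.null(x)) y else x

#' The six medical-record item categories
#'
#' Record items are restricted to the six EMR entry types that are separately
#' identifiable in a typical hospital record system and likely to matter for
#' subspecialty image interpretation: radiology reports, operative notes,
#' laboratory results, pathology reports, endoscopy reports, and microbiology
#' results.
#'
#' @return Character vector of the six category codes.
#' @export
#' @examples
#' item_categories()
item_categories <- function() {
  c("radiology_report", "operative_note", "laboratory_result",
    "pathology_report", "endoscopy_report", "microbiology_result")
}

#' The 4-step relevance scale
#'
#' Relevance is rated on a 4-step scale, stored numerically as 0-3 and shown to
#' raters with canonical labels: 0 = "irrelevant", 1 = "unlikely relevant",
#' 2 = "probably relevant", 3 = "certainly relevant".
#'
#' @return Named character vector mapping score ("0".."3") to label.
#' @export
#' @examples
#' relevance_labels()
relevance_labels <- function() {
  c(`0` = "irrelevant", `1` = "unlikely relevant",
    `2` = "probably relevant", `3` = "certainly relevant")
}

#' Canonical label for a relevance score
#'
#' @param score Integer vector with values in 0..3.
#' @return Character vector of canonical labels.
#' @export
score_label <- function(score) {
  if (length(score) == 0) return(character(0))
  if (any(is.na(score)) || !all(score %in% 0:3)) {
    relrate_abort("relevance score must be an integer in 0..3",
                  "relrate_domain_error")
  }
  unname(relevance_labels()[as.character(as.integer(score))])
}

## Classed condition helper: every package error is a relrate_error with a
## specific subclass tests and callers can match on.
relrate_abort <- function(message, class) {
  stop(errorCondition(message, class = c(class, "relrate_error")))
}

#' Generate random version-4 UUIDs
#'
#' RFC 4122 version-4 identifiers (random, with version and variant bits set).
#' Randomness comes from the R RNG, so identifiers are reproducible under
#' `set.seed()` but fresh on every call otherwise. No mapping from a UUID back
#' to any source identifier is ever retained.
#'
#' @param n Number of UUIDs to generate.
#' @return Character vector of `n` lowercase hyphenated UUIDs.
#' @export
#' @examples
#' uuid4(2)
uuid4 <- function(n = 1L) {
  if (n == 0L) return(character(0))
  bytes <- matrix(sample.int(256L, 16L * n, replace = TRUE) - 1L, nrow = 16L)
  bytes[7L, ] <- bitwOr(bitwAnd(bytes[7L, ], 0x0FL), 0x40L)  # version 4
  bytes[9L, ] <- bitwOr(bitwAnd(bytes[9L, ], 0x3FL), 0x80L)  # variant 10xx
  hex <- apply(bytes, 2L, function(b) paste(sprintf("%02x", b), collapse = ""))
  sub("^(.{8})(.{4})(.{4})(.{4})(.{12})$", "\\1-\\2-\\3-\\4-\\5", hex)
}

is_uuid <- function(x) {
  grepl("^[0-9a-f]{8}-[0-9a-f]{4}-[0-9a-f]{4}-[0-9a-f]{4}-[0-9a-f]{12}$", x)
}

abbrev_uuid <- function(x) substr(x, 1L, 8L)

## Calendar-year shift; Feb 29 targets normalise forward (libc convention).
add_years <- function(date, n) {
  if (n == 0) return(date)
  seq(date, by = sprintf("%d years", as.integer(n)), length.out = 2L)[2L]
}

## Completed years between two calendar dates.
age_at <- function(birth_date, on_date) {
  b <- as.POSIXlt(birth_date)
  o <- as.POSIXlt(on_date)
  age <- o$year - b$year
  if (o$mon < b$mon || (o$mon == b$mon && o$mday < b$mday)) age <- age - 1L
  as.integer(age)
}

iso_utc_now <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

is_iso_utc <- function(x) {
  grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}Z$", x)
}
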