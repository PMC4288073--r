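## Pooling of per-item relevance ratings across raters. The pooled summaries
## (mean, median, full score histogram per item) are the hand-off to
## downstream search-strategy design; no single pooling statistic is imposed.

#' Pool ratings across raters into per-item summaries
#'
#' One summary row per item that received at least one rating: number of
#' raters, mean and median score, and the full histogram of scores 0-3.
#' Rows are ordered by scenario order then item order; pooling is invariant
#' to the order of the rating rows. Items with zero ratings are excluded from
#' the summaries but listed in the `unrated` attribute, so "unrated" is never
#' conflated with "rated irrelevant".
#'
#' @param doc A `ratings_document`.
#' @param family The matching `scenario_family` (see [scenario_family()]).
#' @return Data frame of class `pooled_ratings` with columns scenario_uuid,
#'   item_uuid, category, n_raters, mean_score, median_score, hist_0..hist_3;
#'   attributes `unrated` (data frame of items without ratings) and
#'   `family_uuid` / `family_name`.
#' @export
pool_ratings <- function(doc, family) {
  validate_ratings_document(doc)
  items <- do.call(rbind, c(lapply(seq_along(family$scenarios), function(k) {
    s <- family$scenarios[[k]]
    if (length(s$items) == 0L) return(NULL)
    data.frame(scenario_uuid = s$scenario_uuid,
               item_uuid = vapply(s$items, `[[`, "", "item_uuid"),
               category = vapply(s$items, `[[`, "", "category"),
               stringsAsFactors = FALSE)
  }), list(data.frame(scenario_uuid = character(0), item_uuid = character(0),
                      category = character(0)))))
  r <- doc$ratings
  orphans <- setdiff(r$item_uuid, items$item_uuid)
  if (length(orphans) > 0L) {
    relrate_abort(sprintf("rating references item(s) not in the family: %s",
                          paste(orphans, collapse = ", ")),
                  "relrate_referential_error")
  }
  summarize_item <- function(i) {
    scores <- r$score[r$item_uuid == items$item_uuid[i]]
    if (length(scores) == 0L) return(NULL)
    hist <- tabulate(scores + 1L, nbins = 4L)
    data.frame(scenario_uuid = items$scenario_uuid[i],
               item_uuid = items$item_uuid[i],
               category = items$category[i],
               n_raters = length(scores),
               mean_score = mean(scores),
               median_score = as.numeric(median(scores)),
               hist_0 = hist[1L], hist_1 = hist[2L],
               hist_2 = hist[3L], hist_3 = hist[4L],
               stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(nrow(items)), summarize_item)
  rated <- !vapply(rows, is.null, logical(1))
  out <- do.call(rbind, c(rows[rated], list(data.frame(
    scenario_uuid = character(0), item_uuid = character(0),
    category = character(0), n_raters = integer(0), mean_score = numeric(0),
    median_score = numeric(0), hist_0 = integer(0), hist_1 = integer(0),
    hist_2 = integer(0), hist_3 = integer(0)))))
  rownames(out) <- NULL
  structure(out,
            unrated = items[!rated, , drop = FALSE],
            family_uuid = family$family_uuid,
            family_name = family$name,
            class = c("pooled_ratings", "data.frame"))
}

#' Pool ratings by item category
#'
#' Secondary grouping: pools every rating of every item of a category into
#' one row (number of ratings, mean, median, histogram), ordered as in
#' [item_categories()].
#'
#' @inheritParams pool_ratings
#' @return Data frame with one row per category that received ratings.
#' @export
pool_by_category <- function(doc, family) {
  per_item <- pool_ratings(doc, family)
  r <- doc$ratings
  cat_of <- function(item_uuid) {
    per_item$category[match(item_uuid, per_item$item_uuid)]
  }
  rows <- lapply(item_categories(), function(cat) {
    scores <- r$score[cat_of(r$item_uuid) == cat]
    if (length(scores) == 0L) return(NULL)
    hist <- tabulate(scores + 1L, nbins = 4L)
    data.frame(category = cat, n_ratings = length(scores),
               mean_score = mean(scores),
               median_score = as.numeric(median(scores)),
               hist_0 = hist[1L], hist_1 = hist[2L], hist_2 = hist[3L],
               hist_3 = hist[4L], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(data.frame(
    category = character(0), n_ratings = integer(0), mean_score = numeric(0),
    median_score = numeric(0), hist_0 = integer(0), hist_1 = integer(0),
    hist_2 = integer(0), hist_3 = integer(0)))))
  rownames(out) <- NULL
  out
}

#' Rank pooled items by relevance
#'
#' Stable descending sort of pooled summaries by mean or median score; ties
#' keep the input (scenario order, item order) ordering.
#'
#' @param summaries A `pooled_ratings` data frame.
#' @param by `"mean"` or `"median"`.
#' @return The reordered data frame.
#' @export
rank_items <- function(summaries, by = c("mean", "median")) {
  by <- match.arg(by)
  if (nrow(summaries) == 0L) {
    relrate_abort("summaries must be non-empty", "relrate_param_error")
  }
  col <- paste0(by, "_score")
  out <- summaries[order(-summaries[[col]], method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write pooled summaries as a TSV table
#'
#' @param summaries A `pooled_ratings` data frame (or the per-category
#'   table).
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_pooled_tsv <- function(summaries, path) {
  utils::write.table(as.data.frame(summaries), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
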