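# Five-item, five-star quality checklist --------------------------------------

#' Default five-item quality rubric
#'
#' The checklist scores five facets of a diagnostic-classifier study, 0-2
#' points each (total 0-10, stars = total / 2 rounded to the half-star):
#' \describe{
#'   \item{sample_representativeness}{0 if `n_total < n_threshold` and a
#'     single site; 1 if either large-sample or multi-site; 2 if both.}
#'   \item{cv_scheme}{0 for none/other, 1 for LOOCV, 2 for k-fold or nested
#'     k-fold.}
#'   \item{external_validation}{0 none, 1 independent within-country sample,
#'     2 cross-country sample.}
#'   \item{reporting_transparency}{half a point per reported metric among
#'     sensitivity, specificity, balanced accuracy, AUC (capped at 2).}
#'   \item{availability}{0 nothing shared, 1 data or model claimed, 2 data or
#'     model verified available.}
#' }
#' Missing fields score the item floor with a `not_reported` flag (a
#' transparency penalty, never an error). The rubric ships as a JSON file
#' (`system.file("extdata", "rubric_default.json", package = "metasample")`)
#' so the thresholds and point maps can be replaced wholesale.
#'
#' @param path Optional path to a rubric JSON file to load instead of the
#'   built-in default.
#' @return An object of class `rubric` (list of 5 item definitions plus the
#'   star map parameters).
#' @export
default_rubric <- function(path = NULL) {
  path <- path %||% system.file("extdata", "rubric_default.json",
                                package = "metasample")
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_rubric(spec)
}

validate_rubric <- function(spec) {
  if (length(spec$items$id) != 5L) {
    abort("rubric must define exactly 5 items.")
  }
  structure(spec, class = "rubric")
}

#' @export
print.rubric <- function(x, ...) {
  cat("Quality rubric (5 items, max", sum(x$items$max), "points):\n")
  for (i in seq_len(5)) {
    cat(sprintf("  %d. %s (0-%g)\n", i, x$items$name[i], x$items$max[i]))
  }
  invisible(x)
}

score_item <- function(item_id, record, rubric) {
  pars <- rubric$params
  val <- function(field) {
    v <- record[[field]]
    if (is.null(v) || length(v) == 0L || is.na(v)) NULL else v
  }
  switch(item_id,
    sample_representativeness = {
      n <- val("n_total"); sites <- val("n_sites")
      if (is.null(n) && is.null(sites)) return(list(points = 0, reported = FALSE))
      big <- !is.null(n) && n >= pars$n_threshold
      multi <- !is.null(sites) && sites >= pars$multi_site_min
      list(points = big + multi, reported = TRUE)
    },
    cv_scheme = {
      cv <- val("cv_scheme")
      if (is.null(cv)) return(list(points = 0, reported = FALSE))
      pts <- pars$cv_points[[cv]]
      list(points = if (is.null(pts)) 0 else pts, reported = TRUE)
    },
    external_validation = {
      ev <- val("external_validation")
      if (is.null(ev)) return(list(points = 0, reported = FALSE))
      pts <- pars$external_points[[ev]]
      list(points = if (is.null(pts)) 0 else pts, reported = TRUE)
    },
    reporting_transparency = {
      metrics <- c("sensitivity", "specificity", "balanced_accuracy", "auc")
      n_rep <- if (!is.null(val("reported_metrics"))) {
        rm <- strsplit(record[["reported_metrics"]], ";\\s*")[[1]]
        sum(metrics %in% rm)
      } else {
        sum(vapply(metrics, function(m) !is.null(val(m)), TRUE))
      }
      list(points = min(pars$transparency_cap, n_rep * pars$per_metric_points),
           reported = n_rep > 0)
    },
    availability = {
      verified <- isTRUE(val("data_verified")) || isTRUE(val("model_verified"))
      claimed <- isTRUE(val("data_claimed")) || isTRUE(val("model_claimed"))
      reported <- !is.null(val("data_claimed")) || !is.null(val("model_claimed"))
      list(points = if (verified) 2 else if (claimed) 1 else 0,
           reported = reported)
    },
    abort(sprintf("unknown rubric item `%s`.", item_id))
  )
}

star_map <- function(total, rubric) {
  # total -> half-star rating in {0.5, 1, ..., 5}
  pmax(0.5, floor(total / sum(rubric$items$max) * 10 + 0.5) / 2)
}

#' Score one study against the quality rubric
#'
#' @param record A single-row evidence tibble (or named list) holding the
#'   fields the rubric items read. Missing fields score the item floor and
#'   are flagged as not reported.
#' @param rubric A rubric from [default_rubric()].
#' @return A one-row tibble: `study_id`, one points column per item, `total`,
#'   `stars`, `n_not_reported`.
#' @export
score_study <- function(record, rubric = default_rubric()) {
  if (is.data.frame(record)) {
    if (nrow(record) != 1L) abort("`record` must be a single row; see score_table().")
    record <- as.list(record)
  }
  items <- rubric$items$id
  scored <- lapply(items, score_item, record = record, rubric = rubric)
  pts <- vapply(scored, `[[`, 1, "points")
  out <- as.list(setNames(pts, items))
  out$study_id <- record$study_id %||% NA_character_
  out$total <- sum(pts)
  out$stars <- star_map(out$total, rubric)
  out$n_not_reported <- sum(!vapply(scored, `[[`, TRUE, "reported"))
  as_tibble(out[c("study_id", items, "total", "stars", "n_not_reported")])
}

#' Score every study in an evidence table
#'
#' @param table An evidence table.
#' @param rubric A rubric from [default_rubric()].
#' @param low_quality_stars Studies strictly below this star rating count as
#'   low quality in the summary (default 3).
#' @return An object of class `quality_summary`: `scores` (per-study tibble),
#'   `by_year` and `by_disorder` mean-total tibbles, `low_quality_share`,
#'   `mean_total`, `mean_stars`, `low_quality_stars`.
#' @export
score_table <- function(table, rubric = default_rubric(), low_quality_stars = 3) {
  df <- as_tibble(table)
  if (!nrow(df)) abort("evidence table is empty.")
  scores <- purrr::map_dfr(seq_len(nrow(df)), function(i) {
    score_study(df[i, , drop = FALSE], rubric)
  })
  by_year <- NULL
  if ("year" %in% names(df)) {
    by_year <- tibble(year = df$year, total = scores$total, stars = scores$stars) |>
      dplyr::filter(!is.na(.data$year)) |>
      dplyr::group_by(.data$year) |>
      dplyr::summarise(n = dplyr::n(), mean_total = mean(.data$total),
                       mean_stars = mean(.data$stars), .groups = "drop")
  }
  by_disorder <- NULL
  if ("disorder" %in% names(df)) {
    by_disorder <- tibble(disorder = df$disorder, total = scores$total) |>
      dplyr::filter(!is.na(.data$disorder)) |>
      dplyr::group_by(.data$disorder) |>
      dplyr::summarise(n = dplyr::n(), mean_total = mean(.data$total),
                       .groups = "drop") |>
      dplyr::arrange(dplyr::desc(.data$mean_total))
  }
  structure(list(
    scores = scores,
    by_year = by_year,
    by_disorder = by_disorder,
    mean_total = mean(scores$total),
    mean_stars = mean(scores$stars),
    low_quality_share = mean(scores$stars < low_quality_stars),
    low_quality_stars = low_quality_stars,
    rubric = rubric
  ), class = "quality_summary")
}

#' @export
print.quality_summary <- function(x, ...) {
  cat(sprintf(
    "Quality scores for %d studies: mean total %.2f, mean stars %.2f\n  %.1f%% rated low quality (< %g stars)\n",
    nrow(x$scores), x$mean_total, x$mean_stars,
    100 * x$low_quality_share, x$low_quality_stars))
  invisible(x)
}

#' Flag scorer disagreement for third-rater adjudication
#'
#' Two independent scorings of the same study need a third rater when their
#' totals differ by strictly more than the threshold (default 2 points).
#'
#' @param scoreA,scoreB One-row score tibbles from [score_study()] (or
#'   numeric totals; then `study_id` matching is skipped).
#' @param threshold Maximum tolerated absolute difference (default 2).
#' @return `TRUE` if a third rater is needed.
#' @export
#' @examples
#' adjudicate(4, 7)  # TRUE
#' adjudicate(5, 7)  # FALSE: difference of exactly 2 is tolerated
adjudicate <- function(scoreA, scoreB, threshold = 2) {
  total <- function(s) if (is.data.frame(s)) s$total else as.numeric(s)
  id <- function(s) if (is.data.frame(s)) s$study_id else NA_character_
  ida <- id(scoreA); idb <- id(scoreB)
  if (!is.na(ida) && !is.na(idb) && ida != idb) {
    abort("scores belong to different studies.")
  }
  abs(total(scoreA) - total(scoreB)) > threshold
}
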