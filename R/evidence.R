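# Coded evidence table: schema, IO, validation, aggregation ------------------

# Enumerations used by the coded schema. Unknown levels are row-level
# violations, not hard errors, because coding conventions drift across teams.
evidence_enums <- list(
  first_author_field  = c("computer_data_science", "neuroscience", "psychiatry",
                          "psychology", "other"),
  economic_bloc       = c("MEDC", "LEDC"),
  data_source         = c("self_collected", "open_dataset"),
  modality            = c("MRI_fMRI", "EEG_ERP", "fNIRS", "MEG", "PET", "multimodal"),
  model_family        = c("shallow", "deep"),
  feature_selection   = c("pre_engineered", "algorithmic", "none"),
  cv_scheme           = c("none", "LOOCV", "kfold", "nested_kfold", "other"),
  external_validation = c("none", "within_country", "cross_country")
)

evidence_proportions <- c("accuracy", "sensitivity", "specificity",
                          "balanced_accuracy", "auc")
evidence_counts <- c("n_patients", "n_controls", "n_total", "n_test", "n_sites")
evidence_flags  <- c("data_claimed", "data_verified", "model_claimed", "model_verified")

#' Column schema of the coded evidence table
#'
#' One row per column of the evidence-table dialect the package reads and
#' writes: name, type, and whether the column is mandatory. Mandatory columns
#' are the minimum needed by the downstream inequality, performance and
#' quality stages; all other documented columns are optional and unknown
#' columns are carried through untouched.
#'
#' @return A tibble with columns `column`, `type`, `mandatory`.
#' @export
#' @examples
#' evidence_schema()
evidence_schema <- function() {
  mandatory <- c("study_id", "year", "sample_country", "n_patients",
                 "n_controls", "accuracy", "cv_scheme")
  cols <- c(
    study_id = "character", year = "integer", disorder = "character",
    first_author_field = "character", sample_country = "character",
    sample_region = "character", economic_bloc = "character",
    data_source = "character", modality = "character",
    model_family = "character", feature_selection = "character",
    cv_scheme = "character", external_validation = "character",
    n_patients = "integer", n_controls = "integer", n_total = "integer",
    n_test = "integer", accuracy = "double", sensitivity = "double",
    specificity = "double", balanced_accuracy = "double", auc = "double",
    reported_metrics = "character", n_sites = "integer",
    data_claimed = "logical", data_verified = "logical",
    model_claimed = "logical", model_verified = "logical"
  )
  tibble(column = names(cols), type = unname(cols),
         mandatory = names(cols) %in% mandatory)
}

new_evidence_tbl <- function(df, violations = NULL) {
  out <- as_tibble(df)
  class(out) <- c("evidence_tbl", class(out))
  attr(out, "violations") <- violations %||%
    tibble(row = integer(), study_id = character(), reason = character())
  out
}

#' Validation report of an evidence table
#'
#' @param table An evidence table read by [read_evidence_table()].
#' @return A tibble of dropped/flagged rows with columns `row`, `study_id`,
#'   `reason` (empty when the source file was fully valid).
#' @export
evidence_violations <- function(table) {
  attr(table, "violations") %||%
    tibble(row = integer(), study_id = character(), reason = character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

coerce_evidence_types <- function(df) {
  schema <- evidence_schema()
  for (i in seq_len(nrow(schema))) {
    col <- schema$column[i]
    if (!col %in% names(df)) next
    df[[col]] <- switch(
      schema$type[i],
      character = as.character(df[[col]]),
      integer   = suppressWarnings(as.integer(round(as.numeric(df[[col]])))),
      double    = suppressWarnings(as.numeric(df[[col]])),
      logical   = parse_flag(df[[col]])
    )
  }
  df
}

parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "yes", "y", "1")] <- TRUE
  out[x %in% c("false", "f", "no", "n", "0")] <- FALSE
  out
}

# Row-level rule checks; returns a tibble(row, study_id, reason).
collect_violations <- function(df, raw) {
  v <- list()
  note <- function(rows, reason) {
    if (length(rows)) {
      v[[length(v) + 1L]] <<- tibble(
        row = rows,
        study_id = as.character(df$study_id[rows]),
        reason = reason
      )
    }
  }

  dup <- which(duplicated(df$study_id) | duplicated(df$study_id, fromLast = TRUE))
  dup <- dup[dup != match(df$study_id[dup], df$study_id)] # keep first occurrence
  note(dup, "duplicate study_id")

  for (col in intersect(evidence_proportions, names(df))) {
    raw_present <- !is.na(raw[[col]]) & trimws(as.character(raw[[col]])) != ""
    bad_parse <- which(raw_present & is.na(df[[col]]))
    note(bad_parse, sprintf("unparseable numeric in `%s`", col))
    out_of_range <- which(!is.na(df[[col]]) & (df[[col]] < 0 | df[[col]] > 1))
    note(out_of_range, sprintf("%s out of [0,1]", col))
  }
  for (col in intersect(evidence_counts, names(df))) {
    raw_present <- !is.na(raw[[col]]) & trimws(as.character(raw[[col]])) != ""
    note(which(raw_present & is.na(df[[col]])),
         sprintf("unparseable numeric in `%s`", col))
    note(which(!is.na(df[[col]]) & df[[col]] < 0), sprintf("%s negative", col))
  }
  if ("year" %in% names(df)) {
    note(which(!is.na(df$year) & (df$year < 1990 | df$year > 2030)),
         "year outside [1990, 2030]")
  }
  if (all(c("n_patients", "n_controls", "n_total") %in% names(df))) {
    full <- !is.na(df$n_patients) & !is.na(df$n_controls) & !is.na(df$n_total)
    note(which(full & df$n_total != df$n_patients + df$n_controls),
         "n_total does not equal n_patients + n_controls")
  }
  for (col in intersect(names(evidence_enums), names(df))) {
    bad <- which(!is.na(df[[col]]) & !(df[[col]] %in% evidence_enums[[col]]))
    note(bad, sprintf("invalid %s level", col))
  }
  if (all(c("data_claimed", "data_verified") %in% names(df))) {
    note(which(isTRUE_vec(df$data_verified) & !isTRUE_vec(df$data_claimed)),
         "data_verified without data_claimed")
  }
  if (all(c("model_claimed", "model_verified") %in% names(df))) {
    note(which(isTRUE_vec(df$model_verified) & !isTRUE_vec(df$model_claimed)),
         "model_verified without model_claimed")
  }
  for (col in intersect(c("study_id", "year", "sample_country", "n_patients",
                          "n_controls", "accuracy", "cv_scheme"), names(df))) {
    missing_val <- is.na(df[[col]]) |
      (is.character(df[[col]]) & trimws(df[[col]]) == "")
    raw_blank <- if (col %in% names(raw)) {
      is.na(raw[[col]]) | trimws(as.character(raw[[col]])) == ""
    } else missing_val
    note(which(missing_val & raw_blank), sprintf("mandatory `%s` missing", col))
  }

  if (!length(v)) {
    return(tibble(row = integer(), study_id = character(), reason = character()))
  }
  dplyr::distinct(dplyr::arrange(dplyr::bind_rows(v), .data$row, .data$reason))
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Read and validate a coded evidence table
#'
#' Reads a delimited text file (comma by default, tab auto-detected) holding
#' one coded study per row, coerces columns to the documented schema, fills
#' `n_total` from `n_patients + n_controls` where absent, and checks the
#' row-level coding rules (proportions in \[0,1\], counts nonnegative, year in
#' \[1990, 2030\], count consistency, verified implies claimed, unique ids,
#' mandatory fields present). Unknown columns are preserved as passthrough.
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param strict If `TRUE` any violation aborts; otherwise offending rows are
#'   dropped and reported via [evidence_violations()].
#' @param aliases Optional named character vector mapping file column names to
#'   schema names, e.g. `c(country = "sample_country")`.
#' @param delim Field delimiter; `NULL` (default) auto-detects comma vs tab.
#' @return A validated evidence table (tibble subclass `evidence_tbl`) whose
#'   `"violations"` attribute reports dropped rows and reasons.
#' @seealso [write_evidence_table()], [aggregate_sample_by_unit()]
#' @export
read_evidence_table <- function(path, strict = FALSE, aliases = NULL, delim = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (is.null(delim)) {
    first <- readLines(path, n = 1L, warn = FALSE)
    delim <- if (grepl("\t", first)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           na = c("", "NA"), progress = FALSE,
                           show_col_types = FALSE)
  if (!is.null(aliases)) {
    hit <- names(raw) %in% names(aliases)
    names(raw)[hit] <- unname(aliases[names(raw)[hit]])
  }
  validate_evidence(raw, strict = strict)
}

#' Validate an in-memory evidence data frame
#'
#' Applies the same typing, completion and rule checks as
#' [read_evidence_table()] to a data frame already in memory.
#'
#' @param data A data frame with evidence-table columns.
#' @inheritParams read_evidence_table
#' @return An `evidence_tbl` with a `"violations"` attribute.
#' @export
validate_evidence <- function(data, strict = FALSE) {
  schema <- evidence_schema()
  missing_mandatory <- setdiff(schema$column[schema$mandatory], names(data))
  if (length(missing_mandatory)) {
    abort(sprintf("evidence table is missing mandatory column(s): %s",
                  paste(missing_mandatory, collapse = ", ")))
  }
  raw <- data
  df <- coerce_evidence_types(as_tibble(data))
  if (!"n_total" %in% names(df)) df$n_total <- NA_integer_
  fill <- is.na(df$n_total) & !is.na(df$n_patients) & !is.na(df$n_controls)
  df$n_total[fill] <- df$n_patients[fill] + df$n_controls[fill]

  violations <- collect_violations(df, raw)
  if (strict && nrow(violations)) {
    abort(sprintf(
      "evidence table failed strict validation (%d violation%s); first: row %d: %s",
      nrow(violations), if (nrow(violations) == 1L) "" else "s",
      violations$row[1], violations$reason[1]))
  }
  keep <- setdiff(seq_len(nrow(df)), unique(violations$row))
  new_evidence_tbl(df[keep, , drop = FALSE], violations)
}

#' Write an evidence table back to delimited text
#'
#' Round-trips with [read_evidence_table()]: a valid table written and re-read
#' reproduces every field.
#'
#' @param table An evidence table (or plain data frame).
#' @param path Output file path.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_evidence_table <- function(table, path, delim = ",") {
  readr::write_delim(as_tibble(table), path, delim = delim, na = "NA")
  invisible(path)
}

#' Aggregate sampled population by geographic unit
#'
#' Sums `n_total` over studies per unit (country by default), producing the
#' per-unit sample-population table that the Lorenz/Gini machinery consumes.
#' Each unit can carry a subgroup label ("module", e.g. the MEDC/LEDC economic
#' bloc) used by the Dagum decomposition.
#'
#' @param table An evidence table.
#' @param ... Optional filter expressions evaluated in the data (as in
#'   [dplyr::filter()]), applied before aggregation.
#' @param unit_field Name of the grouping column (default `"sample_country"`).
#' @param module_map Either `NULL` (single module `"all"`), the name of a
#'   column of `table` holding the label (e.g. `"economic_bloc"`), or a named
#'   character vector `c(unit = label, ...)`.
#' @param universe Optional character vector of unit ids to report even when
#'   their aggregated total is zero (zero-sample units are otherwise dropped).
#' @param value_field Column summed within units (default `"n_total"`).
#' @return A tibble with columns `unit`, `value`, `module` (a "grouped
#'   sample").
#' @export
#' @examples
#' ev <- validate_evidence(tibble::tibble(
#'   study_id = c("a", "b", "c"), year = 2020, sample_country = c("CN", "CN", "US"),
#'   n_patients = c(30, 20, 10), n_controls = c(20, 10, 10),
#'   accuracy = 0.8, cv_scheme = "kfold"))
#' aggregate_sample_by_unit(ev)
aggregate_sample_by_unit <- function(table, ..., unit_field = "sample_country",
                                     module_map = NULL, universe = NULL,
                                     value_field = "n_total") {
  df <- as_tibble(table)
  if (!unit_field %in% names(df)) {
    abort(sprintf("`unit_field` '%s' is not a column of the table.", unit_field))
  }
  if (!value_field %in% names(df)) {
    abort(sprintf("`value_field` '%s' is not a column of the table.", value_field))
  }
  dots <- enquos(...)
  if (length(dots)) df <- dplyr::filter(df, !!!dots)
  df <- df[!is.na(df[[unit_field]]) & !is.na(df[[value_field]]), , drop = FALSE]
  if (!nrow(df)) abort("no records left after filtering; nothing to aggregate.")

  module_col <- NULL
  if (is.character(module_map) && length(module_map) == 1L &&
      is.null(names(module_map)) && module_map %in% names(df)) {
    module_col <- module_map
  }
  out <- df |>
    dplyr::group_by(unit = .data[[unit_field]]) |>
    dplyr::summarise(
      value = sum(.data[[value_field]]),
      module = if (!is.null(module_col)) {
        dplyr::first(stats::na.omit(.data[[module_col]]))
      } else NA_character_,
      .groups = "drop")

  if (is.character(module_map) && !is.null(names(module_map))) {
    unresolved <- setdiff(out$unit, names(module_map))
    if (length(unresolved)) {
      abort(sprintf("units not resolvable in `module_map`: %s",
                    paste(unresolved, collapse = ", ")))
    }
    out$module <- unname(module_map[out$unit])
  }
  out$module[is.na(out$module)] <- "all"

  if (!is.null(universe)) {
    extra <- setdiff(universe, out$unit)
    if (length(extra)) {
      out <- dplyr::bind_rows(out, tibble(unit = extra, value = 0, module = "all"))
    }
  } else {
    out <- out[out$value > 0, , drop = FALSE]
  }
  if (!nrow(out)) abort("aggregation produced no units.")
  dplyr::arrange(out, .data$unit)
}
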