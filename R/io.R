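#' Cohort CSV schema
#'
#' Column contract for cohort tables exchanged on disk.  `required` columns
#' must be present for the analysis pipeline; `oracle` columns exist only in
#' synthetic cohorts.
#'
#' @return List with `version`, `required` and `oracle` character vectors.
#' @export
cohort_schema <- function() {
  list(
    version = "1",
    required = c("id", "age", "sofa", "kdigo_stage", "kdigo_stage_highest",
                 "sepsis", "first_icu_admission", "esrd", "potassium",
                 "treated", "died_28d"),
    oracle = c("p_death_control", "p_death_treated")
  )
}

#' Write a cohort table to CSV (with config echo)
#'
#' The first line is a schema-version comment (`# cohort_schema_version: 1`);
#' when the table carries a `sim_config` attribute it is echoed as JSON next
#' to the CSV (`<path>.config.json`).
#'
#' @param table A `cohort_table`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# cohort_schema_version: ", cohort_schema()$version), con)
  utils::write.csv(as.data.frame(table), con, row.names = FALSE)
  cfg <- attr(table, "sim_config")
  if (!is.null(cfg)) {
    cfg$covariate_spec <- lapply(cfg$covariate_spec, function(s) s)
    jsonlite::write_json(unclass(cfg), paste0(path, ".config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read and validate a cohort CSV
#'
#' @param path CSV written by [write_cohort()] (or any CSV with the schema's
#'   required columns; a leading `#` comment line is tolerated).
#' @return A `cohort_table`.
#' @export
read_cohort <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#")
  missing_cols <- setdiff(cohort_schema()$required, names(tab))
  if (length(missing_cols))
    stop("cohort file lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (v in c("sepsis", "first_icu_admission", "esrd", "treated", "died_28d"))
    tab[[v]] <- as.logical(tab[[v]])
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Write a covariate balance report as CSV
#'
#' @param balance Data.frame from [balance_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_balance_report <- function(balance, path) {
  utils::write.csv(balance, path, row.names = FALSE)
  invisible(path)
}

#' Write matched pairs as a two-column CSV
#'
#' @param match A `match_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_match_pairs <- function(match, path) {
  utils::write.csv(match$pairs[c("treated_id", "control_id")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Export uplift scores as CSV
#'
#' @param ids Identifiers.
#' @param p_z Predicted P(Z=1|X).
#' @param scores Uplift scores.
#' @param groups Benefit group factor (optional).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_uplift_scores <- function(ids, p_z, scores, groups = NULL, path) {
  out <- data.frame(id = ids, p_z = p_z, uplift_score = scores)
  if (!is.null(groups)) out$benefit_group <- as.character(groups)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
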