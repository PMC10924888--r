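#' KDIGO staging of acute kidney injury
#'
#' Grades AKI severity 0-3 from serum creatinine dynamics and urine output,
#' following the KDIGO criteria encoded as a declarative threshold table:
#'
#' * stage 1: SCr 1.5-1.9x baseline, or SCr rise >= 0.3 mg/dl within 48 h,
#'   or urine output < 0.5 ml/kg/h for 6-12 h;
#' * stage 2: SCr 2.0-2.9x baseline, or urine output < 0.5 ml/kg/h for
#'   >= 12 h;
#' * stage 3: SCr >= 3.0x baseline, or SCr >= 4.0 mg/dl, or initiation of
#'   renal replacement therapy, or urine output < 0.3 ml/kg/h for >= 24 h,
#'   or anuria >= 12 h.
#'
#' The creatinine-based and urine-output-based stages are computed
#' independently and the maximum is returned; being on RRT forces stage 3.
#' All arguments are vectorized and recycled to a common length.
#'
#' @param scr_ratio Ratio of current to baseline serum creatinine (> 0).
#' @param scr_increase_48h Absolute SCr rise within 48 h, mg/dl (>= 0).
#' @param scr_absolute Current SCr, mg/dl (>= 0).
#' @param uo_rate_6h,uo_rate_12h,uo_rate_24h Mean urine output over the
#'   trailing 6/12/24 h window, ml/kg/h (>= 0).
#' @param anuria_12h Logical; anuria for >= 12 h.
#' @param on_rrt Logical; renal replacement therapy initiated.
#' @param thresholds Named list overriding the encoded thresholds; see
#'   [kdigo_thresholds()].
#' @return Integer vector of stages in `{0, 1, 2, 3}`.
#' @export
kdigo_stage <- function(scr_ratio, scr_increase_48h = 0, scr_absolute = 0,
                        uo_rate_6h = Inf, uo_rate_12h = Inf, uo_rate_24h = Inf,
                        anuria_12h = FALSE, on_rrt = FALSE,
                        thresholds = kdigo_thresholds()) {
  args <- list(scr_ratio = scr_ratio, scr_increase_48h = scr_increase_48h,
               scr_absolute = scr_absolute, uo_rate_6h = uo_rate_6h,
               uo_rate_12h = uo_rate_12h, uo_rate_24h = uo_rate_24h)
  for (nm in names(args)) {
    if (anyNA(args[[nm]]) || any(args[[nm]] < 0))
      stop("`", nm, "` must be non-negative and non-missing", call. = FALSE)
  }
  if (any(scr_ratio <= 0))
    stop("`scr_ratio` must be > 0", call. = FALSE)
  n <- max(lengths(c(args, list(anuria_12h, on_rrt))))
  r <- rep_len(scr_ratio, n)
  inc <- rep_len(scr_increase_48h, n)
  abs_scr <- rep_len(scr_absolute, n)
  u6 <- rep_len(uo_rate_6h, n)
  u12 <- rep_len(uo_rate_12h, n)
  u24 <- rep_len(uo_rate_24h, n)
  anu <- rep_len(as.logical(anuria_12h), n)
  rrt <- rep_len(as.logical(on_rrt), n)
  th <- thresholds

  scr_stage <- ifelse(r >= th$scr_ratio_stage3 | abs_scr >= th$scr_abs_stage3, 3L,
               ifelse(r >= th$scr_ratio_stage2, 2L,
               ifelse(r >= th$scr_ratio_stage1 | inc >= th$scr_rise_stage1, 1L, 0L)))
  uo_stage <- ifelse(u24 < th$uo_rate_stage3 | anu, 3L,
              ifelse(u12 < th$uo_rate_stage12, 2L,
              ifelse(u6 < th$uo_rate_stage12, 1L, 0L)))
  stage <- pmax(scr_stage, uo_stage)
  stage[rrt] <- 3L
  as.integer(stage)
}

#' Default KDIGO threshold table
#'
#' The staging cut-points used by [kdigo_stage()], exposed so they are
#' auditable and overridable.
#'
#' @return Named list of thresholds (creatinine ratios, absolute creatinine
#'   in mg/dl, 48-h rise in mg/dl, urine-output rates in ml/kg/h).
#' @export
kdigo_thresholds <- function() {
  list(scr_ratio_stage1 = 1.5, scr_rise_stage1 = 0.3,
       scr_ratio_stage2 = 2.0,
       scr_ratio_stage3 = 3.0, scr_abs_stage3 = 4.0,
       uo_rate_stage12 = 0.5, uo_rate_stage3 = 0.3)
}

#' Apply study inclusion and exclusion filters to a raw cohort
#'
#' Retains ICU stays that satisfy the study criteria: sepsis diagnosis,
#' AKI (highest KDIGO stage during the stay >= 1), first ICU admission,
#' age >= 18 years, no end-stage renal disease, and blood potassium
#' <= 6.5 mmol/l (potassium above 6.5 is an urgent RRT indication and is
#' excluded).  Filters are conjunctive, applied in the study's order, and
#' each step is recorded in an attrition log.
#'
#' The table must carry both a baseline AKI stage (`kdigo_stage`) and the
#' highest stage observed during the stay (`kdigo_stage_highest`); inclusion
#' is decided on the highest stage, so baseline stage 0 can legitimately
#' appear in the filtered cohort.
#'
#' @param table A `cohort_table` or data.frame with columns `sepsis`,
#'   `kdigo_stage_highest`, `first_icu_admission`, `age`, `esrd`,
#'   `potassium`.
#' @return A list with elements `cohort` (the filtered table, original class
#'   preserved) and `attrition` (a data.frame with columns `filter`,
#'   `removed`, `remaining`, one row per filter plus an initial `input` row).
#' @export
apply_cohort_filters <- function(table) {
  required <- c("sepsis", "kdigo_stage_highest", "first_icu_admission",
                "age", "esrd", "potassium")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols))
    stop("cohort table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  filters <- list(
    sepsis              = function(d) d$sepsis,
    aki_kdigo_ge1       = function(d) d$kdigo_stage_highest >= 1,
    first_icu_admission = function(d) d$first_icu_admission,
    age_ge_18           = function(d) d$age >= 18,
    no_esrd             = function(d) !d$esrd,
    potassium_le_6.5    = function(d) d$potassium <= 6.5
  )

  log <- data.frame(filter = "input", removed = 0L, remaining = nrow(table))
  current <- table
  for (nm in names(filters)) {
    keep <- filters[[nm]](current)
    if (anyNA(keep))
      stop("filter `", nm, "` encountered missing values", call. = FALSE)
    removed <- sum(!keep)
    current <- current[keep, , drop = FALSE]
    log <- rbind(log, data.frame(filter = nm, removed = removed,
                                 remaining = nrow(current)))
  }
  rownames(current) <- NULL
  list(cohort = current, attrition = log)
}

#' Write an attrition log as JSON and pretty text
#'
#' @param attrition The attrition data.frame from [apply_cohort_filters()].
#' @param path Output path; `.json` is written at `path` and a text rendering
#'   at `paste0(path, ".txt")`.
#' @return Invisibly, `path`.
#' @export
write_attrition_log <- function(attrition, path) {
  jsonlite::write_json(attrition, path, dataframe = "rows", pretty = TRUE)
  txt <- sprintf("%-22s removed %6d  remaining %6d",
                 attrition$filter, attrition$removed, attrition$remaining)
  writeLines(txt, paste0(path, ".txt"))
  invisible(path)
}
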