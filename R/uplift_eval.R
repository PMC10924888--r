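#' Adjusted qini index at a fraction phi
#'
#' Evaluates the adjusted qini index
#' `Q(phi) = n_t1(phi)/N_t - n_c1(phi) * n_t(phi) / (N_t * n_c(phi))`
#' where `n_t(phi) = ceiling(phi * N_t)` treated and
#' `n_c(phi) = ceiling(phi * N_c)` control records are selected from the top
#' of each arm's score ranking, and `n_t1`, `n_c1` count observed 28-day
#' survivors among the selections.  The adjustment rescales the control
#' survivor count by the selected treated/control ratio, so arms of unequal
#' size remain comparable.  At `phi = 1` the index reduces to the overall
#' survival-rate difference between arms.
#'
#' @param phi Fraction in (0, 1].
#' @param t_outcomes,c_outcomes Binary outcome vectors (1 = survived 28
#'   days) for the treated and control arms, already ordered by ranker score,
#'   best first.
#' @return Scalar Q(phi).
#' @export
qini_at <- function(phi, t_outcomes, c_outcomes) {
  if (phi <= 0 || phi > 1) stop("`phi` must lie in (0, 1]", call. = FALSE)
  N_t <- length(t_outcomes); N_c <- length(c_outcomes)
  if (!N_t || !N_c) stop("both arms must be nonempty", call. = FALSE)
  n_t <- ceiling(phi * N_t)
  n_c <- ceiling(phi * N_c)
  if (n_c == 0) stop("no control records selected at phi = ", phi, call. = FALSE)
  n_t1 <- sum(t_outcomes[seq_len(n_t)])
  n_c1 <- sum(c_outcomes[seq_len(n_c)])
  n_t1 / N_t - n_c1 * n_t / (N_t * n_c)
}

#' Adjusted qini curve of a ranker
#'
#' Ranks each arm by the supplied score (descending; ties broken by id so
#' the curve is deterministic) and evaluates [qini_at()] over a grid of
#' fractions.  `Q(0) = 0` by definition.  The curve depends on scores only
#' through the within-arm rankings, so any strictly increasing transform of
#' the scores yields an identical curve.
#'
#' @param scores Numeric ranker scores (higher = more predicted benefit).
#' @param treated Logical/0-1 treatment flags.
#' @param survived Logical/0-1 flags for 28-day survival.
#' @param grid Ordered vector of fractions starting at 0 and ending at 1;
#'   default deciles.
#' @param ids Optional identifier vector used to break score ties
#'   deterministically (defaults to position).
#' @param label Ranker label carried on the curve.
#' @return Object of class `qini_curve`: list with `phi`, `Q`, `label`,
#'   `N_t`, `N_c`.
#' @export
qini_curve <- function(scores, treated, survived, grid = seq(0, 1, by = 0.1),
                       ids = seq_along(scores), label = "ranker") {
  n <- length(scores)
  if (length(treated) != n || length(survived) != n || length(ids) != n)
    stop("scores, treated, survived and ids must have equal length",
         call. = FALSE)
  if (grid[1] != 0 || grid[length(grid)] != 1 || is.unsorted(grid, strictly = TRUE))
    stop("`grid` must increase strictly from 0 to 1", call. = FALSE)
  treated <- as.logical(treated)
  y <- as.integer(as.logical(survived))
  if (!any(treated) || !any(!treated))
    stop("both arms must be nonempty", call. = FALSE)

  ord <- order(-scores, as.character(ids))
  treated_o <- treated[ord]; y_o <- y[ord]
  t_out <- y_o[treated_o]
  c_out <- y_o[!treated_o]

  Q <- vapply(grid, function(phi) {
    if (phi == 0) 0 else qini_at(phi, t_out, c_out)
  }, numeric(1))
  structure(list(phi = grid, Q = Q, label = label,
                 N_t = length(t_out), N_c = length(c_out)),
            class = "qini_curve")
}

#' Area under the uplift curve (AUUC)
#'
#' Trapezoidal area between the qini curve and the random line — the chord
#' from (0, 0) to (1, Q(1)).  A positive AUUC means the ranker targets
#' benefit better than random selection.
#'
#' @param curve A `qini_curve`.
#' @return Scalar AUUC.
#' @export
auuc <- function(curve) {
  stopifnot(inherits(curve, "qini_curve"))
  phi <- curve$phi
  excess <- curve$Q - phi * curve$Q[length(curve$Q)]
  sum(diff(phi) * (utils::head(excess, -1) + utils::tail(excess, -1)) / 2)
}

#' Clinical-score comparator ranker
#'
#' Turns a clinical severity score (e.g. SOFA or KDIGO stage) into a ranker
#' comparable with the uplift model in [qini_curve()].  With
#' `direction = "higher_benefits"` (the usual convention for severity
#' scores) higher scores rank first.
#'
#' @param table Cohort table.
#' @param column Score column name, e.g. `"sofa"` or `"kdigo_stage"`.
#' @param direction `"higher_benefits"` or `"lower_benefits"`.
#' @return Numeric score vector usable as `scores` in [qini_curve()].
#' @export
rank_by_clinical_score <- function(table, column,
                                   direction = c("higher_benefits",
                                                 "lower_benefits")) {
  direction <- match.arg(direction)
  if (!column %in% names(table))
    stop("column `", column, "` absent from table", call. = FALSE)
  x <- as.numeric(table[[column]])
  if (direction == "higher_benefits") x else -x
}

#' Additive per-feature contributions of an uplift model
#'
#' Exact additive attributions of each prediction to the model's features.
#' For the gradient-boosted learner these are tree SHAP values; for the
#' penalized logistic learner they are the linear terms `beta_j * x_j`.
#' Attributions are additive on the model's link (log-odds) scale:
#' per record, `baseline + sum_j contribution_j` reproduces the model's
#' margin, whose inverse-logit is the predicted P(Z = 1 | X).  Global
#' importance is the mean absolute contribution per feature.
#'
#' @param fit An `uplift_fit`.
#' @param newdata Table carrying the fit's features.
#' @return List with `contributions` (matrix, one row per record, one column
#'   per feature), `baseline` (per-record intercept/bias vector),
#'   `importance` (named, sorted decreasing) and `margin` (the reconstructed
#'   link-scale prediction).
#' @export
feature_contributions <- function(fit, newdata) {
  stopifnot(inherits(fit, "uplift_fit"))
  X <- impute_features(newdata, fit$features, fit$medians)
  if (fit$learner == "gbm") {
    contrib <- stats::predict(fit$model, xgboost::xgb.DMatrix(X),
                              predcontrib = TRUE)
    contrib <- matrix(contrib, nrow = nrow(X),
                      dimnames = list(NULL, c(fit$features, "BIAS")))
    baseline <- contrib[, "BIAS"]
    contrib <- contrib[, fit$features, drop = FALSE]
  } else if (fit$learner == "glmnet") {
    cf <- as.numeric(stats::coef(fit$model, s = "lambda.min"))
    names(cf) <- rownames(stats::coef(fit$model, s = "lambda.min"))
    baseline <- rep(cf["(Intercept)"], nrow(X))
    contrib <- sweep(X, 2, cf[fit$features], `*`)
  } else {
    stop("unsupported learner `", fit$learner,
         "`; consider a permutation-importance fallback", call. = FALSE)
  }
  importance <- sort(colMeans(abs(contrib)), decreasing = TRUE)
  list(contributions = contrib, baseline = as.numeric(baseline),
       importance = importance,
       margin = as.numeric(baseline) + rowSums(contrib))
}

#' Export qini curves as CSV and an AUUC report as JSON
#'
#' @param curves Named list of `qini_curve` objects.
#' @param csv_path,json_path Output paths (`NULL` to skip either).
#' @return Invisibly, a named list of AUUCs.
#' @export
write_qini_report <- function(curves, csv_path = NULL, json_path = NULL) {
  stopifnot(length(curves) > 0)
  tab <- do.call(rbind, lapply(curves, function(cv)
    data.frame(ranker = cv$label, phi = cv$phi, Q = cv$Q)))
  aucs <- lapply(curves, auuc)
  names(aucs) <- vapply(curves, `[[`, character(1), "label")
  if (!is.null(csv_path)) utils::write.csv(tab, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(aucs, json_path, auto_unbox = TRUE, digits = NA)
  invisible(aucs)
}
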