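#' Estimate propensity scores by main-effects logistic regression
#'
#' Fits `treated ~ covariates` with a binomial GLM and returns each record's
#' estimated probability of treatment.  Constant covariates are dropped with
#' a warning; (near-)perfect separation raises an error naming the covariate
#' with the most extreme coefficient.
#'
#' @param table A `cohort_table` or data.frame with a logical/0-1 `treated`
#'   column and an `id` column.
#' @param covariates Character vector of covariate column names (numeric or
#'   binary-encoded).
#' @param log_transform Covariates (subset of `covariates`) entered on the
#'   log scale — the usual choice for right-skewed positive labs such as
#'   creatinine, lactate, WBC or urine output, whose effect on treatment
#'   propensity is multiplicative rather than additive.  Values must be
#'   strictly positive.
#' @return Named numeric vector of propensity scores in (0, 1), names taken
#'   from `table$id`.
#' @export
fit_propensity <- function(table, covariates, log_transform = character()) {
  if (!all(covariates %in% names(table)))
    stop("covariates absent from table: ",
         paste(setdiff(covariates, names(table)), collapse = ", "),
         call. = FALSE)
  treated <- as.integer(table$treated)
  if (sum(treated == 1L) < 2L || sum(treated == 0L) < 2L)
    stop("need at least 2 records in each treatment arm", call. = FALSE)

  X <- table[covariates]
  for (v in intersect(log_transform, covariates)) {
    if (any(X[[v]] <= 0))
      stop("cannot log-transform `", v, "`: non-positive values present",
           call. = FALSE)
    X[[v]] <- log(X[[v]])
  }
  constant <- vapply(X, function(x) length(unique(x)) <= 1L, logical(1))
  if (any(constant)) {
    warning("dropping constant covariate(s): ",
            paste(covariates[constant], collapse = ", "), call. = FALSE)
    X <- X[!constant]
  }
  if (!ncol(X)) stop("no non-constant covariates left", call. = FALSE)
  dat <- cbind(.treated = treated, X)

  sep_warning <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.treated ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warning <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  ps <- stats::fitted(fit)
  eps <- 1e-9
  if (sep_warning && (any(ps > 1 - eps) || any(ps < eps))) {
    cf <- stats::coef(fit)[-1]
    worst <- names(cf)[which.max(abs(cf))]
    stop("(near-)perfect separation in the propensity model; ",
         "most extreme coefficient: ", worst, call. = FALSE)
  }
  ps <- pmin(pmax(ps, eps), 1 - eps)
  names(ps) <- as.character(table$id)
  ps
}

#' Greedy 1:1 nearest-neighbor propensity matching
#'
#' Matches each treated record to the nearest unmatched control by absolute
#' difference in logit propensity score, without replacement.  Treated
#' records are processed in descending propensity order (hardest-to-match
#' first); ties in processing order and in nearest-control distance are
#' broken by lowest id, so the result is deterministic.  A treated record is
#' left unmatched when its nearest remaining control is farther than the
#' caliper.
#'
#' @param propensity Named numeric vector of propensity scores in (0, 1)
#'   covering all treated and control ids (names are ids).
#' @param treated_ids,control_ids Character or numeric id vectors.
#' @param caliper Maximum allowed |logit(ps) difference|.  `"auto"` (default)
#'   uses 0.2 x SD of the logit propensity over all supplied ids, the common
#'   convention; `NULL` disables the caliper; a number is used as-is.
#' @return An object of class `match_result`: list with `pairs` (data.frame
#'   `treated_id`, `control_id`, `distance`), `propensity`, `caliper_used`
#'   (number or `NA` when disabled) and `n_unmatched_treated`.
#' @export
greedy_match <- function(propensity, treated_ids, control_ids,
                         caliper = "auto") {
  treated_ids <- as.character(treated_ids)
  control_ids <- as.character(control_ids)
  if (!length(control_ids)) stop("empty control pool", call. = FALSE)
  all_ids <- c(treated_ids, control_ids)
  if (!all(all_ids %in% names(propensity)))
    stop("propensity scores missing for some ids", call. = FALSE)
  lp <- stats::qlogis(propensity[all_ids])

  if (identical(caliper, "auto")) {
    caliper_used <- 0.2 * stats::sd(lp)
  } else if (is.null(caliper)) {
    caliper_used <- Inf
  } else {
    stopifnot(is.numeric(caliper), caliper >= 0)
    caliper_used <- caliper
  }

  lp_t <- lp[treated_ids]
  lp_c <- lp[control_ids]
  # descending propensity, then lowest id for determinism
  ord_t <- order(-lp_t, treated_ids)

  avail <- rep(TRUE, length(control_ids))
  # order of control ids used to break distance ties toward the lowest id
  ord_c_id <- order(control_ids)
  pairs_t <- character(0); pairs_c <- character(0); dists <- numeric(0)
  for (i in ord_t) {
    if (!any(avail)) break
    d <- abs(lp_c - lp_t[i])
    d[!avail] <- Inf
    # stable tie-break: among equal distances pick lowest control id
    best <- ord_c_id[which.min(d[ord_c_id])]
    if (d[best] <= caliper_used) {
      avail[best] <- FALSE
      pairs_t <- c(pairs_t, treated_ids[i])
      pairs_c <- c(pairs_c, control_ids[best])
      dists <- c(dists, d[best])
    }
  }
  structure(list(
    pairs = data.frame(treated_id = pairs_t, control_id = pairs_c,
                       distance = dists, stringsAsFactors = FALSE),
    propensity = propensity,
    caliper_used = if (is.infinite(caliper_used)) NA_real_ else caliper_used,
    n_unmatched_treated = length(treated_ids) - length(pairs_t)
  ), class = "match_result")
}

#' Standardized mean difference between two samples
#'
#' Continuous: `(mean_t - mean_c) / sqrt((s_t^2 + s_c^2) / 2)` with sample
#' SDs.  Binary: `(p_t - p_c) / sqrt((p_t(1-p_t) + p_c(1-p_c)) / 2)`.
#' The absolute value is returned; |SMD| < 0.1 conventionally indicates
#' adequate balance.  When the pooled variance is zero the SMD is 0 if the
#' means agree and an error otherwise.
#'
#' @param values_t,values_c Numeric (or logical, for binary) vectors for the
#'   treated and control samples.
#' @param type `"continuous"` or `"binary"`.
#' @return Non-negative scalar.
#' @export
standardized_mean_difference <- function(values_t, values_c,
                                         type = c("continuous", "binary")) {
  type <- match.arg(type)
  if (!length(values_t) || !length(values_c))
    stop("need at least one observation per arm", call. = FALSE)
  if (type == "binary") {
    p_t <- mean(as.numeric(values_t)); p_c <- mean(as.numeric(values_c))
    denom <- sqrt((p_t * (1 - p_t) + p_c * (1 - p_c)) / 2)
    num <- p_t - p_c
  } else {
    num <- mean(values_t) - mean(values_c)
    denom <- sqrt((stats::var(values_t) + stats::var(values_c)) / 2)
  }
  if (is.na(denom) || denom == 0) {
    if (isTRUE(all.equal(num, 0)) || num == 0) return(0)
    stop("zero pooled variance with unequal means: SMD undefined",
         call. = FALSE)
  }
  abs(num / denom)
}

#' Covariate balance before and after matching
#'
#' Computes per-covariate |SMD| between arms in the full cohort and in the
#' matched cohort.  Covariates with exactly two distinct values over the full
#' table are treated as binary, others as continuous.
#'
#' @param table The cohort table used for matching (with `id`, `treated`).
#' @param covariates Character vector of covariate names.
#' @param match A `match_result` from [greedy_match()].
#' @return Data.frame with columns `covariate`, `type`, `smd_before`,
#'   `smd_after`.
#' @export
balance_table <- function(table, covariates, match) {
  id <- as.character(table$id)
  tr <- as.logical(table$treated)
  in_t_after <- id %in% match$pairs$treated_id
  in_c_after <- id %in% match$pairs$control_id
  rows <- lapply(covariates, function(v) {
    x <- table[[v]]
    type <- if (length(unique(x)) == 2L) "binary" else "continuous"
    data.frame(
      covariate = v, type = type,
      smd_before = standardized_mean_difference(x[tr], x[!tr], type),
      smd_after = standardized_mean_difference(x[in_t_after], x[in_c_after],
                                               type)
    )
  })
  do.call(rbind, rows)
}
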