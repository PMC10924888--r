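#' Class-transformation label Z
#'
#' The class transformation reduces uplift estimation to a single binary
#' classification: Z = 1 for treated patients who survived 28 days and for
#' untreated patients who died within 28 days; Z = 0 otherwise.  When the
#' two arms are of equal size, `2 * P(Z = 1 | X) - 1` equals the individual
#' treatment effect on the survival scale.
#'
#' @param treated Logical (or 0/1) treatment flag.
#' @param died_28d Logical (or 0/1) 28-day death flag.
#' @return Integer vector of Z labels in `{0, 1}`.
#' @export
transform_labels <- function(treated, died_28d) {
  if (anyNA(treated) || anyNA(died_28d))
    stop("treatment and outcome flags must be non-missing", call. = FALSE)
  treated <- as.logical(treated)
  died <- as.logical(died_28d)
  as.integer((treated & !died) | (!treated & died))
}

#' Fit the class-transformation uplift model
#'
#' Computes Z labels with [transform_labels()] and fits a probabilistic
#' classifier for P(Z = 1 | X).  The default learner is a gradient-boosted
#' tree ensemble (supports exact additive attributions via
#' [feature_contributions()]); a ridge-penalized logistic regression is
#' available with `learner = "glmnet"`.  Missing covariate values are
#' median-imputed with medians computed on the training table; the same
#' medians are reused at prediction time.
#'
#' The 2P - 1 identity assumes equal arm sizes (as after 1:1 matching); a
#' warning is issued and recorded on the fit when the arms are unequal.
#'
#' @param table Training `cohort_table` with `treated` and `died_28d`.
#' @param features Character vector of feature column names.
#' @param learner `"gbm"` (gradient-boosted trees, default) or `"glmnet"`.
#' @param params For `"gbm"`, a list overriding the xgboost defaults
#'   (`max_depth = 3`, `eta = 0.1`, `nrounds = 200`, `min_child_weight = 20`,
#'   `nthread = 1`); for `"glmnet"`, overrides of `alpha = 0` and `nfolds =
#'   5`.
#' @param seed Integer seed; the fit is deterministic given it.
#' @return An object of class `uplift_fit`: list with `learner`, `model`,
#'   `features`, `medians`, `seed`, `n_t`, `n_c`, `unequal_arms`.
#' @export
fit_class_transformation <- function(table, features, learner = c("gbm", "glmnet"),
                                     params = list(), seed = 1L) {
  learner <- match.arg(learner)
  if (!all(features %in% names(table)))
    stop("features absent from table: ",
         paste(setdiff(features, names(table)), collapse = ", "),
         call. = FALSE)
  treated <- as.logical(table$treated)
  n_t <- sum(treated); n_c <- sum(!treated)
  if (n_t == 0L || n_c == 0L)
    stop("both treatment arms must be present to fit an uplift model",
         call. = FALSE)
  z <- transform_labels(table$treated, table$died_28d)
  if (length(unique(z)) < 2L)
    stop("transformed label Z is single-class; cannot fit a classifier",
         call. = FALSE)
  unequal <- n_t != n_c
  if (unequal)
    warning("treatment arms are unequal (", n_t, " vs ", n_c, "); the ",
            "2*P(Z=1|X)-1 uplift identity assumes equal arm sizes ",
            "(e.g. after 1:1 matching)", call. = FALSE)

  medians <- vapply(table[features],
                    function(x) stats::median(as.numeric(x), na.rm = TRUE),
                    numeric(1))
  X <- impute_features(table, features, medians)

  if (learner == "gbm") {
    p <- utils::modifyList(list(max_depth = 3, eta = 0.1, nrounds = 200,
                                min_child_weight = 20, nthread = 1), params)
    set.seed(seed)
    model <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = p$max_depth,
                    eta = p$eta, min_child_weight = p$min_child_weight,
                    nthread = p$nthread, subsample = 1, colsample_bytree = 1),
      data = xgboost::xgb.DMatrix(X, label = z),
      nrounds = p$nrounds, verbose = 0)
  } else {
    p <- utils::modifyList(list(alpha = 0, nfolds = 5), params)
    set.seed(seed)
    model <- glmnet::cv.glmnet(X, z, family = "binomial", alpha = p$alpha,
                               nfolds = p$nfolds)
  }
  structure(list(learner = learner, model = model, features = features,
                 medians = medians, seed = as.integer(seed),
                 n_t = n_t, n_c = n_c, unequal_arms = unequal),
            class = "uplift_fit")
}

impute_features <- function(table, features, medians) {
  X <- vapply(features, function(v) {
    x <- as.numeric(table[[v]])
    x[is.na(x)] <- medians[[v]]
    x
  }, numeric(nrow(table)))
  X <- matrix(X, nrow = nrow(table), dimnames = list(NULL, features))
  X
}

#' Predicted P(Z = 1 | X)
#'
#' @param fit An `uplift_fit`.
#' @param newdata Table carrying the fit's feature columns.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
predict_pz <- function(fit, newdata) {
  stopifnot(inherits(fit, "uplift_fit"))
  X <- impute_features(newdata, fit$features, fit$medians)
  if (fit$learner == "gbm") {
    as.numeric(stats::predict(fit$model, xgboost::xgb.DMatrix(X)))
  } else {
    as.numeric(stats::predict(fit$model, newx = X, s = "lambda.min",
                              type = "response"))
  }
}

#' Uplift score from a fitted class-transformation model
#'
#' `uplift_score = 2 * P(Z = 1 | X) - 1`, the estimated individual treatment
#' effect on the 28-day survival scale under equal arm sizes.  Predicted
#' probabilities are clipped to \[1e-6, 1 - 1e-6\] before the transform so
#' overfit trees cannot produce spurious exact +/-1 scores.
#'
#' @inheritParams predict_pz
#' @return Numeric vector in (-1, 1).
#' @export
uplift_score <- function(fit, newdata) {
  p <- pmin(pmax(predict_pz(fit, newdata), 1e-6), 1 - 1e-6)
  2 * p - 1
}

#' Stratified development/validation split
#'
#' Randomly partitions a cohort into a development (training) and a
#' validation set of the requested sizes, preserving the treatment-arm
#' proportion in both (largest-remainder allocation per arm, so the totals
#' are exact).  Deterministic given `seed`.
#'
#' @param table Cohort table with `treated`.
#' @param dev_size,val_size Target sizes; must sum to `nrow(table)`.
#' @param stratify Stratify by treatment arm (default `TRUE`).
#' @param seed Integer seed.
#' @return List with elements `development` and `validation`.
#' @export
split_development_validation <- function(table, dev_size, val_size,
                                         stratify = TRUE, seed = 1L) {
  n <- nrow(table)
  if (dev_size + val_size != n)
    stop("dev_size + val_size (", dev_size + val_size,
         ") must equal the cohort size (", n, ")", call. = FALSE)
  if (dev_size < 0 || val_size < 0)
    stop("split sizes must be non-negative", call. = FALSE)
  set.seed(seed)
  if (!stratify) {
    dev_idx <- sort(sample.int(n, dev_size))
  } else {
    arm <- as.logical(table$treated)
    idx_by_arm <- split(seq_len(n), arm)
    sizes <- vapply(idx_by_arm, length, integer(1))
    # largest-remainder allocation of dev_size across arms
    exact <- sizes * dev_size / n
    base <- floor(exact)
    rem <- dev_size - sum(base)
    if (rem > 0) {
      extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1L
    }
    if (any(base > sizes) || any((sizes - base) < 0))
      stop("infeasible stratified split for the given arm sizes",
           call. = FALSE)
    dev_idx <- sort(unlist(mapply(function(idx, k) sample(idx, k),
                                  idx_by_arm, base, SIMPLIFY = FALSE),
                           use.names = FALSE))
  }
  list(development = table[dev_idx, , drop = FALSE],
       validation = table[setdiff(seq_len(n), dev_idx), , drop = FALSE])
}

#' Median split into high- and low-benefit groups
#'
#' Orders records by uplift score (descending, ties broken by id for
#' determinism) and assigns the top half to the high-benefit group; group
#' sizes differ by at most one.
#'
#' @param ids Identifier vector.
#' @param scores Numeric uplift scores, same length as `ids`.
#' @return Factor with levels `c("high", "low")`, named by id.
#' @export
split_benefit_groups <- function(ids, scores) {
  if (length(ids) != length(scores))
    stop("ids and scores must have equal length", call. = FALSE)
  n <- length(ids)
  if (n < 2L) stop("need at least 2 records to split", call. = FALSE)
  ord <- order(-scores, ids)   # ids keep their native ordering (numeric ids
                               # sort numerically)
  n_high <- ceiling(n / 2)
  grp <- rep("low", n)
  grp[ord[seq_len(n_high)]] <- "high"
  stats::setNames(factor(grp, levels = c("high", "low")), as.character(ids))
}
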