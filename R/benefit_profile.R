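#' Compare variables between high- and low-benefit groups
#'
#' For each variable the test is chosen by an explicit rule: categorical
#' variables (logical, factor, or at most `max_levels` distinct values) use
#' the chi-square test (with Yates continuity correction on 2x2 tables);
#' continuous variables use Student's t-test when a Shapiro-Wilk test at
#' `alpha = 0.05` does not reject normality in either group, and the
#' Mann-Whitney U test otherwise.  Constant variables are reported with
#' `p = NA` and flagged.
#'
#' @param table Data with the variables.
#' @param labels Two-level grouping (factor/character/logical), e.g. the
#'   output of [split_benefit_groups()].
#' @param variables Character vector of variable names.
#' @param max_levels Distinct-value cutoff below which a numeric variable is
#'   treated as categorical (default 4, covering KDIGO stage and qSOFA).
#' @return Data.frame of class `group_comparison`: one row per variable with
#'   `variable`, `test`, `statistic`, `p`, group means, and `flag`.
#' @export
compare_groups <- function(table, labels, variables, max_levels = 4L) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L)
    stop("`labels` must have exactly two levels", call. = FALSE)
  g1 <- labels == levels(labels)[1]
  g2 <- labels == levels(labels)[2]
  if (!any(g1) || !any(g2)) stop("both groups must be nonempty", call. = FALSE)

  one <- function(v) {
    x <- table[[v]]
    categorical <- is.logical(x) || is.factor(x) ||
      length(unique(x)) <= max_levels
    x_num <- as.numeric(if (is.factor(x)) as.integer(x) else x)
    m1 <- mean(x_num[g1]); m2 <- mean(x_num[g2])
    if (length(unique(x)) <= 1L)
      return(data.frame(variable = v, test = "none", statistic = NA_real_,
                        p = NA_real_, mean_1 = m1, mean_2 = m2,
                        flag = "constant"))
    if (categorical) {
      tab <- table(factor(x), labels)
      ht <- suppressWarnings(stats::chisq.test(tab))
      test <- "chi-square"
    } else {
      sw_p <- function(g) {
        xs <- x_num[g]
        if (length(xs) < 3 || length(unique(xs)) == 1) return(0)
        if (length(xs) > 4999) xs <- xs[seq(1, length(xs), length.out = 4999)]
        stats::shapiro.test(xs)$p.value
      }
      normal <- sw_p(g1) >= 0.05 && sw_p(g2) >= 0.05
      ht <- if (normal) stats::t.test(x_num[g1], x_num[g2])
            else suppressWarnings(stats::wilcox.test(x_num[g1], x_num[g2]))
      test <- if (normal) "t" else "mann-whitney"
    }
    data.frame(variable = v, test = test,
               statistic = unname(ht$statistic), p = ht$p.value,
               mean_1 = m1, mean_2 = m2, flag = "")
  }
  out <- do.call(rbind, lapply(variables, one))
  names(out)[names(out) == "mean_1"] <- paste0("mean_", levels(labels)[1])
  names(out)[names(out) == "mean_2"] <- paste0("mean_", levels(labels)[2])
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Logistic model of benefit-group membership
#'
#' Fits a main-effects logistic regression of the (binary) benefit label on
#' the selected variables and reports odds ratios with Wald 95% confidence
#' intervals — the classical presentation of a clinical benefit model.
#'
#' @param table Data with the variables.
#' @param labels Two-level benefit labels; the *first* level (e.g. `"high"`)
#'   is modeled as the event.
#' @param variables Character vector of predictor names (numeric).
#' @return List of class `benefit_logistic`: `fit` (the glm), `or_table`
#'   (data.frame `variable`, `or`, `ci_low`, `ci_high`, `p`).
#' @export
fit_benefit_logistic <- function(table, labels, variables) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L)
    stop("`labels` must have exactly two levels", call. = FALSE)
  y <- as.integer(labels == levels(labels)[1])
  if (nrow(table) <= length(variables) + 1L)
    stop("fewer rows than model parameters", call. = FALSE)
  dat <- data.frame(.y = y, table[variables])

  sep_warning <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep_warning <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (sep_warning && (fit$deviance / fit$null.deviance < 1e-4 ||
                      any(abs(stats::coef(fit)[-1]) > 15)))
    stop("(near-)perfect separation in the benefit model", call. = FALSE)

  cf <- summary(fit)$coefficients[-1, , drop = FALSE]
  z <- stats::qnorm(0.975)
  or_table <- data.frame(
    variable = variables,
    or = exp(cf[, "Estimate"]),
    ci_low = exp(cf[, "Estimate"] - z * cf[, "Std. Error"]),
    ci_high = exp(cf[, "Estimate"] + z * cf[, "Std. Error"]),
    p = cf[, "Pr(>|z|)"],
    row.names = NULL
  )
  structure(list(fit = fit, or_table = or_table), class = "benefit_logistic")
}

#' Build a regression nomogram from a logistic benefit model
#'
#' Standard regression-nomogram construction: each variable's axis assigns
#' `points_i(x) = 100 * beta_i * (x - x_i_ref) / K` where `x_i_ref` is the
#' end of the variable's range minimizing `beta_i * x` (so points are always
#' non-negative and a negative-coefficient variable scores highest at the
#' low end of its axis) and `K = max_j |beta_j| * range_j` (so the most
#' influential variable spans 0-100 points).  The total-points axis maps
#' back to probability through the logistic function:
#' `p(total) = plogis(lp0 + K/100 * total)` with
#' `lp0 = intercept + sum_i beta_i * x_i_ref`.
#'
#' @param model A `benefit_logistic` from [fit_benefit_logistic()].
#' @param ranges Named list of `c(low, high)` axis ranges, one per model
#'   variable (finite).
#' @param n_table Rows in the exported total-points-to-probability table.
#' @return Object of class `nomogram`: per-variable axis descriptors
#'   (`range`, `x_ref`, `points_per_unit`), `lp0`, `K`, `coefficients`, and
#'   `prob_table` (data.frame `total_points`, `probability`).
#' @export
build_nomogram <- function(model, ranges, n_table = 101L) {
  stopifnot(inherits(model, "benefit_logistic"))
  beta <- stats::coef(model$fit)
  intercept <- beta["(Intercept)"]
  beta <- beta[-1]
  vars <- names(beta)
  if (!all(vars %in% names(ranges)))
    stop("ranges missing for: ",
         paste(setdiff(vars, names(ranges)), collapse = ", "), call. = FALSE)
  if (all(beta == 0))
    stop("all coefficients are zero; nomogram undefined", call. = FALSE)
  for (v in vars) {
    r <- ranges[[v]]
    if (length(r) != 2L || !all(is.finite(r)) || r[1] >= r[2])
      stop("range for `", v, "` must be a finite c(low, high) with low < high",
           call. = FALSE)
  }
  widths <- vapply(vars, function(v) diff(ranges[[v]]), numeric(1))
  K <- max(abs(beta) * widths)
  axes <- lapply(vars, function(v) {
    r <- ranges[[v]]
    x_ref <- if (beta[[v]] >= 0) r[1] else r[2]
    list(range = r, x_ref = x_ref,
         points_per_unit = 100 * beta[[v]] / K)
  })
  names(axes) <- vars
  lp0 <- intercept + sum(vapply(vars, function(v) beta[[v]] * axes[[v]]$x_ref,
                                numeric(1)))
  max_total <- sum(vapply(vars, function(v)
    100 * abs(beta[[v]]) * widths[[v]] / K, numeric(1)))
  total_grid <- seq(0, max_total, length.out = n_table)
  prob_table <- data.frame(
    total_points = total_grid,
    probability = stats::plogis(lp0 + K / 100 * total_grid))
  structure(list(axes = axes, lp0 = unname(lp0), K = K,
                 coefficients = beta, intercept = unname(intercept),
                 prob_table = prob_table),
            class = "nomogram")
}

#' Points assigned by a nomogram to patient profiles
#'
#' @param nomogram A `nomogram`.
#' @param newdata Data with the nomogram's variables.
#' @return Data.frame with one points column per variable and a
#'   `total_points` column.
#' @export
nomogram_points <- function(nomogram, newdata) {
  stopifnot(inherits(nomogram, "nomogram"))
  pts <- vapply(names(nomogram$axes), function(v) {
    ax <- nomogram$axes[[v]]
    ax$points_per_unit * (as.numeric(newdata[[v]]) - ax$x_ref)
  }, numeric(nrow(newdata)))
  pts <- matrix(pts, nrow = nrow(newdata),
                dimnames = list(NULL, names(nomogram$axes)))
  out <- as.data.frame(pts)
  out$total_points <- rowSums(pts)
  out
}

#' Probability of benefit from nomogram total points
#'
#' @param nomogram A `nomogram`.
#' @param total_points Numeric vector of total points.
#' @return Probabilities via the underlying logistic model.
#' @export
nomogram_probability <- function(nomogram, total_points) {
  stopifnot(inherits(nomogram, "nomogram"))
  stats::plogis(nomogram$lp0 + nomogram$K / 100 * total_points)
}

#' Export a nomogram as JSON
#'
#' Writes the axis descriptors (as breakpoint tables) and the
#' total-points-to-probability table.
#'
#' @param nomogram A `nomogram`.
#' @param path Output JSON path.
#' @param n_breaks Breakpoints per axis.
#' @return Invisibly, `path`.
#' @export
write_nomogram_json <- function(nomogram, path, n_breaks = 11L) {
  axes <- lapply(nomogram$axes, function(ax) {
    xs <- seq(ax$range[1], ax$range[2], length.out = n_breaks)
    list(range = ax$range, x_ref = ax$x_ref,
         breakpoints = data.frame(value = xs,
                                  points = ax$points_per_unit * (xs - ax$x_ref)))
  })
  jsonlite::write_json(list(axes = axes, lp0 = nomogram$lp0, K = nomogram$K,
                            prob_table = nomogram$prob_table),
                       path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Two-proportion chi-square test with continuity correction
#'
#' 2x2 chi-square comparison of two event rates with Yates continuity
#' correction, two-sided — the standard comparison of 28-day mortality
#' between matched arms.
#'
#' @param events_1,n_1 Events and size of group 1.
#' @param events_2,n_2 Events and size of group 2.
#' @return List with `statistic` (X-squared) and `p`.
#' @export
two_proportion_test <- function(events_1, n_1, events_2, n_2) {
  if (events_1 > n_1 || events_2 > n_2 || any(c(events_1, events_2) < 0))
    stop("event counts must lie in [0, n]", call. = FALSE)
  tab <- rbind(c(events_1, n_1 - events_1), c(events_2, n_2 - events_2))
  if (any(colSums(tab) == 0) || any(rowSums(tab) == 0))
    stop("degenerate 2x2 table (zero margin)", call. = FALSE)
  ht <- stats::prop.test(c(events_1, events_2), c(n_1, n_2), correct = TRUE)
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Power for comparing two proportions
#'
#' Two-sided power of the difference-of-proportions test at level `alpha`
#' with `n` subjects per group.  `method = "normal"` uses the standard
#' normal approximation (pooled SE under the null, unpooled under the
#' alternative); `method = "ttest"` exposes the two-sample t-test variant
#' computed on the 0/1 outcomes via [stats::power.t.test()], for
#' comparability with sample-size calculations framed as t-tests.
#'
#' @param p1,p2 True proportions, strictly in (0, 1).
#' @param n Per-group sample size (>= 2).
#' @param alpha Two-sided significance level.
#' @param method `"normal"` (default) or `"ttest"`.
#' @return Power in \[0, 1\].
#' @export
power_two_proportions <- function(p1, p2, n, alpha = 0.05,
                                  method = c("normal", "ttest")) {
  method <- match.arg(method)
  if (p1 <= 0 || p1 >= 1 || p2 <= 0 || p2 >= 1)
    stop("`p1` and `p2` must lie strictly in (0, 1)", call. = FALSE)
  if (n < 2) stop("`n` must be >= 2", call. = FALSE)
  if (method == "ttest") {
    sd_pool <- sqrt((p1 * (1 - p1) + p2 * (1 - p2)) / 2)
    if (p1 == p2) return(alpha)
    return(stats::power.t.test(n = n, delta = abs(p1 - p2), sd = sd_pool,
                               sig.level = alpha)$power)
  }
  pbar <- (p1 + p2) / 2
  se0 <- sqrt(2 * pbar * (1 - pbar) / n)
  se1 <- sqrt(p1 * (1 - p1) / n + p2 * (1 - p2) / n)
  z <- stats::qnorm(1 - alpha / 2)
  d <- abs(p1 - p2)
  stats::pnorm((d - z * se0) / se1) + stats::pnorm((-d - z * se0) / se1)
}
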