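#' Simulation configuration for a synthetic S-AKI cohort
#'
#' Builds the configuration object consumed by [generate_cohort()].  The
#' generator emulates an observational ICU cohort of sepsis-associated acute
#' kidney injury (S-AKI) patients in which renal replacement therapy (RRT) is
#' the binary treatment: treatment assignment is confounded with illness
#' severity (sicker patients are more likely to be treated), the outcome is
#' binary 28-day death, and the individual treatment effect is a known,
#' covariate-dependent function so that downstream estimators can be scored
#' against ground truth.
#'
#' The treatment model is logistic in a standardized severity index built
#' from SOFA, creatinine, lactate and (negated) urine output; its intercept is
#' calibrated by bisection so the expected treated fraction equals
#' `treat_fraction_target`.  Control-arm death probability is logistic in the
#' same severity index.  The treatment effect tau(X) (reduction in death
#' probability under treatment) is linear in standardized covariates on the
#' probability scale:
#' `tau(X) = effect_intercept + sum_v effect_coefs[v] * z_v(X)`,
#' and `p_death_treated = p_death_control - tau(X)` clipped to \[0, 1\]
#' (the number of clipped records is recorded on the generated table).
#'
#' @param n_patients Number of ICU stays to generate (>= 4).
#' @param treat_fraction_target Target expected proportion treated with RRT.
#' @param confounding_strength Log-odds of treatment per SD of the severity
#'   index; 0 gives a randomized cohort.
#' @param baseline_mortality_logit Logit of 28-day death probability for a
#'   control patient of average severity.
#' @param severity_mortality_logodds Log-odds of death per SD of severity.
#' @param effect_intercept Average treatment effect component of tau(X), on
#'   the death-probability scale (positive = treatment reduces mortality).
#' @param effect_coefs Named numeric vector mapping covariate name to its
#'   contribution to tau(X) per SD of that (standardized) covariate.  Every
#'   name must appear in `covariate_spec`.  The default concentrates benefit
#'   in patients with low urine output, high lactate and high white cell
#'   count.
#' @param covariate_spec Named list describing the marginal distribution of
#'   each covariate; see [default_covariate_spec()].
#' @param filter_violation_rates Named numeric vector with elements
#'   `not_first_admission`, `esrd` and `no_sepsis`: fractions of records that
#'   violate the corresponding study inclusion rule, so the cohort filters
#'   have realistic work to do.
#' @param seed Integer master seed; per-stage sub-streams are derived from it
#'   deterministically.
#'
#' @return An object of class `sim_config` (a named list).
#' @seealso [generate_cohort()], [true_uplift()]
#' @export
sim_config <- function(n_patients = 8000L,
                       treat_fraction_target = 0.08,
                       confounding_strength = 1.0,
                       baseline_mortality_logit = stats::qlogis(0.30),
                       severity_mortality_logodds = 0.9,
                       effect_intercept = 0.07,
                       effect_coefs = c(urine_output = -0.08,
                                        lactate = 0.06,
                                        wbc = 0.05),
                       covariate_spec = default_covariate_spec(),
                       filter_violation_rates = c(not_first_admission = 0.05,
                                                  esrd = 0.03,
                                                  no_sepsis = 0.02),
                       seed = 1L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 4)
    stop("`n_patients` must be a single number >= 4", call. = FALSE)
  if (treat_fraction_target <= 0 || treat_fraction_target >= 1)
    stop("`treat_fraction_target` must lie strictly in (0, 1)", call. = FALSE)
  if (confounding_strength < 0)
    stop("`confounding_strength` must be >= 0", call. = FALSE)
  if (length(effect_coefs) && is.null(names(effect_coefs)))
    stop("`effect_coefs` must be a named vector", call. = FALSE)
  missing_vars <- setdiff(names(effect_coefs), names(covariate_spec))
  if (length(missing_vars))
    stop("effect_coefs name covariates absent from covariate_spec: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  needed <- c("sofa", "creatinine", "lactate", "urine_output")
  if (!all(needed %in% names(covariate_spec)))
    stop("covariate_spec must include the severity-index covariates: ",
         paste(needed, collapse = ", "), call. = FALSE)
  for (nm in names(filter_violation_rates))
    if (filter_violation_rates[[nm]] < 0 || filter_violation_rates[[nm]] >= 1)
      stop("filter_violation_rates['", nm, "'] must lie in [0, 1)", call. = FALSE)
  structure(list(
    n_patients = as.integer(n_patients),
    treat_fraction_target = treat_fraction_target,
    confounding_strength = confounding_strength,
    baseline_mortality_logit = baseline_mortality_logit,
    severity_mortality_logodds = severity_mortality_logodds,
    effect_intercept = effect_intercept,
    effect_coefs = effect_coefs,
    covariate_spec = covariate_spec,
    filter_violation_rates = filter_violation_rates,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Log-normal parameters from an arithmetic mean and SD
#'
#' @param mean,sd Arithmetic mean and standard deviation of the target
#'   log-normal distribution (both > 0).
#' @return Named vector `c(meanlog, sdlog)`.
#' @export
lognormal_params <- function(mean, sd) {
  stopifnot(mean > 0, sd > 0)
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  c(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Default covariate distributions for the synthetic S-AKI cohort
#'
#' Marginal distributions chosen to emulate a general adult ICU S-AKI
#' population: log-normal for right-skewed labs and volumes (lactate,
#' creatinine, WBC, BUN, urine output, fluid input), normal for vitals,
#' integer-categorical for ordinal scores (KDIGO baseline stage, qSOFA) and a
#' rounded, clamped normal for SOFA.  Units: creatinine mg/dl, glucose mg/dl
#' (labs reported elsewhere in mmol/l or umol/l are converted once:
#' 1 mg/dl creatinine = 88.4 umol/l; 1 mmol/l glucose = 18.016 mg/dl),
#' urine output and fluid input ml/24h, temperature degrees C.
#'
#' Each element is a list with `dist` one of `"normal"`, `"lognormal"` or
#' `"categorical"`, the corresponding parameters, and optional `round`,
#' `min`, `max` post-processing.
#'
#' @return Named list of distribution descriptors.
#' @export
default_covariate_spec <- function() {
  ln <- function(m, s) {
    p <- lognormal_params(m, s)
    list(dist = "lognormal", meanlog = unname(p["meanlog"]),
         sdlog = unname(p["sdlog"]))
  }
  no <- function(m, s, ...) c(list(dist = "normal", mean = m, sd = s), list(...))
  list(
    age          = no(67.5, 15.6, min = 0),
    sofa         = no(5.5, 3.0, round = TRUE, min = 0, max = 24),
    qsofa        = list(dist = "categorical", levels = 0:3,
                        probs = c(0.05, 0.20, 0.60, 0.15)),
    kdigo_stage  = list(dist = "categorical", levels = 0:3,
                        probs = c(0.320, 0.196, 0.376, 0.108)),
    urine_output = ln(2200, 1700),
    fluid_input  = ln(4200, 3200),
    map          = no(77.6, 9.4, min = 20),
    temperature  = no(36.9, 0.55),
    lactate      = ln(3.31, 2.61),
    creatinine   = ln(1.39, 0.99),
    wbc          = ln(14.57, 6.73),
    bun          = ln(28.0, 19.6),
    glucose      = no(137.5, 31.7, min = 20),
    resp_rate    = no(19.6, 3.6, min = 4),
    heart_rate   = no(86.0, 13.0, min = 20),
    potassium    = no(4.79, 0.74, min = 1.5),
    spo2         = no(96.9, 2.0, max = 100),
    sodium       = no(140.5, 4.8),
    ph           = no(7.43, 0.07)
  )
}

# Deterministic per-stage sub-seed derived from the master seed.
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000003L) * 1009L + 101L * stage
}

draw_covariate <- function(n, spec) {
  x <- switch(spec$dist,
    normal      = stats::rnorm(n, spec$mean, spec$sd),
    lognormal   = stats::rlnorm(n, spec$meanlog, spec$sdlog),
    categorical = sample(spec$levels, n, replace = TRUE, prob = spec$probs),
    stop("unknown distribution family: ", spec$dist, call. = FALSE)
  )
  if (isTRUE(spec$round)) x <- round(x)
  if (!is.null(spec$min)) x <- pmax(x, spec$min)
  if (!is.null(spec$max)) x <- pmin(x, spec$max)
  x
}

# Standardize a covariate using the theoretical moments of its declared
# distribution (log scale for log-normals), so z-scores are stable across
# cohort sizes and seeds.
standardize_covariate <- function(x, spec) {
  switch(spec$dist,
    normal      = (x - spec$mean) / spec$sd,
    lognormal   = (log(x) - spec$meanlog) / spec$sdlog,
    categorical = {
      m <- sum(spec$levels * spec$probs)
      s <- sqrt(sum((spec$levels - m)^2 * spec$probs))
      (x - m) / s
    }
  )
}

# Bisection for the treatment-model intercept alpha so that
# mean(plogis(alpha + eta)) = target.  Monotone in alpha, so bisection on
# [-30, 30] converges to ~1e-10.
calibrate_treatment_intercept <- function(eta, target, tol = 1e-10) {
  f <- function(a) mean(stats::plogis(a + eta)) - target
  lo <- -30; hi <- 30
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' Generate a synthetic S-AKI cohort with known treatment effects
#'
#' Draws covariates, confounded RRT assignment, potential-outcome death
#' probabilities under control and treatment, and the realized 28-day death
#' flag, according to a [sim_config()].  Both potential-outcome probabilities
#' are stored per record so the true individual treatment effect is always
#' available via [true_uplift()].
#'
#' Generation is deterministic given `config$seed`; each stage (covariates,
#' treatment, outcome, inclusion flags) draws from its own deterministically
#' derived sub-stream, so e.g. changing the outcome model does not perturb
#' the covariate draws.
#'
#' @param config A [sim_config()] object.
#' @return A `data.frame` of class `cohort_table`, one row per ICU stay,
#'   with columns `id`, the covariates named in `config$covariate_spec`,
#'   `kdigo_stage_highest`, `sepsis`, `first_icu_admission`, `esrd`,
#'   `treated`, `died_28d`, `p_death_control`, `p_death_treated`.
#'   Attributes: `sim_config` (the config), `n_clipped` (records whose
#'   treated-arm probability was clipped into \[0,1\]).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("`config` must be created by sim_config()", call. = FALSE)
  n <- config$n_patients
  cs <- config$covariate_spec

  set.seed(stage_seed(config$seed, 1L))
  X <- as.data.frame(lapply(cs, function(s) draw_covariate(n, s)))
  Z <- vapply(names(cs), function(v) standardize_covariate(X[[v]], cs[[v]]),
              numeric(n))

  # severity index: mean of 4 independent z-scores has SD 1/2, so divide by
  # 2 to keep ~unit scale
  sev <- (Z[, "sofa"] + Z[, "creatinine"] + Z[, "lactate"] -
            Z[, "urine_output"]) / 2

  eta <- config$confounding_strength * sev
  alpha <- calibrate_treatment_intercept(eta, config$treat_fraction_target)
  p_treat <- stats::plogis(alpha + eta)
  if (all(p_treat <= 0) || all(p_treat >= 1))
    stop("degenerate treatment probabilities; check `confounding_strength` ",
         "and `treat_fraction_target`", call. = FALSE)

  p_death_control <- stats::plogis(config$baseline_mortality_logit +
                                     config$severity_mortality_logodds * sev)
  if (all(p_death_control == 0) || all(p_death_control == 1))
    stop("degenerate control death probabilities; check ",
         "`baseline_mortality_logit`", call. = FALSE)

  tau <- rep(config$effect_intercept, n)
  for (v in names(config$effect_coefs))
    tau <- tau + config$effect_coefs[[v]] * Z[, v]
  p_death_treated_raw <- p_death_control - tau
  p_death_treated <- pmin(pmax(p_death_treated_raw, 0), 1)
  n_clipped <- sum(p_death_treated_raw != p_death_treated)

  set.seed(stage_seed(config$seed, 2L))
  treated <- stats::rbinom(n, 1L, p_treat) == 1L

  set.seed(stage_seed(config$seed, 3L))
  p_obs <- ifelse(treated, p_death_treated, p_death_control)
  died_28d <- stats::rbinom(n, 1L, p_obs) == 1L

  set.seed(stage_seed(config$seed, 4L))
  fv <- config$filter_violation_rates
  first_icu_admission <- stats::runif(n) >= fv[["not_first_admission"]]
  esrd <- stats::runif(n) < fv[["esrd"]]
  sepsis <- stats::runif(n) >= fv[["no_sepsis"]]
  # highest KDIGO stage during the stay (pre-RRT): the baseline stage may
  # escalate; baseline-0 patients reach stage >= 1 often but not always, so
  # the AKI filter has genuine work
  base_stage <- X$kdigo_stage
  esc0 <- sample(0:3, n, replace = TRUE, prob = c(0.30, 0.40, 0.20, 0.10))
  esc1 <- stats::rbinom(n, 1L, 0.2)
  kdigo_stage_highest <- ifelse(base_stage == 0, esc0,
                                pmin(3, base_stage + esc1))

  out <- data.frame(id = seq_len(n), X, kdigo_stage_highest = kdigo_stage_highest,
                    sepsis = sepsis, first_icu_admission = first_icu_admission,
                    esrd = esrd, treated = treated, died_28d = died_28d,
                    p_death_control = p_death_control,
                    p_death_treated = p_death_treated)
  class(out) <- c("cohort_table", "data.frame")
  attr(out, "sim_config") <- config
  attr(out, "n_clipped") <- n_clipped
  out
}

#' True individual treatment effect of a synthetic record
#'
#' Returns the ground-truth uplift `p_death_control - p_death_treated`:
#' the reduction in 28-day death probability (equivalently the gain in
#' survival probability) that treatment confers on each patient.  Only
#' synthetic cohorts carry potential-outcome probabilities; for real-data
#' records the oracle is unavailable and an error is raised.
#'
#' @param table A `cohort_table` (or any data.frame) with columns
#'   `p_death_control` and `p_death_treated`.
#' @return Numeric vector in \[-1, 1\], one value per row.
#' @export
true_uplift <- function(table) {
  if (!all(c("p_death_control", "p_death_treated") %in% names(table)))
    stop("oracle unavailable: potential-outcome probabilities ",
         "(p_death_control, p_death_treated) are absent from this table",
         call. = FALSE)
  pc <- table$p_death_control
  pt <- table$p_death_treated
  if (anyNA(pc) || anyNA(pt))
    stop("oracle unavailable: potential-outcome probabilities contain NA",
         call. = FALSE)
  pc - pt
}
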