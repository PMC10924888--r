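test_that("qini index reduces to the survival-rate difference at phi = 1", {
  t_out <- rep(c(1, 0), c(7, 3))
  c_out <- rep(c(1, 0), c(5, 5))
  expect_equal(qini_at(1, t_out, c_out), 0.7 - 0.5)
})

test_that("qini index matches hand counts on an 8-patient toy", {
  # N_t = N_c = 4; top-2 treated have 2 survivors, top-2 controls have 1
  t_out <- c(1, 1, 0, 0)
  c_out <- c(1, 0, 1, 1)
  expect_equal(qini_at(0.5, t_out, c_out), 2 / 4 - (1 * 2) / (4 * 2))
})

test_that("universal survival gives a flat zero qini curve", {
  sc <- rnorm(20)
  curve <- qini_curve(sc, rep(c(TRUE, FALSE), 10), rep(TRUE, 20))
  expect_equal(curve$Q, rep(0, length(curve$phi)))
})

test_that("qini_curve equals the brute-force oracle on random instances", {
  set.seed(202)
  grid <- seq(0, 1, by = 0.1)
  for (i in 1:300) {
    n <- sample(4:30, 1)
    treated <- c(TRUE, FALSE, runif(n - 2) < 0.5)   # both arms guaranteed
    survived <- runif(n) < 0.6
    scores <- sample(round(runif(n), 2))            # ties likely
    ids <- sprintf("r%03d", seq_len(n))
    curve <- qini_curve(scores, treated, survived, grid, ids = ids)
    oracle <- qini_oracle_curve(scores, treated, survived, grid, ids)
    expect_equal(curve$Q, oracle, tolerance = 1e-12)
  }
})

test_that("Q(1) always equals the overall survival-rate difference", {
  set.seed(203)
  for (i in 1:100) {
    n <- sample(4:40, 1)
    treated <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    survived <- runif(n) < 0.5
    curve <- qini_curve(rnorm(n), treated, survived)
    expect_equal(curve$Q[length(curve$Q)],
                 mean(survived[treated]) - mean(survived[!treated]))
  }
})

test_that("the curve is invariant to strictly monotone score transforms", {
  set.seed(204)
  n <- 60
  treated <- rep(c(TRUE, FALSE), 30)
  survived <- runif(n) < 0.5
  scores <- rnorm(n)
  c1 <- qini_curve(scores, treated, survived)
  c2 <- qini_curve(exp(3 * scores) + 10, treated, survived)
  expect_equal(c1$Q, c2$Q)
})

test_that("AUUC is zero on the random line and recovers a constant offset", {
  mk_curve <- function(phi, Q) {
    structure(list(phi = phi, Q = Q, label = "synthetic", N_t = 1, N_c = 1),
              class = "qini_curve")
  }
  phi <- seq(0, 1, by = 0.1)
  q1 <- 0.2
  expect_equal(auuc(mk_curve(phi, q1 * phi)), 0)
  # random line plus constant c on interior points: trapezoid area
  # approaches c as the grid refines (c * (1 - dphi) exactly)
  cc <- 0.05
  for (m in c(11, 101, 1001)) {
    phi_m <- seq(0, 1, length.out = m)
    Q <- q1 * phi_m + cc
    Q[1] <- 0; Q[m] <- q1
    dphi <- phi_m[2] - phi_m[1]
    expect_equal(auuc(mk_curve(phi_m, Q)), cc * (1 - dphi))
  }
})

test_that("an uninformative ranker has mean AUUC near zero", {
  set.seed(205)
  n <- 200
  treated <- rep(c(TRUE, FALSE), n / 2)
  survived <- runif(n) < 0.5
  aucs <- replicate(200, auuc(qini_curve(rnorm(n), treated, survived)))
  se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs)), 3 * se + 1e-3)
})

test_that("ranking by true uplift yields positive AUUC on heterogeneous cohorts", {
  for (s in 1:3) {
    coh <- randomized_cohort(8000, seed = s)
    curve <- qini_curve(true_uplift(coh), coh$treated, !coh$died_28d,
                        ids = coh$id)
    expect_gt(auuc(curve), 0)
  }
})

test_that("clinical-score rankers order as declared and flip with direction", {
  tab <- data.frame(id = 1:4, kdigo_stage = c(3, 2, 1, 0))
  up <- rank_by_clinical_score(tab, "kdigo_stage", "higher_benefits")
  expect_equal(order(-up), 1:4)
  down <- rank_by_clinical_score(tab, "kdigo_stage", "lower_benefits")
  expect_equal(order(-down), 4:1)
  expect_equal(up, -down)
  expect_error(rank_by_clinical_score(tab, "sofa"), "sofa")
})

test_that("heavily tied scores give identical curves across runs", {
  coh <- generate_cohort(sim_config(n_patients = 600,
                                    treat_fraction_target = 0.5,
                                    confounding_strength = 0, seed = 19))
  sc <- rank_by_clinical_score(coh, "kdigo_stage_highest")
  c1 <- qini_curve(sc, coh$treated, !coh$died_28d, ids = coh$id)
  c2 <- qini_curve(sc, coh$treated, !coh$died_28d, ids = coh$id)
  expect_identical(c1, c2)
})

test_that("feature contributions are additive on the link scale", {
  coh <- randomized_cohort(2000, seed = 23)
  fit <- suppressWarnings(fit_class_transformation(coh, schema_features(), seed = 23))
  fc <- feature_contributions(fit, coh)
  expect_equal(plogis(fc$margin), predict_pz(fit, coh), tolerance = 1e-6)
  expect_equal(unname(fc$margin),
               unname(fc$baseline + rowSums(fc$contributions)))
})

test_that("an ignored feature receives ~zero attribution; a lone feature dominates", {
  set.seed(24)
  n <- 3000
  tab <- data.frame(id = 1:n, x_signal = rnorm(n), x_noise = rnorm(n),
                    treated = rep(c(TRUE, FALSE), n / 2))
  # outcome driven by x_signal only, through the treatment arm
  p_surv <- plogis(1.5 * tab$x_signal)
  tab$died_28d <- ifelse(tab$treated, runif(n) > p_surv, runif(n) < p_surv)
  fit <- fit_class_transformation(tab, c("x_signal", "x_noise"), seed = 24)
  fc <- feature_contributions(fit, tab)
  expect_equal(names(fc$importance)[1], "x_signal")
  expect_gt(fc$importance[["x_signal"]], 5 * fc$importance[["x_noise"]])

  # glmnet path: linear contributions, additive exactly
  fitg <- fit_class_transformation(tab, c("x_signal", "x_noise"),
                                   learner = "glmnet", seed = 24)
  fcg <- feature_contributions(fitg, tab)
  expect_equal(plogis(fcg$margin), predict_pz(fitg, tab), tolerance = 1e-10)
  expect_equal(names(fcg$importance)[1], "x_signal")
})

test_that("qini report round-trips through CSV and JSON", {
  coh <- randomized_cohort(400, seed = 30)
  c1 <- qini_curve(true_uplift(coh), coh$treated, !coh$died_28d,
                   ids = coh$id, label = "oracle")
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  aucs <- write_qini_report(list(c1), csv, js)
  expect_equal(aucs$oracle, auuc(c1))
  back <- read.csv(csv)
  expect_equal(back$Q, c1$Q)
  expect_equal(jsonlite::read_json(js)$oracle, auuc(c1))
})
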