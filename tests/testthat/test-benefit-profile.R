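test_that("identical groups give p-values at or near 1", {
  set.seed(41)
  base <- data.frame(cont = rnorm(60), bin = rep(c(0, 1), 30))
  tab <- rbind(base, base)
  labels <- rep(c("high", "low"), each = 60)
  cmp <- compare_groups(tab, labels, c("cont", "bin"))
  expect_true(all(cmp$p > 0.99))
})

test_that("a two-SD shift is detected at p < 0.001 with 138 per group", {
  set.seed(42)
  tab <- data.frame(shifted = c(rnorm(138, mean = 2), rnorm(138)),
                    null = rnorm(276))
  labels <- rep(c("high", "low"), each = 138)
  cmp <- compare_groups(tab, labels, c("shifted", "null"))
  expect_lt(cmp$p[cmp$variable == "shifted"], 0.001)
  expect_gt(cmp$p[cmp$variable == "null"], 0.001)
})

test_that("binary comparison matches the hand-computed Yates chi-square", {
  tab <- data.frame(flag = rep(c(1, 0, 1, 0), c(30, 70, 45, 55)))
  labels <- rep(c("high", "low"), each = 100)
  cmp <- compare_groups(tab, labels, "flag")
  expect_equal(cmp$test, "chi-square")
  m <- matrix(c(30, 70, 45, 55), nrow = 2, byrow = TRUE)
  ht <- chisq.test(m)   # Yates correction is the 2x2 default
  expect_equal(cmp$statistic, unname(ht$statistic))
  expect_equal(cmp$p, ht$p.value)
})

test_that("the declared test-selection rule is applied per variable", {
  set.seed(43)
  tab <- data.frame(gaussian = rnorm(200),
                    skewed = rlnorm(200, sdlog = 1.5),
                    stage = sample(0:3, 200, replace = TRUE),
                    konst = 1)
  labels <- rep(c("high", "low"), 100)
  cmp <- compare_groups(tab, labels, c("gaussian", "skewed", "stage", "konst"))
  expect_equal(cmp$test[cmp$variable == "gaussian"], "t")
  expect_equal(cmp$test[cmp$variable == "skewed"], "mann-whitney")
  expect_equal(cmp$test[cmp$variable == "stage"], "chi-square")
  expect_true(is.na(cmp$p[cmp$variable == "konst"]))
  expect_equal(cmp$flag[cmp$variable == "konst"], "constant")
})

test_that("group-test p-values are uniform under the null", {
  set.seed(44)
  labels <- rep(c("high", "low"), each = 40)
  ps <- replicate(500, {
    tab <- data.frame(x = rnorm(80))
    compare_groups(tab, labels, "x")$p
  })
  # rank-test p-values are discrete at this n, so exact ties occur; the KS
  # statistic is still valid as a goodness-of-fit screen
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("null benefit model covers OR = 1 for every variable", {
  set.seed(45)
  n <- 10000
  tab <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  labels <- factor(rep(c("high", "low"), n / 2), levels = c("high", "low"))
  fit <- fit_benefit_logistic(tab, labels, c("a", "b", "c"))
  expect_true(all(fit$or_table$ci_low < 1 & fit$or_table$ci_high > 1))
})

test_that("benefit model recovers a known log-odds coefficient", {
  set.seed(46)
  n <- 50000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.3 + 0.5 * x))
  tab <- data.frame(x = x)
  labels <- factor(ifelse(y == 1, "high", "low"), levels = c("high", "low"))
  fit <- fit_benefit_logistic(tab, labels, "x")
  est <- log(fit$or_table$or)
  se <- (log(fit$or_table$ci_high) - log(fit$or_table$or)) / qnorm(0.975)
  expect_lt(abs(est - 0.5), 3 * se)
})

test_that("under-determined or separated benefit models are rejected", {
  tab <- data.frame(a = rnorm(4), b = rnorm(4), c = rnorm(4), d = rnorm(4))
  labels <- c("high", "low", "high", "low")
  expect_error(fit_benefit_logistic(tab, labels, c("a", "b", "c", "d")),
               "fewer rows")
  sep <- data.frame(x = c(rnorm(50, 10), rnorm(50, -10)))
  lab <- rep(c("high", "low"), each = 50)
  expect_error(fit_benefit_logistic(sep, lab, "x"), "separation")
})

test_that("single-variable nomogram is linear with max 100 points", {
  set.seed(47)
  n <- 500
  x <- runif(n, 0, 10)
  y <- rbinom(n, 1, plogis(-2 + 0.4 * x))
  labels <- factor(ifelse(y == 1, "high", "low"), levels = c("high", "low"))
  fit <- fit_benefit_logistic(data.frame(x = x), labels, "x")
  nom <- build_nomogram(fit, list(x = c(0, 10)))
  pts <- nomogram_points(nom, data.frame(x = c(0, 5, 10)))
  expect_equal(pts$total_points, c(0, 50, 100))
})

test_that("negative-coefficient variables score highest at the low axis end", {
  set.seed(48)
  n <- 1000
  x <- runif(n, 0, 4)
  y <- rbinom(n, 1, plogis(1 - 0.8 * x))
  labels <- factor(ifelse(y == 1, "high", "low"), levels = c("high", "low"))
  fit <- fit_benefit_logistic(data.frame(x = x), labels, "x")
  nom <- build_nomogram(fit, list(x = c(0, 4)))
  pts <- nomogram_points(nom, data.frame(x = c(0, 4)))
  expect_gt(pts$x[1], pts$x[2])
  expect_equal(pts$x[2], 0)
  expect_true(all(pts$x >= 0))
})

test_that("nomogram round-trip matches the logistic prediction within 0.01", {
  set.seed(49)
  n <- 2000
  tab <- data.frame(u = runif(n, 0, 2000), v = rnorm(n, 5, 2),
                    w = runif(n, 10, 30))
  lp <- -1 - 0.002 * tab$u + 0.35 * tab$v + 0.05 * tab$w
  labels <- factor(ifelse(rbinom(n, 1, plogis(lp)) == 1, "high", "low"),
                   levels = c("high", "low"))
  fit <- fit_benefit_logistic(tab, labels, c("u", "v", "w"))
  ranges <- lapply(tab, range)
  nom <- build_nomogram(fit, ranges)
  profiles <- data.frame(u = runif(1000, 0, 2000), v = rnorm(1000, 5, 2),
                         w = runif(1000, 10, 30))
  pts <- nomogram_points(nom, profiles)
  p_nom <- nomogram_probability(nom, pts$total_points)
  p_glm <- predict(fit$fit, profiles, type = "response")
  expect_lt(max(abs(p_nom - unname(p_glm))), 0.01)
  # probability is strictly increasing in total points
  pt <- nom$prob_table
  expect_true(all(diff(pt$probability) > 0))
  # JSON export round-trips the probability table
  path <- tempfile(fileext = ".json")
  write_nomogram_json(nom, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$prob_table$probability, pt$probability)
})

test_that("two-proportion test handles equal rates, symmetry and degeneracy", {
  expect_equal(two_proportion_test(50, 100, 50, 100)$p, 1.0)
  a <- two_proportion_test(148, 458, 180, 458)
  b <- two_proportion_test(180, 458, 148, 458)
  expect_equal(a$p, b$p)
  expect_error(two_proportion_test(0, 50, 0, 60), "zero margin")
  expect_error(two_proportion_test(51, 50, 10, 60), "must lie in")
})

test_that("two-proportion test tracks Fisher's exact test at moderate counts", {
  # the Yates-corrected chi-square approximates the exact conditional test;
  # at group sizes of 100-300 the p-value discrepancy stays below ~0.06
  set.seed(50)
  for (i in 1:20) {
    n1 <- sample(100:300, 1); n2 <- sample(100:300, 1)
    x1 <- rbinom(1, n1, 0.4); x2 <- rbinom(1, n2, 0.5)
    p_chi <- two_proportion_test(x1, n1, x2, n2)$p
    p_fisher <- fisher.test(rbind(c(x1, n1 - x1), c(x2, n2 - x2)))$p.value
    expect_lt(abs(p_chi - p_fisher), 0.06)
  }
})

test_that("power equals the level under the null and increases with n", {
  expect_equal(power_two_proportions(0.3, 0.3, 100), 0.05)
  ns <- c(50, 100, 200, 400, 800)
  pw <- sapply(ns, function(n) power_two_proportions(0.393, 0.323, n))
  expect_true(all(diff(pw) > 0))
  expect_error(power_two_proportions(0, 0.3, 100), "strictly")
})

test_that("normal-approximation power matches a Monte-Carlo rejection rate", {
  p1 <- 0.393; p2 <- 0.323; n <- 458; alpha <- 0.05
  set.seed(51)
  B <- 100000
  x1 <- rbinom(B, n, p1); x2 <- rbinom(B, n, p2)
  # uncorrected two-proportion z-test, vectorized
  phat <- (x1 + x2) / (2 * n)
  z <- (x1 / n - x2 / n) / sqrt(2 * phat * (1 - phat) / n)
  mc_power <- mean(abs(z) > qnorm(1 - alpha / 2), na.rm = TRUE)
  expect_lt(abs(power_two_proportions(p1, p2, n, alpha) - mc_power), 0.01)
})
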