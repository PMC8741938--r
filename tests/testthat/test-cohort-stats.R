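# Statistical battery: group tests, Youden cutoff, logistic and
# proportional-odds regression, forest table.

test_that("two-group tests behave on identical, separated and tied data", {
  t0 <- two_group_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p, 1)
  expect_lt(two_group_test(c(1, 2, 3), c(101, 102, 103))$p, 0.01)
  # rank tests cannot reach p < .01 at n = 3 + 3 (min attainable ~ 0.1),
  # so the separated-group check uses n = 10 per group
  expect_lt(two_group_test(1:10, 101:110, method = "mannwhitney")$p, 0.01)
  # U = n^2 / 2 when the groups are equal as multisets
  mw <- two_group_test(c(5, 6, 7, 8), c(5, 6, 7, 8), method = "mannwhitney")
  expect_equal(mw$statistic, 8)
  expect_error(two_group_test(1, c(1, 2)), "n >= 2")
})

test_that("Kruskal-Wallis and Tukey HSD behave on null and separated groups", {
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  m <- multi_group_test(same)
  expect_equal(m$H, 0)
  expect_equal(m$p, 1)
  disj <- list(a = 1:5, b = 11:15, c = 21:25)
  expect_lt(multi_group_test(disj)$p, 0.01)
  set.seed(121)
  eq <- lapply(1:3, function(i) rnorm(20))
  names(eq) <- letters[1:3]
  tk <- multi_group_test(eq, posthoc = TRUE)$tukey
  expect_true(all(tk$p_adj > 0.2))
  expect_error(multi_group_test(list(a = 1:3, b = 1:3)), "two_group_test")
})

test_that("Youden cutoff equals exhaustive search and separates perfect data", {
  y <- youden_cutoff(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(y$J, 1)
  expect_gt(y$cutoff, 3); expect_lt(y$cutoff, 10)
  # constant scores: no separation possible
  expect_equal(youden_cutoff(rep(2, 8), rep(c(0, 1), 4))$J, 0)
  y2 <- youden_cutoff(c(0.1, 0.4, 0.35, 0.8), c(0, 1, 0, 1))
  o2 <- oracle_youden(c(0.1, 0.4, 0.35, 0.8), c(0, 1, 0, 1))
  expect_equal(y2$J, o2$J)
  set.seed(131)
  for (k in 1:30) {
    n <- sample(10:60, 1)
    sc <- round(runif(n), sample(c(1, 2, 3), 1))  # induce ties
    lb <- rbinom(n, 1, plogis(3 * sc - 1.5))
    if (length(unique(lb)) < 2) next
    ours <- youden_cutoff(sc, lb)
    expect_equal(ours$J, oracle_youden(sc, lb)$J, tolerance = 1e-12)
  }
  expect_error(youden_cutoff(1:5, rep(1, 5)), "both classes")
})

test_that("shifting all scores shifts the cutoff, J unchanged", {
  set.seed(141)
  sc <- rnorm(40); lb <- rbinom(40, 1, plogis(2 * sc))
  y1 <- youden_cutoff(sc, lb)
  y2 <- youden_cutoff(sc + 5, lb)
  expect_equal(y2$cutoff, y1$cutoff + 5)
  expect_equal(y2$J, y1$J)
})

test_that("logistic HR on a 2x2 table equals the cross-product odds ratio", {
  y <- rep(c(0, 1), c(50, 40))
  x <- rep(c(0, 1, 0, 1), c(40, 10, 20, 20))
  e <- binary_logit_hr(y, data.frame(v = x))
  expect_equal(e$HR, (40 * 20) / (10 * 20), tolerance = 1e-6)
  expect_false(e$separation)
  expect_true(e$ci_low <= e$HR && e$HR <= e$ci_high)
  expect_error(binary_logit_hr(rep(1, 10), data.frame(v = rnorm(10))),
               "both outcome classes")
  expect_error(binary_logit_hr(rep(c(0, 1), 5), data.frame(v = rep(1, 10))),
               "constant")
})

test_that("separation is flagged with infinite HR, not an error", {
  y <- rep(c(0, 1), each = 10)
  expect_warning(e <- binary_logit_hr(y, data.frame(v = y)), "separation")
  expect_true(e$separation)
  expect_equal(e$HR, Inf)
})

test_that("Firth fit equals the Haldane-corrected odds ratio on saturated 2x2", {
  y <- rep(c(0, 1), each = 10)
  e <- binary_logit_hr(y, data.frame(v = y), method = "firth")
  expect_equal(e$HR, (10.5 * 10.5) / (0.5 * 0.5), tolerance = 1e-6)
  expect_lt(e$p, 0.05)
  # and stays close to ML when the table is well-populated
  y2 <- rep(c(0, 1), c(50, 40))
  x2 <- rep(c(0, 1, 0, 1), c(40, 10, 20, 20))
  expect_equal(
    binary_logit_hr(y2, data.frame(v = x2), method = "firth")$HR,
    (40.5 * 20.5) / (10.5 * 20.5), tolerance = 1e-6)
})

test_that("Wald 95% CI coverage of the logistic OR is near nominal", {
  set.seed(151)
  true_beta <- log(2)
  n <- 500
  covered <- 0L
  reps <- 200L
  for (r in seq_len(reps)) {
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(-0.5 + true_beta * x))
    e <- binary_logit_hr(y, data.frame(x = x))
    if (e$ci_low <= exp(true_beta) && exp(true_beta) <= e$ci_high)
      covered <- covered + 1L
  }
  lo <- qbinom(0.025, reps, 0.95)
  hi <- qbinom(0.975, reps, 0.95)
  expect_gte(covered, lo)
  expect_lte(covered, hi)
})

test_that("two-level ordinal fit reduces to the binary logistic fit", {
  set.seed(161)
  x <- rnorm(300)
  y <- as.integer(x + rlogis(300) > 0.3)
  g <- stats::glm(y ~ x, family = stats::binomial(),
                  control = stats::glm.control(epsilon = 1e-12))
  o <- ordinal_logit(ordered(y), x)
  expect_lt(abs(unname(coef(g)["x"]) - log(o$effects$HR)), 1e-6)
  expect_lt(abs(unname(coef(g)["(Intercept)"]) + o$thresholds[1]), 1e-6)
})

test_that("proportional-odds fit agrees with MASS::polr at 4 levels", {
  set.seed(171)
  n <- 400
  x1 <- rnorm(n); x2 <- rnorm(n)
  lat <- 0.8 * x1 - 0.5 * x2 + rlogis(n)
  y <- ordered(cut(lat, c(-Inf, -1, 0.5, 2, Inf), labels = 1:4))
  o <- ordinal_logit(y, data.frame(x1 = x1, x2 = x2))
  pf <- MASS::polr(y ~ x1 + x2, Hess = TRUE)
  expect_equal(unname(log(o$effects$HR)), unname(coef(pf)), tolerance = 1e-4)
  expect_equal(unname(o$thresholds), unname(pf$zeta), tolerance = 1e-4)
  expect_error(ordinal_logit(factor(y, ordered = FALSE), x1), "ordered")
})

test_that("ordinal regression recovers a known coefficient and holds its size", {
  set.seed(181)
  beta <- 0.9
  hits <- 0L
  reps <- 40L
  for (r in seq_len(reps)) {
    n <- 300
    x <- rnorm(n)
    y <- ordered(cut(beta * x + rlogis(n), c(-Inf, -0.8, 0.8, Inf)))
    o <- ordinal_logit(y, x)
    se <- (log(o$effects$ci_high) - log(o$effects$HR)) / qnorm(0.975)
    if (abs(log(o$effects$HR) - beta) <= 2 * se) hits <- hits + 1L
  }
  expect_gte(hits, qbinom(0.025, reps, 0.95))
  # null predictor: type-I error near 0.05
  rej <- 0L
  reps2 <- 100L
  for (r in seq_len(reps2)) {
    n <- 200
    x <- rnorm(n)
    y <- ordered(cut(rlogis(n), c(-Inf, -0.8, 0.8, Inf)))
    if (ordinal_logit(y, x)$effects$p < 0.05) rej <- rej + 1L
  }
  expect_gte(rej, qbinom(0.025, reps2, 0.05))
  expect_lte(rej, qbinom(0.975, reps2, 0.05))
})

test_that("forest table reports per-variable cutoffs and drops degenerate rows", {
  set.seed(191)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  cohort <- data.frame(
    slide_id = paste0("s", 1:n), outcome = y,
    good = rnorm(n, mean = ifelse(y == 1, 1.5, 0)),
    null1 = rnorm(n),
    flat = rep(3, n))
  expect_message(
    ft <- forest_table(cohort, "outcome", c("good", "null1", "flat")),
    "zero variance")
  expect_true("good" %in% ft$variable)
  expect_false("flat" %in% ft$variable)
  expect_true(all(is.finite(ft$cutoff)))
  expect_gt(ft$HR[ft$variable == "good"], 1)
  expect_lt(ft$p[ft$variable == "good"], 0.05)
  expect_equal(attr(ft, "excluded")[["flat"]],
               "zero variance or too few values")
  # a direction-reversed null variable may be dropped as degenerate, but
  # never reported significant
  if ("null1" %in% ft$variable)
    expect_gt(ft$p[ft$variable == "null1"], 0.05)
  # continuous mode: no cutoff, still an estimate per variable
  ftc <- forest_table(cohort, "outcome", c("good", "null1"),
                      dichotomize = FALSE)
  expect_true(all(is.na(ftc$cutoff)))
  expect_gt(ftc$HR[1], 1)
  expect_equal(ftc$log_hr, log(ftc$HR))
})
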