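test_that("collinearity screen drops one member of each correlated pair", {
  set.seed(41)
  x <- tibble::tibble(a = rnorm(30))
  x$b <- x$a  # identical ranks
  x$c <- rnorm(30)
  scr <- screen_collinearity(x, c("a", "b", "c"))
  expect_equal(length(scr$retained), 2)
  expect_true("c" %in% scr$retained)
  expect_equal(nrow(scr$dropped), 1)

  # nothing dropped when all |rho| below the threshold
  set.seed(42)
  y <- tibble::as_tibble(setNames(as.data.frame(matrix(rnorm(120), 30)), letters[1:4]))
  scr2 <- screen_collinearity(y, letters[1:4])
  expect_equal(sort(scr2$retained), letters[1:4])

  # the drop preference decides which member of a collinear pair goes
  set.seed(43)
  z <- tibble::tibble(a = rnorm(40))
  z$b <- rank(z$a) + rnorm(40, sd = 2)  # rho ~ 0.9
  z$c <- rnorm(40)
  stopifnot(abs(cor(z$a, z$b, method = "spearman")) > 0.7)
  pref <- screen_collinearity(z, c("a", "b", "c"), drop_preference = "a")
  expect_false("a" %in% pref$retained)
  expect_true(all(c("b", "c") %in% pref$retained))
})

test_that("AICc matches its closed form and penalises extra parameters", {
  expect_equal(aicc(0, k = 2, n = 26), 4 + 12 / 23)
  # converges to AIC as n grows
  expect_lt(abs(aicc(-10, 3, 1e6) - (2 * 10 + 6)), 1e-4)
  # equal likelihood, more parameters -> larger AICc
  expect_lt(aicc(-5, 2, 30), aicc(-5, 3, 30))
  # unrankable when the correction denominator vanishes
  expect_equal(aicc(0, 25, 26), Inf)
})

test_that("all-subsets fits agree with the normal-equations oracle", {
  set.seed(44)
  n <- 26
  d <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  d$y <- 1 + 0.5 * d$x1 - 0.8 * d$x3 + rnorm(n)
  models <- fit_all_subsets(d, "y", c("x1", "x2", "x3"))
  expect_equal(nrow(models), 8)  # 2^3 subsets including intercept-only

  for (i in seq_len(nrow(models))) {
    terms <- models$terms[[i]]
    if (length(terms) == 0) {
      expect_equal(unname(models$coef[[i]]), mean(d$y))
      expect_equal(models$loglik[i], gaussian_loglik(d$y, mean(d$y)))
    } else {
      oracle <- ls_coef(as.matrix(d[terms]), d$y)
      expect_equal(unname(models$coef[[i]]), oracle, tolerance = 1e-8)
    }
  }

  # single-predictor slope equals the closed-form simple-regression slope
  m1 <- models[models$model == "x1", ]
  slope <- cov(d$x1, d$y) / var(d$x1)
  expect_equal(unname(m1$coef[[1]][2]), slope)
})

test_that("AICc ranking yields normalised weights and a stable best model", {
  set.seed(45)
  d <- tibble::tibble(x1 = rnorm(26), x2 = rnorm(26))
  d$y <- d$x1 + rnorm(26)
  ranked <- rank_and_weight(fit_all_subsets(d, "y", c("x1", "x2")))
  expect_equal(sum(ranked$weight), 1, tolerance = 1e-12)
  expect_equal(ranked$delta_aicc[1], 0)
  expect_true(all(ranked$delta_aicc >= 0))

  # dAICc = 2 -> weight ratio exp(-1)
  toy <- tibble::tibble(model = c("m1", "m2"), terms = list("a", "b"),
                        coef = list(c(1, 1), c(1, 1)), se = list(c(1, 1), c(1, 1)),
                        loglik = c(0, -1), k = c(3, 3), n_obs = c(26, 26),
                        aicc = c(10, 12), r2 = c(0.5, 0.4), adj_r2 = c(0.5, 0.4))
  rt <- rank_and_weight(toy)
  expect_equal(rt$weight[2] / rt$weight[1], exp(-1))

  # equal AICc over m models -> equal weights
  toy$aicc <- c(10, 10)
  expect_equal(rank_and_weight(toy)$weight, c(0.5, 0.5))

  # the best model is invariant under a constant shift of all log-likelihoods
  shifted <- fit_all_subsets(d, "y", c("x1", "x2"))
  shifted$aicc <- aicc(shifted$loglik + 7, shifted$k, shifted$n_obs)
  expect_equal(rank_and_weight(shifted)$model[1], ranked$model[1])
})

test_that("multimodel summary follows the conditional-averaging convention", {
  toy <- tibble::tibble(
    model = c("x1", "x1+x2", "x2"),
    terms = list("x1", c("x1", "x2"), "x2"),
    coef = list(c(`(Intercept)` = 0, x1 = 1),
                c(`(Intercept)` = 0, x1 = 2, x2 = 5),
                c(`(Intercept)` = 0, x2 = 5)),
    se = list(c(`(Intercept)` = 1, x1 = 0.5),
              c(`(Intercept)` = 1, x1 = 0.5, x2 = 1),
              c(`(Intercept)` = 1, x2 = 1)),
    weight = c(0.6, 0.4, 0))
  s <- mmi_summary(toy, c("x1", "x2", "x9"))
  # selection probability = summed weights of containing models
  expect_equal(s$selection_probability[s$predictor == "x1"], 1)
  expect_equal(s$selection_probability[s$predictor == "x2"], 0.4)
  # conditional average: weights 0.6/0.4 on coefficients 1/2 -> 1.4
  expect_equal(s$coefficient[s$predictor == "x1"], 1.4)
  # single containing model: coefficient passed through
  expect_equal(s$coefficient[s$predictor == "x2"], 5)
  # absent predictor: probability 0, undefined coefficient
  expect_equal(s$selection_probability[s$predictor == "x9"], 0)
  expect_true(is.na(s$coefficient[s$predictor == "x9"]))
  # unconditional SE >= weighted within-model SE alone
  expect_gte(s$se[s$predictor == "x1"], 0.5)
})

test_that("adjusted R-squared matches hand computation", {
  expect_equal(adjusted_r2(1, 10, 3), 1)
  expect_equal(adjusted_r2(0, 10, 0), 0)
  # 3-point simple regression by hand
  x <- c(0, 1, 2); y <- c(0, 2, 3)
  fit <- lm(y ~ x)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  expect_equal(adjusted_r2(r2, 3, 1), 1 - (1 - r2) * 2 / 1)
})

test_that("model-averaged coefficients recover a known linear model", {
  set.seed(46)
  n <- 26
  reps <- 30
  hits <- 0
  z <- numeric(0)
  for (r in seq_len(reps)) {
    d <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n), x4 = rnorm(n))
    d$y <- 1 + 1.0 * d$x1 + 1.0 * d$x2 + rnorm(n)
    fit <- habitat_mmi(d, "y", paste0("x", 1:4), screen = FALSE)
    top2 <- fit$summary$predictor[order(-fit$summary$selection_probability)][1:2]
    hits <- hits + setequal(top2, c("x1", "x2"))
    s <- fit$summary[fit$summary$predictor %in% c("x1", "x2"), ]
    z <- c(z, abs(s$coefficient - 1) / s$se)
  }
  expect_gte(hits / reps, 0.8)
  expect_lt(mean(z), 2)  # on average within 2 SE of truth
})
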