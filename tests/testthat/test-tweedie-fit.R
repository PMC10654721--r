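test_that("intercept-only fit returns the log sample mean", {
  set.seed(1)
  y <- rtweedie_cp(400, 3, 1, 1.5)
  fit <- fit_tweedie_glm(y ~ 1, data.frame(y = y), p = 1.5,
                         phi_method = "pearson")
  expect_equal(unname(coef(fit)), log(mean(y)), tolerance = 1e-9)
})

test_that("IRLS converges to the score equation and matches glmmTMB", {
  set.seed(8)
  n <- 600
  x <- rnorm(n)
  mu <- exp(0.3 + 0.4 * x)
  y <- rtweedie_cp(n, mu, 0.7, 1.5)
  dat <- data.frame(y = y, x = x)
  fit <- fit_tweedie_glm(y ~ x, dat, p = 1.5, phi_method = "pearson")
  X <- cbind(1, x)
  score <- crossprod(X, (y - fit$fitted) * fit$fitted^(1 - 1.5))
  expect_lt(max(abs(score)), 1e-8)

  skip_if_not_installed("glmmTMB")
  ref <- glmmTMB::glmmTMB(y ~ x, family = glmmTMB::tweedie(), data = dat)
  expect_equal(unname(coef(fit)), unname(glmmTMB::fixef(ref)$cond),
               tolerance = 5e-3)
})

test_that("AIC counts dispersion and index power as parameters", {
  set.seed(3)
  y <- rtweedie_cp(200, 2, 1, 1.5)
  fit <- fit_tweedie_glm(y ~ 1, data.frame(y = y), p = 1.5)
  expect_equal(fit$aic, -2 * fit$log_likelihood + 2 * (1 + 2))
  expect_equal(fit$vcov, t(fit$vcov))
  expect_true(all(eigen(fit$vcov, only.values = TRUE)$values > -1e-12))
})

test_that("profiled index power approaches the gamma boundary on gamma data", {
  set.seed(21)
  y <- rgamma(2000, shape = 4, scale = 0.5)
  fit <- fit_tweedie_glm(y ~ 1, data.frame(y = y), p = "profile")
  expect_gt(fit$p, 1.9)
})

test_that("coefficients are recovered within standard errors in simulation", {
  set.seed(42)
  n <- 2000
  covered <- matrix(NA, 20, 2)
  for (r in 1:20) {
    x <- rnorm(n); g <- factor(sample(c("a", "b"), n, TRUE))
    mu <- exp(0.4 - 0.2 * x + ifelse(g == "a", 0.15, -0.15))
    y <- rtweedie_cp(n, mu, 0.8, 1.6)
    fit <- fit_tweedie_glm(y ~ x + g, data.frame(y = y, x = x, g = g),
                           p = 1.6, phi_method = "pearson")
    se <- sqrt(diag(vcov(fit)))
    covered[r, ] <- abs(coef(fit)[c("x", "g1")] - c(-0.2, 0.15)) <=
      3 * se[c("x", "g1")]
  }
  expect_gte(mean(covered), 0.95)
})

test_that("rank-deficient designs fail naming the aliased term", {
  set.seed(2)
  d <- data.frame(y = rtweedie_cp(50, 2, 1, 1.5), x = rnorm(50))
  d$x2 <- 2 * d$x
  expect_error(fit_tweedie_glm(y ~ x + x2, d, p = 1.5), "aliased.*x2")
})

test_that("prediction honours contrasts and levels on new data", {
  set.seed(6)
  d <- data.frame(y = rtweedie_cp(300, 2, 0.8, 1.5),
                  g = factor(sample(c("a", "b", "c"), 300, TRUE)))
  fit <- fit_tweedie_glm(y ~ g, d, p = 1.5, phi_method = "pearson")
  nd <- data.frame(g = c("a", "b", "c"))
  pred <- predict(fit, nd, type = "response")
  obs_means <- tapply(d$y, d$g, mean)
  expect_equal(unname(pred), as.numeric(obs_means), tolerance = 1e-6)
})

test_that("AIC selection is consistent and ties break toward simplicity", {
  set.seed(11)
  n <- 1500
  x <- rnorm(n); g <- factor(sample(c("a", "b", "c"), n, TRUE))
  mu <- exp(0.3 + 0.3 * x + c(a = 0.4, b = 0, c = -0.4)[g] +
              c(a = 0.3, b = -0.3, c = 0)[g] * x)
  y <- rtweedie_cp(n, mu, 0.6, 1.5)
  d <- data.frame(y = y, x = x, g = g)
  cands <- list(base = y ~ x + g, inter = y ~ x * g)
  sel <- select_model_aic(cands, d, p = 1.5)
  expect_equal(sel$best_name, "inter")
  # duplicate candidates: first (simpler position) wins
  sel2 <- select_model_aic(list(first = y ~ x + g, second = y ~ x + g), d,
                           p = 1.5)
  expect_equal(sel2$best_name, "first")
  # null interaction: main-effects model preferred
  mu0 <- exp(0.3 + 0.3 * x)
  y0 <- rtweedie_cp(n, mu0, 0.6, 1.5)
  d0 <- data.frame(y = y0, x = x, g = g)
  sel0 <- select_model_aic(cands, d0, p = 1.5)
  expect_equal(sel0$best_name, "base")
})

test_that("approximate random intercepts collapse to the fixed fit when the variance is zero", {
  set.seed(10)
  n_g <- 80; m <- 12; n <- n_g * m
  g <- factor(rep(seq_len(n_g), each = m))
  x <- rnorm(n)
  y0 <- rtweedie_cp(n, exp(0.5 + 0.3 * x), 0.8, 1.6)
  d0 <- data.frame(y = y0, x = x, g = g)
  fr0 <- fit_random_intercepts(y ~ x, d0, groups = "g", p = 1.6)
  ff0 <- fit_tweedie_glm(y ~ x, d0, p = 1.6, phi_method = "pearson")
  expect_lt(fr0$variance_components[["g"]], 0.05)
  expect_equal(unname(coef(fr0)), unname(coef(ff0)), tolerance = 0.02)
  # predictions with random effects at zero are population-level predictions
  nd <- data.frame(x = c(-1, 0, 1))
  expect_equal(unname(predict(fr0, nd)),
               drop(cbind(1, nd$x) %*% coef(fr0)))
})

test_that("approximate random intercepts recover a nonzero variance component", {
  set.seed(10)
  n_g <- 100; m <- 15; n <- n_g * m
  g <- factor(rep(seq_len(n_g), each = m))
  x <- rnorm(n)
  u <- rnorm(n_g, 0, 0.4)
  y <- rtweedie_cp(n, exp(0.5 + 0.3 * x + u[g]), 0.8, 1.6)
  fr <- fit_random_intercepts(y ~ x, data.frame(y = y, x = x, g = g),
                              groups = "g", p = 1.6)
  expect_true(isTRUE(fr$approximate))
  expect_lt(abs(fr$variance_components[["g"]] - 0.16) / 0.16, 0.3)
})
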