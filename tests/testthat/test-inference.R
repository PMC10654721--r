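make_fit <- function(seed = 3, n = 800, two_regions = TRUE,
                     interaction = TRUE) {
  set.seed(seed)
  g <- factor(sample(c("a", "b", "c"), n, TRUE))
  r <- if (two_regions) factor(sample(c("R1", "R2"), n, TRUE))
       else factor(rep("R1", n))
  x <- rnorm(n)
  eta <- 0.4 + c(a = 0.3, b = 0, c = -0.3)[g] - 0.1 * x +
    (if (two_regions) c(R1 = 0.2, R2 = -0.2)[r] else 0) +
    (if (interaction) c(a = 0.2, b = -0.2, c = 0)[g] * x else 0)
  y <- rtweedie_cp(n, exp(eta), 0.5, 1.5)
  d <- data.frame(y = y, g = g, r = r, x = x)
  form <- if (two_regions) {
    if (interaction) y ~ r + g + x + g:x else y ~ r + g + x
  } else {
    if (interaction) y ~ g + x + g:x else y ~ g + x
  }
  list(fit = fit_tweedie_glm(form, d, p = 1.5, phi_method = "pearson"),
       data = d)
}

test_that("type III Wald tests reduce to (beta/se)^2 for single-df terms", {
  f <- make_fit()$fit
  tab <- type3_wald(f)
  b <- coef(f)["x"]; se <- sqrt(vcov(f)["x", "x"])
  expect_equal(tab$chisq[tab$term == "x"], unname((b / se)^2),
               tolerance = 1e-10)
  expect_equal(tab$df[tab$term == "g"], 2)
  expect_error(type3_wald(f, "nonexistent"), "not in the model")
})

test_that("type III Wald rejection is near nominal under a null term", {
  set.seed(55)
  rej <- replicate(200, {
    n <- 250
    g <- factor(sample(c("a", "b", "c"), n, TRUE))
    y <- rtweedie_cp(n, rep(1.5, n), 0.7, 1.5)   # g has no effect
    fit <- fit_tweedie_glm(y ~ g, data.frame(y = y, g = g), p = 1.5,
                           phi_method = "pearson")
    type3_wald(fit, "g")$p_value < 0.05
  })
  # binomial 3-sigma band around 0.05 with 200 replicates
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("marginal means average on the link scale across regions", {
  f <- make_fit()$fit
  mm <- marginal_means(f, "g")
  # manual: average eta over the two regions at x = mean(x)
  x0 <- mean(f$model_frame$x)
  for (i in seq_len(nrow(mm))) {
    etas <- sapply(c("R1", "R2"), function(rr)
      predict(f, data.frame(g = mm$label[i], r = rr, x = x0)))
    expect_equal(mm$eta[i], mean(etas), tolerance = 1e-10)
    expect_equal(mm$estimate[i], exp(mean(etas)), tolerance = 1e-10)
  }
  # delta-method CI on the response scale = exp of link-scale endpoints
  z <- qnorm(0.975)
  expect_equal(mm$ci_low, exp(mm$eta - z * mm$se_link))
  expect_equal(mm$ci_high, exp(mm$eta + z * mm$se_link))
})

test_that("with a single region the marginal mean is the plain prediction", {
  f <- make_fit(two_regions = FALSE)$fit
  mm <- marginal_means(f, "g")
  x0 <- mean(f$model_frame$x)
  pred <- sapply(mm$label, function(l)
    predict(f, data.frame(g = l, x = x0), type = "response"))
  expect_equal(mm$estimate, unname(pred), tolerance = 1e-10)
})

test_that("simultaneous intervals are Bonferroni-widened", {
  f <- make_fit()$fit
  mm <- marginal_means(f, "g")
  mmb <- marginal_means(f, "g", simultaneous = TRUE)
  expect_true(all(mmb$ci_low < mm$ci_low))
  expect_true(all(mmb$ci_high > mm$ci_high))
})

test_that("pairwise contrasts carry BH adjustment and letters", {
  f <- make_fit()$fit
  mm <- marginal_means(f, "g")
  ct <- pairwise_contrasts_fdr(mm)
  expect_equal(nrow(ct$contrasts), 3)   # k(k-1)/2
  # hand-run Benjamini-Hochberg on the raw p-values
  p <- ct$contrasts$p_value
  o <- order(p, decreasing = TRUE)
  bh <- pmin(1, cummin(p[o] * length(p) / rank(p)[o]))[order(o)]
  expect_equal(ct$contrasts$p_adjusted, bh)
  expect_equal(nrow(ct$letters), 3)

  # two statistically identical levels share a letter
  set.seed(9)
  d <- data.frame(y = rtweedie_cp(600, 2, 0.5, 1.5),
                  g = factor(sample(c("a", "b"), 600, TRUE)))
  f2 <- fit_tweedie_glm(y ~ g, d, p = 1.5, phi_method = "pearson")
  ct2 <- pairwise_contrasts_fdr(marginal_means(f2, "g"))
  expect_equal(ct2$letters$letters[1], ct2$letters$letters[2])
  expect_equal(ct2$contrasts$p_adjusted, ct2$contrasts$p_value)
})

test_that("per-group slopes equal finite-difference derivatives of the predictor", {
  mf <- make_fit()
  f <- mf$fit
  st <- slope_tests(f, "x", by = "g")
  h <- 1e-4
  for (i in seq_len(nrow(st))) {
    eta_p <- mean(sapply(c("R1", "R2"), function(rr)
      predict(f, data.frame(g = st$crop[i], r = rr, x = h))))
    eta_m <- mean(sapply(c("R1", "R2"), function(rr)
      predict(f, data.frame(g = st$crop[i], r = rr, x = -h))))
    expect_equal(st$slope[i], (eta_p - eta_m) / (2 * h), tolerance = 1e-6)
  }
})

test_that("without an interaction every group has the same slope", {
  f <- make_fit(interaction = FALSE)$fit
  st <- slope_tests(f, "x", by = "g")
  expect_equal(st$slope, rep(st$slope[1], 3))
  expect_equal(st$se, rep(st$se[1], 3))
})

test_that("percent change maps scaled slopes to the raw indicator scale", {
  # direct formula: slope -0.10, sd 0.60, raw change 1 -> 4
  set.seed(12)
  n <- 500
  x_raw <- rnorm(n, 2, 0.6)
  sc <- scale_predictors(data.frame(x = x_raw), "x")
  y <- rtweedie_cp(n, exp(0.5 - 0.1 * sc$data$x), 0.5, 1.5)
  d <- data.frame(y = y, x = sc$data$x)
  fit <- fit_tweedie_glm(y ~ x, d, p = 1.5, phi_method = "pearson",
                         scaling = sc$scaling)
  pc <- percent_change_effect(fit, "x", 1, 4, crop = NULL, by = NULL)
  slope <- coef(fit)[["x"]]
  sdv <- sc$scaling$sd[1]
  expect_equal(pc$percent_change,
               100 * (exp(slope * 3 / sdv) - 1), tolerance = 1e-10)
  # frozen arithmetic check of the mapping itself
  expect_equal(100 * (exp(-0.10 * (4 - 1) / 0.60) - 1), -39.34693,
               tolerance = 1e-5)
  # reversal identity: (1 + x/100)(1 + y/100) = 1
  pc_rev <- percent_change_effect(fit, "x", 4, 1, crop = NULL, by = NULL)
  expect_equal((1 + pc$percent_change / 100) * (1 + pc_rev$percent_change / 100),
               1, tolerance = 1e-10)
})

test_that("percent change is invariant to the scaling constants chosen", {
  set.seed(13)
  n <- 600
  x_raw <- rnorm(n, 3, 1.2)
  mu <- exp(0.4 - 0.15 * x_raw)
  y <- rtweedie_cp(n, mu, 0.5, 1.5)
  fit_of <- function(center, scale) {
    d <- data.frame(y = y, x = (x_raw - center) / scale)
    fit_tweedie_glm(y ~ x, d, p = 1.5, phi_method = "pearson",
                    scaling = data.frame(var = "x", mean = center,
                                         sd = scale))
  }
  pc1 <- percent_change_effect(fit_of(3, 1.2), "x", 1, 4, crop = NULL,
                               by = NULL)
  pc2 <- percent_change_effect(fit_of(0, 2.5), "x", 1, 4, crop = NULL,
                               by = NULL)
  expect_equal(pc1$percent_change, pc2$percent_change, tolerance = 1e-6)
})

test_that("slope of a zero-effect indicator gives zero percent change", {
  set.seed(14)
  d <- data.frame(y = rtweedie_cp(300, 2, 0.5, 1.5), x = rnorm(300))
  fit <- fit_tweedie_glm(y ~ 1, d, p = 1.5, phi_method = "pearson")
  # a literal zero slope: synthetic fit with the x term absent is not
  # addressable, so check the formula at slope = 0 directly
  expect_equal(100 * (exp(0 * 5) - 1), 0)
  expect_error(percent_change_effect(fit, "x", 0, 1), "scaling")
})
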