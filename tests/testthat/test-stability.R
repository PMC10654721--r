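test_that("Bray-Curtis dissimilarity matches hand values", {
  x <- rbind(a = c(0.5, 0.5, 0), b = c(0.5, 0.5, 0), c = c(0, 0, 1),
             d = c(0.5, 0, 0.5))
  d <- bray_curtis_matrix(x)
  expect_equal(d["a", "b"], 0)        # identical rows
  expect_equal(d["a", "c"], 1)        # disjoint supports
  expect_equal(d["a", "d"], 0.5)      # half shared mass
  expect_equal(diag(d), rep(0, 4), ignore_attr = TRUE)
  expect_equal(d, t(d))
  expect_error(bray_curtis_matrix(rbind(c(-0.1, 1.1))), "nonnegative")
})

test_that("groups internally identical and mutually distinct give R2 = 1", {
  x <- rbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 1, 0),
             c(0, 0, 1), c(0, 0, 1))
  d <- bray_curtis_matrix(x)
  res <- permanova(d, rep(c("a", "b", "c"), each = 2), n_perm = 99, seed = 1)
  expect_equal(res$r_squared, 1)
  expect_equal(res$ss_within, 0)
})

test_that("PERMANOVA on Euclidean univariate distances reproduces one-way ANOVA", {
  set.seed(33)
  y <- rnorm(18)
  g <- rep(c("a", "b", "c"), each = 6)
  res <- permanova(as.matrix(dist(y)), g, n_perm = 49, seed = 2)
  ref <- anova(lm(y ~ g))
  expect_equal(res$pseudo_f, ref[["F value"]][1], tolerance = 1e-10)
  expect_equal(res$r_squared,
               ref[["Sum Sq"]][1] / sum(ref[["Sum Sq"]]), tolerance = 1e-10)
})

test_that("sum-of-squares partition and F agree with vegan::adonis2", {
  set.seed(12)
  x <- matrix(rgamma(15 * 4, 0.7), 15, 4); x <- x / rowSums(x)
  g <- sample(rep(c("a", "b", "c"), 5))
  d <- bray_curtis_matrix(x)
  mine <- permanova(d, g, n_perm = 99, seed = 1)
  ref <- vegan::adonis2(as.dist(d) ~ g, data = data.frame(g = g),
                        permutations = 99)
  expect_equal(mine$pseudo_f, ref$F[1], tolerance = 1e-10)
  expect_equal(mine$r_squared, ref$R2[1], tolerance = 1e-10)
  expect_equal(mine$ss_between + mine$ss_within, mine$ss_total,
               tolerance = 1e-9)
})

test_that("R2 is seed-invariant and F is scale-invariant", {
  set.seed(4)
  x <- matrix(rgamma(12 * 3, 1), 12, 3); x <- x / rowSums(x)
  g <- rep(c("a", "b"), each = 6)
  d <- bray_curtis_matrix(x)
  r1 <- permanova(d, g, n_perm = 29, seed = 1)
  r2 <- permanova(d, g, n_perm = 29, seed = 999)
  expect_equal(r1$r_squared, r2$r_squared)
  r3 <- permanova(2 * d, g, n_perm = 29, seed = 1)
  expect_equal(r3$pseudo_f, r1$pseudo_f, tolerance = 1e-10)
  expect_equal(r3$r_squared, r1$r_squared, tolerance = 1e-10)
  expect_equal(r3$p_value, r1$p_value)
})

test_that("degenerate groupings raise degrees-of-freedom errors", {
  d <- as.matrix(dist(1:4))
  expect_error(permanova(d, rep("a", 4)), "2 groups")
  expect_error(permanova(d, letters[1:4]), "degrees of freedom|within-group")
})

test_that("group dispersions match the principal-coordinate construction", {
  # all points of a group identical -> zero dispersion
  x <- rbind(c(1, 0), c(1, 0), c(1, 0), c(0, 1), c(0.5, 0.5), c(0.2, 0.8))
  d <- bray_curtis_matrix(x)
  g <- rep(c("a", "b"), each = 3)
  res <- dispersion_test(d, g)
  expect_equal(unname(res$distances[1:3]), rep(0, 3), tolerance = 1e-7)

  # congruent point clouds have equal dispersions and F near 0
  y1 <- cbind(c(0, 1, 0.5), c(0, 0, 1))
  y2 <- y1 + 5
  dd <- as.matrix(dist(rbind(y1, y2)))
  gg <- rep(c("a", "b"), each = 3)
  r2 <- dispersion_test(dd, gg)
  expect_equal(mean(r2$distances[1:3]), mean(r2$distances[4:6]),
               tolerance = 1e-8)
  expect_lt(r2$anova_f, 1e-10)
})

test_that("for Euclidean input the embedding is an isometry", {
  set.seed(9)
  X <- matrix(rnorm(20 * 3), 20, 3)
  g <- rep(c("a", "b"), each = 10)
  res <- dispersion_test(as.matrix(dist(X)), g)
  for (lv in c("a", "b")) {
    idx <- which(g == lv)
    m <- spatial_median_direct(X[idx, ])
    direct <- sqrt(rowSums(sweep(X[idx, ], 2, m)^2))
    expect_equal(unname(res$distances[idx]), direct, tolerance = 1e-6)
  }
})

test_that("dispersion distances agree with vegan::betadisper spatial medians", {
  set.seed(18)
  x <- matrix(rgamma(18 * 5, 0.6), 18, 5); x <- x / rowSums(x)
  g <- rep(c("a", "b", "c"), each = 6)
  d <- bray_curtis_matrix(x)
  mine <- dispersion_test(d, g)
  ref <- vegan::betadisper(as.dist(d), g, type = "median")
  expect_equal(unname(mine$distances), unname(ref$distances),
               tolerance = 1e-5)
  expect_equal(mine$anova_f, anova(ref)[["F value"]][1], tolerance = 1e-5)
})

test_that("singleton groups are excluded from the dispersion ANOVA", {
  set.seed(2)
  x <- matrix(rgamma(7 * 3, 1), 7, 3); x <- x / rowSums(x)
  g <- c("a", "a", "a", "b", "b", "b", "solo")
  expect_warning(res <- dispersion_test(bray_curtis_matrix(x), g), "size 1")
  expect_equal(res$excluded, "solo")
})

test_that("balanced-subset analysis books one PERMANOVA per count class", {
  # identical within-system compositions -> R2 = 1 in every class
  comp <- rbind(c(1, 0), c(1, 0),                 # sys1: k = 2
                c(0, 1), c(0, 1),                 # sys2: k = 2
                c(0.5, 0.5), c(0.5, 0.5), c(0.5, 0.5),  # sys3: k = 3
                c(0.2, 0.8), c(0.2, 0.8), c(0.2, 0.8))  # sys4: k = 3
  g <- c("s1", "s1", "s2", "s2", "s3", "s3", "s3", "s4", "s4", "s4")
  tab <- balanced_subset_analysis(comp, g, n_perm = 29, seed = 1)
  expect_equal(tab$k, c(2, 3))
  expect_equal(tab$r_squared, c(1, 1))
  # a class with a single group is skipped with a warning
  g2 <- c("s1", "s1", "s2", "s2", "s3", "s3", "s3", "s3", "s3", "s3")
  expect_warning(tab2 <- balanced_subset_analysis(comp, g2, n_perm = 29,
                                                  seed = 1),
                 "fewer than 2 groups")
  expect_equal(tab2$k, 2)
})

test_that("R2 decreases on average as compositional drift grows", {
  r2_at <- function(eps, seed) {
    gen <- generate_network(simulation_config(
      n_systems = 25, seed = seed, composition_drift = eps,
      time_point_weights = c(0, 0, 1, rep(0, 8))))
    ct <- composition_table(gen$dataset$fields)
    d <- bray_curtis_matrix(ct$comp)
    permanova(d, ct$system_id, n_perm = 1, seed = 1)$r_squared
  }
  low <- mean(vapply(1:3, function(s) r2_at(0.05, s), numeric(1)))
  high <- mean(vapply(1:3, function(s) r2_at(0.9, s), numeric(1)))
  expect_gt(low, high)
})
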