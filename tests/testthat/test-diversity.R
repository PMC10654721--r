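test_that("order-1 Hill number matches hand-derived values", {
  expect_equal(hill_shannon(1), 1)
  expect_equal(hill_shannon(rep(0.25, 4)), 4)
  # exp(-(0.5 ln 0.5 + 0.3 ln 0.3 + 0.2 ln 0.2)) computed by hand
  expect_equal(hill_shannon(c(0.5, 0.3, 0.2)), 2.8000941, tolerance = 1e-7)
  # zeros contribute nothing
  expect_equal(hill_shannon(c(0.5, 0.3, 0.2, 0, 0)),
               hill_shannon(c(0.5, 0.3, 0.2)))
})

test_that("Hill number rejects invalid compositions", {
  expect_error(hill_shannon(c(0, 0)), "positive")
  expect_error(hill_shannon(c(0.6, -0.1, 0.5)), "nonnegative")
  expect_error(hill_shannon(c(0.5, 0.4)), "sum to 1")
})

test_that("functional/taxonomic decomposition matches the worked example", {
  comp <- c(winter_wheat = 0.5, winter_barley = 0.25, spring_pea = 0.25)
  d <- decompose_diversity(comp)
  expect_equal(d$fd, 1.754765, tolerance = 1e-6)
  expect_equal(d$td_arith, 1.667410, tolerance = 1e-6)
  expect_equal(d$td_geom, 1.611862, tolerance = 1e-5)
  expect_equal(d$fd * d$td_geom, hill_shannon(c(0.5, 0.25, 0.25)),
               tolerance = 1e-10)
})

test_that("decomposition degenerates correctly at one family / one crop per family", {
  one_family <- c(winter_wheat = 0.5, winter_barley = 0.3, maize = 0.2)
  d <- decompose_diversity(one_family)
  expect_equal(d$fd, 1)
  expect_equal(d$td_arith, hill_shannon(c(0.5, 0.3, 0.2)))
  expect_equal(d$td_geom, d$td_arith)

  singletons <- c(spring_pea = 0.4, oilseed_rape = 0.3, sunflower = 0.3)
  d2 <- decompose_diversity(singletons)
  expect_equal(d2$td_arith, 1)
  expect_equal(d2$td_geom, 1)
  expect_equal(d2$fd, hill_shannon(c(0.4, 0.3, 0.3)))
})

test_that("geometric decomposition is exact, arithmetic bounds from below", {
  set.seed(101)
  for (i in 1:1000) {
    comp <- random_composition(sample(2:10, 1))
    h <- hill_shannon(comp)
    d <- decompose_diversity(comp)
    expect_equal(d$fd * d$td_geom, h, tolerance = 1e-10)
    expect_gte(d$fd * d$td_arith, h - 1e-12)
  }
})

test_that("Hill number is permutation-invariant, bounded, and decreases on merges", {
  set.seed(7)
  for (i in 1:50) {
    comp <- random_composition(sample(3:8, 1))
    h <- hill_shannon(comp)
    expect_equal(hill_shannon(sample(comp)), h)
    expect_gte(h, 1)
    expect_lte(h, length(comp) + 1e-12)
    merged <- c(sum(comp[1:2]), comp[-(1:2)])
    expect_lte(hill_shannon(merged / sum(merged)), h + 1e-12)
  }
})

test_that("sowing-period diversity aggregates crop proportions by period", {
  all_winter <- c(winter_wheat = 0.6, winter_barley = 0.4)
  expect_equal(sowing_period_diversity(all_winter), 1)
  half_half <- c(winter_wheat = 0.5, spring_pea = 0.5)
  expect_equal(sowing_period_diversity(half_half), 2)
  # periods (0.5 winter, 0.3 spring, 0.2 summer) -> same oracle value
  mix <- c(winter_wheat = 0.5, spring_pea = 0.3, maize = 0.2)
  expect_equal(sowing_period_diversity(mix), 2.8000941, tolerance = 1e-7)
})

test_that("cover-crop frequency is a field count ratio, areas ignored", {
  expect_equal(cover_crop_frequency(rep(FALSE, 8)), 0)
  expect_equal(cover_crop_frequency(rep(TRUE, 8)), 1)
  expect_equal(cover_crop_frequency(c(rep(TRUE, 3), rep(FALSE, 9))), 0.25)
  expect_error(cover_crop_frequency(logical(0)), "empty")
})

test_that("cereal effective number renormalizes over cereal crops", {
  expect_equal(cereal_effective_number(c(winter_wheat = 1)), 1)
  two_eq <- c(winter_wheat = 0.3, maize = 0.3, spring_pea = 0.4)
  expect_equal(cereal_effective_number(two_eq), 2)
  three <- c(winter_wheat = 0.25, maize = 0.15, winter_barley = 0.1,
             spring_pea = 0.5)
  expect_equal(cereal_effective_number(three), 2.8000941, tolerance = 1e-7)
  expect_message(
    out <- cereal_effective_number(c(spring_pea = 0.5, soybean = 0.5)),
    "no cereal")
  expect_equal(out, 1)
})

test_that("composition from fields equals area-unweighted crop frequencies", {
  crops <- c("maize", "maize", "winter_wheat", "spring_pea")
  comp <- composition_from_fields(crops)
  expect_equal(comp[["maize"]], 0.5)
  expect_equal(sum(comp), 1)
})

test_that("diversity_profiles emits one consistent row per system and time point", {
  ds <- tiny_dataset()
  prof <- diversity_profiles(ds$fields)
  expect_equal(nrow(prof), 2)
  a <- prof[prof$system_id == "sysA", ]
  expect_equal(a$hill_d, 2)     # 4 wheat + 4 pea fields
  expect_equal(a$fd, 2)         # Poaceae + Fabaceae
  expect_equal(a$td_arith, 1)
  expect_equal(a$cover_crop_freq, 0.5)
  b <- prof[prof$system_id == "sysB", ]
  expect_equal(b$hill_d, 1)
  expect_equal(b$cereal_hill, 1)
})
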