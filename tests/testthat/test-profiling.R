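test_that("per-100-kcal rescaling is exact linear scaling", {
  expect_equal(per_100kcal(5, 50), 10)
  expect_equal(per_100kcal(5, 100), 5)
  expect_equal(per_100kcal(3.3, 47), 3.3 * 100 / 47)  # 7.0213 by hand
  expect_error(per_100kcal(5, 0), "energy")
})

test_that("NRF9.3 caps qualifying subscores and leaves limits uncapped", {
  cfg <- default_config()
  dv <- unlist(cfg$nrf$qualifying)
  mrv <- unlist(cfg$nrf$limiting)
  zero <- setNames(rep(0, 12), c(names(dv), names(mrv)))

  # every qualifying nutrient exactly at its DV, no limits -> 900
  at_dv <- zero
  at_dv[names(dv)] <- dv
  expect_equal(nrf93(at_dv, cfg), 900)

  # all qualifying zero, every limit exactly at its MRV -> -300
  at_mrv <- zero
  at_mrv[names(mrv)] <- mrv
  expect_equal(nrf93(at_mrv, cfg), -300)

  # protein 50% DV + fiber 200% DV (capped to 100) - sodium 25% MRV = 125
  mixed <- zero
  mixed["protein"] <- 0.5 * dv["protein"]
  mixed["fiber"] <- 2 * dv["fiber"]
  mixed["sodium"] <- 0.25 * mrv["sodium"]
  expect_equal(nrf93(mixed, cfg), 50 + 100 - 25)

  expect_error(nrf93(zero[-1], cfg), "protein")

  # property: independent capped-sum oracle on random profiles; monotone
  # in qualifying, anti-monotone in limiting; never above 900
  set.seed(7)
  for (i in 1:50) {
    prof <- setNames(runif(12, 0, 3) * c(dv, mrv), names(zero))
    oracle <- sum(pmin(prof[names(dv)] / dv, 1) * 100) -
      sum(prof[names(mrv)] / mrv * 100)
    expect_equal(nrf93(prof, cfg), oracle)
    expect_lte(nrf93(prof, cfg), 900)
    bump <- prof
    bump["iron"] <- bump["iron"] + 1
    expect_gte(nrf93(bump, cfg), nrf93(prof, cfg))
    bump2 <- prof
    bump2["sodium"] <- bump2["sodium"] + 100
    expect_lt(nrf93(bump2, cfg), nrf93(prof, cfg))
  }
})

test_that("cost per 100 kcal follows package price arithmetic", {
  expect_equal(cost_per_100kcal(2.00, 500, 200), 0.20)
  expect_equal(cost_per_100kcal(1.00, 100, 100), 1.00)
  expect_error(cost_per_100kcal(1, 100, 0), "energy")
  expect_error(cost_per_100kcal(-1, 100, 100), "positive")
})

test_that("food profiles floor the ratio at zero and match brute force", {
  cfg <- default_config()
  dir <- withr::local_tempdir()
  write_tiny_csvs(dir)
  ds <- suppressWarnings(load_dataset(
    file.path(dir, "composition.csv"), file.path(dir, "prices.csv"),
    file.path(dir, "coding.csv"), quiet = TRUE))
  fp <- food_profiles(ds, cfg)

  # a1: energy 100, fiber 25 g/100 g = 100% DV/100 kcal -> NRF 100;
  # cost = 2.5/1000*100/100*100 = 0.25 -> ratio 400
  a1 <- fp[fp$food_id == "a1", ]
  expect_equal(a1$nrf_per_100kcal, 100)
  expect_equal(a1$cost_per_100kcal, 0.25)
  expect_equal(a1$ratio, 400)

  # c1 is sugary/fatty: negative NRF floors to ratio 0
  c1 <- fp[fp$food_id == "c1", ]
  expect_lt(c1$nrf_per_100kcal, 0)
  expect_equal(c1$ratio, 0)

  # brute-force recomputation from raw rows for every generated food
  ds2 <- small_dataset()
  fp2 <- food_profiles(ds2, cfg)
  expect_true(all(fp2$ratio >= 0))
  set.seed(11)
  for (fid in sample(fp2$food_id, 20)) {
    row <- ds2$foods[ds2$foods$food_id == fid, ]
    prof <- unlist(row[, c(NRF_QUALIFYING, NRF_LIMITING)]) *
      100 / row$energy_kcal_100g
    pr <- ds2$prices[ds2$prices$food_id == fid, ]
    cost <- mean(pr$price_nzd / pr$package_size_g * 100 /
                   row$energy_kcal_100g * 100)
    expect_equal(fp2$nrf_per_100kcal[fp2$food_id == fid],
                 nrf93(prof, cfg))
    expect_equal(fp2$cost_per_100kcal[fp2$food_id == fid], cost)
  }
})

test_that("category ratio is the mean of food ratios, not a ratio of means", {
  cfg <- default_config()
  # foods with NRF (100, 100) and cost (0.25, 1.0): mean of ratios is
  # (400 + 100)/2 = 250, whereas mean_nrf/mean_cost would give 160
  dir <- withr::local_tempdir()
  write_tiny_csvs(dir)
  ds <- suppressWarnings(load_dataset(
    file.path(dir, "composition.csv"), file.path(dir, "prices.csv"),
    file.path(dir, "coding.csv"), quiet = TRUE))
  cp <- category_profiles(ds, cfg)
  cat_a <- cp[cp$category_id == "cat_a", ]
  expect_equal(cat_a$ratio, 250)
  expect_equal(cat_a$mean_nrf / cat_a$mean_cost, 160)
  expect_equal(cat_a$mean_cost, 0.625)
  # single-food category carries its food's ratio and zero SD
  cat_b <- cp[cp$category_id == "cat_b", ]
  fp <- food_profiles(ds, cfg)
  expect_equal(cat_b$ratio, fp$ratio[fp$food_id == "b1"])
  expect_equal(cat_b$sd_nrf, 0)
})

test_that("quartile assignment uses the ceiling rule with name tie-breaks", {
  mk <- function(ratios, names = sprintf("c%02d", seq_along(ratios))) {
    tibble::tibble(category_id = names, name = names, ratio = ratios)
  }
  # n = 61 -> |Q1| = 16
  q61 <- assign_quartiles(mk(seq(61, 1)))
  expect_equal(as.integer(table(q61$quartile)), c(16L, 15L, 15L, 15L))
  # n = 4 distinct ratios -> one per quartile
  expect_equal(assign_quartiles(mk(c(4, 3, 2, 1)))$quartile, 1:4)
  # n = 5, ratios 5..1 -> Q1 holds the top ceiling(5/4) = 2
  q5 <- assign_quartiles(mk(c(5, 4, 3, 2, 1)))
  expect_equal(sum(q5$quartile == 1), 2)
  expect_equal(q5$ratio[q5$quartile == 1], c(5, 4))
  # ties break by name ascending, deterministically
  tied <- assign_quartiles(mk(c(1, 1, 1, 1), c("d", "b", "a", "c")))
  expect_equal(tied$name, c("a", "b", "c", "d"))
  expect_error(assign_quartiles(mk(numeric(0))), "no categories")
  # quartile sizes always sum to n; Q1 min ratio >= Q2 max ratio
  set.seed(3)
  for (n in c(2, 7, 13, 61, 100)) {
    q <- assign_quartiles(mk(runif(n, 0, 500)))
    expect_equal(nrow(q), n)
    if (any(q$quartile == 2)) {
      expect_gte(min(q$ratio[q$quartile == 1]),
                 max(q$ratio[q$quartile == 2]))
    }
  }
})

test_that("scaling all prices by k divides ratios by k, order unchanged", {
  cfg <- default_config()
  ds <- small_dataset()
  base <- rank_categories(ds, cfg)
  ds_k <- ds
  ds_k$prices$price_nzd <- ds_k$prices$price_nzd * 3
  scaled <- rank_categories(ds_k, cfg)
  m <- match(base$category_id, scaled$category_id)
  expect_equal(scaled$ratio[m], base$ratio / 3, tolerance = 1e-12)
  expect_equal(scaled$category_id, base$category_id)
  expect_equal(scaled$quartile[m], base$quartile)
})
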