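test_that("forest mask applies the >= threshold and the plantation exclusion", {
  g <- grid_spec(1, 4)
  dens <- fp_layer("tcd", "continuous", matrix(c(30, 30, 24.9, NA), 1, 4))
  plant <- fp_layer("plantation_mask", "mask", matrix(c(0, 1, 0, 0), 1, 4))
  m <- build_forest_mask(dens, plant, threshold = 25)
  expect_equal(m$values[1, ], c(1, 0, 0, NA))
  # boundary is inclusive
  m25 <- build_forest_mask(fp_layer("tcd", "continuous", matrix(25, 1, 1)),
                           NULL, 25)
  expect_equal(m25$values[1, 1], 1)
  expect_error(build_forest_mask(dens, plant, threshold = 101),
               "threshold")
})

test_that("commodity maps take precedence over land-use maps", {
  g <- grid_spec(1, 1)
  stack <- build_test_stack(g, loss_year = 2010,
                            extra = list(crop_map = 1, crop_map_obs = 2010,
                                         lu_map = 1, lu_map_obs = 2010))
  reg <- list(ds_landuse(), ds_commodity())  # registry order must not matter
  attr <- attribute_pixels(stack, reg, NULL, g)
  expect_equal(attribution_labels(attr)[1, 1], "soy/commodity")
})

test_that("static maps never attribute losses beyond their last valid year", {
  g <- grid_spec(1, 2)
  stack <- build_test_stack(g, loss_year = matrix(c(2019, 2021), 1, 2),
                            extra = list(cocoa_map = 1))
  reg <- list(ds_commodity("cocoa_map", c(`1` = "cocoa"), lvy = 2020,
                           annual = FALSE))
  attr <- attribute_pixels(stack, reg, NULL, g)
  lab <- attribution_labels(attr)
  expect_equal(lab[1, 1], "cocoa/commodity")   # 2019 <= 2020: eligible
  expect_equal(lab[1, 2], "unattributed/none") # 2021 > 2020: falls through
})

test_that("annual datasets claim pixels only inside the forward lag window", {
  g <- grid_spec(1, 4)
  # observation delays of 0, 3, 4 years, and one unobserved pixel
  stack <- build_test_stack(
    g, loss_year = 2010,
    extra = list(crop_map = matrix(c(1, 1, 1, 0), 1, 4),
                 crop_map_obs = matrix(c(2010, 2013, 2014, 0), 1, 4)))
  reg <- list(ds_commodity())
  lab3 <- attribution_labels(attribute_pixels(stack, reg, NULL, g))
  expect_equal(lab3[1, ], c("soy/commodity", "soy/commodity",
                            "unattributed/none", "unattributed/none"))
  cfg5 <- default_config(); cfg5$spatial_lag_years <- 4L
  lab5 <- attribution_labels(attribute_pixels(stack, reg, cfg5, g))
  expect_equal(lab5[1, 3], "soy/commodity")
})

test_that("agriculture is attributed before fire; fire-only loss is excluded", {
  g <- grid_spec(1, 3)
  stack <- build_test_stack(
    g, loss_year = 2012, fire = matrix(c(2012, 2012, 0), 1, 3),
    extra = list(lu_map = matrix(c(2, 0, 0), 1, 3),
                 lu_map_obs = matrix(c(2012, 0, 0), 1, 3)))
  reg <- list(ds_landuse())
  attr <- attribute_pixels(stack, reg, NULL, g)
  lab <- attribution_labels(attr)
  expect_equal(lab[1, 1], "pasture/land_use")        # agriculture beats fire
  expect_equal(lab[1, 2], "fire_non_commodity/fire") # fire only
  expect_equal(lab[1, 3], "unattributed/none")

  # fire loss is excluded from deforestation totals
  summ <- summarize_attribution(attr, stack$region, g)
  tot <- summ$totals
  expect_equal(tot$fire_ha, g$pixel_area_ha)
  expect_equal(tot$deforestation_ha, 2 * g$pixel_area_ha)
  expect_equal(tot$deforestation_ha + tot$degradation_rotation_ha +
                 tot$fire_ha, tot$total_loss_ha)
  # fire year must match the loss year exactly by default
  stack2 <- build_test_stack(g, loss_year = 2012,
                             fire = matrix(c(2013, 0, 0), 1, 3))
  lab2 <- attribution_labels(attribute_pixels(stack2, list(), NULL, g))
  expect_equal(lab2[1, 1], "unattributed/none")
})

test_that("driver fallback engages after fire, and ties break by rubric score", {
  g <- grid_spec(1, 2)
  stack <- build_test_stack(g, loss_year = 2010,
                            extra = list(drv_map = matrix(c(1, 2), 1, 2)))
  reg <- list(ds_driver())
  lab <- attribution_labels(attribute_pixels(stack, reg, NULL, g))
  expect_equal(lab[1, ], c("commodity_driven/driver", "forestry/driver"))

  # two commodity maps disagree: the higher-scored dataset wins
  stack2 <- build_test_stack(
    g, loss_year = 2010,
    extra = list(a_map = 1, a_map_obs = 2010, b_map = 1, b_map_obs = 2010))
  reg2 <- list(ds_commodity("a_map", c(`1` = "soy"), scores = c(1, 0.5, 1)),
               ds_commodity("b_map", c(`1` = "maize"), scores = c(1, 1, 1)))
  lab2 <- attribution_labels(attribute_pixels(stack2, reg2, NULL, g))
  expect_equal(lab2[1, 1], "maize/commodity")
})

test_that("summary areas are pixel counts times pixel area", {
  g <- grid_spec(10, 10, pixel_area_ha = 0.09)
  stack <- build_test_stack(g, loss_year = 2010,
                            extra = list(crop_map = 1, crop_map_obs = 2010))
  attr <- attribute_pixels(stack, list(ds_commodity()), NULL, g)
  summ <- summarize_attribution(attr, stack$region, g)
  expect_equal(summ$classes$area_ha, 9.0)   # 100 pixels x 0.09 ha
  expect_equal(summ$classes$label, "soy")
  expect_equal(summ$classes$region, "R1")

  # empty loss layer gives an empty summary with zero totals
  stack0 <- build_test_stack(g, loss_year = 0)
  summ0 <- summarize_attribution(attribute_pixels(stack0, list(), NULL, g),
                                 stack0$region, g)
  expect_equal(nrow(summ0$classes), 0L)
  expect_equal(nrow(summ0$totals), 0L)
})

test_that("optimized attribution equals the brute-force oracle", {
  cfg <- default_config()
  for (seed in c(2, 14, 30)) {
    L <- generate_landscape(landscape_params(grid = grid_spec(40, 40),
                                             n_events = 30, seed = seed))
    fast <- attribution_labels(attribute_pixels(L$stack, L$registry, cfg,
                                                L$grid))
    slow <- naive_attribute(L$stack, L$registry, cfg, L$grid)
    expect_identical(fast, slow)
  }
})

test_that("deforestation is monotone in threshold; commodity area in lag", {
  L <- generate_landscape(landscape_params(seed = 17))
  defo_at <- function(th) {
    cfg <- default_config(); cfg$tcd_threshold <- th
    a <- attribute_pixels(L$stack, L$registry, cfg, L$grid)
    sum(summarize_attribution(a, L$stack$region, L$grid)$totals$deforestation_ha)
  }
  expect_lte(defo_at(75), defo_at(25))
  expect_lte(defo_at(25), defo_at(10))

  commodity_at <- function(lag) {
    cfg <- default_config(); cfg$spatial_lag_years <- lag
    a <- attribute_pixels(L$stack, L$registry, cfg, L$grid)
    s <- summarize_attribution(a, L$stack$region, L$grid)
    sum(s$classes$area_ha[s$classes$level == "commodity"])
  }
  areas <- vapply(c(1, 3, 5), commodity_at, numeric(1))
  expect_true(all(diff(areas) >= 0))
})

test_that("every loss pixel lands in exactly one class", {
  L <- generate_landscape(landscape_params(seed = 23))
  attr <- attribute_pixels(L$stack, L$registry, NULL, L$grid)
  n_loss <- sum(L$stack$loss_year$values > 0)
  expect_equal(sum(!is.na(attr$code)), n_loss)
  summ <- summarize_attribution(attr, L$stack$region, L$grid)
  expect_equal(sum(summ$totals$total_loss_ha),
               n_loss * L$grid$pixel_area_ha)
  expect_equal(sum(summ$classes$area_ha),
               sum(summ$totals$deforestation_ha))
})
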