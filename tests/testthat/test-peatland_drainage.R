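test_that("peat overlap equals a brute-force pixel loop", {
  L <- generate_landscape(landscape_params(grid = grid_spec(40, 40),
                                           n_events = 30, peat_fraction = 0.3,
                                           seed = 12))
  attr <- attribute_pixels(L$stack, L$registry, NULL, L$grid)
  ov <- peat_overlap(attr, L$stack$peat_mask, L$stack$region,
                     L$stack$biome, L$grid)
  # brute force: count deforestation pixels on peat per (region, year, label)
  counts <- list()
  for (i in seq_len(L$grid$n_rows)) for (j in seq_len(L$grid$n_cols)) {
    code <- attr$code[i, j]
    if (is.na(code) || L$stack$peat_mask$values[i, j] != 1) next
    lv <- attr$key$level[code]
    if (lv %in% c("fire", "excluded")) next
    k <- paste(L$stack$region$values[i, j], L$stack$loss_year$values[i, j],
               attr$key$label[code])
    counts[[k]] <- if (is.null(counts[[k]])) 1 else counts[[k]] + 1
  }
  got <- setNames(ov$peat_area_ha,
                  paste(sub("^R", "", ov$region), ov$year, ov$label))
  expect_setequal(names(got), names(counts))
  for (k in names(counts))
    expect_equal(got[[k]], counts[[k]] * L$grid$pixel_area_ha)

  # empty peat mask gives nothing
  stack0 <- L$stack
  stack0$peat_mask <- fp_layer("peat_mask", "mask", mkm(0, L$grid),
                               grid = L$grid)
  expect_equal(nrow(peat_overlap(attr, stack0$peat_mask, L$stack$region,
                                 L$stack$biome, L$grid)), 0L)
})

test_that("unresolved peat is split evenly among identified commodities", {
  al <- allocate_peat_area(9, c("soy", "maize", "rice"))
  expect_equal(al$peat_area_ha, rep(3, 3))
  al1 <- allocate_peat_area(5, "cocoa")
  expect_equal(al1$peat_area_ha, 5)
  # empty set falls to the residual class
  al0 <- allocate_peat_area(4, character())
  expect_equal(al0$commodity, "unallocated")
  expect_equal(al0$peat_area_ha, 4)
  # conservation for random sets
  set.seed(7)
  for (k in 1:10) {
    cs <- paste0("c", seq_len(sample(1:8, 1)))
    a <- runif(1, 0, 50)
    expect_equal(sum(allocate_peat_area(a, cs)$peat_area_ha), a,
                 tolerance = 1e-12)
  }
})

test_that("drainage accumulates annually from the deforestation year, inclusive", {
  rec <- tibble::tibble(defo_year = 2010, peat_area_ha = 1,
                        annual_MgCO2 = 54.41)
  out <- accumulate_emissions(rec, "until_end", year_end = 2022)
  expect_equal(out$accrual_years, 13)
  expect_equal(out$accumulated_MgCO2, 13 * 54.41)

  expect_equal(accumulate_emissions(rec, "none", 2022)$accumulated_MgCO2, 0)
  expect_equal(accumulate_emissions(rec, 5, 2022)$accrual_years, 5)
  # a fixed horizon never runs past the window end
  late <- tibble::tibble(defo_year = 2020, peat_area_ha = 1,
                         annual_MgCO2 = 10)
  expect_equal(accumulate_emissions(late, 5, 2022)$accrual_years, 3)
  expect_error(accumulate_emissions(rec, "forever", 2022), "unknown horizon")

  # accumulation is non-decreasing in the end year
  acc <- vapply(2010:2022, function(ye)
    accumulate_emissions(rec, "until_end", ye)$accumulated_MgCO2, numeric(1))
  expect_true(all(diff(acc) >= 0))

  # linear in area and accrual years
  rec2 <- rec; rec2$peat_area_ha <- 3; rec2$annual_MgCO2 <- 3 * 54.41
  expect_equal(accumulate_emissions(rec2, "until_end", 2022)$accumulated_MgCO2,
               3 * out$accumulated_MgCO2)
})

test_that("shorter horizons never exceed the until-end total and are monotone", {
  L <- generate_landscape(landscape_params(seed = 15, peat_fraction = 0.3))
  total_at <- function(h) {
    cfg <- default_config(); cfg$peat$horizon <- h
    sum(run_footprint(L, cfg)$peat$accumulated_MgCO2)
  }
  tot <- vapply(list("none", 5, 10, 15, "until_end"), total_at, numeric(1))
  expect_true(all(diff(tot) >= 0))
  expect_lt(tot[2], tot[5])  # a 5-year horizon strictly underestimates
  expect_equal(tot[1], 0)
})

test_that("peat SOC is never double-counted in the committed emissions", {
  L <- generate_landscape(landscape_params(seed = 18, peat_fraction = 1))
  run <- run_footprint(L)
  expect_equal(sum(run$emissions$soc_MgCO2), 0)
  expect_gt(sum(run$emissions$gross_MgCO2), 0)
})

test_that("spatially attributed peat follows its commodity; pools follow their allocation", {
  p <- landscape_params(seed = 8, noise = 0, spatial_coverage = 1,
                        mosaic_fraction = 0, delay_probs = 1,
                        peat_fraction = 0.4)
  L <- generate_landscape(p)
  run <- run_footprint(L)
  got <- dplyr::summarise(
    dplyr::group_by(run$peat, region, commodity, defo_year),
    a = sum(peat_area_ha), .groups = "drop")
  tru <- dplyr::filter(L$truth, peat_area_ha > 0)
  cmp <- dplyr::full_join(got, tru,
                          by = c("region", "commodity",
                                 defo_year = "year"))
  cmp$a[is.na(cmp$a)] <- 0; cmp$peat_area_ha[is.na(cmp$peat_area_ha)] <- 0
  expect_equal(cmp$a, cmp$peat_area_ha, tolerance = 1e-9)
  # oil palm on tropical peat uses its dedicated 54.41 factor
  op <- dplyr::filter(run$peat, commodity == "oil_palm", biome == "tropical")
  if (nrow(op))
    expect_equal(op$annual_MgCO2, op$peat_area_ha * 54.41, tolerance = 1e-9)
})
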