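test_that("gross and net land-use expansions follow the window rules", {
  st <- make_stats(list(R1 = list(cropland = c(`2008` = 1000, `2009` = 1100,
                                               `2010` = 1050),
                                  pasture = c(`2008` = 500, `2009` = 500,
                                              `2010` = 500))))
  ex_g <- landuse_expansions(st, "R1", 2010, lag = 2, mode = "gross")
  expect_equal(ex_g[["cropland"]], 100)  # only positive increments count
  ex_n <- landuse_expansions(st, "R1", 2010, lag = 2, mode = "net")
  expect_equal(ex_n[["cropland"]], 50)   # endpoint difference
  expect_equal(ex_g[["pasture"]], 0)
  expect_true(is.na(ex_g[["forest_plantation"]]))  # no data in window

  # missing interior years are interpolated linearly
  st2 <- make_stats(list(R1 = list(cropland = c(`2008` = 1000,
                                                `2010` = 1200))))
  ex2 <- landuse_expansions(st2, "R1", 2010, lag = 2, mode = "gross")
  expect_equal(ex2[["cropland"]], 200)
})

test_that("the unresolved pool is allocated cropland-first with statistical caps", {
  ex <- c(cropland = 60, pasture = 40, forest_plantation = 0)
  al <- allocate_landuse(c(unresolved_agriculture = 100), ex)
  got <- setNames(al$area_ha, al$target)
  expect_equal(got[["cropland"]], 60)
  expect_equal(got[["pasture"]], 40)

  cfg <- default_config(); cfg$cropland_first <- FALSE
  al2 <- allocate_landuse(c(unresolved_agriculture = 100), ex, cfg)
  got2 <- setNames(al2$area_ha, al2$target)
  expect_equal(got2[["cropland"]], 60)  # proportional 60:40
  expect_equal(got2[["pasture"]], 40)

  # restricted: expansions total 70, the remaining 30 ha had no production
  ex3 <- c(cropland = 42, pasture = 28, forest_plantation = 0)
  al3 <- allocate_landuse(c(unresolved_agriculture = 100), ex3)
  got3 <- setNames(al3$area_ha, al3$target)
  expect_equal(got3[["without_production"]], 30)
  expect_equal(sum(al3$area_ha), 100)

  # unrestricted: the full pool goes to the land uses
  cfg4 <- default_config(); cfg4$restrict_by_stats <- FALSE
  al4 <- allocate_landuse(c(unresolved_agriculture = 100), ex3, cfg4)
  expect_false("without_production" %in% al4$target)
  expect_equal(sum(al4$area_ha), 100)

  # degenerate input: all expansions zero -> unallocated
  al5 <- allocate_landuse(c(unresolved_agriculture = 50),
                          c(cropland = 0, pasture = 0,
                            forest_plantation = 0))
  expect_equal(setNames(al5$area_ha, al5$target)[["unallocated"]], 50)
  expect_error(allocate_landuse(c(unresolved_agriculture = -1), ex),
               "negative pool")
})

test_that("mosaic pools split between cropland and pasture only; single pools pass through", {
  ex <- c(cropland = 30, pasture = 10, forest_plantation = 100)
  al <- allocate_landuse(c(cropland_pasture_mosaic = 40, pasture_only = 7,
                           plantation_only = 3), ex,
                         modifyList(default_config(),
                                    list(restrict_by_stats = FALSE)))
  got <- tapply(al$area_ha, al$target, sum)
  expect_equal(got[["cropland"]], 30)           # 40 x 30/40
  expect_equal(got[["pasture"]], 10 + 7)        # mosaic share + pass-through
  expect_equal(got[["forest_plantation"]], 3)   # pass-through, uncapped
})

test_that("crop allocation is proportional to harvested-area expansion", {
  st <- make_stats(list(R1 = list(cropland = c(`2007` = 10000, `2010` = 10000))),
                   list(R1 = list(soy = c(`2007` = 100, `2010` = 400),
                                  maize = c(`2007` = 100, `2010` = 200))))
  al <- allocate_commodities(90, st, "R1", 2010, lag = 3)
  got <- setNames(al$area_ha, al$commodity)
  expect_equal(got[["soy"]], 67.5)    # 90 x 300/400
  expect_equal(got[["maize"]], 22.5)  # 90 x 100/400

  # single expanding crop receives the whole pool
  st1 <- make_stats(list(R1 = list(cropland = c(`2007` = 1000, `2010` = 1000))),
                    list(R1 = list(soy = c(`2007` = 100, `2010` = 150),
                                   maize = c(`2007` = 100, `2010` = 90))))
  al1 <- allocate_commodities(50, st1, "R1", 2010, lag = 3)
  expect_equal(al1$commodity, "soy")
  expect_equal(unname(al1$area_ha), 50)

  # no expanding crop: pool reported unallocated
  al0 <- allocate_commodities(50, st1, "R1", 2007, lag = 0)
  expect_equal(al0$commodity, "unallocated")
})

test_that("shares are invariant to rescaling and to uniform cropping intensity", {
  base <- list(R1 = list(soy = c(`2007` = 100, `2010` = 400),
                         maize = c(`2007` = 300, `2010` = 400)))
  lu <- list(R1 = list(cropland = c(`2007` = 10000, `2010` = 10000)))
  st <- make_stats(lu, base)
  al <- allocate_commodities(100, st, "R1", 2010, lag = 3)

  scaled <- lapply(base, function(r) lapply(r, `*`, 7))
  al_s <- allocate_commodities(100, make_stats(lu, scaled), "R1", 2010,
                               lag = 3)
  expect_equal(al[order(al$commodity), ], al_s[order(al_s$commodity), ])

  # CI = 2 in every year cancels out of the shares
  lu2 <- list(R1 = list(cropland = c(`2007` = 200, `2010` = 400)))
  st2 <- make_stats(lu2, base)  # total harvested = 2 x cropland each year
  on  <- allocate_commodities(100, st2, "R1", 2010, lag = 3,
                              multicropping = TRUE)
  off <- allocate_commodities(100, st2, "R1", 2010, lag = 3,
                              multicropping = FALSE)
  expect_equal(on[order(on$commodity), ]$area_ha,
               off[order(off$commodity), ]$area_ha)
})

test_that("turning multicropping off favours the larger-harvested-area crop", {
  # year-varying cropping intensity: the big crop (maize-like) gains when
  # harvested areas are not deflated by CI
  lu <- list(R1 = list(cropland = c(`2007` = 1000, `2010` = 1100)))
  hv <- list(R1 = list(maize = c(`2007` = 1500, `2010` = 1700),
                       beans = c(`2007` = 300, `2010` = 350)))
  st <- make_stats(lu, hv)
  on  <- allocate_commodities(100, st, "R1", 2010, lag = 3,
                              multicropping = TRUE)
  off <- allocate_commodities(100, st, "R1", 2010, lag = 3,
                              multicropping = FALSE)
  m_on <- on$area_ha[on$commodity == "maize"]
  m_off <- off$area_ha[off$commodity == "maize"]
  expect_gt(m_off, m_on)
})

test_that("statistical attribution conserves the pools exactly", {
  for (seed in c(3, 19)) {
    L <- generate_landscape(landscape_params(seed = seed))
    D <- degrade_to_statistical(L)
    attr <- attribute_pixels(D$stack, D$registry, NULL, D$grid)
    summ <- summarize_attribution(attr, D$stack$region, D$grid)
    st <- attribute_statistical(summ, D$stats)
    expect_equal(sum(st$allocations$area_ha) + sum(st$dluc$area_ha),
                 sum(summ$totals$deforestation_ha), tolerance = 1e-9)
    # per region-year too
    per_ry <- dplyr::summarise(
      dplyr::group_by(st$allocations, region, year),
      a = sum(area_ha), .groups = "drop")
    ref <- dplyr::summarise(
      dplyr::group_by(dplyr::filter(summ$classes, level != "commodity"),
                      region, year),
      a = sum(area_ha), .groups = "drop")
    cmp <- dplyr::full_join(per_ry, ref, by = c("region", "year"))
    expect_true(all(abs(cmp$a.x - cmp$a.y) < 1e-9))
  }
})
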