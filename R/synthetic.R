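#' Parameters for the synthetic landscape generator
#'
#' The generator emulates the inputs of the attribution pipeline on a small
#' planar grid: a year-2000 tree-cover-density layer with natural forest,
#' sparse woody cover and managed plantations; clustered conversion events
#' (random rectangles, mimicking frontier clearing geometry) with a loss
#' year drawn uniformly over the study window; commodity, land-use, mosaic
#' and dominant-driver maps consistent with the embedded ground truth up to
#' the configured coverage and label noise; a fire layer of non-commodity
#' burn events; peat and biome layers; carbon-stock layers; and an exactly
#' consistent agricultural-statistics table whose land-use and harvested
#' areas increase by the true converted areas each year.
#'
#' @param grid A [grid_spec()].
#' @param regions Number of regions (vertical strips; biomes cycle
#'   tropical/temperate/boreal across regions).
#' @param commodity_mix Named vector of target deforestation shares summing
#'   to 1. Names must resolve through the configuration's commodity groups;
#'   `cattle_meat_leather` denotes pasture and `forestry_products` denotes
#'   forest plantation conversion.
#' @param spatial_coverage Fraction of converted crop pixels carried by the
#'   commodity map.
#' @param mosaic_fraction Fraction of converted crop/pasture pixels labelled
#'   only as a cropland-pasture mosaic.
#' @param fire_fraction,rotation_fraction,sparse_fraction Fractions of loss
#'   clusters that are non-commodity fire, rotational clearing on managed
#'   plantations, and loss of sparse (sub-threshold) woody cover.
#' @param peat_fraction Fraction of the landscape on peat.
#' @param noise Probability that a commodity-map label is swapped to another
#'   crop (labels swap among commodities only, never forest/non-forest, so
#'   area conservation always holds).
#' @param n_events Number of loss clusters.
#' @param cluster_max Maximum rectangle side length, pixels.
#' @param delay_probs Probabilities of a 0,1,2,... year lag between forest
#'   loss and the first commodity-map observation (tree crops are typically
#'   mapped only some years after clearing).
#' @param forest_cover,plantation_cover,sparse_cover Landscape composition
#'   fractions; the remainder is open land.
#' @param seed Random seed; identical seeds give identical landscapes.
#' @return An object of class `landscape_params`.
#' @export
landscape_params <- function(grid = grid_spec(64, 64),
                             regions = 2L,
                             commodity_mix = c(soy = 0.25, maize = 0.15,
                                               rice = 0.10, oil_palm = 0.20,
                                               cattle_meat_leather = 0.20,
                                               forestry_products = 0.10),
                             spatial_coverage = 0.8,
                             mosaic_fraction = 0.10,
                             fire_fraction = 0.10,
                             rotation_fraction = 0.10,
                             sparse_fraction = 0.10,
                             peat_fraction = 0.15,
                             noise = 0.05,
                             n_events = 60L,
                             cluster_max = 4L,
                             delay_probs = c(0.45, 0.2, 0.15, 0.1, 0.05, 0.05),
                             forest_cover = 0.6,
                             plantation_cover = 0.12,
                             sparse_cover = 0.12,
                             seed = 1L) {
  fr <- c(spatial_coverage, mosaic_fraction, fire_fraction, rotation_fraction,
          sparse_fraction, peat_fraction, noise, forest_cover,
          plantation_cover, sparse_cover)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
  if (abs(sum(commodity_mix) - 1) > 1e-9)
    stop("commodity shares must sum to 1")
  if (fire_fraction + rotation_fraction + sparse_fraction >= 1)
    stop("non-commodity cluster fractions must sum to < 1")
  structure(list(grid = grid, regions = as.integer(regions),
                 commodity_mix = commodity_mix,
                 spatial_coverage = spatial_coverage,
                 mosaic_fraction = mosaic_fraction,
                 fire_fraction = fire_fraction,
                 rotation_fraction = rotation_fraction,
                 sparse_fraction = sparse_fraction,
                 peat_fraction = peat_fraction, noise = noise,
                 n_events = as.integer(n_events),
                 cluster_max = as.integer(cluster_max),
                 delay_probs = delay_probs,
                 forest_cover = forest_cover,
                 plantation_cover = plantation_cover,
                 sparse_cover = sparse_cover,
                 seed = as.integer(seed)),
            class = "landscape_params")
}

BIOMES <- c("tropical", "temperate", "boreal")
AGB_RANGE <- list(tropical = c(100, 400), temperate = c(50, 250),
                  boreal = c(30, 150))
SOC_RANGE <- list(tropical = c(60, 180), temperate = c(40, 140),
                  boreal = c(50, 200))

#' Generate a synthetic landscape with embedded ground truth
#'
#' Produces the aligned layer stack, dataset registry, agricultural
#' statistics and a ground-truth table recording, per (region, commodity,
#' year), the true converted area, gross and net committed emissions
#' (computed from the generated carbon layers with the supplied carbon
#' parameters) and peat area. With `noise = 0` and full coverage, every
#' converted pixel carries its true label and the pipeline recovers the
#' ground truth exactly.
#'
#' @param params A [landscape_params()].
#' @param config A configuration bundle (defaults to [default_config()]);
#'   supplies carbon parameters for the recorded true emissions and the
#'   commodity-group mapping.
#' @return A list of class `cf_landscape` with elements `grid`, `stack`
#'   (named list of [fp_layer()]s), `registry`, `stats` ([ag_stats()]),
#'   `truth` (tibble) and `params`.
#' @export
generate_landscape <- function(params = landscape_params(), config = NULL) {
  config <- as_config(config)
  g <- params$grid
  set.seed(params$seed)
  nr <- g$n_rows; nc <- g$n_cols; n <- nr * nc
  years <- g$year_start:g$year_end

  region <- matrix(rep(pmin(params$regions,
                            ceiling(seq_len(nc) / (nc / params$regions))),
                       each = nr), nr, nc)
  biome_of_region <- ((seq_len(params$regions) - 1L) %% 3L) + 1L
  biome <- matrix(biome_of_region[region], nr, nc)

  # landscape composition: 1 open, 2 sparse, 3 natural forest, 4 plantation
  zone <- matrix(sample(1:4, n, replace = TRUE,
                        prob = c(1 - params$forest_cover -
                                   params$plantation_cover - params$sparse_cover,
                                 params$sparse_cover, params$forest_cover,
                                 params$plantation_cover)), nr, nc)
  tcd <- matrix(stats::runif(n, 0, 20), nr, nc)
  tcd[zone == 2] <- stats::runif(sum(zone == 2), 5, 24)
  tcd[zone == 3] <- stats::runif(sum(zone == 3), 30, 95)
  tcd[zone == 4] <- stats::runif(sum(zone == 4), 40, 95)
  plantation_mask <- (zone == 4) * 1

  peat <- matrix(stats::rbinom(n, 1, params$peat_fraction), nr, nc)

  agb <- matrix(0, nr, nc); soc <- matrix(0, nr, nc)
  for (b in 1:3) {
    idx <- biome == b
    agb[idx] <- stats::runif(sum(idx), AGB_RANGE[[b]][1], AGB_RANGE[[b]][2])
    soc[idx] <- stats::runif(sum(idx), SOC_RANGE[[b]][1], SOC_RANGE[[b]][2])
  }
  agb[tcd < 25] <- agb[tcd < 25] * 0.3   # sparse/open land carries little biomass
  rs_ratio <- matrix(stats::runif(n, 0.18, 0.30), nr, nc)

  loss_year <- matrix(0, nr, nc)
  fire_year <- matrix(0, nr, nc)
  truth_commodity <- matrix(NA_character_, nr, nc)
  delay <- matrix(0L, nr, nc)
  driver <- matrix(0, nr, nc)

  commodities <- names(params$commodity_mix)
  lu_group <- commodity_landuse(commodities, config)
  names(lu_group) <- commodities
  type_probs <- c(commodity = 1 - params$fire_fraction -
                    params$rotation_fraction - params$sparse_fraction,
                  fire = params$fire_fraction,
                  rotation = params$rotation_fraction,
                  sparse = params$sparse_fraction)
  n_delay <- length(params$delay_probs)

  for (ev in seq_len(params$n_events)) {
    type <- sample(names(type_probs), 1, prob = type_probs)
    w <- sample(seq_len(params$cluster_max), 1)
    h <- sample(seq_len(params$cluster_max), 1)
    r0 <- sample(seq_len(nr - h + 1L), 1)
    c0 <- sample(seq_len(nc - w + 1L), 1)
    rows <- r0:(r0 + h - 1L); cols <- c0:(c0 + w - 1L)
    target_zone <- switch(type, commodity = 3, fire = 3, rotation = 4, sparse = 2)
    sel <- which(zone[rows, cols, drop = FALSE] == target_zone &
                   loss_year[rows, cols, drop = FALSE] == 0)
    if (!length(sel)) next
    idx <- as.matrix(expand.grid(rows, cols))[sel, , drop = FALSE]
    yr <- sample(years, 1)
    loss_year[idx] <- yr
    if (type == "fire") {
      fire_year[idx] <- yr
      driver[idx] <- 4  # other
    } else if (type == "commodity") {
      cm <- sample(commodities, 1, prob = params$commodity_mix)
      truth_commodity[idx] <- cm
      delay[idx] <- sample(seq_len(n_delay), 1, prob = params$delay_probs) - 1L
      driver[idx] <- if (lu_group[cm] == "forest_plantation") 2 else 1
    } else {
      driver[idx] <- if (type == "rotation") 2 else 4
    }
  }

  conv <- !is.na(truth_commodity)
  crops <- commodities[lu_group == "cropland"]
  is_crop_px <- conv & truth_commodity %in% crops
  is_pasture_px <- conv & truth_commodity %in%
    commodities[lu_group == "pasture"]

  # mosaic: a fraction of crop/pasture pixels labelled only as mosaic
  mosaic_px <- (is_crop_px | is_pasture_px) &
    matrix(stats::runif(n) < params$mosaic_fraction, nr, nc)

  # land-use map (annual, observed at the loss year) on non-mosaic pixels
  lu_code <- c(cropland = 1, pasture = 2, forest_plantation = 3)
  landuse_map <- matrix(0, nr, nc)
  landuse_map[conv & !mosaic_px] <-
    lu_code[lu_group[truth_commodity[conv & !mosaic_px]]]
  landuse_obs <- matrix(0, nr, nc)
  landuse_obs[landuse_map > 0] <- loss_year[landuse_map > 0]

  mosaic_map <- mosaic_px * 1

  # commodity map: crop pixels only, subject to coverage, noise and delay
  crop_code <- stats::setNames(seq_along(crops), crops)
  commodity_map <- matrix(0, nr, nc)
  commodity_obs <- matrix(0, nr, nc)
  cand <- which(is_crop_px & !mosaic_px &
                  matrix(stats::runif(n) < params$spatial_coverage, nr, nc))
  if (length(cand)) {
    lab <- truth_commodity[cand]
    if (params$noise > 0 && length(crops) > 1) {
      flip <- stats::runif(length(cand)) < params$noise
      lab[flip] <- vapply(lab[flip], function(x)
        sample(setdiff(crops, x), 1), character(1))
    }
    commodity_map[cand] <- crop_code[lab]
    obs <- loss_year[cand] + delay[cand]
    obs[obs > g$year_end] <- 0  # established after the record ends
    commodity_obs[cand] <- obs
  }

  mk <- function(name, kind, m) fp_layer(name, kind, m, grid = g)
  stack <- list(
    tcd = mk("tcd", "continuous", tcd),
    loss_year = mk("loss_year", "year", loss_year),
    plantation_mask = mk("plantation_mask", "mask", plantation_mask),
    fire_year = mk("fire_year", "year", fire_year),
    peat_mask = mk("peat_mask", "mask", peat),
    biome = mk("biome", "categorical", biome),
    region = mk("region", "categorical", region),
    agb = mk("agb", "continuous", agb),
    rs_ratio = mk("rs_ratio", "continuous", rs_ratio),
    soc = mk("soc", "continuous", soc),
    commodity_map = mk("commodity_map", "categorical", commodity_map),
    commodity_obs = mk("commodity_obs", "year", commodity_obs),
    landuse_map = mk("landuse_map", "categorical", landuse_map),
    landuse_obs = mk("landuse_obs", "year", landuse_obs),
    mosaic_map = mk("mosaic_map", "categorical", mosaic_map),
    driver_map = mk("driver_map", "categorical", driver)
  )

  registry <- list(
    dataset_descriptor("commodity_map", "commodity",
                       stats::setNames(crops, as.character(crop_code)),
                       overall_accuracy = max(1 - params$noise, 0.5),
                       spatial_score = 1, temporal_score = 1,
                       explicitness_score = 1,
                       last_valid_year = g$year_end, annual = TRUE,
                       layer = "commodity_map",
                       obs_year_layer = "commodity_obs"),
    dataset_descriptor("landuse_map", "land_use",
                       c(`1` = "cropland", `2` = "pasture",
                         `3` = "forest_plantation"),
                       overall_accuracy = 0.85, spatial_score = 1,
                       temporal_score = 0.75, explicitness_score = 0.25,
                       last_valid_year = g$year_end, annual = TRUE,
                       layer = "landuse_map", obs_year_layer = "landuse_obs"),
    dataset_descriptor("mosaic_map", "mosaic",
                       c(`1` = "cropland_pasture_mosaic"),
                       overall_accuracy = 0.8, spatial_score = 1,
                       temporal_score = 0.5, explicitness_score = 0.25,
                       last_valid_year = g$year_end, annual = FALSE,
                       layer = "mosaic_map"),
    dataset_descriptor("driver_map", "driver",
                       c(`1` = "commodity_driven", `2` = "forestry",
                         `3` = "shifting_agriculture", `4` = "other"),
                       overall_accuracy = 0.75, spatial_score = 0.5,
                       temporal_score = 0.25, explicitness_score = 0.25,
                       last_valid_year = g$year_end, annual = FALSE,
                       layer = "driver_map"),
    dataset_descriptor("fire", "fire", c(`1` = "fire_non_commodity"),
                       overall_accuracy = 0.9, spatial_score = 1,
                       temporal_score = 1, explicitness_score = 1,
                       last_valid_year = g$year_end, annual = FALSE,
                       layer = "fire_year")
  )

  truth <- build_truth(g, region, biome, peat, agb, rs_ratio, soc,
                       loss_year, truth_commodity, config)
  stats_tbl <- build_stats(g, params, truth, config)

  structure(list(grid = g, stack = stack, registry = registry,
                 stats = stats_tbl, truth = truth, params = params),
            class = "cf_landscape")
}

# True per-pixel committed emissions, aggregated by region x commodity x year.
build_truth <- function(g, region, biome, peat, agb, rs_ratio, soc,
                        loss_year, truth_commodity, config) {
  idx <- which(!is.na(truth_commodity))
  if (!length(idx)) {
    return(tibble::tibble(region = character(), commodity = character(),
                          year = integer(), area_ha = numeric(),
                          gross_MgCO2 = numeric(), net_MgCO2 = numeric(),
                          peat_area_ha = numeric()))
  }
  cp <- config$carbon
  cm <- truth_commodity[idx]
  bio <- BIOMES[biome[idx]]
  lu <- commodity_landuse(cm, config)
  on_peat <- peat[idx] == 1
  biomass <- agb[idx] * (1 + rs_ratio[idx] + cp$deadwood_frac[bio] +
                           cp$litter_frac[bio])
  veg_c <- biomass * cp$biomass_to_carbon
  soc_frac <- mapply(function(l, b) cp$soc_loss_frac[[l]][[b]], lu, bio)
  soc_c <- ifelse(on_peat, 0, soc_frac * soc[idx])
  a <- g$pixel_area_ha
  gross <- (veg_c + soc_c) * a * cp$c_to_co2
  net <- gross - plant_stock_for(cm, config) * cp$plant_stock_scale * a *
    cp$c_to_co2
  df <- tibble::tibble(region = paste0("R", region[idx]), commodity = cm,
                       year = as.integer(loss_year[idx]),
                       area_ha = a, gross_MgCO2 = gross, net_MgCO2 = net,
                       peat_area_ha = ifelse(on_peat, a, 0))
  dplyr::summarise(dplyr::group_by(df, .data$region, .data$commodity,
                                   .data$year),
                   dplyr::across(c("area_ha", "gross_MgCO2", "net_MgCO2",
                                   "peat_area_ha"), sum),
                   .groups = "drop")
}

# Exactly consistent statistics: base areas plus cumulative true conversions.
build_stats <- function(g, params, truth, config) {
  years <- (g$year_start - 5L):g$year_end
  regions <- paste0("R", seq_len(params$regions))
  commodities <- names(params$commodity_mix)
  lu_group <- commodity_landuse(commodities, config)
  names(lu_group) <- commodities
  base_lu <- c(cropland = 500, pasture = 800, forest_plantation = 300)

  conv <- tidyr::complete(truth, region = regions, commodity = commodities,
                          year = years, fill = list(area_ha = 0))
  conv$land_use <- unname(lu_group[conv$commodity])
  lu <- dplyr::summarise(
    dplyr::group_by(conv, .data$region, .data$land_use, .data$year),
    inc = sum(.data$area_ha), .groups = "drop")
  lu <- dplyr::arrange(lu, .data$region, .data$land_use, .data$year)
  lu <- dplyr::mutate(dplyr::group_by(lu, .data$region, .data$land_use),
                      area_ha = unname(base_lu[.data$land_use[1]]) +
                        cumsum(.data$inc))
  lu <- dplyr::ungroup(lu)
  land_use <- dplyr::ungroup(dplyr::transmute(
    lu, region = .data$region, year = .data$year, land_use = .data$land_use,
    area_ha = .data$area_ha, flag = "official"))

  crops <- commodities[lu_group == "cropland"]
  hv <- dplyr::filter(conv, .data$commodity %in% crops)
  hv <- dplyr::arrange(hv, .data$region, .data$commodity, .data$year)
  hv <- dplyr::mutate(dplyr::group_by(hv, .data$region, .data$commodity),
                      area_ha = 20 + cumsum(.data$area_ha))
  hv <- dplyr::ungroup(hv)
  harvested <- dplyr::ungroup(dplyr::transmute(
    hv, region = .data$region, year = .data$year, crop = .data$commodity,
    area_ha = .data$area_ha, flag = "official"))
  ag_stats(land_use, harvested)
}

#' Degrade a landscape to the statistical-attribution regime
#'
#' Removes commodity-level datasets (and their layers) from a generated
#' landscape, or truncates their validity, so downstream attribution must
#' fall back on land-use, mosaic and driver layers plus statistics.
#'
#' @param landscape A `cf_landscape` from [generate_landscape()].
#' @param last_valid_year If `NULL` (default), commodity-level datasets are
#'   removed entirely; otherwise their `last_valid_year` is truncated to
#'   this year.
#' @param drop_landuse Also remove land-use and mosaic datasets, leaving
#'   only the driver layer (the fully statistical regime).
#' @return The modified `cf_landscape`.
#' @export
degrade_to_statistical <- function(landscape, last_valid_year = NULL,
                                   drop_landuse = FALSE) {
  lvls <- "commodity"
  if (drop_landuse) lvls <- c(lvls, "land_use", "mosaic")
  keep <- logical(length(landscape$registry))
  for (i in seq_along(landscape$registry)) {
    d <- landscape$registry[[i]]
    if (d$level %in% lvls) {
      if (!is.null(last_valid_year) && d$level == "commodity") {
        d$last_valid_year <- as.integer(last_valid_year)
        landscape$registry[[i]] <- d
        keep[i] <- TRUE
      } else {
        landscape$stack[[d$layer]] <- NULL
        if (!is.null(d$obs_year_layer))
          landscape$stack[[d$obs_year_layer]] <- NULL
      }
    } else keep[i] <- TRUE
  }
  landscape$registry <- landscape$registry[keep]
  landscape
}
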