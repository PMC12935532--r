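#' Default pipeline configuration
#'
#' Returns the full configuration bundle with the published parameter
#' defaults: a tree-cover-density threshold of 25%, three-year spatial and
#' statistical attribution lags, a five-year amortization window, the IPCC
#' biomass-to-carbon ratio of 0.47, soil organic carbon taken over the top
#' 100 cm, and a tropical oil-palm peat drainage factor of 54.41
#' MgCO2/ha/yr. Look-up blocks (deadwood/litter proportions, SOC loss
#' fractions, plant carbon stocks, peat emission factors, quality-flag
#' scores) are ordinary list entries and can be overridden wholesale or per
#' key via a YAML file (see [read_config()]).
#'
#' @return A nested list of class `cf_config`.
#' @export
default_config <- function() {
  cfg <- list(
    tcd_threshold         = 25,
    spatial_lag_years     = 3L,
    statistical_lag_years = 3L,
    amortize_years        = 5L,
    fire_window_years     = 0L,   # fire year must match loss year exactly
    attribution_mode      = "full",  # full | partial_statistical | full_statistical
    cropland_first        = TRUE,
    expansion_mode        = "gross", # gross | net
    restrict_by_stats     = TRUE,
    multicropping         = TRUE,
    carbon = list(
      biomass_to_carbon = 0.47,
      c_to_co2          = 44 / 12,
      soc_depth_cm      = 100,
      # proportions of AGB, by biome
      deadwood_frac = c(tropical = 0.07, temperate = 0.10, boreal = 0.12),
      litter_frac   = c(tropical = 0.03, temperate = 0.05, boreal = 0.08),
      # fraction of 0-100 cm SOC lost, by replacing land-use group x biome
      soc_loss_frac = list(
        cropland          = c(tropical = 0.25, temperate = 0.30, boreal = 0.30),
        pasture           = c(tropical = 0.12, temperate = 0.10, boreal = 0.10),
        forest_plantation = c(tropical = 0.10, temperate = 0.08, boreal = 0.08)
      ),
      # mature plant carbon stocks, MgC/ha
      plant_stock = c(
        soy = 2, maize = 2.5, rice = 2, cassava = 3, wheat = 2,
        oil_palm = 40, cocoa = 35, coffee = 25, rubber = 45,
        cattle_meat_leather = 3, forestry_products = 60
      ),
      plant_stock_group = c(
        annual_crops = 2.5, tree_crops = 35,
        pasture = 3, forest_plantation = 60
      ),
      plant_stock_scale = 1.0
    ),
    # commodity -> group; also drives the replacing land use for SOC and peat
    commodity_groups = c(
      soy = "annual_crops", maize = "annual_crops", rice = "annual_crops",
      cassava = "annual_crops", wheat = "annual_crops",
      oil_palm = "tree_crops", cocoa = "tree_crops", coffee = "tree_crops",
      rubber = "tree_crops",
      cattle_meat_leather = "pasture", forestry_products = "forest_plantation"
    ),
    peat = list(
      horizon = "until_end",   # until_end | none | 5 | 10 | 15
      split   = "even",        # even | proportional
      # MgCO2/ha/yr drainage factors, land-use group x biome
      emission_factors = list(
        cropland          = c(tropical = 35, temperate = 29, boreal = 29),
        pasture           = c(tropical = 25, temperate = 18, boreal = 13),
        forest_plantation = c(tropical = 30, temperate = 10, boreal = 3),
        oil_palm          = c(tropical = 54.41, temperate = 35, boreal = 29)
      )
    ),
    quality = list(
      flag_scores = c(official = 1.0, semi_official = 0.75, estimated = 0.5,
                      imputed = 0.25, unofficial = 0.25),
      band_commodity = 0.60,   # IQI >= 0.60        -> dLUC_commodity
      band_landuse   = 0.55,   # 0.55 <= IQI < 0.60 -> dLUC_landuse; else sLUC
      # accuracy/rubric used for statistics-only contributions (the loss
      # layer itself carries no driver information: explicitness 0)
      fallback_oa     = 0.85,
      fallback_scores = c(spatial = 1, temporal = 1, explicitness = 0)
    )
  )
  class(cfg) <- "cf_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(cfg$tcd_threshold >= 0, cfg$tcd_threshold <= 100,
            cfg$spatial_lag_years >= 0, cfg$statistical_lag_years >= 0,
            cfg$amortize_years >= 1)
  if (!cfg$attribution_mode %in% c("full", "partial_statistical", "full_statistical"))
    stop("unknown attribution_mode: ", cfg$attribution_mode)
  if (!cfg$expansion_mode %in% c("gross", "net"))
    stop("unknown expansion_mode: ", cfg$expansion_mode)
  fr <- unlist(cfg$carbon[c("deadwood_frac", "litter_frac")])
  fr <- c(fr, unlist(cfg$carbon$soc_loss_frac))
  if (any(fr < 0 | fr > 1)) stop("carbon fractions must lie in [0, 1]")
  if (any(unlist(cfg$carbon$plant_stock) < 0)) stop("plant stocks must be >= 0")
  if (any(unlist(cfg$peat$emission_factors) < 0))
    stop("peat emission factors must be >= 0")
  fs <- cfg$quality$flag_scores
  if (any(fs <= 0 | fs > 1) || max(fs) != fs[["official"]])
    stop("flag scores must lie in (0, 1] with 'official' the maximum")
  cfg
}

# Recursively overlay y onto x (named lists / atomic leaves).
modify_config <- function(x, y) {
  for (nm in names(y)) {
    if (is.list(x[[nm]]) && is.list(y[[nm]])) {
      x[[nm]] <- modify_config(x[[nm]], y[[nm]])
    } else if (is.numeric(x[[nm]]) && !is.null(names(x[[nm]])) && is.list(y[[nm]])) {
      v <- x[[nm]]; v[names(y[[nm]])] <- unlist(y[[nm]]); x[[nm]] <- v
    } else {
      x[[nm]] <- y[[nm]]
    }
  }
  x
}

#' Read a configuration file
#'
#' Reads a YAML key/value file and overlays it onto [default_config()], so a
#' file needs to state only the parameters it changes. Nested blocks (for
#' example `carbon: plant_stock_scale: 0.75`) are merged recursively.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `cf_config` list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- modify_config(default_config(), user)
  class(cfg) <- "cf_config"
  validate_config(cfg)
}

as_config <- function(config) {
  if (is.null(config)) return(default_config())
  validate_config(config)
}

# land-use group of a commodity: cropland unless pasture/plantation
commodity_landuse <- function(commodity, config) {
  grp <- unname(config$commodity_groups[commodity])
  out <- rep("cropland", length(commodity))
  out[!is.na(grp) & grp == "pasture"] <- "pasture"
  out[!is.na(grp) & grp == "forest_plantation"] <- "forest_plantation"
  out
}

# plant carbon stock, MgC/ha, with group fallback
plant_stock_for <- function(commodity, config) {
  cp <- config$carbon
  out <- vapply(commodity, function(cm) {
    if (!is.na(cp$plant_stock[cm])) return(unname(cp$plant_stock[cm]))
    grp <- config$commodity_groups[cm]
    if (!is.na(grp) && !is.na(cp$plant_stock_group[grp]))
      return(unname(cp$plant_stock_group[grp]))
    stop("no plant carbon stock for commodity '", cm,
         "' and no commodity group entry resolves it")
  }, numeric(1))
  unname(out)
}
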