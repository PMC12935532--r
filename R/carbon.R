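soc_fraction <- function(landuse, biome, cp) {
  mapply(function(l, b) {
    if (!b %in% BIOMES) stop("unknown biome: ", b)
    if (l == "mixed")
      return(mean(vapply(cp$soc_loss_frac, `[[`, numeric(1), b)))
    cp$soc_loss_frac[[l]][[b]]
  }, landuse, biome)
}

#' Committed carbon components of a deforested pixel
#'
#' Computes, per hectare, the five committed carbon-stock losses: AGB,
#' BGB (AGB times the root-to-shoot ratio), deadwood and litter (biome
#' proportions of AGB), each converted to carbon with the biomass-to-carbon
#' ratio, plus the SOC loss as a land-use- and biome-specific fraction of
#' the 0-100 cm SOC stock. Pixels on peat contribute no SOC component here:
#' their soil emissions are accounted by the peat-drainage module, avoiding
#' double counting.
#'
#' @param agb Above-ground biomass density, Mg/ha.
#' @param rs_ratio Root-to-shoot ratio.
#' @param biome Biome name (`"tropical"`, `"temperate"`, `"boreal"`).
#' @param soc 0-100 cm soil organic carbon stock, MgC/ha.
#' @param on_peat Logical; pixel overlaps the peatland map.
#' @param landuse Replacing land-use group (`"cropland"`, `"pasture"`,
#'   `"forest_plantation"`, or `"mixed"` for unresolved pools, which use the
#'   mean fraction).
#' @param config Configuration bundle (carbon block).
#' @return Tibble of per-hectare components in MgC/ha: `agb_c`, `bgb_c`,
#'   `deadwood_c`, `litter_c`, `soc_c`.
#' @export
pixel_gross_carbon <- function(agb, rs_ratio, biome, soc, on_peat,
                               landuse = "cropland", config = NULL) {
  config <- as_config(config)
  cp <- config$carbon
  if (!all(biome %in% BIOMES))
    stop("unknown biome: ", paste(setdiff(biome, BIOMES), collapse = ", "))
  stopifnot(all(agb >= 0), all(soc >= 0), all(rs_ratio >= 0))
  r <- cp$biomass_to_carbon
  tibble::tibble(
    agb_c = agb * r,
    bgb_c = agb * rs_ratio * r,
    deadwood_c = agb * unname(cp$deadwood_frac[biome]) * r,
    litter_c = agb * unname(cp$litter_frac[biome]) * r,
    soc_c = ifelse(on_peat, 0, unname(soc_fraction(landuse, biome, cp)) * soc)
  )
}

#' Net committed emissions for an attributed area
#'
#' Converts per-hectare gross carbon components to CO2 over an area and
#' deducts the committed sequestration of the replacing commodity: net =
#' gross - plant stock x `plant_stock_scale` x area x 44/12. Plant stocks
#' resolve per commodity, falling back to the commodity group; negative net
#' emissions are allowed and reported.
#'
#' @param gross Per-hectare component tibble from [pixel_gross_carbon()]
#'   (one row), or a named vector of MgC/ha components.
#' @param commodity Replacing commodity label.
#' @param area_ha Attributed area, ha.
#' @param config Configuration bundle.
#' @return One-row tibble: commodity, area_ha, component columns in MgCO2,
#'   `gross_MgCO2`, `net_MgCO2`.
#' @export
net_emissions <- function(gross, commodity, area_ha, config = NULL) {
  config <- as_config(config)
  cp <- config$carbon
  comp_c <- unlist(gross)
  gross_co2 <- sum(comp_c) * area_ha * cp$c_to_co2
  stock <- plant_stock_for(commodity, config)
  net_co2 <- gross_co2 - stock * cp$plant_stock_scale * area_ha * cp$c_to_co2
  out <- tibble::as_tibble(as.list(comp_c * area_ha * cp$c_to_co2))
  names(out) <- sub("_c$", "_MgCO2", names(out))
  dplyr::bind_cols(tibble::tibble(commodity = commodity, area_ha = area_ha),
                   out,
                   tibble::tibble(gross_MgCO2 = gross_co2,
                                  net_MgCO2 = net_co2))
}

#' Apportion a pool's emissions to its allocated commodities
#'
#' Statistically attributed commodities bear the pool's emissions in
#' proportion to their share of the pool's forest-loss area; the pool total
#' is conserved exactly.
#'
#' @param pool_emissions Pool emission total (MgCO2; may be a vector of
#'   component totals).
#' @param allocations Named numeric vector of areas by commodity (ha).
#' @return Numeric matrix (commodity x component) or named vector of MgCO2.
#' @export
apportion_statistical_emissions <- function(pool_emissions, allocations) {
  tot <- sum(allocations)
  if (tot <= 0) {
    if (any(pool_emissions != 0))
      stop("zero pool area with nonzero emission")
    return(outer(allocations, pool_emissions, function(a, e) 0))
  }
  outer(allocations / tot, pool_emissions)
}

# Per-pixel gross CO2 for every deforestation pixel, aggregated per
# attribution class row (dLUC) or statistical pool.
aggregate_gross_emissions <- function(attribution, stack, grid, config) {
  key <- attribution$key
  idx <- which(!is.na(attribution$code))
  empty <- tibble::tibble(region = character(), year = integer(),
                          label = character(), level = character(),
                          source_id = character(), pool = character(),
                          area_ha = numeric(), agb_MgCO2 = numeric(),
                          bgb_MgCO2 = numeric(), deadwood_MgCO2 = numeric(),
                          litter_MgCO2 = numeric(), soc_MgCO2 = numeric(),
                          gross_MgCO2 = numeric())
  if (!length(idx)) return(empty)
  codes <- attribution$code[idx]
  lv <- key$level[codes]
  keep <- !lv %in% c("fire", "excluded")
  idx <- idx[keep]; codes <- codes[keep]
  if (!length(idx)) return(empty)

  label <- key$label[codes]; level <- key$level[codes]
  pool <- class_pool(label, level)
  landuse <- ifelse(level == "commodity", commodity_landuse(label, config),
             ifelse(pool == "cropland_only", "cropland",
             ifelse(pool == "pasture_only", "pasture",
             ifelse(pool == "plantation_only", "forest_plantation", "mixed"))))
  biome <- BIOMES[stack_layer(stack, "biome")[idx]]
  peat <- stack_layer(stack, "peat_mask")[idx] == 1
  comp <- pixel_gross_carbon(stack_layer(stack, "agb")[idx],
                             stack_layer(stack, "rs_ratio")[idx],
                             biome, stack_layer(stack, "soc")[idx],
                             peat, landuse, config)
  a <- grid$pixel_area_ha
  co2 <- config$carbon$c_to_co2
  df <- dplyr::bind_cols(tibble::tibble(
    region = paste0("R", stack_layer(stack, "region")[idx]),
    year = as.integer(attribution$loss_year[idx]),
    label = label, level = level,
    source_id = key$source_id[codes], pool = pool), comp * a * co2)
  names(df) <- sub("_c$", "_MgCO2", names(df))
  df$area_ha <- a
  df$gross_MgCO2 <- df$agb_MgCO2 + df$bgb_MgCO2 + df$deadwood_MgCO2 +
    df$litter_MgCO2 + df$soc_MgCO2
  dplyr::summarise(
    dplyr::group_by(df, .data$region, .data$year, .data$label, .data$level,
                    .data$source_id, .data$pool),
    dplyr::across(c("area_ha", "agb_MgCO2", "bgb_MgCO2", "deadwood_MgCO2",
                    "litter_MgCO2", "soc_MgCO2", "gross_MgCO2"), sum),
    .groups = "drop")
}

COMPONENT_COLS <- c("agb_MgCO2", "bgb_MgCO2", "deadwood_MgCO2",
                    "litter_MgCO2", "soc_MgCO2", "gross_MgCO2")

#' Committed-emission records for an attributed landscape
#'
#' Computes gross committed emissions for every deforestation pixel,
#' aggregates them per spatially attributed commodity (direct) or
#' statistical pool (apportioned to commodities in proportion to allocated
#' area), and deducts replacing-commodity plant stocks to obtain net
#' emissions. Residual classes (`without_production`, `unallocated`,
#' `other`) carry their apportioned gross emissions with no deduction, so
#' CO2 is conserved.
#'
#' @param attribution A `pixel_attribution`.
#' @param statistical A `statistical_attribution`.
#' @param stack The layer stack.
#' @param config Configuration bundle.
#' @param grid A [grid_spec()].
#' @return Tibble: region, year, commodity, attribution (dLUC/sLUC/residual),
#'   area_ha, component columns, gross_MgCO2, net_MgCO2.
#' @export
compute_emissions <- function(attribution, statistical, stack, config = NULL,
                              grid = NULL) {
  config <- as_config(config)
  gr <- aggregate_gross_emissions(attribution, stack, grid, config)
  cp <- config$carbon

  dluc <- dplyr::filter(gr, .data$level == "commodity")
  if (nrow(dluc)) {
    dluc <- dplyr::mutate(
      dluc,
      commodity = .data$label, attribution = "dLUC",
      net_MgCO2 = .data$gross_MgCO2 -
        plant_stock_for(.data$commodity, config) * cp$plant_stock_scale *
        .data$area_ha * cp$c_to_co2)
    dluc <- dplyr::select(dluc, "region", "year", "commodity", "attribution",
                          "area_ha", dplyr::all_of(COMPONENT_COLS),
                          "net_MgCO2")
  } else dluc <- NULL

  pools <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(gr, .data$level != "commodity"),
                    .data$region, .data$year, .data$pool),
    dplyr::across(c("area_ha", dplyr::all_of(COMPONENT_COLS)), sum),
    .groups = "drop")
  sl_rows <- list()
  alloc <- statistical$allocations
  for (i in seq_len(nrow(pools))) {
    pr <- pools[i, ]
    al <- alloc[alloc$region == pr$region & alloc$year == pr$year &
                  alloc$pool == pr$pool, ]
    if (!nrow(al)) {
      if (pr$gross_MgCO2 != 0 || pr$area_ha != 0)
        stop("pool ", pr$pool, " in ", pr$region, "/", pr$year,
             " has pixels but no allocation")
      next
    }
    em <- apportion_statistical_emissions(
      unlist(pr[COMPONENT_COLS]),
      stats::setNames(al$area_ha, al$commodity))
    em <- tibble::as_tibble(em)
    is_res <- al$commodity %in% RESIDUAL_CLASSES
    stock <- numeric(nrow(al))
    if (any(!is_res))
      stock[!is_res] <- plant_stock_for(al$commodity[!is_res], config)
    net <- em$gross_MgCO2 -
      stock * cp$plant_stock_scale * al$area_ha * cp$c_to_co2
    sl_rows[[length(sl_rows) + 1L]] <- dplyr::bind_cols(
      tibble::tibble(region = pr$region, year = pr$year,
                     commodity = al$commodity,
                     attribution = ifelse(is_res, "residual", "sLUC"),
                     area_ha = al$area_ha),
      em, tibble::tibble(net_MgCO2 = net))
  }
  sl <- if (length(sl_rows)) dplyr::bind_rows(sl_rows) else NULL
  out <- dplyr::bind_rows(dluc, sl)
  if (is.null(out) || !nrow(out)) {
    out <- tibble::tibble(region = character(), year = integer(),
                          commodity = character(), attribution = character(),
                          area_ha = numeric())
    for (cc in COMPONENT_COLS) out[[cc]] <- numeric()
    out$net_MgCO2 <- numeric()
  }
  dplyr::arrange(out, .data$region, .data$year, .data$commodity)
}
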