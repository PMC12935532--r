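peat_factor <- function(commodity, biome, config) {
  ef <- config$peat$emission_factors
  grp <- ifelse(commodity == "oil_palm", "oil_palm",
                commodity_landuse(commodity, config))
  mapply(function(g, b) {
    if (is.null(ef[[g]]) || is.na(ef[[g]][b]))
      stop("no peat emission factor for ", g, " / ", b)
    ef[[g]][[b]]
  }, grp, biome)
}

#' Overlay the peat mask onto attributed deforestation
#'
#' Intersects the per-pixel attribution grid with the peatland mask, giving
#' post-2000 peat deforestation area per region, loss year, attribution
#' class and biome (drainage factors are biome-stratified). Only
#' deforestation classes are counted; degradation/rotation and non-commodity
#' fire loss are excluded.
#'
#' @param attribution A `pixel_attribution` from [attribute_pixels()].
#' @param peat_mask Peat mask [fp_layer()].
#' @param region_layer,biome_layer Categorical layers of region and biome
#'   ids.
#' @param grid A [grid_spec()].
#' @return Tibble: region, year, label, level, biome, peat_area_ha.
#' @export
peat_overlap <- function(attribution, peat_mask, region_layer, biome_layer,
                         grid) {
  key <- attribution$key
  p <- peat_mask$values
  idx <- which(!is.na(attribution$code) & !is.na(p) & p == 1)
  empty <- tibble::tibble(region = character(), year = integer(),
                          label = character(), level = character(),
                          biome = character(), peat_area_ha = numeric())
  if (!length(idx)) return(empty)
  codes <- attribution$code[idx]
  keep <- !key$level[codes] %in% c("fire", "excluded")
  idx <- idx[keep]; codes <- codes[keep]
  if (!length(idx)) return(empty)
  df <- tibble::tibble(region = paste0("R", region_layer$values[idx]),
                       year = as.integer(attribution$loss_year[idx]),
                       label = key$label[codes], level = key$level[codes],
                       biome = BIOMES[biome_layer$values[idx]])
  dplyr::summarise(dplyr::group_by(df, .data$region, .data$year, .data$label,
                                   .data$level, .data$biome),
                   peat_area_ha = dplyr::n() * grid$pixel_area_ha,
                   .groups = "drop")
}

#' Evenly allocate unresolved peat area among identified commodities
#'
#' Peat deforestation that overlaps spatial commodity data is attributed
#' directly; peat in unresolved pools is split evenly among the commodities
#' identified as expanding there (those with a positive statistical
#' allocation). An empty set reports the area under the `unallocated`
#' residual class.
#'
#' @param peat_area_ha Unresolved peat area (ha).
#' @param commodities Character vector of identified expanding commodities.
#' @return Tibble: commodity, peat_area_ha.
#' @export
allocate_peat_area <- function(peat_area_ha, commodities) {
  commodities <- setdiff(commodities, RESIDUAL_CLASSES)
  if (!length(commodities))
    return(tibble::tibble(commodity = "unallocated",
                          peat_area_ha = peat_area_ha))
  tibble::tibble(commodity = commodities,
                 peat_area_ha = peat_area_ha / length(commodities))
}

#' Accumulate annual peat drainage emissions to a horizon
#'
#' Drainage emissions accrue every year from the deforestation year
#' (inclusive: a hectare drained in 2010 is charged its annual factor every
#' year until the end year, 13 charges for 2010-2022) until the study end
#' year, or over a fixed horizon of 5/10/15 years, or not at all
#' (`"none"`). `accumulated = annual x accrual years`.
#'
#' @param records Tibble with columns `defo_year`, `peat_area_ha` and
#'   `annual_MgCO2` (plus any id columns, which pass through).
#' @param horizon `"until_end"`, `"none"`, or a number of years (5/10/15 or
#'   any positive integer).
#' @param year_end Last year of the study window.
#' @return `records` with `accrual_years` and `accumulated_MgCO2` added.
#' @export
accumulate_emissions <- function(records, horizon = "until_end", year_end) {
  n_until <- pmax(0, year_end - records$defo_year + 1)
  accr <- if (identical(horizon, "until_end")) {
    n_until
  } else if (identical(horizon, "none")) {
    rep(0, nrow(records))
  } else if (is.numeric(horizon) ||
             !is.na(suppressWarnings(as.numeric(horizon)))) {
    pmin(n_until, as.numeric(horizon))
  } else stop("unknown horizon label: ", horizon)
  records$accrual_years <- accr
  records$accumulated_MgCO2 <- records$annual_MgCO2 * accr
  records
}

#' Peat drainage records for an attributed landscape
#'
#' Combines [peat_overlap()], the statistical allocation (for unresolved
#' pools, split per [allocate_peat_area()] or proportionally to allocated
#' area when `peat$split = "proportional"`), the land-use by biome emission
#' factor table and [accumulate_emissions()] into per (region, commodity,
#' deforestation year, biome) peat records.
#'
#' @param attribution A `pixel_attribution`.
#' @param statistical A `statistical_attribution`.
#' @param stack The layer stack.
#' @param config Configuration bundle.
#' @param grid A [grid_spec()].
#' @return Tibble: region, commodity, defo_year, biome, peat_area_ha,
#'   annual_MgCO2, accrual_years, accumulated_MgCO2.
#' @export
compute_peat <- function(attribution, statistical, stack, config = NULL,
                         grid = NULL) {
  config <- as_config(config)
  ov <- peat_overlap(attribution, stack[["peat_mask"]], stack[["region"]],
                     stack[["biome"]], grid)
  empty <- tibble::tibble(region = character(), commodity = character(),
                          defo_year = integer(), biome = character(),
                          peat_area_ha = numeric(), annual_MgCO2 = numeric(),
                          accrual_years = numeric(),
                          accumulated_MgCO2 = numeric())
  if (!nrow(ov)) return(empty)
  ov$pool <- class_pool(ov$label, ov$level)
  direct <- dplyr::transmute(
    dplyr::filter(ov, .data$level == "commodity"),
    region = .data$region, commodity = .data$label,
    defo_year = .data$year, biome = .data$biome,
    peat_area_ha = .data$peat_area_ha)

  un <- dplyr::filter(ov, .data$level != "commodity", .data$pool != "other")
  alloc <- statistical$allocations
  rows <- list()
  for (i in seq_len(nrow(un))) {
    r <- un[i, ]
    al <- alloc[alloc$region == r$region & alloc$year == r$year &
                  alloc$pool == r$pool & alloc$area_ha > 0, ]
    ident <- setdiff(al$commodity, RESIDUAL_CLASSES)
    if (identical(config$peat$split, "proportional") && length(ident)) {
      w <- al$area_ha[match(ident, al$commodity)]
      sp <- tibble::tibble(commodity = ident,
                           peat_area_ha = r$peat_area_ha * w / sum(w))
    } else {
      sp <- allocate_peat_area(r$peat_area_ha, ident)
    }
    rows[[length(rows) + 1L]] <- dplyr::bind_cols(
      tibble::tibble(region = r$region, defo_year = r$year, biome = r$biome),
      sp)
  }
  stat <- if (length(rows)) dplyr::bind_rows(rows) else NULL
  rec <- dplyr::bind_rows(direct, stat)
  if (!nrow(rec)) return(empty)
  rec <- dplyr::summarise(
    dplyr::group_by(rec, .data$region, .data$commodity, .data$defo_year,
                    .data$biome),
    peat_area_ha = sum(.data$peat_area_ha), .groups = "drop")
  known <- !rec$commodity %in% RESIDUAL_CLASSES
  rec$annual_MgCO2 <- 0
  if (any(known))
    rec$annual_MgCO2[known] <- rec$peat_area_ha[known] *
      peat_factor(rec$commodity[known], rec$biome[known], config)
  accumulate_emissions(rec, config$peat$horizon, grid$year_end)
}
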