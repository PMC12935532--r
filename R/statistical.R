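POOLS <- c("unresolved_agriculture", "cropland_only", "pasture_only",
           "plantation_only", "cropland_pasture_mosaic")
RESIDUAL_CLASSES <- c("without_production", "unallocated", "other")

# linear interpolation of an annual series at the requested years (NA outside
# the observed range)
series_at <- function(years_obs, values_obs, years) {
  ok <- !is.na(values_obs)
  if (sum(ok) == 0) return(rep(NA_real_, length(years)))
  if (sum(ok) == 1)
    return(ifelse(years == years_obs[ok], values_obs[ok], NA_real_))
  stats::approx(years_obs[ok], values_obs[ok], xout = years, rule = 1)$y
}

lu_series <- function(stats, region, land_use, years) {
  df <- stats$land_use[stats$land_use$region == region &
                         stats$land_use$land_use == land_use, ]
  series_at(df$year, df$area_ha, years)
}

crop_series <- function(stats, region, crop, years) {
  df <- stats$harvested[stats$harvested$region == region &
                          stats$harvested$crop == crop, ]
  series_at(df$year, df$area_ha, years)
}

expansion_of <- function(series, mode) {
  if (all(is.na(series))) return(NA_real_)
  if (anyNA(series)) return(NA_real_)
  if (mode == "gross") sum(pmax(0, diff(series)))
  else max(0, series[length(series)] - series[1])
}

#' Statistical land-use expansion over a lag window
#'
#' Computes, per land use, the expansion over `[year - lag, year]` from the
#' statistics table. In `gross` mode the positive year-on-year increments
#' are summed; in `net` mode only the endpoint difference counts (so
#' abandonment within the window nets out). Missing years are interpolated
#' linearly; a land use with no data in the window gets `NA`, in which case
#' the pool it would serve falls to `unallocated`.
#'
#' @param stats An [ag_stats()] table.
#' @param region,year Region id and attribution year.
#' @param lag Window length in years (>= 0).
#' @param mode `"gross"` or `"net"`.
#' @return Named numeric vector over cropland, pasture, forest_plantation
#'   (ha; `NA` where undefined).
#' @export
landuse_expansions <- function(stats, region, year, lag, mode = "gross") {
  years <- (year - lag):year
  out <- vapply(LAND_USES, function(lu)
    expansion_of(lu_series(stats, region, lu, years), mode), numeric(1))
  names(out) <- LAND_USES
  out
}

split_proportional <- function(total, weights) {
  w <- weights
  w[w < 0] <- 0
  if (sum(w) <= 0) return(stats::setNames(rep(0, length(w)), names(weights)))
  total * w / sum(w)
}

#' Allocate unresolved deforestation pools to land uses
#'
#' Implements the first land-balance step for one region-year. Single
#' land-use pools pass through unchanged. The mosaic pool is split between
#' cropland and pasture proportionally to their statistical expansions. The
#' unresolved-agriculture pool is allocated cropland-first by default
#' (cropland expansion is satisfied before the remainder is split between
#' pasture and plantation, modelling cropland displacing pasture into
#' forest); with `cropland_first` off it is split proportionally across all
#' three land uses. With `restrict_by_stats` on, the combined claims of the
#' two split pools on each land use are capped at that land use's expansion
#' (scaled down proportionally when both pools claim it) and the excess is
#' reported as deforestation `without_production`; pools facing all-zero
#' expansions become `unallocated`.
#'
#' @param pools Named numeric vector over
#'   `c("unresolved_agriculture","cropland_only","pasture_only",
#'   "plantation_only","cropland_pasture_mosaic")` (ha, >= 0; missing names
#'   are treated as 0).
#' @param expansions Output of [landuse_expansions()].
#' @param config Configuration bundle (uses `cropland_first`,
#'   `restrict_by_stats`).
#' @return Tibble with columns `pool`, `target` (a land use or residual
#'   class) and `area_ha`; areas sum to `sum(pools)` exactly.
#' @export
allocate_landuse <- function(pools, expansions, config = NULL) {
  config <- as_config(config)
  p <- stats::setNames(rep(0, length(POOLS)), POOLS)
  p[names(pools)] <- pools
  if (any(p < 0)) stop("negative pool")
  ex <- expansions
  ex_known <- !is.na(ex)
  exv <- ifelse(ex_known, pmax(0, ex), 0)

  out <- list()
  add <- function(pool, target, area) {
    if (area > 0)
      out[[length(out) + 1L]] <<- tibble::tibble(pool = pool, target = target,
                                                 area_ha = area)
  }

  # pass-through pools
  add("cropland_only", "cropland", p[["cropland_only"]])
  add("pasture_only", "pasture", p[["pasture_only"]])
  add("plantation_only", "forest_plantation", p[["plantation_only"]])

  claims <- list()  # per split pool: named vector over land uses
  # mosaic: cropland/pasture proportional
  M <- p[["cropland_pasture_mosaic"]]
  if (M > 0) {
    if (!any(ex_known[c("cropland", "pasture")])) {
      add("cropland_pasture_mosaic", "unallocated", M)
    } else {
      w <- exv[c("cropland", "pasture")]
      if (sum(w) <= 0) {
        add("cropland_pasture_mosaic", "unallocated", M)
      } else {
        claims$cropland_pasture_mosaic <-
          c(split_proportional(M, w), forest_plantation = 0)
      }
    }
  }
  # unresolved agriculture
  U <- p[["unresolved_agriculture"]]
  if (U > 0) {
    if (!any(ex_known)) {
      add("unresolved_agriculture", "unallocated", U)
    } else if (isTRUE(config$cropland_first)) {
      cl <- min(U, exv[["cropland"]])
      rem <- U - cl
      w <- exv[c("pasture", "forest_plantation")]
      rest <- if (sum(w) > 0) split_proportional(rem, w)
              else c(pasture = 0, forest_plantation = 0)
      short <- rem - sum(rest)
      if (short > 0) add("unresolved_agriculture", "unallocated", short)
      claims$unresolved_agriculture <- c(cropland = unname(cl), rest)
    } else {
      if (sum(exv) <= 0) {
        add("unresolved_agriculture", "unallocated", U)
      } else {
        claims$unresolved_agriculture <- split_proportional(U, exv)
      }
    }
  }

  if (length(claims)) {
    cl_mat <- do.call(rbind, lapply(claims, function(cc) {
      v <- stats::setNames(rep(0, 3), LAND_USES); v[names(cc)] <- cc; v
    }))
    if (isTRUE(config$restrict_by_stats)) {
      tot <- colSums(cl_mat)
      cap <- ifelse(ex_known, exv, Inf)  # unknown expansion cannot cap
      scale <- ifelse(tot > 0, pmin(1, cap / tot), 1)
      kept <- sweep(cl_mat, 2, scale, `*`)
      excess <- rowSums(cl_mat - kept)
      for (i in seq_len(nrow(cl_mat)))
        if (excess[i] > 0) add(rownames(cl_mat)[i], "without_production",
                               excess[i])
      cl_mat <- kept
    }
    for (i in seq_len(nrow(cl_mat)))
      for (lu in LAND_USES)
        add(rownames(cl_mat)[i], lu, cl_mat[i, lu])
  }

  res <- if (length(out)) dplyr::bind_rows(out)
         else tibble::tibble(pool = character(), target = character(),
                             area_ha = numeric())
  dplyr::filter(res, .data$area_ha > 0)
}

# per-year cropping-intensity-adjusted harvested series
harvested_series <- function(stats, region, crops, years, multicropping) {
  H <- vapply(crops, function(cr) crop_series(stats, region, cr, years),
              numeric(length(years)))
  H <- matrix(H, nrow = length(years),
              dimnames = list(NULL, crops))
  if (multicropping) {
    cropland <- lu_series(stats, region, "cropland", years)
    tot <- rowSums(H, na.rm = TRUE)
    ci <- pmax(1, ifelse(!is.na(cropland) & cropland > 0,
                         tot / cropland, 1))
    H <- H / ci
  }
  H
}

#' Allocate a cropland pool to crop commodities
#'
#' Second land-balance step: crop shares are the positive harvested-area
#' expansions over the lag window, normalized. With `multicropping` on, each
#' year's harvested areas are first divided by the region-year cropping
#' intensity `CI = max(1, total harvested / cropland area)` so double
#' cropping does not inflate land claims. If no crop expands the pool is
#' returned as `unallocated`.
#'
#' @param cropland_ha Cropland pool to allocate (ha).
#' @param stats An [ag_stats()] table.
#' @param region,year Region id and attribution year.
#' @param lag Window length in years.
#' @param multicropping Apply cropping-intensity adjustment.
#' @param mode `"gross"` or `"net"` expansion of harvested areas.
#' @return Tibble with columns `commodity`, `area_ha` (commodities plus
#'   possibly `unallocated`); areas sum to `cropland_ha` exactly.
#' @export
allocate_commodities <- function(cropland_ha, stats, region, year, lag,
                                 multicropping = TRUE, mode = "gross") {
  if (cropland_ha <= 0)
    return(tibble::tibble(commodity = character(), area_ha = numeric()))
  years <- (year - lag):year
  crops <- unique(stats$harvested$crop[stats$harvested$region == region])
  if (!length(crops))
    return(tibble::tibble(commodity = "unallocated", area_ha = cropland_ha))
  H <- harvested_series(stats, region, crops, years, multicropping)
  dH <- apply(H, 2, expansion_of, mode = mode)
  dH[is.na(dH) | dH < 0] <- 0
  if (sum(dH) <= 0)
    return(tibble::tibble(commodity = "unallocated", area_ha = cropland_ha))
  dH <- dH[dH > 0]  # non-expanding crops take no share
  tibble::tibble(commodity = names(dH), area_ha = cropland_ha * dH / sum(dH))
}

# map an attribution-summary class row to its statistical pool (NA = stays)
class_pool <- function(label, level) {
  dplyr::case_when(
    level == "commodity" ~ NA_character_,
    level == "land_use" & label == "cropland" ~ "cropland_only",
    level == "land_use" & label == "pasture" ~ "pasture_only",
    level == "land_use" & label == "forest_plantation" ~ "plantation_only",
    level == "mosaic" ~ "cropland_pasture_mosaic",
    level == "driver" & label %in% c("commodity_driven",
                                     "shifting_agriculture") ~
      "unresolved_agriculture",
    level == "driver" & label == "forestry" ~ "plantation_only",
    level == "driver" & label == "other" ~ "other",
    level == "none" ~ "unresolved_agriculture",
    TRUE ~ NA_character_
  )
}

#' Two-step statistical attribution of unresolved deforestation
#'
#' Routes every non-commodity row of an attribution summary into its
#' statistical pool, allocates pools to land uses per region-year
#' ([allocate_landuse()]), maps pasture to `cattle_meat_leather` and forest
#' plantation to `forestry_products`, and splits cropland allocations into
#' crop commodities ([allocate_commodities()]). Driver-level `other` loss is
#' reported as a residual class, never dropped.
#'
#' @param summary An `attribution_summary` from [summarize_attribution()].
#' @param stats An [ag_stats()] table.
#' @param config Configuration bundle.
#' @return A list of class `statistical_attribution` with tibbles:
#'   `dluc` (spatially commodity-attributed rows), `allocations` (statistical
#'   rows: region, year, pool, commodity, area_ha where `commodity` may be a
#'   residual class), and `pool_sources` (per-source pool composition for
#'   quality scoring).
#' @export
attribute_statistical <- function(summary, stats, config = NULL) {
  config <- as_config(config)
  cls <- summary$classes
  dluc <- dplyr::select(
    dplyr::filter(cls, .data$level == "commodity"),
    "region", "year", commodity = "label", "source_id", "area_ha")

  pooled <- dplyr::mutate(dplyr::filter(cls, .data$level != "commodity"),
                          pool = class_pool(.data$label, .data$level))
  pool_sources <- dplyr::summarise(
    dplyr::group_by(pooled, .data$region, .data$year, .data$pool,
                    .data$source_id),
    area_ha = sum(.data$area_ha), .groups = "drop")

  alloc_rows <- list()
  keys <- dplyr::distinct(pooled, .data$region, .data$year)
  lag <- config$statistical_lag_years
  mode <- config$expansion_mode
  for (i in seq_len(nrow(keys))) {
    rg <- keys$region[i]; yr <- keys$year[i]
    sub <- pooled[pooled$region == rg & pooled$year == yr, ]
    other <- sum(sub$area_ha[sub$pool == "other"])
    if (other > 0)
      alloc_rows[[length(alloc_rows) + 1L]] <- tibble::tibble(
        region = rg, year = yr, pool = "other", commodity = "other",
        area_ha = other)
    pools <- tapply(sub$area_ha[sub$pool != "other"],
                    sub$pool[sub$pool != "other"], sum)
    if (!length(pools)) next
    ex <- landuse_expansions(stats, rg, yr, lag, mode)
    lu_alloc <- allocate_landuse(unlist(pools), ex, config)
    for (j in seq_len(nrow(lu_alloc))) {
      tgt <- lu_alloc$target[j]; area <- lu_alloc$area_ha[j]
      pl <- lu_alloc$pool[j]
      rows <- switch(tgt,
        cropland = {
          cc <- allocate_commodities(area, stats, rg, yr, lag,
                                     config$multicropping, mode)
          tibble::tibble(region = rg, year = yr, pool = pl,
                         commodity = cc$commodity, area_ha = cc$area_ha)
        },
        pasture = tibble::tibble(region = rg, year = yr, pool = pl,
                                 commodity = "cattle_meat_leather",
                                 area_ha = area),
        forest_plantation = tibble::tibble(region = rg, year = yr, pool = pl,
                                           commodity = "forestry_products",
                                           area_ha = area),
        tibble::tibble(region = rg, year = yr, pool = pl, commodity = tgt,
                       area_ha = area))
      alloc_rows[[length(alloc_rows) + 1L]] <- rows
    }
  }
  allocations <- if (length(alloc_rows)) dplyr::bind_rows(alloc_rows)
    else tibble::tibble(region = character(), year = integer(),
                        pool = character(), commodity = character(),
                        area_ha = numeric())
  allocations <- dplyr::summarise(
    dplyr::group_by(allocations, .data$region, .data$year, .data$pool,
                    .data$commodity),
    area_ha = sum(.data$area_ha), .groups = "drop")
  structure(list(dluc = dluc, allocations = allocations,
                 pool_sources = pool_sources),
            class = "statistical_attribution")
}
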