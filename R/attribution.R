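#' Build the natural-forest mask
#'
#' A pixel counts as natural forest when its year-2000 tree-cover density
#' meets the threshold (>= rule) and it is not inside the managed-plantation
#' mask; intensively managed plantations are excluded from the forest
#' definition, so their clearing is rotational, not deforestation. Nodata in
#' either input propagates to the mask.
#'
#' @param density Tree-cover-density [fp_layer()] (percent).
#' @param plantation_mask Plantation mask [fp_layer()], or `NULL` to skip
#'   plantation masking.
#' @param threshold Density threshold in `[0, 100]`; default 25.
#' @return A `mask`-kind [fp_layer()] named `"forest_mask"`.
#' @export
build_forest_mask <- function(density, plantation_mask = NULL, threshold = 25) {
  if (threshold < 0 || threshold > 100) stop("threshold outside [0,100]")
  m <- (density$values >= threshold) * 1
  if (!is.null(plantation_mask)) {
    p <- plantation_mask$values
    m[!is.na(m) & !is.na(p) & p == 1] <- 0
    m[is.na(p)] <- NA
  }
  fp_layer("forest_mask", "mask", m)
}

LEVEL_RANK <- c(commodity = 1, land_use = 2, mosaic = 3)

# priority order: level-major, rubric-score minor, registry order as final tie
order_datasets <- function(registry, levels) {
  ds <- Filter(function(d) d$level %in% levels, registry)
  if (!length(ds)) return(ds)
  rank <- vapply(ds, function(d) LEVEL_RANK[d$level], numeric(1))
  rank[is.na(rank)] <- 4  # driver
  score <- vapply(ds, dataset_score, numeric(1))
  ds[order(rank, -score, seq_along(ds))]
}

#' Sequentially attribute forest-loss pixels
#'
#' Implements the sequential attribution hierarchy. For every natural-forest
#' pixel with a loss year `t`, candidate datasets are scanned in priority
#' order: commodity-level maps first, then land-use maps, then land-use
#' mosaics (ties within a level broken by the higher rubric score, then by
#' registry order). An annual dataset may claim the pixel only if it first
#' observes a class there within `[t, t + spatial_lag_years]` and no later
#' than its last valid year; a static map is valid for all loss years up to
#' its last valid year. A pixel, once claimed, leaves the process. Pixels
#' unclaimed by any agricultural or forestry dataset but marked by the fire
#' layer in the loss year (agriculture is attributed before fire) become
#' non-commodity fire loss; remaining pixels fall through to dominant-driver
#' datasets, and finally to `unattributed`. Loss on non-forest pixels is
#' recorded as degradation/rotational clearing.
#'
#' @param stack Named list of [fp_layer()]s (must include `tcd` and
#'   `loss_year`).
#' @param registry List of [dataset_descriptor()]s.
#' @param config Configuration bundle; `attribution_mode` selects the full
#'   hierarchy, `partial_statistical` (driver datasets only) or
#'   `full_statistical` (loss layer only, no plantation mask and no fire
#'   exclusion).
#' @param grid A [grid_spec()].
#' @return An object of class `pixel_attribution`: the per-pixel class-code
#'   grid plus its code key (label, level, source).
#' @export
attribute_pixels <- function(stack, registry, config = NULL,
                             grid = NULL) {
  config <- as_config(config)
  if (is.null(grid)) stop("grid is required")
  rep <- validate_stack(stack, registry, grid)
  if (!rep$ok)
    stop("stack fails validation:\n - ", paste(rep$violations, collapse = "\n - "))
  mode <- config$attribution_mode
  loss <- stack_layer(stack, "loss_year")
  density <- stack[["tcd"]]
  forest <- build_forest_mask(
    density,
    if (mode == "full_statistical") NULL else stack[["plantation_mask"]],
    config$tcd_threshold)$values
  forest_l <- !is.na(forest) & forest == 1
  loss_px <- !is.na(loss) & loss > 0
  cand <- loss_px & forest_l

  key <- tibble::tibble(code = integer(), label = character(),
                        level = character(), source_id = character())
  code <- matrix(NA_integer_, nrow(loss), ncol(loss))
  claimed <- matrix(FALSE, nrow(loss), ncol(loss))
  lag <- config$spatial_lag_years

  scan <- function(datasets, code, claimed, key) {
    for (d in datasets) {
      vals <- stack_layer(stack, d$layer)
      codes_num <- as.numeric(names(d$class_map))
      has <- !is.na(vals) & vals %in% codes_num
      if (d$annual) {
        obs <- stack_layer(stack, d$obs_year_layer)
        elig <- !is.na(obs) & obs > 0 & obs >= loss & obs <= loss + lag &
          obs <= d$last_valid_year
      } else {
        elig <- loss <= d$last_valid_year
      }
      sel <- cand & !claimed & has & elig
      if (any(sel)) {
        base <- nrow(key)
        key <- dplyr::bind_rows(key, tibble::tibble(
          code = base + seq_along(codes_num),
          label = unname(d$class_map), level = d$level, source_id = d$id))
        code[sel] <- base + match(vals[sel], codes_num)
        claimed <- claimed | sel
      }
    }
    list(code = code, claimed = claimed, key = key)
  }

  ag_levels <- switch(mode, full = c("commodity", "land_use", "mosaic"),
                      partial_statistical = character(),
                      full_statistical = character())
  st <- scan(order_datasets(registry, ag_levels), code, claimed, key)

  # fire exclusion: agriculture first, then fire, then driver fallback
  if (mode != "full_statistical" && !is.null(stack[["fire_year"]])) {
    f <- stack[["fire_year"]]$values
    w <- config$fire_window_years
    sel <- cand & !st$claimed & !is.na(f) & f > 0 & abs(f - loss) <= w
    if (any(sel)) {
      fire_src <- Filter(function(d) d$level == "fire", registry)
      fid <- if (length(fire_src)) fire_src[[1]]$id else "fire"
      st$key <- dplyr::bind_rows(st$key, tibble::tibble(
        code = nrow(st$key) + 1L, label = "fire_non_commodity",
        level = "fire", source_id = fid))
      st$code[sel] <- nrow(st$key)
      st$claimed <- st$claimed | sel
    }
  }

  if (mode != "full_statistical")
    st <- scan(order_datasets(registry, "driver"), st$code, st$claimed, st$key)

  un <- cand & !st$claimed
  st$key <- dplyr::bind_rows(st$key, tibble::tibble(
    code = nrow(st$key) + 1L, label = "unattributed", level = "none",
    source_id = NA_character_))
  st$code[un] <- nrow(st$key)

  deg <- loss_px & !forest_l
  st$key <- dplyr::bind_rows(st$key, tibble::tibble(
    code = nrow(st$key) + 1L, label = "degradation_rotation",
    level = "excluded", source_id = NA_character_))
  st$code[deg] <- nrow(st$key)

  structure(list(code = st$code, key = st$key, loss_year = loss,
                 grid = grid), class = "pixel_attribution")
}

#' Summarize per-pixel attribution to region-year areas
#'
#' Converts the per-pixel attribution grid to areas (pixel counts times
#' pixel area) grouped by region, loss year, class label, hierarchy level
#' and source dataset. Totals per region-year decompose tree-cover loss into
#' deforestation, degradation/rotational clearing, and non-commodity fire,
#' exactly.
#'
#' @param attribution A `pixel_attribution` from [attribute_pixels()].
#' @param region_layer Categorical [fp_layer()] of region ids.
#' @param grid A [grid_spec()].
#' @return A list of class `attribution_summary` with tibbles `classes`
#'   (region, year, label, level, source_id, area_ha) and `totals` (region,
#'   year, total_loss_ha, deforestation_ha, degradation_rotation_ha,
#'   fire_ha).
#' @export
summarize_attribution <- function(attribution, region_layer, grid) {
  a <- grid$pixel_area_ha
  idx <- which(!is.na(attribution$code))
  if (!length(idx)) {
    return(structure(list(
      classes = tibble::tibble(region = character(), year = integer(),
                               label = character(), level = character(),
                               source_id = character(), area_ha = numeric()),
      totals = tibble::tibble(region = character(), year = integer(),
                              total_loss_ha = numeric(),
                              deforestation_ha = numeric(),
                              degradation_rotation_ha = numeric(),
                              fire_ha = numeric()),
      grid = grid), class = "attribution_summary"))
  }
  px <- tibble::tibble(
    region = paste0("R", region_layer$values[idx]),
    year = as.integer(attribution$loss_year[idx]),
    code = attribution$code[idx])
  px <- dplyr::left_join(px, attribution$key, by = "code")
  rows <- dplyr::summarise(
    dplyr::group_by(px, .data$region, .data$year, .data$label, .data$level,
                    .data$source_id),
    area_ha = dplyr::n() * a, .groups = "drop")
  classes <- dplyr::filter(rows, !.data$level %in% c("fire", "excluded"))
  totals <- dplyr::summarise(
    dplyr::group_by(rows, .data$region, .data$year),
    total_loss_ha = sum(.data$area_ha),
    deforestation_ha = sum(.data$area_ha[!.data$level %in%
                                           c("fire", "excluded")]),
    degradation_rotation_ha = sum(.data$area_ha[.data$level == "excluded"]),
    fire_ha = sum(.data$area_ha[.data$level == "fire"]),
    .groups = "drop")
  structure(list(classes = classes, totals = totals, grid = grid),
            class = "attribution_summary")
}
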