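# Shared fixture builders and the brute-force attribution oracle.

mkm <- function(x, g) matrix(x, g$n_rows, g$n_cols)

# minimal aligned stack; any layer can be overridden with a matrix or scalar
build_test_stack <- function(grid, loss_year = 0, tcd = 80,
                             plantation = 0, fire = 0, peat = 0,
                             biome = 1, region = 1, agb = 100,
                             rs_ratio = 0.2, soc = 100, extra = list()) {
  lay <- function(name, kind, v)
    fp_layer(name, kind, if (is.matrix(v)) v else mkm(v, grid), grid = grid)
  stack <- list(
    tcd = lay("tcd", "continuous", tcd),
    loss_year = lay("loss_year", "year", loss_year),
    plantation_mask = lay("plantation_mask", "mask", plantation),
    fire_year = lay("fire_year", "year", fire),
    peat_mask = lay("peat_mask", "mask", peat),
    biome = lay("biome", "categorical", biome),
    region = lay("region", "categorical", region),
    agb = lay("agb", "continuous", agb),
    rs_ratio = lay("rs_ratio", "continuous", rs_ratio),
    soc = lay("soc", "continuous", soc))
  for (nm in names(extra)) {
    v <- extra[[nm]]
    kind <- if (grepl("obs|year", nm)) "year" else "categorical"
    stack[[nm]] <- lay(nm, kind, v)
  }
  stack
}

ds_commodity <- function(id = "crop_map", class_map = c(`1` = "soy"),
                         lvy = 2022, annual = TRUE, oa = 0.95,
                         scores = c(1, 1, 1)) {
  dataset_descriptor(id, "commodity", class_map, oa, scores[1], scores[2],
                     scores[3], lvy, annual = annual, layer = id,
                     obs_year_layer = if (annual) paste0(id, "_obs"))
}

ds_landuse <- function(id = "lu_map", lvy = 2022, annual = TRUE, oa = 0.85,
                       scores = c(1, 1, 0.5)) {
  dataset_descriptor(id, "land_use",
                     c(`1` = "cropland", `2` = "pasture",
                       `3` = "forest_plantation"),
                     oa, scores[1], scores[2], scores[3], lvy,
                     annual = annual, layer = id,
                     obs_year_layer = if (annual) paste0(id, "_obs"))
}

ds_driver <- function(id = "drv_map", lvy = 2022, oa = 0.75) {
  dataset_descriptor(id, "driver",
                     c(`1` = "commodity_driven", `2` = "forestry",
                       `3` = "shifting_agriculture", `4` = "other"),
                     oa, 0.5, 0.25, 0.25, lvy, annual = FALSE, layer = id)
}

# statistics table with explicit series; land_use/harvested given as
# list(region = list(series_name = c(`2009` = ..., ...)))
make_stats <- function(land_use, harvested = list(), flag = "official") {
  lu_rows <- list(); hv_rows <- list()
  for (rg in names(land_use))
    for (lu in names(land_use[[rg]])) {
      s <- land_use[[rg]][[lu]]
      lu_rows[[length(lu_rows) + 1L]] <- tibble::tibble(
        region = rg, year = as.integer(names(s)), land_use = lu,
        area_ha = unname(s), flag = flag)
    }
  for (rg in names(harvested))
    for (cr in names(harvested[[rg]])) {
      s <- harvested[[rg]][[cr]]
      hv_rows[[length(hv_rows) + 1L]] <- tibble::tibble(
        region = rg, year = as.integer(names(s)), crop = cr,
        area_ha = unname(s), flag = flag)
    }
  empty_lu <- tibble::tibble(region = character(), year = integer(),
                             land_use = character(), area_ha = numeric(),
                             flag = character())
  empty_hv <- tibble::tibble(region = character(), year = integer(),
                             crop = character(), area_ha = numeric(),
                             flag = character())
  ag_stats(if (length(lu_rows)) dplyr::bind_rows(lu_rows) else empty_lu,
           if (length(hv_rows)) dplyr::bind_rows(hv_rows) else empty_hv)
}

# ---- brute-force per-pixel attribution oracle (full mode) --------------
# Independent reimplementation of the sequential hierarchy as a naive loop;
# returns a character matrix "label/level" per loss pixel.
naive_attribute <- function(stack, registry, config, grid) {
  th <- config$tcd_threshold
  lag <- config$spatial_lag_years
  fw <- config$fire_window_years
  score <- function(d) mean(c(d$spatial_score, d$temporal_score,
                              d$explicitness_score))
  rank_of <- c(commodity = 1, land_use = 2, mosaic = 3)
  ord <- function(ds) ds[order(vapply(ds, function(d) rank_of[d$level],
                                      numeric(1)),
                               -vapply(ds, score, numeric(1)),
                               seq_along(ds))]
  ag <- ord(Filter(function(d) d$level %in% names(rank_of), registry))
  drv <- Filter(function(d) d$level == "driver", registry)
  drv <- drv[order(-vapply(drv, score, numeric(1)), seq_along(drv))]

  out <- matrix(NA_character_, grid$n_rows, grid$n_cols)
  for (i in seq_len(grid$n_rows)) for (j in seq_len(grid$n_cols)) {
    t <- stack$loss_year$values[i, j]
    if (is.na(t) || t == 0) next
    dens <- stack$tcd$values[i, j]
    pl <- if (is.null(stack$plantation_mask)) 0
          else stack$plantation_mask$values[i, j]
    if (is.na(dens) || dens < th || is.na(pl) || pl == 1) {
      out[i, j] <- "degradation_rotation/excluded"
      next
    }
    claim <- function(ds) {
      for (d in ds) {
        v <- stack[[d$layer]]$values[i, j]
        if (is.na(v) || !as.character(v) %in% names(d$class_map)) next
        ok <- if (d$annual) {
          o <- stack[[d$obs_year_layer]]$values[i, j]
          !is.na(o) && o > 0 && o >= t && o <= t + lag &&
            o <= d$last_valid_year
        } else t <= d$last_valid_year
        if (ok)
          return(paste0(d$class_map[[as.character(v)]], "/", d$level))
      }
      NULL
    }
    res <- claim(ag)
    if (is.null(res)) {
      f <- stack$fire_year$values[i, j]
      if (!is.na(f) && f > 0 && abs(f - t) <= fw)
        res <- "fire_non_commodity/fire"
    }
    if (is.null(res)) res <- claim(drv)
    if (is.null(res)) res <- "unattributed/none"
    out[i, j] <- res
  }
  out
}

# label/level matrix from a pixel_attribution, for oracle comparison
attribution_labels <- function(attr) {
  out <- matrix(NA_character_, nrow(attr$code), ncol(attr$code))
  idx <- which(!is.na(attr$code))
  out[idx] <- paste0(attr$key$label[attr$code[idx]], "/",
                     attr$key$level[attr$code[idx]])
  out
}

residual_free <- function(fp)
  dplyr::filter(fp, !.data$commodity %in%
                  c("without_production", "unallocated", "other"))
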