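#' Rubric score of a dataset
#'
#' Three equally weighted criteria assess each input dataset: spatial
#' granularity, temporal granularity and explicitness of the deforestation
#' driver. The score is their mean.
#'
#' @param desc A [dataset_descriptor()].
#' @return Score in `[0, 1]`.
#' @export
dataset_score <- function(desc) {
  sc <- c(desc$spatial_score, desc$temporal_score, desc$explicitness_score)
  if (any(sc < 0 | sc > 1)) stop("rubric sub-scores out of range")
  mean(sc)
}

flag_score <- function(flag, config) {
  fs <- config$quality$flag_scores
  flag <- as.character(flag)
  bad <- setdiff(flag[!is.na(flag)], names(fs))
  if (length(bad)) stop("unknown flag: ", paste(bad, collapse = ", "))
  out <- rep(1, length(flag))  # absent flag: treated as officially reported
  ok <- !is.na(flag)
  out[ok] <- unname(fs[flag[ok]])
  out
}

#' Flag-adjusted overall accuracy
#'
#' Contributions that come purely from spatial commodity data keep the
#' dataset's overall accuracy; statistically attributed contributions are
#' penalized by the quality of the statistics behind them, multiplying OA by
#' the mean of the land-use and production flag scores. An absent production
#' flag (statistics reported directly by a national agency) scores 1.
#'
#' @param desc A [dataset_descriptor()], or a bare numeric OA.
#' @param flag_land_use,flag_production FAO-style flag labels (or `NA`).
#' @param statistical Did statistics contribute to this estimate?
#' @param config Configuration bundle (flag scores).
#' @return Adjusted OA in `(0, 1]`.
#' @export
adjusted_accuracy <- function(desc, flag_land_use = NA,
                              flag_production = NA, statistical = FALSE,
                              config = NULL) {
  config <- as_config(config)
  oa <- if (inherits(desc, "dataset_descriptor")) desc$overall_accuracy
        else desc
  if (!statistical) return(oa)
  oa * (flag_score(flag_land_use, config) +
          flag_score(flag_production, config)) / 2
}

#' Band label for an IQI value
#'
#' `IQI >= 0.6` marks directly commodity-attributed estimates
#' (`dLUC_commodity`), `0.55 <= IQI < 0.6` broad spatial land-use attribution
#' (`dLUC_landuse`), and `IQI < 0.55` statistically blended estimates
#' (`sLUC`).
#'
#' @param iqi Numeric IQI values.
#' @param config Configuration bundle (band edges).
#' @return Character vector of band labels (`NA` for `NA` input).
#' @export
iqi_band <- function(iqi, config = NULL) {
  config <- as_config(config)
  q <- config$quality
  dplyr::case_when(is.na(iqi) ~ NA_character_,
                   iqi >= q$band_commodity ~ "dLUC_commodity",
                   iqi >= q$band_landuse ~ "dLUC_landuse",
                   TRUE ~ "sLUC")
}

#' Integrated Quality Index of one estimate
#'
#' The IQI is the forest-loss-area-weighted mean of each contributing
#' source's (flag-adjusted) overall accuracy times its rubric score:
#' `IQI = sum(FL_j * OA_j * Score_j) / sum(FL_j)`. With zero total area the
#' IQI is undefined and returned as `NA` rather than fabricated.
#'
#' @param contributions Tibble (or data frame) with columns `fl` (area
#'   weight, >= 0), `oa` (adjusted accuracy) and `score` (rubric score).
#' @param config Configuration bundle (band edges).
#' @return A list of class `iqi_record`: `iqi`, `band`, `contributions`.
#' @export
compute_iqi <- function(contributions, config = NULL) {
  config <- as_config(config)
  ct <- tibble::as_tibble(contributions)
  stopifnot(all(c("fl", "oa", "score") %in% names(ct)))
  if (any(ct$fl < 0)) stop("FL weights must be >= 0")
  tot <- sum(ct$fl)
  iqi <- if (tot > 0) sum(ct$fl * ct$oa * ct$score) / tot else NA_real_
  structure(list(iqi = iqi, band = iqi_band(iqi, config),
                 contributions = ct), class = "iqi_record")
}

#' Weighted multi-year IQI
#'
#' Aggregates per-year IQI values into a single weighted-average IQI using
#' forest-loss areas as weights.
#'
#' @param iqi Per-year IQI values.
#' @param fl Per-year forest-loss areas (weights).
#' @return Weighted mean IQI (`NA` if no weight).
#' @export
weighted_iqi <- function(iqi, fl) {
  ok <- !is.na(iqi) & fl > 0
  if (!any(ok)) return(NA_real_)
  sum(iqi[ok] * fl[ok]) / sum(fl[ok])
}

# flag of the land-use area statistic backing a commodity in a region-year
stat_flags <- function(stats, region, year, commodity, config) {
  lu <- commodity_landuse(commodity, config)
  f_lu <- stats$land_use$flag[stats$land_use$region == region &
                                stats$land_use$year == year &
                                stats$land_use$land_use == lu]
  f_pr <- stats$harvested$flag[stats$harvested$region == region &
                                 stats$harvested$year == year &
                                 stats$harvested$crop == commodity]
  c(land_use = if (length(f_lu)) f_lu[1] else NA_character_,
    production = if (length(f_pr)) f_pr[1] else NA_character_)
}

#' Quality index for every commodity estimate
#'
#' Builds the per-source contribution table of each (region, commodity,
#' year) estimate -- direct spatial contributions keep their dataset's OA;
#' statistical contributions are flag-adjusted and inherit the OA and rubric
#' score of the dataset that delimited their pool (contributions with no
#' spatial source use the configuration's fallback accuracy block) -- and
#' computes the IQI and its band. Residual classes carry no IQI.
#'
#' @param statistical A `statistical_attribution`.
#' @param registry List of [dataset_descriptor()]s.
#' @param stats An [ag_stats()] table.
#' @param config Configuration bundle.
#' @return Tibble: region, commodity, year, iqi, band.
#' @export
compute_quality <- function(statistical, registry, stats, config = NULL) {
  config <- as_config(config)
  q <- config$quality
  desc_by_id <- stats::setNames(registry, vapply(registry, `[[`, "", "id"))
  oa_of <- function(id) {
    if (is.na(id) || is.null(desc_by_id[[id]])) q$fallback_oa
    else desc_by_id[[id]]$overall_accuracy
  }
  score_of <- function(id) {
    if (is.na(id) || is.null(desc_by_id[[id]])) mean(q$fallback_scores)
    else dataset_score(desc_by_id[[id]])
  }

  dl <- statistical$dluc
  contrib <- NULL
  if (nrow(dl)) {
    contrib <- tibble::tibble(
      region = dl$region, year = dl$year, commodity = dl$commodity,
      fl = dl$area_ha,
      oa = vapply(dl$source_id, oa_of, numeric(1)),
      score = vapply(dl$source_id, score_of, numeric(1)))
  }

  al <- dplyr::filter(statistical$allocations,
                      !.data$commodity %in% RESIDUAL_CLASSES)
  ps <- statistical$pool_sources
  rows <- list()
  for (i in seq_len(nrow(al))) {
    r <- al[i, ]
    src <- ps[ps$region == r$region & ps$year == r$year & ps$pool == r$pool, ]
    if (!nrow(src))
      src <- tibble::tibble(source_id = NA_character_, area_ha = 1)
    fl <- r$area_ha * src$area_ha / sum(src$area_ha)
    fg <- stat_flags(stats, r$region, r$year, r$commodity, config)
    oa <- vapply(src$source_id, function(id)
      adjusted_accuracy(oa_of(id), fg[["land_use"]], fg[["production"]],
                        statistical = TRUE, config = config), numeric(1))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      region = r$region, year = r$year, commodity = r$commodity, fl = fl,
      oa = oa, score = vapply(src$source_id, score_of, numeric(1)))
  }
  contrib <- dplyr::bind_rows(contrib, rows)
  if (is.null(contrib) || !nrow(contrib)) {
    return(tibble::tibble(region = character(), commodity = character(),
                          year = integer(), iqi = numeric(),
                          band = character()))
  }
  out <- dplyr::summarise(
    dplyr::group_by(contrib, .data$region, .data$commodity, .data$year),
    iqi = sum(.data$fl * .data$oa * .data$score) / sum(.data$fl),
    .groups = "drop")
  out$iqi[!is.finite(out$iqi)] <- NA_real_
  out$band <- iqi_band(out$iqi, config)
  out
}
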