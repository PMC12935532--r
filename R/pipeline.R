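#' Run the full attribution and accounting pipeline in memory
#'
#' Executes the stages in order: spatial attribution, statistical land
#' balance, committed-emission accounting, peat drainage, quality scoring,
#' and footprint assembly, with stage-by-stage conservation checks. The run
#' is deterministic given inputs and configuration.
#'
#' @param landscape A `cf_landscape` (from [generate_landscape()] or
#'   [read_landscape()]), or any list with elements `grid`, `stack`,
#'   `registry`, `stats`.
#' @param config Configuration bundle (defaults to [default_config()]).
#' @return A list of class `cf_run`: `attribution` (per-pixel grid),
#'   `summary` (attribution summary), `statistical`, `emissions`, `peat`,
#'   `quality`, `footprint` (assembled records) and `checks` (conservation
#'   log tibble).
#' @export
run_footprint <- function(landscape, config = NULL) {
  config <- as_config(config)
  g <- landscape$grid
  stack <- landscape$stack
  registry <- landscape$registry
  stats <- landscape$stats

  attribution <- attribute_pixels(stack, registry, config, g)
  summary <- summarize_attribution(attribution, stack[["region"]], g)
  statistical <- attribute_statistical(summary, stats, config)
  emissions <- compute_emissions(attribution, statistical, stack, config, g)
  peat <- compute_peat(attribution, statistical, stack, config, g)
  quality <- compute_quality(statistical, registry, stats, config)
  footprint <- assemble_footprint(emissions, peat, quality)

  checks <- conservation_checks(attribution, summary, statistical,
                                emissions, g)
  structure(list(attribution = attribution, summary = summary,
                 statistical = statistical, emissions = emissions,
                 peat = peat, quality = quality, footprint = footprint,
                 checks = checks, config = config, grid = g),
            class = "cf_run")
}

# stage-by-stage conservation log; `pass` uses 1e-6 relative tolerance
conservation_checks <- function(attribution, summary, statistical,
                                emissions, grid) {
  a <- grid$pixel_area_ha
  n_loss <- sum(!is.na(attribution$code))
  tot_loss <- sum(summary$totals$total_loss_ha)
  defo <- sum(summary$totals$deforestation_ha)
  cls <- sum(summary$classes$area_ha)
  alloc_tot <- sum(statistical$allocations$area_ha) +
    sum(statistical$dluc$area_ha)
  em_area <- sum(emissions$area_ha)
  rel <- function(x, y) abs(x - y) / max(abs(y), 1e-12)
  row <- function(check, got, want) tibble::tibble(
    check = check, value = got, reference = want,
    pass = rel(got, want) <= 1e-6)
  dplyr::bind_rows(
    row("pixels attributed exactly once", tot_loss, n_loss * a),
    row("class areas sum to deforestation", cls, defo),
    row("statistical allocation conserves the pools", alloc_tot, defo),
    row("emission records cover the attributed area", em_area, defo))
}

#' Assemble footprint records
#'
#' Joins emission, peat and quality tables into one record per (region,
#' commodity, year): deforested area, gross and net committed emissions,
#' accumulated peat drainage emissions (all in MtCO2), IQI and band.
#'
#' @param emissions Output of [compute_emissions()].
#' @param peat Output of [compute_peat()].
#' @param quality Output of [compute_quality()].
#' @return Tibble of footprint records (`amortized = FALSE`).
#' @export
assemble_footprint <- function(emissions, peat, quality) {
  pt <- dplyr::summarise(
    dplyr::group_by(peat, .data$region, .data$commodity,
                    year = .data$defo_year),
    peat_MtCO2 = sum(.data$accumulated_MgCO2) * 1e-6,
    peat_area_ha = sum(.data$peat_area_ha), .groups = "drop")
  fp <- dplyr::transmute(emissions, region = .data$region,
                         commodity = .data$commodity, year = .data$year,
                         attribution = .data$attribution,
                         deforestation_ha = .data$area_ha,
                         gross_MtCO2 = .data$gross_MgCO2 * 1e-6,
                         net_MtCO2 = .data$net_MgCO2 * 1e-6)
  # one record per region-commodity-year (a commodity may gather area from
  # both direct and statistical routes)
  fp <- dplyr::summarise(
    dplyr::group_by(fp, .data$region, .data$commodity, .data$year),
    attribution = paste(sort(unique(.data$attribution)), collapse = "+"),
    dplyr::across(c("deforestation_ha", "gross_MtCO2", "net_MtCO2"), sum),
    .groups = "drop")
  fp <- dplyr::left_join(fp, pt, by = c("region", "commodity", "year"))
  fp$peat_MtCO2[is.na(fp$peat_MtCO2)] <- 0
  fp$peat_area_ha[is.na(fp$peat_area_ha)] <- 0
  fp <- dplyr::left_join(fp, quality,
                         by = c("region", "commodity", "year"))
  fp$amortized <- FALSE
  dplyr::arrange(fp, .data$region, .data$commodity, .data$year)
}

#' Amortize footprint records over a fixed window
#'
#' Spreads each event-year record evenly over `[year, year + window - 1]`
#' (areas and committed emissions; peat drainage columns stay at the event
#' year, unamortized). Totals are conserved over the extended horizon.
#'
#' @param records Footprint tibble from [assemble_footprint()].
#' @param window Amortization window in years (>= 1); default 5.
#' @return Amortized footprint tibble (`amortized = TRUE`).
#' @export
amortize <- function(records, window = 5L) {
  window <- as.integer(window)
  stopifnot(window >= 1L)
  if (!nrow(records)) {
    records$amortized <- logical(0)
    return(records)
  }
  spread_cols <- intersect(c("deforestation_ha", "gross_MtCO2", "net_MtCO2"),
                           names(records))
  peat_cols <- intersect(c("peat_MtCO2", "peat_area_ha"), names(records))
  out <- records[rep(seq_len(nrow(records)), each = window), ]
  out$year <- out$year + rep(0:(window - 1L), nrow(records))
  first <- rep(c(TRUE, rep(FALSE, window - 1L)), nrow(records))
  for (cc in spread_cols) out[[cc]] <- out[[cc]] / window
  for (cc in peat_cols) out[[cc]] <- ifelse(first, out[[cc]], 0)
  out$amortized <- TRUE
  grp_cols <- intersect(c("region", "commodity", "year", "attribution"),
                        names(out))
  agg <- dplyr::summarise(
    dplyr::group_by(out, dplyr::across(dplyr::all_of(grp_cols))),
    dplyr::across(dplyr::where(is.numeric) & !dplyr::any_of(c("iqi")), sum),
    dplyr::across(dplyr::any_of(c("iqi", "band")), dplyr::first),
    amortized = TRUE, .groups = "drop")
  dplyr::arrange(agg, dplyr::across(dplyr::all_of(grp_cols)))
}

# total metrics of a run, used by the sensitivity harness
run_totals <- function(run) {
  dluc <- sum(run$statistical$dluc$area_ha)
  c(deforestation_ha = sum(run$footprint$deforestation_ha),
    dluc_commodity_ha = dluc,
    gross_MtCO2 = sum(run$footprint$gross_MtCO2),
    net_MtCO2 = sum(run$footprint$net_MtCO2),
    peat_MtCO2 = sum(run$footprint$peat_MtCO2))
}

# named sensitivity switch -> configuration field
apply_switch <- function(config, name, value) {
  switch(name,
    tcd_threshold = { config$tcd_threshold <- value },
    spatial_lag_years = { config$spatial_lag_years <- as.integer(value) },
    statistical_lag_years = {
      config$statistical_lag_years <- as.integer(value) },
    attribution_mode = { config$attribution_mode <- value },
    cropland_first = { config$cropland_first <- isTRUE(value) },
    expansion_mode = { config$expansion_mode <- value },
    restrict_by_stats = { config$restrict_by_stats <- isTRUE(value) },
    multicropping = { config$multicropping <- isTRUE(value) },
    peat_horizon = { config$peat$horizon <- value },
    plant_stock_scale = { config$carbon$plant_stock_scale <- value },
    amortize_years = { config$amortize_years <- as.integer(value) },
    stop("switch outside declared set: ", name))
  validate_config(config)
}

#' Sensitivity of estimates to modelling parameters
#'
#' Reruns the pipeline once per switch setting and reports the percentage
#' change of total deforestation, spatially commodity-attributed area, gross
#' and net emissions and accumulated peat emissions against the baseline
#' configuration, to two decimals, as `(variant - reference) / reference x
#' 100`.
#'
#' @param landscape A `cf_landscape`.
#' @param config Baseline configuration.
#' @param switches Named list: switch name -> vector of settings to test,
#'   e.g. `list(tcd_threshold = c(10, 75), peat_horizon = c("none", 5))`.
#' @return Tibble: switch, value, and `pct_*` change columns.
#' @export
sensitivity_run <- function(landscape, config = NULL, switches) {
  config <- as_config(config)
  base <- run_totals(run_footprint(landscape, config))
  rows <- list()
  for (nm in names(switches)) {
    for (val in switches[[nm]]) {
      variant <- apply_switch(config, nm, val)
      tot <- run_totals(run_footprint(landscape, variant))
      pct <- ifelse(base != 0, round(100 * (tot - base) / base, 2),
                    ifelse(tot == 0, 0, NA_real_))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        switch = nm, value = as.character(val),
        pct_deforestation = pct[["deforestation_ha"]],
        pct_dluc_commodity = pct[["dluc_commodity_ha"]],
        pct_gross = pct[["gross_MtCO2"]],
        pct_net = pct[["net_MtCO2"]],
        pct_peat = pct[["peat_MtCO2"]])
    }
  }
  dplyr::bind_rows(rows)
}

# ---- directory I/O -----------------------------------------------------

#' Write / read a landscape directory
#'
#' `write_landscape()` lays out a landscape as text files: `grid.yaml`,
#' `layers/<name>.grid`, `registry.yaml`, `ag_stats.csv`, optionally
#' `ground_truth.csv`, and a `manifest.json` listing the contents.
#' `read_landscape()` is its inverse (ground truth is read back when
#' present).
#'
#' @param landscape A `cf_landscape`.
#' @param dir Directory path (created if needed).
#' @return `write_landscape()` returns `dir` invisibly; `read_landscape()`
#'   returns a `cf_landscape`-compatible list.
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(file.path(dir, "layers"), recursive = TRUE, showWarnings = FALSE)
  g <- landscape$grid
  yaml::write_yaml(unclass(g), file.path(dir, "grid.yaml"))
  for (ly in landscape$stack)
    write_layer(ly, file.path(dir, "layers", paste0(ly$name, ".grid")))
  write_registry(landscape$registry, file.path(dir, "registry.yaml"))
  write_ag_stats(landscape$stats, file.path(dir, "ag_stats.csv"))
  if (!is.null(landscape$truth))
    utils::write.csv(landscape$truth, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE)
  manifest <- list(
    layers = unname(vapply(landscape$stack, `[[`, "", "name")),
    registry = "registry.yaml", stats = "ag_stats.csv",
    seed = if (!is.null(landscape$params)) landscape$params$seed else NULL)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(dir) {
  gl <- yaml::read_yaml(file.path(dir, "grid.yaml"))
  g <- grid_spec(gl$n_rows, gl$n_cols, gl$pixel_area_ha, gl$year_start,
                 gl$year_end)
  files <- list.files(file.path(dir, "layers"), pattern = "\\.grid$",
                      full.names = TRUE)
  stack <- lapply(files, read_layer, grid = g)
  names(stack) <- vapply(stack, `[[`, "", "name")
  truth_path <- file.path(dir, "ground_truth.csv")
  truth <- if (file.exists(truth_path))
    tibble::as_tibble(utils::read.csv(truth_path)) else NULL
  structure(list(grid = g, stack = stack,
                 registry = read_registry(file.path(dir, "registry.yaml")),
                 stats = load_ag_stats(file.path(dir, "ag_stats.csv")),
                 truth = truth, params = NULL),
            class = "cf_landscape")
}

#' Run the pipeline on a landscape directory
#'
#' Reads the inputs from `input_dir` (layout of [write_landscape()]),
#' validates the stack, runs [run_footprint()], and writes the attribution
#' summary, emissions, peat, footprint and amortized-footprint CSVs plus a
#' `manifest.json` (configuration echo and conservation-check log) into
#' `output_dir`. Refuses to run on a failing validation report.
#'
#' @param input_dir Input directory.
#' @param output_dir Output directory (created if needed).
#' @param config Configuration bundle or path to a YAML config file.
#' @return The `cf_run`, invisibly.
#' @export
run_pipeline <- function(input_dir, output_dir, config = NULL) {
  if (is.character(config)) config <- read_config(config)
  config <- as_config(config)
  landscape <- read_landscape(input_dir)
  rep <- validate_stack(landscape$stack, landscape$registry, landscape$grid)
  if (!rep$ok)
    stop("input validation failed:\n - ",
         paste(rep$violations, collapse = "\n - "))
  run <- run_footprint(landscape, config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(output_dir, name), row.names = FALSE)
  wcsv(run$summary$classes, "attribution_classes.csv")
  wcsv(run$summary$totals, "attribution_totals.csv")
  wcsv(run$statistical$allocations, "statistical_allocations.csv")
  wcsv(run$emissions, "emissions.csv")
  wcsv(run$peat, "peat.csv")
  wcsv(run$footprint, "footprint.csv")
  wcsv(amortize(run$footprint, config$amortize_years),
       "footprint_amortized.csv")
  manifest <- list(config = unclass(config),
                   checks = run$checks,
                   all_checks_pass = all(run$checks$pass))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(run)
}
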