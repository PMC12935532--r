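#' Read a raster layer from a plain-text grid file
#'
#' The on-disk format is a single-band plain-text grid: a short header of
#' `key value` lines (`name`, `kind`, `nodata`, `nrows`, `ncols`) followed by
#' `nrows` whitespace-separated rows of `ncols` values, raster origin at the
#' top-left. Any external nodata sentinel is normalized to `NA` on read.
#'
#' @param path Path to a `.grid` file.
#' @param kind Optional layer kind overriding the header
#'   (`"continuous"`, `"categorical"`, `"mask"`, `"year"`).
#' @param grid Optional [grid_spec()] to validate dimensions against.
#' @return An [fp_layer()].
#' @export
read_layer <- function(path, kind = NULL, grid = NULL) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && parts[1] %in%
        c("name", "kind", "nodata", "nrows", "ncols")) {
      hdr[[parts[1]]] <- parts[2]; i <- i + 1L
    } else break
  }
  for (f in c("nrows", "ncols")) if (is.null(hdr[[f]]))
    stop("grid file ", path, " lacks header field '", f, "'")
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  body <- lines[(i + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != nr)
    stop("grid file ", path, ": expected ", nr, " data rows, found ", length(body))
  vals <- scan(text = paste(body, collapse = "\n"), quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("grid file ", path, ": expected ", nr * nc, " values, found ", length(vals))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata)) m[m == as.numeric(hdr$nodata)] <- NA
  nm <- hdr$name %||% sub("\\.grid$", "", basename(path))
  fp_layer(nm, kind %||% hdr$kind %||% "continuous", m, grid = grid)
}

#' Write a raster layer to a plain-text grid file
#'
#' Inverse of [read_layer()]: round trips are value-identical. `NA` cells are
#' written as the nodata sentinel.
#'
#' @param layer An [fp_layer()].
#' @param path Output path.
#' @param nodata Sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_layer <- function(layer, path, nodata = -9999) {
  stopifnot(inherits(layer, "fp_layer"))
  m <- layer$values
  m[is.na(m)] <- nodata
  hdr <- c(paste("name", layer$name), paste("kind", layer$kind),
           paste("nodata", format(nodata, scientific = FALSE)),
           paste("nrows", nrow(m)), paste("ncols", ncol(m)))
  rows <- apply(m, 1, function(r)
    paste(format(r, trim = TRUE, scientific = FALSE, digits = 15), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

AG_FLAGS <- c("official", "semi_official", "estimated", "imputed", "unofficial")
LAND_USES <- c("cropland", "pasture", "forest_plantation")

#' Construct an agricultural-statistics table
#'
#' Holds per region-year land-use areas (cropland, pasture, forest
#' plantation) and per-crop harvested areas, each with an FAO-style quality
#' flag from the closed set official / semi_official / estimated / imputed /
#' unofficial.
#'
#' @param land_use Tibble with columns region, year, land_use, area_ha, flag.
#' @param harvested Tibble with columns region, year, crop, area_ha, flag.
#' @return An object of class `ag_stats`.
#' @export
ag_stats <- function(land_use, harvested) {
  land_use <- tibble::as_tibble(land_use)
  harvested <- tibble::as_tibble(harvested)
  stopifnot(all(c("region", "year", "land_use", "area_ha", "flag") %in%
                  names(land_use)),
            all(c("region", "year", "crop", "area_ha", "flag") %in%
                  names(harvested)))
  if (!all(land_use$land_use %in% LAND_USES))
    stop("unknown land use in statistics table")
  bad <- setdiff(c(land_use$flag, harvested$flag), AG_FLAGS)
  if (length(bad)) stop("unknown flag label: ", paste(bad, collapse = ", "))
  if (any(land_use$area_ha < 0, harvested$area_ha < 0))
    stop("areas must be >= 0")
  structure(list(land_use = land_use, harvested = harvested),
            class = "ag_stats")
}

#' Load agricultural statistics from a long-format CSV
#'
#' The file must have columns `region, year, variable, value, flag`, where
#' `variable` is one of `cropland_area`, `pasture_area`,
#' `forest_plantation_area`, or `harvested:<crop>`. Missing flags default to
#' `"unofficial"`; rows with negative values are rejected with a warning;
#' duplicate `(region, year, variable)` keys and unknown flag labels are
#' errors.
#'
#' @param path Path to the CSV file.
#' @return An [ag_stats()] table.
#' @export
load_ag_stats <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("region", "year", "variable", "value")
  if (!all(need %in% names(df)))
    stop("statistics CSV must have columns region, year, variable, value, flag")
  if (is.null(df$flag)) df$flag <- NA_character_
  df$flag[is.na(df$flag) | df$flag == ""] <- "unofficial"
  bad <- setdiff(unique(df$flag), AG_FLAGS)
  if (length(bad)) stop("unknown flag label: ", paste(bad, collapse = ", "))
  key <- paste(df$region, df$year, df$variable, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate key: ", paste(unique(key[duplicated(key)]), collapse = "; "))
  neg <- df$value < 0
  if (any(neg)) {
    warning(sum(neg), " row(s) with negative area rejected")
    df <- df[!neg, , drop = FALSE]
  }
  is_harv <- startsWith(df$variable, "harvested:")
  lu <- df[!is_harv, , drop = FALSE]
  lu_name <- sub("_area$", "", lu$variable)
  if (!all(lu_name %in% LAND_USES))
    stop("unknown land-use variable: ",
         paste(unique(lu$variable[!lu_name %in% LAND_USES]), collapse = ", "))
  land_use <- tibble::tibble(region = lu$region, year = as.integer(lu$year),
                             land_use = lu_name, area_ha = lu$value,
                             flag = lu$flag)
  hv <- df[is_harv, , drop = FALSE]
  harvested <- tibble::tibble(region = hv$region, year = as.integer(hv$year),
                              crop = sub("^harvested:", "", hv$variable),
                              area_ha = hv$value, flag = hv$flag)
  ag_stats(land_use, harvested)
}

#' Write an agricultural-statistics table to long-format CSV
#'
#' Inverse of [load_ag_stats()].
#'
#' @param stats An [ag_stats()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ag_stats <- function(stats, path) {
  lu <- dplyr::transmute(stats$land_use, region = .data$region,
                         year = .data$year,
                         variable = paste0(.data$land_use, "_area"),
                         value = .data$area_ha, flag = .data$flag)
  hv <- dplyr::transmute(stats$harvested, region = .data$region,
                         year = .data$year,
                         variable = paste0("harvested:", .data$crop),
                         value = .data$area_ha, flag = .data$flag)
  utils::write.csv(dplyr::bind_rows(lu, hv), path, row.names = FALSE)
  invisible(path)
}
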