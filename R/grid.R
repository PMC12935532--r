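#' Grid specification for an aligned raster stack
#'
#' All layers in a stack share one abstract planar grid: `n_rows` x `n_cols`
#' pixels, each of a fixed area in hectares, with an attribution window
#' `[year_start, year_end]`. There is no projection or resampling: layers must
#' be pre-aligned. The default pixel area of 0.09 ha corresponds to the 30-m
#' pixel convention of global tree-cover products; the default window is the
#' 2001--2022 study period.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param pixel_area_ha Area of one pixel in hectares (> 0).
#' @param year_start,year_end First and last attribution year.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, pixel_area_ha = 0.09,
                      year_start = 2001L, year_end = 2022L) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  stopifnot(n_rows >= 1L, n_cols >= 1L, pixel_area_ha > 0,
            year_start <= year_end)
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 pixel_area_ha = pixel_area_ha,
                 year_start = as.integer(year_start),
                 year_end = as.integer(year_end)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d pixels, %.4g ha/pixel, years %d-%d\n",
              x$n_rows, x$n_cols, x$pixel_area_ha, x$year_start, x$year_end))
  invisible(x)
}

LAYER_KINDS <- c("continuous", "categorical", "mask", "year")

# Layers whose codes are structural (region/biome ids) rather than
# attribution classes; they need no dataset descriptor.
RESERVED_CATEGORICAL <- c("region", "biome")

#' A single aligned raster layer
#'
#' A layer is a named 2-D grid of values (row-major, 0-based raster origin at
#' the top-left) of one of four kinds: `continuous` (densities, stocks),
#' `categorical` (class codes), `mask` (0/1) or `year` (0 = no event, else a
#' calendar year). Nodata is always represented internally as `NA`; file
#' readers normalize any external sentinel on read.
#'
#' @param name Layer identifier.
#' @param kind One of `"continuous"`, `"categorical"`, `"mask"`, `"year"`.
#' @param values Numeric matrix; `NA` marks nodata.
#' @param grid Optional [grid_spec()] used to check dimensions and, for
#'   `year` layers, the admissible year range.
#' @return An object of class `fp_layer`.
#' @export
fp_layer <- function(name, kind, values, grid = NULL) {
  kind <- match.arg(kind, LAYER_KINDS)
  if (!is.matrix(values)) stop("layer '", name, "': values must be a matrix")
  storage.mode(values) <- "double"
  if (!is.null(grid) &&
      (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols)) {
    stop(sprintf("layer '%s': dimensions %dx%d do not match grid %dx%d",
                 name, nrow(values), ncol(values), grid$n_rows, grid$n_cols))
  }
  v <- values[!is.na(values)]
  if (kind == "mask" && length(v) && !all(v %in% c(0, 1)))
    stop("layer '", name, "': mask layer must be binary")
  if (kind == "year" && !is.null(grid) && length(v)) {
    bad <- v != 0 & (v < grid$year_start | v > grid$year_end)
    if (any(bad))
      stop(sprintf("layer '%s': year outside window [%d, %d]",
                   name, grid$year_start, grid$year_end))
  }
  structure(list(name = name, kind = kind, values = values),
            class = "fp_layer")
}

#' @export
print.fp_layer <- function(x, ...) {
  cat(sprintf("<fp_layer> '%s' (%s) %d x %d, %d nodata\n", x$name, x$kind,
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

# Pull a required layer from a stack, with a clear error.
stack_layer <- function(stack, name) {
  if (is.null(stack[[name]])) stop("required layer missing: ", name)
  stack[[name]]$values
}
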