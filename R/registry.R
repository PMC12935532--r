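DATASET_LEVELS <- c("commodity", "land_use", "mosaic", "driver", "fire")

#' Describe an attribution dataset
#'
#' Every categorical layer used in attribution carries a descriptor: its
#' level in the attribution hierarchy, the mapping from raster codes to
#' class labels, the dataset's published overall accuracy, three equally
#' weighted rubric sub-scores (spatial and temporal granularity,
#' explicitness of the deforestation driver), the last year for which the
#' dataset is valid, and whether it is an annual series or a static map.
#' Annual datasets reference a companion `year` layer recording when the
#' class was first observed at each pixel.
#'
#' @param id Dataset identifier.
#' @param level One of `"commodity"`, `"land_use"`, `"mosaic"`, `"driver"`,
#'   `"fire"`.
#' @param class_map Named character vector mapping raster codes (names) to
#'   class labels (values).
#' @param overall_accuracy Overall accuracy OA in (0, 1].
#' @param spatial_score,temporal_score,explicitness_score Rubric sub-scores
#'   in `[0, 1]`.
#' @param last_valid_year Last year of observation.
#' @param annual `TRUE` for an annual series, `FALSE` for a static map.
#' @param layer Name of the class-code layer in the stack.
#' @param obs_year_layer For annual datasets, name of the companion layer
#'   holding the first observation year per pixel.
#' @return An object of class `dataset_descriptor`.
#' @export
dataset_descriptor <- function(id, level, class_map, overall_accuracy,
                               spatial_score, temporal_score,
                               explicitness_score, last_valid_year,
                               annual = FALSE, layer = id,
                               obs_year_layer = NULL) {
  level <- match.arg(level, DATASET_LEVELS)
  stopifnot(overall_accuracy > 0, overall_accuracy <= 1)
  sc <- c(spatial_score, temporal_score, explicitness_score)
  if (any(sc < 0 | sc > 1)) stop("rubric sub-scores must lie in [0, 1]")
  if (is.null(names(class_map)) || !length(class_map))
    stop("class_map must be a named (code -> label) vector")
  if (annual && is.null(obs_year_layer))
    stop("annual dataset '", id, "' needs an obs_year_layer")
  structure(list(id = id, level = level,
                 class_map = class_map,
                 overall_accuracy = overall_accuracy,
                 spatial_score = spatial_score,
                 temporal_score = temporal_score,
                 explicitness_score = explicitness_score,
                 last_valid_year = as.integer(last_valid_year),
                 annual = isTRUE(annual),
                 layer = layer, obs_year_layer = obs_year_layer),
            class = "dataset_descriptor")
}

#' Validate an aligned layer stack against its registry
#'
#' Collects (rather than throws) all violations: dimension mismatches,
#' missing required layers (`tcd`, `loss_year`), non-binary masks, loss
#' years outside the study window, categorical layers without a descriptor,
#' descriptors whose layers are absent, and class codes outside the
#' descriptor's class map. The pipeline refuses to run on a failing report.
#'
#' @param stack Named list of [fp_layer()]s.
#' @param registry List of [dataset_descriptor()]s.
#' @param grid A [grid_spec()].
#' @return A list of class `stack_validation` with elements `ok` and
#'   `violations` (character vector).
#' @export
validate_stack <- function(stack, registry, grid) {
  v <- character()
  for (ly in stack) {
    if (nrow(ly$values) != grid$n_rows || ncol(ly$values) != grid$n_cols)
      v <- c(v, sprintf("layer '%s': dimension mismatch (%dx%d vs %dx%d)",
                        ly$name, nrow(ly$values), ncol(ly$values),
                        grid$n_rows, grid$n_cols))
    vals <- ly$values[!is.na(ly$values)]
    if (ly$kind == "mask" && length(vals) && !all(vals %in% c(0, 1)))
      v <- c(v, sprintf("layer '%s': mask layer must be binary", ly$name))
    if (ly$kind == "year" && length(vals)) {
      bad <- vals != 0 & (vals < grid$year_start | vals > grid$year_end)
      if (any(bad))
        v <- c(v, sprintf("layer '%s': year outside window [%d, %d]",
                          ly$name, grid$year_start, grid$year_end))
    }
  }
  for (req in c("tcd", "loss_year"))
    if (is.null(stack[[req]]))
      v <- c(v, sprintf("required layer missing: %s", req))
  described <- unlist(lapply(registry, `[[`, "layer"))
  for (ly in stack) {
    if (ly$kind == "categorical" &&
        !ly$name %in% c(described, RESERVED_CATEGORICAL))
      v <- c(v, sprintf("undescribed dataset: categorical layer '%s' has no descriptor",
                        ly$name))
  }
  for (d in registry) {
    if (is.null(stack[[d$layer]])) {
      v <- c(v, sprintf("descriptor '%s': layer '%s' absent from stack",
                        d$id, d$layer))
      next
    }
    if (d$level != "fire") {
      codes <- unique(stack[[d$layer]]$values)
      codes <- codes[!is.na(codes) & codes != 0]
      bad <- setdiff(as.character(codes), names(d$class_map))
      if (length(bad))
        v <- c(v, sprintf("descriptor '%s': codes outside class map: %s",
                          d$id, paste(bad, collapse = ", ")))
    }
    if (d$annual && is.null(stack[[d$obs_year_layer]]))
      v <- c(v, sprintf("descriptor '%s': obs_year layer '%s' absent",
                        d$id, d$obs_year_layer))
  }
  structure(list(ok = length(v) == 0L, violations = v),
            class = "stack_validation")
}

#' @export
print.stack_validation <- function(x, ...) {
  if (x$ok) cat("<stack_validation> OK: no violations\n")
  else cat("<stack_validation>", length(x$violations), "violation(s):\n -",
           paste(x$violations, collapse = "\n - "), "\n")
  invisible(x)
}

# ---- registry serialization (YAML) ------------------------------------

registry_to_list <- function(registry) {
  lapply(registry, function(d) {
    d <- unclass(d)
    d$class_map <- as.list(d$class_map)
    d
  })
}

registry_from_list <- function(lst) {
  lapply(lst, function(d) {
    dataset_descriptor(
      id = d$id, level = d$level,
      class_map = unlist(d$class_map),
      overall_accuracy = d$overall_accuracy,
      spatial_score = d$spatial_score, temporal_score = d$temporal_score,
      explicitness_score = d$explicitness_score,
      last_valid_year = d$last_valid_year,
      annual = isTRUE(d$annual), layer = d$layer,
      obs_year_layer = d$obs_year_layer
    )
  })
}

#' Write / read a dataset registry
#'
#' @param registry List of [dataset_descriptor()]s.
#' @param path YAML file path.
#' @return `write_registry()` returns `path` invisibly; `read_registry()`
#'   returns the registry list.
#' @export
write_registry <- function(registry, path) {
  yaml::write_yaml(registry_to_list(registry), path)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  registry_from_list(yaml::read_yaml(path))
}
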