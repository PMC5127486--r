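#' Combine the eight standardized pressures into a footprint map
#'
#' Cellwise sum of the eight pressure layers. Before summing, the function
#' verifies that exactly one layer per pressure is supplied, that all layers
#' are co-registered, that each respects its scheme ceiling, and that the
#' land-use exclusion hierarchy holds (no crop or pasture score on built
#' cells, no pasture score on cropped cells). The sum is asserted, never
#' clamped, to stay within `[0, max_possible_score(scheme)]`, so a
#' misconfigured scheme surfaces as an error rather than a silently distorted
#' map. Output cells are nodata where any constituent is nodata.
#'
#' @param layers list of eight [pressure_layer()]s; if unnamed, names are
#'   taken from each layer.
#' @param scheme the [scoring_scheme()] the layers were built with.
#' @param year vintage stamped on the map (default: max of layer years).
#' @return A `footprint_map` with fields `year`, `scores` (`hf_grid`),
#'   `scheme`, and `provenance` (per-layer name/year).
#' @export
combine_pressures <- function(layers, scheme = scoring_scheme(),
                              year = NULL) {
  stopifnot(is.list(layers))
  if (!all(vapply(layers, inherits, TRUE, "pressure_layer")))
    stop("all elements of `layers` must be pressure_layer objects")
  nms <- vapply(layers, `[[`, "", "name")
  names(layers) <- nms
  missing <- setdiff(pressure_names(), nms)
  if (length(missing))
    stop("missing pressure layer(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(nms))
    stop("duplicate pressure layer(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  grids <- lapply(layers, `[[`, "scores")
  check_coregistered(grids)
  ceil <- pressure_ceilings(scheme)
  for (nm in pressure_names()) {
    v <- grids[[nm]]$values[!grids[[nm]]$nodata_mask]
    if (length(v) && (min(v) < -1e-9 || max(v) > ceil[[nm]] + 1e-9))
      stop(sprintf("layer '%s' exceeds its ceiling of %g", nm, ceil[[nm]]))
  }
  built <- grids$built$values; crops <- grids$crops$values
  pasture <- grids$pasture$values
  if (any(built > 0 & (crops > 0 | pasture > 0)))
    stop("exclusion violation: crop/pasture score on built cells")
  if (any(crops > 0 & pasture > 0))
    stop("exclusion violation: pasture score on cropped cells")
  total <- Reduce(`+`, lapply(grids, `[[`, "values"))
  nodata <- Reduce(`|`, lapply(grids, `[[`, "nodata_mask"))
  total[nodata] <- NA_real_
  mx <- max_possible_score(scheme)
  if (any(total[!nodata] > mx + 1e-9) || any(total[!nodata] < -1e-9))
    stop(sprintf("footprint outside [0, %g]: inconsistent layers or scheme", mx))
  g1 <- grids[[1]]
  yrs <- vapply(layers, `[[`, 1L, "year")
  structure(
    list(year = if (is.null(year)) suppressWarnings(max(yrs, na.rm = TRUE))
         else as.integer(year),
         scores = hf_grid(total, g1$cell_size_km, nodata, g1$origin),
         scheme = scheme,
         provenance = data.frame(layer = nms, year = yrs,
                                 row.names = NULL)),
    class = "footprint_map"
  )
}

#' @export
print.footprint_map <- function(x, ...) {
  cat(sprintf("<footprint_map> year %s, max possible %g\n", x$year,
              max_possible_score(x$scheme)))
  print(x$scores)
  invisible(x)
}

#' Sample footprint scores at plot locations
#'
#' Reads the footprint raster at plot cells, mirroring plot-wise extraction
#' of the mapped score for validation.
#'
#' @param footprint a `footprint_map` (or bare `hf_grid`).
#' @param rows,cols integer cell indices of the plots.
#' @return numeric vector of scores (`NA` on nodata cells).
#' @export
sample_footprint <- function(footprint, rows, cols) {
  g <- if (inherits(footprint, "footprint_map")) footprint$scores else footprint
  stopifnot(is_hf_grid(g), length(rows) == length(cols))
  v <- g$values[cbind(rows, cols)]
  v[g$nodata_mask[cbind(rows, cols)]] <- NA_real_
  v
}
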