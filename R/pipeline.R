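#' Run the full footprint pipeline
#'
#' Executes the three mapping steps — standardize each pressure, verify
#' co-registration, sum under the exclusion rules — and, when a validation
#' table is supplied, the plot-level accuracy assessment. Inputs are given
#' either as in-memory objects (an input list, e.g. a `landscape_bundle`) or
#' as file paths in a config; every stage failure is re-raised with the
#' failing stage named.
#'
#' @param inputs list with elements `dn_1994`, `dn_2009`, `population`,
#'   `crop_mask`, `pasture_pct`, `road_mask`, `rail_mask`, `coast_mask`,
#'   `lake_mask` (all `hf_grid`) and `streams` (a [stream_network()]); a
#'   `landscape_bundle` works directly. Grid elements may also be file paths
#'   readable by [read_grid()].
#' @param scheme a [scoring_scheme()]; scheme overrides are the way to run
#'   alternative weightings.
#' @param year which night-lights vintage drives the map: `1994` or `2009`.
#' @param calibration a `dn_calibration` applied to both vintages (default
#'   identity).
#' @param validation optional [validation_table()] (or path to one) for the
#'   accuracy assessment.
#' @param visual_max visual-score maximum for normalization.
#' @param out_dir optional directory; when given, all eight standardized
#'   layers, the footprint grid and a JSON report are written there.
#' @return list with `footprint` (a `footprint_map`), `layers` (named list of
#'   eight [pressure_layer()]s), `light_bins`, `navigable_reaches`,
#'   `validation` (or `NULL`) and `report` (the provenance/statistics list
#'   written as JSON).
#' @export
run_pipeline <- function(inputs, scheme = scoring_scheme(), year = 2009,
                         calibration = identity_calibration(
                           scheme$dn_exclusion_floor),
                         validation = NULL, visual_max = 10,
                         out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  need <- c("dn_1994", "dn_2009", "population", "crop_mask", "pasture_pct",
            "road_mask", "rail_mask", "coast_mask", "lake_mask", "streams")
  for (nm in need)
    if (is.null(inputs[[nm]])) stop(sprintf("input '%s' is missing", nm))
  grids <- stage("read-inputs", {
    lapply(inputs[setdiff(need, "streams")], function(x)
      if (is_hf_grid(x)) x else read_grid(x))
  })
  streams <- inputs$streams
  stage("coregistration", check_coregistered(grids))

  yr <- as.integer(year)
  dn_raw <- if (yr <= 2000) grids$dn_1994 else grids$dn_2009
  dn_cal <- stage("calibrate-lights", apply_dn_calibration(dn_raw, calibration))
  dn_ref <- stage("calibrate-lights",
                  apply_dn_calibration(grids$dn_1994, calibration))

  built <- stage("score-built", score_built(dn_cal, scheme, yr))
  pop <- stage("score-pop", score_population(grids$population, scheme, yr))
  bins <- stage("light-bins", compute_light_bins(dn_ref, scheme))
  lights <- stage("score-lights", score_lights(dn_cal, bins, scheme, yr))
  crops <- stage("score-crops", score_crops(grids$crop_mask, built, scheme, yr))
  pasture <- stage("score-pasture",
                   score_pasture(grids$pasture_pct, built, crops, scheme, yr))
  roads <- stage("score-roads", score_roads(grids$road_mask, scheme, yr))
  rails <- stage("score-rail", score_railways(grids$rail_mask, scheme, yr))

  navwater <- stage("score-navwater", {
    nav_coast <- navigable_coast(grids$coast_mask, dn_cal, scheme)
    nav_lake <- navigable_coast(grids$lake_mask, dn_cal, scheme)
    shore <- hf_grid(pmax(nav_coast$values, nav_lake$values),
                     nav_coast$cell_size_km, nav_coast$nodata_mask,
                     nav_coast$origin)
    reach_ids <- navigable_rivers(streams, dn_cal, shore, scheme)
    rivers <- rasterize_reaches(streams, reach_ids, dn_cal)
    navmask <- hf_grid(pmax(shore$values, rivers$values),
                       shore$cell_size_km, shore$nodata_mask, shore$origin)
    list(layer = score_navwater(navmask, scheme, yr), reach_ids = reach_ids)
  })

  layers <- list(built = built, population = pop, lights = lights,
                 crops = crops, pasture = pasture, roads = roads,
                 railways = rails, navwater = navwater$layer)
  fp <- stage("combine", combine_pressures(layers, scheme, yr))

  val <- NULL
  if (!is.null(validation)) {
    tab <- if (inherits(validation, "validation_table")) validation
      else read_validation_table(validation)
    val <- stage("validate", validate_footprint(fp, tab, visual_max))
  }

  report <- list(
    year = yr,
    scheme = unclass(scheme),
    light_bins = bins,
    navigable_reaches = navwater$reach_ids,
    max_possible_score = max_possible_score(scheme),
    layer_checksums = lapply(layers, function(l) grid_checksum(l$scores)),
    footprint_checksum = grid_checksum(fp$scores),
    score_range = range(fp$scores$values[!fp$scores$nodata_mask]),
    validation = if (!is.null(val)) val[setdiff(names(val), "table")]
  )

  if (!is.null(out_dir)) {
    stage("write-outputs", {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      for (nm in names(layers))
        write_pressure_layer(layers[[nm]],
                             file.path(out_dir, paste0(nm, yr, ".asc")))
      write_grid(fp$scores, file.path(out_dir, paste0("footprint", yr, ".asc")))
      jsonlite::write_json(report, file.path(out_dir, "report.json"),
                           auto_unbox = TRUE, digits = 10, pretty = TRUE,
                           null = "null")
    })
  }
  list(footprint = fp, layers = layers, light_bins = bins,
       navigable_reaches = navwater$reach_ids, validation = val,
       report = report)
}
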