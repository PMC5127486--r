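#' Standardized pressure layer
#'
#' A named, year-stamped grid of standardized scores, bounded above by the
#' scheme weight for that pressure.
#'
#' @param name one of [pressure_names()].
#' @param year integer vintage of the underlying data.
#' @param scores an `hf_grid` of standardized scores.
#' @param max_score ceiling this layer must respect.
#' @param provenance optional free-form character (source dataset, filters).
#' @return A `pressure_layer`.
#' @export
pressure_layer <- function(name, year, scores, max_score,
                           provenance = character()) {
  name <- match.arg(name, pressure_names())
  stopifnot(is_hf_grid(scores))
  v <- scores$values[!scores$nodata_mask]
  if (length(v) && (min(v) < -1e-9 || max(v) > max_score + 1e-9))
    stop(sprintf("layer '%s' violates its score bounds [0, %g]",
                 name, max_score))
  structure(list(name = name, year = as.integer(year), scores = scores,
                 max_score = max_score, provenance = provenance),
            class = "pressure_layer")
}

#' @export
print.pressure_layer <- function(x, ...) {
  cat(sprintf("<pressure_layer> %s (%d), max %g\n", x$name, x$year,
              x$max_score))
  print(x$scores)
  invisible(x)
}

#' Fit a night-lights intercalibration quadratic
#'
#' Satellite night-light composites from different years are made comparable
#' by remapping raw digital numbers (DN) through a second-order polynomial
#' fitted on a reference region assumed unchanged between the years. Fits
#' `target = c0 + c1 * raw + c2 * raw^2` by least squares.
#'
#' @param reference_pairs data frame (or 2-column matrix) with columns
#'   `raw` and `target`, all raw DN above the exclusion floor.
#' @param dn_exclusion_floor DN at or below which values are excluded before
#'   calibration.
#' @return A `dn_calibration` with coefficients `c0`, `c1`, `c2`.
#' @export
fit_dn_calibration <- function(reference_pairs, dn_exclusion_floor = 6) {
  rp <- as.data.frame(reference_pairs)
  if (ncol(rp) < 2) stop("reference_pairs needs columns raw and target")
  if (is.null(rp$raw)) { names(rp)[1:2] <- c("raw", "target") }
  if (length(unique(rp$raw)) < 3)
    stop("calibration is underdetermined: need >= 3 distinct raw DN values")
  if (any(rp$raw <= dn_exclusion_floor))
    stop("all raw DN must exceed the exclusion floor")
  fit <- stats::lm(target ~ raw + I(raw^2), data = rp)
  co <- unname(stats::coef(fit))
  structure(list(c0 = co[1], c1 = co[2], c2 = co[3],
                 dn_exclusion_floor = dn_exclusion_floor),
            class = "dn_calibration")
}

#' Identity DN calibration
#'
#' Used when a single composite is analysed or calibration pairs are
#' unavailable.
#' @param dn_exclusion_floor see [fit_dn_calibration()].
#' @return A `dn_calibration` mapping DN to itself.
#' @export
identity_calibration <- function(dn_exclusion_floor = 6) {
  structure(list(c0 = 0, c1 = 1, c2 = 0,
                 dn_exclusion_floor = dn_exclusion_floor),
            class = "dn_calibration")
}

#' Apply a DN calibration to a night-lights grid
#'
#' DN at or below the exclusion floor are set to 0 before calibration (the
#' quadratic badly distorts very low DN); remaining values are mapped through
#' the quadratic and clamped to the valid DN range `[0, 63]`.
#'
#' @param dn `hf_grid` of raw DN in `[0, 63]`.
#' @param model a `dn_calibration`.
#' @return `hf_grid` of calibrated DN.
#' @export
apply_dn_calibration <- function(dn, model) {
  stopifnot(is_hf_grid(dn), inherits(model, "dn_calibration"))
  v <- dn$values
  ok <- !dn$nodata_mask
  if (any(v[ok] < 0 | v[ok] > 63)) stop("raw DN must lie in [0, 63]")
  out <- ifelse(v <= model$dn_exclusion_floor, 0,
                pmin(pmax(model$c0 + model$c1 * v + model$c2 * v^2, 0), 63))
  out[!ok] <- 0
  hf_grid(out, dn$cell_size_km, dn$nodata_mask, dn$origin)
}

#' Score built environments from calibrated night lights
#'
#' Cells with calibrated DN at or above the built threshold (default 20) are
#' classed as built and receive the full built-environment score.
#'
#' @param calibrated_dn `hf_grid` of calibrated DN.
#' @param scheme a [scoring_scheme()].
#' @param year data vintage for the layer stamp.
#' @return A `pressure_layer` named `"built"`.
#' @export
score_built <- function(calibrated_dn, scheme = scoring_scheme(),
                        year = NA_integer_) {
  stopifnot(is_hf_grid(calibrated_dn))
  s <- ifelse(calibrated_dn$values >= scheme$dn_built_threshold,
              scheme$built_score, 0)
  s[calibrated_dn$nodata_mask] <- 0
  pressure_layer("built", year,
                 hf_grid(s, calibrated_dn$cell_size_km,
                         calibrated_dn$nodata_mask, calibrated_dn$origin),
                 scheme$built_score)
}

#' Score population density
#'
#' Pressure rises logarithmically with density and saturates:
#' `score = min(10, 3.333 * log10(density + 1))`, with a score of 10 assigned
#' at and above the saturation density (default 1000 people/km2). The default
#' coefficient makes the curve continuous at saturation to within 0.001.
#'
#' @param density `hf_grid` of people per km2, non-negative.
#' @param scheme a [scoring_scheme()].
#' @param year data vintage.
#' @return A `pressure_layer` named `"population"`.
#' @export
score_population <- function(density, scheme = scoring_scheme(),
                             year = NA_integer_) {
  stopifnot(is_hf_grid(density))
  d <- density$values
  if (any(d[!density$nodata_mask] < 0)) stop("population density must be >= 0")
  s <- pmin(scheme$pop_coefficient * log10(d + 1), 10)
  s[d >= scheme$pop_saturation_density] <- 10
  s[density$nodata_mask] <- 0
  pressure_layer("population", year,
                 hf_grid(s, density$cell_size_km, density$nodata_mask,
                         density$origin),
                 10)
}

#' Equal-count DN bin thresholds from a reference night-lights grid
#'
#' Splits the above-floor calibrated DN of the reference year into
#' `lights_bins` bins of equal cell count (upper-bound thresholds; ties can
#' make counts unequal and degenerate duplicated thresholds are flagged with
#' a warning). The same thresholds are then applied to every other year so
#' scores stay comparable over time.
#'
#' @param calibrated_dn_reference `hf_grid` of calibrated DN (the reference
#'   year).
#' @param scheme a [scoring_scheme()].
#' @return numeric vector of `lights_bins` non-decreasing thresholds.
#' @export
compute_light_bins <- function(calibrated_dn_reference,
                               scheme = scoring_scheme()) {
  stopifnot(is_hf_grid(calibrated_dn_reference))
  g <- calibrated_dn_reference
  v <- g$values[!g$nodata_mask]
  v <- v[v > scheme$dn_exclusion_floor]
  k <- scheme$lights_bins
  if (length(v) < k)
    stop(sprintf("need at least %d cells above the DN exclusion floor", k))
  thr <- unname(stats::quantile(v, probs = seq_len(k) / k, type = 1))
  if (any(diff(thr) <= 0))
    warning("degenerate light-bin thresholds: heavy ties in the reference DN")
  thr
}

#' Score night-time lights by reference-year bins
#'
#' DN at or below the exclusion floor score 0; other cells score the index
#' (1..bins) of the first bin whose upper threshold is at or above their DN
#' (ties at a threshold fall in the lower bin); DN above the top threshold
#' score the top bin.
#'
#' @param calibrated_dn `hf_grid` of calibrated DN.
#' @param thresholds output of [compute_light_bins()].
#' @param scheme a [scoring_scheme()].
#' @param year data vintage.
#' @return A `pressure_layer` named `"lights"`.
#' @export
score_lights <- function(calibrated_dn, thresholds,
                         scheme = scoring_scheme(), year = NA_integer_) {
  stopifnot(is_hf_grid(calibrated_dn))
  if (is.unsorted(thresholds)) stop("thresholds must be non-decreasing")
  if (length(thresholds) != scheme$lights_bins)
    stop("thresholds length must equal the number of bins")
  v <- calibrated_dn$values
  k <- scheme$lights_bins
  # bin = 1 + number of strictly exceeded thresholds among the first k-1
  excl <- v <= scheme$dn_exclusion_floor | calibrated_dn$nodata_mask
  b <- matrix(1, nrow(v), ncol(v))
  for (t in thresholds[-k]) b <- b + (v > t)
  b[excl] <- 0
  pressure_layer("lights", year,
                 hf_grid(b, calibrated_dn$cell_size_km,
                         calibrated_dn$nodata_mask, calibrated_dn$origin),
                 k)
}

#' Score croplands, excluding built cells
#'
#' @param crop_mask `hf_grid` 0/1 cropland mask.
#' @param built the `"built"` [pressure_layer()] for the same year.
#' @param scheme a [scoring_scheme()].
#' @param year data vintage.
#' @return A `pressure_layer` named `"crops"`.
#' @export
score_crops <- function(crop_mask, built, scheme = scoring_scheme(),
                        year = NA_integer_) {
  stopifnot(is_hf_grid(crop_mask), inherits(built, "pressure_layer"))
  check_coregistered(crop_mask, built$scores)
  s <- ifelse(crop_mask$values > 0 & built$scores$values == 0,
              scheme$crop_score, 0)
  s[crop_mask$nodata_mask] <- 0
  pressure_layer("crops", year,
                 hf_grid(s, crop_mask$cell_size_km, crop_mask$nodata_mask,
                         crop_mask$origin),
                 scheme$crop_score)
}

#' Score pasture lands by percent cover, excluding built and cropped cells
#'
#' @param pct_pasture `hf_grid` of percent pasture cover in `[0, 100]`.
#' @param built,crops the built and crops [pressure_layer()]s.
#' @param scheme a [scoring_scheme()].
#' @param year data vintage.
#' @return A `pressure_layer` named `"pasture"`.
#' @export
score_pasture <- function(pct_pasture, built, crops,
                          scheme = scoring_scheme(), year = NA_integer_) {
  stopifnot(is_hf_grid(pct_pasture), inherits(built, "pressure_layer"),
            inherits(crops, "pressure_layer"))
  check_coregistered(pct_pasture, built$scores, crops$scores)
  p <- pct_pasture$values
  ok <- !pct_pasture$nodata_mask
  if (any(p[ok] < 0 | p[ok] > 100)) stop("percent pasture must lie in [0, 100]")
  s <- ifelse(built$scores$values == 0 & crops$scores$values == 0,
              scheme$pasture_max * p / 100, 0)
  s[!ok] <- 0
  pressure_layer("pasture", year,
                 hf_grid(s, pct_pasture$cell_size_km,
                         pct_pasture$nodata_mask, pct_pasture$origin),
                 scheme$pasture_max)
}

# direct + access road scoring on a precomputed distance grid; exposed so the
# band structure can be checked at sub-cell distances
road_score_from_distance <- function(dist, scheme) {
  kp <- decay_kernel_params(scheme$road_access_max, scheme$direct_halfwidth_km,
                            scheme$decay_dmax_km, scheme$decay_floor)
  access <- apply_decay(dist, kp)$values
  s <- ifelse(dist$values < scheme$direct_halfwidth_km,
              scheme$road_direct, access)
  s[dist$nodata_mask] <- 0
  hf_grid(s, dist$cell_size_km, dist$nodata_mask, dist$origin)
}

#' Score roads: direct band plus exponential access decay
#'
#' Cells within the direct half-width (default 0.5 km) of a road carry the
#' direct score of 8; beyond it, an access score of 4 decays exponentially,
#' reaching zero by 15 km. At exactly the half-width the access value (4)
#' applies.
#'
#' @param road_mask `hf_grid` 0/1 rasterized road mask.
#' @param scheme a [scoring_scheme()].
#' @param year data vintage.
#' @return A `pressure_layer` named `"roads"`. An empty mask yields an
#'   all-zero layer with a warning.
#' @export
score_roads <- function(road_mask, scheme = scoring_scheme(),
                        year = NA_integer_) {
  stopifnot(is_hf_grid(road_mask))
  if (!any(road_mask$values > 0 & !road_mask$nodata_mask)) {
    warning("road mask is empty: returning an all-zero roads layer")
    z <- hf_grid(array(0, dim(road_mask$values)), road_mask$cell_size_km,
                 road_mask$nodata_mask, road_mask$origin)
    return(pressure_layer("roads", year, z,
                          max(scheme$road_direct, scheme$road_access_max)))
  }
  s <- road_score_from_distance(distance_map(road_mask), scheme)
  pressure_layer("roads", year, s,
                 max(scheme$road_direct, scheme$road_access_max))
}

#' Score railways: direct band only
#'
#' Railways carry the direct score within the half-width but no access decay:
#' passengers rarely disembark outside stations, so rail lines do not open
#' the adjacent landscape the way roads do.
#'
#' @param rail_mask `hf_grid` 0/1 rasterized railway mask.
#' @param scheme a [scoring_scheme()].
#' @param year data vintage.
#' @return A `pressure_layer` named `"railways"`; all-zero (with a warning)
#'   on an empty mask.
#' @export
score_railways <- function(rail_mask, scheme = scoring_scheme(),
                           year = NA_integer_) {
  stopifnot(is_hf_grid(rail_mask))
  if (!any(rail_mask$values > 0 & !rail_mask$nodata_mask)) {
    warning("rail mask is empty: returning an all-zero railways layer")
    z <- hf_grid(array(0, dim(rail_mask$values)), rail_mask$cell_size_km,
                 rail_mask$nodata_mask, rail_mask$origin)
    return(pressure_layer("railways", year, z, scheme$rail_direct))
  }
  d <- distance_map(rail_mask)
  s <- ifelse(d$values < scheme$direct_halfwidth_km, scheme$rail_direct, 0)
  s[d$nodata_mask] <- 0
  pressure_layer("railways", year,
                 hf_grid(s, d$cell_size_km, d$nodata_mask, d$origin),
                 scheme$rail_direct)
}
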