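#' Pressure scoring scheme
#'
#' The weights, thresholds and kernel parameters that standardize the eight
#' human pressures onto a common 0-10 scale. Defaults follow the published
#' pressure scheme: built environments 10; population density saturating at
#' 10 for >= 1000 people/km2 via `3.333 * log10(density + 1)`; night-time
#' lights binned into 10 equal-count classes scored 1-10; croplands 7;
#' pasture 0-4 by percent cover; roads 8 direct within 0.5 km plus an access
#' score of 4 decaying exponentially out to 15 km; railways 8 direct only;
#' navigable waterways 4 decaying out to 15 km. Every value can be
#' overridden, so alternative weightings can be mapped with the same
#' pipeline.
#'
#' @param built_score score for built cells (DN at or above
#'   `dn_built_threshold`).
#' @param crop_score score for cropland cells not already built.
#' @param pasture_max score at 100 percent pasture cover (linear in cover).
#' @param road_direct,rail_direct direct score within `direct_halfwidth_km`
#'   of a road / railway.
#' @param road_access_max,nav_access_max access-kernel plateau for roads /
#'   navigable water.
#' @param pop_coefficient,pop_saturation_density coefficient and saturation
#'   density (people/km2) of the logarithmic population scoring.
#' @param lights_bins number of equal-count night-lights bins.
#' @param dn_built_threshold calibrated DN at or above which a cell is built.
#' @param dn_exclusion_floor DN at or below which night-lights are dropped
#'   before calibration and binning.
#' @param nav_dn_threshold DN at or above which a lit cell counts as a
#'   settlement signal for waterway navigability.
#' @param nav_search_km search radius (km) for settlement signals near water.
#' @param nav_range_km along-network / along-coast navigability propagation
#'   range, km.
#' @param nav_depth_threshold_m minimum stream depth (m, exclusive) for boat
#'   traffic.
#' @param direct_halfwidth_km half-width of the direct road/rail band, km.
#' @param decay_dmax_km truncation distance of the access kernels, km.
#' @param decay_floor kernel value below which access scores are zeroed.
#' @return A `scoring_scheme` list.
#' @examples
#' sch <- scoring_scheme()
#' max_possible_score(sch)
#' @export
scoring_scheme <- function(built_score = 10,
                           crop_score = 7,
                           pasture_max = 4,
                           road_direct = 8,
                           road_access_max = 4,
                           rail_direct = 8,
                           nav_access_max = 4,
                           pop_coefficient = 3.333,
                           pop_saturation_density = 1000,
                           lights_bins = 10,
                           dn_built_threshold = 20,
                           dn_exclusion_floor = 6,
                           nav_dn_threshold = 6,
                           nav_search_km = 4,
                           nav_range_km = 80,
                           nav_depth_threshold_m = 2,
                           direct_halfwidth_km = 0.5,
                           decay_dmax_km = 15,
                           decay_floor = road_access_max / 16) {
  sch <- list(built_score = built_score, crop_score = crop_score,
              pasture_max = pasture_max, road_direct = road_direct,
              road_access_max = road_access_max, rail_direct = rail_direct,
              nav_access_max = nav_access_max,
              pop_coefficient = pop_coefficient,
              pop_saturation_density = pop_saturation_density,
              lights_bins = lights_bins,
              dn_built_threshold = dn_built_threshold,
              dn_exclusion_floor = dn_exclusion_floor,
              nav_dn_threshold = nav_dn_threshold,
              nav_search_km = nav_search_km,
              nav_range_km = nav_range_km,
              nav_depth_threshold_m = nav_depth_threshold_m,
              direct_halfwidth_km = direct_halfwidth_km,
              decay_dmax_km = decay_dmax_km,
              decay_floor = decay_floor)
  scores <- c(built_score, crop_score, pasture_max, road_direct,
              road_access_max, rail_direct, nav_access_max)
  if (any(scores < 0 | scores > 10))
    stop("every pressure score/weight must lie in [0, 10]")
  if (pop_saturation_density <= 0 || dn_built_threshold <= 0 ||
      nav_search_km <= 0 || nav_range_km <= 0 || nav_depth_threshold_m <= 0 ||
      direct_halfwidth_km <= 0 || decay_dmax_km <= 0 || lights_bins < 1)
    stop("thresholds must be positive")
  structure(sch, class = "scoring_scheme")
}

#' Names of the eight pressures in a footprint
#' @return character vector of canonical layer names.
#' @export
pressure_names <- function() {
  c("built", "population", "lights", "crops", "pasture",
    "roads", "railways", "navwater")
}

# per-pressure ceilings under a scheme, in pressure_names() order
pressure_ceilings <- function(scheme) {
  c(built = scheme$built_score,
    population = 10,
    lights = scheme$lights_bins,
    crops = scheme$crop_score,
    pasture = scheme$pasture_max,
    roads = max(scheme$road_direct, scheme$road_access_max),
    railways = scheme$rail_direct,
    navwater = scheme$nav_access_max)
}

#' Maximum attainable cumulative footprint score
#'
#' Enumerates the eight per-pressure maxima over all combinations feasible
#' under the land-use exclusion hierarchy (crops score 0 on built cells;
#' pasture scores 0 on built or cropped cells) and returns the largest
#' cellwise sum. Under the default scheme this is 50: built 10 + population
#' 10 + lights 10 + roads 8 + railways 8 + navigable water 4, with crops and
#' pasture excluded by the built cell.
#'
#' @param scheme a [scoring_scheme()].
#' @param exclusions if `FALSE`, ignore the exclusion hierarchy and sum all
#'   eight maxima (61 under the default scheme).
#' @param include pressures counted; defaults to all eight.
#' @return a single number.
#' @export
max_possible_score <- function(scheme = scoring_scheme(), exclusions = TRUE,
                               include = pressure_names()) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  include <- match.arg(include, pressure_names(), several.ok = TRUE)
  ceil <- pressure_ceilings(scheme)
  ceil[setdiff(pressure_names(), include)] <- 0
  always <- ceil[["population"]] + ceil[["lights"]] + ceil[["roads"]] +
    ceil[["railways"]] + ceil[["navwater"]]
  best <- -Inf
  for (b in c(0, 1)) for (cr in c(0, 1)) for (p in c(0, 1)) {
    if (exclusions) {
      if (cr == 1 && b == 1) next
      if (p == 1 && (b == 1 || cr == 1)) next
    }
    s <- b * ceil[["built"]] + cr * ceil[["crops"]] +
      p * ceil[["pasture"]] + always
    if (s > best) best <- s
  }
  best
}
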