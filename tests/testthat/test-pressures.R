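sch <- scoring_scheme()

grid_of <- function(v, nr = NULL) {
  if (is.null(nr)) nr <- floor(sqrt(length(v)))
  nc <- ceiling(length(v) / nr)
  hf_grid(matrix(c(v, rep(0, nr * nc - length(v))), nr, nc), 1)
}

test_that("DN calibration recovers identity and synthetic quadratics", {
  raw <- seq(7, 60, by = 1)
  ident <- fit_dn_calibration(data.frame(raw = raw, target = raw))
  expect_equal(c(ident$c0, ident$c1, ident$c2), c(0, 1, 0), tolerance = 1e-10)
  truth <- c(2, 0.9, 0.001)
  tgt <- truth[1] + truth[2] * raw + truth[3] * raw^2
  fit <- fit_dn_calibration(data.frame(raw = raw, target = tgt))
  expect_equal(c(fit$c0, fit$c1, fit$c2), truth, tolerance = 1e-8)
  expect_error(fit_dn_calibration(data.frame(raw = c(10, 20),
                                             target = c(10, 20))),
               "underdetermined")
  # noisy pairs: least-squares recovery within tolerance
  set.seed(3)
  fitn <- fit_dn_calibration(data.frame(raw = raw,
                                        target = tgt + rnorm(length(raw), 0, 0.5)))
  expect_equal(c(fitn$c0, fitn$c1, fitn$c2), truth, tolerance = 0.2)
})

test_that("applying a calibration zeroes the exclusion floor and clamps", {
  g <- grid_of(c(0, 6, 7, 30, 63), nr = 1)
  cal <- apply_dn_calibration(g, identity_calibration())
  expect_equal(cal$values[1, 1:4], c(0, 0, 7, 30))
  big <- fit_dn_calibration(data.frame(raw = c(10, 30, 50),
                                       target = c(30, 80, 160)))
  expect_true(all(apply_dn_calibration(g, big)$values <= 63))
  expect_error(apply_dn_calibration(grid_of(c(70, 0, 0, 0)),
                                    identity_calibration()), "\\[0, 63\\]")
})

test_that("built scoring thresholds calibrated DN at 20", {
  g <- grid_of(c(0, 19, 20, 63))
  built <- score_built(g, sch)
  expect_equal(as.vector(built$scores$values), c(0, 19 >= 20, 1, 1) * 10)
  expect_equal(built$max_score, 10)
})

test_that("population scoring follows the log curve and saturates at 10", {
  g <- grid_of(c(0, 9, 999, 1000, 5000, 1e5), nr = 2)
  p <- score_population(g, sch)
  v <- p$scores$values
  expect_equal(v[1, 1], 0)
  expect_equal(v[2, 1], 3.333 * log10(10))
  expect_equal(as.vector(v)[4:6], c(10, 10, 10))  # 1000, 5000, 1e5 people/km2
  expect_lte(v[1, 2], 10)
  expect_error(score_population(grid_of(c(-1, 0, 0, 0)), sch), ">= 0")
})

test_that("population score is monotone and continuous at saturation", {
  d <- sort(c(10^seq(-2, 3.2, length.out = 200), 999.9999, 1000))
  g <- hf_grid(matrix(d, 1), 1)
  v <- as.vector(score_population(g, sch)$scores$values)
  expect_true(all(diff(v) >= -1e-12))
  expect_lt(abs(3.333 * log10(1001) - 10), 0.001)
  expect_lt(abs(v[length(v)] - v[length(v) - 1]), 0.001)
})

test_that("light bins are equal-count and match a sort-and-slice oracle", {
  set.seed(5)
  v <- runif(1000, 7, 56)
  g <- hf_grid(matrix(v, 25, 40), 1)
  thr <- compute_light_bins(g, sch)
  srt <- sort(v)
  expect_equal(thr, srt[ceiling((1:10) * length(v) / 10)])
  lights <- score_lights(g, thr, sch)
  counts <- table(lights$scores$values)
  expect_true(all(abs(counts - 100) <= 1))
  expect_equal(sort(unique(as.vector(lights$scores$values))), 1:10)
})

test_that("light binning flags degeneracy and insufficient data", {
  g <- hf_grid(matrix(7, 4, 5), 1)
  expect_warning(compute_light_bins(g, sch), "degenerate")
  small <- hf_grid(matrix(c(rep(0, 20), 8, 9, 10), 1), 1)
  expect_error(compute_light_bins(small, sch), "at least 10")
})

test_that("lights scoring handles the floor, top bin and the rank oracle", {
  set.seed(6)
  ref <- runif(500, 7, 56)
  gref <- hf_grid(matrix(ref, 20, 25), 1)
  thr <- compute_light_bins(gref, sch)
  g <- grid_of(c(0, 6, 70, thr[1], thr[10]), nr = 1)
  s <- score_lights(g, thr, sch)$scores$values
  expect_equal(s[1, 1:3], c(0, 0, 10))
  expect_equal(s[1, 4], 1)   # tie at a threshold goes to the lower bin
  expect_equal(s[1, 5], 10)
  # rank oracle: score = bin of the cell's rank in the reference distribution
  probe <- runif(200, 0, 70)
  got <- as.vector(score_lights(hf_grid(matrix(probe, 10, 20), 1), thr,
                                sch)$scores$values)
  want <- vapply(probe, function(x) {
    if (x <= 6) return(0)
    min(which(x <= c(thr[1:9], Inf)))
  }, 0)
  expect_equal(got, want)
  expect_error(score_lights(g, rev(thr), sch), "non-decreasing")
})

test_that("crop scoring applies the built exclusion", {
  crop <- grid_of(c(1, 1, 0, 0))
  built <- score_built(grid_of(c(0, 25, 0, 25)), sch)
  s <- score_crops(crop, built, sch)$scores$values
  expect_equal(as.vector(s), c(7, 0, 0, 0))
})

test_that("pasture scoring weights by cover and applies both exclusions", {
  pct <- grid_of(c(100, 50, 100, 100))
  built <- score_built(grid_of(c(0, 0, 25, 0)), sch)
  crop <- score_crops(grid_of(c(0, 0, 0, 1)), built, sch)
  s <- score_pasture(pct, built, crop, sch)$scores$values
  expect_equal(as.vector(s), c(4, 2, 0, 0))
  expect_error(score_pasture(grid_of(c(150, 0, 0, 0)), built, crop, sch),
               "\\[0, 100\\]")
})

test_that("road scoring has an 8-band, a 4-plateau at 0.5 km, zero past 15 km", {
  m <- matrix(FALSE, 7, 35); m[4, 1] <- TRUE
  roads <- score_roads(hf_grid(m, 1), sch)
  v <- roads$scores$values
  expect_equal(v[4, 1], 8)        # on the road
  expect_equal(v[4, 17], 0)       # 16 km out: beyond truncation
  expect_true(all(v <= 8))
  # sub-cell band structure via the distance-based scorer
  d <- hf_grid(matrix(c(0, 0.49, 0.5, 15, 15.01, 20), 1), 1)
  b <- footprintr:::road_score_from_distance(d, sch)$values
  expect_equal(as.vector(b), c(8, 8, 4, 0.25, 0, 0))
  expect_warning(z <- score_roads(hf_grid(matrix(FALSE, 4, 4), 1), sch),
                 "empty")
  expect_true(all(z$scores$values == 0))
})

test_that("railways carry no access pressure beyond the direct band", {
  m <- matrix(FALSE, 5, 9); m[3, 5] <- TRUE
  rails <- score_railways(hf_grid(m, 1), sch)
  v <- rails$scores$values
  expect_equal(v[3, 5], 8)
  expect_equal(v[3, 6], 0)   # 1 km away
  expect_true(all(v %in% c(0, 8)))
})

test_that("every standardizer respects its scheme ceiling", {
  b <- make_landscape(9, 48)
  cal <- apply_dn_calibration(b$dn_1994, identity_calibration())
  built <- score_built(cal, sch)
  crops <- score_crops(b$crop_mask, built, sch)
  layers <- list(
    built = built,
    population = score_population(b$population, sch),
    lights = score_lights(cal, compute_light_bins(cal, sch), sch),
    crops = crops,
    pasture = score_pasture(b$pasture_pct, built, crops, sch),
    roads = score_roads(b$road_mask, sch),
    railways = score_railways(b$rail_mask, sch))
  caps <- c(built = 10, population = 10, lights = 10, crops = 7,
            pasture = 4, roads = 8, railways = 8)
  for (nm in names(layers))
    expect_lte(max(layers[[nm]]$scores$values), caps[[nm]])
})
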