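sch <- scoring_scheme()

# hand-build a consistent set of 8 one-cell layers from raw score values
layers_from_scores <- function(s, nr = 1, nc = 1) {
  mk <- function(name, x, mx)
    pressure_layer(name, 2009, hf_grid(matrix(x, nr, nc), 1), mx)
  list(built = mk("built", s[["built"]], 10),
       population = mk("population", s[["population"]], 10),
       lights = mk("lights", s[["lights"]], 10),
       crops = mk("crops", s[["crops"]], 7),
       pasture = mk("pasture", s[["pasture"]], 4),
       roads = mk("roads", s[["roads"]], 8),
       railways = mk("railways", s[["railways"]], 8),
       navwater = mk("navwater", s[["navwater"]], 4))
}

test_that("the scheme-level maxima reproduce 50, 61 and single-pressure cases", {
  expect_equal(max_possible_score(sch), 50)
  expect_equal(max_possible_score(sch, exclusions = FALSE), 61)
  expect_equal(max_possible_score(sch, include = "pasture"), 4)
  expect_equal(max_possible_score(sch, include = c("built", "crops")), 10)
})

test_that("max_possible_score agrees with brute-force enumeration", {
  set.seed(31)
  for (rep in 1:10) {
    s <- scoring_scheme(built_score = sample(0:10, 1),
                        crop_score = sample(0:10, 1),
                        pasture_max = sample(0:10, 1),
                        road_direct = sample(0:10, 1),
                        rail_direct = sample(0:10, 1),
                        nav_access_max = sample(0:10, 1))
    fixed <- 10 + s$lights_bins + max(s$road_direct, s$road_access_max) +
      s$rail_direct + s$nav_access_max
    combos <- expand.grid(b = 0:1, cr = 0:1, p = 0:1)
    ok <- with(combos, !(cr & b) & !(p & (b | cr)))
    want <- max(with(combos[ok, ], b * s$built_score + cr * s$crop_score +
                                     p * s$pasture_max)) + fixed
    expect_equal(max_possible_score(s), want)
  }
})

test_that("combining all-zero layers gives an all-zero map", {
  zero <- stats::setNames(rep(0, 8), pressure_names())
  fp <- combine_pressures(layers_from_scores(zero), sch)
  expect_true(all(fp$scores$values == 0))
  expect_s3_class(fp, "footprint_map")
})

test_that("a maximally pressured built cell sums to 50, a cropped one to 47", {
  s50 <- c(built = 10, population = 10, lights = 10, crops = 0, pasture = 0,
           roads = 8, railways = 8, navwater = 4)
  expect_equal(combine_pressures(layers_from_scores(s50), sch)$scores$values[1, 1],
               50)
  s47 <- s50; s47["built"] <- 0; s47["crops"] <- 7
  expect_equal(combine_pressures(layers_from_scores(s47), sch)$scores$values[1, 1],
               47)
})

test_that("combine is additive and monotone in its layers", {
  set.seed(32)
  vals <- c(built = 0, population = 6.2, lights = 3, crops = 7,
            pasture = 0, roads = 2.5, railways = 0, navwater = 1.1)
  base <- combine_pressures(layers_from_scores(vals), sch)
  doubled <- vals; doubled["roads"] <- 5
  fp2 <- combine_pressures(layers_from_scores(doubled), sch)
  expect_equal(fp2$scores$values - base$scores$values,
               matrix(2.5, 1, 1))
  # monotone: raising any single layer never decreases the total
  for (nm in c("population", "lights", "navwater")) {
    up <- vals; up[nm] <- up[nm] + 0.5
    expect_gte(combine_pressures(layers_from_scores(up),
                                 sch)$scores$values[1, 1],
               base$scores$values[1, 1])
  }
})

test_that("combine rejects missing, duplicate and inconsistent layers", {
  zero <- stats::setNames(rep(0, 8), pressure_names())
  ls <- layers_from_scores(zero)
  expect_error(combine_pressures(ls[-3], sch), "missing pressure.*lights")
  expect_error(combine_pressures(c(ls, ls[3]), sch), "duplicate")
  bad <- ls
  bad$roads <- pressure_layer("roads", 2009, hf_grid(matrix(9, 1, 1), 1), 9)
  expect_error(combine_pressures(bad, sch), "ceiling")
  mis <- ls
  mis$crops <- pressure_layer("crops", 2009, hf_grid(matrix(0, 2, 2), 1), 7)
  expect_error(combine_pressures(mis, sch), "misregistered")
})

test_that("combine enforces the exclusion hierarchy", {
  s <- stats::setNames(rep(0, 8), pressure_names())
  s["built"] <- 10; s["crops"] <- 7
  expect_error(combine_pressures(layers_from_scores(s), sch), "exclusion")
  s2 <- stats::setNames(rep(0, 8), pressure_names())
  s2["crops"] <- 7; s2["pasture"] <- 2
  expect_error(combine_pressures(layers_from_scores(s2), sch), "exclusion")
})

test_that("nodata propagates from any constituent layer", {
  zero <- stats::setNames(rep(0, 8), pressure_names())
  ls <- layers_from_scores(zero, nr = 2, nc = 2)
  nd <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  ls$lights <- pressure_layer("lights", 2009,
                              hf_grid(matrix(0, 2, 2), 1, nd), 10)
  fp <- combine_pressures(ls, sch)
  expect_true(fp$scores$nodata_mask[1, 1])
  expect_false(any(fp$scores$nodata_mask[2:4]))
})

test_that("footprint scores are sampled at plot cells with nodata as NA", {
  zero <- stats::setNames(rep(0, 8), pressure_names())
  ls <- layers_from_scores(zero, nr = 3, nc = 3)
  nd <- matrix(FALSE, 3, 3); nd[3, 3] <- TRUE
  ls$built <- pressure_layer("built", 2009, hf_grid(matrix(0, 3, 3), 1, nd), 10)
  fp <- combine_pressures(ls, sch)
  v <- sample_footprint(fp, c(1, 3), c(1, 3))
  expect_equal(v[1], 0)
  expect_true(is.na(v[2]))
})
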