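sch <- scoring_scheme()

test_that("hydraulic geometry matches the power-law chain", {
  h <- hydraulic_geometry(1)
  expect_equal(h$width_m, 8.1)
  expect_equal(h$velocity_ms, 4 / 8.1, tolerance = 1e-12)
  expect_equal(h$cross_section_m2, 8.1 / 4, tolerance = 1e-12)
  expect_equal(h$depth_m, 0.375)
  expect_equal(hydraulic_geometry(100)$depth_m, 0.375 * 100^0.4,
               tolerance = 1e-12)
  # chained relations reduce to depth = 0.375 Q^0.4 across the range
  q <- 10^seq(-1, 4, length.out = 50)
  expect_equal(hydraulic_geometry(q)$depth_m, 0.375 * q^0.4,
               tolerance = 1e-12)
  expect_error(hydraulic_geometry(0), "positive")
  expect_error(hydraulic_geometry(-3), "positive")
})

test_that("the 2 m depth frontier sits near 65.7 m3/s (bisection oracle)", {
  lo <- 1; hi <- 1000
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    if (hydraulic_geometry(mid)$depth_m > 2) hi <- mid else lo <- mid
  }
  expect_equal(lo, (2 / 0.375)^2.5, tolerance = 1e-9)
  expect_equal(lo, 65.7, tolerance = 0.01)
  # depth strictly increasing in discharge
  q <- 10^seq(-2, 4, length.out = 100)
  expect_true(all(diff(hydraulic_geometry(q)$depth_m) > 0))
})

test_that("settlement signal flags water within 4 km of bright lights", {
  dn <- matrix(0, 9, 9); dn[5, 5] <- 10
  water <- matrix(FALSE, 9, 9)
  water[5, 7] <- TRUE   # 2 km from the lit cell
  water[5, 1] <- TRUE   # 4 km away: inclusive boundary
  water[1, 1] <- TRUE   # sqrt(32) km away: beyond
  sig <- settlement_signal(hf_grid(dn, 1), hf_grid(water, 1))
  expect_equal(sig$values[5, 7], 1)
  expect_equal(sig$values[5, 1], 1)
  expect_equal(sig$values[1, 1], 0)
  dark <- settlement_signal(hf_grid(matrix(0, 9, 9), 1), hf_grid(water, 1))
  expect_true(all(dark$values == 0))
  # DN threshold is inclusive at 6
  dn6 <- matrix(0, 9, 9); dn6[5, 5] <- 6
  expect_equal(settlement_signal(hf_grid(dn6, 1),
                                 hf_grid(water, 1))$values[5, 7], 1)
})

# reach cells spaced 6 km apart so a single lit cell seeds only one reach
chain_network <- function(n, len, q) {
  stream_network(
    data.frame(reach_id = 1:n, from_node = 1:n, to_node = 2:(n + 1),
               length_km = len, discharge_m3s = q),
    data.frame(reach_id = 1:n, row = rep(2, n),
               col = 2 + (seq_len(n) - 1) * 6))
}

lit_dn_at <- function(nr, nc, row, col) {
  dn <- matrix(0, nr, nc); dn[row, col] <- 30
  hf_grid(dn, 1)
}

test_that("an isolated deep lit reach is navigable by itself", {
  net <- chain_network(1, 10, 200)
  dn <- lit_dn_at(5, 10, 2, 2)
  expect_equal(navigable_rivers(net, dn, NULL, sch), 1)
})

test_that("navigability travels 80 km down a deep chain seeded at one end", {
  net <- chain_network(10, 10, 200)          # all deep (depth ~ 3.1 m)
  dn <- lit_dn_at(5, 60, 2, 2)               # lights only near reach 1
  nav <- navigable_rivers(net, dn, NULL, sch)
  expect_equal(sort(nav), 1:8)               # 80 km inclusive of both ends
})

test_that("shallow reaches block propagation", {
  q <- rep(200, 6); q[3] <- 10               # reach 3 is ~0.9 m deep
  net <- chain_network(6, 10, q)
  dn <- lit_dn_at(5, 60, 2, 2)
  expect_equal(sort(navigable_rivers(net, dn, NULL, sch)), 1:2)
})

test_that("a deep unlit chain touching navigable coast is navigable inland", {
  net <- chain_network(10, 10, 200)
  dn <- hf_grid(matrix(0, 5, 60), 1)         # fully dark
  shore <- matrix(0, 5, 60); shore[2, 1] <- 1  # adjacent to reach 1's cell
  nav <- navigable_rivers(net, dn, hf_grid(shore, 1), sch)
  expect_equal(sort(nav), 1:8)
  # without the coast nothing is navigable
  expect_length(navigable_rivers(net, dn, NULL, sch), 0)
})

test_that("navigability is monotone in the propagation range", {
  set.seed(21)
  for (rep in 1:5) {
    net <- random_network(20)
    dn <- lit_dn_at(20, 20, 10, 10)
    n60 <- navigable_rivers(net, dn, NULL, scoring_scheme(nav_range_km = 60))
    n80 <- navigable_rivers(net, dn, NULL, sch)
    expect_true(all(n60 %in% n80))
  }
})

test_that("river propagation equals the igraph shortest-path oracle", {
  set.seed(22)
  for (rep in 1:8) {
    n <- sample(10:50, 1)
    net <- random_network(n)
    dn <- hf_grid(matrix(0, 20, 20), 1)
    dn$values[cbind(sample(20, 5, TRUE), sample(20, 5, TRUE))] <- 30
    got <- sort(navigable_rivers(net, dn, NULL, sch))
    # oracle: recompute seeds and run igraph over the deep subgraph
    depth <- hydraulic_geometry(net$reaches$discharge_m3s)$depth_m
    deep_ids <- net$reaches$reach_id[depth > 2]
    litdist <- oracle_distance(hf_grid(dn$values >= 6, 1))
    sig <- litdist[cbind(net$cells$row, net$cells$col)] <= 4
    seeds <- intersect(unique(net$cells$reach_id[sig]), deep_ids)
    dist <- oracle_reach_distances(net$reaches, seeds, deep_ids)
    want <- sort(net$reaches$reach_id[is.finite(dist) & dist <= 80])
    expect_equal(got, want)
  }
})

test_that("coast navigability spreads 80 km along-coast from settlements", {
  # straight 100-km coast with a single lit settlement at the south end
  coast <- matrix(FALSE, 100, 5); coast[, 3] <- TRUE
  dn <- matrix(0, 100, 5); dn[1, 4] <- 30
  nav <- navigable_coast(hf_grid(coast, 1), hf_grid(dn, 1), sch)
  # settlement-signal seeds: coast rows with sqrt((r-1)^2 + 1) <= 4, i.e. 1:4;
  # navigable rows reach 80 km along-coast past the last seed, i.e. 1:84
  expect_equal(nav$values[1, 3], 1)
  expect_equal(nav$values[84, 3], 1)
  expect_equal(nav$values[85, 3], 0)
  expect_equal(sum(nav$values), 84)
  # empty coast yields an empty result
  none <- navigable_coast(hf_grid(matrix(FALSE, 5, 5), 1),
                          hf_grid(matrix(0, 5, 5), 1), sch)
  expect_true(all(none$values == 0))
})

test_that("a ring island with one settlement gets a ~160 km navigable arc", {
  n <- 60
  ring <- matrix(FALSE, n, n)
  ring[10, 10:50] <- TRUE; ring[50, 10:50] <- TRUE
  ring[10:50, 10] <- TRUE; ring[10:50, 50] <- TRUE
  dn <- matrix(0, n, n); dn[9, 30] <- 30
  rg <- hf_grid(ring, 1); dg <- hf_grid(dn, 1)
  nav <- navigable_coast(rg, dg, sch)
  # compare against the Bellman-Ford along-coast oracle
  sig <- settlement_signal(dg, rg, sch$nav_search_km, sch$nav_dn_threshold)
  seeds <- which(sig$values > 0 & ring, arr.ind = TRUE)
  od <- oracle_coast_distance(ring, 1, seeds)
  want <- matrix(0, n, n)
  want[od[od[, "dist"] <= 80, 1:2, drop = FALSE]] <- 1
  expect_equal(nav$values, want)
  # arc length: ~80 km each way around the ring from the settlement cells
  arc_km <- sum(nav$values) - 1
  expect_gt(arc_km, 150); expect_lt(arc_km, 170)
  # straight-line option reaches across the ring interior
  nav_sl <- navigable_coast(rg, dg, sch, along = FALSE)
  expect_gte(sum(nav_sl$values), sum(nav$values))
})

test_that("navigable-water scoring decays from the water edge", {
  m <- matrix(FALSE, 5, 25); m[3, 1] <- TRUE
  s <- score_navwater(hf_grid(m, 1), sch)
  v <- s$scores$values
  expect_equal(v[3, 1], 4)               # the water cell itself
  expect_equal(v[3, 2], 4)               # adjacent cell holds the plateau
  expect_equal(v[3, 4],                  # 3 km out: on the decay curve
               4 * exp(-log(16) / (15 - sqrt(2)) * (3 - sqrt(2))),
               tolerance = 1e-12)
  expect_equal(v[3, 21], 0)              # 20 km: beyond truncation
  expect_true(all(v >= 0 & v <= 4))
  zero <- score_navwater(hf_grid(matrix(FALSE, 4, 4), 1), sch)
  expect_true(all(zero$scores$values == 0))
  expect_equal(zero$name, "navwater")
})
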