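# run code under a locally seeded RNG without disturbing the caller's stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# disc of TRUE around (r0, c0), radius in cells
disc <- function(nr, nc, r0, c0, radius) {
  outer(seq_len(nr), seq_len(nc),
        function(i, j) (i - r0)^2 + (j - c0)^2 <= radius^2)
}

#' Generate a deterministic synthetic landscape bundle
#'
#' Builds a toy landscape exercising every stage of the pipeline: a bright
#' built core (DN >= 20) with a dense population blob, scattered dim rural
#' lights (6 < DN < 20), a crop field and a pasture gradient, a road crossing
#' the built core with a full 15-km hinterland, a railway, a west-edge coast
#' with one lit coastal settlement, a small inland lake, and a stream chain
#' whose discharges straddle the ~65.7 m3/s depth-navigability frontier. Two
#' night-lights vintages are produced (the later one slightly brighter with a
#' new settlement) so intercalibration and reference-year binning are
#' exercised. A small nodata patch marks the NW corner. Identical seeds give
#' bit-for-bit identical bundles.
#'
#' @param seed integer RNG seed.
#' @param size_cells square grid edge, cells (>= 32; default 64).
#' @param cell_size_km cell size in km (default 1).
#' @return A `landscape_bundle`: grids `dn_1994`, `dn_2009`, `population`,
#'   `crop_mask`, `pasture_pct`, `road_mask`, `rail_mask`, `coast_mask`,
#'   `lake_mask`; a `streams` [stream_network()]; and `seed`.
#' @export
make_landscape <- function(seed = 1, size_cells = 64, cell_size_km = 1) {
  if (size_cells < 32)
    stop("size_cells must be >= 32 to fit the 15-km access kernel")
  n <- as.integer(size_cells)
  with_seed(seed, {
    nodata <- matrix(FALSE, n, n)
    nodata[(n - 1):n, 1:2] <- TRUE   # NW corner patch (rows are south-up)
    g <- function(v) hf_grid(v, cell_size_km, nodata)

    core_r <- round(0.60 * n); core_c <- round(0.30 * n)

    # uninhabited wilderness block: no lights, people, fields or access
    # pressure reaches it (> 15 km from roads and navigable water), so the
    # footprint there is exactly 0 -- every real landscape has remote land
    wild <- matrix(FALSE, n, n)
    wild[round(0.05 * n):round(0.30 * n), round(0.27 * n):round(0.45 * n)] <- TRUE

    # -- night lights, 1994: built core + rural specks + coastal settlement
    dn94 <- matrix(0, n, n)
    core <- disc(n, n, core_r, core_c, 2.2)
    dn94[core] <- sample(35:63, sum(core), replace = TRUE)
    rural <- sample(which(!core & !nodata & !wild), round(0.06 * n * n))
    dn94[rural] <- sample(7:19, length(rural), replace = TRUE)
    settle_r <- round(0.25 * n)
    dn94[settle_r, 2] <- 25                       # settlement near the coast
    dn94[nodata] <- 0

    # -- 2009: brighter core, one new settlement blob
    dn09 <- dn94
    dn09[dn09 > 0 & dn09 < 60] <- dn09[dn09 > 0 & dn09 < 60] + 3
    new_blob <- disc(n, n, round(0.8 * n), round(0.45 * n), 1.2)
    dn09[new_blob] <- sample(21:40, sum(new_blob), replace = TRUE)
    dn09[nodata] <- 0

    # -- population: dense near the core, sparse elsewhere
    dd <- outer(seq_len(n), seq_len(n),
                function(i, j) sqrt((i - core_r)^2 + (j - core_c)^2))
    pop <- 2000 * exp(-dd / 3) + stats::rexp(n * n, rate = 1 / 2)
    pop <- matrix(pop, n, n)
    pop[wild | nodata] <- 0

    # -- crops: a rectangular field east of the core; pasture: SE gradient
    crop <- matrix(0, n, n)
    crop[round(0.45 * n):round(0.6 * n), round(0.55 * n):round(0.7 * n)] <- 1
    pasture <- matrix(0, n, n)
    pr <- round(0.1 * n):round(0.38 * n)
    pc <- round(0.5 * n):round(0.85 * n)
    pasture[pr, pc] <- matrix(
      rep(seq(5, 100, length.out = length(pc)), each = length(pr)),
      length(pr), length(pc))

    # -- road (E-W) and railway (N-S) cross at the built core, so the core
    # cell stacks built + population + lights + road + rail = 46 by design
    road <- matrix(0, n, n); road[core_r, ] <- 1
    rail <- matrix(0, n, n); rail[, core_c] <- 1

    # -- coast along the west edge; small lake in the NE
    coast <- matrix(0, n, n); coast[, 1] <- 1
    lake <- matrix(0, n, n)
    lake[disc(n, n, round(0.85 * n), round(0.85 * n), 1.5)] <- 1

    # -- stream chain from the lake toward the coast; discharges log-uniform
    #    on [1, 1000] m3/s, redrawn until both sides of the frontier occur
    n_reach <- 8L
    q_frontier <- (2 / 0.375)^2.5
    repeat {
      q <- 10^stats::runif(n_reach, 0, 3)
      if (any(q > q_frontier) && any(q < q_frontier)) break
    }
    row_path <- round(seq(0.85 * n, core_r, length.out = n_reach + 1))
    col_path <- round(seq(0.8 * n, 2, length.out = n_reach + 1))
    cells <- NULL
    for (k in seq_len(n_reach)) {
      rr <- round(seq(row_path[k], row_path[k + 1], length.out = 5))
      cc <- round(seq(col_path[k], col_path[k + 1], length.out = 5))
      cells <- rbind(cells, data.frame(reach_id = k, row = rr, col = cc))
    }
    cells <- unique(cells)
    seg_len <- sqrt(diff(row_path)^2 + diff(col_path)^2) * cell_size_km
    reaches <- data.frame(reach_id = seq_len(n_reach),
                          from_node = seq_len(n_reach),
                          to_node = seq_len(n_reach) + 1L,
                          length_km = pmax(seg_len, 0.5),
                          discharge_m3s = q)
    structure(
      list(dn_1994 = g(dn94), dn_2009 = g(dn09), population = g(pop),
           crop_mask = g(crop), pasture_pct = g(pasture),
           road_mask = g(road), rail_mask = g(rail), coast_mask = g(coast),
           lake_mask = g(lake),
           streams = stream_network(reaches, cells),
           seed = as.integer(seed)),
      class = "landscape_bundle")
  })
}

#' Synthetic validation table from a footprint map
#'
#' Samples plots uniformly over data cells and sets each visual score to the
#' normalized footprint score plus additive Gaussian noise truncated to
#' `[0, 1]` (re-expressed on the 0..`visual_max` visual scale). A fraction of
#' plots is flagged `"uncertain"`; strata are quadrant labels. With zero
#' noise the table round-trips to RMSE 0 and kappa 1; truncation at the scale
#' bounds shrinks the recovered error slightly below the injected sd.
#'
#' @param bundle a `landscape_bundle` (supplies the grid geometry).
#' @param footprint the `footprint_map` computed from the bundle.
#' @param noise_sd sd of the additive noise on the 0-1 scale.
#' @param n_plots number of plots (<= number of data cells).
#' @param seed integer RNG seed.
#' @param uncertain_frac fraction of plots flagged `"uncertain"`.
#' @param visual_max maximum of the visual interpretation scale (default 10).
#' @return A [validation_table()] with `row`, `col`, `visual_score`,
#'   `certainty` and `stratum` columns.
#' @export
make_validation_table <- function(bundle, footprint, noise_sd = 0.1,
                                  n_plots = 500, seed = 1,
                                  uncertain_frac = 0.1, visual_max = 10) {
  stopifnot(inherits(bundle, "landscape_bundle"),
            inherits(footprint, "footprint_map"))
  if (n_plots < 2) stop("need at least 2 plots")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  g <- footprint$scores
  ok <- which(!g$nodata_mask)
  if (n_plots > length(ok)) stop("n_plots exceeds available data cells")
  with_seed(seed, {
    cells <- sample(ok, n_plots)
    rc <- arrayInd(cells, dim(g$values))
    fp <- g$values[cells]
    fp_norm <- fp / max_possible_score(footprint$scheme)
    visual <- pmin(1, pmax(0, fp_norm + stats::rnorm(n_plots, 0, noise_sd)))
    half <- dim(g$values) / 2
    stratum <- paste0(ifelse(rc[, 1] > half[1], "N", "S"),
                      ifelse(rc[, 2] > half[2], "E", "W"))
    certainty <- ifelse(stats::runif(n_plots) < uncertain_frac,
                        "uncertain", "certain")
    validation_table(data.frame(
      plot_id = seq_len(n_plots), row = rc[, 1], col = rc[, 2],
      visual_score = visual * visual_max, certainty = certainty,
      stratum = stratum, image_year = footprint$year,
      image_resolution_m = 0.5))
  })
}
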