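#' Hydraulic geometry from discharge
#'
#' Empirical power-law channel geometry: width `8.1 * Q^0.58` (m), velocity
#' `4.0 * Q^0.6 / width` (m/s), cross-section `Q / velocity` (m2) and, for a
#' parabolic channel, depth `1.5 * area / width` (m). The chained relations
#' reduce algebraically to `depth = 0.375 * Q^0.4`, so depth is strictly
#' increasing in discharge and the 2-m navigability frontier is a single
#' discharge threshold near 65.7 m3/s.
#'
#' @param discharge_m3s positive discharge(s), m3/s. Vectorized.
#' @return data frame with columns `discharge_m3s`, `width_m`,
#'   `velocity_ms`, `cross_section_m2`, `depth_m`.
#' @examples
#' hydraulic_geometry(1)
#' @export
hydraulic_geometry <- function(discharge_m3s) {
  q <- discharge_m3s
  if (any(!is.finite(q)) || any(q <= 0)) stop("discharge must be positive")
  width <- 8.1 * q^0.58
  velocity <- 4.0 * q^0.6 / width
  area <- q / velocity
  depth <- 1.5 * area / width
  data.frame(discharge_m3s = q, width_m = width, velocity_ms = velocity,
             cross_section_m2 = area, depth_m = depth)
}

#' Stream network of reaches
#'
#' A reach graph over node ids (reaches sharing a node are neighbours), each
#' reach carrying a discharge, a traversal length, and the grid cells it
#' occupies.
#'
#' @param reaches data frame with columns `reach_id`, `from_node`, `to_node`,
#'   `length_km` (> 0), `discharge_m3s` (>= 0).
#' @param cells data frame with columns `reach_id`, `row`, `col` locating
#'   each reach on the analysis grid.
#' @return A `stream_network`.
#' @export
stream_network <- function(reaches, cells) {
  reaches <- as.data.frame(reaches)
  cells <- as.data.frame(cells)
  need <- c("reach_id", "from_node", "to_node", "length_km", "discharge_m3s")
  if (!all(need %in% names(reaches)))
    stop("reaches must have columns ", paste(need, collapse = ", "))
  if (!all(c("reach_id", "row", "col") %in% names(cells)))
    stop("cells must have columns reach_id, row, col")
  if (anyDuplicated(reaches$reach_id)) stop("duplicate reach ids")
  if (any(reaches$length_km <= 0)) stop("reach lengths must be positive")
  if (any(reaches$discharge_m3s < 0)) stop("discharge must be non-negative")
  if (!all(cells$reach_id %in% reaches$reach_id))
    stop("cells reference unknown reach ids")
  structure(list(reaches = reaches, cells = cells), class = "stream_network")
}

#' Read a stream network from delimited tables
#'
#' @param reach_path,cells_path paths to delimited files (columns as in
#'   [stream_network()]).
#' @param sep field separator, default comma.
#' @return A `stream_network`.
#' @export
read_stream_network <- function(reach_path, cells_path, sep = ",") {
  stream_network(utils::read.table(reach_path, header = TRUE, sep = sep),
                 utils::read.table(cells_path, header = TRUE, sep = sep))
}

#' Water cells with a settlement signal nearby
#'
#' Flags water cells having any night-lights cell at or above the settlement
#' DN threshold within the search radius (default: DN >= 6 within 4 km),
#' the "signs of human settlement" rule that seeds waterway navigability.
#'
#' @param dn `hf_grid` of (calibrated) night-lights DN.
#' @param water_mask `hf_grid` 0/1 water mask, co-registered with `dn`.
#' @param search_km search radius in km.
#' @param dn_threshold settlement DN threshold (inclusive).
#' @return `hf_grid` with 1 on water cells near a settlement, 0 elsewhere.
#' @export
settlement_signal <- function(dn, water_mask, search_km = 4,
                              dn_threshold = 6) {
  stopifnot(is_hf_grid(dn), is_hf_grid(water_mask))
  check_coregistered(dn, water_mask)
  lit <- dn$values >= dn_threshold & !dn$nodata_mask
  water <- water_mask$values > 0 & !water_mask$nodata_mask
  out <- array(0, dim(dn$values))
  if (any(lit)) {
    litdist <- distance_map(hf_grid(array(as.numeric(lit), dim(lit)),
                                    dn$cell_size_km, dn$nodata_mask,
                                    dn$origin))
    out[water & litdist$values <= search_km] <- 1
  }
  hf_grid(out, dn$cell_size_km, water_mask$nodata_mask, dn$origin)
}

# Dijkstra over the reach graph. dist[r] is the cumulative traversed length
# including both the seed reach and r; only reaches in `passable` are entered.
reach_dijkstra <- function(reaches, seed_ids, passable_ids) {
  n <- nrow(reaches)
  dist <- rep(Inf, n)
  names(dist) <- reaches$reach_id
  passable <- reaches$reach_id %in% passable_ids
  # adjacency: reaches sharing a node
  node_members <- split(c(seq_len(n), seq_len(n)),
                        c(reaches$from_node, reaches$to_node))
  adj <- vector("list", n)
  for (members in node_members) {
    for (i in members) adj[[i]] <- c(adj[[i]], setdiff(members, i))
  }
  adj <- lapply(adj, unique)
  seed_idx <- which(reaches$reach_id %in% seed_ids)
  dist[seed_idx] <- reaches$length_km[seed_idx]
  done <- rep(FALSE, n)
  repeat {
    i <- which(!done & is.finite(dist))
    if (!length(i)) break
    i <- i[which.min(dist[i])]
    done[i] <- TRUE
    for (j in adj[[i]]) {
      if (!passable[j]) next
      cand <- dist[i] + reaches$length_km[j]
      if (cand < dist[j]) dist[j] <- cand
    }
  }
  dist
}

#' Navigable river reaches
#'
#' A reach is seeded navigable when its depth (from [hydraulic_geometry()])
#' exceeds the depth threshold and it carries a settlement signal (lights at
#' or above the DN threshold within the search radius of its cells), or when
#' it is deep and contiguous with navigable coast or lake cells. Navigability
#' then propagates along the reach graph through deep reaches only, until the
#' cumulative traversed length (seed and target reaches included) exceeds the
#' range; shallow reaches block propagation.
#'
#' @param network a [stream_network()].
#' @param dn `hf_grid` of calibrated night-lights DN.
#' @param navigable_water optional `hf_grid` 0/1 of already-navigable coast
#'   and lake cells (from [navigable_coast()]); reaches with a cell
#'   8-adjacent to (or on) such a cell are contiguity seeds.
#' @param scheme a [scoring_scheme()] supplying the range (80 km), depth
#'   threshold (2 m), DN threshold (6) and search radius (4 km).
#' @return character/integer vector of navigable `reach_id`s.
#' @export
navigable_rivers <- function(network, dn, navigable_water = NULL,
                             scheme = scoring_scheme()) {
  stopifnot(inherits(network, "stream_network"), is_hf_grid(dn))
  reaches <- network$reaches
  hg <- hydraulic_geometry(pmax(reaches$discharge_m3s, 1e-12))
  deep <- hg$depth_m > scheme$nav_depth_threshold_m &
    reaches$discharge_m3s > 0
  # settlement signal per reach: any reach cell within search_km of a lit cell
  lit <- dn$values >= scheme$nav_dn_threshold & !dn$nodata_mask
  cell_sig <- rep(FALSE, nrow(network$cells))
  if (any(lit)) {
    litdist <- distance_map(hf_grid(array(as.numeric(lit), dim(lit)),
                                    dn$cell_size_km, dn$nodata_mask,
                                    dn$origin))
    cell_sig <- litdist$values[cbind(network$cells$row, network$cells$col)] <=
      scheme$nav_search_km
  }
  sig_reaches <- unique(network$cells$reach_id[cell_sig])
  seeds <- reaches$reach_id[deep & reaches$reach_id %in% sig_reaches]
  # contiguity with navigable coast/lake cells (within one cell, diagonal ok)
  if (!is.null(navigable_water) &&
      any(navigable_water$values > 0 & !navigable_water$nodata_mask)) {
    check_coregistered(dn, navigable_water)
    wd <- distance_map(navigable_water)
    touch <- wd$values[cbind(network$cells$row, network$cells$col)] <=
      sqrt(2) * dn$cell_size_km + 1e-9
    touch_reaches <- unique(network$cells$reach_id[touch])
    seeds <- union(seeds, reaches$reach_id[deep &
                                             reaches$reach_id %in% touch_reaches])
  }
  if (!length(seeds)) return(reaches$reach_id[0])
  dist <- reach_dijkstra(reaches, seeds, reaches$reach_id[deep])
  reaches$reach_id[is.finite(dist) & dist <= scheme$nav_range_km]
}

# igraph over 8-connected TRUE cells of a mask; edge weights are
# centre-to-centre step lengths (1 or sqrt(2) cells).
coast_cell_graph <- function(mask, cell_km) {
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  key <- paste(idx[, 1], idx[, 2])
  lookup <- stats::setNames(seq_len(n), key)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  offs <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1))  # half the moves
  for (k in seq_len(nrow(offs))) {
    nb <- cbind(idx[, 1] + offs[k, 1], idx[, 2] + offs[k, 2])
    j <- lookup[paste(nb[, 1], nb[, 2])]
    ok <- !is.na(j)
    from <- c(from, which(ok)); to <- c(to, unname(j[ok]))
    w <- c(w, rep(sqrt(sum(offs[k, ]^2)) * cell_km, sum(ok)))
  }
  list(idx = idx, n = n,
       graph = igraph::graph_from_data_frame(
         data.frame(from = from, to = to, weight = w),
         directed = FALSE,
         vertices = data.frame(name = seq_len(n))))
}

#' Navigable coast and lake-shore cells
#'
#' Coasts are navigable for a fixed range (default 80 km, roughly the
#' distance a vessel can travel out and back in daylight) either direction of
#' a settlement signal. Distance is accumulated along the coast itself: a
#' breadth-first/shortest-path traversal of 8-connected coast cells with step
#' lengths of 1 or sqrt(2) cells, never a straight-line shortcut across open
#' water. Large lakes are treated exactly like marine coasts. With
#' `along = FALSE`, straight-line (Euclidean) distance from settlement cells
#' is used instead.
#'
#' @param coast_mask `hf_grid` 0/1 coast (or lake) cells.
#' @param dn `hf_grid` of calibrated night-lights DN, co-registered.
#' @param scheme a [scoring_scheme()].
#' @param along measure distance along the coast (default) or straight-line.
#' @return `hf_grid` with 1 on navigable coast cells; all-zero if the mask is
#'   empty or no settlement signal exists.
#' @export
navigable_coast <- function(coast_mask, dn, scheme = scoring_scheme(),
                            along = TRUE) {
  stopifnot(is_hf_grid(coast_mask), is_hf_grid(dn))
  check_coregistered(coast_mask, dn)
  out <- array(0, dim(coast_mask$values))
  res <- hf_grid(out, coast_mask$cell_size_km, coast_mask$nodata_mask,
                 coast_mask$origin)
  mask <- coast_mask$values > 0 & !coast_mask$nodata_mask
  if (!any(mask)) return(res)
  sig <- settlement_signal(dn, coast_mask, scheme$nav_search_km,
                           scheme$nav_dn_threshold)
  seeds <- sig$values > 0 & mask
  if (!any(seeds)) return(res)
  if (!along) {
    sd <- distance_map(hf_grid(array(as.numeric(seeds), dim(seeds)),
                               coast_mask$cell_size_km,
                               coast_mask$nodata_mask, coast_mask$origin))
    out[mask & sd$values <= scheme$nav_range_km] <- 1
  } else {
    cg <- coast_cell_graph(mask, coast_mask$cell_size_km)
    seed_rows <- which(seeds[cbind(cg$idx[, 1], cg$idx[, 2])])
    dmat <- igraph::distances(cg$graph, v = as.character(seed_rows),
                              to = as.character(seq_len(cg$n)))
    dmin <- apply(dmat, 2, min)
    ord <- as.integer(colnames(dmat))
    nav <- ord[dmin <= scheme$nav_range_km]
    out[cg$idx[nav, , drop = FALSE]] <- 1
  }
  hf_grid(out, coast_mask$cell_size_km, coast_mask$nodata_mask,
          coast_mask$origin)
}

#' Rasterize navigable reaches onto the grid
#'
#' @param network a [stream_network()].
#' @param reach_ids navigable reach ids (from [navigable_rivers()]).
#' @param template `hf_grid` defining the output grid.
#' @return `hf_grid` 0/1 of navigable river cells.
#' @export
rasterize_reaches <- function(network, reach_ids, template) {
  stopifnot(inherits(network, "stream_network"), is_hf_grid(template))
  out <- array(0, dim(template$values))
  sel <- network$cells$reach_id %in% reach_ids
  out[cbind(network$cells$row[sel], network$cells$col[sel])] <- 1
  hf_grid(out, template$cell_size_km, template$nodata_mask, template$origin)
}

#' Score navigable waterways: access decay from the water edge
#'
#' Access pressure of 4 adjacent to navigable water, decaying exponentially
#' out to 15 km. Unlike roads, there is no wider direct band: the plateau
#' holds at the water edge — the water cells and their 8-neighbourhood (cell
#' centres within `sqrt(2)` cells) score the full 4 — and the decay runs from
#' there out to the truncation distance.
#'
#' @param navigable_water_mask `hf_grid` 0/1 union of navigable river, coast
#'   and lake cells.
#' @param scheme a [scoring_scheme()].
#' @param year data vintage.
#' @return A `pressure_layer` named `"navwater"`; all-zero when no water is
#'   navigable.
#' @export
score_navwater <- function(navigable_water_mask, scheme = scoring_scheme(),
                           year = NA_integer_) {
  stopifnot(is_hf_grid(navigable_water_mask))
  m <- navigable_water_mask
  if (!any(m$values > 0 & !m$nodata_mask)) {
    z <- hf_grid(array(0, dim(m$values)), m$cell_size_km, m$nodata_mask,
                 m$origin)
    return(pressure_layer("navwater", year, z, scheme$nav_access_max))
  }
  kp <- decay_kernel_params(scheme$nav_access_max, sqrt(2) * m$cell_size_km,
                            scheme$decay_dmax_km, scheme$decay_floor)
  s <- apply_decay(distance_map(m), kp)
  pressure_layer("navwater", year, s, scheme$nav_access_max)
}
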