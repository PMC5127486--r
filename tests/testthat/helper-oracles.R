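# Independent brute-force oracles used to cross-check the implementation.

# exhaustive nearest-feature search over all cell pairs
oracle_distance <- function(mask_grid) {
  src <- which(mask_grid$values > 0 & !mask_grid$nodata_mask, arr.ind = TRUE)
  nr <- nrow(mask_grid$values); nc <- ncol(mask_grid$values)
  out <- matrix(Inf, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc))
    out[i, j] <- min(sqrt((src[, 1] - i)^2 + (src[, 2] - j)^2))
  out * mask_grid$cell_size_km
}

# shortest-path distances over the reach graph via igraph (directed edges
# weighted by the length of the reach being entered); returns, per reach,
# the minimum over seeds of len(seed) + path cost, Inf if unreachable.
oracle_reach_distances <- function(reaches, seed_ids, passable_ids) {
  deep <- reaches[reaches$reach_id %in% passable_ids, , drop = FALSE]
  seeds <- intersect(seed_ids, deep$reach_id)
  dist <- rep(Inf, nrow(reaches))
  names(dist) <- as.character(reaches$reach_id)
  if (!length(seeds)) return(dist)
  ids <- as.character(deep$reach_id)
  el <- NULL
  n <- nrow(deep)
  if (n > 1) {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      if (length(intersect(c(deep$from_node[i], deep$to_node[i]),
                           c(deep$from_node[j], deep$to_node[j]))))
        el <- rbind(el, data.frame(from = ids[i], to = ids[j],
                                   weight = deep$length_km[j]))
    }
  }
  g <- if (is.null(el))
    igraph::make_empty_graph(n) |> igraph::set_vertex_attr("name", value = ids)
  else igraph::graph_from_data_frame(el, directed = TRUE,
                                     vertices = data.frame(name = ids))
  d <- igraph::distances(g, v = as.character(seeds), to = ids, mode = "out")
  seed_len <- reaches$length_km[match(seeds, reaches$reach_id)]
  dmin <- apply(d + seed_len, 2, min)
  dist[colnames(d)] <- dmin
  dist
}

# Bellman-Ford over 8-connected mask cells with 1 / sqrt(2) steps
oracle_coast_distance <- function(mask, cell_km, seed_cells) {
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  key <- paste(idx[, 1], idx[, 2])
  d <- ifelse(key %in% paste(seed_cells[, 1], seed_cells[, 2]), 0, Inf)
  ea <- eb <- integer(0); w <- numeric(0)
  for (a in seq_len(n)) {
    dr <- abs(idx[, 1] - idx[a, 1]); dc <- abs(idx[, 2] - idx[a, 2])
    nb <- which(dr <= 1 & dc <= 1 & (dr + dc) > 0)
    ea <- c(ea, rep(a, length(nb))); eb <- c(eb, nb)
    w <- c(w, sqrt(dr[nb]^2 + dc[nb]^2) * cell_km)
  }
  repeat {
    relaxed <- tapply(d[ea] + w, eb, min)
    nd <- d
    ib <- as.integer(names(relaxed))
    nd[ib] <- pmin(nd[ib], relaxed)
    if (all(nd >= d - 1e-12)) break
    d <- nd
  }
  cbind(idx, dist = d)
}

# random landscape-free mask grid
random_mask <- function(nr, nc, p = 0.1, cell = 1) {
  m <- matrix(runif(nr * nc) < p, nr, nc)
  if (!any(m)) m[sample(length(m), 1)] <- TRUE
  hf_grid(m, cell)
}

# random connected reach network (a tree over nodes) with n reaches
random_network <- function(n_reach, max_len = 20) {
  from <- integer(n_reach); to <- integer(n_reach)
  for (k in seq_len(n_reach)) {
    from[k] <- if (k == 1) 1L else sample(k, 1)
    to[k] <- k + 1L
  }
  reaches <- data.frame(
    reach_id = seq_len(n_reach), from_node = from, to_node = to,
    length_km = round(runif(n_reach, 1, max_len), 2),
    discharge_m3s = 10^runif(n_reach, 0, 3))
  cells <- data.frame(reach_id = seq_len(n_reach),
                      row = sample(20, n_reach, TRUE),
                      col = sample(20, n_reach, TRUE))
  stream_network(reaches, cells)
}
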