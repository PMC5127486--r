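#' Read and write grids
#'
#' Two on-disk forms are supported, chosen by file extension:
#' \describe{
#'   \item{`.asc`}{Esri ASCII grid — plain text, self-describing
#'     (ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value header followed
#'     by rows north to south). Coordinates are interpreted in km.}
#'   \item{`.tif`/`.tiff`}{Single-band 32-bit float TIFF written with the
#'     `tiff` package plus a JSON sidecar (`<file>.json`) carrying cell size,
#'     origin, nodata value and the affine packing used to store arbitrary
#'     value ranges as `[0, 1]` floats. Reading restores the original
#'     values.}
#' }
#'
#' @param grid an `hf_grid`.
#' @param path output/input path (`.asc`, `.tif` or `.tiff`).
#' @param nodata_value value written for nodata cells.
#' @return `write_grid`: the path, invisibly. `read_grid`: an `hf_grid`.
#' @export
write_grid <- function(grid, path, nodata_value = -9999) {
  stopifnot(is_hf_grid(grid))
  ext <- tolower(tools::file_ext(path))
  v <- grid$values
  v[grid$nodata_mask] <- nodata_value
  if (ext == "asc") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      sprintf("ncols %d", ncol(v)),
      sprintf("nrows %d", nrow(v)),
      sprintf("xllcorner %.10g", grid$origin[1]),
      sprintf("yllcorner %.10g", grid$origin[2]),
      sprintf("cellsize %.10g", grid$cell_size_km),
      sprintf("NODATA_value %.10g", nodata_value)), con)
    # .asc rows run north to south; matrix row 1 is the southernmost
    for (i in rev(seq_len(nrow(v))))
      writeLines(paste(formatC(v[i, ], format = "g", digits = 9),
                       collapse = " "), con)
  } else if (ext %in% c("tif", "tiff")) {
    lo <- min(v); hi <- max(v)
    scale <- if (hi > lo) hi - lo else 1
    tiff::writeTIFF((v - lo) / scale, path, bits.per.sample = 32L,
                    compression = "none")
    jsonlite::write_json(
      list(cell_size_km = grid$cell_size_km, origin = grid$origin,
           nodata_value = nodata_value, value_offset = lo,
           value_scale = scale),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  } else stop("unsupported grid format: .", ext)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "asc") {
    hdr <- utils::read.table(path, nrows = 6,
                             col.names = c("key", "value"),
                             stringsAsFactors = FALSE)
    h <- stats::setNames(as.numeric(hdr$value), tolower(hdr$key))
    m <- as.matrix(utils::read.table(path, skip = 6))
    dimnames(m) <- NULL
    m <- m[rev(seq_len(nrow(m))), , drop = FALSE]  # back to south-up rows
    nodata <- m == h[["nodata_value"]]
    m[nodata] <- NA_real_
    hf_grid(m, h[["cellsize"]], nodata, c(h[["xllcorner"]], h[["yllcorner"]]))
  } else if (ext %in% c("tif", "tiff")) {
    meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    m <- tiff::readTIFF(path)
    if (length(dim(m)) == 3) m <- m[, , 1]
    m <- m * meta$value_scale + meta$value_offset
    nodata <- abs(m - meta$nodata_value) < 1e-6 * max(1, abs(meta$nodata_value))
    m[nodata] <- NA_real_
    hf_grid(m, meta$cell_size_km, nodata, meta$origin)
  } else stop("unsupported grid format: .", ext)
}

# supercover rasterization of one segment: mark every cell the segment passes
# through, stepping at sub-cell resolution (robust and adequate at toy scale)
mark_segment <- function(out, x0, y0, x1, y1, cell) {
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  nstep <- max(2L, ceiling(len / (cell / 4)) + 1L)
  t <- seq(0, 1, length.out = nstep)
  cx <- x0 + t * (x1 - x0)
  cy <- y0 + t * (y1 - y0)
  j <- pmin(pmax(ceiling(cx / cell), 1L), ncol(out))
  i <- pmin(pmax(ceiling(cy / cell), 1L), nrow(out))
  out[unique(cbind(i, j))] <- 1
  out
}

point_in_polygon <- function(px, py, vx, vy) {
  # even-odd ray casting
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Rasterize GeoJSON lines or polygons onto a template grid
#'
#' Reads a GeoJSON file (coordinates in projected km, matching the grid) and
#' burns its features into a 0/1 mask: `LineString`/`MultiLineString`
#' features mark every cell the line passes through; `Polygon`/`MultiPolygon`
#' features mark cells whose centre falls inside (centre-intersection rule).
#'
#' @param path GeoJSON file.
#' @param template `hf_grid` defining shape, cell size and origin.
#' @return `hf_grid` 0/1 mask co-registered with the template.
#' @export
rasterize_geojson <- function(path, template) {
  stopifnot(is_hf_grid(template))
  gj <- jsonlite::read_json(path)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features
    else list(gj)
  cell <- template$cell_size_km
  out <- array(0, dim(template$values))
  nr <- nrow(out); nc <- ncol(out)
  ctr_x <- rep((seq_len(nc) - 0.5) * cell, each = nr)
  ctr_y <- rep((seq_len(nr) - 0.5) * cell, times = nc)
  ox <- template$origin[1]; oy <- template$origin[2]
  burn_coords <- function(coords, type) {
    if (type %in% c("LineString")) {
      xy <- do.call(rbind, lapply(coords, function(p)
        c(p[[1]] - ox, p[[2]] - oy)))
      for (k in seq_len(nrow(xy) - 1))
        out <<- mark_segment(out, xy[k, 1], xy[k, 2], xy[k + 1, 1],
                             xy[k + 1, 2], cell)
    } else if (type == "MultiLineString") {
      for (part in coords) burn_coords(part, "LineString")
    } else if (type == "Polygon") {
      ring <- coords[[1]]  # exterior ring; holes not supported at toy scale
      xy <- do.call(rbind, lapply(ring, function(p)
        c(p[[1]] - ox, p[[2]] - oy)))
      inside <- point_in_polygon(ctr_x, ctr_y, xy[, 1], xy[, 2])
      out[matrix(inside, nr, nc)] <<- 1
    } else if (type == "MultiPolygon") {
      for (part in coords) burn_coords(part, "Polygon")
    } else stop("unsupported GeoJSON geometry: ", type)
  }
  for (f in feats) {
    geom <- if (!is.null(f$geometry)) f$geometry else f
    burn_coords(geom$coordinates, geom$type)
  }
  hf_grid(out, cell, template$nodata_mask, template$origin)
}

#' Write a pressure layer (grid + provenance sidecar)
#'
#' @param layer a [pressure_layer()].
#' @param path raster path (`.asc` or `.tif`).
#' @return the path, invisibly.
#' @export
write_pressure_layer <- function(layer, path) {
  stopifnot(inherits(layer, "pressure_layer"))
  write_grid(layer$scores, path)
  jsonlite::write_json(
    list(name = layer$name, year = layer$year, max_score = layer$max_score,
         provenance = layer$provenance,
         checksum = grid_checksum(layer$scores)),
    paste0(tools::file_path_sans_ext(path), "_meta.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Deterministic checksum of a grid's contents
#'
#' Provenance fingerprint written into run reports so a map can be traced to
#' exact inputs.
#' @param grid an `hf_grid`.
#' @return character checksum.
#' @export
grid_checksum <- function(grid) {
  stopifnot(is_hf_grid(grid))
  v <- grid$values
  v[grid$nodata_mask] <- -9999
  x <- c(dim(v), grid$cell_size_km, grid$origin, as.vector(signif(v, 10)))
  # rolling polynomial hash over the serialized numbers; stable text fingerprint
  bytes <- as.integer(charToRaw(paste(format(x, digits = 10), collapse = ",")))
  w <- (seq_along(bytes) %% 9973) + 1
  h <- sum(bytes * w) %% 2147483647
  sprintf("%08x", h)
}
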