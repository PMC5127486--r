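#' Equal-area raster grid
#'
#' A minimal in-memory raster: a numeric matrix of cell values on a square
#' equal-area grid, with an explicit nodata mask. Row `i`, column `j` maps to
#' the cell whose centre sits at
#' `(origin[1] + (j - 0.5) * cell_size_km, origin[2] + (i - 0.5) * cell_size_km)`
#' in projected kilometres. All pipeline layers must share shape, cell size
#' and origin (co-registration); the package never reprojects.
#'
#' @param values numeric matrix of cell values (logical matrices are accepted
#'   for masks and stored as 0/1).
#' @param cell_size_km positive edge length of the square cell, km.
#' @param nodata_mask logical matrix, `TRUE` where the cell carries no data.
#'   Defaults to `is.na(values)`.
#' @param origin numeric length-2, projected (x, y) of the grid's lower-left
#'   corner in km.
#' @return An object of class `hf_grid`.
#' @examples
#' g <- hf_grid(matrix(0, 8, 8), cell_size_km = 1)
#' dim(g$values)
#' @export
hf_grid <- function(values, cell_size_km = 1, nodata_mask = NULL,
                    origin = c(0, 0)) {
  if (is.logical(values)) values <- array(as.numeric(values), dim = dim(values))
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (!is.numeric(cell_size_km) || length(cell_size_km) != 1 ||
      !is.finite(cell_size_km) || cell_size_km <= 0)
    stop("`cell_size_km` must be a single positive number")
  if (is.null(nodata_mask)) nodata_mask <- is.na(values)
  if (!is.logical(nodata_mask) || !identical(dim(nodata_mask), dim(values)))
    stop("`nodata_mask` must be a logical matrix with the shape of `values`")
  if (any(!is.finite(values[!nodata_mask])))
    stop("values must be finite wherever nodata_mask is FALSE")
  if (length(origin) != 2 || !is.numeric(origin))
    stop("`origin` must be numeric length 2")
  structure(
    list(values = values, cell_size_km = cell_size_km,
         nodata_mask = nodata_mask, origin = as.numeric(origin)),
    class = "hf_grid"
  )
}

#' @export
print.hf_grid <- function(x, ...) {
  v <- x$values[!x$nodata_mask]
  cat(sprintf("<hf_grid> %d x %d cells @ %g km, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cell_size_km,
              x$origin[1], x$origin[2]))
  cat(sprintf("  data cells: %d (%d nodata); range [%g, %g]\n",
              length(v), sum(x$nodata_mask),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' @export
plot.hf_grid <- function(x, main = "", ...) {
  v <- x$values
  v[x$nodata_mask] <- NA
  # image() draws columns left-right, rows bottom-up; transpose accordingly
  graphics::image(t(v)[, nrow(v):1, drop = FALSE], main = main, ...)
  invisible(x)
}

#' @rdname hf_grid
#' @param x object to test.
#' @export
is_hf_grid <- function(x) inherits(x, "hf_grid")

#' Check that grids share a common grid definition
#'
#' All layers entering the pipeline must be pre-registered to one grid:
#' identical shape, cell size and origin. Fails loudly otherwise.
#'
#' @param ... two or more `hf_grid` objects.
#' @return `TRUE`, invisibly; otherwise an error.
#' @export
check_coregistered <- function(...) {
  gs <- list(...)
  if (length(gs) == 1 && is.list(gs[[1]]) && !is_hf_grid(gs[[1]])) gs <- gs[[1]]
  stopifnot(length(gs) >= 2)
  ref <- gs[[1]]
  for (g in gs[-1]) {
    if (!is_hf_grid(g) || !is_hf_grid(ref)) stop("inputs must be hf_grid objects")
    if (!identical(dim(g$values), dim(ref$values)))
      stop("grids are misregistered: differing shapes")
    if (!isTRUE(all.equal(g$cell_size_km, ref$cell_size_km)))
      stop("grids are misregistered: differing cell sizes")
    if (!isTRUE(all.equal(g$origin, ref$origin)))
      stop("grids are misregistered: differing origins")
  }
  invisible(TRUE)
}

# 1-D bilinear weight matrix: n_out x n_in, row k interpolates the value at
# output centre k from the two bracketing input centres, extrapolating
# linearly past the first/last centre (keeps affine surfaces exact).
bilinear_weights_1d <- function(n_in, n_out, ratio) {
  # output centre k (1-based) sits at input-index coordinate u:
  # physical (k - 0.5) * target = (u - 0.5) * source  =>  u = (k - 0.5) * ratio + 0.5
  u <- (seq_len(n_out) - 0.5) * ratio + 0.5
  i0 <- pmin(pmax(floor(u), 1L), n_in - 1L)
  w <- u - i0
  W <- matrix(0, n_out, n_in)
  W[cbind(seq_len(n_out), i0)] <- 1 - w
  W[cbind(seq_len(n_out), i0 + 1L)] <- w
  W
}

#' Bilinear resampling to a finer (or coarser) cell size
#'
#' Downscales a grid to a new cell size by bilinear interpolation between
#' input cell centres, the standard treatment for continuous fields such as
#' population density supplied on a coarser grid than the 1-km analysis grid.
#' The output covers exactly the input extent; the target cell size must
#' divide the extent evenly. Values are extrapolated linearly past the
#' outermost cell centres so any affine surface is reproduced exactly.
#' An output cell becomes nodata only when all of its (at most four) support
#' cells are nodata; otherwise the valid supports are renormalised.
#'
#' @param grid an `hf_grid` with at least 2x2 cells.
#' @param target_cell_km positive target cell size; must divide the grid
#'   extent evenly.
#' @return An `hf_grid` at the target resolution.
#' @examples
#' g <- hf_grid(matrix(5, 4, 4), cell_size_km = 4)
#' f <- bilinear_resample(g, 1)
#' unique(as.vector(f$values))
#' @export
bilinear_resample <- function(grid, target_cell_km) {
  stopifnot(is_hf_grid(grid))
  if (!is.numeric(target_cell_km) || length(target_cell_km) != 1 ||
      target_cell_km <= 0)
    stop("target cell size must be a single positive number")
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  if (nr < 2 || nc < 2)
    stop("grid must have at least 2x2 cells for bilinear interpolation")
  ext_y <- nr * grid$cell_size_km
  ext_x <- nc * grid$cell_size_km
  nro <- ext_y / target_cell_km
  nco <- ext_x / target_cell_km
  if (abs(nro - round(nro)) > 1e-9 || abs(nco - round(nco)) > 1e-9)
    stop("target cell size must divide the grid extent evenly")
  nro <- as.integer(round(nro)); nco <- as.integer(round(nco))
  ratio <- target_cell_km / grid$cell_size_km
  A <- bilinear_weights_1d(nr, nro, ratio)   # rows
  B <- bilinear_weights_1d(nc, nco, ratio)   # cols
  valid <- 1 - grid$nodata_mask
  v <- grid$values
  v[grid$nodata_mask] <- 0
  num <- A %*% (v * valid) %*% t(B)
  den <- A %*% valid %*% t(B)
  out <- num / den
  nodata <- den <= 1e-12
  out[nodata] <- NA_real_
  hf_grid(out, cell_size_km = target_cell_km, nodata_mask = nodata,
          origin = grid$origin)
}

#' Euclidean distance to the nearest feature cell
#'
#' Exact centre-to-centre Euclidean distance transform: every cell receives
#' the distance in km to the nearest `TRUE` cell of the feature mask. Used to
#' realize buffered direct-pressure bands and distance-decay access kernels
#' around roads, railways and navigable water. Computed with the separable
#' two-pass squared-distance transform (per-column nearest feature along
#' rows, then a per-row lower-envelope minimisation across columns), which is
#' exact on the square grid. Nodata cells are excluded as sources but still
#' receive a distance.
#'
#' @param feature_mask an `hf_grid` whose values are 0/1 (or logical); cells
#'   with value > 0 and not nodata are feature sources.
#' @return An `hf_grid` of distances in km (0 on feature cells).
#' @export
distance_map <- function(feature_mask) {
  stopifnot(is_hf_grid(feature_mask))
  src <- feature_mask$values > 0 & !feature_mask$nodata_mask
  if (!any(src)) stop("feature mask has no feature cells: distance undefined")
  nr <- nrow(src); nc <- ncol(src)
  # pass 1: squared row-distance to nearest source in each column
  d1 <- matrix(Inf, nr, nc)
  rows <- seq_len(nr)
  for (j in seq_len(nc)) {
    r <- which(src[, j])
    if (length(r))
      d1[, j] <- apply(outer(rows, r, function(a, b) (a - b)^2), 1, min)
  }
  # pass 2: for each row, min over columns k of d1[i,k] + (j-k)^2
  cols <- seq_len(nc)
  sq <- outer(cols, cols, function(a, b) (a - b)^2)  # nc x nc
  d <- matrix(Inf, nr, nc)
  for (i in seq_len(nr)) {
    fin <- is.finite(d1[i, ])
    if (any(fin))
      d[i, ] <- apply(sq[fin, , drop = FALSE] + d1[i, fin], 2, min)
  }
  hf_grid(sqrt(d) * feature_mask$cell_size_km,
          cell_size_km = feature_mask$cell_size_km,
          nodata_mask = feature_mask$nodata_mask,
          origin = feature_mask$origin)
}

#' Truncated exponential distance-decay kernel parameters
#'
#' The access-pressure kernel shared by roads and navigable waterways: a
#' score of `base_score` up to `d_start_km`, decaying exponentially beyond it
#' and truncated to zero past `d_max_km`. A pure exponential never reaches
#' zero, so the decay rate is set such that the kernel hits `floor` exactly
#' at `d_max_km`: `lambda = log(base_score / floor) / (d_max_km - d_start_km)`;
#' values below `floor` (hence all beyond `d_max_km`) are zeroed.
#'
#' @param base_score plateau score in `[0, 10]`.
#' @param d_start_km distance at which decay begins, km (>= 0).
#' @param d_max_km truncation distance, km (> `d_start_km`).
#' @param floor small positive kernel value at which scores are cut to 0;
#'   default `base_score / 16` (0.25 for the road/water base of 4).
#' @return A `decay_kernel_params` list.
#' @export
decay_kernel_params <- function(base_score, d_start_km, d_max_km,
                                floor = base_score / 16) {
  if (!is.numeric(base_score) || base_score < 0 || base_score > 10)
    stop("base_score must be in [0, 10]")
  if (d_start_km < 0) stop("d_start_km must be non-negative")
  if (d_max_km <= d_start_km) stop("d_max_km must exceed d_start_km")
  if (floor < 0 || floor >= base_score)
    stop("floor must satisfy 0 <= floor < base_score")
  structure(list(base_score = base_score, d_start_km = d_start_km,
                 d_max_km = d_max_km, floor = floor),
            class = "decay_kernel_params")
}

#' Apply the distance-decay kernel to a distance grid
#'
#' @param distance an `hf_grid` of non-negative distances in km (typically
#'   from [distance_map()]).
#' @param params a [decay_kernel_params()] object.
#' @return An `hf_grid` of scores in `[0, base_score]`, non-increasing in
#'   distance; nodata cells score 0 and stay masked.
#' @examples
#' p <- decay_kernel_params(4, 0.5, 15)
#' d <- hf_grid(matrix(c(0, 0.5, 7.75, 20), 2, 2))
#' apply_decay(d, p)$values
#' @export
apply_decay <- function(distance, params) {
  stopifnot(is_hf_grid(distance), inherits(params, "decay_kernel_params"))
  d <- distance$values
  if (any(d[!distance$nodata_mask] < 0)) stop("distances must be non-negative")
  lambda <- log(params$base_score / params$floor) /
    (params$d_max_km - params$d_start_km)
  s <- params$base_score * exp(-lambda * pmax(d - params$d_start_km, 0))
  s[d > params$d_max_km] <- 0
  s[s < params$floor] <- 0
  s[distance$nodata_mask] <- 0
  hf_grid(s, cell_size_km = distance$cell_size_km,
          nodata_mask = distance$nodata_mask, origin = distance$origin)
}
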