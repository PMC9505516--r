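#' Build a structured voxel grid over a layer stack
#'
#' Cell-centered finite-volume grid: uniform spacing in x and y, graded in z
#' so that every layer interface coincides with a grid line and thin upper
#' layers are resolved (the stratum corneum always gets at least 2 voxels).
#' The origin is at the array centroid on the skin surface; z grows downward
#' into the tissue.
#'
#' @param stack a [layer_stack()].
#' @param lateral_extent side length (m) of the square simulation footprint;
#'   must comfortably contain the electrode array (default 30 mm).
#' @param resolution `"coarse"`, `"default"`, `"fine"`, or a list with
#'   elements `nx` (lateral cells per side, odd recommended) and `nz_layer`
#'   (integer vector, z-cells per layer, one per stack layer).
#' @return object of class `ep_grid` with cell-center coordinates `xc`, `yc`,
#'   `zc`, spacings `dx`, `dy`, `dz` (per z-index), the per-z-index layer map
#'   `layer_of_k`, voxel volumes, and dimensions `nx`, `ny`, `nz`.
#' @export
build_grid <- function(stack, lateral_extent = 30e-3,
                       resolution = "default") {
  stopifnot(inherits(stack, "layer_stack"))
  nl <- length(stack$layers)
  res <- resolution_preset(resolution, nl)
  nx <- res$nx
  ny <- res$nx
  nz_layer <- res$nz_layer
  if (length(nz_layer) != nl)
    stop("'nz_layer' must give one cell count per layer")
  if (nz_layer[1] < 2L)
    stop("the surface layer must be resolved by at least 2 voxels")
  th <- vapply(stack$layers, `[[`, numeric(1), "thickness")
  dz <- rep(th / nz_layer, nz_layer)
  layer_of_k <- rep(seq_len(nl), nz_layer)
  zc <- cumsum(dz) - dz / 2
  dx <- lateral_extent / nx
  xc <- seq(-lateral_extent / 2 + dx / 2, lateral_extent / 2 - dx / 2,
            length.out = nx)
  structure(list(
    nx = nx, ny = ny, nz = length(dz),
    xc = xc, yc = xc, zc = zc,
    dx = dx, dy = dx, dz = dz,
    layer_of_k = layer_of_k,
    lateral_extent = lateral_extent,
    stack = stack), class = "ep_grid")
}

resolution_preset <- function(resolution, n_layers) {
  if (is.list(resolution)) {
    stopifnot(!is.null(resolution$nx), !is.null(resolution$nz_layer))
    return(list(nx = as.integer(resolution$nx),
                nz_layer = as.integer(resolution$nz_layer)))
  }
  preset <- match.arg(resolution, c("coarse", "default", "fine"))
  if (n_layers != 8L)
    stop("named presets assume the 8-layer stack; pass an explicit list")
  switch(preset,
    coarse  = list(nx = 31L, nz_layer = c(2L, 2L, 2L, 2L, 3L, 3L, 5L, 6L)),
    default = list(nx = 41L, nz_layer = c(2L, 3L, 3L, 2L, 4L, 4L, 6L, 8L)),
    fine    = list(nx = 61L, nz_layer = c(3L, 4L, 4L, 3L, 6L, 5L, 9L, 12L)))
}

#' @export
print.ep_grid <- function(x, ...) {
  cat(sprintf(
    "<ep_grid> %d x %d x %d voxels (%d total), %.3g x %.3g x %.4g mm\n",
    x$nx, x$ny, x$nz, x$nx * x$ny * x$nz, x$lateral_extent * 1e3,
    x$lateral_extent * 1e3, sum(x$dz) * 1e3))
  invisible(x)
}

#' Number of voxels in a grid
#' @param grid an [build_grid()] result.
#' @export
n_voxels <- function(grid) grid$nx * grid$ny * grid$nz

#' Voxel volumes (m^3), in voxel index order
#' @param grid an [build_grid()] result.
#' @return numeric vector of length `n_voxels(grid)`.
#' @export
voxel_volumes <- function(grid) {
  rep(grid$dz, each = grid$nx * grid$ny) * grid$dx * grid$dy
}

#' Layer index of every voxel
#' @param grid an [build_grid()] result.
#' @return integer vector of length `n_voxels(grid)` (layers vary only with
#'   depth).
#' @export
voxel_layer <- function(grid) {
  rep(grid$layer_of_k, each = grid$nx * grid$ny)
}

# linear voxel index from (i, j, k)
vox_index <- function(grid, i, j, k) {
  (k - 1L) * grid$nx * grid$ny + (j - 1L) * grid$nx + i
}
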