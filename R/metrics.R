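#' Classify voxels and measure electroporated volumes
#'
#' A voxel is irreversibly electroporated (IRE) when its field envelope
#' reached the IRE threshold of its layer, and reversibly electroporated
#' (RE) when the envelope reached the (direction-dependent, for muscle) RE
#' threshold but stayed below the IRE threshold. Volumes are sums of voxel
#' volumes; the RE depth is the largest voxel-center depth with RE exposure.
#'
#' @param grid an [build_grid()] result.
#' @param state an `ep_state` produced by [run_protocol()] on the same grid.
#' @param inclusive_re also report `re_volume_inclusive`, counting IRE voxels
#'   as part of the field-above-RE volume (default `TRUE`; the headline
#'   `re_volume` always excludes IRE).
#' @return object of class `volume_metrics`: `re_volume`, `ire_volume`
#'   (m^3), `re_volume_inclusive`, `re_depth` (m), and `per_layer` (data
#'   frame: layer, re, ire volumes in m^3).
#' @export
classify_and_measure <- function(grid, state, inclusive_re = TRUE) {
  stopifnot(inherits(grid, "ep_grid"), inherits(state, "ep_state"))
  if (length(state$e_env) != n_voxels(grid))
    stop("state does not match grid")
  pars <- grid_law_pars(grid)
  elow <- voxel_elow(pars, state$dir_x, state$dir_y, state$dir_z)
  ire <- state$e_env >= pars$ehigh
  above_re <- state$e_env >= elow
  re <- above_re & !ire
  vol <- voxel_volumes(grid)
  lay <- voxel_layer(grid)
  lnames <- vapply(grid$stack$layers, `[[`, character(1), "name")
  # every layer is represented in the grid, so rowsum groups are 1..n_layers
  per_layer <- data.frame(
    layer = lnames,
    re = as.numeric(rowsum(vol * re, lay)),
    ire = as.numeric(rowsum(vol * ire, lay)))
  zdepth <- rep(grid$zc, each = grid$nx * grid$ny)
  structure(list(
    re_volume = sum(vol[re]),
    ire_volume = sum(vol[ire]),
    re_volume_inclusive = if (inclusive_re) sum(vol[above_re]) else NA_real_,
    re_depth = if (any(re)) max(zdepth[re]) else 0,
    per_layer = per_layer,
    re_mask = re, ire_mask = ire), class = "volume_metrics")
}

#' @export
print.volume_metrics <- function(x, ...) {
  cat(sprintf(
    "<volume_metrics> RE %.4g mm^3, IRE %.4g mm^3, RE depth %.3g mm\n",
    x$re_volume * 1e9, x$ire_volume * 1e9, x$re_depth * 1e3))
  invisible(x)
}

#' Compare two protocols' electroporation metrics
#'
#' Percentage differences with the second argument (conventionally the
#' classical protocol) as baseline:
#' `re_pct = 100 * (a$re - b$re) / b$re` (positive when `a` reversibly
#' electroporates more tissue) and
#' `ire_reduction_pct = 100 * (b$ire - a$ire) / b$ire` (positive when `a`
#' causes less irreversible damage).
#'
#' @param a [classify_and_measure()] metrics of the candidate protocol.
#' @param b metrics of the baseline protocol (same grid and stack).
#' @return list with `re_pct`, `ire_reduction_pct`, `depth_diff` (m), and
#'   `undefined` (TRUE when a baseline volume is zero).
#' @export
compare_protocols <- function(a, b) {
  stopifnot(inherits(a, "volume_metrics"), inherits(b, "volume_metrics"))
  undef <- b$re_volume == 0 || b$ire_volume == 0
  list(
    re_pct = if (b$re_volume > 0)
      100 * (a$re_volume - b$re_volume) / b$re_volume else NA_real_,
    ire_reduction_pct = if (b$ire_volume > 0)
      100 * (b$ire_volume - a$ire_volume) / b$ire_volume else NA_real_,
    depth_diff = a$re_depth - b$re_depth,
    undefined = undef)
}

#' Extract a field-magnitude slice
#'
#' Samples the field envelope (or a single step's field magnitude) on a
#' horizontal plane at a given depth, by linear interpolation between the two
#' adjacent voxel-center planes, or on the vertical x-z mid-plane (y = 0,
#' i.e. midway between electrodes for the standard arrays).
#'
#' @param grid an [build_grid()] result.
#' @param x an `ep_state` (uses `e_env`) or a `field_solution` / per-step
#'   solution (uses `e_mag`).
#' @param depth slice depth (m), for `plane = "horizontal"`; must lie in
#'   `[0, domain depth)`.
#' @param plane `"horizontal"` or `"vertical"`.
#' @param log take the natural logarithm of the field (zeros mapped to
#'   `-Inf`)? Default `FALSE`.
#' @return a matrix (rows = x, cols = y for horizontal; rows = x, cols = z
#'   for vertical) with the sampled field (V/m), with coordinate vectors as
#'   attributes `coord1`, `coord2` (m).
#' @export
field_slice <- function(grid, x, depth = NULL,
                        plane = c("horizontal", "vertical"), log = FALSE) {
  plane <- match.arg(plane)
  field <- if (!is.null(x$e_env)) x$e_env else x$e_mag
  if (is.null(field)) stop("'x' carries neither 'e_env' nor 'e_mag'")
  arr <- array(field, dim = c(grid$nx, grid$ny, grid$nz))
  if (plane == "horizontal") {
    if (is.null(depth)) stop("'depth' is required for a horizontal slice")
    if (depth < 0 || depth >= sum(grid$dz))
      stop("'depth' outside the model domain")
    k <- findInterval(depth, grid$zc)
    if (k == 0L) {
      sl <- arr[, , 1L]
    } else if (k >= grid$nz) {
      sl <- arr[, , grid$nz]
    } else {
      w <- (depth - grid$zc[k]) / (grid$zc[k + 1L] - grid$zc[k])
      sl <- (1 - w) * arr[, , k] + w * arr[, , k + 1L]
    }
    attr(sl, "coord1") <- grid$xc
    attr(sl, "coord2") <- grid$yc
  } else {
    jmid <- which.min(abs(grid$yc))
    sl <- arr[, jmid, ]
    attr(sl, "coord1") <- grid$xc
    attr(sl, "coord2") <- grid$zc
  }
  if (log) sl <- base::log(sl)
  sl
}
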