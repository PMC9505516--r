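#' Skin layer description
#'
#' A single tissue layer of the skin model: thickness, diagonal electrical
#' conductivity tensor, reversible (RE) and irreversible (IRE) electroporation
#' thresholds, and the maximal conductivity increase reached once the layer is
#' fully electroporated. Skeletal muscle additionally carries a fiber axis and
#' a second, lower RE threshold for fields parallel to the fibers.
#'
#' All quantities use SI units internally: lengths in m, conductivities in
#' S/m, field thresholds in V/m. Use [v_per_cm()] / [mm()] to convert the
#' units in which tissue properties are usually tabulated.
#'
#' @param name layer name.
#' @param thickness layer thickness (m), `> 0`.
#' @param sigma length-3 numeric, diagonal conductivity tensor
#'   `(sigma_x, sigma_y, sigma_z)` in S/m; a length-1 value is recycled
#'   (isotropic layer).
#' @param re_threshold reversible electroporation threshold (V/m). For muscle
#'   this is the threshold for fields perpendicular to the fibers.
#' @param ire_threshold irreversible electroporation threshold (V/m).
#' @param max_sigma_factor maximal conductivity increase factor (>= 1) at
#'   full electroporation.
#' @param fiber_axis optional length-3 unit vector of the muscle fiber
#'   direction.
#' @param re_threshold_parallel optional RE threshold (V/m) for fields
#'   parallel to `fiber_axis`; must not exceed `re_threshold`.
#' @return an object of class `skin_layer`.
#' @seealso [default_skin_stack()], [sigma_of_field()]
#' @export
skin_layer <- function(name, thickness, sigma, re_threshold, ire_threshold,
                       max_sigma_factor, fiber_axis = NULL,
                       re_threshold_parallel = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(thickness) || length(thickness) != 1L || thickness <= 0)
    stop("'thickness' must be a positive scalar (m)")
  sigma <- as.numeric(sigma)
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  if (length(sigma) != 3L || any(sigma <= 0))
    stop("'sigma' must be 1 or 3 positive values (S/m)")
  if (re_threshold <= 0 || ire_threshold <= 0)
    stop("thresholds must be positive (V/m)")
  if (re_threshold > ire_threshold)
    stop("'re_threshold' must not exceed 'ire_threshold'")
  if (max_sigma_factor < 1)
    stop("'max_sigma_factor' must be >= 1")
  if (!is.null(fiber_axis)) {
    fiber_axis <- as.numeric(fiber_axis)
    stopifnot(length(fiber_axis) == 3L)
    nrm <- sqrt(sum(fiber_axis^2))
    if (nrm == 0) stop("'fiber_axis' must be non-zero")
    fiber_axis <- fiber_axis / nrm
  }
  if (!is.null(re_threshold_parallel)) {
    if (re_threshold_parallel > re_threshold)
      stop("'re_threshold_parallel' must not exceed 're_threshold'")
    if (is.null(fiber_axis))
      stop("'re_threshold_parallel' requires 'fiber_axis'")
  }
  structure(
    list(name = name, thickness = thickness,
         sigma = stats::setNames(sigma, c("x", "y", "z")),
         re_threshold = re_threshold, ire_threshold = ire_threshold,
         max_sigma_factor = max_sigma_factor, fiber_axis = fiber_axis,
         re_threshold_parallel = re_threshold_parallel),
    class = "skin_layer")
}

#' @export
print.skin_layer <- function(x, ...) {
  cat(sprintf("<skin_layer> %s: %.4g mm, sigma = (%.3g, %.3g, %.3g) S/m\n",
              x$name, x$thickness * 1e3, x$sigma[1], x$sigma[2], x$sigma[3]))
  cat(sprintf("  RE %.5g V/m%s, IRE %.5g V/m, max sigma increase %gx\n",
              x$re_threshold,
              if (!is.null(x$re_threshold_parallel))
                sprintf(" (parallel %.5g V/m)", x$re_threshold_parallel) else "",
              x$ire_threshold, x$max_sigma_factor))
  invisible(x)
}

#' Ordered stack of skin layers
#'
#' Layers are ordered from the skin surface (z = 0) downward; depth z grows
#' into the tissue. Interface depths are derived from the cumulative layer
#' thicknesses.
#'
#' @param layers list of [skin_layer()] objects, surface first.
#' @return object of class `layer_stack` with elements `layers` and
#'   `z_interfaces` (length `n_layers + 1`, starting at 0).
#' @export
layer_stack <- function(layers) {
  stopifnot(length(layers) >= 1L,
            all(vapply(layers, inherits, logical(1), "skin_layer")))
  th <- vapply(layers, `[[`, numeric(1), "thickness")
  z <- c(0, cumsum(th))
  structure(list(layers = layers, z_interfaces = z), class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  cat(sprintf("<layer_stack> %d layers, total depth %.4g mm\n",
              length(x$layers), total_depth(x) * 1e3))
  for (l in x$layers) print(l)
  invisible(x)
}

#' Total depth of a layer stack (m)
#' @param stack a [layer_stack()].
#' @export
total_depth <- function(stack) {
  stopifnot(inherits(stack, "layer_stack"))
  stack$z_interfaces[length(stack$z_interfaces)]
}

#' Convert V/cm to V/m
#' @param x field strength in V/cm.
#' @export
v_per_cm <- function(x) x * 100

#' Convert mm to m
#' @param x length in mm.
#' @export
mm <- function(x) x * 1e-3

#' Default eight-layer skin stack
#'
#' The standard layered skin model used for gene-electrotransfer treatment
#' planning: stratum corneum, epidermis, papillary dermis, upper vessel
#' plexus, supply layer, deeper vessel plexus, hypodermis, and skeletal
#' muscle, with anisotropic conductivities, reversible/irreversible
#' electroporation thresholds, and the maximal conductivity increase of each
#' layer upon electroporation. The muscle layer carries a direction-dependent
#' RE threshold (80 V/cm parallel to the fibers, 200 V/cm perpendicular) and
#' its fiber axis is the direction of largest conductivity (y).
#'
#' @return a [layer_stack()] of 8 layers; total depth 27.35 mm.
#' @export
default_skin_stack <- function() {
  layer_stack(list(
    skin_layer("stratum_corneum", 20e-6,
               c(1.10e-2, 1.10e-2, 2.23e-4),
               v_per_cm(400), v_per_cm(1200), 100),
    skin_layer("epidermis", mm(0.1),
               c(5.82e-2, 5.82e-2, 6.36e-2),
               v_per_cm(400), v_per_cm(1200), 3.5),
    skin_layer("papillary_dermis", mm(0.15),
               7.19e-2,
               v_per_cm(300), v_per_cm(1200), 3.5),
    skin_layer("upper_vessel_plexus", 80e-6,
               c(4.22e-1, 3.86e-1, 3.86e-1),
               v_per_cm(300), v_per_cm(1200), 3.5),
    skin_layer("supply_layer", mm(1),
               c(3.12e-1, 3.12e-1, 3.19e-1),
               v_per_cm(300), v_per_cm(1200), 3.5),
    skin_layer("deeper_vessel_plexus", mm(1),
               c(3.42e-1, 3.28e-1, 3.28e-1),
               v_per_cm(300), v_per_cm(1200), 3.5),
    skin_layer("hypodermis", mm(5),
               6.35e-2,
               v_per_cm(300), v_per_cm(1200), 3.5),
    skin_layer("muscle", mm(20),
               c(1.57e-2, 6.86e-2, 1.57e-2),
               v_per_cm(200), v_per_cm(800), 2.5,
               fiber_axis = c(0, 1, 0),
               re_threshold_parallel = v_per_cm(80))
  ))
}

#' Look up the layer containing a given depth
#'
#' Layers occupy half-open depth intervals `[z_top, z_bottom)`, so every
#' depth in `[0, total_depth)` maps to exactly one layer.
#'
#' @param stack a [layer_stack()].
#' @param z depth below the skin surface (m).
#' @return the [skin_layer()] containing `z`.
#' @export
layer_at_depth <- function(stack, z) {
  stopifnot(inherits(stack, "layer_stack"), is.numeric(z), length(z) == 1L)
  if (z < 0 || z >= total_depth(stack))
    stop(sprintf("depth %g m outside the model domain [0, %g m)",
                 z, total_depth(stack)))
  i <- findInterval(z, stack$z_interfaces, rightmost.closed = FALSE)
  stack$layers[[i]]
}

#' Index of the layer containing each depth (vectorized, internal)
#' @noRd
layer_index_at_depth <- function(stack, z) {
  i <- findInterval(z, stack$z_interfaces)
  if (any(i < 1L | i > length(stack$layers)))
    stop("depth outside the model domain")
  i
}

#' Field-dependent conductivity law
#'
#' Conductivity increases with the local electric field following a sigmoid:
#' below the layer's RE threshold the tissue keeps its baseline conductivity;
#' above the IRE threshold the increase saturates at the layer's maximal
#' factor. The transition is a logistic curve centered midway between the two
#' thresholds, normalized so that the endpoint conditions
#' `sigma(0) = sigma0` and `sigma(Inf) = max_factor * sigma0` hold exactly.
#'
#' @param steepness dimensionless steepness `k` of the logistic transition
#'   (default 10; larger values sharpen the RE-to-IRE transition).
#' @return object of class `conductivity_law`.
#' @export
conductivity_law <- function(steepness = 10) {
  stopifnot(is.numeric(steepness), length(steepness) == 1L, steepness > 0)
  structure(list(steepness = steepness), class = "conductivity_law")
}

#' Effective RE threshold for a field direction
#'
#' For layers without a fiber axis this is the scalar RE threshold. For
#' muscle the threshold interpolates elliptically between the parallel and
#' perpendicular values:
#' `E_th(theta)^-2 = (cos(theta)/E_par)^2 + (sin(theta)/E_perp)^2`,
#' where `theta` is the angle between the field and the fiber axis.
#'
#' @param layer a [skin_layer()].
#' @param e_dir unit field direction (length-3), or a 3-column matrix of
#'   directions; ignored for layers without `fiber_axis`. `NULL` means
#'   direction unknown: the (higher) perpendicular threshold is used.
#' @return effective RE threshold(s), V/m.
#' @export
effective_re_threshold <- function(layer, e_dir = NULL) {
  stopifnot(inherits(layer, "skin_layer"))
  if (is.null(layer$fiber_axis) || is.null(layer$re_threshold_parallel) ||
      is.null(e_dir))
    return(layer$re_threshold)
  dirm <- if (is.matrix(e_dir)) e_dir else matrix(e_dir, ncol = 3)
  nrm <- sqrt(rowSums(dirm^2))
  cosang <- numeric(nrow(dirm))
  ok <- nrm > 0
  cosang[ok] <- (dirm[ok, , drop = FALSE] %*% layer$fiber_axis) / nrm[ok]
  cosang <- pmin(1, pmax(-1, cosang))
  c2 <- cosang^2
  s2 <- 1 - c2
  # zero-field voxels have no direction: fall back to perpendicular threshold
  thr <- 1 / sqrt(c2 / layer$re_threshold_parallel^2 +
                    s2 / layer$re_threshold^2)
  thr[!ok] <- layer$re_threshold
  if (is.matrix(e_dir)) thr else thr[1]
}

# Normalized logistic scaling factor in [1, max_factor].
# e_low/e_high may be vectors (muscle voxels have direction-dependent e_low).
sigmoid_factor <- function(e_mag, e_low, e_high, max_factor, steepness) {
  mid <- (e_low + e_high) / 2
  span <- e_high - e_low
  lg <- function(e) stats::plogis(steepness * (e - mid) / span)
  l0 <- lg(0)
  g <- (lg(e_mag) - l0) / (1 - l0)
  1 + (max_factor - 1) * pmin(pmax(g, 0), 1)
}

#' Conductivity scaling factor at a given field
#'
#' Evaluates the sigmoid electroporation law of a layer: the dimensionless
#' factor by which the baseline conductivity tensor is scaled at field
#' magnitude `e_mag`. Rises from 1 (around and below the RE threshold) to
#' `max_sigma_factor` (at and above the IRE threshold).
#'
#' @param layer a [skin_layer()].
#' @param law a [conductivity_law()].
#' @param e_mag field magnitude(s), V/m, `>= 0`; vectorized.
#' @param e_dir optional field direction(s) (length-3 vector or 3-column
#'   matrix), consulted only for layers with a fiber axis.
#' @return numeric factor(s) in `[1, max_sigma_factor]`.
#' @export
sigma_scaling <- function(layer, law, e_mag, e_dir = NULL) {
  stopifnot(inherits(layer, "skin_layer"), inherits(law, "conductivity_law"))
  if (any(e_mag < 0)) stop("'e_mag' must be non-negative")
  e_low <- effective_re_threshold(layer, e_dir)
  sigmoid_factor(e_mag, e_low, layer$ire_threshold, layer$max_sigma_factor,
                 law$steepness)
}

#' Field-dependent conductivity tensor
#'
#' Returns the diagonal conductivity tensor of a layer at the given electric
#' field: the baseline tensor scaled isotropically by the sigmoid
#' electroporation factor.
#'
#' @inheritParams sigma_scaling
#' @return named length-3 numeric `(x, y, z)`, S/m (for scalar `e_mag`), or
#'   a 3-column matrix for vector input.
#' @export
sigma_of_field <- function(layer, law, e_mag, e_dir = NULL) {
  f <- sigma_scaling(layer, law, e_mag, e_dir)
  if (length(f) == 1L) layer$sigma * f
  else outer(f, layer$sigma)
}

#' Serialize a layer stack to a plain configuration list
#'
#' Produces a list (one entry per layer) mirroring the tabulated tissue
#' properties column for column, in the units such tables are printed in
#' (thickness in mm, thresholds in V/cm, conductivities in S/m), suitable for
#' YAML/JSON round trips.
#'
#' @param stack a [layer_stack()].
#' @return a list with one named sub-list per layer.
#' @export
stack_to_config <- function(stack) {
  stopifnot(inherits(stack, "layer_stack"))
  lapply(stack$layers, function(l) {
    cfg <- list(
      name = l$name,
      thickness_mm = l$thickness * 1e3,
      sigma_x_S_per_m = unname(l$sigma[1]),
      sigma_y_S_per_m = unname(l$sigma[2]),
      sigma_z_S_per_m = unname(l$sigma[3]),
      re_threshold_V_per_cm = l$re_threshold / 100,
      ire_threshold_V_per_cm = l$ire_threshold / 100,
      max_sigma_increase = l$max_sigma_factor)
    if (!is.null(l$fiber_axis)) cfg$fiber_axis <- as.numeric(l$fiber_axis)
    if (!is.null(l$re_threshold_parallel))
      cfg$re_threshold_parallel_V_per_cm <- l$re_threshold_parallel / 100
    cfg
  })
}

#' Rebuild a layer stack from its configuration list
#'
#' Inverse of [stack_to_config()].
#'
#' @param cfg list as produced by [stack_to_config()] (or read from YAML).
#' @return a [layer_stack()].
#' @export
stack_from_config <- function(cfg) {
  layer_stack(lapply(cfg, function(l) {
    skin_layer(
      name = l$name,
      thickness = mm(l$thickness_mm),
      sigma = c(l$sigma_x_S_per_m, l$sigma_y_S_per_m, l$sigma_z_S_per_m),
      re_threshold = v_per_cm(l$re_threshold_V_per_cm),
      ire_threshold = v_per_cm(l$ire_threshold_V_per_cm),
      max_sigma_factor = l$max_sigma_increase,
      fiber_axis = l$fiber_axis,
      re_threshold_parallel =
        if (!is.null(l$re_threshold_parallel_V_per_cm))
          v_per_cm(l$re_threshold_parallel_V_per_cm))
  }))
}
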