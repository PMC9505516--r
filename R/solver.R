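#' @useDynLib skinget, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Finite-volume discretization: cell-centered on the structured grid, with
# face conductances formed from the two half-cell resistances in series
# (harmonic averaging). The discrete system is SPD; Dirichlet electrode
# contacts enter through boundary half-cell conductances on the top/bottom
# faces, every other boundary face is insulating (zero normal current).
# ---------------------------------------------------------------------------

# Precompute the face lists and the lower-triangular CSR pattern of the grid.
# The pattern is independent of conductivity and of which electrodes are
# active, so it is built once per grid and reused across all steps.
solver_structure <- function(grid) {
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  n <- nx * ny * nz
  dx <- grid$dx; dy <- grid$dy; dz <- grid$dz

  fidx <- function(i, j, k) (k - 1L) * nx * ny + (j - 1L) * nx + i

  # x-faces
  g <- expand.grid(i = seq_len(nx - 1L), j = seq_len(ny), k = seq_len(nz))
  fx_a <- fidx(g$i, g$j, g$k); fx_b <- fx_a + 1L
  fx_h <- 0.5 * dx / (dy * dz[g$k])          # half-resistance geometry term
  fx_d <- rep(dx, length(fx_a))
  # y-faces
  g <- expand.grid(i = seq_len(nx), j = seq_len(ny - 1L), k = seq_len(nz))
  fy_a <- fidx(g$i, g$j, g$k); fy_b <- fy_a + nx
  fy_h <- 0.5 * dy / (dx * dz[g$k])
  fy_d <- rep(dy, length(fy_a))
  # z-faces (graded: the two half-cells differ)
  g <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz - 1L))
  fz_a <- fidx(g$i, g$j, g$k); fz_b <- fz_a + nx * ny
  fz_ha <- 0.5 * dz[g$k] / (dx * dy)
  fz_hb <- 0.5 * dz[g$k + 1L] / (dx * dy)
  fz_d <- 0.5 * (dz[g$k] + dz[g$k + 1L])

  f_a <- c(fx_a, fy_a, fz_a)
  f_b <- c(fx_b, fy_b, fz_b)
  f_ha <- c(fx_h, fy_h, fz_ha)
  f_hb <- c(fx_h, fy_h, fz_hb)
  f_dist <- c(fx_d, fy_d, fz_d)
  f_axis <- rep.int(1:3, c(length(fx_a), length(fy_a), length(fz_a)))
  f_area <- f_dist / (f_ha + f_hb)  # half terms are 0.5*d/A
  nf <- length(f_a)

  # lower-triangular CSR pattern: off-diagonals at (row = f_b, col = f_a)
  rows <- c(f_b, seq_len(n))
  cols <- c(f_a, seq_len(n))
  o <- order(rows, cols)
  pos <- integer(length(rows)); pos[o] <- seq_along(o)
  rp <- c(0L, cumsum(tabulate(rows, n)))

  list(n = n, f_a = f_a, f_b = f_b, f_ha = f_ha, f_hb = f_hb,
       f_dist = f_dist, f_area = f_area, f_axis = f_axis, nf = nf,
       csr_rp = as.integer(rp), csr_ci = as.integer(cols[o] - 1L),
       face_pos = pos[seq_len(nf)], diag_pos = pos[nf + seq_len(n)])
}

# Per-voxel electroporation-law parameters, expanded from the per-layer table.
grid_law_pars <- function(grid) {
  st <- grid$stack
  lay <- voxel_layer(grid)
  getl <- function(f) vapply(st$layers, f, numeric(1))[lay]
  sx <- getl(function(l) l$sigma[["x"]])
  sy <- getl(function(l) l$sigma[["y"]])
  sz <- getl(function(l) l$sigma[["z"]])
  elow <- getl(function(l) l$re_threshold)
  ehigh <- getl(function(l) l$ire_threshold)
  maxf <- getl(function(l) l$max_sigma_factor)
  elow_par <- getl(function(l)
    if (is.null(l$re_threshold_parallel)) NA_real_ else l$re_threshold_parallel)
  fib <- t(vapply(st$layers, function(l)
    if (is.null(l$fiber_axis)) c(NA_real_, NA_real_, NA_real_)
    else l$fiber_axis, numeric(3)))
  list(sx = sx, sy = sy, sz = sz, elow = elow, ehigh = ehigh, maxf = maxf,
       elow_par = elow_par, fib = fib[lay, , drop = FALSE],
       aniso = !is.na(elow_par))
}

# Effective RE threshold per voxel given field direction components
# (elliptical interpolation between parallel and perpendicular thresholds
# for fiber-bearing layers; others keep their scalar threshold).
voxel_elow <- function(pars, ex, ey, ez) {
  elow <- pars$elow
  m <- pars$aniso
  if (any(m)) {
    nrm2 <- ex[m]^2 + ey[m]^2 + ez[m]^2
    dot <- ex[m] * pars$fib[m, 1] + ey[m] * pars$fib[m, 2] +
      ez[m] * pars$fib[m, 3]
    c2 <- ifelse(nrm2 > 0, pmin(1, dot^2 / nrm2), 0)
    thr <- 1 / sqrt(c2 / pars$elow_par[m]^2 + (1 - c2) / pars$elow[m]^2)
    elow[m] <- ifelse(nrm2 > 0, thr, pars$elow[m])
  }
  elow
}

# Per-voxel conductivity scaling factor at field magnitude e with direction
# components; vectorized over the whole grid.
voxel_sigma_factor <- function(pars, law, e, ex, ey, ez) {
  elow <- voxel_elow(pars, ex, ey, ez)
  sigmoid_factor(e, elow, pars$ehigh, pars$maxf, law$steepness)
}

# Plate/disc contact on the top or bottom boundary, for validation slabs.
#' Dirichlet contact patch on the top or bottom grid face
#'
#' Low-level boundary-condition constructor used by the validation oracles
#' and available for custom simulations: imposes a fixed potential on the
#' boundary faces of all cells whose centers lie within `radius` of
#' `(x, y)` on the chosen face (use `radius = Inf` for a full plate).
#'
#' @param grid an [build_grid()] result.
#' @param value applied potential (V).
#' @param side `"top"` (skin surface) or `"bottom"`.
#' @param x,y patch center (m).
#' @param radius patch radius (m), `Inf` for the whole face.
#' @return a contact description consumed by [solve_field()].
#' @export
contact_patch <- function(grid, value, side = c("top", "bottom"),
                          x = 0, y = 0, radius = Inf) {
  side <- match.arg(side)
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  d2 <- outer(grid$xc - x, rep(1, ny))^2 + outer(rep(1, nx), grid$yc - y)^2
  inside <- which(d2 <= radius^2)
  if (length(inside) == 0L) inside <- which.min(d2)
  k <- if (side == "top") 1L else nz
  cells <- (k - 1L) * nx * ny + inside
  list(cells = cells, values = rep(value, length(inside)),
       half = 0.5 * grid$dz[k] / (grid$dx * grid$dy),
       sigma_comp = "sz",
       e_sign = if (side == "top") +1 else -1)
}

merge_contacts <- function(...) {
  cs <- list(...)
  list(cells = unlist(lapply(cs, `[[`, "cells")),
       values = unlist(lapply(cs, `[[`, "values")),
       half = unlist(lapply(cs, function(c)
         rep(c$half, length(c$cells)))),
       e_sign = unlist(lapply(cs, function(c)
         rep(c$e_sign, length(c$cells)))))
}

# Assemble CSR values and rhs for given per-voxel conductivities, solve, and
# return potential + fields + contact currents.
linear_solve <- function(struct, svox, contacts, x0, lin_tol, lin_maxit) {
  sa_ax <- list(svox$sx, svox$sy, svox$sz)
  sa <- numeric(struct$nf); sb <- numeric(struct$nf)
  for (ax in 1:3) {
    m <- struct$f_axis == ax
    sa[m] <- sa_ax[[ax]][struct$f_a[m]]
    sb[m] <- sa_ax[[ax]][struct$f_b[m]]
  }
  gface <- 1 / (struct$f_ha / sa + struct$f_hb / sb)
  diag <- .scatter_add(c(struct$f_a, struct$f_b), c(gface, gface), struct$n)
  gc_ct <- svox$sz[contacts$cells] / contacts$half
  diag_ct <- .scatter_add(contacts$cells, gc_ct, struct$n)
  rhs <- .scatter_add(contacts$cells, gc_ct * contacts$values, struct$n)
  vals <- numeric(length(struct$csr_ci))
  vals[struct$face_pos] <- -gface
  vals[struct$diag_pos] <- diag + diag_ct
  sol <- .pcg_ic0(struct$csr_rp, struct$csr_ci, vals, rhs, x0,
                  lin_tol, lin_maxit)
  phi <- sol$x

  # flux-consistent field reconstruction: the current density through each
  # face, divided by the adjacent cell's own conductivity, gives that cell's
  # field at the face (exact across material interfaces, where E jumps but J
  # is continuous); the two face values per axis are averaged per voxel.
  # Insulating boundary faces contribute zero, electrode contact faces their
  # half-cell field.
  e <- list()
  for (ax in 1:3) {
    m <- struct$f_axis == ax
    q <- gface[m] * (phi[struct$f_a[m]] - phi[struct$f_b[m]]) /
      struct$f_area[m]  # current density a -> b
    ea <- q / sa[m]
    eb <- q / sb[m]
    acc <- .scatter_add(c(struct$f_a[m], struct$f_b[m]), c(ea, eb), struct$n)
    if (ax == 3L) {
      ec <- contacts$e_sign * (contacts$values - phi[contacts$cells]) /
        contacts$half_dist
      acc <- acc + .scatter_add(contacts$cells, ec, struct$n)
    }
    e[[ax]] <- acc / 2
  }
  emag <- sqrt(e[[1]]^2 + e[[2]]^2 + e[[3]]^2)
  i_contact <- gc_ct * (contacts$values - phi[contacts$cells])
  list(phi = phi, ex = e[[1]], ey = e[[2]], ez = e[[3]], e_mag = emag,
       i_contact = i_contact, pcg_iter = sol$iter, relres = sol$relres)
}

#' Solver control parameters
#'
#' @param picard_tol relative tolerance on the per-voxel field magnitude
#'   between successive conductivity updates (default 1e-3).
#' @param max_iter maximal number of damped Picard iterations per step
#'   (default 50).
#' @param damping damping factor in (0, 1] applied to conductivity-factor
#'   updates (default 0.5; the sigmoid law can oscillate undamped).
#' @param lin_tol relative residual tolerance of the inner conjugate-gradient
#'   solver (default 1e-7; comfortably below the Picard tolerance while
#'   keeping the discrete current balance well under 1%).
#' @param lin_maxit inner CG iteration cap (default 20000).
#' @return a list of class `solver_control`.
#' @export
solver_control <- function(picard_tol = 1e-3, max_iter = 50, damping = 0.5,
                           lin_tol = 1e-7, lin_maxit = 20000) {
  stopifnot(picard_tol > 0, max_iter >= 1, damping > 0, damping <= 1)
  structure(list(picard_tol = picard_tol, max_iter = as.integer(max_iter),
                 damping = damping, lin_tol = lin_tol,
                 lin_maxit = as.integer(lin_maxit)),
            class = "solver_control")
}

#' Solve one stationary field problem at fixed electroporation state
#'
#' Solves the nonlinear stationary current-conservation problem
#' `div(sigma(E) grad(phi)) = 0` with Dirichlet potentials on the given
#' contact patches and insulating outer boundaries. The conductivity is
#' iterated to self-consistency by damped Picard iteration: within the step
#' each voxel responds to the larger of its accumulated field envelope and
#' the present field magnitude.
#'
#' @param grid an [build_grid()] result.
#' @param contacts one contact description ([contact_patch()]) or a list of
#'   them.
#' @param law a [conductivity_law()].
#' @param state optional electroporation state from a previous step
#'   ([new_ep_state()]); defaults to virgin tissue.
#' @param control a [solver_control()].
#' @param struct optional precomputed solver structure (internal reuse).
#' @param pars optional precomputed law parameters (internal reuse).
#' @param phi0 optional initial potential guess (per voxel) for the inner
#'   iterative solver; the solution is independent of it.
#' @return a `field_solution`: potential `phi`, field components
#'   `ex`, `ey`, `ez`, magnitude `e_mag` (all per voxel), contact currents
#'   `i_source` / `i_sink` (A), `picard_iter`, `converged`.
#' @export
solve_field <- function(grid, contacts, law = conductivity_law(),
                        state = NULL, control = solver_control(),
                        struct = NULL, pars = NULL, phi0 = NULL) {
  stopifnot(inherits(grid, "ep_grid"))
  if (!is.null(contacts$cells)) contacts <- list(contacts)
  ct <- do.call(merge_contacts, contacts)
  ct$half_dist <- ct$half * (grid$dx * grid$dy)  # = 0.5 * dz of contact cell
  if (length(ct$cells) == 0L) stop("no contact cells: singular system")
  if (length(unique(ct$values)) < 2L && all(ct$values == 0))
    warning("all contacts grounded; trivial zero solution")
  if (is.null(struct)) struct <- solver_structure(grid)
  if (is.null(pars)) pars <- grid_law_pars(grid)
  n <- struct$n
  if (is.null(state)) state <- new_ep_state(grid)
  f <- state$f
  phi <- if (is.null(phi0)) numeric(n) else phi0
  emag_prev <- NULL
  converged <- FALSE
  iter <- 0L
  damping <- control$damping
  delta_hist <- numeric(0)
  repeat {
    iter <- iter + 1L
    svox <- list(sx = f * pars$sx, sy = f * pars$sy, sz = f * pars$sz)
    sol <- linear_solve(struct, svox, ct, phi, control$lin_tol,
                        control$lin_maxit)
    phi <- sol$phi
    scale <- max(sol$e_mag)
    if (!is.null(emag_prev)) {
      delta <- if (scale > 0) max(abs(sol$e_mag - emag_prev)) / scale else 0
      if (delta < control$picard_tol) { converged <- TRUE; break }
      delta_hist <- c(delta_hist, delta)
      # the steep sigmoid can trap a few voxels in a limit cycle at fixed
      # damping; halve the damping when the iteration stops making progress
      nh <- length(delta_hist)
      if (nh >= 6 && delta_hist[nh] > 0.8 * delta_hist[nh - 4])
        damping <- max(damping / 2, 0.05)
    }
    if (iter >= control$max_iter) break
    emag_prev <- sol$e_mag
    # conductivity responds to max(envelope, current field)
    use_cur <- sol$e_mag >= state$e_env
    eff <- pmax(state$e_env, sol$e_mag)
    ex <- ifelse(use_cur, sol$ex, state$dir_x * state$e_env)
    ey <- ifelse(use_cur, sol$ey, state$dir_y * state$e_env)
    ez <- ifelse(use_cur, sol$ez, state$dir_z * state$e_env)
    f_target <- voxel_sigma_factor(pars, law, eff, ex, ey, ez)
    f <- f + damping * (f_target - f)
  }
  if (!converged)
    warning(sprintf("Picard iteration not converged in %d iterations",
                    control$max_iter))
  pos <- ct$values > 0
  structure(list(phi = sol$phi, ex = sol$ex, ey = sol$ey, ez = sol$ez,
                 e_mag = sol$e_mag,
                 i_source = sum(sol$i_contact[pos]),
                 i_sink = -sum(sol$i_contact[!pos]),
                 picard_iter = iter, converged = converged,
                 pcg_relres = sol$relres, f = f),
            class = "field_solution")
}

#' Fresh electroporation state (virgin tissue)
#'
#' @param grid an [build_grid()] result.
#' @return object of class `ep_state` holding the per-voxel field envelope
#'   `e_env` (V/m), the unit field direction at the envelope maximum
#'   (`dir_x`, `dir_y`, `dir_z`), and the current conductivity scaling
#'   factor `f`.
#' @export
new_ep_state <- function(grid) {
  n <- n_voxels(grid)
  structure(list(e_env = numeric(n),
                 dir_x = numeric(n), dir_y = numeric(n), dir_z = numeric(n),
                 f = rep(1, n), n_steps = 0L),
            class = "ep_state")
}

# Fold a converged step field into the envelope state.
update_state <- function(state, sol, pars, law) {
  upd <- sol$e_mag > state$e_env
  state$e_env[upd] <- sol$e_mag[upd]
  nz <- upd & sol$e_mag > 0
  state$dir_x[nz] <- sol$ex[nz] / sol$e_mag[nz]
  state$dir_y[nz] <- sol$ey[nz] / sol$e_mag[nz]
  state$dir_z[nz] <- sol$ez[nz] / sol$e_mag[nz]
  # across steps only the envelope persists: the factor relaxes to the
  # envelope's self-consistent value
  state$f <- voxel_sigma_factor(pars, law, state$e_env,
                                state$dir_x * state$e_env,
                                state$dir_y * state$e_env,
                                state$dir_z * state$e_env)
  state$n_steps <- state$n_steps + 1L
  state
}

#' Run a full pulse delivery protocol
#'
#' Iterates [solve_field()] over the protocol's activation steps in order.
#' After each converged step the per-voxel field envelope is updated
#' (`e_env <- max(e_env, |E|)`) and the conductivity persists at the
#' envelope's value: electroporation memory in the stationary-sequential
#' model.
#'
#' @param grid an [build_grid()] result (its stack defines the tissue).
#' @param protocol a [generate_protocol()] result; the electrode array must
#'   fit inside the grid footprint.
#' @param law a [conductivity_law()].
#' @param control a [solver_control()].
#' @param keep_solutions keep per-step solutions (`phi`, `e_mag`, currents)?
#'   Default `TRUE`.
#' @param verbose print per-step convergence info to stderr.
#' @return list with `state` (final [new_ep_state()]-class envelope) and
#'   `solutions` (per-step list, or `NULL`).
#' @export
run_protocol <- function(grid, protocol, law = conductivity_law(),
                         control = solver_control(), keep_solutions = TRUE,
                         verbose = FALSE) {
  stopifnot(inherits(grid, "ep_grid"), inherits(protocol, "protocol"))
  struct <- solver_structure(grid)
  pars <- grid_law_pars(grid)
  state <- new_ep_state(grid)
  sols <- if (keep_solutions) vector("list", length(protocol$steps))
  prev_step <- NULL
  prev_phi <- NULL
  for (s in seq_along(protocol$steps)) {
    step <- protocol$steps[[s]]
    ct <- step_contacts(grid, protocol$array, step)
    # a polarity-reversed repeat of the previous step has phi' ~ U - phi
    # when the conductivity state is unchanged: excellent initial guess
    phi0 <- if (!is.null(prev_step) &&
                setequal(step$anodes, prev_step$cathodes) &&
                setequal(step$cathodes, prev_step$anodes) &&
                step$amplitude == prev_step$amplitude)
      step$amplitude - prev_phi
    sol <- solve_field(grid, ct, law, state, control, struct, pars,
                       phi0 = phi0)
    prev_step <- step
    prev_phi <- sol$phi
    state <- update_state(state, sol, pars, law)
    if (keep_solutions)
      sols[[s]] <- list(step = s, phi = sol$phi, e_mag = sol$e_mag,
                        i_source = sol$i_source, i_sink = sol$i_sink,
                        picard_iter = sol$picard_iter,
                        converged = sol$converged)
    if (verbose)
      message(sprintf(
        "step %2d/%d: %2d Picard iters, I = %.3g A, balance %.2e",
        s, length(protocol$steps), sol$picard_iter, sol$i_source,
        abs(sol$i_source - sol$i_sink) / max(sol$i_source, 1e-300)))
  }
  list(state = state, solutions = sols)
}

# Contact patches for one protocol step on an electrode array (top surface).
step_contacts <- function(grid, array, step) {
  el <- array$electrodes
  if (max(abs(c(el$x, el$y))) + max(el$contact_radius) >
      grid$lateral_extent / 2)
    stop("electrode array does not fit inside the grid footprint")
  mk <- function(ids, V) lapply(ids, function(id) {
    e <- el[el$id == id, ]
    if (nrow(e) != 1L) stop("unknown electrode id in protocol step")
    contact_patch(grid, V, side = "top", x = e$x, y = e$y,
                  radius = e$contact_radius)
  })
  c(mk(step$anodes, step$amplitude), mk(step$cathodes, 0))
}
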