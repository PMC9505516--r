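#' Default run configuration
#'
#' Assembles the configuration of a protocol-comparison experiment: the
#' layer stack, electrode geometry, pulse amplitude, conductivity-law
#' steepness, grid preset and solver tolerances. Every default is either a
#' tabulated tissue/device value or a documented package choice.
#'
#' @param amplitude per-step voltage (V), applied to both protocols
#'   (default 560).
#' @param resolution grid preset (`"coarse"`, `"default"`, `"fine"`) or
#'   explicit list, see [build_grid()].
#' @param lateral_extent footprint side (m), default 30 mm.
#' @param steepness sigmoid steepness, see [conductivity_law()].
#' @param diagonal_mode see [generate_protocol()].
#' @param inclusive_re see [classify_and_measure()].
#' @param seed RNG seed recorded for provenance (the field pipeline itself
#'   is deterministic).
#' @param stack_config optional stack configuration list
#'   ([stack_to_config()] format); default is the eight-layer skin model.
#' @return a list of class `run_config`.
#' @export
run_config <- function(amplitude = 560, resolution = "default",
                       lateral_extent = 30e-3, steepness = 10,
                       diagonal_mode = "single", inclusive_re = TRUE,
                       seed = 1L, stack_config = NULL) {
  if (is.null(stack_config)) stack_config <- stack_to_config(default_skin_stack())
  cfg <- list(amplitude = amplitude, resolution = resolution,
              lateral_extent = lateral_extent, steepness = steepness,
              diagonal_mode = diagonal_mode, inclusive_re = inclusive_re,
              seed = as.integer(seed), stack = stack_config)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  stopifnot(is.numeric(cfg$amplitude), cfg$amplitude >= 0,
            is.numeric(cfg$lateral_extent), cfg$lateral_extent > 0,
            is.numeric(cfg$steepness), cfg$steepness > 0,
            cfg$diagonal_mode %in% c("single", "paired"),
            is.logical(cfg$inclusive_re), is.list(cfg$stack))
  invisible(cfg)
}

#' Read a run configuration from YAML
#'
#' Missing fields fall back to the [run_config()] defaults.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- run_config()
  for (nm in intersect(names(y), names(base))) base[[nm]] <- y[[nm]]
  validate_run_config(base)
  class(base) <- "run_config"
  base
}

#' Write a run configuration to YAML
#' @param cfg a [run_config()].
#' @param path output file path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the classical-vs-alternative comparison experiment
#'
#' Executes both hexagonal-array protocols on the same grid and layer stack,
#' classifies the final field envelopes, and (optionally) writes metrics,
#' the comparison record, field slices and provenance to an output
#' directory.
#'
#' @param cfg a [run_config()].
#' @param out_dir optional output directory; created if missing. When
#'   `NULL`, nothing is written.
#' @param verbose print solver progress.
#' @return list with per-protocol results (`classical`, `alternative`: each
#'   with `metrics`, `run`), the `comparison` record, the `grid`, and
#'   `provenance`.
#' @export
run_experiment <- function(cfg = run_config(), out_dir = NULL,
                           verbose = FALSE) {
  validate_run_config(cfg)
  stack <- stack_from_config(cfg$stack)
  grid <- build_grid(stack, cfg$lateral_extent, cfg$resolution)
  law <- conductivity_law(cfg$steepness)
  res <- list()
  for (name in c("classical", "alternative")) {
    arr <- build_array(if (name == "classical") "hex7" else "hex6")
    if (cfg$amplitude == 0) {
      state <- new_ep_state(grid)
      run <- list(state = state, solutions = NULL)
    } else {
      prot <- generate_protocol(arr, name, amplitude = cfg$amplitude,
                                diagonal_mode = cfg$diagonal_mode)
      run <- run_protocol(grid, prot, law, keep_solutions = FALSE,
                          verbose = verbose)
    }
    metrics <- classify_and_measure(grid, run$state,
                                    inclusive_re = cfg$inclusive_re)
    res[[name]] <- list(metrics = metrics, run = run)
  }
  comparison <- compare_protocols(res$alternative$metrics,
                                  res$classical$metrics)
  provenance <- list(
    package_version = as.character(utils::packageVersion("skinget")),
    r_version = R.version.string,
    config = unclass(cfg),
    config_hash = config_hash(cfg),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  out <- list(classical = res$classical, alternative = res$alternative,
              comparison = comparison, grid = grid, provenance = provenance)
  if (!is.null(out_dir)) write_experiment(out, out_dir)
  invisible(out)
}

config_hash <- function(cfg) {
  js <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  # small stable polynomial hash (exact in doubles); enough to detect
  # config drift in provenance
  bytes <- utf8ToInt(as.character(js))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

metrics_row <- function(name, m) {
  data.frame(protocol = name,
             re_volume_mm3 = m$re_volume * 1e9,
             ire_volume_mm3 = m$ire_volume * 1e9,
             re_volume_inclusive_mm3 = m$re_volume_inclusive * 1e9,
             re_depth_mm = m$re_depth * 1e3)
}

write_experiment <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- rbind(metrics_row("classical", res$classical$metrics),
               metrics_row("alternative", res$alternative$metrics))
  utils::write.csv(tab, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  per_layer <- rbind(
    cbind(protocol = "classical", res$classical$metrics$per_layer),
    cbind(protocol = "alternative", res$alternative$metrics$per_layer))
  per_layer$re <- per_layer$re * 1e9
  per_layer$ire <- per_layer$ire * 1e9
  names(per_layer)[3:4] <- c("re_mm3", "ire_mm3")
  utils::write.csv(per_layer, file.path(out_dir, "per_layer.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(comparison = res$comparison, provenance = res$provenance),
    file.path(out_dir, "comparison.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, na = "null")
  for (name in c("classical", "alternative")) {
    sl <- field_slice(res$grid, res[[name]]$run$state, depth = 2e-3)
    utils::write.csv(as.data.frame(sl),
                     file.path(out_dir, sprintf("slice_2mm_%s.csv", name)),
                     row.names = FALSE)
  }
  invisible(out_dir)
}

#' Export grid fields to a legacy VTK structured-grid file
#'
#' Writes an ASCII VTK file (STRUCTURED_GRID, point data at voxel centers)
#' readable by ParaView/VisIt, with one scalar array per supplied field.
#'
#' @param grid an [build_grid()] result.
#' @param fields named list of per-voxel numeric vectors (e.g. `phi`,
#'   `e_mag`, `e_env`, masks coerced to 0/1).
#' @param path output `.vtk` file path.
#' @export
write_vtk <- function(grid, fields, path) {
  stopifnot(inherits(grid, "ep_grid"), is.list(fields),
            !is.null(names(fields)))
  n <- n_voxels(grid)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "skinget field export", "ASCII",
               "DATASET STRUCTURED_GRID",
               sprintf("DIMENSIONS %d %d %d", grid$nx, grid$ny, grid$nz),
               sprintf("POINTS %d double", n)), con)
  pts <- cbind(rep(grid$xc, times = grid$ny * grid$nz),
               rep(rep(grid$yc, each = grid$nx), times = grid$nz),
               rep(grid$zc, each = grid$nx * grid$ny))
  utils::write.table(format(pts, digits = 9, scientific = TRUE,
                            trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  writeLines(sprintf("POINT_DATA %d", n), con)
  for (nm in names(fields)) {
    v <- as.numeric(fields[[nm]])
    if (length(v) != n) stop("field '", nm, "' has wrong length")
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(v, digits = 9, scientific = TRUE, trim = TRUE), con)
  }
  invisible(path)
}
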