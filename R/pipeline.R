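#' Build the detector array described by a configuration
#'
#' The \code{geometry} block selects the builder:
#' \itemize{
#'   \item \code{type: planar} — scanned linear array; requires
#'     \code{channel_pitch} and \code{step_size} (m); element counts come
#'     from \code{num_channels} / \code{num_steps}.
#'   \item \code{type: hemisphere} — Fibonacci hemisphere; requires
#'     \code{radius} (m); element count is
#'     \code{num_channels * num_steps}.
#'   \item \code{type: file} — arbitrary array from a plain-text table
#'     (\code{path}), see [read_detector_table()].
#' }
#'
#' @param cfg a \code{pact_config}.
#' @return a \code{pact_array}.
#' @export
geometry_from_config <- function(cfg) {
  g <- cfg$geometry
  if (is.null(g$type)) {
    stop("configuration needs a geometry block with a \"type\" key",
         call. = FALSE)
  }
  switch(match.arg(g$type, c("planar", "hemisphere", "file")),
    planar = {
      if (is.null(g$channel_pitch) || is.null(g$step_size)) {
        stop("planar geometry requires channel_pitch and step_size (m)",
             call. = FALSE)
      }
      build_planar_synthetic_array(cfg$num_channels,
                                   as.numeric(g$channel_pitch),
                                   cfg$num_steps,
                                   as.numeric(g$step_size))
    },
    hemisphere = {
      if (is.null(g$radius)) {
        stop("hemisphere geometry requires a radius (m)", call. = FALSE)
      }
      build_fibonacci_hemisphere(cfg$num_channels * cfg$num_steps,
                                 as.numeric(g$radius))
    },
    file = read_detector_table(g$path))
}

#' Build the reconstruction grid described by a configuration
#'
#' Reads the \code{grid} block (\code{center} and \code{extent},
#' 3-vectors in m; center defaults to the origin) with voxel spacing
#' \code{cfg$res}.
#'
#' @param cfg a \code{pact_config}.
#' @return a \code{pact_grid}.
#' @export
grid_from_config <- function(cfg) {
  g <- cfg$grid
  if (is.null(g$extent)) {
    stop("configuration needs a grid block with an \"extent\" key (m)",
         call. = FALSE)
  }
  center <- if (is.null(g$center)) c(0, 0, 0) else as.numeric(g$center)
  build_grid(center, as.numeric(g$extent), cfg$res)
}

phantoms_from_config <- function(cfg) {
  if (is.null(cfg$phantom)) {
    stop("configuration needs a phantom block (list of spheres)",
         call. = FALSE)
  }
  ph <- cfg$phantom
  if (!is.null(ph$center)) ph <- list(ph)   # single sphere shorthand
  lapply(ph, function(p) {
    if (is.null(p$center) || is.null(p$radius)) {
      stop("each phantom sphere needs \"center\" (m) and \"radius\" (m)",
           call. = FALSE)
    }
    sphere_phantom(as.numeric(p$center), as.numeric(p$radius),
                   if (is.null(p$amplitude)) 1 else as.numeric(p$amplitude))
  })
}

log_stage <- function(fmt, ...) {
  message(sprintf(paste0("[pactrecon] ", fmt), ...))
}

write_manifest <- function(path, manifest) {
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  file.rename(tmp, path)
  invisible(path)
}

config_snapshot <- function(cfg) {
  lapply(unclass(cfg), function(v) if (is.list(v)) v else unname(v))
}

output_paths <- function(cfg) {
  out <- cfg$output
  dir <- if (is.null(out$dir)) "." else out$dir
  list(dir = dir,
       volume = file.path(dir, if (is.null(out$volume)) "volume.bin"
                               else out$volume),
       mip = file.path(dir, if (is.null(out$mip)) "mip.png" else out$mip),
       manifest = file.path(dir, if (is.null(out$manifest)) "manifest.json"
                                 else out$manifest),
       mip_axis = if (is.null(out$mip_axis)) "z" else out$mip_axis,
       mode = if (is.null(out$mode)) "abs" else out$mode)
}

#' Simulate raw fixture data from a configuration
#'
#' Builds the detector array and phantom list from the configuration,
#' runs the analytical forward model, writes the per-step raw binary
#' files into \code{data_path}, and records a run manifest.  An empty
#' phantom list yields all-zero fixtures.  When the \code{noise} block is
#' present (\code{sd}, \code{seed}) seeded Gaussian noise is added, so
#' two runs with the same configuration produce identical bytes.
#'
#' @param config_path path to a YAML configuration with a phantom block.
#' @return invisibly, the manifest list.
#' @export
run_simulate <- function(config_path) {
  t0 <- proc.time()[["elapsed"]]
  cfg <- load_config(config_path)
  array <- geometry_from_config(cfg)
  phantoms <- if (is.null(cfg$phantom) || length(cfg$phantom) == 0) {
    list()
  } else {
    phantoms_from_config(cfg)
  }
  noise_sd <- if (is.null(cfg$noise$sd)) 0 else as.numeric(cfg$noise$sd)
  noise_seed <- if (is.null(cfg$noise$seed)) NULL else
    as.integer(cfg$noise$seed)

  if (length(phantoms) == 0) {
    S <- matrix(0, nrow = array$n, ncol = cfg$num_times)
  } else {
    S <- simulate_sphere_signals(phantoms, array, cfg,
                                 noise_sd = noise_sd,
                                 noise_seed = noise_seed)
  }
  log_stage("simulated %d detector traces x %d samples; peak |p| = %g",
            nrow(S), ncol(S), max(abs(S)))
  # keep fixtures representable: scale into ~90% of the int16 range
  scale <- 1
  type <- raw_type_info(cfg$data_type)
  if (isTRUE(type$integer) && max(abs(S)) > 0) {
    scale <- floor(0.9 * type$max / max(abs(S)))
    if (scale < 1) scale <- 1
    S <- round(S * scale)
  }
  files <- write_raw_fixture(S, cfg, cfg$data_path)
  t1 <- proc.time()[["elapsed"]]
  log_stage("wrote %d raw files to %s in %.2f s", length(files),
            cfg$data_path, t1 - t0)

  paths <- output_paths(cfg)
  if (!dir.exists(paths$dir)) dir.create(paths$dir, recursive = TRUE)
  manifest <- list(
    stage = "simulate",
    config = config_snapshot(cfg),
    amplitude_scale = scale,
    inputs = list(),
    outputs = list(raw_files = as.list(unname(tools::md5sum(files)))),
    seeds = list(noise_seed = noise_seed),
    timings_s = list(total = t1 - t0)
  )
  write_manifest(paths$manifest, manifest)
  invisible(manifest)
}

#' Run the full reconstruction pipeline from a configuration
#'
#' config -> import -> preprocess -> depth-slab partitioned
#' back-projection -> postprocess -> outputs.  Writes the volume
#' (32-bit float binary + YAML sidecar), a maximum-intensity projection
#' PNG, and a run manifest with input checksums and per-stage timings.
#'
#' @param config_path path to a YAML configuration.
#' @param num_devices optional override of \code{cfg$num_devices}.
#' @param algorithm optional override of \code{cfg$algorithm}
#'   ("das" or "fbp").
#' @return invisibly, the reconstructed \code{pact_volume}.
#' @export
run_reconstruct <- function(config_path, num_devices = NULL,
                            algorithm = NULL) {
  timings <- list()
  tick <- function() proc.time()[["elapsed"]]
  t0 <- tick()

  cfg <- load_config(config_path)
  if (!is.null(num_devices)) cfg$num_devices <- as.integer(num_devices)
  if (!is.null(algorithm)) {
    cfg$algorithm <- match.arg(tolower(algorithm), c("das", "fbp"))
  }
  array <- geometry_from_config(cfg)
  grid <- grid_from_config(cfg)
  timings$setup <- tick() - t0
  log_stage("configured %s reconstruction: %d detectors -> %s voxels",
            toupper(cfg$algorithm), array$n,
            paste(grid$dims, collapse = "x"))

  t1 <- tick()
  input_files <- sort(list.files(cfg$data_path, pattern = "\\.bin$",
                                 full.names = TRUE))
  S <- import_raw_data(cfg)
  timings$import <- tick() - t1
  log_stage("imported %d x %d signal matrix in %.2f s",
            nrow(S), ncol(S), timings$import)

  t2 <- tick()
  S <- preprocess(S, cfg)
  cfg$fs <- attr(S, "fs")
  cfg$num_times <- ncol(S)
  timings$preprocess <- tick() - t2

  t3 <- tick()
  volume <- reconstruct_partitioned(S, array, grid, cfg)
  timings$reconstruct <- tick() - t3
  log_stage("back-projection over %d device slab(s) in %.2f s",
            min(cfg$num_devices, grid$dims[3]), timings$reconstruct)

  t4 <- tick()
  paths <- output_paths(cfg)
  if (!dir.exists(paths$dir)) dir.create(paths$dir, recursive = TRUE)
  write_volume(volume, paths$volume)
  img <- mip(normalize_volume(rectify(volume, paths$mode)), paths$mip_axis)
  write_mip_png(img, paths$mip)
  timings$postprocess <- tick() - t4
  timings$total <- tick() - t0
  log_stage("outputs: %s, %s (total %.2f s)", paths$volume, paths$mip,
            timings$total)

  manifest <- list(
    stage = "reconstruct",
    config = config_snapshot(cfg),
    inputs = as.list(tools::md5sum(input_files)),
    outputs = list(volume = paths$volume, mip = paths$mip),
    seeds = list(),
    timings_s = timings
  )
  write_manifest(paths$manifest, manifest)
  invisible(volume)
}

#' Re-run postprocessing on a saved volume
#'
#' Reads the volume written by [run_reconstruct()] and regenerates the
#' rectified, normalized maximum-intensity projection without
#' re-reconstructing.
#'
#' @param config_path path to the YAML configuration used for the run.
#' @param mode rectification mode ("abs", "square" or "hilbert");
#'   defaults to the configuration's output block.
#' @return invisibly, the \code{pact_mip}.
#' @export
run_postprocess <- function(config_path, mode = NULL) {
  cfg <- load_config(config_path)
  paths <- output_paths(cfg)
  if (!file.exists(paths$volume)) {
    stop("no saved volume at ", paths$volume,
         "; run the reconstruction first", call. = FALSE)
  }
  volume <- read_volume(paths$volume)
  mode <- if (is.null(mode)) paths$mode else mode
  img <- mip(normalize_volume(rectify(volume, mode)), paths$mip_axis)
  write_mip_png(img, paths$mip)
  log_stage("postprocessed %s -> %s (mode %s)", paths$volume, paths$mip,
            mode)
  invisible(img)
}
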