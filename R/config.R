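#' Load and validate a reconstruction configuration
#'
#' Reads a YAML configuration file describing the acquisition and the
#' reconstruction run, applies documented defaults for optional keys, and
#' validates all invariants.  The mandatory keys describe the acquisition:
#' \describe{
#'   \item{vs}{speed of sound in the coupling medium, m/s}
#'   \item{fs}{sampling frequency of the data acquisition, Hz}
#'   \item{num_channels}{number of transducer channels per scan step}
#'   \item{num_steps}{number of scan steps (1 for a fixed array)}
#'   \item{num_times}{time samples recorded per channel}
#'   \item{res}{spacing of the reconstruction grid, m}
#'   \item{data_path}{directory holding the raw per-step binary files}
#'   \item{data_type}{sample scalar type of the raw files
#'     (\code{"int16"}, \code{"int32"}, \code{"float32"} or \code{"float64"})}
#' }
#' Optional keys (with defaults): \code{device} (\code{"cpu"}),
#' \code{num_devices} (1), \code{algorithm} (\code{"das"}),
#' \code{interpolation} (\code{"nearest"}), \code{normalize_solid_angle}
#' (\code{FALSE}), \code{delay_offset} (0 s), \code{filter} (none;
#' a mapping with \code{low}/\code{high} bandpass cutoffs in Hz),
#' \code{resample_fs} (none; target rate in Hz), plus free-form blocks
#' \code{geometry}, \code{grid}, \code{phantom}, \code{noise} and
#' \code{output} consumed by the pipeline drivers.
#'
#' @param path path to a YAML configuration file.
#' @return an object of class \code{pact_config}: a named list of validated
#'   parameters.
#' @seealso [import_raw_data()], [run_reconstruct()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("configuration file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) {
    stop("configuration file is not a YAML mapping: ", path, call. = FALSE)
  }
  as_pact_config(raw, dir = dirname(normalizePath(path)))
}

#' Build a validated configuration from a named list
#'
#' The programmatic counterpart of [load_config()]; useful for constructing
#' configurations in tests and scripts without touching the file system.
#'
#' @param x named list of configuration values.
#' @param dir directory against which a relative \code{data_path} is
#'   resolved (defaults to the working directory).
#' @return a \code{pact_config} object.
#' @export
as_pact_config <- function(x, dir = ".") {
  mandatory <- c("vs", "fs", "num_channels", "num_steps", "num_times",
                 "res", "data_path", "data_type")
  for (key in mandatory) {
    if (is.null(x[[key]])) {
      stop("configuration is missing mandatory key \"", key, "\"",
           call. = FALSE)
    }
  }

  cfg <- x
  cfg$vs <- as.numeric(x$vs)
  cfg$fs <- as.numeric(x$fs)
  cfg$num_channels <- as.integer(x$num_channels)
  cfg$num_steps <- as.integer(x$num_steps)
  cfg$num_times <- as.integer(x$num_times)
  cfg$res <- as.numeric(x$res)
  cfg$data_path <- as.character(x$data_path)
  cfg$data_type <- match.arg(as.character(x$data_type),
                             c("int16", "int32", "float32", "float64"))

  # resolve data_path relative to the config file location
  if (!grepl("^(/|[A-Za-z]:)", cfg$data_path)) {
    cfg$data_path <- file.path(dir, cfg$data_path)
  }

  cfg$device <- if (is.null(x$device)) "cpu" else
    match.arg(as.character(x$device), c("cpu", "gpu"))
  cfg$num_devices <- if (is.null(x$num_devices)) 1L else
    as.integer(x$num_devices)
  cfg$algorithm <- if (is.null(x$algorithm)) "das" else
    match.arg(tolower(as.character(x$algorithm)), c("das", "fbp"))
  cfg$interpolation <- if (is.null(x$interpolation)) "nearest" else
    match.arg(as.character(x$interpolation), c("nearest", "linear"))
  cfg$normalize_solid_angle <-
    if (is.null(x$normalize_solid_angle)) FALSE else
      isTRUE(as.logical(x$normalize_solid_angle))
  cfg$delay_offset <- if (is.null(x$delay_offset)) 0 else
    as.numeric(x$delay_offset)

  validate_positive <- function(value, key) {
    if (!is.finite(value) || value <= 0) {
      stop("configuration key \"", key, "\" must be positive, got ",
           value, call. = FALSE)
    }
  }
  validate_positive(cfg$vs, "vs")
  validate_positive(cfg$fs, "fs")
  validate_positive(cfg$res, "res")
  for (key in c("num_channels", "num_steps", "num_times", "num_devices")) {
    if (is.na(cfg[[key]]) || cfg[[key]] < 1L) {
      stop("configuration key \"", key, "\" must be a count >= 1",
           call. = FALSE)
    }
  }

  if (!is.null(x$filter)) {
    lo <- as.numeric(x$filter$low)
    hi <- as.numeric(x$filter$high)
    if (length(lo) != 1 || length(hi) != 1 || is.na(lo) || is.na(hi)) {
      stop("filter block requires numeric \"low\" and \"high\" cutoffs (Hz)",
           call. = FALSE)
    }
    if (!(0 < lo && lo < hi && hi < cfg$fs / 2)) {
      stop("filter cutoffs must satisfy 0 < low < high < fs/2; got [",
           lo, ", ", hi, "] Hz at fs = ", cfg$fs, " Hz", call. = FALSE)
    }
    cfg$filter <- list(low = lo, high = hi)
  } else {
    cfg$filter <- NULL
  }

  if (!is.null(x$resample_fs)) {
    cfg$resample_fs <- as.numeric(x$resample_fs)
    validate_positive(cfg$resample_fs, "resample_fs")
  }

  structure(cfg, class = "pact_config")
}

#' @export
print.pact_config <- function(x, ...) {
  cat("PACT reconstruction configuration\n")
  cat(sprintf("  speed of sound : %g m/s\n", x$vs))
  cat(sprintf("  sampling rate  : %g MHz\n", x$fs / 1e6))
  cat(sprintf("  signal matrix  : %d detectors x %d samples (%d channels x %d steps)\n",
              x$num_channels * x$num_steps, x$num_times,
              x$num_channels, x$num_steps))
  cat(sprintf("  grid spacing   : %g mm\n", x$res * 1e3))
  cat(sprintf("  algorithm      : %s (%s interpolation%s)\n",
              toupper(x$algorithm), x$interpolation,
              if (x$normalize_solid_angle) ", solid-angle normalized" else ""))
  cat(sprintf("  data           : %s [%s], %d device(s)\n",
              x$data_path, x$data_type, x$num_devices))
  invisible(x)
}
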