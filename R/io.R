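#' Bulk-import raw per-step binary signal files
#'
#' Reads the \code{num_steps} headerless binary files under
#' \code{cfg$data_path} and assembles them into a single signal matrix of
#' shape (\code{num_steps * num_channels}) x \code{num_times}, converted to
#' floating point.  Row ordering is step-major then channel: row index
#' \code{s * num_channels + c} (zero-based) holds channel \code{c} of scan
#' step \code{s}, matching the element ordering of
#' [build_planar_synthetic_array()].
#'
#' File dialect: headerless little-endian samples of \code{cfg$data_type},
#' channel-major within a file (all \code{num_times} samples of channel 0,
#' then channel 1, ...).  Files are sorted by the first numeric token in
#' their filename (zero-padded names sort identically under lexicographic
#' and numeric order), so the import is independent of directory listing
#' order.
#'
#' @param cfg a \code{pact_config}.
#' @return numeric matrix of dimensions
#'   \code{(num_steps * num_channels, num_times)}.
#' @seealso [write_raw_fixture()] which emits the same dialect.
#' @export
import_raw_data <- function(cfg) {
  stopifnot(inherits(cfg, "pact_config"))
  if (!dir.exists(cfg$data_path)) {
    stop("data_path does not exist: ", cfg$data_path, call. = FALSE)
  }
  files <- list.files(cfg$data_path, pattern = "\\.bin$", full.names = TRUE)
  if (length(files) != cfg$num_steps) {
    stop("expected ", cfg$num_steps, " raw data files in ", cfg$data_path,
         " but found ", length(files), call. = FALSE)
  }
  files <- files[order(raw_file_key(files))]

  type <- raw_type_info(cfg$data_type)
  n_samples <- cfg$num_channels * cfg$num_times
  expected_bytes <- n_samples * type$size
  S <- matrix(0, nrow = cfg$num_steps * cfg$num_channels,
              ncol = cfg$num_times)
  for (s in seq_along(files)) {
    actual <- file.size(files[s])
    if (actual != expected_bytes) {
      stop("raw data file ", basename(files[s]), " has ", actual,
           " bytes; expected ", expected_bytes,
           " (num_channels x num_times x ", type$size, ")", call. = FALSE)
    }
    con <- file(files[s], "rb")
    values <- readBin(con, what = type$what, n = n_samples,
                      size = type$size, signed = TRUE, endian = "little")
    close(con)
    # channel-major within a file: reshape as (num_times x num_channels),
    # transpose so rows become channels
    rows <- (s - 1L) * cfg$num_channels + seq_len(cfg$num_channels)
    S[rows, ] <- t(matrix(as.numeric(values), nrow = cfg$num_times,
                          ncol = cfg$num_channels))
  }
  S
}

# numeric sort key: first digit run in the basename
raw_file_key <- function(paths) {
  token <- regmatches(basename(paths), regexpr("[0-9]+", basename(paths)))
  key <- suppressWarnings(as.numeric(token))
  if (length(key) != length(paths) || anyNA(key)) {
    stop("raw data filenames must contain a numeric step token; offending: ",
         paste(basename(paths)[is.na(key)], collapse = ", "), call. = FALSE)
  }
  key
}

raw_type_info <- function(data_type) {
  switch(data_type,
    int16   = list(what = integer(), size = 2L, integer = TRUE,
                   min = -32768, max = 32767),
    int32   = list(what = integer(), size = 4L, integer = TRUE,
                   min = -2147483648, max = 2147483647),
    float32 = list(what = numeric(), size = 4L, integer = FALSE),
    float64 = list(what = numeric(), size = 8L, integer = FALSE),
    stop("unsupported data_type: ", data_type, call. = FALSE))
}

#' Preprocess a raw signal matrix
#'
#' Applies, in order: optional zero-phase bandpass filtering (3rd-order
#' Butterworth, forward-backward so the filter adds no group delay),
#' optional polyphase resampling to \code{cfg$resample_fs}, and finally
#' sets the first and last sample of every detector row to exactly zero.
#' The boundary zeroing is what lets the beamformer clamp out-of-range
#' time-of-flight indices onto samples that contribute nothing.
#'
#' @param S signal matrix, detectors x time samples.
#' @param cfg a \code{pact_config}; \code{cfg$filter} (cutoffs in Hz) and
#'   \code{cfg$resample_fs} select the optional steps.
#' @return the preprocessed matrix.  If resampling was applied the column
#'   count changes accordingly and the attribute \code{"fs"} carries the
#'   new sampling rate; callers must propagate it into the configuration.
#' @export
preprocess <- function(S, cfg) {
  stopifnot(is.matrix(S))
  if (ncol(S) != cfg$num_times) {
    stop("signal matrix has ", ncol(S), " time samples; config says ",
         cfg$num_times, call. = FALSE)
  }
  fs <- cfg$fs
  if (!is.null(cfg$filter)) {
    lo <- cfg$filter$low
    hi <- cfg$filter$high
    if (!(0 < lo && lo < hi && hi < fs / 2)) {
      stop("filter band [", lo, ", ", hi, "] Hz outside (0, fs/2)",
           call. = FALSE)
    }
    bf <- signal::butter(3, c(lo, hi) / (fs / 2), type = "pass")
    S <- t(apply(S, 1L, function(row) signal::filtfilt(bf, row)))
  }
  if (!is.null(cfg$resample_fs) && cfg$resample_fs != fs) {
    ratio <- rational_ratio(cfg$resample_fs / fs)
    S <- t(apply(S, 1L, function(row)
      resample_poly(row, p = ratio$p, q = ratio$q)))
    fs <- fs * ratio$p / ratio$q
  }
  S[, 1L] <- 0
  S[, ncol(S)] <- 0
  attr(S, "fs") <- fs
  S
}

# rational p/q resampling: zero-stuff by p, apply a centered (zero-delay)
# FIR low-pass at the tighter of the two Nyquist bounds, keep every q-th
# sample; edge samples where the symmetric filter overhangs are zeroed
resample_poly <- function(x, p, q) {
  if (p == q) return(x)
  up <- numeric(length(x) * p)
  up[seq(1L, length(up), by = p)] <- x
  order <- 10L * max(p, q)
  if (order %% 2L == 1L) order <- order + 1L
  h <- signal::fir1(order, 1 / max(p, q)) * p
  y <- stats::filter(up, h, method = "convolution", sides = 2L)
  y[is.na(y)] <- 0
  as.numeric(y[seq(1L, length(y), by = q)])
}

# small-denominator rational approximation for the resampling ratio
rational_ratio <- function(x, max_den = 1000L) {
  best <- c(p = 1L, q = 1L, err = Inf)
  for (q in seq_len(max_den)) {
    p <- round(x * q)
    if (p < 1) next
    err <- abs(x - p / q)
    if (err < best["err"] - 1e-15) best <- c(p = p, q = q, err = err)
    if (err < 1e-12) break
  }
  list(p = as.integer(best["p"]), q = as.integer(best["q"]))
}

#' Write a signal matrix as raw fixture files
#'
#' Emits \code{cfg$num_steps} binary files (\code{raw_00000.bin},
#' \code{raw_00001.bin}, ...) in the dialect read by [import_raw_data()]:
#' headerless little-endian samples of \code{cfg$data_type}, channel-major
#' within each file.  Integer target types are quantized by rounding;
#' values outside the representable range are an error rather than being
#' silently wrapped.
#'
#' @param S signal matrix of dimensions
#'   \code{(num_steps * num_channels, num_times)}.
#' @param cfg a \code{pact_config}.
#' @param out_dir output directory (created if absent).
#' @return invisibly, the vector of file paths written.
#' @export
write_raw_fixture <- function(S, cfg, out_dir) {
  stopifnot(is.matrix(S))
  if (nrow(S) != cfg$num_steps * cfg$num_channels ||
      ncol(S) != cfg$num_times) {
    stop("signal matrix shape ", nrow(S), "x", ncol(S),
         " does not match config (", cfg$num_steps * cfg$num_channels,
         "x", cfg$num_times, ")", call. = FALSE)
  }
  type <- raw_type_info(cfg$data_type)
  if (isTRUE(type$integer)) {
    q <- round(S)
    if (any(q < type$min | q > type$max)) {
      stop("signal values outside the ", cfg$data_type,
           " range [", type$min, ", ", type$max, "] cannot be quantized",
           call. = FALSE)
    }
    S <- q
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(cfg$num_steps)
  for (s in seq_len(cfg$num_steps)) {
    rows <- (s - 1L) * cfg$num_channels + seq_len(cfg$num_channels)
    # channel-major: column-major vector of the (num_times x num_channels)
    # transpose puts all samples of channel 0 first
    values <- as.vector(t(S[rows, , drop = FALSE]))
    paths[s] <- file.path(out_dir, sprintf("raw_%05d.bin", s - 1L))
    con <- file(paths[s], "wb")
    if (isTRUE(type$integer)) {
      writeBin(as.integer(values), con, size = type$size, endian = "little")
    } else {
      writeBin(as.numeric(values), con, size = type$size, endian = "little")
    }
    close(con)
  }
  invisible(paths)
}

#' Write a reconstructed volume to disk
#'
#' Stores the voxel values as headerless 32-bit little-endian floats in
#' depth-major order (x fastest, then y, then z — the native flattening of
#' the grid) together with a YAML sidecar \code{<path>.yaml} recording
#' dimensions, spacing and origin so the volume is self-describing.
#'
#' @param volume a \code{pact_volume} from [backproject()].
#' @param path output file path for the binary payload.
#' @return invisibly, \code{path}.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "pact_volume"))
  con <- file(path, "wb")
  writeBin(as.vector(volume$values), con, size = 4L, endian = "little")
  close(con)
  grid <- volume$grid
  first_voxel <- grid$origin +
    (if (is.null(grid$offset)) 0L else grid$offset) * grid$spacing
  yaml::write_yaml(list(
    dims = as.integer(grid$dims),
    spacing = grid$spacing,
    origin = first_voxel,
    order = "x-fastest, z-slowest",
    dtype = "float32"
  ), paste0(path, ".yaml"))
  invisible(path)
}

#' Read a volume written by [write_volume()]
#'
#' @param path path to the binary payload (the sidecar
#'   \code{<path>.yaml} must sit next to it).
#' @return a \code{pact_volume}.
#' @export
read_volume <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  dims <- as.integer(meta$dims)
  con <- file(path, "rb")
  values <- readBin(con, numeric(), n = prod(dims), size = 4L,
                    endian = "little")
  close(con)
  grid <- list(origin = as.numeric(meta$origin),
               spacing = as.numeric(meta$spacing),
               dims = dims)
  class(grid) <- "pact_grid"
  new_pact_volume(array(values, dim = dims), grid)
}
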