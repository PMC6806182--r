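#' Thermal video frame
#'
#' A single-channel thermal image with an optional linear intensity-to-
#' temperature calibration. Calibration is metadata: all detection and fitting
#' runs on raw intensities, and `frame_temperature()` applies the affine map
#' `T(p) = gain * intensity(p) + offset` lazily. Whether the raw grayscale
#' values of a given camera are radiometric is camera-dependent; the affine
#' model here is an assumption the user must validate for their device.
#'
#' @param pixels Numeric matrix (rows x cols) of non-negative intensities;
#'   at least 2 x 2.
#' @param gain Kelvin per intensity unit (default 1).
#' @param offset Kelvin (default 0).
#' @param timestamp Acquisition time in seconds (default 0).
#' @param frame_index Integer frame index (default 0).
#' @return An object of class `thermal_frame`.
#' @export
thermal_frame <- function(pixels, gain = 1, offset = 0, timestamp = 0,
                          frame_index = 0L) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 2 || ncol(pixels) < 2)
    stop_input("thermal_frame: pixels must be at least 2 x 2")
  storage.mode(pixels) <- "double"
  structure(list(pixels = pixels, gain = as.numeric(gain),
                 offset = as.numeric(offset),
                 timestamp = as.numeric(timestamp),
                 frame_index = as.integer(frame_index)),
            class = "thermal_frame")
}

#' @export
print.thermal_frame <- function(x, ...) {
  cat(sprintf("<thermal_frame %d x %d, index %d, t=%.3fs, gain=%g, offset=%g>\n",
              nrow(x$pixels), ncol(x$pixels), x$frame_index, x$timestamp,
              x$gain, x$offset))
  invisible(x)
}

#' Apply the calibration of a frame
#' @param frame A `thermal_frame`.
#' @return Matrix of temperatures in Kelvin (`gain * intensity + offset`).
#' @export
frame_temperature <- function(frame) frame$gain * frame$pixels + frame$offset

#' Read a thermal frame from a single-channel TIFF or PNG file
#'
#' Pixel values are preserved losslessly as integers widened to double; the
#' calibration is attached as metadata, never applied destructively.
#'
#' @param path File path (extension .png, .tif or .tiff).
#' @param gain,offset Linear calibration, Kelvin per unit / Kelvin.
#' @param timestamp,frame_index Optional frame metadata.
#' @return A `thermal_frame`.
#' @export
read_frame <- function(path, gain = 1, offset = 0, timestamp = 0,
                       frame_index = 0L) {
  if (!file.exists(path)) stop_input("read_frame: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    if (length(dim(img)) == 3L)
      stop_format("read_frame: multi-channel PNG not supported: ", path)
    info <- attr(img, "info")
    depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
    pix <- matrix(round(as.vector(img) * (2^depth - 1)),
                  nrow(img), ncol(img))
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) == 3L)
      stop_format("read_frame: multi-channel TIFF not supported: ", path)
    pix <- img
  } else stop_format("read_frame: unsupported extension: ", ext)
  thermal_frame(pix, gain = gain, offset = offset, timestamp = timestamp,
                frame_index = frame_index)
}

#' Write a thermal frame to disk
#'
#' TIFF output is 16-bit (lossless for intensities up to 65535); PNG output is
#' 8-bit and only permitted for intensities up to 255.
#'
#' @param frame A `thermal_frame`.
#' @param path Output path (.tif/.tiff or .png).
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path) {
  ext <- tolower(tools::file_ext(path))
  pix <- round(frame$pixels)
  if (min(pix) < 0) stop_format("write_frame: negative intensities")
  if (ext %in% c("tif", "tiff")) {
    if (max(pix) > 65535) stop_format("write_frame: intensity exceeds 16-bit range")
    tiff::writeTIFF(pix / 65535, path, bits.per.sample = 16L)
  } else if (ext == "png") {
    if (max(pix) > 255)
      stop_format("write_frame: PNG output is 8-bit; intensity exceeds 255 ",
                  "(use TIFF for 16-bit data)")
    png::writePNG(pix / 255, path)
  } else stop_format("write_frame: unsupported extension: ", ext)
  invisible(path)
}

#' Read an ordered thermal image sequence from a directory
#'
#' Filenames must sort lexicographically in temporal order. Frames are
#' assigned indices 0..n-1 and timestamps `index / frame_rate`.
#'
#' @param directory Directory containing the frames.
#' @param pattern Filename regexp (default: PNG/TIFF extensions).
#' @param frame_rate Frames per second used to synthesize timestamps.
#' @param gain,offset Calibration applied to every frame.
#' @return List of `thermal_frame`, ordered.
#' @export
read_sequence <- function(directory, pattern = "\\.(png|tif|tiff)$",
                          frame_rate = 8, gain = 1, offset = 0) {
  files <- sort(list.files(directory, pattern = pattern, full.names = TRUE))
  if (length(files) == 0) stop_input("read_sequence: no frames in ", directory)
  frames <- lapply(seq_along(files), function(i)
    read_frame(files[i], gain = gain, offset = offset,
               timestamp = (i - 1) / frame_rate, frame_index = i - 1L))
  dims <- vapply(frames, function(f) dim(f$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_format("read_sequence: mixed image sizes in ", directory)
  frames
}

#' Read a 68-point landmark file ("pts" dialect)
#'
#' Accepts the common annotation dialect: optional comment lines, a header
#' with `n_points: 68`, and one "x y" pair per line between braces. Files may
#' store 0-based pixel coordinates (this package's convention) or 1-based
#' coordinates; pass `one_based = TRUE` for the latter. The result is always
#' 0-based.
#'
#' @param path File path.
#' @param one_based Set TRUE if the file stores 1-based coordinates.
#' @return A `shape68`.
#' @export
read_pts <- function(path, one_based = FALSE) {
  if (!file.exists(path)) stop_input("read_pts: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  np_line <- grep("^n_points:", lines, value = TRUE)
  if (length(np_line) == 1) {
    np <- as.integer(sub("^n_points:\\s*", "", np_line))
    if (!is.na(np) && np != 68)
      stop_format("read_pts: n_points is ", np, ", expected 68")
  }
  open <- match("{", lines); close <- match("}", lines)
  if (is.na(open) || is.na(close) || close <= open)
    stop_format("read_pts: malformed pts file (missing braces): ", path)
  body <- lines[(open + 1):(close - 1)]
  if (length(body) != 68)
    stop_format("read_pts: found ", length(body), " points, expected 68")
  xy <- do.call(rbind, lapply(strsplit(body, "\\s+"), as.numeric))
  if (anyNA(xy) || ncol(xy) != 2)
    stop_format("read_pts: non-numeric coordinate line in ", path)
  if (one_based) xy <- xy - 1
  shape68(xy)
}

#' Write a 68-point landmark file
#'
#' Writes the canonical form of the dialect read by [read_pts()]: 0-based
#' pixel coordinates at six decimal places, with a header comment declaring
#' the convention. `read_pts(write_pts(s, f))` reproduces coordinates to
#' 1e-6, and re-writing a canonically formatted file is byte-identical.
#'
#' @param shape A `shape68`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pts <- function(shape, path) {
  shape <- shape68(shape)
  lines <- c("# 0-based pixel coordinates (x y), origin at top-left pixel center",
             "version: 1", "n_points: 68", "{",
             sprintf("%.6f %.6f", shape[, 1], shape[, 2]), "}")
  writeLines(lines, path)
  invisible(path)
}

#' Write a scalar time series as CSV (columns time_s,value[,valid])
#' @param times,values Equal-length numeric vectors.
#' @param path Output path.
#' @param valid Optional logical vector of per-sample validity.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(times, values, path, valid = NULL) {
  df <- data.frame(time_s = times, value = values)
  if (!is.null(valid)) df$valid <- as.integer(valid)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a signal CSV written by [write_signal_csv()]
#' @param path CSV path.
#' @return data.frame with columns time_s, value and optionally valid.
#' @export
read_signal_csv <- function(path) {
  if (!file.exists(path)) stop_input("read_signal_csv: no such file: ", path)
  utils::read.csv(path)
}

#' Read a YAML run configuration
#' @param path YAML file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_input("read_config: no such file: ", path)
  yaml::read_yaml(path)
}
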