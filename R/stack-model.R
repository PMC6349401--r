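#' Two-channel confocal z-stack
#'
#' Container for a two-channel 3D fluorescence image plus calibration
#' metadata. Arrays are stored as `[y, x, z]` (row, column, layer) with
#' 1-based indices internally; all exported tables use 0-based `(z, y, x)`
#' coordinates (stated in their header comment).
#'
#' @param green,red 3D numeric arrays `[y, x, z]` of nonnegative intensities,
#'   identical dimensions, `y >= 8`, `x >= 8`, `z >= 1`. A 2D matrix is
#'   promoted to a single-layer stack.
#' @param pixel_size_xy lateral calibration, micrometres per pixel (> 0).
#' @param z_step axial spacing, micrometres per layer (> 0).
#' @param source_id free-text identifier carried into outputs.
#' @return An object of class `two_channel_stack` with fields `green`, `red`,
#'   `pixel_size_xy`, `z_step`, `source_id`.
#' @export
two_channel_stack <- function(green, red, pixel_size_xy, z_step,
                              source_id = "") {
  green <- as_stack_array(green)
  red <- as_stack_array(red)
  if (!identical(dim(green), dim(red)))
    stop("green and red channels must have identical dimensions")
  d <- dim(green)
  if (d[1] < 8L || d[2] < 8L || d[3] < 1L)
    stop("stack must be at least 8 x 8 pixels with >= 1 layer")
  if (anyNA(green) || anyNA(red) || min(green) < 0 || min(red) < 0)
    stop("intensities must be finite and nonnegative")
  stopifnot(is.numeric(pixel_size_xy), length(pixel_size_xy) == 1L,
            pixel_size_xy > 0, is.numeric(z_step), length(z_step) == 1L,
            z_step > 0)
  structure(
    list(green = green, red = red,
         pixel_size_xy = as.numeric(pixel_size_xy),
         z_step = as.numeric(z_step),
         source_id = as.character(source_id)),
    class = "two_channel_stack")
}

as_stack_array <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (!(is.array(x) && length(dim(x)) == 3L))
    stop("channel must be a 2D matrix or 3D array [y, x, z]")
  storage.mode(x) <- "double"
  x
}

#' @export
print.two_channel_stack <- function(x, ...) {
  d <- dim(x$green)
  cat(sprintf(
    "two_channel_stack: %d x %d px, %d layers | %.4g um/px, z-step %.4g um | %s\n",
    d[1], d[2], d[3], x$pixel_size_xy, x$z_step,
    if (nzchar(x$source_id)) x$source_id else "<unnamed>"))
  invisible(x)
}

#' Per-layer cell mask
#'
#' Boolean footprint of the selected cell in every z-layer. The union over z
#' of true pixels forms a single 4-connected island.
#'
#' @param layers logical array `[y, x, z]`.
#' @return Object of class `cell_mask` with fields `layers` and
#'   `projected_area` (number of pixels true in the union over z).
#' @export
cell_mask <- function(layers) {
  stopifnot(is.array(layers), length(dim(layers)) == 3L, is.logical(layers))
  structure(list(layers = layers,
                 projected_area = sum(apply(layers, c(1, 2), any))),
            class = "cell_mask")
}

#' @export
print.cell_mask <- function(x, ...) {
  cat(sprintf("cell_mask: %d layers, projected area %d px, %d voxels\n",
              dim(x$layers)[3], x$projected_area, sum(x$layers)))
  invisible(x)
}

#' Fluorescent foreground image
#'
#' Background-subtracted (and optionally edge-attenuated) intensities,
#' exactly zero outside the cell mask.
#'
#' @param values 3D nonnegative numeric array `[y, x, z]`.
#' @param mask the [cell_mask] it was computed under.
#' @return Object of class `foreground_image`.
#' @export
foreground_image <- function(values, mask) {
  stopifnot(inherits(mask, "cell_mask"),
            identical(dim(values), dim(mask$layers)))
  if (min(values) < 0) stop("foreground values must be nonnegative")
  if (any(values[!mask$layers] != 0))
    stop("foreground must be zero outside the mask")
  structure(list(values = values, mask = mask), class = "foreground_image")
}

#' FRAP intensity trace
#'
#' Raw ROI-mean time series of a fluorescence-recovery-after-photobleaching
#' experiment: the bleached ROI, a reference ROI (whole cell or unbleached
#' region, used for acquisition-bleaching correction) and a background ROI.
#'
#' @param times acquisition times in seconds, strictly increasing.
#' @param bleach_roi,reference_roi,background_roi mean ROI intensity per
#'   frame; equal lengths.
#' @param n_prebleach number of frames acquired before the bleach event
#'   (>= 1); total length must be >= `n_prebleach + 2`.
#' @return Object of class `frap_trace`.
#' @export
frap_trace <- function(times, bleach_roi, reference_roi, background_roi,
                       n_prebleach) {
  n <- length(times)
  stopifnot(n == length(bleach_roi), n == length(reference_roi),
            n == length(background_roi))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  n_prebleach <- as.integer(n_prebleach)
  if (n_prebleach < 1L || n < n_prebleach + 2L)
    stop("need n_prebleach >= 1 and at least 2 post-bleach frames")
  structure(list(times = as.numeric(times),
                 bleach_roi = as.numeric(bleach_roi),
                 reference_roi = as.numeric(reference_roi),
                 background_roi = as.numeric(background_roi),
                 n_prebleach = n_prebleach),
            class = "frap_trace")
}

coord_header <- "# coordinates: 0-based (z, y, x)"

#' Read a two-channel z-stack from a multi-page TIFF
#'
#' Pages are expected interleaved by layer: for each z-layer, one page per
#' channel in a fixed channel order (the layout written by
#' [write_stack()] and by ImageJ composite export). Calibration is taken
#' from metadata when present -- a JSON sidecar file `<path>.json` (written
#' by [write_stack()]) or JSON in the TIFF ImageDescription tag -- else
#' from the `pixel_size_xy` / `z_step` arguments, else the reader errors.
#'
#' @param path TIFF file path.
#' @param channel_map named integer vector assigning `green` and `red` to
#'   distinct 1-based channel indices within each layer group.
#' @param n_channels number of channels stored per layer (default: inferred
#'   from metadata, else `max(channel_map)`).
#' @param pixel_size_xy,z_step calibration fallbacks (micrometres) used when
#'   the file carries none.
#' @param source_id identifier; defaults to the file name.
#' @return A [two_channel_stack].
#' @export
read_stack <- function(path, channel_map = c(green = 1L, red = 2L),
                       n_channels = NULL, pixel_size_xy = NULL, z_step = NULL,
                       source_id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  stopifnot(all(c("green", "red") %in% names(channel_map)))
  channel_map <- vapply(channel_map, as.integer, integer(1))
  if (channel_map[["green"]] == channel_map[["red"]])
    stop("channel_map must assign green and red to distinct channel indices")
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
  meta <- parse_stack_metadata(path, pages)
  if (is.null(n_channels))
    n_channels <- if (!is.null(meta$n_channels)) meta$n_channels
                  else max(channel_map)
  if (max(channel_map) > n_channels)
    stop(sprintf("file holds %d channel(s) per layer but channel_map needs %d",
                 n_channels, max(channel_map)))
  if (length(pages) %% n_channels != 0L)
    stop("page count is not a multiple of the channel count")
  n_z <- length(pages) %/% n_channels
  grab <- function(ch) {
    idx <- (seq_len(n_z) - 1L) * n_channels + ch
    arr <- vapply(pages[idx], function(p) as.matrix(p), pages[[idx[1]]] * 0)
    array(arr, dim = c(dim(pages[[idx[1]]]), n_z))
  }
  px <- if (!is.null(meta$pixel_size_xy)) meta$pixel_size_xy else pixel_size_xy
  zs <- if (!is.null(meta$z_step)) meta$z_step else z_step
  if (is.null(px) || is.null(zs))
    stop("no calibration in file metadata and none supplied: ",
         "give pixel_size_xy and z_step")
  two_channel_stack(grab(channel_map[["green"]]), grab(channel_map[["red"]]),
                    pixel_size_xy = px, z_step = zs, source_id = source_id)
}

parse_stack_metadata <- function(path, pages) {
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    out <- tryCatch(jsonlite::fromJSON(sidecar), error = function(e) NULL)
    if (is.list(out)) return(out)
  }
  desc <- attr(pages[[1]], "description")
  if (is.null(desc) || !nzchar(desc)) return(list())
  out <- tryCatch(jsonlite::fromJSON(desc), error = function(e) NULL)
  if (!is.list(out)) return(list())
  out
}

#' Write a two-channel z-stack as a 16-bit multi-page TIFF
#'
#' Pages are interleaved by layer (green page, red page, next layer, ...);
#' calibration and channel order are written to a JSON sidecar `<path>.json`
#' so that [read_stack()] round-trips losslessly. Intensities must fit in
#' 16 bits (0..65535); they are stored exactly.
#'
#' @param stack a [two_channel_stack].
#' @param path output file path.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "two_channel_stack"))
  if (max(stack$green, stack$red) > 65535)
    stop("intensities exceed 16-bit range")
  n_z <- dim(stack$green)[3]
  pages <- vector("list", 2L * n_z)
  for (z in seq_len(n_z)) {
    pages[[2L * z - 1L]] <- stack$green[, , z] / 65535
    pages[[2L * z]] <- stack$red[, , z] / 65535
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(pixel_size_xy = stack$pixel_size_xy, z_step = stack$z_step,
         n_channels = 2L, channels = c("green", "red"),
         source_id = stack$source_id),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an integer label volume as a 16-bit multi-page TIFF
#'
#' One page per z-layer; labels up to 65535 are stored exactly and
#' recovered by [read_label_tiff()].
#'
#' @param labels integer array `[y, x, z]` (or matrix) of labels >= 0.
#' @param path output file path.
#' @export
write_label_tiff <- function(labels, path) {
  labels <- as_stack_array(labels)
  if (min(labels) < 0 || max(labels) > 65535 || any(labels != round(labels)))
    stop("labels must be integers in 0..65535")
  pages <- lapply(seq_len(dim(labels)[3]),
                  function(z) labels[, , z] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read an integer label volume written by [write_label_tiff()]
#' @param path TIFF file path.
#' @return integer array `[y, x, z]`.
#' @export
read_label_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- vapply(pages, function(p) round(as.matrix(p) * 65535),
                pages[[1]] * 0)
  storage.mode(arr) <- "integer"
  array(arr, dim = c(dim(pages[[1]]), length(pages)))
}

#' Write a result table deterministically
#'
#' CSV output carries a header comment declaring the 0-based `(z, y, x)`
#' coordinate convention; rows and columns are written in a stable order so
#' identical records yield byte-identical files.
#'
#' @param records a data.frame (possibly zero-row).
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @export
write_results <- function(records, path, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(records))
  if (format == "csv") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(coord_header, con)
    utils::write.csv(records, con, row.names = FALSE, eol = "\n")
  } else {
    jsonlite::write_json(records, path, dataframe = "rows", digits = NA)
  }
  invisible(path)
}

#' Read a FRAP trace CSV
#'
#' Expected columns: `time_s, bleach, reference, background`. Lines starting
#' with `#` are comments; a comment of the form `# n_prebleach=10` supplies
#' the pre-bleach frame count, otherwise it must be given as an argument.
#'
#' @param path CSV file path.
#' @param n_prebleach pre-bleach frame count override.
#' @return A [frap_trace].
#' @export
read_frap_trace <- function(path, n_prebleach = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  comments <- grep("^#", lines, value = TRUE)
  m <- regmatches(comments, regexec("n_prebleach\\s*=\\s*(\\d+)", comments))
  hit <- Filter(function(x) length(x) == 2L, m)
  if (is.null(n_prebleach) && length(hit))
    n_prebleach <- as.integer(hit[[1]][2])
  if (is.null(n_prebleach))
    stop("n_prebleach not found in header comments and not supplied")
  df <- utils::read.csv(text = lines, comment.char = "#")
  need <- c("time_s", "bleach", "reference", "background")
  if (!all(need %in% names(df)))
    stop("trace CSV must have columns: ", paste(need, collapse = ", "))
  frap_trace(df$time_s, df$bleach, df$reference, df$background, n_prebleach)
}

#' Write a FRAP trace CSV readable by [read_frap_trace()]
#' @param trace a [frap_trace].
#' @param path output path.
#' @export
write_frap_trace <- function(trace, path) {
  stopifnot(inherits(trace, "frap_trace"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("# n_prebleach=%d", trace$n_prebleach), con)
  utils::write.csv(
    data.frame(time_s = trace$times, bleach = trace$bleach_roi,
               reference = trace$reference_roi,
               background = trace$background_roi),
    con, row.names = FALSE, eol = "\n")
  invisible(path)
}
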