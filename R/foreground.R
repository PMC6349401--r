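#' Median-filter background subtraction
#'
#' Per layer, the diffuse cytoplasmic fluorescence is estimated by a median
#' filter (window larger than the largest expected punctum, so puncta
#' survive subtraction) and subtracted from the in-mask intensities; the
#' difference is clipped at 0 and denoised by a grayscale opening then
#' closing with a small disc. Pixels outside the mask are exactly 0.
#'
#' Out-of-mask pixels are filled with the layer's in-mask median before
#' filtering so the filter window never mixes in background zeros; this
#' makes the result exactly 0 for a constant in-mask image and invariant
#' (up to clipping) under a constant intensity offset.
#'
#' @param channel 3D intensity array `[y, x, z]`.
#' @param mask a [cell_mask].
#' @param median_radius median window radius in pixels (default 15).
#' @param noise_radius disc radius of the post-subtraction grayscale
#'   opening/closing (default 2: wide enough to erase the thin bright-rim
#'   remnant and the speckle filaments that would otherwise join punctum
#'   basins, while preserving foci of 1 um and above).
#' @return A [foreground_image].
#' @export
subtract_background <- function(channel, mask, median_radius = 15L,
                                noise_radius = 2L) {
  stopifnot(inherits(mask, "cell_mask"))
  channel <- as_stack_array(channel)
  stopifnot(identical(dim(channel), dim(mask$layers)), median_radius >= 1)
  out <- array(0, dim(channel))
  brush <- disc_brush(noise_radius)
  for (z in seq_len(dim(channel)[3])) {
    m <- mask$layers[, , z]
    if (!any(m)) next
    layer <- channel[, , z]
    fill <- stats::median(layer[m])
    layer[!m] <- fill
    mx <- max(layer)
    med <- if (mx > 0)
      EBImage::medianFilter(layer / mx, size = as.integer(median_radius)) * mx
    else layer
    fg <- pmax(layer - med, 0)
    # medianFilter runs on a 16-bit quantized copy; zero the sub-quantum
    # residues it leaves, they are numerical noise, not signal
    fg[fg <= mx * 4 / 65535] <- 0
    mx2 <- max(fg)
    if (mx2 > 0)       # EBImage grayscale morphology clamps to [0, 1]
      fg <- EBImage::closing(EBImage::opening(fg / mx2, brush), brush) * mx2
    fg[!m] <- 0
    out[, , z] <- pmax(fg, 0)
  }
  foreground_image(out, mask)
}

#' Attenuation factor as a function of edge distance
#'
#' Bright cell edges are a common false-positive source after background
#' subtraction; values near the edge are scaled by a factor rising linearly
#' from 0 at the edge to 1 at 40 px (0.5 at 20 px). `d` counts pixels
#' between a pixel and the nearest boundary mask pixel: the boundary pixel
#' itself has d = 0.
#'
#' @param d Euclidean distance from the cell edge, pixels.
#' @param full_distance distance at which the factor reaches 1 (default 40).
#' @return factor in `[0, 1]`.
#' @export
edge_factor <- function(d, full_distance = 40) {
  pmin(pmax(d, 0) / full_distance, 1)
}

#' Attenuate the fluorescent foreground near the cell edge
#'
#' For each in-mask pixel the Euclidean distance to the cell edge is
#' computed per layer (2D; axial voxel spacing is anisotropic, so 3D pixel
#' distances would be physically meaningless) with `EBImage::distmap`, and
#' the foreground is multiplied by [edge_factor()] of that distance. The
#' distance convention places the outermost in-mask pixel at d = 0, so edge
#' pixels are zeroed exactly.
#'
#' @param fg a [foreground_image].
#' @param mask the [cell_mask] it was computed under (defaults to
#'   `fg$mask`).
#' @param full_distance see [edge_factor()].
#' @return A [foreground_image] with attenuated values.
#' @export
attenuate_edges <- function(fg, mask = fg$mask, full_distance = 40) {
  stopifnot(inherits(fg, "foreground_image"), inherits(mask, "cell_mask"))
  vals <- fg$values
  for (z in seq_len(dim(vals)[3])) {
    m <- mask$layers[, , z]
    if (!any(m)) next
    d <- edge_distance(m)
    vals[, , z] <- vals[, , z] * edge_factor(d, full_distance)
  }
  foreground_image(vals, mask)
}

# Euclidean distance (px) from each in-mask pixel to the cell edge, with the
# outermost in-mask pixel at 0. distmap assigns 1 to a pixel adjacent to
# background, hence the -1.
edge_distance <- function(mask_layer) {
  d <- EBImage::distmap(EBImage::Image(mask_layer * 1), metric = "euclidean")
  pmax(as.matrix(EBImage::imageData(d)) - 1, 0)
}

#' Compute the fluorescent foreground of both channels
#'
#' Runs [subtract_background()] and [attenuate_edges()] on each channel
#' under the same cell mask.
#'
#' @param stack a [two_channel_stack].
#' @param mask a [cell_mask].
#' @param median_radius,noise_radius,full_distance see
#'   [subtract_background()] and [attenuate_edges()].
#' @return Named list with `foreground_image` elements `green` and `red`.
#' @export
compute_foreground <- function(stack, mask, median_radius = 15L,
                               noise_radius = 2L, full_distance = 40) {
  stopifnot(inherits(stack, "two_channel_stack"))
  lapply(list(green = stack$green, red = stack$red), function(ch)
    attenuate_edges(
      subtract_background(ch, mask, median_radius, noise_radius),
      mask, full_distance))
}
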