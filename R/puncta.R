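#' Laplacian-of-Gaussian kernel
#'
#' Scale-normalized negated LoG kernel, so the response to a bright blob of
#' matching scale is a positive peak.
#'
#' @param sigma Gaussian scale in pixels.
#' @return square numeric matrix (odd side, about 8 sigma wide).
#' @keywords internal
log_kernel <- function(sigma) {
  half <- max(3L, ceiling(4 * sigma))
  ax <- seq(-half, half)
  g <- exp(-ax^2 / (2 * sigma^2))
  gx <- outer(g, g)
  r2 <- outer(ax^2, ax^2, "+")
  k <- (2 - r2 / sigma^2) * gx / (2 * pi * sigma^2)   # -sigma^2 * LoG
  k - mean(k)                       # zero-sum: flat regions respond 0
}

#' Detect punctum seeds by multiscale Laplacian of Gaussian
#'
#' Per layer, the fluorescent foreground is convolved with negated LoG
#' kernels at `n_scales` geometrically spaced sigmas; local maxima of the
#' scale-normalized response over the (y, x, scale) neighbourhood that
#' exceed `rel_threshold` times the strongest response anywhere in the cell
#' (all layers) become seeds. Overlapping detections are resolved by
#' non-maximum suppression, keeping the stronger seed.
#'
#' @param fg a [foreground_image].
#' @param sigma_min,sigma_max scale range in pixels (defaults 2 and 8,
#'   covering roughly 1-3 um foci at 0.05-0.15 um/px).
#' @param n_scales number of scales (default 5).
#' @param rel_threshold response cut-off as a fraction of the cell-wide
#'   maximum response (default 0.1).
#' @return data.frame with columns `layer, y, x, sigma, response`
#'   (1-based pixel indices), ordered by decreasing response.
#' @export
detect_log <- function(fg, sigma_min = 2, sigma_max = 8, n_scales = 5L,
                       rel_threshold = 0.1) {
  stopifnot(inherits(fg, "foreground_image"),
            sigma_min > 0, sigma_min <= sigma_max,
            rel_threshold > 0, rel_threshold < 1)
  sigmas <- if (n_scales == 1L) sigma_min else
    exp(seq(log(sigma_min), log(sigma_max), length.out = n_scales))
  kernels <- lapply(sigmas, log_kernel)
  d <- dim(fg$values)
  empty <- data.frame(layer = integer(), y = integer(), x = integer(),
                      sigma = numeric(), response = numeric())
  if (max(fg$values) == 0) return(empty)
  seeds <- vector("list", d[3])
  for (z in seq_len(d[3])) {
    layer <- fg$values[, , z]
    if (max(layer) == 0) next
    resp <- array(0, c(d[1], d[2], length(sigmas)))
    for (s in seq_along(sigmas))
      resp[, , s] <- as.matrix(EBImage::filter2(layer, kernels[[s]],
                                                boundary = "replicate"))
    peaks <- local_maxima_3d(resp)
    if (!nrow(peaks)) next
    ok <- fg$values[cbind(peaks$y, peaks$x, z)] > 0 & peaks$value > 0
    peaks <- peaks[ok, , drop = FALSE]
    if (!nrow(peaks)) next
    seeds[[z]] <- data.frame(layer = z, y = peaks$y, x = peaks$x,
                             sigma = sigmas[peaks$s], response = peaks$value)
  }
  seeds <- do.call(rbind, seeds)
  if (is.null(seeds) || !nrow(seeds)) return(empty)
  seeds <- seeds[seeds$response >= rel_threshold * max(seeds$response), ,
                 drop = FALSE]
  seeds <- seeds[order(-seeds$response), , drop = FALSE]
  # per-layer non-maximum suppression at blob radius sqrt(2)*sigma
  keep <- logical(nrow(seeds))
  for (z in unique(seeds$layer)) {
    i_z <- which(seeds$layer == z)
    kept <- integer()
    for (i in i_z) {
      r_i <- sqrt(2) * seeds$sigma[i]
      if (!length(kept)) { kept <- i; keep[i] <- TRUE; next }
      dd <- sqrt((seeds$y[kept] - seeds$y[i])^2 +
                 (seeds$x[kept] - seeds$x[i])^2)
      if (all(dd >= pmax(r_i, sqrt(2) * seeds$sigma[kept]))) {
        kept <- c(kept, i); keep[i] <- TRUE
      }
    }
  }
  seeds <- seeds[keep, , drop = FALSE]
  rownames(seeds) <- NULL
  seeds
}

# strict local maxima of a 3D response array over the 26-neighbourhood,
# returned as data.frame(y, x, s, value)
local_maxima_3d <- function(resp) {
  d <- dim(resp)
  is_max <- array(TRUE, d)
  for (dy in -1:1) for (dx in -1:1) for (ds in -1:1) {
    if (dy == 0 && dx == 0 && ds == 0) next
    shifted <- array(-Inf, d)
    ys <- seq_len(d[1]); xs <- seq_len(d[2]); ss <- seq_len(d[3])
    ys_t <- ys + dy; xs_t <- xs + dx; ss_t <- ss + ds
    vy <- ys_t >= 1 & ys_t <= d[1]
    vx <- xs_t >= 1 & xs_t <= d[2]
    vs <- ss_t >= 1 & ss_t <= d[3]
    shifted[ys[vy], xs[vx], ss[vs]] <-
      resp[ys_t[vy], xs_t[vx], ss_t[vs]]
    is_max <- is_max & (resp > shifted | (resp == shifted &
      (dy > 0 | (dy == 0 & (dx > 0 | (dx == 0 & ds > 0))))))
  }
  idx <- which(is_max)
  if (!length(idx))
    return(data.frame(y = integer(), x = integer(), s = integer(),
                      value = numeric()))
  coord <- arrayInd(idx, d)
  data.frame(y = coord[, 1], x = coord[, 2], s = coord[, 3],
             value = resp[idx])
}

#' Segment punctum bodies by marker-seeded watershed
#'
#' The LoG marks where puncta are but not their extent; each seed is used as
#' a marker and the fluorescent-foreground landscape is flooded (seeded
#' region growing restricted to the support `foreground > 0`), yielding one
#' basin per seed. Basins are disjoint, contain only positive-foreground
#' pixels, and a lone seed in an isolated blob claims the blob's entire
#' connected support. Seeds falling on zero foreground are dropped with a
#' warning.
#'
#' @param fg a [foreground_image].
#' @param seeds data.frame from [detect_log()].
#' @return list of `punctum2d` objects: `layer`, `pixels` (2-column matrix
#'   of 1-based (y, x)), `intensity` (foreground sum), `seed` (y, x, sigma).
#' @export
segment_watershed <- function(fg, seeds) {
  stopifnot(inherits(fg, "foreground_image"))
  out <- list()
  if (is.null(seeds) || !nrow(seeds)) return(out)
  on_zero <- fg$values[cbind(seeds$y, seeds$x, seeds$layer)] <= 0
  if (any(on_zero)) {
    warning(sum(on_zero), " seed(s) on zero foreground dropped")
    seeds <- seeds[!on_zero, , drop = FALSE]
  }
  if (!nrow(seeds)) return(out)
  for (z in sort(unique(seeds$layer))) {
    sz <- seeds[seeds$layer == z, , drop = FALSE]
    layer <- fg$values[, , z]
    marker <- matrix(0L, nrow(layer), ncol(layer))
    marker[cbind(sz$y, sz$x)] <- seq_len(nrow(sz))
    basins <- EBImage::propagate(EBImage::Image(layer / max(layer)),
                                 seeds = marker, mask = layer > 0)
    basins <- as.matrix(EBImage::imageData(basins))
    for (i in seq_len(nrow(sz))) {
      pix <- which(basins == i)
      if (!length(pix)) next
      coord <- arrayInd(pix, dim(layer))
      out[[length(out) + 1L]] <- structure(
        list(layer = z, pixels = coord,
             intensity = sum(layer[pix]),
             seed = c(y = sz$y[i], x = sz$x[i], sigma = sz$sigma[i])),
        class = "punctum2d")
    }
  }
  out
}

#' Punctum intensity by basin summation
#'
#' @param p a `punctum2d` from [segment_watershed()].
#' @param fg the [foreground_image] it was segmented on.
#' @return sum of foreground values over the basin's pixels.
#' @export
measure_intensity <- function(p, fg) {
  stopifnot(inherits(p, "punctum2d"), inherits(fg, "foreground_image"))
  sum(fg$values[cbind(p$pixels[, 1], p$pixels[, 2], p$layer)])
}

#' Collate 2D puncta into 3D puncta across adjacent layers
#'
#' Two basins in layers z and z + 1 sharing at least one (y, x) pixel belong
#' to the same 3D punctum; the relation is closed transitively (connected
#' components of the adjacency graph), so a basin overlapping two disjoint
#' basins in the next layer merges all three.
#'
#' @param puncta2d list of `punctum2d` (any layer order).
#' @param channel channel label stored on the output (`"green"`/`"red"`).
#' @param dims optional `[y, x, z]` dimensions (taken from pixels if absent;
#'   only used to build label volumes later).
#' @return list of `punctum3d` objects: `id`, `channel`, `slices`,
#'   `voxels` (3-column matrix of 1-based (z, y, x)), `volume`,
#'   `intensity`, `centroid` (named z, y, x).
#' @export
collate_3d <- function(puncta2d, channel = "green", dims = NULL) {
  n <- length(puncta2d)
  if (!n) return(list())
  layers <- vapply(puncta2d, function(p) p$layer, integer(1))
  # pixel key -> punctum index maps per layer for the adjacency query
  keys <- lapply(puncta2d, function(p)
    p$pixels[, 1] + 1e6 * p$pixels[, 2])
  edges <- list()
  for (z in sort(unique(layers))) {
    a <- which(layers == z); b <- which(layers == z + 1L)
    if (!length(b)) next
    for (i in a) for (j in b)
      if (any(keys[[i]] %in% keys[[j]]))
        edges[[length(edges) + 1L]] <- c(i, j)
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, unlist(edges))
  comp <- igraph::components(g)$membership
  out <- lapply(sort(unique(comp)), function(cid) {
    members <- which(comp == cid)
    members <- members[order(layers[members])]
    vox <- do.call(rbind, lapply(members, function(i)
      cbind(z = puncta2d[[i]]$layer, puncta2d[[i]]$pixels)))
    colnames(vox) <- c("z", "y", "x")
    structure(list(
      id = NA_integer_, channel = channel,
      slices = puncta2d[members],
      voxels = vox,
      volume = nrow(vox),
      intensity = sum(vapply(puncta2d[members], function(p) p$intensity,
                             numeric(1))),
      centroid = c(z = mean(vox[, 1]), y = mean(vox[, 2]),
                   x = mean(vox[, 3]))),
      class = "punctum3d")
  })
  # stable ids: by centroid (z, y, x)
  ord <- order(vapply(out, function(p) p$centroid[["z"]], numeric(1)),
               vapply(out, function(p) p$centroid[["y"]], numeric(1)),
               vapply(out, function(p) p$centroid[["x"]], numeric(1)))
  out <- out[ord]
  for (i in seq_along(out)) out[[i]]$id <- i
  out
}

#' Detect and assemble 3D puncta in one channel
#'
#' Runs [detect_log()], [segment_watershed()] and [collate_3d()].
#'
#' @param fg a [foreground_image].
#' @param channel channel label for the output puncta.
#' @param ... passed to [detect_log()].
#' @return list of `punctum3d`.
#' @export
find_puncta <- function(fg, channel = "green", ...) {
  collate_3d(segment_watershed(fg, detect_log(fg, ...)), channel = channel,
             dims = dim(fg$values))
}

#' Label volume of a punctum set
#'
#' @param puncta list of `punctum3d`.
#' @param dims `[y, x, z]` array dimensions.
#' @return integer array with each punctum's voxels set to its id.
#' @export
puncta_label_volume <- function(puncta, dims) {
  lab <- array(0L, dims)
  for (p in puncta)
    lab[cbind(p$voxels[, "y"], p$voxels[, "x"], p$voxels[, "z"])] <- p$id
  lab
}

#' Puncta summary table
#'
#' One row per 3D punctum with 0-based (z, y, x) centroid and bounding box.
#'
#' @param puncta list of `punctum3d`.
#' @return data.frame with columns `punctum_id, channel, n_layers,
#'   volume_px, intensity, centroid_z, centroid_y, centroid_x,
#'   bbox_zmin, bbox_zmax, bbox_ymin, bbox_ymax, bbox_xmin, bbox_xmax`.
#' @export
puncta_table <- function(puncta) {
  if (!length(puncta))
    return(data.frame(punctum_id = integer(), channel = character(),
                      n_layers = integer(), volume_px = integer(),
                      intensity = numeric(), centroid_z = numeric(),
                      centroid_y = numeric(), centroid_x = numeric(),
                      bbox_zmin = integer(), bbox_zmax = integer(),
                      bbox_ymin = integer(), bbox_ymax = integer(),
                      bbox_xmin = integer(), bbox_xmax = integer()))
  do.call(rbind, lapply(puncta, function(p) data.frame(
    punctum_id = p$id, channel = p$channel,
    n_layers = length(unique(p$voxels[, "z"])),
    volume_px = p$volume, intensity = p$intensity,
    centroid_z = p$centroid[["z"]] - 1, centroid_y = p$centroid[["y"]] - 1,
    centroid_x = p$centroid[["x"]] - 1,
    bbox_zmin = min(p$voxels[, "z"]) - 1L,
    bbox_zmax = max(p$voxels[, "z"]) - 1L,
    bbox_ymin = min(p$voxels[, "y"]) - 1L,
    bbox_ymax = max(p$voxels[, "y"]) - 1L,
    bbox_xmin = min(p$voxels[, "x"]) - 1L,
    bbox_xmax = max(p$voxels[, "x"]) - 1L)))
}
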