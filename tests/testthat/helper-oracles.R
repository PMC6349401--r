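# Independent brute-force oracles and small fixture builders.
# Oracles deliberately avoid the package's code paths.

# exhaustive Otsu: try every integer gray level as the threshold and
# maximize between-class variance directly on the raw sample
brute_otsu <- function(values) {
  lo <- min(values); hi <- max(values)
  if (lo == hi) return(NA_real_)
  candidates <- lo:(hi - 1L)
  bcv <- vapply(candidates, function(t) {
    below <- values <= t
    w0 <- mean(below); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) return(-Inf)
    w0 * w1 * (mean(values[below]) - mean(values[!below]))^2
  }, numeric(1))
  candidates[which.max(bcv)]
}

vox_key <- function(vox) paste(vox[, 1], vox[, 2], vox[, 3])

# brute-force voxel-set intersection overlap
brute_overlap <- function(p, others) {
  other_keys <- unique(unlist(lapply(others, function(q) vox_key(q$voxels))))
  mean(vox_key(p$voxels) %in% other_keys)
}

# brute-force grouping of 2D basins into 3D objects: BFS over the
# shares-a-pixel-in-adjacent-layers relation
brute_collate_groups <- function(p2d) {
  n <- length(p2d)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (abs(p2d[[i]]$layer - p2d[[j]]$layer) != 1L) next
    ki <- paste(p2d[[i]]$pixels[, 1], p2d[[i]]$pixels[, 2])
    kj <- paste(p2d[[j]]$pixels[, 1], p2d[[j]]$pixels[, 2])
    if (any(ki %in% kj)) adj[i, j] <- TRUE
  }
  group <- rep(NA_integer_, n); g <- 0L
  for (s in seq_len(n)) {
    if (!is.na(group[s])) next
    g <- g + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(group[v])) next
      group[v] <- g
      queue <- c(queue, which(adj[v, ] & is.na(group)))
    }
  }
  group
}

# fixture builders ------------------------------------------------------

make_p2d <- function(layer, pixels, intensity = nrow(pixels)) {
  structure(list(layer = as.integer(layer),
                 pixels = cbind(pixels[, 1], pixels[, 2]),
                 intensity = intensity,
                 seed = c(y = pixels[1, 1], x = pixels[1, 2], sigma = 2)),
            class = "punctum2d")
}

make_p3d <- function(voxels, id = 1L, channel = "green") {
  colnames(voxels) <- c("z", "y", "x")
  structure(list(id = id, channel = channel, slices = NULL, voxels = voxels,
                 volume = nrow(voxels), intensity = nrow(voxels),
                 centroid = c(z = mean(voxels[, 1]), y = mean(voxels[, 2]),
                              x = mean(voxels[, 3]))),
            class = "punctum3d")
}

# solid box of voxels
box_voxels <- function(zs, ys, xs) {
  as.matrix(expand.grid(z = zs, y = ys, x = xs))
}

full_mask <- function(ny, nx, nz) {
  cell_mask(array(TRUE, c(ny, nx, nz)))
}

# small, fast synthetic scene used across tests
small_scene <- function(seed = 1L, ...) {
  generate_stack(scene_params(
    ny = 128L, nx = 128L, nz = 10L, cell_radius = 50,
    cell_z_center = 5.5, cell_z_radius = 7,
    n_puncta = 4L, punctum_diameter_um = c(1.0, 1.8),
    n_vacuoles = 1L, vacuole_radius = c(6, 8), ...),
    seed = seed)
}

# match detected puncta to planted ones by 3D centroid distance (px in
# plane, layers axially); returns per-planted nearest distance and index
match_planted <- function(puncta, truth_tab, channel) {
  tt <- truth_tab[truth_tab$channel == channel, , drop = FALSE]
  if (!length(puncta) || !nrow(tt))
    return(data.frame(id = integer(), dist = numeric(), det = integer()))
  cent <- t(vapply(puncta, function(p) p$centroid, numeric(3)))
  out <- lapply(seq_len(nrow(tt)), function(i) {
    d <- sqrt((cent[, "y"] - 1 - tt$centroid_y[i])^2 +
              (cent[, "x"] - 1 - tt$centroid_x[i])^2 +
              (cent[, "z"] - 1 - tt$centroid_z[i])^2)
    data.frame(id = tt$id[i], dist = min(d), det = which.min(d))
  })
  do.call(rbind, out)
}
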