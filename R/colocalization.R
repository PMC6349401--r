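voxel_key <- function(vox, dims) {
  (vox[, "z"] - 1) * (dims[1] * dims[2]) + (vox[, "x"] - 1) * dims[1] +
    vox[, "y"]
}

occupancy <- function(puncta, dims) {
  occ <- array(FALSE, dims)
  for (p in puncta)
    occ[cbind(p$voxels[, "y"], p$voxels[, "x"], p$voxels[, "z"])] <- TRUE
  occ
}

#' Volume-based overlap of one punctum with the other channel
#'
#' For a punctum in one channel, the overlap metric is the number of its
#' voxels lying inside any punctum of the other channel, divided by its
#' total voxel count; overlapped and total volumes are accumulated across
#' all z-layers the punctum spans.
#'
#' @param p a `punctum3d`.
#' @param others list of `punctum3d` from the other channel (same stack and
#'   mask).
#' @param dims `[y, x, z]` stack dimensions.
#' @return one-row data.frame: `punctum_id, channel, overlap_fraction,
#'   overlapped_volume, total_volume`.
#' @export
overlap_fraction <- function(p, others, dims) {
  occ <- occupancy(others, dims)
  overlap_fraction_occ(p, occ)
}

overlap_fraction_occ <- function(p, occ) {
  inside <- occ[cbind(p$voxels[, "y"], p$voxels[, "x"], p$voxels[, "z"])]
  data.frame(punctum_id = p$id, channel = p$channel,
             overlap_fraction = sum(inside) / p$volume,
             overlapped_volume = sum(inside), total_volume = p$volume)
}

#' Per-punctum overlap records for both channels
#'
#' @param green_puncta,red_puncta lists of `punctum3d`.
#' @param dims `[y, x, z]` stack dimensions.
#' @return data.frame of [overlap_fraction()] rows, green puncta first.
#' @export
overlap_records <- function(green_puncta, red_puncta, dims) {
  occ_g <- occupancy(green_puncta, dims)
  occ_r <- occupancy(red_puncta, dims)
  rows <- c(lapply(green_puncta, overlap_fraction_occ, occ = occ_r),
            lapply(red_puncta, overlap_fraction_occ, occ = occ_g))
  if (!length(rows))
    return(data.frame(punctum_id = integer(), channel = character(),
                      overlap_fraction = numeric(),
                      overlapped_volume = integer(),
                      total_volume = integer()))
  do.call(rbind, rows)
}

#' Pixel-based Pearson correlation within the cell
#'
#' Sample Pearson correlation of the two raw channels over all in-mask
#' voxels, the classical global co-localization readout.
#'
#' @param stack a [two_channel_stack].
#' @param mask a [cell_mask].
#' @return correlation in `[-1, 1]`, or `NA` with a warning when either
#'   channel is constant within the mask.
#' @export
pearson_within_cell <- function(stack, mask) {
  stopifnot(inherits(stack, "two_channel_stack"), inherits(mask, "cell_mask"))
  g <- stack$green[mask$layers]
  r <- stack$red[mask$layers]
  if (length(g) < 2L || stats::sd(g) == 0 || stats::sd(r) == 0) {
    warning("Pearson undefined: constant channel within mask")
    return(NA_real_)
  }
  stats::cor(g, r)
}

#' Randomize punctum placements within the cell
#'
#' Re-places each 3D punctum, one at a time in order of decreasing volume,
#' at a uniformly random integer (z, y, x) offset: a rigid translation of
#' all its per-layer components by the same in-plane shift plus a discrete
#' layer shift (no rotation, no reshaping). A placement is rejected and
#' redrawn if any voxel leaves the cell mask or collides with a previously
#' placed punctum of the same set. Fully reproducible given `seed`.
#'
#' @param puncta list of `punctum3d` (one channel).
#' @param mask a [cell_mask]; every punctum must fit inside it at its
#'   original position.
#' @param seed integer seed.
#' @param max_attempts_per_punctum rejection-sampling cap (default 1000);
#'   exceeding it raises a "placement limit reached" error naming the
#'   punctum.
#' @return list of `punctum3d` with translated voxels (slices dropped;
#'   volume, per-layer shapes and layer count preserved exactly).
#' @export
randomize_puncta <- function(puncta, mask, seed,
                             max_attempts_per_punctum = 1000L) {
  stopifnot(inherits(mask, "cell_mask"))
  if (!length(puncta)) return(list())
  dims <- dim(mask$layers)
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    occ <- array(FALSE, dims)
    ord <- order(-vapply(puncta, function(p) p$volume, numeric(1)))
    out <- vector("list", length(puncta))
    for (i in ord) {
      p <- puncta[[i]]
      vox <- p$voxels
      zr <- range(vox[, "z"]); yr <- range(vox[, "y"])
      xr <- range(vox[, "x"])
      placed <- FALSE
      for (attempt in seq_len(max_attempts_per_punctum)) {
        dz <- sample.int(dims[3] - (zr[2] - zr[1]), 1L) - zr[1]
        dy <- sample.int(dims[1] - (yr[2] - yr[1]), 1L) - yr[1]
        dx <- sample.int(dims[2] - (xr[2] - xr[1]), 1L) - xr[1]
        idx <- cbind(vox[, "y"] + dy, vox[, "x"] + dx, vox[, "z"] + dz)
        if (all(mask$layers[idx]) && !any(occ[idx])) {
          occ[idx] <- TRUE
          nv <- cbind(z = vox[, "z"] + dz, y = vox[, "y"] + dy,
                      x = vox[, "x"] + dx)
          q <- p
          q$voxels <- nv
          q$slices <- NULL
          q$centroid <- c(z = mean(nv[, 1]), y = mean(nv[, 2]),
                          x = mean(nv[, 3]))
          out[[i]] <- q
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop(sprintf(
          "placement limit reached for punctum %s (channel %s) after %d attempts",
          p$id, p$channel, max_attempts_per_punctum))
    }
    out
  })
}

#' Background overlap rate from randomized placements
#'
#' Generates `n_replicates` synthetic replicates of the cell in which the
#' puncta of each channel are independently re-placed at random within the
#' mask ([randomize_puncta()]; replicate r uses substreams derived from
#' `seed` and r), recomputes the per-punctum overlap metric, and summarizes
#' the per-replicate mean overlap fraction per channel. The observed means
#' are compared to the null via an empirical exceedance count (number of
#' replicates whose mean is at least the observed mean) reported as a
#' descriptive statistic.
#'
#' @param green_puncta,red_puncta lists of `punctum3d`.
#' @param mask a [cell_mask].
#' @param n_replicates number of synthetic replicates (default 10).
#' @param seed integer seed.
#' @param max_attempts_per_punctum see [randomize_puncta()].
#' @return list with `green` and `red` elements of class `background_rate`
#'   (`replicate_fractions`, `n_replicates`, `seed`, `mean`, `sd`,
#'   `observed_mean`, `exceedance`), plus `replicates` (data.frame of all
#'   per-replicate means).
#' @export
background_overlap <- function(green_puncta, red_puncta, mask,
                               n_replicates = 10L, seed = 1L,
                               max_attempts_per_punctum = 1000L) {
  stopifnot(n_replicates >= 1L)
  dims <- dim(mask$layers)
  obs <- overlap_records(green_puncta, red_puncta, dims)
  obs_mean <- c(
    green = mean(obs$overlap_fraction[obs$channel == "green"]),
    red = mean(obs$overlap_fraction[obs$channel == "red"]))
  fr_g <- fr_r <- rep(NA_real_, n_replicates)
  for (r in seq_len(n_replicates)) {
    rg <- tryCatch(
      randomize_puncta(green_puncta, mask, seed = substream_seed(seed, 2L * r),
                       max_attempts_per_punctum = max_attempts_per_punctum),
      error = function(e) stop("replicate ", r, ": ", conditionMessage(e)))
    rr <- tryCatch(
      randomize_puncta(red_puncta, mask,
                       seed = substream_seed(seed, 2L * r + 1L),
                       max_attempts_per_punctum = max_attempts_per_punctum),
      error = function(e) stop("replicate ", r, ": ", conditionMessage(e)))
    rec <- overlap_records(rg, rr, dims)
    fr_g[r] <- mean(rec$overlap_fraction[rec$channel == "green"])
    fr_r[r] <- mean(rec$overlap_fraction[rec$channel == "red"])
  }
  rate <- function(fr, ch) structure(
    list(channel = ch, replicate_fractions = fr,
         n_replicates = n_replicates, seed = seed,
         mean = mean(fr), sd = stats::sd(fr),
         observed_mean = obs_mean[[ch]],
         exceedance = sum(fr >= obs_mean[[ch]])),
    class = "background_rate")
  list(green = rate(fr_g, "green"), red = rate(fr_r, "red"),
       replicates = data.frame(replicate = seq_len(n_replicates),
                               green_mean = fr_g, red_mean = fr_r))
}

# deterministic substream derivation: distinct small-integer seeds per
# (seed, index) pair, kept within 32-bit range
substream_seed <- function(seed, index) {
  (as.numeric(seed) * 69069 + as.numeric(index) * 104729) %% 2147483647
}

#' Per-cell colocalization summary
#'
#' @param records observed per-punctum table from [overlap_records()].
#' @param rates output of [background_overlap()].
#' @param cell_id identifier.
#' @return one-row-per-channel data.frame with observed mean (unweighted and
#'   volume-weighted), randomized mean, sd, exceedance count, seed and
#'   replicate count.
#' @export
coloc_summary <- function(records, rates, cell_id = "") {
  do.call(rbind, lapply(c("green", "red"), function(ch) {
    rec <- records[records$channel == ch, , drop = FALSE]
    r <- rates[[ch]]
    data.frame(
      cell_id = cell_id, channel = ch, n_puncta = nrow(rec),
      observed_mean = if (nrow(rec)) mean(rec$overlap_fraction) else NA_real_,
      observed_mean_volume_weighted = if (nrow(rec))
        sum(rec$overlap_fraction * rec$total_volume) / sum(rec$total_volume)
        else NA_real_,
      randomized_mean = r$mean, randomized_sd = r$sd,
      exceedance = r$exceedance, n_replicates = r$n_replicates,
      seed = r$seed)
  }))
}
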