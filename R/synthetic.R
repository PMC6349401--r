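#' Default scene parameters for the synthetic stack generator
#'
#' The defaults emulate a single multiciliated-cell-like field: one bright,
#' irregular cell of roughly 20 um across (radius 100 px at 0.1 um/px)
#' spanning most of a 20-layer stack, a brighter rim at the cell edge, a
#' few dark intracellular vacuoles, and 1-3 um puncta placed towards the
#' cell periphery in the middle layers, with shot-like (Poisson) noise plus
#' Gaussian read noise.
#'
#' @param ... overrides for any parameter.
#' @return named list of parameters.
#' @export
scene_params <- function(...) {
  p <- list(
    ny = 256L, nx = 256L, nz = 20L,
    pixel_size_xy = 0.1, z_step = 0.5,
    cell_radius = 100, cell_irregularity = 0.12,
    cell_z_center = 10.5, cell_z_radius = 14,
    background_level = 10, cytoplasm_level = 100,
    rim_width = 3, rim_gain = 1.8,
    n_vacuoles = 2L, vacuole_radius = c(8, 12), vacuole_level = 25,
    n_puncta = 8L, coincident_fraction = 0,
    punctum_diameter_um = c(1.2, 2.8), punctum_amplitude = 160,
    punctum_elongation = c(1, 1.6),
    noise_level = 1, read_noise_sd = 2)
  ov <- list(...)
  stopifnot(all(names(ov) %in% names(p)))
  p[names(ov)] <- ov
  p
}

# dense elliptical-Gaussian punctum profile on its bounding box.
# Returns list(voxels (z,y,x matrix, support = 2-sigma ellipsoid), profile)
render_punctum <- function(center, sigma_y, sigma_x, sigma_z, theta, dims) {
  ry <- ceiling(2.2 * max(sigma_y, sigma_x)); rz <- ceiling(2.2 * sigma_z)
  ys <- max(1, round(center[2]) - ry):min(dims[1], round(center[2]) + ry)
  xs <- max(1, round(center[3]) - ry):min(dims[2], round(center[3]) + ry)
  zs <- max(1, round(center[1]) - rz):min(dims[3], round(center[1]) + rz)
  grid <- expand.grid(y = ys, x = xs, z = zs)
  dyy <- grid$y - center[2]; dxx <- grid$x - center[3]
  u <- cos(theta) * dyy + sin(theta) * dxx
  v <- -sin(theta) * dyy + cos(theta) * dxx
  q <- (u / sigma_y)^2 + (v / sigma_x)^2 + ((grid$z - center[1]) / sigma_z)^2
  keep <- q <= 16            # 4-sigma render support
  grid <- grid[keep, ]; q <- q[keep]
  list(voxels = cbind(z = grid$z[q <= 4], y = grid$y[q <= 4],
                      x = grid$x[q <= 4]),
       all = cbind(z = grid$z, y = grid$y, x = grid$x),
       profile = exp(-q / 2))
}

#' Generate a synthetic two-channel z-stack with known ground truth
#'
#' Renders one bright irregular cell with dark vacuoles and a brighter rim,
#' plants `n_puncta` 3D puncta per channel (thresholded anisotropic
#' Gaussians with random elongation, mimicking irregular foci), a fraction
#' `coincident_fraction` of the red puncta exactly coincident with a green
#' punctum (true overlap 1) and the rest kept clear of the other channel
#' (true overlap 0), then adds signal-dependent Poisson noise and Gaussian
#' read noise. Deterministic per seed.
#'
#' @param params a [scene_params()] list.
#' @param seed integer seed.
#' @return list with `stack` (a [two_channel_stack]), and `truth`: `cell`
#'   (logical array `[y, x, z]` of the planted cell footprint, vacuoles
#'   excluded), `puncta` (list with per-punctum channel, center, voxels),
#'   `table` (data.frame: channel, id, centroid_z/y/x 0-based, volume_px,
#'   true_overlap, partner_id), `params`, `seed`.
#' @export
generate_stack <- function(params = scene_params(), seed = 1L) {
  p <- params
  dims <- c(p$ny, p$nx, p$nz)
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    # --- cell body: irregular radius via low-order Fourier modulation
    ph <- stats::runif(3, 0, 2 * pi)
    amp <- stats::runif(3, 0.3, 1) * p$cell_irregularity
    cy <- p$ny / 2; cx <- p$nx / 2
    yy <- matrix(seq_len(p$ny), p$ny, p$nx)
    xx <- matrix(seq_len(p$nx), p$ny, p$nx, byrow = TRUE)
    ang <- atan2(yy - cy, xx - cx)
    rad <- sqrt((yy - cy)^2 + (xx - cx)^2)
    rim_fun <- 1 + amp[1] * sin(ang + ph[1]) + amp[2] * sin(2 * ang + ph[2]) +
      amp[3] * sin(3 * ang + ph[3])
    cell <- array(FALSE, dims)
    edge_dist <- array(0, dims)
    for (z in seq_len(p$nz)) {
      dz <- (z - p$cell_z_center) / p$cell_z_radius
      if (abs(dz) >= 1) next
      r_z <- p$cell_radius * sqrt(1 - dz^2) * rim_fun
      cell[, , z] <- rad <= r_z
      edge_dist[, , z] <- pmax(r_z - rad, 0)
    }
    if (!any(cell)) stop("degenerate scene: cell is empty")
    # --- vacuoles (dark 3D ellipsoids inside the cell)
    vac <- array(FALSE, dims)
    vac_list <- list()
    for (i in seq_len(p$n_vacuoles)) {
      vr <- stats::runif(1, p$vacuole_radius[1], p$vacuole_radius[2])
      ctr <- c(z = stats::runif(1, p$cell_z_center - 3, p$cell_z_center + 3),
               y = cy + stats::runif(1, -0.4, 0.4) * p$cell_radius,
               x = cx + stats::runif(1, -0.4, 0.4) * p$cell_radius)
      rp <- render_punctum(ctr, vr / 2, vr / 2, vr / 2 / (p$z_step / p$pixel_size_xy),
                           0, dims)
      if (nrow(rp$voxels)) {
        vac[rp$voxels[, c("y", "x", "z")]] <- TRUE
        vac_list[[i]] <- list(center = ctr, radius = vr)
      }
    }
    vac <- vac & cell
    # --- puncta: green placed first, red coincident or clear of green
    axial_ratio <- p$z_step / p$pixel_size_xy       # px per layer
    n_coinc <- round(p$coincident_fraction * p$n_puncta)
    draw_shape <- function() {
      d_um <- stats::runif(1, p$punctum_diameter_um[1], p$punctum_diameter_um[2])
      d_px <- d_um / p$pixel_size_xy
      el <- stats::runif(1, p$punctum_elongation[1], p$punctum_elongation[2])
      # d_um is the major-axis diameter (2 sigma each side); elongation
      # shrinks the minor axis so foci stay within the configured size
      list(sigma_y = d_px / 4, sigma_x = d_px / 4 / el,
           sigma_z = (d_um / p$z_step) / 4,
           theta = stats::runif(1, 0, pi), d_px = d_px)
    }
    draw_center <- function(extent_px, extent_z) {
      for (i in seq_len(2000L)) {
        a <- stats::runif(1, 0, 2 * pi)
        rf <- sqrt(stats::runif(1, 0.35^2, 0.8^2))
        zc <- p$cell_z_center + stats::runif(1, -3, 3)
        r_here <- p$cell_radius *
          sqrt(max(1 - ((zc - p$cell_z_center) / p$cell_z_radius)^2, 0.05)) *
          (1 + amp[1] * sin(a + ph[1]) + amp[2] * sin(2 * a + ph[2]) +
             amp[3] * sin(3 * a + ph[3]))
        ctr <- c(z = zc, y = cy + rf * r_here * sin(a),
                 x = cx + rf * r_here * cos(a))
        margin_ok <- (1 - rf) * r_here > extent_px + 6
        z_ok <- ctr[1] - extent_z >= 2 && ctr[1] + extent_z <= p$nz - 1
        vac_ok <- !length(vac_list) || all(vapply(vac_list, function(v)
          sqrt(sum((v$center[c("y", "x")] - ctr[c("y", "x")])^2)) >
            v$radius + extent_px + 3, logical(1)))
        if (margin_ok && z_ok && vac_ok) return(ctr)
      }
      stop("puncta do not fit in cell: center sampling failed")
    }
    clear_of <- function(ctr, extent, placed, min_gap = 4) {
      !length(placed) || all(vapply(placed, function(q) {
        dxy <- sqrt(sum((q$center[c("y", "x")] - ctr[c("y", "x")])^2))
        dz <- abs(q$center[["z"]] - ctr[["z"]]) * axial_ratio
        sqrt(dxy^2 + dz^2) > extent + q$extent + min_gap
      }, logical(1)))
    }
    place <- function(placed_same, placed_other, avoid_other) {
      for (i in seq_len(2000L)) {
        sh <- draw_shape()
        extent <- 2 * max(sh$sigma_y, sh$sigma_x)
        ctr <- draw_center(extent, 2 * sh$sigma_z)
        if (!clear_of(ctr, extent, placed_same)) next
        if (avoid_other && !clear_of(ctr, extent, placed_other)) next
        return(c(sh, list(center = ctr, extent = extent)))
      }
      stop("puncta do not fit in cell: placement failed")
    }
    green <- list(); red <- list()
    for (i in seq_len(p$n_puncta))
      green[[i]] <- place(green, list(), FALSE)
    for (i in seq_len(p$n_puncta)) {
      if (i <= n_coinc) {
        red[[i]] <- green[[i]]          # same center and shape: overlap 1
      } else {
        red[[i]] <- place(red, green, TRUE)
      }
    }
    # --- render intensity volumes
    base <- array(p$background_level, dims)
    rim <- edge_dist > 0 & edge_dist <= p$rim_width
    base[cell] <- p$cytoplasm_level
    base[rim & cell] <- p$cytoplasm_level * p$rim_gain
    base[vac] <- p$vacuole_level
    g_img <- base; r_img <- base
    add_punctum <- function(img, sp) {
      rp <- render_punctum(sp$center, sp$sigma_y, sp$sigma_x, sp$sigma_z,
                           sp$theta, dims)
      idx <- rp$all[, c("y", "x", "z")]
      img[idx] <- img[idx] + p$punctum_amplitude * rp$profile
      list(img = img, voxels = rp$voxels)
    }
    truth_p <- list(); k <- 0L
    for (i in seq_along(green)) {
      res <- add_punctum(g_img, green[[i]]); g_img <- res$img
      k <- k + 1L
      truth_p[[k]] <- list(channel = "green", id = i,
                           center = green[[i]]$center, voxels = res$voxels,
                           true_overlap = if (i <= n_coinc) 1 else 0,
                           partner_id = if (i <= n_coinc) i else NA_integer_)
    }
    for (i in seq_along(red)) {
      res <- add_punctum(r_img, red[[i]]); r_img <- res$img
      k <- k + 1L
      truth_p[[k]] <- list(channel = "red", id = i,
                           center = red[[i]]$center, voxels = res$voxels,
                           true_overlap = if (i <= n_coinc) 1 else 0,
                           partner_id = if (i <= n_coinc) i else NA_integer_)
    }
    # --- noise: Poisson shot noise plus Gaussian read noise
    noisify <- function(img) {
      if (p$noise_level > 0) {
        shot <- array(stats::rpois(length(img), lambda = img), dim(img)) - img
        img <- img + p$noise_level * shot +
          stats::rnorm(length(img), sd = p$read_noise_sd * p$noise_level)
      }
      array(pmin(pmax(round(img), 0), 65535), dim(img))
    }
    stack <- two_channel_stack(noisify(g_img), noisify(r_img),
                               pixel_size_xy = p$pixel_size_xy,
                               z_step = p$z_step,
                               source_id = sprintf("synthetic_seed%d", seed))
    if (!length(truth_p)) tab <- data.frame(
      channel = character(), id = integer(), centroid_z = numeric(),
      centroid_y = numeric(), centroid_x = numeric(), volume_px = integer(),
      true_overlap = numeric(), partner_id = integer())
    else tab <- do.call(rbind, lapply(truth_p, function(q) data.frame(
      channel = q$channel, id = q$id,
      centroid_z = q$center[["z"]] - 1, centroid_y = q$center[["y"]] - 1,
      centroid_x = q$center[["x"]] - 1, volume_px = nrow(q$voxels),
      true_overlap = q$true_overlap, partner_id = q$partner_id)))
    list(stack = stack,
         truth = list(cell = cell & !vac, vacuoles = vac_list,
                      puncta = truth_p, table = tab, params = p,
                      seed = seed))
  })
}

#' Generate a synthetic FRAP trace with known ground truth
#'
#' Single-exponential recovery sampled at the configured frame interval
#' (defaults: 0.2 s, 300 frames), with multiplicative acquisition bleaching
#' applied to the bleach and reference ROIs alike, an additive constant
#' background, and Gaussian noise. The bleach event coincides with the
#' first post-bleach frame. Deterministic per seed.
#'
#' @param mobile_fraction true mobile fraction, percent.
#' @param tau true recovery time constant, seconds.
#' @param n_prebleach,n_frames frame counts (total includes pre-bleach).
#' @param dt frame interval, seconds.
#' @param bleach_depth normalized level immediately after the bleach.
#' @param prebleach_level,reference_level,background_level raw intensities.
#' @param acq_bleach_rate per-frame fractional acquisition bleaching.
#' @param noise_sd Gaussian noise, as a fraction of each ROI's level.
#' @param seed integer seed.
#' @return list `(trace, mobile_fraction, tau)`; `trace` is a
#'   [frap_trace].
#' @export
generate_frap_trace <- function(mobile_fraction = 70, tau = 3,
                                n_prebleach = 10L, n_frames = 300L,
                                dt = 0.2, bleach_depth = 0.3,
                                prebleach_level = 1000,
                                reference_level = 800,
                                background_level = 50,
                                acq_bleach_rate = 0.005,
                                noise_sd = 0.01, seed = 1L) {
  stopifnot(n_frames > n_prebleach + 10L)
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    times <- (seq_len(n_frames) - 1L) * dt
    frame <- seq_len(n_frames) - 1L
    post <- (n_prebleach + 1L):n_frames
    t_b <- times[post[1]]
    f <- rep(1, n_frames)
    f0 <- bleach_depth
    f_inf <- f0 + (mobile_fraction / 100) * (1 - f0)
    f[post] <- f0 + (f_inf - f0) * (1 - exp(-(times[post] - t_b) / tau))
    acq <- (1 - acq_bleach_rate)^frame
    ble <- background_level + prebleach_level * f * acq
    ref <- background_level + reference_level * acq
    bg <- rep(background_level, n_frames)
    if (noise_sd > 0) {
      ble <- ble + stats::rnorm(n_frames, sd = noise_sd * prebleach_level)
      ref <- ref + stats::rnorm(n_frames, sd = noise_sd * reference_level)
      bg <- bg + stats::rnorm(n_frames, sd = noise_sd * background_level)
    }
    list(trace = frap_trace(times, ble, ref, bg, n_prebleach),
         mobile_fraction = mobile_fraction, tau = tau)
  })
}
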