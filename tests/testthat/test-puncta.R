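gaussian_blob_fg <- function(ny, nx, centers, sigma, amp = 100) {
  layer <- matrix(0, ny, nx)
  yy <- row(layer); xx <- col(layer)
  for (i in seq_len(nrow(centers)))
    layer <- layer + amp * exp(-((yy - centers[i, 1])^2 +
                                 (xx - centers[i, 2])^2) / (2 * sigma^2))
  layer[layer < amp * 1e-3] <- 0
  foreground_image(array(layer, c(ny, nx, 1)), full_mask(ny, nx, 1))
}

test_that("all-zero foreground yields no seeds and no basins", {
  fg <- foreground_image(array(0, c(32, 32, 2)), full_mask(32, 32, 2))
  seeds <- detect_log(fg)
  expect_equal(nrow(seeds), 0L)
  expect_length(segment_watershed(fg, seeds), 0L)
})

test_that("a planted Gaussian blob is found at its center and scale", {
  fg <- gaussian_blob_fg(96, 96, cbind(48, 52), sigma = 4)
  seeds <- detect_log(fg)
  expect_equal(nrow(seeds), 1L)
  expect_lte(sqrt((seeds$y - 48)^2 + (seeds$x - 52)^2), 2)
  expect_lte(max(seeds$sigma / 4, 4 / seeds$sigma), 1.5)
})

test_that("two well-separated blobs give exactly two seeds", {
  fg <- gaussian_blob_fg(128, 128, rbind(c(40, 40), c(40 + 30, 40 + 30)),
                         sigma = 4)
  seeds <- detect_log(fg)
  expect_equal(nrow(seeds), 2L)
})

test_that("a lone seed claims its blob's entire connected support", {
  fg <- gaussian_blob_fg(64, 64, cbind(32, 32), sigma = 4)
  seeds <- data.frame(layer = 1L, y = 32L, x = 32L, sigma = 4,
                      response = 1)
  basins <- segment_watershed(fg, seeds)
  expect_length(basins, 1L)
  support <- which(fg$values[, , 1] > 0)
  got <- sort((basins[[1]]$pixels[, 2] - 1) * 64 + basins[[1]]$pixels[, 1])
  expect_identical(as.integer(got), sort(support))
})

test_that("two seeds in touching blobs give disjoint basins covering both", {
  fg <- gaussian_blob_fg(96, 96, rbind(c(48, 40), c(48, 56)), sigma = 5)
  seeds <- data.frame(layer = c(1L, 1L), y = c(48L, 48L), x = c(40L, 56L),
                      sigma = 5, response = c(1, 1))
  basins <- segment_watershed(fg, seeds)
  expect_length(basins, 2L)
  k1 <- paste(basins[[1]]$pixels[, 1], basins[[1]]$pixels[, 2])
  k2 <- paste(basins[[2]]$pixels[, 1], basins[[2]]$pixels[, 2])
  expect_length(intersect(k1, k2), 0L)
  expect_equal(length(k1) + length(k2), sum(fg$values[, , 1] > 0))
  # every basin pixel has positive foreground
  expect_true(all(fg$values[cbind(basins[[1]]$pixels, 1)] > 0))
})

test_that("seeds on zero foreground are dropped with a warning", {
  fg <- gaussian_blob_fg(64, 64, cbind(32, 32), sigma = 4)
  seeds <- data.frame(layer = c(1L, 1L), y = c(32L, 2L), x = c(32L, 2L),
                      sigma = 4, response = c(1, 0.5))
  expect_warning(basins <- segment_watershed(fg, seeds), "zero foreground")
  expect_length(basins, 1L)
})

test_that("basin intensity equals per-pixel summation", {
  p <- make_p2d(1L, rbind(c(3, 4), c(3, 5), c(4, 4), c(4, 5)))
  vals <- array(0, c(8, 8, 1))
  vals[3:4, 4:5, 1] <- 2
  fg <- foreground_image(vals, full_mask(8, 8, 1))
  expect_equal(measure_intensity(p, fg), 8)
  expect_equal(measure_intensity(p, foreground_image(array(0, c(8, 8, 1)),
                                                     full_mask(8, 8, 1))), 0)
  withr::with_seed(8, {
    vals2 <- array(runif(8 * 8 * 3), c(8, 8, 3))
    fg2 <- foreground_image(vals2, full_mask(8, 8, 3))
    pix <- unique(cbind(sample(1:8, 12, TRUE), sample(1:8, 12, TRUE)))
    p2 <- make_p2d(2L, pix)
    manual <- sum(vapply(seq_len(nrow(pix)), function(i)
      vals2[pix[i, 1], pix[i, 2], 2], numeric(1)))
    expect_equal(measure_intensity(p2, fg2), manual)
  })
})

test_that("identical basins in consecutive layers collate into one punctum", {
  pix <- box_voxels(1, 3:7, 5:6)[, c("y", "x")]
  p2d <- lapply(3:5, function(z) make_p2d(z, pix))
  p3 <- collate_3d(p2d)
  expect_length(p3, 1L)
  expect_equal(p3[[1]]$volume, 30)
  expect_equal(length(unique(p3[[1]]$voxels[, "z"])), 3L)
})

test_that("a layer gap separates puncta (adjacency is |dz| = 1)", {
  pix <- box_voxels(1, 3:7, 5:6)[, c("y", "x")]
  p3 <- collate_3d(list(make_p2d(2L, pix), make_p2d(4L, pix)))
  expect_length(p3, 2L)
})

test_that("a basin bridging two disjoint basins merges all three", {
  wide <- box_voxels(1, 5, 2:12)[, c("y", "x")]
  left <- box_voxels(1, 5, 2:4)[, c("y", "x")]
  right <- box_voxels(1, 5, 10:12)[, c("y", "x")]
  p3 <- collate_3d(list(make_p2d(2L, wide), make_p2d(3L, left),
                        make_p2d(3L, right)))
  expect_length(p3, 1L)
  expect_equal(p3[[1]]$volume, 11 + 3 + 3)
})

test_that("collation conserves voxels and matches a brute-force grouping", {
  withr::with_seed(13, {
    for (rep in 1:10) {
      p2d <- list()
      for (z in 1:5) {
        n_b <- sample(0:3, 1)
        used <- matrix(FALSE, 30, 30)
        for (b in seq_len(n_b)) {
          for (try in 1:20) {
            y0 <- sample(1:24, 1); x0 <- sample(1:24, 1)
            h <- sample(2:6, 1); w <- sample(2:6, 1)
            patch <- used[y0:(y0 + h), x0:(x0 + w)]
            if (!any(patch)) {
              used[y0:(y0 + h), x0:(x0 + w)] <- TRUE
              p2d[[length(p2d) + 1L]] <-
                make_p2d(z, box_voxels(1, y0:(y0 + h),
                                       x0:(x0 + w))[, c("y", "x")])
              break
            }
          }
        }
      }
      if (!length(p2d)) next
      p3 <- collate_3d(p2d)
      expect_equal(sum(vapply(p3, function(p) p$volume, numeric(1))),
                   sum(vapply(p2d, function(p) nrow(p$pixels), numeric(1))))
      groups <- brute_collate_groups(p2d)
      expect_equal(length(p3), length(unique(groups)))
      sizes_pkg <- sort(vapply(p3, function(p) p$volume, numeric(1)))
      sizes_brute <- sort(as.numeric(tapply(
        vapply(p2d, function(p) nrow(p$pixels), numeric(1)), groups, sum)))
      expect_equal(sizes_pkg, sizes_brute)
    }
  })
})

test_that("planted puncta are recovered on a small synthetic scene", {
  sim <- small_scene(seed = 31)
  mask <- segment_cell(sim$stack)
  fg <- compute_foreground(sim$stack, mask)
  for (ch in c("green", "red")) {
    p3 <- find_puncta(fg[[ch]], ch)
    m <- match_planted(p3, sim$truth$table, ch)
    expect_gte(mean(m$dist <= 3), 0.75)
    expect_lte(length(p3) - nrow(m), 1L)
  }
})
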