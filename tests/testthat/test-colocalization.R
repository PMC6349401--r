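test_that("overlap fraction handles containment, disjointness and partial overlap", {
  dims <- c(20, 20, 4)
  p <- make_p3d(box_voxels(2, 5:8, 5:8), id = 1L, channel = "red")
  inside <- make_p3d(box_voxels(1:3, 3:10, 3:10), channel = "green")
  expect_equal(overlap_fraction(p, list(inside), dims)$overlap_fraction, 1)
  far <- make_p3d(box_voxels(4, 15:16, 15:16), channel = "green")
  expect_equal(overlap_fraction(p, list(far), dims)$overlap_fraction, 0)
  # 10 px in each of 2 layers; 5 px of the first layer covered -> 0.25
  p2 <- make_p3d(rbind(box_voxels(1, 5, 1:10), box_voxels(2, 5, 1:10)))
  cover <- make_p3d(box_voxels(1, 5, 1:5), channel = "red")
  rec <- overlap_fraction(p2, list(cover), dims)
  expect_equal(rec$overlap_fraction, 0.25)
  expect_equal(rec$overlapped_volume, 5)
  expect_equal(rec$total_volume, 20)
})

test_that("overlap fraction equals the brute-force voxel-set oracle", {
  withr::with_seed(17, {
    dims <- c(24, 24, 6)
    for (rep in 1:30) {
      rand_punctum <- function(id, ch) {
        z0 <- sample(1:4, 1); y0 <- sample(1:16, 1); x0 <- sample(1:16, 1)
        make_p3d(box_voxels(z0:min(z0 + sample(0:2, 1), 6),
                            y0:(y0 + sample(1:6, 1)),
                            x0:(x0 + sample(1:6, 1))), id = id, channel = ch)
      }
      p <- rand_punctum(1L, "red")
      others <- lapply(1:3, rand_punctum, ch = "green")
      expect_equal(overlap_fraction(p, others, dims)$overlap_fraction,
                   brute_overlap(p, others))
    }
  })
})

test_that("Pearson within the cell hits its algebraic anchors", {
  withr::with_seed(23, {
    g <- array(round(runif(16 * 16 * 2, 0, 255)), c(16, 16, 2))
    mask <- full_mask(16, 16, 2)
    stack_same <- two_channel_stack(g, g, 0.1, 0.5)
    expect_equal(pearson_within_cell(stack_same, mask), 1)
    stack_anti <- two_channel_stack(g, max(g) - g, 0.1, 0.5)
    expect_equal(pearson_within_cell(stack_anti, mask), -1)
    stack_const <- two_channel_stack(g, array(5, dim(g)), 0.1, 0.5)
    expect_warning(r <- pearson_within_cell(stack_const, mask), "constant")
    expect_true(is.na(r))
  })
})

test_that("independent noise channels give near-zero Pearson", {
  withr::with_seed(29, {
    ok <- vapply(1:20, function(i) {
      g <- array(rpois(22 * 22 * 21, 100), c(22, 22, 21))
      r <- array(rpois(22 * 22 * 21, 100), c(22, 22, 21))
      abs(pearson_within_cell(two_channel_stack(g, r, 0.1, 0.5),
                              full_mask(22, 22, 21))) < 0.05
    }, logical(1))
    expect_gte(mean(ok), 0.9)
  })
})

scene_puncta <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- small_scene(seed = 41)
      mask <- segment_cell(sim$stack)
      fg <- compute_foreground(sim$stack, mask)
      cache <<- list(mask = mask,
                     green = find_puncta(fg$green, "green"),
                     red = find_puncta(fg$red, "red"),
                     dims = dim(sim$stack$green))
    }
    cache
  }
})

test_that("randomization preserves shapes, stays in-mask and is reproducible", {
  sc <- scene_puncta()
  orig_vols <- vapply(sc$green, function(p) p$volume, numeric(1))
  for (s in 1:10) {
    rnd <- randomize_puncta(sc$green, sc$mask, seed = s)
    expect_equal(vapply(rnd, function(p) p$volume, numeric(1)), orig_vols)
    for (k in seq_along(rnd)) {
      p <- rnd[[k]]; orig <- sc$green[[k]]
      expect_equal(nrow(p$voxels), p$volume)      # rigid translation
      expect_true(all(sc$mask$layers[p$voxels[, c("y", "x", "z")]]))
      # per-layer slice sizes are preserved exactly
      expect_equal(as.integer(table(p$voxels[, "z"])),
                   as.integer(table(orig$voxels[, "z"])))
    }
    # within-channel disjointness
    keys <- unlist(lapply(rnd, function(p) vox_key(p$voxels)))
    expect_equal(anyDuplicated(keys), 0L)
  }
  r1 <- randomize_puncta(sc$green, sc$mask, seed = 99)
  r2 <- randomize_puncta(sc$green, sc$mask, seed = 99)
  expect_identical(lapply(r1, `[[`, "voxels"), lapply(r2, `[[`, "voxels"))
  r3 <- randomize_puncta(sc$green, sc$mask, seed = 100)
  expect_false(identical(lapply(r1, `[[`, "voxels"),
                         lapply(r3, `[[`, "voxels")))
})

test_that("near-packing randomization hits the placement limit", {
  layers <- array(FALSE, c(16, 16, 1))
  layers[5:7, 5:7, 1] <- TRUE              # room for exactly one 3x3 punctum
  mask <- cell_mask(layers)
  puncta <- list(make_p3d(box_voxels(1, 5:7, 5:7), id = 1L),
                 make_p3d(box_voxels(1, 5:7, 5:7), id = 2L))
  expect_error(randomize_puncta(puncta, mask, seed = 1,
                                max_attempts_per_punctum = 50),
               "placement limit reached")
})

test_that("randomized single-voxel centroids are uniform over the mask", {
  mask <- full_mask(16, 16, 1)
  p <- list(make_p3d(box_voxels(1, 8, 8), id = 1L))
  n_draw <- 1600L
  pos <- t(vapply(seq_len(n_draw), function(s)
    randomize_puncta(p, mask, seed = s)[[1]]$voxels[1, c("y", "x")],
    numeric(2)))
  # coarse 4 x 4 grid chi-square goodness of fit
  cell <- (ceiling(pos[, 1] / 4) - 1) * 4 + ceiling(pos[, 2] / 4)
  counts <- tabulate(cell, 16)
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("background overlap returns one fraction per replicate and channel", {
  sc <- scene_puncta()
  bg <- background_overlap(sc$green, sc$red, sc$mask, n_replicates = 10,
                           seed = 5)
  expect_length(bg$green$replicate_fractions, 10L)
  expect_length(bg$red$replicate_fractions, 10L)
  expect_true(all(bg$replicates$green_mean >= 0 &
                  bg$replicates$green_mean <= 1))
  expect_equal(bg$green$n_replicates, 10L)
  # reproducible under the same seed
  bg2 <- background_overlap(sc$green, sc$red, sc$mask, n_replicates = 10,
                            seed = 5)
  expect_identical(bg$replicates, bg2$replicates)
})

test_that("sparse randomized overlap matches the uniform-placement expectation", {
  mask <- full_mask(60, 60, 5)
  green <- lapply(1:5, function(i)
    make_p3d(box_voxels(i, 10 * i, 10 * i), id = i, channel = "green"))
  red <- lapply(1:3, function(i)
    make_p3d(box_voxels(i, 5:14, 20:29), id = i, channel = "red"))
  occupied_fraction <- sum(vapply(red, function(p) p$volume, numeric(1))) /
    sum(mask$layers)
  bg <- background_overlap(green, red, mask, n_replicates = 200, seed = 77)
  se <- stats::sd(bg$green$replicate_fractions) / sqrt(200)
  expect_lte(abs(bg$green$mean - occupied_fraction), 3 * se + 1e-9)
})

test_that("coincident channels beat their randomized background", {
  sim <- small_scene(seed = 53, coincident_fraction = 1)
  res <- coloc_pipeline(sim$stack, seed = 3)
  s <- res$summary
  expect_true(all(s$observed_mean > 0.5))
  expect_true(all(s$observed_mean > s$randomized_mean + 5 * s$randomized_sd))
  expect_true(all(s$exceedance == 0))
})
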