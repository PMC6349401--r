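#' Otsu threshold of an intensity sample
#'
#' Exhaustive between-class-variance maximization over a 256-bin histogram.
#' For integer-valued data whose range fits in `levels` bins, the histogram
#' uses the exact integer gray levels, so the returned threshold is a gray
#' level and foreground is `values > threshold`. Float data are binned over
#' their range and the lower edge of the selected bin is returned.
#'
#' @param values numeric vector.
#' @param levels histogram bin count (default 256).
#' @return The threshold, or `NA` when all values are equal (degenerate
#'   input: nothing is above threshold).
#' @export
otsu_threshold <- function(values, levels = 256L) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) return(NA_real_)
  lo <- min(values); hi <- max(values)
  if (lo == hi) return(NA_real_)
  integerish <- all(values == round(values)) && (hi - lo) < levels
  if (integerish) {
    mids <- lo:hi
    counts <- tabulate(values - lo + 1L, nbins = length(mids))
  } else {
    breaks <- seq(lo, hi, length.out = levels + 1L)
    bin <- pmin(findInterval(values, breaks, all.inside = TRUE), levels)
    counts <- tabulate(bin, nbins = levels)
    mids <- breaks[-length(breaks)]
  }
  p <- counts / sum(counts)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  k <- seq_len(length(mids) - 1L)           # split after bin k
  w0k <- w0[k]; w1k <- 1 - w0k
  num <- (mu_t * w0k - mu[k])^2
  bcv <- ifelse(w0k > 0 & w1k > 0, num / (w0k * w1k), -Inf)
  as.numeric(mids[which.max(bcv)])
}

#' Per-layer Otsu thresholds and binary masks
#'
#' Applies an Otsu threshold independently to every z-layer of the
#' segmentation channel; pixels above threshold become mask pixels. A layer
#' whose pixels are all equal yields an empty mask (degenerate rule).
#'
#' @param channel 3D intensity array `[y, x, z]` (a matrix is promoted).
#' @return Object of class `layer_thresholds`: `thresholds` (one per layer,
#'   `NA` for degenerate layers) and `masks` (logical array).
#' @export
threshold_layers <- function(channel) {
  channel <- as_stack_array(channel)
  n_z <- dim(channel)[3]
  thresholds <- rep(NA_real_, n_z)
  masks <- array(FALSE, dim(channel))
  for (z in seq_len(n_z)) {
    t_z <- otsu_threshold(channel[, , z])
    thresholds[z] <- t_z
    if (!is.na(t_z)) masks[, , z] <- channel[, , z] > t_z
  }
  structure(list(thresholds = thresholds, masks = masks),
            class = "layer_thresholds")
}

# 4-connected labeling of a logical matrix; returns integer matrix of labels
# (0 = background). Built on igraph components; EBImage::bwlabel is
# 8-connected and unsuitable for the projected-island rule here.
label_components_4 <- function(fg) {
  labels <- matrix(0L, nrow(fg), ncol(fg))
  idx <- which(fg)
  if (!length(idx)) return(labels)
  ny <- nrow(fg)
  n <- length(fg)
  row <- (idx - 1L) %% ny + 1L
  v <- idx[row < ny]                 # neighbour below, same column
  v <- v[fg[v + 1L]]
  h <- idx[idx + ny <= n]            # neighbour to the right
  h <- h[fg[h + ny]]
  vmap <- integer(n)
  vmap[idx] <- seq_along(idx)
  edges <- rbind(cbind(vmap[v], vmap[v + 1L]),
                 cbind(vmap[h], vmap[h + ny]))
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, as.vector(t(edges)))
  labels[idx] <- igraph::components(g)$membership
  labels
}

#' Select the cell from per-layer masks
#'
#' Sums the binary layer masks into a single projected image, labels its
#' disjoint islands by 4-connectivity, scores each island by its projected
#' pixel-value sum (a proxy of volume), keeps the largest, and intersects
#' every layer mask with that island's footprint.
#'
#' @param thresholds a `layer_thresholds` object from [threshold_layers()].
#' @return A [cell_mask].
#' @export
select_cell <- function(thresholds) {
  stopifnot(inherits(thresholds, "layer_thresholds"))
  masks <- thresholds$masks
  proj <- apply(masks, c(1, 2), sum)
  if (all(proj == 0)) stop("no cell found: all layer masks are empty")
  labels <- label_components_4(proj > 0)
  sums <- tapply(proj[labels > 0], labels[labels > 0], sum)
  best <- as.integer(names(sums)[which.max(sums)])
  footprint <- labels == best
  out <- masks
  for (z in seq_len(dim(masks)[3])) out[, , z] <- masks[, , z] & footprint
  cell_mask(out)
}

disc_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

#' Refine the cell mask: morphological clean-up and vacuole removal
#'
#' Per layer, applies morphological closing then opening with a disc to
#' remove small features caused by noise, then a second round of Otsu
#' thresholding restricted to the in-mask intensity histogram of that layer;
#' coherent in-mask regions below this second threshold (intracellular
#' vacuoles and organelles with markedly lower fluorophore concentration)
#' are removed. The below-threshold pixel set is cleaned with a binary
#' opening before removal so that single-pixel noise does not punch holes in
#' the mask (holes would corrupt the edge-distance map downstream).
#'
#' @param mask a [cell_mask].
#' @param channel the segmentation channel, 3D array `[y, x, z]`.
#' @param struct_radius disc radius in pixels for the morphology (default 3).
#' @return A refined [cell_mask].
#' @export
refine_mask <- function(mask, channel, struct_radius = 3L) {
  stopifnot(inherits(mask, "cell_mask"))
  channel <- as_stack_array(channel)
  stopifnot(identical(dim(channel), dim(mask$layers)))
  brush <- disc_brush(struct_radius)
  out <- mask$layers
  for (z in seq_len(dim(out)[3])) {
    m <- out[, , z]
    if (!any(m)) next
    m <- EBImage::opening(EBImage::closing(m * 1, brush), brush) > 0.5
    if (any(m)) {
      vals <- channel[, , z][m]
      t2 <- otsu_threshold(vals)
      # a vacuole is a minority dark compartment: only remove when the
      # below-threshold set is the smaller class, otherwise the split
      # reflects bright structures (rim, puncta), not vacuoles
      if (!is.na(t2) && mean(vals <= t2) < 0.5) {
        vac <- m & channel[, , z] <= t2
        # opening by reconstruction: keep only components with a core at
        # least as large as the structuring element, then remove them
        # whole; per-pixel noise has no core and stays in the mask
        core <- EBImage::opening(vac * 1, brush) > 0.5
        if (any(core)) {
          labs <- label_components_4(vac)
          cored <- setdiff(unique(labs[core]), 0L)
          m <- m & !matrix(labs %in% cored, nrow(labs), ncol(labs))
        }
      }
    }
    out[, , z] <- m
  }
  cell_mask(out)
}

#' Segment the cell of a two-channel stack
#'
#' Convenience wrapper running [threshold_layers()], [select_cell()] and
#' [refine_mask()] on the configured segmentation channel (green by
#' default, as the cell is outlined on the GFP channel).
#'
#' @param stack a [two_channel_stack].
#' @param segmentation_channel `"green"` or `"red"`.
#' @param struct_radius morphology disc radius in pixels.
#' @return A [cell_mask].
#' @export
segment_cell <- function(stack, segmentation_channel = "green",
                         struct_radius = 3L) {
  stopifnot(inherits(stack, "two_channel_stack"))
  ch <- match.arg(segmentation_channel, c("green", "red"))
  refine_mask(select_cell(threshold_layers(stack[[ch]])), stack[[ch]],
              struct_radius = struct_radius)
}
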