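#' Default pipeline configuration
#'
#' Every tunable parameter of the colocalization pipeline with its default.
#' Can be written to / read from a YAML file ([write_config()],
#' [read_config()]) and passed to [run_coloc()].
#'
#' @param ... overrides for any entry.
#' @return named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    segmentation_channel = "green",
    struct_radius = 3L,          # px, disc for mask closing/opening
    median_radius = 15L,         # px, background median window
    noise_radius = 2L,           # px, post-subtraction opening/closing
    edge_full_distance = 40,     # px at which edge attenuation reaches 1
    sigma_min = 2, sigma_max = 8, n_scales = 5L,   # LoG scales, px
    rel_threshold = 0.1,         # LoG response cut-off (fraction of max)
    replicates = 10L,            # randomized-placement replicates
    max_attempts = 1000L,        # placement rejection limit per punctum
    pixel_size_xy = NULL, z_step = NULL)   # calibration fallbacks
  ov <- list(...)
  stopifnot(all(names(ov) %in% names(cfg)))
  cfg[names(ov)] <- ov
  cfg
}

#' @rdname default_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

#' @rdname default_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}

#' Run the full colocalization analysis on one stack in memory
#'
#' Segmentation, fluorescent foreground, puncta detection and assembly,
#' per-punctum overlap, pixel-based Pearson correlation, and the
#' randomized-placement background rate.
#'
#' @param stack a [two_channel_stack].
#' @param config a [default_config()] list.
#' @param seed integer seed for the randomization null.
#' @return list: `mask`, `foreground` (per channel), `puncta` (per
#'   channel), `puncta_table`, `overlaps`, `background` (per channel, see
#'   [background_overlap()]), `pearson`, `summary`.
#' @export
coloc_pipeline <- function(stack, config = default_config(), seed = 1L) {
  mask <- segment_cell(stack, config$segmentation_channel,
                       config$struct_radius)
  fg <- compute_foreground(stack, mask, config$median_radius,
                           config$noise_radius, config$edge_full_distance)
  puncta <- lapply(c(green = "green", red = "red"), function(ch)
    find_puncta(fg[[ch]], channel = ch,
                sigma_min = config$sigma_min, sigma_max = config$sigma_max,
                n_scales = config$n_scales,
                rel_threshold = config$rel_threshold))
  dims <- dim(stack$green)
  overlaps <- overlap_records(puncta$green, puncta$red, dims)
  bg <- background_overlap(puncta$green, puncta$red, mask,
                           n_replicates = config$replicates, seed = seed,
                           max_attempts_per_punctum = config$max_attempts)
  list(mask = mask, foreground = fg, puncta = puncta,
       puncta_table = rbind(puncta_table(puncta$green),
                            puncta_table(puncta$red)),
       overlaps = overlaps, background = bg,
       pearson = pearson_within_cell(stack, mask),
       summary = coloc_summary(overlaps, bg, cell_id = stack$source_id))
}

#' Run the colocalization pipeline on stack files and write results
#'
#' Batch entry point: for each TIFF a per-punctum table, overlap table,
#' per-replicate background table, per-cell summary, label-mask TIFFs and a
#' run manifest (all parameters, seed, package version, input hashes) are
#' written under `out_dir`. Per-stack failures are logged and skipped; the
#' call errors only if every stack fails.
#'
#' @param paths character vector of stack TIFF paths, or a directory.
#' @param out_dir output directory (created).
#' @param config a [default_config()] list.
#' @param seed integer seed.
#' @return invisibly, the combined per-cell summary data.frame.
#' @export
run_coloc <- function(paths, out_dir, config = default_config(), seed = 1L) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.tiff?$", full.names = TRUE)
  stopifnot(length(paths) >= 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summaries <- list(); failures <- character()
  for (path in paths) {
    res <- tryCatch({
      stack <- read_stack(path, pixel_size_xy = config$pixel_size_xy,
                          z_step = config$z_step)
      out <- coloc_pipeline(stack, config, seed = seed)
      tag <- tools::file_path_sans_ext(basename(path))
      write_results(out$puncta_table,
                    file.path(out_dir, paste0(tag, "_puncta.csv")))
      write_results(out$overlaps,
                    file.path(out_dir, paste0(tag, "_overlaps.csv")))
      write_results(out$background$replicates,
                    file.path(out_dir, paste0(tag, "_background.csv")))
      write_results(out$summary,
                    file.path(out_dir, paste0(tag, "_summary.csv")))
      dims <- dim(stack$green)
      for (ch in c("green", "red"))
        write_label_tiff(puncta_label_volume(out$puncta[[ch]], dims),
                         file.path(out_dir, paste0(tag, "_", ch,
                                                   "_labels.tif")))
      if (!nrow(out$puncta_table))
        warning("no detectable puncta in ", path)
      out$summary
    }, error = function(e) {
      message("stack failed, skipping: ", path, " (",
              conditionMessage(e), ")")
      NULL
    })
    if (is.null(res)) failures <- c(failures, path)
    else summaries[[path]] <- res
  }
  if (!length(summaries)) stop("all stacks failed: ",
                               paste(failures, collapse = ", "))
  summary <- do.call(rbind, summaries)
  rownames(summary) <- NULL
  write_results(summary, file.path(out_dir, "cells_summary.csv"))
  write_manifest(file.path(out_dir, "manifest.json"), config = config,
                 seed = seed, inputs = paths, failures = failures)
  invisible(summary)
}

#' Analyze FRAP trace files and write results
#'
#' @param paths character vector of trace CSV paths, or a directory.
#' @param out_dir output directory (created).
#' @param mode `"full_bleach"` or `"half_bleach"`.
#' @param n_prebleach pre-bleach frame count override (otherwise taken from
#'   each file's header comment).
#' @return invisibly, the [batch_frap()] result.
#' @export
run_frap <- function(paths, out_dir, mode = c("full_bleach", "half_bleach"),
                     n_prebleach = NULL) {
  mode <- match.arg(mode)
  if (length(paths) == 1L && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.csv$", full.names = TRUE)
  stopifnot(length(paths) >= 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  traces <- list()
  for (path in paths) {
    tr <- tryCatch(read_frap_trace(path, n_prebleach),
                   error = function(e) {
                     message("trace failed to load: ", path, " (",
                             conditionMessage(e), ")")
                     NULL
                   })
    if (!is.null(tr))
      traces[[tools::file_path_sans_ext(basename(path))]] <- tr
  }
  if (!length(traces)) stop("no readable traces among: ",
                            paste(paths, collapse = ", "))
  out <- batch_frap(traces, mode = mode)
  write_results(out$results, file.path(out_dir, "frap_results.csv"))
  write_results(out$summary, file.path(out_dir, "frap_summary.csv"))
  write_manifest(file.path(out_dir, "manifest.json"),
                 config = list(mode = mode), seed = NA, inputs = paths,
                 failures = character())
  invisible(out)
}

#' Write a synthetic stack and its ground truth to disk
#'
#' @param out_dir output directory.
#' @param params a [scene_params()] list.
#' @param seed integer seed.
#' @return invisibly, paths of the stack TIFF and truth CSV.
#' @export
simulate_stack_files <- function(out_dir, params = scene_params(),
                                 seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- generate_stack(params, seed = seed)
  tif <- file.path(out_dir, sprintf("synthetic_stack_seed%d.tif", seed))
  csv <- file.path(out_dir, sprintf("synthetic_truth_seed%d.csv", seed))
  write_stack(sim$stack, tif)
  write_results(sim$truth$table, csv)
  invisible(c(stack = tif, truth = csv))
}

#' Write synthetic FRAP traces and their ground truth to disk
#'
#' @param out_dir output directory.
#' @param n number of traces.
#' @param seed integer seed (trace i uses a substream of it).
#' @param ... passed to [generate_frap_trace()].
#' @return invisibly, the trace file paths.
#' @export
simulate_frap_files <- function(out_dir, n = 3L, seed = 1L, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(n); truth <- vector("list", n)
  for (i in seq_len(n)) {
    sim <- generate_frap_trace(seed = substream_seed(seed, i), ...)
    paths[i] <- file.path(out_dir, sprintf("synthetic_frap_%02d.csv", i))
    write_frap_trace(sim$trace, paths[i])
    truth[[i]] <- data.frame(trace = basename(paths[i]),
                             mobile_fraction = sim$mobile_fraction,
                             tau = sim$tau)
  }
  jsonlite::write_json(do.call(rbind, truth),
                       file.path(out_dir, "synthetic_frap_truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(paths)
}

write_manifest <- function(path, config, seed, inputs, failures) {
  manifest <- list(
    package = "fociloc",
    version = as.character(utils::packageVersion("fociloc")),
    seed = seed,
    config = config[!vapply(config, is.null, logical(1))],
    inputs = data.frame(path = inputs,
                        md5 = unname(tools::md5sum(inputs))),
    failed = failures,
    coordinates = "0-based (z, y, x)")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
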