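#' Configuration for a full pipeline run
#'
#' Bundles the input source and every stage parameter for [run_pipeline()].
#' Exactly one of `sim` (a [sim_config()], inputs are simulated) or
#' `red_path`/`green_path` (TIFF stacks are read) must be supplied.  For
#' simulated input a matched background movie is generated automatically;
#' for file input supply either `background_path` (a no-green-fluorophore
#' recording) or `background_scalar`.
#'
#' @param sim Optional [sim_config()].
#' @param red_path,green_path Optional input TIFF paths.
#' @param background_path Optional background-movie green TIFF path.
#' @param background_scalar Optional scalar background level.
#' @param frame_interval_s Seconds between frames (file input; simulated
#'   input carries its own).
#' @param block Frames per averaging block.
#' @param radius_px Nucleus radius for detection and masks.
#' @param quality_threshold Minimum LoG response for a detection.
#' @param min_iou Minimum disk IoU for track linking.
#' @param correct_red,correct_green Per-channel photobleaching-correction
#'   opt-outs.
#' @param baseline_degree,baseline_max_iter,baseline_tol Baseline
#'   parameters ([estimate_baseline()]).
#' @param rel_threshold,min_frames,merge_gap Event-calling parameters
#'   ([detect_events()]).
#' @param duration_thresholds_s Duration thresholds for the summary
#'   survival fractions.
#' @param out_dir Optional output directory; when set, every stage artifact
#'   plus a manifest is written there.
#' @param write_stacks Whether to write the (large) corrected image stacks
#'   when `out_dir` is set (default `TRUE`).
#' @return A validated `run_config` object.
#' @export
run_config <- function(sim = NULL,
                       red_path = NULL, green_path = NULL,
                       background_path = NULL, background_scalar = NULL,
                       frame_interval_s = 5,
                       block = 5L,
                       radius_px = 5,
                       quality_threshold = 8,
                       min_iou = 0.1,
                       correct_red = TRUE, correct_green = TRUE,
                       baseline_degree = 3L, baseline_max_iter = 100L,
                       baseline_tol = 1e-3,
                       rel_threshold = 0.25, min_frames = 1L, merge_gap = 0L,
                       duration_thresholds_s = c(20, 60),
                       out_dir = NULL, write_stacks = TRUE) {
  has_sim <- !is.null(sim)
  has_files <- !is.null(red_path) || !is.null(green_path)
  if (has_sim == has_files) {
    stop("supply exactly one input source: 'sim' or red_path/green_path",
         call. = FALSE)
  }
  if (has_sim) stopifnot(inherits(sim, "sim_config"))
  if (has_files && (is.null(red_path) || is.null(green_path))) {
    stop("both 'red_path' and 'green_path' are required for file input",
         call. = FALSE)
  }
  structure(list(sim = sim, red_path = red_path, green_path = green_path,
                 background_path = background_path,
                 background_scalar = background_scalar,
                 frame_interval_s = frame_interval_s,
                 block = as.integer(block), radius_px = radius_px,
                 quality_threshold = quality_threshold, min_iou = min_iou,
                 correct_red = isTRUE(correct_red),
                 correct_green = isTRUE(correct_green),
                 baseline_degree = as.integer(baseline_degree),
                 baseline_max_iter = as.integer(baseline_max_iter),
                 baseline_tol = baseline_tol,
                 rel_threshold = rel_threshold,
                 min_frames = as.integer(min_frames),
                 merge_gap = as.integer(merge_gap),
                 duration_thresholds_s = duration_thresholds_s,
                 out_dir = out_dir, write_stacks = isTRUE(write_stacks)),
            class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full event-detection pipeline
#'
#' Executes the stage chain: acquire (simulate or read) the two-channel
#' movie, correct photobleaching per channel, block-average the red channel,
#' detect and track nuclei, render label masks, extract background-corrected
#' green traces, estimate baselines and call events, and summarize (basal
#' log-variability, duration fractions, counts).  With `out_dir` set, every
#' artifact is written (TIFF stacks, CSV tables, JSON summary) together with
#' a manifest of parameters and MD5 checksums; identical configuration and
#' seed reproduce byte-identical tables.
#'
#' @param config A [run_config()].
#' @return List with `tracks`, `masks`, `traces`, `baselines`, `events`,
#'   `summary`, `bleach_fits`, `background`, `truth` (simulated input only)
#'   and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  truth <- NULL
  if (!is.null(config$sim)) {
    sim <- .stage("simulate", simulate_movie(config$sim))
    movie <- sim$movie
    truth <- sim$truth
    bg_movie_green <- .stage("simulate_background", {
      bg_cfg <- config$sim
      bg_cfg$seed <- (config$sim$seed + 104729L) %% .Machine$integer.max
      simulate_background_movie(bg_cfg)$green
    })
  } else {
    movie <- .stage("read", read_movie(config$red_path, config$green_path,
                                       config$frame_interval_s))
    bg_movie_green <- if (!is.null(config$background_path)) {
      .stage("read_background", read_stack_tiff(config$background_path))
    } else NULL
  }
  dt <- movie$frame_interval_s

  fits <- list()
  red <- movie$red
  if (config$correct_red) {
    fits$red <- .stage("fit_bleach_red", fit_bleach(red, dt, "red"))
    red <- .stage("correct_bleach_red", correct_bleach(red, fits$red))
  }
  green <- movie$green
  if (config$correct_green) {
    fits$green <- .stage("fit_bleach_green", fit_bleach(green, dt, "green"))
    green <- .stage("correct_bleach_green", correct_bleach(green, fits$green))
  }
  movie <- NULL  # release the raw stacks

  red_avg <- .stage("block_average", block_average(red, config$block))
  n_blocks <- attr(red_avg, "n_blocks")

  tracks <- .stage("track", track_nuclei(red_avg, config$radius_px,
                                         config$quality_threshold,
                                         config$min_iou))
  complete <- .stage("filter_tracks",
                     filter_complete_tracks(tracks, n_blocks))
  if (nrow(complete) == 0L) {
    stop("pipeline stage 'filter_tracks' failed: no cell remained trackable ",
         "for the whole movie", call. = FALSE)
  }
  masks <- .stage("masks", render_label_masks(complete, dim(red)[1:2]))

  traces <- .stage("traces", extract_traces(green, masks, config$block, dt))

  background <- NULL
  if (!is.null(bg_movie_green)) {
    if (config$correct_green) {
      bg_fit <- .stage("fit_bleach_background",
                       fit_bleach(bg_movie_green, dt, "green_background"))
      bg_movie_green <- correct_bleach(bg_movie_green, bg_fit)
    }
    background <- .stage("background", estimate_background(bg_movie_green))
    bg_movie_green <- NULL
    traces <- .stage("subtract_background",
                     subtract_background(traces, background))
  } else if (!is.null(config$background_scalar)) {
    background <- config$background_scalar
    traces <- .stage("subtract_background",
                     subtract_background(traces, background))
  }

  det <- .stage("events",
                detect_events_all(traces,
                                  degree = config$baseline_degree,
                                  max_iter = config$baseline_max_iter,
                                  tol = config$baseline_tol,
                                  rel_threshold = config$rel_threshold,
                                  min_frames = config$min_frames,
                                  merge_gap = config$merge_gap))

  summary <- .stage("summary", {
    s <- list(n_cells_tracked = length(unique(complete$track_id)),
              n_blocks = n_blocks,
              n_frames_used = nrow(traces$F),
              n_events = nrow(det$events))
    basal <- basal_summary(traces, det$events)
    s$basal <- basal
    s$log_sd_basal <- if (nrow(basal) >= 2L && all(basal$basal > 0)) {
      as.numeric(log_sd(basal$basal))
    } else NA_real_
    if (nrow(det$events) > 0L) {
      s$duration <- duration_fractions(det$events,
                                       config$duration_thresholds_s, dt)
      s$mean_events_per_cell <- nrow(det$events) / s$n_cells_tracked
    }
    s
  })

  manifest <- list(
    parameters = config[setdiff(names(config), c("sim", "out_dir"))],
    sim = if (!is.null(config$sim)) unclass(config$sim) else NULL,
    counts = list(n_cells_tracked = summary$n_cells_tracked,
                  n_events = summary$n_events,
                  n_true_events = if (!is.null(truth)) nrow(truth$events)
                                  else NA_integer_),
    checksums = NULL)

  if (!is.null(out_dir)) {
    paths <- c()
    wcsv <- function(df, name) {
      p <- file.path(out_dir, name)
      utils::write.csv(df, p, row.names = FALSE)
      p
    }
    paths["tracks"] <- wcsv(complete, "tracks.csv")
    td <- traces_to_df(traces)
    paths["traces"] <- wcsv(td, "traces.csv")
    paths["events"] <- wcsv(det$events, "events.csv")
    paths["basal"] <- wcsv(summary$basal, "basal.csv")
    if (!is.null(truth)) {
      paths["truth_cells"] <- wcsv(truth$cells, "truth_cells.csv")
      paths["truth_events"] <- wcsv(truth$events, "truth_events.csv")
    }
    if (config$write_stacks) {
      paths["red_corrected"] <- file.path(out_dir, "red_corrected.tif")
      write_stack_tiff(red, paths["red_corrected"])
      paths["green_corrected"] <- file.path(out_dir, "green_corrected.tif")
      write_stack_tiff(green, paths["green_corrected"])
      paths["red_averaged"] <- file.path(out_dir, "red_averaged.tif")
      write_stack_tiff(red_avg, paths["red_averaged"])
      paths["masks"] <- file.path(out_dir, "masks.tif")
      write_label_masks(masks, paths["masks"])
    }
    sum_json <- summary[setdiff(names(summary), "basal")]
    paths["summary"] <- file.path(out_dir, "summary.json")
    jsonlite::write_json(sum_json, paths["summary"], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    manifest$checksums <- as.list(tools::md5sum(unname(paths)))
    names(manifest$checksums) <- names(paths)
    manifest$paths <- as.list(paths)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }

  list(tracks = complete, masks = masks, traces = traces,
       baselines = det$baselines, events = det$events, summary = summary,
       bleach_fits = fits, background = background, truth = truth,
       manifest = manifest)
}
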