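#' Configuration for the synthetic movie generator
#'
#' Defines the imaging experiment the simulator emulates: prohemocytes
#' carrying a nuclear red marker plus either a calcium biosensor (signal
#' mode) or an inert green fluorophore (control mode, `control_mode = TRUE`),
#' recorded as a two-channel time lapse.  Defaults describe a 15-minute
#' recording at 5 s per frame.
#'
#' Per-cell expression is log-normal: a shared per-cell driver activity with
#' log-sd `expression_log_sd` scales both channels, with small independent
#' per-channel jitter (`channel_log_jitter_sd`), emulating heterogeneous
#' Gal4-driven expression of both transgenes.  Calcium transients are boxcar
#' elevations of the green cellular signal by a per-event relative amplitude;
#' starts are uniform over the movie and durations geometric over frames.
#' Both channels decay with a global exponential photobleaching envelope, and
#' frames carry a constant additive background plus Gaussian pixel noise.
#'
#' @param n_cells Number of cells to place.
#' @param frames Number of frames (default 180).
#' @param frame_interval_s Seconds between frames (default 5).
#' @param image_size `c(H, W)` in pixels.
#' @param nucleus_radius_px Nucleus blob radius in pixels.  Blobs are
#'   rendered as isotropic Gaussians with sd `nucleus_radius_px / sqrt(2)`
#'   (so a matched-scale blob detector peaks at this radius), truncated at
#'   3 radii.
#' @param drift_step_px Per-frame scale of the per-cell Gaussian random-walk
#'   drift; walks reflect at the image margins.
#' @param expression_log_mean,expression_log_sd Mean and sd of the natural
#'   log of the shared per-cell expression level (intensity units at the
#'   blob peak).
#' @param channel_log_jitter_sd Log-sd of the independent per-channel
#'   multiplicative jitter around the shared level.
#' @param event_rate_per_cell_per_movie Mean number of true events per cell
#'   over the whole movie (Poisson); ignored in control mode.
#' @param event_duration Named list describing the event duration
#'   distribution; currently `list(name = "geometric", p = <per-frame stop
#'   probability>)`, giving durations of `1 + rgeom(p)` frames.
#' @param event_rel_amplitude Median relative amplitude (dF/F) of events.
#' @param event_amplitude_log_sd Log-sd of the per-event amplitude spread
#'   around `event_rel_amplitude`.
#' @param bleach_tau_s Photobleaching time constant(s) in seconds; a scalar
#'   or named vector `c(red = , green = )`.  `Inf` disables bleaching.
#' @param background_level Constant additive background intensity (bleaches
#'   with the same envelope as the cellular signal).
#' @param noise_sd Sd of additive zero-mean Gaussian pixel noise.
#' @param control_mode If `TRUE`, the green fluorophore is inert: no true
#'   events are generated.
#' @param seed Integer seed; identical config and seed give bit-identical
#'   movies.
#' @return A validated object of class `sim_config`.
#' @seealso [simulate_movie()], [simulate_background_movie()]
#' @export
sim_config <- function(n_cells = 30L,
                       frames = 180L,
                       frame_interval_s = 5,
                       image_size = c(160L, 160L),
                       nucleus_radius_px = 5,
                       drift_step_px = 0.15,
                       expression_log_mean = 6.5,
                       expression_log_sd = 1.7,
                       channel_log_jitter_sd = 0.2,
                       event_rate_per_cell_per_movie = 3.3,
                       event_duration = list(name = "geometric", p = 0.3),
                       event_rel_amplitude = 1,
                       event_amplitude_log_sd = 0.5,
                       bleach_tau_s = c(red = 900, green = 900),
                       background_level = 100,
                       noise_sd = 2,
                       control_mode = FALSE,
                       seed = 1L) {
  cfg <- list(n_cells = as.integer(n_cells),
              frames = as.integer(frames),
              frame_interval_s = as.numeric(frame_interval_s),
              image_size = as.integer(image_size),
              nucleus_radius_px = as.numeric(nucleus_radius_px),
              drift_step_px = as.numeric(drift_step_px),
              expression_log_mean = as.numeric(expression_log_mean),
              expression_log_sd = as.numeric(expression_log_sd),
              channel_log_jitter_sd = as.numeric(channel_log_jitter_sd),
              event_rate_per_cell_per_movie = as.numeric(event_rate_per_cell_per_movie),
              event_duration = event_duration,
              event_rel_amplitude = as.numeric(event_rel_amplitude),
              event_amplitude_log_sd = as.numeric(event_amplitude_log_sd),
              bleach_tau_s = .norm_tau(bleach_tau_s),
              background_level = as.numeric(background_level),
              noise_sd = as.numeric(noise_sd),
              control_mode = isTRUE(control_mode),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

.norm_tau <- function(tau) {
  if (length(tau) == 1L) tau <- c(red = unname(tau), green = unname(tau))
  if (is.null(names(tau)) && length(tau) == 2L) names(tau) <- c("red", "green")
  if (!all(c("red", "green") %in% names(tau))) {
    stop("'bleach_tau_s' must be a scalar or named c(red=, green=)", call. = FALSE)
  }
  as.numeric(tau[c("red", "green")]) -> v
  names(v) <- c("red", "green")
  v
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_cells <= 0L) stop("n_cells must be > 0", call. = FALSE)
  if (cfg$frames <= 0L) stop("frames must be > 0", call. = FALSE)
  if (cfg$frame_interval_s <= 0) stop("frame_interval_s must be > 0", call. = FALSE)
  if (length(cfg$image_size) != 2L || any(cfg$image_size <= 0L)) {
    stop("image_size must be c(H, W) with positive entries", call. = FALSE)
  }
  if (cfg$nucleus_radius_px <= 0) stop("nucleus_radius_px must be > 0", call. = FALSE)
  if (cfg$drift_step_px < 0) stop("drift_step_px must be >= 0", call. = FALSE)
  if (cfg$expression_log_sd < 0) stop("expression_log_sd must be >= 0", call. = FALSE)
  if (cfg$event_rate_per_cell_per_movie < 0) {
    stop("event_rate_per_cell_per_movie must be >= 0", call. = FALSE)
  }
  if (!identical(cfg$event_duration$name, "geometric")) {
    stop("only the 'geometric' event duration distribution is implemented",
         call. = FALSE)
  }
  p <- cfg$event_duration$p
  if (is.null(p) || p <= 0 || p > 1) {
    stop("event_duration$p must be in (0, 1]", call. = FALSE)
  }
  if (any(cfg$bleach_tau_s <= 0)) stop("bleach_tau_s must be > 0", call. = FALSE)
  if (cfg$background_level < 0) stop("background_level must be >= 0", call. = FALSE)
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  invisible(cfg)
}

## cell placement: rejection sampling with a minimum center separation
place_cells <- function(n, H, W, margin, min_dist, max_tries = 2000L) {
  lo_r <- margin; hi_r <- (H - 1) - margin
  lo_c <- margin; hi_c <- (W - 1) - margin
  if (hi_r <= lo_r || hi_c <= lo_c) {
    stop("image too small for the requested nucleus size", call. = FALSE)
  }
  rows <- numeric(n); cols <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (k in seq_len(max_tries)) {
      r <- stats::runif(1, lo_r, hi_r)
      c <- stats::runif(1, lo_c, hi_c)
      if (i == 1L ||
          min((rows[seq_len(i - 1L)] - r)^2 + (cols[seq_len(i - 1L)] - c)^2) >=
            min_dist^2) {
        rows[i] <- r; cols[i] <- c; placed <- TRUE; break
      }
    }
    if (!placed) {
      stop(sprintf(paste0("could not place %d non-overlapping nuclei of radius ",
                          "%.1f px in a %d x %d image"), n, min_dist / 2, H, W),
           call. = FALSE)
    }
  }
  cbind(row = rows, col = cols)
}

## reflecting Gaussian random walk, one row per cell, one column per frame
drift_walk <- function(start, n_frames, step, lo, hi) {
  n <- length(start)
  pos <- matrix(0, n, n_frames)
  pos[, 1L] <- start
  if (n_frames > 1L) {
    steps <- matrix(stats::rnorm(n * (n_frames - 1L), 0, step), n)
    for (t in 2L:n_frames) {
      p <- pos[, t - 1L] + steps[, t - 1L]
      # reflect at the margins
      p <- ifelse(p < lo, 2 * lo - p, p)
      p <- ifelse(p > hi, 2 * hi - p, p)
      pos[, t] <- pmin(pmax(p, lo), hi)
    }
  }
  pos
}

## per-cell non-overlapping boxcar events
draw_events <- function(n_cells, n_frames, rate, dur_p, amp_median, amp_log_sd) {
  out <- list()
  for (i in seq_len(n_cells)) {
    k <- stats::rpois(1L, rate)
    if (k == 0L) next
    taken <- logical(n_frames)
    for (e in seq_len(k)) {
      for (try in 1:100) {
        start <- sample.int(n_frames, 1L) - 1L        # 0-based
        dur <- 1L + stats::rgeom(1L, dur_p)
        end <- min(start + dur - 1L, n_frames - 1L)
        span <- (start:end) + 1L
        # reserve one flanking frame so distinct events return to baseline
        guard <- (max(start - 1L, 0L):min(end + 1L, n_frames - 1L)) + 1L
        if (!any(taken[guard])) {
          taken[guard] <- TRUE
          amp <- amp_median * exp(stats::rnorm(1L, 0, amp_log_sd))
          out[[length(out) + 1L]] <- data.frame(cell_id = i,
                                                start_frame = start,
                                                end_frame = end,
                                                amplitude = amp)
          break
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(cell_id = integer(), start_frame = integer(),
                      end_frame = integer(), amplitude = numeric()))
  }
  ev <- do.call(rbind, out)
  ev[order(ev$cell_id, ev$start_frame), , drop = FALSE]
}

## add a truncated Gaussian blob to `frame` in place-ish (returns the frame)
add_blob <- function(frame, r0, c0, amp, sd_px, half) {
  H <- nrow(frame); W <- ncol(frame)
  ir <- max(0L, floor(r0 - half)):min(H - 1L, ceiling(r0 + half))
  ic <- max(0L, floor(c0 - half)):min(W - 1L, ceiling(c0 + half))
  dr2 <- (ir - r0)^2
  dc2 <- (ic - c0)^2
  patch <- amp * exp(-outer(dr2, dc2, "+") / (2 * sd_px^2))
  frame[ir + 1L, ic + 1L] <- frame[ir + 1L, ic + 1L] + patch
  frame
}

.simulate_core <- function(config, green_cellular = TRUE) {
  validate_sim_config(config)
  set.seed(config$seed)
  H <- config$image_size[1L]; W <- config$image_size[2L]
  Tn <- config$frames
  r <- config$nucleus_radius_px
  sd_red <- r / sqrt(2)
  sd_green <- 1.5 * sd_red
  half_red <- 3 * r                 # truncate the nucleus blob at 3 radii
  half_green <- 3 * 1.5 * r
  margin <- ceiling(half_green)

  # centers separated by a cell diameter (cytoplasm ~1.5 nuclear radii), so
  # nuclei are non-overlapping and green footprints only touch at the edges
  centers <- place_cells(config$n_cells, H, W, margin, min_dist = 3 * r)
  shared <- exp(stats::rnorm(config$n_cells, config$expression_log_mean,
                             config$expression_log_sd))
  expr_red <- shared * exp(stats::rnorm(config$n_cells, 0,
                                        config$channel_log_jitter_sd))
  expr_green <- shared * exp(stats::rnorm(config$n_cells, 0,
                                          config$channel_log_jitter_sd))

  rows <- drift_walk(centers[, "row"], Tn, config$drift_step_px,
                     margin, (H - 1) - margin)
  cols <- drift_walk(centers[, "col"], Tn, config$drift_step_px,
                     margin, (W - 1) - margin)

  if (config$control_mode || !green_cellular) {
    events <- data.frame(cell_id = integer(), start_frame = integer(),
                         end_frame = integer(), amplitude = numeric())
  } else {
    events <- draw_events(config$n_cells, Tn,
                          config$event_rate_per_cell_per_movie,
                          config$event_duration$p,
                          config$event_rel_amplitude,
                          config$event_amplitude_log_sd)
  }

  # per-cell per-frame green multiplier: expression * (1 + amplitude in event)
  gmult <- matrix(rep(expr_green, Tn), config$n_cells, Tn)
  if (nrow(events) > 0L) {
    for (e in seq_len(nrow(events))) {
      fr <- (events$start_frame[e]:events$end_frame[e]) + 1L
      gmult[events$cell_id[e], fr] <-
        expr_green[events$cell_id[e]] * (1 + events$amplitude[e])
    }
  }

  tt <- (seq_len(Tn) - 1L) * config$frame_interval_s
  bl_red <- exp(-tt / config$bleach_tau_s[["red"]])
  bl_green <- exp(-tt / config$bleach_tau_s[["green"]])

  red <- array(0, c(H, W, Tn))
  green <- array(0, c(H, W, Tn))
  for (t in seq_len(Tn)) {
    fr_red <- matrix(0, H, W)
    fr_green <- matrix(0, H, W)
    for (i in seq_len(config$n_cells)) {
      fr_red <- add_blob(fr_red, rows[i, t], cols[i, t], expr_red[i],
                         sd_red, half_red)
      if (green_cellular) {
        fr_green <- add_blob(fr_green, rows[i, t], cols[i, t], gmult[i, t],
                             sd_green, half_green)
      }
    }
    fr_red <- (fr_red + config$background_level) * bl_red[t]
    fr_green <- (fr_green + config$background_level) * bl_green[t]
    if (config$noise_sd > 0) {
      fr_red <- fr_red + stats::rnorm(H * W, 0, config$noise_sd)
      fr_green <- fr_green + stats::rnorm(H * W, 0, config$noise_sd)
    }
    red[, , t] <- pmin(pmax(fr_red, 0), 65535)
    green[, , t] <- pmin(pmax(fr_green, 0), 65535)
  }

  cells <- data.frame(
    id = rep(seq_len(config$n_cells), each = Tn),
    frame = rep(0:(Tn - 1L), times = config$n_cells),
    row = as.vector(t(rows)),
    col = as.vector(t(cols)),
    expression = rep(expr_green, each = Tn),
    expression_red = rep(expr_red, each = Tn))

  truth <- structure(list(cells = cells, events = events,
                          n_cells = config$n_cells, frames = Tn),
                     class = "ground_truth")
  list(movie = two_channel_movie(red, green, config$frame_interval_s),
       truth = truth)
}

#' Simulate a ground-truthed two-channel calcium imaging movie
#'
#' Renders a synthetic recording of nuclear-marker-labeled cells expressing
#' either a calcium biosensor (signal mode) or an inert fluorophore
#' (`control_mode = TRUE`): drifting Gaussian-blob nuclei in the red channel,
#' a slightly larger cellular footprint in the green channel whose intensity
#' is elevated by a per-event relative amplitude during boxcar transients,
#' a global exponential photobleaching envelope applied to cellular signal
#' and background alike, plus additive Gaussian pixel noise.  Identical
#' config and seed give bit-identical output.
#'
#' @param config A [sim_config()].
#' @return A list with components `movie` (a [two_channel_movie()]) and
#'   `truth` (a `ground_truth` object holding the per-frame cell positions
#'   and expression levels, and the true event table; empty in control mode).
#' @examples
#' sim <- simulate_movie(sim_config(n_cells = 3, frames = 20, seed = 7))
#' sim$movie
#' nrow(sim$truth$events)
#' @export
simulate_movie <- function(config) {
  .simulate_core(config, green_cellular = TRUE)
}

#' Simulate a background-estimation movie
#'
#' Emulates the background-control genotype: cells carry the red nuclear
#' marker but no green fluorophore, so the green channel contains only
#' background, its photobleaching decay, and pixel noise.  Used to estimate
#' the green-channel background level, mirroring the use of a
#' nuclear-marker-only strain.
#'
#' @param config A [sim_config()].
#' @return A [two_channel_movie()].
#' @export
simulate_background_movie <- function(config) {
  .simulate_core(config, green_cellular = FALSE)$movie
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d cells, %d frames, %d true events\n",
              x$n_cells, x$frames, nrow(x$events)))
  invisible(x)
}

#' Write simulator ground truth as CSV tables
#'
#' @param truth A `ground_truth` object from [simulate_movie()].
#' @param cells_path,events_path Output CSV paths.
#' @return Invisibly, the written paths.
#' @export
write_ground_truth <- function(truth, cells_path, events_path) {
  stopifnot(inherits(truth, "ground_truth"))
  utils::write.csv(truth$cells, cells_path, row.names = FALSE)
  utils::write.csv(truth$events, events_path, row.names = FALSE)
  invisible(c(cells = cells_path, events = events_path))
}
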