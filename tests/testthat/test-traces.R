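static_masks <- function(H, W, centers, radius, n_blocks) {
  tracks <- data.frame(track_id = seq_len(nrow(centers)),
                       block = rep(1L, nrow(centers)),
                       row = centers[, 1], col = centers[, 2],
                       radius = radius, quality = 1)
  tracks <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
    tracks$block <- b; tracks
  }))
  render_label_masks(tracks, c(H, W))
}

test_that("a uniform stack yields constant traces", {
  masks <- static_masks(40, 40, rbind(c(15, 15), c(25, 28)), 4, 2)
  green <- array(10, c(40, 40, 10))
  tr <- extract_traces(green, masks, 5, 5)
  expect_identical(dim(tr$F), c(10L, 2L))
  expect_true(all(tr$F == 10))
  expect_equal(tr$time_s, (0:9) * 5)
})

test_that("traces follow the mask of each frame's block and drop remainder frames", {
  masks <- static_masks(30, 30, cbind(15, 15), 4, 2)
  # block 2 mask moved: rebuild manually with a different center
  tracks2 <- data.frame(track_id = 1L, block = 1:2, row = c(15, 15),
                        col = c(15, 22), radius = 4, quality = 1)
  masks <- render_label_masks(tracks2, c(30, 30))
  green <- array(0, c(30, 30, 12))            # 12 raw frames; 2 full blocks
  green[, 1:20, ] <- 3                        # left region bright
  tr <- extract_traces(green, masks, 5, 5)
  expect_identical(nrow(tr$F), 10L)           # remainder dropped
  expect_true(all(tr$F[1:5, 1] == 3))         # block-1 disk fully in left part
  expect_true(all(tr$F[6:10, 1] < 3))         # block-2 disk straddles the edge
  expect_true(all(tr$F[6:10, 1] > 0))
})

test_that("single-cell noiseless movie gives a boxcar-elevated trace on event frames", {
  cfg <- sim_config(n_cells = 1, frames = 30, image_size = c(64, 64),
                    noise_sd = 0, drift_step_px = 0, bleach_tau_s = Inf,
                    expression_log_sd = 0, channel_log_jitter_sd = 0,
                    event_rel_amplitude = 1, event_amplitude_log_sd = 0,
                    event_rate_per_cell_per_movie = 1, seed = 5)
  sim <- simulate_movie(cfg)
  ev <- sim$truth$events
  expect_gte(nrow(ev), 1L)
  tt <- truth_to_tracks(sim$truth, 5, cfg$nucleus_radius_px)
  masks <- render_label_masks(tt, c(64, 64))
  tr <- extract_traces(sim$movie$green, masks, 5, 5)
  tr <- subtract_background(tr, cfg$background_level)
  ind <- event_frame_labels(nrow(tr$F), ev)
  f_out <- tr$F[!ind, 1]
  expect_lt(diff(range(f_out)) / mean(f_out), 1e-6)
  for (t in which(ind)) {
    expect_equal(tr$F[t, 1] / mean(f_out), 2, tolerance = 0.001)
  }
})

test_that("recovered relative amplitude matches the simulated amplitude", {
  cfg <- sim_config(n_cells = 4, frames = 60, image_size = c(112, 112),
                    noise_sd = 0, drift_step_px = 0, bleach_tau_s = Inf,
                    event_rel_amplitude = 0.9, event_amplitude_log_sd = 0,
                    seed = 23)
  sim <- simulate_movie(cfg)
  tt <- truth_to_tracks(sim$truth, 5, cfg$nucleus_radius_px)
  masks <- render_label_masks(tt, c(112, 112))
  tr <- subtract_background(extract_traces(sim$movie$green, masks, 5, 5),
                            cfg$background_level)
  for (k in seq_len(nrow(sim$truth$events))) {
    ev <- sim$truth$events[k, ]
    if (ev$end_frame >= nrow(tr$F)) next
    j <- match(ev$cell_id, tr$cell_ids)
    ind <- event_frame_labels(nrow(tr$F),
                              sim$truth$events[sim$truth$events$cell_id ==
                                                 ev$cell_id, ])
    basal <- mean(tr$F[!ind, j])
    peak <- mean(tr$F[(ev$start_frame:ev$end_frame) + 1L, j])
    expect_equal((peak - basal) / basal, ev$amplitude, tolerance = 0.05)
  }
})

test_that("background estimation recovers level and bleach decay", {
  cfg <- sim_config(n_cells = 3, frames = 20, image_size = c(96, 96),
                    noise_sd = 0, bleach_tau_s = Inf,
                    background_level = 7, seed = 2)
  bg <- estimate_background(simulate_background_movie(cfg)$green)
  expect_equal(bg$per_frame, rep(7, 20), tolerance = 1e-9)
  expect_equal(bg$mean, 7, tolerance = 1e-9)

  cfg2 <- sim_config(n_cells = 3, frames = 100, image_size = c(96, 96),
                     bleach_tau_s = 300, seed = 2)
  bgm <- simulate_background_movie(cfg2)$green
  bg2 <- estimate_background(bgm)
  fit <- fit_bleach(bgm, 5, "green")
  expect_equal(fit$tau_s, 300, tolerance = 0.1)
  expect_error(estimate_background(array(0, c(2, 2, 0))), "non-empty")
})

test_that("background subtraction floors at epsilon and flags affected cells", {
  masks <- static_masks(30, 30, cbind(15, 15), 4, 1)
  green <- array(15, c(30, 30, 5))
  tr <- extract_traces(green, masks, 5, 5)
  out <- subtract_background(tr, 5)
  expect_true(all(out$F == 10))
  expect_true(out$background_corrected)
  expect_false(any(out$floored))

  ident <- subtract_background(tr, 0)
  expect_equal(ident$F, tr$F)

  floored <- subtract_background(tr, 15)
  expect_true(all(floored$F > 0))
  expect_true(all(floored$floored))

  expect_error(subtract_background(tr, c(1, 2)), "length")
})

test_that("trace errors against truth-footprint means are centred on zero", {
  cfg <- sim_config(n_cells = 6, frames = 40, image_size = c(112, 112),
                    drift_step_px = 0, control_mode = TRUE,
                    bleach_tau_s = Inf, seed = 31)
  sim <- simulate_movie(cfg)
  tt <- truth_to_tracks(sim$truth, 5, cfg$nucleus_radius_px)
  masks <- render_label_masks(tt, c(112, 112))
  tr <- extract_traces(sim$movie$green, masks, 5, 5)
  # noiseless reference from a matched noise-free simulation
  cfg0 <- cfg; cfg0$noise_sd <- 0
  sim0 <- simulate_movie(cfg0)
  tr0 <- extract_traces(sim0$movie$green, masks, 5, 5)
  err <- tr$F - tr0$F
  n_pos <- sum(err > 0)
  n <- length(err)
  # sign test: positive-error fraction within binomial noise of 1/2
  expect_lt(abs(n_pos - n / 2), 3 * sqrt(n / 4))
})
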