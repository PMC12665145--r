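test_that("control mode produces no true events and signal mode does", {
  cfg <- sim_config(n_cells = 5, frames = 40, image_size = c(96, 96),
                    control_mode = TRUE, seed = 2)
  sim <- simulate_movie(cfg)
  expect_identical(nrow(sim$truth$events), 0L)

  cfg$control_mode <- FALSE
  sim2 <- simulate_movie(cfg)
  expect_gt(nrow(sim2$truth$events), 0L)
  ev <- sim2$truth$events
  expect_true(all(ev$start_frame >= 0 & ev$end_frame <= cfg$frames - 1))
  expect_true(all(ev$start_frame <= ev$end_frame))
  # events of one cell are disjoint
  for (cid in unique(ev$cell_id)) {
    e <- ev[ev$cell_id == cid, , drop = FALSE]
    e <- e[order(e$start_frame), , drop = FALSE]
    if (nrow(e) > 1L) {
      expect_true(all(e$start_frame[-1L] > e$end_frame[-nrow(e)]))
    }
  }
})

test_that("identical config and seed give bit-identical movies", {
  cfg <- sim_config(n_cells = 4, frames = 25, image_size = c(80, 80), seed = 9)
  a <- simulate_movie(cfg)
  b <- simulate_movie(cfg)
  expect_identical(a$movie$red, b$movie$red)
  expect_identical(a$movie$green, b$movie$green)
  expect_identical(a$truth$events, b$truth$events)
})

test_that("noiseless static single-cell render elevates the footprint mean by the event amplitude", {
  cfg <- sim_config(n_cells = 1, frames = 30, image_size = c(64, 64),
                    noise_sd = 0, drift_step_px = 0,
                    bleach_tau_s = Inf, expression_log_sd = 0,
                    channel_log_jitter_sd = 0, event_amplitude_log_sd = 0,
                    event_rel_amplitude = 0.8,
                    event_rate_per_cell_per_movie = 1, seed = 5)
  sim <- simulate_movie(cfg)
  expect_gte(nrow(sim$truth$events), 1L)
  ind <- event_frame_labels(cfg$frames, sim$truth$events)
  expect_true(any(!ind))
  out_fr <- which(!ind)[1L]
  cell_px <- which(sim$movie$green[, , out_fr] - cfg$background_level > 1e-3)
  m_out <- mean(sim$movie$green[, , out_fr][cell_px]) - cfg$background_level
  for (t in which(ind)) {
    m_in <- mean(sim$movie$green[, , t][cell_px]) - cfg$background_level
    expect_equal(m_in / m_out, 1 + 0.8, tolerance = 1e-8)
  }
  # and the red channel is unaffected by the event
  expect_equal(sim$movie$red[, , which(ind)[1L]], sim$movie$red[, , out_fr],
               tolerance = 1e-12)
})

test_that("background movie renders background only in green", {
  cfg <- sim_config(n_cells = 4, frames = 12, image_size = c(80, 80),
                    noise_sd = 0, bleach_tau_s = Inf, seed = 3)
  bg <- simulate_background_movie(cfg)
  expect_true(all(abs(bg$green - cfg$background_level) < 1e-9))
  expect_gt(max(bg$red), cfg$background_level)  # nuclei still rendered

  sig <- simulate_movie(cfg)
  expect_lt(mean(bg$green), mean(sig$movie$green))
})

test_that("pixel intensities stay within the unsigned 16-bit range", {
  cfg <- sim_config(n_cells = 6, frames = 10, image_size = c(96, 96),
                    expression_log_mean = 11, expression_log_sd = 1,
                    noise_sd = 50, seed = 4)
  sim <- simulate_movie(cfg)
  for (ch in c("red", "green")) {
    expect_gte(min(sim$movie[[ch]]), 0)
    expect_lte(max(sim$movie[[ch]]), 65535)
  }
})

test_that("per-frame mean green is stationary without bleaching or events", {
  cfg <- sim_config(n_cells = 8, frames = 120, image_size = c(128, 128),
                    bleach_tau_s = Inf, control_mode = TRUE, seed = 6)
  sim <- simulate_movie(cfg)
  means <- apply(sim$movie$green, 3, mean)
  tt <- seq_along(means)
  fit <- summary(lm(means ~ tt))$coefficients
  expect_lt(abs(fit["tt", "Estimate"]), 3 * fit["tt", "Std. Error"])
})

test_that("log expression spread across many cells matches the config", {
  cfg <- sim_config(n_cells = 260, frames = 2, image_size = c(480, 480),
                    seed = 8)
  sim <- simulate_movie(cfg)
  expr <- sim$truth$cells$expression[!duplicated(sim$truth$cells$id)]
  target <- sqrt(cfg$expression_log_sd^2 + cfg$channel_log_jitter_sd^2)
  expect_equal(sd(log(expr)), target, tolerance = 0.1)
})

test_that("doubling the bleach rate halves the 1/e crossing frame", {
  base <- sim_config(n_cells = 3, frames = 160, image_size = c(80, 80),
                     noise_sd = 0, drift_step_px = 0,
                     control_mode = TRUE, seed = 7, bleach_tau_s = 400)
  fast <- base
  fast$bleach_tau_s <- c(red = 200, green = 200)
  crossing <- function(cfg) {
    mv <- simulate_movie(cfg)$movie
    means <- apply(mv$green, 3, mean)
    which(means <= means[1L] / exp(1))[1L]
  }
  c_slow <- crossing(base)
  c_fast <- crossing(fast)
  # exact exponential: first frame with (t-1)*dt >= tau is t = tau/dt + 1
  expect_equal(c_slow, 400 / 5 + 1)
  expect_equal((c_fast - 1) * 2, c_slow - 1)
})

test_that("infeasible placement raises a placement error", {
  expect_error(simulate_movie(sim_config(n_cells = 200, frames = 2,
                                         image_size = c(64, 64), seed = 1)),
               "could not place")
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_cells = 0), "n_cells")
  expect_error(sim_config(frames = -5), "frames")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(event_duration = list(name = "geometric", p = 0)),
               "event_duration")
})
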