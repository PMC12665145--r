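test_that("a single noiseless Gaussian blob is localized within 1 px", {
  img <- blob_image(100, 100, cbind(50, 50), 100, sd_px = 4)
  det <- detect_nuclei(img, radius_px = 4 * sqrt(2), quality_threshold = 10)
  expect_identical(nrow(det), 1L)
  expect_lt(abs(det$row - 50), 1)
  expect_lt(abs(det$col - 50), 1)
  # matched-scale LoG response is about half the blob amplitude
  expect_equal(det$quality, 50, tolerance = 0.15)
})

test_that("a blank frame yields an empty detection list", {
  expect_identical(nrow(detect_nuclei(matrix(0, 50, 50), 5, 1)), 0L)
  expect_identical(nrow(detect_nuclei(matrix(7, 50, 50), 5, 1)), 0L)
})

test_that("well-separated blobs are each detected and localized", {
  sd_px <- 4
  seps <- c(6, 8, 10) * sd_px
  for (sep in seps) {
    centers <- rbind(c(40, 40), c(40, 40 + sep))
    img <- blob_image(100, 160, centers, c(100, 80), sd_px)
    det <- detect_nuclei(img, radius_px = sd_px * sqrt(2),
                         quality_threshold = 10)
    expect_identical(nrow(det), 2L)
    for (k in 1:2) {
      d <- sqrt((det$row - centers[k, 1])^2 + (det$col - centers[k, 2])^2)
      expect_lt(min(d), 1)
    }
  }
})

test_that("constant offsets do not change detections", {
  img <- blob_image(80, 80, cbind(40, 40), 60, sd_px = 3.5)
  d0 <- detect_nuclei(img, 5, 5)
  d1 <- detect_nuclei(img + 500, 5, 5)
  expect_equal(d0, d1, tolerance = 1e-10)
})

test_that("disk IoU matches the Monte-Carlo point-sampling oracle", {
  cases <- rbind(c(0.0, 1, 1), c(0.5, 1, 1), c(1.0, 1, 1), c(1.7, 1, 1),
                 c(0.5, 1, 2), c(2.0, 2, 1), c(5.0, 2, 2))
  for (k in seq_len(nrow(cases))) {
    d <- cases[k, 1]; r1 <- cases[k, 2]; r2 <- cases[k, 3]
    expect_equal(disk_iou(d, r1, r2),
                 oracle_disk_iou_mc(d, r1, r2, n = 4e5, seed = 100 + k),
                 tolerance = 0.01)
  }
  expect_identical(disk_iou(2, 1, 1), 0)            # tangent -> disjoint
  expect_identical(disk_iou(0, 1, 1), 1)            # identical disks
  expect_equal(disk_iou(0, 1, 2), 0.25)             # contained
})

test_that("overlap linking follows the IoU threshold", {
  t0 <- data.frame(track_id = 1L, block = 1L, row = 20, col = 20,
                   radius = 5, quality = 10)
  # same place -> linked
  d_same <- data.frame(row = 20, col = 20, radius = 5, quality = 9)
  tr <- link_overlap(t0, d_same, block = 2L, min_iou = 0.1)
  expect_identical(sort(unique(tr$track_id)), 1L)
  expect_identical(nrow(tr), 2L)

  # displaced by 2 radii -> disjoint -> new track
  d_far <- data.frame(row = 20, col = 30, radius = 5, quality = 9)
  tr <- link_overlap(t0, d_far, block = 2L, min_iou = 0.1)
  expect_identical(sort(unique(tr$track_id)), c(1L, 2L))

  # displacement of 0.5 radius: linked iff min_iou <= analytic IoU
  iou_half <- disk_iou(2.5, 5, 5)
  d_half <- data.frame(row = 20, col = 22.5, radius = 5, quality = 9)
  tr_lo <- link_overlap(t0, d_half, block = 2L, min_iou = iou_half - 0.01)
  expect_identical(max(tr_lo$track_id), 1L)
  tr_hi <- link_overlap(t0, d_half, block = 2L, min_iou = iou_half + 0.01)
  expect_identical(max(tr_hi$track_id), 2L)
})

test_that("complete-track filtering keeps only full-span tracks", {
  tracks <- data.frame(track_id = c(rep(1L, 5), rep(2L, 4)),
                       block = c(1:5, c(1, 2, 4, 5)),
                       row = 10, col = 10, radius = 5, quality = 1)
  kept <- filter_complete_tracks(tracks, 5)
  expect_identical(unique(kept$track_id), 1L)
})

test_that("label masks partition pixels deterministically", {
  tracks <- data.frame(track_id = c(1L, 2L), block = 1L,
                       row = c(20, 20), col = c(20, 27),
                       radius = 5, quality = 1)
  masks <- render_label_masks(tracks, c(40, 40))
  m <- masks[[1]]
  expect_setequal(unique(as.vector(m)), c(0L, 1L, 2L))
  # union pixel count matches the analytic two-disk union area
  d <- 7; r <- 5
  lens <- 2 * r^2 * acos(d / (2 * r)) - (d / 2) * sqrt(4 * r^2 - d^2)
  expect_equal(sum(m > 0), 2 * pi * r^2 - lens, tolerance = 0.05)
  expect_true(all(m[, 1:17][m[, 1:17] > 0] == 1L))
  expect_true(all(m[, 30:40][m[, 30:40] > 0] == 2L))
  # midline pixels: ties go to the lower id
  mid <- m[, 24]
  expect_true(all(mid[mid > 0] == 1L))

  # single static track: identical mask each block, area ~ pi r^2
  tr1 <- data.frame(track_id = 1L, block = 1:3, row = 20, col = 20,
                    radius = 5, quality = 1)
  ms <- render_label_masks(tr1, c(40, 40))
  expect_identical(ms[[1]], ms[[2]])
  expect_equal(sum(ms[[1]] == 1L), pi * 25, tolerance = 0.05)
})

test_that("drift-free noiseless movies are tracked completely and precisely", {
  cfg <- sim_config(n_cells = 20, frames = 60, image_size = c(224, 224),
                    drift_step_px = 0, noise_sd = 0,
                    expression_log_sd = 0.4, seed = 17)
  sim <- simulate_movie(cfg)
  fit <- fit_bleach(sim$movie$red, 5, "red")
  avg <- block_average(correct_bleach(sim$movie$red, fit), 5)
  tracks <- track_nuclei(avg, cfg$nucleus_radius_px, 8, 0.1)
  complete <- filter_complete_tracks(tracks, attr(avg, "n_blocks"))
  expect_identical(length(unique(complete$track_id)), 20L)

  truth0 <- sim$truth$cells[sim$truth$cells$frame == 0, ]
  for (k in seq_len(nrow(complete))) {
    d <- sqrt((truth0$row - complete$row[k])^2 +
                (truth0$col - complete$col[k])^2)
    expect_lt(min(d), 1)
  }

  # masks rendered from truth positions recover >= 95% of each nucleus's
  # pixels (disk of the nucleus radius around the true center)
  tt <- truth_to_tracks(sim$truth, 5, cfg$nucleus_radius_px)
  oracle_masks <- render_label_masks(tt, dim(avg)[1:2])
  H <- dim(avg)[1]; W <- dim(avg)[2]
  rr <- matrix(0:(H - 1), H, W); cc <- matrix(0:(W - 1), H, W, byrow = TRUE)
  for (k in seq_len(nrow(truth0))) {
    nuc <- which((rr - truth0$row[k])^2 + (cc - truth0$col[k])^2 <=
                   cfg$nucleus_radius_px^2)
    lab <- which(oracle_masks[[1L]] == truth0$id[k])
    expect_gte(length(intersect(nuc, lab)) / length(nuc), 0.95)
  }

  # detected masks agree with truth-rendered masks up to sub-pixel
  # localization (< 1 px) of the disk centers
  det_masks <- render_label_masks(complete, dim(avg)[1:2])
  mp <- map_tracks_to_truth(complete, sim$truth)
  expect_identical(nrow(mp), 20L)
  for (b in c(1L, 6L, 12L)) {
    om <- oracle_masks[[b]]; dm <- det_masks[[b]]
    for (k in seq_len(nrow(mp))) {
      o_px <- which(om == mp$truth_id[k])
      d_px <- which(dm == mp$track_id[k])
      expect_gte(length(intersect(o_px, d_px)) / length(o_px), 0.9)
    }
  }
})

test_that("track ids are unique per block and detections belong to one track", {
  cfg <- sim_config(n_cells = 12, frames = 40, image_size = c(160, 160),
                    seed = 19)
  sim <- simulate_movie(cfg)
  fit <- fit_bleach(sim$movie$red, 5, "red")
  avg <- block_average(correct_bleach(sim$movie$red, fit), 5)
  tracks <- track_nuclei(avg, 5, 8, 0.1)
  # at most one detection per track per block
  expect_false(any(duplicated(tracks[, c("track_id", "block")])))
  # block indices of each track are consecutive
  for (id in unique(tracks$track_id)) {
    b <- sort(tracks$block[tracks$track_id == id])
    expect_identical(b, seq(min(b), max(b)))
  }
})
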