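# Independent oracles used to cross-check the package's implementations.
# Each deliberately takes a different computational route than the code it
# checks.

# exponential-decay fit by coarse grid search plus Nelder-Mead refinement
# (independent of the Levenberg-Marquardt path used by fit_bleach)
oracle_fit_exp <- function(means, tt) {
  sse <- function(p) {
    A <- p[1]; tau <- p[2]; C <- p[3]
    if (tau <= 0 || A < 0 || C < 0) return(Inf)
    sum((means - (A * exp(-tt / tau) + C))^2)
  }
  rng <- diff(range(means))
  grid <- expand.grid(A = rng * c(0.5, 1, 2),
                      tau = max(tt) * c(0.05, 0.1, 0.2, 0.5, 1, 2),
                      C = min(means) * c(0, 0.5, 1) + 1e-9)
  errs <- apply(grid, 1L, sse)
  best <- as.numeric(grid[which.min(errs), ])
  fit <- optim(best, sse, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
  list(A = fit$par[1], tau = fit$par[2], C = fit$par[3], sse = fit$value)
}

# run-length event caller by direct scanning (independent of the rle route)
oracle_runs <- function(marked, min_frames, merge_gap) {
  n <- length(marked)
  events <- list()
  i <- 1L
  while (i <= n) {
    if (!marked[i]) { i <- i + 1L; next }
    start <- i
    end <- i
    j <- i + 1L
    while (j <= n) {
      if (marked[j]) { end <- j; j <- j + 1L; next }
      # unmarked: look ahead for a marked frame within merge_gap
      k <- j
      while (k <= n && !marked[k] && (k - j + 1L) <= merge_gap) k <- k + 1L
      if (k <= n && marked[k] && (k - j) <= merge_gap) {
        end <- k; j <- k + 1L
      } else break
    }
    if ((end - start + 1L) >= min_frames) {
      events[[length(events) + 1L]] <- c(start - 1L, end - 1L)  # 0-based
    }
    i <- end + 1L
  }
  if (!length(events)) {
    return(data.frame(start_frame = integer(), end_frame = integer()))
  }
  m <- do.call(rbind, events)
  data.frame(start_frame = m[, 1L], end_frame = m[, 2L])
}

# Monte-Carlo disk IoU by uniform point sampling over the joint bounding box
oracle_disk_iou_mc <- function(d, r1, r2, n = 2e5, seed = 42) {
  set.seed(seed)
  lo <- min(-r1, d - r2); hi <- max(r1, d + r2)
  x <- runif(n, lo, hi); y <- runif(n, -max(r1, r2), max(r1, r2))
  in1 <- x^2 + y^2 <= r1^2
  in2 <- (x - d)^2 + y^2 <= r2^2
  if (!any(in1 | in2)) return(0)
  sum(in1 & in2) / sum(in1 | in2)
}

# analytic Gaussian blob image (0-based pixel-center coordinates)
blob_image <- function(H, W, centers, amps, sd_px, background = 0) {
  img <- matrix(background, H, W)
  rr <- 0:(H - 1); cc <- 0:(W - 1)
  for (k in seq_len(nrow(centers))) {
    img <- img + amps[k] *
      exp(-outer((rr - centers[k, 1])^2, (cc - centers[k, 2])^2, "+") /
            (2 * sd_px^2))
  }
  img
}
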