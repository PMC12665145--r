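#' Fit an exponential photobleaching model to a stack
#'
#' Fits `I(t) = A * exp(-t / tau) + C` by nonlinear least squares to the
#' per-frame spatial mean intensity of the stack (stack-level fitting, not
#' per-pixel).  A stack whose mean trace shows no appreciable decay yields a
#' flagged identity fit whose correction leaves the stack unchanged.
#'
#' @param stack Numeric `H x W x T` array, `T >= 4`.
#' @param frame_interval_s Seconds between frames.
#' @param channel Optional channel tag recorded in the fit (e.g. `"red"`).
#' @return An object of class `bleach_fit`: list with `A`, `tau_s`, `C`,
#'   `frame_interval_s`, `n_frames`, `channel`, `identity` flag, fitted
#'   per-frame `means` and `residuals`.
#' @examples
#' tt <- 0:49 * 5
#' st <- array(rep(100 * exp(-tt / 200) + 10, each = 4), c(2, 2, 50))
#' fit_bleach(st, 5)
#' @export
fit_bleach <- function(stack, frame_interval_s, channel = NA_character_) {
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  Tn <- dim(stack)[3L]
  if (Tn < 4L) stop("need at least 4 frames to fit bleaching", call. = FALSE)
  means <- apply(stack, 3L, mean)
  tt <- (seq_len(Tn) - 1L) * frame_interval_s

  new_fit <- function(A, tau, C, identity, fitted) {
    structure(list(A = A, tau_s = tau, C = C,
                   frame_interval_s = frame_interval_s, n_frames = Tn,
                   channel = channel, identity = identity,
                   means = means, fitted = fitted,
                   residuals = means - fitted,
                   rmse = sqrt(mean((means - fitted)^2))),
              class = "bleach_fit")
  }

  # degenerate: essentially flat trace -> identity correction
  rng <- diff(range(means))
  if (rng <= 1e-9 * max(abs(means), 1)) {
    return(new_fit(0, Inf, mean(means), TRUE, rep(mean(means), Tn)))
  }

  # Levenberg-Marquardt on (A, tau, C) from several starting points: the
  # model is near-collinear when the window is short relative to tau, so a
  # single start can stall in a flat region
  resid_fn <- function(p) means - (p[1L] * exp(-tt / p[2L]) + p[3L])
  starts <- expand.grid(C0 = c(max(min(means), 0), min(means) / 2, 0),
                        tau0 = tt[Tn] * c(0.5, 0.25, 1, 2))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    A0 <- max(means[1L] - starts$C0[s], rng)
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = c(A = A0, tau = max(starts$tau0[s], frame_interval_s),
                C = starts$C0[s]),
        lower = c(0, frame_interval_s * 1e-3, 0),
        fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(res) || !res$info %in% 1:4) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best)) {
    stop(sprintf(paste0("photobleaching fit did not converge from any start; ",
                        "mean trace range [%.3g, %.3g]"),
                 min(means), max(means)), call. = FALSE)
  }
  cf <- best$par
  if (!is.finite(cf[["tau"]]) || cf[["tau"]] <= 0) {
    stop("photobleaching fit returned non-positive tau", call. = FALSE)
  }
  # no meaningful decay captured -> identity
  if (cf[["A"]] <= 1e-9 * max(abs(means), 1)) {
    return(new_fit(0, Inf, mean(means), TRUE, rep(mean(means), Tn)))
  }
  new_fit(cf[["A"]], cf[["tau"]], cf[["C"]], FALSE,
          cf[["A"]] * exp(-tt / cf[["tau"]]) + cf[["C"]])
}

#' @export
print.bleach_fit <- function(x, ...) {
  if (x$identity) {
    cat("bleach_fit: identity (no appreciable decay), mean =",
        format(x$C), "\n")
  } else {
    cat(sprintf("bleach_fit%s: A = %.4g, tau = %.4g s, C = %.4g (rmse %.3g over %d frames)\n",
                if (is.na(x$channel)) "" else paste0(" [", x$channel, "]"),
                x$A, x$tau_s, x$C, x$rmse, x$n_frames))
  }
  invisible(x)
}

#' Correct a stack for photobleaching
#'
#' Multiplies frame `t` by `(A + C) / (A * exp(-t*dt/tau) + C)` so the
#' corrected per-frame mean is approximately constant at its `t = 0` value.
#' The ratio (multiplicative) form preserves relative dF/F excursions, which
#' the downstream event caller relies on.  Output is clipped at 0.
#'
#' @param stack Numeric `H x W x T` array from the same channel as `fit`.
#' @param fit A [fit_bleach()] result.
#' @return The corrected stack.
#' @export
correct_bleach <- function(stack, fit) {
  stopifnot(is.array(stack), length(dim(stack)) == 3L,
            inherits(fit, "bleach_fit"))
  Tn <- dim(stack)[3L]
  if (Tn != fit$n_frames) {
    stop(sprintf("stack has %d frames but the fit was made on %d", Tn,
                 fit$n_frames), call. = FALSE)
  }
  if (fit$identity) return(stack)
  tt <- (seq_len(Tn) - 1L) * fit$frame_interval_s
  fac <- (fit$A + fit$C) / (fit$A * exp(-tt / fit$tau_s) + fit$C)
  out <- stack
  for (t in seq_len(Tn)) out[, , t] <- pmax(stack[, , t] * fac[t], 0)
  out
}

#' Average non-overlapping blocks of consecutive frames
#'
#' Averages every `block` consecutive frames of a stack to improve
#' signal-to-noise ahead of nucleus detection.  Remainder frames beyond the
#' last full block are dropped; the returned object records, for every raw
#' frame, its block index (`NA` for dropped frames).
#'
#' @param stack Numeric `H x W x T` array with `T >= block`.
#' @param block Frames per block (default 5).
#' @return The averaged `H x W x floor(T/block)` array with attributes
#'   `block` (block size), `n_blocks`, and `frame_blocks` (integer vector of
#'   length `T`, 1-based block index per raw frame, `NA` when dropped).
#' @examples
#' st <- array(rep(1:5, each = 1), c(1, 1, 5))
#' block_average(st, 5)[1, 1, 1]  # 3
#' @export
block_average <- function(stack, block = 5L) {
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  block <- as.integer(block)
  if (block <= 0L) stop("'block' must be a positive integer", call. = FALSE)
  d <- dim(stack)
  Tn <- d[3L]
  if (Tn < block) stop("stack has fewer frames than one block", call. = FALSE)
  nb <- Tn %/% block
  used <- stack[, , seq_len(nb * block), drop = FALSE]
  dim(used) <- c(d[1L] * d[2L], block, nb)
  out <- array(0, c(d[1L], d[2L], nb))
  for (b in seq_len(nb)) {
    m <- used[, , b, drop = FALSE]
    dim(m) <- c(d[1L] * d[2L], block)
    out[, , b] <- matrix(rowMeans(m), d[1L], d[2L])
  }
  fb <- rep(NA_integer_, Tn)
  fb[seq_len(nb * block)] <- rep(seq_len(nb), each = block)
  attr(out, "block") <- block
  attr(out, "n_blocks") <- nb
  attr(out, "frame_blocks") <- fb
  out
}
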