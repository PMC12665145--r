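#' Estimate a trace baseline by iterative asymmetric polynomial fitting
#'
#' Fits a degree-`degree` polynomial to the trace, replaces samples lying
#' above the fit plus a noise margin by that clipped value, and refits until
#' the relative change in coefficients falls below `tol` or `max_iter` is
#' reached.  The margin is the standard deviation of the below-fit residuals
#' (an estimate of the noise floor); clipping only above it means transient
#' upward excursions are excluded from the fit while ordinary noise is not,
#' so the baseline settles on the trace's quiescent level instead of
#' ratcheting below it.  The returned baseline is floored at 1e-6 of the
#' trace maximum so baseline-relative ratios stay defined.
#'
#' @param F Numeric trace vector (background-corrected fluorescence).
#' @param degree Polynomial degree (default 3); must be `< length(F)`.
#' @param max_iter Maximum refit iterations (default 100).
#' @param tol Relative coefficient-change convergence tolerance (default
#'   1e-3).
#' @return An object of class `baseline`: list with `B` (fitted baseline per
#'   frame), `converged`, `n_iter`, `degree`, `max_iter`, `tol`.
#' @examples
#' x <- rep(100, 60); x[20:24] <- 160
#' b <- estimate_baseline(x)
#' range(b$B[-(20:24)])
#' @export
estimate_baseline <- function(F, degree = 3L, max_iter = 100L, tol = 1e-3) {
  stopifnot(is.numeric(F), length(F) >= 2L)
  degree <- as.integer(degree)
  if (degree < 0L || degree >= length(F)) {
    stop("'degree' must be in [0, length(F) - 1)", call. = FALSE)
  }
  n <- length(F)
  tt <- seq(0, 1, length.out = n)
  X <- cbind(1, if (degree > 0L) stats::poly(tt, degree) else NULL)
  y <- F
  coef_old <- NULL
  converged <- FALSE
  it <- 0L
  base <- rep(mean(F), n)
  for (it in seq_len(max_iter)) {
    fit <- stats::lm.fit(X, y)
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    base <- drop(X %*% cf)
    if (!is.null(coef_old)) {
      denom <- sqrt(sum(coef_old^2))
      if (denom == 0) denom <- .Machine$double.eps
      if (sqrt(sum((cf - coef_old)^2)) / denom < tol) {
        converged <- TRUE
        break
      }
    }
    coef_old <- cf
    # clip the *original* samples at fit + noise margin: cumulative clipping
    # without a margin ratchets the baseline below the quiescent level
    r <- F - base
    dev <- stats::sd(r[r <= 0])
    if (!is.finite(dev)) dev <- 0
    y <- pmin(F, base + dev)
  }
  eps <- 1e-6 * max(max(F), .Machine$double.eps)
  structure(list(B = pmax(base, eps), converged = converged, n_iter = it,
                 degree = degree, max_iter = max_iter, tol = tol),
            class = "baseline")
}

#' @export
print.baseline <- function(x, ...) {
  cat(sprintf("baseline: degree %d, %d iterations%s, range %.4g-%.4g\n",
              x$degree, x$n_iter,
              if (x$converged) "" else " (not converged)",
              min(x$B), max(x$B)))
  invisible(x)
}

#' Call signaling events as supra-baseline excursions
#'
#' Frames where `(F - B) / B` strictly exceeds `rel_threshold` are marked.
#' Maximal runs of marked frames separated by at most `merge_gap` unmarked
#' frames are merged (gap frames count toward the event duration), and
#' merged runs shorter than `min_frames` are discarded.  Durations are
#' reported in seconds as `(end - start + 1) * frame_interval_s`, so a
#' single-frame event at a 5 s interval has duration 5 s.
#'
#' @param F Numeric trace vector.
#' @param B Baseline vector of the same length (all entries positive), or a
#'   `baseline` object.
#' @param rel_threshold Relative excursion threshold (default 0.25).
#' @param min_frames Minimum merged run length in frames (default 1).
#' @param merge_gap Maximum unmarked gap, in frames, bridged when merging
#'   runs (default 0).
#' @param frame_interval_s Seconds between frames (default 5).
#' @param cell_id Cell identifier copied into the output (default `NA`).
#' @return Data frame with columns `cell_id`, `start_frame`, `end_frame`
#'   (0-based, inclusive), `duration_s`, `peak_rel_amplitude`.
#' @examples
#' x <- rep(100, 40); x[11:13] <- 140
#' detect_events(x, rep(100, 40))
#' @export
detect_events <- function(F, B, rel_threshold = 0.25, min_frames = 1L,
                          merge_gap = 0L, frame_interval_s = 5,
                          cell_id = NA_integer_) {
  if (inherits(B, "baseline")) B <- B$B
  stopifnot(is.numeric(F), is.numeric(B), length(F) == length(B))
  if (rel_threshold <= 0) stop("'rel_threshold' must be > 0", call. = FALSE)
  min_frames <- as.integer(min_frames)
  merge_gap <- as.integer(merge_gap)
  if (min_frames < 1L) stop("'min_frames' must be >= 1", call. = FALSE)
  if (merge_gap < 0L) stop("'merge_gap' must be >= 0", call. = FALSE)
  if (any(B <= 0)) {
    stop("internal invariant violated: baseline must be positive everywhere",
         call. = FALSE)
  }
  rel <- (F - B) / B
  marked <- rel > rel_threshold
  empty <- data.frame(cell_id = integer(), start_frame = integer(),
                      end_frame = integer(), duration_s = numeric(),
                      peak_rel_amplitude = numeric())
  if (!any(marked)) return(empty)

  r <- rle(marked)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge runs separated by <= merge_gap unmarked frames
  merged <- runs[1L, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (k in 2L:nrow(runs)) {
      gap <- runs$start[k] - merged$end[nrow(merged)] - 1L
      if (gap <= merge_gap) {
        merged$end[nrow(merged)] <- runs$end[k]
      } else {
        merged <- rbind(merged, runs[k, , drop = FALSE])
      }
    }
  }
  merged <- merged[(merged$end - merged$start + 1L) >= min_frames, ,
                   drop = FALSE]
  if (nrow(merged) == 0L) return(empty)
  data.frame(cell_id = rep(cell_id, nrow(merged)),
             start_frame = merged$start - 1L,
             end_frame = merged$end - 1L,
             duration_s = (merged$end - merged$start + 1L) * frame_interval_s,
             peak_rel_amplitude = vapply(seq_len(nrow(merged)), function(k) {
               max(rel[merged$start[k]:merged$end[k]])
             }, numeric(1)))
}

#' Call events for every trace in a trace set
#'
#' Estimates a baseline per cell with [estimate_baseline()] and calls
#' events with [detect_events()].
#'
#' @param traces A background-corrected `trace_set`.
#' @param degree,max_iter,tol Baseline parameters, see
#'   [estimate_baseline()].
#' @param rel_threshold,min_frames,merge_gap Detection parameters, see
#'   [detect_events()].
#' @return List with `events` (combined event table across cells) and
#'   `baselines` (numeric `T x n_cells` matrix).
#' @export
detect_events_all <- function(traces, degree = 3L, max_iter = 100L,
                              tol = 1e-3, rel_threshold = 0.25,
                              min_frames = 1L, merge_gap = 0L) {
  stopifnot(inherits(traces, "trace_set"))
  n <- ncol(traces$F)
  B <- matrix(NA_real_, nrow(traces$F), n)
  evs <- vector("list", n)
  for (j in seq_len(n)) {
    bl <- estimate_baseline(traces$F[, j], degree = degree,
                            max_iter = max_iter, tol = tol)
    B[, j] <- bl$B
    evs[[j]] <- detect_events(traces$F[, j], bl$B,
                              rel_threshold = rel_threshold,
                              min_frames = min_frames,
                              merge_gap = merge_gap,
                              frame_interval_s = traces$frame_interval_s,
                              cell_id = traces$cell_ids[j])
  }
  events <- do.call(rbind, evs)
  rownames(events) <- NULL
  list(events = events, baselines = B)
}

#' Per-frame event indicator
#'
#' @param trace_length Number of frames.
#' @param events Event table for one cell (disjoint intervals,
#'   `start_frame`/`end_frame` 0-based inclusive).
#' @return Logical vector of length `trace_length`, `TRUE` inside any event.
#' @export
event_frame_labels <- function(trace_length, events) {
  ind <- logical(trace_length)
  if (is.null(events) || nrow(events) == 0L) return(ind)
  for (k in seq_len(nrow(events))) {
    span <- (events$start_frame[k]:events$end_frame[k]) + 1L
    if (any(span < 1L | span > trace_length)) {
      stop("event interval outside the trace", call. = FALSE)
    }
    if (any(ind[span])) {
      stop("internal invariant violated: overlapping events", call. = FALSE)
    }
    ind[span] <- TRUE
  }
  ind
}
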