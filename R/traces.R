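#' Extract per-cell fluorescence traces from the green channel
#'
#' Applies the per-block label masks to every raw green frame: the trace
#' value of cell `i` at raw frame `t` is the mean green intensity over the
#' pixels labeled `i` in the mask of block `floor(t / block)`.  Traces are
#' sampled at raw-frame resolution so event durations are measurable at the
#' acquisition interval; frames beyond the last full block are dropped to
#' match the block-averaged tracking.
#'
#' @param green Bleach-corrected green-channel stack, `H x W x T`.
#' @param masks A `label_mask_sequence` from [render_label_masks()].
#' @param block Raw frames per block (default 5).
#' @param frame_interval_s Seconds between raw frames.
#' @return A `trace_set`: list with `F` (numeric `T_used x n_cells` matrix),
#'   `cell_ids`, `time_s`, `frame_interval_s`, and flags
#'   `background_corrected`, `floored`.
#' @export
extract_traces <- function(green, masks, block = 5L, frame_interval_s = 5) {
  stopifnot(is.array(green), length(dim(green)) == 3L,
            inherits(masks, "label_mask_sequence"))
  nb <- length(masks)
  if (nb == 0L || length(attr(masks, "label_ids")) == 0L) {
    stop("label mask sequence has no labels", call. = FALSE)
  }
  block <- as.integer(block)
  Tn <- dim(green)[3L]
  if (Tn < nb * block) {
    stop(sprintf("green stack has %d frames; masks cover %d blocks of %d",
                 Tn, nb, block), call. = FALSE)
  }
  ids <- attr(masks, "label_ids")
  n <- length(ids)
  T_used <- nb * block
  F <- matrix(NA_real_, T_used, n)
  for (b in seq_len(nb)) {
    m <- masks[[b]]
    pos <- which(m > 0L)
    grp <- match(m[pos], ids)
    if (anyNA(grp)) {
      stop("mask contains labels absent from label_ids", call. = FALSE)
    }
    counts <- tabulate(grp, nbins = n)
    if (any(counts == 0L)) {
      bad <- ids[which(counts == 0L)[1L]]
      stop(sprintf("label %d has no pixels in block %d", bad, b),
           call. = FALSE)
    }
    for (j in seq_len(block)) {
      t <- (b - 1L) * block + j
      v <- green[, , t][pos]
      sums <- rep(0, n)
      agg <- rowsum(v, grp)
      sums[as.integer(rownames(agg))] <- agg[, 1L]
      F[t, ] <- sums / counts
    }
  }
  structure(list(F = F, cell_ids = as.integer(ids),
                 time_s = (seq_len(T_used) - 1L) * frame_interval_s,
                 frame_interval_s = frame_interval_s,
                 background_corrected = FALSE,
                 floored = rep(FALSE, n)),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("trace_set: %d cells x %d frames at %g s%s\n",
              ncol(x$F), nrow(x$F), x$frame_interval_s,
              if (x$background_corrected) ", background-corrected" else ""))
  invisible(x)
}

#' Convert a trace set to a long data frame
#'
#' @param traces A `trace_set`.
#' @return Data frame with columns `cell_id`, `frame` (0-based), `time_s`,
#'   `F`.
#' @export
traces_to_df <- function(traces) {
  stopifnot(inherits(traces, "trace_set"))
  Tn <- nrow(traces$F); n <- ncol(traces$F)
  data.frame(cell_id = rep(traces$cell_ids, each = Tn),
             frame = rep(0:(Tn - 1L), times = n),
             time_s = rep(traces$time_s, times = n),
             F = as.vector(traces$F))
}

#' Estimate the green-channel background from a no-fluorophore movie
#'
#' The per-frame spatial mean of a green channel recorded from cells that
#' carry the red nuclear marker but no green fluorophore estimates stray
#' light plus autofluorescence.
#'
#' @param stack Green-channel stack of a background movie, `H x W x T`.
#' @return List with `per_frame` (numeric length `T`) and `mean` (scalar
#'   time average), of class `background_estimate`.
#' @export
estimate_background <- function(stack) {
  if (!is.array(stack) || length(dim(stack)) != 3L || dim(stack)[3L] == 0L) {
    stop("'stack' must be a non-empty H x W x T array", call. = FALSE)
  }
  pf <- apply(stack, 3L, mean)
  structure(list(per_frame = pf, mean = mean(pf)),
            class = "background_estimate")
}

#' @export
print.background_estimate <- function(x, ...) {
  cat(sprintf("background_estimate: %d frames, mean %.4g (range %.4g-%.4g)\n",
              length(x$per_frame), x$mean, min(x$per_frame),
              max(x$per_frame)))
  invisible(x)
}

#' Subtract background from traces
#'
#' Subtracts a scalar or per-frame background from every trace, flooring the
#' result at a small positive epsilon (1e-6 of each trace's maximum) so that
#' downstream baseline ratios stay defined.  Background is subtracted (not
#' divided out) because stray light and autofluorescence are additive.
#'
#' @param traces A `trace_set`.
#' @param background Scalar, numeric vector of length `T`, or a
#'   `background_estimate` (its `per_frame` vector is truncated to `T`).
#' @return The corrected `trace_set` with `background_corrected = TRUE`;
#'   cells whose trace hit the floor anywhere are flagged in `floored`.
#' @export
subtract_background <- function(traces, background) {
  stopifnot(inherits(traces, "trace_set"))
  Tn <- nrow(traces$F)
  if (inherits(background, "background_estimate")) {
    background <- background$per_frame
  }
  if (length(background) == 1L) background <- rep(background, Tn)
  if (length(background) < Tn) {
    stop(sprintf("background has length %d but traces have %d frames",
                 length(background), Tn), call. = FALSE)
  }
  background <- background[seq_len(Tn)]
  F <- traces$F - background
  eps <- 1e-6 * pmax(apply(traces$F, 2L, max), .Machine$double.eps)
  floored <- logical(ncol(F))
  for (j in seq_len(ncol(F))) {
    hit <- F[, j] < eps[j]
    floored[j] <- any(hit)
    F[hit, j] <- eps[j]
  }
  traces$F <- F
  traces$background_corrected <- TRUE
  traces$floored <- floored
  traces
}
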