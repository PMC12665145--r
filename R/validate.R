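#' Map track ids to simulator ground-truth cell ids
#'
#' Track ids are assigned in detection order and bear no relation to the
#' simulator's cell ids, so validation against ground truth needs a
#' positional correspondence.  Each complete track is matched to the truth
#' cell whose frame-0 position is nearest to the track's first-block center,
#' greedily by ascending distance, accepting matches closer than
#' `max_dist_px`.
#'
#' @param tracks A complete-track table ([filter_complete_tracks()]).
#' @param truth A `ground_truth` object.
#' @param max_dist_px Maximum accepted center distance (default: the
#'   track radius).
#' @return Data frame with columns `track_id`, `truth_id`, `dist_px`; one
#'   row per matched track.
#' @export
map_tracks_to_truth <- function(tracks, truth, max_dist_px = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (nrow(tracks) == 0L) {
    return(data.frame(track_id = integer(), truth_id = integer(),
                      dist_px = numeric()))
  }
  b1 <- min(tracks$block)
  tb <- tracks[tracks$block == b1, , drop = FALSE]
  if (is.null(max_dist_px)) max_dist_px <- max(tb$radius)
  t0 <- truth$cells[truth$cells$frame == 0L, , drop = FALSE]
  cand <- expand.grid(i = seq_len(nrow(tb)), j = seq_len(nrow(t0)))
  cand$dist <- sqrt((tb$row[cand$i] - t0$row[cand$j])^2 +
                      (tb$col[cand$i] - t0$col[cand$j])^2)
  cand <- cand[cand$dist <= max_dist_px, , drop = FALSE]
  cand <- cand[order(cand$dist, tb$track_id[cand$i]), , drop = FALSE]
  used_i <- logical(nrow(tb)); used_j <- logical(nrow(t0))
  out <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (used_i[i] || used_j[j]) next
    used_i[i] <- TRUE; used_j[j] <- TRUE
    out[[length(out) + 1L]] <- data.frame(track_id = tb$track_id[i],
                                          truth_id = t0$id[j],
                                          dist_px = cand$dist[k])
  }
  if (!length(out)) {
    return(data.frame(track_id = integer(), truth_id = integer(),
                      dist_px = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$track_id), , drop = FALSE]
}

#' Build a track table from simulator ground truth
#'
#' Converts the true per-frame cell positions into the track-table layout
#' produced by [track_nuclei()], averaging positions over each block.  Used
#' to render oracle label masks and to measure downstream stages free of
#' detection and tracking error.
#'
#' @param truth A `ground_truth` object.
#' @param block Raw frames per block (default 5).
#' @param radius_px Disk radius to assign to every detection.
#' @return A track table (`track_id`, `block`, `row`, `col`, `radius`,
#'   `quality`) with `track_id` equal to the truth cell id.
#' @export
truth_to_tracks <- function(truth, block = 5L, radius_px = 5) {
  stopifnot(inherits(truth, "ground_truth"))
  cells <- truth$cells
  nb <- truth$frames %/% block
  cells <- cells[cells$frame < nb * block, , drop = FALSE]
  b <- cells$frame %/% block + 1L
  agg <- stats::aggregate(cells[, c("row", "col")],
                          by = list(track_id = cells$id, block = b), mean)
  agg <- agg[order(agg$track_id, agg$block), , drop = FALSE]
  data.frame(track_id = agg$track_id, block = agg$block,
             row = agg$row, col = agg$col,
             radius = radius_px, quality = NA_real_)
}

#' Relabel detected events with ground-truth cell ids
#'
#' Rewrites the `cell_id` column of an event table from track ids to truth
#' ids using a [map_tracks_to_truth()] correspondence; events of unmapped
#' tracks are dropped.
#'
#' @param events Event table keyed by track id.
#' @param mapping Output of [map_tracks_to_truth()].
#' @return The relabeled event table.
#' @export
relabel_events <- function(events, mapping) {
  idx <- match(events$cell_id, mapping$track_id)
  out <- events[!is.na(idx), , drop = FALSE]
  out$cell_id <- mapping$truth_id[idx[!is.na(idx)]]
  rownames(out) <- NULL
  out
}
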