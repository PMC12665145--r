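## separable Gaussian smoothing and a 5-point Laplacian, replicate-padded.
## Convolution is done as a sum of edge-clamped shifts, which is fast for the
## short kernels used here and keeps the result free of border NAs.

shift_rows <- function(m, k) {
  H <- nrow(m)
  m[pmin(pmax(seq_len(H) + k, 1L), H), , drop = FALSE]
}

shift_cols <- function(m, k) {
  W <- ncol(m)
  m[, pmin(pmax(seq_len(W) + k, 1L), W), drop = FALSE]
}

gaussian_smooth <- function(m, sigma) {
  h <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-h:h, sd = sigma)
  k <- k / sum(k)
  out <- matrix(0, nrow(m), ncol(m))
  for (j in seq_along(k)) out <- out + k[j] * shift_rows(m, j - 1L - h)
  out2 <- matrix(0, nrow(m), ncol(m))
  for (j in seq_along(k)) out2 <- out2 + k[j] * shift_cols(out, j - 1L - h)
  out2
}

laplacian <- function(m) {
  shift_rows(m, 1L) + shift_rows(m, -1L) +
    shift_cols(m, 1L) + shift_cols(m, -1L) - 4 * m
}

#' Scale-normalized Laplacian-of-Gaussian blob response
#'
#' Bright isotropic blobs of radius `radius_px` (Gaussian sd
#' `radius_px/sqrt(2)`) produce positive local maxima in the returned
#' response, with peak value approximately half the blob's peak amplitude.
#'
#' @param frame Numeric `H x W` intensity image.
#' @param radius_px Expected blob radius in pixels; the detection scale is
#'   `sigma = radius_px / sqrt(2)`.
#' @return Numeric `H x W` response matrix.
#' @export
log_response <- function(frame, radius_px) {
  stopifnot(is.matrix(frame), radius_px > 0)
  sigma <- radius_px / sqrt(2)
  -sigma^2 * laplacian(gaussian_smooth(frame, sigma))
}

#' Detect nuclei in a single frame with a LoG blob detector
#'
#' Finds local maxima of the scale-normalized Laplacian-of-Gaussian response
#' at scale `sigma = radius_px / sqrt(2)` that exceed `quality_threshold`.
#' Maxima closer than `radius_px` to a stronger maximum are suppressed
#' (quality ties broken by smaller row, then smaller column).  Centers are
#' refined to sub-pixel precision by per-axis quadratic interpolation of the
#' response.  Coordinates are 0-based `(row, col)` with pixel centers at
#' integer positions.
#'
#' @param frame Numeric `H x W` intensity image (typically a
#'   bleach-corrected, block-averaged red-channel frame).
#' @param radius_px Expected nucleus radius in pixels.
#' @param quality_threshold Minimum LoG response at the maximum.
#' @return A data frame with columns `row`, `col`, `radius`, `quality`,
#'   one row per detection (zero rows for a blank frame).
#' @examples
#' fr <- matrix(0, 64, 64)
#' fr <- fr + 100 * exp(-(outer((0:63 - 30)^2, (0:63 - 40)^2, "+")) / (2 * 12.5))
#' detect_nuclei(fr, radius_px = 5, quality_threshold = 10)
#' @export
detect_nuclei <- function(frame, radius_px, quality_threshold) {
  stopifnot(is.matrix(frame))
  if (radius_px <= 0) stop("'radius_px' must be > 0", call. = FALSE)
  empty <- data.frame(row = numeric(), col = numeric(), radius = numeric(),
                      quality = numeric())
  H <- nrow(frame); W <- ncol(frame)
  if (H < 3L || W < 3L) return(empty)
  resp <- log_response(frame, radius_px)

  is_max <- resp > quality_threshold
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    is_max <- is_max & (resp >= shift_cols(shift_rows(resp, dr), dc))
  }
  is_max[c(1L, H), ] <- FALSE
  is_max[, c(1L, W)] <- FALSE
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)

  q <- resp[is_max]
  # sub-pixel refinement: 1-d quadratic through the 3 samples on each axis
  refine <- function(vm, v0, vp) {
    den <- vm - 2 * v0 + vp
    off <- ifelse(den < 0, 0.5 * (vm - vp) / den, 0)
    pmin(pmax(off, -0.5), 0.5)
  }
  i <- idx[, 1L]; j <- idx[, 2L]
  dr <- refine(resp[cbind(i - 1L, j)], q, resp[cbind(i + 1L, j)])
  dc <- refine(resp[cbind(i, j - 1L)], q, resp[cbind(i, j + 1L)])
  det <- data.frame(row = (i - 1L) + dr, col = (j - 1L) + dc,
                    radius = radius_px, quality = q)

  # non-maximum suppression within one radius, deterministic order
  ord <- order(-det$quality, det$row, det$col)
  det <- det[ord, , drop = FALSE]
  keep <- logical(nrow(det))
  for (k in seq_len(nrow(det))) {
    if (!any(keep)) { keep[k] <- TRUE; next }
    d2 <- (det$row[keep] - det$row[k])^2 + (det$col[keep] - det$col[k])^2
    keep[k] <- min(d2) >= radius_px^2
  }
  out <- det[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersection-over-union of two disks
#'
#' Analytic IoU of two disks from the circle-circle lens area formula.
#'
#' @param d Center distance.
#' @param r1,r2 Disk radii.
#' @return IoU in `[0, 1]`.
#' @export
disk_iou <- function(d, r1, r2) {
  stopifnot(d >= 0, r1 > 0, r2 > 0)
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) {
    rs <- min(r1, r2); rl <- max(r1, r2)
    return(rs^2 / rl^2)
  }
  a1 <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
  a2 <- r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
  a3 <- 0.5 * sqrt(pmax((-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) *
                          (d + r1 + r2), 0))
  inter <- a1 + a2 - a3
  inter / (pi * r1^2 + pi * r2^2 - inter)
}

#' Link one block of detections onto existing tracks by disk overlap
#'
#' Greedy matching of the active tracks' latest detection disks to the next
#' block's detection disks by descending IoU, accepting matches with IoU at
#' least `min_iou`.  Ties are broken by lower track id, then lower detection
#' index.  Unmatched detections open new tracks; unmatched tracks terminate.
#'
#' @param tracks A track table (`track_id`, `block`, `row`, `col`, `radius`,
#'   `quality`) covering blocks up to `block - 1`; may have zero rows.
#' @param detections Detections for block `block`, as from
#'   [detect_nuclei()].
#' @param block 1-based index of the block being linked.
#' @param min_iou Minimum IoU to accept a link (default 0.1).
#' @return The extended track table.
#' @export
link_overlap <- function(tracks, detections, block, min_iou = 0.1) {
  cols <- c("track_id", "block", "row", "col", "radius", "quality")
  if (nrow(tracks) == 0L) {
    tracks <- data.frame(track_id = integer(), block = integer(),
                         row = numeric(), col = numeric(),
                         radius = numeric(), quality = numeric())
  }
  stopifnot(all(cols %in% names(tracks)))
  nd <- nrow(detections)
  # active tracks: those with a detection in the previous block
  active <- tracks[tracks$block == block - 1L, , drop = FALSE]
  next_id <- if (nrow(tracks)) max(tracks$track_id) + 1L else 1L

  matched_det <- integer(0)
  new_rows <- list()
  if (nrow(active) > 0L && nd > 0L) {
    cand <- expand.grid(a = seq_len(nrow(active)), d = seq_len(nd))
    cand$iou <- mapply(function(a, d) {
      dist <- sqrt((active$row[a] - detections$row[d])^2 +
                     (active$col[a] - detections$col[d])^2)
      disk_iou(dist, active$radius[a], detections$radius[d])
    }, cand$a, cand$d)
    cand <- cand[cand$iou >= min_iou, , drop = FALSE]
    cand <- cand[order(-cand$iou, active$track_id[cand$a], cand$d), ,
                 drop = FALSE]
    used_a <- logical(nrow(active)); used_d <- logical(nd)
    for (k in seq_len(nrow(cand))) {
      a <- cand$a[k]; d <- cand$d[k]
      if (used_a[a] || used_d[d]) next
      used_a[a] <- TRUE; used_d[d] <- TRUE
      new_rows[[length(new_rows) + 1L]] <- data.frame(
        track_id = active$track_id[a], block = block,
        row = detections$row[d], col = detections$col[d],
        radius = detections$radius[d], quality = detections$quality[d])
    }
    matched_det <- which(used_d)
  }
  if (nd > 0L) {
    for (d in setdiff(seq_len(nd), matched_det)) {
      new_rows[[length(new_rows) + 1L]] <- data.frame(
        track_id = next_id, block = block,
        row = detections$row[d], col = detections$col[d],
        radius = detections$radius[d], quality = detections$quality[d])
      next_id <- next_id + 1L
    }
  }
  if (length(new_rows)) tracks <- rbind(tracks, do.call(rbind, new_rows))
  rownames(tracks) <- NULL
  tracks
}

#' Detect and track nuclei across a block-averaged stack
#'
#' Runs [detect_nuclei()] on every block frame and links consecutive blocks
#' with [link_overlap()].
#'
#' @param avg_stack Block-averaged (and bleach-corrected) red-channel stack,
#'   `H x W x n_blocks`.
#' @param radius_px Expected nucleus radius in pixels.
#' @param quality_threshold Minimum LoG response.
#' @param min_iou Minimum disk IoU for linking (default 0.1).
#' @return A track table (`track_id`, `block`, `row`, `col`, `radius`,
#'   `quality`) with `block` 1-based.
#' @export
track_nuclei <- function(avg_stack, radius_px, quality_threshold,
                         min_iou = 0.1) {
  stopifnot(is.array(avg_stack), length(dim(avg_stack)) == 3L)
  nb <- dim(avg_stack)[3L]
  tracks <- data.frame(track_id = integer(), block = integer(),
                       row = numeric(), col = numeric(),
                       radius = numeric(), quality = numeric())
  for (b in seq_len(nb)) {
    det <- detect_nuclei(avg_stack[, , b], radius_px, quality_threshold)
    tracks <- link_overlap(tracks, det, block = b, min_iou = min_iou)
  }
  tracks
}

#' Keep only tracks that span every block
#'
#' Cells must remain trackable for the entire recording to contribute a
#' trace; tracks missing any block are discarded.
#'
#' @param tracks A track table from [track_nuclei()].
#' @param n_blocks Total number of blocks in the movie.
#' @return The filtered track table.
#' @export
filter_complete_tracks <- function(tracks, n_blocks) {
  if (nrow(tracks) == 0L) return(tracks)
  n_per <- table(tracks$track_id)
  complete_ids <- as.integer(names(n_per)[n_per == n_blocks])
  out <- tracks[tracks$track_id %in% complete_ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Render per-block label masks from complete tracks
#'
#' For each block, draws a filled disk of the detection radius at every
#' track center, valued at the track id (0 = background).  Pixels claimed by
#' two disks go to the nearer center; exact ties go to the lower id.
#'
#' @param tracks A complete-track table ([filter_complete_tracks()]).
#' @param image_size `c(H, W)` in pixels.
#' @return A list of integer `H x W` label matrices, one per block, of class
#'   `label_mask_sequence` with attribute `label_ids`.
#' @export
render_label_masks <- function(tracks, image_size) {
  H <- image_size[1L]; W <- image_size[2L]
  if (nrow(tracks) == 0L) {
    out <- list()
    class(out) <- "label_mask_sequence"
    attr(out, "label_ids") <- integer()
    return(out)
  }
  blocks <- sort(unique(tracks$block))
  ids <- sort(unique(tracks$track_id))
  out <- vector("list", length(blocks))
  for (bi in seq_along(blocks)) {
    b <- blocks[bi]
    lab <- matrix(0L, H, W)
    best <- matrix(Inf, H, W)
    tb <- tracks[tracks$block == b, , drop = FALSE]
    tb <- tb[order(tb$track_id), , drop = FALSE]
    for (k in seq_len(nrow(tb))) {
      r0 <- tb$row[k]; c0 <- tb$col[k]; rad <- tb$radius[k]
      ir <- max(0L, floor(r0 - rad)):min(H - 1L, ceiling(r0 + rad))
      ic <- max(0L, floor(c0 - rad)):min(W - 1L, ceiling(c0 + rad))
      d2 <- outer((ir - r0)^2, (ic - c0)^2, "+")
      sub_best <- best[ir + 1L, ic + 1L]
      take <- (d2 <= rad^2) & (d2 < sub_best)  # strict: ties keep lower id
      if (any(take)) {
        sub_lab <- lab[ir + 1L, ic + 1L]
        sub_lab[take] <- tb$track_id[k]
        sub_best[take] <- d2[take]
        lab[ir + 1L, ic + 1L] <- sub_lab
        best[ir + 1L, ic + 1L] <- sub_best
      }
    }
    out[[bi]] <- lab
  }
  class(out) <- "label_mask_sequence"
  attr(out, "label_ids") <- as.integer(ids)
  out
}

#' @export
print.label_mask_sequence <- function(x, ...) {
  cat(sprintf("label_mask_sequence: %d blocks, %d labels\n",
              length(x), length(attr(x, "label_ids"))))
  invisible(x)
}

#' Write a label mask sequence as a multi-page 16-bit TIFF
#'
#' @param masks A `label_mask_sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_masks <- function(masks, path) {
  stopifnot(inherits(masks, "label_mask_sequence"), length(masks) > 0L)
  d <- dim(masks[[1L]])
  st <- array(0, c(d[1L], d[2L], length(masks)))
  for (b in seq_along(masks)) st[, , b] <- masks[[b]]
  write_stack_tiff(st, path)
}
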