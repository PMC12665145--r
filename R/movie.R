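#' Two-channel time-lapse movie
#'
#' Container for a paired red (nuclear marker) and green (calcium biosensor
#' or inert control fluorophore) time-lapse recording.  Each channel is a
#' numeric `H x W x T` array (frames along the third dimension) with
#' non-negative intensities on the unsigned 16-bit scale, plus the frame
#' interval in seconds.
#'
#' @param red,green Numeric 3-d arrays of identical dimension `c(H, W, T)`.
#' @param frame_interval_s Time between consecutive frames, in seconds.
#' @return An object of class `two_channel_movie`: a list with elements
#'   `red`, `green` and `frame_interval_s`.
#' @examples
#' mv <- two_channel_movie(array(1, c(4, 4, 3)), array(2, c(4, 4, 3)), 5)
#' n_frames(mv)
#' @export
two_channel_movie <- function(red, green, frame_interval_s) {
  if (!is.array(red) || length(dim(red)) != 3L) {
    stop("'red' must be an H x W x T array", call. = FALSE)
  }
  if (!is.array(green) || length(dim(green)) != 3L) {
    stop("'green' must be an H x W x T array", call. = FALSE)
  }
  if (!identical(dim(red), dim(green))) {
    stop("red and green stacks must share dimensions (H, W, T); got ",
         paste(dim(red), collapse = "x"), " vs ",
         paste(dim(green), collapse = "x"), call. = FALSE)
  }
  if (min(red) < 0 || min(green) < 0) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  if (!is.numeric(frame_interval_s) || length(frame_interval_s) != 1L ||
      frame_interval_s <= 0) {
    stop("'frame_interval_s' must be a single positive number", call. = FALSE)
  }
  structure(list(red = red, green = green,
                 frame_interval_s = as.numeric(frame_interval_s)),
            class = "two_channel_movie")
}

#' @rdname two_channel_movie
#' @param x A `two_channel_movie`.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "two_channel_movie"))
  dim(x$red)[3L]
}

#' @export
print.two_channel_movie <- function(x, ...) {
  d <- dim(x$red)
  cat(sprintf("two_channel_movie: %d x %d px, %d frames at %g s (%.1f min)\n",
              d[1], d[2], d[3], x$frame_interval_s,
              d[3] * x$frame_interval_s / 60))
  invisible(x)
}

## 16-bit grayscale multi-page TIFF I/O ---------------------------------------

#' Read and write intensity stacks as multi-page 16-bit TIFF
#'
#' Stacks are stored as uncompressed multi-page grayscale TIFF.  On write,
#' intensities are clipped to `[0, 65535]` and rounded to integers; reading a
#' written stack therefore reproduces the rounded values exactly.
#'
#' @param stack Numeric `H x W x T` array.
#' @param path File path.
#' @return `read_stack_tiff` returns a numeric `H x W x T` array;
#'   `write_stack_tiff` returns `path` invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  mx <- 65535
  frames <- lapply(seq_len(dim(stack)[3L]), function(t) {
    round(pmin(pmax(stack[, , t], 0), mx)) / mx
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  bits <- attr(frames[[1L]], "bits.per.sample")
  if (!is.null(bits) && bits == 8L) {
    warning("8-bit TIFF input upcast to the 16-bit intensity scale", call. = FALSE)
  }
  d <- dim(frames[[1L]])
  if (length(d) != 2L) stop("expected single-channel grayscale TIFF: ", path,
                            call. = FALSE)
  out <- array(0, c(d[1L], d[2L], length(frames)))
  for (t in seq_along(frames)) out[, , t] <- frames[[t]]
  out
}

#' Read a two-channel movie from per-channel TIFF stacks
#'
#' @param red_path,green_path Paths to the red (nuclear) and green
#'   (biosensor/control) multi-page TIFF stacks.
#' @param frame_interval_s Frame interval in seconds.
#' @return A [two_channel_movie()].
#' @export
read_movie <- function(red_path, green_path, frame_interval_s = 5) {
  red <- read_stack_tiff(red_path)
  green <- read_stack_tiff(green_path)
  if (!identical(dim(red), dim(green))) {
    stop("channel stacks disagree: '", red_path, "' is ",
         paste(dim(red), collapse = "x"), " but '", green_path, "' is ",
         paste(dim(green), collapse = "x"), call. = FALSE)
  }
  two_channel_movie(red, green, frame_interval_s)
}

#' Write a two-channel movie as per-channel TIFF stacks
#'
#' @param movie A [two_channel_movie()].
#' @param red_path,green_path Output file paths.
#' @return A named character vector of the written paths, invisibly.
#' @export
write_movie <- function(movie, red_path, green_path) {
  stopifnot(inherits(movie, "two_channel_movie"))
  write_stack_tiff(movie$red, red_path)
  write_stack_tiff(movie$green, green_path)
  invisible(c(red = red_path, green = green_path))
}
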