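# Frame and frame-sequence containers. A frame is the atomic video unit:
# an H x W x 3 array of channel intensities in [0, 255] plus a timestamp.

#' Create a single video frame
#'
#' @param pixels H x W x 3 numeric array of channel intensities in
#'   `[0, 255]`, channels ordered R, G, B.
#' @param t Timestamp in seconds from recording start.
#' @param index 0-based frame number.
#' @return An object of class `frame`.
#' @export
new_frame <- function(pixels, t, index = 0L) {
  if (!is.array(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] != 3) {
    abort("`pixels` must be an H x W x 3 array.")
  }
  if (dim(pixels)[1] < 1 || dim(pixels)[2] < 1) {
    abort("Frame must have at least one row and one column.")
  }
  if (any(pixels < 0) || any(pixels > 255)) {
    abort("Frame intensities must lie in [0, 255].")
  }
  structure(
    list(pixels = pixels, t = as.numeric(t), index = as.integer(index)),
    class = "frame"
  )
}

#' @export
print.frame <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<frame %d: %d x %d px, t = %.3f s>\n", x$index, d[1], d[2], x$t))
  invisible(x)
}

frame_geometry <- function(frame) dim(frame$pixels)[1:2]

#' Assemble frames into a validated sequence
#'
#' @param frames A list of [new_frame()] objects with identical geometry and
#'   strictly increasing timestamps.
#' @return The list with class `frame_seq`.
#' @export
frame_seq <- function(frames) {
  if (!is.list(frames) || length(frames) == 0) {
    abort("`frames` must be a non-empty list of frame objects.")
  }
  if (!all(vapply(frames, inherits, logical(1), "frame"))) {
    abort("All elements must be `frame` objects (see `new_frame()`).")
  }
  geoms <- vapply(frames, function(f) frame_geometry(f), integer(2))
  if (length(frames) > 1 && any(geoms[1, ] != geoms[1, 1] | geoms[2, ] != geoms[2, 1])) {
    abort("All frames must share the same geometry.")
  }
  ts <- vapply(frames, function(f) f$t, numeric(1))
  if (length(ts) > 1 && any(diff(ts) <= 0)) {
    abort("Frame timestamps must be strictly increasing.")
  }
  structure(frames, class = "frame_seq")
}

#' @export
print.frame_seq <- function(x, ...) {
  g <- frame_geometry(x[[1]])
  ts <- frame_times(x)
  cat(sprintf("<frame_seq: %d frames, %d x %d px, t in [%.3f, %.3f] s>\n",
              length(x), g[1], g[2], min(ts), max(ts)))
  invisible(x)
}

#' @export
`[.frame_seq` <- function(x, i) {
  frame_seq(unclass(x)[i])
}

#' Timestamps of a frame sequence
#'
#' @param frames A `frame_seq`.
#' @return Numeric vector of timestamps in seconds.
#' @export
frame_times <- function(frames) {
  vapply(frames, function(f) f$t, numeric(1))
}
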