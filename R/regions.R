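# Regions of interest: rectangles, grid partitions, circular well plates,
# and per-frame spatial color averaging.
#
# Coordinate convention (package-wide): 0-based indices, row-major, origin
# at the top-left pixel; rectangles are half-open, covering rows
# [top, top + height) and columns [left, left + width).

new_roi <- function(name, mask, kind, rect = NULL) {
  if (!is.matrix(mask) || !is.logical(mask)) abort("`mask` must be a logical matrix.")
  if (!any(mask)) abort(sprintf("ROI '%s' has an empty mask.", name))
  structure(
    list(name = as.character(name), mask = mask, kind = kind, rect = rect),
    class = "roi"
  )
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi '%s' (%s): %d px on a %d x %d grid>\n",
              x$name, x$kind, sum(x$mask), nrow(x$mask), ncol(x$mask)))
  invisible(x)
}

#' Number of pixels in an ROI
#' @param roi An `roi` object.
#' @return Integer pixel count.
#' @export
roi_size <- function(roi) sum(roi$mask)

#' Rectangular region of interest
#'
#' @param top,left 0-based row/column of the top-left corner.
#' @param height,width Extent in pixels (>= 1).
#' @param geometry Frame geometry as `c(H, W)`.
#' @param name ROI label.
#' @return An `roi` object whose mask is true exactly on the half-open
#'   ranges `[top, top + height)` x `[left, left + width)`.
#' @examples
#' roi_rect(2, 3, 4, 5, geometry = c(10, 10))
#' @export
roi_rect <- function(top, left, height, width, geometry, name = "roi") {
  H <- geometry[1]; W <- geometry[2]
  if (height < 1 || width < 1) abort("`height` and `width` must be >= 1.")
  if (top < 0 || left < 0 || top + height > H || left + width > W) {
    abort(sprintf("Rectangle [%d,%d,%d,%d] exceeds the %d x %d frame bounds.",
                  top, left, height, width, H, W))
  }
  mask <- matrix(FALSE, H, W)
  mask[(top + 1):(top + height), (left + 1):(left + width)] <- TRUE
  new_roi(name, mask, "rect", rect = c(top = top, left = left,
                                       height = height, width = width))
}

new_roi_set <- function(rois, geometry) {
  names(rois) <- vapply(rois, function(r) r$name, character(1))
  if (anyDuplicated(names(rois))) abort("ROI names must be unique.")
  structure(list(rois = rois, geometry = as.integer(geometry)), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set: %d ROIs on a %d x %d grid>\n",
              length(x$rois), x$geometry[1], x$geometry[2]))
  cat(" ", paste(utils::head(names(x$rois), 12), collapse = ", "),
      if (length(x$rois) > 12) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.roi_set <- function(x) length(x$rois)

#' Partition a rectangular ROI into a grid of cells
#'
#' Cells are named `"r{i}c{j}"` (1-based labels), are pairwise disjoint, and
#' their union equals the parent rectangle. When the parent dimensions are
#' not divisible, remainder pixels are assigned to the last row/column of
#' cells.
#'
#' @param parent A rectangular `roi` (from [roi_rect()]).
#' @param rows,cols Number of grid rows/columns (>= 1).
#' @return A `roi_set` of `rows * cols` grid cells.
#' @export
roi_grid <- function(parent, rows, cols) {
  if (!inherits(parent, "roi") || parent$kind != "rect" || is.null(parent$rect)) {
    abort("`parent` must be a rectangular ROI created by `roi_rect()`.")
  }
  rc <- parent$rect
  if (rows < 1 || cols < 1) abort("`rows` and `cols` must be >= 1.")
  if (rows > rc["height"] || cols > rc["width"]) {
    abort("Grid dimensions exceed the parent rectangle's pixel dimensions.")
  }
  geometry <- dim(parent$mask)
  rh <- rc[["height"]] %/% rows
  cw <- rc[["width"]] %/% cols
  rois <- list()
  for (i in seq_len(rows)) {
    r0 <- rc[["top"]] + (i - 1) * rh
    hh <- if (i == rows) rc[["height"]] - (rows - 1) * rh else rh
    for (j in seq_len(cols)) {
      c0 <- rc[["left"]] + (j - 1) * cw
      ww <- if (j == cols) rc[["width"]] - (cols - 1) * cw else cw
      cell <- roi_rect(r0, c0, hh, ww, geometry, name = sprintf("r%dc%d", i, j))
      cell$kind <- "grid_cell"
      rois[[length(rois) + 1]] <- cell
    }
  }
  new_roi_set(rois, geometry)
}

#' Circular well-plate layout
#'
#' Builds one circular ROI per well, named in plate convention (`"A1"`,
#' `"B3"`, ...: row letters, column numbers). Wells are either placed on a
#' regular lattice (`origin` + `pitch`) or at explicit `centers`. A pixel
#' belongs to a well when the Euclidean distance from its (0-based) integer
#' coordinates to the well center is at most `radius`. Overlapping wells
#' raise a warning, not an error; a well extending beyond the frame is an
#' error.
#'
#' @param rows,cols Plate shape.
#' @param geometry Frame geometry as `c(H, W)`.
#' @param radius Well radius in pixels (>= 1).
#' @param centers Optional list (or 2-column matrix) of `(row, col)` well
#'   centers, row-major order, length `rows * cols`.
#' @param origin Center of well A1 as `c(row, col)`; used with `pitch` when
#'   `centers` is not given.
#' @param pitch Center-to-center spacing in pixels.
#' @return A `roi_set` of `rows * cols` circular wells.
#' @export
roi_plate <- function(rows, cols, geometry, radius,
                      centers = NULL, origin = NULL, pitch = NULL) {
  if (radius < 1) abort("`radius` must be >= 1 pixel.")
  n <- rows * cols
  if (is.null(centers)) {
    if (is.null(origin) || is.null(pitch)) {
      abort("Provide either `centers` or both `origin` and `pitch`.")
    }
    centers <- vector("list", n)
    idx <- 1
    for (i in seq_len(rows)) {
      for (j in seq_len(cols)) {
        centers[[idx]] <- c(origin[1] + (i - 1) * pitch,
                            origin[2] + (j - 1) * pitch)
        idx <- idx + 1
      }
    }
  }
  if (is.matrix(centers)) centers <- asplit(centers, 1)
  if (length(centers) != n) {
    abort(sprintf("Need %d centers for a %d x %d plate, got %d.",
                  n, rows, cols, length(centers)))
  }
  H <- geometry[1]; W <- geometry[2]
  rr <- matrix(0:(H - 1), H, W)
  cc <- matrix(0:(W - 1), H, W, byrow = TRUE)
  rois <- vector("list", n)
  idx <- 1
  for (i in seq_len(rows)) {
    for (j in seq_len(cols)) {
      ctr <- centers[[idx]]
      if (ctr[1] - radius < 0 || ctr[1] + radius > H - 1 ||
          ctr[2] - radius < 0 || ctr[2] + radius > W - 1) {
        abort(sprintf("Well %s%d (center %.1f, %.1f) extends outside the frame.",
                      LETTERS[i], j, ctr[1], ctr[2]))
      }
      mask <- (rr - ctr[1])^2 + (cc - ctr[2])^2 <= radius^2
      rois[[idx]] <- new_roi(sprintf("%s%d", LETTERS[i], j), mask, "well")
      idx <- idx + 1
    }
  }
  total <- Reduce(`+`, lapply(rois, function(r) r$mask))
  if (any(total > 1)) warn("Some wells overlap; shared pixels contribute to every overlapping well.")
  new_roi_set(rois, geometry)
}

#' Full-frame ROI
#'
#' @param geometry Frame geometry as `c(H, W)`.
#' @param name ROI label.
#' @return An `roi` covering every pixel.
#' @export
roi_full <- function(geometry, name = "full_frame") {
  roi_rect(0, 0, geometry[1], geometry[2], geometry, name = name)
}

#' Spatial mean color of an ROI in one frame
#'
#' Arithmetic mean of each channel over the masked pixels, unrounded.
#'
#' @param frame A `frame`.
#' @param roi An `roi` with matching geometry.
#' @return Named numeric vector `c(r, g, b)`.
#' @export
spatial_mean <- function(frame, roi) {
  if (!all(frame_geometry(frame) == dim(roi$mask))) {
    abort("ROI geometry does not match the frame.")
  }
  m <- roi$mask
  c(r = mean(frame$pixels[, , 1][m]),
    g = mean(frame$pixels[, , 2][m]),
    b = mean(frame$pixels[, , 3][m]))
}

#' Spatial mean color for every ROI in a set
#'
#' @param frame A `frame`.
#' @param rois A `roi_set`.
#' @return A tibble with columns `roi`, `r`, `g`, `b`.
#' @export
spatial_means <- function(frame, rois) {
  purrr::map_dfr(rois$rois, function(roi) {
    m <- spatial_mean(frame, roi)
    tibble(roi = roi$name, r = m[["r"]], g = m[["g"]], b = m[["b"]])
  })
}
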