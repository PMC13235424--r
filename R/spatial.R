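# Spatially resolved mixing metrics: RGB-window binarization, the Contact
# interfacial-perimeter count, and gray-level co-occurrence matrix (GLCM)
# texture features.

#' Binarize a frame with an RGB window
#'
#' A pixel is foreground (TRUE) when all three channels lie inside the
#' inclusive window `[rgb_lo, rgb_hi]`.
#'
#' @param frame A `frame`.
#' @param rgb_lo,rgb_hi Length-3 numeric bounds, channel-wise `lo <= hi`.
#' @return A logical H x W matrix with the thresholds attached as the
#'   `threshold` attribute.
#' @export
binarize <- function(frame, rgb_lo, rgb_hi) {
  if (length(rgb_lo) != 3 || length(rgb_hi) != 3) {
    abort("`rgb_lo` and `rgb_hi` must be length-3 RGB bounds.")
  }
  if (any(rgb_lo > rgb_hi)) abort("`rgb_lo` must be <= `rgb_hi` channel-wise.")
  px <- frame$pixels
  ch <- function(i) matrix(px[, , i], nrow = dim(px)[1])  # keep dims for 1-row frames
  mask <- (ch(1) >= rgb_lo[1] & ch(1) <= rgb_hi[1] &
           ch(2) >= rgb_lo[2] & ch(2) <= rgb_hi[2] &
           ch(3) >= rgb_lo[3] & ch(3) <= rgb_hi[3])
  attr(mask, "threshold") <- list(lo = rgb_lo, hi = rgb_hi)
  mask
}

#' Contact: interfacial perimeter of a binary mask
#'
#' Counts the 4-adjacent pixel pairs (horizontal and vertical neighbors)
#' whose values differ — the total length, in pixel edges, of the
#' black/white interface. A uniform mask has Contact 0 ("no interfacial
#' area"); the count peaks at maximum spatial heterogeneity and decays
#' toward 0 as a mixing system homogenizes. The image border contributes
#' nothing, and the count is invariant under mask complement.
#'
#' @param mask A logical H x W matrix (e.g. from [binarize()]).
#' @param normalize If `TRUE`, also divide by the total number of adjacent
#'   pairs, for comparability across ROI sizes.
#' @return The raw count, or a named vector `c(contact, contact_norm)` if
#'   `normalize = TRUE`.
#' @export
contact <- function(mask, normalize = FALSE) {
  if (!is.matrix(mask) || !is.logical(mask)) abort("`mask` must be a logical matrix.")
  H <- nrow(mask); W <- ncol(mask)
  nh <- if (W > 1) sum(mask[, -1, drop = FALSE] != mask[, -W, drop = FALSE]) else 0L
  nv <- if (H > 1) sum(mask[-1, , drop = FALSE] != mask[-H, , drop = FALSE]) else 0L
  cnt <- nh + nv
  if (!normalize) return(cnt)
  pairs <- H * (W - 1) + (H - 1) * W
  c(contact = cnt, contact_norm = if (pairs > 0) cnt / pairs else 0)
}

#' Quantize a frame to gray levels
#'
#' Luma (`0.299 R + 0.587 G + 0.114 B`) per pixel, then equal-width
#' binning of `[0, 255]` into `levels` gray levels; 255 maps to the top
#' level.
#'
#' @param frame A `frame`.
#' @param levels Number of gray levels G (>= 2).
#' @return An integer H x W matrix with values in `{0, ..., G - 1}`.
#' @export
quantize_gray <- function(frame, levels) {
  if (levels < 2) abort("`levels` must be >= 2.")
  px <- frame$pixels
  luma <- matrix(0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3],
                 nrow = dim(px)[1])
  g <- pmin(floor(luma * levels / 255), levels - 1)
  storage.mode(g) <- "integer"
  g
}

#' Gray-level co-occurrence matrix
#'
#' Tallies pairs of gray levels at a fixed spatial offset: `counts[i, j]`
#' is incremented once for every pixel with level `i` whose neighbor at
#' `offset = c(dr, dc)` has level `j` (levels are 0-based; matrix indices
#' 1-based). With `symmetric = TRUE` the transposed pairs are also
#' accumulated, making the matrix symmetric.
#'
#' @param gray Integer H x W matrix of gray levels in `{0, ..., levels-1}`
#'   (see [quantize_gray()]).
#' @param levels Number of gray levels G.
#' @param offset Integer `c(row delta, column delta)`, nonzero, with
#'   magnitudes smaller than the image dimensions. Default `c(1, 1)` (one
#'   row down, one column right).
#' @param symmetric Accumulate both pair orders (default `TRUE`).
#' @return A `glcm` object: list with `levels`, `offset`, `counts`,
#'   `probabilities` (normalized to sum 1), `symmetric`.
#' @export
compute_glcm <- function(gray, levels, offset = c(1, 1), symmetric = TRUE) {
  if (!is.matrix(gray)) abort("`gray` must be a matrix.")
  if (any(gray != floor(gray)) || any(gray < 0) || any(gray > levels - 1)) {
    abort("`gray` must be quantized to integer levels {0, ..., levels-1}; see `quantize_gray()`.")
  }
  dr <- as.integer(offset[1]); dc <- as.integer(offset[2])
  if (dr == 0 && dc == 0) abort("`offset` must be nonzero.")
  H <- nrow(gray); W <- ncol(gray)
  if (abs(dr) >= H || abs(dc) >= W) abort("`offset` magnitudes must be smaller than the image dimensions.")
  rows <- seq_len(H); cols <- seq_len(W)
  r1 <- rows[rows + dr >= 1 & rows + dr <= H]
  c1 <- cols[cols + dc >= 1 & cols + dc <= W]
  a <- gray[r1, c1, drop = FALSE]
  b <- gray[r1 + dr, c1 + dc, drop = FALSE]
  counts <- matrix(tabulate(a * levels + b + 1L, nbins = levels * levels),
                   nrow = levels, byrow = TRUE)
  if (symmetric) counts <- counts + t(counts)
  total <- sum(counts)
  structure(
    list(levels = levels, offset = c(dr, dc), counts = counts,
         probabilities = counts / total, symmetric = symmetric),
    class = "glcm"
  )
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf("<glcm: %d levels, offset (%d, %d)%s, %d pair counts>\n",
              x$levels, x$offset[1], x$offset[2],
              if (x$symmetric) ", symmetric" else "", sum(x$counts)))
  invisible(x)
}

#' Texture features of a GLCM
#'
#' * `asm` (angular second moment): sum of squared probabilities; 1 for a
#'   perfectly regular (single-pair) texture.
#' * `entropy`: Shannon entropy of the pair distribution in bits
#'   (`0 log 0 = 0`); 0 for a single occupied cell, up to `2 log2(G)`.
#' * `homogeneity`: inverse-difference weighting `sum p / (1 + |i - j|)`
#'   (or the inverse-difference-moment form `1 + (i - j)^2` with
#'   `form = "idm"`); 1 when all mass is on the diagonal.
#'
#' @param g A `glcm` object.
#' @param form Homogeneity weighting: `"inverse_difference"` (default) or
#'   `"idm"`.
#' @return A one-row tibble with columns `asm`, `entropy`, `homogeneity`.
#' @export
glcm_features <- function(g, form = c("inverse_difference", "idm")) {
  form <- match.arg(form)
  if (!inherits(g, "glcm")) abort("`g` must be a `glcm` object.")
  p <- g$probabilities
  if (abs(sum(p) - 1) > 1e-9) abort("GLCM probabilities are not normalized.")
  asm <- sum(p^2)
  nz <- p[p > 0]
  entropy <- -sum(nz * log2(nz))
  ij <- abs(row(p) - col(p))
  w <- if (form == "inverse_difference") 1 / (1 + ij) else 1 / (1 + ij^2)
  tibble(asm = asm, entropy = entropy, homogeneity = sum(p * w))
}

# Crop a frame to the bounding box of an ROI mask.
crop_to_roi <- function(frame, roi) {
  idx <- which(roi$mask, arr.ind = TRUE)
  rr <- range(idx[, 1]); cc <- range(idx[, 2])
  new_frame(frame$pixels[rr[1]:rr[2], cc[1]:cc[2], , drop = FALSE],
            t = frame$t, index = frame$index)
}

#' Time-resolved mixing texture of an ROI
#'
#' For each frame, the ROI bounding box is cropped out, binarized with the
#' RGB window to yield the Contact interfacial count, and quantized to
#' gray levels for GLCM texture features (ASM, entropy, homogeneity).
#'
#' @param frames A `frame_seq`.
#' @param roi An `roi` (defaults to the full frame).
#' @param rgb_lo,rgb_hi Binarization window, as in [binarize()].
#' @param levels GLCM gray levels (default 16).
#' @param offset GLCM offset (default `c(1, 1)`).
#' @param symmetric Symmetric GLCM accumulation (default `TRUE`).
#' @return A `texture_trace` tibble: `frame_index`, `t`, `roi`, `contact`,
#'   `contact_norm`, `asm`, `entropy`, `homogeneity`.
#' @export
texture_trace <- function(frames, roi = NULL, rgb_lo, rgb_hi,
                          levels = 16, offset = c(1, 1), symmetric = TRUE) {
  if (!inherits(frames, "frame_seq")) frames <- frame_seq(frames)
  if (length(frames) < 2) abort("Need at least 2 frames to build a trace.")
  if (is.null(roi)) roi <- roi_full(frame_geometry(frames[[1]]))
  rows <- purrr::map_dfr(frames, function(f) {
    sub <- crop_to_roi(f, roi)
    cn <- contact(binarize(sub, rgb_lo, rgb_hi), normalize = TRUE)
    feat <- glcm_features(compute_glcm(quantize_gray(sub, levels),
                                       levels, offset, symmetric))
    tibble(frame_index = f$index, t = f$t, roi = roi$name,
           contact = unname(cn["contact"]), contact_norm = unname(cn["contact_norm"]),
           asm = feat$asm, entropy = feat$entropy, homogeneity = feat$homogeneity)
  })
  structure(rows, class = c("texture_trace", class(rows)))
}
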