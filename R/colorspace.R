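# Pixel-level color representations: sRGB <-> HSV / CIE-XYZ / CIE-L*a*b*,
# the CIE76 Delta E color distance, and the RGB sum response scalar.
#
# Conventions (fixed package-wide): sRGB primaries, D65 white point, 2 deg
# observer. All arithmetic is done in double precision; rounding to match
# printed tables happens only at presentation time (round half to even).

# sRGB -> XYZ (D65), Y scaled so that reference white has Y = 100.
.SRGB_TO_XYZ <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041
), nrow = 3, byrow = TRUE) * 100

# D65 reference white tristimulus values (Y = 100).
.D65_WHITE <- c(x = 95.047, y = 100, z = 108.883)

# Coerce triples to an n x 3 numeric matrix. Accepts a length-3 vector,
# an n x 3 matrix, or a data frame whose first three numeric-ish columns
# (or columns named like the axes) hold the coordinates.
as_triple_matrix <- function(x, axes = c("r", "g", "b"), arg = "x") {
  if (is.data.frame(x)) {
    nm <- tolower(names(x))
    idx <- match(tolower(axes), nm)
    if (anyNA(idx)) idx <- seq_len(3)
    x <- as.matrix(x[, idx, drop = FALSE])
  }
  if (is.numeric(x) && is.null(dim(x)) && length(x) == 3) {
    x <- matrix(x, nrow = 1)
  }
  if (!is.matrix(x) || ncol(x) != 3 || !is.numeric(x)) {
    abort(sprintf("`%s` must be a length-3 vector, n x 3 matrix, or data frame of %s triples.",
                  arg, paste(axes, collapse = "")))
  }
  if (anyNA(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` contains missing or non-finite values.", arg))
  }
  storage.mode(x) <- "double"
  colnames(x) <- axes
  x
}

check_rgb_range <- function(m, arg = "rgb") {
  if (any(m < 0) || any(m > 255)) {
    abort(sprintf("`%s` channels must lie in [0, 255].", arg))
  }
  m
}

#' Convert RGB to HSV
#'
#' Standard hexcone conversion. Hue is reported in degrees on `[0, 360)`;
#' saturation and value are scaled to `[0, 255]` so that they are directly
#' comparable with 8-bit channel intensities. Achromatic pixels
#' (`r == g == b`) have `s = 0` and hue defined as 0.
#'
#' @param rgb A length-3 numeric vector, an n x 3 matrix, or a data frame
#'   with columns `r`, `g`, `b`; channel intensities in `[0, 255]`.
#' @return A tibble with columns `h`, `s`, `v` (one row per input triple).
#' @examples
#' rgb_to_hsv(c(38, 59, 222))
#' @export
rgb_to_hsv <- function(rgb) {
  m <- check_rgb_range(as_triple_matrix(rgb, c("r", "g", "b"), "rgb"))
  mx <- pmax(m[, 1], m[, 2], m[, 3])
  mn <- pmin(m[, 1], m[, 2], m[, 3])
  d <- mx - mn
  s <- ifelse(mx == 0, 0, 255 * d / mx)
  h <- numeric(nrow(m))
  chrom <- d > 0
  if (any(chrom)) {
    r <- m[, 1]; g <- m[, 2]; b <- m[, 3]
    # first channel attaining the max wins (r, then g, then b)
    is_r <- chrom & (r == mx)
    is_g <- chrom & !is_r & (g == mx)
    is_b <- chrom & !is_r & !is_g
    h[is_r] <- 60 * (((g[is_r] - b[is_r]) / d[is_r]) %% 6)
    h[is_g] <- 60 * ((b[is_g] - r[is_g]) / d[is_g] + 2)
    h[is_b] <- 60 * ((r[is_b] - g[is_b]) / d[is_b] + 4)
    h <- h %% 360
  }
  tibble(h = unname(h), s = unname(s), v = unname(mx))
}

#' Convert RGB to CIE-XYZ
#'
#' sRGB inverse companding (IEC 61966-2-1 piecewise gamma) followed by the
#' standard sRGB -> XYZ matrix for the D65 white point; Y of the reference
#' white is 100.
#'
#' @inheritParams rgb_to_hsv
#' @return A tibble with columns `x`, `y`, `z`.
#' @export
rgb_to_xyz <- function(rgb) {
  m <- check_rgb_range(as_triple_matrix(rgb, c("r", "g", "b"), "rgb"))
  v <- m / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  xyz <- lin %*% t(.SRGB_TO_XYZ)
  tibble(x = unname(xyz[, 1]), y = unname(xyz[, 2]), z = unname(xyz[, 3]))
}

#' Convert CIE-XYZ to CIE-L*a*b*
#'
#' CIE 1976 L*a*b* with the D65 reference white and the standard
#' cube-root / linear-segment transfer function.
#'
#' @param xyz A length-3 numeric vector, n x 3 matrix, or data frame with
#'   columns `x`, `y`, `z` (reference white at Y = 100).
#' @return A tibble with columns `L`, `a`, `b`.
#' @export
xyz_to_lab <- function(xyz) {
  m <- as_triple_matrix(xyz, c("x", "y", "z"), "xyz")
  t3 <- sweep(m, 2, .D65_WHITE, "/")
  eps <- (6 / 29)^3
  f <- ifelse(t3 > eps, t3^(1 / 3), t3 / (3 * (6 / 29)^2) + 4 / 29)
  tibble(
    L = unname(116 * f[, 2] - 16),
    a = unname(500 * (f[, 1] - f[, 2])),
    b = unname(200 * (f[, 2] - f[, 3]))
  )
}

#' Convert RGB directly to CIE-L*a*b*
#'
#' Convenience composition of [rgb_to_xyz()] and [xyz_to_lab()].
#'
#' @inheritParams rgb_to_hsv
#' @return A tibble with columns `L`, `a`, `b`.
#' @export
rgb_to_lab <- function(rgb) {
  xyz_to_lab(rgb_to_xyz(rgb))
}

#' Convert CIE-L*a*b* back to RGB
#'
#' Inverse of [rgb_to_lab()]: Lab -> XYZ (D65) -> linear sRGB -> IEC
#' companding. Out-of-gamut results are clipped to `[0, 255]`.
#'
#' @param lab A length-3 vector, n x 3 matrix, or data frame with columns
#'   `L`, `a`, `b`.
#' @return A tibble with columns `r`, `g`, `b` in `[0, 255]`.
#' @export
lab_to_rgb <- function(lab) {
  m <- as_triple_matrix(lab, c("L", "a", "b"), "lab")
  fy <- (m[, 1] + 16) / 116
  fx <- fy + m[, 2] / 500
  fz <- fy - m[, 3] / 200
  finv <- function(f) {
    ifelse(f > 6 / 29, f^3, 3 * (6 / 29)^2 * (f - 4 / 29))
  }
  xyz <- cbind(finv(fx) * .D65_WHITE[1], finv(fy) * .D65_WHITE[2],
               finv(fz) * .D65_WHITE[3])
  lin <- xyz %*% t(solve(.SRGB_TO_XYZ))
  lin <- pmin(pmax(lin, 0), 1)
  v <- ifelse(lin <= 0.0031308, 12.92 * lin, 1.055 * lin^(1 / 2.4) - 0.055)
  v <- pmin(pmax(v * 255, 0), 255)
  tibble(r = unname(v[, 1]), g = unname(v[, 2]), b = unname(v[, 3]))
}

#' CIE76 Delta E color distance
#'
#' Euclidean distance between two colors in CIE-L*a*b* space:
#' \deqn{\Delta E = \sqrt{(L_2-L_1)^2 + (a_2-a_1)^2 + (b_2-b_1)^2}}
#' A value of 0 means the colors are numerically identical; values above
#' about 10 correspond to visually obvious differences, and changes below
#' about 2 sit at the perceptual/instrumental noise floor.
#'
#' @param lab1,lab2 Lab triples (length-3 vectors, n x 3 matrices, or data
#'   frames with columns `L`, `a`, `b`). Recycled row-wise if one has a
#'   single row.
#' @return A non-negative numeric vector.
#' @examples
#' delta_e_1976(c(54, 43, -63), c(99, 8, 5))
#' @export
delta_e_1976 <- function(lab1, lab2) {
  m1 <- as_triple_matrix(lab1, c("L", "a", "b"), "lab1")
  m2 <- as_triple_matrix(lab2, c("L", "a", "b"), "lab2")
  if (nrow(m1) != nrow(m2)) {
    if (nrow(m1) == 1) m1 <- m1[rep(1, nrow(m2)), , drop = FALSE]
    else if (nrow(m2) == 1) m2 <- m2[rep(1, nrow(m1)), , drop = FALSE]
    else abort("`lab1` and `lab2` must have the same number of rows (or one row).")
  }
  unname(sqrt(rowSums((m2 - m1)^2)))
}

#' RGB sum response
#'
#' The brightness-loss scalar `765 - (R + G + B)`: 0 for pure white, 765 for
#' pure black. Useful when a colored species fades to colorless and the
#' signal is overall brightness rather than a specific hue.
#'
#' @inheritParams rgb_to_hsv
#' @return A numeric vector in `[0, 765]`.
#' @export
rgb_sum_response <- function(rgb) {
  m <- check_rgb_range(as_triple_matrix(rgb, c("r", "g", "b"), "rgb"))
  unname(765 - rowSums(m))
}
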