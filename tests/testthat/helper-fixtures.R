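# Shared fixtures: printed reference conversions, tiny frame builders,
# and brute-force oracles kept deliberately independent of the package's
# own vectorized implementations.

# Printed average-color table for the four apron patches (A-D) under the
# two light sources; HSV as (h, s, v) with s, v on the 0-255 scale.
APRON_PATCHES <- list(
  A = list(rgb = c(38, 59, 222),   hsv = c(53, 211, 222),  lab = c(54, 43, -63)),
  B = list(rgb = c(147, 140, 187), hsv = c(68, 64, 187),   lab = c(79, 17, -10)),
  C = list(rgb = c(147, 140, 187), hsv = c(68, 64, 187),   lab = c(79, 17, -10)),
  D = list(rgb = c(255, 254, 255), hsv = c(300, 1, 255),   lab = c(99, 8, 5))
)

uniform_frame <- function(color, H = 4, W = 4, t = 0, index = 0L) {
  new_frame(array(rep(color, each = H * W), dim = c(H, W, 3)), t = t, index = index)
}

# Frame sequence where frame i is uniformly colors[i, ].
frames_from_colors <- function(colors, fps = 1, H = 4, W = 4) {
  frame_seq(lapply(seq_len(nrow(colors)), function(i) {
    uniform_frame(colors[i, ], H, W, t = (i - 1) / fps, index = i - 1L)
  }))
}

# Minimal single-ROI trace carrying only what the kinetic operations
# read: t, delta_e, roi.
synthetic_de_trace <- function(t, delta_e, roi = "sim") {
  tibble::tibble(frame_index = seq_along(t) - 1L, t = t, roi = roi,
                 delta_e = delta_e)
}

# Brute-force Contact: explicit double loop over 4-neighbor pairs.
brute_contact <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  n <- 0L
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (j < W && mask[i, j] != mask[i, j + 1]) n <- n + 1L
    if (i < H && mask[i + 1, j] != mask[i, j]) n <- n + 1L
  }
  n
}

# Brute-force GLCM counts: explicit double loop, one increment per valid
# ordered pair (plus the transpose when symmetric).
brute_glcm_counts <- function(gray, levels, offset, symmetric = TRUE) {
  H <- nrow(gray); W <- ncol(gray)
  counts <- matrix(0L, levels, levels)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    i2 <- i + offset[1]; j2 <- j + offset[2]
    if (i2 >= 1 && i2 <= H && j2 >= 1 && j2 <= W) {
      a <- gray[i, j] + 1L; b <- gray[i2, j2] + 1L
      counts[a, b] <- counts[a, b] + 1L
      if (symmetric) counts[b, a] <- counts[b, a] + 1L
    }
  }
  counts
}

random_mask <- function(H = 16, W = 16) {
  matrix(stats::runif(H * W) > 0.5, H, W)
}

# Mid-threshold binarization window for the default mixing colors:
# dye-rich pixels have every channel below the midpoint blend.
mixing_threshold <- function(spec) {
  list(lo = c(0, 0, 0), hi = (spec$dye_color + spec$solvent_color) / 2)
}
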