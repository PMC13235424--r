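# Seedable synthetic frame-sequence generators: uniform-vessel color
# reactions, stirred dye mixing, and multi-well plates. These provide
# ground-truth fixtures with the statistical structure the analyses
# assume, so every pipeline stage can be exercised without recorded
# footage.

# Run code with a private RNG stream, leaving the caller's stream intact.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

fractional_conversion <- function(t, model, k) {
  switch(model,
    first_order = 1 - exp(-k * t),
    second_order = (k * t) / (1 + k * t),
    abort(sprintf("Unknown kinetic model '%s'.", model))
  )
}

# Per-frame mean colors along the start -> end transition, as an
# n x 3 RGB matrix. blend = "lab": endpoints are interpolated in Lab
# space, so the Delta E of the mean color is exactly f * dE(start, end)
# (the trace follows the kinetic model exactly). blend = "rgb": literal
# channel-wise interpolation; Delta E then deviates slightly from the
# model because Lab is nonlinear in companded RGB.
blend_colors <- function(color_start, color_end, f, blend) {
  if (blend == "rgb") {
    outer(f, color_end - color_start) +
      matrix(color_start, length(f), 3, byrow = TRUE)
  } else {
    lab <- as.matrix(rgb_to_lab(rbind(color_start, color_end)))
    labs <- outer(f, lab[2, ] - lab[1, ]) +
      matrix(lab[1, ], length(f), 3, byrow = TRUE)
    as.matrix(lab_to_rgb(labs))
  }
}

#' Specification of a synthetic single-vessel color reaction
#'
#' The vessel color moves from `color_start` to `color_end` along a
#' first-order (`1 - exp(-k t)`) or second-order (`k t / (1 + k t)`,
#' initial concentration absorbed into `k`) conversion curve, with i.i.d.
#' Gaussian per-pixel channel noise clipped to `[0, 255]`.
#'
#' @param color_start,color_end RGB triples in `[0, 255]`.
#' @param model `"first_order"` or `"second_order"`.
#' @param k Rate constant (> 0; per second for first order).
#' @param duration Recording length in seconds (> 0).
#' @param fps Frames per second (> 0).
#' @param noise_sigma Channel noise standard deviation (>= 0).
#' @param width,height Frame size in pixels.
#' @param blend Color path between the endpoints: `"lab"` (default;
#'   linear in CIE-L*a*b*, so the Delta E trace follows the kinetic model
#'   exactly) or `"rgb"` (channel-wise linear; Delta E then deviates
#'   slightly from the model because Lab is nonlinear in companded RGB).
#' @param seed RNG seed (explicit, never global state).
#' @return A `reaction_spec` list.
#' @export
reaction_spec <- function(color_start, color_end, model = "first_order",
                          k = 0.05, duration = 300, fps = 2,
                          noise_sigma = 0, width = 32, height = 32,
                          blend = c("lab", "rgb"), seed = 1) {
  blend <- match.arg(blend)
  check_rgb_range(as_triple_matrix(color_start, arg = "color_start"), "color_start")
  check_rgb_range(as_triple_matrix(color_end, arg = "color_end"), "color_end")
  if (k <= 0) abort("`k` must be > 0.")
  if (fps <= 0 || duration <= 0) abort("`fps` and `duration` must be > 0.")
  if (noise_sigma < 0) abort("`noise_sigma` must be >= 0.")
  model <- match.arg(model, c("first_order", "second_order"))
  structure(list(color_start = as.numeric(color_start),
                 color_end = as.numeric(color_end),
                 model = model, k = k, duration = duration, fps = fps,
                 noise_sigma = noise_sigma, width = width, height = height,
                 blend = blend, seed = as.integer(seed)),
            class = "reaction_spec")
}

#' Generate a synthetic single-vessel reaction video
#'
#' @param spec A [reaction_spec()].
#' @return A list with `frames` (a `frame_seq`), and `truth`: a tibble of
#'   `t`, `conversion` and the analytic `delta_e` curve (Delta E between
#'   the endpoint Lab colors scaled by conversion — exact for the
#'   noiseless mean color since the RGB path is linear between endpoints,
#'   Delta E small-signal linearity notwithstanding).
#' @export
gen_reaction <- function(spec) {
  stopifnot(inherits(spec, "reaction_spec"))
  nfr <- floor(spec$duration * spec$fps) + 1
  ts <- (seq_len(nfr) - 1) / spec$fps
  f <- fractional_conversion(ts, spec$model, spec$k)
  npx <- spec$height * spec$width
  mean_rgb <- blend_colors(spec$color_start, spec$color_end, f, spec$blend)
  frames <- with_local_seed(spec$seed, {
    lapply(seq_len(nfr), function(i) {
      px <- array(rep(mean_rgb[i, ], each = npx),
                  dim = c(spec$height, spec$width, 3))
      if (spec$noise_sigma > 0) {
        px <- px + array(rnorm(npx * 3, sd = spec$noise_sigma),
                         dim = dim(px))
      }
      new_frame(pmin(pmax(px, 0), 255), t = ts[i], index = i - 1L)
    })
  })
  lab <- rgb_to_lab(rbind(spec$color_start, spec$color_end))
  de_full <- delta_e_1976(lab[1, ], lab[2, ])
  # Analytic Delta E of the noiseless mean color: f * dE(endpoints) for a
  # Lab-linear path; computed per frame through the conversion for "rgb".
  de_t <- if (spec$blend == "lab") f * de_full
          else delta_e_1976(lab[1, ], rgb_to_lab(mean_rgb))
  list(
    frames = frame_seq(frames),
    truth = list(
      k = spec$k, model = spec$model,
      curve = tibble(t = ts, conversion = f, delta_e = de_t),
      delta_e_endpoints = de_full
    )
  )
}

#' Specification of a synthetic stirred dye-mixing video
#'
#' A circular dye blob in solvent is evolved by operator splitting:
#' differential rotation about the grid center (a swirl whose angular
#' displacement decays with radius, shearing the blob into filaments)
#' followed by 5-point-stencil diffusion with zero-flux boundaries. The
#' total dye mass is conserved exactly: the diffusion stencil conserves it
#' by construction, and the bilinear advection resampling is renormalized
#' to the pre-step total.
#'
#' @param grid Field size `c(H, W)`.
#' @param dye_color,solvent_color RGB triples.
#' @param blob_center `(row, col)` of the initial dye blob (0-based).
#' @param blob_radius Blob radius in pixels.
#' @param diffusion Dimensionless diffusion rate per step in `(0, 0.25]`
#'   (the explicit-scheme stability bound).
#' @param swirl Angular advection strength (radians per step at the
#'   center; decays linearly to 0 at the largest in-grid radius).
#' @param steps Number of time steps (frames).
#' @param fps Frames per second.
#' @param noise_sigma Channel noise sd (>= 0).
#' @param seed RNG seed.
#' @return A `mixing_spec` list.
#' @export
mixing_spec <- function(grid = c(64, 64), dye_color = c(20, 20, 160),
                        solvent_color = c(245, 245, 245),
                        blob_center = NULL, blob_radius = NULL,
                        diffusion = 0.08, swirl = 0.35, steps = 120,
                        fps = 5, noise_sigma = 0, seed = 1) {
  H <- grid[1]; W <- grid[2]
  if (diffusion <= 0 || diffusion > 0.25) {
    abort("`diffusion` must be in (0, 0.25] (explicit-scheme stability bound).")
  }
  if (is.null(blob_center)) blob_center <- c((H - 1) / 2, (W - 1) * 0.3)
  if (is.null(blob_radius)) blob_radius <- round(min(H, W) / 6)
  if (blob_center[1] - blob_radius < 0 || blob_center[1] + blob_radius > H - 1 ||
      blob_center[2] - blob_radius < 0 || blob_center[2] + blob_radius > W - 1) {
    abort("Initial blob must lie inside the grid.")
  }
  structure(list(grid = c(H, W), dye_color = dye_color,
                 solvent_color = solvent_color, blob_center = blob_center,
                 blob_radius = blob_radius, diffusion = diffusion,
                 swirl = swirl, steps = steps, fps = fps,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "mixing_spec")
}

# One swirl advection step: semi-Lagrangian backtrace along a rotation
# whose angle decays linearly with radius, bilinear interpolation, then
# mass renormalization.
advect_swirl <- function(conc, swirl) {
  if (swirl == 0) return(conc)
  H <- nrow(conc); W <- ncol(conc)
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  rr <- matrix(0:(H - 1), H, W) - cy
  cc <- matrix(0:(W - 1), H, W, byrow = TRUE) - cx
  rad <- sqrt(rr^2 + cc^2)
  rmax <- sqrt(cy^2 + cx^2)
  theta <- swirl * pmax(0, 1 - rad / rmax)
  # backtrace: rotate source coordinates by -theta
  src_r <- cy + rr * cos(theta) - cc * sin(theta)
  src_c <- cx + rr * sin(theta) + cc * cos(theta)
  r0 <- pmin(pmax(floor(src_r), 0), H - 2)
  c0 <- pmin(pmax(floor(src_c), 0), W - 2)
  fr <- pmin(pmax(src_r - r0, 0), 1)
  fc <- pmin(pmax(src_c - c0, 0), 1)
  at <- function(ri, ci) conc[cbind(as.vector(ri) + 1L, as.vector(ci) + 1L)]
  out <- (1 - fr) * (1 - fc) * at(r0, c0) +
         (1 - fr) * fc       * at(r0, c0 + 1) +
         fr       * (1 - fc) * at(r0 + 1, c0) +
         fr       * fc       * at(r0 + 1, c0 + 1)
  out <- matrix(out, H, W)
  tot_in <- sum(conc); tot_out <- sum(out)
  if (tot_out > 0) out <- out * (tot_in / tot_out)
  out
}

# 5-point Laplacian diffusion with zero-flux (reflecting) boundaries;
# conserves total mass exactly.
diffuse_step <- function(conc, d) {
  H <- nrow(conc); W <- ncol(conc)
  up    <- conc[c(1, seq_len(H - 1)), , drop = FALSE]
  down  <- conc[c(seq_len(H - 1) + 1, H), , drop = FALSE]
  left  <- conc[, c(1, seq_len(W - 1)), drop = FALSE]
  right <- conc[, c(seq_len(W - 1) + 1, W), drop = FALSE]
  conc + d * (up + down + left + right - 4 * conc)
}

#' Generate a synthetic stirred dye-mixing video
#'
#' @param spec A [mixing_spec()].
#' @return A list with `frames` (a `frame_seq`; per-pixel linear blend
#'   solvent-to-dye by concentration) and `concentration` (list of H x W
#'   fields, one per frame).
#' @export
gen_mixing <- function(spec) {
  stopifnot(inherits(spec, "mixing_spec"))
  H <- spec$grid[1]; W <- spec$grid[2]
  rr <- matrix(0:(H - 1), H, W)
  cc <- matrix(0:(W - 1), H, W, byrow = TRUE)
  conc <- ((rr - spec$blob_center[1])^2 + (cc - spec$blob_center[2])^2 <=
             spec$blob_radius^2) * 1.0
  fields <- vector("list", spec$steps)
  frames <- vector("list", spec$steps)
  with_local_seed(spec$seed, {
    for (s in seq_len(spec$steps)) {
      if (s > 1) {
        conc <- advect_swirl(conc, spec$swirl)
        conc <- diffuse_step(conc, spec$diffusion)
      }
      fields[[s]] <- conc
      px <- array(0, dim = c(H, W, 3))
      for (ch in 1:3) {
        px[, , ch] <- spec$solvent_color[ch] +
          conc * (spec$dye_color[ch] - spec$solvent_color[ch])
      }
      if (spec$noise_sigma > 0) {
        px <- px + array(rnorm(H * W * 3, sd = spec$noise_sigma), dim = dim(px))
      }
      frames[[s]] <- new_frame(pmin(pmax(px, 0), 255),
                               t = (s - 1) / spec$fps, index = s - 1L)
    }
  })
  list(frames = frame_seq(frames), concentration = fields)
}

#' Specification of a synthetic multi-well plate video
#'
#' A canvas of background color carries `rows x cols` circular wells, each
#' following its own first- or second-order color program (per-well rate
#' constants), sharing `color_start`/`color_end`.
#'
#' @param rows,cols Plate shape.
#' @param k Vector of per-well rate constants, row-major, length
#'   `rows * cols` (recycled if length 1).
#' @param color_start,color_end Well RGB endpoints.
#' @param model Kinetic model for all wells.
#' @param duration,fps Recording length and frame rate.
#' @param noise_sigma Channel noise sd.
#' @param well_radius,pitch,origin Plate geometry in pixels; `origin` is
#'   the center of well A1 (`c(row, col)`, 0-based).
#' @param background Canvas RGB color.
#' @param blend Color path, as in [reaction_spec()].
#' @param seed RNG seed.
#' @return A `plate_spec` list.
#' @export
plate_spec <- function(rows = 4, cols = 6, k = 0.05,
                       color_start = c(90, 30, 140), color_end = c(240, 235, 90),
                       model = "first_order", duration = 300, fps = 1,
                       noise_sigma = 0, well_radius = 6, pitch = 18,
                       origin = c(12, 12), background = c(30, 30, 30),
                       blend = c("lab", "rgb"), seed = 1) {
  blend <- match.arg(blend)
  n <- rows * cols
  k <- rep_len(k, n)
  if (any(k <= 0)) abort("All per-well `k` must be > 0.")
  H <- origin[1] + (rows - 1) * pitch + well_radius + origin[1]
  W <- origin[2] + (cols - 1) * pitch + well_radius + origin[2]
  if (origin[1] < well_radius || origin[2] < well_radius) {
    abort("`origin` must leave room for the well radius.")
  }
  structure(list(rows = rows, cols = cols, k = k,
                 color_start = color_start, color_end = color_end,
                 model = match.arg(model, c("first_order", "second_order")),
                 duration = duration, fps = fps, noise_sigma = noise_sigma,
                 well_radius = well_radius, pitch = pitch, origin = origin,
                 background = background, geometry = c(ceiling(H), ceiling(W)),
                 blend = blend, seed = as.integer(seed)),
            class = "plate_spec")
}

#' Generate a synthetic well-plate video
#'
#' @param spec A [plate_spec()].
#' @return A list with `frames`, `rois` (the matching [roi_plate()]
#'   `roi_set`), and `truth` (tibble of `well`, `k`).
#' @export
gen_plate <- function(spec) {
  stopifnot(inherits(spec, "plate_spec"))
  geom <- spec$geometry
  rois <- roi_plate(spec$rows, spec$cols, geom, spec$well_radius,
                    origin = spec$origin, pitch = spec$pitch)
  nfr <- floor(spec$duration * spec$fps) + 1
  ts <- (seq_len(nfr) - 1) / spec$fps
  base <- array(rep(spec$background, each = geom[1] * geom[2]),
                dim = c(geom[1], geom[2], 3))
  masks <- lapply(rois$rois, function(r) r$mask)
  # per-well color programs: well_colors[[w]] is an nfr x 3 RGB matrix
  well_colors <- lapply(seq_len(spec$rows * spec$cols), function(w) {
    f <- fractional_conversion(ts, spec$model, spec$k[w])
    blend_colors(spec$color_start, spec$color_end, f, spec$blend)
  })
  frames <- with_local_seed(spec$seed, {
    lapply(seq_len(nfr), function(i) {
      px <- base
      for (w in seq_along(masks)) {
        col <- well_colors[[w]][i, ]
        for (ch in 1:3) {
          plane <- px[, , ch]
          plane[masks[[w]]] <- col[ch]
          px[, , ch] <- plane
        }
      }
      if (spec$noise_sigma > 0) {
        px <- px + array(rnorm(length(px), sd = spec$noise_sigma), dim = dim(px))
      }
      new_frame(pmin(pmax(px, 0), 255), t = ts[i], index = i - 1L)
    })
  })
  list(
    frames = frame_seq(frames),
    rois = rois,
    truth = tibble(well = names(rois$rois), k = spec$k)
  )
}
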