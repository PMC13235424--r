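# Per-ROI color traces: spatial mean color per frame, expressed in RGB,
# HSV and CIE-L*a*b*, with the CIE76 Delta E against a reference sample and
# the RGB sum response.

new_color_trace <- function(df, reference_index) {
  structure(
    as_tibble(df),
    reference_index = as.integer(reference_index),
    class = c("color_trace", class(as_tibble(df)))
  )
}

#' Build a per-ROI color trace from a frame sequence
#'
#' For each frame, the mean RGB over the ROI is computed and converted to
#' HSV and CIE-L*a*b*; Delta E (CIE76) is computed against the Lab color of
#' the reference sample (the first frame by default) and the RGB sum
#' response against pure white. Delta E is therefore 0 at the reference
#' sample and captures the cumulative color change elsewhere.
#'
#' @param frames A `frame_seq` with at least 2 frames.
#' @param roi An `roi` (defaults to the full frame).
#' @param reference_index 0-based sample index used as the Delta E
#'   reference (matches the `frame_index` column). Default 0 (first frame).
#' @return A `color_trace` tibble with columns `frame_index`, `t`, `roi`,
#'   `R`, `G`, `B`, `H`, `S`, `V`, `L`, `a`, `b`, `delta_e`, `rgb_sum`.
#' @export
build_trace <- function(frames, roi = NULL, reference_index = 0L) {
  if (!inherits(frames, "frame_seq")) frames <- frame_seq(frames)
  if (length(frames) < 2) abort("Need at least 2 frames to build a trace.")
  if (is.null(roi)) roi <- roi_full(frame_geometry(frames[[1]]))
  n <- length(frames)
  reference_index <- as.integer(reference_index)
  if (reference_index < 0 || reference_index >= n) {
    abort(sprintf("`reference_index` must be in [0, %d].", n - 1))
  }
  rgb <- t(vapply(frames, function(f) spatial_mean(f, roi), numeric(3)))
  hsv <- rgb_to_hsv(rgb)
  lab <- rgb_to_lab(rgb)
  ref_lab <- as.matrix(lab)[reference_index + 1L, , drop = FALSE]
  df <- tibble(
    frame_index = vapply(frames, function(f) f$index, integer(1)),
    t = frame_times(frames),
    roi = roi$name,
    R = rgb[, 1], G = rgb[, 2], B = rgb[, 3],
    H = hsv$h, S = hsv$s, V = hsv$v,
    L = lab$L, a = lab$a, b = lab$b,
    delta_e = delta_e_1976(ref_lab, lab),
    rgb_sum = rgb_sum_response(rgb)
  )
  new_color_trace(df, reference_index)
}

#' Build color traces for every ROI in a set
#'
#' @inheritParams build_trace
#' @param rois A `roi_set`.
#' @return A `color_trace` tibble with one block of rows per ROI.
#' @export
build_traces <- function(frames, rois, reference_index = 0L) {
  out <- purrr::map_dfr(rois$rois, function(roi) {
    build_trace(frames, roi, reference_index)
  })
  new_color_trace(out, reference_index)
}

#' Delta E reference sample of a trace
#' @param trace A `color_trace`.
#' @return The 0-based reference sample index.
#' @export
reference_index <- function(trace) attr(trace, "reference_index")

#' Thin a color trace to a lower effective frame rate
#'
#' Keeps samples 0, `keep_every`, `2 * keep_every`, ... (per ROI) and
#' re-anchors Delta E to the retained reference sample: if the original
#' reference sample survives the thinning it stays the reference, otherwise
#' the first retained sample takes over. This emulates recording (or
#' pruning to) a lower frame rate; transients shorter than the retained
#' spacing disappear from the thinned trace.
#'
#' @param trace A `color_trace`.
#' @param keep_every Positive integer decimation factor; 1 is the identity.
#' @return A `color_trace` with `ceiling(n / keep_every)` samples per ROI.
#' @export
resample_trace <- function(trace, keep_every) {
  keep_every <- as.integer(keep_every)
  if (is.na(keep_every) || keep_every < 1) abort("`keep_every` must be a positive integer.")
  ref <- reference_index(trace)
  thin_one <- function(df) {
    keep <- seq(1, nrow(df), by = keep_every)
    out <- df[keep, , drop = FALSE]
    ref_pos <- match(ref, out$frame_index)
    if (is.na(ref_pos)) ref_pos <- 1L
    ref_lab <- as.matrix(out[ref_pos, c("L", "a", "b")])
    out$delta_e <- delta_e_1976(ref_lab, as.matrix(out[, c("L", "a", "b")]))
    out
  }
  df <- trace
  class(df) <- c("tbl_df", "tbl", "data.frame")
  out <- df |>
    dplyr::group_by(.data$roi) |>
    dplyr::group_modify(~ thin_one(.x)) |>
    dplyr::ungroup() |>
    dplyr::relocate("roi", .after = "t")
  new_color_trace(out, ref)
}

#' Pixel-wise mean Delta E trace
#'
#' Whereas [build_trace()] averages color first and then takes Delta E
#' (the right order for a well-mixed vessel), this computes Delta E per
#' pixel against the same pixel of a reference frame and averages the
#' distances over the ROI. For spatially heterogeneous processes
#' (stirring, dissolution) the two differ fundamentally: a closed mixing
#' system conserves its mean color, so the mean-color Delta E stays near
#' zero while the pixel-wise Delta E tracks the rearrangement itself.
#' With `reference = "last"` the trace measures the distance from the
#' final (homogeneous) state; its fastest decay marks the phase of most
#' rapid homogenization.
#'
#' @param frames A `frame_seq`.
#' @param roi An `roi` (defaults to the full frame).
#' @param reference `"first"`, `"last"`, or a 0-based frame position.
#' @return A tibble with columns `frame_index`, `t`, `roi`, `mean_delta_e`.
#' @export
pixel_delta_e_trace <- function(frames, roi = NULL, reference = "first") {
  if (!inherits(frames, "frame_seq")) frames <- frame_seq(frames)
  if (length(frames) < 2) abort("Need at least 2 frames.")
  if (is.null(roi)) roi <- roi_full(frame_geometry(frames[[1]]))
  n <- length(frames)
  ref_pos <- if (identical(reference, "first")) 1L
             else if (identical(reference, "last")) n
             else as.integer(reference) + 1L
  if (is.na(ref_pos) || ref_pos < 1 || ref_pos > n) abort("Invalid `reference`.")
  m <- roi$mask
  lab_px <- function(f) {
    px <- f$pixels
    as.matrix(rgb_to_lab(cbind(px[, , 1][m], px[, , 2][m], px[, , 3][m])))
  }
  ref_lab <- lab_px(frames[[ref_pos]])
  tibble(
    frame_index = vapply(frames, function(f) f$index, integer(1)),
    t = frame_times(frames),
    roi = roi$name,
    mean_delta_e = vapply(frames, function(f) {
      mean(sqrt(rowSums((lab_px(f) - ref_lab)^2)))
    }, numeric(1))
  )
}

#' Pair a color trace with sparse offline measurements
#'
#' For each offline time point inside the trace's time span, the
#' nearest-in-time trace sample is selected (ties go to the earlier
#' sample). Offline points outside the span are dropped with a warning.
#' The paired vectors are suitable for [mutual_information()] or ordinary
#' linear correlation.
#'
#' @param trace A `color_trace` for a single ROI.
#' @param offline A data frame with columns `t` (seconds, strictly
#'   increasing) and `value` (the offline measurement, e.g. conversion).
#' @return A tibble with columns `t_offline`, `t_trace`, `frame_index`,
#'   `delta_e`, `value`.
#' @export
align_offline <- function(trace, offline) {
  if (length(unique(trace$roi)) != 1) {
    abort("`align_offline()` expects a single-ROI trace; filter first.")
  }
  if (!all(c("t", "value") %in% names(offline))) {
    abort("`offline` must have columns `t` and `value`.")
  }
  if (any(diff(offline$t) <= 0)) abort("Offline times must be strictly increasing.")
  if (any(!is.finite(offline$value))) abort("Offline values must be finite.")
  span <- range(trace$t)
  inside <- offline$t >= span[1] & offline$t <= span[2]
  if (any(!inside)) {
    warn(sprintf("%d offline point(s) outside the trace time span were dropped.",
                 sum(!inside)))
  }
  off <- offline[inside, , drop = FALSE]
  idx <- vapply(off$t, function(t0) {
    d <- abs(trace$t - t0)
    which(d == min(d))[1]  # ties -> earlier sample
  }, integer(1))
  tibble(
    t_offline = off$t,
    t_trace = trace$t[idx],
    frame_index = trace$frame_index[idx],
    delta_e = trace$delta_e[idx],
    value = off$value
  )
}

#' Write a trace to tidy CSV
#'
#' Numeric columns are written with 6 significant digits.
#'
#' @param trace A `color_trace` or `texture_trace` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  out <- dplyr::mutate(as_tibble(trace),
                       dplyr::across(dplyr::where(is.double), ~ signif(.x, 6)))
  names(out)[names(out) == "t"] <- "t_seconds"
  names(out)[names(out) == "entropy"] <- "entropy_bits"
  readr::write_csv(out, path)
  invisible(path)
}

#' Read an offline measurement series from CSV
#'
#' Expects two columns: time in seconds and the measured value
#' (`t_seconds,value` headers, or any two-column file).
#'
#' @param path CSV file path.
#' @return A tibble with columns `t` and `value`.
#' @export
read_offline <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (ncol(df) < 2) abort("Offline CSV must have two columns: time, value.")
  out <- tibble(t = as.numeric(df[[1]]), value = as.numeric(df[[2]]))
  if (any(diff(out$t) <= 0)) abort("Offline times must be strictly increasing.")
  out
}
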