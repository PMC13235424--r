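# Frame ingestion, YAML configuration, and the end-to-end pipeline:
# read -> ROIs -> color/texture traces -> kinetic summaries -> tidy CSV +
# JSON + provenance log.

VIDEO_EXTENSIONS <- c("mp4", "avi", "mov", "mkv", "webm", "m4v")

#' Read a frame sequence from a directory of still images
#'
#' Reads lexicographically ordered PNG (or TIFF) stills into a
#' `frame_seq`, decoding to RGB channel order regardless of the source
#' convention. Timestamps are `frame index / fps` of the source sequence;
#' with `sample_every = k`, every k-th source frame is retained (keeping
#' its original timestamp). Video containers are not decoded directly:
#' extract frames to numbered stills first (any frame-extraction tool can
#' write `frame_%05d.png`).
#'
#' @param path Directory containing the stills.
#' @param fps Frames per second of the source sequence (required for
#'   stills, which carry no rate metadata).
#' @param sample_every Keep every k-th frame (default 1 = all).
#' @return A `frame_seq`.
#' @export
read_frames <- function(path, fps = NULL, sample_every = 1) {
  sample_every <- as.integer(sample_every)
  if (is.na(sample_every) || sample_every < 1) abort("`sample_every` must be >= 1.")
  if (!file.exists(path)) abort(sprintf("Input path '%s' does not exist.", path))
  ext <- tolower(tools::file_ext(path))
  if (!dir.exists(path) && ext %in% VIDEO_EXTENSIONS) {
    abort(sprintf(paste0(
      "Cannot decode video container '%s' directly. ",
      "Extract frames to a directory of numbered PNG stills and point ",
      "`read_frames()` at that directory (with `fps` set to the recording rate)."
    ), path))
  }
  if (!dir.exists(path)) abort(sprintf("'%s' is neither a directory of stills nor a supported input.", path))
  if (is.null(fps)) abort("`fps` must be provided for still-image directories (no rate metadata).")
  files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0) abort(sprintf("No PNG/TIFF stills found under '%s'.", path))
  keep <- seq(1, length(files), by = sample_every)
  frames <- lapply(keep, function(i) {
    img <- read_still(files[i])
    new_frame(img, t = (i - 1) / fps, index = i - 1L)
  })
  frame_seq(frames)
}

read_still <- function(file) {
  ext <- tolower(tools::file_ext(file))
  img <- if (ext == "png") {
    png::readPNG(file)
  } else {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      abort("Reading TIFF stills requires the 'tiff' package.")
    }
    tiff::readTIFF(file)
  }
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  img * 255
}

#' Write a frame sequence as numbered PNG stills
#'
#' Lossless output (PNG avoids codec color shifts); files are named
#' `<prefix>_00000.png`, ... so they re-read in order.
#'
#' @param frames A `frame_seq`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return The directory path, invisibly.
#' @export
write_frames <- function(frames, dir, prefix = "frame") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(frames)) {
    png::writePNG(frames[[i]]$pixels / 255,
                  file.path(dir, sprintf("%s_%05d.png", prefix, i - 1)))
  }
  invisible(dir)
}

#' Build a `roi_set` from configuration entries
#'
#' Each entry is a list with a `type` field:
#' * `rect`: `rect: [top, left, height, width]` (+ optional `name`)
#' * `grid`: `rect: [...]`, `rows`, `cols`
#' * `plate`: `rows`, `cols`, `origin: [row, col]`, `pitch`, `radius`
#'
#' @param entries List of ROI config entries (e.g. from YAML).
#' @param geometry Frame geometry `c(H, W)`.
#' @return A `roi_set`.
#' @export
rois_from_config <- function(entries, geometry) {
  if (is.null(entries) || length(entries) == 0) {
    warn("No ROIs configured; using the full frame.")
    return(new_roi_set(list(roi_full(geometry)), geometry))
  }
  rois <- list()
  for (e in entries) {
    type <- e$type %||% "rect"
    if (type == "rect") {
      r <- e$rect
      rois <- c(rois, list(roi_rect(r[1], r[2], r[3], r[4], geometry,
                                    name = e$name %||% sprintf("rect%d", length(rois) + 1))))
    } else if (type == "grid") {
      r <- e$rect
      parent <- roi_rect(r[1], r[2], r[3], r[4], geometry)
      gs <- roi_grid(parent, e$rows, e$cols)
      rois <- c(rois, gs$rois)
    } else if (type == "plate") {
      ps <- roi_plate(e$rows, e$cols, geometry, e$radius,
                      origin = unlist(e$origin), pitch = e$pitch)
      rois <- c(rois, ps$rois)
    } else {
      abort(sprintf("Unknown ROI type '%s'.", type))
    }
  }
  new_roi_set(rois, geometry)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline from a configuration
#'
#' Executes read -> ROIs -> color trace (and optionally texture trace) ->
#' kinetic summary per ROI, and writes `traces.csv`,
#' `texture.csv` (if enabled), `summaries.json` and a provenance log
#' (`run.log`: config echo, package version, frame counts, seed) to the
#' output directory.
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#'   Recognized keys: `input` (`path`, `fps`, `sample_every`), `rois`
#'   (list of entries, see [rois_from_config()]), `analyses` (`color`,
#'   `texture`), `params` (`reference_index`, `window`, `eps_onset`,
#'   `eps_plateau`, `min_run`, `min_excursion`, `model`, `glcm_levels`,
#'   `glcm_offset`, `binarize_lo`, `binarize_hi`), `output_dir`, `seed`.
#' @param output_dir Optional override of the configured output directory.
#' @return Invisibly, a list with `traces`, `texture` (or `NULL`),
#'   `summaries`, and the output paths.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  out_dir <- output_dir %||% cfg$output_dir %||% abort("No output directory configured.")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
    log_lines <<- c(log_lines, line)
  }
  say("chromatrace %s", as.character(utils::packageVersion("chromatrace")))
  say("config: %s", gsub("\n", " | ", yaml::as.yaml(cfg)))
  seed <- cfg$seed %||% 1L
  say("seed: %d", as.integer(seed))

  inp <- cfg$input %||% abort("Config must name an `input`.")
  frames <- read_frames(inp$path, fps = inp$fps,
                        sample_every = inp$sample_every %||% 1)
  geom <- frame_geometry(frames[[1]])
  say("read %d frames (%d x %d px) from %s", length(frames), geom[1], geom[2], inp$path)

  rois <- withCallingHandlers(
    rois_from_config(cfg$rois, geom),
    warning = function(w) { say("warning: %s", conditionMessage(w)); invokeRestart("muffleWarning") }
  )
  say("%d ROI(s): %s", length(rois), paste(head(names(rois$rois), 20), collapse = ", "))

  p <- cfg$params %||% list()
  analyses <- cfg$analyses %||% list(color = TRUE, texture = FALSE)

  result <- list(output_dir = out_dir)
  step <- function(label, roi_name, expr) {
    tryCatch(expr, error = function(e) {
      say("ERROR in %s (roi %s): %s", label, roi_name, conditionMessage(e))
      writeLines(log_lines, log_path)
      abort(sprintf("Pipeline aborted in %s (roi %s): %s",
                    label, roi_name, conditionMessage(e)))
    })
  }

  if (isTRUE(analyses$color %||% TRUE)) {
    traces <- step("build_traces", "all",
                   build_traces(frames, rois, p$reference_index %||% 0L))
    trace_path <- file.path(out_dir, "traces.csv")
    write_trace_csv(traces, trace_path)
    say("wrote %s (%d rows)", trace_path, nrow(traces))
    summaries <- step("kinetic_summary", "all", kinetic_summary(
      traces,
      model = p$model %||% "first_order",
      window = p$window %||% 5,
      eps_onset = p$eps_onset %||% 0.1,
      eps_plateau = p$eps_plateau %||% 0.05,
      min_run = p$min_run %||% 3,
      min_excursion = p$min_excursion %||% 3
    ))
    sum_path <- file.path(out_dir, "summaries.json")
    jsonlite::write_json(summaries, sum_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    say("wrote %s (%d ROI summaries)", sum_path, nrow(summaries))
    result$traces <- traces
    result$summaries <- summaries
  }

  if (isTRUE(analyses$texture)) {
    lo <- unlist(p$binarize_lo %||% c(0, 0, 0))
    hi <- unlist(p$binarize_hi %||% c(127, 127, 127))
    tex <- purrr::map(rois$rois, function(roi) {
      bb <- apply(which(roi$mask, arr.ind = TRUE), 2, range)
      if (diff(bb[, 1]) < 1 || diff(bb[, 2]) < 1) {
        say("warning: texture skipped for ROI %s (bounding box too small for GLCM)", roi$name)
        return(NULL)
      }
      step("texture_trace", roi$name,
           texture_trace(frames, roi, lo, hi,
                         levels = p$glcm_levels %||% 16,
                         offset = unlist(p$glcm_offset %||% c(1, 1))))
    })
    tex <- dplyr::bind_rows(tex[!vapply(tex, is.null, logical(1))])
    if (nrow(tex) > 0) {
      tex_path <- file.path(out_dir, "texture.csv")
      write_trace_csv(tex, tex_path)
      say("wrote %s (%d rows)", tex_path, nrow(tex))
    }
    result$texture <- tex
  }

  writeLines(log_lines, log_path)
  result$log <- log_path
  invisible(result)
}

#' Run a synthetic-video generator from a spec config
#'
#' Reads a YAML spec (`kind: reaction | mixing | plate` plus the fields of
#' the matching `*_spec()`), generates the frames, and writes them as PNG
#' stills to `output_dir`.
#'
#' @param config Path to a YAML spec file, or an equivalent list.
#' @param output_dir Optional override.
#' @return Invisibly, the generator's return value.
#' @export
run_simulation <- function(config, output_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  out_dir <- output_dir %||% cfg$output_dir %||% abort("No output directory configured.")
  kind <- cfg$kind %||% abort("Spec config must name a `kind` (reaction/mixing/plate).")
  cfg$kind <- NULL; cfg$output_dir <- NULL
  for (nm in c("color_start", "color_end", "dye_color", "solvent_color",
               "background", "grid", "blob_center", "origin", "k")) {
    if (!is.null(cfg[[nm]])) cfg[[nm]] <- unlist(cfg[[nm]])
  }
  gen <- switch(kind,
    reaction = gen_reaction(do.call(reaction_spec, cfg)),
    mixing = gen_mixing(do.call(mixing_spec, cfg)),
    plate = gen_plate(do.call(plate_spec, cfg)),
    abort(sprintf("Unknown spec kind '%s'.", kind))
  )
  write_frames(gen$frames, out_dir)
  invisible(gen)
}
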