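#' Compose a masked Landolt-C stimulus sequence
#'
#' Renders the full frame sequence for one trial of a given condition:
#' per frame, the Landolt C is drawn at its path position, the opaque mask
#' elements are overdrawn at the background luminance (the mask occludes
#' the target), and the fixation cross is drawn at the origin. At the
#' default 75 Hz and 1/3 s duration a sequence has 25 frames. The target's
#' mid-trajectory center sits on the horizontal meridian at 10 deg
#' temporal eccentricity. Updating masks draw a fresh element pattern per
#' frame from a seeded stream, so sequences are bit-reproducible from
#' `seed` alone.
#'
#' For simulation efficiency, rendering can be restricted to the model
#' observer's analysis window (`window = "auto"`, a region centered on the
#' mid-trajectory target position covering three target diameters plus the
#' motion path); pixel values are identical to the corresponding region of
#' the full-canvas render.
#'
#' @param condition a [condition_spec()].
#' @param gap_size Landolt gap in arcmin (> 0); the target diameter is
#'   `5 * gap_size`.
#' @param orientation gap orientation, one of the four obliques.
#' @param seed integer seed controlling motion direction, shuffling and
#'   mask sampling.
#' @param display a [display_model()].
#' @param duration trial duration in seconds.
#' @param window `"auto"` (analysis window) or `"full"` (whole canvas).
#' @param window_factor analysis-window extent in target diameters.
#' @return an object of class `stimulus_sequence`: `frames` (list of
#'   luminance matrices), `geom` (window geometry), `target_positions`,
#'   `mask_positions`, `masks`, and the generating parameters.
#' @export
#' @examples
#' cond <- condition_spec("static_static", 0.5)
#' seq <- compose_sequence(cond, gap_size = 10, orientation = "upper-left",
#'                         seed = 7)
#' seq$n_frames # 25
compose_sequence <- function(condition, gap_size, orientation, seed,
                             display = display_model(), duration = 1 / 3,
                             window = c("auto", "full"), window_factor = 3) {
  stopifnot(inherits(condition, "condition_spec"))
  window <- match.arg(window)
  orientation <- match.arg(orientation, ORIENTATIONS)
  target <- landolt_target(gap_size, orientation) # validates gap_size
  app <- display$arcmin_per_pixel
  if (target$diameter < app)
    stop("degenerate stimulus: target diameter below one pixel")
  n_frames <- round(duration * display$frame_rate)
  if (n_frames < 1) stop("duration too short for one frame")
  ecc <- display$eccentricity

  draw_direction <- function(s)
    with_seed(s, sample(c("clockwise", "counterclockwise"), 1))

  target_path <- switch(condition$target_path_kind,
    static = static_path(n_frames, eccentricity = ecc),
    smooth_arc = smooth_arc_path(n_frames, eccentricity = ecc,
                                 direction = draw_direction(derive_seed(seed, 1)),
                                 display = display),
    shuffled_arc = shuffle_path(
      smooth_arc_path(n_frames, eccentricity = ecc,
                      direction = draw_direction(derive_seed(seed, 1)),
                      display = display),
      derive_seed(seed, 2))
  )
  mask_path <- switch(condition$mask_path_kind,
    static = static_path(n_frames, eccentricity = ecc),
    smooth_arc = smooth_arc_path(n_frames, eccentricity = ecc,
                                 direction = draw_direction(derive_seed(seed, 3)),
                                 display = display)
  )

  # the target's path must stay within the mask extent on every frame
  half_mask <- display$mask_extent / 2
  off <- abs(target_path$positions - mask_path$positions)
  if (any(off > half_mask))
    stop("coverage error: target path exits the mask extent")

  geom <- if (window == "full") {
    full_canvas_geom(display)
  } else {
    center <- c(display$eccentricity_arcmin, 0)
    span_x <- max(abs(target_path$positions[, 1] - center[1]))
    span_y <- max(abs(target_path$positions[, 2] - center[2]))
    half <- window_factor / 2 * target$diameter + 10 * app
    window_geom(display, center, half + span_x, half + span_y)
  }

  # mask element patterns: one fixed pattern, or one per frame
  if (condition$mask_regenerate_per_frame) {
    masks <- lapply(seq_len(n_frames), function(f)
      generate_mask(condition$density, derive_seed(seed, 10L + f), display,
                    regenerate_per_frame = TRUE))
  } else {
    masks <- list(generate_mask(condition$density, derive_seed(seed, 10L),
                                display))
  }

  bg <- display$background_luminance
  tl <- display$target_luminance
  fix_cov <- if (geom$x_tl - app / 2 <= display$fixation_size / 2 &&
                 window == "full") fixation_coverage(display, geom) else NULL

  static_mask_cov <- NULL
  mask_map <- NULL
  if (condition$mask_path_kind == "static") {
    if (!condition$mask_regenerate_per_frame) {
      static_mask_cov <- mask_coverage(masks[[1]], mask_path$positions[1, ],
                                       display, geom)
    } else {
      # fixed geometry, per-frame patterns: precompute the element map
      mask_map <- mask_index_map(masks[[1]], mask_path$positions[1, ],
                                 display, geom)
    }
  }

  # fully static trials have bit-identical frames; render once
  all_static <- condition$target_path_kind == "static" &&
    condition$mask_path_kind == "static" &&
    !condition$mask_regenerate_per_frame
  frames <- vector("list", n_frames)
  for (f in seq_len(if (all_static) 1L else n_frames)) {
    cov <- cpp_render_landolt(geom$ny, geom$nx, geom$x_tl, geom$y_tl, app,
                              target_path$positions[f, 1],
                              target_path$positions[f, 2],
                              target$diameter, target$axis[1],
                              target$axis[2], 4L)
    frame <- bg + cov * (tl - bg)
    mcov <- if (!is.null(static_mask_cov)) {
      static_mask_cov
    } else if (!is.null(mask_map)) {
      mask_coverage_from_index(mask_map, masks[[f]]$pattern, geom)
    } else {
      mask_coverage(masks[[if (length(masks) == 1) 1 else f]],
                    mask_path$positions[f, ], display, geom)
    }
    frame <- frame * (1 - mcov) + bg * mcov
    if (!is.null(fix_cov)) frame <- frame * (1 - fix_cov) + tl * fix_cov
    frames[[f]] <- frame
  }
  if (all_static) for (f in seq_len(n_frames)[-1]) frames[[f]] <- frames[[1]]

  structure(
    list(frames = frames, n_frames = n_frames, geom = geom,
         target_positions = target_path$positions,
         mask_positions = mask_path$positions,
         target_path_kind = target_path$kind,
         masks = masks, condition = condition, gap_size = gap_size,
         diameter = target$diameter, orientation = orientation,
         seed = seed, display = display),
    class = "stimulus_sequence"
  )
}

# Coverage of the 0.5 x 0.5 deg fixation cross (two orthogonal bars of
# width 3 pixels) over a window geometry; analytic pixel overlap.
fixation_coverage <- function(display, geom) {
  app <- display$arcmin_per_pixel
  half <- display$fixation_size / 2
  w <- 1.5 * app
  rect_cov <- function(x0, x1, y0, y1) {
    xs <- geom_x(geom); ys <- geom_y(geom)
    fx <- pmax(0, (pmin(x1, xs + app / 2) - pmax(x0, xs - app / 2)) / app)
    fy <- pmax(0, (pmin(y1, ys + app / 2) - pmax(y0, ys - app / 2)) / app)
    outer(fy, fx)
  }
  h <- rect_cov(-half, half, -w, w)
  v <- rect_cov(-w, w, -half, half)
  o <- rect_cov(-w, w, -w, w)
  h + v - o
}

#' @export
print.stimulus_sequence <- function(x, ...) {
  cat(sprintf(
    "<stimulus_sequence> %s, density %g: %d frames of %d x %d px, gap %.2f arcmin (%s)\n",
    x$condition$label, x$condition$density, x$n_frames, x$geom$ny, x$geom$nx,
    x$gap_size, x$orientation))
  invisible(x)
}

#' Export a stimulus sequence as a multi-page TIFF plus JSON sidecar
#'
#' Writes one 16-bit grayscale page per frame, luminance scaled as
#' cd/m^2 x 100, and a JSON sidecar recording the condition, gap,
#' orientation, seed and per-frame path coordinates.
#'
#' @param sequence a [compose_sequence()] result.
#' @param path output TIFF file path; the sidecar is written alongside
#'   with extension `.json`.
#' @return `path`, invisibly.
#' @export
write_stimulus_tiff <- function(sequence, path) {
  stopifnot(inherits(sequence, "stimulus_sequence"))
  pages <- lapply(sequence$frames, function(f) f * 100 / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = TRUE)
  sidecar <- list(
    condition = sequence$condition$label,
    density = sequence$condition$density,
    gap_arcmin = sequence$gap_size,
    orientation = sequence$orientation,
    seed = sequence$seed,
    n_frames = sequence$n_frames,
    luminance_scale = "cd/m^2 x 100, 16-bit",
    target_path = apply(sequence$target_positions, 1, function(p)
      list(x = p[1], y = p[2])),
    mask_path = apply(sequence$mask_positions, 1, function(p)
      list(x = p[1], y = p[2]))
  )
  jsonlite::write_json(sidecar, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
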