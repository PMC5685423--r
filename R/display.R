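#' Physical display model
#'
#' Describes the rendering context of the simulated CRT presentation: frame
#' rate, angular pixel size, the two luminances, the target eccentricity and
#' the occluder-mask geometry. All lengths are in arcmin of visual angle;
#' luminances in cd/m^2. Defaults reproduce the experimental apparatus: a
#' 75 Hz display with 1.05 arcmin pixels, white 85 cd/m^2 targets on a gray
#' 45 cd/m^2 background, targets at 10 deg eccentricity on the horizontal
#' meridian of the temporal field, and a 7 x 7 deg mask of 5.25 arcmin
#' elements (an 80 x 80 element grid).
#'
#' The canvas is the rasterized region: a pixel grid that contains the
#' fixation cross (at the coordinate origin) and the whole mask at every
#' position along the configured motion paths, with margin to spare.
#' Coordinates are arcmin offsets from fixation, x positive temporal
#' (rightward), y positive up; images are matrices with row 1 at the top.
#'
#' @param frame_rate frames per second (Hz).
#' @param arcmin_per_pixel angular size of one display pixel (arcmin).
#' @param background_luminance gray background level (cd/m^2).
#' @param target_luminance level of target and fixation cross (cd/m^2);
#'   must exceed the background.
#' @param eccentricity target eccentricity (deg).
#' @param mask_extent side length of the square occluder mask (arcmin).
#' @param element_size side length of one mask element (arcmin).
#' @param path_margin extra canvas allowance for moving masks (arcmin).
#' @return an object of class `display_model`.
#' @export
#' @examples
#' disp <- display_model()
#' disp$n_elements # 80 x 80 mask grid
display_model <- function(frame_rate = 75,
                          arcmin_per_pixel = 1.05,
                          background_luminance = 45,
                          target_luminance = 85,
                          eccentricity = 10,
                          mask_extent = 420,
                          element_size = 5.25,
                          path_margin = 30) {
  if (frame_rate <= 0) stop("frame_rate must be positive")
  if (arcmin_per_pixel <= 0) stop("arcmin_per_pixel must be positive")
  if (target_luminance <= background_luminance)
    stop("target_luminance must exceed background_luminance")
  if (mask_extent <= 0 || element_size <= 0 || mask_extent < element_size)
    stop("invalid mask geometry")
  n_side <- round(mask_extent / element_size)
  if (abs(n_side * element_size - mask_extent) > 1e-9)
    stop("mask_extent must be an integer multiple of element_size")
  app <- arcmin_per_pixel
  ecc_arcmin <- eccentricity * 60
  half_mask <- mask_extent / 2
  margin <- 10 * app
  # canvas bounds: fixation cross (0.5 deg square at origin) .. mask at any
  # path position (x centered near the eccentricity point, y within
  # +/- path_margin of the meridian)
  x_min <- -(15 + margin)
  x_max <- ecc_arcmin + half_mask + margin
  y_max <- half_mask + path_margin + margin
  nx <- ceiling((x_max - x_min) / app)
  ny <- 2 * ceiling(y_max / app)
  canvas <- list(
    x_left = x_min,              # left edge of pixel (., 1)
    y_top = y_min_top(y_max, ny, app), # top edge of pixel (1, .)
    nx = as.integer(nx),
    ny = as.integer(ny)
  )
  structure(
    list(
      frame_rate = frame_rate,
      arcmin_per_pixel = app,
      background_luminance = background_luminance,
      target_luminance = target_luminance,
      eccentricity = eccentricity,
      eccentricity_arcmin = ecc_arcmin,
      mask_extent = mask_extent,
      element_size = element_size,
      n_side = as.integer(n_side),
      n_elements = as.integer(n_side)^2,
      path_margin = path_margin,
      fixation_size = 30,        # 0.5 deg cross
      canvas = canvas
    ),
    class = "display_model"
  )
}

# symmetric-about-meridian top edge for an even pixel count
y_min_top <- function(y_max, ny, app) (ny / 2) * app

#' @export
print.display_model <- function(x, ...) {
  cat("<display_model>\n")
  cat(sprintf("  %g Hz, %g arcmin/pixel\n", x$frame_rate, x$arcmin_per_pixel))
  cat(sprintf("  luminance %g (background) / %g (target) cd/m^2\n",
              x$background_luminance, x$target_luminance))
  cat(sprintf("  target eccentricity %g deg; mask %g x %g arcmin (%d x %d elements of %g arcmin)\n",
              x$eccentricity, x$mask_extent, x$mask_extent,
              x$n_side, x$n_side, x$element_size))
  cat(sprintf("  canvas %d x %d pixels\n", x$canvas$ny, x$canvas$nx))
  invisible(x)
}

# --- canvas geometry helpers (internal) -------------------------------------

# A `geom` describes a rectangular pixel window on the canvas grid:
# x_tl / y_tl are the arcmin coordinates of the *center* of its top-left
# pixel, nx / ny its size, row_off / col_off its 0-based offset within the
# full canvas.
full_canvas_geom <- function(display) {
  cv <- display$canvas
  app <- display$arcmin_per_pixel
  list(x_tl = cv$x_left + app / 2, y_tl = cv$y_top - app / 2,
       nx = cv$nx, ny = cv$ny, row_off = 0L, col_off = 0L,
       arcmin_per_pixel = app)
}

# Window of the canvas covering [cx-hw, cx+hw] x [cy-hh, cy+hh], snapped to
# the canvas pixel grid and clipped to it.
window_geom <- function(display, center, half_w, half_h = half_w) {
  cv <- display$canvas
  app <- display$arcmin_per_pixel
  c_lo <- max(1L, 1L + floor((center[1] - half_w - cv$x_left) / app))
  c_hi <- min(cv$nx, ceiling((center[1] + half_w - cv$x_left) / app))
  r_lo <- max(1L, 1L + floor((cv$y_top - (center[2] + half_h)) / app))
  r_hi <- min(cv$ny, ceiling((cv$y_top - (center[2] - half_h)) / app))
  if (c_hi < c_lo || r_hi < r_lo) stop("analysis window is empty")
  list(x_tl = cv$x_left + (c_lo - 0.5) * app,
       y_tl = cv$y_top - (r_lo - 0.5) * app,
       nx = as.integer(c_hi - c_lo + 1L), ny = as.integer(r_hi - r_lo + 1L),
       row_off = as.integer(r_lo - 1L), col_off = as.integer(c_lo - 1L),
       arcmin_per_pixel = app)
}

# coordinates of pixel centers of a geom
geom_x <- function(geom) geom$x_tl + (seq_len(geom$nx) - 1) * geom$arcmin_per_pixel
geom_y <- function(geom) geom$y_tl - (seq_len(geom$ny) - 1) * geom$arcmin_per_pixel
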