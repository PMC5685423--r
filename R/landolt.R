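ORIENTATIONS <- c("lower-left", "lower-right", "upper-left", "upper-right")
ORIENTATION_ANGLE <- c("lower-left" = 225, "lower-right" = 315,
                       "upper-left" = 135, "upper-right" = 45)

#' Landolt-C target specification
#'
#' A geometric Landolt ring: annulus of outer diameter `diameter`, stroke
#' width fixed at 20% of the diameter, with a square-profile gap of width
#' 20% of the diameter cut along one of the four oblique directions. The
#' gap is the critical detail of the optotype; the adaptive procedure
#' manipulates `gap_size` and the diameter follows as `5 * gap_size`.
#'
#' @param gap_size gap width in arcmin (> 0).
#' @param orientation one of `"lower-left"`, `"lower-right"`,
#'   `"upper-left"`, `"upper-right"` (gap centered at polar angle 225, 315,
#'   135, 45 deg respectively).
#' @return an object of class `landolt_target` with fields `diameter`,
#'   `gap_size`, `stroke_width`, `orientation` and the unit gap-axis vector.
#' @export
#' @examples
#' landolt_target(6, "upper-right")$diameter # 30 arcmin
landolt_target <- function(gap_size, orientation = "upper-right") {
  if (!is.numeric(gap_size) || length(gap_size) != 1 || !is.finite(gap_size) ||
      gap_size <= 0)
    stop("gap_size must be a single positive number (arcmin)")
  orientation <- match.arg(orientation, ORIENTATIONS)
  diameter <- 5 * gap_size
  ang <- ORIENTATION_ANGLE[[orientation]] * pi / 180
  structure(
    list(diameter = diameter, gap_size = gap_size,
         stroke_width = 0.2 * diameter, orientation = orientation,
         axis = c(cos(ang), sin(ang))),
    class = "landolt_target"
  )
}

#' Render a Landolt C as a luminance image
#'
#' Rasterizes the ring at an arbitrary (sub-pixel) position on the canvas
#' pixel grid. Rendering supersamples each pixel 4 x 4 and area-averages,
#' so edges are anti-aliased; pixel values run from the background to the
#' target luminance.
#'
#' @param target a [landolt_target()].
#' @param position length-2 numeric, arcmin coordinates of the ring center
#'   relative to fixation.
#' @param display a [display_model()].
#' @param geom optional window geometry (internal); defaults to the full
#'   canvas.
#' @param supersample supersampling factor per axis.
#' @return numeric matrix of luminances (cd/m^2).
#' @export
render_landolt <- function(target, position, display = display_model(),
                           geom = NULL, supersample = 4) {
  stopifnot(inherits(target, "landolt_target"))
  app <- display$arcmin_per_pixel
  if (target$diameter < app)
    stop("degenerate stimulus: target diameter below one pixel")
  if (is.null(geom)) geom <- full_canvas_geom(display)
  half <- target$diameter / 2 + app
  cv <- display$canvas
  if (position[1] - half < cv$x_left ||
      position[1] + half > cv$x_left + cv$nx * app ||
      position[2] + half > cv$y_top ||
      position[2] - half < cv$y_top - cv$ny * app)
    stop("clipping error: target position outside canvas")
  cov <- cpp_render_landolt(geom$ny, geom$nx, geom$x_tl, geom$y_tl, app,
                            position[1], position[2], target$diameter,
                            target$axis[1], target$axis[2],
                            as.integer(supersample))
  display$background_luminance +
    cov * (display$target_luminance - display$background_luminance)
}

# Analytic area of the rendered glyph (annulus minus gap slot), arcmin^2.
# Used as an independent check on rasterization.
landolt_area <- function(target) {
  R <- target$diameter / 2
  r <- 0.3 * target$diameter
  w2 <- 0.1 * target$diameter # half width of the slot
  seg <- function(a, t) (t * sqrt(a^2 - t^2) + a^2 * asin(t / a)) / 2
  strip <- 4 * (seg(R, w2) - seg(r, w2)) # full strip through the annulus
  pi * (R^2 - r^2) - strip / 2           # gap removes one side only
}
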