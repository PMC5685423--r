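#' Generate an occluder mask pattern
#'
#' The mask is a square grid of `n_side` x `n_side` elements (80 x 80 at
#' the default 7 deg extent with 5.25 arcmin elements). A mask of density
#' `d` has exactly `round(d * n_side^2)` opaque elements, drawn uniformly
#' without replacement; opaque elements are rendered at the background
#' luminance, so they occlude the target without being visible against the
#' background.
#'
#' @param density fraction of opaque elements, in \[0, 1\].
#' @param seed integer seed; equal seeds give identical patterns.
#' @param display a [display_model()] (supplies the grid geometry).
#' @param regenerate_per_frame logical, recorded on the returned object:
#'   whether a sequence using this spec redraws the pattern on every frame.
#' @return an object of class `mask_spec` with the opacity `pattern`
#'   (0/1 integer matrix, row 1 = top row of the mask) and `opaque_set`
#'   (sorted linear element indices).
#' @export
#' @examples
#' m <- generate_mask(0.5, seed = 1)
#' length(m$opaque_set) # 3200
generate_mask <- function(density, seed, display = display_model(),
                          regenerate_per_frame = FALSE) {
  if (!is.numeric(density) || length(density) != 1 || is.na(density) ||
      density < 0 || density > 1)
    stop("density must be a single number in [0, 1]")
  n_side <- display$n_side
  n <- n_side^2
  k <- round(density * n)
  pattern <- matrix(0L, n_side, n_side)
  if (k == n) {
    pattern[] <- 1L
  } else if (k > 0) {
    # draw the smaller of the opaque/transparent sets for speed; both
    # give a uniform draw of k opaque elements without replacement
    if (k <= n / 2) {
      pattern[with_seed(seed, sample.int(n, k))] <- 1L
    } else {
      pattern[] <- 1L
      pattern[with_seed(seed, sample.int(n, n - k))] <- 0L
    }
  }
  idx <- which(pattern == 1L)
  structure(
    list(density = density, n_side = n_side, opaque_set = idx,
         pattern = pattern, element_size = display$element_size,
         regenerate_per_frame = isTRUE(regenerate_per_frame), seed = seed),
    class = "mask_spec"
  )
}

# Coverage image of a mask pattern centered at `center` (arcmin), over a
# window geometry. Supersampled so partially covered border pixels get
# fractional opacity.
mask_coverage <- function(mask, center, display, geom, supersample = 4) {
  half <- mask$n_side * mask$element_size / 2
  cpp_mask_coverage(geom$ny, geom$nx, geom$x_tl, geom$y_tl,
                    display$arcmin_per_pixel,
                    center[1] - half, center[2] + half,
                    mask$element_size, mask$pattern,
                    as.integer(supersample))
}

# For masks whose position is fixed across frames: precompute the
# subsample-to-element index map once, then resolve each frame's pattern
# against it (used for per-frame regenerated masks).
mask_index_map <- function(mask, center, display, geom, supersample = 4) {
  half <- mask$n_side * mask$element_size / 2
  cpp_mask_index(geom$ny, geom$nx, geom$x_tl, geom$y_tl,
                 display$arcmin_per_pixel,
                 center[1] - half, center[2] + half,
                 mask$element_size, mask$n_side, as.integer(supersample))
}

mask_coverage_from_index <- function(map, pattern, geom) {
  matrix(cpp_mask_cov_indexed(map, pattern), geom$ny, geom$nx)
}
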