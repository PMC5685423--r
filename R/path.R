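#' Smooth isoeccentric arc path
#'
#' Per-frame target (or mask) center positions along a circle of constant
#' eccentricity about fixation, moving at constant angular speed. The path
#' is centered on the horizontal meridian of the temporal field: start and
#' end positions are equally spaced above and below it, and the
#' middle-of-trajectory position lies exactly on the meridian. Consecutive
#' positions are separated by an arc of `speed / frame_rate`.
#'
#' @param n_frames number of frames (>= 1).
#' @param speed angular speed along the arc (deg/s).
#' @param eccentricity radius of the arc (deg from fixation).
#' @param direction `"counterclockwise"` (upward through the meridian) or
#'   `"clockwise"`.
#' @param display a [display_model()] (supplies the frame rate).
#' @return an object of class `motion_path`: `kind`, `positions`
#'   (`n_frames` x 2 matrix of arcmin coordinates), `eccentricity`,
#'   `speed`, `direction`.
#' @export
#' @examples
#' p <- smooth_arc_path(25)
#' sqrt(rowSums(p$positions^2))[1] / 60 # 10 deg
smooth_arc_path <- function(n_frames, speed = 2, eccentricity = 10,
                            direction = c("counterclockwise", "clockwise"),
                            display = display_model()) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (eccentricity <= 0) stop("eccentricity must be positive")
  if (speed < 0) stop("speed must be non-negative")
  direction <- match.arg(direction)
  ecc <- eccentricity * 60
  step <- (speed * 60 / display$frame_rate) / ecc # radians per frame
  sgn <- if (direction == "counterclockwise") 1 else -1
  theta <- sgn * (seq_len(n_frames) - (n_frames + 1) / 2) * step
  structure(
    list(kind = "smooth_arc",
         positions = cbind(x = ecc * cos(theta), y = ecc * sin(theta)),
         theta = theta, eccentricity = eccentricity, speed = speed,
         direction = direction),
    class = "motion_path"
  )
}

#' Static path
#'
#' Degenerate path keeping the object at one position for every frame
#' (default: the eccentricity point on the horizontal meridian).
#'
#' @inheritParams smooth_arc_path
#' @param position length-2 arcmin coordinates; default 10 deg temporal.
#' @return a `motion_path` of kind `"static"`.
#' @export
static_path <- function(n_frames, position = NULL, eccentricity = 10) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (is.null(position)) position <- c(eccentricity * 60, 0)
  structure(
    list(kind = "static",
         positions = cbind(x = rep(position[1], n_frames),
                           y = rep(position[2], n_frames)),
         eccentricity = eccentricity, speed = 0, direction = "none"),
    class = "motion_path"
  )
}

#' Shuffle the frame order of a smooth path
#'
#' Produces the unpredictable-motion path: the same multiset of per-frame
#' positions as the smooth arc, presented in a seeded uniform random order.
#'
#' @param path a `motion_path` of kind `"smooth_arc"`.
#' @param seed integer seed; equal seeds give equal permutations.
#' @return a `motion_path` of kind `"shuffled_arc"` with the permutation
#'   recorded in `order`.
#' @export
shuffle_path <- function(path, seed) {
  stopifnot(inherits(path, "motion_path"))
  if (path$kind != "smooth_arc")
    stop("shuffle_path() requires a smooth_arc path")
  n <- nrow(path$positions)
  ord <- if (n == 1) 1L else with_seed(seed, sample.int(n))
  out <- path
  out$kind <- "shuffled_arc"
  out$positions <- path$positions[ord, , drop = FALSE]
  out$theta <- path$theta[ord]
  out$order <- ord
  out
}
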