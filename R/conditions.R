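CONDITION_LABELS <- c("static_static", "smooth_static",
                      "static_updating", "smooth_updating",
                      "static_smoothmask", "shuffled_static")

#' Overview of the six experimental conditions
#'
#' @return a tibble with one row per condition: label, target path kind,
#'   mask path kind, and whether the mask element pattern is regenerated on
#'   every frame.
#' @export
conditions <- function() {
  tibble::tibble(
    label = CONDITION_LABELS,
    target_path = c("static", "smooth_arc", "static", "smooth_arc",
                    "static", "shuffled_arc"),
    mask_path = c("static", "static", "static", "static",
                  "smooth_arc", "static"),
    mask_updating = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
    description = c(
      "static target behind a static, fixed-pattern mask",
      "target moves along the isoeccentric arc; mask static, fixed pattern",
      "static target; mask pattern regenerated on every frame",
      "moving target; mask pattern regenerated on every frame",
      "static target; fixed-pattern mask moves along the arc",
      "target visits the smooth-path locations in shuffled order; mask static"
    )
  )
}

#' Condition specification
#'
#' Binds one of the six target/mask dynamic conditions to a mask density.
#'
#' @param label one of `conditions()$label`.
#' @param density opaque element fraction in \[0, 1\].
#' @return an object of class `condition_spec`.
#' @export
#' @examples
#' condition_spec("smooth_static", 0.75)
condition_spec <- function(label, density) {
  label <- match.arg(label, CONDITION_LABELS)
  if (!is.numeric(density) || length(density) != 1 || is.na(density) ||
      density < 0 || density > 1)
    stop("density must be a single number in [0, 1]")
  info <- conditions()
  row <- info[info$label == label, ]
  structure(
    list(label = label,
         target_path_kind = row$target_path,
         mask_path_kind = row$mask_path,
         mask_regenerate_per_frame = row$mask_updating,
         density = density),
    class = "condition_spec"
  )
}
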