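#' Default pipeline configuration
#'
#' The complete set of tunable parameters of the simulation, grouped as
#' `display`, `conditions`, `observer`, `staircase`, `fit` and
#' `experiment` blocks. [read_config()] merges a user JSON or YAML file
#' over these defaults.
#'
#' @return a nested list of defaults.
#' @export
default_config <- function() {
  list(
    display = list(frame_rate = 75, arcmin_per_pixel = 1.05,
                   background_luminance = 45, target_luminance = 85,
                   eccentricity = 10, mask_extent = 420,
                   element_size = 5.25),
    conditions = list(labels = CONDITION_LABELS,
                      densities = c(0, 0.5, 0.75),
                      duration = 1 / 3),
    observer = list(strategy = "super_resolution", blur_sigma = 2.5,
                    noise_sd = 4, sample_pitch = 0,
                    motion_knowledge = "oracle", window_factor = 3,
                    est_max_shift = 8, est_decimate = 3,
                    est_trajectory = "linear", jitter_sdlog = 0.2),
    staircase = list(initial_gap = 17.8, initial_step = 4.5,
                     max_reversals = 8, max_trials = 50, gap_floor = 1.05),
    fit = list(n_boot = 1000, bootstrap_unit = "trial"),
    experiment = list(n_subjects = 8, n_runs = 10)
  )
}

#' Read a configuration file
#'
#' Reads a JSON or YAML configuration (by extension) and merges it
#' recursively over [default_config()]; unspecified entries keep their
#' defaults.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return the merged configuration list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  user <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("config must be .json, .yaml or .yml"))
  merge_lists(default_config(), user)
}

merge_lists <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_lists(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}
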