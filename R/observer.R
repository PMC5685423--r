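#' Model-observer parameters
#'
#' Configuration of the synthetic subject that replaces a human observer.
#' The observer sees each frame through a peripheral front end (Gaussian
#' blur, optionally a coarse canvas-fixed sampling lattice, and additive
#' Gaussian internal noise) and converts the evidence into a 4AFC response
#' by template correlation under one of three strategies:
#'
#' * `single_frame`: decide on the middle frame only.
#' * `prob_summation`: decide on every frame independently and pool with a
#'   max rule over per-orientation evidence (probability summation: more
#'   independent looks, no cross-frame integration).
#' * `super_resolution`: register all frames to the middle frame
#'   (shift-and-add) and decide on the merged composite.
#'
#' @param strategy decision strategy (see above).
#' @param blur_sigma front-end Gaussian blur scale (arcmin).
#' @param noise_sd per-frame additive internal noise SD (cd/m^2).
#' @param sample_pitch pitch of the canvas-fixed sampling lattice (arcmin);
#'   `0` disables the lattice. The lattice phase is redrawn per trial
#'   (fixation varies between trials) but fixed within a trial.
#' @param motion_knowledge how the super-resolution observer registers
#'   frames: `"oracle"` (true path metadata), `"estimated"` (chained
#'   pairwise cross-correlation shift estimates), or `"none"` (zero
#'   shifts).
#' @param window_factor decision-window extent in target diameters.
#' @param est_max_shift short-range motion prior for `"estimated"`
#'   registration: the largest admissible inter-frame displacement
#'   (arcmin). Displacements beyond it cannot be registered — this is
#'   what makes unpredictable (frame-shuffled) trajectories hard to
#'   co-register while smooth ones remain easy.
#' @param est_decimate decimation factor for the motion-estimation stage
#'   (shift estimation runs on the decision region at reduced
#'   resolution; registration itself stays at full resolution).
#' @param est_trajectory `"linear"` (default) fits a constant-velocity
#'   trajectory to the chained shift estimates before registering —
#'   the model's use of trajectory predictability; `"raw"` uses the
#'   chained estimates directly.
#' @return an object of class `observer_params`.
#' @export
observer_params <- function(strategy = c("super_resolution", "single_frame",
                                         "prob_summation"),
                            blur_sigma = 2.5, noise_sd = 4,
                            sample_pitch = 0,
                            motion_knowledge = c("oracle", "estimated", "none"),
                            window_factor = 3, est_max_shift = 8,
                            est_decimate = 3L,
                            est_trajectory = c("linear", "raw")) {
  strategy <- match.arg(strategy)
  motion_knowledge <- match.arg(motion_knowledge)
  est_trajectory <- match.arg(est_trajectory)
  if (blur_sigma < 0 || noise_sd < 0 || sample_pitch < 0)
    stop("blur_sigma, noise_sd and sample_pitch must be >= 0")
  if (est_max_shift <= 0 || est_decimate < 1)
    stop("est_max_shift must be positive and est_decimate >= 1")
  structure(
    list(strategy = strategy, blur_sigma = blur_sigma, noise_sd = noise_sd,
         sample_pitch = sample_pitch, motion_knowledge = motion_knowledge,
         window_factor = window_factor, est_max_shift = est_max_shift,
         est_decimate = as.integer(est_decimate),
         est_trajectory = est_trajectory),
    class = "observer_params"
  )
}

#' Peripheral front end
#'
#' Applies the observer's early visual transform to one luminance frame:
#' Gaussian blur of scale `blur_sigma`, optional averaging over the coarse
#' sampling lattice, then independent zero-mean Gaussian pixel noise of SD
#' `noise_sd`. With all parameters zero the image passes through
#' unchanged.
#'
#' @param image luminance matrix.
#' @param params an [observer_params()].
#' @param seed integer seed for the noise draw (required when
#'   `noise_sd > 0`).
#' @param phase length-2 integer lattice phase (row, col) in pixels.
#' @param arcmin_per_pixel pixel size used to convert arcmin parameters.
#' @return the internal-response matrix.
#' @export
front_end <- function(image, params, seed = NULL, phase = c(0L, 0L),
                      arcmin_per_pixel = 1.05) {
  stopifnot(inherits(params, "observer_params"))
  if (!all(is.finite(c(params$blur_sigma, params$noise_sd))))
    stop("blur_sigma and noise_sd must be finite")
  out <- image
  if (params$blur_sigma > 0)
    out <- cpp_gaussian_blur(out, params$blur_sigma / arcmin_per_pixel)
  p <- round(params$sample_pitch / arcmin_per_pixel)
  if (p > 1)
    out <- cpp_block_sample(out, as.integer(p),
                            as.integer(phase[1] %% p),
                            as.integer(phase[2] %% p))
  if (params$noise_sd > 0) {
    if (is.null(seed)) stop("a seed is required when noise_sd > 0")
    out <- with_seed(seed, cpp_add_noise(out, params$noise_sd))
  }
  out
}

#' Estimate the translation between two frames
#'
#' Normalized cross-correlation (computed via FFT over circular shifts)
#' between two equally sized internal-response frames, with quadratic
#' sub-pixel interpolation around the correlation peak. Returns the shift
#' of `frame_b`'s content relative to `frame_a` in arcmin, and the peak
#' correlation as a confidence in \[-1, 1\].
#'
#' @param frame_a,frame_b numeric matrices of identical size.
#' @param arcmin_per_pixel pixel size (arcmin).
#' @param max_shift optional cap on the admissible shift magnitude per
#'   axis (arcmin); the peak is searched within it.
#' @return a list with `shift` (x, y arcmin) and `confidence`.
#' @export
estimate_shift <- function(frame_a, frame_b, arcmin_per_pixel = 1.05,
                           max_shift = NULL) {
  if (!all(dim(frame_a) == dim(frame_b)))
    stop("frames must have the same shape")
  ncc_peak(prep_ncc(frame_a), prep_ncc(frame_b), arcmin_per_pixel, max_shift)
}

# Mean-removed FFT of a frame, optionally zero-padded to a composite size
# for FFT efficiency, plus its norm.
prep_ncc <- function(img, pad_dim = NULL) {
  z <- img - mean(img)
  nrm <- sqrt(sum(z^2))
  if (nrm == 0) stop("undefined correlation: zero-variance frame")
  if (!is.null(pad_dim) && any(pad_dim > dim(z))) {
    p <- matrix(0, pad_dim[1], pad_dim[2])
    p[seq_len(nrow(z)), seq_len(ncol(z))] <- z
    z <- p
  }
  list(F = stats::fft(z), norm = nrm, n = length(z))
}

# Correlation-surface peak between two prepared frames; shift of b's
# content relative to a, in arcmin, with quadratic sub-pixel refinement.
ncc_peak <- function(pa, pb, arcmin_per_pixel, max_shift = NULL) {
  # conj(F_a) * F_b peaks at the displacement of b's content relative to a
  cc <- Re(stats::fft(Conj(pa$F) * pb$F, inverse = TRUE)) /
    (pa$n * pa$norm * pb$norm)
  n <- nrow(cc); m <- ncol(cc)
  sh_r <- ifelse(0:(n - 1) <= n %/% 2, 0:(n - 1), 0:(n - 1) - n)
  sh_c <- ifelse(0:(m - 1) <= m %/% 2, 0:(m - 1), 0:(m - 1) - m)
  if (!is.null(max_shift)) {
    lim <- max_shift / arcmin_per_pixel
    cc[abs(sh_r) > lim, ] <- -Inf
    cc[, abs(sh_c) > lim] <- -Inf
  }
  pk <- arrayInd(which.max(cc), dim(cc))
  pi_ <- pk[1]; pj <- pk[2]
  peak <- cc[pi_, pj]
  refine <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (!is.finite(den) || den >= 0 || !is.finite(cm) || !is.finite(cp))
      return(0)
    max(-0.5, min(0.5, 0.5 * (cm - cp) / den))
  }
  wrap <- function(i, n) ((i - 1) %% n) + 1
  dr <- refine(cc[wrap(pi_ - 1, n), pj], peak, cc[wrap(pi_ + 1, n), pj])
  dc <- refine(cc[pi_, wrap(pj - 1, m)], peak, cc[pi_, wrap(pj + 1, m)])
  drow <- sh_r[pi_] + dr
  dcol <- sh_c[pj] + dc
  # rows increase downwards: content moving up (y+) decreases its row
  list(shift = c(x = dcol * arcmin_per_pixel, y = -drow * arcmin_per_pixel),
       confidence = peak)
}

#' Shift-and-add accumulation
#'
#' Registers a sequence of internal-response frames to a common reference
#' and averages them. Each frame is translated by the negative of its
#' `shift` (its target displacement relative to the reference frame), so
#' target structure aligns across frames; pixels that fall outside a
#' frame after translation are excluded from that frame's average via the
#' per-pixel sample count.
#'
#' @param frames list of equally sized matrices.
#' @param shifts `n x 2` matrix of (x, y) arcmin displacements, one row
#'   per frame.
#' @param arcmin_per_pixel pixel size (arcmin).
#' @return list with `composite` (weighted mean image) and `counts`
#'   (per-pixel effective sample count).
#' @export
accumulate_sr <- function(frames, shifts, arcmin_per_pixel = 1.05) {
  n <- length(frames)
  shifts <- matrix(shifts, ncol = 2)
  if (nrow(shifts) != n)
    stop("need exactly one shift per frame")
  acc <- 0
  wacc <- 0
  ones <- matrix(1, nrow(frames[[1]]), ncol(frames[[1]]))
  for (f in seq_len(n)) {
    drow <- shifts[f, 2] / arcmin_per_pixel  # undo: content moves by -shift
    dcol <- -shifts[f, 1] / arcmin_per_pixel
    if (drow == 0 && dcol == 0) {
      acc <- acc + frames[[f]]
      wacc <- wacc + ones
    } else {
      acc <- acc + cpp_translate(frames[[f]], drow, dcol, 0)
      wacc <- wacc + cpp_translate(ones, drow, dcol, 0)
    }
  }
  w <- pmax(wacc, 1e-12)
  composite <- acc / w
  # pixels never covered by any frame: fill with the composite mean so they
  # carry no structure
  uncovered <- wacc < 1e-6
  if (any(uncovered)) composite[uncovered] <- mean(composite[!uncovered])
  list(composite = composite, counts = wacc)
}

# Render the four oblique Landolt templates at `position` on `geom`.
render_templates <- function(gap_size, position, display, geom) {
  diam <- 5 * gap_size
  lapply(ORIENTATIONS, function(o) {
    ang <- ORIENTATION_ANGLE[[o]] * pi / 180
    cpp_render_landolt(geom$ny, geom$nx, geom$x_tl, geom$y_tl,
                       display$arcmin_per_pixel,
                       position[1], position[2], diam,
                       cos(ang), sin(ang), 4L)
  })
}

# Correlation of an image against prepared templates; named decision
# variables, NA when image or template has zero variance.
corr_templates <- function(image, templates) {
  v <- as.vector(image)
  sv <- stats::sd(v)
  dv <- vapply(templates, function(tpl) {
    st <- stats::sd(as.vector(tpl))
    if (is.na(sv) || sv == 0 || st == 0) NA_real_
    else stats::cor(v, as.vector(tpl))
  }, numeric(1))
  names(dv) <- ORIENTATIONS
  dv
}

# Correlation of an image against the four oblique Landolt templates
# rendered at `position` on the window `geom`.
template_corrs <- function(image, gap_size, position, display, geom) {
  corr_templates(image, render_templates(gap_size, position, display, geom))
}

# Crop a window geometry (and image) to the decision region around a
# position. Returns list(image, geom).
crop_to_decision <- function(image, geom, display, position, half) {
  sub <- window_geom(display, position, half)
  r0 <- sub$row_off - geom$row_off
  c0 <- sub$col_off - geom$col_off
  r_lo <- max(0L, r0); c_lo <- max(0L, c0)
  r_hi <- min(geom$ny, r0 + sub$ny); c_hi <- min(geom$nx, c0 + sub$nx)
  if (r_hi <= r_lo || c_hi <= c_lo) stop("analysis window is empty")
  g <- geom
  g$row_off <- geom$row_off + r_lo
  g$col_off <- geom$col_off + c_lo
  g$ny <- r_hi - r_lo
  g$nx <- c_hi - c_lo
  app <- geom$arcmin_per_pixel
  g$x_tl <- geom$x_tl + c_lo * app
  g$y_tl <- geom$y_tl - r_lo * app
  list(image = image[(r_lo + 1):r_hi, (c_lo + 1):c_hi, drop = FALSE],
       geom = g)
}

#' 4AFC template decision
#'
#' Correlates the (possibly merged) internal image against four noiseless
#' Landolt templates differing only in gap orientation, within the
#' decision window centered on the assumed target position, and chooses
#' the orientation with the largest correlation. Exact ties (including a
#' structureless image, where all four correlations are undefined) are
#' broken by a seeded uniform choice among the tied orientations.
#'
#' @param composite internal-response matrix.
#' @param gap_size assumed gap size (arcmin).
#' @param assumed_position assumed target center (arcmin coordinates).
#' @param params an [observer_params()].
#' @param seed integer seed for tie-breaking.
#' @param display a [display_model()].
#' @param geom window geometry of `composite`.
#' @return an object of class `trial_response`: `chosen_orientation`,
#'   `correct` (`NA`; filled by [simulate_trial()]), `decision_variables`,
#'   `strategy`.
#' @export
decide_4afc <- function(composite, gap_size, assumed_position, params, seed,
                        display = display_model(), geom = NULL) {
  if (gap_size <= 0) stop("gap_size must be positive")
  if (is.null(geom)) geom <- full_canvas_geom(display)
  half <- params$window_factor / 2 * 5 * gap_size +
    10 * display$arcmin_per_pixel
  cr <- crop_to_decision(composite, geom, display, assumed_position, half)
  dv <- template_corrs(cr$image, gap_size, assumed_position, display, cr$geom)
  chosen <- choose_max(dv, seed)
  structure(
    list(chosen_orientation = chosen, correct = NA,
         decision_variables = dv, strategy = params$strategy),
    class = "trial_response"
  )
}

# argmax with seeded uniform tie-break; all-NA counts as a 4-way tie
choose_max <- function(dv, seed) {
  v <- ifelse(is.na(dv), -Inf, dv)
  cand <- which(v == max(v))
  if (length(cand) > 1)
    cand <- with_seed(seed, sample(cand, 1))
  ORIENTATIONS[cand]
}

#' Simulate one 4AFC trial
#'
#' Runs the configured observer on a stimulus sequence: applies the front
#' end, pools evidence according to the observer's strategy
#' (middle frame, per-frame max rule, or shift-and-add registration with
#' oracle / estimated / absent motion knowledge) and returns the 4AFC
#' response.
#'
#' @param sequence a [compose_sequence()] result.
#' @param params an [observer_params()].
#' @param seed integer seed (noise draws, lattice phase, tie-breaks).
#' @return a `trial_response` with `correct` filled in.
#' @export
simulate_trial <- function(sequence, params, seed) {
  stopifnot(inherits(sequence, "stimulus_sequence"),
            inherits(params, "observer_params"))
  display <- sequence$display
  geom <- sequence$geom
  app <- display$arcmin_per_pixel
  n <- sequence$n_frames
  mid <- as.integer(ceiling(n / 2))
  if (params$motion_knowledge == "oracle" &&
      is.null(sequence$target_positions))
    stop("configuration error: oracle motion knowledge requires path metadata")
  pos <- sequence$target_positions
  mid_pos <- pos[mid, ]

  # per-trial lattice phase (canvas-anchored)
  p <- round(params$sample_pitch / app)
  phase <- if (p > 1) {
    ph <- with_seed(derive_seed(seed, 77L), sample.int(p, 2) - 1L)
    c((geom$row_off + ph[1]) %% p, (geom$col_off + ph[2]) %% p)
  } else c(0L, 0L)

  fe <- function(f) front_end(sequence$frames[[f]], params,
                              seed = derive_seed(seed, 100L + f),
                              phase = phase, arcmin_per_pixel = app)

  resp <- switch(params$strategy,
    single_frame = {
      decide_4afc(fe(mid), sequence$gap_size, mid_pos, params,
                  derive_seed(seed, 7L), display, geom)
    },
    prob_summation = {
      half <- params$window_factor / 2 * sequence$diameter + 10 * app
      tpl_cache <- new.env(parent = emptyenv())
      dvs <- vapply(seq_len(n), function(f) {
        apos <- if (params$motion_knowledge == "none") mid_pos else pos[f, ]
        cr <- crop_to_decision(fe(f), geom, display, apos, half)
        key <- sprintf("%.6f_%.6f", apos[1], apos[2])
        tpls <- tpl_cache[[key]]
        if (is.null(tpls)) {
          tpls <- render_templates(sequence$gap_size, apos, display, cr$geom)
          tpl_cache[[key]] <- tpls
        }
        corr_templates(cr$image, tpls)
      }, numeric(4))
      dv <- apply(dvs, 1, function(r) if (all(is.na(r))) NA_real_
                                      else max(r, na.rm = TRUE))
      names(dv) <- ORIENTATIONS
      structure(
        list(chosen_orientation = choose_max(dv, derive_seed(seed, 7L)),
             correct = NA, decision_variables = dv,
             strategy = params$strategy),
        class = "trial_response")
    },
    super_resolution = {
      frames <- lapply(seq_len(n), fe)
      shifts <- switch(params$motion_knowledge,
        oracle = sweep(pos, 2, mid_pos),
        none = matrix(0, n, 2),
        estimated = {
          # estimate on the attended region at reduced resolution (the
          # registration itself stays at full resolution); per-frame FFTs
          # are computed once and reused across consecutive pairs
          half <- params$window_factor / 2 * sequence$diameter + 10 * app
          dec <- params$est_decimate
          est_frames <- lapply(frames, function(f) {
            cr <- crop_to_decision(f, geom, display, mid_pos, half)$image
            if (dec > 1) cr[seq(1, nrow(cr), dec), seq(1, ncol(cr), dec)]
            else cr
          })
          pad <- c(stats::nextn(nrow(est_frames[[1]]), c(2, 3)),
                   stats::nextn(ncol(est_frames[[1]]), c(2, 3)))
          preps <- lapply(est_frames, prep_ncc, pad_dim = pad)
          cum <- matrix(0, n, 2)
          for (f in seq_len(n - 1)) {
            est <- ncc_peak(preps[[f]], preps[[f + 1]], app * dec,
                            max_shift = params$est_max_shift)
            cum[f + 1, ] <- cum[f, ] + est$shift
          }
          if (params$est_trajectory == "linear") {
            # predictable-trajectory prior: regress the chained track on
            # frame index and register along the fitted constant-velocity
            # path, suppressing chaining drift. Unpredictable paths yield
            # near-zero fitted velocity and hence almost no registration.
            t_idx <- seq_len(n) - mid
            cum <- apply(cum, 2, function(v)
              mean(v) + t_idx * sum(t_idx * (v - mean(v))) / sum(t_idx^2))
          }
          sweep(cum, 2, cum[mid, ])
        })
      comp <- accumulate_sr(frames, shifts, app)$composite
      decide_4afc(comp, sequence$gap_size, mid_pos, params,
                  derive_seed(seed, 7L), display, geom)
    })
  resp$correct <- identical(resp$chosen_orientation, sequence$orientation)
  resp
}
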