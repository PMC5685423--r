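#' Initialize a 3-down-1-up staircase
#'
#' The adaptive track starts at a gap of 17.8 arcmin with a step of
#' 4.5 arcmin. The gap decreases by one step after three consecutive
#' correct responses and increases by one step after every error; the step
#' halves on every size-increasing reversal. A run terminates after
#' `max_reversals` reversals or `max_trials` trials, whichever comes first
#' (8 and 50 by default). The rule converges near the 79.4%-correct point
#' of the psychometric function (0.5^(1/3)).
#'
#' @param initial_gap starting gap size (arcmin).
#' @param initial_step starting step size (arcmin).
#' @param max_reversals reversal count at which the run terminates.
#' @param max_trials trial count at which the run terminates.
#' @param gap_floor smallest presentable gap (arcmin); defaults to one
#'   display pixel.
#' @param gap_ceiling largest presentable gap (arcmin); defaults to the
#'   gap of a target whose diameter fills the 7 deg mask.
#' @return an object of class `staircase_state`.
#' @export
#' @examples
#' s <- init_staircase()
#' s$current_gap # 17.8
init_staircase <- function(initial_gap = 17.8, initial_step = 4.5,
                           max_reversals = 8, max_trials = 50,
                           gap_floor = 1.05, gap_ceiling = 84) {
  stopifnot(initial_gap > 0, initial_step > 0, max_reversals >= 1,
            max_trials >= 1, gap_floor > 0, gap_ceiling > gap_floor)
  structure(
    list(current_gap = initial_gap, step = initial_step,
         consecutive_correct = 0L, n_trials = 0L, n_reversals = 0L,
         last_direction = "none", terminated = FALSE,
         max_reversals = as.integer(max_reversals),
         max_trials = as.integer(max_trials), gap_floor = gap_floor,
         gap_ceiling = gap_ceiling,
         reversal_gaps = numeric(0),
         gap_history = numeric(0), correct_history = logical(0)),
    class = "staircase_state"
  )
}

#' Advance the staircase by one response
#'
#' Applies the 3-down-1-up bookkeeping: an error moves the gap up by one
#' step and resets the correct counter; a third consecutive correct moves
#' it down by one step (clipped at the gap floor) and resets the counter;
#' other correct responses leave the gap unchanged. A change in movement
#' direction counts as a reversal, and on size-increasing reversals
#' (decreasing -> increasing) the step is halved, with the halved step
#' taking effect from the following movement. Termination flags are set when the reversal or trial cap is
#' reached.
#'
#' @param state a `staircase_state`.
#' @param correct logical response to the trial presented at
#'   `state$current_gap`.
#' @return the updated `staircase_state`.
#' @export
staircase_update <- function(state, correct) {
  stopifnot(inherits(state, "staircase_state"), is.logical(correct))
  if (state$terminated) stop("staircase already terminated")
  state$n_trials <- state$n_trials + 1L
  state$gap_history <- c(state$gap_history, state$current_gap)
  state$correct_history <- c(state$correct_history, correct)
  direction <- NULL
  if (!correct) {
    state$consecutive_correct <- 0L
    direction <- "increasing"
  } else {
    state$consecutive_correct <- state$consecutive_correct + 1L
    if (state$consecutive_correct >= 3L) {
      state$consecutive_correct <- 0L
      direction <- "decreasing"
    }
  }
  if (!is.null(direction)) {
    reversal <- state$last_direction != "none" &&
      direction != state$last_direction
    if (reversal) {
      state$n_reversals <- state$n_reversals + 1L
      state$reversal_gaps <- c(state$reversal_gaps, state$current_gap)
    }
    if (direction == "increasing") {
      state$current_gap <- min(state$current_gap + state$step,
                               state$gap_ceiling)
      # the halved step takes effect from the next movement onwards
      if (reversal) state$step <- state$step / 2
    } else {
      state$current_gap <- max(state$current_gap - state$step,
                               state$gap_floor)
    }
    state$last_direction <- direction
  }
  if (state$n_reversals >= state$max_reversals ||
      state$n_trials >= state$max_trials)
    state$terminated <- TRUE
  state
}

#' Run one adaptive staircase against an observer
#'
#' Loops compose -> simulate -> update until the track terminates. Each
#' trial draws a fresh uniform gap orientation, composes the stimulus
#' sequence for the given condition at the track's current gap, obtains
#' the model observer's response and advances the staircase. All
#' randomness derives from `seed`.
#'
#' Alternatively a `responder` function can stand in for the full
#' stimulus-plus-observer pipeline (used for synthetic subjects whose
#' accuracy follows a known psychometric function, see
#' [make_logistic_responder()]).
#'
#' @param condition a [condition_spec()] (ignored when `responder` is
#'   given).
#' @param observer an [observer_params()] (ignored when `responder` is
#'   given).
#' @param seed integer master seed for the run.
#' @param display a [display_model()].
#' @param staircase a [init_staircase()] state to start from.
#' @param responder optional `function(gap, seed)` returning a logical.
#' @param subject_id,run_id labels copied into the trial records.
#' @return a tibble of trial records: `subject_id`, `condition`,
#'   `density`, `run`, `trial`, `gap_arcmin`, `orientation`, `response`,
#'   `correct`, `seed`, plus the final state in attribute `"state"`.
#' @export
run_staircase <- function(condition = NULL, observer = NULL, seed,
                          display = display_model(),
                          staircase = init_staircase(),
                          responder = NULL,
                          subject_id = "s1", run_id = 1L) {
  if (is.null(responder) &&
      (is.null(condition) || is.null(observer)))
    stop("need either a condition and observer, or a responder")
  state <- staircase
  rows <- list()
  trial <- 0L
  while (!state$terminated) {
    trial <- trial + 1L
    trial_seed <- derive_seed(seed, trial)
    gap <- state$current_gap
    if (is.null(responder)) {
      orientation <- with_seed(derive_seed(trial_seed, 1),
                               sample(ORIENTATIONS, 1))
      seq <- compose_sequence(condition, gap, orientation,
                              seed = derive_seed(trial_seed, 2),
                              display = display)
      resp <- simulate_trial(seq, observer, seed = derive_seed(trial_seed, 3))
      correct <- resp$correct
    } else {
      orientation <- NA_character_
      resp <- list(chosen_orientation = NA_character_)
      correct <- isTRUE(responder(gap, trial_seed))
    }
    cond_label <- if (is.null(condition)) NA_character_ else condition$label
    cond_density <- if (is.null(condition)) NA_real_ else condition$density
    rows[[trial]] <- tibble::tibble(
      subject_id = subject_id,
      condition = cond_label,
      density = cond_density,
      run = run_id, trial = trial, gap_arcmin = gap,
      orientation = orientation, response = resp$chosen_orientation,
      correct = correct, seed = trial_seed)
    state <- staircase_update(state, correct)
  }
  out <- do.call(rbind, rows)
  attr(out, "state") <- state
  out
}

#' Write trial records to CSV
#'
#' One row per trial with the standard columns (`subject_id`, `condition`,
#' `density`, `run`, `trial`, `gap_arcmin`, `orientation`, `response`,
#' `correct`, `seed`) and a header line.
#'
#' @param trials a trial-record tibble from [run_staircase()] or
#'   [run_condition()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE)
  invisible(path)
}
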