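# Shared fixtures for the test suite. Everything is generated in code.

DISP <- display_model()

ALL_ORIENTATIONS <- c("lower-left", "lower-right", "upper-left", "upper-right")

# quick sequence constructor with package defaults
make_seq <- function(label = "static_static", density = 0.5, gap = 10,
                     orientation = "upper-left", seed = 1,
                     window = "auto", ...) {
  compose_sequence(condition_spec(label, density), gap, orientation,
                   seed = seed, display = DISP, window = window, ...)
}

# accuracy of an observer over n trials at a fixed gap, fresh seeds
observer_accuracy <- function(label, density, gap, obs, n, seed0 = 1) {
  mean(vapply(seq_len(n), function(i) {
    s <- derive_seed(seed0, i)
    ori <- ALL_ORIENTATIONS[1 + (s %% 4)]
    sq <- make_seq(label, density, gap, ori, seed = derive_seed(s, 1))
    simulate_trial(sq, obs, seed = derive_seed(s, 2))$correct
  }, logical(1)))
}

# pooled staircase threshold (ML fit) for one observer/condition cell
staircase_threshold <- function(label, density, obs, seed, n_runs = 1,
                                max_trials = 40) {
  st <- init_staircase(max_trials = max_trials)
  trials <- do.call(rbind, lapply(seq_len(n_runs), function(r) {
    run_staircase(condition_spec(label, density), obs,
                  seed = derive_seed(seed, r), display = DISP,
                  staircase = st, run_id = r)
  }))
  fit_ml(trials)$mu
}
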