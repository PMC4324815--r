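# Shared fixtures: tiny deterministic series and parameter sets used across
# test files. Kept small so individual tests stay readable.

impulse_series <- function(w, id = "r1") {
  training_series(id, w = w)
}

# A small noisy two-rat cohort built from explicit sessions (not the
# generator), for IO and fitting edge cases.
two_rat_sessions <- function() {
  cal <- training_calendar(8)
  rbind(
    climb_sessions("a", cal$session_day, body_mass = 0.27 + 0.002 * (cal$session_day - 1),
                   load_mass = 0.15, climb_height = 1, repetitions = 10,
                   total_time = seq(90, 76, length.out = 8)),
    climb_sessions("b", cal$session_day, body_mass = 0.29 + 0.002 * (cal$session_day - 1),
                   load_mass = 0.16, climb_height = 1, repetitions = 10,
                   total_time = seq(100, 80, length.out = 8)))
}

reference_gain_params <- function(p0 = 0.4) {
  model_params("TWO_COMP", p0 = p0, k1 = 0.0186, tau1 = 5.31,
               k2 = 0.0200, tau2 = 4.3)
}

random_impulse_train <- function(n, rate = 0.7, max_w = 100) {
  runif(n, 0, max_w) * rbinom(n, 1, rate)
}
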