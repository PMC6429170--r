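# Shared fixtures. Small sessions (fs 250 Hz, 250-sample epochs) keep the
# unit tests fast; the acceptance tests use full-geometry sessions
# (6 x 150 epochs at 1000 Hz), cached once per test run.

tiny_config <- function(seed, reps = 25, blink_rate = 0, ...) {
  session_config(reps_per_tag = reps, fs = 250, epoch_len = 250,
                 blink_rate = blink_rate, seed = seed, ...)
}

tiny_profile <- function(seed, amplitude = 4, ...) {
  make_user_profile(seed = seed, amplitude = amplitude,
                    epoch_len = 250, fs = 250, ...)
}

tiny_session <- function(pseed = 1, sseed = 2, amplitude = 4, reps = 25,
                         blink_rate = 0, ...) {
  simulate_session(tiny_profile(pseed, amplitude, ...),
                   tiny_config(sseed, reps, blink_rate))
}

# filtered + concatenated observations for a tiny session
tiny_obs <- function(pseed = 1, sseed = 2, amplitude = 4, reps = 25, ...) {
  s <- tiny_session(pseed, sseed, amplitude, reps, ...)
  select_concat(bandpass(s), channels = c("P7", "P8"))
}

.fixture_env <- new.env(parent = emptyenv())

# full-geometry session of the default calibrated user, simulated and
# preprocessed once per test run
default_session <- function() {
  if (is.null(.fixture_env$session)) {
    p <- make_user_profile(seed = 101)
    .fixture_env$session <- simulate_session(p, session_config(seed = 102))
  }
  .fixture_env$session
}

default_obs <- function() {
  if (is.null(.fixture_env$obs)) {
    rej <- reject_artifacts(bandpass(default_session()))
    .fixture_env$obs <- select_concat(rej$epochs)
    .fixture_env$rejected <- rej$rejected_ids
  }
  .fixture_env$obs
}

default_rejected <- function() {
  invisible(default_obs())
  .fixture_env$rejected
}
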