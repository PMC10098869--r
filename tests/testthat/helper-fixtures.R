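# Shared small fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

tiny_design <- function(...) {
  study_design(
    n_participants = 3, n_sessions = 2, n_channels = 16,
    n_locations = 120, n_trials = 3, trial_s = 10, ...
  )
}

# a small shared-coupling study plus sensor-space features
tiny_shared <- function() {
  fixture("tiny_shared", function() {
    st <- gen_study(tiny_design(), "shared", snr_db = 10, seed = 5)
    list(study = st, feats = prepare_features(st, "sensor"))
  })
}

# strongly coupled noiseless study for exact-recovery style checks
tiny_clean <- function() {
  fixture("tiny_clean", function() {
    gen_study(tiny_design(coupling_strength = 1), "shared",
      snr_db = Inf, seed = 7, background = FALSE
    )
  })
}

tiny_leadfield <- function() {
  fixture("tiny_leadfield", function() gen_leadfield(16, 120, seed = 3))
}
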