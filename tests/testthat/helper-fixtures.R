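# Small shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cache <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, expr, envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# four-arm miniature study: +/- single 10 Gy pulse x isotype/anti-PD-L1
tiny_config <- function() {
  rad <- data.frame(step = 3, dose_gy = 10)
  ms <- c(1L, 4L, 7L, 10L, 14L, 18L)
  arms <- list(
    list(id = "ctrl_iso", rad = NULL, agent = "isotype"),
    list(id = "ctrl_anti", rad = NULL, agent = "anti_pdl1"),
    list(id = "rt_iso", rad = rad, agent = "isotype"),
    list(id = "rt_anti", rad = rad, agent = "anti_pdl1")
  )
  structure(lapply(arms, function(a) {
    list(group_id = a$id, n_animals = 4L,
         schedule = treatment_schedule(radiation = a$rad,
                                       drug = every_other_day(a$agent),
                                       measurement_steps = ms))
  }), class = "study_config")
}

tiny_params <- function() {
  dynamics_params(alpha = 0.05, beta = 0.005, noise_cv = 0.1)
}

tiny_study <- function() {
  cache("study", generate_study(tiny_config(), tiny_params(), seed = 42))
}

tiny_dataset <- function() {
  cache("dataset", build_dataset(tiny_study(), n_samples = 8, seed = 43))
}

# small surrogate trained enough to be a meaningful function of its inputs
tiny_trained <- function() {
  cache("trained", {
    cfg <- model_config(hidden_units = 8L, epochs = 150L, batch_size = 16L,
                        seed = 44L, holdout_groups = 0L)
    train(tiny_dataset(), cfg)
  })
}

# an initialized (untrained) surrogate: valid for structural identities
raw_model <- function(hidden_units = 8L, seed = 7L,
                      lq = list(alpha = 0.3, beta = 0.03,
                                encoding = "log_kill")) {
  withr::with_seed(seed, {
    w <- pulsim:::lstm_init(2L, hidden_units, 5L)
    structure(
      list(weights = w,
           config = model_config(hidden_units = hidden_units,
                                 epochs = 1L, holdout_groups = 0L),
           lq = lq, target_scale = 100, n_steps = 18L),
      class = "pulsim_model")
  })
}

random_schedule <- function(seed) {
  withr::with_seed(seed, {
    n_pulse <- sample(0:2, 1)
    rad <- if (n_pulse) {
      data.frame(step = sort(sample(1:18, n_pulse)),
                 dose_gy = sample(c(10, 15, 20, 40), n_pulse, replace = TRUE))
    } else NULL
    treatment_schedule(radiation = rad,
                       drug = every_other_day(
                         sample(c("isotype", "anti_pdl1"), 1)))
  })
}
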