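test_that("parameter validation rejects non-physical values", {
  expect_error(dynamics_params(rho = -1), "rho")
  expect_error(dynamics_params(rho = NaN), "rho")
  expect_error(dynamics_params(alpha = -0.1), "alpha")
  expect_error(dynamics_params(kappa = 0.1, kappa_bare = 0.2), "kappa_bare")
  expect_error(dynamics_params(immune_duration = 0), "immune_duration")
  expect_error(dynamics_params(noise_cv = -1), "noise_cv")
})

test_that("untreated noiseless growth matches the closed-form exponential", {
  p <- dynamics_params(noise_cv = 0)
  s <- treatment_schedule(measurement_steps = c(1, 9, 18))
  v <- simulate_animal(p, s, seed = 5)
  expect_length(v, 18)
  expect_true(all(diff(v) > 0))
  # oracle: V(t) = V(1) * exp(rho * (t - 1)), exactly
  expect_equal(v, v[1] * exp(p$rho * (0:17)))
  expect_true(v[1] >= 150 && v[1] <= 200)
})

test_that("a pulse multiplies the trajectory by exactly SF(d) from its step on", {
  p <- dynamics_params(noise_cv = 0, kappa = 0, kappa_bare = 0)
  bare <- treatment_schedule()
  pulsed <- treatment_schedule(radiation = data.frame(step = 7, dose_gy = 20))
  v0 <- simulate_animal(p, bare, seed = 9)
  v1 <- simulate_animal(p, pulsed, seed = 9)
  sf <- exp(-(p$alpha * 20 + p$beta * 20^2))
  expect_equal(v1[1:6], v0[1:6])
  expect_equal(v1[7:18], v0[7:18] * sf)
  expect_true(all(v1 > 0))
})

test_that("disabling the immune term makes the drug schedule irrelevant", {
  p <- dynamics_params(noise_cv = 0, kappa = 0, kappa_bare = 0)
  rad <- data.frame(step = 3, dose_gy = 15)
  with_drug <- treatment_schedule(radiation = rad,
                                  drug = every_other_day("anti_pdl1"))
  without <- treatment_schedule(radiation = rad)
  expect_equal(simulate_animal(p, with_drug, seed = 3),
               simulate_animal(p, without, seed = 3))
})

test_that("radiation never increases later volumes when immunity is off", {
  p <- dynamics_params(noise_cv = 0, kappa = 0, kappa_bare = 0)
  for (seed in 1:5) {
    sched <- random_schedule(seed)
    bare <- treatment_schedule(drug = sched$drug)
    v_bare <- simulate_animal(p, bare, seed = seed)
    v_rad <- simulate_animal(p, sched, seed = seed)
    expect_true(all(v_rad <= v_bare + 1e-12))
  }
})

test_that("anti-PD-L1 lowers seed-matched terminal volume when kappa > kappa_bare", {
  p <- dynamics_params(noise_cv = 0.1)
  rad <- data.frame(step = 3, dose_gy = 20)
  ms <- c(1, 4, 7, 10, 14, 18)
  iso <- treatment_schedule(radiation = rad,
                            drug = every_other_day("isotype"),
                            measurement_steps = ms)
  anti <- treatment_schedule(radiation = rad,
                             drug = every_other_day("anti_pdl1"),
                             measurement_steps = ms)
  term <- sapply(1:8, function(s) {
    c(simulate_animal(p, iso, seed = s)[18],
      simulate_animal(p, anti, seed = s)[18])
  })
  expect_true(mean(term[2, ]) <= mean(term[1, ]))
  expect_true(all(term[2, ] <= term[1, ]))  # seed-matched animals
})

test_that("simulate_animal is deterministic given a seed and leaves the RNG alone", {
  p <- dynamics_params()
  s <- treatment_schedule(radiation = data.frame(step = 3, dose_gy = 10))
  set.seed(1); before <- runif(1)
  set.seed(1); runif(1)
  v1 <- simulate_animal(p, s, seed = 77)
  after <- runif(1)
  v2 <- simulate_animal(p, s, seed = 77)
  expect_identical(v1, v2)
  set.seed(1); runif(1)
  expect_identical(runif(1), after)  # RNG stream undisturbed
})

test_that("group summaries use the sample SD convention and preserve counts", {
  flat <- matrix(rep(c(100, 200), each = 5), nrow = 2, byrow = TRUE)
  gs <- summarize_group(flat, measurement_steps = c(1, 3, 5), group_id = "g")
  expect_equal(gs$records$mean_mm3, rep(150, 3))
  expect_equal(gs$records$sd_mm3, rep(sd(c(100, 200)), 3))

  same <- matrix(rep(1:6, 3), nrow = 3, byrow = TRUE)
  gs2 <- summarize_group(same, measurement_steps = 1:6)
  expect_equal(gs2$records$sd_mm3, rep(0, 6))

  eight <- matrix(runif(8 * 18, 100, 200), nrow = 8)
  expect_equal(summarize_group(eight, c(1, 18))$n_animals, 8)
  expect_error(summarize_group(eight[1, , drop = FALSE], 1), "at least 2")
  expect_error(summarize_group(list(), 1), "no trajectories")
})

test_that("schedule construction enforces the window and dose invariants", {
  expect_error(treatment_schedule(radiation = data.frame(step = 19, dose_gy = 10)),
               "1\\.\\.18")
  expect_error(treatment_schedule(radiation = data.frame(step = 3, dose_gy = -1)),
               "positive")
  expect_error(treatment_schedule(drug = data.frame(step = 1, agent = "aspirin")),
               "isotype")
  expect_error(treatment_schedule(measurement_steps = c(4, 4)), "increasing")
  expect_error(treatment_schedule(measurement_steps = 1:7), "at most 6")
})
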