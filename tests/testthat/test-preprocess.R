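test_that("the LQ effect follows alpha*d + beta*d^2 and its variants", {
  expect_equal(lq_effect(0), 0)
  expect_equal(lq_effect(20, 0.3, 0.03), 18)   # 6 + 12, by hand
  expect_equal(lq_effect(10, 0.3, 0.03), 6)
  expect_gt(lq_effect(40), lq_effect(20))
  expect_equal(lq_effect(20, encoding = "one_minus_sf"), 1 - exp(-18))
  expect_equal(lq_effect(20, encoding = "dose"), 20)
  expect_equal(lq_effect(0, encoding = "one_minus_sf"), 0)
  expect_error(lq_effect(-5), "nonnegative")
})

test_that("caliper volume is xyz/2", {
  expect_equal(tumor_volume(2, 2, 2), 4)
  expect_equal(tumor_volume(0, 5, 5), 0)
  expect_equal(tumor_volume(1.0, 0.8, 0.5), 0.2)
  expect_error(tumor_volume(-1, 1, 1), "nonnegative")
})

test_that("augmentation draws the requested samples from the shrunken Gaussian", {
  gs <- tiny_study()$groups[[1]]$summary
  draws <- augment_group(gs, seed = 1)
  expect_equal(dim(draws), c(50L, nrow(gs$records)))  # default 50 per group
  expect_identical(draws, augment_group(gs, seed = 1))

  # zero SD collapses every sample onto the mean series
  gs0 <- gs
  gs0$records$sd_mm3 <- 0
  d0 <- augment_group(gs0, n_samples = 7, seed = 2)
  expect_equal(unname(d0), matrix(rep(gs0$records$mean_mm3, each = 7), 7))

  empty <- structure(list(group_id = "x", n_animals = 2,
                          records = NULL), class = "group_summary")
  expect_error(augment_group(empty), "no records")
  expect_error(augment_group(gs, sd_shrink = 0), "sd_shrink")
})

test_that("negative draws are clipped at the physical floor", {
  gs <- structure(list(group_id = "x", n_animals = 2,
                       records = data.frame(step = 1, mean_mm3 = 0.5,
                                            sd_mm3 = 50)),
                  class = "group_summary")
  d <- augment_group(gs, n_samples = 500, sd_shrink = 1, seed = 3)
  expect_true(all(d >= 1))
})

test_that("input encoding places LQ values and drug codes on the right steps", {
  empty <- encode_inputs(treatment_schedule())
  expect_equal(dim(empty), c(18L, 2L))
  expect_true(all(empty == 0))

  iso <- encode_inputs(treatment_schedule(drug = every_other_day("isotype")))
  expect_equal(unname(iso[, "drug"]), rep(c(1, 0), 9))
  expect_true(all(iso[, "radiation"] == 0))

  anti <- encode_inputs(treatment_schedule(drug = every_other_day("anti_pdl1")))
  expect_equal(unname(anti[seq(1, 18, 2), "drug"]), rep(2, 9))

  x <- encode_inputs(treatment_schedule(
    radiation = data.frame(step = 3, dose_gy = 20)))
  expect_equal(unname(x[3, "radiation"]), lq_effect(20))
  expect_equal(sum(x[, "radiation"] != 0), 1L)
  expect_true(all(x[, "radiation"] >= 0))
})

test_that("volume changes are consecutive differences with a validity mask", {
  vc <- compute_volume_changes(c(100, 150, 130))
  expect_equal(vc$targets, c(50, -20, 0, 0, 0))
  expect_equal(vc$mask, c(TRUE, TRUE, FALSE, FALSE, FALSE))

  six <- compute_volume_changes(c(150, 180, 240, 300, 420, 500))
  expect_equal(sum(six$mask), 5L)             # six measurements -> five deltas

  flat <- compute_volume_changes(rep(200, 4))
  expect_equal(flat$targets[flat$mask], rep(0, 3))

  one <- compute_volume_changes(42)
  expect_false(any(one$mask))

  expect_error(compute_volume_changes(numeric(0)), "1\\.\\.6")
  expect_error(compute_volume_changes(1:7), "1\\.\\.6")
})

test_that("cumulative summation of masked targets recovers the series", {
  for (seed in 1:20) {
    v <- withr::with_seed(seed, runif(sample(2:6, 1), 50, 900))
    vc <- compute_volume_changes(v)
    expect_equal(v[1] + cumsum(vc$targets[vc$mask]), v[-1])
  }
})

test_that("dataset assembly yields one encoded 18-step sample per draw", {
  ds <- tiny_dataset()
  expect_s3_class(ds, "pulsim_dataset")
  expect_equal(dim(ds$inputs), c(4 * 8, 18, 2))
  expect_equal(dim(ds$targets), c(32L, 5L))
  expect_equal(dim(ds$mask), c(32L, 5L))
  expect_true(all(ds$inputs[, , "drug"] %in% c(0, 1, 2)))
  expect_true(all(ds$inputs[, , "radiation"] >= 0))
  expect_equal(rowSums(ds$mask), rep(5, 32))

  one <- build_dataset(tiny_study(), n_samples = 1, seed = 1)
  expect_equal(dim(one$inputs)[1], 4L)
  expect_identical(build_dataset(tiny_study(), n_samples = 3, seed = 5),
                   build_dataset(tiny_study(), n_samples = 3, seed = 5))
})

test_that("groups too sparse to yield a target are skipped with a warning", {
  study <- tiny_study()
  study$groups[[2]]$schedule$measurement_steps <- 4L
  study$groups[[2]]$summary$records <-
    study$groups[[2]]$summary$records[2, , drop = FALSE]
  expect_warning(ds <- build_dataset(study, n_samples = 2, seed = 1),
                 "skipped")
  expect_false("ctrl_anti" %in% ds$group_id)
  expect_equal(dim(ds$inputs)[1], 6L)
})

test_that("augmentation moments converge to mean and sd/shrink", {
  # moderate-n version of the moment property (acceptance runs n = 1e5)
  gs <- structure(list(group_id = "m", n_animals = 8,
                       records = data.frame(step = c(1, 10),
                                            mean_mm3 = c(200, 800),
                                            sd_mm3 = c(50, 250))),
                  class = "group_summary")
  d <- augment_group(gs, n_samples = 20000, seed = 4)
  expect_equal(colMeans(d), c(200, 800), tolerance = 0.01,
               ignore_attr = TRUE)
  expect_equal(apply(d, 2, sd), c(10, 50), tolerance = 0.03,
               ignore_attr = TRUE)
})
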