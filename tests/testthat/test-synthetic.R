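test_that("template generation is deterministic, seed-sensitive, shaped", {
  a <- make_template(c(16, 16, 16), seed = 4)
  b <- make_template(c(16, 16, 16), seed = 4)
  c <- make_template(c(16, 16, 16), seed = 5)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, c$data))
  expect_identical(dim(a$data), c(16L, 16L, 16L))
  expect_true(all(a$data > 0))
  expect_error(make_template(c(4, 16, 16)), ">= 8")
})

test_that("null generative model yields outcome driven by demographics only", {
  cfg <- generative_config(n_subjects = 40, shape = c(8, 8, 8),
                           effects = list(), loading = 0,
                           outcome_noise_sd = 0, seed = 2)
  sim <- simulate_cohort(cfg)
  expect_equal(sim$cohort$memory,
               -0.02 * sim$cohort$age + 0.03 * sim$cohort$education,
               tolerance = 1e-12)
  expect_equal(mask_count(sim$truth), 0)
  # volumes carry no latent signal: correlation of voxel with latent ~ 0
  g <- vapply(sim$volumes, function(v) v$data[5, 5, 5], numeric(1))
  expect_lt(abs(cor(g, sim$cohort$latent)), 0.5)
})

test_that("simulation is reproducible and validates regions", {
  cfg <- generative_config(n_subjects = 12, shape = c(8, 8, 8), seed = 9,
                           effects = list(effect_spec("box", lo = c(2, 2, 2),
                                                      hi = c(5, 5, 5),
                                                      effect_size = 0.1)))
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$volumes[[3]]$data, s2$volumes[[3]]$data)
  expect_equal(mask_count(s1$truth), 64)
  expect_setequal(unique(s1$cohort$diagnosis), c("CN", "MCI", "Dementia"))

  bad <- generative_config(n_subjects = 5, shape = c(8, 8, 8),
                           effects = list(effect_spec("box", lo = c(2, 2, 2),
                                                      hi = c(9, 5, 5))))
  expect_error(simulate_cohort(bad), "outside grid")
})

test_that("inverse-scored outcomes flip the sign of planted associations", {
  t_in_region <- function(sign, seed = 21) {
    sim <- small_sim(n = 80, effect = 0.15, seed = seed,
                     outcome_sign = sign)
    mask <- make_analysis_mask(sim$template, 0.3)
    tm <- voxelwise_tmap(sim$cohort, sim$volumes, mask, "memory")
    vox <- which(sim$truth$data[which(mask$data)])
    mean(tm$tvals[vox], na.rm = TRUE)
  }
  expect_gt(t_in_region(+1), 2)
  expect_lt(t_in_region(-1), -2)
})

test_that("planted-region t grows with effect size", {
  mean_t <- vapply(c(0.02, 0.08, 0.2), function(es) {
    sim <- small_sim(n = 60, effect = es, seed = 31)
    mask <- make_analysis_mask(sim$template, 0.3)
    tm <- voxelwise_tmap(sim$cohort, sim$volumes, mask, "memory")
    vox <- which(sim$truth$data[which(mask$data)])
    mean(tm$tvals[vox], na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(mean_t) > 0))
})

test_that("discovery/validation split is disjoint, exhaustive, reproducible", {
  co <- make_demo_cohort(100, seed = 6)
  sp <- split_discovery_validation(co, 0.5, seed = 3)
  expect_equal(nrow(sp$discovery), 50)
  expect_equal(nrow(sp$validation), 50)
  expect_length(intersect(sp$discovery$subject_id,
                          sp$validation$subject_id), 0)
  expect_setequal(c(sp$discovery$subject_id, sp$validation$subject_id),
                  co$subject_id)
  sp2 <- split_discovery_validation(co, 0.5, seed = 3)
  expect_identical(sp$discovery$subject_id, sp2$discovery$subject_id)
  expect_error(split_discovery_validation(co[1:2, ], 0.1), "empty")
})

test_that("simulation artifacts round-trip through disk", {
  dir <- withr::local_tempdir()
  sim <- small_sim(n = 12, shape = c(8, 8, 8), seed = 77)
  write_simulation(sim, dir)
  expect_true(file.exists(file.path(dir, "provenance.json")))
  ct <- suppressMessages(read_cohort(
    file.path(dir, "cohort.csv"),
    schema = list(subject_id = "subject_id", age = "age", gender = "gender",
                  education = "education", outcomes = "memory",
                  diagnosis = "diagnosis", volume_ref = "volume_ref")))
  expect_equal(nrow(ct), 12)
  v1 <- read_volume(file.path(dir, ct$volume_ref[1]))
  expect_equal(v1$data, sim$volumes[[1]]$data, tolerance = 1e-12)
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"))
  expect_equal(prov$seed, 77)
})
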