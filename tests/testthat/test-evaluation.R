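# A compact validation world shared by the evaluation tests: one simulated
# cohort plus a signature mask set equal to the planted region split in two.
local_eval_world <- local({
  world <- NULL
  function() {
    if (is.null(world)) {
      sim <- small_sim(n = 150, shape = c(12, 12, 12), effect = 0.15,
                       seed = 71)
      mask <- make_analysis_mask(sim$template, 0.3)
      vox <- which(sim$truth$data)
      half <- vox[seq_len(floor(length(vox) / 2))]
      a1 <- array(FALSE, dim(sim$truth$data)); a1[vox] <- TRUE
      a2 <- array(FALSE, dim(sim$truth$data)); a2[half] <- TRUE
      ms <- structure(list(masks = list(t3 = gm_mask(a1, like = sim$template),
                                        t5 = gm_mask(a2, like = sim$template)),
                           t_levels = c(3, 5), provenance = list()),
                      class = "signature_mask_set")
      world <<- list(sim = sim, mask = mask, ms = ms)
    }
    world
  }
})

test_that("identical mask sets give identical paired fits and zero bias", {
  w <- local_eval_world()
  paired <- replication_trial(w$sim$cohort, w$sim$volumes, w$ms, w$ms,
                              "memory", n_subsets = 12, subset_size = 60,
                              seed = 4)
  expect_equal(paired$r2_a, paired$r2_b)
  ba <- bland_altman(paired)
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_lower, 0)
  expect_false(ba$significant)

  rerun <- replication_trial(w$sim$cohort, w$sim$volumes, w$ms, w$ms,
                             "memory", n_subsets = 12, subset_size = 60,
                             seed = 4)
  expect_identical(paired$r2_a, rerun$r2_a)

  expect_error(replication_trial(w$sim$cohort, w$sim$volumes, w$ms, w$ms,
                                 "memory", n_subsets = 3, subset_size = 60,
                                 discovery_ids = w$sim$cohort$subject_id[1]),
               "overlap")
})

test_that("refit and frozen signature modes both yield sensible fits", {
  w <- local_eval_world()
  for (mode in c("refit", "frozen")) {
    paired <- replication_trial(w$sim$cohort, w$sim$volumes, w$ms, w$ms,
                                "memory", n_subsets = 6, subset_size = 70,
                                seed = 11, mode = mode)
    expect_true(all(is.finite(paired$r2_a)))
    expect_gt(mean(paired$r2_a), 0.05)  # planted signal is detectable
  }
})

test_that("Bland-Altman statistics follow their closed forms", {
  zero <- data.frame(r2_a = rep(0.3, 10), r2_b = rep(0.3, 10))
  ba0 <- bland_altman(zero)
  expect_equal(c(ba0$bias, ba0$loa_lower, ba0$loa_upper), c(0, 0, 0))
  expect_false(ba0$significant)

  sym <- data.frame(r2_a = rep(0.3, 10),
                    r2_b = 0.3 + rep(c(0.02, -0.02), 5))
  expect_equal(bland_altman(sym)$bias, 0)

  # differences drawn near the scale reported for paired validation fits
  d <- withr::with_seed(99, rnorm(50, mean = 0.004, sd = 0.01))
  ba <- bland_altman(data.frame(r2_a = 0.3, r2_b = 0.3 + d))
  expect_equal(ba$bias, 0.004, tolerance = 0.8)      # MC scatter of the mean
  expect_equal(ba$loa_upper - ba$bias, 1.96 * 0.01, tolerance = 0.25)
  expect_equal(ba$loa_lower - ba$bias, -1.96 * 0.01, tolerance = 0.25)
  expect_lt(abs(ba$bias), 0.02)

  expect_error(bland_altman(zero[1:2, ]), "at least 3")
  expect_warning(bland_altman(data.frame(r2_a = rep(0, 5),
                                         r2_b = rep(0.1, 5))),
                 "degenerate")
})

test_that("bootstrapping a model against itself finds no superiority", {
  co <- make_demo_cohort(60, seed = 42)
  co$tsroi_t3 <- withr::with_seed(1, co$memory + rnorm(60, sd = 0.8))
  # competitor = the same single TsROI mean: S is an affine map of it, so
  # both models span the same column space and every difference is zero
  b <- bootstrap_r2_difference(co, "memory", competitor = "tsroi_t3",
                               n_boot = 150, seed = 3)
  expect_equal(max(abs(b$diffs)), 0, tolerance = 1e-10)
  expect_false(any(b$intervals$superior))
})

test_that("bootstrap intervals nest across confidence levels", {
  w <- local_eval_world()
  means <- roi_mean_vector(w$sim$volumes, w$ms,
                           subject_ids = w$sim$cohort$subject_id)
  data <- cbind(w$sim$cohort, means[, -1])
  b <- bootstrap_r2_difference(data, "memory", competitor = character(0),
                               n_boot = 250, seed = 8)
  iv <- b$intervals[order(b$intervals$level), ]
  expect_true(all(diff(iv$lower) <= 1e-12))
  expect_true(all(diff(iv$upper) >= -1e-12))
  # superiority flags are monotone: superiority at a high level implies it
  # at every lower level (non-increasing in the level ordering)
  expect_true(all(diff(as.integer(iv$superior)) <= 0))
  # planted signal beats demographics-only here
  expect_gt(b$observed, 0)

  # same lineage, more resamples: observed identical, intervals close
  b2 <- bootstrap_r2_difference(data, "memory", competitor = character(0),
                                n_boot = 1000, seed = 8)
  expect_equal(b2$observed, b$observed)
  expect_equal(b2$intervals$lower, b$intervals$lower, tolerance = 0.15)
})

test_that("BCa intervals are available and bracket the point estimate", {
  w <- local_eval_world()
  means <- roi_mean_vector(w$sim$volumes, w$ms,
                           subject_ids = w$sim$cohort$subject_id)
  data <- cbind(w$sim$cohort, means[, -1])
  b <- bootstrap_r2_difference(data, "memory", competitor = character(0),
                               n_boot = 200, seed = 5, ci_type = "bca")
  expect_true(all(b$intervals$lower <= b$observed))
  expect_true(all(b$intervals$upper >= b$observed))
})

test_that("diagnosis interaction test is calibrated under equal slopes", {
  pvals <- vapply(1:60, function(r) {
    withr::with_seed(5000 + r, {
      n <- 120
      S <- rnorm(n)
      dx <- sample(c("CN", "MCI", "Dementia"), n, replace = TRUE)
      df <- data.frame(age = runif(n, 55, 90), gender = rbinom(n, 1, 0.5),
                       education = round(runif(n, 10, 20)), S = S,
                       diagnosis = dx)
      # same S-slope in every group; group main effects allowed
      df$memory <- 0.5 * S + ifelse(dx == "CN", 0.3, 0) + rnorm(n)
      diagnosis_interaction(df, "memory")$p_interaction
    })
  }, numeric(1))
  expect_equal(mean(pvals < 0.05), 0.05, tolerance = 0.08)  # absolute band
})

test_that("diagnosis interaction power grows with the slope gap", {
  p_at_gap <- function(gap) {
    median(vapply(1:15, function(r) withr::with_seed(7000 + 31 * r, {
      n <- 150
      S <- rnorm(n)
      dx <- rep(c("CN", "MCI", "Dementia"), length.out = n)
      slope <- 0.5 + gap * (dx == "Dementia")
      df <- data.frame(age = runif(n, 55, 90), gender = rbinom(n, 1, 0.5),
                       education = round(runif(n, 10, 20)), S = S,
                       diagnosis = dx,
                       memory = slope * S + rnorm(n))
      diagnosis_interaction(df, "memory")$p_interaction
    }), numeric(1)))
  }
  p0 <- p_at_gap(0); p1 <- p_at_gap(0.8); p2 <- p_at_gap(2)
  expect_gt(p0, p2)
  expect_gt(p1, p2)

  df1 <- data.frame(age = 1:20, gender = rep(0:1, 10), education = 12,
                    S = rnorm(20), diagnosis = "CN", memory = rnorm(20))
  expect_error(diagnosis_interaction(df1, "memory"), "2 levels")
})
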