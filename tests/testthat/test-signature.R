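make_maskset <- function(dims, regions, t_levels = c(3, 5, 7)) {
  masks <- lapply(regions, function(r) {
    a <- array(FALSE, dims); a[r] <- TRUE; gm_mask(a)
  })
  names(masks) <- paste0("t", t_levels[seq_along(masks)])
  structure(list(masks = masks, t_levels = t_levels[seq_along(masks)],
                 provenance = list()), class = "signature_mask_set")
}

test_that("TsROI means reduce volumes correctly", {
  dims <- c(6, 6, 6)
  ms <- make_maskset(dims, list(1:10, 11, 101:150))
  vols <- list(gm_volume(array(2.5, dims)),
               gm_volume(array(seq_len(216) / 10, dims)))
  mv <- roi_mean_vector(vols, ms)
  expect_equal(unname(unlist(mv[1, -1])), rep(2.5, 3))
  expect_equal(mv$tsroi_t5[2], 1.1)               # single-voxel mask
  expect_equal(mv$tsroi_t3[2], mean((1:10) / 10))

  # block-constant volume with disjoint masks
  blocks <- array(0, dims); blocks[1:10] <- 4; blocks[101:150] <- 9
  mv2 <- roi_mean_vector(list(gm_volume(blocks)), ms)
  expect_equal(mv2$tsroi_t3, 4)
  expect_equal(mv2$tsroi_t7, 9)

  # empty level skipped with warning; all empty errors
  ms_empty <- make_maskset(dims, list(1:10, integer(0)))
  expect_warning(mv3 <- roi_mean_vector(vols, ms_empty), "empty")
  expect_false("tsroi_t5" %in% names(mv3))
  expect_error(suppressWarnings(
    roi_mean_vector(vols, make_maskset(dims, list(integer(0))))), "empty")
})

test_that("GM-matrix and volume-list paths agree on TsROI means", {
  dims <- c(6, 6, 6)
  ms <- make_maskset(dims, list(1:30, 5:12))
  vols <- make_random_volumes(9, dims, seed = 3)
  mask <- full_mask(dims)
  a <- roi_mean_vector(vols, ms)
  b <- roi_mean_vector(gm_matrix(vols, mask), ms, analysis_mask = mask)
  expect_equal(a[, -1], b[, -1], tolerance = 1e-12)
})

test_that("signature variable fitting matches the normal-equation oracle", {
  co <- make_demo_cohort(8, seed = 12)
  tsroi <- data.frame(subject_id = co$subject_id,
                      tsroi_t3 = withr::with_seed(1, rnorm(8)),
                      tsroi_t5 = withr::with_seed(2, rnorm(8)),
                      tsroi_t7 = withr::with_seed(3, rnorm(8)))
  sv <- fit_signature_variable(co, tsroi, "memory")
  X <- cbind(1, as.matrix(tsroi[, -1]))
  beta <- solve(t(X) %*% X, t(X) %*% co$memory)
  expect_equal(unname(sv$model$coefficients), unname(drop(beta)),
               tolerance = 1e-8)
  expect_equal(unname(sv$S), drop(X %*% beta), tolerance = 1e-8)
})

test_that("signature regression handles exact and null dependence", {
  co <- make_demo_cohort(30, seed = 7)
  tsroi <- data.frame(subject_id = co$subject_id,
                      tsroi_t3 = withr::with_seed(4, rnorm(30)),
                      tsroi_t5 = withr::with_seed(5, rnorm(30)),
                      tsroi_t7 = withr::with_seed(6, rnorm(30)))
  # outcome exactly linear in the first mean: other betas vanish
  co$memory <- 2 + 3 * tsroi$tsroi_t3
  sv <- fit_signature_variable(co, tsroi, "memory")
  expect_equal(unname(sv$model$coefficients[c("tsroi_t5", "tsroi_t7")]),
               c(0, 0), tolerance = 1e-8)
  expect_equal(unname(sv$S[co$subject_id]), co$memory, tolerance = 1e-8)

  # outcome independent: R^2 near 0, S near the outcome mean
  co$memory <- withr::with_seed(9, rnorm(30))
  sv0 <- fit_signature_variable(co, tsroi, "memory")
  expect_lt(sv0$model$r_squared, 0.35)
  expect_lt(sd(sv0$S), sd(co$memory))
})

test_that("collinear TsROI means fall back to a flagged pseudo-inverse", {
  co <- make_demo_cohort(20, seed = 3)
  base <- withr::with_seed(10, rnorm(20))
  tsroi <- data.frame(subject_id = co$subject_id, tsroi_t3 = base,
                      tsroi_t5 = 2 * base, tsroi_t7 = base + 1)
  expect_warning(sv <- fit_signature_variable(co, tsroi, "memory"),
                 "pseudo-inverse")
  expect_true(sv$model$pseudo_inverse)
  expect_true(all(is.finite(sv$S)))
})

test_that("outcome models report R2 and adjusted R2 per the fit invariant", {
  co <- make_demo_cohort(40, seed = 21)
  f <- fit_outcome_model(co, "memory")
  expect_equal(f$adj_r_squared,
               1 - (1 - f$r_squared) * (f$n - 1) / (f$n - f$p - 1))
  expect_lte(f$adj_r_squared, f$r_squared)

  # intercept-only model
  f0 <- fit_outcome_model(co, "memory", character(0), label = "null")
  expect_equal(f0$r_squared, 0)
  expect_equal(f0$adj_r_squared, 0)

  # perfect fit
  co$exact <- 1 + 2 * co$age
  fp <- suppressWarnings(fit_outcome_model(co, "exact", "age"))
  expect_equal(fp$r_squared, 1, tolerance = 1e-12)
  expect_equal(fp$adj_r_squared, 1, tolerance = 1e-12)

  # printed-arithmetic check of the adjustment formula
  expect_equal(gmsignature:::adjusted_r2(0.5, 101, 4), 1 - 0.5 * 100 / 96,
               tolerance = 1e-12)

  co$age2 <- co$age
  expect_error(fit_outcome_model(co, "memory", c("age", "age2")), "age2")
})

test_that("frozen-coefficient signatures transfer across sets", {
  co <- make_demo_cohort(30, seed = 31)
  tsroi <- data.frame(subject_id = co$subject_id,
                      tsroi_t3 = withr::with_seed(7, rnorm(30)))
  sv <- fit_signature_variable(co, tsroi, "memory")
  new_means <- data.frame(subject_id = c("x", "y"),
                          tsroi_t3 = c(0, 1))
  S <- predict_signature(sv$model, new_means)
  b <- sv$model$coefficients
  expect_equal(unname(S), unname(c(b[1], b[1] + b[2])), tolerance = 1e-10)
  expect_error(predict_signature(sv$model,
                                 data.frame(subject_id = "x", other = 1)),
               "tsroi_t3")
})

test_that("atlas ROI means honor labels and reject absent ones", {
  dims <- c(6, 6, 6)
  lab <- array(0L, dims); lab[1:20] <- 1L; lab[30:49] <- 2L
  atlas <- gm_volume(lab)
  vols <- list(gm_volume(array(3, dims)))
  m <- atlas_roi_means(vols, atlas, c(hippocampus = 1, caudate = 2))
  expect_equal(m$hippocampus, 3)
  expect_equal(m$caudate, 3)

  blocks <- array(0, dims); blocks[1:20] <- 5; blocks[30:49] <- 7
  m2 <- atlas_roi_means(list(gm_volume(blocks)), atlas,
                        c(hippocampus = 1, caudate = 2))
  expect_equal(m2$hippocampus, 5)
  expect_equal(m2$caudate, 7)

  expect_error(atlas_roi_means(vols, atlas, c(amygdala = 9)), "amygdala")
})
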