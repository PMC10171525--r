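mask_from_voxels <- function(vox, dims = c(8, 8, 8)) {
  a <- array(FALSE, dims); a[vox] <- TRUE
  gm_mask(a)
}

test_that("adjacency definitions distinguish faces from corners", {
  dims <- c(8, 8, 8)
  # two voxels sharing a face
  a <- array(FALSE, dims); a[2, 2, 2] <- a[3, 2, 2] <- TRUE
  cs <- label_clusters(gm_mask(a), 6)
  expect_length(cs$clusters, 1)
  expect_equal(cs$sizes, 2)

  # sharing only a corner: separate at 6, joined at 26
  b <- array(FALSE, dims); b[2, 2, 2] <- b[3, 3, 3] <- TRUE
  expect_length(label_clusters(gm_mask(b), 6)$clusters, 2)
  expect_length(label_clusters(gm_mask(b), 18)$clusters, 2)
  expect_length(label_clusters(gm_mask(b), 26)$clusters, 1)

  # sharing an edge: joined at 18
  d <- array(FALSE, dims); d[2, 2, 2] <- d[3, 3, 2] <- TRUE
  expect_length(label_clusters(gm_mask(d), 6)$clusters, 2)
  expect_length(label_clusters(gm_mask(d), 18)$clusters, 1)

  expect_length(label_clusters(gm_mask(array(FALSE, dims)), 26)$clusters, 0)
})

test_that("component labeling matches a flood-fill oracle on random masks", {
  for (conn in c(6, 18, 26)) {
    for (rep in 1:3) {
      dims <- c(20, 20, 20)
      a <- withr::with_seed(rep * 10 + conn,
                            array(runif(prod(dims)) < 0.12, dims))
      cs <- label_clusters(gm_mask(a), conn)
      oracle <- oracle_components(which(a), dims, conn)
      # same partition: compare as sets of sorted index vectors
      expect_setequal(lapply(cs$clusters, paste, collapse = ","),
                      lapply(oracle, paste, collapse = ","))
    }
  }
})

test_that("cluster ordering is size-descending with index tie-breaks", {
  a <- array(FALSE, c(8, 8, 8))
  a[6:7, 6, 6] <- TRUE          # size 2, high index
  a[1:2, 1, 1] <- TRUE          # size 2, low index
  a[4, 4, 1:4] <- TRUE          # size 4
  cs <- label_clusters(gm_mask(a), 6)
  expect_equal(cs$sizes, c(4, 2, 2))
  expect_equal(cs$clusters[[2]][1], 1)   # tie broken by smallest index
})

test_that("identity permutation reproduces the observed maximum", {
  sim <- small_sim(n = 40, effect = 0.12, seed = 3)
  mask <- make_analysis_mask(sim$template, 0.3)
  tm <- voxelwise_tmap(sim$cohort, sim$volumes, mask, "memory")
  obs <- label_clusters(signed_threshold(tm, 2), 26)
  null <- permutation_null(sim$cohort, sim$volumes, mask, "memory",
                           t_thresh = 2, direction = "positive",
                           perms = matrix(1:40, nrow = 1))
  expect_equal(null$max_sizes, max(obs$sizes))
})

test_that("seeded draws without duplication reproduce exhaustive enumeration", {
  co <- make_demo_cohort(6, seed = 41)
  vols <- make_random_volumes(6, c(5, 5, 5), seed = 42)
  mask <- full_mask(c(5, 5, 5))
  ex <- permutation_null(co, vols, mask, "memory", t_thresh = 1.5,
                         covariates = character(0), exhaustive = TRUE,
                         min_n = 4)
  expect_equal(ex$n_perm, 720)
  dr <- permutation_null(co, vols, mask, "memory", t_thresh = 1.5,
                         covariates = character(0), n_perm = 720,
                         unique_perms = TRUE, seed = 99, min_n = 4)
  expect_identical(sort(ex$max_sizes), sort(dr$max_sizes))
})

test_that("permutation engine is reproducible and seed-sensitive", {
  sim <- small_sim(n = 30, effect = 0, seed = 13)
  mask <- make_analysis_mask(sim$template, 0.3)
  n1 <- permutation_null(sim$cohort, sim$volumes, mask, "memory", 3,
                         n_perm = 60, seed = 5)
  n2 <- permutation_null(sim$cohort, sim$volumes, mask, "memory", 3,
                         n_perm = 60, seed = 5)
  n3 <- permutation_null(sim$cohort, sim$volumes, mask, "memory", 3,
                         n_perm = 60, seed = 6)
  expect_identical(n1$max_sizes, n2$max_sizes)
  expect_false(identical(n1$max_sizes, n3$max_sizes))
})

test_that("cluster retention follows the inclusive 95th-percentile rule", {
  null_dist <- function(ms) structure(list(max_sizes = ms,
                                           n_perm = length(ms),
                                           t_thresh = 3),
                                      class = "null_cluster_dist")
  # null sizes 1..100: threshold is 95; size-95 retained, 94 not
  expect_equal(cluster_size_threshold(null_dist(sample(1:100))), 95)
  obs <- label_clusters(mask_from_voxels(1:95, c(10, 10, 10)), 26,
                        t_thresh = 3)
  expect_equal(mask_count(significant_mask(obs, null_dist(1:100))), 95)
  obs94 <- label_clusters(mask_from_voxels(1:94, c(10, 10, 10)), 26,
                          t_thresh = 3)
  expect_equal(mask_count(significant_mask(obs94, null_dist(1:100))), 0)

  # all-zero null: everything survives
  expect_equal(mask_count(significant_mask(obs94, null_dist(rep(0, 50)))), 94)
  # observed below every null value: nothing survives
  expect_equal(mask_count(significant_mask(obs94, null_dist(rep(200, 50)))), 0)
  # mismatched t-levels are rejected
  expect_error(significant_mask(obs94, null_dist_alt <- structure(
    list(max_sizes = 1:10, n_perm = 10, t_thresh = 5),
    class = "null_cluster_dist")), "t-threshold")
})

test_that("single-subset discovery is deterministic and nested pre-retention", {
  sim <- small_sim(n = 80, effect = 0.15, seed = 19)
  mask <- make_analysis_mask(sim$template, 0.3)
  cfg <- discovery_config(t_levels = c(2, 3, 4), n_perm = 80, seed = 31)
  s1 <- discover_signature_masks(sim$cohort, sim$volumes, mask, "memory", cfg)
  s2 <- discover_signature_masks(sim$cohort, sim$volumes, mask, "memory", cfg)
  for (lvl in names(s1$masks))
    expect_identical(s1$masks[[lvl]]$data, s2$masks[[lvl]]$data)

  tm <- voxelwise_tmap(sim$cohort, sim$volumes, mask, "memory")
  m2 <- signed_threshold(tm, 2); m3 <- signed_threshold(tm, 3)
  m4 <- signed_threshold(tm, 4)
  expect_true(all(m2$data[m3$data]))
  expect_true(all(m3$data[m4$data]))
})
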