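#' Draw random discovery subsets of subject ids
#'
#' Each subset is drawn uniformly without replacement *within itself*;
#' subsets are drawn independently of one another, so different subsets may
#' overlap (the expected pairwise intersection is `subset_size^2 / n_ids` by
#' the hypergeometric argument).  One master seed spawns per-subset
#' sub-seeds, so any subset can be recomputed in isolation.
#'
#' @param ids character or integer vector of subject ids.
#' @param k_subsets number of subsets (>= 1).
#' @param subset_size size of each subset (<= length(ids)).
#' @param seed master seed.
#' @return list of `k_subsets` id vectors.
#' @export
sample_subsets <- function(ids, k_subsets, subset_size, seed = 1) {
  stopifnot(k_subsets >= 1)
  if (subset_size > length(ids))
    stop(sprintf("subset_size (%d) exceeds number of ids (%d)",
                 subset_size, length(ids)))
  seeds <- spawn_seeds(seed, k_subsets)
  lapply(seq_len(k_subsets), function(k)
    with_seed(seeds[k], sample(ids, subset_size)))
}

#' Mean pairwise intersection size of a list of subsets
#' @param subsets list of id vectors.
#' @return mean over all pairs of `length(intersect(a, b))`.
#' @export
mean_pairwise_overlap <- function(subsets) {
  k <- length(subsets)
  stopifnot(k >= 2)
  tot <- 0
  for (i in 1:(k - 1))
    for (j in (i + 1):k)
      tot <- tot + length(intersect(subsets[[i]], subsets[[j]]))
  tot / (k * (k - 1) / 2)
}

#' Overlap frequency map of a list of signature masks
#'
#' @param masks list of aligned `gm_mask` objects (one per discovery subset).
#' @param t_thresh optional t-level recorded for provenance.
#' @return a `frequency_map`: list with `counts` (integer [gm_volume()]),
#'   `K` (number of masks), `t_thresh`.
#' @export
frequency_map <- function(masks, t_thresh = NA_real_) {
  stopifnot(length(masks) >= 1)
  for (m in masks[-1]) stop_unless_aligned(masks[[1]], m, "frequency masks")
  counts <- Reduce(`+`, lapply(masks, function(m) array(as.integer(m$data),
                                                        dim(m$data))))
  structure(list(counts = gm_volume(counts, masks[[1]]$voxel_size,
                                    masks[[1]]$space_tag),
                 K = length(masks), t_thresh = t_thresh),
            class = "frequency_map")
}

#' Consensus mask from an overlap frequency map
#'
#' Keeps voxels contained in at least `threshold_fraction` of the masks;
#' the count threshold is `ceiling(threshold_fraction * K)` (inclusive), so
#' with the default 0.70 and K = 40 a voxel needs 28 of the 40 masks.
#'
#' @param freq a [frequency_map()].
#' @param threshold_fraction fraction in (0, 1].
#' @return a `gm_mask` (possibly empty).
#' @export
consensus_mask <- function(freq, threshold_fraction = 0.70) {
  stopifnot(threshold_fraction > 0, threshold_fraction <= 1)
  need <- ceiling(threshold_fraction * freq$K)
  gm_mask(freq$counts$data >= need, like = freq$counts)
}

#' Configuration for consensus discovery
#'
#' Defaults are the production-scale settings: 40 discovery subsets of size
#' 400, t-levels 3/5/7, 2000 permutations per null, 70% consensus.
#'
#' @param k_subsets number of discovery subsets.
#' @param subset_size subjects per subset.
#' @param t_levels,n_perm,direction,connectivity,alpha,scheme
#'   per-subset discovery settings (see [discovery_config()]).
#' @param consensus_fraction consensus threshold fraction.
#' @param seed master seed.
#' @return a `consensus_config` list.
#' @export
consensus_config <- function(k_subsets = 40, subset_size = 400,
                             t_levels = c(3, 5, 7), n_perm = 2000,
                             direction = "positive", connectivity = 26,
                             alpha = 0.05, scheme = "freedman_lane",
                             consensus_fraction = 0.70, seed = 1) {
  structure(list(k_subsets = k_subsets, subset_size = subset_size,
                 t_levels = t_levels, n_perm = n_perm, direction = direction,
                 connectivity = connectivity, alpha = alpha, scheme = scheme,
                 consensus_fraction = consensus_fraction, seed = seed),
            class = "consensus_config")
}

#' Random-subset consensus discovery of signature masks
#'
#' Draws `k_subsets` random discovery subsets, runs per-subset signature
#' discovery ([discover_signature_masks()]) in each, and aggregates the
#' per-subset TsROI masks into overlap frequency maps and consensus masks at
#' every t-level.
#'
#' @param cohort cohort data.frame (complete cases for `outcome` are used).
#' @param volumes list of subject volumes in cohort row order, or a
#'   [gm_matrix()] over `mask` whose rows match the complete-case cohort.
#' @param mask analysis `gm_mask`.
#' @param outcome outcome column name.
#' @param config a [consensus_config()].
#' @return list with `mask_set` (consensus `signature_mask_set`),
#'   `freq_maps` (per t-level [frequency_map()]), `subset_masks` (per-subset
#'   `signature_mask_set`s), `subsets` (id lists), `provenance`.
#' @export
run_consensus_discovery <- function(cohort, volumes, mask, outcome,
                                    config = consensus_config()) {
  cc <- complete_for_outcome(cohort, outcome)
  G <- if (is.matrix(volumes)) {
    if (nrow(volumes) != nrow(cc))
      stop("GM matrix rows must match complete-case cohort rows")
    gm_matrix(volumes, mask)
  } else {
    gm_matrix(volumes[cohort$subject_id %in% cc$subject_id], mask)
  }
  subsets <- sample_subsets(cc$subject_id, config$k_subsets,
                            config$subset_size, seed = config$seed)
  subset_seeds <- spawn_seeds(config$seed + 1L, config$k_subsets)
  dcfg <- discovery_config(t_levels = config$t_levels,
                           n_perm = config$n_perm,
                           direction = config$direction,
                           connectivity = config$connectivity,
                           alpha = config$alpha, scheme = config$scheme)
  subset_masks <- vector("list", config$k_subsets)
  for (k in seq_len(config$k_subsets)) {
    rows <- match(subsets[[k]], cc$subject_id)
    Gk <- G[rows, , drop = FALSE]
    attr(Gk, "mask_voxels") <- attr(G, "mask_voxels")
    dcfg$seed <- subset_seeds[k]
    subset_masks[[k]] <- discover_signature_masks(cc[rows, , drop = FALSE],
                                                  Gk, mask, outcome, dcfg)
  }
  freq_maps <- list()
  cons <- list()
  for (i in seq_along(config$t_levels)) {
    lvl <- paste0("t", config$t_levels[i])
    freq_maps[[lvl]] <- frequency_map(lapply(subset_masks,
                                             function(s) s$masks[[lvl]]),
                                      t_thresh = config$t_levels[i])
    cons[[lvl]] <- consensus_mask(freq_maps[[lvl]],
                                  config$consensus_fraction)
    if (mask_count(cons[[lvl]]) == 0)
      warning(sprintf("consensus mask at t = %g is empty",
                      config$t_levels[i]))
  }
  prov <- list(outcome = outcome, n_cohort = nrow(cc),
               n_excluded = attr(cc, "n_excluded"),
               config = unclass(config), seed = config$seed,
               config_hash = config_hash(unclass(config)))
  mask_set <- structure(list(masks = cons, t_levels = config$t_levels,
                             provenance = prov),
                        class = "signature_mask_set")
  list(mask_set = mask_set, freq_maps = freq_maps,
       subset_masks = subset_masks, subsets = subsets, provenance = prov)
}
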