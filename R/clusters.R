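# Neighbor offsets (half-set: lexicographically positive) for a 3D
# connectivity scheme: 6 = faces, 18 = faces+edges, 26 = faces+edges+corners.
.half_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
                 "6" = rowSums(abs(g)) == 1,
                 "18" = rowSums(abs(g)) <= 2,
                 "26" = rep(TRUE, nrow(g)),
                 stop("connectivity must be 6, 18 or 26"))
  g <- g[keep, , drop = FALSE]
  pos <- g[, 3] > 0 | (g[, 3] == 0 & (g[, 2] > 0 | (g[, 2] == 0 & g[, 1] > 0)))
  g[pos, , drop = FALSE]
}

# Adjacency edge list among `idx` (sorted linear voxel indices) on a grid of
# extents `dims`; returns a 2-column matrix of positions into `idx`.
.mask_edges <- function(idx, dims, connectivity) {
  offs <- .half_offsets(connectivity)
  coords <- arrayInd(idx, dims)
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(offs))) {
    nc1 <- coords[, 1] + offs[k, 1]
    nc2 <- coords[, 2] + offs[k, 2]
    nc3 <- coords[, 3] + offs[k, 3]
    ok <- nc1 >= 1L & nc1 <= dims[1] & nc2 >= 1L & nc2 <= dims[2] &
      nc3 >= 1L & nc3 <= dims[3]
    if (!any(ok)) next
    nlin <- (nc3[ok] - 1L) * dims[1] * dims[2] + (nc2[ok] - 1L) * dims[1] +
      nc1[ok]
    j <- match(nlin, idx)
    hit <- !is.na(j)
    from <- c(from, which(ok)[hit])
    to <- c(to, j[hit])
  }
  cbind(from, to)
}

.component_membership <- function(idx, dims, connectivity) {
  k <- length(idx)
  if (k == 0L) return(integer(0))
  if (k == 1L) return(1L)
  edges <- .mask_edges(idx, dims, connectivity)
  g <- igraph::make_empty_graph(n = k, directed = FALSE)
  if (nrow(edges) > 0)
    g <- igraph::add_edges(g, as.vector(t(edges)))
  igraph::components(g)$membership
}

.max_component_size <- function(idx, dims, connectivity) {
  k <- length(idx)
  if (k <= 1L) return(k)
  max(tabulate(.component_membership(idx, dims, connectivity)))
}

#' Decompose a binary mask into connected clusters
#'
#' Connected-component decomposition under face (6), face+edge (18) or
#' face+edge+corner (26) adjacency.  Clusters are ordered by size descending,
#' ties broken by smallest linear voxel index, so the ordering is
#' deterministic.
#'
#' @param mask a `gm_mask`.
#' @param connectivity 6, 18 or 26 (default 26).
#' @param t_thresh optional t-threshold recorded for provenance.
#' @return a `cluster_set`: list with `clusters` (list of sorted linear voxel
#'   index vectors), `sizes`, `t_thresh`, `connectivity`, and the mask
#'   geometry (`dim`, `voxel_size`, `space_tag`).
#' @export
label_clusters <- function(mask, connectivity = 26, t_thresh = NA_real_) {
  stopifnot(inherits(mask, "gm_mask"))
  dims <- dim(mask$data)
  idx <- which(mask$data)
  memb <- .component_membership(idx, dims, connectivity)
  clusters <- if (length(idx)) unname(split(idx, memb)) else list()
  clusters <- lapply(clusters, sort)
  if (length(clusters)) {
    sizes <- lengths(clusters)
    firsts <- vapply(clusters, `[`, numeric(1), 1L)
    ord <- order(-sizes, firsts)
    clusters <- clusters[ord]
  }
  structure(list(clusters = clusters, sizes = lengths(clusters),
                 t_thresh = t_thresh, connectivity = connectivity,
                 dim = dims, voxel_size = mask$voxel_size,
                 space_tag = mask$space_tag),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d cluster(s), connectivity %d%s; sizes: %s\n",
              length(x$clusters), x$connectivity,
              if (is.na(x$t_thresh)) "" else sprintf(", t >= %g", x$t_thresh),
              paste(utils::head(x$sizes, 10), collapse = ", ")))
  invisible(x)
}

# Shared design preparation for the t-map and its permutation null.
.prepare_design <- function(cohort, volumes, mask, outcome,
                            covariates = c("age", "gender", "education"),
                            min_n = 10) {
  cc <- complete_for_outcome(cohort, outcome)
  if (is.matrix(volumes)) {
    if (nrow(volumes) != nrow(cc))
      stop("GM matrix rows must match complete-case cohort rows")
    G <- gm_matrix(volumes, mask)
  } else {
    keep <- cohort$subject_id %in% cc$subject_id
    G <- gm_matrix(volumes[keep], mask)
  }
  n <- nrow(cc)
  p_total <- length(covariates) + 2L
  if (n < min_n || n <= p_total + 2)
    stop(sprintf("need n >= %d and n > %d subjects, got %d", min_n,
                 p_total + 2, n))
  des <- covariate_design(cc, covariates)
  y <- cc[[outcome]]
  Gr <- qr.resid(des$qr, G)
  list(cc = cc, qr = des$qr, y = y, e = qr.resid(des$qr, y),
       Gr = Gr, gg = colSums(Gr^2),
       df = n - p_total, n = n, mask_voxels = attr(G, "mask_voxels"),
       dims = dim(mask$data))
}

# All permutations of 1..n as an (n!, n) matrix (small n only).
.all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .all_perms(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- matrix(0L, nrow(sub), n)
    block[, pos] <- n
    block[, -pos] <- sub
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

.draw_perms <- function(n, n_perm, seed, unique_perms = FALSE) {
  with_seed(seed, {
    if (!unique_perms) {
      t(replicate(n_perm, sample.int(n)))
    } else {
      if (n <= 12 && n_perm > factorial(n))
        stop("cannot draw more distinct permutations than n!")
      seen <- character(0)
      out <- matrix(0L, n_perm, n)
      got <- 0L
      while (got < n_perm) {
        p <- sample.int(n)
        key <- paste(p, collapse = ",")
        if (!key %in% seen) {
          got <- got + 1L
          out[got, ] <- p
          seen <- c(seen, key)
        }
      }
      out
    }
  })
}

#' Permutation null distribution of maximal cluster size
#'
#' Recomputes the voxelwise t-map under permuted brain-outcome pairings,
#' thresholds it, and records the maximal suprathreshold cluster size per
#' permutation (0 when nothing survives).  The default scheme is
#' Freedman-Lane: the outcome's residuals under the nuisance-only model
#' (age, gender, education) are permuted and refitted, preserving the
#' covariate structure; `scheme = "raw"` shuffles the outcome itself.
#'
#' @param cohort,volumes,mask,outcome,covariates as [voxelwise_tmap()].
#' @param t_thresh positive t threshold.
#' @param direction `"positive"`, `"negative"` or `"absolute"`.
#' @param n_perm number of permutations (production default 2000; use
#'   >= 100 outside tests).
#' @param seed RNG seed (ignored when `perms` given or `exhaustive`).
#' @param connectivity cluster connectivity (6, 18, 26).
#' @param scheme `"freedman_lane"` (default) or `"raw"`.
#' @param perms optional integer matrix of permutations (rows), overriding
#'   random draws — e.g. a single identity row.
#' @param exhaustive enumerate all `n!` permutations (requires n <= 8).
#' @param unique_perms draw permutations without duplication.
#' @param min_n smallest admissible n; production analyses keep the default
#'   10, verification runs on tiny designs (e.g. exhaustive enumeration with
#'   a reduced covariate set) may lower it.
#' @return a `null_cluster_dist`: list with `max_sizes`, `n_perm`,
#'   `t_thresh`, `seed`, `connectivity`, `scheme`.
#' @export
permutation_null <- function(cohort, volumes, mask, outcome, t_thresh,
                             direction = c("positive", "negative",
                                           "absolute"),
                             n_perm = 2000, seed = 1, connectivity = 26,
                             scheme = c("freedman_lane", "raw"),
                             covariates = c("age", "gender", "education"),
                             perms = NULL, exhaustive = FALSE,
                             unique_perms = FALSE, min_n = 10, prep = NULL) {
  direction <- match.arg(direction)
  scheme <- match.arg(scheme)
  stopifnot(t_thresh > 0)
  if (is.null(prep))
    prep <- .prepare_design(cohort, volumes, mask, outcome, covariates,
                            min_n = min_n)
  n <- prep$n
  if (exhaustive) {
    if (n > 8) stop("exhaustive enumeration limited to n <= 8")
    perms <- .all_perms(n)
  }
  if (is.null(perms)) {
    perms <- .draw_perms(n, n_perm, seed, unique_perms)
  }
  n_perm <- nrow(perms)
  base <- if (scheme == "freedman_lane") prep$e else prep$y
  max_sizes <- integer(n_perm)
  chunk <- 256L
  sqrt_df <- sqrt(prep$df)
  undef <- prep$gg <= 1e-12 * max(prep$gg, 1)
  for (start in seq(1L, n_perm, by = chunk)) {
    cols <- start:min(start + chunk - 1L, n_perm)
    E <- matrix(base[t(perms[cols, , drop = FALSE])], nrow = n)
    Z <- qr.resid(prep$qr, E)
    num <- crossprod(prep$Gr, Z)
    zz <- colSums(Z^2)
    denom2 <- outer(prep$gg, zz) - num^2
    tmat <- num * sqrt_df / sqrt(pmax(denom2, .Machine$double.eps))
    if (any(undef)) tmat[undef, ] <- NA_real_
    for (b in seq_along(cols)) {
      t_b <- tmat[, b]
      supra <- switch(direction,
                      positive = t_b >= t_thresh,
                      negative = t_b <= -t_thresh,
                      absolute = abs(t_b) >= t_thresh)
      supra[is.na(supra)] <- FALSE
      idx <- prep$mask_voxels[supra]
      max_sizes[cols[b]] <- .max_component_size(idx, prep$dims, connectivity)
    }
  }
  structure(list(max_sizes = max_sizes, n_perm = n_perm, t_thresh = t_thresh,
                 seed = seed, connectivity = connectivity, scheme = scheme),
            class = "null_cluster_dist")
}

#' Cluster-size significance threshold from a permutation null
#'
#' The empirical `1 - alpha` quantile: the smallest null value with at least
#' `(1-alpha) * n_perm` null values less than or equal to it.
#'
#' @param null a `null_cluster_dist`.
#' @param alpha significance level (default 0.05).
#' @return integer cluster-size threshold.
#' @export
cluster_size_threshold <- function(null, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  sort(null$max_sizes)[ceiling((1 - alpha) * null$n_perm)]
}

#' Retain clusters exceeding the permutation-null size threshold
#'
#' Clusters whose size is greater than or equal to the empirical 95th (for
#' `alpha = 0.05`) percentile of null maximal cluster sizes are retained
#' (inclusive retention: "in the top 5%").
#'
#' @param observed `cluster_set` from [label_clusters()].
#' @param null `null_cluster_dist` computed at the same t-threshold.
#' @param alpha significance level.
#' @return a `gm_mask` (possibly empty): the union of retained clusters.
#' @export
significant_mask <- function(observed, null, alpha = 0.05) {
  if (!is.na(observed$t_thresh) && !is.na(null$t_thresh) &&
      observed$t_thresh != null$t_thresh)
    stop("observed clusters and null distribution use different t-thresholds")
  q <- cluster_size_threshold(null, alpha)
  arr <- array(FALSE, observed$dim)
  for (cl in observed$clusters[observed$sizes >= q]) arr[cl] <- TRUE
  gm_mask(arr, voxel_size = observed$voxel_size,
          space_tag = observed$space_tag)
}

#' Configuration for single-subset signature discovery
#'
#' @param t_levels t-thresholds (default 3, 5, 7).
#' @param n_perm permutations per t-level (default 2000).
#' @param direction thresholding direction.
#' @param connectivity cluster connectivity.
#' @param alpha cluster-size significance level.
#' @param scheme permutation scheme.
#' @param seed master seed; each t-level's null gets its own spawned sub-seed.
#' @return a `discovery_config` list.
#' @export
discovery_config <- function(t_levels = c(3, 5, 7), n_perm = 2000,
                             direction = "positive", connectivity = 26,
                             alpha = 0.05, scheme = "freedman_lane",
                             seed = 1) {
  structure(list(t_levels = t_levels, n_perm = n_perm, direction = direction,
                 connectivity = connectivity, alpha = alpha, scheme = scheme,
                 seed = seed),
            class = "discovery_config")
}

#' Discover signature masks in one discovery set
#'
#' Runs the voxelwise t-map once, then for each t-level a separate
#' permutation null and cluster-size retention, yielding one signature
#' (TsROI) mask per level.
#'
#' @param cohort,volumes,mask,outcome as [voxelwise_tmap()].
#' @param config a [discovery_config()].
#' @return a `signature_mask_set`: list with `masks` (named `t3`, `t5`, ...),
#'   `t_levels`, and `provenance`.
#' @export
discover_signature_masks <- function(cohort, volumes, mask, outcome,
                                     config = discovery_config()) {
  prep <- .prepare_design(cohort, volumes, mask, outcome)
  tmap <- structure(list(tvals = .tvals_from_residuals(prep$Gr, prep$e,
                                                       prep$df),
                         mask = mask, df = prep$df, outcome = outcome,
                         n = prep$n, mask_voxels = prep$mask_voxels),
                    class = "gm_tmap")
  seeds <- spawn_seeds(config$seed, length(config$t_levels))
  masks <- vector("list", length(config$t_levels))
  names(masks) <- paste0("t", config$t_levels)
  for (i in seq_along(config$t_levels)) {
    tt <- config$t_levels[i]
    thr <- signed_threshold(tmap, tt, config$direction)
    obs <- label_clusters(thr, config$connectivity, t_thresh = tt)
    null <- permutation_null(cohort, volumes, mask, outcome, t_thresh = tt,
                             direction = config$direction,
                             n_perm = config$n_perm, seed = seeds[i],
                             connectivity = config$connectivity,
                             scheme = config$scheme, prep = prep)
    masks[[i]] <- significant_mask(obs, null, config$alpha)
  }
  structure(list(masks = masks, t_levels = config$t_levels,
                 provenance = list(outcome = outcome, n = prep$n,
                                   config = unclass(config))),
            class = "signature_mask_set")
}

#' @export
print.signature_mask_set <- function(x, ...) {
  cat(sprintf("<signature_mask_set> t-levels %s; voxel counts %s\n",
              paste(x$t_levels, collapse = "/"),
              paste(vapply(x$masks, mask_count, numeric(1)),
                    collapse = "/")))
  invisible(x)
}

#' Family-wise error calibration of the cluster-size procedure
#'
#' Simulates independent no-effect cohorts (volumes are template plus
#' smoothed noise; the outcome depends only on demographics and noise), runs
#' the full t-map / threshold / permutation-null / retention chain on each,
#' and reports the fraction of cohorts in which any cluster survives — the
#' empirical family-wise error rate, which should approximate `alpha`.
#'
#' @param n_datasets number of null cohorts.
#' @param shape grid extents.
#' @param n subjects per cohort.
#' @param n_perm permutations per cohort.
#' @param t_thresh t threshold.
#' @param direction thresholding direction.
#' @param alpha retention level.
#' @param connectivity cluster connectivity.
#' @param noise_sd,noise_smooth_sigma noise model of the null volumes.
#' @param seed master seed (spawns one sub-seed per dataset).
#' @return list with `fwer_pct` (percentage), `any_retained` (logical per
#'   dataset), `n_datasets`, and the arguments used.
#' @export
fwer_calibration <- function(n_datasets = 200, shape = c(16, 16, 16), n = 60,
                             n_perm = 500, t_thresh = 3,
                             direction = "positive", alpha = 0.05,
                             connectivity = 26, noise_sd = 0.1,
                             noise_smooth_sigma = 1, seed = 1) {
  seeds <- spawn_seeds(seed, n_datasets)
  any_retained <- logical(n_datasets)
  for (d in seq_len(n_datasets)) {
    cfg <- generative_config(n_subjects = n, shape = shape,
                             effects = list(), loading = 0,
                             noise_sd = noise_sd,
                             noise_smooth_sigma = noise_smooth_sigma,
                             seed = seeds[d])
    sim <- simulate_cohort(cfg)
    mask <- make_analysis_mask(sim$template, 0.3)
    prep <- .prepare_design(sim$cohort, sim$volumes, mask, "memory")
    tmap <- structure(list(tvals = .tvals_from_residuals(prep$Gr, prep$e,
                                                         prep$df),
                           mask = mask, df = prep$df, outcome = "memory",
                           n = prep$n, mask_voxels = prep$mask_voxels),
                      class = "gm_tmap")
    thr <- signed_threshold(tmap, t_thresh, direction)
    obs <- label_clusters(thr, connectivity, t_thresh = t_thresh)
    null <- permutation_null(sim$cohort, sim$volumes, mask, "memory",
                             t_thresh = t_thresh, direction = direction,
                             n_perm = n_perm, seed = seeds[d] + 1L,
                             connectivity = connectivity, prep = prep)
    sig <- significant_mask(obs, null, alpha)
    any_retained[d] <- mask_count(sig) > 0
  }
  list(fwer_pct = 100 * mean(any_retained), any_retained = any_retained,
       n_datasets = n_datasets, n = n, n_perm = n_perm, t_thresh = t_thresh,
       alpha = alpha, seed = seed)
}
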