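`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG state without disturbing the caller's.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# One master seed deterministically spawns k sub-seeds so that per-subset /
# per-dataset computations can run in any order (or in parallel) with results
# identical to serial execution.
spawn_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

# Stable hash of an R object (used for provenance); md5 of its serialization.
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(x, NULL, version = 2), f)
  unname(tools::md5sum(f))
}

write_provenance <- function(path, config, seed, extra = list()) {
  prov <- c(list(config = config, seed = seed,
                 config_hash = config_hash(config),
                 package = "gmsignature",
                 version = as.character(utils::packageVersion("gmsignature"))),
            extra)
  jsonlite::write_json(prov, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

# --- separable 3D Gaussian smoothing -------------------------------------
# Truncated kernel (radius 3*sigma), renormalized at the grid edges; applied
# as an axis matrix product per dimension.  Suited to the small grids the
# synthetic module works on.

.gauss_axis_matrix <- function(d, sigma) {
  if (sigma <= 0) return(diag(d))
  r <- max(1L, ceiling(3 * sigma))
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  K <- matrix(0, d, d)
  for (i in seq_len(d)) {
    j <- (i - r):(i + r)
    ok <- j >= 1 & j <= d
    K[i, j[ok]] <- w[ok]
  }
  K / rowSums(K)
}

#' Smooth a 3D array with a separable Gaussian kernel
#'
#' @param a 3D numeric array.
#' @param sigma kernel standard deviation in voxels (scalar); 0 returns `a`.
#' @return smoothed array of the same shape.
#' @keywords internal
gaussian_smooth3d <- function(a, sigma) {
  d <- dim(a)
  if (sigma <= 0) return(a)
  K1 <- .gauss_axis_matrix(d[1], sigma)
  K2 <- .gauss_axis_matrix(d[2], sigma)
  K3 <- .gauss_axis_matrix(d[3], sigma)
  # axis 1
  m <- K1 %*% matrix(a, d[1])
  a <- array(m, d)
  # axis 2
  p <- aperm(a, c(2, 1, 3))
  m <- K2 %*% matrix(p, d[2])
  a <- aperm(array(m, d[c(2, 1, 3)]), c(2, 1, 3))
  # axis 3
  p <- aperm(a, c(3, 1, 2))
  m <- K3 %*% matrix(p, d[3])
  aperm(array(m, d[c(3, 1, 2)]), c(2, 3, 1))
}

# Interior variance-shrink factor of the smoothing operator: smoothing white
# noise of sd 1 yields sd sqrt(prod_axis sum(w^2)).  Used to rescale smoothed
# noise back to a requested marginal sd.
.smooth_sd_factor <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w <- w / sum(w)
  sqrt(sum(w^2))^3
}
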