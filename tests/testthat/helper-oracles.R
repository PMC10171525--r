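# Independent oracles and small fixture builders.  Every oracle here is a
# deliberately naive implementation (explicit loops, normal equations, BFS)
# kept free of the package's computational paths.

# Per-voxel t of the GM coefficient from the full normal equations
# (X'X)^-1 X'y with design [1, g_v, covariates].
oracle_tmap_t <- function(y, G, covs) {
  vapply(seq_len(ncol(G)), function(v) {
    X <- cbind(1, G[, v], covs)
    XtX <- t(X) %*% X
    beta <- solve(XtX, t(X) %*% y)
    res <- y - X %*% beta
    df <- length(y) - ncol(X)
    sigma2 <- sum(res^2) / df
    se <- sqrt(sigma2 * solve(XtX)[2, 2])
    beta[2] / se
  }, numeric(1))
}

# Flood-fill (BFS) connected components over linear indices `idx` on a grid.
oracle_components <- function(idx, dims, connectivity) {
  if (!length(idx)) return(list())
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  offs <- switch(as.character(connectivity),
                 "6" = offs[rowSums(abs(offs)) == 1, ],
                 "18" = offs[rowSums(abs(offs)) <= 2, ],
                 "26" = offs)
  inmask <- array(FALSE, dims); inmask[idx] <- TRUE
  seen <- array(FALSE, dims)
  comps <- list()
  for (start in idx) {
    if (seen[start]) next
    queue <- start; seen[start] <- TRUE; comp <- integer(0)
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      comp <- c(comp, cur)
      co <- arrayInd(cur, dims)
      for (r in seq_len(nrow(offs))) {
        nb <- co + as.integer(offs[r, ])
        if (any(nb < 1) || any(nb > dims)) next
        lin <- (nb[3] - 1) * dims[1] * dims[2] + (nb[2] - 1) * dims[1] + nb[1]
        if (inmask[lin] && !seen[lin]) {
          seen[lin] <- TRUE
          queue <- c(queue, lin)
        }
      }
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

# Direct elementwise eta^2 evaluation.
oracle_eta2 <- function(a, b) {
  m <- (a + b) / 2
  M <- mean(c(a, b))
  num <- 0; den <- 0
  for (i in seq_along(a)) {
    num <- num + (a[i] - m[i])^2 + (b[i] - m[i])^2
    den <- den + (a[i] - M)^2 + (b[i] - M)^2
  }
  1 - num / den
}

# Demographics-only cohort table (no volumes).
make_demo_cohort <- function(n, seed = 1, outcome = NULL) {
  withr::with_seed(seed, {
    df <- data.frame(subject_id = sprintf("s%03d", seq_len(n)),
                     age = runif(n, 55, 90),
                     gender = rbinom(n, 1, 0.5),
                     education = round(runif(n, 10, 20)),
                     stringsAsFactors = FALSE)
    df$memory <- if (is.null(outcome)) rnorm(n) else outcome(df)
    df
  })
}

# Random aligned volumes on a small grid.
make_random_volumes <- function(n, dims = c(8, 8, 8), seed = 1) {
  withr::with_seed(seed, lapply(seq_len(n), function(i)
    gm_volume(array(rnorm(prod(dims)), dims))))
}

full_mask <- function(dims = c(8, 8, 8)) gm_mask(array(TRUE, dims))

# Small simulated cohort used by several files.
small_sim <- function(n = 60, shape = c(12, 12, 12), effect = 0.1,
                      seed = 5, ...) {
  simulate_cohort(generative_config(
    n_subjects = n, shape = shape,
    effects = list(effect_spec("box", lo = rep(4, 3), hi = rep(8, 3),
                               effect_size = effect)),
    seed = seed, ...))
}
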