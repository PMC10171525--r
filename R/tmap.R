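#' Extract the masked GM matrix from a set of subject volumes
#'
#' Stacks subject volumes into an `n x V` matrix over the analysis-mask
#' voxels (column `j` is voxel `which(mask$data)[j]`).  A matrix that already
#' carries the right mask passes through unchanged, so expensive conversions
#' can be hoisted out of subset loops.
#'
#' @param volumes list of aligned [gm_volume()] objects, or a previously
#'   computed GM matrix.
#' @param mask analysis `gm_mask`.
#' @return numeric matrix with attribute `mask_voxels` (linear indices).
#' @export
gm_matrix <- function(volumes, mask) {
  vox <- which(mask$data)
  if (is.matrix(volumes)) {
    if (!identical(attr(volumes, "mask_voxels"), vox))
      stop("GM matrix was built for a different mask")
    return(volumes)
  }
  stopifnot(length(volumes) >= 1)
  for (v in volumes) stop_unless_aligned(v, mask, "subject volume and mask")
  out <- matrix(0, nrow = length(volumes), ncol = length(vox))
  for (i in seq_along(volumes)) out[i, ] <- volumes[[i]]$data[vox]
  attr(out, "mask_voxels") <- vox
  out
}

# Covariate design (intercept, age, gender, education); errors name the
# offending column on rank deficiency.
covariate_design <- function(cohort,
                             covariates = c("age", "gender", "education")) {
  X <- cbind(`(Intercept)` = 1,
             as.matrix(cohort[, covariates, drop = FALSE]))
  if (any(!is.finite(X))) stop("non-finite covariate values")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("rank-deficient design: column(s) %s",
                 paste(bad, collapse = ", ")))
  }
  list(X = X, qr = qrX)
}

#' Voxelwise GLM t-map of the GM-density coefficient
#'
#' At every analysis-mask voxel, fits ordinary least squares of the outcome
#' on intercept, GM density at that voxel, age, gender, and education, and
#' records the t-statistic of the GM coefficient.  Computed for all voxels at
#' once by residualizing outcome and GM on the covariates (Frisch-Waugh);
#' the result equals the per-voxel full-design solve exactly.
#'
#' Voxels whose GM density is constant across subjects (zero residual
#' variance) are undefined (`NA`), not errors.
#'
#' @param cohort cohort data.frame (complete cases are taken per outcome).
#' @param volumes list of subject volumes in cohort row order, or a
#'   [gm_matrix()] built over `mask` whose rows match the *complete-case*
#'   rows of `cohort`.
#' @param mask analysis `gm_mask`.
#' @param outcome outcome column name.
#' @param covariates nuisance covariate columns.
#' @return a `gm_tmap`: list with `tvals` (vector over mask voxels, `NA`
#'   where undefined), `mask`, `df` (residual degrees of freedom), `outcome`,
#'   `n`.
#' @export
voxelwise_tmap <- function(cohort, volumes, mask, outcome,
                           covariates = c("age", "gender", "education")) {
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
  p_total <- length(covariates) + 2L            # + intercept + GM
  if (n < 10 || n <= p_total + 2)
    stop(sprintf("need n >= 10 and n > %d subjects, got %d", p_total + 2, n))
  des <- covariate_design(cc, covariates)
  y <- cc[[outcome]]
  yr <- qr.resid(des$qr, y)
  Gr <- qr.resid(des$qr, G)
  fit <- .tvals_from_residuals(Gr, yr, df = n - p_total)
  structure(list(tvals = fit, mask = mask, df = n - p_total,
                 outcome = outcome, n = n,
                 mask_voxels = attr(G, "mask_voxels")),
            class = "gm_tmap")
}

# t of the GM slope from covariate-residualized GM columns and outcome.
# t = num * sqrt(df) / sqrt(gg * sum(z^2) - num^2), num = Gr'z, gg = ||Gr_v||^2.
.tvals_from_residuals <- function(Gr, z, df) {
  gg <- colSums(Gr^2)
  num <- as.vector(crossprod(Gr, z))
  denom2 <- gg * sum(z^2) - num^2
  t <- rep(NA_real_, length(gg))
  ok <- gg > 1e-12 * max(gg, 1) & denom2 > 0
  t[ok] <- num[ok] * sqrt(df) / sqrt(denom2[ok])
  t
}

#' @export
print.gm_tmap <- function(x, ...) {
  cat(sprintf("<gm_tmap> outcome '%s': %d voxels, n = %d, df = %d, t in [%.2f, %.2f]\n",
              x$outcome, length(x$tvals), x$n, x$df,
              min(x$tvals, na.rm = TRUE), max(x$tvals, na.rm = TRUE)))
  invisible(x)
}

#' Convert a t-map to a volume (NA outside the analysis mask)
#' @param tmap a `gm_tmap`.
#' @return a [gm_volume()] of t-values.
#' @export
tmap_as_volume <- function(tmap) {
  arr <- array(NA_real_, dim(tmap$mask$data))
  arr[tmap$mask_voxels] <- tmap$tvals
  gm_volume(arr, tmap$mask$voxel_size, tmap$mask$space_tag)
}

#' Write a t-map as NIfTI with a JSON sidecar
#' @param tmap a `gm_tmap`.
#' @param path output `.nii`/`.nii.gz` path; sidecar replaces the extension
#'   with `.json`.
#' @return `path`, invisibly.
#' @export
write_tmap <- function(tmap, path) {
  v <- tmap_as_volume(tmap)
  v$data[is.na(v$data)] <- 0
  write_volume(v, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(outcome = tmap$outcome, n = tmap$n, df = tmap$df),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Threshold a t-map into a suprathreshold binary mask
#'
#' @param tmap a `gm_tmap`.
#' @param t_thresh positive t threshold (the paper-style levels are 3, 5, 7).
#' @param direction `"positive"` keeps `t >= t_thresh`, `"negative"` keeps
#'   `t <= -t_thresh` (the expected direction for inverse-scored outcomes),
#'   `"absolute"` keeps `|t| >= t_thresh`.  Undefined voxels never survive.
#' @return a `gm_mask`.
#' @export
signed_threshold <- function(tmap, t_thresh,
                             direction = c("positive", "negative",
                                           "absolute")) {
  direction <- match.arg(direction)
  stopifnot(t_thresh > 0)
  t <- tmap$tvals
  keep <- switch(direction,
                 positive = t >= t_thresh,
                 negative = t <= -t_thresh,
                 absolute = abs(t) >= t_thresh)
  keep[is.na(keep)] <- FALSE
  arr <- array(FALSE, dim(tmap$mask$data))
  arr[tmap$mask_voxels[keep]] <- TRUE
  gm_mask(arr, like = tmap$mask)
}
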