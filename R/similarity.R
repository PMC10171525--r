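#' Dice coefficient between two binary masks
#'
#' The default is the standard Dice score `2|A∩B| / (|A| + |B|)`, which is 1
#' exactly when two non-empty masks coincide.  `definition = "union"`
#' computes `2|A∩B| / |A∪B|` instead (a denominator convention that appears
#' in parts of the literature; it reaches 2 for identical masks).
#'
#' @param m1,m2 aligned `gm_mask` objects, not both empty.
#' @param definition `"standard"` or `"union"`.
#' @return numeric score.
#' @export
dice <- function(m1, m2, definition = c("standard", "union")) {
  definition <- match.arg(definition)
  stop_unless_aligned(m1, m2, "masks")
  a <- sum(m1$data); b <- sum(m2$data)
  if (a + b == 0) stop("Dice undefined: both masks are empty")
  inter <- sum(m1$data & m2$data)
  if (definition == "standard") 2 * inter / (a + b)
  else 2 * inter / sum(m1$data | m2$data)
}

#' Eta-squared similarity between two scalar volumes
#'
#' A voxelwise agreement measure sensitive to both local and global
#' magnitude differences:
#' `eta2 = 1 - sum((a-m)^2 + (b-m)^2) / sum((a-M)^2 + (b-M)^2)` with
#' `m = (a+b)/2` per voxel and `M` the grand mean over both images.  Equals
#' 1 for identical images; symmetric in its arguments.
#'
#' @param v1,v2 aligned `gm_volume`s.
#' @param mask aligned non-empty `gm_mask` restricting the evaluation.
#' @return numeric score.
#' @export
eta2 <- function(v1, v2, mask = NULL) {
  stop_unless_aligned(v1, v2, "volumes")
  if (is.null(mask)) {
    vox <- seq_along(v1$data)
  } else {
    stop_unless_aligned(v1, mask, "volume and mask")
    vox <- which(mask$data)
    if (!length(vox)) stop("eta2 undefined: empty mask")
  }
  a <- as.numeric(v1$data[vox]); b <- as.numeric(v2$data[vox])
  m <- (a + b) / 2
  M <- mean(c(a, b))
  denom <- sum((a - M)^2 + (b - M)^2)
  if (denom == 0) stop("eta2 undefined: zero total variance")
  1 - sum((a - m)^2 + (b - m)^2) / denom
}

#' Code a signature mask set as a t-level volume
#'
#' 0 outside every mask, otherwise the highest t-level whose mask contains
#' the voxel (the paper-style levels yield codes 0/3/5/7).  This coded
#' volume is what [eta2()] compares when scoring two signature mask sets
#' with correspondence of t-value locations.
#'
#' @param mask_set a `signature_mask_set`.
#' @return a [gm_volume()] of t-level codes.
#' @export
mask_set_coded_volume <- function(mask_set) {
  ref <- mask_set$masks[[1]]
  arr <- array(0, dim(ref$data))
  for (i in order(mask_set$t_levels))
    arr[mask_set$masks[[i]]$data] <- mask_set$t_levels[i]
  gm_volume(arr, ref$voxel_size, ref$space_tag)
}

#' Pairwise similarity of two signature mask sets
#'
#' Dice on the outermost (lowest-t, t >= 3) masks plus eta-squared on the
#' t-level coded volumes.
#'
#' @param set1,set2 `signature_mask_set`s on the same grid.
#' @param mask analysis mask over which eta-squared is evaluated (default:
#'   whole grid).
#' @param labels length-2 character vector naming the pair.
#' @return a `similarity_scores` list: `dice`, `eta2`, `labels`.
#' @export
similarity_scores <- function(set1, set2, mask = NULL,
                              labels = c("set1", "set2")) {
  lo1 <- which.min(set1$t_levels)
  lo2 <- which.min(set2$t_levels)
  structure(list(dice = dice(set1$masks[[lo1]], set2$masks[[lo2]]),
                 eta2 = eta2(mask_set_coded_volume(set1),
                             mask_set_coded_volume(set2), mask),
                 labels = labels),
            class = "similarity_scores")
}

#' @export
print.similarity_scores <- function(x, ...) {
  cat(sprintf("<similarity_scores> %s vs %s: Dice %.3f, eta2 %.3f\n",
              x$labels[1], x$labels[2], x$dice, x$eta2))
  invisible(x)
}

#' Atlas-region overlap table for a signature mask
#'
#' For each labeled atlas region, the fraction of its voxels covered by the
#' mask, `|mask ∩ region| / |region|`, sorted descending.
#'
#' @param mask a `gm_mask` (typically the t >= 3 consensus mask).
#' @param atlas aligned label `gm_volume` with integer region codes.
#' @param labels named integer vector: region name -> label code.
#' @return data.frame `region`, `label`, `region_voxels`, `overlap`
#'   (fraction in `[0, 1]`, `NA` for empty regions, flagged via the
#'   `empty_regions` attribute), sorted by overlap descending.
#' @export
atlas_overlap_table <- function(mask, atlas, labels) {
  stop_unless_aligned(mask, atlas, "mask and atlas")
  if (is.null(names(labels))) names(labels) <- paste0("roi_", labels)
  rows <- lapply(names(labels), function(nm) {
    region <- atlas$data == labels[[nm]]
    nv <- sum(region)
    data.frame(region = nm, label = labels[[nm]], region_voxels = nv,
               overlap = if (nv == 0) NA_real_ else
                 sum(mask$data & region) / nv)
  })
  out <- do.call(rbind, rows)
  empty <- out$region[is.na(out$overlap)]
  if (length(empty))
    warning(sprintf("empty atlas region(s): %s", paste(empty, collapse = ", ")))
  out <- out[order(-ifelse(is.na(out$overlap), -1, out$overlap)), ]
  rownames(out) <- NULL
  attr(out, "empty_regions") <- empty
  out
}
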