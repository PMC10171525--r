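#' Construct a 3D volume
#'
#' A `gm_volume` is the unit of imaging data in this package: a 3D scalar grid
#' (template gray-matter density, subject GM density, t-map, frequency map)
#' together with its voxel dimensions in mm and a free-text identifier of the
#' template space it lives in.  Two volumes are *aligned* when their grid
#' shapes, voxel sizes, and space tags all match; every multi-volume operation
#' in the package requires alignment.
#'
#' @param data 3D numeric (or logical) array; all three extents must be >= 1.
#' @param voxel_size numeric length-3, voxel edge lengths (dx, dy, dz) in mm,
#'   all > 0.
#' @param space_tag character scalar naming the template space.
#' @return An object of class `gm_volume`: a list with elements `data`,
#'   `voxel_size`, `space_tag`.
#' @export
gm_volume <- function(data, voxel_size = c(1, 1, 1), space_tag = "synthetic") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(dim(data) < 1L)) stop("all grid extents must be >= 1")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("`voxel_size` must be three positive finite numbers")
  structure(list(data = data, voxel_size = voxel_size,
                 space_tag = as.character(space_tag)[1]),
            class = "gm_volume")
}

#' @export
print.gm_volume <- function(x, ...) {
  cat(sprintf("<gm_volume> %s  voxels %s mm  space '%s'\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x"),
              x$space_tag))
  invisible(x)
}

#' @export
dim.gm_volume <- function(x) dim(x$data)

is_gm_volume <- function(x) inherits(x, "gm_volume")

#' Test whether two volumes are aligned
#'
#' @param a,b `gm_volume` objects (masks count as volumes).
#' @param tol relative tolerance on voxel sizes.
#' @return `TRUE` iff shapes, voxel sizes and space tags match.
#' @export
volumes_aligned <- function(a, b, tol = 1e-5) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$voxel_size - b$voxel_size) <= tol * pmax(a$voxel_size, 1)) &&
    identical(a$space_tag, b$space_tag)
}

stop_unless_aligned <- function(a, b, what = "volumes") {
  if (!volumes_aligned(a, b))
    stop(sprintf("%s are not aligned (shape/voxel size/space tag mismatch)",
                 what))
  invisible(TRUE)
}

#' Construct a binary mask on a volume grid
#'
#' @param data logical (or 0/1) 3D array.
#' @param like a `gm_volume` supplying geometry, or `NULL` to pass
#'   `voxel_size`/`space_tag` directly.
#' @param voxel_size,space_tag geometry when `like` is `NULL`.
#' @return A `gm_mask` (also a `gm_volume`) whose `data` is logical.
#' @export
gm_mask <- function(data, like = NULL, voxel_size = c(1, 1, 1),
                    space_tag = "synthetic") {
  if (!is.null(like)) {
    voxel_size <- like$voxel_size
    space_tag <- like$space_tag
    if (!identical(dim(data), dim(like$data)))
      stop("mask shape does not match parent volume")
  }
  if (is.numeric(data)) {
    if (!all(data %in% c(0, 1))) stop("mask values must be in {0,1}")
    data <- array(data != 0, dim(data))
  }
  v <- gm_volume(data, voxel_size, space_tag)
  class(v) <- c("gm_mask", class(v))
  v
}

#' Number of voxels in a mask
#' @param mask a `gm_mask`.
#' @return integer voxel count.
#' @export
mask_count <- function(mask) sum(mask$data)

#' Read a NIfTI-1 volume
#'
#' 4D inputs with a singleton last axis are squeezed to 3D; any other
#' dimensionality is rejected.  The `space_tag` is taken from the header's
#' `descrip` field (empty descriptions become `"unknown"`).
#'
#' @param path path to a readable NIfTI-1 file.
#' @return a [gm_volume()].
#' @export
read_volume <- function(path) {
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e)
                    stop(sprintf("cannot read NIfTI volume '%s': %s",
                                 path, conditionMessage(e)), call. = FALSE))
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img2 <- array(as.numeric(img), d[1:3])
    pd <- RNifti::pixdim(img)[1:3]
    tag <- .descrip_tag(img)
    return(gm_volume(img2, pd, tag))
  }
  if (length(d) != 3L)
    stop(sprintf("'%s': expected 3D volume, got %dD", path, length(d)))
  gm_volume(array(as.numeric(img), d), RNifti::pixdim(img)[1:3],
            .descrip_tag(img))
}

.descrip_tag <- function(img) {
  tag <- tryCatch(RNifti::niftiHeader(img)$descrip, error = function(e) "")
  if (is.null(tag) || !nzchar(tag)) "unknown" else tag
}

#' Write a volume as NIfTI-1
#'
#' Grid values round-trip bit-exactly (float64 storage; masks as uint8) and
#' voxel sizes to float32 precision.  The `space_tag` is stored in the header
#' `descrip` field.
#'
#' @param v a `gm_volume` or `gm_mask`.
#' @param path destination path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(is_gm_volume(v))
  dtype <- if (inherits(v, "gm_mask")) "uint8" else "double"
  arr <- if (inherits(v, "gm_mask")) array(as.integer(v$data), dim(v$data))
         else array(as.numeric(v$data), dim(v$data))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- v$voxel_size
  img <- RNifti::asNifti(img, list(descrip = v$space_tag))
  ok <- tryCatch({RNifti::writeNifti(img, path, datatype = dtype); TRUE},
                 error = function(e) FALSE)
  if (!ok || !file.exists(path))
    stop(sprintf("failed to write NIfTI volume to '%s'", path))
  invisible(path)
}

#' Define the analysis mask from a template GM density volume
#'
#' All voxelwise computation in the package iterates only over this mask:
#' voxels where the template density exceeds `min_density`.
#'
#' @param template_gm template GM density `gm_volume`.
#' @param min_density non-negative density threshold.
#' @return a `gm_mask`.
#' @export
make_analysis_mask <- function(template_gm, min_density = 0.3) {
  stopifnot(is_gm_volume(template_gm), min_density >= 0)
  m <- template_gm$data > min_density
  if (!any(m)) stop("no analysis voxels: template never exceeds min_density")
  gm_mask(m, like = template_gm)
}
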