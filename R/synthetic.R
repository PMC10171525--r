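#' Make a smooth synthetic template GM density field
#'
#' The template emulates a gray-matter density map in a common space: a
#' spatially smooth, strictly positive field with baseline density near 1.
#' Deterministic given `seed`.
#'
#' @param shape integer length-3 grid extents, each >= 8.
#' @param seed integer RNG seed.
#' @param voxel_size,space_tag geometry of the synthetic space.
#' @return a [gm_volume()].
#' @export
make_template <- function(shape = c(24, 24, 24), seed = 1,
                          voxel_size = c(1, 1, 1),
                          space_tag = "synthetic-template") {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L))
    stop("template shape must have three extents, each >= 8")
  field <- with_seed(seed, {
    z <- array(stats::rnorm(prod(shape)), shape)
    s <- gaussian_smooth3d(z, sigma = 2)
    s <- (s - mean(s)) / stats::sd(s)
    pmax(1 + 0.2 * s, 0.25)
  })
  gm_volume(field, voxel_size, space_tag)
}

#' Specify a planted spatial effect
#'
#' Defines a region on the template grid and the GM-density change per unit
#' of the subject latent trait inside it.  `effect_size` may be 0 to plant a
#' null region.
#'
#' @param shape one of `"box"`, `"sphere"`, `"voxels"`.
#' @param lo,hi box corners (1-based inclusive grid indices) for `"box"`.
#' @param center,radius sphere parameters (voxel units) for `"sphere"`.
#' @param voxels integer linear voxel indices for `"voxels"`.
#' @param effect_size GM-density units per unit latent trait.
#' @return an `effect_spec` list.
#' @export
effect_spec <- function(shape = c("box", "sphere", "voxels"),
                        lo = NULL, hi = NULL, center = NULL, radius = NULL,
                        voxels = NULL, effect_size = 0.06) {
  shape <- match.arg(shape)
  stopifnot(is.finite(effect_size))
  structure(list(shape = shape, lo = lo, hi = hi, center = center,
                 radius = radius, voxels = voxels,
                 effect_size = effect_size),
            class = "effect_spec")
}

# Render an effect region as a logical array on the given grid.
effect_region <- function(spec, dims) {
  out <- array(FALSE, dims)
  if (spec$shape == "box") {
    lo <- as.integer(spec$lo); hi <- as.integer(spec$hi)
    if (any(lo < 1L) || any(hi > dims) || any(lo > hi))
      stop("effect region outside grid")
    out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  } else if (spec$shape == "sphere") {
    ctr <- spec$center; r <- spec$radius
    if (any(ctr - r < 1) || any(ctr + r > dims))
      stop("effect region outside grid")
    g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                     z = seq_len(dims[3]))
    d2 <- (g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2
    out[d2 <= r^2] <- TRUE
  } else {
    v <- as.integer(spec$voxels)
    if (any(v < 1L) || any(v > prod(dims)))
      stop("effect region outside grid")
    out[v] <- TRUE
  }
  out
}

#' Generative configuration for synthetic cohorts
#'
#' Subject volumes are `template + sum(effect_size_r * latent_i)` inside each
#' planted region plus spatially smoothed Gaussian noise; the outcome is
#' `outcome_sign * loading * latent_i + age_coef*age + gender_coef*gender +
#' edu_coef*education + eps`.  `outcome_sign = -1` emulates inverse-scored
#' (ECog-like) outcomes in which higher scores indicate worse function, so
#' that voxelwise GM-outcome associations in planted regions are negative.
#' Diagnosis (CN / MCI / Dementia) is assigned from outcome-severity cut
#' points (tertiles by default).
#'
#' Defaults describe the study conditions the package is calibrated and
#' tested under: cohorts of a few hundred subjects on a 24^3 grid, a single
#' planted 7^3 box, per-voxel noise sd 0.1 GM units with 1-voxel smoothing,
#' unit latent loading, outcome noise sd 0.8, ages uniform on [55, 90].
#'
#' @param n_subjects cohort size (>= 1).
#' @param shape template grid extents.
#' @param effects list of [effect_spec()] objects.
#' @param latent_sd sd of the standard-normal-by-default latent trait.
#' @param noise_sd marginal sd of the per-voxel noise after smoothing.
#' @param noise_smooth_sigma Gaussian kernel sd of the noise, in voxels.
#' @param loading outcome loading on the latent trait.
#' @param age_coef,gender_coef,edu_coef demographic effects on the outcome.
#' @param outcome_noise_sd sd of outcome noise.
#' @param outcome_sign +1 or -1 (ECog-like inverse scoring).
#' @param outcome_name outcome column name in the generated cohort table.
#' @param age_range,female_frac,edu_mean,edu_sd demographic distributions.
#' @param diagnosis_cuts quantile cut points on outcome severity.
#' @param seed master seed; recorded in every output.
#' @return a `generative_config` list.
#' @export
generative_config <- function(n_subjects = 400, shape = c(24, 24, 24),
                              effects = list(effect_spec("box",
                                                         lo = c(9, 9, 9),
                                                         hi = c(15, 15, 15),
                                                         effect_size = 0.06)),
                              latent_sd = 1, noise_sd = 0.1,
                              noise_smooth_sigma = 1,
                              loading = 1, age_coef = -0.02,
                              gender_coef = 0, edu_coef = 0.03,
                              outcome_noise_sd = 0.8, outcome_sign = 1,
                              outcome_name = "memory",
                              age_range = c(55, 90), female_frac = 0.55,
                              edu_mean = 16, edu_sd = 2.5,
                              diagnosis_cuts = c(1 / 3, 2 / 3), seed = 1) {
  stopifnot(n_subjects >= 1, latent_sd >= 0, noise_sd >= 0,
            noise_smooth_sigma >= 0, outcome_noise_sd >= 0,
            outcome_sign %in% c(-1, 1))
  structure(as.list(environment()), class = "generative_config")
}

#' Simulate a cohort with known ground truth
#'
#' @param cfg a [generative_config()].
#' @return list with `cohort` (data.frame: subject_id, age, gender, education,
#'   outcome column, diagnosis, latent), `volumes` (list of [gm_volume()]),
#'   `truth` (ground-truth `gm_mask`, union of nonzero-effect regions),
#'   `template`, and `config`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "generative_config"))
  n <- cfg$n_subjects
  dims <- as.integer(cfg$shape)
  template <- make_template(dims, seed = cfg$seed + 1L)
  regions <- lapply(cfg$effects, effect_region, dims = dims)
  sizes <- vapply(cfg$effects, function(e) e$effect_size, numeric(1))
  truth_arr <- array(FALSE, dims)
  for (i in seq_along(regions))
    if (sizes[i] != 0) truth_arr <- truth_arr | regions[[i]]

  sim <- with_seed(cfg$seed, {
    age <- stats::runif(n, cfg$age_range[1], cfg$age_range[2])
    gender <- stats::rbinom(n, 1, cfg$female_frac)
    education <- pmin(pmax(round(stats::rnorm(n, cfg$edu_mean, cfg$edu_sd)),
                           8), 20)
    latent <- stats::rnorm(n, 0, cfg$latent_sd)
    y <- cfg$outcome_sign * (cfg$loading * latent) +
      cfg$age_coef * age + cfg$gender_coef * gender +
      cfg$edu_coef * education +
      stats::rnorm(n, 0, cfg$outcome_noise_sd)
    shrink <- .smooth_sd_factor(cfg$noise_smooth_sigma)
    vols <- vector("list", n)
    for (i in seq_len(n)) {
      noise <- gaussian_smooth3d(array(stats::rnorm(prod(dims)), dims),
                                 cfg$noise_smooth_sigma)
      v <- template$data + (cfg$noise_sd / shrink) * noise
      for (r in seq_along(regions))
        if (sizes[r] != 0) v[regions[[r]]] <- v[regions[[r]]] +
            sizes[r] * latent[i]
      vols[[i]] <- gm_volume(v, template$voxel_size, template$space_tag)
    }
    list(age = age, gender = gender, education = education,
         latent = latent, y = y, vols = vols)
  })

  severity <- -cfg$outcome_sign * sim$y   # higher = worse, whatever the sign
  cuts <- stats::quantile(severity, probs = cfg$diagnosis_cuts, names = FALSE)
  diagnosis <- cut(severity, c(-Inf, cuts, Inf),
                   labels = c("CN", "MCI", "Dementia"))
  cohort <- data.frame(subject_id = sprintf("s%04d", seq_len(n)),
                       age = sim$age, gender = sim$gender,
                       education = sim$education,
                       diagnosis = as.character(diagnosis),
                       latent = sim$latent, stringsAsFactors = FALSE)
  cohort[[cfg$outcome_name]] <- sim$y
  attr(cohort, "seed") <- cfg$seed
  list(cohort = cohort, volumes = sim$vols,
       truth = gm_mask(truth_arr, like = template),
       template = template, config = cfg)
}

#' Split a cohort into disjoint discovery and validation parts
#'
#' @param cohort cohort data.frame.
#' @param fraction discovery fraction, in (0, 1).
#' @param seed RNG seed.
#' @return list with `discovery` and `validation` data.frames.
#' @export
split_discovery_validation <- function(cohort, fraction = 0.5, seed = 1) {
  stopifnot(fraction > 0, fraction < 1)
  n <- nrow(cohort)
  n_disc <- floor(fraction * n)
  if (n_disc < 1 || n_disc >= n)
    stop("fraction yields an empty discovery or validation side")
  idx <- with_seed(seed, sample.int(n, n_disc))
  list(discovery = cohort[sort(idx), , drop = FALSE],
       validation = cohort[-sort(idx), , drop = FALSE])
}

#' Write a simulated cohort to disk
#'
#' Emits per-subject NIfTI volumes, the cohort CSV (with `volume_ref` paths),
#' the ground-truth mask, the template, and a JSON provenance file holding the
#' full generative configuration and seed.
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vol_dir <- file.path(dir, "volumes")
  dir.create(vol_dir, showWarnings = FALSE)
  refs <- character(nrow(sim$cohort))
  for (i in seq_len(nrow(sim$cohort))) {
    refs[i] <- file.path("volumes",
                         paste0(sim$cohort$subject_id[i], ".nii.gz"))
    write_volume(sim$volumes[[i]], file.path(dir, refs[i]))
  }
  cohort <- sim$cohort
  cohort$volume_ref <- refs
  utils::write.csv(cohort, file.path(dir, "cohort.csv"), row.names = FALSE)
  write_volume(sim$truth, file.path(dir, "truth_mask.nii.gz"))
  write_volume(sim$template, file.path(dir, "template.nii.gz"))
  cfg <- sim$config
  cfg$effects <- lapply(cfg$effects, unclass)
  write_provenance(file.path(dir, "provenance.json"), unclass(cfg),
                   seed = cfg$seed)
  invisible(dir)
}
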