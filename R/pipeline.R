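#' Full pipeline run configuration
#'
#' Bundles every stage's parameters with one master seed.  Defaults are the
#' production-scale settings (40 discovery subsets of 400, t-levels 3/5/7,
#' 2000 permutations, 70% consensus, 50 validation subsets of 200, 10000
#' bootstrap iterations, CI levels 80/90/95/99%); smoke-scale runs override
#' them.  The whole configuration is serialized verbatim into the
#' provenance JSON of every stage.
#'
#' @param generative a [generative_config()] for the `simulate` stage.
#' @param discovery a [consensus_config()] for `discover`/`consensus`.
#' @param split_fraction discovery fraction of the simulated cohort.
#' @param outcome outcome column name.
#' @param n_validation_subsets,validation_subset_size `validate` stage.
#' @param n_boot,ci_levels `compare` stage.
#' @param seed master seed (stage seeds are spawned from it).
#' @return a `run_config` list.
#' @export
run_config <- function(generative = generative_config(),
                       discovery = consensus_config(),
                       split_fraction = 0.5, outcome = "memory",
                       n_validation_subsets = 50,
                       validation_subset_size = 200,
                       n_boot = 10000,
                       ci_levels = c(0.80, 0.90, 0.95, 0.99),
                       seed = 1) {
  structure(list(generative = generative, discovery = discovery,
                 split_fraction = split_fraction, outcome = outcome,
                 n_validation_subsets = n_validation_subsets,
                 validation_subset_size = validation_subset_size,
                 n_boot = n_boot, ci_levels = ci_levels, seed = seed),
            class = "run_config")
}

.need_artifact <- function(path, stage) {
  if (!file.exists(path))
    stop(sprintf("stage '%s' requires missing artifact '%s'", stage, path))
  path
}

.load_simulation <- function(out_dir) {
  sim_dir <- file.path(out_dir, "simulate")
  cohort <- read_cohort(.need_artifact(file.path(sim_dir, "cohort.csv"),
                                       "discover"),
                        schema = list(subject_id = "subject_id", age = "age",
                                      gender = "gender",
                                      education = "education",
                                      outcomes = setdiff(
                                        names(utils::read.csv(
                                          file.path(sim_dir, "cohort.csv"),
                                          nrows = 1)),
                                        c("subject_id", "age", "gender",
                                          "education", "diagnosis", "latent",
                                          "volume_ref")),
                                      diagnosis = "diagnosis",
                                      volume_ref = "volume_ref"))
  volumes <- lapply(cohort$volume_ref,
                    function(p) read_volume(file.path(sim_dir, p)))
  template <- read_volume(file.path(sim_dir, "template.nii.gz"))
  truth_v <- read_volume(file.path(sim_dir, "truth_mask.nii.gz"))
  list(cohort = cohort, volumes = volumes, template = template,
       truth = gm_mask(truth_v$data != 0, like = truth_v))
}

.load_consensus <- function(out_dir, t_levels, stage) {
  cons_dir <- file.path(out_dir, "consensus")
  masks <- list()
  for (tt in t_levels) {
    p <- .need_artifact(file.path(cons_dir,
                                  sprintf("consensus_t%g.nii.gz", tt)),
                        stage)
    v <- read_volume(p)
    masks[[paste0("t", tt)]] <- gm_mask(v$data != 0, like = v)
  }
  structure(list(masks = masks, t_levels = t_levels,
                 provenance = list(loaded_from = cons_dir)),
            class = "signature_mask_set")
}

#' Run the discovery-validation pipeline
#'
#' Orchestrates the stages of the consensus-signature workflow on a
#' synthetic cohort: `simulate` (generate cohort, volumes, ground truth),
#' `discover` + `consensus` (random-subset discovery and consensus masks),
#' `fit` (signature variable and outcome models in the discovery half),
#' `validate` (repeated validation-subset fits and Bland-Altman agreement),
#' `compare` (bootstrap adjusted-R2 difference against the demographics
#' competitor), and `similarity` (consensus masks against ground truth).
#' Stage outputs, structured logs, and provenance JSON (config hash + seed)
#' land under `out_dir/<stage>/`; re-running with the same configuration
#' reproduces all numeric outputs.
#'
#' @param config a [run_config()].
#' @param stages subset of
#'   `c("simulate","discover","consensus","fit","validate","compare","similarity")`.
#' @param out_dir artifact directory.
#' @param quiet suppress stage log messages.
#' @return invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config, stages = c("simulate", "discover",
                                            "consensus", "fit", "validate",
                                            "compare", "similarity"),
                         out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) if (!quiet) message(sprintf(...))
  state <- list()
  t_levels <- config$discovery$t_levels

  if ("simulate" %in% stages) {
    state$sim <- simulate_cohort(config$generative)
    write_simulation(state$sim, file.path(out_dir, "simulate"))
    log_msg("simulate: %d subjects on %s grid, %d truth voxels",
            nrow(state$sim$cohort),
            paste(dim(state$sim$template$data), collapse = "x"),
            mask_count(state$sim$truth))
  }

  needs_sim <- intersect(stages, c("discover", "fit", "validate", "compare",
                                   "similarity"))
  if (length(needs_sim) && is.null(state$sim)) {
    loaded <- .load_simulation(out_dir)
    state$sim <- list(cohort = loaded$cohort, volumes = loaded$volumes,
                      template = loaded$template, truth = loaded$truth,
                      config = config$generative)
  }

  if (length(intersect(stages, c("discover", "fit", "validate",
                                 "compare", "similarity")))) {
    state$mask <- make_analysis_mask(state$sim$template, 0.3)
    state$split <- split_discovery_validation(state$sim$cohort,
                                              config$split_fraction,
                                              seed = config$seed + 17L)
    state$G <- gm_matrix(state$sim$volumes, state$mask)
  }

  if ("discover" %in% stages) {
    rows <- match(state$split$discovery$subject_id,
                  state$sim$cohort$subject_id)
    Gd <- state$G[rows, , drop = FALSE]
    attr(Gd, "mask_voxels") <- attr(state$G, "mask_voxels")
    state$consensus <- run_consensus_discovery(state$split$discovery, Gd,
                                               state$mask, config$outcome,
                                               config$discovery)
    log_msg("discover: %d subsets of %d; consensus voxels %s",
            config$discovery$k_subsets, config$discovery$subset_size,
            paste(vapply(state$consensus$mask_set$masks, mask_count,
                         numeric(1)), collapse = "/"))
  }

  if ("consensus" %in% stages) {
    if (is.null(state$consensus))
      stop("stage 'consensus' requires the 'discover' stage results")
    cons_dir <- file.path(out_dir, "consensus")
    dir.create(cons_dir, showWarnings = FALSE)
    summary_rows <- list()
    for (tt in t_levels) {
      lvl <- paste0("t", tt)
      write_volume(state$consensus$mask_set$masks[[lvl]],
                   file.path(cons_dir, sprintf("consensus_t%g.nii.gz", tt)))
      write_volume(gm_volume(
        array(as.numeric(state$consensus$freq_maps[[lvl]]$counts$data),
              dim(state$mask$data)),
        state$mask$voxel_size, state$mask$space_tag),
        file.path(cons_dir, sprintf("frequency_t%g.nii.gz", tt)))
      summary_rows[[lvl]] <- data.frame(
        t_level = tt,
        consensus_voxels = mask_count(state$consensus$mask_set$masks[[lvl]]),
        max_frequency = max(state$consensus$freq_maps[[lvl]]$counts$data))
    }
    utils::write.csv(do.call(rbind, summary_rows),
                     file.path(cons_dir, "consensus_summary.csv"),
                     row.names = FALSE)
    write_provenance(file.path(cons_dir, "provenance.json"),
                     unclass(config$discovery), seed = config$seed)
  }

  if (length(intersect(stages, c("fit", "validate", "compare",
                                 "similarity"))) &&
      is.null(state$consensus)) {
    state$mask_set <- .load_consensus(out_dir, t_levels, "fit/validate")
  } else if (!is.null(state$consensus)) {
    state$mask_set <- state$consensus$mask_set
  }

  subj_rows <- function(ids) match(ids, state$sim$cohort$subject_id)
  sub_G <- function(ids) {
    Gs <- state$G[subj_rows(ids), , drop = FALSE]
    attr(Gs, "mask_voxels") <- attr(state$G, "mask_voxels")
    Gs
  }

  if ("fit" %in% stages) {
    disc <- state$split$discovery
    sf <- signature_fit(disc, sub_G(disc$subject_id), state$mask_set,
                        config$outcome, analysis_mask = state$mask)
    demo <- fit_outcome_model(disc, config$outcome,
                              c("age", "gender", "education"),
                              label = "demographics")
    fit_dir <- file.path(out_dir, "fit")
    dir.create(fit_dir, showWarnings = FALSE)
    fits <- data.frame(model = c("signature", "demographics"),
                       n = c(sf$fit$n, demo$n), p = c(sf$fit$p, demo$p),
                       r_squared = c(sf$fit$r_squared, demo$r_squared),
                       adj_r_squared = c(sf$fit$adj_r_squared,
                                         demo$adj_r_squared))
    utils::write.csv(fits, file.path(fit_dir, "fits.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(signature_coefficients =
                                as.list(sf$signature$coefficients),
                              fits = fits, seed = config$seed),
                         file.path(fit_dir, "fit.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    state$fit <- list(signature = sf, demographics = demo)
    log_msg("fit: signature adj R2 %.3f vs demographics %.3f",
            sf$fit$adj_r_squared, demo$adj_r_squared)
  }

  if ("validate" %in% stages) {
    val <- state$split$validation
    paired <- replication_trial(val, sub_G(val$subject_id),
                                state$mask_set, state$mask_set,
                                config$outcome,
                                n_subsets = config$n_validation_subsets,
                                subset_size = min(config$validation_subset_size,
                                                  nrow(val)),
                                seed = config$seed + 23L,
                                analysis_mask = state$mask)
    ba <- bland_altman(paired)
    val_dir <- file.path(out_dir, "validate")
    dir.create(val_dir, showWarnings = FALSE)
    utils::write.csv(paired, file.path(val_dir, "paired_fits.csv"),
                     row.names = FALSE)
    jsonlite::write_json(unclass(ba)[c("bias", "loa_lower", "loa_upper",
                                       "ci_lower", "ci_upper", "n",
                                       "significant")],
                         file.path(val_dir, "bland_altman.json"),
                         auto_unbox = TRUE, digits = NA)
    state$validate <- list(paired = paired, bland_altman = ba)
    log_msg("validate: mean adj R2 %.3f over %d subsets",
            mean(paired$r2_a), nrow(paired))
  }

  if ("compare" %in% stages) {
    val <- state$split$validation
    means <- roi_mean_vector(sub_G(val$subject_id), state$mask_set,
                             analysis_mask = state$mask,
                             subject_ids = val$subject_id)
    data <- cbind(val, means[, -1, drop = FALSE])
    boot <- bootstrap_r2_difference(data, config$outcome,
                                    competitor = character(0),
                                    n_boot = config$n_boot,
                                    levels = config$ci_levels,
                                    seed = config$seed + 31L)
    cmp_dir <- file.path(out_dir, "compare")
    dir.create(cmp_dir, showWarnings = FALSE)
    utils::write.csv(boot$intervals,
                     file.path(cmp_dir, "bootstrap_intervals.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(observed = boot$observed,
                              intervals = boot$intervals,
                              n_boot = boot$n_boot,
                              n_redrawn = boot$n_redrawn,
                              seed = boot$seed),
                         file.path(cmp_dir, "compare.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    state$compare <- boot
    log_msg("compare: observed adj R2 difference %.3f vs demographics",
            boot$observed)
  }

  if ("similarity" %in% stages) {
    sim_dir <- file.path(out_dir, "similarity")
    dir.create(sim_dir, showWarnings = FALSE)
    rows <- lapply(t_levels, function(tt) {
      m <- state$mask_set$masks[[paste0("t", tt)]]
      data.frame(t_level = tt, voxels = mask_count(m),
                 dice_vs_truth = if (mask_count(m) +
                                     mask_count(state$sim$truth) > 0)
                   dice(m, state$sim$truth) else NA_real_)
    })
    tab <- do.call(rbind, rows)
    utils::write.csv(tab, file.path(sim_dir, "similarity.csv"),
                     row.names = FALSE)
    state$similarity <- tab
    log_msg("similarity: Dice(t=%g vs truth) = %.3f", t_levels[1],
            tab$dice_vs_truth[1])
  }

  write_provenance(file.path(out_dir, "provenance.json"),
                   lapply(unclass(config), function(x)
                     if (is.list(x)) unclass(x) else x),
                   seed = config$seed, extra = list(stages = stages))
  invisible(state)
}
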