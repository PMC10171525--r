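#' Per-subject mean GM density inside each signature mask
#'
#' @param volumes list of subject volumes, or a [gm_matrix()] over
#'   `analysis_mask` with one row per subject.
#' @param mask_set a `signature_mask_set` (consensus masks at the t-levels).
#' @param analysis_mask the analysis `gm_mask` (needed when `volumes` is a
#'   GM matrix; otherwise inferred from the masks' grid).
#' @param subject_ids optional ids for the row names.
#' @return data.frame with `subject_id` and one `tsroi_t*` column per
#'   non-empty mask level (empty levels are skipped with a warning).
#' @export
roi_mean_vector <- function(volumes, mask_set, analysis_mask = NULL,
                            subject_ids = NULL) {
  counts <- vapply(mask_set$masks, mask_count, numeric(1))
  if (all(counts == 0)) stop("all signature masks are empty")
  if (any(counts == 0))
    warning(sprintf("skipping empty signature mask level(s): %s",
                    paste(names(counts)[counts == 0], collapse = ", ")))
  use <- names(counts)[counts > 0]
  if (is.matrix(volumes)) {
    if (is.null(analysis_mask))
      stop("analysis_mask is required when volumes is a GM matrix")
    G <- gm_matrix(volumes, analysis_mask)
    vox <- attr(G, "mask_voxels")
    out <- data.frame(row.names = seq_len(nrow(G)))
    for (lvl in use) {
      cols <- match(which(mask_set$masks[[lvl]]$data), vox)
      if (anyNA(cols))
        stop("signature mask extends outside the analysis mask")
      out[[paste0("tsroi_", lvl)]] <- rowMeans(G[, cols, drop = FALSE])
    }
    n <- nrow(G)
  } else {
    n <- length(volumes)
    out <- data.frame(row.names = seq_len(n))
    for (lvl in use) {
      m <- mask_set$masks[[lvl]]
      vox <- which(m$data)
      for (v in volumes) stop_unless_aligned(v, m, "volume and mask")
      out[[paste0("tsroi_", lvl)]] <-
        vapply(volumes, function(v) mean(v$data[vox]), numeric(1))
    }
  }
  out <- cbind(subject_id = subject_ids %||% sprintf("row%04d", seq_len(n)),
               out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Fit the signature variable S
#'
#' Regresses the outcome on the per-subject TsROI mean GM values
#' (`Y = b0 + b1*TsROI1 + b2*TsROI2 + b3*TsROI3`, fewer terms when a mask
#' level is empty); `S` is the vector of fitted values in the target set.
#' Near-collinear mask means (condition number above `kappa_max`) trigger a
#' warning and a minimum-norm pseudo-inverse solve, flagged in the result.
#'
#' @param cohort cohort data.frame (rows matched to `tsroi_means` by
#'   `subject_id`).
#' @param tsroi_means output of [roi_mean_vector()].
#' @param outcome outcome column name.
#' @param kappa_max condition-number bound before the pseudo-inverse path.
#' @return list with `model` (a `signature_model`: coefficients, terms,
#'   `pseudo_inverse` flag, `r_squared`) and `S` (named fitted values).
#' @export
fit_signature_variable <- function(cohort, tsroi_means, outcome,
                                   kappa_max = 1e8) {
  df <- merge(cohort[, c("subject_id", outcome)], tsroi_means,
              by = "subject_id", sort = FALSE)
  terms <- grep("^tsroi_", names(df), value = TRUE)
  n <- nrow(df)
  if (n <= length(terms) + 1)
    stop("need more subjects than signature-mask terms")
  X <- cbind(`(Intercept)` = 1, as.matrix(df[, terms, drop = FALSE]))
  y <- df[[outcome]]
  kap <- kappa(X, exact = TRUE)
  pseudo <- FALSE
  if (!is.finite(kap) || kap > kappa_max) {
    warning(sprintf("collinear TsROI means (condition number %.3g); using pseudo-inverse solve", kap))
    pseudo <- TRUE
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-12
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
    beta <- drop(beta)
  } else {
    beta <- drop(qr.coef(qr(X), y))
  }
  names(beta) <- colnames(X)
  S <- drop(X %*% beta)
  names(S) <- df$subject_id
  ss_res <- sum((y - S)^2)
  ss_tot <- sum((y - mean(y))^2)
  model <- structure(list(coefficients = beta, terms = terms,
                          outcome = outcome, n = n,
                          pseudo_inverse = pseudo,
                          r_squared = 1 - ss_res / ss_tot),
                     class = "signature_model")
  list(model = model, S = S)
}

#' Apply a fitted signature model to new TsROI means
#'
#' Frozen-coefficients mode: computes `S` in a new set from coefficients fit
#' elsewhere (the alternative to refitting within each target set).
#'
#' @param model a `signature_model`.
#' @param tsroi_means output of [roi_mean_vector()] with matching columns.
#' @return named numeric vector of S values.
#' @export
predict_signature <- function(model, tsroi_means) {
  miss <- setdiff(model$terms, names(tsroi_means))
  if (length(miss))
    stop(sprintf("tsroi_means lacks column(s): %s",
                 paste(miss, collapse = ", ")))
  X <- cbind(1, as.matrix(tsroi_means[, model$terms, drop = FALSE]))
  S <- drop(X %*% model$coefficients)
  names(S) <- tsroi_means$subject_id
  S
}

adjusted_r2 <- function(r2, n, p) 1 - (1 - r2) * (n - 1) / (n - p - 1)

#' Fit an outcome model and report (adjusted) R-squared
#'
#' Ordinary least squares of the outcome on the named predictor columns.
#' Covers the model battery: demographics-only; demographics plus a single
#' ROI mean; demographics plus the four atlas ROI means ("FourROIs");
#' demographics plus the signature variable S.
#'
#' @param data data.frame holding outcome and predictors.
#' @param outcome outcome column name.
#' @param predictors character vector of predictor column names (may be
#'   empty for the intercept-only model).
#' @param label model label carried in the result.
#' @return a `fit_result`: list with `label`, `coefficients`, `n`, `p`
#'   (predictors excluding intercept), `r_squared`, `adj_r_squared`,
#'   `df_residual`, and the `lm` fit.
#' @export
fit_outcome_model <- function(data, outcome,
                              predictors = c("age", "gender", "education"),
                              label = paste(predictors, collapse = "+")) {
  miss <- setdiff(c(outcome, predictors), names(data))
  if (length(miss))
    stop(sprintf("column(s) not in data: %s", paste(miss, collapse = ", ")))
  n <- nrow(data)
  p <- length(predictors)
  if (n <= p + 1) stop("need n > number of predictors + 1")
  fml <- stats::reformulate(if (p) predictors else "1", response = outcome)
  fit <- stats::lm(fml, data = data)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop(sprintf("rank-deficient model; aliased column(s): %s",
                 paste(bad, collapse = ", ")))
  }
  r2 <- if (p == 0) 0 else summary(fit)$r.squared
  structure(list(label = label, coefficients = stats::coef(fit), n = n,
                 p = p, r_squared = r2,
                 adj_r_squared = if (p == 0) 0 else adjusted_r2(r2, n, p),
                 df_residual = fit$df.residual, fit = fit),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s: n = %d, p = %d, R2 = %.4f, adj R2 = %.4f\n",
              x$label, x$n, x$p, x$r_squared, x$adj_r_squared))
  invisible(x)
}

#' Signature model fit in a target set
#'
#' Convenience chain: TsROI means -> signature variable S -> fit of the
#' outcome on S plus demographics, reporting adjusted R-squared.  By default
#' the signature regression is refit within the target set ("refit" mode);
#' `mode = "frozen"` applies coefficients fit elsewhere (`frozen_model`).
#'
#' @param cohort target-set cohort data.frame.
#' @param volumes subject volumes (list or [gm_matrix()] over
#'   `analysis_mask`) matching `cohort` rows.
#' @param mask_set consensus `signature_mask_set`.
#' @param outcome outcome column name.
#' @param analysis_mask required when `volumes` is a GM matrix.
#' @param mode `"refit"` or `"frozen"`.
#' @param frozen_model `signature_model` used when `mode = "frozen"`.
#' @param covariates demographic covariates for the outcome model.
#' @return list with `fit` (a [fit_outcome_model()] result for
#'   demographics + S), `signature` (model or NULL), `S`.
#' @export
signature_fit <- function(cohort, volumes, mask_set, outcome,
                          analysis_mask = NULL,
                          mode = c("refit", "frozen"), frozen_model = NULL,
                          covariates = c("age", "gender", "education")) {
  mode <- match.arg(mode)
  means <- roi_mean_vector(volumes, mask_set, analysis_mask = analysis_mask,
                           subject_ids = cohort$subject_id)
  if (mode == "refit") {
    sv <- fit_signature_variable(cohort, means, outcome)
    S <- sv$S
    model <- sv$model
  } else {
    if (is.null(frozen_model)) stop("frozen mode requires `frozen_model`")
    S <- predict_signature(frozen_model, means)
    model <- frozen_model
  }
  data <- cohort
  data$S <- S[match(cohort$subject_id, names(S))]
  fit <- fit_outcome_model(data, outcome, c("S", covariates),
                           label = "signature")
  list(fit = fit, signature = model, S = S)
}

#' Per-subject mean GM density within atlas-labeled regions
#'
#' @param volumes list of subject volumes, or a [gm_matrix()] over
#'   `analysis_mask`.
#' @param atlas label `gm_volume` (integer codes) aligned with the volumes.
#' @param labels named integer vector: region name -> label code.
#' @param analysis_mask required when `volumes` is a GM matrix; atlas regions
#'   are then intersected with the analysis mask.
#' @param subject_ids optional ids.
#' @return data.frame with `subject_id` and one column per region.
#' @export
atlas_roi_means <- function(volumes, atlas, labels, analysis_mask = NULL,
                            subject_ids = NULL) {
  stopifnot(is_gm_volume(atlas))
  if (is.null(names(labels)))
    names(labels) <- paste0("roi_", labels)
  present <- unique(as.vector(atlas$data))
  miss <- labels[!labels %in% present]
  if (length(miss))
    stop(sprintf("label(s) absent from atlas: %s",
                 paste(names(miss), collapse = ", ")))
  if (is.matrix(volumes)) {
    if (is.null(analysis_mask))
      stop("analysis_mask is required when volumes is a GM matrix")
    stop_unless_aligned(atlas, analysis_mask, "atlas and analysis mask")
    G <- gm_matrix(volumes, analysis_mask)
    vox <- attr(G, "mask_voxels")
    out <- data.frame(row.names = seq_len(nrow(G)))
    for (nm in names(labels)) {
      cols <- which(atlas$data[vox] == labels[[nm]])
      if (!length(cols))
        stop(sprintf("label '%s' does not intersect the analysis mask", nm))
      out[[nm]] <- rowMeans(G[, cols, drop = FALSE])
    }
    n <- nrow(G)
  } else {
    for (v in volumes) stop_unless_aligned(v, atlas, "volume and atlas")
    n <- length(volumes)
    out <- data.frame(row.names = seq_len(n))
    for (nm in names(labels)) {
      vox <- which(atlas$data == labels[[nm]])
      out[[nm]] <- vapply(volumes, function(v) mean(v$data[vox]), numeric(1))
    }
  }
  out <- cbind(subject_id = subject_ids %||% sprintf("row%04d", seq_len(n)),
               out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
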