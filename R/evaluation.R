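# Adjusted R2 of y on a design matrix (with intercept column); NULL on rank
# deficiency (caller decides whether that aborts or triggers a redraw).
.adj_r2_qr <- function(X, y) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) return(NULL)
  res <- qr.resid(qx, y)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  adjusted_r2(r2, length(y), ncol(X) - 1L)
}

# Signature-model adjusted R2 in one subject set: refit the TsROI-means
# regression there, then the outcome ~ S + covariates model.  The first-step
# fitted values are well-defined even when mask means are collinear in a
# small subset, so the refit tolerates a rank-deficient TsROI design.
.signature_adj_r2 <- function(df, outcome, tsroi_cols, covariates) {
  X1 <- cbind(1, as.matrix(df[, tsroi_cols, drop = FALSE]))
  S <- qr.fitted(qr(X1), df[[outcome]])
  X2 <- cbind(1, S, as.matrix(df[, covariates, drop = FALSE]))
  .adj_r2_qr(X2, df[[outcome]])
}

#' Paired signature-model fits over repeated validation subsets
#'
#' Draws random subsets of a validation cohort and, within each subset,
#' computes the adjusted R-squared of the outcome model (outcome on S plus
#' demographics) for two signature mask sets — e.g. masks discovered in two
#' different cohorts.  Both fits use the identical subject subset, giving a
#' paired table for agreement analysis.
#'
#' The signature regression is refit within each subset (the default
#' "refit" reading); `mode = "frozen"` instead applies signature
#' coefficients fit once on the full validation cohort.
#'
#' @param cohort validation cohort data.frame.
#' @param volumes subject volumes (list or [gm_matrix()] over
#'   `analysis_mask`) matching `cohort` rows.
#' @param masks_a,masks_b two `signature_mask_set`s.
#' @param outcome outcome column name.
#' @param n_subsets number of validation subsets (default 50).
#' @param subset_size subjects per subset (default 200).
#' @param seed RNG seed.
#' @param analysis_mask required when `volumes` is a GM matrix.
#' @param discovery_ids optional ids of the discovery subjects; if given,
#'   any overlap with the validation cohort is an error.
#' @param mode `"refit"` or `"frozen"`.
#' @param covariates demographic covariates.
#' @return a `paired_fit_table` data.frame: `subset`, `r2_a`, `r2_b`, with
#'   attributes `subset_size` and `seed`.
#' @export
replication_trial <- function(cohort, volumes, masks_a, masks_b, outcome,
                              n_subsets = 50, subset_size = 200, seed = 1,
                              analysis_mask = NULL, discovery_ids = NULL,
                              mode = c("refit", "frozen"),
                              covariates = c("age", "gender", "education")) {
  mode <- match.arg(mode)
  if (!is.null(discovery_ids) &&
      length(intersect(discovery_ids, cohort$subject_id)))
    stop("validation cohort overlaps the discovery set")
  cc <- complete_for_outcome(cohort, outcome)
  if (is.matrix(volumes) && nrow(volumes) != nrow(cc))
    stop("GM matrix rows must match complete-case cohort rows")
  if (subset_size > nrow(cc))
    stop("subset_size exceeds validation cohort size")
  vols_cc <- if (is.matrix(volumes)) volumes else
    volumes[cohort$subject_id %in% cc$subject_id]
  means_a <- roi_mean_vector(vols_cc, masks_a, analysis_mask = analysis_mask,
                             subject_ids = cc$subject_id)
  means_b <- roi_mean_vector(vols_cc, masks_b, analysis_mask = analysis_mask,
                             subject_ids = cc$subject_id)
  cols_a <- grep("^tsroi_", names(means_a), value = TRUE)
  cols_b <- grep("^tsroi_", names(means_b), value = TRUE)
  names(means_a)[match(cols_a, names(means_a))] <- paste0("a_", cols_a)
  names(means_b)[match(cols_b, names(means_b))] <- paste0("b_", cols_b)
  df <- cbind(cc, means_a[, -1, drop = FALSE], means_b[, -1, drop = FALSE])
  frozen_a <- frozen_b <- NULL
  if (mode == "frozen") {
    frozen_a <- .signature_frozen(df, outcome, paste0("a_", cols_a))
    frozen_b <- .signature_frozen(df, outcome, paste0("b_", cols_b))
  }
  subsets <- sample_subsets(cc$subject_id, n_subsets, subset_size, seed)
  r2_a <- r2_b <- numeric(n_subsets)
  for (k in seq_len(n_subsets)) {
    sub <- df[match(subsets[[k]], df$subject_id), , drop = FALSE]
    if (mode == "refit") {
      r2_a[k] <- .signature_adj_r2(sub, outcome, paste0("a_", cols_a),
                                   covariates)
      r2_b[k] <- .signature_adj_r2(sub, outcome, paste0("b_", cols_b),
                                   covariates)
    } else {
      Sa <- drop(cbind(1, as.matrix(sub[, paste0("a_", cols_a)])) %*% frozen_a)
      Sb <- drop(cbind(1, as.matrix(sub[, paste0("b_", cols_b)])) %*% frozen_b)
      r2_a[k] <- .adj_r2_qr(cbind(1, Sa, as.matrix(sub[, covariates])),
                            sub[[outcome]])
      r2_b[k] <- .adj_r2_qr(cbind(1, Sb, as.matrix(sub[, covariates])),
                            sub[[outcome]])
    }
  }
  out <- data.frame(subset = seq_len(n_subsets), r2_a = r2_a, r2_b = r2_b)
  attr(out, "subset_size") <- subset_size
  attr(out, "seed") <- seed
  class(out) <- c("paired_fit_table", class(out))
  out
}

.signature_frozen <- function(df, outcome, tsroi_cols) {
  X <- cbind(1, as.matrix(df[, tsroi_cols, drop = FALSE]))
  qr.coef(qr(X), df[[outcome]])
}

#' Bland-Altman agreement analysis of paired model fits
#'
#' Computes the bias (mean of differences `r2_b - r2_a`), the limits of
#' agreement (bias +/- 1.96 sd of differences), and a t-based confidence
#' interval for the bias; the bias is "significant" when that interval
#' excludes zero.
#'
#' @param paired a [replication_trial()] table (or any data.frame with
#'   `r2_a`, `r2_b`); needs >= 3 rows.
#' @param ci_level confidence level for the bias CI (default 0.95).
#' @return a `bland_altman` list: `bias`, `loa_lower`, `loa_upper`,
#'   `ci_lower`, `ci_upper`, `sd_diff`, `n`, `significant`, `degenerate`.
#' @export
bland_altman <- function(paired, ci_level = 0.95) {
  d <- paired$r2_b - paired$r2_a
  n <- length(d)
  if (n < 3) stop("need at least 3 paired rows")
  bias <- mean(d)
  sd_d <- stats::sd(d)
  degenerate <- sd_d == 0
  if (degenerate && bias != 0)
    warning("zero variance of differences with nonzero bias: degenerate CI")
  half <- stats::qt((1 + ci_level) / 2, n - 1) * sd_d / sqrt(n)
  structure(list(bias = bias, loa_lower = bias - 1.96 * sd_d,
                 loa_upper = bias + 1.96 * sd_d,
                 ci_lower = bias - half, ci_upper = bias + half,
                 sd_diff = sd_d, n = n, ci_level = ci_level,
                 significant = !degenerate &&
                   (bias - half > 0 || bias + half < 0),
                 degenerate = degenerate),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> bias %.4g [%.4g, %.4g] (%d%% CI), LoA [%.4g, %.4g], n = %d%s\n",
              x$bias, x$ci_lower, x$ci_upper, round(100 * x$ci_level),
              x$loa_lower, x$loa_upper, x$n,
              if (x$significant) ", significant bias" else ""))
  invisible(x)
}

#' Bootstrap confidence intervals for an adjusted-R2 difference
#'
#' Resamples subjects with replacement; in every resample *both* models are
#' refit — the signature model (TsROI-means regression producing S, then
#' outcome on S plus covariates) and a competitor — and the difference of
#' adjusted R-squared (signature minus competitor) is recorded.  Percentile
#' intervals are reported at each confidence level, with a superiority flag
#' when an interval lies entirely above 0.  Rank-deficient resamples are
#' redrawn and counted.
#'
#' @param data data.frame holding the outcome, `tsroi_*` mean columns,
#'   competitor predictor columns, and covariates.
#' @param outcome outcome column name.
#' @param competitor character vector of competitor predictor columns
#'   (empty for the demographics-only competitor).
#' @param covariates demographic covariates entering both models (drop
#'   entries to form the covariate-dropped variants).
#' @param tsroi_cols TsROI mean columns (default: every `tsroi_*` column).
#' @param n_boot bootstrap iterations (production default 10000).
#' @param levels confidence levels.
#' @param seed RNG seed.
#' @param ci_type `"percentile"` (default) or `"bca"`.
#' @return a `bootstrap_r2_result`: `observed` difference, `intervals`
#'   (data.frame: level, lower, upper, superior), `n_boot`, `n_redrawn`,
#'   `seed`, `diffs`.
#' @export
bootstrap_r2_difference <- function(data, outcome, competitor,
                                    covariates = c("age", "gender",
                                                   "education"),
                                    tsroi_cols = grep("^tsroi_", names(data),
                                                      value = TRUE),
                                    n_boot = 10000,
                                    levels = c(0.80, 0.90, 0.95, 0.99),
                                    seed = 1,
                                    ci_type = c("percentile", "bca")) {
  ci_type <- match.arg(ci_type)
  if (!length(tsroi_cols)) stop("no tsroi_* columns in data")
  n <- nrow(data)
  y <- data[[outcome]]
  one_diff <- function(idx) {
    df <- data[idx, , drop = FALSE]
    rs <- .signature_adj_r2(df, outcome, tsroi_cols, covariates)
    Xc <- cbind(1, as.matrix(df[, c(competitor, covariates), drop = FALSE]))
    rc <- .adj_r2_qr(Xc, df[[outcome]])
    if (is.null(rs) || is.null(rc)) return(NULL)
    rs - rc
  }
  observed <- one_diff(seq_len(n))
  if (is.null(observed)) stop("rank-deficient design on the full data")
  n_redrawn <- 0L
  diffs <- with_seed(seed, {
    out <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      repeat {
        d <- one_diff(sample.int(n, n, replace = TRUE))
        if (!is.null(d)) break
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > 100 * n_boot)
          stop("resamples are persistently rank-deficient")
      }
      out[b] <- d
    }
    out
  })
  intervals <- do.call(rbind, lapply(levels, function(lv) {
    if (ci_type == "percentile") {
      qs <- stats::quantile(diffs, c((1 - lv) / 2, (1 + lv) / 2),
                            names = FALSE)
    } else {
      qs <- .bca_interval(diffs, observed, lv, data, one_diff)
    }
    data.frame(level = lv, lower = qs[1], upper = qs[2],
               superior = qs[1] > 0)
  }))
  structure(list(observed = observed, intervals = intervals,
                 n_boot = n_boot, n_redrawn = n_redrawn, seed = seed,
                 ci_type = ci_type, diffs = diffs),
            class = "bootstrap_r2_result")
}

# BCa interval: bias correction from the bootstrap distribution, jackknife
# acceleration.
.bca_interval <- function(diffs, observed, level, data, statistic) {
  n <- nrow(data)
  z0 <- stats::qnorm(mean(diffs < observed))
  jack <- vapply(seq_len(n), function(i) {
    d <- statistic(setdiff(seq_len(n), i))
    if (is.null(d)) NA_real_ else d
  }, numeric(1))
  jack <- jack[is.finite(jack)]
  u <- mean(jack) - jack
  a <- sum(u^3) / (6 * sum(u^2)^1.5)
  alphas <- c((1 - level) / 2, (1 + level) / 2)
  zq <- stats::qnorm(alphas)
  adj <- stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  stats::quantile(diffs, adj, names = FALSE)
}

#' @export
print.bootstrap_r2_result <- function(x, ...) {
  cat(sprintf("<bootstrap_r2_result> observed diff %.4f (%d resamples, %s)\n",
              x$observed, x$n_boot, x$ci_type))
  print(x$intervals, row.names = FALSE)
  invisible(x)
}

#' Diagnosis main-effect and interaction model
#'
#' Regresses the outcome on demographics, the signature variable S,
#' dummy-coded diagnosis, and the S-by-diagnosis interaction; reports
#' partial-F p-values for the diagnosis main-effect block, the S main
#' effect, and the interaction block.
#'
#' @param data data.frame with the outcome, covariates, `S`, and a
#'   `diagnosis` factor (>= 2 levels among the rows used).
#' @param outcome outcome column name.
#' @param covariates demographic covariates.
#' @return a `diagnosis_interaction` list: `fit` (full `lm`), `p_diagnosis`,
#'   `p_signature`, `p_interaction`, `levels`.
#' @export
diagnosis_interaction <- function(data, outcome,
                                  covariates = c("age", "gender",
                                                 "education")) {
  if (!"diagnosis" %in% names(data)) stop("data lacks a diagnosis column")
  if (!"S" %in% names(data)) stop("data lacks the signature column S")
  data <- data[!is.na(data$diagnosis) & is.finite(data$S) &
                 is.finite(data[[outcome]]), , drop = FALSE]
  data$diagnosis <- factor(data$diagnosis)
  if (nlevels(droplevels(data$diagnosis)) < 2)
    stop("diagnosis must have at least 2 levels")
  data$diagnosis <- droplevels(data$diagnosis)
  base <- paste(c(covariates, "S"), collapse = " + ")
  f_full <- stats::as.formula(paste(outcome, "~", base,
                                    "+ diagnosis + S:diagnosis"))
  f_main <- stats::as.formula(paste(outcome, "~", base, "+ diagnosis"))
  f_nodx <- stats::as.formula(paste(outcome, "~", base))
  f_nos <- stats::as.formula(paste(outcome, "~",
                                   paste(covariates, collapse = " + "),
                                   "+ diagnosis"))
  fit_full <- stats::lm(f_full, data = data)
  fit_main <- stats::lm(f_main, data = data)
  fit_nodx <- stats::lm(f_nodx, data = data)
  fit_nos <- stats::lm(f_nos, data = data)
  p_int <- stats::anova(fit_main, fit_full)[2, "Pr(>F)"]
  p_dx <- stats::anova(fit_nodx, fit_main)[2, "Pr(>F)"]
  p_s <- stats::anova(fit_nos, fit_main)[2, "Pr(>F)"]
  structure(list(fit = fit_full, p_diagnosis = p_dx, p_signature = p_s,
                 p_interaction = p_int,
                 levels = levels(data$diagnosis), n = nrow(data)),
            class = "diagnosis_interaction")
}

#' @export
print.diagnosis_interaction <- function(x, ...) {
  cat(sprintf("<diagnosis_interaction> n = %d, levels %s\n  p(diagnosis) = %.3g, p(S) = %.3g, p(S x diagnosis) = %.3g\n",
              x$n, paste(x$levels, collapse = "/"),
              x$p_diagnosis, x$p_signature, x$p_interaction))
  invisible(x)
}
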