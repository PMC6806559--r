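# End-to-end orchestration of the two study stages:
#   training (observational cohort): standardize -> ICC filter -> IPTW ->
#     interaction screen -> redundancy filter -> modified-covariate fit ->
#     backward selection -> ICTOS model;
#   validation (randomized cohort): score -> split at 0 -> per-group arm
#     contrasts -> interaction test -> risk stratification of the low group.

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Fit the ICTOS model on a training cohort
#'
#' Runs the full model-construction pipeline on an extracted feature table
#' and clinical cohort: training-cohort z-score standardization, optional
#' reproducibility (ICC) filtering from repeat-segmentation feature tables,
#' optional IPTW balancing, univariate interaction screening, greedy
#' correlation-redundancy filtering, the modified-covariate Cox fit on the
#' top-ranked candidates, and backward step-wise selection.
#'
#' @param features numeric matrix/data.frame, rows aligned to
#'   \code{cohort} rows, named feature columns (raw, unstandardized).
#' @param cohort clinical table with \code{time_months}, \code{event},
#'   \code{arm} and, if \code{iptw = TRUE}, the balancing covariates.
#' @param icc_intra,icc_inter optional lists of two feature tables each
#'   (repeat segmentations of a reproducibility subset) for the ICC filter;
#'   both \code{NULL} skips the filter.
#' @param icc_threshold ICC retention threshold (default 0.8).
#' @param iptw balance arms by inverse probability of treatment weighting.
#' @param covariates IPTW covariate names.
#' @param r_max redundancy-filter correlation threshold (default 0.8).
#' @param alpha backward-selection significance level (default 0.05).
#' @param k_max candidates entering the multivariable stage (default 10).
#' @param screen_weighted use the IPTW weights during interaction screening
#'   (default TRUE).
#' @return A list of class \code{ictos_training}: \code{model} (an
#'   \code{\link{ictos_model}} with the standardizer embedded, or
#'   \code{NULL}), \code{screen}, \code{candidates}, \code{icc},
#'   \code{balance}, \code{weights}, \code{standardizer}, \code{config}.
#' @export
run_training <- function(features, cohort,
                         icc_intra = NULL, icc_inter = NULL,
                         icc_threshold = 0.8,
                         iptw = TRUE, covariates = iptw_default_covariates,
                         r_max = 0.8, alpha = 0.05, k_max = 10,
                         screen_weighted = TRUE) {
  assert_that(nrow(as.matrix(features)) == nrow(cohort),
              "'features' rows must align to 'cohort' rows")
  run_stage("events-check",
            assert_that(sum(cohort$event) > 0, "no events in training cohort"))

  std <- run_stage("standardize", fit_standardizer(features))
  Xs <- run_stage("standardize", apply_standardizer(std, features))

  icc_res <- NULL
  if (!is.null(icc_intra) || !is.null(icc_inter)) {
    assert_that(!is.null(icc_intra) && !is.null(icc_inter),
                "supply both 'icc_intra' and 'icc_inter' (or neither)")
    icc_res <- run_stage("icc-filter",
                         icc_filter_features(icc_intra, icc_inter,
                                             threshold = icc_threshold))
    keep <- intersect(colnames(Xs), icc_res$retained)
    assert_that(length(keep) > 0, "no feature survived the ICC filter")
    Xs <- Xs[, keep, drop = FALSE]
  }

  w <- rep(1, nrow(cohort))
  bal <- NULL
  if (iptw) {
    ps <- run_stage("iptw", fit_propensity(cohort, covariates))
    w <- run_stage("iptw", compute_weights(ps$scores, cohort$arm))
    bal <- run_stage("iptw", balance_report(cohort, w, covariates))
  }

  screen <- run_stage("interaction-screen",
                      screen_interactions(Xs, cohort,
                                          weights = if (screen_weighted) w else NULL))
  candidates <- run_stage("redundancy-filter",
                          redundancy_filter(screen$feature, Xs, r_max = r_max))
  candidates <- utils::head(candidates, k_max)

  model <- run_stage("modified-covariate-fit",
                     backward_select(Xs[, candidates, drop = FALSE], cohort,
                                     weights = w, alpha = alpha,
                                     standardizer = std))
  structure(list(model = model, screen = screen, candidates = candidates,
                 icc = icc_res, balance = bal, weights = w,
                 standardizer = std,
                 config = list(icc_threshold = icc_threshold, iptw = iptw,
                               r_max = r_max, alpha = alpha, k_max = k_max,
                               screen_weighted = screen_weighted)),
            class = "ictos_training")
}

#' @export
print.ictos_training <- function(x, ...) {
  cat("ICTOS training run\n")
  if (!is.null(x$icc))
    cat(sprintf("  ICC filter: %d feature(s) retained\n", x$icc$n_retained))
  cat(sprintf("  candidates after redundancy filter: %d\n",
              length(x$candidates)))
  if (is.null(x$model)) cat("  final model: none (no significant features)\n")
  else print(x$model)
  invisible(x)
}

#' Evaluate an ICTOS model on a validation cohort
#'
#' Scores every patient, splits at the model cutoff into high/low ICTOS,
#' and produces, per group, the weighted KM read-offs and the arm contrast
#' (HR, CI, log-rank p), plus the treatment-by-ICTOS interaction test and
#' the risk stratification of the low-ICTOS group. When every patient falls
#' on one side of the cutoff a single-group report is returned and the
#' interaction test is skipped with a notice.
#'
#' @param model an \code{\link{ictos_model}}.
#' @param features feature table aligned to \code{cohort} rows. Standardized
#'   values are expected unless the model embeds a standardizer, in which
#'   case raw features are standardized with the training parameters.
#' @param cohort clinical table (\code{time_months}, \code{event},
#'   \code{arm}, stratification covariates).
#' @param weights optional observation weights (unit for a randomized
#'   validation cohort).
#' @param times_at KM read-off times (default 36 and 60 months).
#' @return A list of class \code{ictos_validation}: \code{scores} (per
#'   patient), \code{group_sizes}, \code{km} (per group x arm),
#'   \code{arm_contrast} (per group), \code{interaction}
#'   (p_interaction or NULL), \code{stratification} (low group), and
#'   \code{overall} arm contrast.
#' @export
run_validation <- function(model, features, cohort, weights = NULL,
                           times_at = c(36, 60)) {
  stopifnot(inherits(model, "ictos_model"))
  assert_columns(cohort, c("time_months", "event", "arm"), "cohort")
  assert_that(nrow(as.matrix(features)) == nrow(cohort),
              "'features' rows must align to 'cohort' rows")
  missing <- setdiff(model$features,
                     colnames(as.matrix(features)))
  if (length(missing) > 0 && !is.null(model$standardizer))
    missing <- setdiff(model$features, names(model$standardizer$mean))
  assert_that(length(missing) == 0L,
              paste("validation features missing model feature(s):",
                    paste(missing, collapse = ", ")))
  if (is.null(weights)) weights <- rep(1, nrow(cohort))

  sc <- run_stage("score",
                  ictos_score(model, features,
                              standardized = is.null(model$standardizer)))
  sc$id <- if ("id" %in% names(cohort)) cohort$id else seq_len(nrow(cohort))

  groups <- levels(sc$label)[table(sc$label) > 0]
  km <- list(); contrast <- list()
  for (g in groups) {
    sel <- sc$label == g
    km[[g]] <- lapply(split(seq_len(nrow(cohort))[sel], cohort$arm[sel]),
                      function(idx) km_weighted(cohort$time_months[idx],
                                                cohort$event[idx],
                                                weights[idx],
                                                times_at = times_at))
    contrast[[g]] <- run_stage(
      paste0("arm-contrast-", g),
      compare_arms(cohort$time_months[sel], cohort$event[sel],
                   cohort$arm[sel], weights[sel]))
  }
  inter <- NULL
  if (length(groups) == 2) {
    inter <- run_stage("interaction-test",
                       interaction_test(cohort$time_months, cohort$event,
                                        cohort$arm, sc$label, weights))
  } else {
    message("single ICTOS group (every score on one side of the cutoff): ",
            "interaction test skipped")
  }
  strat <- NULL
  if (any(sc$label == "low") &&
      all(c("n_stage", "t_stage", "tumor_volume_ml", "pebv_dna") %in%
            names(cohort))) {
    strat <- stratify_low_ictos(cohort[sc$label == "low", , drop = FALSE])
  }
  overall <- run_stage("arm-contrast-overall",
                       compare_arms(cohort$time_months, cohort$event,
                                    cohort$arm, weights))
  structure(list(scores = sc,
                 group_sizes = table(sc$label),
                 km = km, arm_contrast = contrast, interaction = inter,
                 stratification = strat, overall = overall),
            class = "ictos_validation")
}

#' @export
print.ictos_validation <- function(x, ...) {
  cat("ICTOS validation run\n")
  gs <- x$group_sizes
  cat(sprintf("  groups: low n=%d, high n=%d\n",
              gs[["low"]] %||% 0, gs[["high"]] %||% 0))
  for (g in names(x$arm_contrast)) {
    ac <- x$arm_contrast[[g]]
    cat(sprintf("  %s ICTOS arm contrast: HR %.2f (95%% CI %.2f-%.2f), log-rank p %.3g\n",
                g, ac$hr, ac$ci[1], ac$ci[2], ac$p_logrank))
  }
  if (!is.null(x$interaction))
    cat(sprintf("  p_interaction (arm x ICTOS): %.3g\n",
                x$interaction$p_interaction))
  invisible(x)
}

#' Simulate a complete imaging study with ground truth
#'
#' Generates a cohort (\code{\link{generate_cohort}}), one three-sequence
#' phantom per patient whose texture follows the patient's latent features,
#' extracts the 819-feature table, and (optionally) builds the
#' repeat-segmentation feature tables for the reproducibility subset. This
#' is the desk-scale stand-in for the image archive: everything downstream
#' of segmentation can run on its output.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param grid_shape,roi_radius phantom geometry per patient.
#' @param n_icc_patients size of the reproducibility subset (0 skips the
#'   repeat segmentations).
#' @param jitter_vox segmentation jitter for the repeat masks.
#' @param n_bins,target_spacing_mm extraction settings.
#' @param progress print a dot every 25 patients.
#' @return A list: \code{cohort}, \code{features} (patients x 819),
#'   \code{icc_intra}, \code{icc_inter} (lists of two tables or NULL).
#' @export
simulate_imaging_study <- function(spec, grid_shape = c(3L, 40L, 40L),
                                   roi_radius = 9, n_icc_patients = 30L,
                                   jitter_vox = 1L, n_bins = 32L,
                                   target_spacing_mm = NULL,
                                   progress = FALSE) {
  cohort <- generate_cohort(spec)
  n <- nrow(cohort)
  extract_one <- function(vols, mask) {
    extract_patient_features(vols[c("T1", "T2", "T1C")], mask,
                             n_bins = n_bins,
                             target_spacing_mm = target_spacing_mm)
  }
  feats <- matrix(NA_real_, n, 819L)
  icc_n <- min(n_icc_patients, n)
  intra1 <- intra2 <- inter2 <- if (icc_n > 0) matrix(NA_real_, icc_n, 819L)
  for (i in seq_len(n)) {
    ps <- cohort_phantom_spec(cohort[i, ], grid_shape = grid_shape,
                              roi_radius = roi_radius,
                              seed = spec$seed * 1000L + i)
    ph <- generate_phantom(ps)
    fv <- extract_one(ph, ph$mask)
    feats[i, ] <- fv
    if (i == 1) colnames(feats) <- names(fv)
    if (i <= icc_n) {
      # the initial segmentation doubles as the first rating of both tests
      intra1[i, ] <- fv
      m2 <- perturb_mask(ph$mask, jitter_vox, seed = spec$seed * 2000L + i)
      intra2[i, ] <- extract_one(ph, m2)
      m3 <- perturb_mask(ph$mask, jitter_vox, seed = spec$seed * 3000L + i)
      inter2[i, ] <- extract_one(ph, m3)
    }
    if (progress && i %% 25 == 0) cat(".")
  }
  if (progress) cat("\n")
  if (icc_n > 0) {
    colnames(intra1) <- colnames(intra2) <- colnames(inter2) <- colnames(feats)
  }
  list(cohort = cohort, features = feats,
       icc_intra = if (icc_n > 0) list(intra1, intra2),
       icc_inter = if (icc_n > 0) list(intra1, inter2))
}
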