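# Treatment-benefit modelling: interaction screening, redundancy filtering,
# the modified-covariate Cox fit, backward selection, and ICTOS scoring.
#
# Conventions used throughout:
#   arm T in {0 CCRT, 1 ICT+CCRT};
#   modified covariate W = x * (2T - 1) / 2, fitted without main effects, so
#   the per-patient treatment log-HR is gamma' x;
#   ICTOS = -gamma' x (positive = lower predicted hazard under ICT = benefit),
#   label high when score > 0, low when score <= 0.

#' Univariate treatment-interaction screen
#'
#' For each feature, fits the weighted Cox model
#' \eqn{h \propto \exp(\beta_1 T + \beta_2 x + \beta_3 T x)} with FFS as the
#' endpoint and ranks features by the Wald p-value of the interaction term
#' \eqn{\beta_3}. Non-convergent fits are assigned p = 1 and recorded.
#'
#' @param features numeric matrix/data.frame of standardized features
#'   (rows = patients, named columns).
#' @param cohort table with \code{time_months}, \code{event}, \code{arm}.
#' @param weights observation weights (IPTW), default unit.
#' @return A data.frame ordered by ascending \code{p_interaction}:
#'   \code{feature}, \code{beta_interaction}, \code{p_interaction},
#'   \code{converged}, \code{rank}.
#' @export
screen_interactions <- function(features, cohort, weights = NULL) {
  X <- as.matrix(features)
  assert_columns(cohort, c("time_months", "event", "arm"), "cohort")
  assert_that(sum(cohort$event) > 0, "no events in cohort")
  if (is.null(weights)) weights <- rep(1, nrow(cohort))
  assert_that(nrow(X) == nrow(cohort), "'features' rows must align to cohort")
  y <- survival::Surv(cohort$time_months, cohort$event)
  arm <- cohort$arm
  res <- lapply(colnames(X), function(f) {
    x <- X[, f]
    fit <- tryCatch({
      m <- survival::coxph(y ~ arm * x, weights = weights,
                           ties = "efron",
                           control = survival::coxph.control(iter.max = 100))
      co <- m$coefficients["arm:x"]
      se <- sqrt(diag(m$var))[3]
      p <- 2 * stats::pnorm(-abs(co / se))
      if (!is.finite(p)) stop("non-finite Wald statistic")
      list(beta = unname(co), p = unname(p), ok = TRUE)
    }, error = function(e) list(beta = NA_real_, p = 1, ok = FALSE),
       warning = function(w) {
      m <- suppressWarnings(
        survival::coxph(y ~ arm * x, weights = weights, ties = "efron"))
      co <- m$coefficients["arm:x"]
      se <- sqrt(diag(m$var))[3]
      p <- 2 * stats::pnorm(-abs(co / se))
      if (!is.finite(p)) list(beta = NA_real_, p = 1, ok = FALSE)
      else list(beta = unname(co), p = unname(p), ok = TRUE)
    })
    data.frame(feature = f, beta_interaction = fit$beta,
               p_interaction = fit$p, converged = fit$ok)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$p_interaction, seq_len(nrow(out))), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Greedy correlation-redundancy filter
#'
#' Walks the screened features in rank order and drops any feature whose
#' absolute Pearson correlation with an already-retained feature exceeds
#' \code{r_max}. Constant features (undefined correlation) are dropped with
#' a warning.
#'
#' @param ranked character vector of feature names in screening rank order.
#' @param features feature matrix containing those columns; ignored when
#'   \code{cor_matrix} is given.
#' @param r_max correlation threshold (default 0.8; strictly-greater drops).
#' @param cor_matrix optional precomputed correlation matrix (named rows and
#'   columns covering \code{ranked}).
#' @return Character vector of retained feature names, in rank order.
#' @export
redundancy_filter <- function(ranked, features, r_max = 0.8,
                              cor_matrix = NULL) {
  if (is.null(cor_matrix)) {
    X <- as.matrix(features)[, ranked, drop = FALSE]
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0)) {
      warning("dropping constant feature(s) with undefined correlation: ",
              paste(ranked[sds == 0], collapse = ", "))
      ranked <- ranked[sds > 0]
      X <- X[, ranked, drop = FALSE]
    }
    cor_matrix <- stats::cor(X)
  }
  kept <- character(0)
  for (f in ranked) {
    if (length(kept) == 0) { kept <- f; next }
    r <- abs(cor_matrix[f, kept])
    if (all(r <= r_max)) kept <- c(kept, f)
  }
  kept
}

#' Modified-covariate Cox fit of treatment benefit
#'
#' Implements the modified covariate method for treatment-interaction
#' estimation: each candidate feature is replaced by
#' \eqn{W = x (2T - 1)/2} and a weighted Cox model is fitted on the modified
#' covariates only (no main effects). The fitted coefficients \eqn{\gamma}
#' estimate the per-feature modification of the treatment log-HR: a patient's
#' predicted treatment log-HR is \eqn{\gamma' x}.
#'
#' @param features standardized feature matrix (candidate columns only).
#' @param cohort table with \code{time_months}, \code{event}, \code{arm}
#'   (both arms present, >= 1 event per arm).
#' @param weights observation weights entering the partial likelihood
#'   (IPTW composition), default unit.
#' @param ties,eps,iter.max Cox fitting controls (Efron ties, 1e-9, 100).
#' @return A list with \code{gamma} (named coefficients), \code{se},
#'   \code{p} (Wald), \code{loglik} (partial log-likelihood at the
#'   solution), and \code{fit} (the \code{coxph} object).
#' @export
fit_modified_covariate_cox <- function(features, cohort, weights = NULL,
                                       ties = "efron", eps = 1e-9,
                                       iter.max = 100) {
  X <- as.matrix(features)
  assert_that(ncol(X) >= 1, "no candidate features supplied")
  assert_that(!is.null(colnames(X)), "feature columns must be named")
  assert_columns(cohort, c("time_months", "event", "arm"), "cohort")
  assert_that(all(cohort$arm %in% c(0, 1)), "'arm' must be coded 0/1")
  assert_that(length(unique(cohort$arm)) == 2, "both arms must be present")
  for (a in 0:1)
    assert_that(sum(cohort$event[cohort$arm == a]) >= 1,
                sprintf("no events in arm %d", a))
  if (all(apply(X, 2, function(x) all(x == 0))))
    stop("all candidate features are identically zero: nothing to fit",
         call. = FALSE)
  if (is.null(weights)) weights <- rep(1, nrow(cohort))

  W <- X * (2 * cohort$arm - 1) / 2
  colnames(W) <- colnames(X)
  y <- survival::Surv(cohort$time_months, cohort$event)
  fit <- tryCatch(
    suppressWarnings(survival::coxph(
      y ~ W, weights = weights, ties = ties,
      control = survival::coxph.control(eps = eps, iter.max = iter.max))),
    error = function(e) stop("modified-covariate Cox fit failed: ",
                             conditionMessage(e), call. = FALSE))
  if (any(!is.finite(fit$coefficients)))
    stop("modified-covariate Cox fit did not converge to finite coefficients",
         call. = FALSE)
  gamma <- stats::setNames(as.numeric(fit$coefficients), colnames(W))
  se <- stats::setNames(sqrt(diag(fit$var)), colnames(W))
  p <- 2 * stats::pnorm(-abs(gamma / se))
  list(gamma = gamma, se = se, p = p, loglik = fit$loglik[2], fit = fit)
}

#' Backward step-wise selection of the benefit model
#'
#' Starting from the full modified-covariate fit, iteratively removes the
#' coefficient with the largest Wald p-value (ties broken by dropping the
#' later-ranked feature) and refits, until every remaining coefficient has
#' p < \code{alpha}. An empty final set is an explicit "no significant
#' benefit features" outcome.
#'
#' @param features standardized candidate feature matrix, columns in
#'   screening rank order.
#' @param cohort,weights as in \code{\link{fit_modified_covariate_cox}}.
#' @param alpha Wald significance threshold (default 0.05).
#' @param standardizer optional \code{feature_standardizer} to embed in the
#'   returned model (so scoring can standardize raw features).
#' @return An \code{\link{ictos_model}}, or \code{NULL} (with a message) when
#'   no feature reaches significance.
#' @export
backward_select <- function(features, cohort, weights = NULL, alpha = 0.05,
                            standardizer = NULL) {
  X <- as.matrix(features)
  current <- colnames(X)
  rank_of <- stats::setNames(seq_along(current), current)
  while (length(current) > 0) {
    fit <- fit_modified_covariate_cox(X[, current, drop = FALSE], cohort,
                                      weights = weights)
    if (all(fit$p < alpha)) {
      return(ictos_model(gamma = fit$gamma, se = fit$se, p = fit$p,
                         standardizer = standardizer))
    }
    worst_p <- max(fit$p)
    ties_at <- names(fit$p)[fit$p == worst_p]
    drop_f <- ties_at[which.max(rank_of[ties_at])]
    current <- setdiff(current, drop_f)
  }
  message("backward selection removed every feature: ",
          "no significant benefit features")
  NULL
}

#' ICTOS benefit model
#'
#' Container for the fitted (or published) treatment-benefit model. The
#' stored \code{coefficients} are in score orientation: ICTOS =
#' \code{sum(coefficients * x)} with positive scores predicting lower hazard
#' under ICT+CCRT. For a model fitted by the modified covariate method the
#' score coefficients are \eqn{-\gamma} (negated hazard-side coefficients).
#'
#' @param gamma named hazard-orientation coefficients from the
#'   modified-covariate fit; mutually exclusive with \code{coefficients}.
#' @param coefficients named score-orientation coefficients (as printed for
#'   the published model).
#' @param se,p optional named Wald SEs / p-values.
#' @param standardizer optional \code{feature_standardizer}.
#' @param cutoff high/low decision cutoff on the score scale (0: the
#'   no-predicted-difference point).
#' @return An object of class \code{ictos_model}.
#' @export
ictos_model <- function(gamma = NULL, coefficients = NULL, se = NULL, p = NULL,
                        standardizer = NULL, cutoff = 0) {
  assert_that(xor(is.null(gamma), is.null(coefficients)),
              "supply exactly one of 'gamma' (hazard side) or 'coefficients' (score side)")
  coefs <- if (is.null(coefficients)) -gamma else coefficients
  assert_that(length(coefs) >= 1 && all(is.finite(coefs)) &&
                !is.null(names(coefs)),
              "model coefficients must be a named finite vector")
  structure(list(features = names(coefs),
                 coefficients = coefs,
                 gamma = if (is.null(gamma)) -coefs else gamma,
                 se = se, p = p,
                 treatment_coding = "0=CCRT, 1=ICT+CCRT",
                 cutoff = cutoff,
                 standardizer = standardizer),
            class = "ictos_model")
}

#' @export
print.ictos_model <- function(x, ...) {
  cat("ICTOS benefit model (score > ", x$cutoff, " predicts ICT benefit)\n",
      sep = "")
  terms <- sprintf("%+.3f*%s", x$coefficients, x$features)
  cat("  ICTOS =", paste(terms, collapse = " "), "\n")
  if (!is.null(x$p))
    cat("  Wald p:", paste(sprintf("%s=%.3g", names(x$p), x$p),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Score patients with an ICTOS model
#'
#' Computes ICTOS = \code{sum(coefficients * x)} for each patient and labels
#' \code{"high"} (score > cutoff, predicted ICT benefit) or \code{"low"}.
#' Features must be present by name (no imputation); raw features are
#' standardized first when the model embeds a standardizer and
#' \code{standardized = FALSE}.
#'
#' @param model an \code{\link{ictos_model}}.
#' @param features named numeric vector (one patient) or matrix/data.frame
#'   (rows = patients) holding the model's features.
#' @param standardized set to \code{FALSE} to apply the model's embedded
#'   standardizer to raw feature values first.
#' @return A data.frame with \code{score} and \code{label} (factor
#'   high/low), one row per patient.
#' @export
ictos_score <- function(model, features, standardized = TRUE) {
  stopifnot(inherits(model, "ictos_model"))
  if (is.null(dim(features))) features <- t(as.matrix(features))
  X <- as.matrix(features)
  if (!standardized) {
    assert_that(!is.null(model$standardizer),
                "model has no embedded standardizer; pass standardized features")
    X <- apply_standardizer(model$standardizer, X)
  }
  missing <- setdiff(model$features, colnames(X))
  assert_that(length(missing) == 0L,
              paste("missing model feature(s):", paste(missing, collapse = ", ")))
  s <- drop(X[, model$features, drop = FALSE] %*% model$coefficients)
  data.frame(score = as.numeric(s),
             label = factor(ifelse(s > model$cutoff, "high", "low"),
                            levels = c("low", "high")))
}

#' Read and write ICTOS models as YAML
#'
#' Serializes the score-orientation coefficients, cutoff and (when present)
#' the embedded standardization parameters. Writing the same model twice
#' yields byte-identical files, so a rerun of the training pipeline under a
#' fixed seed reproduces its model artifact exactly.
#'
#' @param model an \code{\link{ictos_model}}.
#' @param path YAML file path.
#' @return \code{write_ictos_model}: \code{path} invisibly;
#'   \code{read_ictos_model}: an \code{\link{ictos_model}}.
#' @export
write_ictos_model <- function(model, path) {
  stopifnot(inherits(model, "ictos_model"))
  obj <- list(coefficients = as.list(model$coefficients),
              cutoff = model$cutoff)
  if (!is.null(model$standardizer)) {
    obj$standardizer <- list(mean = as.list(model$standardizer$mean[model$features]),
                             sd = as.list(model$standardizer$sd[model$features]))
  }
  yaml::write_yaml(obj, path, precision = 17L)
  invisible(path)
}

#' @rdname write_ictos_model
#' @export
read_ictos_model <- function(path) {
  y <- yaml::read_yaml(path)
  std <- NULL
  if (!is.null(y$standardizer)) {
    std <- structure(list(mean = unlist(y$standardizer$mean),
                          sd = unlist(y$standardizer$sd),
                          dropped = character(0),
                          denominator = "population"),
                     class = "feature_standardizer")
  }
  ictos_model(coefficients = unlist(y$coefficients),
              cutoff = y$cutoff %||% 0, standardizer = std)
}

#' The published three-feature ICTOS model
#'
#' Loads the packaged read-only fixture of the published model,
#' ICTOS = -0.668*skewness - 0.442*GLCM_variance + 0.410*GLRLM_LRHGLE,
#' defined on training-cohort-standardized contrast-enhanced-T1 features.
#' The printed coefficients are rounded to three decimals, so scores computed
#' from them can differ from published score read-outs by a few hundredths.
#'
#' @return An \code{\link{ictos_model}} with features \code{skewness},
#'   \code{GLCM_variance}, \code{GLRLM_LRHGLE}.
#' @export
ictos_paper_model <- function() {
  path <- system.file("extdata", "ictos_paper.yaml", package = "ictosr",
                      mustWork = TRUE)
  y <- yaml::read_yaml(path)
  ictos_model(coefficients = unlist(y$coefficients), cutoff = y$cutoff)
}
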