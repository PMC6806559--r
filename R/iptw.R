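# Inverse probability of treatment weighting and covariate balance.

iptw_default_covariates <- c("age", "sex", "pebv_dna", "nodal_necrosis",
                             "tumor_volume_ml", "n_stage", "t_stage")

# Design matrix for propensity/balance: T and N stage as dummy indicators,
# EBV DNA as the binary >= 2000 copies/ml split used throughout the cohort
# analyses, other covariates as-is.
iptw_design <- function(cohort, covariates = iptw_default_covariates) {
  assert_columns(cohort, covariates, "cohort")
  cols <- list()
  for (cv in covariates) {
    if (cv == "pebv_dna") {
      cols[["pebv_ge2000"]] <- as.numeric(cohort$pebv_dna >= 2000)
    } else if (cv %in% c("t_stage", "n_stage")) {
      lev <- sort(unique(cohort[[cv]]))
      for (l in lev[-1]) {
        cols[[sprintf("%s_%s", cv, l)]] <- as.numeric(cohort[[cv]] == l)
      }
    } else {
      cols[[cv]] <- as.numeric(cohort[[cv]])
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- NULL
  m
}

#' Fit the propensity-score model
#'
#' Logistic regression of treatment arm on the balancing covariates (age,
#' sex, EBV DNA >= 2000 copies/ml, cervical nodal necrosis, primary tumor
#' volume, N-stage and T-stage indicators by default).
#'
#' @param cohort cohort table with an \code{arm} column (0/1) and the
#'   covariate columns; no missing values.
#' @param covariates covariate column names (cohort-table naming).
#' @return A list with \code{scores} (propensity e(x), strictly inside
#'   (0, 1)), \code{fit} (the \code{glm} object) and \code{design} (the
#'   expanded design matrix).
#' @export
fit_propensity <- function(cohort, covariates = iptw_default_covariates) {
  assert_columns(cohort, "arm", "cohort")
  assert_that(length(unique(cohort$arm)) == 2, "both arms must be present")
  X <- iptw_design(cohort, covariates)
  assert_that(!anyNA(X), "covariates must not contain missing values")
  df <- data.frame(arm = cohort$arm, X, check.names = FALSE)
  fit <- suppressWarnings(
    stats::glm(arm ~ ., data = df, family = stats::binomial()))
  e <- stats::fitted(fit)
  eps <- 1e-8
  if (any(e < eps | e > 1 - eps))
    stop("propensity model shows (near-)perfect separation: fitted ",
         "probabilities reach 0/1; revise the covariate specification",
         call. = FALSE)
  list(scores = as.numeric(e), fit = fit, design = X)
}

#' Inverse-probability-of-treatment (ATE) weights
#'
#' Unstabilized weights are \eqn{T/e + (1-T)/(1-e)}; stabilized weights
#' multiply by the marginal arm probabilities. Weights beyond the configured
#' truncation quantiles are clipped, with the clip count recorded.
#'
#' @param scores propensity scores in (0, 1).
#' @param arm treatment indicator (0/1) aligned to \code{scores}.
#' @param stabilized multiply by marginal arm probabilities (default TRUE).
#' @param truncate lower/upper weight truncation quantiles (default
#'   1st/99th percentile); \code{NULL} disables truncation.
#' @return Numeric weights with attributes \code{"n_truncated"} and
#'   \code{"weighted_n"} (per-arm weighted totals).
#' @export
compute_weights <- function(scores, arm, stabilized = TRUE,
                            truncate = c(0.01, 0.99)) {
  assert_that(length(scores) == length(arm), "'scores' and 'arm' lengths differ")
  assert_that(all(scores > 0 & scores < 1), "'scores' must lie strictly in (0, 1)")
  p1 <- mean(arm)
  w <- ifelse(arm == 1, 1 / scores, 1 / (1 - scores))
  if (stabilized) w <- w * ifelse(arm == 1, p1, 1 - p1)
  n_trunc <- 0L
  if (!is.null(truncate)) {
    q <- stats::quantile(w, truncate, names = FALSE)
    n_trunc <- sum(w < q[1] | w > q[2])
    w <- pmin(pmax(w, q[1]), q[2])
  }
  attr(w, "n_truncated") <- n_trunc
  attr(w, "weighted_n") <- c(arm0 = sum(w[arm == 0]), arm1 = sum(w[arm == 1]))
  w
}

# Weighted standardized mean difference for one covariate column.
smd_one <- function(x, arm, w) {
  x1 <- x[arm == 1]; x0 <- x[arm == 0]
  w1 <- w[arm == 1]; w0 <- w[arm == 0]
  m1 <- wmean(x1, w1); m0 <- wmean(x0, w0)
  binary <- all(x %in% c(0, 1))
  v1 <- if (binary) m1 * (1 - m1) else wvar(x1, w1)
  v0 <- if (binary) m0 * (1 - m0) else wvar(x0, w0)
  pooled <- (v1 + v0) / 2
  if (pooled == 0) return(if (isTRUE(all.equal(m1, m0))) 0 else Inf)
  abs(m1 - m0) / sqrt(pooled)
}

#' Covariate balance before and after weighting
#'
#' Standardized mean differences (SMD) per expanded covariate, unweighted
#' and under the supplied weights. Continuous SMD is
#' \eqn{|\mu_1-\mu_0| / \sqrt{(s_1^2+s_0^2)/2}}; binary covariates use the
#' proportion-based analogue.
#'
#' @param cohort cohort table with \code{arm} and covariate columns.
#' @param weights IPTW weights aligned to rows (unit weights give
#'   before = after).
#' @param covariates covariate names (cohort-table naming).
#' @return An object of class \code{balance_report}: data.frame with columns
#'   \code{covariate}, \code{smd_unweighted}, \code{smd_weighted}; weighted
#'   per-arm sizes in attribute \code{"weighted_n"}.
#' @export
balance_report <- function(cohort, weights,
                           covariates = iptw_default_covariates) {
  assert_that(length(weights) == nrow(cohort), "'weights' must align to rows")
  assert_that(all(is.finite(weights) & weights >= 0),
              "'weights' must be nonnegative and finite")
  X <- iptw_design(cohort, covariates)
  arm <- cohort$arm
  unit <- rep(1, nrow(cohort))
  out <- data.frame(
    covariate = colnames(X),
    smd_unweighted = apply(X, 2, smd_one, arm = arm, w = unit),
    smd_weighted = apply(X, 2, smd_one, arm = arm, w = weights),
    row.names = NULL)
  structure(out, class = c("balance_report", "data.frame"),
            weighted_n = c(arm0 = sum(weights[arm == 0]),
                           arm1 = sum(weights[arm == 1])))
}

#' @export
print.balance_report <- function(x, ...) {
  wn <- attr(x, "weighted_n")
  cat(sprintf("Covariate balance (weighted n: CCRT %.1f, ICT+CCRT %.1f)\n",
              wn[1], wn[2]))
  print.data.frame(x, digits = 3, ...)
  invisible(x)
}
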