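# Reproducibility screening by intraclass correlation.

#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-rater ICC from the
#' ANOVA mean squares (the Shrout–Fleiss ICC(2,1)):
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with \eqn{MS_R} the between-subject, \eqn{MS_C} the between-rater and
#' \eqn{MS_E} the residual mean square.
#'
#' @param ratings numeric matrix, n subjects x k raters (k >= 2), no missing
#'   entries.
#' @return ICC estimate in [-1, 1]; \code{NaN} with a warning when both the
#'   subject and rater variance are zero (agreement undefined).
#' @export
icc <- function(ratings) {
  x <- as.matrix(ratings)
  n <- nrow(x); k <- ncol(x)
  assert_that(n >= 2, "need at least 2 subjects")
  assert_that(k >= 2, "need at least 2 raters/repeats")
  assert_that(!anyNA(x), "ratings must not contain missing values")
  grand <- mean(x)
  rm_ <- rowMeans(x); cm <- colMeans(x)
  msr <- k * sum((rm_ - grand)^2) / (n - 1)
  msc <- n * sum((cm - grand)^2) / (k - 1)
  mse <- sum((x - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + grand)^2) /
    ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom == 0) {
    warning("ICC undefined: zero between-subject and between-rater variance")
    return(NaN)
  }
  (msr - mse) / denom
}

#' Reproducibility filter on repeat-segmentation features
#'
#' Computes the per-feature intra-observer and inter-observer ICC from two
#' pairs of feature tables (same patients, repeated segmentations) and
#' retains features whose ICCs clear the threshold in \emph{both} tests.
#'
#' @param intra list of two feature tables (matrix/data.frame, rows =
#'   subjects, identical columns): the same rater's two segmentations.
#' @param inter list of two feature tables: two raters' segmentations.
#' @param threshold retention threshold; features with intra-ICC and
#'   inter-ICC both \code{>= threshold} are kept (default 0.8).
#' @return A list with \code{retained} (character vector of feature names),
#'   \code{icc} (data.frame: feature, icc_intra, icc_inter, retained) and
#'   \code{n_retained}.
#' @export
icc_filter_features <- function(intra, inter, threshold = 0.8) {
  stopifnot(is.list(intra), length(intra) == 2L,
            is.list(inter), length(inter) == 2L)
  a1 <- as.matrix(intra[[1]]); a2 <- as.matrix(intra[[2]])
  b1 <- as.matrix(inter[[1]]); b2 <- as.matrix(inter[[2]])
  feats <- colnames(a1)
  assert_that(identical(feats, colnames(a2)) && identical(feats, colnames(b1)) &&
                identical(feats, colnames(b2)),
              "all four tables must share an identical feature set (columns)")
  icc_pair <- function(u, v) {
    vapply(seq_along(feats),
           function(j) suppressWarnings(icc(cbind(u[, j], v[, j]))),
           numeric(1))
  }
  icc_intra <- icc_pair(a1, a2)
  icc_inter <- icc_pair(b1, b2)
  keep <- !is.na(icc_intra) & !is.na(icc_inter) &
    icc_intra >= threshold & icc_inter >= threshold
  res <- data.frame(feature = feats, icc_intra = icc_intra,
                    icc_inter = icc_inter, retained = keep)
  list(retained = feats[keep], icc = res, n_retained = sum(keep))
}
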