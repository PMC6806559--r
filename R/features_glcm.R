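# Gray-level co-occurrence matrices and their 24 scalar features.
#
# 2D convention: pairs are counted per axial slice at the requested in-plane
# offset, counts are accumulated over slices, the pooled count matrix is
# symmetrized and normalized once per ROI.

glcm_offset <- function(direction) {
  switch(as.character(direction),
         "0"   = c(0L, 1L),
         "45"  = c(-1L, 1L),
         "90"  = c(1L, 0L),
         "135" = c(1L, 1L),
         stop("'direction' must be one of 0, 45, 90, 135 (degrees)", call. = FALSE))
}

#' Gray-level co-occurrence matrix
#'
#' Counts in-ROI voxel pairs at the given in-plane offset, per slice, sums
#' the counts over slices, symmetrizes, and normalizes to sum 1.
#'
#' @param gray a \code{gray_level_map} from \code{\link{discretize}}.
#' @param distance pair offset magnitude in voxels (>= 1).
#' @param direction in-plane angle in degrees: 0, 45, 90 or 135.
#' @return A \code{n_bins x n_bins} matrix summing to 1, with attribute
#'   \code{"n_pairs"} (raw pair count) and \code{"degenerate"} set when no
#'   valid pair exists (matrix is then all zeros).
#' @export
glcm_matrix <- function(gray, distance = 1L, direction = 0) {
  stopifnot(inherits(gray, "gray_level_map"))
  assert_scalar_number(distance, "distance", lower = 1)
  off <- glcm_offset(direction) * as.integer(distance)
  ng <- gray$n_bins
  counts <- matrix(0, ng, ng)
  d <- dim(gray$labels)
  for (s in seq_len(d[1])) {
    sl <- get_slice(gray$labels, s)
    nr <- nrow(sl); nc <- ncol(sl)
    r1 <- seq_len(nr); c1 <- seq_len(nc)
    r2 <- r1 + off[1]; c2 <- c1 + off[2]
    keep_r <- r2 >= 1 & r2 <= nr
    keep_c <- c2 >= 1 & c2 <= nc
    if (!any(keep_r) || !any(keep_c)) next
    a <- sl[r1[keep_r], c1[keep_c], drop = FALSE]
    b <- sl[r2[keep_r], c2[keep_c], drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    counts <- counts + matrix(tabulate((a[ok] - 1L) * ng + b[ok], nbins = ng * ng),
                              ng, ng, byrow = TRUE)
  }
  n_pairs <- sum(counts)
  sym <- counts + t(counts)
  p <- if (n_pairs > 0) sym / sum(sym) else sym
  attr(p, "n_pairs") <- n_pairs
  attr(p, "degenerate") <- n_pairs == 0
  p
}

glcm_feature_names <- c(
  "autocorrelation", "joint_average", "cluster_prominence", "cluster_shade",
  "cluster_tendency", "contrast", "correlation", "difference_average",
  "difference_entropy", "difference_variance", "dissimilarity", "energy",
  "entropy", "homogeneity", "idm", "idmn", "idn", "inverse_variance",
  "maximum_probability", "sum_average", "sum_entropy", "sum_variance",
  "variance", "imc1")

#' Scalar features of a co-occurrence matrix
#'
#' Computes 24 standard co-occurrence features. \code{variance} is the joint
#' (gray-level) variance \eqn{\sum_{i,j} P(i,j)(i-\mu)^2} with
#' \eqn{\mu = \sum_{i,j} P(i,j)\, i} — the quantity the benefit model calls
#' GLCM_variance. On a degenerate (all-zero) matrix every feature is 0 by
#' convention and the result carries \code{attr(, "degenerate") = TRUE}.
#'
#' @param P normalized symmetric co-occurrence matrix from
#'   \code{\link{glcm_matrix}}.
#' @return Named numeric vector of length 24.
#' @export
glcm_features <- function(P) {
  ng <- nrow(P)
  out <- stats::setNames(numeric(length(glcm_feature_names)), glcm_feature_names)
  if (isTRUE(attr(P, "degenerate")) || sum(P) == 0) {
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(P)                      # marginal (symmetric: px == py)
  mu <- sum(P * i)
  sigma2 <- sum(P * (i - mu)^2)
  log2p <- function(x) ifelse(x > 0, log2(x), 0)

  # |i-j| and i+j distributions
  kdiff <- 0:(ng - 1)
  pdiff <- vapply(kdiff, function(k) sum(P[abs(i - j) == k]), numeric(1))
  ksum <- 2:(2 * ng)
  psum <- vapply(ksum, function(k) sum(P[(i + j) == k]), numeric(1))

  out["autocorrelation"] <- sum(P * i * j)
  out["joint_average"] <- mu
  out["cluster_prominence"] <- sum(P * (i + j - 2 * mu)^4)
  out["cluster_shade"] <- sum(P * (i + j - 2 * mu)^3)
  out["cluster_tendency"] <- sum(P * (i + j - 2 * mu)^2)
  out["contrast"] <- sum(P * (i - j)^2)
  out["correlation"] <- if (sigma2 > 0) (sum(P * i * j) - mu^2) / sigma2 else 0
  da <- sum(kdiff * pdiff)
  out["difference_average"] <- da
  out["difference_entropy"] <- -sum(pdiff * log2p(pdiff))
  out["difference_variance"] <- sum(pdiff * (kdiff - da)^2)
  out["dissimilarity"] <- sum(P * abs(i - j))
  out["energy"] <- sum(P^2)
  out["entropy"] <- -sum(P * log2p(P))
  out["homogeneity"] <- sum(P / (1 + abs(i - j)))
  out["idm"] <- sum(P / (1 + (i - j)^2))
  out["idmn"] <- sum(P / (1 + (i - j)^2 / ng^2))
  out["idn"] <- sum(P / (1 + abs(i - j) / ng))
  out["inverse_variance"] <- sum(P[i != j] / (i[i != j] - j[i != j])^2)
  out["maximum_probability"] <- max(P)
  sa <- sum(ksum * psum)
  out["sum_average"] <- sa
  out["sum_entropy"] <- -sum(psum * log2p(psum))
  out["sum_variance"] <- sum(psum * (ksum - sa)^2)
  out["variance"] <- sigma2
  hxy <- out[["entropy"]]
  pxy <- outer(px, px)
  hxy1 <- -sum(P * log2p(pxy))
  hx <- -sum(px * log2p(px))
  out["imc1"] <- if (hx > 0) (hxy - hxy1) / hx else 0
  out
}
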