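# First-order (intensity histogram) and 2D shape features.

intensity_feature_names <- c(
  "mean", "median", "minimum", "maximum", "range", "variance", "sd",
  "skewness", "kurtosis", "energy", "rms", "entropy", "uniformity",
  "p10", "p25", "p75", "p90", "iqr", "mad")

#' Fisher moment skewness
#'
#' \eqn{m_3 / m_2^{3/2}} with population moments; 0 by convention for a
#' zero-variance sample.
#' @param x numeric vector (>= 3 values for a meaningful third moment).
#' @return Skewness statistic.
#' @export
moment_skewness <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^3) / m2^1.5
}

#' First-order intensity features of an ROI
#'
#' 19 features of the pooled ROI intensity sample (all slices together):
#' location, dispersion, moment shape (Fisher skewness and excess kurtosis),
#' energy, histogram entropy/uniformity (32 fixed bins over the ROI range),
#' and percentiles. A zero-variance ROI gets skewness and kurtosis 0 by
#' convention and carries \code{attr(, "degenerate") = TRUE}.
#'
#' @param vol an \code{\link{mr_volume}}.
#' @param mask the aligned \code{\link{roi_mask}} with >= 3 voxels.
#' @param n_bins histogram bins for entropy/uniformity.
#' @return Named numeric vector of length 19.
#' @export
intensity_features <- function(vol, mask, n_bins = 32L) {
  stopifnot(inherits(vol, "mr_volume"), inherits(mask, "roi_mask"))
  x <- vol$voxels[mask$voxels]
  assert_that(length(x) >= 3, "ROI must contain at least 3 voxels")
  m <- mean(x)
  v <- pop_var(x)
  q <- stats::quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  if (v > 0) {
    h <- tabulate(pmin(floor((x - min(x)) / ((max(x) - min(x)) / n_bins)) + 1L,
                       n_bins), nbins = n_bins)
    p <- h / sum(h)
    p <- p[p > 0]
    skew <- mean((x - m)^3) / v^1.5
    kurt <- mean((x - m)^4) / v^2 - 3
    entropy <- -sum(p * log2(p))
    uniformity <- sum(p^2)
  } else {
    skew <- 0; kurt <- 0; entropy <- 0; uniformity <- 1
  }
  out <- c(mean = m, median = stats::median(x), minimum = min(x),
           maximum = max(x), range = max(x) - min(x), variance = v,
           sd = sqrt(v), skewness = skew, kurtosis = kurt,
           energy = sum(x^2), rms = sqrt(mean(x^2)), entropy = entropy,
           uniformity = uniformity, p10 = q[1], p25 = q[2], p75 = q[3],
           p90 = q[4], iqr = q[3] - q[2], mad = mean(abs(x - m)))
  if (v == 0) attr(out, "degenerate") <- TRUE
  out
}

shape_feature_names <- c(
  "area_mm2", "perimeter_mm", "perimeter_area_ratio", "major_axis_mm",
  "minor_axis_mm", "elongation", "circularity", "max_diameter_mm",
  "eccentricity", "aspect_ratio")

#' 2D shape features of a tumor mask
#'
#' Computed on the axial slice of maximum ROI area. Area is voxel count times
#' pixel area; perimeter is the exposed-pixel-face boundary length; axis
#' lengths come from the second central moments of the pixel-center
#' coordinates (4 sd along the principal axes, the image-moments ellipse
#' convention); the maximum in-plane diameter is the largest pairwise
#' distance between convex-hull pixel centers.
#'
#' @param mask a nonempty \code{\link{roi_mask}}.
#' @return Named numeric vector of length 10.
#' @export
shape_features <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  areas <- apply(mask$voxels, 1, sum)
  assert_that(sum(areas) > 0, "'mask' is empty")
  sl <- get_slice(mask$voxels, which.max(areas))
  sp <- mask$in_plane_spacing
  n <- sum(sl)
  area <- n * sp^2

  # exposed faces: for each ROI pixel, faces not shared with an ROI neighbor
  exposed <- 4 * n - 2 * (sum(sl[-nrow(sl), ] & sl[-1, ]) +
                          sum(sl[, -ncol(sl)] & sl[, -1]))
  perimeter <- exposed * sp

  idx <- which(sl, arr.ind = TRUE)
  xy <- idx * sp
  if (n >= 2) {
    cv <- stats::cov(xy) * (n - 1) / n
    ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev <- pmax(ev, 0)
    major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2])
    hull <- idx[grDevices::chull(idx), , drop = FALSE] * sp
    dmax <- max(stats::dist(hull))
  } else {
    major <- minor <- 0; dmax <- 0
  }
  circ <- if (perimeter > 0) 4 * pi * area / perimeter^2 else 0
  c(area_mm2 = area, perimeter_mm = perimeter,
    perimeter_area_ratio = perimeter / area,
    major_axis_mm = major, minor_axis_mm = minor,
    elongation = if (major > 0) minor / major else 1,
    circularity = circ, max_diameter_mm = dmax,
    eccentricity = if (major > 0) sqrt(pmax(1 - (minor / major)^2, 0)) else 0,
    aspect_ratio = if (minor > 0) major / minor else 1)
}
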