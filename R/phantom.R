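#' Specification of a synthetic texture phantom
#'
#' A phantom is a stack of axial slices containing a disk-shaped "tumor" ROI
#' embedded in a homogeneous "body" disk on a zero background. Three texture
#' knobs map monotonically (in expectation) onto the three image features the
#' benefit model is built from:
#' \describe{
#'   \item{\code{target_skew}}{sign and magnitude of the ROI intensity-histogram
#'     skewness (a standardized, sign-flipped gamma component).}
#'   \item{\code{heterogeneity}}{amplitude of patchwise gray-level plateaus,
#'     driving gray-level co-occurrence (joint) variance.}
#'   \item{\code{run_structure}}{side length of the plateaus, driving
#'     long-run / high-gray run-length emphasis.}
#' }
#'
#' @param grid_shape integer vector (slices, rows, cols) of the voxel grid.
#' @param roi_radius in-plane ROI radius in voxels; the ROI must fit inside
#'   the grid with a 1-voxel margin.
#' @param target_skew dimensionless; sign of the intended ROI skewness.
#' @param heterogeneity nonnegative; plateau amplitude (intensity units are
#'   arbitrary MR units).
#' @param run_structure nonnegative; plateau side = 1 + floor(run_structure).
#' @param noise_sd nonnegative intensity scale of the stochastic (skew-shaped)
#'   component; 0 together with \code{heterogeneity = 0} yields a constant ROI.
#' @param in_plane_spacing,slice_thickness voxel spacing in mm.
#' @param seed integer RNG seed; identical seeds give bit-identical phantoms.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(grid_shape = c(4L, 48L, 48L), roi_radius = 10,
                         target_skew = 0, heterogeneity = 1, run_structure = 1,
                         noise_sd = 40, in_plane_spacing = 1, slice_thickness = 4,
                         seed = 1L) {
  assert_that(length(grid_shape) == 3L && all(grid_shape >= 1),
              "'grid_shape' must be three positive integers (slices, rows, cols)")
  assert_scalar_number(roi_radius, "roi_radius", lower = 1)
  assert_scalar_number(heterogeneity, "heterogeneity", lower = 0)
  assert_scalar_number(run_structure, "run_structure", lower = 0)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  assert_scalar_number(in_plane_spacing, "in_plane_spacing", lower = 0, strict_lower = TRUE)
  assert_scalar_number(slice_thickness, "slice_thickness", lower = 0, strict_lower = TRUE)
  if (2 * roi_radius + 2 > min(grid_shape[2:3]))
    stop("ROI of radius ", roi_radius, " does not fit inside a ",
         grid_shape[2], "x", grid_shape[3], " in-plane grid", call. = FALSE)
  structure(list(grid_shape = as.integer(grid_shape), roi_radius = roi_radius,
                 target_skew = target_skew, heterogeneity = heterogeneity,
                 run_structure = run_structure, noise_sd = noise_sd,
                 in_plane_spacing = in_plane_spacing,
                 slice_thickness = slice_thickness, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Standardized (mean 0, sd 1) sample with Fisher skewness ~ s in expectation.
# s = 0 falls back to the normal; otherwise a sign-flipped standardized gamma
# with shape (2/|s|)^2, whose skewness is exactly 2/sqrt(shape) = |s|.
skewed_sample <- function(n, s) {
  if (abs(s) < 1e-12) return(stats::rnorm(n))
  shape <- (2 / abs(s))^2
  g <- (stats::rgamma(n, shape = shape, rate = 1) - shape) / sqrt(shape)
  sign(s) * g
}

# Expand a per-patch quantity to the full in-plane grid (square patches of
# side ps).
patch_expand <- function(values, rows, cols, ps) {
  pr <- ceiling(rows / ps)
  pc <- ceiling(cols / ps)
  m <- matrix(values, pr, pc)
  m[ceiling(seq_len(rows) / ps), ceiling(seq_len(cols) / ps), drop = FALSE]
}

# Textured ROI slice values. Three independent-by-design components:
#  - a skew-shaped voxelwise field (controls histogram skewness);
#  - "solid" patches that share a single draw of the same field, so the
#    marginal distribution is unchanged but same-gray runs lengthen with
#    patch size (controls run-length structure);
#  - a symmetric two-point (+/-) patch offset whose amplitude separates the
#    histogram into modes (controls co-occurrence variance).
roi_texture <- function(n_roi, roi2d, spec, ps) {
  nr <- nrow(roi2d); nc <- ncol(roi2d)
  pr <- ceiling(nr / ps); pc <- ceiling(nc / ps)
  g_vox <- skewed_sample(n_roi, spec$target_skew)
  g_patch <- patch_expand(skewed_sample(pr * pc, spec$target_skew), nr, nc, ps)[roi2d]
  solid <- patch_expand(stats::runif(pr * pc) < 0.6, nr, nc, ps)[roi2d]
  b <- patch_expand(sample(c(-1, 1), pr * pc, replace = TRUE), nr, nc, ps)[roi2d]
  g <- ifelse(solid & ps > 1, g_patch, g_vox)
  spec$noise_sd * (g + 0.8 * spec$heterogeneity * b)
}

disk_mask <- function(rows, cols, cr, cc, radius) {
  rr <- matrix(seq_len(rows), rows, cols)
  cc_ <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  (rr - cr)^2 + (cc_ - cc)^2 <= radius^2
}

#' Generate a three-sequence texture phantom
#'
#' Produces co-registered T1, T2 and contrast-enhanced T1 (T1C) image stacks
#' plus one binary tumor mask. All three sequences share the textured ROI
#' (each with its own base intensity and independent noise realization); the
#' texture knobs of \code{spec} apply to every sequence.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return A list with elements \code{T1}, \code{T2}, \code{T1C} (each an
#'   \code{\link{mr_volume}}) and \code{mask} (an \code{\link{roi_mask}}).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  ns <- spec$grid_shape[1]; nr <- spec$grid_shape[2]; nc <- spec$grid_shape[3]
  set.seed(spec$seed)

  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  roi2d <- disk_mask(nr, nc, cr, cc, spec$roi_radius)
  body2d <- disk_mask(nr, nc, cr, cc, min(nr, nc) / 2 - 0.5)
  ps <- 1L + floor(spec$run_structure)

  mask <- array(FALSE, c(ns, nr, nc))
  for (s in seq_len(ns)) mask[s, , ] <- roi2d

  base <- c(T1 = 300, T2 = 600, T1C = 800)
  n_roi <- sum(roi2d)
  vols <- lapply(names(base), function(seq_label) {
    vox <- array(0, c(ns, nr, nc))
    for (s in seq_len(ns)) {
      sl <- matrix(0, nr, nc)
      # mild tumor-to-body contrast, as on contrast-enhanced sequences
      sl[body2d] <- base[[seq_label]] * 0.85
      sl[roi2d] <- base[[seq_label]] + roi_texture(n_roi, roi2d, spec, ps)
      vox[s, , ] <- sl
    }
    mr_volume(vox, sequence_label = seq_label,
              in_plane_spacing = spec$in_plane_spacing,
              slice_thickness = spec$slice_thickness)
  })
  names(vols) <- names(base)
  vols$mask <- roi_mask(mask, in_plane_spacing = spec$in_plane_spacing,
                        slice_thickness = spec$slice_thickness)
  vols
}

shift_slice <- function(m, dr, dc) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  rs <- seq_len(nrow(m)) - dr
  cs <- seq_len(ncol(m)) - dc
  ok_r <- rs >= 1 & rs <= nrow(m)
  ok_c <- cs >= 1 & cs <= ncol(m)
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

dilate4 <- function(m) {
  m | shift_slice(m, 1, 0) | shift_slice(m, -1, 0) |
    shift_slice(m, 0, 1) | shift_slice(m, 0, -1)
}

erode4 <- function(m) {
  m & shift_slice(m, 1, 0) & shift_slice(m, -1, 0) &
    shift_slice(m, 0, 1) & shift_slice(m, 0, -1)
}

#' Perturb a tumor mask to emulate re-segmentation
#'
#' Applies a random in-plane shift of up to \code{jitter_vox} voxels plus
#' \code{jitter_vox} random single-voxel dilation/erosion passes, emulating
#' boundary disagreement between repeated manual segmentations. The Dice
#' overlap with the original decreases as \code{jitter_vox} grows.
#'
#' @param mask an \code{\link{roi_mask}} (nonempty).
#' @param jitter_vox nonnegative integer jitter magnitude; 0 returns the mask
#'   unchanged.
#' @param seed integer RNG seed.
#' @return A perturbed \code{\link{roi_mask}}.
#' @export
perturb_mask <- function(mask, jitter_vox = 1L, seed = 1L) {
  stopifnot(inherits(mask, "roi_mask"))
  assert_that(sum(mask$voxels) > 0, "'mask' is empty")
  assert_scalar_number(jitter_vox, "jitter_vox", lower = 0)
  jitter_vox <- as.integer(jitter_vox)
  if (jitter_vox == 0L) return(mask)
  set.seed(seed)
  dr <- sample(-jitter_vox:jitter_vox, 1)
  dc <- sample(-jitter_vox:jitter_vox, 1)
  vox <- mask$voxels
  out <- array(FALSE, dim(vox))
  for (s in seq_len(dim(vox)[1])) {
    sl <- shift_slice(get_slice(vox, s), dr, dc)
    for (k in seq_len(jitter_vox)) {
      sl <- if (stats::runif(1) < 0.5) dilate4(sl) else erode4(sl)
    }
    out[s, , ] <- sl
  }
  if (sum(out) == 0)
    stop("perturbation emptied the mask; reduce 'jitter_vox'", call. = FALSE)
  roi_mask(out, in_plane_spacing = mask$in_plane_spacing,
           slice_thickness = mask$slice_thickness)
}

#' Dice overlap between two binary masks
#'
#' @param a,b \code{\link{roi_mask}} objects or logical arrays of equal shape.
#' @return Dice coefficient 2|A∩B| / (|A|+|B|) in [0, 1].
#' @export
dice <- function(a, b) {
  va <- if (inherits(a, "roi_mask")) a$voxels else a
  vb <- if (inherits(b, "roi_mask")) b$voxels else b
  stopifnot(identical(dim(va), dim(vb)))
  2 * sum(va & vb) / (sum(va) + sum(vb))
}
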