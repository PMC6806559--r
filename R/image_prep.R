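#' MR volume container
#'
#' A single-sequence image stack stored as a (slices x rows x cols) numeric
#' array with its voxel spacing. All texture computation downstream is 2D,
#' per axial slice; the slice dimension is never interpolated.
#'
#' @param voxels numeric array, slices x rows x cols, finite.
#' @param sequence_label one of \code{"T1"}, \code{"T2"}, \code{"T1C"}.
#' @param in_plane_spacing in-plane voxel size in mm (square pixels).
#' @param slice_thickness slice spacing in mm.
#' @return An object of class \code{mr_volume}.
#' @export
mr_volume <- function(voxels, sequence_label = c("T1", "T2", "T1C"),
                      in_plane_spacing = 1, slice_thickness = 4) {
  sequence_label <- match.arg(sequence_label)
  if (length(dim(voxels)) == 2L) voxels <- array(voxels, c(1L, dim(voxels)))
  assert_that(length(dim(voxels)) == 3L, "'voxels' must be a 3D array (slices x rows x cols)")
  assert_that(all(is.finite(voxels)), "'voxels' must be finite")
  assert_scalar_number(in_plane_spacing, "in_plane_spacing", lower = 0, strict_lower = TRUE)
  assert_scalar_number(slice_thickness, "slice_thickness", lower = 0, strict_lower = TRUE)
  structure(list(voxels = voxels, sequence_label = sequence_label,
                 in_plane_spacing = in_plane_spacing,
                 slice_thickness = slice_thickness),
            class = "mr_volume")
}

#' Binary tumor-mask container
#'
#' @param voxels logical (or 0/1) array aligned to an \code{\link{mr_volume}}.
#' @inheritParams mr_volume
#' @return An object of class \code{roi_mask}.
#' @export
roi_mask <- function(voxels, in_plane_spacing = 1, slice_thickness = 4) {
  if (length(dim(voxels)) == 2L) voxels <- array(voxels, c(1L, dim(voxels)))
  assert_that(length(dim(voxels)) == 3L, "'voxels' must be a 3D array")
  storage.mode(voxels) <- "logical"
  assert_that(!anyNA(voxels), "'voxels' must be binary with no missing values")
  structure(list(voxels = voxels, in_plane_spacing = in_plane_spacing,
                 slice_thickness = slice_thickness),
            class = "roi_mask")
}

#' @export
print.mr_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<mr_volume %s: %d slice(s) x %d x %d, %.3g mm in-plane / %.3g mm slices>\n",
              x$sequence_label, d[1], d[2], d[3], x$in_plane_spacing, x$slice_thickness))
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<roi_mask: %d slice(s) x %d x %d, %d voxels in ROI>\n",
              d[1], d[2], d[3], sum(x$voxels)))
  invisible(x)
}

# Bilinear interpolation of a matrix at (continuous) row/col coordinates.
bilinear_at <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- pmin(pmax(floor(r), 1L), nr); r1 <- pmin(r0 + 1L, nr)
  c0 <- pmin(pmax(floor(c), 1L), nc); c1 <- pmin(c0 + 1L, nc)
  fr <- pmin(pmax(r - r0, 0), 1); fc <- pmin(pmax(c - c0, 0), 1)
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) + m[cbind(r1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c1)] * (1 - fr) * fc + m[cbind(r1, c1)] * fr * fc
}

#' Resample image and mask in-plane to a target spacing
#'
#' Bilinear interpolation for the image, nearest-neighbor for the mask; the
#' slice dimension is untouched (2D radiomics convention). New grid centers
#' are placed so the physical field of view is preserved.
#'
#' @param vol an \code{\link{mr_volume}}.
#' @param mask the aligned \code{\link{roi_mask}}.
#' @param target_spacing_mm positive target in-plane spacing (default 1 mm).
#' @return A list with resampled \code{vol} and \code{mask}.
#' @export
resample_inplane <- function(vol, mask, target_spacing_mm = 1) {
  stopifnot(inherits(vol, "mr_volume"), inherits(mask, "roi_mask"))
  assert_scalar_number(target_spacing_mm, "target_spacing_mm",
                       lower = 0, strict_lower = TRUE)
  stopifnot(identical(dim(vol$voxels), dim(mask$voxels)))
  sp <- vol$in_plane_spacing
  if (isTRUE(all.equal(sp, target_spacing_mm))) return(list(vol = vol, mask = mask))

  d <- dim(vol$voxels)
  nr2 <- max(2L, round(d[2] * sp / target_spacing_mm))
  nc2 <- max(2L, round(d[3] * sp / target_spacing_mm))
  # pixel-center coordinates of the new grid expressed on the old grid
  r_new <- ((seq_len(nr2) - 0.5) * target_spacing_mm) / sp + 0.5
  c_new <- ((seq_len(nc2) - 0.5) * target_spacing_mm) / sp + 0.5
  rc <- cbind(rep(r_new, times = nc2), rep(c_new, each = nr2))

  v2 <- array(0, c(d[1], nr2, nc2))
  m2 <- array(FALSE, c(d[1], nr2, nc2))
  rn <- pmin(pmax(round(rc[, 1]), 1L), d[2])
  cn <- pmin(pmax(round(rc[, 2]), 1L), d[3])
  for (s in seq_len(d[1])) {
    sl <- get_slice(vol$voxels, s)
    v2[s, , ] <- matrix(bilinear_at(sl, rc[, 1], rc[, 2]), nr2, nc2)
    msl <- get_slice(mask$voxels, s)
    m2[s, , ] <- matrix(msl[cbind(rn, cn)], nr2, nc2)
  }
  list(vol = mr_volume(v2, vol$sequence_label, target_spacing_mm, vol$slice_thickness),
       mask = roi_mask(m2, target_spacing_mm, mask$slice_thickness))
}

#' Z-score intensity normalization over in-body voxels
#'
#' Standardizes intensities to mean 0 / SD 1 over the nonzero ("in-body")
#' voxels (population-SD convention, matching the feature z-score), leaving
#' exact-zero background at zero. Whole-volume (not ROI-only) normalization
#' preserves first-order contrasts inside the tumor.
#'
#' @param vol an \code{\link{mr_volume}} with more than one distinct
#'   in-body intensity.
#' @return A normalized \code{\link{mr_volume}}.
#' @export
normalize_intensity <- function(vol) {
  stopifnot(inherits(vol, "mr_volume"))
  v <- vol$voxels
  body <- v != 0
  assert_that(sum(body) >= 2, "volume has fewer than 2 in-body (nonzero) voxels")
  x <- v[body]
  s <- pop_sd(x)
  if (s == 0)
    stop("zero variance: volume intensities are constant over in-body voxels",
         call. = FALSE)
  v[body] <- (x - mean(x)) / s
  mr_volume(v, vol$sequence_label, vol$in_plane_spacing, vol$slice_thickness)
}

#' Discretize ROI intensities to a fixed number of gray levels
#'
#' Fixed-bin-count discretization over the [min, max] range of the ROI
#' intensities: the minimum maps to level 1, the maximum to level
#' \code{n_bins}. Voxels outside the ROI are unlabeled (NA).
#'
#' @param vol an \code{\link{mr_volume}}.
#' @param mask the aligned, nonempty \code{\link{roi_mask}}.
#' @param n_bins number of gray levels (>= 2; default 32, a standard choice
#'   for arbitrary-unit MR intensities).
#' @return An object of class \code{gray_level_map}: list with \code{labels}
#'   (integer array, NA outside ROI), \code{n_bins}, \code{breaks}, spacing
#'   fields, and a \code{degenerate} flag set when the ROI is constant (all
#'   voxels then map to level 1).
#' @export
discretize <- function(vol, mask, n_bins = 32L) {
  stopifnot(inherits(vol, "mr_volume"), inherits(mask, "roi_mask"))
  stopifnot(identical(dim(vol$voxels), dim(mask$voxels)))
  assert_scalar_number(n_bins, "n_bins", lower = 2)
  n_bins <- as.integer(n_bins)
  inroi <- mask$voxels
  assert_that(sum(inroi) > 0, "'mask' is empty")
  x <- vol$voxels[inroi]
  lo <- min(x); hi <- max(x)
  labels <- array(NA_integer_, dim(vol$voxels))
  degenerate <- hi <= lo
  if (degenerate) {
    labels[inroi] <- 1L
    breaks <- c(lo, lo)
  } else {
    width <- (hi - lo) / n_bins
    lab <- pmin(floor((x - lo) / width) + 1L, n_bins)
    labels[inroi] <- as.integer(lab)
    breaks <- seq(lo, hi, length.out = n_bins + 1L)
  }
  structure(list(labels = labels, n_bins = n_bins, breaks = breaks,
                 degenerate = degenerate,
                 in_plane_spacing = mask$in_plane_spacing,
                 slice_thickness = mask$slice_thickness),
            class = "gray_level_map")
}

#' Read / write NIfTI volumes
#'
#' Thin wrappers over \pkg{RNifti} keeping the (slices x rows x cols) array
#' convention used in this package: on disk the array is stored (cols x rows
#' x slices) as is conventional for NIfTI.
#'
#' @param vol an \code{\link{mr_volume}} or \code{\link{roi_mask}}.
#' @param path output path (".nii" or ".nii.gz").
#' @return \code{write_nifti} returns \code{path} invisibly;
#'   \code{read_nifti_volume} returns an \code{\link{mr_volume}} and
#'   \code{read_nifti_mask} an \code{\link{roi_mask}}.
#' @export
write_nifti <- function(vol, path) {
  vox <- vol$voxels
  storage.mode(vox) <- "double"
  arr <- aperm(vox, c(3, 2, 1))
  img <- RNifti::asNifti(arr, pixdim = c(vol$in_plane_spacing,
                                         vol$in_plane_spacing,
                                         vol$slice_thickness))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti
#' @param sequence_label sequence label to attach on read.
#' @export
read_nifti_volume <- function(path, sequence_label = "T1") {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  arr <- aperm(as.array(img), c(3, 2, 1))
  mr_volume(arr, sequence_label, in_plane_spacing = pd[1], slice_thickness = pd[3])
}

#' @rdname write_nifti
#' @export
read_nifti_mask <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  arr <- aperm(as.array(img), c(3, 2, 1)) > 0.5
  roi_mask(arr, in_plane_spacing = pd[1], slice_thickness = pd[3])
}
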