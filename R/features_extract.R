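# Feature catalogue and per-ROI / per-patient extraction.
#
# Catalogue contract: 19 first-order + 10 shape
#   + 24 GLCM x 4 directions x 2 distances (192)
#   + 13 GLRLM x 4 directions (52)       = 273 features per ROI,
# concatenated over the three sequences  = 819 per patient.

texture_directions <- c(0, 45, 90, 135)
glcm_distances <- c(1L, 2L)

#' The 2D radiomic feature catalogue
#'
#' Enumerates the 273 per-ROI feature names with their family, direction and
#' distance. Texture features are reported per offset (not direction-averaged)
#' so that 24 co-occurrence and 13 run-length formulas yield 192 + 52 values.
#' Totals (273 per ROI, 819 = 3 x 273 per patient) are asserted at build time.
#'
#' @return A data.frame with columns \code{name}, \code{family}
#'   (\code{intensity}, \code{shape}, \code{glcm}, \code{glrlm}),
#'   \code{direction} and \code{distance} (NA where not applicable).
#' @export
feature_catalogue <- function() {
  rows <- list(
    data.frame(name = paste0("firstorder_", intensity_feature_names),
               family = "intensity", direction = NA_real_, distance = NA_integer_),
    data.frame(name = paste0("shape_", shape_feature_names),
               family = "shape", direction = NA_real_, distance = NA_integer_))
  for (d in glcm_distances) for (a in texture_directions) {
    rows[[length(rows) + 1L]] <-
      data.frame(name = sprintf("glcm_d%d_a%d_%s", d, a, glcm_feature_names),
                 family = "glcm", direction = a, distance = d)
  }
  for (a in texture_directions) {
    rows[[length(rows) + 1L]] <-
      data.frame(name = sprintf("glrlm_a%d_%s", a, glrlm_feature_names),
                 family = "glrlm", direction = a, distance = NA_integer_)
  }
  cat <- do.call(rbind, rows)
  stopifnot(nrow(cat) == 273L, !anyDuplicated(cat$name))
  cat
}

#' Extract the 273-feature vector of one ROI
#'
#' Runs the full per-ROI pipeline: optional in-plane resampling to
#' \code{target_spacing_mm}, optional z-score intensity normalization,
#' fixed-bin-count discretization, then first-order, shape, co-occurrence and
#' run-length features in catalogue order.
#'
#' @param vol an \code{\link{mr_volume}}.
#' @param mask the aligned, nonempty \code{\link{roi_mask}}.
#' @param n_bins gray levels for texture discretization (default 32).
#' @param target_spacing_mm in-plane resampling target; \code{NULL} to skip.
#' @param normalization \code{"zscore"} (default) or \code{"none"}.
#' @return Named numeric vector of length 273.
#' @export
extract_roi_features <- function(vol, mask, n_bins = 32L,
                                 target_spacing_mm = 1,
                                 normalization = c("zscore", "none")) {
  normalization <- match.arg(normalization)
  assert_that(sum(mask$voxels) > 0, "'mask' is empty")
  if (!is.null(target_spacing_mm)) {
    rs <- resample_inplane(vol, mask, target_spacing_mm)
    vol <- rs$vol; mask <- rs$mask
    assert_that(sum(mask$voxels) > 0, "ROI vanished during resampling")
  }
  if (normalization == "zscore") vol <- normalize_intensity(vol)
  gl <- discretize(vol, mask, n_bins = n_bins)

  fo <- intensity_features(vol, mask)
  sh <- shape_features(mask)
  glcm_vals <- numeric(0)
  for (d in glcm_distances) for (a in texture_directions) {
    P <- glcm_matrix(gl, distance = d, direction = a)
    v <- glcm_features(P)
    names(v) <- sprintf("glcm_d%d_a%d_%s", d, a, names(v))
    glcm_vals <- c(glcm_vals, v)
  }
  glrlm_vals <- numeric(0)
  for (a in texture_directions) {
    R <- glrlm_matrix(gl, direction = a)
    v <- glrlm_features(R)
    names(v) <- sprintf("glrlm_a%d_%s", a, names(v))
    glrlm_vals <- c(glrlm_vals, v)
  }
  out <- c(stats::setNames(as.numeric(fo), paste0("firstorder_", names(fo))),
           stats::setNames(as.numeric(sh), paste0("shape_", names(sh))),
           glcm_vals, glrlm_vals)
  stopifnot(length(out) == 273L,
            identical(names(out), feature_catalogue()$name))
  out
}

#' Extract the 819-feature vector of one patient
#'
#' Applies \code{\link{extract_roi_features}} to each of the three
#' co-registered sequences and concatenates the results with the sequence
#' label as prefix: 3 x 273 = 819 values.
#'
#' @param volumes named list with elements \code{T1}, \code{T2}, \code{T1C},
#'   each an \code{\link{mr_volume}}; no sequence may be missing.
#' @param masks a single \code{\link{roi_mask}} shared by all sequences, or a
#'   named list of per-sequence masks.
#' @param ... passed to \code{\link{extract_roi_features}}.
#' @return Named numeric vector of length 819.
#' @export
extract_patient_features <- function(volumes, masks, ...) {
  need <- c("T1", "T2", "T1C")
  missing <- setdiff(need, names(volumes))
  assert_that(length(missing) == 0L,
              paste("missing sequence(s):", paste(missing, collapse = ", ")))
  if (inherits(masks, "roi_mask")) {
    masks <- stats::setNames(rep(list(masks), 3), need)
  }
  out <- unlist(lapply(need, function(sq) {
    v <- extract_roi_features(volumes[[sq]], masks[[sq]], ...)
    stats::setNames(as.numeric(v), paste0(sq, "_", names(v)))
  }))
  stopifnot(length(out) == 819L)
  out
}

#' Fit and apply training-cohort z-score standardization
#'
#' \code{fit_standardizer} estimates the per-feature mean and population-SD
#' (n denominator) on the training feature table; \code{apply_standardizer}
#' transforms any table with those training parameters only (the validation
#' cohort is never refit). Zero-SD features are excluded with a warning and
#' recorded in the params.
#'
#' @param x numeric matrix or data.frame of features (rows = patients),
#'   >= 2 rows.
#' @return \code{fit_standardizer}: an object of class
#'   \code{feature_standardizer} with \code{mean}, \code{sd} and
#'   \code{dropped}; \code{apply_standardizer}: the standardized table with
#'   dropped features removed.
#' @export
fit_standardizer <- function(x) {
  x <- as.matrix(x)
  assert_that(nrow(x) >= 2, "training table must have at least 2 rows")
  assert_that(!is.null(colnames(x)), "feature columns must be named")
  mu <- colMeans(x)
  sdv <- apply(x, 2, pop_sd)
  dropped <- colnames(x)[sdv == 0]
  if (length(dropped) > 0)
    warning(length(dropped), " zero-SD feature(s) excluded from standardization: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  keep <- sdv > 0
  structure(list(mean = mu[keep], sd = sdv[keep], dropped = dropped,
                 denominator = "population"),
            class = "feature_standardizer")
}

#' @rdname fit_standardizer
#' @param params a \code{feature_standardizer} from \code{fit_standardizer}.
#' @export
apply_standardizer <- function(params, x) {
  stopifnot(inherits(params, "feature_standardizer"))
  x <- as.matrix(x)
  missing <- setdiff(names(params$mean), colnames(x))
  assert_that(length(missing) == 0L,
              paste("table is missing standardized feature(s):",
                    paste(utils::head(missing, 5), collapse = ", ")))
  x <- x[, names(params$mean), drop = FALSE]
  sweep(sweep(x, 2, params$mean, "-"), 2, params$sd, "/")
}
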