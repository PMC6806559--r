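# Gray-level run-length matrices and their 13 scalar features.
#
# A run is a maximal sequence of in-ROI voxels sharing one gray level along
# a direction within one slice; voxels outside the ROI break runs. Runs are
# accumulated over all slices into one R(level, length) matrix per ROI.

# All maximal lines of a matrix along an in-plane direction, as a list of
# vectors (NA where outside ROI).
matrix_lines <- function(m, direction) {
  nr <- nrow(m); nc <- ncol(m)
  switch(as.character(direction),
         "0"   = lapply(seq_len(nr), function(r) m[r, ]),
         "90"  = lapply(seq_len(nc), function(c) m[, c]),
         "45"  = {                       # anti-diagonals, i.e. offset (-1, 1)
           split(m[order(row(m) + col(m), -row(m))],
                 sort(row(m) + col(m)))
         },
         "135" = {                       # main diagonals, offset (1, 1)
           split(m[order(col(m) - row(m), row(m))],
                 sort(col(m) - row(m)))
         },
         stop("'direction' must be one of 0, 45, 90, 135 (degrees)", call. = FALSE))
}

#' Gray-level run-length matrix
#'
#' @param gray a \code{gray_level_map} from \code{\link{discretize}}.
#' @param direction in-plane angle in degrees: 0, 45, 90 or 135.
#' @return Matrix \code{R} with \code{n_bins} rows (gray level) and
#'   \code{max run length} columns; \code{R[i, l]} counts maximal runs of
#'   level \code{i} and length \code{l}. Attribute \code{"n_voxels"} holds
#'   the ROI voxel count (for run percentage).
#' @export
glrlm_matrix <- function(gray, direction = 0) {
  stopifnot(inherits(gray, "gray_level_map"))
  n_vox <- sum(!is.na(gray$labels))
  assert_that(n_vox > 0, "ROI is empty")
  ng <- gray$n_bins
  d <- dim(gray$labels)
  max_len <- max(d[2], d[3])
  R <- matrix(0, ng, max_len)
  for (s in seq_len(d[1])) {
    sl <- get_slice(gray$labels, s)
    for (line in matrix_lines(sl, direction)) {
      r <- rle(line)
      keep <- !is.na(r$values)
      if (!any(keep)) next
      lev <- r$values[keep]
      len <- r$lengths[keep]
      for (k in seq_along(lev)) R[lev[k], len[k]] <- R[lev[k], len[k]] + 1
    }
  }
  attr(R, "n_voxels") <- n_vox
  R
}

glrlm_feature_names <- c("SRE", "LRE", "GLN", "RLN", "RP", "LGLRE", "HGLRE",
                         "SRLGLE", "SRHGLE", "LRLGLE", "LRHGLE", "GLV", "RLV")

#' Scalar features of a run-length matrix
#'
#' Computes the 13 standard run-length features. \code{LRHGLE} (long-run
#' high-gray-level emphasis) is
#' \eqn{\sum_{i,l} R(i,l)\, i^2 l^2 / \sum_{i,l} R(i,l)} — the quantity the
#' benefit model calls GLRLM_LRHGLE.
#'
#' @param R run-length matrix from \code{\link{glrlm_matrix}} (>= 1 run).
#' @return Named numeric vector of length 13.
#' @export
glrlm_features <- function(R) {
  n_runs <- sum(R)
  assert_that(n_runs > 0, "run-length matrix has zero runs")
  n_vox <- attr(R, "n_voxels") %||% sum(R %*% seq_len(ncol(R)))
  i <- matrix(seq_len(nrow(R)), nrow(R), ncol(R))
  l <- matrix(seq_len(ncol(R)), nrow(R), ncol(R), byrow = TRUE)
  out <- stats::setNames(numeric(13), glrlm_feature_names)
  out["SRE"] <- sum(R / l^2) / n_runs
  out["LRE"] <- sum(R * l^2) / n_runs
  out["GLN"] <- sum(rowSums(R)^2) / n_runs
  out["RLN"] <- sum(colSums(R)^2) / n_runs
  out["RP"] <- n_runs / n_vox
  out["LGLRE"] <- sum(R / i^2) / n_runs
  out["HGLRE"] <- sum(R * i^2) / n_runs
  out["SRLGLE"] <- sum(R / (i^2 * l^2)) / n_runs
  out["SRHGLE"] <- sum(R * i^2 / l^2) / n_runs
  out["LRLGLE"] <- sum(R * l^2 / i^2) / n_runs
  out["LRHGLE"] <- sum(R * i^2 * l^2) / n_runs
  p <- R / n_runs
  mu_i <- sum(p * i)
  mu_l <- sum(p * l)
  out["GLV"] <- sum(p * (i - mu_i)^2)
  out["RLV"] <- sum(p * (l - mu_l)^2)
  out
}
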