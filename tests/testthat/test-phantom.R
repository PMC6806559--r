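test_that("phantom generation is deterministic and rejects impossible ROIs", {
  a <- generate_phantom(phantom_spec(seed = 42))
  b <- generate_phantom(phantom_spec(seed = 42))
  expect_identical(a$T1$voxels, b$T1$voxels)
  expect_identical(a$T1C$voxels, b$T1C$voxels)
  expect_identical(a$mask$voxels, b$mask$voxels)
  c_ <- generate_phantom(phantom_spec(seed = 43))
  expect_false(identical(a$T1$voxels, c_$T1$voxels))
  expect_error(phantom_spec(grid_shape = c(3, 20, 20), roi_radius = 12),
               "does not fit")
})

test_that("ROI is one connected in-plane component and sequences are co-registered", {
  ph <- generate_phantom(phantom_spec(seed = 5))
  sl <- ph$mask$voxels[1, , , drop = TRUE]
  # flood fill from one ROI voxel must reach every ROI voxel
  start <- which(sl, arr.ind = TRUE)[1, ]
  reached <- matrix(FALSE, nrow(sl), ncol(sl))
  frontier <- matrix(start, ncol = 2)
  reached[frontier] <- TRUE
  while (nrow(frontier) > 0) {
    nb <- rbind(frontier + rep(c(1, 0), each = nrow(frontier)),
                frontier + rep(c(-1, 0), each = nrow(frontier)),
                frontier + rep(c(0, 1), each = nrow(frontier)),
                frontier + rep(c(0, -1), each = nrow(frontier)))
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= nrow(sl) &
               nb[, 2] >= 1 & nb[, 2] <= ncol(sl), , drop = FALSE]
    keep <- sl[nb] & !reached[nb]
    frontier <- nb[keep, , drop = FALSE]
    reached[frontier] <- TRUE
  }
  expect_identical(reached, sl)
  expect_identical(dim(ph$T1$voxels), dim(ph$T2$voxels))
  expect_identical(dim(ph$T1$voxels), dim(ph$mask$voxels))
})

test_that("zero noise and zero heterogeneity give a constant ROI", {
  ph <- generate_phantom(phantom_spec(noise_sd = 0, heterogeneity = 0, seed = 1))
  roi_vals <- ph$T1C$voxels[ph$mask$voxels]
  expect_equal(length(unique(roi_vals)), 1L)
  expect_equal(moment_skewness(roi_vals), 0)
})

test_that("target_skew orders the extracted ROI skewness across phantoms", {
  sk <- function(s, seed) {
    ph <- generate_phantom(phantom_spec(target_skew = s, seed = seed))
    moment_skewness(normalize_intensity(ph$T1C)$voxels[ph$mask$voxels])
  }
  neg <- vapply(1:100, function(i) sk(-2, i), numeric(1))
  pos <- vapply(1:100, function(i) sk(2, 100 + i), numeric(1))
  expect_lt(mean(neg), 0)
  expect_gt(mean(pos), 0)
  expect_lt(mean(neg), mean(pos))
})

test_that("run_structure raises long-run high-gray emphasis in expectation", {
  lrh <- function(rs, seed) {
    ph <- generate_phantom(phantom_spec(run_structure = rs, seed = seed))
    gl <- discretize(normalize_intensity(ph$T1C), ph$mask)
    glrlm_features(glrlm_matrix(gl, 0))[["LRHGLE"]]
  }
  short <- mean(vapply(1:30, function(i) lrh(0, i), numeric(1)))
  long <- mean(vapply(1:30, function(i) lrh(3, 200 + i), numeric(1)))
  expect_gt(long, short)
})

test_that("mask perturbation behaves like re-segmentation jitter", {
  ph <- generate_phantom(phantom_spec(roi_radius = 10, seed = 3))
  expect_identical(perturb_mask(ph$mask, 0, seed = 1), ph$mask)
  m1 <- perturb_mask(ph$mask, 1, seed = 7)
  expect_identical(m1$voxels, perturb_mask(ph$mask, 1, seed = 7)$voxels)
  expect_gt(dice(ph$mask, m1), 0.8)
  d3 <- mean(vapply(1:10, function(i) dice(ph$mask, perturb_mask(ph$mask, 3, seed = i)),
                    numeric(1)))
  d1 <- mean(vapply(1:10, function(i) dice(ph$mask, perturb_mask(ph$mask, 1, seed = i)),
                    numeric(1)))
  expect_lt(d3, d1)
  tiny <- roi_mask(array(c(TRUE, rep(FALSE, 24)), c(1, 5, 5)))
  expect_error(perturb_mask(tiny, 4, seed = 1), "emptied|empty")
})

test_that("nifti round trip preserves voxels and spacing", {
  ph <- generate_phantom(phantom_spec(grid_shape = c(2, 16, 16), roi_radius = 5, seed = 2))
  f <- tempfile(fileext = ".nii.gz")
  write_nifti(ph$T1C, f)
  back <- read_nifti_volume(f, "T1C")
  expect_equal(back$voxels, ph$T1C$voxels, tolerance = 1e-6)
  expect_equal(back$in_plane_spacing, 1)
  fm <- tempfile(fileext = ".nii.gz")
  write_nifti(ph$mask, fm)
  expect_identical(read_nifti_mask(fm)$voxels, ph$mask$voxels)
  unlink(c(f, fm))
})
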