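test_that("the catalogue enumerates 273 features per ROI in fixed order", {
  cat_ <- feature_catalogue()
  expect_equal(nrow(cat_), 273L)
  expect_equal(sum(cat_$family == "intensity"), 19L)
  expect_equal(sum(cat_$family == "shape"), 10L)
  expect_equal(sum(cat_$family == "glcm"), 192L)
  expect_equal(sum(cat_$family == "glrlm"), 52L)
  expect_false(anyDuplicated(cat_$name) > 0)
})

test_that("co-occurrence matrix matches hand-worked cases", {
  # single row [1, 2]: one horizontal pair, symmetrized
  g <- gray_map_from_labels(matrix(c(1L, 2L), 1, 2), 2)
  P <- glcm_matrix(g, 1, 0)
  expect_equal(P, matrix(c(0, 0.5, 0.5, 0), 2, 2), ignore_attr = TRUE)
  f <- glcm_features(P)
  expect_equal(f[["joint_average"]], 1.5)
  expect_equal(f[["variance"]], 0.25)
  # 3x3 worked example against exhaustive enumeration
  lab <- matrix(c(1L, 1L, 2L, 1L, 2L, 2L, 2L, 2L, 3L), 3, 3, byrow = TRUE)
  P2 <- glcm_matrix(gray_map_from_labels(lab, 3), 1, 0)
  expect_equal(unclass(P2), oracle_glcm(lab, 3, 0, 1), ignore_attr = TRUE)
  expect_equal(sum(P2), 1)
})

test_that("co-occurrence features are bounded and degenerate-safe", {
  set.seed(4)
  lab <- random_label_map(8, 8, 4, 0.1)
  P <- glcm_matrix(gray_map_from_labels(lab, 4), 1, 45)
  f <- glcm_features(P)
  expect_gte(f[["variance"]], 0)
  expect_true(f[["energy"]] > 0 && f[["energy"]] <= 1)
  # one-level ROI: zero dispersion
  g1 <- gray_map_from_labels(matrix(1L, 3, 3), 2)
  expect_equal(glcm_features(glcm_matrix(g1, 1, 0))[["variance"]], 0)
  # no valid pair: flagged degenerate, features zero by convention
  lone <- gray_map_from_labels(matrix(c(1L, NA), 1, 2), 2)
  Pd <- glcm_matrix(lone, 1, 0)
  expect_true(attr(Pd, "degenerate"))
  expect_true(all(glcm_features(Pd) == 0))
})

test_that("run-length matrix matches hand-worked cases and conserves voxels", {
  g <- gray_map_from_labels(matrix(c(3L, 3L, 3L), 1, 3), 3)
  R <- glrlm_matrix(g, 0)
  expect_equal(R[3, 3], 1)
  expect_equal(sum(R), 1)
  expect_equal(glrlm_features(R)[["LRHGLE"]], 81)
  g2 <- gray_map_from_labels(matrix(c(1L, 2L, 1L), 1, 3), 2)
  R2 <- glrlm_matrix(g2, 0)
  expect_equal(R2[1, 1], 2); expect_equal(R2[2, 1], 1)
  # all runs length 1 at level 1
  g3 <- gray_map_from_labels(matrix(c(1L, 2L, 1L, 2L), 1, 4), 2)
  expect_equal(glrlm_features(glrlm_matrix(g3, 0))[["LRHGLE"]],
               (2 * 1 + 2 * 4) / 4)
  # conservation: sum l * R(i, l) = ROI voxel count, every direction
  set.seed(5)
  lab <- random_label_map(8, 8, 3, 0.25)
  for (a in c(0, 45, 90, 135)) {
    R <- glrlm_matrix(gray_map_from_labels(lab, 3), a)
    expect_equal(sum(sweep(R, 2, seq_len(ncol(R)), "*")), sum(!is.na(lab)))
  }
})

test_that("texture matrices and all 37 features match brute-force oracles", {
  set.seed(6)
  for (rep in 1:60) {
    ng <- sample(3:5, 1)
    lab <- random_label_map(8, 8, ng, runif(1, 0, 0.3))
    if (sum(!is.na(lab)) < 4) next
    g <- gray_map_from_labels(lab, ng)
    a <- sample(c(0, 45, 90, 135), 1)
    d <- sample(1:2, 1)
    P <- glcm_matrix(g, d, a)
    expect_equal(unclass(P), oracle_glcm(lab, ng, a, d), ignore_attr = TRUE)
    if (!attr(P, "degenerate"))
      expect_equal(glcm_features(P), oracle_glcm_features(P), tolerance = 1e-12)
    R <- glrlm_matrix(g, a)
    expect_equal(unclass(R), oracle_glrlm(lab, ng, a, ncol(R)),
                 ignore_attr = TRUE)
    expect_equal(glrlm_features(R),
                 oracle_glrlm_features(R, sum(!is.na(lab))), tolerance = 1e-12)
  }
})

test_that("rotating a slice by 90 degrees swaps the 0/90-degree features", {
  set.seed(7)
  lab <- random_label_map(8, 8, 4, 0.15)
  rot <- t(lab[nrow(lab):1, ])  # 90-degree rotation
  g <- gray_map_from_labels(lab, 4); gr <- gray_map_from_labels(rot, 4)
  expect_equal(glcm_features(glcm_matrix(g, 1, 0)),
               glcm_features(glcm_matrix(gr, 1, 90)))
  expect_equal(glrlm_features(glrlm_matrix(g, 0)),
               glrlm_features(glrlm_matrix(gr, 90)))
})

test_that("first-order features match hand arithmetic", {
  v <- mr_volume(array(c(1, 2, 3), c(1, 1, 3)))
  m <- roi_mask(array(TRUE, c(1, 1, 3)))
  f <- intensity_features(v, m)
  expect_length(f, 19L)
  expect_equal(f[["skewness"]], 0)
  expect_equal(f[["mean"]], 2)
  expect_equal(f[["variance"]], 2 / 3)
  # {0,0,0,1}: hand moment computation gives 2/sqrt(3)
  v2 <- mr_volume(array(c(0, 0, 0, 1), c(1, 1, 4)))
  m2 <- roi_mask(array(TRUE, c(1, 1, 4)))
  expect_equal(intensity_features(v2, m2)[["skewness"]], 2 / sqrt(3))
  expect_equal(moment_skewness(c(0, 0, 0, 1)), 2 / sqrt(3))
  # printed 5-value sample, direct summation
  x <- c(2, 4, 4, 4, 6)
  v3 <- mr_volume(array(x, c(1, 1, 5)))
  f3 <- intensity_features(v3, roi_mask(array(TRUE, c(1, 1, 5))))
  expect_equal(f3[["mean"]], 4)
  expect_equal(f3[["variance"]], mean((x - 4)^2))
  expect_equal(f3[["energy"]], sum(x^2))
  # zero-variance ROI: flagged, skewness 0 by convention
  fc <- intensity_features(mr_volume(array(5, c(1, 2, 2))),
                           roi_mask(array(TRUE, c(1, 2, 2))))
  expect_true(attr(fc, "degenerate"))
  expect_equal(fc[["skewness"]], 0)
})

test_that("shape features scale with spacing and separate circle from ellipse", {
  sq <- array(FALSE, c(1, 14, 14)); sq[1, 3:12, 3:12] <- TRUE
  f <- shape_features(roi_mask(sq, 1))
  expect_equal(f[["area_mm2"]], 100)
  f2 <- shape_features(roi_mask(sq, 2))
  expect_equal(f2[["area_mm2"]], 400)
  # circle vs elongated ellipse of (approximately) equal area
  grid <- expand.grid(r = 1:40, c = 1:40)
  circ <- matrix((grid$r - 20)^2 + (grid$c - 20)^2 <= 100, 40, 40)
  ell <- matrix((grid$r - 20)^2 / 25 + (grid$c - 20)^2 / 400 <= 1, 40, 40)
  fc <- shape_features(roi_mask(array(circ, c(1, 40, 40))))
  fe <- shape_features(roi_mask(array(ell, c(1, 40, 40))))
  expect_gt(fc[["circularity"]], fe[["circularity"]])
  expect_gt(fe[["aspect_ratio"]], fc[["aspect_ratio"]])
  expect_error(shape_features(roi_mask(array(FALSE, c(1, 4, 4)))), "empty")
})

test_that("patient extraction yields 819 named values and rejects missing sequences", {
  ph <- generate_phantom(phantom_spec(grid_shape = c(2, 32, 32), roi_radius = 8,
                                      seed = 9))
  fv <- extract_patient_features(ph[c("T1", "T2", "T1C")], ph$mask)
  expect_length(fv, 819L)
  expect_true(all(is.finite(fv)))
  expect_equal(sum(startsWith(names(fv), "T1C_")), 273L)
  expect_error(extract_patient_features(ph[c("T1", "T2")], ph$mask),
               "missing sequence")
  # duplicate sequence inputs give identical blocks
  dup <- list(T1 = ph$T1C, T2 = ph$T1C, T1C = ph$T1C)
  fd <- extract_patient_features(dup, ph$mask)
  expect_equal(unname(fd[1:273]), unname(fd[274:546]))
})

test_that("extracted features are invariant to affine intensity rescaling", {
  ph <- generate_phantom(phantom_spec(grid_shape = c(2, 32, 32), roi_radius = 8,
                                      seed = 10))
  v2 <- mr_volume(2.5 * ph$T1C$voxels, "T1C")  # positive affine, zero offset
  f1 <- extract_roi_features(ph$T1C, ph$mask)
  f2 <- extract_roi_features(v2, ph$mask)
  texture <- !grepl("^firstorder_(energy|rms)", names(f1))
  expect_equal(f1[texture], f2[texture], tolerance = 1e-8)
})

test_that("standardizer uses training parameters with a population denominator", {
  x <- matrix(c(1, 3, 2, 6), 2, 2, dimnames = list(NULL, c("a", "b")))
  p <- fit_standardizer(x)
  expect_equal(unname(p$mean), c(2, 4))
  expect_equal(unname(p$sd), c(1, 2))
  xs <- apply_standardizer(p, x)
  expect_equal(unname(xs[, "a"]), c(-1, 1))
  expect_equal(colMeans(xs), c(a = 0, b = 0))
  # single-row validation table transformed with training params only
  v <- apply_standardizer(p, matrix(c(5, 0), 1, 2, dimnames = list(NULL, c("a", "b"))))
  expect_equal(unname(v[1, ]), c(3, -2))
  # zero-SD features excluded with warning
  xz <- cbind(x, cnst = c(4, 4))
  expect_warning(pz <- fit_standardizer(xz), "zero-SD")
  expect_equal(pz$dropped, "cnst")
})
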