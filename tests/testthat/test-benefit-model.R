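sim_features <- function(co, n_noise = 3, seed = 1) {
  set.seed(seed + 100000)
  X <- as.matrix(co[, c("z_skewness", "z_glcm_variance", "z_lrhgle")])
  cbind(X, matrix(rnorm(nrow(co) * n_noise), nrow(co), n_noise,
                  dimnames = list(NULL, paste0("noise", seq_len(n_noise)))))
}

test_that("interaction screening ranks a strong planted interaction first", {
  co <- generate_cohort(cohort_spec(n_patients = 800, seed = 40))
  X <- sim_features(co, n_noise = 10, seed = 40)
  scr <- screen_interactions(X, co)
  expect_true(all(scr$p_interaction >= 0 & scr$p_interaction <= 1))
  expect_true(!is.unsorted(scr$p_interaction))
  expect_true(scr$feature[1] %in% c("z_skewness", "z_glcm_variance"))
  # equal weights leave the ranking unchanged (point estimates are weight-
  # scale invariant; standard errors are not, so only the order is compared)
  scr_w <- screen_interactions(X, co, weights = rep(2.5, nrow(co)))
  expect_identical(scr$feature, scr_w$feature)
  expect_equal(scr$beta_interaction, scr_w$beta_interaction, tolerance = 1e-6)
})

test_that("the redundancy filter applies the greedy rank-order rule", {
  cm <- matrix(c(1, 0.9, 0.5,
                 0.9, 1, 0.9,
                 0.5, 0.9, 1), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_identical(redundancy_filter(c("A", "B", "C"), cor_matrix = cm),
                   c("A", "C"))
  # perfectly correlated pair: only the better-ranked survives
  set.seed(41)
  x <- rnorm(100)
  X <- cbind(f1 = x, f2 = x, f3 = rnorm(100))
  expect_identical(redundancy_filter(c("f1", "f2", "f3"), X), c("f1", "f3"))
  # orthogonal features all retained
  X2 <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_length(redundancy_filter(c("a", "b", "c"), X2), 3L)
  # constant feature dropped with warning
  X3 <- cbind(X2, cnst = rep(1, 100))
  expect_warning(out <- redundancy_filter(c("a", "cnst", "b", "c"), X3),
                 "constant")
  expect_false("cnst" %in% out)
})

test_that("modified-covariate fit is antisymmetric in the treatment labels", {
  co <- generate_cohort(cohort_spec(n_patients = 600, seed = 42))
  X <- as.matrix(co[, c("z_skewness", "z_glcm_variance", "z_lrhgle")])
  fit <- fit_modified_covariate_cox(X, co)
  co_flip <- co; co_flip$arm <- 1 - co$arm
  fit_flip <- fit_modified_covariate_cox(X, co_flip)
  expect_equal(fit$gamma, -fit_flip$gamma, tolerance = 1e-6)
  # degenerate all-zero design rejected
  X0 <- matrix(0, nrow(co), 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_modified_covariate_cox(X0, co), "identically zero")
  # single-arm input rejected
  co1 <- co[co$arm == 1, ]
  expect_error(fit_modified_covariate_cox(X[co$arm == 1, ], co1), "both arms")
})

test_that("modified-covariate fit recovers planted interaction coefficients", {
  co <- generate_cohort(cohort_spec(n_patients = 4000, confounding_strength = 0,
                                    censor_rate = 0, seed = 43))
  X <- as.matrix(co[, c("z_skewness", "z_glcm_variance", "z_lrhgle")])
  fit <- fit_modified_covariate_cox(X, co)
  truth <- attr(co, "spec")$true_benefit_coefs
  expect_identical(sign(unname(fit$gamma)), sign(unname(truth)))
  expect_equal(unname(fit$gamma), unname(truth), tolerance = 0.35)
})

test_that("backward selection keeps the planted signal and is deterministic", {
  co <- generate_cohort(cohort_spec(n_patients = 1500, seed = 44))
  X <- sim_features(co, n_noise = 2, seed = 44)
  m1 <- backward_select(X, co)
  m2 <- backward_select(X, co)
  expect_false(is.null(m1))
  expect_identical(m1$coefficients, m2$coefficients)
  expect_true(any(c("z_skewness", "z_glcm_variance", "z_lrhgle") %in% m1$features))
  expect_true(all(m1$p < 0.05))
  # a model already fully significant is the fixed point
  m3 <- backward_select(X[, m1$features, drop = FALSE], co)
  expect_setequal(m3$features, m1$features)
  # pure-noise design rarely keeps anything; never keeps all three
  set.seed(99)
  Xn <- matrix(rnorm(nrow(co) * 3), nrow(co), 3,
               dimnames = list(NULL, paste0("n", 1:3)))
  mn <- suppressMessages(backward_select(Xn, co))
  expect_true(is.null(mn) || length(mn$features) < 3)
})

test_that("ICTOS scoring follows the published linear form and cutoff", {
  m <- ictos_paper_model()
  expect_setequal(m$features, c("skewness", "GLCM_variance", "GLRLM_LRHGLE"))
  # printed low-score patient: direct arithmetic oracle
  low <- ictos_score(m, c(skewness = 1.82, GLCM_variance = 1.37,
                          GLRLM_LRHGLE = -1.46))
  hand <- -0.668 * 1.82 - 0.442 * 1.37 + 0.410 * (-1.46)
  expect_equal(low$score, hand, tolerance = 1e-12)
  expect_equal(as.character(low$label), "low")
  # cutoff boundary: all-zero features score 0 -> low
  z <- ictos_score(m, c(skewness = 0, GLCM_variance = 0, GLRLM_LRHGLE = 0))
  expect_equal(z$score, 0)
  expect_equal(as.character(z$label), "low")
  # missing feature rejected, no imputation
  expect_error(ictos_score(m, c(skewness = 1)), "missing model feature")
  # label invariance under positive rescaling of the coefficients
  m2 <- ictos_model(coefficients = 3 * m$coefficients)
  x <- matrix(rnorm(60), 20, 3,
              dimnames = list(NULL, c("skewness", "GLCM_variance", "GLRLM_LRHGLE")))
  expect_identical(ictos_score(m, x)$label, ictos_score(m2, x)$label)
})

test_that("score orientation: positive score predicts lower hazard under ICT", {
  co <- generate_cohort(cohort_spec(n_patients = 3000, censor_rate = 0, seed = 45))
  X <- as.matrix(co[, c("z_skewness", "z_glcm_variance", "z_lrhgle")])
  fit <- fit_modified_covariate_cox(X, co)
  model <- ictos_model(gamma = fit$gamma)
  sc <- ictos_score(model, X)
  # the score must be anticorrelated with the true treatment log-HR
  expect_lt(cor(sc$score, co$true_benefit), -0.9)
})
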