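#' Specification of a synthetic two-arm cohort
#'
#' Defines the study conditions for a simulated locoregionally advanced
#' nasopharyngeal carcinoma cohort: treatment arms ICT+CCRT (arm 1) vs CCRT
#' alone (arm 0), failure-free survival (FFS, months) under a proportional
#' hazards model with an exponential baseline calibrated so the control-arm
#' 5-year event-free fraction equals \code{baseline_5yr_ffs}, and a latent
#' feature-by-treatment interaction so that a true benefit subgroup exists.
#'
#' Three latent standard-normal features per patient stand for the true
#' (standardized) tumor skewness, co-occurrence variance and long-run
#' high-gray emphasis; they drive both the phantom texture parameters (via
#' \code{\link{cohort_phantom_spec}}) and the per-patient treatment effect
#' \eqn{\log HR_i = base\_effect + \sum_j c_j z_{ij}}. The coefficients are
#' on the hazard side, so the default (+0.7, +0.45, -0.4) reproduces the
#' published benefit phenotype — low skewness, low co-occurrence variance
#' and high run emphasis predict benefit — at the scale of the published
#' score model (whose benefit-oriented coefficients are the negation of
#' these); deep in the benefit subgroup the treatment HR approaches the 0.25
#' design target.
#'
#' @param n_patients total number of patients (>= 2).
#' @param arm_ratio target fraction assigned to ICT+CCRT.
#' @param baseline_5yr_ffs control-arm 5-year (60-month) event-free fraction,
#'   in (0, 1); default 0.65, the design assumption for the unselected
#'   population.
#' @param true_benefit_coefs length-3 log-HR modification per latent feature.
#' @param base_effect treatment log-HR at latent-feature value 0.
#' @param confounding_strength scales a logistic arm-assignment model on the
#'   baseline covariates; 0 gives a randomized trial, positive values give an
#'   observational cohort where sicker patients preferentially receive ICT.
#' @param prognostic_strength scales the prognostic (both-arm) covariate
#'   effects on the hazard; 0 gives a constant baseline hazard.
#' @param censor_rate probability of random (drop-out) censoring before the
#'   administrative horizon; 1 censors every record at time 0.
#' @param admin_censor_time administrative censoring horizon in months.
#' @param seed integer RNG seed.
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_patients = 500L, arm_ratio = 0.5,
                        baseline_5yr_ffs = 0.65,
                        true_benefit_coefs = c(skewness = 0.7,
                                               glcm_variance = 0.45,
                                               lrhgle = -0.4),
                        base_effect = 0,
                        confounding_strength = 0,
                        prognostic_strength = 1,
                        censor_rate = 0.15,
                        admin_censor_time = 84,
                        seed = 1L) {
  assert_scalar_number(n_patients, "n_patients", lower = 2)
  assert_scalar_number(arm_ratio, "arm_ratio", lower = 0, upper = 1)
  assert_scalar_number(baseline_5yr_ffs, "baseline_5yr_ffs",
                       lower = 0, upper = 1, strict_lower = TRUE, strict_upper = TRUE)
  assert_that(length(true_benefit_coefs) == 3 && all(is.finite(true_benefit_coefs)),
              "'true_benefit_coefs' must be 3 finite numbers")
  assert_scalar_number(censor_rate, "censor_rate", lower = 0, upper = 1)
  assert_scalar_number(admin_censor_time, "admin_censor_time",
                       lower = 0, strict_lower = TRUE)
  structure(list(n_patients = as.integer(n_patients), arm_ratio = arm_ratio,
                 baseline_5yr_ffs = baseline_5yr_ffs,
                 true_benefit_coefs = true_benefit_coefs,
                 base_effect = base_effect,
                 confounding_strength = confounding_strength,
                 prognostic_strength = prognostic_strength,
                 censor_rate = censor_rate,
                 admin_censor_time = admin_censor_time,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic two-arm cohort with survival and ground truth
#'
#' Draws baseline covariates, assigns the treatment arm by a logistic model
#' scaled by \code{confounding_strength}, and samples FFS times by inverse
#' transform from an exponential proportional-hazards model whose
#' per-patient treatment log-HR is \code{base_effect +
#' sum(true_benefit_coefs * z)}. Prognostic effects of T4 stage, N2-3 stage,
#' high EBV DNA and tumor volume act in both arms, so a confounded arm
#' assignment biases the naive arm contrast (making the weighting stage's
#' job real). Censoring combines random drop-out with administrative
#' censoring at \code{admin_censor_time}.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return A data.frame with one row per patient: \code{id}, \code{arm}
#'   (0 = CCRT, 1 = ICT+CCRT), \code{time_months}, \code{event} (0/1),
#'   covariates \code{age}, \code{sex} (1 = male), \code{t_stage} (1-4),
#'   \code{n_stage} (1-3), \code{stage} (3-4), \code{nodal_necrosis} (0/1),
#'   \code{tumor_volume_ml}, \code{pebv_dna} (copies/ml), the latent truth
#'   \code{z_skewness}, \code{z_glcm_variance}, \code{z_lrhgle} and
#'   \code{true_benefit} (per-patient treatment log-HR; negative = ICT
#'   lowers the hazard). The spec is attached as attribute \code{"spec"}.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients

  z <- matrix(stats::rnorm(3 * n), n, 3,
              dimnames = list(NULL, c("z_skewness", "z_glcm_variance", "z_lrhgle")))

  age <- round(stats::rnorm(n, 45, 10))
  sex <- stats::rbinom(n, 1, 0.75)
  t_stage <- sample(1:4, n, replace = TRUE, prob = c(0.03, 0.08, 0.57, 0.32))
  n_stage <- sample(1:3, n, replace = TRUE, prob = c(0.48, 0.38, 0.14))
  stage <- ifelse(t_stage == 4 | n_stage == 3, 4L, 3L)
  nodal_necrosis <- stats::rbinom(n, 1, 0.3)
  tumor_volume_ml <- exp(stats::rnorm(n, log(30), 0.5))
  pebv_dna <- exp(stats::rnorm(n, log(1500), 1.3))

  # arm assignment: randomized at confounding_strength 0, otherwise sicker
  # patients are channelled to ICT+CCRT
  risk_lin <- 0.5 * (t_stage == 4) + 0.4 * (n_stage >= 2) +
    0.4 * (pebv_dna >= 2000) + 0.3 * scale(log(tumor_volume_ml))[, 1] +
    0.2 * nodal_necrosis + 0.2 * scale(age)[, 1]
  eta <- spec$confounding_strength * (risk_lin - mean(risk_lin)) +
    stats::qlogis(spec$arm_ratio)
  arm <- stats::rbinom(n, 1, stats::plogis(eta))

  # proportional-hazards survival, exponential baseline calibrated to the
  # control-arm 5-year FFS at covariate/latent profile zero
  h0 <- -log(spec$baseline_5yr_ffs) / 60
  prognostic <- 0.3 * (t_stage == 4) + 0.3 * (n_stage >= 2) +
    0.25 * (pebv_dna >= 2000) + 0.15 * scale(log(tumor_volume_ml))[, 1]
  prognostic <- spec$prognostic_strength * (prognostic - mean(prognostic))
  true_benefit <- spec$base_effect + drop(z %*% spec$true_benefit_coefs)
  h <- h0 * exp(prognostic + arm * true_benefit)
  t_event <- stats::rexp(n, rate = h)

  if (spec$censor_rate >= 1) {
    t_cens <- rep(0, n)
  } else if (spec$censor_rate > 0) {
    rc <- -log(1 - spec$censor_rate) / spec$admin_censor_time
    t_cens <- pmin(stats::rexp(n, rate = rc), spec$admin_censor_time)
  } else {
    t_cens <- rep(spec$admin_censor_time, n)
  }
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  out <- data.frame(id = sprintf("P%04d", seq_len(n)), arm = arm,
                    time_months = time, event = event, age = age, sex = sex,
                    t_stage = t_stage, n_stage = n_stage, stage = stage,
                    nodal_necrosis = nodal_necrosis,
                    tumor_volume_ml = tumor_volume_ml, pebv_dna = pebv_dna,
                    z, true_benefit = true_benefit)
  attr(out, "spec") <- spec
  out
}

#' Phantom specification for one synthetic patient
#'
#' Maps a patient's latent texture features onto phantom knobs so that the
#' extracted image features correlate with the latent truth: skewness with
#' \code{z_skewness}, plateau amplitude (co-occurrence variance) with
#' \code{z_glcm_variance}, plateau size (long-run high-gray emphasis) with
#' \code{z_lrhgle}.
#'
#' @param patient one row of a \code{\link{generate_cohort}} table.
#' @param grid_shape,roi_radius phantom geometry (see
#'   \code{\link{phantom_spec}}).
#' @param seed integer seed for this patient's phantom.
#' @return A \code{\link{phantom_spec}}.
#' @export
cohort_phantom_spec <- function(patient, grid_shape = c(3L, 40L, 40L),
                                roi_radius = 9, seed = 1L) {
  phantom_spec(grid_shape = grid_shape, roi_radius = roi_radius,
               target_skew = 1.2 * patient$z_skewness,
               heterogeneity = exp(0.5 * patient$z_glcm_variance),
               run_structure = pmax(0, 1.5 + 0.9 * patient$z_lrhgle),
               noise_sd = 40, seed = seed)
}

#' Write a cohort's clinical table as CSV
#'
#' Writes the documented clinical columns (id, arm, time_months, event, age,
#' sex, t_stage, n_stage, stage, nodal_necrosis, tumor_volume_ml, pebv_dna)
#' without the latent ground-truth columns unless \code{truth = TRUE}.
#'
#' @param cohort a \code{\link{generate_cohort}} table.
#' @param path output CSV path.
#' @param truth include latent ground-truth columns.
#' @return \code{path}, invisibly.
#' @export
write_cohort_csv <- function(cohort, path, truth = FALSE) {
  cols <- c("id", "arm", "time_months", "event", "age", "sex", "t_stage",
            "n_stage", "stage", "nodal_necrosis", "tumor_volume_ml", "pebv_dna")
  if (truth) cols <- c(cols, "z_skewness", "z_glcm_variance", "z_lrhgle",
                       "true_benefit")
  utils::write.csv(cohort[, cols], path, row.names = FALSE)
  invisible(path)
}
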