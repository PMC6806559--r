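# Weighted Kaplan-Meier estimation, arm comparisons, interaction testing,
# log-rank power, required cohort size, and risk stratification.

#' Weighted Kaplan-Meier curve with Greenwood confidence intervals
#'
#' Product-limit estimator with weighted risk sets and event counts
#' (via \code{survival::survfit}), Greenwood variance, and the log-log CI
#' transform by default (plain Greenwood available). Survival read-offs at
#' requested times use the step function's left-continuous value (the value
#' just before \code{t}).
#'
#' @param time,event aligned follow-up times (months) and 0/1 event flags.
#' @param weights nonnegative observation weights (default unit).
#' @param conf_type \code{"log-log"} (default) or \code{"plain"}.
#' @param times_at times (months) at which to read off survival (default 36
#'   and 60 = 3 and 5 years).
#' @return A list of class \code{km_curve}: \code{time}, \code{surv},
#'   \code{lower}, \code{upper} (step function), \code{at} (data.frame of
#'   read-offs with CIs), \code{n_events}, and \code{no_events} flag (curve
#'   is flat at 1 and CIs are undefined when no event occurred).
#' @export
km_weighted <- function(time, event, weights = NULL,
                        conf_type = c("log-log", "plain"),
                        times_at = c(36, 60)) {
  conf_type <- match.arg(conf_type)
  assert_that(length(time) == length(event), "'time' and 'event' lengths differ")
  assert_that(all(time >= 0), "'time' must be nonnegative")
  if (is.null(weights)) weights <- rep(1, length(time))
  assert_that(all(weights >= 0 & is.finite(weights)),
              "'weights' must be nonnegative and finite")
  no_events <- sum(event) == 0
  fit <- survival::survfit(
    survival::Surv(time, event) ~ 1, weights = weights,
    conf.type = if (conf_type == "log-log") "log-log" else "plain",
    se.fit = TRUE)
  # left-continuous read-off: survival just before t
  read_at <- function(t) {
    idx <- which(fit$time < t & fit$n.event > 0)
    if (length(idx) == 0) return(c(surv = 1, lower = NA, upper = NA))
    i <- max(idx)
    c(surv = fit$surv[i], lower = fit$lower[i], upper = fit$upper[i])
  }
  at <- as.data.frame(t(vapply(times_at, read_at, numeric(3))))
  at$time <- times_at
  at <- at[, c("time", "surv", "lower", "upper")]
  structure(list(time = fit$time, surv = fit$surv,
                 lower = fit$lower, upper = fit$upper,
                 n_risk = fit$n.risk, n_event = fit$n.event,
                 at = at, n_events = sum(event * weights > 0),
                 no_events = no_events, conf_type = conf_type),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Weighted Kaplan-Meier curve (", x$conf_type, " CI)\n", sep = "")
  if (x$no_events) cat("  no events: S(t) = 1 throughout, CIs undefined\n")
  print(x$at, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Weighted two-group survival comparison
#'
#' Hazard ratio with Wald 95% CI from a weighted univariate Cox model
#' (Efron ties; robust variance when weights are non-unit) and the weighted
#' log-rank p-value, implemented as the score test of the weighted Cox fit.
#'
#' @param time,event follow-up and event indicator.
#' @param group two-level group indicator; the HR is for the second level
#'   vs the first (code the treated arm so 1 vs 0 gives ICT+CCRT vs CCRT).
#' @param weights observation weights (default unit).
#' @param conf_level CI level (default 0.95).
#' @return A list: \code{hr}, \code{ci} (length-2), \code{p_wald},
#'   \code{p_logrank}, \code{n}, \code{n_events}.
#' @export
compare_arms <- function(time, event, group, weights = NULL,
                         conf_level = 0.95) {
  g <- as.numeric(factor(group)) - 1
  assert_that(length(unique(g)) == 2, "exactly two groups are required")
  assert_that(sum(event) >= 1, "no events: comparison undefined")
  if (is.null(weights)) weights <- rep(1, length(time))
  robust <- !all(weights == 1)
  fit <- suppressWarnings(survival::coxph(
    survival::Surv(time, event) ~ g, weights = weights,
    ties = "efron", robust = robust))
  beta <- unname(fit$coefficients)
  se <- if (robust) sqrt(fit$var[1, 1]) else sqrt(fit$var[1, 1])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p_logrank <- stats::pchisq(fit$score, df = 1, lower.tail = FALSE)
  list(hr = exp(beta), ci = exp(beta + c(-1, 1) * z * se),
       p_wald = 2 * stats::pnorm(-abs(beta / se)),
       p_logrank = unname(p_logrank),
       n = length(time), n_events = sum(event))
}

#' Treatment-by-subgroup interaction test
#'
#' Weighted Cox model with arm, subgroup label, and their product; returns
#' the Wald p-value of the product term (does the treatment effect differ
#' between label groups?).
#'
#' @param time,event follow-up and event indicator.
#' @param arm treatment 0/1.
#' @param label two-level subgroup label (e.g. high/low ICTOS).
#' @param weights observation weights (default unit).
#' @return A list: \code{p_interaction}, \code{beta_interaction},
#'   \code{fit}.
#' @export
interaction_test <- function(time, event, arm, label, weights = NULL) {
  lab <- as.numeric(factor(label)) - 1
  assert_that(length(unique(lab)) == 2, "'label' must have two levels")
  tab <- table(arm, lab)
  if (any(tab == 0)) {
    empty <- which(tab == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty stratum: arm=%s, label=%s",
                 rownames(tab)[empty[1]], colnames(tab)[empty[2]]),
         call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, length(time))
  fit <- suppressWarnings(survival::coxph(
    survival::Surv(time, event) ~ arm * lab, weights = weights,
    ties = "efron", robust = !all(weights == 1)))
  co <- fit$coefficients["arm:lab"]
  se <- sqrt(diag(fit$var))[3]
  list(p_interaction = unname(2 * stats::pnorm(-abs(co / se))),
       beta_interaction = unname(co), fit = fit)
}

#' Log-rank power by the Schoenfeld approximation
#'
#' \deqn{power = \Phi\left(\sqrt{D\,p(1-p)}\;|\log HR| - z_{1-\alpha/2}\right)}
#' with \eqn{D} the number of events and \eqn{p} the allocation fraction.
#' With the design values D = 29 events, 1:1 allocation, HR = 0.25 and
#' two-sided alpha 0.05 this returns 0.96 (two decimals).
#'
#' @param n_events number of events D (>= 1).
#' @param allocation treated fraction p in (0, 1) (default 0.5).
#' @param hr hazard ratio under the alternative (> 0).
#' @param alpha two-sided significance level (default 0.05).
#' @return Power in (0, 1). At HR = 1 this is the lower bound
#'   \eqn{\Phi(-z_{1-\alpha/2})} (= 0.025 at alpha 0.05), returned with a
#'   message.
#' @export
logrank_power <- function(n_events, allocation = 0.5, hr, alpha = 0.05) {
  assert_scalar_number(n_events, "n_events", lower = 1)
  assert_scalar_number(allocation, "allocation", lower = 0, upper = 1,
                       strict_lower = TRUE, strict_upper = TRUE)
  assert_scalar_number(hr, "hr", lower = 0, strict_lower = TRUE)
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1,
                       strict_lower = TRUE, strict_upper = TRUE)
  if (hr == 1) message("HR = 1: power equals the null lower bound")
  stats::pnorm(sqrt(n_events * allocation * (1 - allocation)) * abs(log(hr)) -
                 stats::qnorm(1 - alpha / 2))
}

#' Required total cohort size given subgroup prevalence
#'
#' Scales a required subgroup size up by its prevalence in the population,
#' rounding to the nearest whole patient: with 110 patients needed in a
#' subgroup accounting for 47% of the population, 234 patients are required
#' in total.
#'
#' @param subgroup_n required number of patients in the subgroup.
#' @param prevalence subgroup prevalence in (0, 1].
#' @return Required total cohort size (integer).
#' @export
required_cohort_size <- function(subgroup_n, prevalence) {
  assert_scalar_number(subgroup_n, "subgroup_n", lower = 1)
  assert_scalar_number(prevalence, "prevalence", lower = 0, upper = 1,
                       strict_lower = TRUE)
  as.integer(floor(subgroup_n / prevalence + 0.5))
}

#' Risk stratification of low-ICTOS patients
#'
#' Counts, per patient, the four high-risk factors N2-3 stage, T4 stage,
#' primary tumor volume >= 34 ml and plasma EBV DNA >= 2000 copies/ml, and
#' labels patients with \code{>= min_factors} of them high-risk. The default
#' \code{min_factors = 3} is the literal reading of "more than two high-risk
#' factors"; the cutpoint is configurable because the looser reading
#' (>= 2) is also defensible.
#'
#' @param cohort table with \code{n_stage}, \code{t_stage},
#'   \code{tumor_volume_ml}, \code{pebv_dna}; rows with missing values are
#'   excluded with a warning.
#' @param min_factors factor count at/above which a patient is high-risk.
#' @param volume_cut,pebv_cut factor cutpoints (34 ml, 2000 copies/ml).
#' @return A data.frame aligned to the (complete) cohort rows: \code{id}
#'   (when present), the four factor indicators, \code{n_factors} (0-4) and
#'   \code{risk_group} (factor low/high).
#' @export
stratify_low_ictos <- function(cohort, min_factors = 3,
                               volume_cut = 34, pebv_cut = 2000) {
  need <- c("n_stage", "t_stage", "tumor_volume_ml", "pebv_dna")
  assert_columns(cohort, need, "cohort")
  ok <- stats::complete.cases(cohort[, need])
  if (!all(ok))
    warning(sum(!ok), " patient(s) excluded for missing stratification covariates")
  d <- cohort[ok, , drop = FALSE]
  f <- data.frame(
    factor_n23 = as.integer(d$n_stage >= 2),
    factor_t4 = as.integer(d$t_stage == 4),
    factor_volume = as.integer(d$tumor_volume_ml >= volume_cut),
    factor_pebv = as.integer(d$pebv_dna >= pebv_cut))
  f$n_factors <- rowSums(f)
  f$risk_group <- factor(ifelse(f$n_factors >= min_factors, "high", "low"),
                         levels = c("low", "high"))
  if ("id" %in% names(d)) f <- cbind(id = d$id, f)
  f
}
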