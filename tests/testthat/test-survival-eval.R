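test_that("weighted KM with unit weights equals the textbook product-limit curve", {
  # printed 6-patient toy set, hand-computed:
  # t=2 (event): S = 5/6; t=4 (event, one censored at 4): S = 5/6 * 4/5 = 2/3
  # t=6 (event): S = 2/3 * 2/3 = 4/9; t=9 (event): S = 0
  time <- c(2, 4, 4, 6, 8, 9)
  event <- c(1, 1, 0, 1, 0, 1)
  km <- km_weighted(time, event)
  ev <- km$n_event > 0
  expect_equal(km$surv[ev], c(5 / 6, 2 / 3, 4 / 9, 0), tolerance = 1e-12)
  orc <- oracle_km(time, event)
  expect_equal(km$surv[ev], orc$surv, tolerance = 1e-12)
  # Greenwood CIs ordered and inside [0, 1] where defined
  ok <- !is.na(km$lower)
  expect_true(all(km$lower[ok] <= km$surv[ok] + 1e-12))
  expect_true(all(km$upper[ok] >= km$surv[ok] - 1e-12))
  expect_true(all(km$lower[ok] >= 0 & km$upper[ok] <= 1))
  # random cohorts: oracle equivalence
  set.seed(50)
  for (r in 1:10) {
    t_ <- rexp(40, 0.05); e_ <- rbinom(40, 1, 0.6)
    if (sum(e_) == 0) next
    k <- km_weighted(t_, e_)
    o <- oracle_km(t_, e_)
    expect_equal(k$surv[k$n_event > 0], o$surv, tolerance = 1e-10)
  }
})

test_that("integer weights reproduce row replication and no events flatten the curve", {
  time <- c(3, 5, 7, 11); event <- c(1, 0, 1, 1)
  w <- c(3, 2, 1, 2)
  k1 <- km_weighted(time, event, w)
  k2 <- km_weighted(rep(time, w), rep(event, w))
  expect_equal(k1$surv[k1$n_event > 0], k2$surv[k2$n_event > 0],
               tolerance = 1e-10)
  kc <- km_weighted(c(1, 2, 3), c(0, 0, 0))
  expect_true(kc$no_events)
  expect_true(all(kc$surv == 1))
  expect_true(all(is.na(kc$at$lower)))
})

test_that("KM read-offs are left-continuous and CIs carry over event-free gaps", {
  time <- c(10, 36, 50); event <- c(1, 1, 1)
  km <- km_weighted(time, event, times_at = c(36, 40, 60))
  # at t = 36 the read-off excludes the event at exactly 36
  expect_equal(km$at$surv[km$at$time == 36], 2 / 3)
  # between events (t = 40) the CI equals the one at the previous event time
  i36 <- which(km$time == 36)
  expect_equal(km$at$lower[km$at$time == 40], km$lower[i36])
  expect_equal(km$at$surv[km$at$time == 60], 0)
})

test_that("arm comparison returns null HR under identical distributions", {
  set.seed(51)
  n <- 3000
  time <- rexp(n, 0.03); event <- rbinom(n, 1, 0.8)
  group <- rep(0:1, n / 2)
  cmp <- compare_arms(time, event, group)
  expect_equal(cmp$hr, 1, tolerance = 0.12)
  expect_gt(cmp$p_logrank, 0.01)
  # time-scale invariance of the hazard ratio
  cmp2 <- compare_arms(time / 2, event, group)
  expect_equal(cmp$hr, cmp2$hr, tolerance = 1e-8)
  # unit-weight log-rank (Cox score test) agrees with survdiff's chi-square
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  expect_equal(cmp$p_logrank, stats::pchisq(sd_$chisq, 1, lower.tail = FALSE),
               tolerance = 0.02)
  expect_error(compare_arms(time, event, rep(1, n)), "two groups")
})

test_that("CI for a known hazard ratio covers the truth at the nominal rate", {
  set.seed(52)
  cover <- 0
  reps <- 60
  for (r in 1:reps) {
    n <- 400
    arm <- rep(0:1, n / 2)
    t_ <- rexp(n, 0.03 * 0.5^arm)
    cmp <- compare_arms(t_, rep(1, n), arm)
    if (cmp$ci[1] <= 0.5 && 0.5 <= cmp$ci[2]) cover <- cover + 1
  }
  expect_gt(cover / reps, 0.85)
})

test_that("interaction test is invariant to label coding and rejects empty cells", {
  set.seed(53)
  co <- generate_cohort(cohort_spec(n_patients = 800, seed = 53))
  lab <- ifelse(co$z_skewness < 0, "high", "low")
  it1 <- interaction_test(co$time_months, co$event, co$arm, lab)
  it2 <- interaction_test(co$time_months, co$event, co$arm,
                          ifelse(lab == "high", "B", "A"))
  expect_equal(it1$p_interaction, it2$p_interaction, tolerance = 1e-6)
  # planted label-dependent effect is detected far above chance at this n
  expect_lt(it1$p_interaction, 0.05)
  lab_bad <- ifelse(co$arm == 1, "high", "low")
  expect_error(interaction_test(co$time_months, co$event, co$arm, lab_bad),
               "empty stratum")
})

test_that("Schoenfeld power formula reproduces design values and monotonicity", {
  expect_equal(round(logrank_power(29, 0.5, 0.25, 0.05), 2), 0.96)
  expect_equal(suppressMessages(logrank_power(29, 0.5, 1, 0.05)),
               pnorm(-qnorm(0.975)), tolerance = 1e-12)
  d_grid <- c(10, 20, 40, 80, 160)
  p_d <- vapply(d_grid, function(d) logrank_power(d, 0.5, 0.5), numeric(1))
  expect_true(all(diff(p_d) > 0))
  hr_grid <- c(0.9, 0.7, 0.5, 0.3)
  p_hr <- vapply(hr_grid, function(h) logrank_power(50, 0.5, h), numeric(1))
  expect_true(all(diff(p_hr) > 0))
  expect_gt(logrank_power(50, 0.5, 0.5, 0.05),
            logrank_power(50, 0.5, 0.5, 0.01))
})

test_that("required cohort size follows the prevalence scaling", {
  expect_equal(required_cohort_size(110, 0.47), 234L)
  expect_equal(required_cohort_size(100, 1), 100L)
  expect_equal(required_cohort_size(1, 0.5), 2L)
  expect_error(required_cohort_size(100, 0), "prevalence")
})

test_that("risk stratification counts the four factors with the literal rule", {
  co <- data.frame(id = c("a", "b", "c"),
                   n_stage = c(1, 3, 2), t_stage = c(2, 4, 4),
                   tumor_volume_ml = c(20, 50, 40), pebv_dna = c(500, 5000, 1000))
  rs <- stratify_low_ictos(co)
  expect_equal(rs$n_factors, c(0, 4, 3))
  expect_equal(as.character(rs$risk_group), c("low", "high", "high"))
  # exactly two factors stays low-risk under the literal "more than two"
  co2 <- data.frame(n_stage = 2, t_stage = 4, tumor_volume_ml = 10,
                    pebv_dna = 100)
  expect_equal(as.character(stratify_low_ictos(co2)$risk_group), "low")
  # looser reading available as a knob
  expect_equal(as.character(stratify_low_ictos(co2, min_factors = 2)$risk_group),
               "high")
  co3 <- co; co3$pebv_dna[2] <- NA
  expect_warning(rs3 <- stratify_low_ictos(co3), "excluded")
  expect_equal(nrow(rs3), 2L)
})
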