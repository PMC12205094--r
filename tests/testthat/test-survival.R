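# Kaplan-Meier estimation, medians, milestones; response tallies; duration
# of response; growth-modulation index.

test_that("KM with no censoring equals the empirical survivor function", {
  curve <- km_fit(c(1, 2, 3), c(1, 1, 1))
  expect_equal(curve$steps$surv, c(2 / 3, 1 / 3, 0))
  # property: for arbitrary fully-observed data, S(t) = 1 - ECDF(t)
  set.seed(5)
  for (i in 1:5) {
    tm <- round(rexp(40, 0.3), 2)
    curve <- km_fit(tm, rep(1, 40))
    ecdf_c <- 1 - stats::ecdf(tm)(curve$steps$time)
    expect_equal(curve$steps$surv, ecdf_c, tolerance = 1e-12)
  }
})

test_that("KM matches the hand-worked product-limit table with censoring", {
  # times 1 (censored), 2 (event), 3 (censored), 4 (event), 5 (event)
  curve <- km_fit(c(1, 2, 3, 4, 5), c(0, 1, 0, 1, 1))
  s <- curve$steps
  ev <- s[s$n_event > 0, ]
  expect_equal(ev$time, c(2, 4, 5))
  expect_equal(ev$surv, c(3 / 4, 3 / 8, 0))
  expect_equal(ev$n_risk, c(4, 2, 1))
  # single censored record: curve stays at 1
  c1 <- km_fit(3, 0)
  expect_equal(c1$steps$surv, 1)
  expect_true(is.na(km_median(c1)$median))
})

test_that("tied events and censorings resolve events-first", {
  # at t=2: one event and one censoring; the censored subject still counts
  # in the risk set of the event
  curve <- km_fit(c(1, 2, 2, 3), c(1, 1, 0, 1))
  s <- curve$steps
  expect_equal(s$surv[s$time == 2][1], (3 / 4) * (2 / 3))
})

test_that("Greenwood SE is zero before the first event and scale-invariant", {
  curve <- km_fit(c(2, 3, 5), c(1, 1, 0))
  expect_equal(km_milestone(curve, 1)$se, 0)
  expect_equal(km_milestone(curve, 1)$estimate, 1)
  # months -> days rescaling leaves survival and SE values identical
  tm <- c(1.1, 2.3, 2.3, 4.0, 6.5, 8.2)
  ev <- c(1, 1, 0, 1, 0, 1)
  m_curve <- km_fit(tm, ev)
  d_curve <- km_fit(tm * 365 / 12, ev)
  expect_equal(m_curve$steps$surv, d_curve$steps$surv)
  expect_equal(m_curve$steps$se, d_curve$steps$se)
  expect_equal(d_curve$steps$time, m_curve$steps$time * 365 / 12)
})

test_that("km_median uses the smallest-time-at-or-below-0.5 convention", {
  # S hits exactly 0.5 at t = 2
  med <- km_median(km_fit(c(1, 2, 3, 4), c(1, 1, 1, 1)))
  expect_identical(med$median, 2)
  # never reaches 0.5 -> NR flags
  med_nr <- km_median(km_fit(c(1, 2, 3, 4), c(1, 0, 0, 0)))
  expect_true(is.na(med_nr$median))
  expect_true(med_nr$not_reached)
  expect_true(is.na(med_nr$ci_high))
})

test_that("km_milestone interpolates the step function with bands", {
  curve <- km_fit(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km_milestone(curve, 0)$estimate, 1)
  expect_equal(km_milestone(curve, 2.5)$estimate, 0.5)
  ms <- km_milestone(curve, 2.5)
  expect_true(ms$ci_low <= 0.5 && ms$ci_high >= 0.5)
  expect_false(ms$truncated)
  expect_warning(ms_far <- km_milestone(curve, 10), "truncated")
  expect_true(ms_far$truncated)
})

test_that("KM recovers the generator truth on a large synthetic cohort", {
  sc <- cohort_scenario(n_patients = 2000, seed = 424)
  cohort <- generate_cohort(sc)
  curve <- km_fit(cohort$pfs_months, cohort$pfs_event, endpoint = "PFS")
  med <- km_median(curve)
  expect_lt(abs(med$median - 1.8) / 1.8, 0.10)
  # milestone at 6 months vs the closed-form mixture survival, within 3 SE
  ms <- km_milestone(curve, 6)
  truth <- true_pfs_survival(sc, 6)
  expect_lt(abs(ms$estimate - truth), 3 * ms$se)
})

test_that("summarize_response tallies categories and emits the trial state", {
  df <- data.frame(
    patient_id = 1:43,
    bor = c(rep("PR", 4), rep("SD", 17), rep("PD", 22)),
    pfs_months = c(rep(8, 4), rep(7, 3), rep(2, 14), rep(1, 22))
  )
  res <- summarize_response(df)
  expect_identical(res$state$n_evaluable, 43L)
  expect_identical(res$state$n_responders, 4L)
  expect_equal(res$counts[["SD"]], 17L)
  expect_equal(res$orr, 4 / 43)
  expect_identical(res$disease_control_6mo, 7L)
  # permutation invariance
  perm <- df[sample(nrow(df)), ]
  expect_identical(summarize_response(perm)$counts, res$counts)
  # edge cases
  empty <- summarize_response(df[0, ])
  expect_false(empty$orr_defined)
  expect_null(empty$state)
  all_cr <- summarize_response(data.frame(bor = rep("CR", 5), pfs_months = 9,
                                          response_onset_months = 2))
  expect_equal(all_cr$orr, 1)
  expect_error(summarize_response(data.frame(bor = "XX", pfs_months = 1)))
  # non-evaluable rows are excluded when the column is present
  df$evaluable_efficacy <- 1
  df$evaluable_efficacy[1] <- 0
  expect_identical(summarize_response(df)$state$n_evaluable, 42L)
})

test_that("duration_of_response subtracts onset and censors correctly", {
  df <- data.frame(patient_id = c("a", "b", "c"),
                   bor = c("PR", "CR", "SD"),
                   response_onset_months = c(2, 1.5, NA),
                   pfs_months = c(9.8, 5.5, 3),
                   pfs_event = c(1, 0, 1))
  dor <- duration_of_response(df)
  expect_equal(dor$records$time, c(7.8, 4.0))
  expect_equal(dor$records$event, c(1L, 0L))
  expect_identical(dor$n_responders, 2L)
  # no responders: undefined median, no error
  none <- duration_of_response(df[3, ])
  expect_identical(none$n_responders, 0L)
  expect_true(is.na(none$median$median))
  # responder without onset: validation error
  bad <- df
  bad$response_onset_months[1] <- NA
  expect_error(duration_of_response(bad), "onset")
})

test_that("gmi_compute reproduces hand arithmetic and the threshold rule", {
  g <- gmi_compute(c(6, 2, 1), c(3, 4, 2))
  expect_equal(g$records$gmi, c(2.0, 0.5, 0.5))
  expect_equal(g$median_gmi, 0.5)
  expect_equal(g$fraction_ge_threshold, 1 / 3)
  # inclusive threshold: a GMI of exactly 1.33 counts
  g_edge <- gmi_compute(c(1.33, 1), c(1, 1))
  expect_identical(g_edge$n_ge_threshold, 1L)
  # all ratios equal one
  g1 <- gmi_compute(rep(2, 5), rep(2, 5))
  expect_equal(g1$median_gmi, 1)
  expect_identical(g1$n_ge_threshold, 0L)
  # 6 of 43 at or above threshold reports 14.0 (one decimal, half-up)
  g43 <- gmi_compute(c(rep(4, 6), rep(1, 37)), rep(2, 43))
  expect_identical(g43$percent_ge_threshold, 14.0)
  # scale invariance: common rescaling of both PFS columns
  g_days <- gmi_compute(c(6, 2, 1) * 365 / 12, c(3, 4, 2) * 365 / 12)
  expect_equal(g_days$records$gmi, g$records$gmi)
  # validation
  expect_error(gmi_compute(1, 0), "positive")
  # censored pairs flagged and excludable
  gc <- gmi_compute(c(6, 2), c(3, 4), censored = c(TRUE, FALSE))
  expect_identical(gc$n, 2L)
  expect_true(gc$records$censored[1])
  gx <- gmi_compute(c(6, 2), c(3, 4), censored = c(TRUE, FALSE),
                    include_censored = FALSE)
  expect_identical(gx$n, 1L)
})
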