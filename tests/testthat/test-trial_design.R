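# Beta-binomial design: posterior updates, tail probabilities, stopping
# rules, trial simulation, operating characteristics.

test_that("design constructor enforces its invariants", {
  expect_s3_class(trial_design(), "trial_design")
  expect_error(trial_design(prior_alpha = 0))
  expect_error(trial_design(p_futility = 0.3, p_efficacy = 0.2))
  expect_error(trial_design(threshold_futility = 0.4))
  expect_error(trial_design(n_first_interim = 60, n_max = 50))
  expect_error(trial_state(10, 11))
  expect_error(trial_state(-1, 0))
})

test_that("update_posterior returns the conjugate posterior with correct CI", {
  d <- trial_design()  # Beta(1,1)
  # uniform prior unchanged by no data
  p0 <- update_posterior(d, trial_state(0, 0))
  expect_equal(p0$mean, 0.5)
  expect_equal(p0$ci_low, 0.025, tolerance = 1e-9)
  expect_equal(p0$ci_high, 0.975, tolerance = 1e-9)
  # reported trial outcome: 4/43 under Beta(1,1)
  p <- update_posterior(d, trial_state(43, 4))
  expect_equal(p$alpha_post, 5)
  expect_equal(p$beta_post, 40)
  expect_equal(p$mean, 5 / 45)
  # Beta(2,3) prior with 3/10: mean 1/3, equal-tailed quantiles against a
  # trapezoid-integration oracle of the Beta(5,10) density
  d2 <- trial_design(prior_alpha = 2, prior_beta = 3)
  p2 <- update_posterior(d2, trial_state(10, 3))
  expect_equal(p2$mean, 1 / 3)
  expect_equal(p2$ci_low, 0.127599, tolerance = 1e-4)
  expect_equal(p2$ci_high, 0.581035, tolerance = 1e-4)
})

test_that("credible intervals match the trapezoid oracle over a parameter sweep", {
  # shapes >= 1 keep the density bounded, where the trapezoid rule is valid
  for (ab in list(c(1, 1), c(2, 3), c(5, 40), c(3, 7), c(100, 100))) {
    lo <- oracle_beta_quantile(0.025, ab[1], ab[2])
    hi <- oracle_beta_quantile(0.975, ab[1], ab[2])
    expect_equal(stats::qbeta(0.025, ab[1], ab[2]), lo, tolerance = 1e-5)
    expect_equal(stats::qbeta(0.975, ab[1], ab[2]), hi, tolerance = 1e-5)
  }
  # and the package reports exactly the equal-tailed qbeta quantiles
  p <- update_posterior(trial_design(), trial_state(20, 5))
  expect_equal(p$ci_low, stats::qbeta(0.025, 6, 16), tolerance = 1e-12)
  expect_equal(p$ci_high, stats::qbeta(0.975, 6, 16), tolerance = 1e-12)
})

test_that("pooled and sequential posterior updates agree (conjugacy)", {
  d <- trial_design(prior_alpha = 2, prior_beta = 3)
  pooled <- update_posterior(d, trial_state(25, 7))
  d_mid <- trial_design(prior_alpha = 2 + 4, prior_beta = 3 + 11)  # after 15 pts, 4 resp
  seq2 <- update_posterior(d_mid, trial_state(10, 3))
  expect_identical(pooled$alpha_post, seq2$alpha_post)
  expect_identical(pooled$beta_post, seq2$beta_post)
  expect_identical(pooled$mean, seq2$mean)
})

test_that("posterior tail probabilities are coherent and match quadrature", {
  d <- trial_design()
  p <- update_posterior(d, trial_state(0, 0))
  expect_equal(posterior_tail_prob(p, 1, "at_most"), 1)
  expect_equal(posterior_tail_prob(p, 0.25, "at_least"), 0.75)
  p2 <- update_posterior(d, trial_state(43, 4))  # Beta(5,40)
  expect_equal(posterior_tail_prob(p2, 0.10, "at_most"), 0.45279693,
               tolerance = 1e-6)
  # the two directions always sum to one (continuous law)
  for (thr in c(0.05, 0.1, 0.25, 0.5, 0.9)) {
    expect_equal(posterior_tail_prob(p2, thr, "at_most") +
                   posterior_tail_prob(p2, thr, "at_least"), 1,
                 tolerance = 1e-9)
  }
})

test_that("predictive_prob_success matches exhaustive sequence enumeration", {
  d <- trial_design(n_max = 15)
  expect_equal(predictive_prob_success(d, trial_state(10, 2)),
               0.1387362637, tolerance = 1e-9)
  # boundary: no patients remain -> 0/1 indicator of final criterion
  d50 <- trial_design()
  expect_identical(predictive_prob_success(d50, trial_state(50, 20)), 1)
  expect_identical(predictive_prob_success(d50, trial_state(50, 4)), 0)
  # sweep of small-remainder states vs the 2^m oracle
  for (nm in c(8, 12)) {
    dd <- trial_design(n_first_interim = 4, n_max = nm)
    for (n in c(nm - 8, nm - 5, nm - 2)) {
      if (n < 0) next
      for (r in 0:n) {
        expect_equal(predictive_prob_success(dd, trial_state(n, r)),
                     oracle_predictive_success(dd, n, r), tolerance = 1e-9,
                     label = sprintf("n_max=%d n=%d r=%d", nm, n, r))
      }
    }
  }
})

test_that("interim decisions reproduce the closed-form Beta(1, b) thresholds", {
  d <- trial_design()
  # P(p <= 0.10 | 0/10) = 1 - 0.9^11 < 0.80 -> continue
  dec10 <- interim_decision(d, trial_state(10, 0))
  expect_equal(dec10$prob_futility_event, 1 - 0.9^11, tolerance = 1e-9)
  expect_identical(dec10$action, "continue")
  # P(p <= 0.10 | 0/15) = 1 - 0.9^16 >= 0.80 -> stop for futility
  dec15 <- interim_decision(d, trial_state(15, 0))
  expect_equal(dec15$prob_futility_event, 1 - 0.9^16, tolerance = 1e-9)
  expect_identical(dec15$action, "stop_futility")
  # all responders at first look: P(p >= 0.25 | Beta(11,1)) = 1 - 0.25^11
  dec_eff <- interim_decision(d, trial_state(10, 10))
  expect_equal(dec_eff$prob_efficacy_event, 1 - 0.25^11, tolerance = 1e-9)
  expect_identical(dec_eff$action, "stop_efficacy")
  expect_error(interim_decision(d, trial_state(51, 0)))
})

test_that("decisions are monotone in responders, and rules never both fire", {
  for (rule in c("posterior", "predictive")) {
    d <- trial_design(rule = rule)
    for (n in interim_schedule(d)) {
      actions <- vapply(0:n, function(r) {
        interim_decision(d, trial_state(n, r))$action
      }, character(1))
      fut <- which(actions == "stop_futility")
      eff <- which(actions == "stop_efficacy")
      # futility below some cutoff, efficacy above some cutoff
      if (length(fut) > 0) expect_identical(fut, seq_len(max(fut)))
      if (length(eff) > 0) expect_identical(eff, seq.int(min(eff), n + 1))
      if (length(fut) > 0 && length(eff) > 0) {
        expect_true(max(fut) < min(eff))
      }
      # with default thresholds the two events cannot fire simultaneously
      probs <- vapply(0:n, function(r) {
        dec <- interim_decision(d, trial_state(n, r))
        c(dec$prob_futility_event, dec$prob_efficacy_event)
      }, numeric(2))
      expect_false(any(probs[1, ] >= d$threshold_futility &
                         probs[2, ] >= d$threshold_efficacy))
    }
  }
})

test_that("predictive rule degenerates to the final criterion at n_max", {
  d <- trial_design(rule = "predictive")
  dec <- interim_decision(d, trial_state(50, 20))
  expect_identical(dec$prob_efficacy_event,
                   predictive_prob_success(d, trial_state(50, 20)))
})

test_that("interim_schedule covers first look to n_max", {
  expect_identical(interim_schedule(trial_design()),
                   as.integer(seq(10, 50, by = 5)))
  expect_identical(interim_schedule(trial_design(n_first_interim = 10,
                                                 n_max = 10)), 10L)
  expect_identical(
    interim_schedule(trial_design(n_first_interim = 4, cohort_step = 3,
                                  n_max = 10)),
    c(4L, 7L, 10L))
  # ragged step still ends at n_max
  expect_identical(
    interim_schedule(trial_design(n_first_interim = 10, cohort_step = 7,
                                  n_max = 20)),
    c(10L, 17L, 20L))
})

test_that("simulate_trial follows the rules and is reproducible", {
  d <- trial_design()
  # degenerate ORR = 0: futility triggers at the first closed-form crossing
  tr0 <- simulate_trial(d, 0, seed = 11)
  expect_identical(tr0$final_action, "stop_futility")
  expect_identical(tr0$final_n, 15L)
  expect_identical(tr0$final_r, 0L)
  # degenerate ORR = 1: efficacy at the first look
  tr1 <- simulate_trial(d, 1, seed = 11)
  expect_identical(tr1$final_action, "stop_efficacy")
  expect_identical(tr1$final_n, 10L)
  # determinism
  a <- simulate_trial(d, 0.2, seed = 42)
  b <- simulate_trial(d, 0.2, seed = 42)
  expect_identical(a$looks, b$looks)
  expect_identical(a$final_action, b$final_action)
  # the trial always ends at a scheduled look
  for (s in 1:20) {
    expect_true(simulate_trial(d, 0.15, seed = s)$final_n %in%
                  interim_schedule(d))
  }
})

test_that("operating characteristics are coherent and monotone in true ORR", {
  d <- trial_design()
  oc <- operating_characteristics(d, c(0.02, 0.10, 0.25, 0.6), n_sims = 200,
                                  seed = 7)
  sums <- oc$prob_stop_futility + oc$prob_stop_efficacy + oc$prob_run_to_n_max
  expect_equal(sums, rep(1, 4), tolerance = 1e-12)
  expect_true(all(oc$expected_n >= d$n_first_interim))
  expect_true(all(oc$expected_n <= d$n_max))
  # stage distribution sums to one
  stage_cols <- grep("^p_stop_at_", names(oc))
  expect_equal(rowSums(oc[stage_cols]), rep(1, 4), tolerance = 1e-12)
  # monotone within Monte-Carlo error (3 SE with n = 200 ~ 0.106)
  mc3se <- 3 * sqrt(0.25 / 200) * sqrt(2)
  expect_true(all(diff(oc$prob_stop_futility) <= mc3se))
  expect_true(all(diff(oc$prob_stop_efficacy) >= -mc3se))
  # extremes
  oc1 <- operating_characteristics(d, 1.0, n_sims = 50, seed = 3)
  expect_identical(oc1$prob_stop_efficacy, 1)
  expect_identical(oc1$expected_n, as.numeric(d$n_first_interim))
  # degenerate single-look design enrolls exactly n_first_interim
  d1 <- trial_design(n_first_interim = 10, n_max = 10)
  oc_d <- operating_characteristics(d1, 0.10, n_sims = 50, seed = 3)
  expect_identical(oc_d$expected_n, 10)
})

test_that("HPD interval is narrower than equal tails and holds the mass", {
  d <- trial_design(prior_alpha = 2, prior_beta = 3)
  eq <- update_posterior(d, trial_state(10, 3))
  hpd <- update_posterior(d, trial_state(10, 3), hpd = TRUE)
  expect_lt(hpd$ci_high - hpd$ci_low, eq$ci_high - eq$ci_low + 1e-12)
  mass <- stats::pbeta(hpd$ci_high, 5, 10) - stats::pbeta(hpd$ci_low, 5, 10)
  expect_equal(mass, 0.95, tolerance = 1e-6)
})
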