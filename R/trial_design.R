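# Beta-binomial adaptive design: posterior monitoring, stopping rules,
# trial simulation and operating characteristics.

#' Define a beta-binomial adaptive phase-II design
#'
#' Encapsulates every constant of the single-arm Bayesian monitoring scheme:
#' a conjugate Beta prior on the objective response rate (ORR), the null and
#' alternative response rates, the stopping thresholds, and the interim
#' schedule (a first look after `n_first_interim` evaluable patients, then
#' one look per additional `cohort_step` patients up to `n_max`).
#'
#' Two readings of the stopping rule are supported via `rule`:
#' `"posterior"` compares posterior tail probabilities
#' \eqn{P(p \le p_{fut} \mid data)} and \eqn{P(p \ge p_{eff} \mid data)}
#' directly against the thresholds (the literal event reading), while
#' `"predictive"` marginalises over all future patients up to `n_max` and
#' asks how likely the trial is to *conclude* futility or efficacy at its
#' final analysis (the textbook predictive-probability design).
#'
#' @param prior_alpha,prior_beta Positive shape parameters of the Beta prior
#'   (pseudo-responders / pseudo-non-responders). Default `Beta(1, 1)`.
#' @param p_futility Null response rate; the futility event is
#'   \eqn{p \le p_futility}. Default 0.10.
#' @param p_efficacy Target response rate; the efficacy event is
#'   \eqn{p \ge p_efficacy}. Default 0.25.
#' @param threshold_futility,threshold_efficacy Probability thresholds that
#'   trigger stopping. Default 0.80 each.
#' @param n_first_interim Evaluable patients at the first look. Default 10.
#' @param cohort_step Additional patients between looks. Default 5.
#' @param n_max Maximum evaluable sample size. Default 50.
#' @param evaluation_window_weeks Observation window before a patient counts
#'   as evaluable at an interim (gates timing only, not the mathematics).
#'   Default 16.
#' @param rule Stopping-rule interpretation, `"posterior"` (default) or
#'   `"predictive"`.
#' @return An object of class `trial_design`.
#' @examples
#' d <- trial_design()
#' interim_schedule(d)
#' @export
trial_design <- function(prior_alpha = 1, prior_beta = 1,
                         p_futility = 0.10, p_efficacy = 0.25,
                         threshold_futility = 0.80, threshold_efficacy = 0.80,
                         n_first_interim = 10, cohort_step = 5, n_max = 50,
                         evaluation_window_weeks = 16,
                         rule = c("posterior", "predictive")) {
  rule <- match.arg(rule)
  stopifnot(
    prior_alpha > 0, prior_beta > 0,
    p_futility > 0, p_efficacy < 1, p_futility < p_efficacy,
    threshold_futility >= 0.5, threshold_futility < 1,
    threshold_efficacy >= 0.5, threshold_efficacy < 1,
    n_first_interim >= 1, n_first_interim <= n_max,
    cohort_step >= 1, evaluation_window_weeks >= 0
  )
  structure(
    list(prior_alpha = prior_alpha, prior_beta = prior_beta,
         p_futility = p_futility, p_efficacy = p_efficacy,
         threshold_futility = threshold_futility,
         threshold_efficacy = threshold_efficacy,
         n_first_interim = as.integer(n_first_interim),
         cohort_step = as.integer(cohort_step),
         n_max = as.integer(n_max),
         evaluation_window_weeks = evaluation_window_weeks,
         rule = rule),
    class = "trial_design"
  )
}

#' @export
print.trial_design <- function(x, ...) {
  cat("Beta-binomial adaptive design\n")
  cat(sprintf("  prior: Beta(%g, %g)\n", x$prior_alpha, x$prior_beta))
  cat(sprintf("  futility: P(p <= %g) >= %g   efficacy: P(p >= %g) >= %g\n",
              x$p_futility, x$threshold_futility,
              x$p_efficacy, x$threshold_efficacy))
  cat(sprintf("  looks at n = %s (rule: %s)\n",
              paste(interim_schedule(x), collapse = ", "), x$rule))
  invisible(x)
}

#' Accumulated trial state
#'
#' Number of evaluable patients and observed responders at an analysis.
#'
#' @param n_evaluable Non-negative integer count of evaluable patients.
#' @param n_responders Integer count of objective responders,
#'   `0 <= n_responders <= n_evaluable`.
#' @return An object of class `trial_state`.
#' @export
trial_state <- function(n_evaluable, n_responders) {
  n_evaluable <- as.integer(n_evaluable)
  n_responders <- as.integer(n_responders)
  if (is.na(n_evaluable) || is.na(n_responders) || n_evaluable < 0 ||
      n_responders < 0 || n_responders > n_evaluable) {
    stop("invalid trial state: need 0 <= n_responders <= n_evaluable")
  }
  structure(list(n_evaluable = n_evaluable, n_responders = n_responders),
            class = "trial_state")
}

#' Conjugate posterior for the objective response rate
#'
#' Updates the design's Beta prior with the observed responder counts:
#' `Beta(prior_alpha + r, prior_beta + n - r)`. Summaries are the posterior
#' mean and an equal-tailed credible interval (highest-posterior-density
#' interval available via `hpd = TRUE`).
#'
#' @param design A [trial_design].
#' @param state A [trial_state] (or anything accepted by [trial_state] when
#'   given as `list(n_evaluable, n_responders)`).
#' @param ci_level Credible level, default 0.95.
#' @param hpd If `TRUE`, report the highest-posterior-density interval
#'   instead of equal tails.
#' @return A `beta_posterior` object with fields `alpha_post`, `beta_post`,
#'   `mean`, `ci_low`, `ci_high`, `ci_level`.
#' @examples
#' update_posterior(trial_design(), trial_state(43, 4))
#' @export
update_posterior <- function(design, state, ci_level = 0.95, hpd = FALSE) {
  stopifnot(inherits(design, "trial_design"), ci_level > 0, ci_level < 1)
  state <- as_trial_state(state)
  a <- design$prior_alpha + state$n_responders
  b <- design$prior_beta + state$n_evaluable - state$n_responders
  lo <- (1 - ci_level) / 2
  if (hpd) {
    ci <- beta_hpd(a, b, ci_level)
  } else {
    ci <- c(stats::qbeta(lo, a, b), stats::qbeta(1 - lo, a, b))
  }
  structure(
    list(alpha_post = a, beta_post = b, mean = a / (a + b),
         ci_low = ci[1], ci_high = ci[2], ci_level = ci_level),
    class = "beta_posterior"
  )
}

as_trial_state <- function(state) {
  if (inherits(state, "trial_state")) return(state)
  if (is.list(state) && all(c("n_evaluable", "n_responders") %in% names(state)))
    return(trial_state(state$n_evaluable, state$n_responders))
  stop("`state` must be a trial_state")
}

# Shortest interval with the requested posterior mass, by optimising the
# lower tail probability. Falls back to equal tails for flat cases.
beta_hpd <- function(a, b, level) {
  if (a <= 1 && b <= 1) {  # flat or U-shaped: HPD ill-defined, use equal tails
    lo <- (1 - level) / 2
    return(c(stats::qbeta(lo, a, b), stats::qbeta(1 - lo, a, b)))
  }
  width <- function(lo_p) {
    stats::qbeta(lo_p + level, a, b) - stats::qbeta(lo_p, a, b)
  }
  opt <- stats::optimize(width, c(0, 1 - level))
  c(stats::qbeta(opt$minimum, a, b), stats::qbeta(opt$minimum + level, a, b))
}

#' @export
print.beta_posterior <- function(x, ...) {
  cat(sprintf("Beta(%g, %g) posterior: mean %.3f, %g%% CrI (%.3f, %.3f)\n",
              x$alpha_post, x$beta_post, x$mean, 100 * x$ci_level,
              x$ci_low, x$ci_high))
  invisible(x)
}

#' Posterior tail probability of the response rate
#'
#' \eqn{P(p \le t \mid data)} or \eqn{P(p \ge t \mid data)} under a
#' `beta_posterior`. The law is continuous so the two directions sum to 1.
#'
#' @param posterior A `beta_posterior` from [update_posterior].
#' @param threshold Response-rate threshold in `[0, 1]`.
#' @param direction `"at_most"` or `"at_least"`.
#' @return A probability.
#' @export
posterior_tail_prob <- function(posterior, threshold,
                                direction = c("at_most", "at_least")) {
  direction <- match.arg(direction)
  stopifnot(inherits(posterior, "beta_posterior"),
            threshold >= 0, threshold <= 1)
  p <- stats::pbeta(threshold, posterior$alpha_post, posterior$beta_post)
  if (direction == "at_most") p else 1 - p
}

# Beta-binomial pmf for k future responders out of m, given posterior (a, b).
beta_binom_pmf <- function(k, m, a, b) {
  exp(lchoose(m, k) + lbeta(a + k, b + m - k) - lbeta(a, b))
}

# Predictive probability that the final analysis at n_max declares the
# given event. `direction` "at_least" with p_efficacy/threshold_efficacy is
# the usual probability of success; "at_most" is its futility mirror.
predictive_prob_event <- function(design, state, direction) {
  n <- state$n_evaluable; r <- state$n_responders
  m <- design$n_max - n
  if (m < 0) stop("state exceeds the design's maximum sample size")
  a <- design$prior_alpha + r
  b <- design$prior_beta + n - r
  k <- 0:m
  pmf <- beta_binom_pmf(k, m, a, b)
  if (direction == "at_least") {
    tail <- 1 - stats::pbeta(design$p_efficacy, a + k, b + (m - k))
    meets <- tail >= design$threshold_efficacy
  } else {
    tail <- stats::pbeta(design$p_futility, a + k, b + (m - k))
    meets <- tail >= design$threshold_futility
  }
  sum(pmf[meets])
}

#' Predictive probability of final success
#'
#' With `m = n_max - n` patients still to be observed, marginalises the
#' number of future responders over the beta-binomial posterior predictive
#' and returns the probability that the *final* posterior at `n_max`
#' satisfies the efficacy criterion
#' \eqn{P(p \ge p_{eff} \mid data) \ge threshold_{eff}}. At `n = n_max`
#' this degenerates to the 0/1 indicator of the final criterion.
#'
#' @inheritParams update_posterior
#' @return A probability.
#' @examples
#' d <- trial_design(n_max = 15)
#' predictive_prob_success(d, trial_state(10, 2))
#' @export
predictive_prob_success <- function(design, state) {
  stopifnot(inherits(design, "trial_design"))
  state <- as_trial_state(state)
  predictive_prob_event(design, state, "at_least")
}

#' Interim stopping decision
#'
#' Evaluates both stopping events at the current state and applies the
#' design thresholds, futility first (conservative precedence; with the
#' default thresholds both events cannot fire simultaneously at any
#' scheduled look).
#'
#' Under `rule = "posterior"` the event probabilities are posterior tail
#' probabilities; under `rule = "predictive"` they are end-of-trial
#' predictive probabilities that the final analysis declares the event.
#'
#' @inheritParams update_posterior
#' @return An `interim_decision` object: `action` (one of `"continue"`,
#'   `"stop_futility"`, `"stop_efficacy"`), `prob_futility_event`,
#'   `prob_efficacy_event`, `interim_n`.
#' @examples
#' d <- trial_design()
#' interim_decision(d, trial_state(15, 0))  # stops for futility
#' @export
interim_decision <- function(design, state) {
  stopifnot(inherits(design, "trial_design"))
  state <- as_trial_state(state)
  if (state$n_evaluable > design$n_max) {
    stop("state exceeds the design's maximum sample size")
  }
  if (design$rule == "posterior") {
    post <- update_posterior(design, state)
    p_fut <- posterior_tail_prob(post, design$p_futility, "at_most")
    p_eff <- posterior_tail_prob(post, design$p_efficacy, "at_least")
  } else {
    p_fut <- predictive_prob_event(design, state, "at_most")
    p_eff <- predictive_prob_event(design, state, "at_least")
  }
  action <- if (p_fut >= design$threshold_futility) {
    "stop_futility"
  } else if (p_eff >= design$threshold_efficacy) {
    "stop_efficacy"
  } else {
    "continue"
  }
  structure(
    list(action = action, prob_futility_event = p_fut,
         prob_efficacy_event = p_eff, interim_n = state$n_evaluable),
    class = "interim_decision"
  )
}

#' @export
print.interim_decision <- function(x, ...) {
  cat(sprintf("n = %d: %s  [P(futility event) = %.3f, P(efficacy event) = %.3f]\n",
              x$interim_n, x$action, x$prob_futility_event,
              x$prob_efficacy_event))
  invisible(x)
}

#' Scheduled interim sample sizes
#'
#' `n_first_interim, n_first_interim + cohort_step, ...` capped at and always
#' ending with `n_max`.
#'
#' @param design A [trial_design].
#' @return Integer vector of evaluable sample sizes at each look.
#' @export
interim_schedule <- function(design) {
  stopifnot(inherits(design, "trial_design"))
  looks <- seq.int(design$n_first_interim, design$n_max, by = design$cohort_step)
  if (looks[length(looks)] != design$n_max) looks <- c(looks, design$n_max)
  as.integer(looks)
}

#' Simulate one trial trajectory
#'
#' Draws `n_max` i.i.d. Bernoulli(`true_orr`) responses, then walks the
#' interim schedule applying [interim_decision] at each look until the trial
#' stops or reaches the final analysis.
#'
#' @param design A [trial_design].
#' @param true_orr True response probability in `[0, 1]`.
#' @param seed Integer seed; the trajectory is reproducible given the seed.
#' @return A `trial_trajectory`: data frame `looks` (one row per performed
#'   look with `n`, `r`, action and event probabilities), `final_action`
#'   (`"stop_futility"`, `"stop_efficacy"` or `"max_n_reached"`), `final_n`,
#'   `final_r`.
#' @export
simulate_trial <- function(design, true_orr, seed) {
  stopifnot(inherits(design, "trial_design"), true_orr >= 0, true_orr <= 1)
  responses <- withr_seed(seed, function() {
    stats::rbinom(design$n_max, 1L, true_orr)
  })
  simulate_trial_responses(design, responses)
}

# Deterministic walk over a fixed 0/1 response vector of length n_max.
simulate_trial_responses <- function(design, responses) {
  schedule <- interim_schedule(design)
  cum_r <- cumsum(responses)
  looks <- vector("list", length(schedule))
  final_action <- "max_n_reached"
  final_n <- design$n_max
  for (i in seq_along(schedule)) {
    n <- schedule[i]
    r <- cum_r[n]
    dec <- interim_decision(design, trial_state(n, r))
    looks[[i]] <- data.frame(
      n = n, r = r, action = dec$action,
      prob_futility_event = dec$prob_futility_event,
      prob_efficacy_event = dec$prob_efficacy_event
    )
    if (dec$action != "continue") {
      final_action <- dec$action
      final_n <- n
      looks <- looks[seq_len(i)]
      break
    }
  }
  looks <- do.call(rbind, looks)
  structure(
    list(looks = looks, final_action = final_action,
         final_n = final_n, final_r = cum_r[final_n]),
    class = "trial_trajectory"
  )
}

# Run `fn` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. Counter-based seeding keeps simulated trials
# independent of evaluation order.
withr_seed <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  fn()
}

#' Operating characteristics of the design
#'
#' Monte-Carlo frequencies of futility stops, efficacy stops and full
#' enrollment, the expected sample size, and the stopping-stage distribution,
#' over a grid of true response rates. Trial `i` at grid point `g` uses seed
#' `seed + (g - 1) * n_sims + i`, so results are reproducible and independent
#' of evaluation order.
#'
#' @param design A [trial_design].
#' @param orr_grid Vector of true response probabilities.
#' @param n_sims Simulated trials per grid point.
#' @param seed Integer base seed.
#' @return A data frame of class `operating_characteristics` with one row per
#'   grid point: `true_orr`, `n_sims`, `prob_stop_futility`,
#'   `prob_stop_efficacy`, `prob_run_to_n_max`, `expected_n`, plus one
#'   `p_stop_at_<n>` column per scheduled look giving the probability the
#'   trial ends at that look.
#' @export
operating_characteristics <- function(design, orr_grid, n_sims, seed = 1L) {
  stopifnot(inherits(design, "trial_design"), n_sims >= 1,
            all(orr_grid >= 0), all(orr_grid <= 1))
  schedule <- interim_schedule(design)
  rows <- lapply(seq_along(orr_grid), function(g) {
    orr <- orr_grid[g]
    final_n <- integer(n_sims)
    final_action <- character(n_sims)
    for (i in seq_len(n_sims)) {
      tr <- simulate_trial(design, orr, seed + (g - 1L) * n_sims + i)
      final_n[i] <- tr$final_n
      final_action[i] <- tr$final_action
    }
    stage <- vapply(schedule, function(n) {
      mean(final_n == n & final_action != "max_n_reached")
    }, numeric(1))
    # trials reaching n_max (stopped there or run to completion) end at n_max
    stage[length(stage)] <- mean(final_n == design$n_max)
    out <- data.frame(
      true_orr = orr, n_sims = n_sims,
      prob_stop_futility = mean(final_action == "stop_futility"),
      prob_stop_efficacy = mean(final_action == "stop_efficacy"),
      prob_run_to_n_max = mean(final_action == "max_n_reached"),
      expected_n = mean(final_n)
    )
    stage_df <- as.data.frame(as.list(stage))
    names(stage_df) <- paste0("p_stop_at_", schedule)
    cbind(out, stage_df)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("operating_characteristics", class(out))
  out
}
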