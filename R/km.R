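# Kaplan-Meier estimation. The product-limit computation itself is delegated
# to survival::survfit (the field-standard implementation, with events
# processed before censorings at tied times); this file owns the curve
# container, the median convention (smallest t with S(t) <= 0.5) and the
# log(-log) confidence machinery for medians and milestones.

#' Fit a Kaplan-Meier curve
#'
#' Product-limit estimate \eqn{\hat S(t) = \prod_{t_i \le t} (1 - d_i/n_i)}
#' with Greenwood standard errors and pointwise confidence bands.
#'
#' @param time Non-negative follow-up times (months are the package's
#'   canonical unit, but any unit works).
#' @param event Event indicator: 1/TRUE = event observed, 0/FALSE = censored.
#' @param conf_level Pointwise confidence level, default 0.95.
#' @param conf_type Band transformation: `"log-log"` (default; bands stay in
#'   `[0, 1]` and drive the median CI) or `"linear"` (plain Greenwood).
#' @param endpoint Optional label (`"PFS"`, `"OS"`, `"DOR"`, ...) carried in
#'   the result.
#' @return A `km_curve`: data frame `steps` with columns `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`, `se` (Greenwood SE of S), `lower`,
#'   `upper`; plus attributes `n`, `conf_level`, `conf_type`, `endpoint`.
#' @examples
#' km_fit(c(1, 2, 3), c(1, 1, 1))
#' @export
km_fit <- function(time, event, conf_level = 0.95,
                   conf_type = c("log-log", "linear"), endpoint = NULL) {
  conf_type <- match.arg(conf_type)
  if (length(time) == 0) stop("no observations")
  if (any(!is.finite(time)) || any(time < 0)) {
    stop("follow-up times must be finite and non-negative")
  }
  event <- as.integer(as.logical(event))
  if (length(event) != length(time)) stop("time and event lengths differ")
  st <- if (conf_type == "log-log") "log-log" else "plain"
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.int = conf_level, conf.type = st)
  # survfit returns NA bands where S = 1 (degenerate: band is {1}) and where
  # S = 0 (log-log undefined: keep the upper limit NA = "no information",
  # matching survfit's own median-CI convention).
  lower <- fit$lower
  upper <- fit$upper
  lower[is.na(lower)] <- ifelse(fit$surv[is.na(lower)] == 1, 1, 0)
  upper[is.na(upper) & fit$surv == 1] <- 1
  steps <- data.frame(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, surv = fit$surv,
    se = fit$surv * fit$std.err,   # survfit std.err is on the log scale
    lower = lower, upper = upper
  )
  structure(
    list(steps = steps, n = length(time), conf_level = conf_level,
         conf_type = conf_type, endpoint = endpoint),
    class = "km_curve"
  )
}

#' @export
print.km_curve <- function(x, ...) {
  med <- km_median(x)
  cat(sprintf("Kaplan-Meier curve (%s), n = %d, %d events\n",
              if (is.null(x$endpoint)) "unlabelled" else x$endpoint,
              x$n, sum(x$steps$n_event)))
  cat(sprintf("  median: %s (%g%% CI %s-%s)\n",
              fmt_nr(med$median), 100 * x$conf_level,
              fmt_nr(med$ci_low), fmt_nr(med$ci_high)))
  invisible(x)
}

fmt_nr <- function(v) if (is.na(v)) "NR" else format(round(v, 2))

# Step-function lookup: S(t) and band values at arbitrary times.
km_step_at <- function(curve, t, col = "surv") {
  s <- curve$steps
  vapply(t, function(ti) {
    idx <- which(s$time <= ti)
    if (length(idx) == 0) {
      if (col == "surv") 1 else if (col == "se") 0 else
        if (col == "lower") 1 else 1
    } else {
      s[[col]][max(idx)]
    }
  }, numeric(1))
}

#' Median survival with confidence interval
#'
#' Median = smallest observed time with \eqn{\hat S(t) \le 0.5}; `NA`
#' ("not reached") if the curve never drops to 0.5. The confidence interval
#' inverts the pointwise band (Brookmeyer-Crowley style): the lower bound is
#' the first time the lower band reaches 0.5, the upper bound the first time
#' the upper band does; either may be not reached.
#'
#' @param curve A `km_curve` from [km_fit].
#' @return List with `median`, `ci_low`, `ci_high` (each `NA` when not
#'   reached) and `not_reached` flag for the point estimate.
#' @export
km_median <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  med <- km_quantile_time(curve, "surv")
  list(median = med,
       ci_low = km_quantile_time(curve, "lower"),
       ci_high = km_quantile_time(curve, "upper"),
       not_reached = is.na(med))
}

# First time the given curve column drops to <= 0.5 (with a numerical
# tolerance so an exact 0.5 step counts). NA band values carry no
# information and never count as a crossing.
km_quantile_time <- function(curve, col, q = 0.5) {
  s <- curve$steps
  hit <- which(!is.na(s[[col]]) & s[[col]] <= q + 1e-12)
  if (length(hit) == 0) NA_real_ else s$time[min(hit)]
}

#' Milestone survival estimate
#'
#' \eqn{\hat S(t)} at a landmark time with its pointwise confidence band.
#' Before the first event the estimate is 1 with a degenerate interval.
#' A landmark beyond the last follow-up time returns the last value with
#' `truncated = TRUE`.
#'
#' @param curve A `km_curve`.
#' @param t Landmark time (same unit as the fit), `t >= 0`.
#' @return List with `time`, `estimate`, `ci_low`, `ci_high`, `se`,
#'   `truncated`.
#' @examples
#' km_milestone(km_fit(c(1, 2, 3, 4), rep(1, 4)), 2.5)
#' @export
km_milestone <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"), t >= 0)
  truncated <- t > max(curve$steps$time)
  if (truncated) {
    warning("landmark time beyond last follow-up; estimate is truncated")
  }
  est <- km_step_at(curve, t, "surv")
  list(time = t, estimate = est,
       ci_low = if (est == 1) 1 else km_step_at(curve, t, "lower"),
       ci_high = if (est == 1) 1 else km_step_at(curve, t, "upper"),
       se = km_step_at(curve, t, "se"),
       truncated = truncated)
}
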