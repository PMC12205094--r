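# Synthetic trial cohorts and paired cell maps. The defaults emulate the
# published cohort: ~50 patients, true ORR near 10%, median PFS 1.8 months,
# median OS 15.1 months, median duration of response 7.8 months, and seven
# paired baseline/C2D1 biopsies with treatment-shifted immune densities.

#' Cohort-generation scenario
#'
#' Describes the stochastic world the cohort generator draws from. Survival
#' is exponential (single-parameter, pinned to the stated medians):
#' non-responders progress at a rate calibrated so that the *marginal* PFS
#' median equals `pfs_median_months` once responders (whose PFS is response
#' onset + duration of response) are mixed in; overall survival is PFS plus
#' an independent exponential residual calibrated to the marginal OS median,
#' which guarantees OS >= PFS patient by patient. Patients accrue uniformly
#' at `accrual_rate`; administrative censoring is applied at database lock,
#' `censor_admin_months` after the end of accrual. Response is assessed on
#' an 8-week schedule, so responders' onset is fixed at the first
#' assessment.
#'
#' @param n_patients Cohort size, default 50.
#' @param true_orr True objective response probability, default 0.10
#'   (must be `< 0.5` so the median calibration is well defined).
#' @param accrual_rate Patients per month, default 1.85 (50 patients over
#'   ~27 months).
#' @param pfs_median_months Marginal PFS median, default 1.8.
#' @param os_median_months Marginal OS median, default 15.1.
#' @param dor_median_months Median duration of response among responders,
#'   default 7.8.
#' @param prior_pfs_meanlog,prior_pfs_sdlog Log-normal parameters of the
#'   prior-line PFS used for the growth-modulation index, defaults
#'   `log(3)` and 0.8 (median 3 months).
#' @param censor_admin_months Months between the end of accrual and the
#'   database lock, default 7.
#' @param prob_evaluable Probability a patient is evaluable for the primary
#'   endpoint, default 0.86 (43/50).
#' @param seed Integer seed.
#' @return A `cohort_scenario` object (list of the above plus the calibrated
#'   rates `rate_nonresponder_pfs`, `rate_dor`, `rate_os_residual`, and
#'   `onset_months`).
#' @export
cohort_scenario <- function(n_patients = 50, true_orr = 0.10,
                            accrual_rate = 1.85,
                            pfs_median_months = 1.8,
                            os_median_months = 15.1,
                            dor_median_months = 7.8,
                            prior_pfs_meanlog = log(3),
                            prior_pfs_sdlog = 0.8,
                            censor_admin_months = 7,
                            prob_evaluable = 0.86,
                            seed = 1L) {
  stopifnot(n_patients >= 1, true_orr >= 0, true_orr < 0.5,
            accrual_rate > 0, pfs_median_months > 0, dor_median_months > 0,
            censor_admin_months > 0, prob_evaluable > 0, prob_evaluable <= 1)
  if (os_median_months <= pfs_median_months) {
    stop("os_median_months must exceed pfs_median_months")
  }
  onset <- 8 * 7 / DAYS_PER_MONTH  # first tumor assessment (8 weeks), months
  rate_dor <- log(2) / dor_median_months
  sc <- list(n_patients = as.integer(n_patients), true_orr = true_orr,
             accrual_rate = accrual_rate,
             pfs_median_months = pfs_median_months,
             os_median_months = os_median_months,
             dor_median_months = dor_median_months,
             prior_pfs_meanlog = prior_pfs_meanlog,
             prior_pfs_sdlog = prior_pfs_sdlog,
             censor_admin_months = censor_admin_months,
             prob_evaluable = prob_evaluable,
             onset_months = onset, rate_dor = rate_dor,
             seed = as.integer(seed))
  sc$rate_nonresponder_pfs <- calibrate_pfs_rate(sc)
  sc$rate_os_residual <- calibrate_os_rate(sc)
  class(sc) <- "cohort_scenario"
  sc
}

# Survival function of a responder's PFS (= fixed onset + exponential DOR).
responder_pfs_survival <- function(sc, t) {
  ifelse(t <= sc$onset_months, 1, exp(-sc$rate_dor * (t - sc$onset_months)))
}

# Marginal PFS survival given a candidate non-responder rate.
pfs_survival_rate <- function(sc, t, rate_nr) {
  (1 - sc$true_orr) * exp(-rate_nr * t) +
    sc$true_orr * responder_pfs_survival(sc, t)
}

# Non-responder progression rate such that the cohort PFS median equals the
# stated value.
calibrate_pfs_rate <- function(sc) {
  g <- function(rate) pfs_survival_rate(sc, sc$pfs_median_months, rate) - 0.5
  stats::uniroot(g, c(1e-8, 100), tol = 1e-12)$root
}

#' True marginal PFS survival function of a cohort scenario
#'
#' Closed-form \eqn{S(t)} of the generator's PFS mixture; the oracle the
#' recovery tests compare Kaplan-Meier estimates against.
#'
#' @param scenario A [cohort_scenario].
#' @param t Time(s) in months.
#' @return Survival probabilities.
#' @export
true_pfs_survival <- function(scenario, t) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  pfs_survival_rate(scenario, t, scenario$rate_nonresponder_pfs)
}

# Marginal OS survival for a candidate residual rate: OS = PFS + Exp(rate).
# S_OS(t) = S_PFS(t) + int_0^t f_PFS(u) exp(-rate (t-u)) du, by quadrature.
os_survival_rate <- function(sc, t, rate) {
  rate_nr <- sc$rate_nonresponder_pfs
  f_pfs <- function(u) {
    (1 - sc$true_orr) * rate_nr * exp(-rate_nr * u) +
      sc$true_orr * ifelse(u <= sc$onset_months, 0,
                           sc$rate_dor * exp(-sc$rate_dor * (u - sc$onset_months)))
  }
  vapply(t, function(ti) {
    conv <- stats::integrate(function(u) f_pfs(u) * exp(-rate * (ti - u)),
                             0, ti, rel.tol = 1e-9)$value
    true_pfs_survival_raw(sc, ti) + conv
  }, numeric(1))
}

true_pfs_survival_raw <- function(sc, t) {
  pfs_survival_rate(sc, t, sc$rate_nonresponder_pfs)
}

calibrate_os_rate <- function(sc) {
  g <- function(rate) os_survival_rate(sc, sc$os_median_months, rate) - 0.5
  stats::uniroot(g, c(1e-6, 10), tol = 1e-10)$root
}

#' True marginal OS survival function of a cohort scenario
#'
#' @inheritParams true_pfs_survival
#' @return Survival probabilities.
#' @export
true_os_survival <- function(scenario, t) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  os_survival_rate(scenario, t, scenario$rate_os_residual)
}

#' Generate a synthetic trial cohort
#'
#' Draws one patient table from a [cohort_scenario], reproducibly from its
#' seed. Responses are i.i.d. Bernoulli(`true_orr`); responders' PFS is
#' onset + exponential duration of response, non-responders' PFS is
#' exponential at the calibrated rate; OS adds an exponential residual;
#' uniform accrual plus a database lock yields administrative censoring.
#' Best overall response is `PR` for responders, `SD` for non-responders
#' progressing after the first assessment, `PD` otherwise, `NE` for
#' non-evaluable patients. Histology labels are cosmetic (sampled from the
#' cohort mix: 45% leiomyosarcoma, 18% synovial sarcoma, rest other).
#'
#' @param scenario A [cohort_scenario].
#' @return Data frame in the patient-table schema: `patient_id`,
#'   `histology`, `evaluable_efficacy`, `bor`, `response_onset_months`,
#'   `pfs_months`, `pfs_event`, `os_months`, `os_event`,
#'   `prior_pfs_months`. Times are rounded to 4 decimals so written CSVs
#'   are byte-stable.
#' @examples
#' head(generate_cohort(cohort_scenario(seed = 7)))
#' @export
generate_cohort <- function(scenario) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  sc <- scenario
  withr_seed(sc$seed, function() {
    n <- sc$n_patients
    responder <- stats::rbinom(n, 1L, sc$true_orr) == 1
    evaluable <- stats::rbinom(n, 1L, sc$prob_evaluable)
    pfs_true <- numeric(n)
    pfs_true[!responder] <- stats::rexp(sum(!responder),
                                        sc$rate_nonresponder_pfs)
    dor_true <- stats::rexp(sum(responder), sc$rate_dor)
    pfs_true[responder] <- sc$onset_months + dor_true
    os_true <- pfs_true + stats::rexp(n, sc$rate_os_residual)

    accrual_len <- n / sc$accrual_rate
    entry <- stats::runif(n, 0, accrual_len)
    follow <- accrual_len + sc$censor_admin_months - entry

    pfs_event <- as.integer(pfs_true <= follow)
    pfs_obs <- pmin(pfs_true, follow)
    os_event <- as.integer(os_true <= follow)
    os_obs <- pmin(os_true, follow)

    onset <- ifelse(responder & sc$onset_months <= follow,
                    sc$onset_months, NA_real_)
    # responder whose response was never observed before lock: no response
    seen_response <- responder & !is.na(onset)
    bor <- ifelse(seen_response, "PR",
                  ifelse(pfs_obs > sc$onset_months, "SD", "PD"))
    bor[evaluable == 0] <- "NE"

    histology <- sample(c("leiomyosarcoma", "synovial sarcoma", "other"),
                        n, replace = TRUE, prob = c(0.45, 0.18, 0.37))
    prior_pfs <- stats::rlnorm(n, sc$prior_pfs_meanlog, sc$prior_pfs_sdlog)

    data.frame(
      patient_id = sprintf("P%03d", seq_len(n)),
      histology = histology,
      evaluable_efficacy = evaluable,
      bor = bor,
      response_onset_months = round(onset, 4),
      pfs_months = round(pfs_obs, 4),
      pfs_event = pfs_event,
      os_months = round(os_obs, 4),
      os_event = os_event,
      prior_pfs_months = round(prior_pfs, 4),
      stringsAsFactors = FALSE
    )
  })
}

#' Spatial (paired biopsy) scenario
#'
#' Describes the point-process world behind the paired cell maps: per
#' patient a shared log-normal abundance effect, Poisson cell counts at the
#' baseline densities pre-treatment and at `post_fold_change` times those
#' densities on treatment, uniform (or Thomas-clustered) coordinates in a
#' square region, and PD-1 flags assigned to T cells at the configured
#' fractions.
#'
#' @param n_pairs Number of patients with paired biopsies, default 7.
#' @param area_mm2 Region area per map, default 1.
#' @param baseline_density_per_mm2 Named vector of expected baseline
#'   densities (cells/mm^2); default
#'   `c(CD8 = 150, CD4 = 200, CD20 = 100, CD163 = 300)`.
#' @param post_fold_change Named vector of on-treatment density
#'   multipliers; default `c(CD8 = 2, CD4 = 1.5, CD20 = 1.8, CD163 = 1.5)`
#'   (immune infiltration increases on treatment).
#' @param clustering Thomas-process parent intensity per mm^2; 0 (default)
#'   gives a homogeneous Poisson pattern.
#' @param cluster_sd_um Offspring dispersion of the Thomas process, default
#'   30.
#' @param pd1_fraction_pre,pd1_fraction_post PD-1-positive fraction of T
#'   cells at baseline / on treatment, defaults 0.20 / 0.35.
#' @param patient_sd_log SD of the per-patient log abundance effect shared
#'   by both timepoints, default 0.4.
#' @param seed Integer seed.
#' @return A `spatial_scenario` object.
#' @export
spatial_scenario <- function(n_pairs = 7, area_mm2 = 1,
                             baseline_density_per_mm2 =
                               c(CD8 = 150, CD4 = 200, CD20 = 100, CD163 = 300),
                             post_fold_change =
                               c(CD8 = 2, CD4 = 1.5, CD20 = 1.8, CD163 = 1.5),
                             clustering = 0, cluster_sd_um = 30,
                             pd1_fraction_pre = 0.20,
                             pd1_fraction_post = 0.35,
                             patient_sd_log = 0.4,
                             seed = 1L) {
  stopifnot(n_pairs >= 1, area_mm2 > 0,
            all(baseline_density_per_mm2 >= 0),
            all(post_fold_change > 0), clustering >= 0,
            pd1_fraction_pre >= 0, pd1_fraction_pre <= 1,
            pd1_fraction_post >= 0, pd1_fraction_post <= 1,
            patient_sd_log >= 0)
  check_phenotype(names(baseline_density_per_mm2))
  stopifnot(all(names(post_fold_change) %in% names(baseline_density_per_mm2)))
  structure(
    list(n_pairs = as.integer(n_pairs), area_mm2 = area_mm2,
         baseline_density_per_mm2 = baseline_density_per_mm2,
         post_fold_change = post_fold_change,
         clustering = clustering, cluster_sd_um = cluster_sd_um,
         pd1_fraction_pre = pd1_fraction_pre,
         pd1_fraction_post = pd1_fraction_post,
         patient_sd_log = patient_sd_log, seed = as.integer(seed)),
    class = "spatial_scenario"
  )
}

# One point pattern for one phenotype: homogeneous Poisson, or a Thomas
# cluster process (parents Poisson(clustering * area), Gaussian offspring
# clamped to the window).
draw_points <- function(n_cells, side_um, clustering, cluster_sd, area_mm2) {
  if (n_cells == 0) {
    return(data.frame(x_um = numeric(0), y_um = numeric(0)))
  }
  if (clustering <= 0) {
    return(data.frame(x_um = stats::runif(n_cells, 0, side_um),
                      y_um = stats::runif(n_cells, 0, side_um)))
  }
  n_parents <- max(1L, stats::rpois(1, clustering * area_mm2))
  px <- stats::runif(n_parents, 0, side_um)
  py <- stats::runif(n_parents, 0, side_um)
  pick <- sample.int(n_parents, n_cells, replace = TRUE)
  data.frame(
    x_um = pmin(pmax(px[pick] + stats::rnorm(n_cells, 0, cluster_sd), 0),
                side_um),
    y_um = pmin(pmax(py[pick] + stats::rnorm(n_cells, 0, cluster_sd), 0),
                side_um)
  )
}

#' Generate paired synthetic cell maps
#'
#' Draws `n_pairs` baseline/C2D1 [cell_map] pairs from a
#' [spatial_scenario], reproducibly from its seed.
#'
#' @param scenario A [spatial_scenario].
#' @return List with `maps` (list of `cell_map`, two per patient), `cells`
#'   (long data frame in the cells-CSV schema) and `samples` (one row per
#'   map with `sample_id`, `patient_id`, `timepoint`, `area_mm2`).
#' @examples
#' out <- generate_cell_maps(spatial_scenario(n_pairs = 2, seed = 3))
#' length(out$maps)
#' @export
generate_cell_maps <- function(scenario) {
  stopifnot(inherits(scenario, "spatial_scenario"))
  sc <- scenario
  side <- sqrt(sc$area_mm2) * 1000  # window side in micrometres
  withr_seed(sc$seed, function() {
    maps <- list()
    for (p in seq_len(sc$n_pairs)) {
      pid <- sprintf("P%03d", p)
      effect <- exp(stats::rnorm(1, 0, sc$patient_sd_log))
      for (tp in c("baseline", "C2D1")) {
        rows <- lapply(names(sc$baseline_density_per_mm2), function(ph) {
          fc <- if (tp == "C2D1" && ph %in% names(sc$post_fold_change)) {
            sc$post_fold_change[[ph]]
          } else 1
          lambda <- sc$baseline_density_per_mm2[[ph]] * effect * fc
          n_cells <- stats::rpois(1, lambda * sc$area_mm2)
          pts <- draw_points(n_cells, side, sc$clustering, sc$cluster_sd_um,
                             sc$area_mm2)
          if (n_cells > 0) pts[[ph]] <- 1L
          pts
        })
        cells <- Reduce(function(a, b) merge_cell_rows(a, b), rows)
        for (ph in names(sc$baseline_density_per_mm2)) {
          if (!ph %in% names(cells)) cells[[ph]] <- integer(nrow(cells))
        }
        for (ph in c("CD8", "CD4", "CD20")) {
          if (!ph %in% names(cells)) cells[[ph]] <- integer(nrow(cells))
        }
        pd1_frac <- if (tp == "baseline") sc$pd1_fraction_pre
                    else sc$pd1_fraction_post
        is_t <- cells$CD8 == 1 | cells$CD4 == 1
        cells$PD1 <- integer(nrow(cells))
        cells$PD1[is_t] <- stats::rbinom(sum(is_t), 1L, pd1_frac)
        # CD23 marks a small follicular subset of B cells (cosmetic)
        is_b <- cells$CD20 == 1
        cells$CD23 <- integer(nrow(cells))
        cells$CD23[is_b] <- stats::rbinom(sum(is_b), 1L, 0.1)
        maps[[paste0(pid, "_", tp)]] <- cell_map(
          cells, area_mm2 = sc$area_mm2,
          sample_id = paste0(pid, "_", tp), patient_id = pid,
          timepoint = tp
        )
      }
    }
    cells_df <- do.call(rbind, lapply(maps, function(m) {
      if (nrow(m$cells) == 0) return(NULL)
      cbind(data.frame(sample_id = m$sample_id, patient_id = m$patient_id,
                       timepoint = m$timepoint),
            round_coords(m$cells))
    }))
    rownames(cells_df) <- NULL
    samples_df <- do.call(rbind, lapply(maps, function(m) {
      data.frame(sample_id = m$sample_id, patient_id = m$patient_id,
                 timepoint = m$timepoint, area_mm2 = m$area_mm2)
    }))
    rownames(samples_df) <- NULL
    list(maps = unname(maps), cells = cells_df, samples = samples_df)
  })
}

round_coords <- function(cells) {
  cells$x_um <- round(cells$x_um, 3)
  cells$y_um <- round(cells$y_um, 3)
  cells
}

# rbind data frames whose phenotype columns may differ; absent flags are 0.
merge_cell_rows <- function(a, b) {
  cols <- union(names(a), names(b))
  for (cl in cols) {
    if (!cl %in% names(a)) a[[cl]] <- if (nrow(a)) 0L else integer(0)
    if (!cl %in% names(b)) b[[cl]] <- if (nrow(b)) 0L else integer(0)
  }
  rbind(a[cols], b[cols])
}

#' Presets emulating the published cohort
#'
#' @return List with `cohort` (a [cohort_scenario]) and `spatial` (a
#'   [spatial_scenario]) at their documented defaults: 50 patients, true
#'   ORR 0.10, median PFS 1.8 / OS 15.1 / DOR 7.8 months, and 7 paired
#'   biopsies.
#' @param seed Integer seed stored in both presets.
#' @export
paper_like_scenario <- function(seed = 1L) {
  list(cohort = cohort_scenario(seed = seed),
       spatial = spatial_scenario(seed = seed))
}
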