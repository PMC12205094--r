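# Best-overall-response tallies, duration of response and the
# growth-modulation index.

BOR_LEVELS <- c("CR", "PR", "SD", "PD", "NE")
MONTHS_PER_YEAR <- 12
DAYS_PER_MONTH <- 365 / 12  # fixed months<->days conversion

#' Tally best overall response and derive the trial state
#'
#' Counts RECIST-style best-overall-response categories among evaluable
#' patients, computes the objective response rate (ORR = CR + PR over
#' evaluable), the number of patients with disease control (CR/PR/SD)
#' lasting at least six months, and emits the [trial_state] the design
#' module consumes.
#'
#' @param patients Data frame in the patient-table schema (see
#'   [read_patient_table]); only `bor` and `pfs_months` are required here.
#'   Rows with `evaluable_efficacy == 0` are dropped if that column exists.
#' @return List with `counts` (named integer vector over CR/PR/SD/PD/NE),
#'   `rates` (same categories as proportions of evaluable, rounded to one
#'   decimal when expressed in percent by the report writer), `n_evaluable`,
#'   `n_responders`, `orr` (`NA` with `orr_defined = FALSE` when no
#'   evaluable patients), `disease_control_6mo`, and `state`.
#' @examples
#' df <- data.frame(bor = c(rep("PR", 4), rep("SD", 17), rep("PD", 22)),
#'                  pfs_months = 2)
#' summarize_response(df)$state
#' @export
summarize_response <- function(patients) {
  if ("evaluable_efficacy" %in% names(patients)) {
    patients <- patients[patients$evaluable_efficacy %in% c(1, TRUE), ,
                         drop = FALSE]
  }
  bor <- factor(as.character(patients$bor), levels = BOR_LEVELS)
  if (nrow(patients) > 0 && anyNA(bor)) {
    stop("bor values outside {", paste(BOR_LEVELS, collapse = ", "), "}")
  }
  counts <- table(bor)
  n <- nrow(patients)
  r <- sum(counts[c("CR", "PR")])
  dc6 <- if (n == 0 || !("pfs_months" %in% names(patients))) {
    NA_integer_
  } else {
    sum(bor %in% c("CR", "PR", "SD") &
          !is.na(patients$pfs_months) & patients$pfs_months >= 6)
  }
  list(
    counts = stats::setNames(as.integer(counts), BOR_LEVELS),
    rates = if (n > 0) as.numeric(counts) / n else rep(NA_real_, 5),
    n_evaluable = n, n_responders = as.integer(r),
    orr = if (n > 0) r / n else NA_real_,
    orr_defined = n > 0,
    disease_control_6mo = dc6,
    state = if (n > 0) trial_state(n, r) else NULL
  )
}

#' Duration of response among responders
#'
#' For each responder (best overall response CR or PR), the duration of
#' response runs from response onset to progression or censoring;
#' non-progressed responders are censored. Returns the survival records and
#' a Kaplan-Meier median.
#'
#' @param patients Patient table restricted by this function to responders;
#'   needs `bor`, `response_onset_months`, `pfs_months` (progression or
#'   censoring time from treatment start) and `pfs_event`.
#' @return List with `records` (data frame: `patient_id`, `time`, `event`,
#'   endpoint `"DOR"`), `curve` (`km_curve`, `NULL` when no responders),
#'   `median` (list as in [km_median], `NA` fields when undefined) and
#'   `n_responders`.
#' @export
duration_of_response <- function(patients) {
  resp <- patients[patients$bor %in% c("CR", "PR"), , drop = FALSE]
  if (nrow(resp) == 0) {
    return(list(records = NULL, curve = NULL,
                median = list(median = NA_real_, ci_low = NA_real_,
                              ci_high = NA_real_, not_reached = NA),
                n_responders = 0L))
  }
  if (anyNA(resp$response_onset_months)) {
    stop("responder without a response onset time")
  }
  dor <- resp$pfs_months - resp$response_onset_months
  if (any(dor < 0)) stop("progression/censoring precedes response onset")
  records <- data.frame(
    patient_id = resp$patient_id, time = dor,
    event = as.integer(resp$pfs_event), endpoint = "DOR"
  )
  curve <- km_fit(records$time, records$event, endpoint = "DOR")
  list(records = records, curve = curve, median = km_median(curve),
       n_responders = nrow(resp))
}

#' Growth-modulation index
#'
#' Per patient, the GMI is the ratio of the progression-free survival on the
#' current treatment to the PFS recorded on the immediately preceding line;
#' `GMI >= 1.33` (inclusive) is the conventional signal that the current
#' line outperformed the previous one.
#'
#' Patients whose current-line PFS is censored have a GMI that is a lower
#' bound; they are included by default and flagged, with
#' `include_censored = FALSE` available as a sensitivity analysis.
#'
#' @param pfs_current Positive current-line PFS (months).
#' @param pfs_prior Positive prior-line PFS (months, same unit).
#' @param censored Logical, `TRUE` when `pfs_current` is censored. Default
#'   all observed.
#' @param patient_id Optional identifiers carried into the output.
#' @param threshold Benefit threshold, default 1.33.
#' @param include_censored Include censored pairs (default `TRUE`).
#' @return List with `records` (per-patient data frame: `patient_id`,
#'   `pfs_current`, `pfs_prior`, `censored`, `gmi`), `median_gmi`,
#'   `n_ge_threshold`, `fraction_ge_threshold`, `percent_ge_threshold`
#'   (rounded half-up to one decimal), `threshold`, `n`.
#' @examples
#' gmi_compute(c(6, 2, 1), c(3, 4, 2))
#' @export
gmi_compute <- function(pfs_current, pfs_prior, censored = NULL,
                        patient_id = NULL, threshold = 1.33,
                        include_censored = TRUE) {
  n_in <- length(pfs_current)
  stopifnot(length(pfs_prior) == n_in)
  if (any(!is.finite(pfs_prior)) || any(pfs_prior <= 0)) {
    stop("prior-line PFS must be positive")
  }
  if (any(!is.finite(pfs_current)) || any(pfs_current <= 0)) {
    stop("current-line PFS must be positive")
  }
  if (is.null(censored)) censored <- rep(FALSE, n_in)
  if (is.null(patient_id)) patient_id <- seq_len(n_in)
  keep <- if (include_censored) rep(TRUE, n_in) else !censored
  records <- data.frame(
    patient_id = patient_id[keep],
    pfs_current = pfs_current[keep], pfs_prior = pfs_prior[keep],
    censored = censored[keep],
    gmi = pfs_current[keep] / pfs_prior[keep]
  )
  n <- nrow(records)
  n_ge <- sum(records$gmi >= threshold)
  frac <- if (n > 0) n_ge / n else NA_real_
  list(records = records,
       median_gmi = if (n > 0) stats::median(records$gmi) else NA_real_,
       n_ge_threshold = n_ge,
       fraction_ge_threshold = frac,
       percent_ge_threshold = if (n > 0) round_half_up(100 * frac, 1)
                              else NA_real_,
       threshold = threshold, n = n)
}

# round() uses banker's rounding; reported percentages round half away
# from zero to one decimal.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
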