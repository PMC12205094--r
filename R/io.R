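# CSV readers/writers for the patient and cell schemas, and the combined
# JSON report. Comma-separated, UTF-8, "." decimal; months are the
# canonical time unit.

PATIENT_REQUIRED_COLS <- c("patient_id", "evaluable_efficacy", "bor",
                           "response_onset_months", "pfs_months",
                           "pfs_event", "os_months", "os_event",
                           "prior_pfs_months")
CELLS_REQUIRED_COLS <- c("sample_id", "patient_id", "timepoint",
                         "x_um", "y_um")
SAMPLES_REQUIRED_COLS <- c("sample_id", "patient_id", "timepoint",
                           "area_mm2")

#' Read and validate a patient table
#'
#' Reads the patient CSV schema (`patient_id, evaluable_efficacy, bor,
#' response_onset_months, pfs_months, pfs_event, os_months, os_event,
#' prior_pfs_months`, missing values as empty fields), checks the header,
#' and collects row-level validation problems with line numbers.
#'
#' @param path Path to a CSV file.
#' @param time_unit Unit of the time columns in the file: `"months"`
#'   (default), `"days"` or `"weeks"`; values are converted to months on
#'   ingest.
#' @return The validated data frame (times in months). Schema violations
#'   are errors; row-level problems are reported together in a single
#'   error message naming the offending lines.
#' @export
read_patient_table <- function(path, time_unit = c("months", "days", "weeks")) {
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(PATIENT_REQUIRED_COLS, names(df))
  if (length(missing) > 0) {
    stop("patient table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  problems <- character(0)
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  bad_bor <- !df$bor %in% BOR_LEVELS
  if (any(bad_bor)) {
    problems <- c(problems, sprintf(
      "line %d: bor '%s' not in {%s}", line[bad_bor], df$bor[bad_bor],
      paste(BOR_LEVELS, collapse = ", ")))
  }
  for (col in c("pfs_months", "os_months")) {
    bad <- !is.na(df[[col]]) & (!is.finite(df[[col]]) | df[[col]] < 0)
    if (any(bad)) {
      problems <- c(problems,
                    sprintf("line %d: %s must be non-negative", line[bad], col))
    }
  }
  onset_missing <- df$bor %in% c("CR", "PR") & is.na(df$response_onset_months)
  if (any(onset_missing)) {
    problems <- c(problems, sprintf(
      "line %d: responder without response_onset_months", line[onset_missing]))
  }
  if (length(problems) > 0) {
    stop("invalid patient table:\n  ", paste(problems, collapse = "\n  "))
  }
  scale <- switch(time_unit, months = 1, days = 1 / DAYS_PER_MONTH,
                  weeks = 7 / DAYS_PER_MONTH)
  for (col in c("response_onset_months", "pfs_months", "os_months",
                "prior_pfs_months")) {
    df[[col]] <- df[[col]] * scale
  }
  df
}

#' Read paired cell and sample tables into cell maps
#'
#' The cells CSV carries `sample_id, patient_id, timepoint, x_um, y_um` and
#' one 0/1 column per phenotype flag; the companion samples CSV carries the
#' analysed `area_mm2` per sample (so samples with zero detected cells are
#' still represented).
#'
#' @param cells_path,samples_path CSV paths.
#' @return List of [cell_map] objects, one per row of the samples table.
#' @export
read_cell_tables <- function(cells_path, samples_path) {
  for (p in c(cells_path, samples_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  cells <- utils::read.csv(cells_path, stringsAsFactors = FALSE)
  samples <- utils::read.csv(samples_path, stringsAsFactors = FALSE)
  miss_c <- setdiff(CELLS_REQUIRED_COLS, names(cells))
  miss_s <- setdiff(SAMPLES_REQUIRED_COLS, names(samples))
  if (length(miss_c) > 0) {
    stop("cells table is missing column(s): ", paste(miss_c, collapse = ", "))
  }
  if (length(miss_s) > 0) {
    stop("samples table is missing column(s): ", paste(miss_s, collapse = ", "))
  }
  if (any(!samples$timepoint %in% c("baseline", "C2D1"))) {
    stop("samples timepoint must be 'baseline' or 'C2D1'")
  }
  lapply(seq_len(nrow(samples)), function(i) {
    s <- samples[i, ]
    sub <- cells[cells$sample_id == s$sample_id, , drop = FALSE]
    cell_map(sub[setdiff(names(sub),
                         c("sample_id", "patient_id", "timepoint"))],
             area_mm2 = s$area_mm2, sample_id = s$sample_id,
             patient_id = s$patient_id, timepoint = s$timepoint)
  })
}

#' Write a patient table
#'
#' Inverse of [read_patient_table]; writes the canonical schema with empty
#' fields for missing values, deterministically (no row names, fixed
#' column order).
#'
#' @param patients Patient data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_patient_table <- function(patients, path) {
  cols <- intersect(c("patient_id", "histology", PATIENT_REQUIRED_COLS),
                    names(patients))
  cols <- unique(cols)
  utils::write.csv(patients[cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write cells and samples tables
#'
#' @param cell_maps Output of [generate_cell_maps] or a list of [cell_map].
#' @param cells_path,samples_path Output CSV paths.
#' @return `cells_path`, invisibly.
#' @export
write_cell_tables <- function(cell_maps, cells_path, samples_path) {
  if (inherits(cell_maps, "cell_map")) cell_maps <- list(cell_maps)
  if (is.list(cell_maps) && !is.null(cell_maps$cells)) {
    cells <- cell_maps$cells
    samples <- cell_maps$samples
  } else {
    cells <- do.call(rbind, lapply(cell_maps, function(m) {
      if (nrow(m$cells) == 0) return(NULL)
      cbind(data.frame(sample_id = m$sample_id, patient_id = m$patient_id,
                       timepoint = m$timepoint), round_coords(m$cells))
    }))
    samples <- do.call(rbind, lapply(cell_maps, function(m) {
      data.frame(sample_id = m$sample_id, patient_id = m$patient_id,
                 timepoint = m$timepoint, area_mm2 = m$area_mm2)
    }))
  }
  utils::write.csv(cells, cells_path, row.names = FALSE, na = "")
  utils::write.csv(samples, samples_path, row.names = FALSE, na = "")
  invisible(cells_path)
}

# "not reached" medians serialize as null plus an explicit flag
nr_field <- function(v) {
  list(value = if (is.na(v)) NULL else v, not_reached = is.na(v))
}

#' Assemble and write the combined analysis report
#'
#' Runs the design, survival, GMI and (optionally) spatial layers on the
#' given inputs and writes one JSON document embedding the configuration
#' and seed needed to regenerate it. "Not reached" medians serialize as
#' `null` with a `not_reached` flag.
#'
#' @param patients Patient data frame (schema of [read_patient_table]).
#' @param design A [trial_design].
#' @param cell_maps Optional list of paired [cell_map] objects.
#' @param milestones Landmark times in months for PFS/OS, default `c(6, 12)`.
#' @param path Output JSON path, or `NULL` to return the report list only.
#' @param seed Seed echoed into the report.
#' @return The report as a list, invisibly when written.
#' @export
write_report <- function(patients, design = trial_design(), cell_maps = NULL,
                         milestones = c(6, 12), path = NULL, seed = NA) {
  resp <- summarize_response(patients)
  post <- if (resp$orr_defined) update_posterior(design, resp$state) else NULL
  decision <- if (resp$orr_defined) interim_decision(design, resp$state)
              else NULL

  km_block <- function(time, event, endpoint) {
    curve <- km_fit(time, event, endpoint = endpoint)
    med <- km_median(curve)
    list(
      n = curve$n, n_events = sum(curve$steps$n_event),
      median_months = nr_field(med$median),
      ci_low = nr_field(med$ci_low), ci_high = nr_field(med$ci_high),
      milestones = lapply(milestones, function(t) {
        ms <- suppressWarnings(km_milestone(curve, t))
        list(time_months = t, estimate = ms$estimate,
             ci_low = ms$ci_low, ci_high = ms$ci_high,
             truncated = ms$truncated)
      })
    )
  }
  evaluable <- patients[patients$evaluable_efficacy %in% c(1, TRUE), ,
                        drop = FALSE]
  pfs <- km_block(evaluable$pfs_months, evaluable$pfs_event, "PFS")
  os <- km_block(evaluable$os_months, evaluable$os_event, "OS")
  dor <- duration_of_response(evaluable)
  gmi_ok <- !is.na(evaluable$prior_pfs_months) & evaluable$prior_pfs_months > 0
  gmi <- gmi_compute(evaluable$pfs_months[gmi_ok],
                     evaluable$prior_pfs_months[gmi_ok],
                     censored = evaluable$pfs_event[gmi_ok] == 0,
                     patient_id = evaluable$patient_id[gmi_ok])

  spatial <- if (!is.null(cell_maps)) {
    pa <- paired_panel_analysis(cell_maps)
    list(
      phenotypes = lapply(pa$density, function(d) {
        list(phenotype = d$phenotype, n_pairs = d$n_pairs,
             n_increased = d$n_increased,
             mean_density_pre = mean(d$densities_pre),
             mean_density_post = mean(d$densities_post),
             wilcoxon_statistic = d$wilcoxon_statistic, p_value = d$p_value)
      }),
      colocalization = list(
        source = pa$colocalization$source,
        targets = pa$colocalization$targets,
        radius_um = pa$colocalization$radius_um,
        mean_fraction_pre = mean(pa$colocalization$table$fraction_pre),
        mean_fraction_post = mean(pa$colocalization$table$fraction_post),
        p_value = pa$colocalization$p_value
      ),
      pd1 = lapply(pa$marker, function(m) {
        list(base = m$base, n_increased = m$n_increased,
             p_value = m$p_value)
      })
    )
  } else NULL

  report <- list(
    tool = "coldtrial",
    version = as.character(utils::packageVersion("coldtrial")),
    seed = seed,
    config = list(design = unclass(design)),
    response = list(
      counts = as.list(resp$counts), n_evaluable = resp$n_evaluable,
      n_responders = resp$n_responders, orr = resp$orr,
      disease_control_6mo = resp$disease_control_6mo
    ),
    posterior = if (!is.null(post)) list(
      alpha = post$alpha_post, beta = post$beta_post,
      mean = post$mean, mean_percent = round_half_up(100 * post$mean, 1),
      ci_low = post$ci_low, ci_high = post$ci_high,
      ci_level = post$ci_level
    ),
    decision = if (!is.null(decision)) list(
      action = decision$action,
      prob_futility_event = decision$prob_futility_event,
      prob_efficacy_event = decision$prob_efficacy_event,
      interim_n = decision$interim_n
    ),
    pfs = pfs, os = os,
    duration_of_response = list(
      n_responders = dor$n_responders,
      median_months = nr_field(dor$median$median)
    ),
    gmi = list(
      n = gmi$n, median_gmi = gmi$median_gmi,
      n_ge_threshold = gmi$n_ge_threshold,
      percent_ge_threshold = gmi$percent_ge_threshold,
      threshold = gmi$threshold
    ),
    spatial = spatial
  )
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    return(invisible(report))
  }
  report
}
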