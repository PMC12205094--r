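# Paired multiplex-immunofluorescence statistics on phenotyped cell maps:
# densities per mm^2, radius-based colocalization, marker-positive fractions.
# Phenotyping (thresholding of marker intensities) is upstream; this module
# consumes binary phenotype flags.

PHENOTYPE_FLAGS <- c("CD8", "CD4", "CD20", "CD163", "CD3", "PD1", "CD23")

#' Build a phenotyped cell map
#'
#' A cell map is the unit of spatial analysis: one tissue region from one
#' sample, with micrometre cell coordinates, binary phenotype flags and the
#' analysed area. The CD3 lineage flag is enforced for every CD4+ or CD8+
#' cell (T-cell lineage consistency).
#'
#' @param cells Data frame with `x_um`, `y_um` and one 0/1 column per
#'   phenotype flag (any subset of CD8, CD4, CD20, CD163, CD3, PD1, CD23;
#'   missing flag columns are filled with 0).
#' @param area_mm2 Analysed region area in mm^2, `> 0`.
#' @param sample_id,patient_id Identifiers.
#' @param timepoint `"baseline"` or `"C2D1"` (day 1 of cycle 2).
#' @return A `cell_map` object.
#' @examples
#' cell_map(data.frame(x_um = 1, y_um = 2, CD8 = 1), area_mm2 = 0.5,
#'          sample_id = "s1", patient_id = "p1", timepoint = "baseline")
#' @export
cell_map <- function(cells, area_mm2, sample_id = "sample",
                     patient_id = "patient",
                     timepoint = c("baseline", "C2D1")) {
  timepoint <- match.arg(timepoint)
  stopifnot(is.data.frame(cells), area_mm2 > 0, is.finite(area_mm2))
  if (nrow(cells) > 0) {
    stopifnot(all(c("x_um", "y_um") %in% names(cells)),
              all(is.finite(cells$x_um)), all(is.finite(cells$y_um)))
  } else if (!all(c("x_um", "y_um") %in% names(cells))) {
    cells <- data.frame(x_um = numeric(0), y_um = numeric(0))
  }
  for (ph in PHENOTYPE_FLAGS) {
    cells[[ph]] <- if (ph %in% names(cells)) as.integer(cells[[ph]] != 0)
                   else integer(nrow(cells))
  }
  # lineage consistency: CD4+ and CD8+ cells are CD3+ T cells
  cells$CD3 <- as.integer(cells$CD3 | cells$CD4 | cells$CD8)
  structure(
    list(cells = cells[c("x_um", "y_um", PHENOTYPE_FLAGS)],
         area_mm2 = area_mm2, sample_id = sample_id,
         patient_id = patient_id, timepoint = timepoint),
    class = "cell_map"
  )
}

#' @export
print.cell_map <- function(x, ...) {
  cat(sprintf("cell_map %s (patient %s, %s): %d cells in %.3g mm^2\n",
              x$sample_id, x$patient_id, x$timepoint, nrow(x$cells),
              x$area_mm2))
  invisible(x)
}

check_phenotype <- function(phenotype) {
  bad <- setdiff(phenotype, PHENOTYPE_FLAGS)
  if (length(bad) > 0) {
    stop("unknown phenotype label(s): ", paste(bad, collapse = ", "))
  }
  phenotype
}

#' Cell density of a phenotype
#'
#' Count of cells carrying the flag divided by the analysed area, in
#' cells/mm^2.
#'
#' @param map A [cell_map].
#' @param phenotype A single phenotype label.
#' @return Density in cells per mm^2.
#' @export
cell_density <- function(map, phenotype) {
  stopifnot(inherits(map, "cell_map"), length(phenotype) == 1)
  check_phenotype(phenotype)
  sum(map$cells[[phenotype]]) / map$area_mm2
}

#' Fraction of source cells with a target cell within a radius
#'
#' A source cell (default CD20+, i.e. a B cell) is "colocalized" when at
#' least one *distinct* cell carrying any target flag (default CD4 or CD8,
#' i.e. a T cell) lies at Euclidean distance `<= radius_um` (closed ball).
#' A cell carrying both source and target flags never counts as its own
#' neighbour. Neighbour search uses a bucket-grid spatial index with cell
#' width `radius_um`; `method = "brute"` runs the all-pairs scan instead
#' (identical result, used as an internal cross-check).
#'
#' @param map A [cell_map].
#' @param source Source phenotype label, default `"CD20"`.
#' @param targets Character vector of target labels, default
#'   `c("CD4", "CD8")`.
#' @param radius_um Neighbourhood radius in micrometres, default 10.
#' @param method `"grid"` (default) or `"brute"`.
#' @return A `colocalization_result`: `sample_id`, `radius_um`, `n_source`,
#'   `n_colocalized`, `fraction` (0 with `empty_source = TRUE` when the map
#'   has no source cells), and `colocalized` (logical vector over source
#'   cells, in map order).
#' @examples
#' m <- cell_map(data.frame(x_um = c(0, 10), y_um = c(0, 0),
#'                          CD20 = c(1, 0), CD4 = c(0, 1)), 1)
#' colocalization_fraction(m)$fraction
#' @export
colocalization_fraction <- function(map, source = "CD20",
                                    targets = c("CD4", "CD8"),
                                    radius_um = 10,
                                    method = c("grid", "brute")) {
  method <- match.arg(method)
  stopifnot(inherits(map, "cell_map"), radius_um > 0, length(source) == 1)
  check_phenotype(c(source, targets))
  cells <- map$cells
  is_src <- cells[[source]] == 1
  is_tgt <- Reduce(`|`, lapply(targets, function(t) cells[[t]] == 1))
  if (length(is_tgt) == 0) is_tgt <- logical(0)
  src_idx <- which(is_src)
  tgt_idx <- which(is_tgt)
  n_src <- length(src_idx)
  if (n_src == 0) {
    return(structure(list(sample_id = map$sample_id, radius_um = radius_um,
                          n_source = 0L, n_colocalized = 0L, fraction = 0,
                          empty_source = TRUE, colocalized = logical(0)),
                     class = "colocalization_result"))
  }
  colocalized <- if (method == "brute") {
    coloc_brute(cells, src_idx, tgt_idx, radius_um)
  } else {
    coloc_grid(cells, src_idx, tgt_idx, radius_um)
  }
  structure(
    list(sample_id = map$sample_id, radius_um = radius_um,
         n_source = n_src, n_colocalized = sum(colocalized),
         fraction = mean(colocalized), empty_source = FALSE,
         colocalized = colocalized),
    class = "colocalization_result"
  )
}

# All-pairs scan; distance comparison on squared distances (exact for the
# inclusive boundary).
coloc_brute <- function(cells, src_idx, tgt_idx, radius) {
  r2 <- radius^2
  x <- cells$x_um; y <- cells$y_um
  vapply(src_idx, function(i) {
    tj <- tgt_idx[tgt_idx != i]
    if (length(tj) == 0) return(FALSE)
    any((x[tj] - x[i])^2 + (y[tj] - y[i])^2 <= r2)
  }, logical(1))
}

# Bucket-grid index: targets are hashed into square buckets of side
# `radius`; each source cell only inspects the 3x3 bucket neighbourhood.
coloc_grid <- function(cells, src_idx, tgt_idx, radius) {
  if (length(tgt_idx) == 0) return(rep(FALSE, length(src_idx)))
  x <- cells$x_um; y <- cells$y_um
  r2 <- radius^2
  gx <- floor(x / radius); gy <- floor(y / radius)
  key <- function(ix, iy) paste(ix, iy)
  buckets <- split(tgt_idx, key(gx[tgt_idx], gy[tgt_idx]))
  vapply(src_idx, function(i) {
    for (dx in -1:1) for (dy in -1:1) {
      tj <- buckets[[key(gx[i] + dx, gy[i] + dy)]]
      if (is.null(tj)) next
      tj <- tj[tj != i]
      if (length(tj) > 0 &&
          any((x[tj] - x[i])^2 + (y[tj] - y[i])^2 <= r2)) return(TRUE)
    }
    FALSE
  }, logical(1))
}

#' Fraction of base-phenotype cells positive for a marker
#'
#' E.g. the PD-1-positive fraction of CD8+ T cells. When the map carries no
#' base cells the fraction is reported as 0 with `empty_base = TRUE`.
#'
#' @param map A [cell_map].
#' @param base Base phenotype label (denominator).
#' @param marker Marker flag (numerator), default `"PD1"`.
#' @return List with `fraction`, `n_base`, `n_positive`, `empty_base`.
#' @export
marker_positive_fraction <- function(map, base, marker = "PD1") {
  stopifnot(inherits(map, "cell_map"))
  check_phenotype(c(base, marker))
  is_base <- map$cells[[base]] == 1
  n_base <- sum(is_base)
  n_pos <- sum(is_base & map$cells[[marker]] == 1)
  list(fraction = if (n_base > 0) n_pos / n_base else 0,
       n_base = n_base, n_positive = n_pos, empty_base = n_base == 0)
}

#' Paired analysis of pre- vs on-treatment cell maps
#'
#' For each phenotype: paired baseline/C2D1 densities per patient, the
#' number of patients whose density increased on treatment, and the exact
#' paired Wilcoxon signed-rank p-value. Additionally computes the
#' source-target colocalization fraction per sample and its paired delta
#' per patient.
#'
#' @param maps List of [cell_map] objects; every patient must contribute
#'   exactly one `baseline` and one `C2D1` map.
#' @param phenotypes Phenotype labels to analyse, default
#'   `c("CD8", "CD4", "CD20", "CD163")`.
#' @param source,targets,radius_um Colocalization settings, defaults as in
#'   [colocalization_fraction].
#' @param marker_base Phenotypes for which the PD-1-positive fraction is
#'   also compared pre/post, default `c("CD8", "CD4")`.
#' @return List with `density` (one `paired_density_result` per phenotype),
#'   `colocalization` (data frame per patient: pre/post fraction and delta,
#'   plus the Wilcoxon test over patients), and `marker` (per base
#'   phenotype, the paired PD-1 fraction test).
#' @export
paired_panel_analysis <- function(maps,
                                  phenotypes = c("CD8", "CD4", "CD20", "CD163"),
                                  source = "CD20", targets = c("CD4", "CD8"),
                                  radius_um = 10,
                                  marker_base = c("CD8", "CD4")) {
  check_phenotype(phenotypes)
  pts <- vapply(maps, function(m) as.character(m$patient_id), character(1))
  tps <- vapply(maps, function(m) m$timepoint, character(1))
  patients <- sort(unique(pts))
  pre_maps <- post_maps <- vector("list", length(patients))
  for (i in seq_along(patients)) {
    pre_i <- which(pts == patients[i] & tps == "baseline")
    post_i <- which(pts == patients[i] & tps == "C2D1")
    if (length(pre_i) != 1 || length(post_i) != 1) {
      stop("patient ", patients[i],
           " must have exactly one baseline and one C2D1 map")
    }
    pre_maps[[i]] <- maps[[pre_i]]
    post_maps[[i]] <- maps[[post_i]]
  }
  density <- lapply(phenotypes, function(ph) {
    pre <- vapply(pre_maps, cell_density, numeric(1), phenotype = ph)
    post <- vapply(post_maps, cell_density, numeric(1), phenotype = ph)
    wt <- paired_wilcoxon(pre, post)
    structure(
      list(phenotype = ph, patient_id = patients,
           densities_pre = pre, densities_post = post,
           n_pairs = length(patients),
           n_increased = sum(post > pre),
           wilcoxon_statistic = wt$statistic, p_value = wt$p_value,
           degenerate = wt$degenerate),
      class = "paired_density_result"
    )
  })
  names(density) <- phenotypes

  coloc_of <- function(m) {
    colocalization_fraction(m, source, targets, radius_um)$fraction
  }
  pre_f <- vapply(pre_maps, coloc_of, numeric(1))
  post_f <- vapply(post_maps, coloc_of, numeric(1))
  wt_col <- paired_wilcoxon(pre_f, post_f)
  colocalization <- list(
    table = data.frame(patient_id = patients, fraction_pre = pre_f,
                       fraction_post = post_f, delta = post_f - pre_f),
    source = source, targets = targets, radius_um = radius_um,
    wilcoxon_statistic = wt_col$statistic, p_value = wt_col$p_value,
    degenerate = wt_col$degenerate
  )

  marker <- lapply(marker_base, function(ph) {
    pre <- vapply(pre_maps, function(m)
      marker_positive_fraction(m, ph)$fraction, numeric(1))
    post <- vapply(post_maps, function(m)
      marker_positive_fraction(m, ph)$fraction, numeric(1))
    wt <- paired_wilcoxon(pre, post)
    list(base = ph, marker = "PD1", fraction_pre = pre, fraction_post = post,
         n_increased = sum(post > pre),
         wilcoxon_statistic = wt$statistic, p_value = wt$p_value,
         degenerate = wt$degenerate)
  })
  names(marker) <- marker_base

  list(density = density, colocalization = colocalization, marker = marker,
       patients = patients)
}

#' @export
print.paired_density_result <- function(x, ...) {
  cat(sprintf("%s density: %d/%d patients increased, V = %g, p = %.4g%s\n",
              x$phenotype, x$n_increased, x$n_pairs, x$wilcoxon_statistic,
              x$p_value, if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}
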