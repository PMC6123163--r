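# Cohort DVH meta-analysis: search structures across patients by name,
# resample cumulative curves onto a common dose grid, and summarize the
# cohort as envelope curves (mean, median, mu +/- 1 sigma) plus the
# distributions of D(V), V(D) and maximum structure dose.

#' Search DVH documents for a structure by name
#'
#' Case-insensitive substring match of `query` against both the canonical
#' `roi_name` and the original planner-typed `tps_roi_name`, so
#' inconsistent contour nomenclature ("Rectum", "RECTUM_JD", ...) is still
#' found. At most one structure per document is returned — the first match
#' in stored order; documents with several matches are flagged in the
#' `multi_match` column. An empty query matches every document's first
#' structure.
#'
#' @param dvh_docs List of [dvh_document()] objects.
#' @param query Search string ("" matches everything).
#' @return A tibble with `patient_id`, `plan_name`, `roi_name`,
#'   `tps_roi_name`, `multi_match` and a list-column `structure` holding the
#'   matched structure (with its curves). Zero rows is a valid outcome.
#' @export
find_structures <- function(dvh_docs, query = "") {
  needle <- tolower(query)
  rows <- list()
  for (doc in dvh_docs) {
    hits <- which(vapply(doc$structures, function(s) {
      nzchar(needle) == FALSE ||
        grepl(needle, tolower(s$roi_name), fixed = TRUE) ||
        grepl(needle, tolower(s$tps_roi_name), fixed = TRUE)
    }, TRUE))
    if (length(hits) == 0) next
    s <- doc$structures[[hits[1]]]
    rows[[length(rows) + 1]] <- tibble::tibble(
      patient_id = doc$patient_id, plan_name = doc$plan_name,
      roi_name = s$roi_name, tps_roi_name = s$tps_roi_name,
      multi_match = length(hits) > 1, structure = list(s))
  }
  if (!length(rows)) {
    return(tibble::tibble(patient_id = character(), plan_name = character(),
                          roi_name = character(), tps_roi_name = character(),
                          multi_match = logical(), structure = list()))
  }
  dplyr::bind_rows(rows)
}

#' Resample a cumulative DVH curve onto a dose grid
#'
#' Linear interpolation inside the curve's native dose range; 0% volume
#' beyond its last dose point (cumulative-DVH semantics: no part of the
#' structure receives more than its maximum dose). Resampling onto the
#' curve's own native grid reproduces the tabulated values exactly, and the
#' output is monotone non-increasing with 100% at 0 Gy.
#'
#' @param crv A [dvh_curve()].
#' @param grid Numeric vector of query doses (Gy), nonnegative.
#' @return Numeric vector of volumes (percent) on `grid`.
#' @export
resample_curve <- function(crv, grid) {
  validate_dvh_curve(crv)
  if (any(grid < 0)) pc_abort("dose grid must be nonnegative", "pc_config_error")
  approx(crv$dose_gy, crv$volume_pct, xout = grid, method = "linear",
         yleft = 100, yright = 0, ties = "ordered")$y
}

#' Minimum dose to the hottest V% of a structure, D(V)
#'
#' The largest dose d on the cumulative curve with V(d) >= v, by inverse
#' linear interpolation across the bracketing grid interval. On a flat
#' segment whose volume equals `v` exactly, the segment's high-dose end is
#' returned ("minimum dose to the hottest V%"). If even the curve's last
#' point retains more than `v`% volume, the maximum tabulated dose is
#' returned with attribute `saturated = TRUE`.
#'
#' @param crv A [dvh_curve()].
#' @param v Volume threshold, percent, in (0, 100].
#' @return Dose in Gy (scalar).
#' @examples
#' crv <- dvh_curve("tps", c(0, 70), c(100, 0))
#' d_at_v(crv, 50)  # 35
#' @export
d_at_v <- function(crv, v) {
  validate_dvh_curve(crv)
  if (!is_scalar_number(v) || v <= 0 || v > 100) {
    pc_abort("v must be a volume percentage in (0, 100]", "pc_config_error")
  }
  vol <- crv$volume_pct; dose <- crv$dose_gy
  i <- max(which(vol >= v))        # exists: vol[1] == 100 >= v
  if (i == length(vol)) {
    out <- dose[i]
    attr(out, "saturated") <- TRUE
    return(out)
  }
  # vol[i] >= v > vol[i + 1]; on exact equality vol[i] == v this returns
  # dose[i], the high-dose end of any flat segment at v
  dose[i] + (vol[i] - v) / (vol[i] - vol[i + 1]) * (dose[i + 1] - dose[i])
}

#' Volume receiving at least dose D, V(D)
#'
#' Linear interpolation of the cumulative curve at `d`; 100% at 0 Gy by
#' normalization, 0% beyond the curve's maximum tabulated dose.
#'
#' @param crv A [dvh_curve()].
#' @param d Dose in Gy, >= 0.
#' @return Volume in percent (scalar).
#' @export
v_at_d <- function(crv, d) {
  if (!is_scalar_number(d) || d < 0) {
    pc_abort("dose must be nonnegative", "pc_config_error")
  }
  resample_curve(crv, d)
}

#' Maximum dose to a structure from its cumulative DVH
#'
#' The largest dose with V(d) > `eps`, located by inverse linear
#' interpolation to the V = `eps` crossing. With the default `eps = 0` this
#' is the dose where the curve first reaches zero volume (the curve's last
#' tabulated dose if volume never reaches zero).
#'
#' @param crv A [dvh_curve()].
#' @param eps Volume threshold in percent; 0 gives the conventional
#'   maximum, small positive values give a near-maximum dose robust to thin
#'   DVH tails.
#' @return Dose in Gy (scalar).
#' @examples
#' crv <- dvh_curve("tps", c(0, 70), c(100, 0))
#' d_max(crv)          # 70
#' d_max(crv, eps = 2) # 68.6
#' @export
d_max <- function(crv, eps = 0) {
  validate_dvh_curve(crv)
  stopifnot(is_scalar_number(eps), eps >= 0, eps < 100)
  vol <- crv$volume_pct; dose <- crv$dose_gy
  i <- max(which(vol > eps))
  if (i == length(vol)) return(dose[i])
  dose[i] + (vol[i] - eps) / (vol[i] - vol[i + 1]) * (dose[i + 1] - dose[i])
}

#' Summarize a DVH cohort for one structure
#'
#' Takes the structures matched by [find_structures()], selects one
#' calculation source, resamples every curve onto a shared uniform dose
#' grid spanning 0 to the cohort maximum dose, and computes pointwise
#' envelope curves — mean, median, and mu +/- 1 sample SD (n - 1), the
#' lower envelope floored at 0 — plus, per patient, D(`v_sel`),
#' V(`d_sel`) and the maximum structure dose.
#'
#' @param matches Tibble from [find_structures()], >= 1 row.
#' @param source `"tps"` or `"check"`: which calculation system's curves to
#'   analyze.
#' @param grid_step Common dose-grid spacing in Gy; default 0.1.
#' @param v_sel Selected volume constraint (percent) for the D(V)
#'   distribution; default 50.
#' @param d_sel Selected dose constraint (Gy) for the V(D) distribution;
#'   default the midpoint of the cohort grid.
#' @return A list of class `cohort_dvh_summary`: `dose_grid`, matrix
#'   `curves` (patients x grid), `mean_curve`, `median_curve`,
#'   `upper_curve`, `lower_curve`, `n_patients`, `source`, and
#'   `distributions` — a list with `selected_volume_pct`,
#'   `selected_dose_gy` and per-patient vectors `d_at_v`, `v_at_d`,
#'   `d_max`.
#' @export
summarize_dvh_cohort <- function(matches, source = c("tps", "check"),
                                 grid_step = 0.1, v_sel = 50, d_sel = NULL) {
  source <- match.arg(source)
  if (!is.data.frame(matches) || nrow(matches) == 0) {
    pc_abort("empty cohort: no matched structures", "pc_empty_cohort_error")
  }
  curves <- lapply(matches$structure, function(s) {
    srcs <- vapply(s$curves, `[[`, "", "source")
    j <- which(srcs == source)
    if (!length(j)) {
      pc_abort(sprintf("structure '%s' has no '%s' curve", s$roi_name,
                       source), "pc_validation_error")
    }
    s$curves[[j[1]]]
  })
  dmaxes <- vapply(curves, d_max, 0)
  grid_max <- max(dmaxes)
  grid <- seq(0, grid_max, by = grid_step)
  if (tail(grid, 1) < grid_max) grid <- c(grid, grid_max)
  if (is.null(d_sel)) d_sel <- grid_max / 2

  mat <- do.call(rbind, lapply(curves, resample_curve, grid = grid))
  mean_curve <- colMeans(mat)
  median_curve <- apply(mat, 2, median)
  sd_curve <- if (nrow(mat) >= 2) apply(mat, 2, sd) else rep(0, ncol(mat))
  structure(list(
    dose_grid = grid, curves = mat,
    mean_curve = mean_curve, median_curve = median_curve,
    upper_curve = mean_curve + sd_curve,
    lower_curve = pmax(mean_curve - sd_curve, 0),
    n_patients = nrow(mat), source = source,
    distributions = list(
      selected_volume_pct = v_sel, selected_dose_gy = d_sel,
      d_at_v = vapply(curves, function(crv) as.numeric(d_at_v(crv, v_sel)), 0),
      v_at_d = vapply(curves, v_at_d, 0, d = d_sel),
      d_max = dmaxes)
  ), class = "cohort_dvh_summary")
}

#' @export
print.cohort_dvh_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<cohort_dvh_summary> n=%d patients, source=%s, grid 0-%.4g Gy",
           " (%d points)\n  D(%g%%): median %.2f Gy   V(%.4g Gy): median",
           " %.1f%%   Dmax: median %.2f Gy\n"),
    x$n_patients, x$source, max(x$dose_grid), length(x$dose_grid),
    x$distributions$selected_volume_pct,
    median(x$distributions$d_at_v),
    x$distributions$selected_dose_gy,
    median(x$distributions$v_at_d),
    median(x$distributions$d_max)))
  invisible(x)
}
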