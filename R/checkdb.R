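# The record database: one analyzable row per approved plan-check, with
# wildcard filtering, grouping and the summary statistics a physicist reads
# off a filtered cohort (mean/max/SD discrepancy, mean/min gamma).

#' Select the primary target of a plan-check
#'
#' With multiple nested target volumes (GTV/CTV/PTV) only one target per
#' plan-check enters the analysis, to avoid skewing process-control
#' statistics. The primary target is the one receiving the highest TPS mean
#' dose; exact dose ties break to the lexicographically smallest `roi_name`
#' so the choice is deterministic.
#'
#' @param targets Non-empty list of target results (see
#'   [plan_check_document()]).
#' @return The selected target (a list).
#' @export
select_primary_target <- function(targets) {
  if (!is.list(targets) || length(targets) == 0) {
    pc_abort("plan-check has no targets", "pc_no_target_error")
  }
  doses <- vapply(targets, function(t) as.numeric(t$mean_dose_tps), 0)
  names_ <- vapply(targets, function(t) as.character(t$roi_name), "")
  cand <- which(doses == max(doses))
  targets[[cand[order(names_[cand])[1]]]]
}

#' Signed mean-dose discrepancy of a target, in percent
#'
#' `100 * (mean_dose_check - mean_dose_tps) / mean_dose_tps`: positive when
#' the independent check computes a hotter target than the planning system.
#' The sign convention is fixed package-wide; control limits are symmetric,
#' so downstream results are sign-robust.
#'
#' @param target A target result with positive `mean_dose_tps` and
#'   `mean_dose_check`.
#' @return Signed percentage (scalar).
#' @examples
#' mean_dose_diff_pct(list(roi_name = "PTV", mean_dose_tps = 70,
#'                         mean_dose_check = 69.3))  # -1
#' @export
mean_dose_diff_pct <- function(target) {
  if (!is_scalar_number(target$mean_dose_tps) || target$mean_dose_tps <= 0) {
    pc_abort("TPS mean dose must be > 0", "pc_invalid_record_error")
  }
  100 * (target$mean_dose_check - target$mean_dose_tps) / target$mean_dose_tps
}

majority_label <- function(x) {
  tab <- sort(table(x), decreasing = TRUE)
  # ties break alphabetically (sort is stable on the already-sorted names)
  nm <- names(tab)[tab == max(tab)]
  sort(nm)[1]
}

#' Flatten approved plan-check documents into the record table
#'
#' One row per approved document; documents without an approval stamp (or
#' without targets) are excluded and listed in the `exclusions` attribute
#' with a reason. The row carries the primary target only, its signed
#' mean-dose discrepancy, and the plan-level gamma pass rate. Beam-level
#' energy and MLC mode collapse to the majority label across beams; plans
#' whose beams disagree get `multi_energy`/`multi_mlc` flags.
#'
#' @param docs List of [plan_check_document()] objects.
#' @param paths Optional character vector of source paths (same length),
#'   carried into the table for traceability.
#' @return A tibble with columns `patient_name`, `patient_id`, `plan_name`,
#'   `approved_at` (POSIXct UTC), `approver`, `role`, `tps`, `machine`,
#'   `energy_label`, `mlc_mode`, `target_name`, `mean_dose_diff_pct`,
#'   `gamma_pass_pct`, `multi_energy`, `multi_mlc`, `path`. Attribute
#'   `exclusions`: tibble of (`patient_id`, `plan_name`, `reason`).
#' @export
build_records <- function(docs, paths = NULL) {
  if (is.null(paths)) paths <- rep(NA_character_, length(docs))
  rows <- list(); excl <- list()
  for (i in seq_along(docs)) {
    doc <- docs[[i]]
    if (length(doc$approvals) == 0) {
      excl[[length(excl) + 1]] <- tibble::tibble(
        patient_id = doc$patient_id, plan_name = doc$plan_name,
        reason = "unapproved")
      next
    }
    if (length(doc$targets) == 0) {
      excl[[length(excl) + 1]] <- tibble::tibble(
        patient_id = doc$patient_id, plan_name = doc$plan_name,
        reason = "no targets")
      next
    }
    # the final (latest) approval stamp defines the record's approval
    appr_times <- parse_iso_datetime(
      vapply(doc$approvals, `[[`, "", "approved_at"))
    last <- which.max(appr_times)
    primary <- select_primary_target(doc$targets)
    energies <- vapply(doc$beams, `[[`, "", "energy_label")
    modes <- vapply(doc$beams, `[[`, "", "mlc_mode")
    rows[[length(rows) + 1]] <- tibble::tibble(
      patient_name = doc$patient_name, patient_id = doc$patient_id,
      plan_name = doc$plan_name, approved_at = appr_times[last],
      approver = doc$approvals[[last]]$approver_name,
      role = doc$approvals[[last]]$role,
      tps = doc$tps, machine = doc$machine,
      energy_label = if (length(energies)) majority_label(energies)
                     else NA_character_,
      mlc_mode = if (length(modes)) majority_label(modes)
                 else NA_character_,
      target_name = primary$roi_name,
      mean_dose_diff_pct = mean_dose_diff_pct(primary),
      gamma_pass_pct = doc$gamma_pass_pct,
      multi_energy = length(unique(energies)) > 1,
      multi_mlc = length(unique(modes)) > 1,
      path = paths[i])
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else empty_record_table()
  attr(out, "exclusions") <- if (length(excl)) dplyr::bind_rows(excl) else
    tibble::tibble(patient_id = character(), plan_name = character(),
                   reason = character())
  out
}

empty_record_table <- function() {
  tibble::tibble(
    patient_name = character(), patient_id = character(),
    plan_name = character(),
    approved_at = as.POSIXct(character(), tz = "UTC"),
    approver = character(), role = character(), tps = character(),
    machine = character(), energy_label = character(),
    mlc_mode = character(), target_name = character(),
    mean_dose_diff_pct = numeric(), gamma_pass_pct = numeric(),
    multi_energy = logical(), multi_mlc = logical(), path = character())
}

FILTERABLE_COLUMNS <- c("patient_name", "patient_id", "plan_name", "tps",
                        "machine", "energy_label", "mlc_mode", "approver",
                        "role", "target_name")

#' Specify a record filter
#'
#' Per-column patterns combined conjunctively. Each pattern is either
#' `"all"` / `NULL` (no constraint), a wildcard `"*X"` matching records
#' whose field contains `X` case-insensitively (so `"*PROS"` matches
#' `PROS`, `PROSTATE`, `PH1_prostate` and `PH1 Pros`, coping with
#' inconsistent plan naming), or a bare string matched exactly. A date
#' window on the approval timestamp is given via `date_from` / `date_to`
#' (inclusive ISO dates).
#'
#' @param ... Named patterns; names from `plan_name`, `tps`, `machine`,
#'   `energy_label`, `mlc_mode`, `approver`, `role`, `patient_name`,
#'   `patient_id`, `target_name`.
#' @param date_from,date_to Optional ISO date strings bounding
#'   `approved_at`.
#' @return A list of class `filter_spec`. An empty spec matches everything.
#' @export
filter_spec <- function(..., date_from = NULL, date_to = NULL) {
  pats <- list(...)
  if (length(pats) && (is.null(names(pats)) || any(names(pats) == ""))) {
    pc_abort("all filter patterns must be named", "pc_config_error")
  }
  bad <- setdiff(names(pats), FILTERABLE_COLUMNS)
  if (length(bad)) {
    pc_abort(sprintf("unknown filter column(s): %s",
                     paste(bad, collapse = ", ")), "pc_config_error")
  }
  structure(list(patterns = pats, date_from = date_from, date_to = date_to),
            class = "filter_spec")
}

#' Filter the record table
#'
#' Applies a [filter_spec()] conjunctively across columns, preserving the
#' original record order. Wildcard patterns are case-insensitive substring
#' matches; bare patterns are exact.
#'
#' @param records Record tibble from [build_records()].
#' @param f A [filter_spec()].
#' @return The matching subset, original order.
#' @export
apply_filter <- function(records, f) {
  stopifnot(inherits(f, "filter_spec"))
  keep <- rep(TRUE, nrow(records))
  for (col in names(f$patterns)) {
    pat <- f$patterns[[col]]
    # wildcard text is matched literally (fixed), not as a regex
    vals <- records[[col]]
    if (is.null(pat) || identical(pat, "all")) next
    keep <- keep & if (startsWith(pat, "*")) {
      needle <- tolower(substring(pat, 2))
      !is.na(vals) & grepl(needle, tolower(vals), fixed = TRUE)
    } else {
      !is.na(vals) & vals == pat
    }
  }
  if (!is.null(f$date_from)) {
    keep <- keep & records$approved_at >= parse_iso_datetime(f$date_from)
  }
  if (!is.null(f$date_to)) {
    keep <- keep &
      records$approved_at < parse_iso_datetime(f$date_to) + 86400
  }
  out <- records[keep, , drop = FALSE]
  attr(out, "exclusions") <- NULL
  out
}

#' Summary statistics of a plan-check cohort
#'
#' The summary block of a filtered cohort: number of checks, mean, maximum
#' absolute and sample standard deviation (n - 1) of the signed mean-dose
#' discrepancies, and mean and minimum gamma pass rates. Signed extremes
#' are reported alongside the absolute maximum.
#'
#' @param records Non-empty record tibble.
#' @return One-row tibble: `n`, `mean_diff_pct`, `max_abs_diff_pct`,
#'   `min_diff_pct`, `max_diff_pct`, `sd_diff_pct` (NA for n = 1),
#'   `mean_gamma_pct`, `min_gamma_pct`.
#' @export
summarize_records <- function(records) {
  n <- nrow(records)
  if (n == 0) pc_abort("empty cohort: nothing to summarize",
                       "pc_empty_cohort_error")
  d <- records$mean_dose_diff_pct
  g <- records$gamma_pass_pct
  tibble::tibble(
    n = n, mean_diff_pct = mean(d), max_abs_diff_pct = max(abs(d)),
    min_diff_pct = min(d), max_diff_pct = max(d),
    sd_diff_pct = if (n >= 2) sd(d) else NA_real_,
    mean_gamma_pct = mean(g), min_gamma_pct = min(g))
}

GROUPABLE_AXES <- c("tps", "machine", "energy_label", "mlc_mode")

#' Per-group summary statistics along one axis
#'
#' Partitions records by one population axis (planning system, machine,
#' energy or MLC mode) and summarizes each group. The partition is
#' exhaustive and disjoint: group sizes sum to the total.
#'
#' @param records Record tibble.
#' @param axis One of `"tps"`, `"machine"`, `"energy_label"`, `"mlc_mode"`.
#' @return A tibble with the axis value in the first column followed by the
#'   [summarize_records()] columns, one row per observed group.
#' @export
group_summarize <- function(records, axis) {
  if (!axis %in% GROUPABLE_AXES) {
    pc_abort(sprintf("unknown grouping axis '%s'", axis), "pc_config_error")
  }
  vals <- sort(unique(records[[axis]]))
  out <- lapply(vals, function(v) {
    s <- summarize_records(records[records[[axis]] == v, , drop = FALSE])
    dplyr::bind_cols(tibble::as_tibble(setNames(list(v), axis)), s)
  })
  dplyr::bind_rows(out)
}
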