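#' The plan-check / DVH JSON dialect
#'
#' A vendor-neutral, versioned JSON dialect for per-patient plan-check
#' documents and dose-volume-histogram (DVH) documents, mirroring the field
#' inventory that independent secondary-dose-check systems store for every
#' approved check: patient demographics, plan and beam parameters, approval
#' stamps, per-target mean doses from both the treatment planning system
#' (TPS) and the independent check, the 3D gamma pass rate, and cumulative
#' DVH curves per structure from both calculation sources.
#'
#' Two files per patient plan are expected — one plan-check document and one
#' DVH document — linked by exact equality of `patient_id` + `plan_name`.
#' Doses are total plan doses in Gy (`n_fractions` is carried separately);
#' volumes are percent of structure volume; all timestamps are ISO-8601 in
#' UTC. Machine-readable JSON-schema files for both document types ship in
#' `system.file("schema", package = "plancheckminer")`.
#'
#' @name plancheck-dialect
NULL

PC_SCHEMA_VERSION <- "1.0"
MLC_MODES <- c("static", "dynamic", "vmat")
DVH_SOURCES <- c("tps", "check")

#' Construct a plan-check document
#'
#' Builds and validates an in-memory plan-check document, the unit stored as
#' one JSON file per approved (or pending) secondary dose-calculation check.
#'
#' @param patient_id Opaque patient identifier.
#' @param patient_name Patient name string.
#' @param patient_sex Sex string.
#' @param birth_date ISO-8601 date string.
#' @param plan_name Plan name as typed by the planner (nomenclature is
#'   inconsistent in practice; downstream filtering is wildcard-based).
#' @param institution Institution name.
#' @param machine Treatment machine (linac) name.
#' @param tps Treatment planning system name, e.g. `"Eclipse"`, `"iPlan"`.
#' @param approvals List of approval stamps, each a list with
#'   `approver_name`, `role`, `approved_at` (ISO-8601 datetime). May be
#'   empty: such a document is an unapproved check and is excluded from
#'   analysis downstream.
#' @param beams List of beam records, each a list with `beam_name`,
#'   `energy_label`, `mlc_mode` (one of `"static"`, `"dynamic"`, `"vmat"`),
#'   `gantry_angles`, `collimator_angles` (degrees in `[0, 360)`) and `mu`.
#' @param targets List of target results, each a list with `roi_name`,
#'   `mean_dose_tps`, `mean_dose_check` (Gy, strictly positive) and optional
#'   `coverage_90_pct`.
#' @param gamma_pass_pct 3D gamma pass rate, percent in `[0, 100]`.
#' @param gamma_criteria Criteria label, e.g. `"3%/3mm"`.
#' @param n_fractions Positive integer number of fractions.
#' @param notes Free-text notes.
#' @param created_at ISO-8601 datetime the check was created.
#' @return A validated object of class `plan_check_document`.
#' @seealso [read_plan_check()], [write_plan_check()]
#' @export
plan_check_document <- function(patient_id, patient_name, patient_sex,
                                birth_date, plan_name, institution, machine,
                                tps, approvals = list(), beams = list(),
                                targets = list(), gamma_pass_pct,
                                gamma_criteria = "3%/3mm", n_fractions,
                                notes = "", created_at) {
  # normalize numeric storage types so JSON round-trips are type-stable
  # (whole-number doses parse as integers otherwise)
  beams <- lapply(beams, function(b) {
    b$gantry_angles <- as.numeric(unlist(b$gantry_angles))
    b$collimator_angles <- as.numeric(unlist(b$collimator_angles))
    if (!is.null(b$mu)) b$mu <- as.numeric(b$mu)
    b
  })
  targets <- lapply(targets, function(t) {
    for (f in c("mean_dose_tps", "mean_dose_check", "coverage_90_pct")) {
      if (!is.null(t[[f]])) t[[f]] <- as.numeric(t[[f]])
    }
    t
  })
  doc <- structure(list(
    schema_version = PC_SCHEMA_VERSION,
    document_type = "plan_check",
    patient_id = patient_id, patient_name = patient_name,
    patient_sex = patient_sex, birth_date = birth_date,
    plan_name = plan_name, institution = institution,
    machine = machine, tps = tps,
    approvals = approvals, beams = beams, targets = targets,
    gamma_pass_pct = as.numeric(gamma_pass_pct),
    gamma_criteria = gamma_criteria,
    n_fractions = if (is_scalar_number(n_fractions))
      as.integer(n_fractions) else n_fractions,
    notes = notes, created_at = created_at
  ), class = "plan_check_document")
  validate_plan_check(doc)
}

#' Construct a DVH document
#'
#' @param patient_id,plan_name Linkage key shared with the plan-check
#'   document of the same patient plan.
#' @param n_fractions Positive integer.
#' @param structures Non-empty list; each element a list with `roi_name`
#'   (canonical name assigned by the check system), `tps_roi_name` (original
#'   TPS name, searchable to cope with inconsistent nomenclature), `curves`
#'   (list of [dvh_curve()] objects, at least one, sources from
#'   `"tps"`/`"check"`) and optional `constraints` (each with at least one of
#'   `volume_pct` / `dose_gy`, plus `achieved_value` and `result` in
#'   `"pass"`/`"warn"`/`"fail"`).
#' @return A validated object of class `dvh_document`.
#' @export
dvh_document <- function(patient_id, plan_name, n_fractions, structures) {
  structures <- lapply(structures, function(s) {
    if (is.list(s$constraints)) {
      s$constraints <- lapply(s$constraints, function(con) {
        for (f in c("volume_pct", "dose_gy", "achieved_value")) {
          if (!is.null(con[[f]])) con[[f]] <- as.numeric(con[[f]])
        }
        con
      })
    }
    s
  })
  doc <- structure(list(
    schema_version = PC_SCHEMA_VERSION,
    document_type = "dvh",
    patient_id = patient_id, plan_name = plan_name,
    n_fractions = if (is_scalar_number(n_fractions))
      as.integer(n_fractions) else n_fractions,
    structures = structures
  ), class = "dvh_document")
  validate_dvh(doc)
}

#' Construct a cumulative DVH curve
#'
#' A cumulative dose-volume curve V(d): the percentage of a structure's
#' volume receiving at least dose d. Starts at 100% at 0 Gy and is
#' non-increasing in dose.
#'
#' @param source `"tps"` (planning system) or `"check"` (independent
#'   recalculation).
#' @param dose_gy Strictly increasing dose grid starting at 0 Gy.
#' @param volume_pct Volumes in percent, same length as `dose_gy`,
#'   non-increasing, first value 100.
#' @return An object of class `dvh_curve`.
#' @export
dvh_curve <- function(source, dose_gy, volume_pct) {
  crv <- structure(list(source = source, dose_gy = as.numeric(dose_gy),
                        volume_pct = as.numeric(volume_pct)),
                   class = "dvh_curve")
  validate_dvh_curve(crv)
}

#' Validate a plan-check document
#'
#' Checks every dialect invariant; raises a classed `pc_validation_error`
#' naming the offending field. Validation is total: a document that passes
#' has every field well-formed.
#'
#' @param doc A `plan_check_document`.
#' @param path Optional source path quoted in error messages.
#' @return `doc`, invisibly unchanged, if valid.
#' @export
validate_plan_check <- function(doc, path = NULL) {
  req <- function(field, ok, detail) {
    if (!isTRUE(ok)) pc_validation_error(field, detail, path)
  }
  for (f in c("patient_id", "patient_name", "patient_sex", "birth_date",
              "plan_name", "institution", "machine", "tps", "gamma_criteria",
              "notes", "created_at")) {
    req(f, is_scalar_string(doc[[f]]), "must be a single string")
  }
  req("gamma_pass_pct", is_scalar_number(doc$gamma_pass_pct) &&
        doc$gamma_pass_pct >= 0 && doc$gamma_pass_pct <= 100,
      "must be a percentage in [0, 100]")
  req("n_fractions", is_scalar_number(doc$n_fractions) &&
        doc$n_fractions >= 1 && doc$n_fractions == round(doc$n_fractions),
      "must be a positive integer")
  req("approvals", is.list(doc$approvals), "must be a list (possibly empty)")
  for (a in doc$approvals) {
    req("approvals", is_scalar_string(a$approver_name) &&
          is_scalar_string(a$role), "each stamp needs approver_name and role")
    ok <- tryCatch({ parse_iso_datetime(a$approved_at); TRUE },
                   error = function(e) FALSE)
    req("approved_at", ok, "must be an ISO-8601 datetime")
  }
  req("beams", is.list(doc$beams), "must be a list")
  for (b in doc$beams) {
    req("mlc_mode", is_scalar_string(b$mlc_mode) && b$mlc_mode %in% MLC_MODES,
        sprintf("must be one of %s", paste(MLC_MODES, collapse = "/")))
    req("energy_label", is_scalar_string(b$energy_label), "must be a string")
    for (ang in c("gantry_angles", "collimator_angles")) {
      v <- as.numeric(unlist(b[[ang]]))
      req(ang, !anyNA(v) && all(v >= 0 & v < 360),
          "angles must lie in [0, 360)")
    }
    req("mu", is_scalar_number(b$mu) && b$mu >= 0, "must be nonnegative")
  }
  req("targets", is.list(doc$targets), "must be a list")
  for (t in doc$targets) {
    req("roi_name", is_scalar_string(t$roi_name), "must be a string")
    req("mean_dose_tps", is_scalar_number(t$mean_dose_tps) &&
          t$mean_dose_tps > 0, "must be a dose in Gy > 0")
    req("mean_dose_check", is_scalar_number(t$mean_dose_check) &&
          t$mean_dose_check > 0, "must be a dose in Gy > 0")
    if (!is.null(t$coverage_90_pct)) {
      req("coverage_90_pct", is_scalar_number(t$coverage_90_pct) &&
            t$coverage_90_pct >= 0 && t$coverage_90_pct <= 100,
          "must be a percentage in [0, 100] or absent")
    }
  }
  invisible(doc)
}

#' Validate a DVH document
#'
#' @inheritParams validate_plan_check
#' @param doc A `dvh_document`.
#' @return `doc`, invisibly, if valid.
#' @export
validate_dvh <- function(doc, path = NULL) {
  req <- function(field, ok, detail) {
    if (!isTRUE(ok)) pc_validation_error(field, detail, path)
  }
  for (f in c("patient_id", "plan_name")) {
    req(f, is_scalar_string(doc[[f]]), "must be a single string")
  }
  req("n_fractions", is_scalar_number(doc$n_fractions) &&
        doc$n_fractions >= 1, "must be a positive integer")
  req("structures", is.list(doc$structures) && length(doc$structures) >= 1,
      "must be a non-empty list")
  for (s in doc$structures) {
    req("roi_name", is_scalar_string(s$roi_name), "must be a string")
    req("tps_roi_name", is_scalar_string(s$tps_roi_name), "must be a string")
    req("curves", is.list(s$curves) && length(s$curves) >= 1,
        "each structure needs at least one curve")
    for (crv in s$curves) validate_dvh_curve(crv, path = path)
    for (con in s$constraints %||% list()) {
      req("constraints", !is.null(con$volume_pct) || !is.null(con$dose_gy),
          "each constraint needs volume_pct and/or dose_gy")
      req("result", is_scalar_string(con$result) &&
            con$result %in% c("pass", "warn", "fail"),
          "must be one of pass/warn/fail")
    }
  }
  invisible(doc)
}

#' Validate a cumulative DVH curve
#'
#' @param crv A `dvh_curve`.
#' @param path Optional source path for error messages.
#' @return `crv`, invisibly, if valid.
#' @export
validate_dvh_curve <- function(crv, path = NULL) {
  req <- function(field, ok, detail) {
    if (!isTRUE(ok)) pc_validation_error(field, detail, path)
  }
  req("source", is_scalar_string(crv$source) && crv$source %in% DVH_SOURCES,
      "must be 'tps' or 'check'")
  d <- crv$dose_gy; v <- crv$volume_pct
  req("dose_gy", is.numeric(d) && length(d) >= 2 && !anyNA(d),
      "must be a numeric grid of length >= 2")
  req("dose_gy", d[1] == 0 && all(diff(d) > 0),
      "must be strictly increasing and start at 0")
  req("volume_pct", is.numeric(v) && length(v) == length(d) && !anyNA(v),
      "must match dose_gy in length")
  req("volume_pct", all(v >= 0 & v <= 100), "must lie in [0, 100]")
  req("volume_pct", all(diff(v) <= 0), "must be monotone non-increasing")
  req("volume_pct", v[1] == 100, "must start at 100% at 0 Gy")
  invisible(crv)
}

#' @export
print.plan_check_document <- function(x, ...) {
  appr <- if (length(x$approvals)) {
    sprintf("approved (%d stamp%s)", length(x$approvals),
            if (length(x$approvals) > 1) "s" else "")
  } else "UNAPPROVED"
  cat(sprintf(
    "<plan_check_document> %s / '%s' [%s]\n  tps=%s machine=%s beams=%d targets=%d gamma=%.1f%% (%s)\n",
    x$patient_id, x$plan_name, appr, x$tps, x$machine,
    length(x$beams), length(x$targets), x$gamma_pass_pct, x$gamma_criteria))
  invisible(x)
}

#' @export
print.dvh_document <- function(x, ...) {
  cat(sprintf("<dvh_document> %s / '%s': %d structure(s): %s\n",
              x$patient_id, x$plan_name, length(x$structures),
              paste(vapply(x$structures, `[[`, "", "roi_name"),
                    collapse = ", ")))
  invisible(x)
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve> source=%s, %d points, dose 0-%.4g Gy\n",
              x$source, length(x$dose_gy), max(x$dose_gy)))
  invisible(x)
}
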