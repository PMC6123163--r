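# JSON (de)serialization of the dialect. jsonlite does the parsing; these
# functions only map between the JSON tree and the validated S3 documents.

read_json_tree <- function(path) {
  if (!file.exists(path)) {
    pc_abort(sprintf("file '%s' does not exist", path), "pc_io_error")
  }
  tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) pc_parse_error(path, conditionMessage(e))
  )
}

as_num <- function(x) as.numeric(unlist(x, use.names = FALSE))

#' Read a plan-check JSON file
#'
#' Parses and fully validates one plan-check document. Malformed JSON raises
#' a `pc_parse_error` carrying the path; a dialect violation raises a
#' `pc_validation_error` naming the offending field. Both are ordinary
#' conditions, so batch drivers ([ingest()]) can skip and log bad files.
#'
#' @param path Path to a UTF-8 JSON file in the plan-check dialect.
#' @return A validated [plan_check_document()].
#' @examples
#' doc <- plan_check_document(
#'   patient_id = "PT00001", patient_name = "Doe, Jane", patient_sex = "F",
#'   birth_date = "1955-03-02", plan_name = "PROSTATE", institution = "Clinic",
#'   machine = "LA1", tps = "Eclipse",
#'   approvals = list(list(approver_name = "Physicist A", role = "physicist",
#'                         approved_at = "2016-05-01T10:00:00Z")),
#'   beams = list(list(beam_name = "B1", energy_label = "6MV",
#'                     mlc_mode = "vmat", gantry_angles = c(180, 0),
#'                     collimator_angles = 30, mu = 450)),
#'   targets = list(list(roi_name = "PTV", mean_dose_tps = 70,
#'                       mean_dose_check = 69.5, coverage_90_pct = 98)),
#'   gamma_pass_pct = 98.5, n_fractions = 35,
#'   created_at = "2016-04-30T16:00:00Z")
#' f <- tempfile(fileext = ".json")
#' write_plan_check(doc, f)
#' identical(read_plan_check(f)$plan_name, "PROSTATE")
#' @export
read_plan_check <- function(path) {
  x <- read_json_tree(path)
  if (!identical(x$document_type %||% "plan_check", "plan_check")) {
    pc_validation_error("document_type", "expected 'plan_check'", path)
  }
  doc <- tryCatch(
    plan_check_document(
      patient_id = x$patient_id, patient_name = x$patient_name,
      patient_sex = x$patient_sex, birth_date = x$birth_date,
      plan_name = x$plan_name, institution = x$institution,
      machine = x$machine, tps = x$tps,
      approvals = lapply(x$approvals %||% list(), function(a) {
        list(approver_name = a$approver_name, role = a$role,
             approved_at = a$approved_at)
      }),
      beams = lapply(x$beams %||% list(), function(b) {
        list(beam_name = b$beam_name, energy_label = b$energy_label,
             mlc_mode = b$mlc_mode, gantry_angles = as_num(b$gantry_angles),
             collimator_angles = as_num(b$collimator_angles), mu = b$mu)
      }),
      targets = lapply(x$targets %||% list(), function(t) {
        list(roi_name = t$roi_name, mean_dose_tps = t$mean_dose_tps,
             mean_dose_check = t$mean_dose_check,
             coverage_90_pct = t$coverage_90_pct)
      }),
      gamma_pass_pct = x$gamma_pass_pct,
      gamma_criteria = x$gamma_criteria %||% "3%/3mm",
      n_fractions = x$n_fractions, notes = x$notes %||% "",
      created_at = x$created_at),
    pc_validation_error = function(e) {
      pc_validation_error(e$field, "see dialect invariants", path)
    },
    error = function(e) {
      if (inherits(e, "pc_error")) stop(e)
      pc_validation_error("(document)", conditionMessage(e), path)
    })
  doc
}

#' Read a DVH JSON file
#'
#' Counterpart of [read_plan_check()] for the dose-volume-histogram
#' document: per-structure cumulative DVH curves from the planning system
#' and the independent check, with optional dose/volume constraints. Both
#' the canonical `roi_name` and the original `tps_roi_name` are preserved so
#' structure search can cope with inconsistent contour nomenclature.
#'
#' @param path Path to a UTF-8 JSON file in the DVH dialect.
#' @return A validated [dvh_document()].
#' @export
read_dvh <- function(path) {
  x <- read_json_tree(path)
  if (!identical(x$document_type %||% "dvh", "dvh")) {
    pc_validation_error("document_type", "expected 'dvh'", path)
  }
  tryCatch(
    dvh_document(
      patient_id = x$patient_id, plan_name = x$plan_name,
      n_fractions = x$n_fractions,
      structures = lapply(x$structures %||% list(), function(s) {
        list(roi_name = s$roi_name, tps_roi_name = s$tps_roi_name,
             curves = lapply(s$curves %||% list(), function(crv) {
               dvh_curve(crv$source, as_num(crv$dose_gy), as_num(crv$volume_pct))
             }),
             constraints = lapply(s$constraints %||% list(), function(con) {
               list(volume_pct = con$volume_pct, dose_gy = con$dose_gy,
                    achieved_value = con$achieved_value, result = con$result)
             }))
      })),
    pc_validation_error = function(e) {
      pc_validation_error(e$field, "see dialect invariants", path)
    },
    error = function(e) {
      if (inherits(e, "pc_error")) stop(e)
      pc_validation_error("(document)", conditionMessage(e), path)
    })
}

json_write <- function(x, path) {
  ok <- tryCatch({
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.exists(path)) {
    pc_abort(sprintf("cannot write '%s'", path), "pc_io_error")
  }
  invisible(path)
}

#' Write a plan-check document as JSON
#'
#' Serialization is lossless: `read_plan_check(write_plan_check(doc))`
#' reproduces every field (bit-exact strings and integers; reals to full
#' double precision). Array-valued fields stay JSON arrays even at length 1.
#'
#' @param doc A validated [plan_check_document()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plan_check <- function(doc, path) {
  validate_plan_check(doc)
  x <- unclass(doc)
  x$approvals <- lapply(x$approvals, identity)
  x$beams <- lapply(x$beams, function(b) {
    b$gantry_angles <- I(as.numeric(b$gantry_angles))
    b$collimator_angles <- I(as.numeric(b$collimator_angles))
    b
  })
  json_write(x, path)
}

#' Write a DVH document as JSON
#'
#' @param doc A validated [dvh_document()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dvh <- function(doc, path) {
  validate_dvh(doc)
  x <- unclass(doc)
  x$structures <- lapply(x$structures, function(s) {
    s$curves <- lapply(s$curves, function(crv) {
      list(source = crv$source, dose_gy = I(crv$dose_gy),
           volume_pct = I(crv$volume_pct))
    })
    if (is.null(s$constraints)) s$constraints <- list()
    s
  })
  json_write(x, path)
}
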