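# In-code fixtures: small valid documents and record tables built fresh for
# each test, no stored data files.

fix_approval <- function(when = "2016-05-01T10:00:00Z",
                         who = "Physicist A", role = "physicist") {
  list(approver_name = who, role = role, approved_at = when)
}

fix_beam <- function(energy = "6MV", mlc = "vmat") {
  list(beam_name = "B1", energy_label = energy, mlc_mode = mlc,
       gantry_angles = c(181.0, 179.0), collimator_angles = 30,
       mu = 450.5)
}

fix_target <- function(name = "PTV", tps = 70, check = 69.3,
                       coverage = 97.5) {
  list(roi_name = name, mean_dose_tps = tps, mean_dose_check = check,
       coverage_90_pct = coverage)
}

fix_plan_doc <- function(patient_id = "PT00001", plan_name = "PROSTATE",
                         approvals = list(fix_approval()),
                         beams = list(fix_beam()),
                         targets = list(fix_target()),
                         gamma = 98, machine = "LA1", tps = "Eclipse",
                         patient_name = "Doe, Jane") {
  plan_check_document(
    patient_id = patient_id, patient_name = patient_name,
    patient_sex = "F", birth_date = "1955-03-02",
    plan_name = plan_name, institution = "Clinic", machine = machine,
    tps = tps, approvals = approvals, beams = beams, targets = targets,
    gamma_pass_pct = gamma, n_fractions = 35,
    created_at = "2016-04-30T16:00:00Z")
}

fix_structure <- function(roi = "Rectum", tps_roi = roi, d50 = 35,
                          dmax = 70, steepness = 0.2) {
  crv <- make_dvh_curve(list(d50 = d50, steepness = steepness, dmax = dmax))
  list(roi_name = roi, tps_roi_name = tps_roi,
       curves = list(crv, dvh_curve("check", crv$dose_gy * 1.01,
                                    crv$volume_pct)),
       constraints = list(list(volume_pct = 50, dose_gy = 45,
                               achieved_value = 20, result = "pass")))
}

fix_dvh_doc <- function(patient_id = "PT00001", plan_name = "PROSTATE",
                        structures = list(fix_structure())) {
  dvh_document(patient_id = patient_id, plan_name = plan_name,
               n_fractions = 35, structures = structures)
}

# a record table with controllable diffs/gammas, bypassing document I/O
fix_records <- function(diffs, gammas = rep(99, length(diffs)),
                        plan_names = rep("PROSTATE", length(diffs)),
                        machines = rep("LA1", length(diffs)),
                        tps = rep("Eclipse", length(diffs)),
                        energies = rep("6MV", length(diffs)),
                        mlc = rep("vmat", length(diffs))) {
  n <- length(diffs)
  tibble::tibble(
    patient_name = sprintf("Pt %d", seq_len(n)),
    patient_id = sprintf("PT%05d", seq_len(n)),
    plan_name = plan_names,
    approved_at = as.POSIXct("2016-01-01", tz = "UTC") +
      seq_len(n) * 3600,
    approver = "Physicist A", role = "physicist",
    tps = tps, machine = machines, energy_label = energies,
    mlc_mode = mlc, target_name = "PTV",
    mean_dose_diff_pct = diffs, gamma_pass_pct = gammas,
    multi_energy = FALSE, multi_mlc = FALSE, path = NA_character_)
}

# independent brute-force oracle for wildcard filtering: per-record
# case-insensitive substring predicate scan
oracle_filter_idx <- function(values, needle) {
  which(vapply(values, function(v) {
    grepl(tolower(needle), tolower(v), fixed = TRUE)
  }, TRUE))
}
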