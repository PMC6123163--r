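# Seeded synthetic cohorts: statistically controlled plan-check/DVH file
# pairs so every downstream module is testable without clinical data. Each
# stratum fixes the plan-population axes (TPS x machine x energy x MLC mode
# x site) and the generating distributions for the primary-target mean-dose
# discrepancy and the gamma pass rate; the returned manifest is the ground
# truth that parameter-recovery tests check against.

#' Specify one cohort stratum
#'
#' A stratum is one cell of the clinic's plan population: a planning system,
#' machine, energy and MLC mode, a treatment-site label used as the
#' plan-name stem, and the generating distributions for the mean-dose
#' discrepancy (Normal, unbounded) and gamma pass rate (Normal truncated to
#' `[0, 100]`).
#'
#' @param weight Sampling probability of the stratum; weights across a
#'   cohort must sum to 1.
#' @param tps,machine,energy_label,mlc_mode Plan-population axes; `mlc_mode`
#'   one of `"static"`, `"dynamic"`, `"vmat"`.
#' @param site_label Treatment-site stem, e.g. `"PROSTATE"`. Emitted plan
#'   names vary the spelling (`"PROS"`, `"PH1_prostate"`, `"PH1 Pros"`, ...)
#'   to emulate the inconsistent nomenclature wildcard filtering must cope
#'   with.
#' @param diff_mean_pct,diff_sd_pct Mean and SD (percent) of the signed
#'   primary-target mean-dose discrepancy, `100 * (check - TPS) / TPS`.
#' @param gamma_mean_pct,gamma_sd_pct Mean and SD of the gamma pass rate
#'   before truncation to `[0, 100]`.
#' @param rx_dose_gy Prescription (primary-target TPS mean) dose, Gy.
#' @param n_fractions Fractionation of the site.
#' @param oar_templates List of organ-at-risk templates, each a list with
#'   `roi_name`, `name_variants` (spellings drawn for the stored TPS name)
#'   and `dvh_shape_params` (`d50`, `steepness`, `dmax` for
#'   [make_dvh_curve()]).
#' @param contam_frac Optional heavy-tail contamination: fraction of
#'   discrepancy draws taken from a Normal with `contam_sd_scale` times the
#'   stratum SD. Default 0 (pure Normal).
#' @param contam_sd_scale SD multiplier for contaminated draws.
#' @return A list of class `stratum_spec`.
#' @export
stratum_spec <- function(weight, tps, machine, energy_label, mlc_mode,
                         site_label, diff_mean_pct, diff_sd_pct,
                         gamma_mean_pct, gamma_sd_pct,
                         rx_dose_gy = 60, n_fractions = 30,
                         oar_templates = default_oar_templates(site_label),
                         contam_frac = 0, contam_sd_scale = 3) {
  stopifnot(weight >= 0, weight <= 1, diff_sd_pct > 0, gamma_sd_pct > 0,
            mlc_mode %in% MLC_MODES, gamma_mean_pct >= 0,
            gamma_mean_pct <= 100, rx_dose_gy > 0,
            contam_frac >= 0, contam_frac < 1)
  structure(list(weight = weight, tps = tps, machine = machine,
                 energy_label = energy_label, mlc_mode = mlc_mode,
                 site_label = site_label, diff_mean_pct = diff_mean_pct,
                 diff_sd_pct = diff_sd_pct, gamma_mean_pct = gamma_mean_pct,
                 gamma_sd_pct = gamma_sd_pct, rx_dose_gy = rx_dose_gy,
                 n_fractions = n_fractions, oar_templates = oar_templates,
                 contam_frac = contam_frac,
                 contam_sd_scale = contam_sd_scale),
            class = "stratum_spec")
}

#' Default organ-at-risk templates for a site label
#'
#' Rectum + bladder for prostate-like sites, generic OARs otherwise, each
#' with name variants and sigmoid DVH shape parameters plausible for a
#' conventionally fractionated plan.
#'
#' @param site_label Site stem string.
#' @return List of OAR templates (see [stratum_spec()]).
#' @export
default_oar_templates <- function(site_label) {
  if (grepl("PROS", site_label, ignore.case = TRUE)) {
    list(
      list(roi_name = "Rectum",
           name_variants = c("Rectum", "RECTUM_JD", "rectum", "Rectum_1"),
           dvh_shape_params = list(d50 = 35, steepness = 0.15, dmax = 76)),
      list(roi_name = "Bladder",
           name_variants = c("Bladder", "BLADDER", "bladder_w"),
           dvh_shape_params = list(d50 = 30, steepness = 0.12, dmax = 78))
    )
  } else {
    list(
      list(roi_name = "OAR1",
           name_variants = c("OAR1", "oar_1", "OAR1_JD"),
           dvh_shape_params = list(d50 = 20, steepness = 0.2, dmax = 55))
    )
  }
}

#' Specify a synthetic cohort
#'
#' @param n_patients Number of linked plan-check/DVH file pairs to emit.
#' @param strata List of [stratum_spec()] objects; weights must sum to 1
#'   (tolerance 1e-9).
#' @param seed Integer RNG seed; identical spec + seed reproduces the
#'   output byte for byte.
#' @param date_range Character vector `c(start, end)` of ISO dates; approval
#'   timestamps are drawn uniformly over this window. The default spans a
#'   three-year clinical accrual window.
#' @param dvh_perturbation_pct Multiplicative dose offset (percent) applied
#'   to the independent-check DVH curve relative to the planning-system
#'   curve, so the two-source comparison surface is exercised. Default 1.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients, strata, seed,
                        date_range = c("2014-04-01", "2017-04-30"),
                        dvh_perturbation_pct = 1) {
  stopifnot(n_patients >= 1, length(strata) >= 1, is.numeric(seed))
  w <- vapply(strata, `[[`, 0, "weight")
  if (abs(sum(w) - 1) > 1e-9) {
    pc_abort(sprintf("stratum weights sum to %.12g, not 1", sum(w)),
             "pc_config_error")
  }
  structure(list(n_patients = as.integer(n_patients), strata = strata,
                 seed = as.integer(seed), date_range = date_range,
                 dvh_perturbation_pct = dvh_perturbation_pct),
            class = "cohort_spec")
}

#' Default single-clinic cohort specification
#'
#' A two-TPS, multi-machine mix whose pooled discrepancy distribution is
#' centred near -0.13% with SD near 1.2% and gamma pass rates near 98%,
#' i.e. the scale of a mature clinical plan-check history.
#'
#' @param n_patients Cohort size.
#' @param seed RNG seed.
#' @return A [cohort_spec()].
#' @export
default_cohort_spec <- function(n_patients = 500, seed = 1) {
  cohort_spec(
    n_patients = n_patients, seed = seed,
    strata = list(
      stratum_spec(0.35, "Eclipse", "LA1", "6MV", "vmat", "PROSTATE",
                   diff_mean_pct = -0.3, diff_sd_pct = 1.0,
                   gamma_mean_pct = 98.5, gamma_sd_pct = 1.2,
                   rx_dose_gy = 78, n_fractions = 39),
      stratum_spec(0.25, "Eclipse", "LA2", "6MV", "dynamic", "BREAST",
                   diff_mean_pct = 0.1, diff_sd_pct = 1.3,
                   gamma_mean_pct = 97.5, gamma_sd_pct = 1.8,
                   rx_dose_gy = 50, n_fractions = 25),
      stratum_spec(0.25, "Eclipse", "LA3", "10MV", "static", "PELVIS",
                   diff_mean_pct = -0.2, diff_sd_pct = 1.2,
                   gamma_mean_pct = 98.0, gamma_sd_pct = 1.5,
                   rx_dose_gy = 45, n_fractions = 25),
      stratum_spec(0.15, "iPlan", "WL1", "6MV", "static", "BRAIN",
                   diff_mean_pct = 0.2, diff_sd_pct = 1.4,
                   gamma_mean_pct = 97.0, gamma_sd_pct = 2.0,
                   rx_dose_gy = 30, n_fractions = 10)
    ))
}

#' Generate a physically plausible cumulative DVH curve
#'
#' Closed-form sigmoid generator: the cumulative volume is a logistic in
#' dose with midpoint `d50` and slope parameter `steepness`, renormalized so
#' that V(0) = 100% exactly and V(`dmax`) = 0% exactly:
#' \deqn{V(d) = 100 \frac{f(d) - f(d_{max})}{f(0) - f(d_{max})}, \quad
#'       f(d) = \frac{1}{1 + e^{s (d - d_{50})}}}
#' For `d50` well inside `(0, dmax)` the midpoint property V(d50) = 50%
#' holds to within a grid step; large `steepness` approaches a step function
#' at `d50` (a target-like DVH), small values give shallow OAR-like curves.
#'
#' @param shape_params List with `d50` (Gy, midpoint), `steepness`
#'   (1/Gy, > 0) and `dmax` (Gy, maximum dose; `0 < d50 < dmax`).
#' @param grid_step Native dose-grid spacing in Gy.
#' @return A validated [dvh_curve()] with source `"tps"`.
#' @examples
#' crv <- make_dvh_curve(list(d50 = 35, steepness = 0.3, dmax = 70))
#' v_at_d(crv, 35)  # ~50
#' @export
make_dvh_curve <- function(shape_params, grid_step = 0.5) {
  d50 <- shape_params$d50; s <- shape_params$steepness
  dmax <- shape_params$dmax
  if (!is_scalar_number(s) || s <= 0) {
    pc_abort("steepness must be positive", "pc_config_error")
  }
  if (!is_scalar_number(d50) || !is_scalar_number(dmax) ||
      d50 <= 0 || d50 >= dmax) {
    pc_abort("require 0 < d50 < dmax", "pc_config_error")
  }
  d <- seq(0, dmax, by = grid_step)
  # close the grid at dmax; snap rather than append when the remainder is
  # negligible, so no two grid points nearly coincide
  if (tail(d, 1) < dmax - 1e-3) d <- c(d, dmax) else d[length(d)] <- dmax
  # logistic is computed on a shifted scale to avoid overflow at large s*d
  f <- stats::plogis(-s * (d - d50))
  v <- 100 * (f - f[length(f)]) / (f[1] - f[length(f)])
  v[1] <- 100; v[length(v)] <- 0
  v <- pmin(100, pmax(0, v))
  dvh_curve("tps", d, v)
}

# Truncated-Normal draws by rejection; truncation bounds far from the mean
# would loop long, but gamma means sit well inside [0, 100] in practice.
rtrunc_norm <- function(n, mean, sd, lo = 0, hi = 100) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

# Plan-name spelling variants for a site stem, echoing real clinic
# nomenclature drift: "PROSTATE" -> PROS / PH1_prostate / PH1 Pros ...
site_name_variants <- function(site_label) {
  ab <- substr(site_label, 1, 4)
  c(site_label,
    ab,
    paste0("PH1_", tolower(site_label)),
    paste0("PH1 ", paste0(substr(ab, 1, 1), tolower(substr(ab, 2, 4)))))
}

#' Generate a linked synthetic cohort on disk
#'
#' Writes `n_patients` plan-check/DVH JSON file pairs under `out_dir` and
#' returns the ground-truth manifest: one row per patient with the stratum,
#' the drawn discrepancy and gamma values, the approval timestamp and both
#' file paths. The manifest is also written as `ground_truth.csv`. Output is
#' deterministic given the spec and its seed (the caller's RNG state is
#' left untouched).
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Output directory, created if needed.
#' @return A tibble manifest (invisibly a plain data frame is avoided;
#'   columns: `patient_id`, `plan_name`, `stratum`, `site_label`, `tps`,
#'   `machine`, `energy_label`, `mlc_mode`, `diff_pct`, `gamma_pct`,
#'   `approved_at`, `plan_check_path`, `dvh_path`).
#' @export
generate_cohort <- function(spec, out_dir) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    pc_abort(sprintf("cannot create output directory '%s'", out_dir),
             "pc_io_error")
  }
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)

  n <- spec$n_patients
  w <- vapply(spec$strata, `[[`, 0, "weight")
  stratum_idx <- sample.int(length(spec$strata), n, replace = TRUE, prob = w)

  t0 <- as.numeric(parse_iso_datetime(spec$date_range[1]))
  t1 <- as.numeric(parse_iso_datetime(spec$date_range[2])) + 86399
  approved_t <- round(runif(n, t0, t1))

  approvers <- list(
    physicist = c("Physicist A", "Physicist B"),
    therapist = c("Therapist C", "Therapist D", "Therapist E"))
  surnames <- c("Smith", "Jones", "Nguyen", "Brown", "Wilson", "Taylor",
                "Lee", "Martin", "White", "Chen")

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    st <- spec$strata[[stratum_idx[i]]]
    pid <- sprintf("PT%05d", i)

    diff_i <- if (st$contam_frac > 0 && runif(1) < st$contam_frac) {
      rnorm(1, st$diff_mean_pct, st$diff_sd_pct * st$contam_sd_scale)
    } else {
      rnorm(1, st$diff_mean_pct, st$diff_sd_pct)
    }
    gamma_i <- rtrunc_norm(1, st$gamma_mean_pct, st$gamma_sd_pct)
    plan_name <- sample(site_name_variants(st$site_label), 1)

    # primary target carries the drawn discrepancy and the highest TPS dose;
    # extra nested targets get strictly lower doses and independent diffs
    rx <- st$rx_dose_gy
    targets <- list(list(
      roi_name = "PTV", mean_dose_tps = rx,
      mean_dose_check = rx * (1 + diff_i / 100),
      coverage_90_pct = round(rtrunc_norm(1, 97, 2, 80, 100), 2)))
    n_extra <- sample(0:2, 1)
    extra_names <- c("CTV", "GTV")
    extra_scale <- c(0.97, 0.94)
    for (k in seq_len(n_extra)) {
      dk <- rx * extra_scale[k]
      diff_k <- rnorm(1, st$diff_mean_pct, st$diff_sd_pct)
      targets[[k + 1]] <- list(
        roi_name = extra_names[k], mean_dose_tps = dk,
        mean_dose_check = dk * (1 + diff_k / 100),
        coverage_90_pct = NULL)
    }

    n_beams <- if (st$mlc_mode == "vmat") 2L else sample(4:7, 1)
    beams <- lapply(seq_len(n_beams), function(b) {
      list(beam_name = sprintf("B%d", b), energy_label = st$energy_label,
           mlc_mode = st$mlc_mode,
           gantry_angles = round(runif(if (st$mlc_mode == "vmat") 2 else 1,
                                       0, 359.9), 1),
           collimator_angles = round(runif(1, 0, 359.9), 1),
           mu = round(runif(1, 80, 600), 1))
    })

    role <- if (st$mlc_mode == "static") "radiation therapist" else "physicist"
    pool <- if (role == "physicist") approvers$physicist else approvers$therapist
    approved_at <- format_iso_datetime(
      as.POSIXct(approved_t[i], origin = "1970-01-01", tz = "UTC"))
    created_at <- format_iso_datetime(
      as.POSIXct(approved_t[i] - round(runif(1, 3600, 3 * 86400)),
                 origin = "1970-01-01", tz = "UTC"))

    doc <- plan_check_document(
      patient_id = pid,
      patient_name = sprintf("%s, Pt%05d", sample(surnames, 1), i),
      patient_sex = sample(c("F", "M"), 1),
      birth_date = format(as.Date("1930-01-01") +
                            sample.int(22000, 1), "%Y-%m-%d"),
      plan_name = plan_name, institution = "Synthetic Clinic",
      machine = st$machine, tps = st$tps,
      approvals = list(list(approver_name = sample(pool, 1), role = role,
                            approved_at = approved_at)),
      beams = beams, targets = targets,
      gamma_pass_pct = round(gamma_i, 4),
      n_fractions = st$n_fractions, created_at = created_at)

    pert <- 1 + spec$dvh_perturbation_pct / 100
    structures <- lapply(st$oar_templates, function(tmpl) {
      p <- tmpl$dvh_shape_params
      d50 <- min(max(p$d50 * runif(1, 0.9, 1.1), 1), p$dmax * 0.9)
      dmx <- p$dmax * runif(1, 0.95, 1.05)
      raw <- make_dvh_curve(list(d50 = d50, steepness = p$steepness,
                                 dmax = dmx))
      # storage resolution: 1e-4 Gy / 1e-4 %, far below clinical relevance
      tps_crv <- dvh_curve("tps", round(raw$dose_gy, 4),
                           round(raw$volume_pct, 4))
      chk_crv <- dvh_curve("check", round(raw$dose_gy * pert, 4),
                           tps_crv$volume_pct)
      con_d <- round(d50 * 1.4, 1)
      achieved <- v_at_d(tps_crv, con_d)
      list(roi_name = tmpl$roi_name,
           tps_roi_name = sample(tmpl$name_variants, 1),
           curves = list(tps_crv, chk_crv),
           constraints = list(list(
             volume_pct = 50, dose_gy = con_d,
             achieved_value = round(achieved, 2),
             result = if (achieved <= 50) "pass" else "fail")))
    })
    # target DVH: near-step at the prescription dose
    tgt_raw <- make_dvh_curve(list(d50 = rx * 1.005, steepness = 2,
                                   dmax = rx * 1.08), grid_step = 0.25)
    tgt_crv <- dvh_curve("tps", round(tgt_raw$dose_gy, 4),
                         round(tgt_raw$volume_pct, 4))
    structures <- c(structures, list(list(
      roi_name = "PTV", tps_roi_name = "PTV",
      curves = list(tgt_crv,
                    dvh_curve("check", round(tgt_crv$dose_gy * pert, 4),
                              tgt_crv$volume_pct)),
      constraints = list())))

    dvh_doc <- dvh_document(patient_id = pid, plan_name = plan_name,
                            n_fractions = st$n_fractions,
                            structures = structures)

    plan_path <- file.path(out_dir, sprintf("%s_plan.json", pid))
    dvh_path <- file.path(out_dir, sprintf("%s_dvh.json", pid))
    write_plan_check(doc, plan_path)
    write_dvh(dvh_doc, dvh_path)

    rows[[i]] <- tibble::tibble(
      patient_id = pid, plan_name = plan_name,
      stratum = stratum_idx[i], site_label = st$site_label,
      tps = st$tps, machine = st$machine,
      energy_label = st$energy_label, mlc_mode = st$mlc_mode,
      diff_pct = diff_i, gamma_pct = round(gamma_i, 4),
      approved_at = approved_at,
      plan_check_path = plan_path, dvh_path = dvh_path)
  }
  manifest <- dplyr::bind_rows(rows)
  write.csv(manifest, file.path(out_dir, "ground_truth.csv"),
            row.names = FALSE)
  manifest
}
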