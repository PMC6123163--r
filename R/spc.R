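# Shewhart-style individuals control chart over a filtered plan-check
# cohort. Limits are always recomputed from the cohort at hand (no cached
# global sigma), matching the workflow where a physicist filters to a site
# or machine and reads off tightened site-specific limits.

#' SPC configuration
#'
#' @param k_warn Warning-band half-width in sample SDs; default 2.
#' @param k_action Action (out-of-tolerance) half-width in SDs; default 3.
#'   Must exceed `k_warn`.
#' @param gamma_floor_pct Hard lower limit on the gamma pass rate, percent;
#'   any record below it is flagged `action` regardless of its discrepancy.
#'   `NULL` disables the floor. Default 90. Gamma is monitored only by this
#'   floor — it is bounded above at 100 and visibly non-Normal, so
#'   symmetric k-sigma bands would be meaningless for it.
#' @return A list of class `spc_config`.
#' @export
spc_config <- function(k_warn = 2, k_action = 3, gamma_floor_pct = 90) {
  if (!is_scalar_number(k_warn) || !is_scalar_number(k_action) ||
      k_warn <= 0 || k_action <= k_warn) {
    pc_abort("need 0 < k_warn < k_action", "pc_config_error")
  }
  if (!is.null(gamma_floor_pct) &&
      (!is_scalar_number(gamma_floor_pct) || gamma_floor_pct < 0 ||
       gamma_floor_pct > 100)) {
    pc_abort("gamma_floor_pct must be in [0, 100] or NULL", "pc_config_error")
  }
  structure(list(k_warn = k_warn, k_action = k_action,
                 gamma_floor_pct = gamma_floor_pct), class = "spc_config")
}

#' Compute control limits for mean-dose discrepancies
#'
#' Retrospective individuals chart: mu is the sample mean and sigma the
#' sample standard deviation (n - 1 denominator) of all points in the
#' cohort, in a single pass — flagged points are not trimmed and limits are
#' not re-estimated iteratively. Warning limits sit at mu +/- k_warn sigma,
#' action limits at mu +/- k_action sigma.
#'
#' @param diffs Numeric vector of signed discrepancies (percent), length
#'   >= 2.
#' @param cfg An [spc_config()].
#' @return Object of class `spc_result`: `mu`, `sigma`, `n`, `warn_low`,
#'   `warn_high`, `action_low`, `action_high`, `cfg`.
#' @examples
#' compute_limits(c(-1, 0, 1), spc_config())  # mu 0, sigma 1, action +/- 3
#' @export
compute_limits <- function(diffs, cfg = spc_config()) {
  stopifnot(inherits(cfg, "spc_config"))
  diffs <- as.numeric(diffs)
  if (length(diffs) < 2 || anyNA(diffs)) {
    pc_abort("control limits need >= 2 non-missing points",
             "pc_insufficient_data_error")
  }
  mu <- mean(diffs); sigma <- sd(diffs)
  structure(list(
    mu = mu, sigma = sigma, n = length(diffs),
    warn_low = mu - cfg$k_warn * sigma, warn_high = mu + cfg$k_warn * sigma,
    action_low = mu - cfg$k_action * sigma,
    action_high = mu + cfg$k_action * sigma,
    cfg = cfg), class = "spc_result")
}

#' @export
print.spc_result <- function(x, ...) {
  cat(sprintf(
    paste0("<spc_result> n=%d  mu=%.4g  sigma=%.4g\n",
           "  warning: [%.4g, %.4g]   action: [%.4g, %.4g]\n"),
    x$n, x$mu, x$sigma, x$warn_low, x$warn_high, x$action_low,
    x$action_high))
  invisible(x)
}

#' Flag records against control limits
#'
#' A record's discrepancy strictly outside the action band flags `action`;
#' strictly outside the warning band flags `warning`; otherwise
#' `in_control`. Points exactly on a boundary are in control (strict
#' inequality triggers a flag). Independently, a gamma pass rate below the
#' configured floor forces `action` whatever the discrepancy.
#'
#' @param records Record tibble with `mean_dose_diff_pct` and
#'   `gamma_pass_pct`.
#' @param limits An [compute_limits()] result.
#' @param cfg An [spc_config()]; defaults to the one the limits were
#'   computed with.
#' @return `records` with an added factor column `spc_flag` (levels
#'   `in_control`, `warning`, `action`).
#' @export
flag_records <- function(records, limits, cfg = limits$cfg) {
  stopifnot(inherits(limits, "spc_result"))
  d <- records$mean_dose_diff_pct
  flag <- rep("in_control", length(d))
  flag[d < limits$warn_low | d > limits$warn_high] <- "warning"
  flag[d < limits$action_low | d > limits$action_high] <- "action"
  if (!is.null(cfg$gamma_floor_pct)) {
    flag[records$gamma_pass_pct < cfg$gamma_floor_pct] <- "action"
  }
  records$spc_flag <- factor(flag,
                             levels = c("in_control", "warning", "action"))
  records
}

#' Ratio of action-band half-widths between two cohorts
#'
#' Quantifies limit tightening when a site-specific (or machine-specific)
#' cohort replaces the pooled history: since both bands use the same k, the
#' ratio reduces to sigma_B / sigma_A. A homogeneous treatment site carved
#' out of a mixed clinic history typically halves the band.
#'
#' @param cohort_a,cohort_b Numeric vectors of discrepancies, or record
#'   tibbles (their `mean_dose_diff_pct` column is used). Cohort A is the
#'   reference (e.g. pooled), B the refined cohort.
#' @param cfg An [spc_config()].
#' @return Scalar ratio (half-width of B) / (half-width of A).
#' @export
compare_limit_widths <- function(cohort_a, cohort_b, cfg = spc_config()) {
  get_diffs <- function(x) {
    if (is.data.frame(x)) x$mean_dose_diff_pct else as.numeric(x)
  }
  la <- compute_limits(get_diffs(cohort_a), cfg)
  lb <- compute_limits(get_diffs(cohort_b), cfg)
  (lb$action_high - lb$action_low) / (la$action_high - la$action_low)
}
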