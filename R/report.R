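# Batch ingest driver and static reporting: scan a directory of JSON
# documents, skip-and-log bad files, flatten approved checks into the
# record table, and emit tables (CSV + Excel SpreadsheetML backup) and the
# standard cohort figures (time series, histogram, grouped boxplots).

#' Ingest a directory of plan-check and DVH JSON files
#'
#' Scans `dir` for `.json` files, classifies each by its `document_type`
#' field, parses and validates them, and builds the record table from the
#' approved plan-check documents. Malformed or invalid files are skipped
#' and logged in the manifest — a bad file never aborts a batch. With
#' `last_n`, only the `last_n` most recently approved records are kept
#' (ties broken by path order).
#'
#' @param dir Directory to scan.
#' @param last_n Optional count of most recent approved records to keep.
#' @return A list with `records` (tibble, see [build_records()]),
#'   `dvh_docs` (list of [dvh_document()]), and `manifest` — counts
#'   `scanned`, `parsed`, `approved`, `records_built` plus a `skipped`
#'   tibble of (`path`, `reason`). Invariants: `scanned == parsed +
#'   nrow(skipped)` and `records_built <= approved <= parsed`.
#' @export
ingest <- function(dir, last_n = NULL) {
  if (!dir.exists(dir)) {
    pc_abort(sprintf("directory '%s' does not exist", dir), "pc_io_error")
  }
  paths <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  paths <- paths[!grepl("schema", basename(paths))]
  plan_docs <- list(); plan_paths <- character(); dvh_docs <- list()
  skipped <- list()
  for (p in paths) {
    res <- tryCatch({
      tree <- read_json_tree(p)
      type <- tree$document_type %||% ""
      if (identical(type, "plan_check")) {
        list(kind = "plan", doc = read_plan_check(p))
      } else if (identical(type, "dvh")) {
        list(kind = "dvh", doc = read_dvh(p))
      } else {
        pc_validation_error("document_type",
                            "must be 'plan_check' or 'dvh'", p)
      }
    }, pc_error = function(e) e)
    if (inherits(res, "pc_error")) {
      ingest_log("skip", p, conditionMessage(res))
      skipped[[length(skipped) + 1]] <- tibble::tibble(
        path = p, reason = conditionMessage(res))
    } else if (res$kind == "plan") {
      plan_docs[[length(plan_docs) + 1]] <- res$doc
      plan_paths <- c(plan_paths, p)
    } else {
      dvh_docs[[length(dvh_docs) + 1]] <- res$doc
    }
  }
  records <- build_records(plan_docs, plan_paths)
  n_approved <- sum(vapply(plan_docs, function(d) length(d$approvals) > 0,
                           TRUE))
  if (!is.null(last_n) && nrow(records) > last_n) {
    ord <- order(records$approved_at, seq_len(nrow(records)),
                 decreasing = FALSE)
    keep <- sort(tail(ord, last_n))
    records <- records[keep, , drop = FALSE]
  }
  skipped_tbl <- if (length(skipped)) dplyr::bind_rows(skipped) else
    tibble::tibble(path = character(), reason = character())
  manifest <- list(
    scanned = length(paths),
    parsed = length(plan_docs) + length(dvh_docs),
    approved = n_approved,
    records_built = nrow(records),
    skipped = skipped_tbl)
  list(records = records, dvh_docs = dvh_docs, manifest = manifest)
}

ingest_log <- function(action, path, detail) {
  message(sprintf("[%s] %s %s: %s",
                  format_iso_datetime(Sys.time()), action, path, detail))
}

# --- Excel 2003 SpreadsheetML writer -------------------------------------
# The secondary "Excel backup" of the record table. SpreadsheetML is the
# plain-text XML workbook format Excel opens natively; writing it directly
# keeps the backup human-auditable and dependency-free.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

spreadsheetml <- function(df, sheet = "records") {
  cell <- function(v) {
    if (is.na(v)) return("<Cell/>")
    if (is.numeric(v)) {
      sprintf('<Cell><Data ss:Type="Number">%s</Data></Cell>',
              format(v, digits = 15, scientific = FALSE, trim = TRUE))
    } else {
      sprintf('<Cell><Data ss:Type="String">%s</Data></Cell>',
              xml_escape(as.character(v)))
    }
  }
  header <- paste0("<Row>", paste0(
    sprintf('<Cell><Data ss:Type="String">%s</Data></Cell>',
            xml_escape(names(df))), collapse = ""), "</Row>")
  body <- vapply(seq_len(nrow(df)), function(i) {
    paste0("<Row>", paste0(vapply(df[i, ], cell, ""), collapse = ""),
           "</Row>")
  }, "")
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<?mso-application progid="Excel.Sheet"?>\n',
    '<Workbook xmlns="urn:schemas-microsoft-com:office:spreadsheet"',
    ' xmlns:ss="urn:schemas-microsoft-com:office:spreadsheet">\n',
    sprintf('<Worksheet ss:Name="%s"><Table>\n', xml_escape(sheet)),
    paste(c(header, body), collapse = "\n"),
    "\n</Table></Worksheet></Workbook>\n")
}

#' Export the record table
#'
#' Writes the flattened record table as CSV and, as a secondary backup, an
#' Excel-readable SpreadsheetML workbook (`.xml`). Column order follows the
#' record inventory: patient name, plan name, approval date, approver,
#' role, planning system, machine, energy, MLC mode, target name, mean
#' dose difference and gamma pass rate. Output is deterministic given the
#' records.
#'
#' @param records Record tibble.
#' @param path Output path; `format = "excel_xml"` replaces/forces an
#'   `.xml` extension, `"csv"` a `.csv`.
#' @param format `"csv"` or `"excel_xml"`.
#' @return The written path, invisibly.
#' @export
export_records <- function(records, path, format = c("csv", "excel_xml")) {
  format <- match.arg(format)
  cols <- c("patient_name", "patient_id", "plan_name", "approved_at",
            "approver", "role", "tps", "machine", "energy_label",
            "mlc_mode", "target_name", "mean_dose_diff_pct",
            "gamma_pass_pct")
  df <- as.data.frame(records[, intersect(cols, names(records))])
  if ("approved_at" %in% names(df)) {
    df$approved_at <- format_iso_datetime(df$approved_at)
  }
  if (format == "csv") {
    write.csv(df, path, row.names = FALSE)
  } else {
    writeLines(spreadsheetml(df), path, useBytes = TRUE)
  }
  invisible(path)
}

#' Write the standard cohort report
#'
#' Emits, under `out_dir`: the full record table (`records.csv` plus the
#' Excel SpreadsheetML backup `records.xml`), the cohort summary-statistics
#' block (`summary.csv`), per-axis grouped summaries, and static figures —
#' time series of discrepancy and gamma versus approval date with SPC
#' bands, a histogram of discrepancies, and per-axis boxplots. An empty
#' cohort yields header-only tables, no plots, and a warning.
#'
#' @param records Record tibble (typically filtered).
#' @param out_dir Output directory, created if needed.
#' @param cfg [spc_config()] used for the control bands on the time series.
#' @param axes Grouping axes for boxplots/summaries.
#' @param plot_format `"png"` or `"svg"`.
#' @return Character vector of written file paths, invisibly.
#' @export
write_report <- function(records, out_dir, cfg = spc_config(),
                         axes = c("tps", "machine", "energy_label",
                                  "mlc_mode"),
                         plot_format = c("png", "svg")) {
  plot_format <- match.arg(plot_format)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  add <- function(p) written <<- c(written, p)

  add(export_records(records, file.path(out_dir, "records.csv"), "csv"))
  add(export_records(records, file.path(out_dir, "records.xml"),
                     "excel_xml"))
  if (nrow(records) == 0) {
    warning("empty cohort: tables written with headers only, no plots")
    write.csv(summarize_records_template(), file.path(out_dir, "summary.csv"),
              row.names = FALSE)
    add(file.path(out_dir, "summary.csv"))
    return(invisible(written))
  }
  smry <- summarize_records(records)
  write.csv(as.data.frame(smry), file.path(out_dir, "summary.csv"),
            row.names = FALSE)
  add(file.path(out_dir, "summary.csv"))
  for (ax in intersect(axes, GROUPABLE_AXES)) {
    f <- file.path(out_dir, sprintf("summary_by_%s.csv", ax))
    write.csv(as.data.frame(group_summarize(records, ax)), f,
              row.names = FALSE)
    add(f)
  }

  save_plot <- function(p, name, width = 7, height = 4.5) {
    f <- file.path(out_dir, paste0(name, ".", plot_format))
    dev_fun <- if (plot_format == "png") {
      function(f) grDevices::png(f, width = width * 100,
                                 height = height * 100, res = 100)
    } else {
      function(f) grDevices::svg(f, width = width, height = height)
    }
    dev_fun(f); on.exit(grDevices::dev.off(), add = TRUE)
    print(p)
    add(f)
  }

  lim <- if (nrow(records) >= 2) {
    compute_limits(records$mean_dose_diff_pct, cfg)
  } else NULL
  ts_base <- ggplot2::ggplot(records,
                             ggplot2::aes(x = .data$approved_at,
                                          y = .data$mean_dose_diff_pct)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::labs(x = "Approval date",
                  y = "Mean dose difference to target (%)") +
    ggplot2::theme_bw()
  if (!is.null(lim)) {
    ts_base <- ts_base +
      ggplot2::geom_hline(yintercept = c(lim$warn_low, lim$warn_high),
                          linetype = "dashed", colour = "orange") +
      ggplot2::geom_hline(yintercept = c(lim$action_low, lim$action_high),
                          linetype = "dashed", colour = "red") +
      ggplot2::geom_hline(yintercept = lim$mu, colour = "grey40")
  }
  save_plot(ts_base, "timeseries_diff")

  ts_gamma <- ggplot2::ggplot(records,
                              ggplot2::aes(x = .data$approved_at,
                                           y = .data$gamma_pass_pct)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::labs(x = "Approval date", y = "3D gamma pass rate (%)") +
    ggplot2::theme_bw()
  if (!is.null(cfg$gamma_floor_pct)) {
    ts_gamma <- ts_gamma +
      ggplot2::geom_hline(yintercept = cfg$gamma_floor_pct,
                          linetype = "dashed", colour = "red")
  }
  save_plot(ts_gamma, "timeseries_gamma")

  save_plot(
    ggplot2::ggplot(records, ggplot2::aes(x = .data$mean_dose_diff_pct)) +
      ggplot2::geom_histogram(bins = 40, fill = "steelblue",
                              colour = "white") +
      ggplot2::labs(x = "Mean dose difference to target (%)", y = "Checks") +
      ggplot2::theme_bw(),
    "hist_diff")

  box_data <- dplyr::bind_rows(lapply(intersect(axes, GROUPABLE_AXES),
                                      function(ax) {
    tibble::tibble(axis = ax, group = records[[ax]],
                   diff = records$mean_dose_diff_pct)
  }))
  save_plot(
    ggplot2::ggplot(box_data, ggplot2::aes(x = .data$group, y = .data$diff)) +
      ggplot2::geom_boxplot(outlier.shape = 3) +
      ggplot2::facet_grid(cols = ggplot2::vars(.data$axis), scales = "free_x",
                          space = "free_x") +
      ggplot2::labs(x = NULL, y = "Mean dose difference (%)") +
      ggplot2::theme_bw() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                         hjust = 1)),
    "boxplots", width = 9)

  invisible(written)
}

summarize_records_template <- function() {
  tibble::tibble(n = integer(), mean_diff_pct = numeric(),
                 max_abs_diff_pct = numeric(), min_diff_pct = numeric(),
                 max_diff_pct = numeric(), sd_diff_pct = numeric(),
                 mean_gamma_pct = numeric(), min_gamma_pct = numeric())
}

#' Write cohort DVH summary artifacts
#'
#' Envelope-curve table (`dvh_envelope.csv`: grid dose, mean, median,
#' mu +/- 1 sigma), the per-patient constraint distributions
#' (`dvh_distributions.csv`: D(V), V(D), Dmax), and a static cohort DVH
#' figure — per-patient spaghetti, mean/median/±1 sigma envelopes, and a
#' crosshair at the selected dose/volume constraint.
#'
#' @param summary A [summarize_dvh_cohort()] result.
#' @param out_dir Output directory.
#' @param plot_format `"png"` or `"svg"`.
#' @return Written paths, invisibly.
#' @export
write_dvh_report <- function(summary, out_dir,
                             plot_format = c("png", "svg")) {
  plot_format <- match.arg(plot_format)
  stopifnot(inherits(summary, "cohort_dvh_summary"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  env_tbl <- data.frame(dose_gy = summary$dose_grid,
                        mean_pct = summary$mean_curve,
                        median_pct = summary$median_curve,
                        upper_pct = summary$upper_curve,
                        lower_pct = summary$lower_curve)
  f1 <- file.path(out_dir, "dvh_envelope.csv")
  write.csv(env_tbl, f1, row.names = FALSE)
  dst <- summary$distributions
  f2 <- file.path(out_dir, "dvh_distributions.csv")
  write.csv(data.frame(d_at_v_gy = dst$d_at_v, v_at_d_pct = dst$v_at_d,
                       d_max_gy = dst$d_max), f2, row.names = FALSE)

  spag <- do.call(rbind, lapply(seq_len(summary$n_patients), function(i) {
    data.frame(patient = i, dose = summary$dose_grid,
               vol = summary$curves[i, ])
  }))
  p <- ggplot2::ggplot() +
    ggplot2::geom_line(data = spag,
                       ggplot2::aes(x = .data$dose, y = .data$vol,
                                    group = .data$patient),
                       colour = "grey70", linewidth = 0.2) +
    ggplot2::geom_line(data = env_tbl,
                       ggplot2::aes(x = .data$dose_gy, y = .data$mean_pct),
                       colour = "blue", linetype = "dashed",
                       linewidth = 0.9) +
    ggplot2::geom_line(data = env_tbl,
                       ggplot2::aes(x = .data$dose_gy, y = .data$median_pct),
                       colour = "red", linetype = "dashed",
                       linewidth = 0.9) +
    ggplot2::geom_line(data = env_tbl,
                       ggplot2::aes(x = .data$dose_gy, y = .data$upper_pct),
                       colour = "darkgreen", linetype = "dashed") +
    ggplot2::geom_line(data = env_tbl,
                       ggplot2::aes(x = .data$dose_gy, y = .data$lower_pct),
                       colour = "darkgreen", linetype = "dashed") +
    ggplot2::geom_vline(xintercept = dst$selected_dose_gy,
                        linetype = "dotted") +
    ggplot2::geom_hline(yintercept = dst$selected_volume_pct,
                        linetype = "dotted") +
    ggplot2::labs(x = "Dose (Gy)", y = "Volume (%)") +
    ggplot2::theme_bw()
  f3 <- file.path(out_dir, paste0("dvh_cohort.", plot_format))
  if (plot_format == "png") {
    grDevices::png(f3, width = 700, height = 500, res = 100)
  } else {
    grDevices::svg(f3, width = 7, height = 5)
  }
  print(p); grDevices::dev.off()
  invisible(c(f1, f2, f3))
}
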