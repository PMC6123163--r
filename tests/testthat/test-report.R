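test_that("ingest skips corrupt files, logs them, and keeps its invariants", {
  d <- withr::local_tempdir()
  m <- generate_cohort(default_cohort_spec(n_patients = 25, seed = 9), d)
  writeLines("{broken", file.path(d, "zz_corrupt.json"))
  ing <- suppressMessages(ingest(d))
  man <- ing$manifest
  expect_identical(man$scanned, 51L)
  expect_identical(man$parsed, 50L)
  expect_identical(nrow(man$skipped), 1L)
  expect_identical(man$scanned, man$parsed + nrow(man$skipped))
  expect_lte(man$records_built, man$approved)
  expect_lte(man$approved, man$parsed)
  expect_identical(man$records_built, 25L)
  expect_match(man$skipped$path, "zz_corrupt")
  expect_error(ingest(file.path(d, "missing_dir")), class = "pc_io_error")
})

test_that("unapproved checks are parsed but never become records", {
  d <- withr::local_tempdir()
  m <- generate_cohort(default_cohort_spec(n_patients = 10, seed = 2), d)
  # strip the approvals from three plan-check files
  for (p in m$plan_check_path[1:3]) {
    doc <- read_plan_check(p)
    doc$approvals <- list()
    write_plan_check(doc, p)
  }
  ing <- ingest(d)
  expect_identical(ing$manifest$approved, 7L)
  expect_identical(nrow(ing$records), 7L)
  expect_identical(nrow(attr(ing$records, "exclusions")), 3L)
})

test_that("last_n keeps the most recently approved records", {
  d <- withr::local_tempdir()
  m <- generate_cohort(default_cohort_spec(n_patients = 20, seed = 4), d)
  ing <- ingest(d, last_n = 5)
  expect_identical(nrow(ing$records), 5L)
  cutoff <- sort(as.numeric(as.POSIXct(m$approved_at, tz = "UTC",
                                       format = "%Y-%m-%dT%H:%M:%SZ")),
                 decreasing = TRUE)[5]
  expect_true(all(as.numeric(ing$records$approved_at) >= cutoff))
  # re-running on an unchanged directory is deterministic
  ing2 <- ingest(d, last_n = 5)
  expect_identical(ing$records, ing2$records)
  expect_identical(ing$manifest[c("scanned", "parsed", "approved")],
                   ing2$manifest[c("scanned", "parsed", "approved")])
})

test_that("record exports carry every record and re-export byte-identically", {
  set.seed(44)
  rec <- fix_records(rnorm(100), gammas = runif(100, 92, 100))
  d <- withr::local_tempdir()
  f_csv <- export_records(rec, file.path(d, "r.csv"), "csv")
  expect_identical(length(readLines(f_csv)), 101L)  # header + 100 rows
  f_xml <- export_records(rec, file.path(d, "r.xml"), "excel_xml")
  xml <- readLines(f_xml, warn = FALSE)
  expect_identical(sum(grepl("<Row>", xml, fixed = TRUE)), 101L)
  expect_match(xml[1], "xml version", fixed = TRUE)
  # determinism: identical inputs give identical bytes
  export_records(rec, file.path(d, "r2.csv"), "csv")
  expect_identical(readLines(f_csv), readLines(file.path(d, "r2.csv")))
  # XML escaping of special characters
  rec2 <- fix_records(0.1)
  rec2$patient_name <- "A <&> \"B\""
  f3 <- export_records(rec2, file.path(d, "r3.xml"), "excel_xml")
  expect_match(paste(readLines(f3, warn = FALSE), collapse = ""),
               "A &lt;&amp;&gt; &quot;B&quot;", fixed = TRUE)
})

test_that("the full report writes its tables and figures", {
  set.seed(46)
  rec <- fix_records(rnorm(60), gammas = runif(60, 92, 100),
                     machines = sample(c("LA1", "LA2"), 60, TRUE),
                     tps = sample(c("Eclipse", "iPlan"), 60, TRUE))
  d <- withr::local_tempdir()
  written <- write_report(rec, d)
  expect_true(file.exists(file.path(d, "records.csv")))
  expect_true(file.exists(file.path(d, "records.xml")))
  expect_true(file.exists(file.path(d, "summary.csv")))
  expect_true(file.exists(file.path(d, "summary_by_machine.csv")))
  expect_true(file.exists(file.path(d, "timeseries_diff.png")))
  expect_true(file.exists(file.path(d, "timeseries_gamma.png")))
  expect_true(file.exists(file.path(d, "hist_diff.png")))
  expect_true(file.exists(file.path(d, "boxplots.png")))
  # boxplot data covers all strata labels
  by_tps <- read.csv(file.path(d, "summary_by_tps.csv"))
  expect_setequal(by_tps$tps, c("Eclipse", "iPlan"))
  expect_identical(sum(by_tps$n), 60L)
})

test_that("an empty cohort yields header-only tables and no plots", {
  d <- withr::local_tempdir()
  rec <- fix_records(numeric())
  expect_warning(write_report(rec, d), "empty cohort")
  expect_identical(length(readLines(file.path(d, "records.csv"))), 1L)
  expect_identical(length(readLines(file.path(d, "summary.csv"))), 1L)
  expect_false(any(grepl("\\.png$", list.files(d))))
})

test_that("DVH report artifacts match the summary object", {
  d0 <- withr::local_tempdir()
  m <- generate_cohort(default_cohort_spec(n_patients = 15, seed = 12), d0)
  ing <- ingest(d0)
  s <- summarize_dvh_cohort(find_structures(ing$dvh_docs, "rectum"), "tps",
                            v_sel = 50, d_sel = 45)
  d <- withr::local_tempdir()
  write_dvh_report(s, d)
  env <- read.csv(file.path(d, "dvh_envelope.csv"))
  expect_identical(nrow(env), length(s$dose_grid))
  expect_equal(env$mean_pct, unname(s$mean_curve))
  dst <- read.csv(file.path(d, "dvh_distributions.csv"))
  expect_identical(nrow(dst), s$n_patients)
  expect_true(file.exists(file.path(d, "dvh_cohort.png")))
})

test_that("the CLI drives generate, db, spc and oar end to end", {
  d_in <- file.path(withr::local_tempdir(), "cohort")
  spec_file <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    n_patients = 30, seed = 5,
    strata = list(list(weight = 1, tps = "Eclipse", machine = "LA1",
                       energy_label = "6MV", mlc_mode = "vmat",
                       site_label = "PROSTATE", diff_mean_pct = -0.13,
                       diff_sd_pct = 1.2, gamma_mean_pct = 98,
                       gamma_sd_pct = 1.5, rx_dose_gy = 78,
                       n_fractions = 39))),
    spec_file, auto_unbox = TRUE)
  expect_output(pcm_main(c("generate", "--spec", spec_file,
                           "--out-dir", d_in)),
                "generated 30 plan-check/DVH pairs", fixed = TRUE)

  d_out <- withr::local_tempdir()
  expect_output(pcm_main(c("db", "--in-dir", d_in, "--filter",
                           "plan_name=*PROS", "--out-dir", d_out)),
                "mean_diff_pct")
  expect_true(file.exists(file.path(d_out, "records.xml")))

  d_spc <- withr::local_tempdir()
  expect_output(pcm_main(c("spc", "--in-dir", d_in, "--k-warn", "2",
                           "--k-action", "3", "--gamma-floor", "90",
                           "--out-dir", d_spc)),
                "<spc_result>", fixed = TRUE)
  lim <- read.csv(file.path(d_spc, "limits.csv"))
  expect_equal(lim$warn_high - lim$warn_low, 4 * lim$sigma)
  expect_true(file.exists(file.path(d_spc, "flagged.csv")))

  d_oar <- withr::local_tempdir()
  expect_output(pcm_main(c("oar", "--in-dir", d_in, "--query", "rectum",
                           "--volume", "50", "--dose", "60",
                           "--out-dir", d_oar)),
                "<cohort_dvh_summary>", fixed = TRUE)
  expect_true(file.exists(file.path(d_oar, "dvh_envelope.csv")))

  # config file values are used unless overridden on the command line
  cfgf <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(k_warn = 1.5, k_action = 4), cfgf,
                       auto_unbox = TRUE)
  d_spc2 <- withr::local_tempdir()
  expect_output(pcm_main(c("spc", "--in-dir", d_in, "--config", cfgf,
                           "--out-dir", d_spc2)))
  lim2 <- read.csv(file.path(d_spc2, "limits.csv"))
  expect_equal(lim2$action_high - lim2$action_low, 8 * lim2$sigma)
  expect_error(pcm_main(c("bogus")), class = "pc_config_error")
})
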