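linear_curve <- function(dmax = 70) dvh_curve("tps", c(0, dmax), c(100, 0))

test_that("structure search matches either stored name, once per document", {
  docs <- list(
    fix_dvh_doc("PT00001", structures = list(
      fix_structure("Rectum", "Rectum"), fix_structure("Bladder"))),
    fix_dvh_doc("PT00002", structures = list(
      fix_structure("Bladder"), fix_structure("Rectum", "RECTUM_JD"))),
    fix_dvh_doc("PT00003", structures = list(fix_structure("Bladder"))))
  m <- find_structures(docs, "rectum")
  expect_identical(m$patient_id, c("PT00001", "PT00002"))
  expect_identical(m$tps_roi_name, c("Rectum", "RECTUM_JD"))
  expect_false(any(m$multi_match))
  # the planner-typed name alone is enough to match
  docs2 <- list(fix_dvh_doc(structures = list(
    fix_structure("Organ7", "Rectum_JD"))))
  expect_identical(nrow(find_structures(docs2, "rectum")), 1L)
  # empty query: every document's first structure
  all_m <- find_structures(docs, "")
  expect_identical(all_m$roi_name, c("Rectum", "Bladder", "Bladder"))
  expect_identical(nrow(find_structures(docs, "femur")), 0L)
})

test_that("search equals a brute-force substring scan on random names", {
  set.seed(19)
  pool <- c("Rectum", "RECTUM_JD", "rectum_1", "Bladder", "BLADDER",
            "FemHead_L", "PTV", "Bowel", "recTUM x")
  for (rep in 1:25) {
    names_ <- sample(pool, 6, replace = TRUE)
    docs <- lapply(seq_along(names_), function(i) {
      fix_dvh_doc(sprintf("PT%05d", i),
                  structures = list(fix_structure(names_[i], names_[i])))
    })
    got <- find_structures(docs, "rectum")$patient_id
    want <- sprintf("PT%05d", oracle_filter_idx(names_, "rectum"))
    expect_identical(got, want)
  }
})

test_that("resampling interpolates linearly and zero-extends beyond dmax", {
  crv <- linear_curve(70)
  expect_equal(resample_curve(crv, c(0, 35, 70, 80)), c(100, 50, 0, 0))
  # resampling onto the native grid is the identity
  gen <- make_dvh_curve(list(d50 = 30, steepness = 0.25, dmax = 60))
  expect_identical(resample_curve(gen, gen$dose_gy), gen$volume_pct)
  expect_error(resample_curve(gen, c(-1, 3)), class = "pc_config_error")
})

test_that("D(V), V(D) and Dmax follow linear inverse interpolation", {
  crv <- linear_curve(70)
  expect_equal(d_at_v(crv, 50), 35)
  expect_equal(d_at_v(crv, 100), 0)
  expect_equal(v_at_d(crv, 0), 100)
  expect_equal(v_at_d(crv, 52.5), 25)
  expect_equal(d_max(crv), 70)
  expect_equal(d_max(crv, eps = 2), 68.6)
  expect_error(d_at_v(crv, 0), class = "pc_config_error")
  expect_error(v_at_d(crv, -1), class = "pc_config_error")
})

test_that("D(V) returns the high-dose end of a flat segment and saturates", {
  flat <- dvh_curve("tps", c(0, 10, 20, 30), c(100, 50, 50, 20))
  expect_equal(d_at_v(flat, 50), 20)   # high-dose end of the 50% plateau
  # curve never drops to 10%: D(10) saturates at the last dose point
  sat <- dvh_curve("tps", c(0, 10, 20), c(100, 60, 30))
  d <- d_at_v(sat, 10)
  expect_equal(as.numeric(d), 20)
  expect_true(isTRUE(attr(d, "saturated")))
})

test_that("D(V)/V(D) round-trip within slope x grid-step (property)", {
  set.seed(29)
  for (i in 1:40) {
    dmax <- runif(1, 20, 80)
    crv <- make_dvh_curve(list(d50 = runif(1, 0.2, 0.8) * dmax,
                               steepness = exp(runif(1, log(0.08), log(1))),
                               dmax = dmax), grid_step = 0.5)
    for (v in c(5, 25, 50, 75, 95)) {
      d <- as.numeric(d_at_v(crv, v))
      expect_gte(v_at_d(crv, d), v - 1e-9)
      # inverse interpolation is exact on piecewise-linear curves
      expect_lt(abs(v_at_d(crv, d) - v), 1e-6)
    }
    # dense-scan oracle for Dmax
    dense <- seq(0, dmax, by = 1e-3)
    vol <- approx(crv$dose_gy, crv$volume_pct, dense, ties = "ordered")$y
    expect_lt(abs(d_max(crv) - max(dense[vol > 0])), 1e-3 + 1e-9)
  }
})

test_that("cohort envelopes are bracketed, monotone and exact on degenerates", {
  crv <- make_dvh_curve(list(d50 = 35, steepness = 0.2, dmax = 70))
  docs <- lapply(1:5, function(i) {
    fix_dvh_doc(sprintf("PT%05d", i), structures = list(list(
      roi_name = "Rectum", tps_roi_name = "Rectum",
      curves = list(crv), constraints = list())))
  })
  s <- summarize_dvh_cohort(find_structures(docs, "rectum"), "tps")
  # identical curves: mean = median = curve, zero-width envelope
  expect_equal(s$mean_curve, s$median_curve)
  expect_equal(s$upper_curve, s$lower_curve)
  expect_equal(s$mean_curve, resample_curve(crv, s$dose_grid))
  expect_equal(unname(s$distributions$d_max), rep(d_max(crv), 5))
})

test_that("curves ending early are zero-extended into the cohort grid", {
  docs <- list(
    fix_dvh_doc("PT00001", structures = list(list(
      roi_name = "R", tps_roi_name = "R", curves = list(linear_curve(60)),
      constraints = list()))),
    fix_dvh_doc("PT00002", structures = list(list(
      roi_name = "R", tps_roi_name = "R", curves = list(linear_curve(80)),
      constraints = list()))))
  s <- summarize_dvh_cohort(find_structures(docs, "R"), "tps",
                            grid_step = 0.1, d_sel = 70)
  j <- which.min(abs(s$dose_grid - 70))
  v2 <- v_at_d(linear_curve(80), 70)
  expect_equal(s$mean_curve[j], (0 + v2) / 2)
  expect_equal(max(s$dose_grid), 80)
})

test_that("cohort envelope invariants hold on a mixed synthetic cohort", {
  set.seed(37)
  docs <- lapply(1:30, function(i) {
    dmax <- runif(1, 55, 80)
    fix_dvh_doc(sprintf("PT%05d", i), structures = list(
      fix_structure("Rectum", d50 = runif(1, 25, 45), dmax = dmax,
                    steepness = runif(1, 0.1, 0.4))))
  })
  m <- find_structures(docs, "rectum")
  s <- summarize_dvh_cohort(m, "tps", v_sel = 50, d_sel = 40)
  lo <- apply(s$curves, 2, min); hi <- apply(s$curves, 2, max)
  expect_true(all(s$lower_curve >= pmin(lo, s$lower_curve) - 1e-12))
  expect_true(all(s$mean_curve >= lo - 1e-12 & s$mean_curve <= hi + 1e-12))
  expect_true(all(s$lower_curve <= s$mean_curve + 1e-12))
  expect_true(all(s$mean_curve <= s$upper_curve + 1e-12))
  # every resampled curve and both central envelopes are non-increasing
  expect_true(all(apply(s$curves, 1, function(r) all(diff(r) <= 1e-9))))
  expect_true(all(diff(s$mean_curve) <= 1e-9))
  expect_true(all(diff(s$median_curve) <= 1e-9))
  expect_identical(length(s$distributions$d_at_v), 30L)
})

test_that("tps and check summaries differ by the injected perturbation", {
  d <- withr::local_tempdir()
  m <- generate_cohort(default_cohort_spec(n_patients = 40, seed = 51), d)
  ing <- ingest(d)
  mt <- find_structures(ing$dvh_docs, "rectum")
  s_tps <- summarize_dvh_cohort(mt, "tps", v_sel = 50, d_sel = 40)
  s_chk <- summarize_dvh_cohort(mt, "check", v_sel = 50, d_sel = 40)
  # check doses are 1% hotter: D(50%) scales by 1.01, Dmax likewise
  expect_equal(s_chk$distributions$d_at_v / s_tps$distributions$d_at_v,
               rep(1.01, nrow(mt)), tolerance = 1e-3)
  expect_equal(median(s_chk$distributions$d_max) /
                 median(s_tps$distributions$d_max), 1.01, tolerance = 1e-3)
})

test_that("an empty match set is an error for the cohort summary", {
  expect_error(summarize_dvh_cohort(find_structures(list(), "x"), "tps"),
               class = "pc_empty_cohort_error")
})
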