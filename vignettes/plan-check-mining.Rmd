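---
title: "Mining plan-check databases: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining plan-check databases: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements, the assumptions behind them, the knobs that matter, and the
choices made where the design was genuinely open.

## 1. What is being modelled

An independent dose-verification system recalculates every approved
radiotherapy plan and compares its dose to the treatment planning system's
(TPS). Each check leaves two JSON documents: the plan-check proper (plan,
beams, approval stamps, per-target mean doses from both systems, a 3D
gamma pass rate) and a DVH document (cumulative dose-volume curves per
structure from both systems). The package turns a directory of such pairs
into three analyses:

1. a **record table**, one row per *approved* check, carrying the signed
   primary-target mean-dose discrepancy
   `diff% = 100 (D̄_check − D̄_TPS) / D̄_TPS` and the gamma pass rate;
2. **control limits** over any filtered subset of that table;
3. **cohort DVH envelopes and constraint distributions** for any searched
   structure.

Only one target per check enters the record table. Plans routinely carry
nested GTV/CTV/PTV contours whose discrepancies are strongly correlated;
counting them all would multiply-weight those patients and bias the
process statistics. The primary target is defined as the target with the
highest TPS mean dose; exact ties (rare, but possible with copied
contours) break to the lexicographically smallest name so the selection is
deterministic.

The sign convention — check minus TPS, over TPS — is fixed package-wide.
Published summaries of such discrepancies rarely state a sign convention;
since all control limits here are symmetric about the cohort mean, every
downstream result is sign-robust, and the signed minimum/maximum are
reported alongside the absolute maximum so either reading is available.

## 2. Control limits

`compute_limits()` fits a retrospective Shewhart-style *individuals*
chart: over the n points of the cohort at hand it takes μ̂ = sample mean
and σ̂ = sample SD (n − 1 denominator) in a single pass, and places

* warning limits at μ̂ ± `k_warn` σ̂ (default `k_warn = 2`),
* action limits at μ̂ ± `k_action` σ̂ (default `k_action = 3`).

Design choices worth stating explicitly:

* **No subgrouping, no moving-range σ.** Classical individuals charts
  often estimate σ from the average moving range. Here the chart is
  retrospective over an arbitrarily filtered cohort whose time ordering
  may interleave many machines and sites; the plain sample SD of all
  points is the simplest estimator consistent with "limits adapt to the
  data of interest", and is what the parameter-recovery tests check.
* **No iterative trimming.** Out-of-control points are *not* excluded and
  limits are *not* re-estimated. With clean synthetic data the difference
  is negligible (≈0.3% of points beyond 3σ); with real data, exclusion
  rules are a policy decision we deliberately leave to the user, who can
  filter and recompute.
* **Boundary rule.** A point exactly on a limit is *in control*; strict
  inequality raises the flag. Any convention works; this one is documented
  and tested.
* **Gamma handling.** The gamma pass rate is bounded above at 100% and
  heavily left-skewed, so symmetric k·σ bands are meaningless for it. It
  is monitored solely by a hard floor (`gamma_floor_pct`, default 90%):
  any record below the floor is flagged `action` regardless of its dose
  discrepancy. Set it to `NULL` to disable.
* **Limits are never cached.** `compute_limits(apply_filter(...))` is the
  only path; a site-filtered cohort always gets its own σ̂. That is the
  whole point of the limit-tightening workflow: a homogeneous site carved
  out of a mixed history has smaller σ̂, and `compare_limit_widths()`
  reports exactly σ̂_B/σ̂_A.

## 3. DVH meta-analysis

A cumulative DVH V(d) gives the percent of a structure's volume receiving
at least d Gy: V(0) = 100, non-increasing. Native grids differ per
patient, so cohort statistics require a common support:

* **Common grid.** Uniform, default step 0.1 Gy, from 0 to the cohort
  maximum dose. 0.1 Gy is well below any clinically quoted DVH precision
  and keeps a 140-patient × 80 Gy cohort at ~800 grid points — trivially
  cheap.
* **Zero-extension.** Beyond a curve's own maximum dose its volume is 0%
  — that is what "cumulative" means physically (no voxel receives more
  than the structure's maximum dose), so averaging short and long curves
  on the shared grid needs no special casing.
* **Envelopes.** Mean, median and μ ± 1σ are computed pointwise; σ is the
  sample SD (n − 1) and the lower envelope is floored at 0%. The mean of
  non-increasing functions is non-increasing, and the tests assert it.
* **D(V) on flat segments.** D(V) is the largest dose with V(d) ≥ v
  (inverse linear interpolation). Where the curve has a plateau exactly at
  v, the *high-dose end* is returned — the "minimum dose to the hottest
  V%" reading. If even the last tabulated point retains more than v%, the
  last dose is returned with a `saturated` attribute rather than
  extrapolating.
* **Maximum dose.** `d_max()` locates the V = ε crossing (ε = 0 by
  default, i.e. where the curve reaches zero volume); small positive ε
  gives a near-maximum robust to thin DVH tails.
* **One structure per patient.** A query like `"rectum"` matches both the
  canonical and the original planner-typed name, case-insensitively, as a
  substring. If a document matches several structures, only the first in
  stored order contributes (a `multi_match` flag is set) — otherwise a
  patient with `Rectum` and `Rectum_old` would be double-counted.

## 4. The synthetic cohort generator

No clinical archive can ship with the package, so every analysis is
validated against seeded synthetic cohorts whose ground truth is known.
The generator emulates, per stratum (TPS × machine × energy × MLC mode ×
site):

* **Discrepancies** drawn Normal(diff_mean, diff_sd), unbounded. Clinical
  histograms of this quantity are visually Normal at the percent scale;
  the default clinic spec centres the pooled distribution near −0.13%
  with SD near 1.2%, the scale of a mature plan-check history. Real
  distributions are likely heavier-tailed than Normal (a 5% extreme in a
  ~4000-check history is >4σ for σ = 1.2); an optional contamination
  fraction (`contam_frac`, default 0, with `contam_sd_scale`, default 3)
  mixes in wide-SD draws for users who want such tails. It is off by
  default because no published mixture parameters exist to calibrate it.
* **Gamma pass rates** drawn Normal truncated to [0, 100] by rejection
  (means ~97–98.5%, SD 1.2–2).
* **Name drift**: plan names vary the site stem exactly the way clinics
  do (`PROSTATE`, `PROS`, `PH1_prostate`, `PH1 Pros`), and OAR templates
  carry spelling variants (`Rectum`, `RECTUM_JD`, ...), so the wildcard
  filtering and structure-search tests are honest.
* **DVH curves** are renormalized logistics in dose:
  V(d) = 100·(f(d) − f(dmax))/(f(0) − f(dmax)) with
  f(d) = 1/(1 + exp(s(d − d50))), which is exactly 100% at 0 Gy, exactly
  0% at dmax, strictly decreasing, hits ~50% at d50, and approaches a
  step function (a target-like DVH) as s grows. Per patient, d50 and dmax
  are jittered ±10%/±5%. The check-system curve is the TPS curve with its
  dose axis scaled by 1 + `dvh_perturbation_pct`/100 (default 1%), so the
  two-source comparison surface is exercised with a known injected
  offset.
* **Approvals**: one stamp per check, uniform over the accrual window
  (default a three-year clinical history), therapist role for static
  plans and physicist for modulated ones.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: heavy-tailed or drifting discrepancy processes
(no time trends, no change points), correlated beams or machine-specific
systematic offsets beyond the stratum means, realistic MLC sequences
(placeholder arrays), absolute-volume DVHs, and non-Normal gamma shapes
beyond simple truncation.

Determinism: the generator seeds R's RNG from the spec, restores the
caller's RNG state afterwards, and writes JSON with full double precision
(curve samples at a storage resolution of 10⁻⁴ Gy / 10⁻⁴ %), so identical
spec + seed reproduces output byte for byte.

## 5. The JSON dialect

Vendors' native storage schemas are proprietary; the package defines an
open, versioned dialect (machine-readable JSON-schema files under
`inst/schema/`) whose field inventory mirrors what such systems store.
Two files per patient plan, linked by exact `patient_id` + `plan_name`
equality. Doses are total plan doses in Gy, with `n_fractions` carried
separately — "mean dose" summaries in the wild are sometimes
per-fraction, so the dialect pins down one convention and lets users
divide. Timestamps are ISO-8601 UTC. Validation is total: a file either
yields a fully validated document or a typed error naming the offending
field, and batch ingest skips-and-logs rather than aborting — one corrupt
file in a 4000-file history must not kill the run.

## 6. Numerical choices and degenerate inputs

* Constant cohorts give σ̂ = 0, zero-width bands, everything in control.
* A single record has no SD: the summary reports it absent, and
  `compute_limits()` refuses n < 2 with a typed error.
* An empty filter result is a typed empty-cohort error for summaries, but
  a valid (empty) result for `apply_filter()` itself; reports on empty
  cohorts emit header-only tables and no figures.
* Wildcard patterns match literally (no regex metacharacters), so plan
  names like `H&N boost` or `PH1 Pros` are safe.
* Multi-energy/multi-MLC plans collapse to the majority beam label
  (alphabetical tie-break) with `multi_energy`/`multi_mlc` flags kept on
  the record — the record table has one energy column, as a physicist's
  summary table does.
* Curve resampling is plain linear interpolation (`stats::approx`), with
  the inverse operations solved exactly on the bracketing segment, so
  V(D(v)) = v to machine precision wherever the curve is strictly
  decreasing, and within (max slope × grid step) elsewhere.

## 7. Problem sizes used in the test suite

The suite validates at the scale of a real clinic history where it
matters, smaller where it doesn't: serialization fidelity on 1000
generated file pairs (byte-compared after write→read→write); parameter
recovery on a 4091-check single-stratum history (mean recovered within
3σ/√n, SD within 5%); flag-rate calibration on 10⁴ standard-Normal draws
(action ≈ 0.27%, warning-or-worse ≈ 4.6%, within binomial tolerance);
limit tightening on a 4000-check two-site history with a 10% homogeneous
subgroup of half the SD, where the expected band ratio is
√0.36/√(0.9·1.44 + 0.1·0.36) ≈ 0.52; filtering against a brute-force
substring oracle over 500 random name fixtures; and DVH extraction
against dense numeric scans on 200 random curves plus a 140-curve cohort
whose envelopes are compared point-by-point with an independent loop.
These sizes were fixed once, as representative of the application, before
being wired into the tests.

## 8. Known limitations

* The SPC layer implements no run rules (Western Electric), CUSUM or
  EWMA, and no formal sampling design — the retrospective chart is a
  screening tool, not a monitoring scheme.
* Whether out-of-control points should be excluded before recomputing
  limits is a policy question the package does not answer; it never
  excludes automatically.
* DVH analysis is percent-volume only; absolute-volume (cc) curves,
  differential DVHs and toxicity models (NTCP/TCP) are out of scope.
* The dialect is this package's own; nothing reads a vendor's proprietary
  server files or DICOM.
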