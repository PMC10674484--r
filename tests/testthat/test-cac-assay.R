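# Pyrene vibronic ratio extraction and segmented-regression cac estimation.

test_that("vibronic ratio reads band maxima robustly", {
  wl <- seq(360, 420, by = 0.5)
  flat <- emission_spectrum(wl, rep(7, length(wl)))
  expect_equal(vibronic_ratio(flat), 1)

  two_band <- emission_spectrum(
    wl, 178 * exp(-(wl - 372)^2 / 18) + 100 * exp(-(wl - 387)^2 / 18))
  expect_equal(vibronic_ratio(two_band), 1.78, tolerance = 0.005)
  # scale invariance
  doubled <- emission_spectrum(wl, 2 * two_band$intensities)
  expect_equal(vibronic_ratio(doubled), vibronic_ratio(two_band))
  # tolerant to a small calibration shift
  shifted <- emission_spectrum(
    wl, 178 * exp(-(wl - 373.5)^2 / 18) + 100 * exp(-(wl - 388.5)^2 / 18))
  expect_equal(vibronic_ratio(shifted), 1.78, tolerance = 0.02)

  narrow <- emission_spectrum(seq(380, 420, 0.5), rep(1, 81))
  expect_error(vibronic_ratio(narrow), "not covered")
  zero3 <- emission_spectrum(wl, ifelse(abs(wl - 372) < 5, 100, 0))
  expect_error(vibronic_ratio(zero3), "I3")
})

test_that("noiseless titration recovers the breakpoint to under 1%", {
  ts <- generate_titration(titration_sim_spec(noise_sd = 0))
  fit <- fit_cac_segmented(ts, n_bootstrap = 0)
  expect_identical(fit$flag, "ok")
  expect_equal(fit$cac_uM, 4.3, tolerance = 0.01)
})

test_that("spectra-to-cac chain matches the direct titration path", {
  spec <- titration_sim_spec(noise_sd = 0)
  ts <- ratios_from_spectra(generate_pyrene_spectra(spec))
  fit <- fit_cac_segmented(ts, n_bootstrap = 0)
  expect_equal(fit$cac_uM, 4.3, tolerance = 0.01)
})

test_that("a single straight line is flagged as no breakpoint", {
  x <- 10^seq(-1, 1.3, length.out = 10)
  ts <- titration_series(x, 1.8 - 0.02 * log10(x))
  fit <- fit_cac_segmented(ts, n_bootstrap = 0)
  expect_identical(fit$flag, "no_breakpoint")
  expect_true(is.na(fit$cac_uM))
  # the degenerate generator spec produces the same outcome
  ts2 <- generate_titration(titration_sim_spec(slope_below = -0.3,
                                               slope_above = -0.3,
                                               noise_sd = 0))
  expect_identical(fit_cac_segmented(ts2, n_bootstrap = 0)$flag,
                   "no_breakpoint")
})

test_that("breakpoint recovery at 2% noise stays within 0.05 log units", {
  errs <- vapply(1:200, function(s) {
    ts <- generate_titration(titration_sim_spec(breakpoint_uM = 5,
                                                noise_sd = 0.02, seed = s))
    f <- fit_cac_segmented(ts, n_bootstrap = 0)
    if (f$flag != "ok") return(NA_real_)
    abs(log10(f$cac_uM / 5))
  }, numeric(1))
  expect_gt(mean(!is.na(errs)), 0.9)
  expect_lte(median(errs, na.rm = TRUE), 0.05)
})

test_that("bootstrap confidence interval covers the truth in most runs", {
  hits <- vapply(1:40, function(s) {
    ts <- generate_titration(titration_sim_spec(noise_sd = 0.02, seed = s))
    f <- fit_cac_segmented(ts, n_bootstrap = 200, seed = s)
    if (f$flag != "ok" || any(is.na(f$bootstrap_ci_uM))) return(NA)
    f$bootstrap_ci_uM[1] <= 4.3 && 4.3 <= f$bootstrap_ci_uM[2]
  }, logical(1))
  expect_gte(mean(hits, na.rm = TRUE), 0.9)
})

test_that("cac estimate is scale-equivariant and shift-invariant", {
  ts <- generate_titration(titration_sim_spec(noise_sd = 0.02, seed = 9))
  f0 <- fit_cac_segmented(ts, n_bootstrap = 0)
  k <- 7.5
  ts_k <- titration_series(ts$points$concentration_uM * k, ts$points$ratio)
  f_k <- fit_cac_segmented(ts_k, n_bootstrap = 0)
  expect_equal(f_k$cac_uM, k * f0$cac_uM, tolerance = 1e-9)

  ts_s <- titration_series(ts$points$concentration_uM, ts$points$ratio + 3)
  f_s <- fit_cac_segmented(ts_s, n_bootstrap = 0)
  expect_equal(f_s$cac_uM, f0$cac_uM, tolerance = 1e-9)
})

test_that("reported segments intersect exactly at the reported cac", {
  ts <- generate_titration(titration_sim_spec(noise_sd = 0.02, seed = 21))
  f <- fit_cac_segmented(ts, n_bootstrap = 0)
  s <- f$segments
  y_below <- s$intercept[1] + s$slope[1] * f$log10_cac
  y_above <- s$intercept[2] + s$slope[2] * f$log10_cac
  expect_lt(abs(y_below - y_above), 1e-9)
})

test_that("manual region selection reproduces the grid answer", {
  ts <- generate_titration(titration_sim_spec(noise_sd = 0))
  g <- fit_cac_segmented(ts, n_bootstrap = 0)
  m <- fit_cac_segmented(ts, method = "manual_regions",
                         regions = list(1:g$split_index,
                                        (g$split_index + 1):nrow(ts$points)),
                         n_bootstrap = 0)
  expect_equal(m$cac_uM, g$cac_uM, tolerance = 1e-9)
  expect_error(fit_cac_segmented(ts, method = "manual_regions"), "regions")
})

test_that("cac fit serializes with its segment table", {
  ts <- generate_titration(titration_sim_spec(seed = 2))
  f <- fit_cac_segmented(ts, n_bootstrap = 50, seed = 2)
  jp <- withr::local_tempfile(fileext = ".json")
  tp <- withr::local_tempfile(fileext = ".tsv")
  write_cac_fit(f, jp, tp, ts)
  rep <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(rep$cac_uM, f$cac_uM, tolerance = 1e-12)
  expect_true(file.exists(tp))
})
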