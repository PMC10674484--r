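# Generators: statistical structure, determinism, and agreement with the
# closed forms they are built to satisfy.

test_that("single-exponential decay has the right log-linear slope", {
  spec <- decay_sim_spec(components = list(c(1, 3)), irf_width_ns = 0,
                         peak_counts = 1e4, background = 0, seed = 42)
  tr <- generate_decay(spec)
  keep <- tr$counts > 50   # Poisson noise on log scale stays manageable
  sl <- coef(lm(log(tr$counts[keep]) ~ tr$times_ns[keep]))[2]
  expect_equal(unname(sl), -1 / 3, tolerance = 0.02)
})

test_that("decay generation is bit-reproducible given a seed", {
  spec <- decay_sim_spec(seed = 99)
  expect_identical(generate_decay(spec)$counts, generate_decay(spec)$counts)
  spec2 <- decay_sim_spec(seed = 100)
  expect_false(identical(generate_decay(spec)$counts,
                         generate_decay(spec2)$counts))
})

test_that("expected counts are conserved under IRF convolution to 0.1%", {
  tr <- generate_decay(decay_sim_spec(irf_width_ns = 0.4, seed = 1))
  expect_lt(abs(tr$metadata$conv_count_ratio - 1), 1e-3)
})

test_that("decay spec rejects invalid fields by name", {
  expect_error(decay_sim_spec(components = list(c(1, -3))), "lifetime")
  expect_error(decay_sim_spec(components = list(c(0.5, 3))), "sum to 1")
  expect_error(decay_sim_spec(time_window_ns = -1), "time_window")
  expect_error(decay_sim_spec(n_channels = 32), "n_channels")
})

test_that("noiseless anisotropy pairs satisfy the defining identities", {
  p <- generate_anisotropy_pair(0, 3e5, noise_sd = 0)
  expect_equal(unname(p["Ivv"]), unname(p["Ivh"]))
  p <- generate_anisotropy_pair(0.110, 3e5, noise_sd = 0)
  expect_equal(unname(p["Ivv"] + 2 * p["Ivh"]), 3e5)
  expect_equal(unname(anisotropy_from_intensities(p["Ivv"], p["Ivh"])),
               0.110, tolerance = 1e-12)
  expect_error(generate_anisotropy_pair(1, 100), "r_true")
})

test_that("noisy anisotropy pairs recover the true value in the mean", {
  r_hat <- vapply(1:1000, function(s) {
    p <- generate_anisotropy_pair(0.25, 1e5, noise_sd = 0.01, seed = s)
    anisotropy_from_intensities(p["Ivv"], p["Ivh"])
  }, numeric(1))
  se <- sd(r_hat) / sqrt(length(r_hat))
  expect_lt(abs(mean(r_hat) - 0.25), 3 * se)
})

test_that("titration generator is piecewise linear with an exact kink", {
  spec <- titration_sim_spec(noise_sd = 0)
  ts <- generate_titration(spec)
  x <- log10(ts$points$concentration_uM)
  y <- ts$points$ratio
  xb <- log10(spec$breakpoint_uM)
  below <- x <= xb
  expect_equal(diff(y[below]) / diff(x[below]),
               rep(spec$slope_below, sum(below) - 1), tolerance = 1e-9)
  expect_equal(diff(y[!below]) / diff(x[!below]),
               rep(spec$slope_above, sum(!below) - 1), tolerance = 1e-9)
  # both segments extrapolate to the same value at the breakpoint
  expect_equal(y[max(which(below))] +
                 spec$slope_below * (xb - x[max(which(below))]),
               spec$plateau_ratio, tolerance = 1e-9)
  expect_true(!is.unsorted(ts$points$concentration_uM))
})

test_that("titration spec enforces breakpoint placement and point counts", {
  expect_error(titration_sim_spec(concentrations_uM = c(1, 2, 3, 4, 5, 6),
                                  breakpoint_uM = 10), "inside")
  expect_error(titration_sim_spec(concentrations_uM = c(1, 2, 3, 4, 5, 6),
                                  breakpoint_uM = 5.5), "each side")
  expect_error(titration_sim_spec(slope_below = -0.5, slope_above = -0.1),
               "slope_above")
})

test_that("helix fixture matches direct-sum geometry oracles", {
  # two collinear points at distance d: both size metrics equal d/2 and d
  g2 <- build_helix(2, radius_A = 0, rise_A = 7)
  expect_equal(kirkwood_rh(g2$coordinates, selection = NULL), 7)
  g32 <- build_helix(32)
  expect_equal(radius_of_gyration(g32$coordinates, g32$masses),
               rg_brute(g32$coordinates), tolerance = 1e-10)
  # Rg grows strictly with chain length
  rgs <- vapply(c(4, 8, 16, 32, 64), function(n) {
    g <- build_helix(n)
    radius_of_gyration(g$coordinates, g$masses)
  }, numeric(1))
  expect_true(all(diff(rgs) > 0))
})

test_that("uniform-ball samples reach their closed-form metrics", {
  b <- sample_uniform_ball(20000, 10, seed = 7)
  expect_equal(radius_of_gyration(b$coordinates, b$masses),
               sqrt(3 / 5) * 10, tolerance = 0.01)
  expect_equal(kirkwood_rh(b$coordinates, b$elements),
               (5 / 6) * 10, tolerance = 0.02)
  # homogeneity: doubling the radius doubles both metrics exactly
  b2 <- b
  b2$coordinates <- b$coordinates * 2
  expect_equal(radius_of_gyration(b2$coordinates, b2$masses),
               2 * radius_of_gyration(b$coordinates, b$masses))
  expect_equal(kirkwood_rh(b2$coordinates, b2$elements),
               2 * kirkwood_rh(b$coordinates, b$elements))
})

test_that("generators round-trip noiselessly through their analyses", {
  tr <- generate_decay(decay_sim_spec(), noiseless = TRUE)
  fit <- fit_multiexponential(tr, 3)
  expect_equal(fit$components$tau_ns, trp_taus, tolerance = 1e-6)
  expect_equal(fit$components$alpha, trp_alphas, tolerance = 1e-6)
  expect_lt(fit$chi2_reduced, 1e-12)
})

test_that("written tables round-trip through the readers", {
  tr <- generate_decay(decay_sim_spec(seed = 3))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_decay_table(tr, p)
  tr2 <- read_decay_table(p)
  expect_equal(tr2$counts, tr$counts)
  expect_equal(tr2$times_ns, tr$times_ns, tolerance = 1e-9)

  ts <- generate_titration(titration_sim_spec(seed = 3))
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_titration_table(ts, p2)
  ts2 <- read_titration_table(p2)
  expect_equal(ts2$points$ratio, ts$points$ratio, tolerance = 1e-9)
})
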