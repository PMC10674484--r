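# Coordinate descriptors: Rg, Kirkwood Rh, sphere volumes, RMSF, and the
# PDB trajectory plumbing around them.

test_that("radius of gyration matches elementary cases and the direct sum", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1)), 0)
  dumbbell <- rbind(c(0, 0, 0), c(10, 0, 0))
  expect_equal(radius_of_gyration(dumbbell), 5)
  # mass weighting moves the centre toward the heavy atom
  expect_lt(radius_of_gyration(dumbbell, masses = c(3, 1)),
            radius_of_gyration(dumbbell))
  set.seed(2)
  cloud <- matrix(rnorm(300), ncol = 3)
  m <- runif(100, 1, 16)
  expect_equal(radius_of_gyration(cloud, m), rg_brute(cloud, m),
               tolerance = 1e-10)
})

test_that("Kirkwood radius matches enumerated pair oracles", {
  expect_equal(kirkwood_rh(rbind(c(0, 0, 0), c(10, 0, 0)),
                           selection = NULL), 10)
  square <- rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0), c(0, 10, 0))
  expect_equal(kirkwood_rh(square, selection = NULL),
               1 / ((4 / 10 + 2 / (10 * sqrt(2))) / 6), tolerance = 1e-12)
  expect_equal(kirkwood_rh(square, selection = NULL), 11.08,
               tolerance = 1e-3)
  dup <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1))
  expect_error(kirkwood_rh(dup, selection = NULL), "coincident")
})

test_that("Kirkwood radius agrees with the brute-force double loop", {
  set.seed(11)
  for (n in c(10, 100, 500)) {
    xyz <- matrix(rnorm(3 * n, sd = 8), ncol = 3)
    expect_equal(kirkwood_rh(xyz, selection = NULL), kirkwood_brute(xyz),
                 tolerance = 1e-10)
  }
})

test_that("element selection restricts the Kirkwood average", {
  xyz <- rbind(c(0, 0, 0), c(10, 0, 0), c(100, 0, 0))
  el <- c("C", "C", "N")
  expect_equal(kirkwood_rh(xyz, el, selection = "C"), 10)
  expect_equal(kirkwood_rh(xyz, el, selection = NULL),
               kirkwood_brute(xyz), tolerance = 1e-12)
  expect_error(kirkwood_rh(xyz, el, selection = "S"), "2 selected")
})

test_that("Rg and Rh are invariant under rigid motions and scale linearly", {
  set.seed(13)
  xyz <- sample_uniform_ball(200, 10, seed = 13)$coordinates
  rg0 <- radius_of_gyration(xyz)
  rh0 <- kirkwood_rh(xyz, selection = NULL)
  for (i in 1:5) {
    R <- random_rotation()
    moved <- xyz %*% R + matrix(rnorm(3, sd = 50), nrow(xyz), 3,
                                byrow = TRUE)
    expect_equal(radius_of_gyration(moved), rg0, tolerance = 1e-9)
    expect_equal(kirkwood_rh(moved, selection = NULL), rh0,
                 tolerance = 1e-9)
  }
  expect_equal(radius_of_gyration(xyz * 3.7), 3.7 * rg0, tolerance = 1e-12)
  expect_equal(kirkwood_rh(xyz * 3.7, selection = NULL), 3.7 * rh0,
               tolerance = 1e-12)
})

test_that("gyration volume applies the sphere formula to published radii", {
  expect_equal(gyration_volume(13.9), 11.3, tolerance = 0.01)
  expect_equal(gyration_volume(45.2), 386.8, tolerance = 0.001)
  expect_equal(gyration_volume(10), 4 * pi / 3)
  # all species rows are internally consistent with the sphere relation
  expect_true(all(abs(gyration_volume(species_table$Rg_A) -
                        species_table$Vg_nm3) < 0.1))
  expect_true(all(abs(volume_from_radius(species_table$Rh_A) -
                        species_table$Vh_nm3) < 0.1))
})

test_that("PDB files round-trip as trajectories", {
  hx <- build_helix(12)
  p <- withr::local_tempfile(fileext = ".pdb")
  write_geometry_pdb(hx, p)
  tj <- read_structure(p)
  expect_length(tj$frames, 1)
  expect_equal(nrow(tj$frames[[1]]), 12)
  expect_lt(max(abs(tj$frames[[1]] - hx$coordinates)), 1e-3)

  set.seed(4)
  frames <- lapply(1:5, function(i)
    hx$coordinates + matrix(rnorm(36, 0, 0.2), ncol = 3))
  fx <- lapply(frames, function(f)
    geometry_fixture("f", f, hx$elements, hx$masses))
  write_geometry_pdb(fx, p)
  tj5 <- read_structure(p)
  expect_length(tj5$frames, 5)
  # frame order is preserved
  for (i in 1:5)
    expect_lt(max(abs(tj5$frames[[i]] - frames[[i]])), 1e-3)
  expect_true(all(tj5$elements == "C"))
  expect_true(all(abs(tj5$masses - 12.0107) < 0.01))
})

test_that("rmsf is zero for static and rigidly rotating trajectories", {
  hx <- build_helix(20)
  static <- trajectory(rep(list(hx$coordinates), 4), hx$elements,
                       hx$masses, atom_names = rep("CA", 20))
  expect_true(all(rmsf(static)$rmsf_A == 0))

  set.seed(6)
  rot <- lapply(1:6, function(i)
    hx$coordinates %*% random_rotation() +
      matrix(rnorm(3, sd = 5), 20, 3, byrow = TRUE))
  tj <- trajectory(rot, hx$elements, hx$masses, atom_names = rep("CA", 20))
  expect_lt(max(rmsf(tj, superpose = TRUE)$rmsf_A), 1e-6)
  # without superposition the rigid motion dominates
  expect_gt(max(rmsf(tj, superpose = FALSE)$rmsf_A), 1)
})

test_that("unsuperposed rmsf of an isotropically jittered atom tends to s*sqrt(3)", {
  hx <- build_helix(10)
  s <- 0.5
  set.seed(8)
  frames <- lapply(1:4000, function(i) {
    f <- hx$coordinates
    f[5, ] <- f[5, ] + rnorm(3, 0, s)
    f
  })
  tj <- trajectory(frames, hx$elements, hx$masses,
                   atom_names = rep("CA", 10))
  out <- rmsf(tj, superpose = FALSE)
  expect_equal(out$rmsf_A[5], s * sqrt(3), tolerance = 0.05)
  expect_lt(max(out$rmsf_A[-5]), 1e-10)
})

test_that("rmsf input contracts are enforced", {
  hx <- build_helix(5)
  one <- trajectory(list(hx$coordinates), hx$elements, hx$masses)
  expect_error(rmsf(one), "2 frames")
  two <- trajectory(rep(list(hx$coordinates), 2), hx$elements, hx$masses,
                    atom_names = c("CA", "CB", "CB", "CB", "CB"))
  expect_error(rmsf(two, selection = "CA"), "3 selected")
})

test_that("trajectory summary ties the per-frame metrics together", {
  hx <- build_helix(16)
  static <- trajectory(rep(list(hx$coordinates), 3), hx$elements,
                       hx$masses, atom_names = rep("CA", 16))
  sm <- trajectory_summary(static)
  expect_equal(sm$Rg_sd_A, 0)
  expect_equal(sm$Rh_sd_A, 0)
  expect_equal(sm$Rg_mean_A, rg_brute(hx$coordinates), tolerance = 1e-10)
  # volumes derive from the mean radii through the shared sphere formula
  expect_identical(sm$Vh_nm3, volume_from_radius(sm$Rh_mean_A))
  expect_identical(sm$Vg_nm3, gyration_volume(sm$Rg_mean_A))
})

test_that("superposition cross-checks against the bio3d reference fit", {
  hx <- build_helix(15)
  set.seed(10)
  moved <- hx$coordinates %*% random_rotation() +
    matrix(c(3, -2, 7), 15, 3, byrow = TRUE)
  fit <- lipoaggr:::kabsch_superpose(moved, hx$coordinates)
  ours <- fit$apply(moved)
  ref <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.numeric(t(hx$coordinates)),
                   mobile = as.numeric(t(moved))))
  expect_lt(max(abs(ours - matrix(ref, ncol = 3, byrow = TRUE))), 1e-6)
})
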