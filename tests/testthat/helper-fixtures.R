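# Shared fixtures: the published tryptophan decay parameters and the
# measurement conditions used throughout the suite.

trp_alphas <- c(0.45, 0.41, 0.14)
trp_taus <- c(1.22, 3.66, 7.40)

water_cond <- hydro_conditions(viscosity_cP = 0.89, temperature_K = 298,
                               r0 = 0.260)

# Concentration series: (concentration uM, average lifetime ns, anisotropy)
anisotropy_series <- data.frame(
  concentration_uM = c(3, 21, 36),
  tau_ns = c(2.80, 3.00, 3.01),
  r = c(0.109, 0.112, 0.127))

# Published (Vh nm^3, Rh A) for the rows above
anisotropy_series_expected <- data.frame(
  Vh_nm3 = c(9.3, 10.5, 13.3),
  Rh_A = c(13.0, 13.5, 14.7))

# Species-series radii (A) and volumes (nm^3): monomer .. hexadecamer
species_table <- data.frame(
  species = c("monomer", "dimer", "tetramer", "octamer", "hexadecamer"),
  Rg_A = c(13.9, 25.1, 36.1, 38.5, 45.2),
  Vg_nm3 = c(11.3, 66.2, 197.1, 239.0, 386.8),
  Rh_A = c(10.8, 10.9, 11.2, 12.1, 13.8),
  Vh_nm3 = c(5.3, 5.4, 5.9, 7.4, 11.0))

# Brute-force oracles, independent of the package implementations
rg_brute <- function(xyz, m = rep(1, nrow(xyz))) {
  com <- colSums(xyz * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(xyz, 2, com)^2)) / sum(m))
}

kirkwood_brute <- function(xyz) {
  n <- nrow(xyz)
  s <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- s + 1 / sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    np <- np + 1
  }
  1 / (s / np)
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}
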