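# Seeded generators for every input the analysis chain consumes: TCSPC
# decay traces, polarized intensity pairs, pyrene titration series and
# spectra, and coordinate fixtures with known size metrics.

# Run `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic TCSPC decay
#'
#' Describes a multi-exponential photon-counting decay: component weights and
#' lifetimes, an optional Gaussian instrument response, the acquisition
#' window, and the counting statistics.  Defaults reproduce a tryptophan-like
#' tri-exponential decay recorded over 50 ns in 1024 channels.
#'
#' @param components Two-column matrix or list of `c(weight, lifetime_ns)`
#'   pairs.  Weights must be strictly positive and sum to 1 (to 1e-9);
#'   lifetimes strictly positive and distinct.
#' @param irf_width_ns Gaussian sigma of the instrument response in ns;
#'   0 means a delta-function excitation.
#' @param time_window_ns Acquisition window in ns.
#' @param n_channels Number of time channels (>= 64).
#' @param peak_counts Expected counts in the peak channel.
#' @param background Expected background counts per channel.
#' @param seed Integer seed; the same spec always yields the same trace.
#' @return A `decay_sim_spec` object.
#' @examples
#' decay_sim_spec(components = list(c(1, 3)), peak_counts = 1e4)
#' @export
decay_sim_spec <- function(components = list(c(0.45, 1.22),
                                             c(0.41, 3.66),
                                             c(0.14, 7.40)),
                           irf_width_ns = 0,
                           time_window_ns = 50,
                           n_channels = 1024,
                           peak_counts = 1e4,
                           background = 0,
                           seed = 1L) {
  comp <- do.call(rbind, lapply(components, function(x) {
    stopifnot(length(x) == 2)
    as.numeric(x)
  }))
  colnames(comp) <- c("weight", "lifetime_ns")
  if (any(comp[, "weight"] <= 0))
    stop("components: weights must be strictly positive")
  if (abs(sum(comp[, "weight"]) - 1) > 1e-9)
    stop("components: weights must sum to 1")
  if (any(comp[, "lifetime_ns"] <= 0))
    stop("components: lifetimes must be strictly positive")
  if (anyDuplicated(comp[, "lifetime_ns"]))
    stop("components: lifetimes must be distinct")
  if (irf_width_ns < 0) stop("irf_width_ns must be >= 0")
  if (time_window_ns <= 0) stop("time_window_ns must be > 0")
  if (n_channels < 64) stop("n_channels must be >= 64")
  if (peak_counts <= 0) stop("peak_counts must be > 0")
  if (background < 0) stop("background must be >= 0")
  structure(list(components = comp, irf_width_ns = irf_width_ns,
                 time_window_ns = time_window_ns,
                 n_channels = as.integer(n_channels),
                 peak_counts = peak_counts, background = background,
                 seed = as.integer(seed)),
            class = "decay_sim_spec")
}

# Noiseless expected-count curve for a spec; also used by tests to verify
# count conservation under convolution.  Returns list(times, mean, irf).
decay_model_curve <- function(spec) {
  times <- seq(0, spec$time_window_ns, length.out = spec$n_channels)
  d <- colSums(spec$components[, "weight"] *
                 exp(-outer(1 / spec$components[, "lifetime_ns"], times)))
  irf <- NULL
  if (spec$irf_width_ns > 0) {
    # normalized Gaussian IRF centred a few sigma into the window so the
    # pulse is fully contained; edge effects are negligible for windows
    # much longer than the lifetimes
    t0 <- 5 * spec$irf_width_ns
    irf <- stats::dnorm(times, mean = t0, sd = spec$irf_width_ns)
    irf <- irf / sum(irf)
    n <- length(times)
    total_before <- sum(d)
    # causal linear convolution, truncated to the acquisition window
    d <- as.numeric(stats::convolve(d, rev(irf), type = "open"))[seq_len(n)]
    conv_ratio <- sum(d) / total_before
  } else conv_ratio <- 1
  m <- d / max(d) * spec$peak_counts + spec$background
  list(times = times, mean = m, irf = irf, conv_count_ratio = conv_ratio)
}

#' Generate a synthetic TCSPC decay trace
#'
#' Draws Poisson counts around the (optionally IRF-convolved)
#' multi-exponential model described by `spec`, scaled so that the maximum
#' expected count equals `peak_counts`, plus a flat background.
#'
#' @param spec A [decay_sim_spec()] object.
#' @param noiseless Return the expected (non-integer) counts instead of a
#'   Poisson draw; useful for exact round-trip checks.
#' @return A [decay_trace()] with the simulated counts (and the IRF on the
#'   same grid when `irf_width_ns > 0`).
#' @examples
#' tr <- generate_decay(decay_sim_spec(components = list(c(1, 3))))
#' @export
generate_decay <- function(spec, noiseless = FALSE) {
  stopifnot(inherits(spec, "decay_sim_spec"))
  mc <- decay_model_curve(spec)
  counts <- if (noiseless) mc$mean
            else with_seed(spec$seed, stats::rpois(length(mc$mean), mc$mean))
  irf_counts <- if (!is.null(mc$irf)) mc$irf * spec$peak_counts else NULL
  decay_trace(times_ns = mc$times, counts = counts, irf = irf_counts,
              metadata = list(truth = spec,
                              conv_count_ratio = mc$conv_count_ratio))
}

#' Generate a polarized intensity pair with known anisotropy
#'
#' Produces (Ivv, Ivh) whose noiseless values satisfy
#' Ivv + 2 Ivh = `total_intensity` and (Ivv - Ivh)/(Ivv + 2 Ivh) = `r_true`;
#' Gaussian relative noise is applied independently to each channel.
#'
#' @param r_true True anisotropy, in [-0.2, 1).
#' @param total_intensity Total intensity Ivv + 2 Ivh (> 0).
#' @param noise_sd Relative Gaussian noise (0 = noiseless).
#' @param seed Integer seed.
#' @return Named numeric vector `c(Ivv = ..., Ivh = ...)`.
#' @examples
#' generate_anisotropy_pair(0.110, 1e5)
#' @export
generate_anisotropy_pair <- function(r_true, total_intensity,
                                     noise_sd = 0, seed = 1L) {
  if (r_true >= 1) stop("r_true must be < 1")
  if (r_true < -0.2) stop("r_true must be >= -0.2")
  if (total_intensity <= 0) stop("total_intensity must be > 0")
  Ivv <- total_intensity * (1 + 2 * r_true) / 3
  Ivh <- total_intensity * (1 - r_true) / 3
  if (noise_sd > 0) {
    eps <- with_seed(seed, stats::rnorm(2, 0, noise_sd))
    Ivv <- Ivv * (1 + eps[1])
    Ivh <- Ivh * (1 + eps[2])
  }
  c(Ivv = Ivv, Ivh = Ivh)
}

#' Specification of a synthetic pyrene titration
#'
#' Describes an I1/I3 vs concentration series that is piecewise linear in
#' log10(concentration) with a single breakpoint at the critical aggregation
#' concentration: nearly flat below it, steeply decreasing above it.
#' Defaults emulate a pyrene assay titrated from 0.2 to 21 uM with a
#' breakpoint at 4.3 uM and the I1/I3 plateau of pyrene in water (about 1.8).
#'
#' @param concentrations_uM Concentrations in uM (>= 6 values, >= 2 on each
#'   side of the breakpoint).  Default: 12 log-spaced points over 0.2-21 uM.
#' @param breakpoint_uM Breakpoint (cac) in uM, inside the range.
#' @param plateau_ratio I1/I3 value at the breakpoint (the low-concentration
#'   plateau level).
#' @param slope_below,slope_above Segment slopes in ratio units per
#'   log10(uM); `slope_above` must be smaller (descending branch steeper).
#' @param noise_sd Gaussian noise sd on the ratio.
#' @param seed Integer seed.
#' @return A `titration_sim_spec` object.
#' @export
titration_sim_spec <- function(concentrations_uM =
                                 10^seq(log10(0.2), log10(21), length.out = 12),
                               breakpoint_uM = 4.3,
                               plateau_ratio = 1.80,
                               slope_below = -0.02,
                               slope_above = -0.60,
                               noise_sd = 0.02,
                               seed = 1L) {
  conc <- sort(as.numeric(concentrations_uM))
  if (any(conc <= 0)) stop("concentrations_uM must be > 0")
  if (length(conc) < 6) stop("need at least 6 concentrations")
  if (breakpoint_uM <= min(conc) || breakpoint_uM >= max(conc))
    stop("breakpoint_uM must lie strictly inside the concentration range")
  if (sum(conc < breakpoint_uM) < 2 || sum(conc > breakpoint_uM) < 2)
    stop("need at least 2 concentrations on each side of the breakpoint")
  # equality is allowed only to exercise the degenerate single-line case
  if (slope_above > slope_below)
    stop("slope_above must be <= slope_below (descending branch steeper)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(concentrations_uM = conc, breakpoint_uM = breakpoint_uM,
                 plateau_ratio = plateau_ratio, slope_below = slope_below,
                 slope_above = slope_above, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "titration_sim_spec")
}

# Noiseless piecewise-linear ratio curve; segments meet exactly at the
# breakpoint.
titration_true_ratio <- function(spec, conc = spec$concentrations_uM) {
  x <- log10(conc)
  xb <- log10(spec$breakpoint_uM)
  ifelse(x <= xb,
         spec$plateau_ratio + spec$slope_below * (x - xb),
         spec$plateau_ratio + spec$slope_above * (x - xb))
}

#' Generate a synthetic pyrene I1/I3 titration series
#'
#' @param spec A [titration_sim_spec()] object.
#' @return A [titration_series()] sorted by concentration.
#' @examples
#' ts <- generate_titration(titration_sim_spec(noise_sd = 0))
#' @export
generate_titration <- function(spec) {
  stopifnot(inherits(spec, "titration_sim_spec"))
  ratio <- titration_true_ratio(spec)
  if (spec$noise_sd > 0)
    ratio <- ratio + with_seed(spec$seed,
                               stats::rnorm(length(ratio), 0, spec$noise_sd))
  titration_series(concentration_uM = spec$concentrations_uM, ratio = ratio)
}

#' Generate synthetic pyrene emission spectra for a titration
#'
#' Builds one emission spectrum per concentration on the 360-420 nm band:
#' Gaussian vibronic bands at 372 nm (I1) and 387 nm (I3) whose height ratio
#' follows the piecewise-linear titration model, plus overall quenching with
#' increasing peptide concentration (the ratio is unaffected by quenching).
#'
#' @param spec A [titration_sim_spec()] object.
#' @param wavelengths_nm Wavelength grid (must cover 360-420 nm).
#' @param band_sd_nm Gaussian width of each vibronic band.
#' @return A list of `emission_spectrum` objects, one per concentration.
#' @export
generate_pyrene_spectra <- function(spec,
                                    wavelengths_nm = seq(360, 420, by = 0.5),
                                    band_sd_nm = 3) {
  stopifnot(inherits(spec, "titration_sim_spec"))
  ratio <- titration_true_ratio(spec)
  if (spec$noise_sd > 0)
    ratio <- ratio + with_seed(spec$seed,
                               stats::rnorm(length(ratio), 0, spec$noise_sd))
  lapply(seq_along(spec$concentrations_uM), function(i) {
    c_uM <- spec$concentrations_uM[i]
    quench <- 1 / (1 + c_uM / 20)   # monotone self-quenching, ratio-neutral
    i1 <- ratio[i] * exp(-(wavelengths_nm - 372)^2 / (2 * band_sd_nm^2))
    i3 <- exp(-(wavelengths_nm - 387)^2 / (2 * band_sd_nm^2))
    emission_spectrum(wavelengths_nm = wavelengths_nm,
                      intensities = quench * (i1 + i3) * 100,
                      label_uM = c_uM)
  })
}

#' Ideal alpha-helical C-alpha trace
#'
#' Places `n_residues` points on a regular helix (default geometry of an
#' alpha helix: 1.5 A rise and 100 degree twist per residue on a 2.3 A
#' radius), labelled as carbon atoms with unit masses.
#'
#' @param n_residues Number of residues (>= 2).
#' @param rise_A Rise per residue in angstrom.
#' @param radius_A Helix radius in angstrom.
#' @param twist_deg Twist per residue in degrees.
#' @return A `geometry_fixture` list with `coordinates` (N x 3, angstrom),
#'   `elements`, `masses` and a `label`.
#' @examples
#' build_helix(32)
#' @export
build_helix <- function(n_residues, rise_A = 1.5, radius_A = 2.3,
                        twist_deg = 100) {
  if (n_residues < 2) stop("n_residues must be >= 2")
  i <- seq_len(n_residues) - 1
  th <- i * twist_deg * pi / 180
  xyz <- cbind(radius_A * cos(th), radius_A * sin(th), rise_A * i)
  geometry_fixture(label = sprintf("helix_%d", n_residues),
                   coordinates = xyz,
                   elements = rep("C", n_residues),
                   masses = rep(1, n_residues))
}

#' Points uniform in a solid ball, with closed-form reference metrics
#'
#' Samples `n_points` i.i.d. uniform in the ball of radius `radius_A`.  The
#' asymptotic reference values are Rg -> sqrt(3/5) * R and Kirkwood
#' Rh -> (5/6) * R, stored in `reference_values`.
#'
#' @param n_points Number of points (>= 2).
#' @param radius_A Ball radius in angstrom (> 0).
#' @param seed Integer seed.
#' @return A `geometry_fixture` with `reference_values$Rg_A` and
#'   `reference_values$Rh_A`.
#' @export
sample_uniform_ball <- function(n_points, radius_A, seed = 1L) {
  if (n_points < 2) stop("n_points must be >= 2")
  if (radius_A <= 0) stop("radius_A must be > 0")
  xyz <- with_seed(seed, {
    u <- matrix(stats::rnorm(3 * n_points), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    r <- radius_A * stats::runif(n_points)^(1 / 3)
    u * r
  })
  geometry_fixture(label = sprintf("ball_R%g_n%d", radius_A, n_points),
                   coordinates = xyz,
                   elements = rep("C", n_points),
                   masses = rep(1, n_points),
                   reference_values = list(Rg_A = sqrt(3 / 5) * radius_A,
                                           Rh_A = (5 / 6) * radius_A))
}

#' Construct a coordinate fixture
#'
#' @param label Text label.
#' @param coordinates N x 3 matrix of coordinates in angstrom.
#' @param elements Per-atom element symbols.
#' @param masses Per-atom masses in amu (> 0).
#' @param reference_values Optional list of known metric values.
#' @return A `geometry_fixture` list.
#' @export
geometry_fixture <- function(label, coordinates, elements, masses,
                             reference_values = NULL) {
  coordinates <- as.matrix(coordinates)
  stopifnot(ncol(coordinates) == 3, nrow(coordinates) >= 1,
            length(elements) == nrow(coordinates),
            length(masses) == nrow(coordinates))
  if (!all(is.finite(coordinates))) stop("coordinates must be finite")
  if (any(masses <= 0)) stop("masses must be > 0")
  structure(list(label = label, coordinates = coordinates,
                 elements = elements, masses = masses,
                 reference_values = reference_values),
            class = "geometry_fixture")
}

#' Write a decay trace as delimited text
#'
#' Two columns `time_ns`, `counts` (plus `irf_counts` when present),
#' tab-separated with a header row.
#'
#' @param trace A [decay_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_decay_table <- function(trace, path) {
  df <- data.frame(time_ns = trace$times_ns, counts = trace$counts)
  if (!is.null(trace$irf)) df$irf_counts <- trace$irf
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a titration series as delimited text
#'
#' Columns `concentration_uM`, `ratio`, tab-separated with a header.
#'
#' @param series A [titration_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_titration_table <- function(series, path) {
  utils::write.table(series$points, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a geometry fixture (or trajectory of fixtures) as PDB
#'
#' Single fixtures become single-MODEL files; a list of fixtures with
#' identical atom counts becomes a multi-MODEL file readable as a
#' trajectory.
#'
#' @param geom A `geometry_fixture` or list of them (identical atom layout).
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_geometry_pdb <- function(geom, path) {
  frames <- if (inherits(geom, "geometry_fixture")) list(geom) else geom
  stopifnot(length(frames) >= 1,
            all(vapply(frames, inherits, logical(1), "geometry_fixture")))
  n <- nrow(frames[[1]]$coordinates)
  xyz <- do.call(rbind, lapply(frames, function(f) {
    stopifnot(nrow(f$coordinates) == n)
    as.numeric(t(f$coordinates))
  }))
  el <- frames[[1]]$elements
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = seq_len(n), resid = rep("GLY", n),
                   eleno = seq_len(n),
                   elety = ifelse(el == "C", "CA", el),
                   chain = rep("A", n))
  invisible(path)
}
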