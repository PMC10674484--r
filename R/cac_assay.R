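# Pyrene I1/I3 vibronic-ratio extraction and critical aggregation
# concentration (cac) estimation as the intersection of two linear regimes
# in semi-log space.

#' Construct a pyrene emission spectrum
#'
#' @param wavelengths_nm Strictly increasing wavelength grid in nm; must
#'   cover the 360-420 nm pyrene emission band for ratio extraction.
#' @param intensities Non-negative intensities (arbitrary units).
#' @param label_uM Peptide concentration this spectrum was recorded at.
#' @return An `emission_spectrum` object.
#' @export
emission_spectrum <- function(wavelengths_nm, intensities, label_uM = NA) {
  wavelengths_nm <- as.numeric(wavelengths_nm)
  intensities <- as.numeric(intensities)
  stopifnot(length(wavelengths_nm) == length(intensities))
  if (any(diff(wavelengths_nm) <= 0))
    stop("wavelengths_nm must be strictly increasing")
  if (any(intensities < 0)) stop("intensities must be >= 0")
  structure(list(wavelengths_nm = wavelengths_nm, intensities = intensities,
                 label_uM = label_uM),
            class = "emission_spectrum")
}

#' Pyrene I1/I3 vibronic intensity ratio
#'
#' The intensity of each vibronic band is taken as the maximum within
#' `window_nm` of its nominal wavelength (first band 372 nm, third band
#' 387 nm), making the ratio robust to small calibration shifts.
#'
#' @param spectrum An [emission_spectrum()].
#' @param lambda1_nm,lambda3_nm Nominal band positions in nm.
#' @param window_nm Half-width of the search window in nm.
#' @return I1/I3 (dimensionless).
#' @export
vibronic_ratio <- function(spectrum, lambda1_nm = 372, lambda3_nm = 387,
                           window_nm = 2) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  wl <- spectrum$wavelengths_nm
  band_max <- function(l0) {
    idx <- which(wl >= l0 - window_nm & wl <= l0 + window_nm)
    if (length(idx) == 0 || l0 - window_nm < min(wl) || l0 + window_nm > max(wl))
      stop(sprintf("band at %g nm (+/- %g nm) not covered by the grid",
                   l0, window_nm))
    max(spectrum$intensities[idx])
  }
  i1 <- band_max(lambda1_nm)
  i3 <- band_max(lambda3_nm)
  if (i3 == 0) stop("I3 band intensity is zero: ratio undefined")
  i1 / i3
}

#' Construct a titration series of (concentration, I1/I3) points
#'
#' @param concentration_uM Concentrations in uM (> 0, >= 6 points).
#' @param ratio I1/I3 ratios.
#' @param provenance Optional per-point labels (e.g. source spectrum files).
#' @return A `titration_series` with points sorted by concentration.
#' @export
titration_series <- function(concentration_uM, ratio, provenance = NULL) {
  stopifnot(length(concentration_uM) == length(ratio))
  if (any(concentration_uM <= 0)) stop("concentrations must be > 0")
  if (length(concentration_uM) < 6) stop("need at least 6 titration points")
  ord <- order(concentration_uM)
  pts <- data.frame(concentration_uM = concentration_uM[ord],
                    ratio = ratio[ord])
  if (!is.null(provenance)) pts$provenance <- provenance[ord]
  structure(list(points = pts), class = "titration_series")
}

#' Titration series from a list of emission spectra
#'
#' Extracts the I1/I3 ratio of each spectrum with [vibronic_ratio()] and
#' assembles a [titration_series()] keyed by each spectrum's concentration
#' label.
#'
#' @param spectra List of [emission_spectrum()] objects with `label_uM` set.
#' @param ... Passed to [vibronic_ratio()].
#' @return A `titration_series`.
#' @export
ratios_from_spectra <- function(spectra, ...) {
  conc <- vapply(spectra, function(s) as.numeric(s$label_uM), numeric(1))
  if (any(is.na(conc)))
    stop("every spectrum needs a concentration label (label_uM)")
  r <- vapply(spectra, vibronic_ratio, numeric(1), ...)
  titration_series(concentration_uM = conc, ratio = r,
                   provenance = sprintf("spectrum_%g_uM", conc))
}

#' Read a titration table (concentration_uM, ratio) from delimited text
#'
#' @param path Input file path.
#' @return A [titration_series()].
#' @export
read_titration_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (ncol(df) < 2) df <- utils::read.table(path, header = TRUE)
  if (all(c("I1", "I3") %in% names(df)))
    titration_series(df$concentration_uM, df$I1 / df$I3)
  else
    titration_series(df[[1]], df[[2]])
}

# Closed-form simple regression of y on x: intercept, slope, SSE and the
# slope's standard error.  Used instead of lm() for speed inside the
# breakpoint grid search and the bootstrap.
line_fit <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) return(list(a = my, b = 0, sse = sum((y - my)^2),
                            se_b = NA_real_))
  b <- sum((x - mx) * (y - my)) / sxx
  a <- my - b * mx
  sse <- sum((y - a - b * x)^2)
  se_b <- if (n > 2) sqrt(sse / (n - 2) / sxx) else NA_real_
  list(a = a, b = b, sse = sse, se_b = se_b)
}

# Two lines fitted to the left/right point sets in (log10 c, ratio) space;
# returns their coefficients, joint SSE and the intersection abscissa.
segment_pair_fit <- function(x, y, m) {
  n <- length(x)
  fl <- line_fit(x[seq_len(m)], y[seq_len(m)])
  fr <- line_fit(x[(m + 1):n], y[(m + 1):n])
  ds <- fl$b - fr$b
  xint <- if (abs(ds) < 1e-12) NA_real_ else (fr$a - fl$a) / ds
  list(int_left = fl$a, slope_left = fl$b,
       int_right = fr$a, slope_right = fr$b,
       se_slope_left = fl$se_b, se_slope_right = fr$se_b,
       sse = fl$sse + fr$sse,
       x_intersect = xint)
}

# Core grid-breakpoint estimator on (log10 c, ratio); returns the best
# admissible split or NULL when none exists.
cac_grid_search <- function(x, y, min_seg = 3) {
  n <- length(x)
  best <- NULL
  for (m in min_seg:(n - min_seg)) {
    f <- segment_pair_fit(x, y, m)
    # intersection must fall between the two points bracketing the split
    if (!is.finite(f$x_intersect)) next
    if (f$x_intersect < x[m] || f$x_intersect > x[m + 1]) next
    if (is.null(best) || f$sse < best$sse) {
      best <- f
      best$split <- m
    }
  }
  best
}

#' Estimate the critical aggregation concentration by segmented regression
#'
#' Fits two straight lines to the I1/I3 ratio vs log10(concentration) curve
#' and returns the concentration at their intersection.  In
#' `grid_breakpoint` mode every split of the sorted points into a left and a
#' right set (each with at least `min_segment` points) is tried; a split is
#' admissible when the fitted lines intersect between its two bracketing
#' concentrations, and the admissible split with the smallest total sum of
#' squared residuals wins.  In `manual_regions` mode the caller names the
#' two index ranges.  A bootstrap confidence interval is computed by
#' resampling points with replacement.  When the two slopes are
#' indistinguishable within their joint standard error (or no admissible
#' split exists) the fit is flagged `no_breakpoint`.
#'
#' @param series A [titration_series()].
#' @param method `"grid_breakpoint"` (default) or `"manual_regions"`.
#' @param regions For `manual_regions`: list of two integer index vectors
#'   (into the sorted points) naming the below- and above-cac sets.
#' @param min_segment Minimum points per segment (default 3).
#' @param n_bootstrap Bootstrap replicates for the CI (default 500; 0 skips).
#' @param conf_level Bootstrap CI level.
#' @param seed Integer seed for the bootstrap.
#' @return A `cac_fit` list: `cac_uM`, `log10_cac`, `segments` (slopes and
#'   intercepts in (log10 uM, ratio) space), `sse`, `bootstrap_ci_uM`,
#'   `flag` (`"ok"` or `"no_breakpoint"`).
#' @examples
#' ts <- generate_titration(titration_sim_spec(noise_sd = 0))
#' fit_cac_segmented(ts, n_bootstrap = 0)$cac_uM   # 4.3
#' @export
fit_cac_segmented <- function(series,
                              method = c("grid_breakpoint", "manual_regions"),
                              regions = NULL, min_segment = 3,
                              n_bootstrap = 500, conf_level = 0.95,
                              seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(series, "titration_series"))
  pts <- series$points
  x <- log10(pts$concentration_uM)
  y <- pts$ratio
  n <- length(x)
  if (n < 2 * min_segment)
    stop(sprintf("need at least %d points for two segments of %d",
                 2 * min_segment, min_segment))

  no_bp <- function() structure(
    list(cac_uM = NA_real_, log10_cac = NA_real_, segments = NULL,
         sse = NA_real_, bootstrap_ci_uM = c(NA_real_, NA_real_),
         flag = "no_breakpoint"),
    class = "cac_fit")

  if (method == "grid_breakpoint") {
    best <- cac_grid_search(x, y, min_segment)
    if (is.null(best)) return(no_bp())
  } else {
    if (is.null(regions) || length(regions) != 2)
      stop("manual_regions needs `regions`: a list of two index vectors")
    li <- sort(regions[[1]])
    ri <- sort(regions[[2]])
    if (length(li) < 2 || length(ri) < 2) stop("each region needs >= 2 points")
    fl <- line_fit(x[li], y[li])
    fr <- line_fit(x[ri], y[ri])
    ds <- fl$b - fr$b
    if (abs(ds) < 1e-12) return(no_bp())
    best <- list(int_left = fl$a, slope_left = fl$b,
                 int_right = fr$a, slope_right = fr$b,
                 se_slope_left = fl$se_b, se_slope_right = fr$se_b,
                 sse = fl$sse + fr$sse,
                 x_intersect = (fr$a - fl$a) / ds,
                 split = max(li))
  }

  # slopes equal within their joint standard error -> no detectable kink
  joint_se <- sqrt(sum(c(best$se_slope_left, best$se_slope_right)^2,
                       na.rm = TRUE))
  if (is.finite(joint_se) &&
      abs(best$slope_left - best$slope_right) <= joint_se)
    return(no_bp())

  ci <- c(NA_real_, NA_real_)
  if (n_bootstrap > 0) {
    boots <- with_seed(seed, vapply(seq_len(n_bootstrap), function(b) {
      idx <- sort(sample.int(n, n, replace = TRUE))
      xb <- x[idx]; yb <- y[idx]
      # resampling can produce duplicated abscissae; the grid search copes
      bb <- tryCatch(cac_grid_search(xb, yb, min_segment),
                     error = function(e) NULL)
      if (is.null(bb)) NA_real_ else bb$x_intersect
    }, numeric(1)))
    qs <- stats::quantile(boots, c((1 - conf_level) / 2,
                                   1 - (1 - conf_level) / 2), na.rm = TRUE)
    ci <- 10^unname(qs)
  }

  structure(list(
    cac_uM = 10^best$x_intersect,
    log10_cac = best$x_intersect,
    segments = data.frame(
      side = c("below", "above"),
      intercept = c(best$int_left, best$int_right),
      slope = c(best$slope_left, best$slope_right),
      slope_se = c(best$se_slope_left, best$se_slope_right)),
    sse = best$sse,
    split_index = best$split,
    bootstrap_ci_uM = ci,
    flag = "ok"),
    class = "cac_fit")
}

#' Write a cac fit as JSON plus a plot-ready table of both segments
#'
#' @param fit A `cac_fit`.
#' @param json_path Output path for the JSON report.
#' @param table_path Optional output path for the fitted-segment table
#'   (log10 concentration grid, both fitted lines).
#' @param series Optional originating [titration_series()] used to set the
#'   table's concentration grid.
#' @return `json_path`, invisibly.
#' @export
write_cac_fit <- function(fit, json_path, table_path = NULL, series = NULL) {
  jsonlite::write_json(
    list(cac_uM = fit$cac_uM, log10_cac = fit$log10_cac,
         segments = fit$segments, sse = fit$sse,
         bootstrap_ci_uM = fit$bootstrap_ci_uM, flag = fit$flag),
    json_path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  if (!is.null(table_path) && !is.null(series) && fit$flag == "ok") {
    xg <- seq(log10(min(series$points$concentration_uM)),
              log10(max(series$points$concentration_uM)), length.out = 100)
    s <- fit$segments
    utils::write.table(
      data.frame(log10_concentration_uM = xg,
                 fit_below = s$intercept[1] + s$slope[1] * xg,
                 fit_above = s$intercept[2] + s$slope[2] * xg),
      table_path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(json_path)
}
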