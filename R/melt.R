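#' Construct a melt curve
#'
#' A melt curve is one well's fluorescence trace over the post-PCR melt ramp
#' (typically 70-90 degrees C in 0.1 degree steps). Fluorescence (RFU) falls
#' as the double-stranded amplicon denatures; the shape of the fall carries
#' the allele composition of the sample.
#'
#' @param well Well identifier (e.g. `"A1"`). Treated as an opaque label; no
#'   plate-geometry semantics are assumed.
#' @param temperature Numeric vector of temperatures in degrees C, strictly
#'   increasing, length >= 10.
#' @param rfu Numeric fluorescence vector of the same length.
#' @param normalized Logical; `TRUE` if `rfu` has already been min-max
#'   rescaled to `[0, 1]`.
#' @return An object of class `melt_curve`: a list with elements `well`,
#'   `temperature`, `rfu` and `normalized`.
#' @seealso [normalize_curve()], [melting_temperature()], [difference_curve()]
#' @examples
#' tt <- seq(70, 90, by = 0.1)
#' mc <- melt_curve("A1", tt, 1000 / (1 + exp((tt - 81) / 0.4)) + 100)
#' mc
#' @export
melt_curve <- function(well, temperature, rfu, normalized = FALSE) {
  stopifnot(is.character(well), length(well) == 1L)
  temperature <- as.numeric(temperature)
  rfu <- as.numeric(rfu)
  if (length(temperature) != length(rfu))
    stop("temperature and rfu must have the same length (well ", well, ")")
  if (length(temperature) < 10L)
    stop("melt curve for well ", well, " has fewer than 10 points")
  if (anyNA(temperature) || anyNA(rfu))
    stop("melt curve for well ", well, " contains missing values")
  if (any(diff(temperature) <= 0))
    stop("temperatures must be strictly increasing (well ", well,
         "); duplicated or unsorted temperatures are a data error")
  if (normalized) {
    if (abs(min(rfu)) > 1e-9 || abs(max(rfu) - 1) > 1e-9)
      stop("curve flagged normalized but rfu range is not [0, 1]")
  }
  structure(list(well = well, temperature = temperature, rfu = rfu,
                 normalized = isTRUE(normalized)),
            class = "melt_curve")
}

#' @export
print.melt_curve <- function(x, ...) {
  cat(sprintf("<melt_curve> well %s: %d points, %.1f-%.1f C%s\n",
              x$well, length(x$temperature), min(x$temperature),
              max(x$temperature),
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' @export
plot.melt_curve <- function(x, ...) {
  graphics::plot(x$temperature, x$rfu, type = "l",
                 xlab = "Temperature (°C)",
                 ylab = if (x$normalized) "Normalized RFU" else "RFU",
                 main = x$well, ...)
  invisible(x)
}

#' Min-max normalize a melt curve
#'
#' Rescales the fluorescence of a raw melt curve affinely so that its minimum
#' is 0 and its maximum is 1 over the whole measured window. Normalization
#' absorbs per-well gain and offset differences so curves from different
#' wells become comparable.
#'
#' A curve with constant fluorescence (typically a no-template control that
#' never amplified) cannot be normalized and raises an error.
#'
#' @param curve A raw [melt_curve()].
#' @param window Optional numeric length-2 vector: restrict the min/max used
#'   for scaling to this temperature window; scaling is still applied to the
#'   whole curve. The default uses the full curve.
#' @return The normalized `melt_curve` (temperatures unchanged).
#' @export
normalize_curve <- function(curve, window = NULL) {
  stopifnot(inherits(curve, "melt_curve"))
  if (curve$normalized)
    stop("curve for well ", curve$well, " is already normalized")
  r <- curve$rfu
  if (!is.null(window)) {
    stopifnot(length(window) == 2L)
    sel <- curve$temperature >= min(window) & curve$temperature <= max(window)
    if (sum(sel) < 2L) stop("normalization window contains fewer than 2 points")
    lo <- min(r[sel]); hi <- max(r[sel])
  } else {
    lo <- min(r); hi <- max(r)
  }
  if (hi <= lo)
    stop("degenerate (constant) curve in well ", curve$well,
         ": cannot normalize; is this a no-template control?")
  melt_curve(curve$well, curve$temperature, (r - lo) / (hi - lo),
             normalized = TRUE)
}

#' Call the melting temperature of a curve
#'
#' The melting temperature (Tm) is the inflection point of the melt curve:
#' the temperature at which fluorescence falls fastest. It is located as the
#' maximum, over a dense temperature grid, of a cubic-spline interpolant of
#' the negative first derivative of the normalized curve. The derivative is
#' first computed by central finite differences on the measured grid
#' (one-sided at the ends), then interpolated.
#'
#' @param curve A normalized [melt_curve()].
#' @param grid_step Step of the dense evaluation grid in degrees C
#'   (default 0.01).
#' @param spar Optional smoothing parameter passed to
#'   [stats::smooth.spline()]; by default an interpolating spline
#'   ([stats::splinefun()], `"fmm"` end conditions) is used, which is
#'   appropriate for low-noise instrument exports.
#' @return Tm in degrees C (scalar), guaranteed to lie within the curve's
#'   temperature range.
#' @examples
#' tt <- seq(70, 90, by = 0.1)
#' mc <- melt_curve("A1", tt, 1 / (1 + exp((tt - 81.5) / 0.4)),
#'                  normalized = TRUE)
#' melting_temperature(mc) # 81.5
#' @export
melting_temperature <- function(curve, grid_step = 0.01, spar = NULL) {
  stopifnot(inherits(curve, "melt_curve"))
  if (!curve$normalized)
    stop("melting_temperature expects a normalized curve; call normalize_curve() first")
  tt <- curve$temperature
  r <- curve$rfu
  n <- length(tt)
  if (n < 4L) stop("need at least 4 points for the derivative spline")
  d <- neg_first_derivative(tt, r)
  dense <- seq(tt[1L], tt[n], by = grid_step)
  if (is.null(spar)) {
    f <- stats::splinefun(tt, d, method = "fmm")
    vals <- f(dense)
  } else {
    sm <- stats::smooth.spline(tt, d, spar = spar)
    vals <- stats::predict(sm, dense)$y
  }
  dense[which.max(vals)]
}

# negative first derivative -d(rfu)/dT: central differences in the interior,
# one-sided at the boundary points
neg_first_derivative <- function(tt, r) {
  n <- length(tt)
  d <- numeric(n)
  d[1L] <- -(r[2L] - r[1L]) / (tt[2L] - tt[1L])
  d[n] <- -(r[n] - r[n - 1L]) / (tt[n] - tt[n - 1L])
  i <- 2:(n - 1L)
  d[i] <- -(r[i + 1L] - r[i - 1L]) / (tt[i + 1L] - tt[i - 1L])
  d
}

#' Difference curve relative to a control
#'
#' Pointwise subtraction of a normalized control curve (conventionally the
#' pure marked-allele positive control) from a normalized sample curve.
#' Difference curves amplify shape differences between alleles that are
#' subtle on the raw melt curves.
#'
#' Both curves must be normalized and share the same temperature grid; use
#' [align_to_grid()] first when grids differ.
#'
#' @param sample,control Normalized [melt_curve()] objects on a common grid.
#' @return An object of class `melt_diff`: list with `well`, `temperature`
#'   and `diff` (sample minus control).
#' @export
difference_curve <- function(sample, control) {
  stopifnot(inherits(sample, "melt_curve"), inherits(control, "melt_curve"))
  if (!sample$normalized || !control$normalized)
    stop("difference_curve expects normalized curves")
  if (length(sample$temperature) != length(control$temperature) ||
      any(abs(sample$temperature - control$temperature) > 1e-8))
    stop("sample and control are on different temperature grids; align first")
  structure(list(well = sample$well, temperature = sample$temperature,
                 diff = sample$rfu - control$rfu),
            class = "melt_diff")
}

#' @export
print.melt_diff <- function(x, ...) {
  cat(sprintf("<melt_diff> well %s: %d points, range [%.3f, %.3f]\n",
              x$well, length(x$temperature), min(x$diff), max(x$diff)))
  invisible(x)
}

#' Interpolate a melt curve onto a reference temperature grid
#'
#' Linear interpolation of the fluorescence values onto `grid`. Used to put
#' every well of a plate on the grid of the marked positive control before
#' difference curves are computed. Grid points outside the curve's measured
#' range are an error.
#'
#' @param curve A [melt_curve()].
#' @param grid Ascending numeric vector of target temperatures.
#' @return A `melt_curve` on the new grid, re-normalized flag preserved.
#' @export
align_to_grid <- function(curve, grid) {
  stopifnot(inherits(curve, "melt_curve"))
  grid <- as.numeric(grid)
  if (min(grid) < min(curve$temperature) - 1e-8 ||
      max(grid) > max(curve$temperature) + 1e-8)
    stop("target grid extends beyond the measured range of well ", curve$well)
  if (length(grid) == length(curve$temperature) &&
      all(abs(grid - curve$temperature) < 1e-8))
    return(curve)
  r <- stats::approx(curve$temperature, curve$rfu, xout = grid)$y
  # interpolation cannot extend the [0,1] range, so the normalized flag is
  # only kept when the endpoints still attain it
  norm <- curve$normalized && abs(min(r)) < 1e-9 && abs(max(r) - 1) < 1e-9
  melt_curve(curve$well, grid, r, normalized = norm)
}

#' Select the discriminating temperature from standard difference curves
#'
#' The proportion signal is read off each difference curve at a single
#' temperature, chosen per plate as the temperature where the difference
#' curves of the two pure standards (marked-allele proportions 0 and 1) are
#' farthest apart -- this maximizes the dynamic range of the standard curve.
#' Ties are broken deterministically toward the lowest such temperature.
#'
#' @param diffs List of `melt_diff` objects for the standard wells, all on a
#'   common grid.
#' @param proportions Numeric vector of the known marked-allele proportions,
#'   parallel to `diffs`; must contain both 0 and 1. Replicate standards at
#'   the same proportion are averaged.
#' @return The discriminating temperature in degrees C.
#' @export
select_discriminating_temperature <- function(diffs, proportions) {
  stopifnot(is.list(diffs), length(diffs) == length(proportions))
  proportions <- as.numeric(proportions)
  i0 <- which(abs(proportions) < 1e-9)
  i1 <- which(abs(proportions - 1) < 1e-9)
  if (length(i0) == 0L || length(i1) == 0L)
    stop("standards must include proportions 0 and 1 to pick a discriminating temperature")
  grid <- diffs[[1L]]$temperature
  for (d in diffs)
    if (length(d$temperature) != length(grid) ||
        any(abs(d$temperature - grid) > 1e-8))
      stop("standard difference curves are on different grids")
  avg <- function(idx) rowMeans(sapply(diffs[idx], `[[`, "diff"))
  sep <- abs(avg(i0) - avg(i1))
  if (max(sep) <= 1e-12)
    warning("difference curves of the 0 and 1 standards are identical; ",
            "no discrimination possible on this plate")
  grid[which.max(sep)] # which.max takes the first (lowest T) maximum
}

#' Read the melt signal off a difference curve
#'
#' Linear interpolation of a difference curve at the discriminating
#' temperature. This scalar -- the normalized-RFU difference relative to the
#' marked positive control -- is the response `y` of the standard curve.
#'
#' @param diff A `melt_diff` object.
#' @param temperature Evaluation temperature in degrees C; must lie within
#'   the curve's measured range.
#' @return Dimensionless signal (scalar).
#' @export
signal_at <- function(diff, temperature) {
  stopifnot(inherits(diff, "melt_diff"), length(temperature) == 1L)
  if (temperature < min(diff$temperature) - 1e-8 ||
      temperature > max(diff$temperature) + 1e-8)
    stop(sprintf("temperature %.2f outside curve range [%.2f, %.2f]",
                 temperature, min(diff$temperature), max(diff$temperature)))
  stats::approx(diff$temperature, diff$diff, xout = temperature)$y
}
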