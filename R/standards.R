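#' Prior settings for the standard curve
#'
#' Weakly regularizing defaults: Normal(0, 10) on the intercept and slope of
#' the line relating the melt signal to the marked-allele proportion, and a
#' half-Cauchy(0, 2) prior (location 0, scale 2, truncated to positives) on
#' the residual standard deviation.
#'
#' @param intercept_sd,slope_sd Normal prior standard deviations for the
#'   intercept `a` and slope `B`.
#' @param sigma_scale Half-Cauchy scale for the residual sd.
#' @return List of class `std_priors`.
#' @export
std_priors <- function(intercept_sd = 10, slope_sd = 10, sigma_scale = 2) {
  stopifnot(intercept_sd > 0, slope_sd > 0, sigma_scale > 0)
  structure(list(intercept_sd = intercept_sd, slope_sd = slope_sd,
                 sigma_scale = sigma_scale), class = "std_priors")
}

std_curve_model <- "model {
  for (i in 1:N) {
    y[i] ~ dnorm(a + B * x[i], tau)
  }
  a ~ dnorm(0, a_tau)
  B ~ dnorm(0, b_tau)
  sigma ~ dt(0, s_tau, 1) T(0,)
  tau <- pow(sigma, -2)
}"

#' Fit a Bayesian standard curve
#'
#' Fits the linear calibration model `y = a + B x + error` relating the melt
#' signal `y` (normalized-RFU difference at the discriminating temperature,
#' or the melting temperature) of standard wells to their known
#' marked-allele proportion `x`. The model is
#' `y_i ~ Normal(a + B x_i, sigma)` with priors `a, B ~ Normal(0, 10)` and
#' `sigma ~ half-Cauchy(0, 2)`; keeping the signal as the response (rather
#' than regressing proportion on signal) lets a Normal likelihood apply to
#' the unconstrained signal while the bounded proportion is recovered by
#' inversion ([estimate_proportion()]).
#'
#' Both replicate standard series of a plate are pooled into a single fit by
#' default: the inversion uses one `(a, B)` pair per plate, and pooling uses
#' all the information.
#'
#' @param x Known proportions in `[0, 1]` (at least 3 distinct values), or a
#'   data frame with columns `proportion` and `signal`.
#' @param y Melt signals, same length as `x` (ignored when `x` is a data
#'   frame).
#' @param priors A [std_priors()] object.
#' @param mcmc An [mcmc_control()]; defaults to 2 chains, 1000 warmup, 3000
#'   sampling iterations.
#' @param seed Integer seed for the chains (required for reproducibility).
#' @return Object of class `std_curve_fit` with posterior draws of
#'   `a`, `B`, `sigma`, per-parameter split R-hat, and a `converged` flag
#'   (all R-hat <= 1.05). Non-convergence is a warning, not an error.
#' @seealso [estimate_proportion()], [plate_signals()]
#' @export
fit_standard_curve <- function(x, y = NULL, priors = std_priors(),
                               mcmc = mcmc_control(2L, 1000L, 3000L),
                               seed = 1L) {
  if (is.data.frame(x)) {
    stopifnot(all(c("proportion", "signal") %in% names(x)))
    y <- x$signal
    x <- x$proportion
  }
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (any(x < 0 | x > 1)) stop("standard proportions must lie in [0, 1]")
  if (any(!is.finite(y))) stop("standard signals must be finite")
  if (length(unique(x)) < 3L)
    stop("need at least 3 distinct standard proportions")
  if (stats::sd(x) == 0) stop("all standards at one proportion: slope unidentifiable")
  fit <- run_jags(std_curve_model,
                  data = list(N = length(x), x = x, y = y,
                              a_tau = priors$intercept_sd^-2,
                              b_tau = priors$slope_sd^-2,
                              s_tau = priors$sigma_scale^-2),
                  monitor = c("a", "B", "sigma"),
                  chains = mcmc$chains, warmup = mcmc$warmup,
                  sampling = mcmc$sampling, seed = seed)
  converged <- all(is.finite(fit$rhat)) && max(fit$rhat) <= 1.05
  if (!converged)
    warning("standard-curve fit may not have converged (max R-hat = ",
            signif(max(fit$rhat, na.rm = TRUE), 4), ")")
  structure(list(draws = fit$draws[, c("a", "B", "sigma")],
                 chain = fit$chain, rhat = fit$rhat, converged = converged,
                 priors = priors, mcmc = mcmc, seed = fit$seed,
                 data = data.frame(proportion = x, signal = y)),
            class = "std_curve_fit")
}

# bare constructor used internally and by tests to build degenerate fits
new_std_curve_fit <- function(draws, chain = rep(1:2, length.out = nrow(draws)),
                              converged = TRUE) {
  stopifnot(is.matrix(draws), all(c("a", "B", "sigma") %in% colnames(draws)))
  structure(list(draws = draws[, c("a", "B", "sigma")], chain = chain,
                 rhat = c(a = NA_real_, B = NA_real_, sigma = NA_real_),
                 converged = converged, priors = NULL, mcmc = NULL,
                 seed = NA_integer_, data = NULL),
            class = "std_curve_fit")
}

#' @export
as.matrix.std_curve_fit <- function(x, ...) x$draws

#' @export
coef.std_curve_fit <- function(object, ...) colMeans(object$draws)

#' @export
print.std_curve_fit <- function(x, ...) {
  cm <- colMeans(x$draws)
  cat("Bayesian standard curve: signal = a + B * proportion\n")
  cat(sprintf("  a = %.4f, B = %.4f, sigma = %.4f (posterior means, %d draws)\n",
              cm["a"], cm["B"], cm["sigma"], nrow(x$draws)))
  if (all(is.finite(x$rhat)))
    cat(sprintf("  max R-hat = %.3f%s\n", max(x$rhat),
                if (x$converged) "" else "  ** NOT CONVERGED **"))
  invisible(x)
}

#' @export
summary.std_curve_fit <- function(object, mass = 0.95, ...) {
  d <- object$draws
  out <- data.frame(parameter = colnames(d), mean = colMeans(d),
                    sd = apply(d, 2, stats::sd),
                    t(apply(d, 2, hpdi, mass = mass)),
                    rhat = object$rhat[colnames(d)], row.names = NULL)
  names(out)[4:5] <- c("hpdi_lower", "hpdi_upper")
  out
}

#' @export
predict.std_curve_fit <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata$proportion else as.numeric(newdata)
  cm <- colMeans(object$draws)
  cm["a"] + cm["B"] * x
}

#' @export
plot.std_curve_fit <- function(x, ...) {
  if (is.null(x$data)) stop("fit carries no standards data to plot")
  graphics::plot(x$data$proportion, x$data$signal,
                 xlab = "Marked-allele proportion",
                 ylab = "Melt signal (normalized RFU difference)", ...)
  cm <- colMeans(x$draws)
  graphics::abline(cm["a"], cm["B"], col = "steelblue")
  invisible(x)
}

#' Estimate marked-allele proportions by inverting the standard curve
#'
#' For each unknown signal `y` the standard curve is inverted draw by draw:
#' `x = (y - a - e) / B`, where `(a, B, sigma)` run over the posterior draws
#' of the fit and `e ~ Normal(0, sigma)` is the measurement noise of the
#' unknown well itself (set `predictive = FALSE` to drop `e` and propagate
#' only the curve uncertainty -- note the resulting intervals are then far
#' too narrow to be calibrated). Draws falling outside `[0, 1]` are set to
#' the nearest limit, so the full posterior respects the physical range;
#' clamping happens per draw, before summarizing.
#'
#' Draws with `B` exactly 0 are dropped with a warning. A posterior that
#' collapses onto a boundary can have an sd of (near) zero; because the
#' downstream fitness models require a positive measurement sd, the reported
#' sd is floored at `sd_floor`.
#'
#' @param fit A converged [fit_standard_curve()] result (`force = TRUE`
#'   overrides the convergence gate).
#' @param y Numeric vector of unknown melt signals.
#' @param sample_id Optional character vector of sample ids (defaults to
#'   `"s1"`, `"s2"`, ...).
#' @param mass HPDI mass for the summaries (default 0.95).
#' @param predictive Include the unknown well's own measurement noise
#'   (default `TRUE`).
#' @param sd_floor Lower bound for the reported sd (default 1e-3).
#' @param seed Integer seed for the predictive noise draws.
#' @param force Estimate despite a non-converged fit.
#' @return Object of class `proportion_estimates`: a data frame with columns
#'   `sample_id`, `mean`, `sd`, `hpdi_lower`, `hpdi_upper`, `n_draws`, with
#'   the clamped posterior draws (one column per sample) in attribute
#'   `draws`.
#' @export
estimate_proportion <- function(fit, y, sample_id = NULL, mass = 0.95,
                                predictive = TRUE, sd_floor = 1e-3,
                                seed = 1L, force = FALSE) {
  stopifnot(inherits(fit, "std_curve_fit"))
  if (!isTRUE(fit$converged) && !force)
    stop("standard-curve fit did not converge; rerun or use force = TRUE")
  y <- as.numeric(y)
  stopifnot(length(y) >= 1L, all(is.finite(y)))
  if (is.null(sample_id)) sample_id <- paste0("s", seq_along(y))
  stopifnot(length(sample_id) == length(y))
  a <- fit$draws[, "a"]; B <- fit$draws[, "B"]; s <- fit$draws[, "sigma"]
  keep <- B != 0
  if (!all(keep)) {
    warning(sum(!keep), " draw(s) with slope exactly 0 dropped")
    if (!any(keep)) stop("all posterior draws have zero slope")
    a <- a[keep]; B <- B[keep]; s <- s[keep]
  }
  n <- length(a)
  set.seed(as.integer(seed))
  draws <- vapply(y, function(yi) {
    e <- if (predictive) stats::rnorm(n, 0, s) else 0
    pmin(1, pmax(0, (yi - a - e) / B))
  }, numeric(n))
  colnames(draws) <- sample_id
  sds <- pmax(apply(draws, 2, stats::sd), sd_floor)
  hp <- apply(draws, 2, hpdi, mass = mass)
  out <- data.frame(sample_id = sample_id, mean = colMeans(draws), sd = sds,
                    hpdi_lower = hp[1L, ], hpdi_upper = hp[2L, ],
                    n_draws = n, row.names = NULL)
  structure(out, class = c("proportion_estimates", "data.frame"),
            draws = draws, mass = mass)
}

#' @export
print.proportion_estimates <- function(x, ...) {
  cat(sprintf("Marked-allele proportion estimates for %d sample(s) (%d draws each):\n",
              nrow(x), x$n_draws[1L]))
  print.data.frame(x, digits = 4)
  invisible(x)
}
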