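#' Highest posterior density interval
#'
#' The narrowest contiguous interval containing at least `mass` of the
#' posterior draws: among all windows of `ceiling(mass * n)` consecutive
#' sorted draws, the one of minimal width. Width ties are broken toward the
#' lowest lower bound, making the result deterministic.
#'
#' @param draws Numeric vector of posterior draws (at least 50).
#' @param mass Probability mass of the interval, in (0, 1); default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' hpdi(rnorm(10000), 0.95) # close to c(-1.96, 1.96)
#' @export
hpdi <- function(draws, mass = 0.95) {
  draws <- as.numeric(draws)
  draws <- draws[!is.na(draws)]
  n <- length(draws)
  if (n < 50L) stop("need at least 50 draws for an HPDI")
  if (!(mass > 0 && mass < 1)) stop("mass must be in (0, 1)")
  s <- sort(draws)
  m <- ceiling(mass * n)
  k <- n - m + 1L                     # candidate window starts
  widths <- s[m:n] - s[1:k]
  i <- which.min(widths)              # first minimum = lowest lower bound
  c(lower = s[i], upper = s[i + m - 1L])
}

#' Split R-hat convergence diagnostic
#'
#' The potential scale reduction factor comparing within- and between-chain
#' variance, computed on split chains (each chain halved, so stationarity
#' within a chain is also checked). Values near 1 indicate convergence;
#' fits in this package are flagged when any parameter exceeds 1.05.
#'
#' When every (split) chain has zero internal variance the statistic is
#' undefined and `NA` is returned with a warning -- constant chains carry no
#' convergence information.
#'
#' @param chains A matrix with one column per chain (iterations in rows), or
#'   a list of equal-length numeric vectors. At least 2 chains of at least
#'   10 iterations.
#' @return Scalar R-hat (>= 1 up to floating error), or `NA` for the
#'   degenerate constant case.
#' @export
rhat <- function(chains) {
  if (is.list(chains)) {
    len <- unique(lengths(chains))
    if (length(len) != 1L) stop("chains must have equal length")
    chains <- do.call(cbind, chains)
  }
  chains <- as.matrix(chains)
  if (ncol(chains) < 2L) stop("need at least 2 chains")
  if (nrow(chains) < 10L) stop("chains must have at least 10 iterations")
  half <- floor(nrow(chains) / 2L)
  split <- cbind(chains[seq_len(half), , drop = FALSE],
                 chains[(nrow(chains) - half + 1L):nrow(chains), , drop = FALSE])
  w <- apply(split, 2L, stats::var)
  if (all(w < .Machine$double.eps)) {
    warning("all chains are constant; R-hat is undefined")
    return(NA_real_)
  }
  n <- nrow(split)
  W <- mean(w)
  B <- n * stats::var(colMeans(split))
  sqrt(((n - 1) / n * W + B / n) / W)
}

# split R-hat for every column of a draws matrix given a chain id vector
rhat_all <- function(draws, chain) {
  vapply(colnames(draws), function(p) {
    m <- do.call(cbind, split(draws[, p], chain))
    suppressWarnings(rhat(m))
  }, numeric(1))
}
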