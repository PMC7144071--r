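# shared builders for synthetic curves and degenerate fits

sigmoid_curve <- function(well, centre, width = 0.4,
                          grid = seq(70, 90, by = 0.1), normalized = TRUE) {
  v <- 1 / (1 + exp((grid - centre) / width))
  if (normalized) v <- (v - min(v)) / (max(v) - min(v))
  melt_curve(well, grid, v, normalized = normalized)
}

# point-mass standard-curve fit (used to check the pure Eq-1 arithmetic);
# sigma = 0 makes the predictive noise draw vanish
point_mass_fit <- function(a = 0.9, b = -0.8, sigma = 0, n = 200L) {
  hrmcompete:::new_std_curve_fit(
    cbind(a = rep(a, n), B = rep(b, n), sigma = rep(sigma, n)))
}

flat_diff <- function(values, grid = seq(70, 90, by = 0.1), well = "D1") {
  structure(list(well = well, temperature = grid, diff = values),
            class = "melt_diff")
}
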