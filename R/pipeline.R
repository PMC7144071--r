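#' Per-well melt signals for a plate
#'
#' Runs the melt-curve processing chain for one plate: match curves to the
#' layout, normalize each well (no-template controls are skipped), align
#' everything onto the temperature grid of the marked positive control,
#' compute difference curves against that control, call each well's melting
#' temperature, pick the plate's discriminating temperature from the
#' standards, and read each well's signal there.
#'
#' The plate must contain exactly one `positive_marked` well and standards
#' covering proportions 0 and 1 (the two pure standards can stand in for
#' missing positive controls only if so designated in the layout).
#'
#' @param curves Named list of raw [melt_curve()]s.
#' @param layout A [plate_layout()].
#' @return Data frame of class `plate_signals` with columns `well`, `role`,
#'   `known_proportion`, `sample_id`, `tm`, `signal`; the discriminating
#'   temperature is in attribute `disc_temp`, the control well in
#'   `control_well`.
#' @export
plate_signals <- function(curves, layout) {
  stopifnot(inherits(layout, "plate_layout"))
  mw <- match_wells(curves, layout)
  lay <- mw$layout
  use <- lay$role != "ntc"
  lay <- lay[use, , drop = FALSE]
  cur <- mw$curves[use]
  ctrl_i <- which(lay$role == "positive_marked")
  if (length(ctrl_i) != 1L)
    stop("plate must have exactly one marked-allele positive control (found ",
         length(ctrl_i), ")")
  norm <- lapply(cur, normalize_curve)
  grid <- norm[[ctrl_i]]$temperature
  norm <- lapply(norm, align_to_grid, grid = grid)
  ctrl <- norm[[ctrl_i]]
  diffs <- lapply(norm, difference_curve, control = ctrl)
  tms <- vapply(norm, melting_temperature, numeric(1))
  std_i <- which(lay$role == "standard")
  if (length(std_i) < 2L ||
      length(unique(lay$known_proportion[std_i])) < 2L)
    stop("plate needs at least 2 standards with distinct proportions")
  disc <- select_discriminating_temperature(diffs[std_i],
                                            lay$known_proportion[std_i])
  sig <- vapply(diffs, signal_at, numeric(1), temperature = disc)
  out <- data.frame(well = lay$well, role = lay$role,
                    known_proportion = lay$known_proportion,
                    sample_id = lay$sample_id,
                    tm = unname(tms), signal = unname(sig),
                    stringsAsFactors = FALSE)
  structure(out, class = c("plate_signals", "data.frame"),
            disc_temp = disc, control_well = ctrl$well,
            plate_id = attr(layout, "plate_id"))
}

#' Estimate unknown-sample proportions for a whole plate
#'
#' End-to-end convenience wrapper: [plate_signals()], then a pooled
#' [fit_standard_curve()] on the plate's standards, then
#' [estimate_proportion()] for every unknown well. Unknowns are only ever
#' estimated against their own plate's standard curve.
#'
#' @param curves Named list of raw [melt_curve()]s.
#' @param layout A [plate_layout()].
#' @param priors,mcmc,seed Passed to the standard-curve fit; the estimation
#'   step reuses `seed`.
#' @param ... Passed on to [estimate_proportion()] (e.g. `mass`,
#'   `predictive`).
#' @return List of class `plate_estimate` with elements `signals`, `fit`
#'   and `estimates`.
#' @export
estimate_plate <- function(curves, layout, priors = std_priors(),
                           mcmc = mcmc_control(2L, 1000L, 3000L),
                           seed = 1L, ...) {
  sig <- plate_signals(curves, layout)
  std <- sig[sig$role == "standard", , drop = FALSE]
  fit <- fit_standard_curve(std$known_proportion, std$signal,
                            priors = priors, mcmc = mcmc, seed = seed)
  unk <- sig[sig$role == "unknown", , drop = FALSE]
  est <- if (nrow(unk))
    estimate_proportion(fit, unk$signal, sample_id = unk$sample_id,
                        seed = seed, ...)
  else NULL
  structure(list(signals = sig, fit = fit, estimates = est),
            class = "plate_estimate")
}

#' @export
print.plate_estimate <- function(x, ...) {
  cat(sprintf("Plate '%s': discriminating T = %.2f C (control well %s)\n",
              attr(x$signals, "plate_id") %||% "?",
              attr(x$signals, "disc_temp"), attr(x$signals, "control_well")))
  print(x$fit)
  if (!is.null(x$estimates)) print(x$estimates)
  invisible(x)
}
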