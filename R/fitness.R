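#' Relative fitness from a logistic-scale slope
#'
#' In a serial-transfer competition between two asexual genotypes the
#' log-odds of the focal genotype's frequency changes linearly with
#' transfer number, with slope log(W); W is its per-transfer relative
#' fitness (W = 1 means no frequency change).
#'
#' @param beta Slope(s) on the log-odds-per-transfer scale.
#' @return `exp(beta)`.
#' @examples
#' fitness_from_slope(0)        # 1
#' fitness_from_slope(log(0.5)) # 0.5
#' @export
fitness_from_slope <- function(beta) {
  stopifnot(all(is.finite(beta)))
  exp(beta)
}

#' Prior settings for the fitness models
#'
#' Defaults follow the competition design the models were built for:
#' a tight Normal(0, 0.065) prior on the intercepts (competitions start at
#' frequency 0.5, i.e. 0 on the log-odds scale), Normal(0, 1) on all slope
#' effects, and half-Cauchy(0, 2) on the residual sd.
#'
#' @param alpha_sd Prior sd of the per-population (or per-competition)
#'   intercepts on the log-odds scale.
#' @param beta_pop_sd Prior sd of the per-population slope deviations.
#' @param effect_sd Prior sd of the shared genotype effects (marker, mating
#'   type, focal mutation).
#' @param sigma_scale Half-Cauchy scale of the residual sd.
#' @return List of class `fitness_priors`.
#' @export
fitness_priors <- function(alpha_sd = 0.065, beta_pop_sd = 1, effect_sd = 1,
                           sigma_scale = 2) {
  stopifnot(alpha_sd > 0, beta_pop_sd > 0, effect_sd > 0, sigma_scale > 0)
  structure(list(alpha_sd = alpha_sd, beta_pop_sd = beta_pop_sd,
                 effect_sd = effect_sd, sigma_scale = sigma_scale),
            class = "fitness_priors")
}

# marker + mating-type model; slopes use the centered parameterization
# b[j] ~ N(beta_csr + beta_matA * m_j, beta_pop_sd) so the shared effects
# are hyper-means (same joint posterior as beta_pop + beta_csr + ...,
# vastly better Gibbs mixing), and the measurement layer is marginalized:
# x_obs ~ N(mu, sqrt(sigma^2 + x_sd^2)) is the exact marginal of
# x_est ~ N(mu, sigma); x_obs ~ N(x_est, x_sd).
marker_mat_model <- "model {
  for (i in 1:N) {
    mu[i] <- ilogit(alpha[pop[i]] + b[pop[i]] * t[i])
    xobs[i] ~ dnorm(mu[i], 1 / (sigma^2 + xsd[i]^2))
  }
  for (j in 1:P) {
    alpha[j] ~ dnorm(0, alpha_tau)
    b[j] ~ dnorm(beta_csr + beta_matA * mpop[j], bpop_tau)
  }
  beta_csr ~ dnorm(0, eff_tau)
  beta_matA ~ dnorm(0, eff_tau)
  sigma ~ dt(0, s_tau, 1) T(0,)
}"

focal_model <- "model {
  for (i in 1:N) {
    mu[i] <- ilogit(alpha[comp[i]] + b[pop[i]] * t[i])
    xobs[i] ~ dnorm(mu[i], 1 / (sigma^2 + xsd[i]^2))
  }
  for (k in 1:C) {
    alpha[k] ~ dnorm(0, alpha_tau)
  }
  for (j in 1:P) {
    b[j] ~ dnorm(beta_focal + beta_csr * cpop[j] + beta_matA * mpop[j], bpop_tau)
  }
  beta_focal ~ dnorm(0, eff_tau)
  beta_csr ~ dnorm(0, eff_tau)
  beta_matA ~ dnorm(0, eff_tau)
  sigma ~ dt(0, s_tau, 1) T(0,)
}"

#' Fit a hierarchical competitive-fitness model
#'
#' Estimates per-transfer relative fitness effects from time series of
#' marked-allele proportion estimates, propagating each observation's
#' posterior sd through a measurement-error layer. Two models are
#' available:
#'
#' * `model = "marker_mat"`: the response is the marked-allele frequency;
#'   the log-odds slope of population *j* decomposes into a population
#'   deviation plus the marker effect `beta_csr` plus the mating-type
#'   effect `beta_matA * m` (m = +1/-1/0 as the marked strain is
#'   *mat A* / *mat a* / mating types equal). One intercept per population.
#' * `model = "focal"`: the response is the focal-mutation strain's
#'   frequency (see [transform_to_focal()]); the slope decomposes into a
#'   population deviation plus `beta_focal + beta_csr * c + beta_matA * m`
#'   with c, m in \{-1, +1\}, and one intercept per competition.
#'
#' Formally, with mu_i the inverse-logit of the linear predictor at
#' transfer t_i, the likelihood is `x_est_i ~ Normal(mu_i, sigma)`,
#' `x_obs_i ~ Normal(x_est_i, x_sd_i)`; the latent layer is integrated out
#' analytically before sampling (identical posterior). Proportions of
#' exactly 0 or 1 (fixation) are retained: no logit of data is ever taken.
#'
#' Populations observed at fewer than 2 transfers are excluded with a
#' warning (their slope is not identifiable). If every record has m = 0,
#' `beta_matA` is prior-dominated and flagged. Relative fitness draws are
#' derived as `W = exp(beta)` per effect.
#'
#' @param obs Data frame of competition observations with columns `x_obs`,
#'   `x_sd` (> 0), `transfer`, `population_id`, `competition_id`, `m`, and
#'   for the focal model `c`. [competition_observations()] and
#'   [transform_to_focal()] build this from a proportions table plus a
#'   design.
#' @param model `"marker_mat"` or `"focal"`.
#' @param priors A [fitness_priors()] object.
#' @param mcmc An [mcmc_control()]; defaults follow the model: 2 chains
#'   with 2500 warmup + 2500 sampling (`marker_mat`, 10000 iterations in
#'   total) or 1250 + 1250 (`focal`, 5000 in total).
#' @param seed Integer seed (required for reproducibility; recorded in the
#'   result).
#' @return Object of class `fitness_fit`: posterior draws of all effects,
#'   per-population slopes/intercepts and sigma; split R-hat per parameter;
#'   `converged` flag (all R-hat <= 1.05); the data and settings used.
#' @seealso [summary.fitness_fit()], [simulate_competition()]
#' @export
fit_fitness <- function(obs, model = c("marker_mat", "focal"),
                        priors = fitness_priors(), mcmc = NULL, seed = 1L) {
  model <- match.arg(model)
  obs <- validate_observations(obs, model)
  if (is.null(mcmc))
    mcmc <- if (model == "marker_mat") mcmc_control(2L, 2500L, 2500L)
            else mcmc_control(2L, 1250L, 1250L)

  # drop populations with a single time point: slope unidentifiable
  npts <- tapply(obs$transfer, obs$population_id,
                 function(t) length(unique(t)))
  single <- names(npts)[npts < 2L]
  if (length(single)) {
    warning("excluding population(s) with a single transfer: ",
            paste(single, collapse = ", "))
    obs <- obs[!obs$population_id %in% single, , drop = FALSE]
    if (nrow(obs) == 0L) stop("no populations with >= 2 transfers remain")
  }

  pops <- sort(unique(obs$population_id))
  pop <- match(obs$population_id, pops)
  # per-population indicators (constant within a population by validation)
  mpop <- obs$m[match(pops, obs$population_id)]
  flags <- character(0)

  dat <- list(N = nrow(obs), P = length(pops), pop = pop,
              t = obs$transfer, xobs = obs$x_obs, xsd = obs$x_sd,
              mpop = mpop,
              alpha_tau = priors$alpha_sd^-2,
              bpop_tau = priors$beta_pop_sd^-2,
              eff_tau = priors$effect_sd^-2,
              s_tau = priors$sigma_scale^-2)

  if (model == "marker_mat") {
    if (all(obs$m == 0)) {
      flags <- c(flags, "all m = 0: beta_matA is prior-dominated (unidentifiable)")
      warning("all records have m = 0; beta_matA is not identifiable ",
              "and its posterior will echo the prior")
    }
    monitor <- c("beta_csr", "beta_matA", "sigma", "alpha", "b")
    ms <- marker_mat_model
    comps <- NULL
  } else {
    comps <- sort(unique(obs$competition_id))
    dat$C <- length(comps)
    dat$comp <- match(obs$competition_id, comps)
    dat$cpop <- obs$c[match(pops, obs$population_id)]
    cfg <- unique(data.frame(c = dat$cpop, m = mpop))
    if (length(comps) == 1L && nrow(cfg) == 1L) {
      flags <- c(flags,
                 "single competition with one (c, m) configuration: beta_focal confounded with beta_csr/beta_matA")
      warning("only one (c, m) configuration present; beta_focal is ",
              "confounded with the marker and mating-type effects")
    }
    monitor <- c("beta_focal", "beta_csr", "beta_matA", "sigma", "alpha", "b")
    ms <- focal_model
  }

  fit <- run_jags(ms, dat, monitor, chains = mcmc$chains,
                  warmup = mcmc$warmup, sampling = mcmc$sampling, seed = seed)
  effects <- intersect(c("beta_focal", "beta_csr", "beta_matA"),
                       colnames(fit$draws))
  converged <- all(is.finite(fit$rhat)) && max(fit$rhat) <= 1.05
  if (!converged)
    warning("fitness fit may not have converged (max R-hat = ",
            signif(max(fit$rhat, na.rm = TRUE), 4), ")")
  structure(list(draws = fit$draws, chain = fit$chain, rhat = fit$rhat,
                 converged = converged, model = model, effects = effects,
                 populations = pops, competitions = comps,
                 priors = priors, mcmc = mcmc, seed = fit$seed,
                 flags = flags, data = obs),
            class = "fitness_fit")
}

validate_observations <- function(obs, model) {
  req <- c("x_obs", "x_sd", "transfer", "population_id", "competition_id", "m")
  miss <- setdiff(req, names(obs))
  if (length(miss))
    stop("observations are missing columns: ", paste(miss, collapse = ", "))
  obs <- as.data.frame(obs)
  obs$x_obs <- as.numeric(obs$x_obs)
  obs$x_sd <- as.numeric(obs$x_sd)
  obs$transfer <- as.numeric(obs$transfer)
  obs$population_id <- as.character(obs$population_id)
  obs$competition_id <- as.character(obs$competition_id)
  if (any(!is.finite(obs$x_obs) | obs$x_obs < 0 | obs$x_obs > 1))
    stop("x_obs must lie in [0, 1]")
  if (any(!is.finite(obs$x_sd) | obs$x_sd <= 0))
    stop("x_sd must be > 0 for every record (see the sd floor in estimate_proportion)")
  if (any(obs$transfer < 0)) stop("transfer must be >= 0")
  if (!all(obs$m %in% c(-1, 0, 1)))
    stop("m must be -1, 0 or +1")
  bad_m <- tapply(obs$m, obs$population_id, function(v) length(unique(v)) > 1L)
  if (any(bad_m))
    stop("m must be constant within a population (it codes the competition): ",
         paste(names(bad_m)[bad_m], collapse = ", "))
  if (model == "focal") {
    if (!"c" %in% names(obs))
      stop("the focal model needs a 'c' column (use transform_to_focal())")
    if (!all(obs$c %in% c(-1, 1)) || !all(obs$m %in% c(-1, 1)))
      stop("the focal model requires c and m in {-1, +1} for every record")
    bad_c <- tapply(obs$c, obs$population_id, function(v) length(unique(v)) > 1L)
    if (any(bad_c))
      stop("c must be constant within a population: ",
           paste(names(bad_c)[bad_c], collapse = ", "))
  }
  obs
}

#' Join proportion estimates with a competition design
#'
#' Matches a table of per-sample proportion estimates (from
#' [estimate_proportion()] / [read_proportions()]) to the design records by
#' `sample_id`, producing the observation table the fitness models consume.
#' The response stays on the marked-allele scale; `m` is taken from
#' `marked_strain_matA`.
#'
#' @param estimates Data frame with columns `sample_id`, `mean`, `sd`.
#' @param design A [competition_design()].
#' @return Data frame with columns `sample_id`, `x_obs`, `x_sd`, `transfer`,
#'   `population_id`, `competition_id`, `m`, `focal_in_marked`.
#' @export
competition_observations <- function(estimates, design) {
  estimates <- as.data.frame(estimates)
  stopifnot(all(c("sample_id", "mean", "sd") %in% names(estimates)))
  idx <- match(design$sample_id, estimates$sample_id)
  if (anyNA(idx))
    stop("design sample(s) missing from the estimates: ",
         paste(design$sample_id[is.na(idx)], collapse = ", "))
  data.frame(sample_id = design$sample_id,
             x_obs = estimates$mean[idx], x_sd = estimates$sd[idx],
             transfer = design$transfer,
             population_id = design$population_id,
             competition_id = design$competition_id,
             m = design$marked_strain_matA,
             focal_in_marked = design$focal_in_marked,
             stringsAsFactors = FALSE)
}

#' Re-express observations on the focal-mutation scale
#'
#' The melt assay always reports the marked-allele frequency, but the focal
#' model needs the frequency of the strain carrying the focal mutation
#' (e.g. a *qde-2* deletion). Where the focal strain does not carry the
#' marked allele (`focal_in_marked = -1`) the proportion mean is
#' complemented (`x -> 1 - x`, sd unchanged); where it does
#' (`focal_in_marked = +1`) it is left alone. The indicator `c` attached to
#' each record equals `focal_in_marked`. Applying the transform twice
#' returns the original values.
#'
#' @param estimates Data frame with columns `sample_id`, `mean`, `sd` (an
#'   estimates table), or an observation table from
#'   [competition_observations()] (columns `x_obs`, `x_sd`).
#' @param design A [competition_design()] whose `focal_in_marked` is set
#'   for every sample.
#' @return Observation data frame on the focal scale with columns as
#'   [competition_observations()] plus `c`.
#' @export
transform_to_focal <- function(estimates, design) {
  obs <- if (all(c("x_obs", "x_sd") %in% names(estimates)))
    as.data.frame(estimates)
  else competition_observations(estimates, design)
  idx <- match(obs$sample_id, design$sample_id)
  if (anyNA(idx)) stop("observation sample(s) missing from the design")
  fim <- design$focal_in_marked[idx]
  if (anyNA(fim))
    stop("focal_in_marked must be set for every sample to fit the focal model")
  obs$x_obs <- ifelse(fim == -1, 1 - obs$x_obs, obs$x_obs)
  obs$c <- as.integer(fim)
  obs$focal_in_marked <- as.integer(fim)
  obs
}

#' @export
as.matrix.fitness_fit <- function(x, ...) x$draws

#' @export
coef.fitness_fit <- function(object, ...) colMeans(object$draws[, object$effects, drop = FALSE])

#' @export
print.fitness_fit <- function(x, ...) {
  cat(sprintf("Hierarchical fitness model ('%s'): %d populations, %d observations\n",
              x$model, length(x$populations), nrow(x$data)))
  s <- summary(x)
  print(s, digits = 3, row.names = FALSE)
  if (!x$converged) cat("** warning: max R-hat > 1.05 -- inspect chains **\n")
  for (f in x$flags) cat("** flag:", f, "**\n")
  invisible(x)
}

#' Posterior summary of fitness effects
#'
#' One row per shared effect with the relative fitness `W = exp(beta)`
#' summarized by its posterior mean, sd, 66% and 95% HPDIs, and the
#' effect's R-hat.
#'
#' @param object A [fit_fitness()] result.
#' @param ... Unused.
#' @return Data frame with columns `effect`, `W_mean`, `W_sd`, and HPDI
#'   bounds `W_l66`, `W_u66`, `W_l95`, `W_u95`, plus `rhat`.
#' @export
summary.fitness_fit <- function(object, ...) {
  rows <- lapply(object$effects, function(p) {
    w <- exp(object$draws[, p])
    h66 <- hpdi(w, 0.66); h95 <- hpdi(w, 0.95)
    data.frame(effect = sub("^beta_", "W_", p), W_mean = mean(w),
               W_sd = stats::sd(w),
               W_l66 = h66[["lower"]], W_u66 = h66[["upper"]],
               W_l95 = h95[["lower"]], W_u95 = h95[["upper"]],
               rhat = object$rhat[[p]])
  })
  do.call(rbind, rows)
}

#' Plot posterior fitness effects
#'
#' Dot-and-interval display of the relative fitness of each shared effect:
#' points at the posterior mean, thick segments spanning the 66% HPDI and
#' thin segments the 95% HPDI, with a dashed reference line at W = 1 (no
#' fitness difference).
#'
#' @param x A [fit_fitness()] result.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.fitness_fit <- function(x, ...) {
  s <- summary(x)
  k <- nrow(s)
  graphics::plot(NA, xlim = range(c(s$W_l95, s$W_u95, 1)),
                 ylim = c(0.5, k + 0.5), yaxt = "n",
                 xlab = "Relative fitness W", ylab = "", ...)
  graphics::axis(2, at = seq_len(k), labels = s$effect, las = 1)
  graphics::abline(v = 1, lty = 2, col = "grey50")
  graphics::segments(s$W_l95, seq_len(k), s$W_u95, seq_len(k), lwd = 1)
  graphics::segments(s$W_l66, seq_len(k), s$W_u66, seq_len(k), lwd = 3)
  graphics::points(s$W_mean, seq_len(k), pch = 19)
  invisible(x)
}

#' Write a fitness posterior summary as JSON
#'
#' Serializes the per-effect summaries of a [fit_fitness()] result
#' (mean, sd, 66%/95% HPDI bounds and R-hat of W per effect, plus sigma
#' and the settings used) to a JSON file.
#'
#' @param fit A `fitness_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fitness_json <- function(fit, path) {
  stopifnot(inherits(fit, "fitness_fit"))
  s <- summary(fit)
  eff <- lapply(seq_len(nrow(s)), function(i) as.list(s[i, -1]))
  names(eff) <- s$effect
  sig <- fit$draws[, "sigma"]
  out <- list(model = fit$model, effects = eff,
              sigma = list(mean = mean(sig), sd = stats::sd(sig),
                           rhat = fit$rhat[["sigma"]]),
              n_populations = length(fit$populations),
              converged = fit$converged, seed = fit$seed,
              mcmc = unclass(fit$mcmc), flags = fit$flags)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Dilution-series quality control for the PCR assay
#'
#' Regresses quantification cycle (Cq) on log10 template amount over a
#' dilution series. Perfect doubling each cycle gives a slope of
#' -1/log10(2) = -3.32 per decade; a noticeably shallower slope (above
#' -3.3) indicates PCR inhibition and is flagged. Inhibition does not
#' invalidate relative quantification within a sample, but is worth
#' knowing.
#'
#' @param cq Numeric vector of Cq values.
#' @param conidia_per_ml Positive template amounts (e.g. conidia/ml),
#'   same length, at least 3 distinct values.
#' @return List of class `cq_dilution` with `slope` (Cq per decade),
#'   `intercept`, and `inhibition_suspected` (slope > -3.3).
#' @examples
#' n <- 10^(4:8)
#' cq_dilution_slope(30 - 1.9 * log10(n), n)
#' @export
cq_dilution_slope <- function(cq, conidia_per_ml) {
  cq <- as.numeric(cq); conc <- as.numeric(conidia_per_ml)
  stopifnot(length(cq) == length(conc), length(cq) >= 3L)
  if (any(conc <= 0)) stop("template amounts must be positive")
  lx <- log10(conc)
  if (stats::sd(lx) == 0) stop("all template amounts equal: slope undefined")
  co <- stats::coef(stats::lm(cq ~ lx))
  slope <- unname(co[2L])
  structure(list(slope = slope, intercept = unname(co[1L]),
                 inhibition_suspected = slope > -3.3),
            class = "cq_dilution")
}

#' @export
print.cq_dilution <- function(x, ...) {
  cat(sprintf("Cq dilution slope: %.3f per log10 unit (%s)\n", x$slope,
              if (x$inhibition_suspected)
                "slope > -3.3: PCR inhibition suspected"
              else "consistent with efficient amplification"))
  invisible(x)
}
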