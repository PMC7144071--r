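#' Melt-curve simulation parameters
#'
#' Conditions emulating the real assay: the marked and wild-type alleles
#' melt about one degree apart (defaults 81.0 and 82.1 C), curves are
#' measured from 70 to 90 C in 0.1 degree steps, and each allele's melt is
#' a falling sigmoid with a 0.4 degree transition width. Mixtures are
#' linear combinations of the two allele curves; an optional
#' `heteroduplex_shift` moves the marked-allele component of mixture wells
#' to mimic heteroduplex distortion (off by default).
#'
#' @param tm_marked,tm_wt Allele melting temperatures in degrees C.
#' @param width Sigmoid transition width in degrees C (> 0).
#' @param heteroduplex_shift Degrees C added to the marked component's Tm
#'   in mixture wells (0 disables).
#' @param noise_sd Gaussian noise sd on the unit-amplitude curve before the
#'   per-well gain is applied.
#' @param grid Measurement grid in degrees C.
#' @return List of class `melt_sim_params`.
#' @export
melt_sim_params <- function(tm_marked = 81.0, tm_wt = 82.1, width = 0.4,
                            heteroduplex_shift = 0, noise_sd = 0.02,
                            grid = seq(70, 90, by = 0.1)) {
  stopifnot(width > 0, noise_sd >= 0,
            tm_marked > min(grid), tm_marked < max(grid),
            tm_wt > min(grid), tm_wt < max(grid))
  structure(list(tm_marked = tm_marked, tm_wt = tm_wt, width = width,
                 heteroduplex_shift = heteroduplex_shift,
                 noise_sd = noise_sd, grid = as.numeric(grid)),
            class = "melt_sim_params")
}

# falling sigmoid: 1 at low T, 0 at high T, centre = tm
melt_sigmoid <- function(temp, tm, width) 1 / (1 + exp((temp - tm) / width))

#' Simulate the melt curves of one plate
#'
#' Generates one raw melt curve per layout well. The underlying
#' unit-amplitude curve of a well with marked-allele proportion x is
#' `x * S(T; tm_marked) + (1 - x) * S(T; tm_wt)` with S a falling sigmoid;
#' standards use their known proportion, unknown wells draw a hidden truth
#' uniformly on (0, 1) (returned alongside), the pure positive controls use
#' x = 1 and x = 0, and no-template controls are a flat near-zero trace.
#' Each well gets its own random gain and offset so that normalization is
#' genuinely exercised, plus pointwise Gaussian noise.
#'
#' @param layout A [plate_layout()].
#' @param params A [melt_sim_params()].
#' @param seed Integer seed; all randomness flows from it.
#' @return List with `curves` (named list of raw [melt_curve()]s) and
#'   `truth` (data frame well, role, sample_id, true_proportion; NA for
#'   NTC wells).
#' @export
simulate_melt_plate <- function(layout, params = melt_sim_params(), seed = 1L) {
  stopifnot(inherits(layout, "plate_layout"), inherits(params, "melt_sim_params"))
  set.seed(as.integer(seed))
  tt <- params$grid
  truth <- data.frame(well = layout$well, role = layout$role,
                      sample_id = layout$sample_id,
                      true_proportion = NA_real_, stringsAsFactors = FALSE)
  curves <- vector("list", nrow(layout))
  names(curves) <- layout$well
  for (i in seq_len(nrow(layout))) {
    role <- layout$role[i]
    x <- switch(role,
                standard = layout$known_proportion[i],
                positive_marked = 1,
                positive_wt = 0,
                unknown = stats::runif(1),
                ntc = NA_real_)
    truth$true_proportion[i] <- x
    gain <- stats::runif(1, 800, 1200)
    offset <- stats::runif(1, 50, 150)
    if (role == "ntc") {
      base <- rep(0.01, length(tt))   # never amplified: flat trace
      noise_sd <- params$noise_sd / 10
    } else {
      tm_m <- params$tm_marked +
        if (x > 0 && x < 1) params$heteroduplex_shift else 0
      base <- x * melt_sigmoid(tt, tm_m, params$width) +
        (1 - x) * melt_sigmoid(tt, params$tm_wt, params$width)
      noise_sd <- params$noise_sd
    }
    rfu <- gain * (base + stats::rnorm(length(tt), 0, noise_sd)) + offset
    curves[[i]] <- melt_curve(layout$well[i], tt, rfu)
  }
  list(curves = curves, truth = truth)
}

#' The canonical plate layout used for simulations
#'
#' Standards at marked-allele proportions 1.0 down to 0.0 by 0.1, in two
#' replicate series, plus one marked and one wild-type positive control,
#' one no-template control, and `n_unknowns` unknown sample wells.
#'
#' @param n_unknowns Number of unknown wells (default 8).
#' @param plate_id Plate identifier.
#' @return A [plate_layout()].
#' @export
standard_plate_layout <- function(n_unknowns = 8L, plate_id = "simplate") {
  props <- rep(seq(1, 0, by = -0.1), 2L)
  n_std <- length(props)
  wells <- sprintf("W%02d", seq_len(n_std + 3L + n_unknowns))
  df <- data.frame(
    well = wells,
    role = c(rep("standard", n_std), "positive_marked", "positive_wt", "ntc",
             rep("unknown", n_unknowns)),
    known_proportion = c(props, rep(NA_real_, 3L + n_unknowns)),
    sample_id = c(rep(NA_character_, n_std + 3L),
                  if (n_unknowns > 0) sprintf("unk%02d", seq_len(n_unknowns))),
    stringsAsFactors = FALSE)
  plate_layout(df, plate_id = plate_id)
}

#' Simulate noisy standard observations from a known line
#'
#' Draws melt signals `y = a + B x + Normal(0, sigma)` at the given
#' proportions -- the signal-level generating model of the Bayesian
#' standard curve, used for calibration and recovery checks without
#' simulating whole melt curves.
#'
#' @param x Proportions of the standards (default the plate series 0..1 by
#'   0.1 in two replicates).
#' @param a,b True intercept and slope.
#' @param sigma True residual sd.
#' @param seed Integer seed.
#' @return Data frame with columns `proportion`, `signal`.
#' @export
simulate_standards <- function(x = rep(seq(0, 1, by = 0.1), 2L),
                               a = 0.9, b = -0.8, sigma = 0.02, seed = 1L) {
  stopifnot(all(x >= 0 & x <= 1), sigma >= 0)
  set.seed(as.integer(seed))
  data.frame(proportion = x,
             signal = a + b * x + stats::rnorm(length(x), 0, sigma))
}

#' Competition-trajectory simulation parameters
#'
#' Defaults mirror the two competition designs the models were built for.
#' For `model = "marker_mat"`: four competition types (marked strain
#' *mat A* vs *mat a* opponent, marked *mat a* vs *mat A*, and the two
#' same-mating-type pairings), 15 replicate populations each (60 total),
#' generating fitness effects W_csr = 0.71 and W_matA = 0.58. For
#' `model = "focal"`: the four (c, m) swap configurations with 5 replicates
#' each (20 total) and W_focal = 0.30, W_matA = 0.68, W_csr = 1.0. Both
#' start near frequency 0.5 and run for 3 transfers with observation noise
#' sd 0.03 on the proportion scale; replicate populations get log-slope
#' perturbations of sd `sd_pop` = 0.1 and log-odds intercept jitter of sd
#' `sd_alpha` = 0.05.
#'
#' @param model `"marker_mat"` or `"focal"`.
#' @param W_csr,W_matA,W_focal Generating per-transfer relative fitness of
#'   the marker, the mating type and the focal mutation (W_focal unused by
#'   `marker_mat`).
#' @param p0 Starting frequency of the marked (resp. focal) strain.
#' @param n_transfers Number of transfers after inoculation (observations
#'   at t = 0, ..., n_transfers).
#' @param n_per_type Replicate populations per competition type.
#' @param obs_noise_sd Observation noise sd on the proportion scale; also
#'   reported as `x_sd`.
#' @param sd_pop Sd of the per-population log-slope perturbation.
#' @param sd_alpha Sd of the per-population intercept jitter (log-odds).
#' @return List of class `competition_sim_params`.
#' @export
competition_sim_params <- function(model = c("marker_mat", "focal"),
                                   W_csr = NULL, W_matA = NULL, W_focal = NULL,
                                   p0 = 0.5, n_transfers = 3L,
                                   n_per_type = NULL, obs_noise_sd = 0.03,
                                   sd_pop = 0.1, sd_alpha = 0.05) {
  model <- match.arg(model)
  if (model == "marker_mat") {
    W_csr <- W_csr %||% 0.71
    W_matA <- W_matA %||% 0.58
    W_focal <- W_focal %||% 1
    n_per_type <- n_per_type %||% 15L
  } else {
    W_csr <- W_csr %||% 1
    W_matA <- W_matA %||% 0.68
    W_focal <- W_focal %||% 0.30
    n_per_type <- n_per_type %||% 5L
  }
  stopifnot(W_csr > 0, W_matA > 0, W_focal > 0, p0 > 0, p0 < 1,
            n_transfers >= 1L, n_per_type >= 1L, obs_noise_sd >= 0,
            sd_pop >= 0, sd_alpha >= 0)
  structure(list(model = model, W_csr = W_csr, W_matA = W_matA,
                 W_focal = W_focal, p0 = p0,
                 n_transfers = as.integer(n_transfers),
                 n_per_type = as.integer(n_per_type),
                 obs_noise_sd = obs_noise_sd, sd_pop = sd_pop,
                 sd_alpha = sd_alpha),
            class = "competition_sim_params")
}

# draws from Normal(mu, sd) truncated to [0, 1], via inverse-CDF
rtruncnorm01 <- function(n, mu, sd) {
  if (sd == 0) return(pmin(1, pmax(0, mu)))
  lo <- stats::pnorm((0 - mu) / sd)
  hi <- stats::pnorm((1 - mu) / sd)
  mu + sd * stats::qnorm(lo + stats::runif(n) * (hi - lo))
}

#' Simulate a serial-transfer competition experiment
#'
#' Generates observed proportion trajectories with known ground truth.
#' Each population's latent frequency follows the logistic trajectory
#' `logit(p_t) = alpha + log(W_total) * t`, where `log(W_total)` sums the
#' generating effects according to the population's competition type
#' (marker, mating type, and for the focal design the focal mutation) plus
#' a population-level perturbation `Normal(0, sd_pop)`; `alpha` is
#' `logit(p0)` plus jitter. Observations are truncated-Normal draws around
#' the latent frequency on `[0, 1]`, with `x_sd` set to the observation
#' noise sd -- matching what the melt-curve pipeline emits.
#'
#' For the focal design the latent trajectory tracks the focal strain, but
#' the returned `x_obs` is on the marked-allele scale (as assay output
#' would be): wells where the focal strain is unmarked are complemented.
#' Use [transform_to_focal()] to map back.
#'
#' @param params A [competition_sim_params()].
#' @param seed Integer seed; all randomness flows from it.
#' @return List with `design` (a [competition_design()]), `estimates`
#'   (data frame sample_id, mean, sd as the proportions table),
#'   `observations` (ready for [fit_fitness()]; focal designs still need
#'   [transform_to_focal()]), and `truth` (per-population generating
#'   values and latent trajectories).
#' @export
simulate_competition <- function(params = competition_sim_params(), seed = 1L) {
  stopifnot(inherits(params, "competition_sim_params"))
  set.seed(as.integer(seed))
  if (params$model == "marker_mat") {
    # m: marked strain's mating type vs opponent; c unused (no focal locus)
    types <- data.frame(competition_id = c("AvsA_a", "avsA_A", "AvsA", "avsa"),
                        m = c(1L, -1L, 0L, 0L), c = NA_integer_)
    types$logW <- log(params$W_csr) + types$m * log(params$W_matA)
  } else {
    # four marker/mating-type swap configurations of the focal strain
    types <- expand.grid(c = c(1L, -1L), m = c(1L, -1L))
    types$competition_id <- sprintf("comp_c%+d_m%+d", types$c, types$m)
    types$logW <- log(params$W_focal) + types$c * log(params$W_csr) +
      types$m * log(params$W_matA)
  }
  tvec <- 0:params$n_transfers
  rows <- list()
  truth_pop <- list()
  pop_counter <- 0L
  for (k in seq_len(nrow(types))) {
    for (r in seq_len(params$n_per_type)) {
      pop_counter <- pop_counter + 1L
      pid <- sprintf("pop%02d", pop_counter)
      beta <- types$logW[k] + stats::rnorm(1, 0, params$sd_pop)
      alpha <- stats::qlogis(params$p0) + stats::rnorm(1, 0, params$sd_alpha)
      p_focal <- stats::plogis(alpha + beta * tvec)
      obs_focal <- rtruncnorm01(length(tvec), p_focal, params$obs_noise_sd)
      if (params$model == "focal" && types$c[k] == -1L) {
        x_obs <- 1 - obs_focal         # assay reports the marked allele
        p_marked <- 1 - p_focal
      } else {
        x_obs <- obs_focal
        p_marked <- p_focal
      }
      rows[[pop_counter]] <- data.frame(
        sample_id = sprintf("%s_t%d", pid, tvec),
        population_id = pid, competition_id = types$competition_id[k],
        transfer = tvec,
        marked_strain_matA = types$m[k],
        focal_in_marked = types$c[k],
        x_obs = x_obs, x_sd = params$obs_noise_sd,
        p_latent_marked = p_marked, stringsAsFactors = FALSE)
      truth_pop[[pop_counter]] <- data.frame(
        population_id = pid, competition_id = types$competition_id[k],
        beta = beta, alpha = alpha, stringsAsFactors = FALSE)
    }
  }
  all <- do.call(rbind, rows)
  design <- competition_design(all[c("sample_id", "population_id",
                                     "competition_id", "transfer",
                                     "marked_strain_matA", "focal_in_marked")])
  estimates <- data.frame(sample_id = all$sample_id, mean = all$x_obs,
                          sd = all$x_sd,
                          hpdi_lower = pmax(0, all$x_obs - 2 * all$x_sd),
                          hpdi_upper = pmin(1, all$x_obs + 2 * all$x_sd),
                          n_draws = NA_integer_, stringsAsFactors = FALSE)
  observations <- competition_observations(estimates, design)
  truth <- list(populations = do.call(rbind, truth_pop),
                types = types, params = params,
                latent = all[c("sample_id", "p_latent_marked")])
  list(design = design, estimates = estimates,
       observations = observations, truth = truth)
}

#' Write a self-contained synthetic fixture bundle
#'
#' Writes, under `out_dir`: a simulated melt plate (`melt_long.csv`, long
#' format) with its layout (`layout.csv`) and per-well truth
#' (`melt_truth.csv`), and a simulated competition dataset
#' (`design.csv`, `proportions.csv`, `competition_truth.csv`). Every file
#' is deterministic given `seed`.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Named character vector of the files written, invisibly.
#' @export
make_fixture_bundle <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  layout <- standard_plate_layout()
  plate <- simulate_melt_plate(layout, melt_sim_params(), seed = seed)
  long <- do.call(rbind, lapply(plate$curves, function(cu)
    data.frame(well = cu$well, temperature = cu$temperature, rfu = cu$rfu)))
  files <- c(melt = file.path(out_dir, "melt_long.csv"),
             layout = file.path(out_dir, "layout.csv"),
             melt_truth = file.path(out_dir, "melt_truth.csv"),
             design = file.path(out_dir, "design.csv"),
             proportions = file.path(out_dir, "proportions.csv"),
             comp_truth = file.path(out_dir, "competition_truth.csv"))
  utils::write.csv(long, files["melt"], row.names = FALSE)
  utils::write.csv(as.data.frame(layout), files["layout"], row.names = FALSE)
  utils::write.csv(plate$truth, files["melt_truth"], row.names = FALSE)
  comp <- simulate_competition(
    competition_sim_params("marker_mat", n_per_type = 3L), seed = seed + 1L)
  utils::write.csv(as.data.frame(comp$design), files["design"], row.names = FALSE)
  utils::write.csv(comp$estimates, files["proportions"], row.names = FALSE)
  utils::write.csv(comp$truth$populations, files["comp_truth"], row.names = FALSE)
  invisible(files)
}
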