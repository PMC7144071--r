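test_that("relative fitness is the exponential of the log-odds slope", {
  expect_equal(fitness_from_slope(0), 1)
  expect_equal(fitness_from_slope(log(0.5)), 0.5)
  expect_equal(fitness_from_slope(c(log(2), log(0.25))), c(2, 0.25))
})

test_that("focal transform complements unmarked-focal wells and is an involution", {
  est <- data.frame(sample_id = c("s1", "s2"), mean = c(0.3, 0.3),
                    sd = c(0.03, 0.03))
  d <- competition_design(data.frame(
    sample_id = c("s1", "s2"), population_id = c("p1", "p2"),
    competition_id = c("c1", "c2"), transfer = 0,
    marked_strain_matA = c(1, -1), focal_in_marked = c(1, -1)))
  obs <- transform_to_focal(est, d)
  expect_equal(obs$x_obs, c(0.3, 0.7))
  expect_equal(obs$c, c(1L, -1L))
  expect_equal(obs$x_sd, c(0.03, 0.03))
  # applying the transform twice restores the marked-allele scale
  expect_equal(transform_to_focal(obs, d)$x_obs, c(0.3, 0.3))
  d_na <- d; d_na$focal_in_marked <- NA_integer_
  expect_error(transform_to_focal(est, d_na), "focal_in_marked")
})

test_that("observation validation enforces the model contracts", {
  sim <- simulate_competition(competition_sim_params(n_per_type = 2L), seed = 1)
  obs <- sim$observations
  bad <- obs; bad$x_sd[1] <- 0
  expect_error(fit_fitness(bad, seed = 1), "x_sd")
  bad2 <- obs; bad2$m[1] <- 2
  expect_error(fit_fitness(bad2, seed = 1), "m must be")
  # focal model needs c and m in {-1, +1}
  expect_error(fit_fitness(obs, model = "focal", seed = 1), "'c' column|c and m")
})

test_that("single-timepoint populations are excluded with a warning", {
  sim <- simulate_competition(competition_sim_params(n_per_type = 2L), seed = 2)
  obs <- sim$observations
  keep <- !(obs$population_id == "pop01" & obs$transfer > 0)
  expect_warning(fit <- fit_fitness(obs[keep, ], seed = 2,
                                    mcmc = mcmc_control(2L, 300L, 300L)),
                 "pop01")
  expect_false("pop01" %in% fit$populations)
})

test_that("same-mating-type-only data leave the mating-type effect at its prior", {
  sim <- simulate_competition(
    competition_sim_params(n_per_type = 8L, W_matA = 1), seed = 3)
  obs <- sim$observations[sim$observations$m == 0, ]
  expect_warning(fit <- fit_fitness(obs, seed = 3), "m = 0")
  expect_match(paste(fit$flags, collapse = " "), "prior-dominated")
  # posterior sd of beta_matA should echo the Normal(0, 1) prior
  expect_gt(sd(fit$draws[, "beta_matA"]), 0.7)
  expect_lt(sd(fit$draws[, "beta_matA"]), 1.3)
  # the marker effect is still estimable from these competitions
  expect_lt(sd(fit$draws[, "beta_csr"]), 0.5)
})

test_that("with vanishing measurement error the fit matches direct regression", {
  p <- competition_sim_params(n_per_type = 6L, obs_noise_sd = 1e-3,
                              sd_pop = 0.05, sd_alpha = 0)
  sim <- simulate_competition(p, seed = 4)
  obs <- sim$observations
  fit <- fit_fitness(obs, seed = 4)
  # oracle: per-population OLS slope of logit(x_obs) on t, then the effect
  # contrasts implied by the m coding (+1, -1 types identify beta_matA)
  sl <- sapply(split(obs, obs$population_id), function(g)
    coef(lm(qlogis(pmin(0.999, pmax(0.001, g$x_obs))) ~ g$transfer))[2])
  mpop <- sapply(split(obs, obs$population_id), function(g) g$m[1])
  b_mat <- (mean(sl[mpop == 1]) - mean(sl[mpop == -1])) / 2
  b_csr <- (mean(sl[mpop == 1]) + mean(sl[mpop == -1])) / 2
  expect_lt(abs(mean(fit$draws[, "beta_matA"]) - b_mat), 0.08)
  expect_lt(abs(mean(fit$draws[, "beta_csr"]) - b_csr), 0.08)
})

test_that("relabelling the marked strain inverts the fitness effects", {
  p <- competition_sim_params(n_per_type = 6L)
  sim <- simulate_competition(p, seed = 5)
  obs <- sim$observations
  fit <- fit_fitness(obs, seed = 5)
  flipped <- obs
  flipped$x_obs <- 1 - obs$x_obs
  flipped$m <- -obs$m
  fit2 <- fit_fitness(flipped, seed = 6)
  # exact distributional symmetry, so means agree up to Monte-Carlo error:
  # the marker effect negates, while the mating-type effect (mat A relative
  # to mat a, a labelling that did not change) stays put
  expect_lt(abs(mean(fit2$draws[, "beta_csr"]) + mean(fit$draws[, "beta_csr"])),
            0.05)
  expect_lt(abs(mean(fit2$draws[, "beta_matA"]) - mean(fit$draws[, "beta_matA"])),
            0.05)
  w <- mean(exp(fit$draws[, "beta_csr"]))
  w_inv <- mean(exp(fit2$draws[, "beta_csr"]))
  expect_lt(abs(log(w) + log(w_inv)), 0.1)
})

test_that("focal-model sign symmetry leaves the focal effect unchanged", {
  p <- competition_sim_params("focal", n_per_type = 4L)
  sim <- simulate_competition(p, seed = 7)
  obs <- transform_to_focal(sim$estimates, sim$design)
  fit <- fit_fitness(obs, model = "focal", seed = 7)
  flipped <- obs
  flipped$x_obs <- 1 - obs$x_obs        # relabel marker AND mating type
  flipped$m <- -obs$m
  flipped$c <- -obs$c
  # the focal strain is unchanged, so beta_focal must not move; the flipped
  # dataset is the same experiment with the opposite marker assignment
  fit2 <- fit_fitness(flipped, model = "focal", seed = 8)
  expect_lt(abs(mean(fit$draws[, "beta_focal"]) +
                  mean(fit2$draws[, "beta_focal"])), 0.12)
})

test_that("Cq dilution QC flags inhibition by the slope rule", {
  n <- 10^(4:8)
  qc <- cq_dilution_slope(30 - 1.9 * log10(n), n)
  expect_equal(qc$slope, -1.9)
  expect_true(qc$inhibition_suspected)
  qc2 <- cq_dilution_slope(rep(25, 5), n)
  expect_equal(qc2$slope, 0)
  expect_true(qc2$inhibition_suspected)
  qc3 <- cq_dilution_slope(40 - 3.32 * log10(n), n)
  expect_false(qc3$inhibition_suspected)
  expect_error(cq_dilution_slope(c(30, 29, 28), rep(1e5, 3)), "equal")
  expect_error(cq_dilution_slope(c(30, 29, 28), c(1e5, -1, 1e7)), "positive")
})

test_that("fitness summaries expose W with HPDIs and diagnostics", {
  sim <- simulate_competition(competition_sim_params(n_per_type = 3L), seed = 9)
  fit <- fit_fitness(sim$observations, seed = 9,
                     mcmc = mcmc_control(2L, 500L, 500L))
  s <- summary(fit)
  expect_setequal(s$effect, c("W_csr", "W_matA"))
  expect_true(all(s$W_l95 <= s$W_l66 & s$W_u66 <= s$W_u95))
  expect_true(all(s$W_mean > 0))
  f <- tempfile(fileext = ".json")
  write_fitness_json(fit, f)
  j <- jsonlite::read_json(f)
  expect_equal(j$model, "marker_mat")
  expect_named(j$effects, c("W_csr", "W_matA"), ignore.order = TRUE)
})
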