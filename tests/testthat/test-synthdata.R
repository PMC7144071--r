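test_that("melt simulation is deterministic in the seed", {
  lay <- standard_plate_layout(n_unknowns = 2L)
  s1 <- simulate_melt_plate(lay, seed = 10)
  s2 <- simulate_melt_plate(lay, seed = 10)
  expect_identical(s1, s2)
  s3 <- simulate_melt_plate(lay, seed = 11)
  expect_false(identical(s1$curves[[1]]$rfu, s3$curves[[1]]$rfu))
  # truth structure (which wells exist, their roles) is seed-independent
  expect_identical(s1$truth[c("well", "role")], s3$truth[c("well", "role")])
})

test_that("noiseless pure wells melt at the allele temperatures", {
  lay <- standard_plate_layout(n_unknowns = 0L)
  sim <- simulate_melt_plate(lay, melt_sim_params(noise_sd = 0), seed = 1)
  sig <- plate_signals(sim$curves, lay)
  tm_marked <- sig$tm[sig$role == "positive_marked"]
  tm_wt <- sig$tm[sig$role == "positive_wt"]
  expect_lt(abs(tm_marked - 81.0), 0.01 + 1e-9)
  expect_lt(abs(tm_wt - 82.1), 0.01 + 1e-9)
})

test_that("the expected melt signal is affine in the true proportion", {
  lay <- standard_plate_layout(n_unknowns = 0L)
  sim <- simulate_melt_plate(lay, melt_sim_params(noise_sd = 0), seed = 1)
  sig <- plate_signals(sim$curves, lay)
  std <- sig[sig$role == "standard", ]
  fitl <- lm(signal ~ known_proportion, std)
  expect_lt(max(abs(resid(fitl))), 1e-6)
  # the 0.5 mixture sits exactly halfway between the pure standards
  y0 <- mean(std$signal[std$known_proportion == 0])
  y1 <- mean(std$signal[std$known_proportion == 1])
  y5 <- mean(std$signal[std$known_proportion == 0.5])
  expect_lt(abs(y5 - (y0 + y1) / 2), 1e-6)
  # monotone in x: the basis of the linear standard curve
  agg <- aggregate(signal ~ known_proportion, std, mean)
  expect_true(all(diff(agg$signal[order(agg$known_proportion)]) < 0))
})

test_that("the wild-type curve is farthest from the marked control", {
  lay <- standard_plate_layout(n_unknowns = 0L)
  sim <- simulate_melt_plate(lay, melt_sim_params(noise_sd = 0), seed = 1)
  sig <- plate_signals(sim$curves, lay)
  std <- sig[sig$role == "standard", ]
  agg <- aggregate(abs(signal) ~ known_proportion, std, mean)
  expect_equal(agg$known_proportion[which.max(agg[[2]])], 0)
})

test_that("noiseless trajectories follow the logistic closed form", {
  p <- competition_sim_params(W_csr = 1, W_matA = 1, obs_noise_sd = 0,
                              sd_pop = 0, sd_alpha = 0, n_per_type = 1L)
  sim <- simulate_competition(p, seed = 1)
  expect_true(all(abs(sim$observations$x_obs - 0.5) < 1e-12))
  p2 <- competition_sim_params(W_csr = 0.5, W_matA = 1, obs_noise_sd = 0,
                               sd_pop = 0, sd_alpha = 0, n_per_type = 1L)
  sim2 <- simulate_competition(p2, seed = 1)
  x3 <- sim2$observations$x_obs[sim2$observations$transfer == 3]
  expect_equal(unique(round(x3, 10)), round(1 / (1 + exp(-3 * log(0.5))), 10))
})

test_that("competition simulation is deterministic and well-formed", {
  p <- competition_sim_params(n_per_type = 3L)
  s1 <- simulate_competition(p, seed = 2)
  expect_identical(s1, simulate_competition(p, seed = 2))
  expect_false(identical(s1$observations$x_obs,
                         simulate_competition(p, seed = 3)$observations$x_obs))
  expect_equal(length(unique(s1$observations$population_id)), 12L)
  expect_equal(sort(unique(s1$observations$transfer)), 0:3)
  expect_true(all(s1$observations$x_obs >= 0 & s1$observations$x_obs <= 1))
})

test_that("the focal design exposes all four swap configurations", {
  sim <- simulate_competition(competition_sim_params("focal"), seed = 4)
  cfg <- unique(sim$observations[c("m", "focal_in_marked")])
  expect_equal(nrow(cfg), 4L)
  expect_setequal(cfg$m, c(-1L, 1L))
  expect_equal(length(unique(sim$observations$population_id)), 20L)
})

test_that("fixture bundles are reproducible and loadable end to end", {
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  f1 <- make_fixture_bundle(d1, seed = 5)
  f2 <- make_fixture_bundle(d2, seed = 5)
  for (k in names(f1))
    expect_identical(readLines(f1[[k]]), readLines(f2[[k]]), label = k)
  d3 <- file.path(tempdir(), "fx3")
  f3 <- make_fixture_bundle(d3, seed = 6)
  expect_false(identical(readLines(f1[["melt"]]), readLines(f3[["melt"]])))

  curves <- read_melt_export(f1[["melt"]])
  lay <- read_layout(f1[["layout"]])
  sig <- plate_signals(curves, lay)
  expect_equal(nrow(sig), sum(lay$role != "ntc"))
  props <- read_proportions(f1[["proportions"]])
  des <- read_competition_design(f1[["design"]])
  obs <- competition_observations(props, des)
  expect_equal(nrow(obs), nrow(des))
  unlink(c(d1, d2, d3), recursive = TRUE)
})

test_that("the full plate pipeline recovers hidden unknown proportions", {
  lay <- standard_plate_layout(n_unknowns = 8L)
  sim <- simulate_melt_plate(lay, melt_sim_params(noise_sd = 0.02), seed = 20)
  pe <- estimate_plate(sim$curves, lay, seed = 20)
  truth <- sim$truth$true_proportion[sim$truth$role == "unknown"]
  err <- pe$estimates$mean - truth
  expect_lt(mean(abs(err)), 0.05)
  # each miss is explained by its own posterior spread
  expect_true(all(abs(err) < pmax(3.5 * pe$estimates$sd, 0.05)))
  covered <- truth >= pe$estimates$hpdi_lower & truth <= pe$estimates$hpdi_upper
  expect_gte(mean(covered), 0.75)
})
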