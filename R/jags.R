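# Internal rjags driver shared by the standard-curve and fitness fits.
#
# `warmup` covers both JAGS adaptation and burn-in (half each, at least 100
# adaptation steps); `sampling` iterations per chain are retained. Chain RNGs
# are seeded deterministically from `seed` so fits are reproducible.

run_jags <- function(model_string, data, monitor, chains = 2L,
                     warmup = 1000L, sampling = 3000L, seed = 1L) {
  stopifnot(chains >= 2L, warmup >= 2L, sampling >= 10L)
  seed <- as.integer(seed)
  inits <- lapply(seq_len(chains), function(k)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer((as.numeric(seed) * 1000 + k) %% 2147483647)))
  n_adapt <- max(100L, floor(warmup / 2L))
  n_burn <- max(0L, warmup - n_adapt)
  jm <- rjags::jags.model(textConnection(model_string), data = data,
                          inits = inits, n.chains = chains,
                          n.adapt = n_adapt, quiet = TRUE)
  if (n_burn > 0L) stats::update(jm, n.iter = n_burn, progress.bar = "none")
  samp <- rjags::coda.samples(jm, variable.names = monitor,
                              n.iter = sampling, progress.bar = "none")
  draws <- do.call(rbind, lapply(samp, as.matrix))
  chain_id <- rep(seq_len(chains), each = sampling)
  list(draws = draws, chain = chain_id,
       rhat = rhat_all(draws, chain_id),
       chains = chains, warmup = warmup, sampling = sampling, seed = seed)
}

#' MCMC settings
#'
#' Container for the sampler settings shared by the Bayesian fits:
#' number of chains, warmup iterations (adaptation plus burn-in) and
#' retained sampling iterations, each per chain.
#'
#' @param chains Number of chains (>= 2 so R-hat can be computed).
#' @param warmup Warmup iterations per chain.
#' @param sampling Retained iterations per chain.
#' @return A list of class `mcmc_control`.
#' @export
mcmc_control <- function(chains = 2L, warmup = 1000L, sampling = 3000L) {
  stopifnot(chains >= 2L, warmup >= 2L, sampling >= 10L)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 sampling = as.integer(sampling)), class = "mcmc_control")
}
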