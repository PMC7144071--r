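# hrmcompete

Estimating competitive fitness of microbial genotypes from high-resolution
melting (HRM) assays of marked-allele frequency.

## The problem

Measuring fitness in filamentous fungi such as *Neurospora crassa* means
competing two strains in serial-transfer culture and following their
frequencies. A practical readout is a post-PCR HRM assay on pooled spore
samples: a genetically marked allele (e.g. an engineered *csr-1* variant)
melts about one degree below the wild-type allele, so a sample's melt-curve
shape encodes the allele mixture. Two statistical steps then remain, and
both carry real uncertainty:

1. **Calibration.** On each plate, standards of known marked proportion
   `x` give melt signals `y` (the normalized-RFU difference from the pure
   marked control at the plate's most discriminating temperature). A
   Bayesian linear standard curve

   `y_i ~ Normal(a + B x_i, σ)`, with `a, B ~ N(0, 10)`, `σ ~ halfCauchy(0, 2)`,

   is inverted draw-by-draw, `x = (y − a − ε)/B` with `ε ~ N(0, σ)`,
   clamped to [0, 1], to give a full posterior for every unknown sample's
   proportion.

2. **Fitness.** For asexual competitors the log-odds of the marked strain's
   frequency is linear in transfer number `t` with slope `log W`;
   `W = exp(β)` is per-transfer relative fitness. A hierarchical
   measurement-error model estimates the shared effects (marker `β_csr`,
   mating type `β_matA`, optionally a focal mutation `β_focal`) across all
   populations while propagating each observation's posterior sd:

   `x_est,i ~ N(μ_i, σ)`, `logit(μ_i) = α_pop[i] + (β_pop[i] + β_csr + β_matA·m_i)·t_i`,
   `x_obs,i ~ N(x_est,i, x_sd,i)`.

Everything is seeded and convergence-gated (split R-hat ≤ 1.05); intervals
are highest-posterior-density intervals. A synthetic-data module generates
melt plates and competition trajectories with known ground truth, so the
whole pipeline is testable end to end without instrument data.

## Worked example

```r
library(hrmcompete)

# a simulated plate: 22 standards (1.0 .. 0.0 by 0.1, two replicate series),
# controls, and 4 unknown wells with hidden true proportions
layout <- standard_plate_layout(n_unknowns = 4)
plate  <- simulate_melt_plate(layout, melt_sim_params(), seed = 7)
result <- estimate_plate(plate$curves, layout, seed = 7)
result
#> Plate 'simplate': discriminating T = 81.50 C (control well W23)
#> Bayesian standard curve: signal = a + B * proportion
#>   a = 0.5310, B = -0.5454, sigma = 0.0177 (posterior means, 6000 draws)
#>   max R-hat = 1.000
#> Marked-allele proportion estimates for 4 sample(s) (6000 draws each):
#>   sample_id   mean      sd hpdi_lower hpdi_upper n_draws
#> 1     unk01 0.1038 0.03491    0.03831     0.1755    6000
#> 2     unk02 0.2944 0.03463    0.22360     0.3609    6000
#> 3     unk03 0.7287 0.03443    0.65970     0.7960    6000
#> 4     unk04 0.5983 0.03308    0.53219     0.6630    6000
```

The plate's discriminating temperature (81.5 °C) is where the difference
curves of the 0 and 1 standards separate most; the fitted line maps signals
back to proportions, and each unknown gets a posterior mean, sd and 95%
HPDI. (The hidden truths for seed 7 are 0.12, 0.30, 0.79, 0.66 —
`plate$truth` — all inside their intervals.)

Fitness estimation from a simulated 60-population marker/mating-type
design (generating effects W_csr = 0.71, W_matA = 0.58):

```r
sim <- simulate_competition(competition_sim_params("marker_mat"), seed = 7)
fit <- fit_fitness(sim$observations, model = "marker_mat", seed = 7)
summary(fit)
#>   effect    W_mean       W_sd     W_l66     W_u66     W_l95     W_u95      rhat
#> 1  W_csr 0.7259105 0.09372073 0.6209382 0.7952311 0.5507915 0.9134372 1.0000217
#> 2 W_matA 0.6027791 0.10970308 0.4890482 0.6851859 0.3937396 0.8186594 0.9996491
```

Both 95% HPDIs cover the generating values: the marked allele carries a
~27% per-transfer fitness cost here, and *mat A* a ~40% disadvantage
relative to *mat a*. `plot(fit)` draws the dot-and-interval display;
`write_fitness_json(fit, path)` serializes the summary.

Real data enter through `read_melt_export()` (long or wide CSV),
`read_layout()`, and `read_competition_design()`; `write_proportions()` /
`read_proportions()` bridge the two stages. A thin CLI with subcommands
`tm`, `standards`, `estimate`, `fitness` and `simulate` is installed at
`exec/hrmcompete`.

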