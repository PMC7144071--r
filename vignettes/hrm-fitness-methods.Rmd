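---
title: "From melt curves to competitive fitness: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From melt curves to competitive fitness: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrmcompete)
```

## The measurement problem

Competition experiments with filamentous fungi such as *Neurospora crassa*
track the frequency of a genetically marked strain across serial transfers.
A convenient readout is post-PCR high-resolution melting (HRM): a short
amplicon spanning the marker locus is amplified from a pooled spore (conidia)
sample in the presence of a double-strand-specific dye, and fluorescence is
recorded while temperature ramps from 70 to 90 °C in 0.1° steps. The marked
and wild-type alleles melt at slightly different temperatures (about 1°
apart), so the *shape* of a sample's melt curve carries the allele mixture.
`hrmcompete` turns those curves into a posterior distribution for the
marked-allele proportion of each sample, and then turns time series of such
posteriors into estimates of relative competitive fitness.

## Melt-curve processing

Raw fluorescence differs between wells by gain and offset, so every curve is
first min–max rescaled to [0, 1] (`normalize_curve()`). The default
normalizes over the full 70–90° window; a `window` argument allows the
pre-/post-melt-region variant common in HRM software, but the global map is
the default because the simulated and typical real ramps start fully
double-stranded and end fully melted.

The melting temperature (`melting_temperature()`) is the inflection point of
the curve: we compute the negative first derivative by central finite
differences *on the measured grid*, then interpolate that derivative with a
cubic spline and take the argmax on a dense grid (0.01° steps). Doing the
derivative before the spline keeps the estimator linear in the data and
makes the spline's job one of smooth interpolation rather than
differentiation. We use R's `"fmm"` end conditions (an exact cubic through
the four points nearest each end); by default the spline interpolates
(no smoothing), with an optional `spar` for noisy instruments. Ties in the
argmax cannot occur on the dense grid in practice, but the first (lowest
temperature) maximum is taken, making the call deterministic.

Tm alone is a poor mixture readout here: heteroduplexes formed by
re-annealing of mismatched strands distort mixture curves, so their Tm is
not the linear interpolation of the pure-allele Tms. Instead the pipeline
subtracts the normalized curve of the plate's pure marked-allele control
from every well (`difference_curve()`) and reads a scalar signal off the
difference curve at a single *discriminating temperature*
(`signal_at()`). That temperature is chosen per plate
(`select_discriminating_temperature()`) as the point of maximal separation
between the difference curves of the 0 and 1 standards — the temperature
with the largest dynamic range. Ties break to the lowest temperature.
Choosing it per plate (rather than once globally) lets each plate's own
controls absorb run-to-run shifts; plates are never mixed: unknowns are only
inverted through their own plate's curve.

Curves on different grids are linearly interpolated onto the grid of the
marked positive control before subtraction; interpolation error is
quadratic in the 0.1° step and negligible against instrument noise.

## The Bayesian standard curve and its inversion

Each plate carries standards at known marked proportions 1.0 … 0.0 in 0.1
decrements, in two independently constructed replicate series. With \(y\)
the melt signal and \(x\) the known proportion, the calibration model is

\[ y_i \sim \mathrm{Normal}(a + B x_i, \sigma),\qquad
   a, B \sim \mathrm{Normal}(0, 10),\qquad
   \sigma \sim \mathrm{halfCauchy}(0, 2). \]

Keeping the unconstrained signal as the response lets a Normal likelihood
apply cleanly; the bounded proportion is recovered by inversion. Both
replicate series are pooled into a single fit per plate: the inversion uses
one \((a, B)\) pair, and pooling uses all 22 standards. (Per-replicate fits
remain possible by subsetting the signals table, as a QC comparison.)
Sampling uses 2 chains with 1000 warmup and 3000 retained iterations each;
split R-hat is computed for every parameter and the fit is flagged
non-converged above 1.05.

For an unknown sample with signal \(y\), each posterior draw is inverted as

\[ x^{(d)} = \frac{y - a^{(d)} - \varepsilon^{(d)}}{B^{(d)}},
   \qquad \varepsilon^{(d)} \sim \mathrm{Normal}(0, \sigma^{(d)}), \]

and draws outside [0, 1] are set to the nearest limit — clamping happens per
draw, *before* summarizing, so posterior means near a boundary shrink
inward, which is the behaviour we want for a physical proportion. The
\(\varepsilon\) term is the unknown well's own measurement noise: omitting
it (available as `predictive = FALSE`) propagates only the uncertainty of
the fitted line, which with 22 standards is several times smaller than
\(\sigma/|B|\) and produces intervals that badly undercover the truth.
With the predictive term the 95% HPDIs of simulated unknowns cover the true
proportion at close to nominal rate on average; coverage *conditional on one
plate's curve* still fluctuates by several points from plate to plate
because \(\sigma\) is estimated from only 22 points.

A posterior that collapses entirely onto a boundary can have sd ≈ 0; since
the fitness models require a strictly positive measurement sd, reported sds
are floored at 10⁻³ (with the floor recorded in the output contract, not
hidden).

`hpdi()` implements the highest-posterior-density interval as the narrowest
window of ⌈mass·n⌉ consecutive sorted draws, ties broken toward the lowest
lower bound; `rhat()` is the split-half potential-scale-reduction factor,
returning `NA` (with a warning) when all chains are constant, since such
chains carry no convergence information.

## From proportion time series to relative fitness

For two asexual competitors the ratio of their frequencies grows
geometrically, so the log-odds of the marked strain's frequency is linear
in transfer number \(t\) with slope \(\log W\) — \(W\) being the marked
strain's per-transfer relative fitness. Transfers, not cell-division
generations, are deliberately the time unit: a transfer spans all the
mycelial growth and conidiation between spore samplings, so \(W\) is a
spore-to-spore fitness. The inoculation measurement at \(t = 0\) is data
like any other.

`fit_fitness()` embeds this line in a hierarchical measurement-error model.
For the marker/mating-type design (`model = "marker_mat"`):

\[
x_{\mathrm{est},i} \sim \mathrm{Normal}(\mu_i, \sigma),\qquad
\mathrm{logit}(\mu_i) = \alpha_{\mathrm{pop}[i]} +
 (\beta_{\mathrm{pop}[i]} + \beta_{csr} + \beta_{matA} m_i)\, t_i,\qquad
x_{\mathrm{obs},i} \sim \mathrm{Normal}(x_{\mathrm{est},i}, x_{\mathrm{sd},i})
\]

with priors \(\alpha \sim \mathrm{N}(0, 0.065)\),
\(\beta \sim \mathrm{N}(0, 1)\), \(\sigma \sim \mathrm{halfCauchy}(0,2)\).
The indicator \(m \in \{-1, 0, +1\}\) codes the marked strain's mating type
(+1 *mat A*, −1 *mat a*, 0 same-mating-type competition), so every
competition informs \(\beta_{matA}\) with the correct sign and
same-mating-type pairs contribute nothing to it. The tight intercept prior
encodes the known design: competitions start at frequency ≈ 0.5, which is 0
on the log-odds scale. Effects are reported as \(W = e^\beta\) with 66% and
95% HPDIs.

The focal-mutation design (`model = "focal"`) first re-expresses the
response as the frequency of the strain carrying the focal mutation
(`transform_to_focal()`: wells where the focal strain is unmarked are
complemented, sd unchanged — an involution). Its linear predictor is
\(\alpha_{\mathrm{comp}[i]} + (\beta_{\mathrm{pop}[i]} + \beta_{focal} +
\beta_{csr} c_i + \beta_{matA} m_i) t_i\) with \(c, m \in \{-1, +1\}\): the
marker and mating-type effects are never absent, only present in different
configurations, and the four swap configurations separate them from the
focal effect. Intercepts are per competition (four of them), matching how
inoculation was standardized.

Observed proportions of exactly 0 or 1 (fixation) are retained: the
likelihood lives on the proportion scale and no logit of data is ever
taken — only \(\mu\) passes through the inverse logit. The latent
\(x_{\mathrm{est}}\) is not truncated to [0, 1]; truncation would change
boundary behaviour and is not part of the model.

### Computation

Models are written in JAGS and sampled with `rjags`. Two reformulations —
both exact, changing nothing about the posterior — matter for mixing with a
Gibbs-type sampler:

* the measurement layer is marginalized analytically,
  \(x_{\mathrm{obs},i} \sim \mathrm{Normal}(\mu_i,
  \sqrt{\sigma^2 + x_{\mathrm{sd},i}^2})\), removing ~240 latent variables
  whose coupling with \(\sigma\) otherwise creates a funnel;
* population slopes use the centered parameterization
  \(b_j \sim \mathrm{Normal}(\beta_{csr} + \beta_{matA} m_j, 1)\), with the
  shared effects as hyper-means; the per-population deviation
  \(\beta_{\mathrm{pop},j} = b_j - \beta_{csr} - \beta_{matA} m_j\) is
  recoverable from the draws.

With these, all parameters reach split R-hat ≈ 1.00 at the default
iteration counts (2 chains; 2500 warmup + 2500 retained each for the
marker/mating-type model — 10 000 iterations in total; 1250 + 1250 for the
focal model — 5000 in total; warmup is split evenly between sampler
adaptation and burn-in). Every stochastic entry point takes an explicit
integer seed that is recorded in the fit.

Populations observed at fewer than two transfers are excluded with a
warning (their slope is not identifiable); designs in which every record
has \(m = 0\) leave \(\beta_{matA}\) at its prior and are flagged rather
than refused.

## What the simulator emulates — and what it does not

`simulate_melt_plate()` builds each well's raw curve as
\(\mathrm{gain}\cdot[x\,S(T; 81.0) + (1-x)\,S(T; 82.1)] + \mathrm{offset} +
\mathrm{noise}\), with \(S\) a falling sigmoid of width 0.4° (chosen to
give realistic, clearly resolvable derivative peaks ~1° apart), per-well
gain uniform on [800, 1200] RFU and offset on [50, 150] RFU so that
normalization is genuinely exercised, and Gaussian noise of sd 0.02 on the
unit-amplitude scale. No-template controls are near-flat traces. Because
the mixture curve is exactly linear in \(x\), the expected signal at the
discriminating temperature is affine in the true proportion — the linear
standard curve is well-specified on synthetic plates by construction.

Real mixtures are *not* exactly linear: heteroduplex formation distorts
curve shape, which is precisely why the difference-curve signal rather than
Tm is the default response. An optional `heteroduplex_shift` perturbs
mixture wells to stress-test the pipeline, but is off by default, so
passing recovery tests on synthetic plates demonstrates correctness of the
estimation machinery, not robustness to heteroduplex chemistry. Binomial
sampling of conidia, pipetting error and spatial plate effects are likewise
not modelled; `x_sd` from the inversion is what carries sample-level
uncertainty downstream.

`simulate_competition()` generates latent logistic trajectories with the
effect-summed \(\log W\) for each competition type plus a per-population
slope perturbation (sd 0.1 — replicate populations in real experiments do
not share one exact slope) and intercept jitter (sd 0.05 around
logit 0.5), then truncated-Normal observation noise of sd 0.03 on the
proportion scale, reported as `x_sd`. Default designs are 4 competition
types × 15 populations × transfers 0–3 (marker/mating-type) and
4 types × 5 populations (focal); default generating effects are
W_csr = 0.71, W_matA = 0.58, and W_focal = 0.30 with W_matA = 0.68,
W_csr = 1 — realistic magnitudes for marker costs, mating-type asymmetry
and a deleterious regulatory mutation in this system.

## Quality control

`cq_dilution_slope()` regresses quantification cycle on log10 template
amount. Perfect per-cycle doubling gives −1/log10(2) ≈ −3.32 per decade;
shallower slopes (above −3.3) mark suspected PCR inhibition. Inhibited but
allele-balanced reactions still quantify *relative* proportions correctly,
which is all this assay asks of them.

## Problem sizes and verification

The test suite verifies each stage against an independent oracle: analytic
sigmoid centres for Tm (|error| < 0.01° across centres 75–88°), exhaustive
grid scans for the discriminating temperature, ordinary least squares for
the standard-curve posterior in the small-noise limit, the closed-form
logistic trajectory (\(p_3 = 1/(1+e^{-3\ln 0.5}) = 1/9\)) for the fitness
slope, per-population logit regression for the fitness model in the
vanishing-measurement-error limit, and parameter recovery plus HPDI
calibration at the full 60- and 20-population designs (one plate of 22
standards, 200 simulated unknowns). These sizes match the designs described
above and keep the default suite fast; symmetry checks (marker relabelling
inverts the marker's \(W\) and leaves the mating-type effect fixed) use
6 populations per type.

## Known limitations

* Two alleles only; no multi-allele mixtures, no absolute quantification.
* The standard curve is linear by assumption; strongly heteroduplex-driven
  nonlinearity would require a curvature term and is not implemented.
* Unknowns cannot be estimated against another plate's standard curve.
* The latent fitness-model residual \(\sigma\) absorbs any trajectory
  nonlinearity (e.g. frequency-dependent selection) rather than modelling
  it.
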