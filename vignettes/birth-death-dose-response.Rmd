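---
title: "Modelling chemo-sensitivity assays as birth-death processes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling chemo-sensitivity assays as birth-death processes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bdrates)
```

## The model

An in-vitro chemo-sensitivity experiment seeds wells with a known number of
tumour cells `n0`, treats them with a dilution series of a compound, and
reads out the surviving population after a fixed follow-up (typically 72 h)
through a luminescence or fluorescence proxy for cell count. `bdrates`
models the cell population in each well as a linear birth-death (Kendall)
process: a community of `k` cells divides at aggregate rate `k * lambda(z)`
and dies at rate `k * mu(z)`, where `z` is the log10 molar concentration of
the compound. Because the follow-up time is the same for every well, it is
absorbed into the rates: `lambda` and `mu` are per-cell expected event
counts over the whole experiment.

Two classical results about the linear birth-death process drive everything
else. Starting from `n0` cells, the final count `N` has

* mean `m = n0 * exp(lambda - mu)`, and
* variance `v = n0 * (lambda + mu) / (lambda - mu) * exp(lambda - mu) *
  (exp(lambda - mu) - 1)`, with the continuous limit
  `v = n0 * (lambda + mu)` on the line `lambda = mu`.

The mean depends on the rates only through their difference, but the
variance carries `lambda + mu`. Replicate wells at the same dose therefore
contain information that separates division from death: a quiescent
population (`lambda` and `mu` both near 0) and a high-turnover population
(`lambda = mu`, both large) have identical expected counts but very
different spreads. This is the mechanistic heart of the method — a single
fitted growth curve cannot make that distinction.

For assay-scale initial counts the exact transition law (a combinatorial
sum that the package evaluates in `bdp_transition_prob()`, in extended
precision, as a validation oracle) is impractical in a likelihood, so the
count is approximated by a Gaussian with the matched mean and variance.
Measured intensities also carry additive background noise
`epsilon ~ N(theta, sigma^2)`, estimated from compound-free wells; the
likelihood of a well is then `N(m + theta, v + sigma^2)`, and background
wells contribute `N(theta, sigma^2)` terms. At least two background wells
are required or `theta` and `sigma^2` are not identifiable; real plates
carry an entire column or more of blanks.

Dose dependence is modelled non-parametrically. The log rates
`phi_lambda(z) = log lambda(z)` and `phi_mu(z) = log mu(z)` get independent
Gaussian-process priors with constant means `alpha` and squared-exponential
kernels `K(z, z') = tau^2 * exp(-(z - z')^2 / l^2)`. No monotonicity or
sigmoidal shape is imposed: plateaus, shoulders and even hormetic bumps are
all in the prior's support.

## Priors and their defaults

All hyperprior constants are user-settable through `bd_hyperprior()`; the
defaults were chosen once, by prior-predictive reasoning and calibration
against the synthetic scenarios described below, and are deliberately
informative *on the biological scale*:

* `alpha ~ N(0, 2.25)` (sd 1.5). Per-experiment log rates essentially
  always lie within e^(+/-3) — between one event per twenty cells and
  twenty events per cell over a three-day follow-up. A much wider prior
  (e.g. variance 100) looks harmless but places around a third of its mass
  on rate curves so close to zero that they leave no trace in the counts;
  the posterior then develops a spurious mode in which the background
  variance absorbs the birth-death variance, and both interval calibration
  and sampler behaviour degrade badly.
* `tau^2 ~ Inverse-Gamma(2, 1)` (mean 1). Supports curve amplitudes of
  several e-folds across the tested range while damping the heavy upper
  tail that permits isolated single-dose rate spikes.
* `l^2 ~ Gamma(2, 1)` (mean 2 squared decades). Zero-avoiding; features
  much narrower than half a dilution step cannot be resolved by a 9-dose
  design anyway, and very short length-scales let the curves chase
  replicate noise.
* `theta` flat and `sigma^2` log-uniform (improper); the background wells
  make the posterior proper.

The Gaussian-mean prior variance (one scalar per rate curve) and the
remaining constants can be overridden per fit, e.g.
`bd_fit(e, hyperprior = bd_hyperprior(s_alpha2_mu = 9))`.

## Posterior computation

`bd_fit()` runs a Metropolis-within-Gibbs sampler over the latent log-rate
vectors at the tested doses plus the eight hyperparameters. The latent
field is sampled *only at the tested doses*: the likelihood touches no
other point, so the dense curves shown in figures are reconstructed
afterwards, per retained draw, from the exact GP conditional under that
draw's hyperparameters. This is distributionally equivalent to carrying a
dense grid through the sampler and far cheaper (a d x d Cholesky per
kernel update instead of a 100+ dimensional one).

The update blocks, in sweep order:

* **Latent curves** — preconditioned Crank-Nicolson proposals in the
  whitened space of the current kernel; the proposal preserves the GP
  prior exactly, so acceptance is on the likelihood ratio alone.
* **GP means** — exact conjugate draws, interleaved with *non-centred*
  Metropolis shifts that move `alpha` and the whole curve together. The
  non-centred move matters: when a rate is too small to register in the
  counts, the centred draw alone lets `alpha` wander into the prior tails
  (the classic funnel) with no way back.
* **Kernel hyperparameters** — joint random-walk Metropolis on
  `(log tau^2, log l^2)` against the GP marginal and their priors.
* **Turnover moves** — the mean pins `lambda - mu` tightly, so the
  sampler includes dedicated moves along the weakly identified
  `lambda + mu` direction: a global additive shift of both rates (with the
  log-parameterisation Jacobian), per-dose versions with individually
  adapted scales and occasional heavy-tailed (Cauchy) jumps, and a
  "ridge" variant that also shifts `sigma^2` by the induced change in
  birth-death variance, so the total well variance — the only quantity the
  replicates constrain directly — is preserved across the jump.
* **Noise** — conjugate draw for `theta`; log-scale Metropolis for
  `sigma^2` (its log-uniform prior is flat there).

Proposal scales adapt toward standard targets (0.23 vector, 0.44 scalar)
during burn-in only and are frozen afterwards, so retained draws target
the exact posterior. One user seed drives the whole run; identical seeds
give bit-identical results. Defaults are 20,000 iterations, 10,000
burn-in, thinning 10; the package's own simulation studies use 8,000 to
12,000 iterations on 9-dose triplicate designs, which split-R-hat and
effective-sample-size diagnostics (`bd_diagnostics()`) accept.

Initialisation is method-of-moments: the net rate from the lowest-dose
mean count ratio, the turnover from the median of per-dose
variance-implied estimates (a single dose's 2-df variance estimate is far
too noisy to trust alone), and the noise moments from the background
wells.

The sampler was validated three ways: prior recovery with the likelihood
disabled, closed-form conjugate checks of the noise updates, and a
joint-distribution (Geweke-style) test comparing forward prior-data
simulation against the successive-conditional chain on a small design.
The Geweke harness fixes `theta` and `sigma^2` (their improper priors
cannot be forward-sampled) and uses a deliberately tame hyperprior and a
small `n0`: with assay-scale counts the likelihood is so tight that the
state-data feedback freezes the level coordinates and the check measures
mixing, not correctness.

## Summaries

`bd_curves()` reports pointwise summaries of the expected-count curve
`m(n0, z)` and both rate curves. `bd_potency()` turns draws into the three
classical potency summaries, defined relative to the smallest tested
concentration as control (the only reference always available from the
modelled data; a fixed external control growth can be supplied instead):

* **GI50** — smallest `z` where net growth `m(z) - n0` falls to half the
  control's net growth;
* **TGI** — smallest `z` where `m(z) = n0`;
* **LC50** — smallest `z` where `m(z) = n0 / 2`.

Crossings are solved per draw on a dense grid by linear interpolation,
taking the smallest crossing when a non-monotone curve crosses more than
once (the multiple-crossing fraction is reported). Draws that never reach
a threshold inside the tested range are censored, counted, and excluded
from the mean and interval — extrapolated potencies are never fabricated.
The point estimate solves the same crossing on the posterior-mean curve;
the credible interval is the 2.5/97.5 equal-quantile interval of the
per-draw crossings. Concentrations are reported in molar with log10
companions.

Two numerical choices deserve note. First, pointwise "mean" summaries of
rates and curves use a 1%-per-tail trimmed mean: under triplicate
replication the posterior keeps a thin, extremely heavy tail of isolated
large-turnover excursions, and on the exponential scale a handful of such
draws can dominate a raw mean while leaving quantiles untouched. Second,
dense-grid curves interpolate each draw by the GP conditional *mean*;
sampling the conditional noise as well would feed a double exponential
whose outliers again destroy pointwise means, while adding nothing at the
tested doses.

## What the synthetic generator emulates — and what it does not

`simulate_experiment()` reproduces the design of a large public
chemo-sensitivity screen: 9 doses log-spaced over `z` in [-9, -4]
(nanomolar to 100 micromolar), triplicate wells, `n0 = 1000` cells per
well, one follow-up, and a set of compound-free background wells
(default 16, a plate column of blanks; background noise
`N(theta = 20, sigma = 10)` in count units, i.e. a small additive offset
relative to a 10^3-cell signal). Counts are exact Gillespie draws from
the birth-death process — not draws from the model's own Gaussian
approximation — so fits against it also probe the approximation error.
Named scenarios cover constant rates, pure birth inhibition, pure death
induction, both effects (birth halves, death triples), matched
quiescence/turnover pairs, and a two-transition "plateau" response whose
mean curve no four-parameter sigmoid can track. Scenario transitions use
widths of 0.35-0.5 decades; sharper features than half a dilution step
are not resolvable by the design and are not claimed.

The generator does not simulate plate or edge effects, luminescence
calibration curves, pipetting error in `n0` (treated as known, as in the
model), or dose-dependent measurement noise. Passing the simulation
studies therefore demonstrates correctness of the inference given the
mechanistic model, not robustness to the artefacts of real plates, which
should be handled by upstream quality control.

## Known limitations

* With triplicate wells the turnover direction `lambda + mu` leans
  entirely on 2-df variance estimates. Intervals for the individual
  rates are then honest but wide, and for *exactly matched* large rates
  (`lambda = mu`) the posterior genuinely splits between "high turnover,
  ordinary noise" and "low turnover, inflated noise" explanations —
  the data barely distinguish them. More replicates, or more background
  wells pinning `sigma^2`, sharpen this quickly.
* Rates are time-homogeneous within the follow-up and density
  independent; population-level feedback (rates depending on the current
  cell count) is outside the model.
* Each experiment is fitted independently; no information is shared
  across compounds or cell lines.
* The Gaussian approximation degrades for very small `n0` or
  near-complete kill (final counts approaching single digits).

## A worked example

```{r example, eval = FALSE}
sim <- simulate_experiment("both", seed = 1)
fit <- bd_fit(sim$experiment, seed = 1)
tidy(fit, "rates")      # per-dose birth and death rates with 95% CIs
bd_potency(fit)         # GI50 / TGI / LC50, posterior means and CIs
bd_rate_change(fit)     # percent change of each rate across the range
autoplot(fit)           # growth curve with credible ribbon
autoplot(fit, "rates")  # birth and death rate panels
```

The README shows this example with its printed output.
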