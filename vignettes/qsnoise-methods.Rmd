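---
title: "Noise in quorum-sensing signalling near the activation threshold: model and methods"
author: "qsnoise authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise in quorum-sensing signalling near the activation threshold: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsnoise)
```

## The model

Gram-negative bacteria count themselves by exchanging a small diffusible
signalling molecule (an autoinducer of the acyl-homoserine-lactone family,
synthesised by LuxI-type enzymes). Below the activation threshold of the
quorum-sensing switch, the synthase gene is transcribed at a low
constitutive level -- rarely more than one transcript per cell at a time --
and the feedback loops that fire above threshold can be neglected.
`qsnoise` models exactly this regime, for `N` identical cells in a shared,
well-stirred medium:

* **Telegraph mRNA.** Each cell's transcript count switches between 0 and 1,
  on at rate $\beta$ (transcription) and off at rate $\alpha$ (mRNA
  degradation). The resulting drive is *colored* noise with correlation
  time $\tau_c = 1/(\alpha+\beta)$: while a transcript lives, synthesis
  persists.
* **Synthesis and turnover.** With a transcript present, autoinducer
  molecules are produced at rate $k_+$ (translation and synthesis collapsed
  into one step). Molecules are removed at rate $k_-$ both inside and
  outside the cells; under the dilution protocol that keeps the cell
  density constant, dilution dominates chemical decay, so a single
  effective rate is appropriate.
* **Exchange.** Molecules cross the membrane at rate $D$ (out) and return
  from the pool at rate $rD$ per molecule, where $r = V/V_\mathrm{ext}$ is
  the cell-to-medium volume ratio. The medium is one well-stirred
  compartment; no spatial gradients.

The package works in minutes and nanomolar externally and in integer
molecule counts internally. Standard geometry: $N = 100$, $r = 10^{-5}$
(sensing potential $\nu = 1/(rN) = 10^3$, in the experimentally estimated
range), $V = 1.5\,\mu m^3$, $k_- = 2\times 10^{-2}\,\mathrm{min}^{-1}$.

In units of the molecule lifetime $1/k_-$ and of the maximal single-cell
concentration $c_A^+ = k_+/(k_- V)$, the reduced single-cell equation is

$$\dot{\tilde c}_A = \hat c_{M}(\tilde t) + k_+^{\mathrm{eff}}(\langle
\tilde c_A\rangle) - k_-^{\mathrm{eff}} \tilde c_A, \qquad
k_-^{\mathrm{eff}} = 1 + \tilde D,\quad
k_+^{\mathrm{eff}} = \frac{\langle \tilde c_A\rangle \tilde D}{1 + 1/(N
\tilde D r)},$$

with $\hat c_M$ the telegraph drive with dimensionless rates
$\tilde\alpha = \alpha/k_-$, $\tilde\beta = \beta/k_-$, and the pool
treated in quasi-steady state. The mean-field influx term makes the
equation self-consistent: the package solves the fixed point both in
closed form (`mean_dimensionless()`) and by damped iteration
(`self_consistent_mean()`), and each result is required, in the tests, to
confirm the other.

On the affine transform $x = k_-^{\mathrm{eff}} \tilde c_A -
k_+^{\mathrm{eff}}$ the stationary law is
$\mathrm{Beta}(\tilde\beta/k_-^{\mathrm{eff}},
\tilde\alpha/k_-^{\mathrm{eff}})$, giving closed forms for the density,
its support (width exactly $1/(1+\tilde D)$), the mean, all moments, and
the transcriptional noise

$$\eta^2_{\mathrm{tran}} = \frac{\tilde\alpha\,(1+\tilde D+\tilde D N
r)^2}{\tilde\beta\,(1+\tilde D)(1+\tilde D N r)^2(1+\tilde
D+\tilde\alpha+\tilde\beta)}.$$

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| $\alpha$ | mRNA degradation, 1/min | preset (e.g. 0.3) | half-lives of 2--5 min, so $\tilde\alpha > 1$ |
| $\beta$ | transcription rate, 1/min | preset (e.g. 0.1) | low constitutive expression: $\alpha > 2\beta$ keeps $\le 1$ transcript |
| $k_-$ | effective degradation, 1/min | 0.02 | dilution compensating a ~50 min cell cycle |
| $D$ | membrane exchange, 1/min | scanned | passive diffusion $\tilde D \sim 10^4$; active transport $\tilde D \sim 10^{-1}..10$ |
| target mean | operating point, nM | 25 | middle of the 10--50 nM activation range |
| $N, r$ | population geometry | 100, $10^{-5}$ | $\nu = 10^3$; $N$ large enough to avoid small-population artefacts |

The four presets $\gamma_1 = (8,2)$, $\gamma_2 = (15,5)$, $\gamma_3 =
(8,0.5)$, $\gamma_4 = (15,0.5)$ (dimensionless $(\tilde\alpha,
\tilde\beta)$) span the admissible wedge $\tilde\alpha > 2\tilde\beta$,
$\tilde\alpha > 1$. At every diffusion value, $k_+$ is recalibrated by
`calibrate_k_plus()` so the mean stays at the operating point; the
calibrated mean count ($\approx 22.58$ molecules at 25 nM) is kept as a
real number -- the simulator consumes rates, never rounded counts.

## Two engines, one law

`ssa_run()` samples the full master equation exactly (Gillespie direct
method). Design choices worth knowing:

* Pool influx is one lumped channel of propensity $N r D A_\mathrm{ext}$
  with a uniform destination draw -- the master equation is identical to
  $N$ per-cell channels, with fewer propensities to maintain.
* All stationary statistics are exact time-weighted integrals of the
  piecewise-constant trajectory between events. Nothing is read off a
  sampling grid, so moment estimates carry no discretisation bias.
* Per-cell concentrations are pooled across cells and stationary time;
  cells are exchangeable, so pooling estimates the single-cell stationary
  law with lower variance.
* Default burn-in is $20\times$ the slowest relaxation scale
  ($\max(1/k_-, \tau_c, 1/(k_-+D))$, i.e. 1000 min at the standard
  $k_-$); runs initialised with `initial_state(..., "stationary_guess")`
  (Bernoulli occupancy, Poisson counts at the calibrated means) relax much
  faster, and the scan experiments use a 250 min burn-in on top of that
  start. Uncertainty is always the standard error across $\ge 8$
  independent replicate runs with recorded seeds (`seed + replicate`),
  since the stationary theory provides no error protocol of its own.
* `ssa_run_dual()` doubles the synthesis/degradation/exchange reactions:
  two distinguishable reporters driven by the *same* transcript, with
  separate external pools.

`pdmp_run()` simulates the reduced equation as a piecewise-deterministic
Markov process: exponential switch times, closed-form exponential
relaxation between switches, and closed-form segment integrals for the
first two moments. It has no ODE step and therefore no numerical error
beyond sampling; it realises the analytic law exactly (checked by a KS
test against the closed-form CDF) and serves as the intrinsic-noise-free
counterpart of the SSA. Its mean-field influx is frozen at the stationary
self-consistent value -- the same closure under which the stationary
density is derived -- not updated from the running average.

## Numerical choices

* Density arithmetic is in log space with `lgamma`; at large $\tilde D$
  both Beta exponents tend to zero and the density has integrable
  singularities at both support edges. Production moments therefore always
  use the closed-form Beta moments; quadrature appears only in the test
  suite (with endpoint-desingularising power substitutions) and only for
  $\tilde D \le 2000$.
* Density evaluation exactly at a singular endpoint returns `+Inf`, never
  `NaN`; outside the support it returns 0.
* Shape classification (`classify_shape()`) implements the strict
  inequality against $k_-^{\mathrm{eff}} = 1+\tilde D$; ties within
  $10^{-12}$ are reported `"degenerate"` rather than silently broken.
  `"no_extremum"` is one class; `density_slope_at_lower()` reports which
  monotone branch applies (under low constitutive expression it is the
  decaying one).
* The fixed-point solver uses damping 0.5 and at most $10^4$ iterations;
  the damped map is affine and contracting for all admissible parameters,
  and non-convergence is an error with diagnostics, not a silent result.
* The noise-curve argmax is located on a 200-point log grid over
  $[10^{-2}, 10^6]$ and refined by golden-section search on the bracket;
  the slope at $\tilde D = 0$ uses a forward difference with step
  $10^{-6}$.

## The diffusion scan and what it shows

`diffusion_scan()` re-runs the calibrated model across a diffusion grid
and decomposes the noise as $\eta^2_{\mathrm{tot}} =
\eta^2_{\mathrm{int}} + \eta^2_{\mathrm{tran}}$: the intrinsic component
is the simulated total minus the closed-form transcriptional part, and an
independent dual-reporter estimator
$\langle(c_1-c_2)^2\rangle/(2\langle c_1\rangle\langle c_2\rangle)$ --
the operational form of the "spread perpendicular to the diagonal" in a
reporter-vs-reporter plot; the theory writes no estimator itself, so the
package adopts this standard one -- must agree with it. Three facts the
package's tests verify:

* The total noise is **non-monotonic** in diffusion: it rises from
  $\eta^2(0) = \tilde\alpha/(\tilde\beta(1+\tilde\alpha+\tilde\beta))$,
  peaks near $\tilde D \approx 94$ for $\gamma_2$ at a value
  $\approx 2.07 > 1$ (dispersion exceeding the mean), and decays. The
  initial slope $\eta^2(0)\,(1 - 1/(1+\tilde\alpha+\tilde\beta))$ is
  positive for any finite switching rates: the rise is a pure consequence
  of the *colored* character of the transcriptional noise. In the
  fast-switching (white-noise) limit $(\tilde\alpha,\tilde\beta) \to
  \kappa(\tilde\alpha,\tilde\beta)$, $\kappa\to\infty$, the slope decays
  like $1/\kappa$ to zero. Note that the squared *coefficient of
  variation* remains non-monotonic at any finite $\kappa$ (the rise factor
  $(1+\tilde D+\tilde DNr)^2/((1+\tilde D)(1+\tilde DNr)^2)$ does not
  involve the switching scale); it is the stationary *variance*,
  $s(1-s)/((1+\tilde D)(1+\tilde D+\tilde\alpha+\tilde\beta))$ with
  $s=\tilde\beta/(\tilde\alpha+\tilde\beta)$, that decreases monotonically
  with diffusion. The tests assert exactly these statements.
* At $\tilde D = 0$ an exact oracle exists: conditioned on the mRNA path
  the counts are Poisson, so $\eta^2_{\mathrm{tot}} = 1/\bar n +
  \eta^2_{\mathrm{tran}}$ exactly ($\approx 0.0443 + 0.1429$ at the 25 nM
  operating point). The simulated total must match it within 3 SE.
* The intrinsic component stays at the copy-number floor $\sim 1/\bar n$
  across the whole grid (its regression slope against $\tilde D$ is
  consistent with zero), because the calibration holds the mean count
  fixed. Diffusion does **not** amplify molecular noise; it only
  redistributes the transcriptional component.

The desk-scale grid is $\tilde D \in \{0, 1, 10, 10^2, 10^3\}$ with 8
replicates of 2250 min (250 min discarded): event rates grow linearly with
$\tilde D$, and this grid resolves the whole non-monotonic structure while
keeping a full scan in minutes on one core. The far tail
($\tilde D$ up to $5\times 10^4$, where the support narrows so far below
the molecular-noise scale that simulated histograms show a single
effective peak even though the analytic class is still interior-minimum)
is reachable by passing a larger grid and longer runs explicitly.

## What the generator does and does not emulate

All experiments are generated in-house: the model itself is the data
generator, at the parameter values above. Passing tests therefore show
that the implementation realises this model and its closed-form theory --
not that the model captures any particular organism. Real populations add,
at least: cell-to-cell parameter variability, growth and division (here
absorbed into $k_-$ as an effective dilution), intermediate synthesis
steps (which would raise the intrinsic-noise floor), autoinduction
feedback above threshold, receptor-side detection noise, and spatial
structure. Within the model, the known approximations are the
quasi-steady-state pool closure (best at large $\tilde D$, where it is
also least needed) and the mean-field constancy of the influx term; both
enter the analytics only -- the Gillespie engine samples the full finite-N
master equation exactly, which is precisely why the decomposition
experiment is informative.

## Worked example

```{r example, eval = FALSE}
m <- qs_preset("gamma2", D_t = 100)
summary(m)

runs <- ssa_replicates(m, t_end = 2250, t_burn = 250, replicates = 8,
                       seed = 1)
tot <- total_noise(runs)
tot
intrinsic_by_decomposition(tot)

sc <- diffusion_scan("gamma2", D_t_grid = c(0, 1, 10, 100, 1000),
                     replicates = 8, seed = 1)
sc
plot(sc)
```

## Known limitations

* The low-expression constraint $\alpha > 2\beta$ is advisory (a warning):
  the stationary formulas hold outside it, but the "one transcript at a
  time" interpretation does not.
* `effective_diffusion_from_active_transport()` maps active transport onto
  the passive model only when $D_\mathrm{in}/D_\mathrm{out} \approx r$;
  far from that condition the validity flag is false and the mapping is a
  rough guide at best.
* Quadrature of the density is unreliable beyond $\tilde D \sim 2000$
  (endpoint singularities); use the closed-form moments there.
* The dual-reporter estimator assumes exchangeable reporters; asymmetric
  reporter kinetics are out of scope.
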