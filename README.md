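# qsnoise

Stochastic modelling of autoinducer noise in quorum-sensing (QS) bacterial
populations **below the activation threshold**.

Bacteria such as *Vibrio fischeri* count their own density by producing,
exchanging and detecting a small diffusible signalling molecule (an
acyl-homoserine-lactone autoinducer). Near the activation threshold the
synthase gene is expressed constitutively at very low level — at most one
mRNA per cell at a time — so the autoinducer concentration fluctuates under
two distinct noise sources: the **telegraph switching** of the transcript
(colored "transcriptional" noise with correlation time
τ<sub>c</sub> = 1/(α+β)) and the **molecular shot noise** of low copy
numbers ("intrinsic" noise). `qsnoise` is for researchers who want to
quantify how membrane diffusion reshapes these fluctuations — e.g. when
designing synthetic circuits that communicate through a QS module.

## The model

For each of N cells coupled to one well-stirred extracellular pool:

```
M0 <-> M1            (beta on, alpha off: telegraph mRNA, 0 or 1 copy)
M1  -> M1 + A        (k+ : synthesis while a transcript is present)
A   -> 0,  Aext -> 0 (k- : degradation/dilution, inside and outside)
A  <-> Aext          (D out, r*D in: exchange with the shared pool)
```

The package provides, side by side:

- an **exact Gillespie simulator** of the full network (`ssa_run()`),
  including a dual-reporter variant (`ssa_run_dual()`) in which two
  distinguishable reporters share one transcript;
- the **closed-form stationary theory** of the reduced (shot-noise-free)
  model: on the transform x = k<sup>eff</sup>c − k₊<sup>eff</sup> the
  stationary law is Beta(β̃/k<sup>eff</sup>, α̃/k<sup>eff</sup>) with
  k<sup>eff</sup> = 1 + D̃, giving density, support (width 1/(1+D̃)),
  mean, shape classification and the transcriptional noise
  η²<sub>tran</sub> = α̃(1+D̃+D̃Nr)² / [β̃(1+D̃)(1+D̃Nr)²(1+D̃+α̃+β̃)]
  (`stationary_density()`, `transcriptional_noise()`, `classify_shape()`);
- a **piecewise-deterministic (PDMP) simulator** of the reduced equation
  (`pdmp_run()`), exact between switches, as the intrinsic-noise-free
  cross-check;
- the **noise decomposition** η²<sub>tot</sub> = η²<sub>int</sub> +
  η²<sub>tran</sub> and the diffusion-scan experiment (`diffusion_scan()`,
  `intrinsic_by_decomposition()`, `intrinsic_dual_reporter()`).

The central scientific result the package reproduces: total autoinducer
noise is **non-monotonic in the diffusion rate** — it rises (a consequence
of the colored mRNA noise), peaks near D̃ ≈ 94 for the γ₂ parameter set at
η² ≈ 2.07 (> 1: dispersion exceeding the mean), then decays — while the
intrinsic component stays pinned at the copy-number floor 1/n̄ when the
mean is held at the 25 nM operating point.

## Worked example

```r
library(qsnoise)

m <- qs_preset("gamma2", D_t = 100)   # (alpha_t, beta_t) = (15, 5)
m
#> Quorum-sensing noise model (preset gamma2)
#>   cells N = 100, r = 1e-05 (sensing potential nu = 1000), V = 1.5 um^3
#>   rates [1/min]: alpha = 0.3, beta = 0.1, k- = 0.02, D = 2
#>   k+ = 166.047 molecules/min (calibrated to <cA> = 25 nM, nbar = 22.58 molecules)
#>   dimensionless: alpha_t = 15, beta_t = 5, D_t = 100, k_eff = 101
#>   mRNA correlation time tau_c = 2.5 min; low-expression regime: TRUE

stationary_density(m)
#> Stationary density of the reduced quorum-sensing model
#>   alpha_t = 15, beta_t = 5, D_t = 100, N*r = 0.001
#>   mean <c~A> = 0.00272008, support [0.000244832, 0.0101458] (width 1/(1+D_t) = 0.00990099)
#>   Beta exponents (a, b) = (0.049505, 0.148515); shape: interior_min
```

The `interior_min` class means a bimodal (bistable) concentration: at
D̃ = 100 the cell alternates between a diffusion-fed low state and a
high state during transcription bursts. The calibrated `k_plus` has risen
from 1.81 to 166 molecules/min to hold the 25 nM mean against the leakage.

```r
sc <- diffusion_scan("gamma2", D_t_grid = c(0, 1, 10, 100, 1000),
                     replicates = 8, seed = 1)
sc
#> Diffusion scan (ssa engine, 8 replicates/point, base seed 1)
#>  D_t eta2_total eta2_total_se eta2_tran eta2_int eta2_int_se n_reps seed0
#>    0    0.18847     0.0017595   0.14286 0.045617   0.0017595      8     1
#>    1    0.31837     0.0020551   0.27245 0.045919   0.0020551      8  1001
#>   10    1.08915     0.0044980   1.04544 0.043716   0.0044980      8  2001
#>  100    2.11483     0.0084533   2.07363 0.041196   0.0084533      8  3001
#> 1000    0.78312     0.0021074   0.73678 0.046343   0.0021074      8  4001
#> intrinsic-noise slope vs D_t: 1.89e-06 +/- 2.6e-06 (OLS); total-noise argmax on grid: D_t = 100
```

Read the table column-wise: `eta2_total` (simulation) is non-monotonic and
tracks `eta2_tran` (closed form) over the whole grid, while `eta2_int` =
total − transcriptional stays flat at ≈ 0.044 ≈ 1/n̄ — diffusion does not
amplify molecular noise, and the OLS slope of the intrinsic column is
consistent with zero.

At D̃ = 0 an exact oracle is available (conditioned on the mRNA path the
counts are Poisson): η²<sub>tot</sub> = 1/n̄ + 1/7 ≈ 0.1871, which the
first row reproduces within its standard error.

See `vignettes/qsnoise-methods.Rmd` for the full model description,
parameter rationale and numerical choices.

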