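#' Piecewise-deterministic simulation of the reduced model
#'
#' Simulates the dimensionless reduced equation
#' `dc/dt = m(t) + k_plus_eff - k_eff * c`, with `m(t)` the telegraph
#' process, as a piecewise-deterministic Markov process: exponential
#' waiting times between switches and *closed-form* exponential relaxation
#' in between, with moments accumulated as exact integrals of every
#' segment. There is no ODE solver and hence no discretisation error; the
#' only randomness is the switching. Because molecular discreteness is
#' absent, this engine realises exactly the law whose density, mean and
#' noise the analytics module gives in closed form, and is the
#' intrinsic-noise-free counterpart of [ssa_run()].
#'
#' The mean-field influx `k_plus_eff` is held constant during a run at the
#' stationary self-consistent value (closed form or fixed-point solver,
#' per `mean_mode`), matching the closure under which the stationary
#' density is derived.
#'
#' @param x a `"qs_model"`, `"qs_dimless"`, or `"qs_density"`.
#' @param t_end total dimensionless simulated time.
#' @param t_burn discarded transient (default `20 * max(1, tau_c_t)`).
#' @param seed integer seed or `NULL`.
#' @param mean_mode `"analytic"` (closed-form mean) or `"self_consistent"`
#'   (fixed-point solver).
#' @param thin_dt optional sampling interval for recorded values of `c`
#'   (used by [pdmp_density_check()]; choose at least
#'   `5 * max(1/k_eff, 1/(alpha_t+beta_t))` for effectively independent
#'   samples).
#' @return An object of class `"qs_pdmp"` with `mean_c`, `var_c`, `eta2`
#'   (squared CV), `occupancy`, `n_switch`, the thinned `samples`, and the
#'   underlying `"qs_density"`.
#' @examples
#' \donttest{
#' p <- pdmp_run(qs_preset("gamma2", D_t = 1), t_end = 5000, seed = 1)
#' p$eta2 # close to transcriptional_noise(15, 5, 1, Nr = 1e-3)
#' }
#' @export
pdmp_run <- function(x, t_end, t_burn = NULL, seed = NULL,
                     mean_mode = c("analytic", "self_consistent"),
                     thin_dt = NA) {
  mean_mode <- match.arg(mean_mode)
  d <- if (inherits(x, "qs_density")) x else
    stationary_density(x, mean_mode = mean_mode)
  at <- d$alpha_t; bt <- d$beta_t
  if (is.null(t_burn))
    t_burn <- 20 * max(1, if (at + bt > 0) 1 / (at + bt) else 1)
  if (!(t_end > t_burn) || t_burn < 0) stop("need t_end > t_burn >= 0")
  if (!is.null(seed)) set.seed(seed)
  m0 <- if (at + bt > 0) stats::rbinom(1, 1, bt / (at + bt)) else 0L
  raw <- .pdmp_core(at, bt, d$k_eff, d$k_plus_eff, as.integer(m0), d$mean,
                    t_burn, t_end,
                    if (is.na(thin_dt)) NA_real_ else thin_dt)
  mean_c <- raw$int_c / raw$T
  var_c <- raw$int_c2 / raw$T - mean_c^2
  structure(list(
    mean_c = mean_c, var_c = var_c, eta2 = var_c / mean_c^2,
    occupancy = raw$occ / raw$T, n_switch = raw$n_switch,
    samples = raw$samples, T_window = raw$T,
    t_burn = t_burn, t_end = t_end, seed = seed, density = d
  ), class = "qs_pdmp")
}

#' Goodness of fit of PDMP samples against the closed-form law
#'
#' Kolmogorov--Smirnov sup-distance between the empirical CDF of thinned
#' PDMP samples and the closed-form stationary CDF (the regularised
#' incomplete Beta function of the transformed variable). A correct engine
#' drives the distance to zero as the sample grows; at `n = 1e4`
#' effectively independent samples it should sit below the 1% critical
#' value `1.628/sqrt(n)`.
#'
#' @param d a `"qs_density"`.
#' @param samples numeric vector of (effectively independent) stationary
#'   samples, at least `min_n` of them.
#' @param min_n minimum sample size accepted.
#' @return list with `statistic` (the KS distance), `n`, and `crit_1pct`.
#' @export
pdmp_density_check <- function(d, samples, min_n = 1e4) {
  stopifnot(inherits(d, "qs_density"))
  n <- length(samples)
  if (n < min_n)
    stop(sprintf("need at least %g samples, got %d", min_n, n))
  s <- sort(samples)
  Fs <- pstationary(s, d)
  ks <- max(pmax(seq_len(n) / n - Fs, Fs - (seq_len(n) - 1) / n))
  list(statistic = ks, n = n, crit_1pct = 1.628 / sqrt(n))
}

#' @export
print.qs_pdmp <- function(x, ...) {
  cat(sprintf("PDMP run: %.0f switches, window %.6g (dimensionless time)\n",
              x$n_switch, x$T_window))
  cat(sprintf("  mean = %.6g (closed form %.6g), eta2 = %.6g, occupancy = %.4g\n",
              x$mean_c, x$density$mean, x$eta2, x$occupancy))
  invisible(x)
}
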