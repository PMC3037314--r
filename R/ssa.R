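#' Draw an initial state for the stochastic simulator
#'
#' `"stationary_guess"` samples each telegraph state from its stationary
#' Bernoulli occupancy `beta/(alpha+beta)`, each intracellular count from a
#' Poisson at the calibrated stationary mean, and the external pool from a
#' Poisson at the quasi-steady-state level, which removes most of the
#' burn-in transient. `"zeros"` starts every count at zero.
#'
#' @param model a `"qs_model"`.
#' @param mode `"stationary_guess"` or `"zeros"`.
#' @param dual if `TRUE`, lay out two reporters (paired counts, separate
#'   external pools).
#' @return list with integer vector `M` (length `N`), count matrix `A`
#'   (`N` x reporters) and external pool vector `Aext`.
#' @export
initial_state <- function(model, mode = c("stationary_guess", "zeros"),
                          dual = FALSE) {
  stopifnot(inherits(model, "qs_model"))
  mode <- match.arg(mode)
  n_rep <- if (dual) 2L else 1L
  N <- model$N
  if (mode == "zeros") {
    return(list(M = integer(N), A = matrix(0, N, n_rep),
                Aext = numeric(n_rep)))
  }
  d <- dimensionless(model)
  occ <- if (model$alpha + model$beta > 0)
    model$beta / (model$alpha + model$beta) else 0
  lam <- model$k_plus / model$k_minus *
    mean_dimensionless(d$alpha_t, d$beta_t, d$D_t, d$Nr)
  mean_nM <- concentration_from_molecules(lam, model$V)
  ext_nM <- suppressMessages(
    external_qss_concentration(mean_nM, d$D_t, model$N, model$r))
  lam_ext <- molecules_from_concentration(ext_nM, model$V / model$r)
  list(M = stats::rbinom(N, 1L, occ),
       A = matrix(stats::rpois(N * n_rep, lam), N, n_rep),
       Aext = as.numeric(stats::rpois(n_rep, lam_ext)))
}

# default burn-in: 20x the slowest relaxation scale (1/k- = 50 min for the
# standard parameterisation)
default_burn_in <- function(model) {
  20 * max(1 / model$k_minus, model$tau_c,
           1 / (model$k_minus + model$D))
}

#' Exact Gillespie simulation of the multicellular network
#'
#' Direct-method stochastic simulation of the full reaction network
#' (telegraph mRNA, synthesis, degradation, membrane exchange with the
#' shared pool, external degradation) for `N` cells. Pool influx is
#' implemented as one lumped channel of propensity `N*r*D*Aext` with a
#' uniform destination draw, which has the identical master equation to `N`
#' per-cell channels. All stationary statistics are exact time-weighted
#' integrals of the piecewise-constant trajectory over `(t_burn, t_end]`;
#' nothing is estimated from grid samples, so there is no discretisation
#' bias in the reported moments.
#'
#' @param model a `"qs_model"`.
#' @param t_end total simulated time, min.
#' @param t_burn discarded transient, min; default
#'   `20 * max(1/k_minus, tau_c, 1/(k_minus + D))`.
#' @param seed integer seed (`set.seed`) or `NULL` to continue the current
#'   RNG stream.
#' @param init `"stationary_guess"`, `"zeros"`, or a state list as returned
#'   by [initial_state()].
#' @param dual if `TRUE` run the dual-reporter variant: both reporters are
#'   synthesised from the same transcript and the exchange/degradation
#'   reactions are doubled, with separate external pools.
#' @param thin_dt optional recording interval (min) for a thinned trajectory
#'   of one cell (analysis never uses it; it is for inspection/plots only).
#' @param thin_cell 1-based index of the recorded cell.
#' @param max_events safety cap on the number of reaction events.
#' @return An object of class `"qs_sim"`; see Details.
#' @details The returned object contains the pooled (across cells and
#'   stationary time) per-cell statistics: `mean_count`/`mean_nM`,
#'   `var_count`, `eta2_total = var/mean^2`, mRNA `occupancy`, external pool
#'   mean, the cross-cell covariance of counts, and for dual runs the paired
#'   means, cross moment `<A1*A2>` and squared-difference moment used by the
#'   dual-reporter intrinsic-noise estimator. The final state, event count,
#'   seed and a parameter echo are included so a run can be reproduced or
#'   extended; `absorbed` flags an early stop in an absorbing state (zero
#'   total propensity, e.g. `beta = 0` with all counts zero).
#' @examples
#' \donttest{
#' m <- qs_preset("gamma2", D_t = 0)
#' run <- ssa_run(m, t_end = 1500, seed = 1)
#' run
#' }
#' @export
ssa_run <- function(model, t_end, t_burn = NULL, seed = NULL,
                    init = "stationary_guess", dual = FALSE,
                    thin_dt = NA, thin_cell = 1L, max_events = 2e10) {
  stopifnot(inherits(model, "qs_model"))
  if (is.null(t_burn)) t_burn <- default_burn_in(model)
  if (!(t_end > t_burn) || t_burn < 0)
    stop("need t_end > t_burn >= 0")
  if (!is.null(seed)) set.seed(seed)
  state <- if (is.list(init)) init else initial_state(model, init, dual = dual)
  n_rep <- ncol(state$A)

  raw <- .ssa_core(model$alpha, model$beta, model$k_plus, model$k_minus,
                   model$D, model$r, model$N, n_rep,
                   as.integer(state$M), as.matrix(state$A) * 1.0,
                   as.numeric(state$Aext),
                   t_burn, t_end,
                   if (is.na(thin_dt)) NA_real_ else thin_dt,
                   as.integer(thin_cell) - 1L, max_events)

  N <- model$N
  Tw <- raw$T
  mean_count <- raw$accA / (Tw * N)
  mean2 <- raw$accA2 / (Tw * N)
  var_count <- mean2 - mean_count^2
  nM_per_molecule <- concentration_from_molecules(1, model$V)
  pair <- raw$accPair / (Tw * N * (N - 1))
  out <- list(
    mean_count = mean_count,
    var_count = var_count,
    mean_nM = mean_count * nM_per_molecule,
    eta2_total = var_count[1] / mean_count[1]^2,
    occupancy = raw$accM / (Tw * N),
    ext_mean_count = raw$accExt / Tw,
    cross_cell_cov = pair - mean_count[1]^2,
    dual = n_rep == 2L,
    t_burn = t_burn, t_end = t_end, T_window = Tw,
    n_events = raw$n_events, absorbed = raw$absorbed,
    seed = seed, model = model,
    final_state = list(M = raw$M_final, A = raw$A_final,
                       Aext = raw$Aext_final, t = raw$t_final)
  )
  if (n_rep == 2L) {
    out$cross_moment <- raw$accCross / (Tw * N)       # <A1 A2> per cell
    out$diff2_moment <- raw$accDiff2 / (Tw * N)       # <(A1 - A2)^2>
  }
  if (!is.na(thin_dt) && length(raw$thin)) {
    tr <- as.data.frame(raw$thin)
    tr$cA_nM <- tr$A1 * nM_per_molecule
    tr$cell_id <- as.integer(thin_cell)
    out$trajectory <- tr
  }
  if (out$absorbed)
    message("run reached an absorbing state (zero total propensity); ",
            "remaining time accumulated at the frozen state")
  class(out) <- "qs_sim"
  out
}

#' @rdname ssa_run
#' @export
ssa_run_dual <- function(model, t_end, t_burn = NULL, seed = NULL, ...) {
  ssa_run(model, t_end, t_burn = t_burn, seed = seed, dual = TRUE, ...)
}

#' Replicate stochastic runs with sequential seeds
#'
#' Runs `replicates` independent simulations seeded `seed + 0, 1, ...`
#' (one RNG stream per replicate) and returns the list of `"qs_sim"`
#' results. Downstream estimators ([total_noise()] etc.) take such lists
#' and report the across-replicate standard error.
#'
#' @inheritParams ssa_run
#' @param replicates number of independent runs.
#' @param seed base seed; replicate `i` uses `seed + i - 1`.
#' @param ... passed to [ssa_run()].
#' @export
ssa_replicates <- function(model, t_end, replicates = 8, seed = 1, ...) {
  lapply(seq_len(replicates) - 1L,
         function(i) ssa_run(model, t_end, seed = seed + i, ...))
}

#' @export
print.qs_sim <- function(x, ...) {
  cat(sprintf("Gillespie run%s: N = %d cells, %.0f events, window %.6g min (burn-in %.6g)\n",
              if (x$dual) " (dual reporter)" else "", x$model$N,
              x$n_events, x$T_window, x$t_burn))
  cat(sprintf("  pooled mean = %.6g molecules/cell (%.6g nM), eta2_total = %.6g\n",
              x$mean_count[1], x$mean_nM[1], x$eta2_total))
  cat(sprintf("  mRNA occupancy = %.4g, external pool mean = %.6g molecules\n",
              x$occupancy, x$ext_mean_count[1]))
  if (x$dual)
    cat(sprintf("  reporter means = (%.6g, %.6g), <(A1-A2)^2> = %.6g\n",
                x$mean_count[1], x$mean_count[2], x$diff2_moment))
  if (x$absorbed) cat("  [absorbing state reached]\n")
  invisible(x)
}
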