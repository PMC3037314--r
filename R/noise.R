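#' Total noise of the autoinducer concentration
#'
#' Squared coefficient of variation (variance over squared mean) of the
#' pooled per-cell concentration, from one run or a list of replicate runs
#' ([ssa_replicates()] or repeated [pdmp_run()]). With replicates, the
#' estimate is the across-replicate mean and the uncertainty its standard
#' error; a single run reports `se = NA`.
#'
#' @param run a `"qs_sim"`, a `"qs_pdmp"`, or a list of either.
#' @return An object of class `"qs_noise"`: `eta2`, `se`, `source`
#'   (`"ssa_total"` or `"pdmp_total"`), `n_reps`, and a parameter echo.
#' @export
total_noise <- function(run) {
  runs <- if (inherits(run, c("qs_sim", "qs_pdmp"))) list(run) else run
  is_ssa <- inherits(runs[[1]], "qs_sim")
  eta <- vapply(runs, function(r) {
    m <- if (is_ssa) r$mean_count[1] else r$mean_c
    if (!is.finite(m) || m <= 0) stop("zero mean: noise undefined")
    if (is_ssa) r$eta2_total else r$eta2
  }, numeric(1))
  structure(list(
    eta2 = mean(eta), se = if (length(eta) > 1) stats::sd(eta) / sqrt(length(eta)) else NA_real_,
    per_replicate = eta, n_reps = length(eta),
    source = if (is_ssa) "ssa_total" else "pdmp_total",
    model = if (is_ssa) runs[[1]]$model else NULL,
    density = if (is_ssa) NULL else runs[[1]]$density,
    seeds = vapply(runs, function(r) r$seed %||% NA_real_, numeric(1))
  ), class = "qs_noise")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Intrinsic noise by analytic decomposition
#'
#' The total noise splits into intrinsic (molecular shot noise) and
#' transcriptional (mRNA-switching) components,
#' `eta2_total = eta2_int + eta2_tran`. Subtracting the closed-form
#' transcriptional noise from a simulated total gives the intrinsic
#' component. The standard error is inherited from the total (the
#' subtracted term is exact). A negative estimate within two standard
#' errors of zero is ordinary sampling fluctuation; a more negative value
#' is flagged.
#'
#' @param total a `"qs_noise"` built from SSA runs (must carry the model).
#' @param model optional `"qs_model"` to check against the echo in `total`;
#'   an inconsistent model is an error.
#' @return A `"qs_noise"` with `source = "decomposition_intrinsic"`.
#' @export
intrinsic_by_decomposition <- function(total, model = NULL) {
  stopifnot(inherits(total, "qs_noise"))
  if (is.null(total$model) && is.null(total$density))
    stop("decomposition needs a total-noise estimate with a parameter echo")
  if (!is.null(model) && !is.null(total$model) &&
      !isTRUE(all.equal(coef(model), coef(total$model))))
    stop("mismatched parameters between noise estimate and model")
  m <- total$model
  d <- if (!is.null(m)) dimensionless(m) else total$density
  tran <- transcriptional_noise(d$alpha_t, d$beta_t, d$D_t, Nr = d$Nr)
  eta2 <- total$eta2 - tran
  flagged <- is.finite(total$se) && eta2 < 0 && abs(eta2) > 2 * total$se
  if (flagged)
    warning("intrinsic estimate negative beyond 2 SE; check stationarity",
            call. = FALSE)
  structure(list(eta2 = eta2, se = total$se, eta2_tran = tran,
                 per_replicate = total$per_replicate - tran,
                 n_reps = total$n_reps,
                 source = "decomposition_intrinsic", model = m,
                 flagged = flagged, seeds = total$seeds),
            class = "qs_noise")
}

#' Intrinsic noise from a dual-reporter experiment
#'
#' Two distinguishable reporters synthesised from the same transcript share
#' all extrinsic (here: transcriptional) fluctuations; their squared
#' difference isolates the intrinsic component. The estimator is the
#' standard `<(c1 - c2)^2> / (2 <c1> <c2>)`, the operational form of the
#' "spread perpendicular to the diagonal" in a reporter-vs-reporter
#' density plot. Concentration scaling cancels, so counts are used
#' directly.
#'
#' @param run a dual-reporter `"qs_sim"` or list of them.
#' @return A `"qs_noise"` with `source = "dual_reporter_intrinsic"`.
#' @export
intrinsic_dual_reporter <- function(run) {
  runs <- if (inherits(run, "qs_sim")) list(run) else run
  eta <- vapply(runs, function(r) {
    if (!isTRUE(r$dual)) stop("not a dual-reporter run")
    m1 <- r$mean_count[1]; m2 <- r$mean_count[2]
    if (m1 <= 0 || m2 <= 0) stop("zero mean: noise undefined")
    r$diff2_moment / (2 * m1 * m2)
  }, numeric(1))
  structure(list(
    eta2 = mean(eta), se = if (length(eta) > 1) stats::sd(eta) / sqrt(length(eta)) else NA_real_,
    per_replicate = eta, n_reps = length(eta),
    source = "dual_reporter_intrinsic", model = runs[[1]]$model,
    seeds = vapply(runs, function(r) r$seed %||% NA_real_, numeric(1))
  ), class = "qs_noise")
}

#' Diffusion-scan experiment
#'
#' Re-runs the stochastic model across a grid of dimensionless diffusion
#' values, recalibrating `k_plus` at every point so the mean concentration
#' stays at the preset's operating target, and tabulates total,
#' transcriptional (closed form) and intrinsic (by decomposition) noise
#' with replicate standard errors. This is the experiment exhibiting the
#' non-monotonic total-noise curve: the transcriptional component first
#' grows with diffusion, peaks, then decays, while the intrinsic floor set
#' by the mean copy number stays flat.
#'
#' Replicate `j` at grid point `i` uses seed `seed + 1000*(i-1) + (j-1)`.
#'
#' @param preset preset name passed to [qs_preset()], or a `"qs_model"`
#'   whose rates (except `k_plus`) are reused.
#' @param D_t_grid dimensionless diffusion values (default desk-scale grid
#'   `c(0, 1, 10, 100, 1000)`; event rates grow linearly with `D_t`, so the
#'   far tail of the curve is deliberately left to longer opt-in runs).
#' @param replicates independent runs per grid point.
#' @param seed base seed.
#' @param t_end,t_burn simulation window per run, min.
#' @param engine `"ssa"` (full model) or `"pdmp"` (reduced model; its
#'   intrinsic column is zero up to sampling noise).
#' @param dual also run dual-reporter replicates and add the dual-reporter
#'   intrinsic estimate column.
#' @param ... further arguments to [ssa_run()].
#' @return A `data.frame` of class `"qs_scan"` with columns `D_t`,
#'   `eta2_total`, `eta2_total_se`, `eta2_tran`, `eta2_int`, `eta2_int_se`
#'   (and `eta2_int_dual`, `eta2_int_dual_se` when `dual = TRUE`), plus
#'   attributes `slope`, `slope_se` (OLS fit of `eta2_int` on `D_t`),
#'   `argmax` (grid argmax of `eta2_total`), `seed`, `replicates`.
#' @examples
#' \donttest{
#' sc <- diffusion_scan("gamma2", D_t_grid = c(0, 10), replicates = 4,
#'                      t_end = 700, t_burn = 200, seed = 1)
#' sc
#' }
#' @export
diffusion_scan <- function(preset = "gamma2",
                           D_t_grid = c(0, 1, 10, 100, 1000),
                           replicates = 8, seed = 1,
                           t_end = 2250, t_burn = 250,
                           engine = c("ssa", "pdmp"), dual = FALSE, ...) {
  engine <- match.arg(engine)
  if (length(D_t_grid) == 0) stop("empty diffusion grid")
  ord <- order(D_t_grid)
  D_t_grid <- D_t_grid[ord]
  build <- function(Dt) {
    if (inherits(preset, "qs_model"))
      qs_model(alpha = preset$alpha, beta = preset$beta,
               k_minus = preset$k_minus, D_t = Dt,
               target_mean_nM = if (is.na(preset$target_mean_nM)) 25
                                else preset$target_mean_nM,
               N = preset$N, r = preset$r, V = preset$V)
    else qs_preset(preset, D_t = Dt)
  }
  rows <- vector("list", length(D_t_grid))
  for (i in seq_along(D_t_grid)) {
    Dt <- D_t_grid[i]
    m <- build(Dt)
    d <- dimensionless(m)
    seed_i <- seed + 1000 * (i - 1)
    tran <- transcriptional_noise(d$alpha_t, d$beta_t, d$D_t, Nr = d$Nr)
    if (engine == "ssa") {
      runs <- ssa_replicates(m, t_end, replicates = replicates,
                             seed = seed_i, t_burn = t_burn, ...)
      tot <- total_noise(runs)
      intr <- intrinsic_by_decomposition(tot)
    } else {
      runs <- lapply(seq_len(replicates) - 1L, function(j)
        pdmp_run(m, t_end = t_end * m$k_minus, t_burn = t_burn * m$k_minus,
                 seed = seed_i + j))
      tot <- total_noise(runs)
      intr <- list(eta2 = tot$eta2 - tran, se = tot$se)
    }
    row <- data.frame(D_t = Dt, eta2_total = tot$eta2,
                      eta2_total_se = tot$se, eta2_tran = tran,
                      eta2_int = intr$eta2, eta2_int_se = intr$se,
                      n_reps = replicates, seed0 = seed_i)
    if (dual && engine == "ssa") {
      druns <- ssa_replicates(m, t_end, replicates = replicates,
                              seed = seed_i + 500, t_burn = t_burn,
                              dual = TRUE, ...)
      dint <- intrinsic_dual_reporter(druns)
      row$eta2_int_dual <- dint$eta2
      row$eta2_int_dual_se <- dint$se
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  fit <- if (nrow(out) >= 3) {
    summary(stats::lm(eta2_int ~ D_t, data = out))$coefficients
  } else NULL
  attr(out, "slope") <- if (!is.null(fit)) fit["D_t", "Estimate"] else NA_real_
  attr(out, "slope_se") <- if (!is.null(fit)) fit["D_t", "Std. Error"] else NA_real_
  attr(out, "argmax") <- out$D_t[which.max(out$eta2_total)]
  attr(out, "seed") <- seed
  attr(out, "replicates") <- replicates
  attr(out, "engine") <- engine
  class(out) <- c("qs_scan", "data.frame")
  out
}

#' @export
print.qs_scan <- function(x, ...) {
  cat(sprintf("Diffusion scan (%s engine, %d replicates/point, base seed %s)\n",
              attr(x, "engine"), attr(x, "replicates"), attr(x, "seed")))
  print.data.frame(x, row.names = FALSE, digits = 5)
  cat(sprintf("intrinsic-noise slope vs D_t: %.3g +/- %.3g (OLS); total-noise argmax on grid: D_t = %g\n",
              attr(x, "slope"), attr(x, "slope_se"), attr(x, "argmax")))
  invisible(x)
}

#' @export
plot.qs_scan <- function(x, ...) {
  Dp <- pmax(x$D_t, min(x$D_t[x$D_t > 0]) / 10)
  graphics::plot(Dp, x$eta2_total, log = "xy", pch = 16,
                 xlab = "dimensionless diffusion D_t",
                 ylab = expression(eta^2), ...)
  graphics::lines(Dp, x$eta2_tran)
  graphics::points(Dp, pmax(x$eta2_int, .Machine$double.eps), pch = 0)
  graphics::legend("bottomleft", pch = c(16, NA, 0), lty = c(NA, 1, NA),
                   legend = c("total (simulation)",
                              "transcriptional (closed form)",
                              "intrinsic (decomposition)"), bty = "n")
  invisible(x)
}

#' @export
print.qs_noise <- function(x, ...) {
  cat(sprintf("eta^2 = %.6g%s  [%s, %d replicate%s]\n", x$eta2,
              if (is.finite(x$se)) sprintf(" +/- %.2g (SE)", x$se) else "",
              x$source, x$n_reps, if (x$n_reps == 1) "" else "s"))
  invisible(x)
}

#' Simulate a quorum-sensing model
#'
#' `simulate()` method dispatching to the exact Gillespie engine
#' ([ssa_run()]) or the reduced PDMP engine ([pdmp_run()]). With
#' `nsim > 1`, replicate `i` is seeded `seed + i - 1` and a list is
#' returned.
#'
#' @param object a `"qs_model"`.
#' @param nsim number of replicate runs.
#' @param seed base seed (replicates use `seed + 0:(nsim-1)`).
#' @param engine `"ssa"` or `"pdmp"`.
#' @param t_end simulated time: minutes for the SSA, dimensionless for the
#'   PDMP (default `t_end * k_minus` of the SSA default).
#' @param ... passed to the engine.
#' @return A single run object, or a list of them when `nsim > 1`.
#' @export
simulate.qs_model <- function(object, nsim = 1, seed = 1,
                              engine = c("ssa", "pdmp"), t_end = 2000, ...) {
  engine <- match.arg(engine)
  one <- function(s) switch(engine,
    ssa = ssa_run(object, t_end = t_end, seed = s, ...),
    pdmp = pdmp_run(object, t_end = t_end * object$k_minus, seed = s, ...))
  if (nsim == 1) one(seed) else lapply(seed + seq_len(nsim) - 1L, one)
}
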