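#' Construct a quorum-sensing noise model
#'
#' Defines one instance of the multicellular autoinducer model: `N` cells,
#' each carrying a telegraph mRNA (0 or 1 transcript, switching on at rate
#' `beta` and off at rate `alpha`), synthesising the signalling molecule at
#' rate `k_plus` per transcript, with degradation/dilution `k_minus` acting
#' identically inside and outside the cells, and membrane exchange at rate
#' `D` with a shared extracellular volume `V/r`.
#'
#' If `k_plus` is omitted it is calibrated with [calibrate_k_plus()] so that
#' the stationary mean intracellular concentration equals `target_mean_nM`,
#' the regime of interest being the activation threshold (10--50 nM for most
#' quorum-sensing systems; 25 nM is the default operating point).
#'
#' The model assumes low constitutive expression, `alpha > 2 * beta`, so that
#' at most one transcript is present at a time; violating it only triggers a
#' warning because the stationary formulas remain mathematically valid.
#'
#' @param alpha mRNA degradation (switch-off) rate, 1/min.
#' @param beta transcription (switch-on) rate, 1/min.
#' @param k_minus effective degradation/dilution rate of the autoinducer,
#'   1/min; must be positive. Dominated by the dilution protocol that keeps
#'   the cell density constant (default 2e-2, i.e. a ~50 min cell cycle).
#' @param D membrane exchange (diffusion) rate, 1/min. Give either `D` or
#'   its dimensionless version `D_t = D / k_minus`, not both.
#' @param D_t dimensionless diffusion rate.
#' @param k_plus autoinducer synthesis rate per transcript, molecules/min,
#'   or `NULL` to calibrate from `target_mean_nM`.
#' @param target_mean_nM stationary mean concentration used for calibration
#'   when `k_plus` is `NULL` (nM).
#' @param N number of cells (integer >= 1).
#' @param r ratio of one cell volume to the extracellular volume (> 0).
#' @param V cell volume, um^3.
#' @return An object of class `"qs_model"`: a list of the physical
#'   parameters plus derived quantities `nu = 1/(r*N)` (sensing potential),
#'   `tau_c = 1/(alpha+beta)` (mRNA correlation time, min), `nbar` (target
#'   mean molecule count per cell) and `low_expression`
#'   (`TRUE` iff `alpha > 2*beta`).
#' @seealso [qs_preset()] for the parameter sets used throughout the
#'   package's experiments, [dimensionless()], [simulate.qs_model()].
#' @examples
#' m <- qs_model(alpha = 0.3, beta = 0.1, D_t = 100)
#' m
#' dimensionless(m)
#' @export
qs_model <- function(alpha, beta, k_minus = 0.02, D = NULL, D_t = NULL,
                     k_plus = NULL, target_mean_nM = 25,
                     N = 100, r = 1e-5, V = 1.5) {
  if (!is.null(D) && !is.null(D_t))
    stop("give either `D` or `D_t`, not both")
  if (is.null(D)) {
    if (is.null(D_t)) stop("one of `D` or `D_t` is required")
    D <- D_t * k_minus
  }
  stopifnot(length(alpha) == 1, length(beta) == 1, length(D) == 1,
            length(N) == 1, length(r) == 1, length(V) == 1)
  if (alpha < 0 || beta < 0 || D < 0) stop("rates must be non-negative")
  if (k_minus <= 0) stop("degradation rate must be positive")
  if (N < 1 || N != round(N)) stop("N must be an integer >= 1")
  if (r <= 0) stop("volume ratio r must be positive")
  if (V <= 0) stop("cell volume V must be positive")

  if (is.null(k_plus)) {
    k_plus <- calibrate_k_plus(target_mean_nM, alpha, beta, k_minus, D,
                               N = N, r = r, V = V)
  } else {
    if (k_plus < 0) stop("rates must be non-negative")
    target_mean_nM <- NA_real_
  }

  low <- alpha > 2 * beta
  if (!low)
    warning("alpha <= 2*beta: outside the low-constitutive-expression ",
            "regime (more than one transcript may be present); the closed-",
            "form analytics remain valid", call. = FALSE)

  structure(list(
    alpha = alpha, beta = beta, k_plus = k_plus, k_minus = k_minus,
    D = D, N = as.integer(N), r = r, V = V,
    target_mean_nM = target_mean_nM,
    nu = 1 / (r * N),
    tau_c = if (alpha + beta > 0) 1 / (alpha + beta) else Inf,
    nbar = if (!is.na(target_mean_nM)) {
      molecules_from_concentration(target_mean_nM, V)
    } else if (alpha + beta > 0) {
      k_plus / k_minus * mean_dimensionless(alpha / k_minus, beta / k_minus,
                                            D / k_minus, N * r)
    } else NA_real_,
    low_expression = low
  ), class = "qs_model")
}

# (alpha_t, beta_t) pairs of the standard simulation presets
.qs_presets <- list(gamma1 = c(8, 2), gamma2 = c(15, 5),
                    gamma3 = c(8, 0.5), gamma4 = c(15, 0.5))

#' Named parameter presets
#'
#' The four dimensionless `(alpha_t, beta_t)` operating points used in the
#' package's experiments -- `gamma1 = (8, 2)`, `gamma2 = (15, 5)`,
#' `gamma3 = (8, 0.5)`, `gamma4 = (15, 0.5)` -- combined with the standard
#' population geometry `N = 100`, `r = 1e-5`, `k_minus = 0.02/min`,
#' `V = 1.5 um^3` and a 25 nM calibration target. All satisfy the
#' low-expression constraint `alpha_t > 2 * beta_t` and the biologically
#' motivated `alpha_t > 1` (mRNA half-lives of 2--5 min).
#'
#' @param name one of `"gamma1"`, `"gamma2"`, `"gamma3"`, `"gamma4"`.
#' @param D_t dimensionless diffusion rate (default 0).
#' @param ... overrides passed on to [qs_model()].
#' @return A `"qs_model"` object with `k_plus` calibrated to the target mean.
#' @examples
#' qs_preset("gamma2", D_t = 100)
#' @export
qs_preset <- function(name = c("gamma1", "gamma2", "gamma3", "gamma4"),
                      D_t = 0, ...) {
  name <- match.arg(name)
  g <- .qs_presets[[name]]
  k_minus <- list(...)$k_minus
  if (is.null(k_minus)) k_minus <- 0.02
  args <- list(alpha = g[1] * k_minus, beta = g[2] * k_minus,
               k_minus = k_minus, D_t = D_t)
  extra <- list(...)
  extra$k_minus <- NULL
  m <- do.call(qs_model, c(args, extra))
  m$preset <- name
  m
}

#' Reduce a model to its dimensionless parameters
#'
#' Rates are measured in units of the signalling-molecule lifetime
#' `1/k_minus` and concentrations in units of the single-cell maximum
#' `c_A+ = k_plus / (k_minus * V)` (the level reached under permanent
#' transcription without diffusion). The reduced parameter set
#' `(alpha_t, beta_t, D_t, N*r)` drives every closed-form result in the
#' package; `k_eff = 1 + D_t` is the effective relaxation rate and
#' `k_plus_eff` the effective dimensionless influx from the shared pool at
#' the self-consistent mean.
#'
#' @param x a `"qs_model"` object.
#' @param ... unused.
#' @return An object of class `"qs_dimless"`: list with `alpha_t`, `beta_t`,
#'   `D_t`, `Nr`, `k_eff`, `k_plus_eff`, `c_scale` (molecules per cell
#'   volume, i.e. `k_plus/(k_minus*V)` in nM-equivalent count units), and
#'   the geometry (`N`, `r`, `k_minus`, `V`, `k_plus`) needed to invert.
#' @seealso [from_dimensionless()]
#' @export
dimensionless <- function(x, ...) UseMethod("dimensionless")

#' @export
dimensionless.qs_model <- function(x, ...) {
  at <- x$alpha / x$k_minus
  bt <- x$beta / x$k_minus
  Dt <- x$D / x$k_minus
  Nr <- x$N * x$r
  m <- if (at + bt > 0) mean_dimensionless(at, bt, Dt, Nr) else 0
  structure(list(
    alpha_t = at, beta_t = bt, D_t = Dt, Nr = Nr,
    k_eff = 1 + Dt,
    k_plus_eff = .k_plus_eff(m, Dt, Nr),
    c_scale = x$k_plus / (x$k_minus * x$V),
    N = x$N, r = x$r, k_minus = x$k_minus, V = x$V, k_plus = x$k_plus
  ), class = "qs_dimless")
}

#' Rebuild a physical model from dimensionless parameters
#'
#' Inverse of [dimensionless()]: given the reduced parameters and the
#' dimensional anchors (`k_minus`, `V`, `N`, `k_plus`), recovers the
#' physical model to machine precision.
#'
#' @param d a `"qs_dimless"` object (or list with the same fields).
#' @param k_minus,V,N,k_plus dimensional anchors; default to the values
#'   carried by `d`.
#' @return A `"qs_model"` object.
#' @export
from_dimensionless <- function(d, k_minus = d$k_minus, V = d$V, N = d$N,
                               k_plus = d$k_plus) {
  if (is.null(k_minus) || k_minus <= 0)
    stop("degradation rate must be positive")
  qs_model(alpha = d$alpha_t * k_minus, beta = d$beta_t * k_minus,
           k_minus = k_minus, D = d$D_t * k_minus, k_plus = k_plus,
           N = N, r = d$Nr / N, V = V)
}

#' Calibrate the synthesis rate to a target mean concentration
#'
#' Solves the closed-form stationary mean for `k_plus`: the mean molecule
#' count per cell is `k_plus/k_minus` times the dimensionless mean, so
#' `k_plus = nbar * k_minus / mean_dimensionless(...)` with `nbar` the
#' molecule count equivalent to `target_mean_nM` in volume `V`. Because the
#' dimensionless mean decreases with diffusion, keeping the operating point
#' fixed across a diffusion scan requires recalibrating at every `D`.
#'
#' @param target_mean_nM desired stationary mean concentration, nM (> 0).
#' @param alpha,beta,k_minus,D physical rates, 1/min.
#' @param N,r,V population geometry as in [qs_model()].
#' @return `k_plus` in molecules/min.
#' @examples
#' # no diffusion: mean is beta_t/(alpha_t+beta_t) = 0.25
#' calibrate_k_plus(25, 0.3, 0.1, 0.02, D = 0) # ~1.81
#' @export
calibrate_k_plus <- function(target_mean_nM, alpha, beta, k_minus, D,
                             N = 100, r = 1e-5, V = 1.5) {
  if (k_minus <= 0) stop("degradation rate must be positive")
  if (target_mean_nM <= 0) stop("target mean must be positive")
  if (beta <= 0) stop("mean autoinducer level is zero; cannot calibrate")
  nbar <- molecules_from_concentration(target_mean_nM, V)
  m <- mean_dimensionless(alpha / k_minus, beta / k_minus, D / k_minus, N * r)
  nbar * k_minus / m
}

#' Map active transport onto the passive-diffusion model
#'
#' The model's exchange reactions describe transport driven by concentration
#' differences. Active import/export at rates `D_in`/`D_out` is nevertheless
#' well described by the same equations with `D = D_out`, provided the rate
#' ratio matches the volume ratio, `D_in/D_out ~ r`. This helper returns
#' `D_out` together with a validity flag for that condition.
#'
#' @param D_in active import rate, 1/min.
#' @param D_out active export rate, 1/min (> 0).
#' @param r cell-to-external volume ratio.
#' @param tol_factor the mapping is flagged valid when `D_in/D_out` lies
#'   within a factor `tol_factor` of `r` (default 10).
#' @return list with `D` (= `D_out`), `valid`, and `mismatch`
#'   (`(D_in/D_out)/r`, 1 meaning a perfect match).
#' @examples
#' effective_diffusion_from_active_transport(1e-3, 1e-1, r = 1e-2)
#' @export
effective_diffusion_from_active_transport <- function(D_in, D_out, r,
                                                      tol_factor = 10) {
  if (D_in < 0 || D_out < 0) stop("rates must be non-negative")
  if (D_out == 0) stop("D_out must be positive")
  mismatch <- (D_in / D_out) / r
  valid <- mismatch <= tol_factor && mismatch >= 1 / tol_factor
  message(sprintf(
    "active-transport mapping: D = D_out = %g/min, D_in/D_out = %g vs r = %g (ratio %g, %s)",
    D_out, D_in / D_out, r, mismatch, if (valid) "valid" else "outside tolerance"))
  list(D = D_out, valid = valid, mismatch = mismatch)
}

#' @export
print.qs_model <- function(x, ...) {
  d <- dimensionless(x)
  cat("Quorum-sensing noise model",
      if (!is.null(x$preset)) sprintf("(preset %s)", x$preset) else "", "\n")
  cat(sprintf("  cells N = %d, r = %g (sensing potential nu = %g), V = %g um^3\n",
              x$N, x$r, x$nu, x$V))
  cat(sprintf("  rates [1/min]: alpha = %g, beta = %g, k- = %g, D = %g\n",
              x$alpha, x$beta, x$k_minus, x$D))
  cat(sprintf("  k+ = %g molecules/min%s\n", x$k_plus,
              if (!is.na(x$target_mean_nM))
                sprintf(" (calibrated to <cA> = %g nM, nbar = %.4g molecules)",
                        x$target_mean_nM, x$nbar) else ""))
  cat(sprintf("  dimensionless: alpha_t = %g, beta_t = %g, D_t = %g, k_eff = %g\n",
              d$alpha_t, d$beta_t, d$D_t, d$k_eff))
  cat(sprintf("  mRNA correlation time tau_c = %g min; low-expression regime: %s\n",
              x$tau_c, x$low_expression))
  invisible(x)
}

#' @export
coef.qs_model <- function(object, ...) {
  c(alpha = object$alpha, beta = object$beta, k_plus = object$k_plus,
    k_minus = object$k_minus, D = object$D)
}

#' @export
summary.qs_model <- function(object, ...) {
  d <- dimensionless(object)
  dens <- stationary_density(object)
  out <- list(model = object, dimless = d, density = dens,
              eta2_tran = transcriptional_noise(d$alpha_t, d$beta_t, d$D_t,
                                                Nr = d$Nr))
  class(out) <- "summary.qs_model"
  out
}

#' @export
print.summary.qs_model <- function(x, ...) {
  print(x$model)
  cat("\nStationary law of the reduced model:\n")
  print(x$density)
  cat(sprintf("transcriptional noise eta^2_tran = %.6g\n", x$eta2_tran))
  invisible(x)
}

#' @export
print.qs_dimless <- function(x, ...) {
  cat("Dimensionless quorum-sensing parameters\n")
  cat(sprintf("  alpha_t = %g, beta_t = %g, D_t = %g, N*r = %g\n",
              x$alpha_t, x$beta_t, x$D_t, x$Nr))
  cat(sprintf("  k_eff = %g, k_plus_eff = %g, concentration scale c_A+ = %g\n",
              x$k_eff, x$k_plus_eff, x$c_scale))
  invisible(x)
}
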