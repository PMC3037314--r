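#' Closed-form stationary mean of the reduced model
#'
#' The self-consistent stationary mean of the dimensionless autoinducer
#' concentration,
#' \deqn{\langle \tilde c_A \rangle = \frac{1 + \tilde D N r}{1 + \tilde D N r + \tilde D}\,
#'       \frac{\tilde\beta}{\tilde\alpha + \tilde\beta},}
#' which reduces to the telegraph occupancy `beta_t/(alpha_t+beta_t)` without
#' diffusion and decreases strictly with `D_t`: diffusion dilutes the signal
#' into the shared pool, of which only the fraction set by `N*r` returns.
#'
#' @param alpha_t,beta_t dimensionless switching rates (`alpha_t+beta_t > 0`).
#' @param D_t dimensionless diffusion rate.
#' @param Nr product of cell number and volume ratio, `N * r`.
#' @return the dimensionless mean, in `[0, beta_t/(alpha_t+beta_t)]`.
#' @export
mean_dimensionless <- function(alpha_t, beta_t, D_t, Nr) {
  if (any(alpha_t + beta_t <= 0))
    stop("alpha_t + beta_t must be positive")
  if (any(c(alpha_t, beta_t, D_t, Nr) < 0))
    stop("dimensionless parameters must be non-negative")
  DNr <- D_t * Nr
  (1 + DNr) / (1 + DNr + D_t) * beta_t / (alpha_t + beta_t)
}

# effective dimensionless influx from the shared pool, given the mean:
# k+eff(m) = m * D_t / (1 + 1/(N*D_t*r)) = m * D_t^2 * Nr / (1 + D_t*Nr)
.k_plus_eff <- function(mean_c, D_t, Nr) {
  mean_c * D_t^2 * Nr / (1 + D_t * Nr)
}

#' Quasi-steady-state concentration of the external pool
#'
#' Under the quasi-steady-state closure the extracellular concentration
#' tracks the population average: `c_ext = <c_A> / (1 + 1/(N * D_t * r))`
#' (same units as `mean_cA`). It vanishes by convention when `D_t = 0`
#' (no exchange) and approaches `mean_cA` as diffusion grows.
#'
#' @param mean_cA mean intracellular concentration (any fixed units).
#' @param D_t dimensionless diffusion rate.
#' @param N number of cells.
#' @param r cell-to-external volume ratio.
#' @export
external_qss_concentration <- function(mean_cA, D_t, N, r) {
  if (D_t == 0) {
    message("D = 0: no exchange, external concentration set to 0")
    return(0 * mean_cA)
  }
  mean_cA / (1 + 1 / (N * D_t * r))
}

#' Support of the stationary density
#'
#' The stationary concentration is confined between two reflecting
#' barriers: the lower one, `k_plus_eff / k_eff`, is the level sustained by
#' pool influx alone (zero iff `D_t = 0` or `beta_t = 0`), and the support
#' width is exactly `1/(1 + D_t)` -- larger diffusion squeezes the
#' attainable range.
#'
#' @inheritParams mean_dimensionless
#' @return numeric vector `c(lower, upper)`.
#' @export
support_bounds <- function(alpha_t, beta_t, D_t, Nr) {
  m <- mean_dimensionless(alpha_t, beta_t, D_t, Nr)
  lower <- .k_plus_eff(m, D_t, Nr) / (1 + D_t)
  c(lower, lower + 1 / (1 + D_t))
}

#' Stationary density of the reduced dichotomous-noise model
#'
#' Builds the closed-form stationary law of the dimensionless concentration
#' driven by telegraph switching. In the shifted/scaled variable
#' `x = k_eff * c - k_plus_eff`, which spans `(0, 1)` on the support, the
#' law is Beta with shape parameters `beta_t/k_eff` and `alpha_t/k_eff`;
#' the density of `c` itself is
#' `N * x^(beta_t/k_eff - 1) * (1 - x)^(alpha_t/k_eff - 1)` with the
#' normalisation constant computed through log-gamma. At large `D_t` both
#' exponents approach zero and the density develops integrable endpoint
#' singularities, which is why all moments are taken from the closed-form
#' Beta moments ([stationary_moment()]) rather than quadrature.
#'
#' @param x a `"qs_model"`, `"qs_dimless"`, or the first of four numeric
#'   dimensionless parameters.
#' @param beta_t,D_t,Nr used when `x` is numeric (`alpha_t`).
#' @param mean_mode `"analytic"` uses the closed-form mean;
#'   `"self_consistent"` solves the fixed-point condition numerically with
#'   [self_consistent_mean()] (the two agree to ~1e-12; both are exposed so
#'   one can verify the other).
#' @return An object of class `"qs_density"` with fields `alpha_t`,
#'   `beta_t`, `D_t`, `Nr`, `k_eff`, `mean`, `k_plus_eff`, `support`,
#'   `shape` (Beta exponents `a`, `b`), `shape_class` and `log_norm`.
#' @seealso [dstationary()], [pstationary()], [stationary_moment()],
#'   [classify_shape()]
#' @examples
#' d <- stationary_density(qs_preset("gamma2", D_t = 100))
#' d
#' stationary_moment(d, 1) # equals d$mean
#' @export
stationary_density <- function(x, beta_t, D_t, Nr,
                               mean_mode = c("analytic", "self_consistent")) {
  mean_mode <- match.arg(mean_mode)
  if (inherits(x, "qs_model")) x <- dimensionless(x)
  if (inherits(x, "qs_dimless")) {
    alpha_t <- x$alpha_t; beta_t <- x$beta_t; D_t <- x$D_t; Nr <- x$Nr
  } else {
    alpha_t <- x
  }
  if (beta_t < 0 || alpha_t < 0 || D_t < 0 || Nr < 0)
    stop("dimensionless parameters must be non-negative")
  k <- 1 + D_t
  m <- switch(mean_mode,
              analytic = mean_dimensionless(alpha_t, beta_t, D_t, Nr),
              self_consistent = self_consistent_mean(alpha_t, beta_t, D_t, Nr))
  kpe <- .k_plus_eff(m, D_t, Nr)
  a <- beta_t / k
  b <- alpha_t / k
  structure(list(
    alpha_t = alpha_t, beta_t = beta_t, D_t = D_t, Nr = Nr,
    k_eff = k, mean = m, k_plus_eff = kpe,
    support = c(kpe / k, kpe / k + 1 / k),
    shape = c(a = a, b = b),
    shape_class = classify_shape(alpha_t, beta_t, D_t),
    log_norm = log(k) + lgamma(a + b) - lgamma(a) - lgamma(b)
  ), class = "qs_density")
}

#' Evaluate the stationary probability density / distribution function
#'
#' `dstationary()` evaluates the closed-form density in log-space
#' (log-gamma normalisation), returning 0 outside the open support and
#' `+Inf` exactly at an endpoint whose Beta exponent is below one (the
#' integrable singularity), never `NaN`. `pstationary()` is the CDF, the
#' regularised incomplete Beta function of the transformed variable.
#'
#' @param x,q dimensionless concentration values.
#' @param d a `"qs_density"` from [stationary_density()].
#' @param log if `TRUE` return the log-density.
#' @export
dstationary <- function(x, d, log = FALSE) {
  stopifnot(inherits(d, "qs_density"))
  a <- d$shape[["a"]]; b <- d$shape[["b"]]
  u <- d$k_eff * x - d$k_plus_eff
  # snap round-off onto the exact endpoints (the support bounds themselves
  # do not always map back to u = 0, 1 exactly in floating point)
  eps <- 4 * .Machine$double.eps * max(1, d$k_plus_eff)
  at0 <- abs(u) <= eps
  at1 <- abs(u - 1) <= eps
  out <- rep(-Inf, length(x))
  inside <- !at0 & !at1 & u > 0 & u < 1
  out[inside] <- d$log_norm + (a - 1) * base::log(u[inside]) +
    (b - 1) * log1p(-u[inside])
  # endpoints: +Inf for a diverging (exponent < 1) edge, finite for == 1
  out[at0] <- if (a < 1) Inf else if (a == 1) d$log_norm else -Inf
  out[at1] <- if (b < 1) Inf else if (b == 1) d$log_norm else -Inf
  if (log) out else exp(out)
}

#' @rdname dstationary
#' @export
pstationary <- function(q, d) {
  stopifnot(inherits(d, "qs_density"))
  u <- pmin(pmax(d$k_eff * q - d$k_plus_eff, 0), 1)
  stats::pbeta(u, d$shape[["a"]], d$shape[["b"]])
}

#' Raw moments of the stationary concentration
#'
#' Exact `k`-th raw moment of the dimensionless concentration, via the
#' closed-form raw moments of the underlying Beta variable and the binomial
#' shift/scale back to `c = (x + k_plus_eff)/k_eff`. Stable at every
#' diffusion value, including where quadrature fails on the endpoint
#' singularities.
#'
#' @param d a `"qs_density"`.
#' @param k non-negative integer moment order.
#' @export
stationary_moment <- function(d, k) {
  stopifnot(inherits(d, "qs_density"), k >= 0, k == round(k))
  a <- d$shape[["a"]]; b <- d$shape[["b"]]
  # raw Beta moments E[x^j] = prod_{l<j} (a+l)/(a+b+l)
  ex <- cumprod(c(1, (a + seq_len(k) - 1) / (a + b + seq_len(k) - 1)))
  j <- 0:k
  sum(choose(k, j) * d$k_plus_eff^(k - j) * ex[j + 1]) / d$k_eff^k
}

#' Shape classification of the stationary density
#'
#' The density has an interior maximum when both `alpha_t` and `beta_t`
#' exceed `k_eff = 1 + D_t` (single-peak dynamics), an interior minimum when
#' both lie below it (bistable, double-peaked dynamics), and no extremum
#' when `k_eff` separates them (monotone density, burst-like dynamics).
#' Because the transition lines sit at `alpha_t, beta_t = 1 + D_t`,
#' increasing diffusion alone walks a fixed `(alpha_t, beta_t)` point
#' through these phases. Ties within `tol` are reported as `"degenerate"`
#' (the classification is a strict inequality; ties are measure-zero).
#'
#' @inheritParams mean_dimensionless
#' @param tol absolute tolerance on `alpha_t - k_eff` and `beta_t - k_eff`.
#' @return one of `"interior_max"`, `"no_extremum"`, `"interior_min"`,
#'   `"degenerate"`.
#' @seealso [density_slope_at_lower()] to distinguish the rising from the
#'   decaying monotone case.
#' @export
classify_shape <- function(alpha_t, beta_t, D_t, tol = 1e-12) {
  k <- 1 + D_t
  da <- alpha_t - k
  db <- beta_t - k
  if (abs(da) <= tol || abs(db) <= tol) return("degenerate")
  if (da > 0 && db > 0) return("interior_max")
  if (da < 0 && db < 0) return("interior_min")
  "no_extremum"
}

#' Sign of the density slope at the lower support edge
#'
#' Distinguishes the two monotone (`"no_extremum"`) cases: `-1` when the
#' density decays from a diverging lower edge (`beta_t < k_eff`, burst-like
#' dynamics -- the case reachable under low constitutive expression), `+1`
#' when it rises from zero (`beta_t > k_eff`).
#'
#' @param d a `"qs_density"`.
#' @export
density_slope_at_lower <- function(d) {
  a <- d$shape[["a"]]; b <- d$shape[["b"]]
  if (a > 1) 1L else if (a < 1) -1L else as.integer(sign(1 - b))
}

#' Transcriptional noise of the autoinducer concentration
#'
#' Closed-form squared coefficient of variation of the stationary
#' concentration in the reduced model (mRNA switching as the only noise
#' source):
#' \deqn{\eta^2 = \frac{\tilde\alpha\,(1+\tilde D+\tilde D N r)^2}
#'   {\tilde\beta\,(1+\tilde D)(1+\tilde D N r)^2(1+\tilde D+\tilde\alpha+\tilde\beta)}.}
#' At `D_t = 0` this is `alpha_t / (beta_t * (1 + alpha_t + beta_t))`; it
#' decays to zero at large diffusion, and in between it is non-monotonic --
#' see [noise_curve_features()].
#'
#' @inheritParams mean_dimensionless
#' @export
transcriptional_noise <- function(alpha_t, beta_t, D_t, Nr) {
  if (any(beta_t <= 0)) stop("beta_t = 0: coefficient of variation undefined")
  DNr <- D_t * Nr
  alpha_t * (1 + D_t + DNr)^2 /
    (beta_t * (1 + D_t) * (1 + DNr)^2 * (1 + D_t + alpha_t + beta_t))
}

#' Self-consistent stationary mean by fixed-point iteration
#'
#' Solves the self-consistency condition -- the mean must equal the first
#' moment of the stationary density evaluated at that same mean -- by damped
#' fixed-point iteration on `m -> (E[x] + k_plus_eff(m)) / k_eff`. The map
#' is affine and contracting here; damping (default 0.5) guards pathological
#' inputs. Agrees with the closed form [mean_dimensionless()] to ~1e-12 and
#' serves as its independent check.
#'
#' @inheritParams mean_dimensionless
#' @param tol relative convergence tolerance.
#' @param damping damping factor in `(0, 1]`.
#' @param max_iter iteration cap; non-convergence is an error carrying the
#'   last iterate and residual.
#' @export
self_consistent_mean <- function(alpha_t, beta_t, D_t, Nr, tol = 1e-13,
                                 damping = 0.5, max_iter = 1e4) {
  if (alpha_t + beta_t <= 0) stop("alpha_t + beta_t must be positive")
  if (beta_t == 0) return(0)
  s <- beta_t / (alpha_t + beta_t)   # E[x] of the Beta variable
  k <- 1 + D_t
  g <- D_t^2 * Nr / (1 + D_t * Nr)   # k_plus_eff(m) = g * m
  m <- s / k
  for (it in seq_len(max_iter)) {
    m_new <- (1 - damping) * m + damping * (s + g * m) / k
    if (abs(m_new - m) <= tol * max(abs(m_new), 1e-300)) return(m_new)
    m <- m_new
  }
  stop(sprintf(paste0("self-consistency iteration did not converge after ",
                      "%d iterations (last m = %.15g, residual = %.3g)"),
               max_iter, m, abs((s + g * m) / k - m)))
}

#' Features of the transcriptional-noise curve over diffusion
#'
#' Locates the interior maximum of [transcriptional_noise()] as a function
#' of `D_t` (coarse log-spaced grid, then golden-section refinement of the
#' bracketing interval) and measures the slope at `D_t = 0` by a forward
#' finite difference. The slope is positive for any finite
#' `alpha_t + beta_t` -- the noise first *rises* with diffusion, a
#' consequence of the colored (finite correlation time) mRNA noise -- and
#' the curve then decays, so a unique interior maximum exists.
#'
#' @param alpha_t,beta_t dimensionless switching rates.
#' @param N,r population geometry.
#' @param D_grid evaluation grid (default 200 log-spaced points in
#'   `[1e-2, 1e6]`).
#' @param h step of the forward difference at 0.
#' @return list with `argmax` (refined, relative tolerance ~1e-6), `max`,
#'   `slope0`, and the grid `data.frame(D_t, eta2)`.
#' @export
noise_curve_features <- function(alpha_t, beta_t, N, r,
                                 D_grid = 10^seq(-2, 6, length.out = 200),
                                 h = 1e-6) {
  if (beta_t <= 0) stop("beta_t = 0: coefficient of variation undefined")
  Nr <- N * r
  f <- function(Dt) transcriptional_noise(alpha_t, beta_t, Dt, Nr)
  eta2 <- f(D_grid)
  i <- which.max(eta2)
  lo <- if (i > 1) D_grid[i - 1] else D_grid[1]
  hi <- if (i < length(D_grid)) D_grid[i + 1] else D_grid[length(D_grid)]
  opt <- stats::optimize(function(l) -f(10^l), c(log10(lo), log10(hi)),
                         tol = 1e-8)
  slope0 <- (f(h) - f(0)) / h
  list(argmax = 10^opt$minimum, max = -opt$objective, slope0 = slope0,
       grid = data.frame(D_t = D_grid, eta2 = eta2))
}

#' @export
print.qs_density <- function(x, digits = 6, ...) {
  cat("Stationary density of the reduced quorum-sensing model\n")
  cat(sprintf("  alpha_t = %g, beta_t = %g, D_t = %g, N*r = %g\n",
              x$alpha_t, x$beta_t, x$D_t, x$Nr))
  cat(sprintf("  mean <c~A> = %.*g, support [%.*g, %.*g] (width 1/(1+D_t) = %.*g)\n",
              digits, x$mean, digits, x$support[1], digits, x$support[2],
              digits, 1 / x$k_eff))
  cat(sprintf("  Beta exponents (a, b) = (%.*g, %.*g); shape: %s\n",
              digits, x$shape[["a"]], digits, x$shape[["b"]], x$shape_class))
  invisible(x)
}

#' @export
plot.qs_density <- function(x, n = 512, ...) {
  eps <- diff(x$support) * 1e-4
  cc <- seq(x$support[1] + eps, x$support[2] - eps, length.out = n)
  graphics::plot(cc, dstationary(cc, x), type = "l",
                 xlab = "dimensionless concentration",
                 ylab = "stationary density",
                 main = sprintf("(alpha_t, beta_t, D_t) = (%g, %g, %g): %s",
                                x$alpha_t, x$beta_t, x$D_t, x$shape_class),
                 ...)
  invisible(x)
}
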