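# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: moments come from Beta-distribution identities
# and from endpoint-desingularised quadrature, densities from dbeta().

# the standard dimensionless operating points
preset_table <- list(gamma1 = c(8, 2), gamma2 = c(15, 5),
                     gamma3 = c(8, 0.5), gamma4 = c(15, 0.5))

# CV^2 of the stationary concentration via Beta-moment algebra on
# x = k_eff*c - k_plus_eff  (independent of the closed-form noise formula)
cv2_beta_oracle <- function(alpha_t, beta_t, D_t, Nr) {
  k <- 1 + D_t
  a <- beta_t / k
  b <- alpha_t / k
  m <- (1 + D_t * Nr) / (1 + D_t * Nr + D_t) * beta_t / (alpha_t + beta_t)
  var_x <- a * b / ((a + b)^2 * (a + b + 1))
  var_x / (k * m)^2
}

mean_beta_oracle <- function(alpha_t, beta_t, D_t, Nr) {
  k <- 1 + D_t
  a <- beta_t / k
  b <- alpha_t / k
  kpe <- (1 + D_t * Nr) / (1 + D_t * Nr + D_t) * beta_t / (alpha_t + beta_t) *
    D_t^2 * Nr / (1 + D_t * Nr)
  (a / (a + b) + kpe) / k
}

# integral of f(u) against the density of a "qs_density", by quadrature with
# the power substitutions u = v^(1/a) (lower half) and 1-u = w^(1/b) (upper
# half) that remove the integrable endpoint singularities
quad_density_oracle <- function(d, f = function(u) rep(1, length(u))) {
  a <- d$shape[["a"]]; b <- d$shape[["b"]]
  lo <- stats::integrate(function(v) f(v^(1 / a)) * (1 - v^(1 / a))^(b - 1) / a,
                         0, 0.5^a, rel.tol = 1e-12,
                         subdivisions = 4000L)$value
  hi <- stats::integrate(function(w) f(1 - w^(1 / b)) * (1 - w^(1 / b))^(a - 1) / b,
                         0, 0.5^b, rel.tol = 1e-12,
                         subdivisions = 4000L)$value
  exp(d$log_norm) / d$k_eff * (lo + hi)
}

# across-replicate mean, SE and z-score against a reference value
zscore <- function(values, reference) {
  se <- stats::sd(values) / sqrt(length(values))
  (mean(values) - reference) / se
}
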