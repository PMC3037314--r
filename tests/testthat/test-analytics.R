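Nr_std <- 1e-3  # N = 100, r = 1e-5

test_that("stationary mean: closed form, limits, monotonicity in diffusion", {
  expect_equal(mean_dimensionless(15, 5, 0, Nr_std), 0.25)
  expect_equal(mean_dimensionless(15, 5, 100, Nr_std), 0.25 * 1.1 / 101.1,
               tolerance = 1e-14)
  expect_equal(mean_dimensionless(15, 5, 100, Nr_std), 2.7201e-3,
               tolerance = 1e-4)
  # D -> inf limit: Nr/(1+Nr) * beta_t/(alpha_t+beta_t)
  expect_equal(mean_dimensionless(15, 5, 1e12, Nr_std),
               Nr_std / (1 + Nr_std) * 0.25, tolerance = 1e-9)
  # strictly decreasing in D, always below the diffusionless value
  grid <- c(0, 10^seq(-2, 6, length.out = 60))
  means <- sapply(grid, function(Dt) mean_dimensionless(15, 5, Dt, Nr_std))
  expect_true(all(diff(means) < 0))
  expect_true(all(means[-1] < 0.25))
  expect_error(mean_dimensionless(0, 0, 1, Nr_std), "positive")
})

test_that("external pool sits at the quasi-steady-state fraction of the cell mean", {
  # N*D_t*r = 0.1  ->  c_ext = <c>/11
  expect_equal(external_qss_concentration(0.25, 100, 100, 1e-5), 0.25 / 11)
  expect_equal(external_qss_concentration(0.25, 1e13, 100, 1e-5), 0.25,
               tolerance = 1e-9)
  # N*D_t*r = 1 is the half-way point
  expect_equal(external_qss_concentration(1, 1000, 100, 1e-5), 0.5)
  expect_message(external_qss_concentration(0.25, 0, 100, 1e-5), "D = 0")
  expect_equal(suppressMessages(
    external_qss_concentration(0.25, 0, 100, 1e-5)), 0)
})

test_that("support: lower barrier formula and exact width 1/(1+D_t)", {
  expect_equal(support_bounds(15, 5, 0, Nr_std), c(0, 1))
  # direct barrier expression: D^2*Nr/((1+D)(1+D+D*Nr)) * beta_t/(alpha_t+beta_t)
  lower_direct <- function(at, bt, Dt, Nr)
    Dt^2 * Nr / ((1 + Dt) * (1 + Dt + Dt * Nr)) * bt / (at + bt)
  for (Dt in c(0, 1, 10, 100, 2000, 5e4)) {
    s <- support_bounds(15, 5, Dt, Nr_std)
    expect_equal(s[1], lower_direct(15, 5, Dt, Nr_std), tolerance = 1e-13)
    expect_equal(diff(s), 1 / (1 + Dt), tolerance = 1e-13)
  }
  expect_equal(support_bounds(15, 5, 100, Nr_std)[1], 2.448e-4,
               tolerance = 1e-3)
  # lower barrier vanishes iff no diffusion or no transcription
  expect_equal(support_bounds(15, 0.5, 0, Nr_std)[1], 0)
  expect_gt(support_bounds(15, 5, 1, Nr_std)[1], 0)
})

test_that("density matches the Beta law under the affine change of variables", {
  d0 <- stationary_density(15, 5, 0, Nr_std)
  # no diffusion: c itself is Beta(beta_t, alpha_t)
  cc <- seq(0.01, 0.99, by = 0.01)
  expect_equal(dstationary(cc, d0), dbeta(cc, 5, 15), tolerance = 1e-12)
  expect_equal(dstationary(0.25, d0), dbeta(0.25, 5, 15), tolerance = 1e-12)
  # interior mode at (beta_t-1)/(alpha_t+beta_t-2) = 4/18
  opt <- optimize(function(x) dstationary(x, d0), c(0, 1), maximum = TRUE)
  expect_equal(opt$maximum, 4 / 18, tolerance = 1e-4)
  # with diffusion: k_eff * Beta density of the transformed variable
  d1 <- stationary_density(15, 5, 10, Nr_std)
  cc <- seq(d1$support[1] + 1e-4, d1$support[2] - 1e-4, length.out = 101)
  u <- d1$k_eff * cc - d1$k_plus_eff
  expect_equal(dstationary(cc, d1),
               d1$k_eff * dbeta(u, 5 / 11, 15 / 11), tolerance = 1e-12)
  # zero outside the support, +Inf (not NaN) at singular endpoints:
  # at D_t=10 only the lower exponent (5/11) is below one
  expect_equal(dstationary(c(-1, d1$support[2] + 1e-6), d1), c(0, 0))
  expect_identical(dstationary(d1$support, d1), c(Inf, 0))
  # at D_t=100 both exponents are below one and both edges diverge
  d2 <- stationary_density(15, 5, 100, Nr_std)
  expect_identical(dstationary(d2$support, d2), c(Inf, Inf))
  expect_false(anyNA(dstationary(seq(-1, 1, by = 0.01), d2)))
  # mean_mode self_consistent builds the same law
  d1b <- stationary_density(15, 5, 10, Nr_std, mean_mode = "self_consistent")
  expect_equal(d1b$mean, d1$mean, tolerance = 1e-10)
})

test_that("closed-form moments: normalisation, mean, CV^2 identities", {
  d <- stationary_density(15, 5, 100, Nr_std)
  expect_equal(stationary_moment(d, 0), 1)
  expect_equal(stationary_moment(d, 1), mean_dimensionless(15, 5, 100, Nr_std),
               tolerance = 1e-14)
  # squared CV of Beta(5, 15): alpha_t/(beta_t*(1+alpha_t+beta_t)) = 1/7
  d0 <- stationary_density(15, 5, 0, Nr_std)
  m1 <- stationary_moment(d0, 1); m2 <- stationary_moment(d0, 2)
  expect_equal((m2 - m1^2) / m1^2, 1 / 7, tolerance = 1e-12)
})

test_that("three-way moment agreement: closed form vs Beta algebra vs quadrature", {
  for (nm in names(preset_table)) {
    g <- preset_table[[nm]]
    for (Dt in c(0, 1, 10, 100, 2000, 5e4)) {
      lbl <- sprintf("%s, D_t=%g", nm, Dt)
      m_closed <- mean_dimensionless(g[1], g[2], Dt, Nr_std)
      e_closed <- transcriptional_noise(g[1], g[2], Dt, Nr_std)
      # (a) = (b): Beta-moment oracle to 1e-12
      expect_equal(m_closed, mean_beta_oracle(g[1], g[2], Dt, Nr_std),
                   tolerance = 1e-12, label = lbl)
      expect_equal(e_closed, cv2_beta_oracle(g[1], g[2], Dt, Nr_std),
                   tolerance = 1e-12, label = lbl)
      d <- stationary_density(g[1], g[2], Dt, Nr_std)
      m1 <- stationary_moment(d, 1); m2 <- stationary_moment(d, 2)
      # raw-moment route loses ~2 digits to cancellation in m2 - m1^2 at
      # extreme diffusion (shift term kpe dominates both moments)
      expect_equal((m2 - m1^2) / m1^2, e_closed,
                   tolerance = if (Dt <= 2000) 1e-12 else 1e-10, label = lbl)
      # (a) = (c): desingularised quadrature to 1e-8 (quadrature-safe range)
      if (Dt <= 2000) {
        expect_equal(quad_density_oracle(d), 1, tolerance = 1e-8, label = lbl)
        mq <- quad_density_oracle(d, function(u) (u + d$k_plus_eff) / d$k_eff)
        expect_equal(mq, m_closed, tolerance = 1e-8, label = lbl)
      }
      # log-gamma normalisation against the quadrature-derived constant
      if (Dt <= 2000) {
        a <- d$shape[["a"]]; b <- d$shape[["b"]]
        raw <- quad_density_oracle(d) / exp(d$log_norm) * d$k_eff # = B(a,b)
        expect_equal(d$log_norm, log(d$k_eff) - log(raw), tolerance = 1e-8,
                     label = lbl)
      }
    }
  }
})

test_that("self-consistent fixed point reproduces the closed-form mean", {
  for (nm in names(preset_table)) {
    g <- preset_table[[nm]]
    for (Dt in c(0, 1, 10, 100, 2000, 5e4)) {
      expect_equal(self_consistent_mean(g[1], g[2], Dt, Nr_std),
                   mean_dimensionless(g[1], g[2], Dt, Nr_std),
                   tolerance = 1e-10,
                   label = sprintf("%s, D_t=%g", nm, Dt))
    }
  }
  # no production -> zero mean in one step
  expect_equal(self_consistent_mean(15, 0, 100, Nr_std), 0)
  expect_error(self_consistent_mean(0, 0, 1, Nr_std), "positive")
})

test_that("shape classification walks through the diffusion phases", {
  # transition lines at alpha_t, beta_t = 1 + D_t
  expect_equal(classify_shape(15, 5, 1), "interior_max")
  expect_equal(classify_shape(15, 5, 10), "no_extremum")
  expect_equal(classify_shape(15, 5, 100), "interior_min")
  expect_equal(classify_shape(15, 5, 2000), "interior_min")
  expect_equal(classify_shape(15, 5, 4), "degenerate")   # beta_t == k_eff
  expect_equal(classify_shape(15, 5, 14), "degenerate")  # alpha_t == k_eff
  # full phase sequence for each preset as D_t grows
  for (nm in names(preset_table)) {
    g <- preset_table[[nm]]
    Dt_seq <- c(0.99, 10^seq(0, 5, by = 0.25)) * 1.0001
    cls <- sapply(Dt_seq, function(Dt) classify_shape(g[1], g[2], Dt))
    cls <- cls[cls != "degenerate"]
    runs <- rle(cls)$values
    allowed <- c("interior_max", "no_extremum", "interior_min")
    expect_true(all(runs %in% allowed), label = nm)
    # phases appear in order of increasing diffusion, no re-entry
    expect_equal(runs, allowed[allowed %in% runs], label = nm)
  }
  # monotone-decreasing branch of no_extremum (the low-expression case)
  d <- stationary_density(15, 5, 10, Nr_std)
  expect_equal(density_slope_at_lower(d), -1L)
  d_up <- stationary_density(0.5, 8, 2, Nr_std) # beta_t > k_eff > alpha_t
  expect_equal(density_slope_at_lower(d_up), 1L)
})

test_that("transcriptional noise: anchors, decay, error cases", {
  expect_equal(transcriptional_noise(15, 5, 0, Nr_std), 1 / 7,
               tolerance = 1e-14)
  expect_equal(transcriptional_noise(15, 5, 100, Nr_std),
               cv2_beta_oracle(15, 5, 100, Nr_std), tolerance = 1e-13)
  expect_equal(transcriptional_noise(15, 5, 100, Nr_std), 2.0736,
               tolerance = 1e-4)
  expect_lt(transcriptional_noise(15, 5, 1e6, Nr_std), 1e-4)
  expect_error(transcriptional_noise(15, 0, 1, Nr_std), "undefined")
})

test_that("noise-vs-diffusion curve: positive initial slope, unique interior peak, decay", {
  nf <- noise_curve_features(15, 5, N = 100, r = 1e-5)
  expect_gt(nf$slope0, 0)
  # analytic slope at 0: eta2(0) * (1 - 1/(1 + alpha_t + beta_t))
  expect_equal(nf$slope0, (1 / 7) * (1 - 1 / 21), tolerance = 1e-4)
  # frozen from two independent routes (fine-grid scan of the closed form
  # and of the Beta-moment oracle): argmax 94.081, peak 2.07478
  expect_equal(nf$argmax, 94.081, tolerance = 1e-3)
  expect_equal(nf$max, 2.074777, tolerance = 1e-5)
  # unimodal on the log grid: exactly one sign change of the differences
  signs <- sign(diff(nf$grid$eta2))
  expect_equal(sum(diff(signs) != 0), 1)
  expect_lt(nf$grid$eta2[nrow(nf$grid)], 1e-5)
})

test_that("white-noise limit: initial slope of the noise curve becomes null", {
  # scaling (alpha_t, beta_t) -> (kappa*alpha_t, kappa*beta_t) sends the mRNA
  # correlation time to zero; the slope at D_t = 0 scales like
  # eta2(0) ~ 1/kappa and vanishes in the limit
  s1 <- noise_curve_features(15, 5, 100, 1e-5)$slope0
  s3 <- noise_curve_features(15e3, 5e3, 100, 1e-5)$slope0
  s5 <- noise_curve_features(15e5, 5e5, 100, 1e-5)$slope0
  expect_equal(s3 / s1, 1e-3, tolerance = 0.05)
  expect_equal(s5 / s3, 1e-2, tolerance = 0.05)
  expect_lt(s5, 2e-6)
  # and the stationary *variance* decreases monotonically with diffusion at
  # any switching scale
  for (kappa in c(1, 1e3)) {
    v <- sapply(c(0, 1, 10, 100, 1000, 1e4), function(Dt) {
      d <- stationary_density(15 * kappa, 5 * kappa, Dt, Nr_std)
      stationary_moment(d, 2) - stationary_moment(d, 1)^2
    })
    expect_true(all(diff(v) < 0), label = sprintf("kappa=%g", kappa))
  }
})
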