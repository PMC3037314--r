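# shared replicate set at the diffusionless operating point (gamma2,
# calibrated to 25 nM); reused by several blocks below
m_g2_D0 <- qs_preset("gamma2", D_t = 0)
runs_D0 <- ssa_replicates(m_g2_D0, t_end = 2000, replicates = 8, seed = 11,
                          t_burn = 250)

test_that("pure transport conserves total molecule number exactly", {
  set.seed(42)
  N <- 20L
  A0 <- matrix(as.numeric(rpois(N, 30)), N, 1)
  Aext0 <- 500
  raw <- qsnoise:::.ssa_core(0, 0, 0, 0, 2, 1e-2, N, 1L,
                             integer(N), A0, Aext0, 0, 50,
                             NA_real_, 0L, 1e9)
  expect_identical(sum(raw$A_final) + raw$Aext_final, sum(A0) + Aext0)
  expect_gt(raw$n_events, 0)
})

test_that("telegraph occupancy and calibrated mean are recovered without diffusion", {
  occ <- sapply(runs_D0, function(r) r$occupancy)
  expect_lt(abs(zscore(occ, 0.25)), 3)
  mu <- sapply(runs_D0, function(r) r$mean_nM[1])
  expect_lt(abs(zscore(mu, 25)), 3)
  # no exchange: the external pool stays empty
  expect_equal(sapply(runs_D0, function(r) r$ext_mean_count[1]),
               rep(0, 8))
})

test_that("cells are statistically independent without diffusion", {
  cc <- sapply(runs_D0, function(r) r$cross_cell_cov)
  expect_lt(abs(zscore(cc, 0)), 3)
})

test_that("total noise at D=0 matches the exact mixed-Poisson value", {
  # conditioned on the mRNA path the counts are Poisson, so
  # eta2_total = 1/nbar + eta2_tran exactly
  ref <- 1 / m_g2_D0$nbar + transcriptional_noise(15, 5, 0, 1e-3)
  e2 <- sapply(runs_D0, function(r) r$eta2_total)
  expect_lt(abs(zscore(e2, ref)), 3)
})

test_that("stationary mean follows the closed form when diffusion is on", {
  for (Dt in c(1, 10)) {
    m <- qs_preset("gamma2", D_t = Dt)
    runs <- ssa_replicates(m, t_end = 1250, replicates = 6, seed = 21,
                           t_burn = 250)
    counts <- sapply(runs, function(r) r$mean_count[1])
    d <- dimensionless(m)
    ref <- m$k_plus / m$k_minus *
      mean_dimensionless(d$alpha_t, d$beta_t, d$D_t, d$Nr)
    expect_lt(abs(zscore(counts, ref)), 3, label = sprintf("D_t=%g", Dt))
    # external pool near its quasi-steady-state level
    ext <- sapply(runs, function(r) r$ext_mean_count[1])
    ext_ref <- molecules_from_concentration(
      suppressMessages(external_qss_concentration(25, Dt, 100, 1e-5)),
      m$V / m$r)
    expect_lt(abs(zscore(ext, ext_ref)) , 4, label = sprintf("ext D_t=%g", Dt))
  }
})

test_that("zero transcription from an empty state is reported as absorbing", {
  m <- suppressWarnings(qs_model(alpha = 0.3, beta = 0, k_plus = 2, D = 0))
  expect_message(
    r <- ssa_run(m, t_end = 100, t_burn = 0, seed = 1, init = "zeros"),
    "absorbing")
  expect_true(r$absorbed)
  expect_equal(r$mean_count[1], 0)
  expect_error(total_noise(r), "undefined")
})

test_that("initial states: zeros and stationary guess", {
  m <- qs_preset("gamma2", D_t = 100)
  z <- initial_state(m, "zeros")
  expect_equal(z$M, integer(100))
  expect_equal(sum(z$A), 0)
  expect_equal(z$Aext, 0)
  set.seed(5)
  s <- initial_state(m, "stationary_guess")
  # counts drawn at the calibrated mean (Poisson, so SE = sqrt(nbar/N))
  expect_lt(abs(mean(s$A) - m$nbar) / sqrt(m$nbar / 100), 4)
  expect_true(all(s$M %in% 0:1))
  # external pool at the QSS level (~1/11 of the cell concentration here)
  ext_ref <- molecules_from_concentration(25 / 11, m$V / m$r)
  expect_lt(abs(s$Aext - ext_ref) / sqrt(ext_ref), 4)
  sd2 <- initial_state(m, "stationary_guess", dual = TRUE)
  expect_equal(dim(sd2$A), c(100L, 2L))
  expect_length(sd2$Aext, 2)
})

test_that("identical seeds give identical runs", {
  m <- qs_preset("gamma2", D_t = 10)
  a <- ssa_run(m, t_end = 400, t_burn = 100, seed = 99, thin_dt = 5)
  b <- ssa_run(m, t_end = 400, t_burn = 100, seed = 99, thin_dt = 5)
  expect_identical(a$mean_count, b$mean_count)
  expect_identical(a$var_count, b$var_count)
  expect_identical(a$n_events, b$n_events)
  expect_identical(a$final_state, b$final_state)
  expect_identical(a$trajectory, b$trajectory)
})

test_that("thinned trajectory is a valid piecewise-constant record", {
  m <- qs_preset("gamma2", D_t = 0)
  r <- ssa_run(m, t_end = 300, t_burn = 100, seed = 3, thin_dt = 1)
  tr <- r$trajectory
  expect_true(all(c("t", "M", "A1", "Aext", "cA_nM", "cell_id") %in%
                  names(tr)))
  expect_true(all(tr$t >= 100 & tr$t <= 300))
  expect_equal(nrow(tr), 201)
  expect_true(all(tr$A1 >= 0) && all(tr$M %in% 0:1))
  expect_equal(tr$cA_nM, concentration_from_molecules(tr$A1, m$V))
})

test_that("dual reporters are exchangeable and positively correlated", {
  druns <- ssa_replicates(m_g2_D0, t_end = 2000, replicates = 8, seed = 31,
                          t_burn = 250, dual = TRUE)
  d1 <- sapply(druns, function(r) r$mean_count[1])
  d2 <- sapply(druns, function(r) r$mean_count[2])
  expect_lt(abs(zscore(d1 - d2, 0)), 3)
  # shared mRNA source: covariance equals the transcriptional variance
  # component (mixed-Poisson argument), so correlation is clearly positive
  covs <- sapply(druns, function(r) r$cross_moment - prod(r$mean_count))
  nbar <- m_g2_D0$nbar
  cov_ref <- transcriptional_noise(15, 5, 0, 1e-3) * nbar^2
  expect_lt(abs(zscore(covs, cov_ref)), 3)
  expect_gt(mean(covs), 0)
})
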