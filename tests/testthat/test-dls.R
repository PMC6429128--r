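test_that("scattering vector follows instrument geometry", {
  expect_equal(scattering_vector(633, 173, 1.33), 2.635e7,
               tolerance = 1e-3)
  expect_equal(scattering_vector(633, 173, 2 * 1.33),
               2 * scattering_vector(633, 173, 1.33), tolerance = 1e-12)
  expect_lt(scattering_vector(633, 0.01, 1.33), 1e4)   # q -> 0 with angle
  expect_error(scattering_vector(633, 0, 1.33), "angle")
  expect_error(scattering_vector(633, 181, 1.33), "angle")
})

test_that("the Siegert inversion is exact on constructed traces", {
  q <- scattering_vector()
  corr <- synth_correlogram(4e-7, q = q, noise_sigma = 0, seed = 1)
  gamma <- 4e-11 * q^2
  expect_equal(g1_squared(corr), exp(-2 * gamma * corr$lag_times),
               tolerance = 1e-12)
  flat <- correlogram(corr$lag_times, rep(1, length(corr$lag_times)),
                      baseline = 1, beta = 0.9, q = q)
  expect_equal(g1_squared(flat), rep(0, length(corr$lag_times)))
  expect_error(correlogram(corr$lag_times, corr$g2, beta = -1, q = q), "beta")
})

test_that("cumulant fit recovers exact and noisy decay rates", {
  q <- scattering_vector()
  # noiseless: Gamma recovered to 1e-6 relative, near-zero PDI
  gamma_true <- 1000
  t <- exp(seq(log(1e-6), log(2e-2), length.out = 150))
  fit <- cumulant_fit(exp(-2 * gamma_true * t), t)
  expect_lt(abs(fit$gamma / gamma_true - 1), 1e-6)
  expect_lt(fit$pdi, 0.02)
  expect_gte(fit$pdi, 0)

  # noisy monodisperse trace within 2%
  corr <- synth_correlogram(4e-7, q = q, noise_sigma = 0.01, seed = 11)
  f2 <- cumulant_fit(g1_squared(corr), corr$lag_times)
  expect_lt(abs(f2$gamma / (4e-11 * q^2) - 1), 0.02)

  # flat trace errors out
  expect_error(cumulant_fit(rep(0, 100), seq_len(100) * 1e-5), "flat")
  expect_error(cumulant_fit(exp(-2 * 1000 * t[1:5]), t[1:5]), "usable|high-amplitude")
})

test_that("fit is invariant to the coherence factor (normalisation upstream)", {
  q <- scattering_vector()
  c1 <- synth_correlogram(3e-7, q = q, beta = 0.9, noise_sigma = 0, seed = 1)
  c2 <- synth_correlogram(3e-7, q = q, beta = 0.45, noise_sigma = 0, seed = 1)
  f1 <- cumulant_fit(g1_squared(c1), c1$lag_times)
  f2 <- cumulant_fit(g1_squared(c2), c2$lag_times)
  expect_equal(f1$gamma, f2$gamma, tolerance = 1e-9)
})

test_that("decay rate converts to diffusion with q^2 scaling", {
  expect_equal(diffusion_from_gamma(2.77e4, 2.635e7), 3.99e-7,
               tolerance = 1e-3)
  expect_equal(diffusion_from_gamma(2.77e4, 2 * 2.635e7),
               diffusion_from_gamma(2.77e4, 2.635e7) / 4, tolerance = 1e-12)
  expect_error(diffusion_from_gamma(-1, 1), "positive")
})

test_that("end-to-end D recovery is accurate over two decades of D", {
  Ds <- 10^seq(-7, -6, length.out = 20)
  errs <- vapply(seq_along(Ds), function(i) {
    corr <- synth_correlogram(Ds[i], seed = 100 + i)
    abs(dls_analyze(corr)$D / Ds[i] - 1)
  }, numeric(1))
  expect_lt(stats::median(errs), 0.02)
  expect_lt(max(errs), 0.05)
  # the published-scale case specifically
  corr <- synth_correlogram(4.46e-7, seed = 7)
  expect_lt(abs(dls_analyze(corr)$D / 4.46e-7 - 1), 0.02)
})
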