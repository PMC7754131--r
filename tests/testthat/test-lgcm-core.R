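test_that("design and parameter constructors enforce their invariants", {
  expect_error(measurement_design(numeric(0)), "at least one occasion")
  expect_error(measurement_design(c(0, 2, 1)), "strictly increasing")
  expect_error(measurement_design(0:2, slope_loadings = c(1, 2)),
               "one entry per occasion")
  expect_error(lgcm_parameters(sigma2_I = -1, sigma2_S = 0, sigma2_E = 1),
               "sigma2_I")
  expect_error(lgcm_parameters(sigma2_I = 1, sigma2_S = 0, sigma2_E = 0),
               "sigma2_E")
  expect_error(lgcm_parameters(sigma2_I = 1, sigma2_S = 1, sigma2_E = 1,
                               sigma_IS = 2), "positive semidefinite")
  d <- measurement_design(0:6)
  expect_equal(n_occasions(d), 7L)
  expect_equal(design_duration(d), 6)
  expect_equal(d$slope_loadings, as.numeric(0:6))
})

test_that("implied moments: only the residual term survives when latent variances vanish", {
  d <- measurement_design(c(0, 1, 2))
  p <- lgcm_parameters(sigma2_I = 0, sigma2_S = 0, sigma2_E = 2,
                       mu_I = 1.5, mu_S = -0.5)
  mom <- implied_moments(d, p)
  expect_equal(mom$Sigma, 2 * diag(3))
  expect_equal(mom$mu, 1.5 - 0.5 * c(0, 1, 2))
})

test_that("implied moments reproduce the compound-symmetric case with zero slope variance", {
  d <- measurement_design(c(0, 2, 5, 9))
  p <- lgcm_parameters(sigma2_I = 43.6, sigma2_S = 0, sigma2_E = 21.45)
  mom <- implied_moments(d, p)
  expect_equal(diag(mom$Sigma), rep(65.05, 4))
  off <- mom$Sigma[upper.tri(mom$Sigma)]
  expect_equal(off, rep(43.6, 6))
})

test_that("implied moments equal the Lambda Phi Lambda' assembly on random instances", {
  set.seed(41)
  for (rep in 1:20) {
    d <- rand_design(4)
    p <- rand_params()
    mom <- implied_moments(d, p)
    expect_equal(mom$Sigma, oracle_implied_sigma(d, p), tolerance = 1e-12)
  }
})

test_that("minus-two log-likelihood equals k at the identity instance", {
  mom <- structure(list(Sigma = diag(3), mu = c(1, 2, 3)),
                   class = "implied_moments")
  data <- sample_moments(S = diag(3), m = c(1, 2, 3), N = 1)
  expect_equal(minus_two_log_likelihood(mom, data), 3)
})

test_that("minus-two log-likelihood matches the per-observation density oracle", {
  set.seed(7)
  for (rep in 1:10) {
    d <- rand_design(3)
    p <- rand_params()
    sim <- simulate_sample(d, p, N = 5, seed = 100 + rep)
    mom <- implied_moments(d, p)
    m2ll <- minus_two_log_likelihood(mom, sim$moments)
    oracle <- -2 * oracle_mvn_loglik_rows(sim$data, mom$mu, mom$Sigma) -
      5 * 3 * log(2 * pi)
    expect_equal(m2ll, oracle, tolerance = 1e-9)
  }
})

test_that("likelihood is invariant under orthogonal transformation of model and data", {
  set.seed(13)
  worst <- 0
  for (rep in 1:200) {
    k <- sample(2:5, 1)
    d <- rand_design(k)
    p <- rand_params()
    sim <- simulate_sample(d, p, N = 20, seed = 5000 + rep)
    mom <- implied_moments(d, p)
    base <- minus_two_log_likelihood(mom, sim$moments)
    Q <- rand_orthogonal(k)
    mom_q <- structure(list(Sigma = Q %*% mom$Sigma %*% t(Q),
                            mu = drop(Q %*% mom$mu)),
                       class = "implied_moments")
    data_q <- sample_moments(Q %*% sim$moments$S %*% t(Q),
                             drop(Q %*% sim$moments$m), sim$moments$N)
    rotated <- minus_two_log_likelihood(mom_q, data_q)
    worst <- max(worst, abs(rotated - base) / abs(base))
  }
  expect_lt(worst, 1e-10)
})

test_that("singular model covariance fails loudly, naming the matrix", {
  mom <- structure(list(Sigma = matrix(1, 2, 2), mu = c(0, 0)),
                   class = "implied_moments")
  data <- sample_moments(diag(2), c(0, 0), N = 4)
  expect_error(minus_two_log_likelihood(mom, data), "Sigma")
})

test_that("simulation is deterministic given a seed and nearly noiseless in the degenerate limit", {
  d <- measurement_design(0:3)
  p <- lgcm_parameters(sigma2_I = 0, sigma2_S = 0, sigma2_E = 1e-12,
                       mu_I = 2, mu_S = 1)
  s1 <- simulate_sample(d, p, N = 10, seed = 321)
  s2 <- simulate_sample(d, p, N = 10, seed = 321)
  expect_identical(s1$data, s2$data)
  expect_identical(s1$moments$S, s2$moments$S)
  mu <- 2 + 1 * (0:3)
  expect_lt(max(abs(sweep(s1$data, 2, mu))), 1e-4)
  expect_error(simulate_sample(d, p, N = 0), "N")
})

test_that("empirical moments converge to the implied moments at large N", {
  d <- app_design()
  p <- app_params(sigma2_S = 1)
  sim <- simulate_sample(d, p, N = 50000, seed = 2024)
  mom <- implied_moments(d, p)
  se_S <- sqrt((outer(diag(mom$Sigma), diag(mom$Sigma)) + mom$Sigma^2) / 50000)
  expect_true(all(abs(sim$moments$S - mom$Sigma) < 5 * se_S))
  se_m <- sqrt(diag(mom$Sigma) / 50000)
  expect_true(all(abs(sim$moments$m - mom$mu) < 5 * se_m))
})

test_that("raw data round-trips through CSV with occasion-time headers", {
  d <- measurement_design(c(0, 1.5, 4))
  p <- lgcm_parameters(sigma2_I = 1, sigma2_S = 0.5, sigma2_E = 1)
  sim <- simulate_sample(d, p, N = 6, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sample_csv(sim, path)
  back <- read_sample_csv(path)
  expect_equal(unname(back), unname(sim$data), tolerance = 1e-12)
  expect_equal(colnames(back), format(d$times, trim = TRUE))
})
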