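# Independent brute-force oracles used to pin expected values. These are
# deliberately written against different primitives than the package
# (determinant()/solve() instead of Cholesky, per-observation densities
# instead of sufficient statistics, explicit matrix assembly instead of the
# closed forms) so that agreement is evidence, not tautology.

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# random orthogonal matrix via QR of a Gaussian matrix
rand_orthogonal <- function(k) {
  qr.Q(qr(matrix(rnorm(k * k), k, k)))
}

# random strictly-increasing design
rand_design <- function(k) {
  measurement_design(cumsum(runif(k, 0.2, 2)))
}

rand_params <- function(max_s2 = 3) {
  s2i <- runif(1, 0.3, 4)
  s2s <- runif(1, 0, max_s2)
  # keep the latent covariance comfortably PSD
  sis <- runif(1, -0.8, 0.8) * sqrt(s2i * s2s)
  lgcm_parameters(sigma2_I = s2i, sigma2_S = s2s,
                  sigma2_E = runif(1, 0.5, 3), sigma_IS = sis,
                  mu_I = rnorm(1), mu_S = rnorm(1, sd = 0.5))
}

# implied covariance assembled as Lambda Phi Lambda' + sigma2_E I
oracle_implied_sigma <- function(design, params) {
  Lambda <- cbind(1, design$slope_loadings)
  Phi <- matrix(c(params$sigma2_I, params$sigma_IS,
                  params$sigma_IS, params$sigma2_S), 2, 2)
  Lambda %*% Phi %*% t(Lambda) + params$sigma2_E * diag(length(design$times))
}

# sum of per-observation multivariate normal log densities, one row at a time
oracle_mvn_loglik_rows <- function(y, mu, Sigma) {
  k <- ncol(y)
  logdet <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus)
  Sinv <- solve(Sigma)
  total <- 0
  for (i in seq_len(nrow(y))) {
    d <- y[i, ] - mu
    total <- total - 0.5 * (k * log(2 * pi) + logdet +
                              drop(t(d) %*% Sinv %*% d))
  }
  total
}

# log likelihood (constant omitted, matching the package's convention) at a
# given slope variance, from explicit matrix assembly and determinant/solve
oracle_loglik_at <- function(v, data, design, params) {
  p <- params
  p$sigma2_S <- v
  Sigma <- oracle_implied_sigma(design, p)
  mu <- p$mu_I + p$mu_S * design$times
  logdet <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus)
  Sinv <- solve(Sigma)
  d <- data$m - mu
  -0.5 * data$N * (logdet + sum(Sinv * data$S) + drop(t(d) %*% Sinv %*% d))
}

# log marginal likelihood under a gamma prior by a fixed-grid trapezoid rule
# on sigma2_S in [0, upper]
oracle_trapezoid_lml <- function(data, design, params, shape, rate,
                                 upper = 60, nodes = 20000L) {
  vs <- seq(0, upper, length.out = nodes)
  h <- vs[2] - vs[1]
  logf <- vapply(vs, function(v) {
    oracle_loglik_at(v, data, design, params) +
      dgamma(v, shape = shape, rate = rate, log = TRUE)
  }, numeric(1))
  logf[!is.finite(logf)] <- -Inf  # gamma density at 0 for shape < 1
  logw <- rep(log(h), nodes)
  logw[c(1, nodes)] <- log(h / 2)
  logsumexp(logf + logw)
}

# effective error variance by direct k x k matrix inversion
oracle_effective_error <- function(design, sigma2_I, sigma2_E) {
  k <- length(design$slope_loadings)
  Sigma0 <- sigma2_I * matrix(1, k, k) + sigma2_E * diag(k)
  1 / drop(t(design$slope_loadings) %*% solve(Sigma0) %*%
             design$slope_loadings)
}

# duration of the equally spaced k-occasion design matching a reference
# effective error, by interval bisection
oracle_bisect_duration <- function(k_new, reference, sigma2_I, sigma2_E,
                                   lo = 1e-6, hi = 1e3, tol = 1e-10) {
  target <- oracle_effective_error(reference, sigma2_I, sigma2_E)
  f <- function(T) {
    d <- measurement_design(seq(0, T, length.out = k_new))
    oracle_effective_error(d, sigma2_I, sigma2_E) - target
  }
  stopifnot(f(lo) > 0, f(hi) < 0)
  while ((hi - lo) > tol * hi) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# small random dataset with a comfortably wide marginal-likelihood integrand
# (small N, effective error rescaled into [6, 10]) so that a fixed-grid
# trapezoid oracle with spacing h has negligible O(h^2) discretisation error
rand_bayes_case <- function() {
  k <- sample(2:3, 1)
  design <- rand_design(k)
  params <- lgcm_parameters(sigma2_I = runif(1, 0.5, 2),
                            sigma2_S = runif(1, 0, 2),
                            sigma2_E = runif(1, 1, 4))
  s2eff <- effective_error_variance(design, params$sigma2_I, params$sigma2_E)
  scale <- sqrt(s2eff / runif(1, 6, 10))
  design <- measurement_design(design$times * scale)
  sim <- simulate_sample(design, params, N = sample(4:8, 1),
                         seed = sample.int(1e6, 1))
  list(design = design, params = params, data = sim$moments, sim = sim)
}

app_design <- function() measurement_design(0:6)
app_params <- function(sigma2_S = 0) {
  lgcm_parameters(sigma2_I = 43.6, sigma2_S = sigma2_S, sigma2_E = 21.45)
}
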