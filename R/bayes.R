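#' Priors on the slope variance
#'
#' The hypothesis test at the centre of this package compares
#' \eqn{H_0: \sigma_S^2 = 0} against \eqn{H_1: \sigma_S^2 \sim \pi_1}. Both
#' hypotheses are expressed as priors on \eqn{\sigma_S^2}: a point mass
#' (degenerate prior, used for \eqn{H_0} and for design priors with a known
#' true value) or a gamma distribution. The gamma prior with shape 1 and
#' rate 0.5 places most of its weight on values between 0 and 6, a plausible
#' range for slope variances of psychological outcome scales.
#'
#' @param value Location of the point mass, `>= 0`.
#' @param shape,rate Gamma shape \eqn{> 0} and rate \eqn{> 0}.
#' @return An object of class `"slope_prior"` with element `kind`
#'   (`"point"` or `"gamma"`).
#' @examples
#' gamma_prior(1, 0.5)   # default analysis prior for H1
#' point_prior(0)        # H0
#' @name slope_prior
NULL

#' @rdname slope_prior
#' @export
point_prior <- function(value) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) || value < 0) {
    stop("point prior `value` must be a single number >= 0", call. = FALSE)
  }
  structure(list(kind = "point", value = value), class = "slope_prior")
}

#' @rdname slope_prior
#' @export
gamma_prior <- function(shape = 1, rate = 0.5) {
  if (!is.numeric(shape) || length(shape) != 1L || !is.finite(shape) || shape <= 0) {
    stop("gamma prior `shape` must be > 0", call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    stop("gamma prior `rate` must be > 0", call. = FALSE)
  }
  structure(list(kind = "gamma", shape = shape, rate = rate),
            class = "slope_prior")
}

#' @export
print.slope_prior <- function(x, ...) {
  if (x$kind == "point") {
    cat("Slope-variance prior: point mass at", x$value, "\n")
  } else {
    cat(sprintf("Slope-variance prior: gamma(shape = %g, rate = %g)\n",
                x$shape, x$rate))
  }
  invisible(x)
}

# draw one true sigma2_S from a design prior (uses the current RNG stream)
sample_slope_prior <- function(prior) {
  stopifnot(inherits(prior, "slope_prior"))
  if (prior$kind == "point") prior$value
  else stats::rgamma(1L, shape = prior$shape, rate = prior$rate)
}

# log likelihood of the sample moments as a function of sigma2_S, all other
# parameters fixed; the Nk*log(2*pi)/2 constant is omitted throughout
log_lik_at_slope_var <- function(v, data, design, params) {
  p <- params
  p$sigma2_S <- v
  -0.5 * minus_two_log_likelihood(implied_moments(design, p), data)
}

#' Log marginal likelihood of sample moments under a slope-variance prior
#'
#' For a point prior this is the log likelihood at that value. For a gamma
#' prior it is \eqn{\log \int_0^\infty L(\mathrm{data} \mid \sigma_S^2)\,
#' \mathrm{Gamma}(\sigma_S^2; \mathrm{shape}, \mathrm{rate})\,
#' d\sigma_S^2}, evaluated in log space: the integrand is normalised at its
#' mode (located by a coarse log-spaced grid refined with [stats::optimize()])
#' and integrated with adaptive quadrature ([stats::integrate()]) on the two
#' pieces meeting at the mode, \eqn{(0, \hat v)} and \eqn{(\hat v, \infty)}. The
#' \eqn{N k \ln(2\pi)/2} constant is omitted consistently, so only
#' differences of the returned values are meaningful.
#'
#' @param data A [sample_moments()] object.
#' @param design A [measurement_design()].
#' @param params An [lgcm_parameters()] object carrying the fixed nuisance
#'   parameters; its `sigma2_S` entry is ignored (the prior replaces it).
#' @param prior A [point_prior()] or [gamma_prior()] on \eqn{\sigma_S^2}.
#' @return Scalar log marginal likelihood (up to the shared omitted
#'   constant). Errors, rather than returning silently, if the quadrature
#'   does not converge.
#' @export
log_marginal_likelihood <- function(data, design, params, prior) {
  stopifnot(inherits(data, "sample_moments"),
            inherits(prior, "slope_prior"))
  if (prior$kind == "point") {
    return(log_lik_at_slope_var(prior$value, data, design, params))
  }

  g <- function(v) {
    log_lik_at_slope_var(v, data, design, params) +
      stats::dgamma(v, shape = prior$shape, rate = prior$rate, log = TRUE)
  }

  # locate the mode of the integrand: coarse grid in log space, then refine
  grid <- c(1e-6, exp(seq(log(1e-3), log(1e3), length.out = 50)))
  gv <- vapply(grid, g, numeric(1))
  i <- which.max(gv)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(g, lower = lo, upper = hi, maximum = TRUE,
                         tol = 1e-9)
  v_hat <- opt$maximum
  g_max <- max(opt$objective, gv[i])

  # split at the mode so each piece has its peak on a boundary, which the
  # adaptive rule always resolves, however narrow the integrand
  f <- function(v) exp(vapply(v, g, numeric(1)) - g_max)
  split <- max(v_hat, 1e-8)
  q1 <- stats::integrate(f, 0, split, rel.tol = 1e-10, abs.tol = 0,
                         subdivisions = 400L, stop.on.error = FALSE)
  q2 <- stats::integrate(f, split, Inf, rel.tol = 1e-10, abs.tol = 0,
                         subdivisions = 400L, stop.on.error = FALSE)
  total <- q1$value + q2$value
  err <- q1$abs.error + q2$abs.error
  ok <- q1$message == "OK" && q2$message == "OK"
  if (!ok || !is.finite(total) || total <= 0 || err > 1e-6 * total) {
    stop(sprintf(
      "marginal-likelihood quadrature did not converge (value %.3e, estimated error %.3e)",
      total, err), call. = FALSE)
  }
  g_max + log(total)
}

#' Bayes factor for the slope-variance test
#'
#' Computes \eqn{BF_{10}}, the ratio of the marginal likelihood of the data
#' under \eqn{H_1: \sigma_S^2 \sim \pi_1} to the likelihood under
#' \eqn{H_0: \sigma_S^2 = 0}, with all nuisance parameters fixed at the
#' values in `params`. Both marginal likelihoods omit the same additive
#' constant, so the ratio is exact. The computation is identical whether
#' `data`/`design`/`params` describe the full k-occasion model or the
#' univariate minimal model produced by [reduce_dataset()]; the two routes
#' give the same Bayes factor.
#'
#' @inheritParams log_marginal_likelihood
#' @param prior_h1 Prior on \eqn{\sigma_S^2} under \eqn{H_1}.
#' @return An object of class `"bayes_factor"`: list with `log_bf10`
#'   (natural log) and `bf10`.
#' @examples
#' d <- measurement_design(0:6)
#' p <- lgcm_parameters(sigma2_I = 43.6, sigma2_S = 0, sigma2_E = 21.45)
#' s <- simulate_sample(d, p, N = 50, seed = 1)
#' bayes_factor_10(s$moments, d, p, gamma_prior(1, 0.5))
#' @export
bayes_factor_10 <- function(data, design, params, prior_h1) {
  log_m1 <- log_marginal_likelihood(data, design, params, prior_h1)
  log_m0 <- log_marginal_likelihood(data, design, params, point_prior(0))
  log_bf <- log_m1 - log_m0
  structure(list(log_bf10 = log_bf, bf10 = exp(log_bf)),
            class = "bayes_factor")
}

#' @export
print.bayes_factor <- function(x, ...) {
  cat(sprintf("BF10 = %.6g  (log BF10 = %.4f)\n", x$bf10, x$log_bf10))
  invisible(x)
}
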