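#' Effective error variance of a design for the slope-variance test
#'
#' The information a design carries about the latent slope can be summarised
#' by a single number: the error variance attached to the generalized
#' least-squares slope score. With null covariance
#' \eqn{\Sigma_0 = \sigma_I^2 11' + \sigma_E^2 I} the effective error
#' variance is the inverse GLS precision
#' \deqn{\sigma_{eff}^2 = (\lambda' \Sigma_0^{-1} \lambda)^{-1}
#'   = \frac{\sigma_E^2}{\sum_j \lambda_j^2 -
#'     (\sum_j \lambda_j)^2 / (k + \sigma_E^2/\sigma_I^2)}.}
#' Two designs with equal \eqn{\sigma_{eff}^2} are power equivalent for the
#' test of \eqn{\sigma_S^2}: they carry identical information about the slope
#' variance and share one Bayes-factor distribution.
#'
#' @param design A [measurement_design()] with slope loadings \eqn{\lambda}.
#' @param sigma2_I Intercept variance \eqn{\ge 0}. `sigma2_I = 0` uses the
#'   limit \eqn{\sigma_E^2 / \sum \lambda^2}.
#' @param sigma2_E Residual variance \eqn{> 0}.
#' @return The effective error variance, a positive scalar.
#' @examples
#' d <- measurement_design(0:6)
#' effective_error_variance(d, sigma2_I = 43.6, sigma2_E = 21.45)
#' @export
effective_error_variance <- function(design, sigma2_I, sigma2_E) {
  stopifnot(inherits(design, "measurement_design"))
  if (!is.finite(sigma2_E) || sigma2_E <= 0) {
    stop("`sigma2_E` must be > 0", call. = FALSE)
  }
  if (!is.finite(sigma2_I) || sigma2_I < 0) {
    stop("`sigma2_I` must be >= 0", call. = FALSE)
  }
  lam <- design$slope_loadings
  if (all(lam == 0)) {
    stop("slope loadings are all zero: the design carries no information about the slope",
         call. = FALSE)
  }
  k <- length(lam)
  denom <- if (sigma2_I == 0) {
    sum(lam^2)
  } else {
    sum(lam^2) - sum(lam)^2 / (k + sigma2_E / sigma2_I)
  }
  if (denom <= 0) {
    stop("degenerate design: non-positive GLS precision for the slope",
         call. = FALSE)
  }
  sigma2_E / denom
}

# GLS slope-score weights w such that s_hat_i = w' y_i; w = sigma2_eff *
# Sigma0^-1 lambda. Shared by reduce_dataset and kept separate so the
# covariance algebra is written once.
slope_score_weights <- function(design, sigma2_I, sigma2_E) {
  lam <- design$slope_loadings
  k <- length(lam)
  s2eff <- effective_error_variance(design, sigma2_I, sigma2_E)
  Sigma0 <- sigma2_I * matrix(1, k, k) + sigma2_E * diag(k)
  w <- s2eff * solve(Sigma0, lam)
  list(w = drop(w), sigma2_eff = s2eff)
}

#' Reduce a dataset to its minimal power-equivalent form
#'
#' Projects each participant's observation vector onto the GLS slope score
#' \eqn{\hat{s}_i = \sigma_{eff}^2 \, \lambda' \Sigma_0^{-1} y_i}. Under the
#' generating LGCM, \eqn{\hat{s}_i \sim N(\mu^*, \sigma_S^2 +
#' \sigma_{eff}^2)}: a univariate model that carries all the information the
#' full k-variate data hold about the slope variance. The Bayes factor for
#' \eqn{\sigma_S^2} computed from the reduced scores equals the one computed
#' from the full data.
#'
#' @inheritParams effective_error_variance
#' @param data N x k numeric matrix of raw observations (or an
#'   `"lgcm_sample"`).
#' @param mu Optional length-k model mean vector of the full model, used to
#'   locate the minimal model's mean \eqn{\mu^* = w'\mu}. Defaults to zeros.
#' @return An object of class `"reduced_data"`: list with `scores` (length-N
#'   vector), `moments` (their 1 x 1 [sample_moments()]), `design` and
#'   `params` describing the minimal univariate model
#'   \eqn{N(\mu^*, \sigma_S^2 + \sigma_{eff}^2)} (slope loading 1, residual
#'   variance \eqn{\sigma_{eff}^2}), and `sigma2_eff`.
#' @seealso [bayes_factor_10()] accepts the reduced `moments`/`design`/
#'   `params` triple directly.
#' @export
reduce_dataset <- function(design, sigma2_I, sigma2_E, data, mu = NULL) {
  stopifnot(inherits(design, "measurement_design"))
  if (inherits(data, "lgcm_sample")) data <- data$data
  data <- as.matrix(data)
  k <- n_occasions(design)
  if (ncol(data) != k) {
    stop("`data` must have one column per design occasion", call. = FALSE)
  }
  if (is.null(mu)) mu <- rep(0, k)
  if (length(mu) != k) stop("`mu` must have length k", call. = FALSE)
  ws <- slope_score_weights(design, sigma2_I, sigma2_E)
  scores <- drop(data %*% ws$w)
  mu_star <- drop(crossprod(ws$w, mu))
  min_design <- measurement_design(times = 0, slope_loadings = 1)
  min_params <- lgcm_parameters(sigma2_I = 0, sigma2_S = 0,
                                sigma2_E = ws$sigma2_eff,
                                mu_I = mu_star, mu_S = 0)
  structure(list(scores = scores,
                 moments = compute_sample_moments(matrix(scores, ncol = 1)),
                 design = min_design, params = min_params,
                 sigma2_eff = ws$sigma2_eff),
            class = "reduced_data")
}

#' @export
print.reduced_data <- function(x, ...) {
  cat("Reduced dataset:", length(x$scores), "slope scores;",
      "sigma2_eff =", format(x$sigma2_eff, digits = 6), "\n")
  invisible(x)
}

# shape constant of an equally spaced design 0..T with lambda = times:
# lambda' Sigma0^-1 lambda = T^2 * c(k, r) / sigma2_E, r = sigma2_E/sigma2_I
pe_shape_constant <- function(k, r) {
  js <- (0:(k - 1)) / (k - 1)
  if (is.infinite(r)) sum(js^2) else sum(js^2) - sum(js)^2 / (k + r)
}

#' Solve for an equally spaced power-equivalent design
#'
#' Finds the equally spaced design with `k_new` occasions, first occasion at
#' time 0 and slope loadings equal to the occasion times, whose effective
#' error variance equals that of a reference design. The duration has the
#' closed form
#' \deqn{T = \sqrt{ \sigma_E^2 / (\sigma_{eff,ref}^2 \; c(k, r)) }, \qquad
#'   c(k, r) = \sum_{j=0}^{k-1} \left(\tfrac{j}{k-1}\right)^2 -
#'   \frac{\left(\sum_{j=0}^{k-1} j/(k-1)\right)^2}{k + r}, \quad
#'   r = \sigma_E^2/\sigma_I^2,}
#' which the function confirms with a numeric root-finder on the
#' effective-error equality before returning.
#'
#' @param k_new Number of occasions of the solved design, `k_new >= 2`.
#' @param reference A [measurement_design()] whose effective error variance
#'   is to be matched (any layout, not necessarily equally spaced).
#' @param sigma2_I,sigma2_E Fixed nuisance variances shared by both designs.
#' @return A [measurement_design()] with attribute `"sigma2_eff"` carrying
#'   the matched effective error variance.
#' @examples
#' ref <- measurement_design(0:6)
#' solve_equivalent_design(3, ref, sigma2_I = 43.6, sigma2_E = 21.45)
#' @export
solve_equivalent_design <- function(k_new, reference, sigma2_I, sigma2_E) {
  k_new <- as.integer(k_new)
  if (is.na(k_new) || k_new < 2L) {
    stop("`k_new` must be an integer >= 2", call. = FALSE)
  }
  s2eff_ref <- effective_error_variance(reference, sigma2_I, sigma2_E)
  r <- if (sigma2_I > 0) sigma2_E / sigma2_I else Inf
  cc <- pe_shape_constant(k_new, r)
  if (cc <= 0) stop("no positive solution for the requested design", call. = FALSE)
  T_closed <- sqrt(sigma2_E / (s2eff_ref * cc))

  # confirm the closed form on the effective-error equality itself;
  # sigma2_eff(T) is strictly decreasing in T so the root is unique
  f <- function(T) {
    effective_error_variance(equally_spaced_design(k_new, T),
                             sigma2_I, sigma2_E) - s2eff_ref
  }
  root <- stats::uniroot(f, interval = c(1e-6, 1e3), tol = 1e-10)$root
  if (abs(root - T_closed) > 1e-6 * max(1, T_closed)) {
    stop("closed-form duration not confirmed by root-finding", call. = FALSE)
  }

  out <- equally_spaced_design(k_new, T_closed)
  attr(out, "sigma2_eff") <- s2eff_ref
  out
}
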