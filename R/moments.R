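#' Model-implied mean and covariance of an LGCM
#'
#' Assembles the moments of the multivariate normal distribution implied by a
#' linear latent growth curve model:
#' \deqn{\Sigma = \sigma_I^2 \, 11' + \sigma_S^2 \, \lambda\lambda' +
#'   \sigma_{IS} (1\lambda' + \lambda 1') + \sigma_E^2 I, \qquad
#'   \mu_j = \mu_I + \mu_S t_j.}
#'
#' @param design A [measurement_design()].
#' @param params An [lgcm_parameters()] object.
#' @return An object of class `"implied_moments"`: list with `Sigma` (k x k
#'   covariance) and `mu` (length-k mean).
#' @examples
#' d <- measurement_design(0:6)
#' p <- lgcm_parameters(sigma2_I = 43.6, sigma2_S = 1, sigma2_E = 21.45)
#' implied_moments(d, p)$Sigma[1:3, 1:3]
#' @export
implied_moments <- function(design, params) {
  stopifnot(inherits(design, "measurement_design"),
            inherits(params, "lgcm_parameters"))
  lam <- design$slope_loadings
  k <- length(lam)
  ones <- rep(1, k)
  Sigma <- params$sigma2_I * tcrossprod(ones) +
    params$sigma2_S * tcrossprod(lam) +
    params$sigma_IS * (tcrossprod(ones, lam) + tcrossprod(lam, ones)) +
    params$sigma2_E * diag(k)
  mu <- params$mu_I + params$mu_S * design$times
  structure(list(Sigma = Sigma, mu = mu), class = "implied_moments")
}

#' Per-participant sample moments
#'
#' Container for the sufficient statistics of a multivariate-normal sample:
#' the maximum-likelihood sample covariance (divisor `N`), the sample mean,
#' and the number of participants. These are the only data quantities the
#' likelihood, and hence every Bayes factor in this package, depends on.
#'
#' @param S k x k sample covariance matrix, ML form (divisor `N`).
#' @param m Length-k sample mean vector.
#' @param N Number of participants, `N >= 1`.
#' @return An object of class `"sample_moments"`.
#' @seealso [compute_sample_moments()], [simulate_sample()]
#' @export
sample_moments <- function(S, m, N) {
  S <- as.matrix(S)
  m <- as.numeric(m)
  if (nrow(S) != ncol(S) || nrow(S) != length(m)) {
    stop("`S` must be square with dimension matching `m`", call. = FALSE)
  }
  if (anyNA(S) || any(!is.finite(S)) || anyNA(m) || any(!is.finite(m))) {
    stop("`S` and `m` must be finite", call. = FALSE)
  }
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S)))) {
    stop("`S` must be symmetric", call. = FALSE)
  }
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N < 1) {
    stop("`N` must be a count >= 1", call. = FALSE)
  }
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(1, max(abs(ev)))) {
    stop("`S` must be positive semidefinite", call. = FALSE)
  }
  structure(list(S = (S + t(S)) / 2, m = m, N = as.integer(N)),
            class = "sample_moments")
}

#' Sample moments of a raw data matrix
#'
#' @param data N x k numeric matrix, one row per participant.
#' @return A [sample_moments()] object with the ML (divisor `N`) covariance.
#' @export
compute_sample_moments <- function(data) {
  data <- as.matrix(data)
  N <- nrow(data)
  if (N < 1L) stop("`data` must have at least one row", call. = FALSE)
  m <- colMeans(data)
  centred <- sweep(data, 2L, m)
  S <- crossprod(centred) / N
  sample_moments(S, m, N)
}

#' @export
print.implied_moments <- function(x, ...) {
  cat("Implied moments for", length(x$mu), "occasions\n")
  cat("mu:\n")
  print(x$mu)
  cat("Sigma:\n")
  print(x$Sigma)
  invisible(x)
}

#' @export
print.sample_moments <- function(x, ...) {
  cat("Sample moments: N =", x$N, ", k =", length(x$m), "\n")
  invisible(x)
}
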