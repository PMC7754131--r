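#' Population parameters of a latent growth curve model
#'
#' Collects the latent (co)variances, the residual variance and the latent
#' means of a linear LGCM. The focal parameter of the hypothesis test
#' implemented in this package is the slope variance `sigma2_S`; all other
#' entries are nuisance parameters treated as known and fixed.
#'
#' @param sigma2_I Intercept variance \eqn{\sigma_I^2 \ge 0}: between-person
#'   variability at the occasion where the slope loading is zero.
#' @param sigma2_S Slope variance \eqn{\sigma_S^2 \ge 0}: between-person
#'   variability of the rate of change.
#' @param sigma2_E Residual variance \eqn{\sigma_E^2 > 0} of the
#'   occasion-specific measurement error.
#' @param sigma_IS Intercept-slope covariance \eqn{\sigma_{IS}}; the 2x2
#'   latent covariance matrix must be positive semidefinite. Defaults to 0.
#' @param mu_I,mu_S Latent intercept and slope means; default 0. The Bayes
#'   factor for the slope variance is invariant to known means, so the
#'   defaults only pin down simulated datasets.
#'
#' @return An object of class `"lgcm_parameters"`.
#' @examples
#' lgcm_parameters(sigma2_I = 43.6, sigma2_S = 0, sigma2_E = 21.45)
#' @export
lgcm_parameters <- function(sigma2_I, sigma2_S, sigma2_E, sigma_IS = 0,
                            mu_I = 0, mu_S = 0) {
  for (nm in c("sigma2_I", "sigma2_S", "sigma2_E", "sigma_IS", "mu_I", "mu_S")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("`%s` must be a single finite number", nm), call. = FALSE)
    }
  }
  if (sigma2_I < 0) stop("`sigma2_I` must be >= 0", call. = FALSE)
  if (sigma2_S < 0) stop("`sigma2_S` must be >= 0", call. = FALSE)
  if (sigma2_E <= 0) stop("`sigma2_E` must be > 0", call. = FALSE)
  # PSD of [[sigma2_I, sigma_IS], [sigma_IS, sigma2_S]], with a little slack
  # for round-tripped values
  if (sigma_IS^2 > sigma2_I * sigma2_S * (1 + 1e-12) + 1e-12) {
    stop("`sigma_IS` violates positive semidefiniteness of the latent covariance",
         call. = FALSE)
  }
  structure(list(sigma2_I = sigma2_I, sigma2_S = sigma2_S,
                 sigma2_E = sigma2_E, sigma_IS = sigma_IS,
                 mu_I = mu_I, mu_S = mu_S),
            class = "lgcm_parameters")
}

#' @export
print.lgcm_parameters <- function(x, ...) {
  cat("LGCM parameters:\n")
  cat(sprintf("  sigma2_I = %g, sigma2_S = %g, sigma_IS = %g, sigma2_E = %g\n",
              x$sigma2_I, x$sigma2_S, x$sigma_IS, x$sigma2_E))
  cat(sprintf("  mu_I = %g, mu_S = %g\n", x$mu_I, x$mu_S))
  invisible(x)
}
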