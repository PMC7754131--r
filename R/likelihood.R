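#' Minus two log-likelihood of sample moments under a multivariate normal
#'
#' Evaluates, for model moments \eqn{(\Sigma, \mu)} and sample moments
#' \eqn{(S, m)} of \eqn{N} participants,
#' \deqn{N \left[ \ln|\Sigma| + \mathrm{Tr}(\Sigma^{-1} S) +
#'   (m - \mu)' \Sigma^{-1} (m - \mu) \right].}
#' The additive constant \eqn{N k \ln(2\pi)} is omitted: every quantity this
#' package derives from the likelihood is a difference or a ratio in which it
#' cancels. The value is invariant under a joint orthogonal transformation of
#' \eqn{(\Sigma, \mu, S, m)}, which is what makes power-equivalent reductions
#' possible.
#'
#' @param moments An [implied_moments()] object (or list with `Sigma`, `mu`).
#' @param data A [sample_moments()] object.
#' @return The scalar minus-two-log-likelihood (constant omitted).
#' @export
minus_two_log_likelihood <- function(moments, data) {
  Sigma <- moments$Sigma
  mu <- moments$mu
  if (length(mu) != length(data$m) || nrow(Sigma) != length(data$m)) {
    stop("dimension mismatch between model moments and sample moments",
         call. = FALSE)
  }
  R <- tryCatch(chol(Sigma), error = function(e) {
    stop("model covariance `Sigma` is singular or not positive definite",
         call. = FALSE)
  })
  log_det <- 2 * sum(log(diag(R)))
  Sigma_inv <- chol2inv(R)
  trace_term <- sum(Sigma_inv * data$S)
  d <- data$m - mu
  quad <- drop(crossprod(d, Sigma_inv %*% d))
  data$N * (log_det + trace_term + quad)
}
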