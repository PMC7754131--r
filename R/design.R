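#' Define a longitudinal measurement design
#'
#' A measurement design fixes the occasion times at which an outcome is
#' observed (in study-time units, typically weeks) and the loading of each
#' occasion on the latent slope. Loadings on the latent intercept are always
#' 1 and are therefore not stored. Slope loadings default to the occasion
#' times themselves, which encodes linear growth: occasion \eqn{j} is modelled
#' as \eqn{x_j = I + \lambda_j S + e_j}.
#'
#' @param times Numeric vector of occasion times, strictly increasing,
#'   length \eqn{k \ge 1}.
#' @param slope_loadings Numeric vector \eqn{\lambda} of slope loadings, one
#'   per occasion. Defaults to `times` (linear growth).
#'
#' @return An object of class `"measurement_design"`: a list with elements
#'   `times` and `slope_loadings`.
#'
#' @examples
#' # seven weekly assessments over six weeks
#' measurement_design(0:6)
#'
#' @seealso [equally_spaced_design()], [implied_moments()]
#' @export
measurement_design <- function(times, slope_loadings = times) {
  times <- as.numeric(times)
  if (length(times) < 1L) {
    stop("`times` must contain at least one occasion", call. = FALSE)
  }
  if (anyNA(times) || any(!is.finite(times))) {
    stop("`times` must be finite and non-missing", call. = FALSE)
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  slope_loadings <- as.numeric(slope_loadings)
  if (length(slope_loadings) != length(times)) {
    stop("`slope_loadings` must have one entry per occasion in `times`",
         call. = FALSE)
  }
  if (anyNA(slope_loadings) || any(!is.finite(slope_loadings))) {
    stop("`slope_loadings` must be finite and non-missing", call. = FALSE)
  }
  structure(list(times = times, slope_loadings = slope_loadings),
            class = "measurement_design")
}

#' Equally spaced design starting at time zero
#'
#' Convenience constructor for the design family used when solving for
#' power-equivalent layouts: `k` occasions at times
#' \eqn{0, T/(k-1), \dots, T}, slope loadings equal to the times.
#'
#' @param k Number of occasions, `k >= 2`.
#' @param duration Total study duration \eqn{T > 0} (last minus first
#'   occasion time).
#' @return A [measurement_design()].
#' @export
equally_spaced_design <- function(k, duration) {
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("`k` must be an integer >= 2", call. = FALSE)
  if (!is.finite(duration) || duration <= 0) {
    stop("`duration` must be a positive number", call. = FALSE)
  }
  measurement_design(seq(0, duration, length.out = k))
}

#' @export
print.measurement_design <- function(x, ...) {
  cat("Measurement design:", length(x$times), "occasions over",
      format(design_duration(x)), "time units\n")
  cat("  times         :", paste(format(x$times, digits = 4), collapse = " "), "\n")
  cat("  slope loadings:", paste(format(x$slope_loadings, digits = 4), collapse = " "), "\n")
  invisible(x)
}

#' Number of occasions in a design
#' @param design A [measurement_design()].
#' @return Integer count of measurement occasions.
#' @export
n_occasions <- function(design) {
  stopifnot(inherits(design, "measurement_design"))
  length(design$times)
}

#' Total study duration of a design
#' @param design A [measurement_design()].
#' @return Last minus first occasion time.
#' @export
design_duration <- function(design) {
  stopifnot(inherits(design, "measurement_design"))
  design$times[length(design$times)] - design$times[1L]
}
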