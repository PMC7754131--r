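#' Simulate a dataset from a latent growth curve model
#'
#' Draws `N` independent participants from the multivariate normal
#' distribution implied by `design` and `params` (see [implied_moments()])
#' and returns both the raw data matrix and its [sample_moments()]. The same
#' `seed` with the same inputs reproduces the draw bit for bit.
#'
#' @param design A [measurement_design()].
#' @param params An [lgcm_parameters()] object.
#' @param N Number of participants, `N >= 1`.
#' @param seed Optional integer seed. When `NULL`, the current RNG state is
#'   used (and advanced).
#' @return An object of class `"lgcm_sample"`: list with `data` (N x k
#'   matrix, columns named by occasion time), `moments` (a
#'   [sample_moments()]), `design` and `params`.
#' @examples
#' d <- measurement_design(0:6)
#' p <- lgcm_parameters(sigma2_I = 43.6, sigma2_S = 0, sigma2_E = 21.45)
#' s <- simulate_sample(d, p, N = 50, seed = 1)
#' dim(s$data)
#' @export
simulate_sample <- function(design, params, N, seed = NULL) {
  stopifnot(inherits(design, "measurement_design"),
            inherits(params, "lgcm_parameters"))
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N < 1) {
    stop("`N` must be a count >= 1", call. = FALSE)
  }
  N <- as.integer(N)
  if (!is.null(seed)) set.seed(as.integer(seed))
  mom <- implied_moments(design, params)
  data <- MASS::mvrnorm(n = N, mu = mom$mu, Sigma = mom$Sigma)
  data <- matrix(data, nrow = N, ncol = length(mom$mu))
  colnames(data) <- format(design$times, trim = TRUE)
  structure(list(data = data,
                 moments = compute_sample_moments(data),
                 design = design, params = params),
            class = "lgcm_sample")
}

#' @export
print.lgcm_sample <- function(x, ...) {
  cat("Simulated LGCM sample: N =", nrow(x$data), "participants,",
      ncol(x$data), "occasions\n")
  invisible(x)
}

#' Write a simulated sample to CSV
#'
#' One row per participant, one column per occasion; the header carries the
#' occasion times, so the file round-trips into a design skeleton.
#'
#' @param sample An `"lgcm_sample"` from [simulate_sample()], or a plain
#'   numeric matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sample_csv <- function(sample, path) {
  data <- if (inherits(sample, "lgcm_sample")) sample$data else as.matrix(sample)
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' Read a sample written by [write_sample_csv()]
#'
#' @param path CSV file path.
#' @return Numeric matrix, one row per participant.
#' @export
read_sample_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  as.matrix(df)
}
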