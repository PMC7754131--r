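#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration describing a design, its population
#' parameters, priors, BFDA settings and a cost model, validates it, fills
#' defaults and resolves it into the package's types. Unknown keys are
#' rejected (typo safety) and every violated constraint is reported with the
#' offending key name.
#'
#' Recognised top-level keys: `seed`, `design` (`times`, optional
#' `slope_loadings`), `params` (`sigma2_I`, `sigma2_S`, `sigma2_E`, optional
#' `sigma_IS`, `mu_I`, `mu_S`), `analysis_prior` and `design_prior`
#' (`kind: point|gamma` plus `value` or `shape`/`rate`), `bfda` (`N`,
#' `n_iter`, `lower`, `upper`) and `costs`
#' (`cost_per_wave_per_participant`, `running_cost_per_week`, `N`).
#' Defaults: analysis prior gamma(1, 0.5); design prior = point mass at
#' `params$sigma2_S`; BFDA `n_iter` 500, thresholds 1/10 and 10, `N` 100;
#' seed 1.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An object of class `"run_config"`: list with resolved `seed`,
#'   `design`, `params`, `analysis_prior`, `design_prior`, `bfda` (list) and
#'   `costs` (a [cost_model()] or `NULL`).
#' @seealso [save_config()] for the canonical JSON serialization.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config file must be .yaml, .yml or .json: ", path, call. = FALSE)
  }
  resolve_config(raw)
}

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config key%s in `%s`: %s",
                 if (length(unknown) > 1L) "s" else "", where,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
}

resolve_prior <- function(x, where) {
  if (is.null(x)) return(NULL)
  check_keys(x, c("kind", "value", "shape", "rate"), where)
  kind <- x$kind
  if (is.null(kind) || !kind %in% c("point", "gamma")) {
    stop(sprintf("`%s$kind` must be \"point\" or \"gamma\"", where),
         call. = FALSE)
  }
  if (kind == "point") {
    if (is.null(x$value)) {
      stop(sprintf("`%s` of kind point needs `value`", where), call. = FALSE)
    }
    point_prior(x$value)
  } else {
    gamma_prior(shape = x$shape %||% 1, rate = x$rate %||% 0.5)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolve_config <- function(raw) {
  if (!is.list(raw)) stop("config must be a mapping of sections", call. = FALSE)
  check_keys(raw, c("seed", "design", "params", "analysis_prior",
                    "design_prior", "bfda", "costs"), "<top level>")
  if (is.null(raw$design) || is.null(raw$design$times)) {
    stop("config requires `design$times`", call. = FALSE)
  }
  check_keys(raw$design, c("times", "slope_loadings"), "design")
  design <- measurement_design(raw$design$times,
                               raw$design$slope_loadings %||% raw$design$times)

  if (is.null(raw$params)) stop("config requires `params`", call. = FALSE)
  check_keys(raw$params, c("sigma2_I", "sigma2_S", "sigma2_E", "sigma_IS",
                           "mu_I", "mu_S"), "params")
  for (nm in c("sigma2_I", "sigma2_S", "sigma2_E")) {
    if (is.null(raw$params[[nm]])) {
      stop(sprintf("config requires `params$%s`", nm), call. = FALSE)
    }
  }
  params <- lgcm_parameters(sigma2_I = raw$params$sigma2_I,
                            sigma2_S = raw$params$sigma2_S,
                            sigma2_E = raw$params$sigma2_E,
                            sigma_IS = raw$params$sigma_IS %||% 0,
                            mu_I = raw$params$mu_I %||% 0,
                            mu_S = raw$params$mu_S %||% 0)

  analysis_prior <- resolve_prior(raw$analysis_prior, "analysis_prior") %||%
    gamma_prior(1, 0.5)
  design_prior <- resolve_prior(raw$design_prior, "design_prior") %||%
    point_prior(params$sigma2_S)

  bfda_raw <- raw$bfda %||% list()
  check_keys(bfda_raw, c("N", "n_iter", "lower", "upper"), "bfda")
  bfda <- list(N = as.integer(bfda_raw$N %||% 100L),
               n_iter = as.integer(bfda_raw$n_iter %||% 500L),
               lower = bfda_raw$lower %||% 0.1,
               upper = bfda_raw$upper %||% 10)
  if (bfda$lower >= bfda$upper) {
    stop("`bfda$lower` must be smaller than `bfda$upper`", call. = FALSE)
  }

  costs <- NULL
  if (!is.null(raw$costs)) {
    check_keys(raw$costs, c("cost_per_wave_per_participant",
                            "running_cost_per_week", "N"), "costs")
    costs <- cost_model(
      cost_per_wave_per_participant = raw$costs$cost_per_wave_per_participant %||% 10,
      running_cost_per_week = raw$costs$running_cost_per_week %||% 500,
      N = raw$costs$N %||% bfda$N)
  }

  structure(list(seed = as.integer(raw$seed %||% 1L),
                 design = design, params = params,
                 analysis_prior = analysis_prior,
                 design_prior = design_prior,
                 bfda = bfda, costs = costs),
            class = "run_config")
}

prior_to_list <- function(prior) {
  if (prior$kind == "point") list(kind = "point", value = prior$value)
  else list(kind = "gamma", shape = prior$shape, rate = prior$rate)
}

#' Plain-list form of a resolved configuration
#'
#' Inverse of the resolution performed by [load_config()]: a fully explicit
#' list (no defaults left implicit) that serializes to the canonical JSON
#' form and loads back to an identical `run_config`.
#'
#' @param config A `"run_config"` object.
#' @return A named list mirroring the config file schema.
#' @export
config_to_list <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- list(
    seed = config$seed,
    design = list(times = config$design$times,
                  slope_loadings = config$design$slope_loadings),
    params = unclass(config$params),
    analysis_prior = prior_to_list(config$analysis_prior),
    design_prior = prior_to_list(config$design_prior),
    bfda = config$bfda
  )
  if (!is.null(config$costs)) {
    out$costs = list(
      cost_per_wave_per_participant = config$costs$cost_per_wave_per_participant,
      running_cost_per_week = config$costs$running_cost_per_week,
      N = config$costs$N)
  }
  out
}

#' Serialize a resolved configuration to JSON
#'
#' Writes the fully resolved configuration (defaults made explicit, full
#' numeric precision) so that every run can leave an audit copy of exactly
#' what it executed. `load_config(save_config(x, path))` returns a config
#' identical to `x`.
#'
#' @param config A `"run_config"` object.
#' @param path Output path, conventionally ending in `.json`.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(config_to_list(config), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration (seed ", x$seed, ")\n", sep = "")
  print(x$design)
  print(x$params)
  cat("analysis prior: ")
  print(x$analysis_prior)
  cat("design prior:   ")
  print(x$design_prior)
  cat(sprintf("BFDA: N = %d, n_iter = %d, thresholds %g / %g\n",
              x$bfda$N, x$bfda$n_iter, x$bfda$lower, x$bfda$upper))
  invisible(x)
}

#' Build a BFDA configuration from a resolved run configuration
#'
#' @param config A `"run_config"` from [load_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return A [bfda_config()].
#' @export
as_bfda_config <- function(config, seed = NULL) {
  stopifnot(inherits(config, "run_config"))
  bfda_config(design = config$design, params = config$params,
              design_prior = config$design_prior,
              analysis_prior = config$analysis_prior,
              N = config$bfda$N, n_iter = config$bfda$n_iter,
              seed = seed %||% config$seed,
              lower = config$bfda$lower, upper = config$bfda$upper)
}
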