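#' Study cost model
#'
#' Two cost drivers of a longitudinal study: a per-occasion, per-participant
#' assessment cost (compensation, data entry) and a per-week running cost
#' (lab space, staff). Defaults are $10 per wave per participant and $500
#' per week.
#'
#' @param cost_per_wave_per_participant Currency units per measurement
#'   occasion per participant; default 10.
#' @param running_cost_per_week Currency units per week of study duration;
#'   default 500.
#' @param N Number of participants.
#' @return An object of class `"cost_model"`.
#' @export
cost_model <- function(cost_per_wave_per_participant = 10,
                       running_cost_per_week = 500, N) {
  for (nm in c("cost_per_wave_per_participant", "running_cost_per_week", "N")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop(sprintf("`%s` must be a single non-negative number", nm),
           call. = FALSE)
    }
  }
  structure(list(cost_per_wave_per_participant = cost_per_wave_per_participant,
                 running_cost_per_week = running_cost_per_week,
                 N = as.integer(N)),
            class = "cost_model")
}

# round half away from zero, for printing whole currency units
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Cost of one design
#'
#' Wave costs are `cost_per_wave_per_participant * N * k`; running costs are
#' `running_cost_per_week * duration` with the *unrounded* duration (last
#' minus first occasion time). Totals are kept at full precision; rounding
#' to whole currency units happens only when printing.
#'
#' @param design A [measurement_design()].
#' @param model A [cost_model()].
#' @return An object of class `"costed_design"`: list with `waves`,
#'   `assessment_time`, `wave_costs`, `running_costs`, `total_costs`.
#' @examples
#' cost_design(measurement_design(0:6), cost_model(N = 50))
#' @export
cost_design <- function(design, model) {
  stopifnot(inherits(design, "measurement_design"),
            inherits(model, "cost_model"))
  k <- n_occasions(design)
  duration <- design_duration(design)
  wave <- model$cost_per_wave_per_participant * model$N * k
  running <- model$running_cost_per_week * duration
  structure(list(waves = k, assessment_time = duration,
                 wave_costs = wave, running_costs = running,
                 total_costs = wave + running),
            class = "costed_design")
}

#' @export
print.costed_design <- function(x, ...) {
  cat(sprintf("%d waves over %.2f weeks: wave costs %s + running costs %s = total %s\n",
              x$waves, x$assessment_time,
              format(round_half_up(x$wave_costs), big.mark = ","),
              format(round_half_up(x$running_costs), big.mark = ","),
              format(round_half_up(x$total_costs), big.mark = ",")))
  invisible(x)
}

#' Rank power-equivalent designs by total cost
#'
#' For every requested number of occasions, solves for the equally spaced
#' design power equivalent to `reference` (see [solve_equivalent_design()]),
#' costs it, and returns the table sorted by total cost (ties broken by
#' fewer waves). Savings are relative to the cost of the reference design
#' itself.
#'
#' @param reference A [measurement_design()] to match.
#' @param k_list Integer vector of occasion counts to solve for.
#' @param sigma2_I,sigma2_E Fixed nuisance variances.
#' @param model A [cost_model()].
#' @return A `data.frame` with columns `waves`, `assessment_time`,
#'   `wave_costs`, `running_costs`, `total_costs`, `saving_pct` (percent
#'   saving of each row's total versus the reference design's total),
#'   sorted ascending by `total_costs`. The reference total is attached as
#'   attribute `"reference_total"`.
#' @examples
#' rank_equivalent_designs(measurement_design(0:6), c(3, 7),
#'                         sigma2_I = 43.6, sigma2_E = 21.45,
#'                         model = cost_model(N = 50))
#' @export
rank_equivalent_designs <- function(reference, k_list, sigma2_I, sigma2_E,
                                    model) {
  stopifnot(inherits(reference, "measurement_design"),
            inherits(model, "cost_model"))
  k_list <- as.integer(k_list)
  if (length(k_list) < 1L || anyNA(k_list)) {
    stop("`k_list` must contain at least one occasion count", call. = FALSE)
  }
  ref_total <- cost_design(reference, model)$total_costs
  rows <- lapply(k_list, function(k) {
    d <- solve_equivalent_design(k, reference, sigma2_I, sigma2_E)
    cd <- cost_design(d, model)
    data.frame(waves = cd$waves, assessment_time = cd$assessment_time,
               wave_costs = cd$wave_costs, running_costs = cd$running_costs,
               total_costs = cd$total_costs,
               saving_pct = 100 * (1 - cd$total_costs / ref_total))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$total_costs, out$waves), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "reference_total") <- ref_total
  out
}
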