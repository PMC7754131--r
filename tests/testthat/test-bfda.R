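cheap_trio_setup <- function() {
  ref <- measurement_design(0:6)
  list(ref = ref, sigma2_I = 2, sigma2_E = 1)
}

test_that("BFDA configuration validates thresholds and sizes", {
  d <- measurement_design(0:2)
  p <- lgcm_parameters(1, 0, 1)
  expect_error(bfda_config(d, p, design_prior = 0, N = 1), "N")
  expect_error(bfda_config(d, p, design_prior = 0, N = 10, n_iter = 0),
               "n_iter")
  expect_error(bfda_config(d, p, design_prior = 0, N = 10,
                           lower = 10, upper = 1), "lower")
  cfg <- bfda_config(d, p, design_prior = 0.5, N = 10)
  expect_equal(cfg$design_prior$kind, "point")
  expect_equal(cfg$design_prior$value, 0.5)
})

test_that("identical configuration and seed reproduce the run bit for bit", {
  d <- measurement_design(0:2)
  p <- lgcm_parameters(1, 0, 1)
  cfg <- bfda_config(d, p, design_prior = gamma_prior(1, 0.5), N = 20,
                     n_iter = 3, seed = 42)
  r1 <- run_bfda(cfg)
  r2 <- run_bfda(cfg)
  expect_identical(r1$log_bf, r2$log_bf)
  expect_identical(r1$quantiles, r2$quantiles)
})

test_that("result summaries are internally consistent", {
  d <- measurement_design(0:2)
  p <- lgcm_parameters(1, 0, 1)
  cfg <- bfda_config(d, p, design_prior = 0, N = 30, n_iter = 40, seed = 8)
  res <- run_bfda(cfg)
  expect_length(res$log_bf, 40)
  expect_true(res$p_below_lower >= 0 && res$p_below_lower <= 1)
  expect_lte(res$p_below_lower + res$p_above_upper, 1)
  expect_true(all(diff(res$quantiles) >= 0))
  expect_equal(res$p_below_lower, mean(exp(res$log_bf) < 0.1))
  s <- summary(res)
  expect_equal(s$p_inconclusive,
               1 - res$p_below_lower - res$p_above_upper)
})

test_that("an overwhelming true effect pushes almost every BF over the upper threshold", {
  st <- cheap_trio_setup()
  d <- solve_equivalent_design(3, st$ref, st$sigma2_I, st$sigma2_E)
  p <- lgcm_parameters(st$sigma2_I, 0, st$sigma2_E)
  cfg <- bfda_config(d, p, design_prior = 25, N = 300, n_iter = 200,
                     seed = 99)
  res <- run_bfda(cfg)
  expect_gte(res$p_above_upper, 0.995)
})

test_that("under a true null the median Bayes factor favours the null", {
  st <- cheap_trio_setup()
  p <- lgcm_parameters(st$sigma2_I, 0, st$sigma2_E)
  for (k in c(3L, 7L)) {
    d <- solve_equivalent_design(k, st$ref, st$sigma2_I, st$sigma2_E)
    cfg <- bfda_config(d, p, design_prior = 0, N = 100, n_iter = 60,
                       seed = 1000 + k)
    res <- run_bfda(cfg)
    expect_lt(unname(res$quantiles[["50%"]]), 0)
  }
})

test_that("comparing a result with itself gives a zero KS statistic", {
  d <- measurement_design(0:2)
  p <- lgcm_parameters(1, 0, 1)
  cfg <- bfda_config(d, p, design_prior = 0, N = 20, n_iter = 25, seed = 3)
  res <- run_bfda(cfg)
  cmp <- compare_bfda(list(res, res))
  expect_equal(cmp$ks$statistic, 0)
  expect_equal(cmp$ks$p.value, 1)
  expect_error(compare_bfda(list(res)), "at least two")
})

test_that("a deliberately non-equivalent design is flagged by the KS comparison", {
  st <- cheap_trio_setup()
  p <- lgcm_parameters(st$sigma2_I, 1, st$sigma2_E)
  d_eq <- solve_equivalent_design(3, st$ref, st$sigma2_I, st$sigma2_E)
  d_half <- equally_spaced_design(3, design_duration(d_eq) / 2)
  cfg_ref <- bfda_config(st$ref, p, design_prior = 1, N = 100, n_iter = 300,
                         seed = 11)
  cfg_half <- bfda_config(d_half, p, design_prior = 1, N = 100, n_iter = 300,
                          seed = 12)
  cmp <- compare_bfda(list(run_bfda(cfg_ref), run_bfda(cfg_half)))
  expect_lt(cmp$ks$p.value, 0.01)
})

test_that("power-equivalent pairs are not over-flagged across repeated experiments", {
  # 20 independent pairs of BFDAs on two power-equivalent designs; at
  # alpha = 0.01 the expected number of false flags is 0.2, so more than two
  # flags would indicate a real distributional difference
  st <- cheap_trio_setup()
  p <- lgcm_parameters(st$sigma2_I, 0.5, st$sigma2_E)
  d3 <- solve_equivalent_design(3, st$ref, st$sigma2_I, st$sigma2_E)
  d7 <- solve_equivalent_design(7, st$ref, st$sigma2_I, st$sigma2_E)
  flags <- 0
  for (pair in 1:20) {
    r3 <- run_bfda(bfda_config(d3, p, design_prior = 0.5, N = 100,
                               n_iter = 120, seed = 20000 + 2 * pair))
    r7 <- run_bfda(bfda_config(d7, p, design_prior = 0.5, N = 100,
                               n_iter = 120, seed = 20001 + 2 * pair))
    cmp <- compare_bfda(list(r3, r7))
    flags <- flags + (cmp$ks$p.value < 0.01)
  }
  expect_lte(flags, 2)
})
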