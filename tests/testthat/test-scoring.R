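areas <- function(suc = 1, a = 0, b = 0, f = 0, c = 0.25) {
  list(sucrose = suc, alpha_glucose = a, beta_glucose = b, fructose = f,
       citrate = c)
}

t1 <- mandarin_table1()

test_that("sweetening power is the weighted sugar sum", {
  expect_equal(sweetening_power(areas()), 1.0)
  expect_equal(sweetening_power(areas(a = 0.5, b = 0.5, f = 1.0)), 2.9)
  # linearity in the sugar areas
  expect_equal(sweetening_power(areas(a = 1.0, b = 1.0, f = 2.0)), 2 * 2.9 - 1)
  # custom weights override the defaults
  w <- sweetness_weights(sucrose = 2, fructose = 1, glucose = 1)
  expect_equal(sweetening_power(areas(a = 1, b = 1, f = 1), w), 2 + 2 + 1)
})

test_that("the ratio divides sweetening power by the citrate area", {
  expect_equal(sweetness_acid_ratio(areas(a = 0.5, b = 0.5, f = 1.0, c = 0.29)),
               10.0)
  expect_error(sweetness_acid_ratio(areas(c = 0)), "citrate")
  # degree-0 homogeneity: rescaling all five areas changes nothing
  a1 <- areas(a = 0.4, b = 0.3, f = 0.6, c = 0.2)
  a2 <- lapply(a1, function(v) v * 3.7)
  expect_equal(sweetness_acid_ratio(a2), sweetness_acid_ratio(a1),
               tolerance = 1e-12)
})

test_that("the high-field variety regression reproduces the reference fit", {
  fit <- fit_acceptability_model(t1$ratio_400, t1$acceptability)
  expect_equal(fit$fitted_values, c(6.76, 7.27, 5.75, 4.90, 3.53),
               tolerance = 0.011)
  expect_lt(abs(fit$r_squared - 0.94), 0.005)
  expect_lt(abs(fit$rmse - 0.35), 0.005)
  # slope/intercept frozen from the closed-form OLS solution
  expect_equal(fit$slope, 0.6282123, tolerance = 1e-6)
  expect_equal(fit$intercept, 0.9120741, tolerance = 1e-6)
})

test_that("the benchtop variety regression reproduces the reference fit", {
  fit <- fit_acceptability_model(t1$ratio_60, t1$acceptability)
  expect_equal(fit$fitted_values, c(6.88, 7.21, 5.72, 4.89, 3.50),
               tolerance = 0.011)
  expect_lt(abs(fit$rmse - 0.29), 0.005)
  # recomputed from the rounded variety means the coefficient of
  # determination is ~0.955 (the table's own print rounds it up)
  expect_gte(fit$r_squared, 0.95)
  expect_lte(fit$r_squared, 0.96)
})

test_that("OLS machinery satisfies its exact properties", {
  # perfectly collinear data
  x <- c(1, 2, 3, 4, 5)
  fit <- fit_acceptability_model(x, 2 * x + 1)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$rmse, 0, tolerance = 1e-10)
  # residuals sum to zero; fitted-vs-y correlation equals sqrt(R2)
  fit2 <- fit_acceptability_model(t1$ratio_400, t1$acceptability)
  expect_equal(sum(fit2$residuals), 0, tolerance = 1e-10)
  expect_equal(stats::cor(fit2$fitted_values, t1$acceptability),
               sqrt(fit2$r_squared), tolerance = 1e-10)
  # prediction at the mean ratio returns the mean acceptability
  expect_equal(predict(fit2, mean(t1$ratio_400)), mean(t1$acceptability),
               tolerance = 1e-10)
  expect_equal(predict(fit2, 9.31), 6.76, tolerance = 0.011)
  expect_equal(unname(coef(fit2)), c(fit2$intercept, fit2$slope))
  # guards
  expect_error(fit_acceptability_model(c(1, 1, 1), c(1, 2, 3)), "degenerate")
  expect_error(fit_acceptability_model(c(1, 2), c(1, 2)), "3 varieties")
})

test_that("OLS coefficients match an independent grid-search SSE minimiser", {
  gs <- grid_search_ols(t1$ratio_400, t1$acceptability)
  fit <- fit_acceptability_model(t1$ratio_400, t1$acceptability)
  expect_equal(unname(gs["slope"]), fit$slope, tolerance = 1e-6)
  expect_equal(unname(gs["intercept"]), fit$intercept, tolerance = 1e-6)
})

test_that("squared correlation behaves like Pearson r^2", {
  x <- c(1, 3, 2, 5, 4)
  expect_equal(squared_correlation(x, x), 1.0)
  expect_equal(squared_correlation(x, -x), 1.0)
  expect_gt(squared_correlation(t1$ratio_60, t1$ratio_400), 0.99)
  expect_error(squared_correlation(x, rep(1, 5)), "variance")
  expect_error(squared_correlation(x, x[1:3]), "length")
})

test_that("instrument comparison reports the equivalence quantities", {
  va <- data.frame(variety_id = t1$variety_id,
                   acceptability = t1$acceptability,
                   mean_ratio = t1$ratio_400)
  vb <- data.frame(variety_id = t1$variety_id,
                   acceptability = t1$acceptability,
                   mean_ratio = t1$ratio_60)
  cmp <- compare_instruments(va, vb)
  expect_gt(cmp$ratio_r_squared, 0.99)
  expect_gt(cmp$prediction_r_squared, 0.99)
  # identical inputs correlate perfectly
  same <- compare_instruments(va, va)
  expect_equal(same$ratio_r_squared, 1.0, tolerance = 1e-12)
  # ratios scaled by 2 are a linear map: ratio correlation unchanged
  vb2 <- va; vb2$mean_ratio <- 2 * va$mean_ratio
  expect_equal(compare_instruments(va, vb2)$ratio_r_squared, 1.0,
               tolerance = 1e-12)
  # variety mismatch fails
  vb3 <- vb; vb3$variety_id[1] <- "other"
  expect_error(compare_instruments(va, vb3), "same varieties")
})

test_that("a known linear acceptability rule is recovered within 2 SE", {
  # ratio-level parameter recovery: acceptability = 1 + 0.6 * ratio + noise.
  # 20 varieties keep the +/- 2 SE band at ~94% nominal coverage (with only
  # 5 varieties the t(3) sampling distribution alone caps coverage at ~86%)
  ratios <- seq(4, 12, length.out = 20)
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    acc <- 1 + 0.6 * ratios + rnorm(length(ratios), 0, 0.25)
    fit <- fit_acceptability_model(ratios, acc)
    se <- summary(fit$lm)$coefficients["mean_ratio", "Std. Error"]
    if (abs(fit$slope - 0.6) <= 2 * se) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("score_cohort and aggregate_varieties summarise replicates", {
  vt <- data.frame(variety_id = c("A", "B"), target_ratio = c(5, 9))
  fids <- simulate_cohort(vt, n_replicates = 3, scheme = scheme_high_field(),
                          seed = 2)
  specs <- process_cohort(fids, simulation_processing_params())
  scored <- score_cohort(specs, default_windows("high_field"))
  expect_equal(nrow(scored), 6L)
  agg <- aggregate_varieties(scored)
  expect_setequal(agg$variety_id, c("A", "B"))
  expect_equal(agg$n_rep, c(3L, 3L))
  expect_equal(agg$mean_ratio,
               vapply(split(scored$ratio, scored$variety_id), mean,
                      numeric(1)),
               ignore_attr = TRUE)
})
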