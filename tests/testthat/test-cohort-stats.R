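test_that("Kaplan-Meier estimates match hand expectations", {
  all_cens <- data.frame(time = c(5, 10, 15), event = 0)
  km <- km_estimate(all_cens)
  expect_true(all(km$curves$survival == 1))

  d <- data.frame(time = c(10, 20, 30, 40), event = c(1, 0, 0, 0))
  km <- km_estimate(d)
  expect_equal(km$curves$survival[km$curves$time == 10], 0.75)

  # no censoring: product-limit equals the empirical survival function
  t5 <- c(3, 7, 9, 12, 20)
  km5 <- km_estimate(data.frame(time = t5, event = 1))
  expect_equal(km5$curves$survival, 1 - seq_along(t5) / 5)

  two <- data.frame(time = rep(c(5, 8, 12), 2), event = rep(c(1, 1, 0), 2),
                    grp = rep(c("a", "b"), each = 3))
  lr <- km_estimate(two, group = "grp")$logrank
  expect_equal(lr$statistic, 0)
  expect_equal(lr$p.value, 1)
})

test_that("Cox fits match the survival package and shrink under ridge", {
  d <- gen_cohort_ph(n = 300, seed = 12)
  d$time <- ceiling(d$time)  # day granularity introduces ties
  fit <- cox_fit(d, "x")
  expect_true(fit$converged)
  ref <- survival::coxph(survival::Surv(time, event) ~ x, data = d,
                         ties = "efron")
  expect_equal(fit$coefficients$estimate, unname(coef(ref)), tolerance = 1e-7)
  expect_equal(fit$coefficients$hazard_ratio,
               exp(fit$coefficients$estimate))

  # a dominating penalty pushes coefficients to zero
  big <- cox_fit(d, "x", lambda = 1e8)
  expect_lt(abs(big$coefficients$estimate), 1e-4)
  expect_equal(big$coefficients$hazard_ratio, 1, tolerance = 1e-3)

  # ridge path: coefficient norm non-increasing in lambda
  norms <- vapply(c(0, 0.5, 5, 50, 500), function(l) {
    sqrt(sum(cox_fit(d, "x", lambda = l)$coefficients$estimate^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("duplicating every record leaves the Efron fit essentially unchanged", {
  # duplication turns every event into a tie; under Efron's tie
  # correction the estimate matches the reference implementation
  # exactly and the original fit closely (exact invariance holds only
  # for Breslow ties, where doubling shifts the likelihood by a
  # constant)
  d <- gen_cohort_ph(n = 80, seed = 3)
  fit1 <- cox_fit(d, "x")
  dup <- dplyr::bind_rows(d, d)
  fit2 <- cox_fit(dup, "x")
  ref2 <- survival::coxph(survival::Surv(time, event) ~ x, data = dup,
                          ties = "efron")
  expect_equal(fit2$coefficients$estimate, unname(coef(ref2)),
               tolerance = 1e-7)
  expect_equal(fit1$coefficients$estimate, fit2$coefficients$estimate,
               tolerance = 0.05)
})

test_that("Newton's optimum agrees with a derivative-free maximizer", {
  d <- gen_cohort_ph(n = 60, seed = 8)
  fit <- cox_fit(d, "x")
  X <- matrix(d$x, ncol = 1)
  op <- optim(0, function(b) -cox_partial_loglik(b, X, d$time, d$event),
              method = "Brent", lower = -5, upper = 5,
              control = list(reltol = 1e-14))
  expect_lt(abs(op$par - fit$coefficients$estimate), 1e-6)
})

test_that("cross-validated ridge selection is seeded and handles collinearity", {
  d <- gen_cohort_ph(n = 150, seed = 5)
  expect_equal(select_ridge_lambda(d, "x", lambda_grid = 0, seed = 1)$lambda, 0)

  d2 <- dplyr::mutate(d, x_copy = x)  # perfectly collinear duplicate
  sel <- select_ridge_lambda(d2, c("x", "x_copy"),
                             lambda_grid = c(0.01, 1, 100), folds = 5,
                             seed = 2)
  expect_true(sel$lambda > 0)
  fit <- cox_fit(d2, c("x", "x_copy"), lambda = sel$lambda)
  expect_true(all(is.finite(fit$coefficients$estimate)))

  sel2 <- select_ridge_lambda(d2, c("x", "x_copy"),
                              lambda_grid = c(0.01, 1, 100), folds = 5,
                              seed = 2)
  expect_equal(sel$lambda, sel2$lambda)
})

test_that("log-normal AFT recovers coefficients and percentage changes", {
  expect_equal(100 * (exp(0) - 1), 0)
  expect_equal(100 * (exp(log(2)) - 1), 100)

  sim <- gen_cohort(cohort_sim_config(n_patients = 1000, seed = 31))
  fit <- aft_fit(sim$cohort, c("tp53", "ecDNA"))
  est <- fit$coefficients
  expect_equal(est$estimate[est$term == "ecDNA"], sim$truth$beta_m,
               tolerance = 0.12)
  expect_equal(est$percentage_change,
               100 * (exp(est$estimate) - 1))

  # bias across replicates
  biases <- vapply(1:20, function(s) {
    sm <- gen_cohort(cohort_sim_config(n_patients = 1000, seed = 100 + s))
    f <- aft_fit(sm$cohort, c("tp53", "ecDNA"))
    f$coefficients$estimate[f$coefficients$term == "ecDNA"] - sm$truth$beta_m
  }, numeric(1))
  expect_lt(abs(mean(biases)), 0.05)
})

test_that("mediation decomposes a fully mediated exposure effect", {
  sim <- gen_cohort(cohort_sim_config(n_patients = 2000, beta_e = 0,
                                      a1 = 4, seed = 41))
  med <- mediation_baron_kenny(sim$cohort, exposure = "tp53",
                               mediator = "ecDNA")
  expect_lt(abs(med$direct_effect), 0.1)
  total_se <- med$total_model$coefficients$std.error[
    med$total_model$coefficients$term == "tp53"]
  expect_gt(abs(med$total_effect), 3 * total_se)
  expect_gt(med$attenuation, 0.8)

  # a mediator unrelated to exposure and outcome leaves the effect intact
  sim2 <- gen_cohort(cohort_sim_config(n_patients = 2000, beta_e = -0.5,
                                       beta_m = 0, a1 = 0, seed = 43))
  med2 <- mediation_baron_kenny(sim2$cohort, exposure = "tp53",
                                mediator = "ecDNA")
  expect_lt(abs(med2$attenuation), 0.15)

  d <- sim$cohort
  d$same <- d$tp53
  expect_error(mediation_baron_kenny(d, "tp53", "same"), "collinearity")
  d$const <- 1
  expect_error(mediation_baron_kenny(d, "tp53", "const"), "constant")
})

test_that("mediation attenuation grows toward 1 with sample size", {
  atten <- vapply(c(250, 1000, 4000), function(n) {
    sim <- gen_cohort(cohort_sim_config(n_patients = n, beta_e = 0,
                                        a1 = 4, seed = 59))
    mediation_baron_kenny(sim$cohort, "tp53", "ecDNA")$attenuation
  }, numeric(1))
  expect_gt(atten[3], 0.85)
  expect_gt(min(atten), 0.5)
})

test_that("chi-squared on 2x2 tables applies Yates by default", {
  tabs <- fixture_tables()
  res <- chi2_2x2(tabs$shh_vs_rest)
  expect_equal(round(res$statistic, 2), 7.66)
  expect_equal(round(res$p.value, 3), 0.006)

  flat <- chi2_2x2(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p.value, 1)

  # without Yates: hand-computed sum of (O-E)^2/E
  m <- matrix(c(8, 2, 3, 7), 2, 2, byrow = TRUE)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  hand <- sum((m - expected)^2 / expected)
  expect_equal(chi2_2x2(m, yates = FALSE)$statistic, hand)
  expect_error(chi2_2x2(c(0, 0, 3, 4)), "zero margin")
})

test_that("Fisher's exact test matches enumeration and handles extremes", {
  expect_equal(fisher_exact_2x2(matrix(1, 2, 2))$p.value, 1)
  res <- fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2, 2, byrow = TRUE))
  expect_equal(res$p.value, 2 / choose(10, 5))
  expect_equal(res$odds_ratio, Inf)

  set.seed(11)
  for (i in 1:15) {
    m <- matrix(rpois(4, 5) + 1, 2, 2)
    expect_equal(fisher_exact_2x2(m)$p.value, fisher_enum_oracle(m),
                 tolerance = 1e-10)
  }
})
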