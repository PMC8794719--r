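test_that("intercept-only known-fate MLE equals the binomial closed form", {
  f <- validate_histories(single_interval_females(4, 3), "female")
  fit <- fit_known_fate(f, "intercept")
  s_hat <- stats::plogis(fit$coefficients[[1]])
  expect_equal(s_hat, 0.75, tolerance = 1e-8)
  expect_equal(fit$logLik, 3 * log(0.75) + log(0.25), tolerance = 1e-10)
  expect_equal(fit$n_eff, 4)
})

test_that("likelihood collapses to the shared-probability binomial form", {
  # any design that assigns one probability to all intervals must give
  # logL = k log p + (n-k) log(1-p) at p = k/n
  set.seed(21)
  truth <- simulation_truth(years = 2013:2014)
  iv <- kf_intervals(simulate_females(truth))
  fit <- fit_known_fate(iv, "intercept")
  k <- sum(iv$survived)
  n <- nrow(iv)
  expect_equal(stats::plogis(fit$coefficients[[1]]), k / n,
               tolerance = 1e-8)
  expect_equal(fit$logLik, k * log(k / n) + (n - k) * log(1 - k / n),
               tolerance = 1e-8)
})

test_that("known-fate fit matches the logistic-regression oracle", {
  set.seed(22)
  truth <- simulation_truth(years = 2013:2015)
  iv <- kf_intervals(simulate_females(truth))
  fit <- fit_known_fate(iv, "year + age + winter")
  oracle <- stats::glm(survived ~ year + age + winter, stats::binomial,
                       data = iv)
  expect_equal(unname(fit$coefficients), unname(stats::coef(oracle)),
               tolerance = 1e-6)
  expect_equal(fit$logLik, as.numeric(stats::logLik(oracle)),
               tolerance = 1e-8)
  expect_equal(unname(diag(fit$vcov)), unname(diag(stats::vcov(oracle))),
               tolerance = 1e-4)
})

test_that("complete survival is flagged at the boundary and penalized", {
  f <- validate_histories(single_interval_females(10, 10), "female")
  expect_warning(fit <- fit_known_fate(f, "intercept"), "separation")
  expect_true(fit$penalized)
  expect_true(stats::plogis(fit$coefficients[[1]]) > 0.9)
})

test_that("censoring and staggered entry remove intervals from the risk set", {
  f <- rbind(one_female("F1", entry = 1, months_alive = 3,
                        terminal = "censored"),
             one_female("F2", entry = 5, months_alive = 4, terminal = "dead"))
  iv <- kf_intervals(validate_histories(f, "female"))
  # F1 contributes 3 alive intervals (censored month dropped);
  # F2 contributes months 5..9 only
  expect_equal(nrow(iv), 3 + 5)
  expect_false(any(iv$interval[iv$id == "F2/2013"] < 5))
})

test_that("AICc bookkeeping: weights, ratios and the small-sample penalty", {
  expect_equal(aicc(-10, 2, 100), 20 + 4 + 12 / 97)
  expect_true(is.infinite(aicc(-10, 50, 40)))

  tab <- rank_models(list(a = stub_fit("a", 100), b = stub_fit("b", 102)))
  expect_equal(tab$delta_aicc, c(0, 2))
  expect_equal(tab$weight, c(0.731, 0.269), tolerance = 1e-3)
  expect_equal(tab$weight[1] / tab$weight[2], exp(1), tolerance = 1e-10)

  tab2 <- rank_models(list(a = stub_fit("a", 100), b = stub_fit("b", 101)))
  expect_equal(tab2$weight[1] / tab2$weight[2], exp(0.5), tolerance = 1e-10)

  tab3 <- rank_models(list(a = stub_fit("a", 100), b = stub_fit("b", 100)))
  expect_equal(tab3$weight, c(0.5, 0.5))
  expect_equal(sum(tab$weight), 1, tolerance = 1e-12)

  bad <- stub_fit("c", 99)
  bad$data_signature <- c(2, 2, 2)
  expect_error(rank_models(list(stub_fit("a", 100), bad)), "identical data")
})

test_that("model averaging combines estimates with unconditional variance", {
  avg <- akaike_average(c(0.4, 0.6), c(0, 0), c(0.5, 0.5))
  expect_equal(avg$estimate, 0.5)
  expect_equal(avg$variance, 0.01)

  # single-model average returns that model's estimates
  set.seed(23)
  truth <- simulation_truth(years = 2013:2014)
  iv <- kf_intervals(simulate_females(truth))
  fit <- fit_known_fate(iv, "year")
  ma <- model_average(list(year = fit))
  expect_equal(ma$estimate, interval_survival(fit)$estimate)

  # averaged estimate lies within the per-model extremes (convexity)
  f2 <- fit_known_fate(iv, "intercept")
  ma2 <- model_average(list(fit, f2))
  lo <- pmin(interval_survival(fit)$estimate, interval_survival(f2)$estimate)
  hi <- pmax(interval_survival(fit)$estimate, interval_survival(f2)$estimate)
  expect_true(all(ma2$estimate >= lo - 1e-12 & ma2$estimate <= hi + 1e-12))
})

test_that("window products multiply per-interval survival over the window", {
  # constant daily survival 0.97 over 27 days and 0.95 over 12 months
  f <- validate_histories(single_interval_females(100, 95), "female")
  fit <- fit_known_fate(f, "intercept")
  ann <- derive_window_products(fit, "annual12")
  expect_equal(ann$estimate, 0.95^12, tolerance = 1e-6)

  # delta-method SE through the coefficient covariance agrees with the
  # independent product rule on the per-interval scale
  iv12 <- interval_survival(fit)
  dm <- delta_method_product(iv12$estimate,
                             cov = outer(iv12$se, iv12$se))  # fully correlated
  expect_equal(ann$se, dm$se, tolerance = 1e-3)

  seas <- derive_window_products(fit, "season4")
  expect_equal(sort(unique(seas$window)), c("breeding", "fall", "winter"))
  expect_equal(seas$estimate, rep(0.95^4, 3), tolerance = 1e-6)

  # absorbing zero interval on the averaged pathway
  iv0 <- iv12
  iv0$estimate[3] <- 0
  ann0 <- derive_window_products(iv0, "annual12")
  expect_equal(ann0$estimate, 0)
})

test_that("nest window products: 27-day survival from constant daily rate", {
  nests <- do.call(rbind, lapply(1:40, function(i) {
    days <- 1:27
    data.frame(nest_id = paste0("N", i), female_id = paste0("F", i),
               age_class = "ASY", attempt = "first", year = 2013,
               start_doy = 100 + (i %% 10), day_index = days,
               state = c(rep("active", 26),
                         if (i <= 30) "hatched" else "failed"))
  }))
  # failures only on the last day: daily survival = 1049/1080... use fit
  fit <- fit_known_fate(validate_histories(nests, "nest"), "intercept")
  p <- stats::plogis(fit$coefficients[[1]])
  ns <- derive_window_products(fit, "nest27")
  expect_equal(ns$estimate, p^27, tolerance = 1e-8)
})

test_that("known-fate recovery: simulated monthly survival is recovered", {
  set.seed(24)
  # 200 females at constant monthly survival 0.95, intercept model
  f <- do.call(rbind, lapply(1:200, function(i) {
    alive <- stats::rbinom(12, 1, 0.95)
    death <- match(0, alive)
    months <- 1:(if (is.na(death)) 12 else death)
    data.frame(female_id = paste0("F", i), age_class = "ASY", year = 2013,
               month_index = months,
               state = c(rep("alive", length(months) - 1),
                         if (is.na(death)) "alive" else "dead"))
  }))
  fit <- fit_known_fate(validate_histories(f, "female"), "intercept")
  s_hat <- stats::plogis(fit$coefficients[[1]])
  n_int <- fit$n_eff
  mc_se <- sqrt(0.95 * 0.05 / n_int)
  expect_lt(abs(s_hat - 0.95), 3 * mc_se)
})

test_that("model selection recovers the generating design on average", {
  # data simulated with a winter effect: year + age + winter should beat
  # the no-season and full-season alternatives on mean AICc
  set.seed(25)
  truth <- simulation_truth(years = 2013:2018, winter_hazard_ratio = 0.35,
                            censor_rate = 0)
  nper <- stats::setNames(lapply(2013:2018, function(y) c(SY = 20, ASY = 35)),
                          2013:2018)
  designs <- c("year + age", "year + age + winter", "year + age + season")
  wins <- matrix(NA_real_, 20, length(designs),
                 dimnames = list(NULL, designs))
  for (r in 1:20) {
    iv <- kf_intervals(simulate_females(truth, nper))
    for (d in designs) wins[r, d] <- fit_known_fate(iv, d)$aicc
  }
  means <- colMeans(wins)
  expect_equal(names(which.min(means)), "year + age + winter")
})
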