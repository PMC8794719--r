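test_that("forward DP equals exhaustive latent-path enumeration", {
  # fixed small case
  spec <- brood_model_spec("day", "day")  # free per-interval parameters
  b <- validate_histories(one_brood(n0 = 2, counts = rep(1, 5)), "brood")
  par <- c(stats::qlogis(0.9), rep(0, 4), stats::qlogis(0.9), rep(0, 4))
  ll <- brood_likelihood(b, spec, par)
  expect_equal(ll, log(enum_brood_lik(2, rep(1, 5), rep(0.9, 5),
                                      rep(0.9, 5))),
               tolerance = 1e-10)

  # 100 random parameter draws, N0 <= 4
  set.seed(31)
  for (i in 1:100) {
    n0 <- sample(1:4, 1)
    phi <- runif(5, 0.2, 0.95)
    rho <- runif(5, 0.2, 0.95)
    y <- integer(5)
    a <- n0
    for (t in 1:5) {
      a <- rbinom(1, a, phi[t])
      y[t] <- rbinom(1, a, rho[t])
    }
    b <- validate_histories(one_brood(n0 = n0, counts = y), "brood")
    par <- c(stats::qlogis(phi[1]), stats::qlogis(phi[-1]) -
               stats::qlogis(phi[1]),
             stats::qlogis(rho[1]), stats::qlogis(rho[-1]) -
               stats::qlogis(rho[1]))
    expect_equal(brood_likelihood(b, spec, par),
                 log(enum_brood_lik(n0, y, phi, rho)), tolerance = 1e-8)
  }
})

test_that("perfect detection reduces the likelihood to known-fate form", {
  # with rho = 1 the counts reveal the latent states exactly, so the
  # likelihood is the product of binomial thinning terms on the counts
  y <- c(4, 3, 3, 2, 2)
  phi <- 0.8
  b <- validate_histories(one_brood(n0 = 6, counts = y), "brood")
  spec <- brood_model_spec("intercept", "intercept")
  par <- c(stats::qlogis(phi), 20)  # logit rho ~ +20 => rho ~ 1
  direct <- sum(stats::dbinom(y, c(6, y[-5]), phi, log = TRUE))
  expect_equal(brood_likelihood(b, spec, par), direct, tolerance = 1e-6)
})

test_that("an absorbing zero survival interval forbids later sightings", {
  ll <- grousedemog:::brood_forward(3, c(2, NA, 1, 0, 0),
                                   phi = c(0.9, 0, 0.9, 0.9, 0.9),
                                   rho = rep(0.9, 5))
  expect_identical(ll, -Inf)
})

test_that("likelihood is invariant to brood order and additive over broods", {
  set.seed(32)
  truth <- simulation_truth(years = 2013:2014)
  broods <- simulate_broods(truth)
  spec <- brood_model_spec("T", "T")  # covariate-only: valid on any subset
  par <- c(0.5, -0.2, -0.5, 1.5)
  ll <- brood_likelihood(broods, spec, par)
  shuffled <- broods[sample(nrow(broods)), ]
  expect_equal(brood_likelihood(validate_histories(shuffled, "brood"),
                                spec, par), ll)
  # additivity: likelihood of a subset plus complement equals the total
  ids <- unique(broods$brood_id)
  half <- ids[seq_len(length(ids) %/% 2)]
  b1 <- validate_histories(broods[broods$brood_id %in% half, ], "brood")
  b2 <- validate_histories(broods[!broods$brood_id %in% half, ], "brood")
  expect_equal(brood_likelihood(b1, spec, par) +
                 brood_likelihood(b2, spec, par), ll, tolerance = 1e-10)
})

test_that("54-day chick survival is the product of interval survivals", {
  set.seed(33)
  truth <- simulation_truth(years = 2013:2014)
  fit <- fit_brood_model(simulate_broods(truth),
                         brood_model_spec("year", "T"))
  sc <- chick_survival_54day(fit)
  for (i in seq_len(nrow(sc))) {
    phi <- fit$grid$phi[as.character(fit$grid$year) ==
                          as.character(sc$year[i])]
    expect_equal(sc$estimate[i], prod(phi))
  }
  # monotone: increasing any interval survival increases the product
  expect_true(all(sc$estimate <= 1 & sc$estimate >= 0))
})

test_that("brood model recovers survival and the detection trend", {
  set.seed(34)
  # 60 broods, interval survival 0.8 (54-day 0.8^5), detection rising
  n0s <- pmax(1, rpois(60, 5))
  rho_true <- seq(0.3, 0.9, length.out = 5)
  rows <- lapply(1:60, function(i) {
    a <- n0s[i]
    y <- integer(5)
    for (t in 1:5) {
      a <- rbinom(1, a, 0.8)
      y[t] <- rbinom(1, a, rho_true[t])
    }
    one_brood(paste0("B", i), 2013, n0s[i], y)
  })
  broods <- validate_histories(do.call(rbind, rows), "brood")
  fit <- fit_brood_model(broods, brood_model_spec("intercept", "T"))
  s54 <- chick_survival_54day(fit)
  expect_lt(abs(s54$estimate - 0.8^5), 3 * s54$se)
  # fitted detection trend coefficient is positive
  expect_gt(fit$coefficients[fit$kp + 2], 0)
})

test_that("rising detection yields a positive trend coefficient reliably", {
  set.seed(35)
  rho_true <- seq(0.3, 0.9, length.out = 5)
  positive <- replicate(50, {
    rows <- lapply(1:30, function(i) {
      n0 <- max(1, rpois(1, 5))
      a <- n0
      y <- integer(5)
      for (t in 1:5) {
        a <- rbinom(1, a, 0.8)
        y[t] <- rbinom(1, a, rho_true[t])
      }
      one_brood(paste0("B", i), 2013, n0, y)
    })
    broods <- validate_histories(do.call(rbind, rows), "brood")
    fit <- fit_brood_model(broods, brood_model_spec("intercept", "T"))
    fit$coefficients[fit$kp + 2] > 0
  })
  expect_gte(mean(positive), 0.9)
})

test_that("all-counts-at-maximum flags the boundary", {
  b <- validate_histories(one_brood(n0 = 5, counts = rep(5, 5)), "brood")
  fit <- fit_brood_model(b, brood_model_spec("intercept", "intercept"))
  expect_true(fit$boundary)
})

test_that("two-stage selection finds the detection trend structure", {
  set.seed(36)
  truth <- simulation_truth(years = 2013:2015)
  broods <- simulate_broods(truth)  # truth detection rises 0.3 -> 0.9
  ts <- brood_two_stage(broods,
                        rho_structures = c("intercept", "T"),
                        phi_structures = c("intercept", "year"))
  expect_equal(ts$best_rho, "T")
  expect_s3_class(ts$phi_table, "kf_model_table")
  expect_equal(sum(ts$rho_table$weight), 1, tolerance = 1e-12)
})
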