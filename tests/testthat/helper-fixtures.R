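# Small in-code fixtures and independent oracles shared across tests.

# One female with a terminal state at a given month.
one_female <- function(id = "F1", age = "ASY", year = 2013, entry = 1,
                       months_alive = 5, terminal = "dead") {
  months <- entry:(entry + months_alive)
  data.frame(female_id = id, age_class = age, year = year,
             month_index = months,
             state = c(rep("alive", months_alive), terminal),
             stringsAsFactors = FALSE)
}

# n females each monitored for a single interval; k survive.
single_interval_females <- function(n, k) {
  do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(female_id = paste0("F", i), age_class = "ASY", year = 2013,
               month_index = 1,
               state = if (i <= k) "alive" else "dead",
               stringsAsFactors = FALSE)))
}

one_brood <- function(id = "B1", year = 2013, n0 = 6,
                      counts = c(4, 3, 3, 2, 2)) {
  data.frame(brood_id = id, year = year, occasion_index = 0:5,
             count = c(n0, counts), stringsAsFactors = FALSE)
}

# Exhaustive-path oracle for the brood likelihood: sum over every latent
# trajectory A_1..A_5 in [0, N0]^5 of the product of binomial transition and
# observation probabilities. Independent of the package's forward DP.
enum_brood_lik <- function(n0, y, phi, rho) {
  grid <- expand.grid(rep(list(0:n0), 5))
  total <- 0
  for (r in seq_len(nrow(grid))) {
    a <- as.numeric(grid[r, ])
    prev <- c(n0, a[-5])
    p <- prod(dbinom(a, prev, phi))
    if (p == 0) next
    obs <- dbinom(y, a, rho)
    obs[is.na(y)] <- 1
    total <- total + p * prod(obs)
  }
  total
}

# Monte-Carlo oracle for the variance of a product of independent normals.
mc_product_se <- function(means, ses, n = 1e5) {
  draws <- vapply(seq_along(means),
                  function(i) rnorm(n, means[i], ses[i]), numeric(n))
  stats::sd(apply(draws, 1, prod))
}

# Fabricated ranked-fit stubs for testing AICc bookkeeping arithmetic.
stub_fit <- function(design, aicc_value, K = 2, loglik = -10) {
  structure(list(design = design, K = K, logLik = loglik, aicc = aicc_value,
                 n_eff = 100, data_signature = c(1, 1, 1)),
            class = "kf_fit")
}

table1 <- function() trout_creek_rates()
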