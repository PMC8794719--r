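# Synthetic encounter-history generator. Emulates the field study's
# data-generating processes — staggered-entry monthly survival of telemetered
# females, daily nest survival over a 27-day incubation window with
# re-nesting after failure, and binomially thinned brood counts with
# imperfect detection — with known truth, so every estimation stage can be
# tested without the original telemetry data.

#' Simulation truth: true vital rates and cohort sizes
#'
#' Defaults reproduce the study conditions: per-year true rates equal to the
#' packaged vital-rate table and cohort sizes equal to its `n` column, with a
#' detection trajectory rising from 0.3 to 0.9 across the five brood counts
#' (detection improves as chicks age) and a small monthly censoring hazard
#' for transmitter failure.
#'
#' @param years Years to simulate.
#' @param rates Optional `vital_rate_table` supplying true rates (default:
#'   the packaged study table).
#' @param rho Detection probability at each of the five brood counts.
#' @param censor_rate Monthly probability a female is censored.
#' @param entry_months Months (1 = March) over which capture/entry is
#'   uniform.
#' @param winter_hazard_ratio Ratio of the winter monthly log-hazard to the
#'   non-winter monthly log-hazard (1 = constant monthly survival; < 1 gives
#'   the higher winter survival seen in the study). Monthly survivals are
#'   solved so their 12-month product always equals the annual truth.
#' @param seed Seed stored with the truth (used by [simulate_study()]).
#' @return List of class `simulation_truth`.
#' @export
simulation_truth <- function(years = 2013:2018, rates = trout_creek_rates(),
                             rho = seq(0.3, 0.9, length.out = 5),
                             censor_rate = 0.02,
                             entry_months = 1:3,
                             winter_hazard_ratio = 1, seed = 20130801) {
  yrs <- intersect(sort(unique(rates$year)), years)
  truth <- list(
    years = yrs,
    rates = stats::setNames(lapply(yrs, function(y) rates_vector(rates, y)),
                            as.character(yrs)),
    n = stats::setNames(lapply(yrs, function(y) {
      sub <- rates[rates$year == y, ]
      key <- ifelse(sub$age_class == "pooled", sub$rate_name,
                    paste(sub$rate_name, sub$age_class, sep = "_"))
      stats::setNames(sub$n, key)
    }), as.character(yrs)),
    rho = rho, censor_rate = censor_rate, entry_months = entry_months,
    winter_hazard_ratio = winter_hazard_ratio, seed = seed
  )
  class(truth) <- "simulation_truth"
  truth
}

truth_rate <- function(truth, year, key) truth$rates[[as.character(year)]][[key]]

# Monthly survival schedule (months 1..12, 1 = March) whose product equals
# the annual truth, with winter months (Dec-Mar: 10, 11, 12, 1) on a reduced
# log-hazard when winter_hazard_ratio < 1.
monthly_survival_schedule <- function(s_annual, winter_hazard_ratio = 1) {
  r <- winter_hazard_ratio
  # s_w = s_o^r and s_w^4 * s_o^8 = S  =>  s_o = S^(1/(4r + 8))
  s_o <- s_annual^(1 / (4 * r + 8))
  s_w <- s_o^r
  ifelse(seq_len(12) %in% c(10:12, 1), s_w, s_o)
}

#' Simulate telemetered female monthly encounter histories
#'
#' Staggered entry uniform over the capture window; survival is Bernoulli
#' each month on the schedule implied by the annual truth (constant monthly
#' survival, or with elevated winter survival when the truth's
#' `winter_hazard_ratio` < 1); censoring (transmitter loss) is Bernoulli per
#' month at the truth's censor rate. Yearlings confirmed alive through
#' February re-enter the following year as adults with entry month 1,
#' replacing new captures up to the year's target cohort size.
#'
#' @param truth A [simulation_truth()].
#' @param n_per_year Named list/vector: females per year per age class, e.g.
#'   `list("2013" = c(SY = 16, ASY = 30))`. Defaults to the truth's `n` for
#'   annual survival.
#' @return A `female_histories` data frame.
#' @export
simulate_females <- function(truth, n_per_year = NULL) {
  rows <- list()
  id <- 0
  carryover <- character(0)  # ids of survivors re-entering as ASY
  sim_bird <- function(fid, age, y, entry) {
    sched <- monthly_survival_schedule(truth_rate(truth, y, paste0("S_", age)),
                                       truth$winter_hazard_ratio)
    state <- character(0)
    for (m in entry:12) {
      if (stats::runif(1) < truth$censor_rate) {
        state <- c(state, "censored"); break
      }
      alive <- stats::runif(1) < sched[m]
      state <- c(state, if (alive) "alive" else "dead")
      if (!alive) break
    }
    data.frame(female_id = fid, age_class = age, year = y,
               month_index = entry:(entry + length(state) - 1),
               state = state, stringsAsFactors = FALSE)
  }
  for (y in truth$years) {
    nn <- if (!is.null(n_per_year)) n_per_year[[as.character(y)]] else
      c(SY = unname(truth$n[[as.character(y)]]["S_annual_SY"]),
        ASY = unname(truth$n[[as.character(y)]]["S_annual_ASY"]))
    next_carry <- character(0)
    for (fid in carryover) {
      h <- sim_bird(fid, "ASY", y, 1L)
      rows[[length(rows) + 1]] <- h
      if (h$state[nrow(h)] == "alive" && h$month_index[nrow(h)] == 12)
        next_carry <- c(next_carry, fid)
    }
    for (age in c("SY", "ASY")) {
      n_new <- nn[[age]] - if (age == "ASY") length(carryover) else 0L
      for (i in seq_len(max(0L, n_new))) {
        id <- id + 1
        fid <- sprintf("F%04d", id)
        h <- sim_bird(fid, age, y, sample(truth$entry_months, 1))
        rows[[length(rows) + 1]] <- h
        survived <- h$state[nrow(h)] == "alive" && h$month_index[nrow(h)] == 12
        if (age == "SY" && survived) next_carry <- c(next_carry, fid)
      }
    }
    carryover <- next_carry
  }
  validate_histories(do.call(rbind, rows), "female")
}

#' Simulate nest encounter histories
#'
#' Each monitored female initiates a first nest with probability `NI1` for
#' her age; daily nest survival is `NS1^(1/27)` over a 27-day incubation
#' window. A failed first nest is followed by a re-nest with probability
#' `NI2` (daily survival `NS2^(1/27)`). Incubation start days are drawn
#' uniformly within a April-May nesting season.
#'
#' @param truth A [simulation_truth()].
#' @param n_females Named list/vector: monitored females per year per age
#'   class. Defaults to the truth's `n` for first-nest initiation.
#' @return A `nest_histories` data frame.
#' @export
simulate_nests <- function(truth, n_females = NULL) {
  rows <- list()
  nest <- 0
  sim_one <- function(year, age, attempt, female, dns, start) {
    nest <<- nest + 1
    states <- character(0)
    for (d in 1:27) {
      alive <- stats::runif(1) < dns
      states <- c(states, if (!alive) "failed"
                  else if (d == 27) "hatched" else "active")
      if (!alive) break
    }
    data.frame(nest_id = sprintf("N%04d", nest), female_id = female,
               age_class = age, attempt = attempt, year = year,
               start_doy = start, day_index = seq_along(states),
               state = states, stringsAsFactors = FALSE)
  }
  for (y in truth$years) {
    nn <- if (!is.null(n_females)) n_females[[as.character(y)]] else
      c(SY = unname(truth$n[[as.character(y)]]["NI1_SY"]),
        ASY = unname(truth$n[[as.character(y)]]["NI1_ASY"]))
    for (age in c("SY", "ASY")) {
      ni1 <- truth_rate(truth, y, paste0("NI1_", age))
      dns1 <- truth_rate(truth, y, paste0("NS1_", age))^(1 / 27)
      ni2 <- truth_rate(truth, y, "NI2")
      dns2 <- truth_rate(truth, y, "NS2")^(1 / 27)
      for (i in seq_len(nn[[age]])) {
        female <- sprintf("%s-%d-%s%03d", "FY", y %% 100, age, i)
        if (stats::runif(1) >= ni1) next
        start <- sample(91:151, 1)  # April-May incubation starts
        h <- sim_one(y, age, "first", female, dns1, start)
        rows[[length(rows) + 1]] <- h
        failed <- any(h$state == "failed")
        if (failed && stats::runif(1) < ni2)
          rows[[length(rows) + 1]] <-
            sim_one(y, age, "renest", female, dns2, start + 30)
      }
    }
  }
  validate_histories(do.call(rbind, rows), "nest")
}

#' Simulate brood flush-count histories
#'
#' Initial counts are eggs hatched (rounded normal around the age-pooled
#' clutch size times hatchability, minimum 1). The latent alive count thins
#' binomially each interval with survival `S_chick^(1/5)`; each flush count
#' is a binomial sample of the latent count with the truth's detection
#' trajectory.
#'
#' @param truth A [simulation_truth()].
#' @param n_broods Named vector: broods per year. Defaults to the truth's
#'   `n` for chick survival.
#' @return A `brood_histories` data frame.
#' @export
simulate_broods <- function(truth, n_broods = NULL) {
  rows <- list()
  bid <- 0
  for (y in truth$years) {
    nb <- if (!is.null(n_broods)) n_broods[[as.character(y)]] else
      unname(truth$n[[as.character(y)]]["S_chick"])
    phi <- truth_rate(truth, y, "S_chick")^(1 / 5)
    cs <- mean(c(truth_rate(truth, y, "CS1_SY"),
                 truth_rate(truth, y, "CS1_ASY")))
    h <- truth_rate(truth, y, "H")
    for (i in seq_len(nb)) {
      bid <- bid + 1
      n0 <- max(1L, as.integer(round(stats::rnorm(1, cs * h, 1))))
      alive <- n0
      counts <- integer(5)
      for (t in 1:5) {
        alive <- stats::rbinom(1, alive, phi)
        counts[t] <- stats::rbinom(1, alive, truth$rho[t])
      }
      rows[[bid]] <- data.frame(
        brood_id = sprintf("B%04d", bid), year = y, occasion_index = 0:5,
        count = c(n0, counts), stringsAsFactors = FALSE)
    }
  }
  validate_histories(do.call(rbind, rows), "brood")
}

#' Simulate a full study: females, nests and broods, with recorded truth
#'
#' Per-stage seeds are derived deterministically from the truth's seed so
#' that adding a stage never perturbs earlier draws.
#'
#' @param truth A [simulation_truth()].
#' @param dir Optional directory; when given, writes `females.csv`,
#'   `nests.csv`, `broods.csv` and `truth.json`.
#' @return List with `females`, `nests`, `broods` and `truth`.
#' @export
simulate_study <- function(truth = simulation_truth(), dir = NULL) {
  base <- truth$seed %% 2147480000L
  withr_seed <- function(offset, expr) {
    set.seed(base + offset)
    expr
  }
  females <- withr_seed(1L, simulate_females(truth))
  nests <- withr_seed(2L, simulate_nests(truth))
  broods <- withr_seed(3L, simulate_broods(truth))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_encounter_histories(females, file.path(dir, "females.csv"))
    write_encounter_histories(nests, file.path(dir, "nests.csv"))
    write_encounter_histories(broods, file.path(dir, "broods.csv"))
    tr <- unclass(truth)
    tr$rates <- lapply(tr$rates, function(r) as.list(unclass(r)))
    jsonlite::write_json(tr, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(females = females, nests = nests, broods = broods, truth = truth)
}
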