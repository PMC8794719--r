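test_that("vital-rate table reader parses the packaged study table", {
  vrt <- trout_creek_rates(complete = FALSE)
  r <- vrt[vrt$year == 2013 & vrt$rate_name == "S_annual" &
             vrt$age_class == "ASY", ]
  expect_equal(r$mean, 0.27)
  expect_equal(r$se, 0.07)
  expect_equal(r$n, 30)
  # 15 rate/age rows per year, six years
  expect_equal(nrow(vrt), 90)
})

test_that("reader handles the empty table and rejects invalid rows", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines("year,rate_name,age_class,mean,se,n", tmp)
  expect_equal(nrow(read_vital_rate_table(tmp)), 0)

  writeLines(c("year,rate_name,age_class,mean,se,n",
               "2013,NS1,SY,1.2,0.1,5"), tmp)
  expect_error(read_vital_rate_table(tmp), "probability")

  writeLines(c("year,rate_name,age_class,mean,se,n",
               "2013,NI2,SY,0.2,0.1,5"), tmp)
  expect_error(read_vital_rate_table(tmp), "pooled")

  writeLines(c("year,rate_name,age_class,mean,se,n",
               "2013,CS1,SY,-1,0.1,5"), tmp)
  expect_error(read_vital_rate_table(tmp), "positive")
})

test_that("vital-rate table round-trips through CSV bit-exactly", {
  vrt <- trout_creek_rates()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_vital_rate_table(vrt, tmp)
  back <- read_vital_rate_table(tmp)
  expect_equal(as.data.frame(back), as.data.frame(vrt))
})

test_that("missing re-nest clutch sizes fall back to the offset rule", {
  vrt <- trout_creek_rates(complete = FALSE)
  expect_true(any(is.na(vrt$mean[vrt$rate_name == "CS2"])))
  full <- complete_cs2(vrt)
  expect_false(any(is.na(full$mean[full$rate_name == "CS2"])))
  # 2013 SY: CS1 6.26 - 1.39
  got <- full$mean[full$year == 2013 & full$rate_name == "CS2" &
                     full$age_class == "SY"]
  expect_equal(got, 6.26 - 1.39)
  # observed CS2 rows are untouched
  expect_equal(full$mean[full$year == 2014 & full$rate_name == "CS2" &
                           full$age_class == "SY"], 4.61)
})

test_that("rates_vector assembles the 15 matrix inputs with SEs", {
  rv <- rates_vector(trout_creek_rates(), 2013)
  expect_length(rv, 15)
  expect_equal(rv[["S_ASY"]], 0.27)
  expect_equal(rv[["CS2_ASY"]], 4.64)
  expect_equal(attr(rv, "se")[["NS2"]], 0.21)
  expect_error(rates_vector(trout_creek_rates(complete = FALSE), 2013),
               "missing vital rate")
})

test_that("encounter histories validate their dialect invariants", {
  f <- one_female()
  expect_s3_class(validate_histories(f, "female"), "female_histories")

  # records after death are rejected
  bad <- rbind(one_female(months_alive = 3),
               data.frame(female_id = "F1", age_class = "ASY", year = 2013,
                          month_index = 5, state = "alive"))
  expect_error(validate_histories(bad, "female"), "terminal")

  # brood flush count above the initial count is rejected
  expect_error(validate_histories(one_brood(n0 = 3, counts = c(4, 1, 1, 1, 1)),
                                  "brood"), "exceeds")
  # a feasible non-increasing series is accepted
  expect_s3_class(validate_histories(one_brood(), "brood"),
                  "brood_histories")

  # nest day out of the 27-day window
  nest <- data.frame(nest_id = "N1", female_id = "F1", age_class = "ASY",
                     attempt = "first", year = 2013, start_doy = 100,
                     day_index = 28, state = "active")
  expect_error(validate_histories(nest, "nest"), "1\\.\\.27")
})

test_that("all three dialects round-trip through CSV", {
  set.seed(11)
  truth <- simulation_truth(years = 2013:2014)
  sim <- simulate_study(truth)
  for (dialect in c("nest", "female", "brood")) {
    x <- sim[[paste0(dialect, "s")]]
    tmp <- withr::local_tempfile(fileext = ".csv")
    write_encounter_histories(x, tmp)
    back <- read_encounter_histories(tmp, dialect)
    expect_equal(as.data.frame(back), as.data.frame(x))
  }
})

test_that("validation accepts every simulator output (fuzz)", {
  n_hist <- 0
  for (seed in 1:3) {
    truth <- simulation_truth(years = 2013:2018, seed = seed,
                              winter_hazard_ratio = 0.6)
    sim <- simulate_study(truth)
    # simulate_study validates internally; re-validate explicitly
    expect_s3_class(validate_histories(sim$females, "female"),
                    "female_histories")
    expect_s3_class(validate_histories(sim$nests, "nest"), "nest_histories")
    expect_s3_class(validate_histories(sim$broods, "brood"),
                    "brood_histories")
    n_hist <- n_hist + length(unique(sim$females$female_id)) +
      length(unique(sim$nests$nest_id)) + length(unique(sim$broods$brood_id))
  }
  expect_gte(n_hist, 1000)
})

test_that("yearlings confirmed alive become adults the next March", {
  h <- rbind(one_female("F1", "SY", 2013, entry = 1, months_alive = 12,
                        terminal = "alive")[1:12, ],
             one_female("F1", "SY", 2014, entry = 1, months_alive = 4))
  h <- validate_histories(h, "female")
  out <- apply_age_transition(h)
  expect_true(all(out$age_class[out$year == 2014] == "ASY"))
  expect_true(all(out$age_class[out$year == 2013] == "SY"))

  # censored in February: fate unknown, no transition applied
  h2 <- rbind(one_female("F2", "SY", 2013, entry = 1, months_alive = 11,
                         terminal = "censored"),
              one_female("F2", "SY", 2014, entry = 1, months_alive = 4))
  out2 <- apply_age_transition(validate_histories(h2, "female"))
  expect_true(all(out2$age_class == "SY"))
})

test_that("MARK known-fate export encodes survival, death and entry", {
  f <- rbind(one_female("F1", months_alive = 3, terminal = "dead"),
             one_female("F2", entry = 3, months_alive = 2,
                        terminal = "alive"))
  s <- mark_known_fate_strings(validate_histories(f, "female"))
  expect_equal(unname(s[1]), paste0(c(rep("10", 3), "11", rep("00", 8)),
                                    collapse = ""))
  expect_equal(unname(s[2]), paste0(c("00", "00", "10", "10", "10",
                                      rep("00", 7)), collapse = ""))
})
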