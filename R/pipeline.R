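# End-to-end orchestration: (optionally) simulate encounter data, estimate
# survival rates from it, assemble the annual vital-rate table, bootstrap
# the matrix model, and run the LTRE. Stages communicate through the CSV
# contracts only, so any stage can be re-run from files.

#' Default pipeline configuration
#'
#' @param replicates Bootstrap replicates per year.
#' @param sjuv_mode Juvenile-survival pathway for the matrix (`"table"` or
#'   `"derived"`; see [bootstrap_config()]).
#' @param cs2_mode Re-nest clutch-size pathway (`"table"` or `"offset"`).
#' @param ltre_eval LTRE sensitivity evaluation rule.
#' @param simulate Simulate encounter data and re-estimate survival rates
#'   from it (otherwise the supplied vital-rate table is used directly).
#' @param nest_models,female_models Model-name vectors for the known-fate
#'   model sets.
#' @param rho_structures,phi_structures Brood model structures (two-stage).
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(replicates = 10000,
                            sjuv_mode = c("table", "derived"),
                            cs2_mode = c("table", "offset"),
                            ltre_eval = c("midpoint", "reference",
                                          "treatment"),
                            simulate = FALSE,
                            nest_models = c("intercept", "year", "year + T"),
                            female_models = c("year + age",
                                              "year + age + winter",
                                              "year + age + season"),
                            rho_structures = c("T", "year", "intercept"),
                            phi_structures = c("year", "year + T",
                                               "intercept")) {
  structure(list(replicates = replicates,
                 sjuv_mode = match.arg(sjuv_mode),
                 cs2_mode = match.arg(cs2_mode),
                 ltre_eval = match.arg(ltre_eval),
                 simulate = simulate,
                 nest_models = nest_models, female_models = female_models,
                 rho_structures = rho_structures,
                 phi_structures = phi_structures),
            class = "pipeline_config")
}

#' Estimate survival vital rates from encounter data
#'
#' Fits the configured known-fate model sets to nest and female histories
#' (separate runs for SY first nests, ASY first nests and pooled re-nests;
#' one run for females with year + age base structure), the two-stage brood
#' model, and returns a vital-rate table in which the survival rows (NS1,
#' NS2, S_annual, S_chick) are replaced by model-averaged estimates. Rates
#' not estimable from encounter histories (NI, CS, H, S_juv) are carried
#' over from `base_rates`.
#'
#' @param nests,females,broods Encounter-history data frames.
#' @param base_rates `vital_rate_table` supplying the non-survival rows.
#' @param config A [pipeline_config()].
#' @return List: `rates` (vital_rate_table), `model_tables` (named list).
#' @export
estimate_vital_rates <- function(nests, females, broods,
                                 base_rates = trout_creek_rates(),
                                 config = pipeline_config()) {
  rates <- as.data.frame(base_rates)
  tables <- list()
  put <- function(rates, rate_name, age, year, est, se) {
    i <- which(rates$rate_name == rate_name & rates$age_class == age &
                 rates$year == year)
    if (length(i) == 1) {
      rates$mean[i] <- est
      rates$se[i] <- se
    }
    rates
  }

  nest_groups <- list(
    NS1_SY = nests[nests$attempt == "first" & nests$age_class == "SY", ],
    NS1_ASY = nests[nests$attempt == "first" & nests$age_class == "ASY", ],
    NS2 = nests[nests$attempt == "renest", ]
  )
  for (gname in names(nest_groups)) {
    sub <- validate_histories(nest_groups[[gname]], "nest")
    iv <- kf_intervals(sub)
    fits <- lapply(config$nest_models, function(m) fit_known_fate(iv, m))
    names(fits) <- config$nest_models
    tab <- rank_models(fits)
    tables[[paste0("nest_", gname)]] <- tab
    ns <- derive_window_products(model_average(tab), "nest27")
    rate_name <- if (gname == "NS2") "NS2" else "NS1"
    age <- if (gname == "NS2") "pooled" else sub("NS1_", "", gname)
    for (k in seq_len(nrow(ns)))
      rates <- put(rates, rate_name, age, as.integer(as.character(ns$year[k])),
                   ns$estimate[k], ns$se[k])
  }

  iv <- kf_intervals(females)
  fits <- lapply(config$female_models, function(m) fit_known_fate(iv, m))
  names(fits) <- config$female_models
  tab <- rank_models(fits)
  tables$female <- tab
  ann <- derive_window_products(model_average(tab), "annual12")
  for (k in seq_len(nrow(ann)))
    rates <- put(rates, "S_annual", as.character(ann$age[k]),
                 as.integer(as.character(ann$year[k])),
                 ann$estimate[k], ann$se[k])

  if (length(config$rho_structures) == 1 &&
      length(config$phi_structures) == 1) {
    best_fit <- fit_brood_model(broods,
                                brood_model_spec(config$phi_structures,
                                                 config$rho_structures))
  } else {
    bs <- brood_two_stage(broods, config$rho_structures,
                          config$phi_structures)
    tables$brood_rho <- bs$rho_table
    tables$brood_phi <- bs$phi_table
    best_fit <- bs$best_fit
  }
  sc <- chick_survival_54day(best_fit)
  for (k in seq_len(nrow(sc)))
    rates <- put(rates, "S_chick", "pooled", sc$year[k], sc$estimate[k],
                 sc$se[k])

  class(rates) <- c("vital_rate_table", "data.frame")
  list(rates = rates, model_tables = tables)
}

#' Run the full demographic pipeline
#'
#' Deterministic given `seed`. Writes `vital_rates.csv`,
#' `lambda_results.csv`, `ltre_contributions.csv`, `ltre_totals.csv`,
#' model-selection tables when estimation ran, and a `report.md` embedding
#' the seed and configuration.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for all randomness.
#' @param rates Input `vital_rate_table` (default: the packaged study table).
#' @param config A [pipeline_config()].
#' @return Invisible list with `lambda` (list of `lambda_result`), `summary`,
#'   `ltre`, `rates`, and `model_tables` when estimation ran.
#' @export
run_pipeline <- function(out_dir, seed = 1, rates = trout_creek_rates(),
                         config = pipeline_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  model_tables <- NULL
  if (isTRUE(config$simulate)) {
    truth <- simulation_truth(rates = rates, seed = seed)
    sim <- simulate_study(truth, dir = file.path(out_dir, "sim"))
    est <- estimate_vital_rates(sim$nests, sim$females, sim$broods,
                                base_rates = rates, config = config)
    rates <- est$rates
    model_tables <- est$model_tables
    for (nm in names(model_tables))
      utils::write.csv(as.data.frame(model_tables[[nm]]),
                       file.path(out_dir, paste0("model_selection_", nm,
                                                 ".csv")),
                       row.names = FALSE)
  }
  write_vital_rate_table(rates, file.path(out_dir, "vital_rates.csv"))

  by_year <- annual_rates(rates)
  cfg <- bootstrap_config(config$replicates, config$sjuv_mode,
                          config$cs2_mode)
  set.seed(seed + 1L)
  lambdas <- lapply(names(by_year), function(y)
    bootstrap_lambda(by_year[[y]], cfg, year = as.integer(y)))
  ltab <- lambda_table(lambdas)
  utils::write.csv(ltab, file.path(out_dir, "lambda_results.csv"),
                   row.names = FALSE)
  summ <- multi_year_summary(lambdas)

  ltre <- ltre_contributions(by_year, reference = names(by_year)[1],
                             eval_rule = config$ltre_eval)
  utils::write.csv(ltre$contributions,
                   file.path(out_dir, "ltre_contributions.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(rate = names(ltre$totals),
                              total = unname(ltre$totals)),
                   file.path(out_dir, "ltre_totals.csv"), row.names = FALSE)

  report <- c(
    "# Demographic pipeline report", "",
    paste0("seed: ", seed),
    paste0("config: ", jsonlite::toJSON(unclass(config), auto_unbox = TRUE)),
    "",
    "## Annual finite rate of population change", "",
    utils::capture.output(print(ltab, row.names = FALSE)),
    "",
    sprintf("Geometric mean lambda (point pathway): %.3f",
            summ$geometric_mean),
    sprintf("Geometric mean lambda (replicate pathway): %.3f (95%% CI %.3f-%.3f)",
            summ$replicate_mean, summ$ci[1], summ$ci[2]),
    "",
    paste0("## LTRE totals vs ", ltre$reference, " (rule: ", ltre$eval_rule,
           ")"), "",
    utils::capture.output(print(round(sort(ltre$totals, decreasing = TRUE),
                                      3)))
  )
  writeLines(report, file.path(out_dir, "report.md"))
  invisible(list(lambda = lambdas, summary = summ, ltre = ltre,
                 rates = rates, model_tables = model_tables))
}
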