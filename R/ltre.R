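# Life-table response experiment: decompose differences in lambda between a
# reference year and each treatment year into per-vital-rate contributions
# (rate difference times the sensitivity of lambda to that rate).

LTRE_RATES <- c("NI1_SY", "NI1_ASY", "NI2", "CS1_SY", "CS1_ASY", "CS2_SY",
                "CS2_ASY", "H", "NS1_SY", "NS1_ASY", "NS2", "S_chick",
                "S_juv", "S_SY", "S_ASY")
LTRE_SURVIVAL_GROUP <- c("S_SY", "S_ASY", "S_juv")

#' Sensitivities of lambda to the lower-level vital rates
#'
#' Chain rule through the matrix entries: `dlambda/da_kl = v_k w_l` (with
#' eigenvectors scaled so that `sum(v w) = 1`), composed with the analytic
#' partials of the fecundity equation and of the entries
#' `a11 = F_SY S_juv`, `a12 = F_ASY S_juv`, `a21 = S_SY`, `a22 = S_ASY`.
#'
#' @param rates Named vector of the 15 lower-level rates ([rates_vector()]).
#' @return Named vector of `dlambda/dx` over `LTRE_RATES`.
#' @export
lambda_sensitivities <- function(rates) {
  pm <- build_matrix(rates)
  sv <- outer(pm$v, pm$w)  # dlambda/da_kl
  x <- as.list(rates)
  dF_SY <- do.call(fecundity_partials, fecundity_args(x, "SY"))
  dF_ASY <- do.call(fecundity_partials, fecundity_args(x, "ASY"))
  sjuv <- x$S_juv
  s <- stats::setNames(numeric(length(LTRE_RATES)), LTRE_RATES)
  fec_map <- list(
    NI1_SY = c("SY", "NI1"), CS1_SY = c("SY", "CS1"), NS1_SY = c("SY", "NS1"),
    CS2_SY = c("SY", "CS2"),
    NI1_ASY = c("ASY", "NI1"), CS1_ASY = c("ASY", "CS1"),
    NS1_ASY = c("ASY", "NS1"), CS2_ASY = c("ASY", "CS2")
  )
  for (r in names(fec_map)) {
    age <- fec_map[[r]][1]; term <- fec_map[[r]][2]
    d <- if (age == "SY") dF_SY[[term]] else dF_ASY[[term]]
    col <- if (age == "SY") 1 else 2
    s[r] <- sv[1, col] * d * sjuv
  }
  for (r in c("NI2", "NS2", "H", "S_chick")) {  # shared by both fecundities
    s[r] <- sv[1, 1] * dF_SY[[r]] * sjuv + sv[1, 2] * dF_ASY[[r]] * sjuv
  }
  s["S_juv"] <- sv[1, 1] * pm$F_SY + sv[1, 2] * pm$F_ASY
  s["S_SY"] <- sv[2, 1]
  s["S_ASY"] <- sv[2, 2]
  s
}

#' Finite-difference check of [lambda_sensitivities()]
#'
#' @param rates Named rate vector.
#' @param h Central-difference step.
#' @return Named vector of central-difference sensitivities.
#' @export
lambda_sensitivities_fd <- function(rates, h = 1e-6) {
  base <- unclass(rates)[LTRE_RATES]
  vapply(LTRE_RATES, function(r) {
    up <- base; dn <- base
    up[r] <- up[r] + h; dn[r] <- dn[r] - h
    (build_matrix(up)$lambda - build_matrix(dn)$lambda) / (2 * h)
  }, numeric(1))
}

#' Life-table response experiment against a reference year
#'
#' For each treatment year `j`, the contribution of vital rate `i` is
#' `c_ij = (x_i^j - x_i^ref) * dlambda/dx_i`, with the sensitivity evaluated
#' at the reference matrix, the treatment matrix, or the midpoint ("mean
#' matrix") of the two rate vectors. Contributions are signed for
#' `lambda^j - lambda^ref`, so a rate that improved after the reference year
#' contributes positively.
#'
#' @param rates_by_year Named list of rate vectors ([annual_rates()]).
#' @param reference Name (year) of the reference entry.
#' @param eval_rule `"midpoint"` (default), `"reference"` or `"treatment"`.
#' @return Object of class `ltre_result`: per-year/rate `contributions`,
#'   per-rate `totals`, grouped totals, and the first-order residual
#'   (`sum(c_ij)` vs the actual lambda difference) per year.
#' @export
ltre_contributions <- function(rates_by_year, reference = names(rates_by_year)[1],
                               eval_rule = c("midpoint", "reference",
                                             "treatment")) {
  eval_rule <- match.arg(eval_rule)
  reference <- as.character(reference)
  stopifnot(reference %in% names(rates_by_year))
  ref <- rates_by_year[[reference]]
  treatments <- setdiff(names(rates_by_year), reference)
  lam_ref <- build_matrix(ref)$lambda
  contr <- list()
  checks <- list()
  for (yr in treatments) {
    trt <- rates_by_year[[yr]]
    if (!identical(names(unclass(trt))[seq_along(LTRE_RATES)],
                   names(unclass(ref))[seq_along(LTRE_RATES)]))
      stop("rate keys differ between reference and treatment ", yr)
    xe <- switch(eval_rule,
                 reference = unclass(ref)[LTRE_RATES],
                 treatment = unclass(trt)[LTRE_RATES],
                 midpoint = (unclass(ref)[LTRE_RATES] +
                               unclass(trt)[LTRE_RATES]) / 2)
    s <- lambda_sensitivities(xe)
    diff <- unclass(trt)[LTRE_RATES] - unclass(ref)[LTRE_RATES]
    c_ij <- diff * s
    contr[[yr]] <- data.frame(year = yr, rate = LTRE_RATES,
                              contribution = unname(c_ij),
                              stringsAsFactors = FALSE)
    lam_trt <- build_matrix(trt)$lambda
    checks[[yr]] <- data.frame(
      year = yr, predicted = sum(c_ij), actual = lam_trt - lam_ref,
      residual = sum(c_ij) - (lam_trt - lam_ref))
  }
  contributions <- do.call(rbind, contr)
  totals <- tapply(contributions$contribution, contributions$rate, sum)
  totals <- totals[LTRE_RATES]
  grouped <- c(
    survival = sum(totals[LTRE_SURVIVAL_GROUP]),
    fecundity = sum(totals[setdiff(LTRE_RATES, LTRE_SURVIVAL_GROUP)])
  )
  structure(list(reference = reference, eval_rule = eval_rule,
                 contributions = contributions, totals = totals,
                 grouped_totals = grouped,
                 accuracy = do.call(rbind, checks)),
            class = "ltre_result")
}

#' @export
print.ltre_result <- function(x, ...) {
  cat("LTRE vs reference", x$reference, "(eval rule:", x$eval_rule, ")\n")
  cat("Total contributions to lambda, largest first:\n")
  print(round(sort(x$totals, decreasing = TRUE), 3))
  invisible(x)
}

#' Compare LTRE totals across the three evaluation rules
#'
#' The evaluation matrix for the sensitivities is a genuine methodological
#' choice; this helper runs the decomposition under all three rules so a
#' report can state which rule a published total corresponds to.
#'
#' @param rates_by_year Named list of rate vectors.
#' @param reference Reference year name.
#' @return Data frame of per-rate totals with one column per rule.
#' @export
ltre_rule_comparison <- function(rates_by_year,
                                 reference = names(rates_by_year)[1]) {
  rules <- c("reference", "midpoint", "treatment")
  cols <- lapply(rules, function(r)
    ltre_contributions(rates_by_year, reference, r)$totals)
  out <- data.frame(rate = LTRE_RATES)
  for (i in seq_along(rules)) out[[rules[i]]] <- unname(cols[[i]])
  out
}
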