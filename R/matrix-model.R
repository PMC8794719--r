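# Two-age female pre-birth-pulse projection matrix and parametric bootstrap
# of the finite rate of population change. The census sits just before the
# birth pulse (female survival is monitored from March), so fecundity terms
# carry offspring through juvenile survival to census age:
#   A = | F_SY * S_juv   F_ASY * S_juv |
#       | S_SY           S_ASY         |

#' Age-specific fecundity (female chicks per female at 54 days post-hatch)
#'
#' `F = [NI1*CS1*NS1 + (1-NS1)*NI2*CS2*NS2] * H * 0.5 * S_chick`: expected
#' eggs carried through first nests plus re-nests after first-nest failure,
#' times hatchability, the female sex ratio and 54-day chick survival.
#' All arguments are vectorized.
#'
#' @param NI1,NS1,CS1 First-nest initiation, 27-day nest survival and clutch
#'   size for the age class.
#' @param NI2,NS2,CS2 Re-nest initiation (pooled), re-nest survival (pooled)
#'   and age-specific re-nest clutch size.
#' @param H Hatchability.
#' @param S_chick 54-day chick survival.
#' @return Fecundity (female offspring per female).
#' @export
fecundity <- function(NI1, CS1, NS1, NI2, CS2, NS2, H, S_chick) {
  (NI1 * CS1 * NS1 + (1 - NS1) * NI2 * CS2 * NS2) * H * 0.5 * S_chick
}

# Analytic partial derivatives of fecundity wrt each input.
fecundity_partials <- function(NI1, CS1, NS1, NI2, CS2, NS2, H, S_chick) {
  inner <- NI1 * CS1 * NS1 + (1 - NS1) * NI2 * CS2 * NS2
  k <- H * 0.5 * S_chick
  list(
    NI1 = CS1 * NS1 * k,
    CS1 = NI1 * NS1 * k,
    NS1 = (NI1 * CS1 - NI2 * CS2 * NS2) * k,
    NI2 = (1 - NS1) * CS2 * NS2 * k,
    CS2 = (1 - NS1) * NI2 * NS2 * k,
    NS2 = (1 - NS1) * NI2 * CS2 * k,
    H = inner * 0.5 * S_chick,
    S_chick = inner * H * 0.5
  )
}

# Dominant eigenvalue of a nonnegative 2x2 matrix, closed form (vectorized).
lambda_2x2 <- function(a11, a12, a21, a22) {
  ((a11 + a22) + sqrt((a11 - a22)^2 + 4 * a12 * a21)) / 2
}

fecundity_args <- function(x, age) {
  list(NI1 = x[[paste0("NI1_", age)]], CS1 = x[[paste0("CS1_", age)]],
       NS1 = x[[paste0("NS1_", age)]], NI2 = x[["NI2"]],
       CS2 = x[[paste0("CS2_", age)]], NS2 = x[["NS2"]],
       H = x[["H"]], S_chick = x[["S_chick"]])
}

#' Build the annual two-age projection matrix
#'
#' @param rates Named vector (or list) of lower-level rates as produced by
#'   [rates_vector()]: `NI1_SY`, `NI1_ASY`, `NI2`, `CS1_*`, `CS2_*`, `H`,
#'   `NS1_*`, `NS2`, `S_chick`, `S_juv`, `S_SY`, `S_ASY`.
#' @param sjuv_mode `"table"` uses the supplied `S_juv`; `"derived"` replaces
#'   it with `0.7 * S_ASY^(7/12)` (see [derive_juvenile_survival()]).
#' @return Object of class `projection_matrix`: the matrix `A`, dominant
#'   eigenvalue `lambda`, right eigenvector `w` (stable age distribution,
#'   summing to 1), left eigenvector `v` (reproductive values, scaled so
#'   `sum(v * w) = 1`), fecundities and the input rates.
#' @export
build_matrix <- function(rates, sjuv_mode = c("table", "derived")) {
  sjuv_mode <- match.arg(sjuv_mode)
  x <- as.list(rates)
  req <- c("NI1_SY", "NI1_ASY", "NI2", "CS1_SY", "CS1_ASY", "CS2_SY",
           "CS2_ASY", "H", "NS1_SY", "NS1_ASY", "NS2", "S_chick", "S_juv",
           "S_SY", "S_ASY")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop("missing vital rates: ", paste(miss, collapse = ", "))
  sjuv <- if (sjuv_mode == "derived")
    derive_juvenile_survival(x$S_ASY)$mean else x$S_juv
  F_SY <- do.call(fecundity, fecundity_args(x, "SY"))
  F_ASY <- do.call(fecundity, fecundity_args(x, "ASY"))
  A <- matrix(c(F_SY * sjuv, F_ASY * sjuv, x$S_SY, x$S_ASY),
              2, 2, byrow = TRUE,
              dimnames = list(c("SY", "ASY"), c("SY", "ASY")))
  lam <- lambda_2x2(A[1, 1], A[1, 2], A[2, 1], A[2, 2])
  if (A[1, 2] > 0 || A[2, 1] > 0 || A[1, 1] != A[2, 2]) {
    w <- c(A[1, 2], lam - A[1, 1])
    if (all(w == 0)) w <- c(lam - A[2, 2], A[2, 1])
    v <- c(A[2, 1], lam - A[1, 1])
    if (all(v == 0)) v <- c(lam - A[2, 2], A[1, 2])
  } else {
    w <- v <- c(1, 1)  # diagonal with equal entries
  }
  w <- w / sum(w)
  v <- v / sum(v * w)
  structure(list(A = A, lambda = lam, w = w, v = v,
                 F_SY = F_SY, F_ASY = F_ASY, S_juv_used = sjuv,
                 sjuv_mode = sjuv_mode, rates = unlist(x[req])),
            class = "projection_matrix")
}

#' @export
print.projection_matrix <- function(x, ...) {
  cat("Pre-birth-pulse projection matrix (lambda =",
      format(x$lambda, digits = 4), ")\n")
  print(round(x$A, 4))
  invisible(x)
}

#' Moment-matched beta parameters for a probability vital rate
#'
#' Solves `alpha = m(m(1-m)/v - 1)`, `beta = (1-m)(m(1-m)/v - 1)`. When the
#' requested variance is infeasible (`v >= m(1-m)`) it is clipped to
#' `0.95 * m(1-m)` with a warning, preserving the mean with maximal proper
#' dispersion.
#'
#' @param m Mean in (0, 1).
#' @param v Variance.
#' @return List with `alpha`, `beta` and logical `clipped`.
#' @export
beta_moment_match <- function(m, v) {
  stopifnot(m > 0, m < 1, v > 0)
  vmax <- m * (1 - m)
  clipped <- v >= vmax
  if (clipped) {
    warning("beta moment match infeasible (v >= m(1-m)); clipping variance")
    v <- 0.95 * vmax
  }
  k <- vmax / v - 1
  list(alpha = m * k, beta = (1 - m) * k, clipped = clipped)
}

draw_rate <- function(n, m, se, kind = c("prob", "clutch"), resample = TRUE) {
  kind <- match.arg(kind)
  if (!resample || se <= 0) return(rep(m, n))
  if (kind == "prob") {
    if (m <= 0 || m >= 1) return(rep(m, n))  # degenerate mean: held fixed
    bm <- beta_moment_match(m, se^2)
    stats::rbeta(n, bm$alpha, bm$beta)
  } else {
    # clutch sizes: normal truncated to a biologically plausible [1, 15] eggs
    pmin(pmax(stats::rnorm(n, m, se), 1), 15)
  }
}

#' Bootstrap configuration for the matrix model
#'
#' @param n_replicates Number of parametric-bootstrap replicates.
#' @param sjuv_mode `"table"`: juvenile survival drawn from its tabled
#'   mean/SE; `"derived"`: recomputed per replicate from the adult survival
#'   draw as `0.7 * S_ASY^(7/12)`.
#' @param cs2_mode `"table"`: re-nest clutch size drawn independently from
#'   its tabled mean/SE; `"offset"`: recomputed per draw as the first-nest
#'   draw minus the fixed age offset.
#' @param resample_h Resample hatchability? Default `FALSE` (held at its
#'   point estimate, whose SE is negligible).
#' @return List of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_replicates = 10000,
                             sjuv_mode = c("table", "derived"),
                             cs2_mode = c("table", "offset"),
                             resample_h = FALSE) {
  structure(list(n_replicates = n_replicates,
                 sjuv_mode = match.arg(sjuv_mode),
                 cs2_mode = match.arg(cs2_mode),
                 resample_h = resample_h),
            class = "bootstrap_config")
}

#' Parametric bootstrap of the annual finite rate of population change
#'
#' Draws every lower-level vital rate from its sampling distribution (beta,
#' moment-matched to the mean/SE, for probabilities; truncated normal for
#' clutch sizes), rebuilds the fecundities and the projection matrix for each
#' replicate, and records the dominant eigenvalue. Rates with SE 0 are held
#' fixed. Uses the current RNG state; seed externally with `set.seed()`.
#'
#' @param rates Named rate vector from [rates_vector()] (with `se` attribute),
#'   or a `vital_rate_table` plus `year`.
#' @param cfg A [bootstrap_config()].
#' @param year Year label carried into the result (optional).
#' @return Object of class `lambda_result`: point estimate, replicates, mean
#'   of replicates, percentile 95% CI and trend classification.
#' @export
bootstrap_lambda <- function(rates, cfg = bootstrap_config(), year = NA) {
  se <- attr(rates, "se")
  if (is.null(se)) stop("rates vector must carry an 'se' attribute")
  R <- cfg$n_replicates
  d <- function(key, kind = "prob")
    draw_rate(R, rates[[key]], se[[key]], kind)
  dr <- list(
    NI1_SY = d("NI1_SY"), NI1_ASY = d("NI1_ASY"), NI2 = d("NI2"),
    CS1_SY = d("CS1_SY", "clutch"), CS1_ASY = d("CS1_ASY", "clutch"),
    NS1_SY = d("NS1_SY"), NS1_ASY = d("NS1_ASY"), NS2 = d("NS2"),
    S_chick = d("S_chick"), S_SY = d("S_SY"), S_ASY = d("S_ASY")
  )
  dr$H <- if (cfg$resample_h) d("H") else rep(rates[["H"]], R)
  dr$CS2_SY <- if (cfg$cs2_mode == "table") d("CS2_SY", "clutch") else
    pmax(dr$CS1_SY - 1.39, 1)
  dr$CS2_ASY <- if (cfg$cs2_mode == "table") d("CS2_ASY", "clutch") else
    pmax(dr$CS1_ASY - 1.63, 1)
  dr$S_juv <- if (cfg$sjuv_mode == "table") d("S_juv") else
    derive_juvenile_survival(dr$S_ASY)$mean
  F_SY <- do.call(fecundity, fecundity_args(dr, "SY"))
  F_ASY <- do.call(fecundity, fecundity_args(dr, "ASY"))
  reps <- lambda_2x2(F_SY * dr$S_juv, F_ASY * dr$S_juv, dr$S_SY, dr$S_ASY)
  point <- build_matrix(rates, sjuv_mode = cfg$sjuv_mode)$lambda
  ci <- unname(stats::quantile(reps, c(0.025, 0.975)))
  classification <-
    if (ci[1] > 1) "increasing"
    else if (ci[2] < 1) "decreasing"
    else if (point == 1) "stable"
    else "uncertain"
  structure(list(year = year, lambda_point = point, replicates = reps,
                 lambda_boot_mean = mean(reps), ci = ci,
                 classification = classification, config = cfg),
            class = "lambda_result")
}

#' @export
print.lambda_result <- function(x, ...) {
  cat(sprintf("lambda[%s] = %.3f (boot mean %.3f, 95%% CI %.3f-%.3f) %s\n",
              as.character(x$year), x$lambda_point, x$lambda_boot_mean,
              x$ci[1], x$ci[2], x$classification))
  invisible(x)
}

#' Flatten lambda results into a reporting table
#'
#' @param results List of `lambda_result` objects.
#' @return Data frame: `year`, `lambda_point`, `lambda_boot_mean`, `ci_lo`,
#'   `ci_hi`, `classification`.
#' @export
lambda_table <- function(results) {
  do.call(rbind, lapply(results, function(r)
    data.frame(year = r$year, lambda_point = r$lambda_point,
               lambda_boot_mean = r$lambda_boot_mean,
               ci_lo = r$ci[1], ci_hi = r$ci[2],
               classification = r$classification)))
}

#' Geometric-mean population growth over a span of years
#'
#' The point pathway takes the geometric mean of the annual point (or
#' bootstrap-mean) estimates; the CI pathway pairs bootstrap replicates
#' across years by index (independent draws per year) and takes percentiles
#' of the per-replicate geometric means.
#'
#' @param results List of `lambda_result` objects (one per year).
#' @return List: `geometric_mean` (of point estimates), `geometric_mean_boot`
#'   (of per-year bootstrap means), `replicate_mean` and `ci` from the
#'   per-replicate geometric means.
#' @export
multi_year_summary <- function(results) {
  stopifnot(length(results) >= 1)
  pts <- vapply(results, function(r) r$lambda_point, numeric(1))
  bms <- vapply(results, function(r) r$lambda_boot_mean, numeric(1))
  gm <- function(x) if (any(x == 0)) 0 else exp(mean(log(x)))
  reps <- sapply(results, function(r) r$replicates)
  gm_reps <- apply(reps, 1, gm)
  list(geometric_mean = gm(pts), geometric_mean_boot = gm(bms),
       replicate_mean = mean(gm_reps),
       ci = unname(stats::quantile(gm_reps, c(0.025, 0.975))),
       zero_flagged = any(pts == 0))
}
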