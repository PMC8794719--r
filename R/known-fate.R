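# Known-fate survival likelihood engine. Each monitored interval (nest-day
# or bird-month) contributes a Bernoulli term on interval survival through a
# logit link; staggered entry and censoring simply remove intervals from the
# risk set. Fits are ranked by AICc and model-averaged.

#' Expand encounter histories into monitored-interval records
#'
#' One row per monitored interval with the interval survival indicator and
#' temporal covariates: `year`, `age`, `interval`, categorical `day`/`month`,
#' `season` (breeding Apr-Jul, fall Aug-Nov, winter Dec-Mar) with indicator
#' columns, a within-window linear trend `t_lin` scaled to [0, 1], and for
#' nests the standardized incubation start day `julian_s`. Censored intervals
#' and intervals before staggered entry are absent.
#'
#' @param x A `nest_histories` or `female_histories` data frame.
#' @return Data frame of class `kf_intervals` with attribute `dialect`.
#' @export
kf_intervals <- function(x) {
  if (inherits(x, "nest_histories")) {
    keep <- x$state != "censored"
    iv <- data.frame(
      id = x$nest_id[keep],
      year = factor(x$year[keep]),
      age = factor(x$age_class[keep], levels = c("ASY", "SY")),
      attempt = x$attempt[keep],
      interval = x$day_index[keep],
      julian = x$start_doy[keep],
      survived = as.integer(x$state[keep] != "failed"),
      stringsAsFactors = FALSE
    )
    dialect <- "nest"
  } else if (inherits(x, "female_histories")) {
    keep <- x$state != "censored"
    iv <- data.frame(
      id = paste(x$female_id[keep], x$year[keep], sep = "/"),
      year = factor(x$year[keep]),
      age = factor(x$age_class[keep], levels = c("ASY", "SY")),
      interval = x$month_index[keep],
      survived = as.integer(x$state[keep] != "dead"),
      stringsAsFactors = FALSE
    )
    dialect <- "female"
  } else stop("expected nest or female histories")
  iv <- add_kf_covariates(iv, dialect)
  class(iv) <- c("kf_intervals", "data.frame")
  attr(iv, "dialect") <- dialect
  iv
}

# Derived temporal covariates shared by fitting and prediction grids.
add_kf_covariates <- function(iv, dialect) {
  width <- if (dialect == "nest") 27L else 12L
  iv$t_lin <- (iv$interval - 1) / (width - 1)
  if (dialect == "nest") {
    iv$day <- factor(iv$interval, levels = 1:27)
    if (is.null(iv$julian)) iv$julian <- 0
    iv$julian_s <- if (isTRUE(stats::sd(iv$julian) > 0))
      (iv$julian - mean(iv$julian)) / stats::sd(iv$julian) else 0
  } else {
    iv$month <- factor(iv$interval, levels = 1:12)
    # month 1 = March; breeding Apr-Jul, fall Aug-Nov, winter Dec-Mar
    season <- ifelse(iv$interval %in% 2:5, "breeding",
                     ifelse(iv$interval %in% 6:9, "fall", "winter"))
    iv$season <- factor(season, levels = c("breeding", "fall", "winter"))
    iv$winter <- as.numeric(season == "winter")
    iv$breeding <- as.numeric(season == "breeding")
    iv$fall <- as.numeric(season == "fall")
  }
  iv
}

#' Translate a model-name string into a survival design formula
#'
#' Accepts the compact model names used in model-selection tables, e.g.
#' `"intercept"`, `"year + age + winter"`, `"year * day"`, `"year + T"`,
#' `"year + julian"`. Terms: `year`, `age`, `season`, `month`, `day`,
#' `winter`/`breeding`/`fall` indicators, `T` (linear trend), `julian`.
#'
#' @param design Model-name string.
#' @return A one-sided formula.
#' @export
parse_design <- function(design) {
  s <- gsub("×", "*", design)
  s <- gsub("\\bT\\b", "t_lin", s)
  s <- gsub("\\bjulian\\b", "julian_s", s)
  s <- gsub("\\bintercept\\b", "1", s, ignore.case = TRUE)
  stats::as.formula(paste("~", s))
}

kf_negloglik <- function(beta, X, y, ridge = 0) {
  eta <- drop(X %*% beta)
  ll <- sum(stats::plogis(ifelse(y == 1, eta, -eta), log.p = TRUE))
  -ll + ridge * sum(beta^2) / 2
}

kf_gradient <- function(beta, X, y, ridge = 0) {
  p <- stats::plogis(drop(X %*% beta))
  -drop(crossprod(X, y - p)) + ridge * beta
}

kf_hessian <- function(beta, X, ridge = 0) {
  p <- stats::plogis(drop(X %*% beta))
  crossprod(X, X * (p * (1 - p))) + diag(ridge, ncol(X))
}

#' Small-sample Akaike information criterion
#'
#' `AICc = -2 logL + 2K + 2K(K+1)/(n - K - 1)`; infinite when the correction
#' denominator is not positive (more parameters than the effective sample
#' size supports).
#'
#' @param loglik Maximized log-likelihood.
#' @param K Number of free coefficients.
#' @param n Effective sample size (monitored intervals).
#' @return AICc value.
#' @export
aicc <- function(loglik, K, n) {
  if (n - K - 1 <= 0) return(Inf)
  -2 * loglik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Fit a known-fate survival model
#'
#' Maximizes the known-fate likelihood (Bernoulli interval survival, logit
#' link) by quasi-Newton from zero-initialized coefficients, followed by
#' Newton polishing to a gradient infinity-norm below `tol`. Complete
#' separation (coefficients diverging to the boundary) triggers a weak ridge
#' penalty (prior variance 100 on the logit scale) with a flag rather than
#' failure. The effective sample size for AICc is the number of monitored
#' intervals (exposure days for nests, bird-months for females).
#'
#' @param histories A `nest_histories`/`female_histories` data frame, or a
#'   pre-built `kf_intervals` object.
#' @param design Model-name string (see [parse_design()]).
#' @param tol Convergence tolerance on the gradient infinity-norm.
#' @return An object of class `kf_fit`.
#' @export
fit_known_fate <- function(histories, design = "intercept", tol = 1e-8) {
  iv <- if (inherits(histories, "kf_intervals")) histories
        else kf_intervals(histories)
  if (nrow(iv) == 0) stop("no monitored intervals")
  form <- parse_design(design)
  trm <- stats::terms(form, data = iv)
  mf <- stats::model.frame(trm, iv)
  X <- stats::model.matrix(trm, mf)
  y <- iv$survived
  fit <- kf_optimize(X, y, tol)
  ll <- -kf_negloglik(fit$beta, X, y)
  res <- list(
    coefficients = stats::setNames(fit$beta, colnames(X)),
    vcov = fit$vcov, logLik = ll, K = ncol(X), n_eff = nrow(X),
    aicc = aicc(ll, ncol(X), nrow(X)),
    design = design, terms = trm,
    xlevels = stats::.getXlevels(trm, mf),
    data = iv, dialect = attr(iv, "dialect"),
    penalized = fit$penalized, boundary = fit$boundary,
    gradient_norm = fit$gnorm,
    data_signature = c(nrow(iv), sum(y), sum(iv$interval))
  )
  class(res) <- "kf_fit"
  res
}

kf_optimize <- function(X, y, tol = 1e-8, ridge = 0) {
  beta0 <- rep(0, ncol(X))
  opt <- stats::optim(beta0, kf_negloglik, kf_gradient, X = X, y = y,
                      ridge = ridge, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  beta <- opt$par
  # Newton polish
  for (i in 1:50) {
    g <- kf_gradient(beta, X, y, ridge)
    if (max(abs(g)) < tol) break
    H <- kf_hessian(beta, X, ridge)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    f0 <- kf_negloglik(beta, X, y, ridge)
    sc <- 1
    repeat {
      bnew <- beta - sc * step
      if (kf_negloglik(bnew, X, y, ridge) <= f0 || sc < 1e-6) break
      sc <- sc / 2
    }
    beta <- bnew
  }
  g <- kf_gradient(beta, X, y, ridge)
  separated <- max(abs(beta)) > 15 || !all(is.finite(g))
  if (ridge == 0 && (separated || max(abs(g)) > 1e-4)) {
    if (separated)
      warning("complete separation: refitting with a weak ridge penalty")
    return(kf_optimize(X, y, tol, ridge = if (separated) 1 / 100 else ridge))
  }
  H <- kf_hessian(beta, X, ridge)
  V <- tryCatch(solve(H), error = function(e) {
    warning("singular information matrix; using pseudo-inverse")
    ev <- eigen(H, symmetric = TRUE)
    pos <- ev$values > max(ev$values) * 1e-10
    ev$vectors[, pos, drop = FALSE] %*%
      (t(ev$vectors[, pos, drop = FALSE]) / ev$values[pos])
  })
  p <- stats::plogis(drop(X %*% beta))
  list(beta = beta, vcov = V, penalized = ridge > 0,
       boundary = any(p > 1 - 1e-8) || any(p < 1e-8),
       gnorm = max(abs(g)))
}

#' @export
print.kf_fit <- function(x, ...) {
  cat("Known-fate fit (", x$dialect, "): ", x$design, "\n", sep = "")
  cat(sprintf("  logLik %.3f  K %d  n_eff %d  AICc %.2f\n",
              x$logLik, x$K, x$n_eff, x$aicc))
  if (x$penalized) cat("  [ridge-penalized: separation detected]\n")
  if (x$boundary) cat("  [estimate at probability boundary]\n")
  invisible(x)
}

# Prediction grid covering every interval of the design window for each
# year (and age) present in the data.
kf_grid <- function(fit) {
  width <- if (fit$dialect == "nest") 27L else 12L
  lev_year <- levels(fit$data$year)
  lev_age <- unique(as.character(fit$data$age))
  g <- expand.grid(year = lev_year, age = lev_age, interval = 1:width,
                   stringsAsFactors = FALSE)
  g$year <- factor(g$year, levels = lev_year)
  g$age <- factor(g$age, levels = levels(fit$data$age))
  if (fit$dialect == "nest") g$julian <- mean(fit$data$julian)
  g <- add_kf_covariates(g, fit$dialect)
  if (fit$dialect == "nest") g$julian_s <- 0  # evaluated at the mean start day
  g
}

kf_model_matrix <- function(fit, newdata) {
  stats::model.matrix(stats::delete.response(fit$terms), newdata,
                      xlev = fit$xlevels)
}

#' Per-interval survival estimates from a known-fate fit
#'
#' @param fit A `kf_fit`.
#' @param newdata Optional grid; defaults to every interval x year x age.
#' @return Data frame of class `interval_survival`: grid columns plus
#'   `estimate` and `se` (delta method on the logit scale).
#' @export
interval_survival <- function(fit, newdata = NULL) {
  g <- if (is.null(newdata)) kf_grid(fit) else newdata
  X <- kf_model_matrix(fit, g)
  eta <- drop(X %*% fit$coefficients)
  p <- stats::plogis(eta)
  se_eta <- sqrt(pmax(rowSums((X %*% fit$vcov) * X), 0))
  out <- g[c("year", "age", "interval")]
  out$estimate <- p
  out$se <- p * (1 - p) * se_eta
  class(out) <- c("interval_survival", "data.frame")
  attr(out, "dialect") <- fit$dialect
  out
}

#' Rank known-fate models by AICc
#'
#' @param fits Named list of `kf_fit` objects fitted to identical data.
#' @return Data frame of class `kf_model_table` with columns `model`, `K`,
#'   `log_likelihood`, `aicc`, `delta_aicc`, `weight`, sorted by AICc; the
#'   ranked fits are carried in attribute `fits`.
#' @export
rank_models <- function(fits) {
  stopifnot(length(fits) >= 1)
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- vapply(fits, function(f) f$design, character(1))
  sig <- vapply(fits, function(f) paste(f$data_signature, collapse = ","),
                character(1))
  if (length(unique(sig)) != 1)
    stop("models were not fitted to identical data; refusing to rank")
  tab <- data.frame(
    model = names(fits),
    K = vapply(fits, function(f) f$K, numeric(1)),
    log_likelihood = vapply(fits, function(f) f$logLik, numeric(1)),
    aicc = vapply(fits, function(f) f$aicc, numeric(1)),
    stringsAsFactors = FALSE
  )
  ord <- order(tab$aicc)
  tab <- tab[ord, ]
  tab$delta_aicc <- tab$aicc - tab$aicc[1]
  w <- exp(-tab$delta_aicc / 2)
  tab$weight <- w / sum(w)
  rownames(tab) <- NULL
  class(tab) <- c("kf_model_table", "data.frame")
  attr(tab, "fits") <- fits[ord]
  tab
}

#' Model-averaged per-interval survival
#'
#' Point estimate is the Akaike-weighted mean across models; the
#' unconditional variance adds the between-model spread to each model's
#' conditional variance.
#'
#' @param model_table A `kf_model_table` from [rank_models()], or a list of
#'   fits (ranked internally).
#' @return An `interval_survival` data frame.
#' @export
model_average <- function(model_table) {
  if (!inherits(model_table, "kf_model_table"))
    model_table <- rank_models(model_table)
  fits <- attr(model_table, "fits")
  w <- model_table$weight
  preds <- lapply(fits, interval_survival)
  est <- sapply(preds, function(p) p$estimate)
  va <- sapply(preds, function(p) p$se^2)
  avg <- akaike_average(est, va, w)
  out <- preds[[1]][c("year", "age", "interval")]
  out$estimate <- avg$estimate
  out$se <- sqrt(avg$variance)
  class(out) <- c("interval_survival", "data.frame")
  attr(out, "dialect") <- attr(preds[[1]], "dialect")
  out
}

#' Akaike-weighted model averaging with unconditional variance
#'
#' `theta_bar = sum_i w_i theta_i`;
#' `var = sum_i w_i (var_i + (theta_i - theta_bar)^2)`.
#'
#' @param estimates Matrix (quantities x models) or vector of per-model
#'   estimates.
#' @param variances Conditional variances, same shape.
#' @param weights Akaike weights (summing to 1).
#' @return List with `estimate` and (unconditional) `variance`.
#' @export
akaike_average <- function(estimates, variances, weights) {
  estimates <- rbind(estimates)
  variances <- rbind(variances)
  dimnames(estimates) <- dimnames(variances) <- NULL
  stopifnot(ncol(estimates) == length(weights))
  pbar <- drop(estimates %*% weights)
  vunc <- drop((variances + (estimates - pbar)^2) %*% weights)
  list(estimate = pbar, variance = vunc)
}

KF_WINDOWS <- list(
  nest27 = list(dialect = "nest", intervals = list(nest27 = 1:27)),
  season4 = list(dialect = "female",
                 intervals = list(breeding = 2:5, fall = 6:9,
                                  winter = c(10:12, 1))),
  annual12 = list(dialect = "female", intervals = list(annual12 = 1:12))
)

#' Survival over a derived window (27-day nest, 4-month season, 12-month year)
#'
#' Products of per-interval survival over the declared window. For a single
#' `kf_fit` the SE propagates the full coefficient covariance through the
#' product analytically; for model-averaged `interval_survival` input the
#' per-interval unconditional variances are combined by the delta method
#' treating intervals as independent.
#'
#' @param x A `kf_fit` or `interval_survival` object.
#' @param window `"nest27"`, `"season4"` or `"annual12"`.
#' @return Data frame: `year`, `age`, `window`, `estimate`, `se`.
#' @export
derive_window_products <- function(x,
                                   window = c("nest27", "season4",
                                              "annual12")) {
  window <- match.arg(window)
  spec <- KF_WINDOWS[[window]]
  dialect <- if (inherits(x, "kf_fit")) x$dialect else attr(x, "dialect")
  if (!identical(dialect, spec$dialect))
    stop("window ", window, " needs ", spec$dialect, " intervals")
  out <- list()
  if (inherits(x, "kf_fit")) {
    g <- kf_grid(x)
    X <- kf_model_matrix(x, g)
    p <- stats::plogis(drop(X %*% x$coefficients))
    for (wn in names(spec$intervals)) {
      ivs <- spec$intervals[[wn]]
      for (yr in levels(g$year)) for (ag in unique(as.character(g$age))) {
        sel <- g$year == yr & as.character(g$age) == ag & g$interval %in% ivs
        if (sum(sel) != length(ivs)) stop("incomplete window ", wn)
        P <- prod(p[sel])
        grad <- drop(P * colSums((1 - p[sel]) * X[sel, , drop = FALSE]))
        v <- drop(grad %*% x$vcov %*% grad)
        out[[length(out) + 1]] <- data.frame(
          year = yr, age = ag, window = wn, estimate = P,
          se = sqrt(max(v, 0)), stringsAsFactors = FALSE)
      }
    }
  } else if (inherits(x, "interval_survival")) {
    for (wn in names(spec$intervals)) {
      ivs <- spec$intervals[[wn]]
      for (yr in unique(as.character(x$year)))
        for (ag in unique(as.character(x$age))) {
          sel <- as.character(x$year) == yr & as.character(x$age) == ag &
            x$interval %in% ivs
          if (sum(sel) != length(ivs)) stop("incomplete window ", wn)
          dm <- if (any(x$estimate[sel] == 0))
            list(mean = 0, se = 0)  # absorbing interval
          else delta_method_product(x$estimate[sel], x$se[sel])
          out[[length(out) + 1]] <- data.frame(
            year = yr, age = ag, window = wn, estimate = dm$mean,
            se = dm$se, stringsAsFactors = FALSE)
        }
    }
  } else stop("expected a kf_fit or interval_survival object")
  do.call(rbind, out)
}
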