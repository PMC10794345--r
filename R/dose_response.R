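## Gated concentration-response engine.
##
## Quantal-source endpoints are dichotomized against pooled controls
## (deviation beyond k*SD of the control mean); continuous endpoints
## (ISV count, heart rate) are normalized within-replicate to the control
## mean.  Effect concentrations are modeled only when three gates pass:
## (1) a Tukey-type trend test over three dose metameters with
##     multiplicity-adjusted p <= alpha,
## (2) the AIC of the log-logistic fit is below the AIC of a flat
##     (slope-zero) model in the same likelihood family,
## (3) at least a 30% effect is reached in some tested concentration.
## Otherwise the endpoint is reported as "no effect".

#' Concentration-response configuration
#'
#' @param deviation_k SD multiplier for dichotomization (default 1.5).
#' @param min_effect minimum effect magnitude required in at least one
#'   concentration (default 0.30, inclusive).
#' @param trend_alpha significance level of the trend gate.
#' @param ecx_levels effect levels (percent) to report.
#' @param ci_level confidence level of the ECx intervals.
#' @return an object of class `cr_config`.
#' @export
cr_config <- function(deviation_k = 1.5, min_effect = 0.30,
                      trend_alpha = 0.05, ecx_levels = c(10, 50),
                      ci_level = 0.95) {
  if (deviation_k <= 0) stopf("`deviation_k` must be > 0")
  if (min_effect <= 0 || min_effect >= 1) stopf("`min_effect` must be in (0,1)")
  if (trend_alpha <= 0 || trend_alpha >= 1) stopf("`trend_alpha` in (0,1)")
  structure(as.list(environment()), class = "cr_config")
}

as_observations <- function(obs) {
  need <- c("concentration_uM", "replicate", "value")
  if (!all(need %in% names(obs)))
    stopf("observations need columns: %s", paste(need, collapse = ", "))
  if (is.null(obs$alive)) obs$alive <- TRUE
  if (is.null(obs$is_control)) obs$is_control <- obs$concentration_uM == 0
  if (any(obs$concentration_uM < 0)) stopf("concentrations must be >= 0")
  obs
}

filter_endpoint <- function(obs, endpoint) {
  if (!is.null(endpoint) && !is.null(obs$endpoint))
    obs <- obs[obs$endpoint == endpoint, , drop = FALSE]
  obs
}

#' Pool control embryos across experiments
#'
#' Mean and sample SD of all (living) control embryos across replicates
#' for one endpoint; the control reference for dichotomization.
#'
#' @param obs per-embryo observations (see [simulate_cr_dataset()] for the
#'   column contract).
#' @param endpoint endpoint name to select, or NULL for all rows.
#' @return a `control_stats` object (mean, sd, n, cv).
#' @export
pool_controls <- function(obs, endpoint = NULL) {
  obs <- filter_endpoint(as_observations(obs), endpoint)
  x <- obs$value[obs$is_control & obs$alive]
  if (length(x) < 2) stopf("need at least 2 control embryos")
  m <- mean(x); s <- sd(x)
  structure(list(mean = m, sd = s, n = length(x),
                 cv = if (m > 0) s / m else NA_real_),
            class = "control_stats")
}

#' Dichotomize a continuous endpoint against pooled controls
#'
#' An embryo is affected when its value lies outside `k` standard
#' deviations of the pooled control mean, i.e. |value - mean| > k*sd.
#' Dead embryos are excluded from sublethal denominators.  A zero control
#' SD is floored at 1e-12 with a warning (every deviating embryo is then
#' affected).
#'
#' @param obs per-embryo observations.
#' @param control_stats a [pool_controls()] result.
#' @param k SD multiplier (default 1.5).
#' @param endpoint optional endpoint filter.
#' @return an `affected_table`: per concentration x replicate counts of
#'   affected embryos; per-embryo status in attribute `per_embryo`.
#' @export
dichotomize <- function(obs, control_stats, k = 1.5, endpoint = NULL) {
  obs <- filter_endpoint(as_observations(obs), endpoint)
  obs <- obs[obs$alive, , drop = FALSE]
  s <- control_stats$sd
  if (s <= 0) {
    warning("control SD is 0; floored at 1e-12, any deviation is affected")
    s <- 1e-12
  }
  affected <- abs(obs$value - control_stats$mean) > k * s
  per_embryo <- cbind(obs, affected = affected)
  tab <- aggregate_affected(obs$concentration_uM, obs$replicate, affected)
  structure(tab, class = c("affected_table", "data.frame"),
            per_embryo = per_embryo)
}

aggregate_affected <- function(conc, replicate, affected) {
  key <- interaction(conc, replicate, drop = TRUE)
  idx <- split(seq_along(conc), key)
  rows <- lapply(idx, function(i) data.frame(
    concentration_uM = conc[i][1], replicate = replicate[i][1],
    n_affected = sum(affected[i]), n_total = length(i)))
  tab <- do.call(rbind, rows)
  tab$fraction <- tab$n_affected / tab$n_total
  tab <- tab[order(tab$replicate, tab$concentration_uM), ]
  rownames(tab) <- NULL
  tab
}

#' Build an affected table from already-binary observations
#'
#' For endpoints recorded directly as 0/1 (e.g. mortality), skips the
#' dichotomization step.
#' @inheritParams dichotomize
#' @return an `affected_table`.
#' @export
quantal_table <- function(obs, endpoint = NULL) {
  obs <- filter_endpoint(as_observations(obs), endpoint)
  obs <- obs[obs$alive | obs$endpoint %in% "mortality", , drop = FALSE]
  if (!all(obs$value %in% c(0, 1)))
    stopf("`quantal_table()` expects 0/1 values; use dichotomize()")
  tab <- aggregate_affected(obs$concentration_uM, obs$replicate,
                            obs$value == 1)
  structure(tab, class = c("affected_table", "data.frame"),
            per_embryo = cbind(obs, affected = obs$value == 1))
}

#' Normalize a continuous endpoint to same-replicate controls
#'
#' For each replicate, per-concentration treatment means are divided by
#' that replicate's control mean, giving dimensionless fractions with 1.0
#' at control level.
#'
#' @param obs per-embryo observations.
#' @param endpoint optional endpoint filter.
#' @return a `normalized_table` data.frame with columns concentration_uM,
#'   replicate, normalized, n.
#' @export
normalize_continuous <- function(obs, endpoint = NULL) {
  obs <- filter_endpoint(as_observations(obs), endpoint)
  obs <- obs[obs$alive, , drop = FALSE]
  out <- lapply(split(obs, obs$replicate), function(d) {
    cm <- mean(d$value[d$is_control])
    if (!is.finite(cm) || cm == 0)
      stopf("control mean is zero or missing in replicate %s",
            d$replicate[1])
    agg <- lapply(split(d, d$concentration_uM), function(g) data.frame(
      concentration_uM = g$concentration_uM[1], replicate = g$replicate[1],
      normalized = mean(g$value) / cm, n = nrow(g)))
    do.call(rbind, agg)
  })
  tab <- do.call(rbind, out)
  tab <- tab[order(tab$replicate, tab$concentration_uM), ]
  rownames(tab) <- NULL
  structure(tab, class = c("normalized_table", "data.frame"))
}

#' Tukey-type trend test over dose metameters
#'
#' Fits the trend model under three dose metameters — arithmetic dose,
#' ordinal rank and log-dose (the control concentration replaced by one
#' tenth of the lowest tested concentration) — and returns the
#' multiplicity-adjusted minimum p-value of the slope tests, using the
#' joint normal approximation of the correlated statistics (single-step
#' adjustment over the stacked marginal models).  If the joint computation
#' fails, a Bonferroni adjustment is used and flagged.
#'
#' @param dose per-observation concentrations (including controls at 0).
#' @param response per-embryo 0/1 outcomes (`kind = "quantal"`) or
#'   per-replicate normalized values (`kind = "continuous"`).
#' @param kind endpoint kind.
#' @return an object of class `tukey_trend` with fields `p_adjusted`,
#'   `p_by_metameter`, `statistics` and `method`.
#' @export
tukey_trend_test <- function(dose, response,
                             kind = c("quantal", "continuous")) {
  kind <- match.arg(kind)
  if (length(dose) != length(response)) stopf("dose/response lengths differ")
  if (length(unique(dose)) < 3)
    stopf("need at least 3 dose levels including control")
  if (var(response) == 0) {
    return(structure(list(p_adjusted = 1,
                          p_by_metameter = c(arith = 1, ordinal = 1, log = 1),
                          statistics = c(arith = 0, ordinal = 0, log = 0),
                          method = "degenerate"),
                     class = "tukey_trend"))
  }
  lowest <- min(dose[dose > 0])
  mets <- list(
    arith = dose,
    ordinal = as.numeric(factor(dose, levels = sort(unique(dose)))) - 1,
    log = log(ifelse(dose == 0, lowest / 10, dose))
  )
  fits <- lapply(mets, function(m) {
    d <- data.frame(y = response, dose = m)
    if (kind == "quantal") glm(y ~ dose, family = binomial(), data = d)
    else lm(y ~ dose, data = d)
  })
  stats <- vapply(fits, function(f) summary(f)$coefficients["dose", 3],
                  numeric(1))
  joint <- tryCatch({
    g <- multcomp::glht(do.call(multcomp::mmm, fits),
                        multcomp::mlf("dose = 0"))
    ss <- summary(g, test = multcomp::adjusted("single-step"))
    p <- as.numeric(ss$test$pvalues)
    names(p) <- names(mets)
    list(p = p, method = "single-step")
  }, error = function(e) NULL)
  if (is.null(joint)) {
    praw <- vapply(fits, function(f) summary(f)$coefficients["dose", 4],
                   numeric(1))
    joint <- list(p = pmin(1, 3 * praw), method = "bonferroni")
  }
  structure(list(p_adjusted = min(joint$p), p_by_metameter = joint$p,
                 statistics = stats, method = joint$method),
            class = "tukey_trend")
}

#' @export
print.tukey_trend <- function(x, ...) {
  cat(sprintf("<tukey_trend> adjusted p = %.4g (%s)\n",
              x$p_adjusted, x$method))
  print(round(x$p_by_metameter, 4))
  invisible(x)
}

## log-logistic response functions ------------------------------------

## quantal (increasing affected fraction), b < 0:
##   f(x) = 1 / (1 + exp(b * (log x - log e)))
ll2_prob <- function(conc, b, loge) {
  p <- ifelse(conc > 0, plogis(-b * (log(conc) - loge)),
              as.numeric(b > 0))
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

## continuous normalized (upper asymptote fixed at 1, lower c >= 0), b > 0:
##   f(x) = c + (1 - c) / (1 + exp(b * (log x - log e)))
ll3_mean <- function(conc, b, loge, c0) {
  ifelse(conc > 0, c0 + (1 - c0) * plogis(-b * (log(conc) - loge)),
         if (b > 0) 1 else c0)
}

#' Fit a log-logistic concentration-response model
#'
#' Quantal tables are fitted with the two-parameter log-logistic by
#' binomial maximum likelihood; continuous (normalized) tables with a
#' three-parameter log-logistic (upper asymptote fixed at 1, lower
#' asymptote bounded below by 0) by least squares on per-concentration
#' replicate means.  Use `model = "flat"` for the slope-zero reference
#' model in the same likelihood family.
#'
#' @param table an `affected_table` (quantal) or `normalized_table`
#'   (continuous).
#' @param kind endpoint kind; inferred from the table class by default.
#' @param model `"log-logistic"` or `"flat"`.
#' @param weighted for continuous tables: weight the per-concentration
#'   replicate means by the number of embryos behind them (per-embryo
#'   weighting) instead of treating all means equally.
#' @return an object of class `crfit` with coefficients, covariance,
#'   log-likelihood and AIC.
#' @export
fit_log_logistic <- function(table, kind = NULL,
                             model = c("log-logistic", "flat"),
                             weighted = FALSE) {
  model <- match.arg(model)
  kind <- kind %||% if (inherits(table, "affected_table")) "quantal"
                    else "continuous"
  if (kind == "quantal") fit_ll_quantal(table, model)
  else fit_ll_continuous(table, model, weighted)
}

new_crfit <- function(model, kind, coefficients, vcov, loglik, npar, n,
                      converged, data) {
  structure(list(model = model, kind = kind, coefficients = coefficients,
                 vcov = vcov, loglik = loglik, npar = npar, n = n,
                 AIC = 2 * npar - 2 * loglik, converged = converged,
                 data = data),
            class = "crfit")
}

fit_ll_quantal <- function(table, model) {
  ## pool replicates per concentration
  agg <- lapply(split(table, table$concentration_uM), function(g) data.frame(
    concentration_uM = g$concentration_uM[1],
    n_affected = sum(g$n_affected), n_total = sum(g$n_total)))
  agg <- do.call(rbind, agg)
  agg <- agg[order(agg$concentration_uM), ]
  a <- agg$n_affected; n <- agg$n_total; conc <- agg$concentration_uM
  if (model == "flat") {
    p <- sum(a) / sum(n)
    ll <- sum(dbinom(a, n, pmin(pmax(p, 1e-12), 1 - 1e-12), log = TRUE))
    return(new_crfit("flat", "quantal", c(p = p), matrix(NA, 1, 1),
                     ll, 1L, sum(n), TRUE, agg))
  }
  if (sum(conc > 0) < 3) stopf("need at least 3 nonzero concentrations")
  negll <- function(par) {
    -sum(dbinom(a, n, ll2_prob(conc, par[1], par[2]), log = TRUE))
  }
  ## start from an adjusted-logit regression on the nonzero concentrations
  nz <- conc > 0
  padj <- (a[nz] + 0.5) / (n[nz] + 1)
  co <- tryCatch(coef(lm(qlogis(padj) ~ log(conc[nz]))),
                 error = function(e) c(0, 1))
  b0 <- -co[2]; if (!is.finite(b0) || abs(b0) < 0.1) b0 <- -1
  loge0 <- if (abs(co[2]) > 1e-8) co[1] / b0 else log(exp(mean(log(conc[nz]))))
  if (!is.finite(loge0)) loge0 <- mean(log(conc[nz]))
  opt <- tryCatch(
    optim(c(b = unname(b0), log_e = unname(loge0)), negll,
          method = "BFGS", hessian = TRUE, control = list(maxit = 500)),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value)) {
    return(new_crfit("log-logistic", "quantal",
                     c(b = NA_real_, log_e = NA_real_), matrix(NA, 2, 2),
                     -Inf, 2L, sum(n), FALSE, agg))
  }
  V <- tryCatch(solve(opt$hessian), error = function(e) matrix(NA, 2, 2))
  new_crfit("log-logistic", "quantal", opt$par, V, -opt$value, 2L,
            sum(n), opt$convergence == 0, agg)
}

fit_ll_continuous <- function(table, model, weighted = FALSE) {
  y <- table$normalized; conc <- table$concentration_uM
  n <- length(y)
  w <- if (weighted && !is.null(table$n)) table$n / mean(table$n)
       else rep(1, n)
  gauss_ll <- function(rss) -n / 2 * (log(2 * pi * rss / n) + 1)
  if (model == "flat") {
    m <- sum(w * y) / sum(w); rss <- sum(w * (y - m)^2)
    return(new_crfit("flat", "continuous", c(mu = m), matrix(NA, 1, 1),
                     gauss_ll(max(rss, 1e-300)), 2L, n, TRUE, table))
  }
  if (sum(unique(conc) > 0) < 3) stopf("need at least 3 nonzero concentrations")
  rssfun <- function(par) {
    mu <- ll3_mean(conc, par[1], par[2], par[3])
    sum(w * (y - mu)^2)
  }
  dir_down <- mean(y[conc == max(conc)]) <= mean(y[conc == 0])
  start <- c(b = if (dir_down) 1 else -1,
             log_e = mean(log(conc[conc > 0])),
             c0 = if (dir_down) max(0, min(y)) else max(y))
  opt <- tryCatch(
    optim(start, rssfun, method = "L-BFGS-B",
          lower = c(-50, -30, 0), upper = c(50, 30, 10),
          control = list(maxit = 1000)),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value)) {
    return(new_crfit("log-logistic", "continuous",
                     c(b = NA_real_, log_e = NA_real_, c0 = NA_real_),
                     matrix(NA, 3, 3), -Inf, 4L, n, FALSE, table))
  }
  rss <- max(opt$value, 1e-300)
  ## observed information from the profile likelihood n/2*log(RSS)
  prof <- function(par) n / 2 * log(max(rssfun(par), 1e-300))
  H <- tryCatch(optimHess(opt$par, prof), error = function(e) NULL)
  V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) matrix(NA, 3, 3))
       else matrix(NA, 3, 3)
  ## npar = b, log_e, c0 plus the residual variance
  new_crfit("log-logistic", "continuous", opt$par, V, gauss_ll(rss), 4L,
            n, opt$convergence == 0, table)
}

#' @export
print.crfit <- function(x, ...) {
  cat(sprintf("<crfit> %s %s model, n = %d, logLik = %.3f, AIC = %.3f%s\n",
              x$kind, x$model, x$n, x$loglik, x$AIC,
              if (x$converged) "" else " (NOT converged)"))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.crfit <- function(object, ...) object$coefficients

#' @export
vcov.crfit <- function(object, ...) object$vcov

#' @export
logLik.crfit <- function(object, ...) {
  structure(object$loglik, df = object$npar, nobs = object$n,
            class = "logLik")
}

#' @export
predict.crfit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$concentration_uM
          else if (is.data.frame(newdata)) newdata$concentration_uM
          else as.numeric(newdata)
  cf <- object$coefficients
  if (object$model == "flat")
    return(rep(unname(cf[1]), length(conc)))
  if (object$kind == "quantal") ll2_prob(conc, cf["b"], cf["log_e"])
  else ll3_mean(conc, cf["b"], cf["log_e"], cf["c0"])
}

#' @export
residuals.crfit <- function(object, ...) {
  obs <- if (object$kind == "quantal") object$data$n_affected / object$data$n_total
         else object$data$normalized
  obs - predict(object)
}

#' @export
plot.crfit <- function(x, ...) {
  d <- x$data
  conc <- d$concentration_uM
  obs <- if (x$kind == "quantal") d$n_affected / d$n_total else d$normalized
  lo <- min(conc[conc > 0])
  px <- exp(seq(log(lo / 10), log(max(conc) * 2), length.out = 200))
  plot(ifelse(conc == 0, lo / 10, conc), obs, log = "x",
       xlab = "concentration (uM)",
       ylab = if (x$kind == "quantal") "affected fraction" else "normalized response",
       ...)
  lines(px, predict(x, px))
  invisible(x)
}

#' AIC model-selection gate
#'
#' TRUE when the log-logistic model has strictly lower AIC than the flat
#' (slope-zero) model fitted in the same likelihood family.
#'
#' @param ll_fit,flat_fit `crfit` objects on the same data.
#' @return logical.
#' @export
aic_gate <- function(ll_fit, flat_fit) {
  isTRUE(ll_fit$converged) && is.finite(ll_fit$AIC) &&
    ll_fit$AIC < flat_fit$AIC
}

#' Effect-magnitude gate
#'
#' Quantal: at least `min_effect` of embryos affected in at least one
#' tested concentration.  Continuous: a normalized reduction or increase
#' of at least `min_effect` at some tested concentration.  Both
#' comparisons are inclusive ("at least 30%").
#'
#' @param table `affected_table` or `normalized_table`.
#' @param kind endpoint kind (inferred from the table class by default).
#' @param min_effect threshold, default 0.30.
#' @return logical.
#' @export
magnitude_gate <- function(table, kind = NULL, min_effect = 0.30) {
  kind <- kind %||% if (inherits(table, "affected_table")) "quantal"
                    else "continuous"
  tab <- table[table$concentration_uM > 0, , drop = FALSE]
  if (nrow(tab) == 0) return(FALSE)
  if (kind == "quantal") {
    agg <- tapply(tab$n_affected, tab$concentration_uM, sum) /
      tapply(tab$n_total, tab$concentration_uM, sum)
    max(agg) >= min_effect
  } else {
    agg <- tapply(tab$normalized, tab$concentration_uM, mean)
    max(abs(agg - 1)) >= min_effect
  }
}

#' Effect concentration with delta-method confidence interval
#'
#' Solves the fitted log-logistic for the concentration eliciting x% of
#' the modeled effect range.  For the quantal two-parameter model
#' ECx = e * ((100-x)/x)^(1/b); for the continuous model (b > 0 for a
#' decreasing response) ECx = e * (x/(100-x))^(1/b); in both cases
#' ECx < EC50 for x < 50 on a monotone curve, and EC50 = e.  The CI is a
#' delta-method interval on log ECx.
#'
#' @param fit a converged `crfit` log-logistic fit.
#' @param x effect level in percent, in (0, 100).
#' @param ci_level confidence level.
#' @param method `"delta"` (default) or `"bootstrap"` (seeded percentile
#'   bootstrap: embryos resampled within concentration for quantal fits,
#'   residuals resampled onto fitted means for continuous fits).
#' @param n_boot bootstrap resamples.
#' @param seed bootstrap seed.
#' @return one-row data.frame: x, ecx, lower, upper, extrapolated.
#' @export
estimate_ecx <- function(fit, x, ci_level = 0.95,
                         method = c("delta", "bootstrap"),
                         n_boot = 1000, seed = 1) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "crfit"), fit$model == "log-logistic")
  if (!fit$converged) stopf("fit did not converge; no ECx defined")
  if (x <= 0 || x >= 100) stopf("`x` must be in (0, 100)")
  ecx_of <- function(b, loge) {
    L <- if (fit$kind == "quantal") log((100 - x) / x) else log(x / (100 - x))
    exp(loge + L / b)
  }
  b <- fit$coefficients[["b"]]; loge <- fit$coefficients[["log_e"]]
  ecx <- ecx_of(b, loge)
  if (method == "delta") {
    L <- if (fit$kind == "quantal") log((100 - x) / x) else log(x / (100 - x))
    V <- fit$vcov[c("b", "log_e"), c("b", "log_e")]
    grad <- c(-L / b^2, 1)
    se <- sqrt(max(0, drop(t(grad) %*% V %*% grad)))
    z <- qnorm(1 - (1 - ci_level) / 2)
    ci <- exp(log(ecx) + c(-1, 1) * z * se)
  } else {
    ci <- with_seed(seed, {
      boots <- vapply(seq_len(n_boot), function(i) {
        tab <- fit$data
        if (fit$kind == "quantal") {
          tab$n_affected <- rbinom(nrow(tab), tab$n_total,
                                   tab$n_affected / tab$n_total)
          tab$fraction <- tab$n_affected / tab$n_total
          class(tab) <- c("affected_table", "data.frame")
        } else {
          res <- tab$normalized - predict(fit)
          tab$normalized <- predict(fit) + sample(res, replace = TRUE)
          class(tab) <- c("normalized_table", "data.frame")
        }
        bf <- tryCatch(fit_log_logistic(tab, fit$kind),
                       error = function(e) NULL)
        if (is.null(bf) || !bf$converged) return(NA_real_)
        ecx_of(bf$coefficients[["b"]], bf$coefficients[["log_e"]])
      }, numeric(1))
      quantile(boots, c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2),
               na.rm = TRUE, names = FALSE)
    })
  }
  conc <- fit$data$concentration_uM
  extrap <- ecx < min(conc[conc > 0]) || ecx > max(conc)
  data.frame(x = x, ecx = ecx, lower = ci[1], upper = ci[2],
             extrapolated = extrap)
}

#' Run the full gated concentration-response analysis for one endpoint
#'
#' Pools controls, dichotomizes (quantal-source metrics) or normalizes
#' (continuous endpoints), evaluates the three modeling gates and, when
#' all pass, fits the log-logistic model and reports the configured ECx
#' levels; otherwise the endpoint is reported as "no effect".
#'
#' @param obs per-embryo observations (see [simulate_cr_dataset()]).
#' @param endpoint endpoint name to analyse (NULL for all rows).
#' @param config a [cr_config()].
#' @param kind `"quantal"` or `"continuous"`; defaults to the
#'   `endpoint_kind` attribute of `obs`.
#' @return an object of class `cr_result`.
#' @export
run_endpoint <- function(obs, endpoint = NULL, config = cr_config(),
                         kind = NULL) {
  obs <- filter_endpoint(as_observations(obs), endpoint)
  if (nrow(obs) == 0) stopf("no observations for endpoint")
  kind <- kind %||% attr(obs, "endpoint_kind") %||% "continuous"

  if (kind == "quantal") {
    if (all(obs$value %in% c(0, 1))) {
      table <- quantal_table(obs)
    } else {
      cs <- pool_controls(obs)
      table <- dichotomize(obs, cs, k = config$deviation_k)
    }
    pe <- attr(table, "per_embryo")
    trend <- tukey_trend_test(pe$concentration_uM, as.numeric(pe$affected),
                              kind = "quantal")
  } else {
    table <- normalize_continuous(obs)
    trend <- tukey_trend_test(table$concentration_uM, table$normalized,
                              kind = "continuous")
  }

  gate_trend <- trend$p_adjusted <= config$trend_alpha
  gate_magnitude <- magnitude_gate(table, kind, config$min_effect)
  fit <- tryCatch(fit_log_logistic(table, kind), error = function(e) NULL)
  flat <- fit_log_logistic(table, kind, model = "flat")
  gate_aic <- !is.null(fit) && aic_gate(fit, flat)

  status <- if (gate_trend && gate_aic && gate_magnitude) "modeled"
            else "no-effect"
  ecx <- NULL
  if (status == "modeled") {
    ecx <- do.call(rbind, lapply(config$ecx_levels, function(lv)
      estimate_ecx(fit, lv, config$ci_level)))
  }
  structure(list(
    status = status,
    gates = list(trend = gate_trend, aic = gate_aic,
                 magnitude = gate_magnitude),
    trend = trend, fit = fit, flat_fit = flat, ecx = ecx,
    table = table, kind = kind, endpoint = endpoint, config = config
  ), class = "cr_result")
}

#' @export
print.cr_result <- function(x, ...) {
  cat(sprintf("<cr_result> %s endpoint%s: %s\n", x$kind,
              if (!is.null(x$endpoint)) paste0(" '", x$endpoint, "'") else "",
              x$status))
  cat(sprintf("  gates: trend %s (p = %.4g), AIC %s, magnitude %s\n",
              x$gates$trend, x$trend$p_adjusted, x$gates$aic,
              x$gates$magnitude))
  if (!is.null(x$ecx)) {
    for (i in seq_len(nrow(x$ecx)))
      cat(sprintf("  EC%g = %.4g uM [%.4g, %.4g]%s\n", x$ecx$x[i],
                  x$ecx$ecx[i], x$ecx$lower[i], x$ecx$upper[i],
                  if (x$ecx$extrapolated[i]) " (extrapolated)" else ""))
  } else cat("  no effect concentrations emitted\n")
  invisible(x)
}

#' @export
summary.cr_result <- function(object, ...) {
  cat("Gated concentration-response analysis\n")
  print(object)
  if (!is.null(object$fit)) print(object$fit)
  invisible(object)
}
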