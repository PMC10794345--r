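test_that("control pooling gives mean and sample SD across replicates", {
  obs <- data.frame(concentration_uM = c(0, 0, 0, 1),
                    replicate = c(1, 1, 2, 1),
                    value = c(9, 10, 11, 5))
  cs <- pool_controls(obs)
  expect_equal(cs$mean, 10)
  expect_equal(cs$sd, 1)
  expect_identical(cs$n, 3L)
  expect_error(pool_controls(data.frame(concentration_uM = 0, replicate = 1,
                                        value = 10)), "2 control")
})

test_that("dichotomization flags deviations beyond k standard deviations", {
  cs <- structure(list(mean = 10, sd = 1, n = 10), class = "control_stats")
  obs <- data.frame(concentration_uM = rep(1, 5), replicate = 1,
                    value = c(10, 11.4, 8.6, 12, 7))
  tab <- dichotomize(obs, cs, k = 1.5)
  pe <- attr(tab, "per_embryo")
  expect_identical(pe$affected, c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(tab$fraction, 0.4)

  # boundary: exactly mean + 2 sd is affected at k = 1.5, the mean is not
  b <- dichotomize(data.frame(concentration_uM = 1, replicate = 1,
                              value = c(10, 12)), cs, k = 1.5)
  expect_identical(attr(b, "per_embryo")$affected, c(FALSE, TRUE))

  # symmetry: affected status depends only on |value - mean|
  up <- dichotomize(data.frame(concentration_uM = 1, replicate = 1,
                               value = 10 + c(1, 2, 3)), cs)
  dn <- dichotomize(data.frame(concentration_uM = 1, replicate = 1,
                               value = 10 - c(1, 2, 3)), cs)
  expect_identical(attr(up, "per_embryo")$affected,
                   attr(dn, "per_embryo")$affected)
})

test_that("zero control SD is floored with a warning", {
  cs <- structure(list(mean = 10, sd = 0, n = 5), class = "control_stats")
  obs <- data.frame(concentration_uM = 1, replicate = 1, value = c(10, 10.01))
  expect_warning(tab <- dichotomize(obs, cs), "floored")
  expect_identical(attr(tab, "per_embryo")$affected, c(FALSE, TRUE))
})

test_that("normalization divides by the same-replicate control mean", {
  obs <- data.frame(
    concentration_uM = c(0, 0, 1, 1, 0, 0, 1, 1),
    replicate = c(1, 1, 1, 1, 2, 2, 2, 2),
    value = c(20, 20, 10, 10, 10, 10, 8, 6))
  tab <- normalize_continuous(obs)
  r1 <- tab$normalized[tab$replicate == 1 & tab$concentration_uM == 1]
  r2 <- tab$normalized[tab$replicate == 2 & tab$concentration_uM == 1]
  expect_equal(r1, 0.5)       # 10 / 20
  expect_equal(r2, 0.7)       # 7 / 10
  expect_true(all(tab$normalized[tab$concentration_uM == 0] == 1))

  zero <- data.frame(concentration_uM = c(0, 1), replicate = 1,
                     value = c(0, 5))
  expect_error(normalize_continuous(zero), "control mean")
})

test_that("trend test returns p = 1 for constant responses", {
  tt <- tukey_trend_test(rep(c(0, 1, 2, 4), each = 8), rep(0.5, 32),
                         kind = "continuous")
  expect_equal(tt$p_adjusted, 1)
  expect_error(tukey_trend_test(rep(c(0, 1), each = 8), rnorm(16), "continuous"),
               "3 dose levels")
})

test_that("trend test detects a strong monotone response", {
  obs <- fraction_obs(c(0, 0.1, 0.5, 0.9, 1), conc = c(0, 1, 2, 4, 8))
  set.seed(1)  # single-step adjustment integrates over a quasi-random grid
  tt <- tukey_trend_test(obs$concentration_uM, obs$value, kind = "quantal")
  expect_lt(tt$p_adjusted, 0.05)
  expect_identical(tt$method, "single-step")

  # permutation oracle on the arithmetic-dose correlation statistic
  set.seed(99)
  obs_stat <- abs(cor(obs$concentration_uM, obs$value))
  perm <- replicate(1e4, abs(cor(obs$concentration_uM, sample(obs$value))))
  p_perm <- mean(perm >= obs_stat)
  expect_lt(p_perm, 0.05)
})

test_that("log-logistic fits recover noiseless parameters", {
  concs <- c(0.31, 0.63, 1.25, 2.5, 5, 10)
  # continuous: data exactly on the curve (e = 2, hill = 3, floor 0)
  tab <- expand.grid(concentration_uM = c(0, concs), replicate = 1:2)
  tab$normalized <- ifelse(tab$concentration_uM == 0, 1,
                           1 / (1 + (tab$concentration_uM / 2)^3))
  tab$n <- 16
  class(tab) <- c("normalized_table", "data.frame")
  fit <- fit_log_logistic(tab, "continuous")
  expect_equal(exp(coef(fit)[["log_e"]]), 2, tolerance = 1e-6)
  expect_equal(coef(fit)[["b"]], 3, tolerance = 1e-5)

  # quantal: expected counts at huge n (e = 2, b = -3)
  p <- 1 / (1 + (concs / 2)^(-3))
  at <- data.frame(concentration_uM = c(0, concs), replicate = 1,
                   n_affected = c(0, round(1e7 * p)), n_total = 1e7)
  at$fraction <- at$n_affected / at$n_total
  class(at) <- c("affected_table", "data.frame")
  fq <- fit_log_logistic(at, "quantal")
  expect_equal(exp(coef(fq)[["log_e"]]), 2, tolerance = 1e-3)
  expect_equal(coef(fq)[["b"]], -3, tolerance = 1e-3)
  expect_error(estimate_ecx(fit_log_logistic(at, "quantal", model = "flat"),
                            10))
})

test_that("ECx follows the closed form and EC10 < EC50 on monotone curves", {
  mkfit <- function(kind, b) {
    V <- diag(1e-20, 2, 2)
    dimnames(V) <- list(c("b", "log_e"), c("b", "log_e"))
    structure(list(
      model = "log-logistic", kind = kind,
      coefficients = c(b = b, log_e = log(2)),
      vcov = V, converged = TRUE,
      data = data.frame(concentration_uM = c(0, 0.1, 1, 10))),
      class = "crfit")
  }

  q <- mkfit("quantal", -1)
  expect_equal(estimate_ecx(q, 50)$ecx, 2)
  expect_equal(estimate_ecx(q, 10)$ecx, 2 * 10 / 90, tolerance = 1e-12)
  cont <- mkfit("continuous", 1)
  expect_equal(estimate_ecx(cont, 10)$ecx, 2 * 10 / 90, tolerance = 1e-12)
  # monotone curve: EC10 below EC50 on the concentration axis
  expect_lt(estimate_ecx(q, 10)$ecx, estimate_ecx(q, 50)$ecx)
  # noiseless limit: delta-method interval collapses onto the estimate
  e10 <- estimate_ecx(q, 10)
  expect_lt(e10$upper - e10$lower, 1e-6)
  expect_error(estimate_ecx(q, 0), "0, 100")
})

test_that("AIC gate prefers the flat model on constant data", {
  at <- data.frame(concentration_uM = c(0, 1, 2, 4, 8), replicate = 1,
                   n_affected = rep(8L, 5), n_total = rep(16L, 5),
                   fraction = 0.5)
  class(at) <- c("affected_table", "data.frame")
  ll <- fit_log_logistic(at, "quantal")
  flat <- fit_log_logistic(at, "quantal", model = "flat")
  expect_false(aic_gate(ll, flat))
  # and matches the sign of the hand-computed AIC difference
  expect_identical(aic_gate(ll, flat), ll$AIC < flat$AIC)
})

test_that("magnitude gate applies the inclusive 30% rule", {
  mk <- function(fracs) {
    n <- 100L
    at <- data.frame(concentration_uM = seq_along(fracs), replicate = 1,
                     n_affected = as.integer(round(fracs * n)), n_total = n)
    at$fraction <- at$n_affected / at$n_total
    class(at) <- c("affected_table", "data.frame")
    at
  }
  expect_false(magnitude_gate(mk(c(0.1, 0.29))))
  expect_true(magnitude_gate(mk(c(0.1, 0.30))))

  mkc <- function(vals) {
    tab <- data.frame(concentration_uM = seq_along(vals), replicate = 1,
                      normalized = vals, n = 16)
    class(tab) <- c("normalized_table", "data.frame")
    tab
  }
  expect_false(magnitude_gate(mkc(c(0.8, 0.95, 1.1))))
  expect_true(magnitude_gate(mkc(c(0.9, 0.65, 0.8))))   # 35% reduction
  expect_true(magnitude_gate(mkc(c(1.1, 1.35))))        # 35% increase
})

test_that("run_endpoint models strong signals and rejects flat ones", {
  concs <- c(0.31, 0.63, 1.25, 2.5, 5, 10)
  strong <- simulate_cr_dataset(2, 3, concs, kind = "quantal", seed = 42)
  r <- run_endpoint(strong)
  expect_identical(r$status, "modeled")
  expect_true(all(unlist(r$gates)))
  ec50 <- r$ecx$ecx[r$ecx$x == 50]
  expect_equal(ec50, 2, tolerance = 0.4)
  expect_lt(r$ecx$ecx[r$ecx$x == 10], ec50)

  flat <- simulate_cr_dataset(1e6, 3, concs, kind = "quantal", seed = 43)
  rf <- run_endpoint(flat)
  expect_identical(rf$status, "no-effect")
  expect_null(rf$ecx)
})

test_that("a significant trend with a sub-30% effect is gated out", {
  obs <- fraction_obs(c(0, 0.05, 0.08, 0.12, 0.2),
                      conc = c(0, 1, 2, 4, 8), n = 100)
  r <- run_endpoint(obs)
  expect_true(r$gates$trend)
  expect_false(r$gates$magnitude)
  expect_identical(r$status, "no-effect")
  expect_null(r$ecx)
})

test_that("continuous endpoints run end to end with replicate means", {
  obs <- simulate_cr_dataset(2, 3, c(0.31, 0.63, 1.25, 2.5, 5, 10),
                             kind = "continuous", control_mean = 20,
                             control_sd = 2, seed = 7)
  r <- run_endpoint(obs)
  expect_identical(r$kind, "continuous")
  expect_identical(r$status, "modeled")
  expect_equal(r$ecx$ecx[r$ecx$x == 50], 2, tolerance = 0.5)
})

test_that("bootstrap ECx intervals agree with the delta method", {
  obs <- simulate_cr_dataset(2, 3, c(0.31, 0.63, 1.25, 2.5, 5, 10),
                             kind = "quantal", seed = 8)
  fit <- fit_log_logistic(quantal_table(obs), "quantal")
  delta <- estimate_ecx(fit, 50)
  boot <- estimate_ecx(fit, 50, method = "bootstrap", n_boot = 200, seed = 4)
  expect_equal(boot$ecx, delta$ecx)         # the point estimate is shared
  expect_lt(boot$lower, boot$ecx)
  expect_gt(boot$upper, boot$ecx)
  # comparable interval widths on a well-behaved dataset
  expect_lt(abs(log(boot$upper / boot$lower) /
                  log(delta$upper / delta$lower) - 1), 0.75)
  # seeded: reproducible
  boot2 <- estimate_ecx(fit, 50, method = "bootstrap", n_boot = 200, seed = 4)
  expect_identical(boot, boot2)
})

test_that("per-embryo weighting changes only unbalanced continuous fits", {
  tab <- expand.grid(concentration_uM = c(0, 0.5, 1, 2, 4), replicate = 1:2)
  set.seed(2)
  tab$normalized <- ifelse(tab$concentration_uM == 0, 1,
                           1 / (1 + (tab$concentration_uM / 1.5)^2)) +
    rnorm(nrow(tab), 0, 0.03)
  tab$n <- 16
  class(tab) <- c("normalized_table", "data.frame")
  f1 <- fit_log_logistic(tab, "continuous")
  f2 <- fit_log_logistic(tab, "continuous", weighted = TRUE)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-4)  # balanced: identical
  tab$n[1] <- 160
  f3 <- fit_log_logistic(tab, "continuous", weighted = TRUE)
  expect_false(isTRUE(all.equal(coef(f1), coef(f3), tolerance = 1e-8)))
})

test_that("the analysis is reproducible given the seed", {
  concs <- c(0.31, 0.63, 1.25, 2.5, 5, 10)
  r1 <- run_endpoint(simulate_cr_dataset(2, 3, concs, kind = "quantal",
                                         seed = 11))
  r2 <- run_endpoint(simulate_cr_dataset(2, 3, concs, kind = "quantal",
                                         seed = 11))
  expect_identical(r1$ecx, r2$ecx)
  expect_identical(r1$trend$statistics, r2$trend$statistics)
})
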