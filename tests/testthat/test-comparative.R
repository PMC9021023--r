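# Comparative regressions: lifespan quantiles, the heteroscedastic LME and
# its OLS limit, FVE, nested LRTs, allometric/partial regressions,
# bootstrap and PGLS.

test_that("lifespan quantile estimation follows the interpolated empirical
           quantile", {
  expect_equal(estimate_lifespan(rep(10, 50), n_boot = 0)$q80, 10)
  est <- estimate_lifespan(1:100, n_boot = 200, seed = 2)
  expect_equal(est$q80, 80.2)
  expect_lte(est$ci_low, est$q80)
  expect_gte(est$ci_high, est$q80)
  # monotone in q, invariant to record order
  expect_lte(estimate_lifespan(1:100, q = 0.5, n_boot = 0)$q80,
             estimate_lifespan(1:100, q = 0.9, n_boot = 0)$q80)
  expect_equal(estimate_lifespan(sample(1:100), n_boot = 0)$q80, 80.2)
  # juveniles are excluded before estimation
  expect_equal(estimate_lifespan(c(0.5, 0.5, rep(10, 10)),
                                 maturity_age = 2, n_boot = 0)$q80, 10)
  expect_error(estimate_lifespan(c(0.2, 0.4), maturity_age = 2), "maturity")
  # Gompertz cohort recovers the closed-form quantile within 2%
  m <- simulate_mortality(1e4, shape = 0.12, rate = 0.015,
                          maturity_age = 1, seed = 3)
  p0 <- flexsurv::pgompertz(1, 0.12, 0.015)
  q_true <- flexsurv::qgompertz(p0 + 0.8 * (1 - p0), 0.12, 0.015)
  expect_lt(abs(estimate_lifespan(m$age, n_boot = 0)$q80 - q_true) / q_true,
            0.02)
})

test_that("multi-cohort pooling is the arithmetic mean", {
  expect_equal(round(multi_cohort_lifespan(c(87, 83, 81)), 1), 83.7)
  expect_equal(multi_cohort_lifespan(c(81, 87, 83)),
               multi_cohort_lifespan(c(87, 83, 81)))
  expect_equal(multi_cohort_lifespan(42), 42)
})

test_that("noiseless rates k/L give a degenerate exact fit", {
  co <- simulate_cohort(sim_config(n_species = 6, seed = 9))
  d <- truth_rate_table(co)
  d$rate_per_year <- 3000 * d$inv_lifespan   # exact, no noise
  fit <- fit_lme(d, "inv_lifespan", zero_intercept = TRUE, restarts = 3,
                 seed = 1)
  expect_equal(fit$slope, 3000, tolerance = 1e-6)
  expect_lt(fit$var_species, 1e-6)
  expect_lt(fit$var_individual, 1e-6)
  expect_equal(fve(fit), 1, tolerance = 1e-9)
})

test_that("the LME reduces to OLS when random effects are fixed at zero and
           residual variances tied", {
  co <- simulate_cohort(sim_config(n_species = 8, seed = 15))
  d <- truth_rate_table(co)
  fit <- fit_lme(d, "inv_lifespan", heteroscedastic = FALSE,
                 fix_var_species = 0, fix_var_individual = 0,
                 restarts = 2, seed = 1)
  ols <- lm(rate_per_year ~ inv_lifespan, data = d)
  expect_equal(unname(fit$coefficients), unname(coef(ols)),
               tolerance = 1e-6)
  # ML residual variance (divisor n) against lm's
  expect_equal(unname(fit$var_residual[1]),
               sum(resid(ols)^2) / nrow(d), tolerance = 1e-4)
})

test_that("single-cohort k recovery and Wald CI behave sensibly", {
  co <- simulate_cohort(sim_config(seed = 23))
  d <- truth_rate_table(co)
  fit <- fit_lme(d, "inv_lifespan", zero_intercept = TRUE, restarts = 3,
                 seed = 2)
  expect_lt(abs(fit$slope - 3000) / 3000, 0.1)
  expect_lt(fit$slope_ci[1], fit$slope)
  expect_gt(fit$slope_ci[2], fit$slope)
  # free intercept never fits worse than zero intercept
  free <- fit_lme(d, "inv_lifespan", zero_intercept = FALSE, restarts = 3,
                  seed = 2)
  expect_gte(free$loglik, fit$loglik - 1e-6)
  lrt <- lrt_models(fit, free)
  expect_equal(lrt$df, 1)
  expect_true(lrt$p >= 0 && lrt$p <= 1)
  # identical models give p = 1
  same <- lrt_models(fit, fit)
  expect_equal(same$p, 1)
})

test_that("FVE matches its definition on a hand-computed example", {
  d <- data.frame(
    rate_per_year = c(10, 12, 20, 22, 40, 38),
    species = rep(c("s1", "s2", "s3"), each = 2),
    individual = paste0("i", 1:6),
    inv_lifespan = rep(c(0.1, 0.2, 0.4), each = 2))
  fit <- fit_lme(d, "inv_lifespan", restarts = 2, seed = 1)
  obs <- c(11, 21, 39)
  pred <- unname(fit$coefficients[1] + fit$coefficients[2] * c(0.1, 0.2, 0.4))
  ess <- sum((pred - mean(obs))^2); rss <- sum((obs - pred)^2)
  expect_equal(fve(fit), ess / (ess + rss))
  # perfect predictions give 1; constant predictions give 0
  expect_equal(local({
    pr <- obs; ess <- sum((pr - mean(obs))^2); ess / (ess + 0)
  }), 1)
  mean_pred <- rep(mean(obs), 3)
  expect_equal(sum((mean_pred - mean(obs))^2) /
                 (sum((mean_pred - mean(obs))^2) +
                    sum((obs - mean_pred)^2)), 0)
})

test_that("allometric regression and partial residuals follow OLS algebra", {
  x <- c(2, 5, 11, 24, 60)
  a <- suppressWarnings(allometric_fit(x, 1 / x))  # exact fit
  expect_equal(a$slope, -1, tolerance = 1e-9)
  expect_equal(a$fve, 1, tolerance = 1e-9)
  flat <- suppressWarnings(allometric_fit(x, rep(3, 5)))
  expect_equal(flat$slope, 0, tolerance = 1e-9)
  # closed-form check on a 5-point example
  y <- c(3, 7, 12, 20, 55)
  f <- allometric_fit(x, y)
  lx <- log10(x); ly <- log10(y)
  slope_hat <- cov(lx, ly) / var(lx)
  expect_equal(f$slope, slope_hat)
  expect_equal(f$intercept, mean(ly) - slope_hat * mean(lx))
  # residual regressions have zero-mean residuals
  set.seed(4)
  z <- runif(100, 1, 50); yy <- z^1.3 * rlnorm(100, 0, 0.1)
  xx <- z^0.8 * rlnorm(100, 0, 0.1)
  pr <- partial_residual_regression(yy, xx, z)
  expect_lt(abs(mean(pr$residual_y)), 1e-10)
  expect_lt(abs(mean(pr$residual_x)), 1e-10)
  # y driven by z alone (plus independent noise): residual association
  # with x is negligible
  y_z <- z^1.5 * rlnorm(100, 0, 0.05)
  pr2 <- partial_residual_regression(y_z, xx, z)
  expect_lt(pr2$fve, 0.05)
})

test_that("bootstrap FVE is reproducible and brackets the point estimate", {
  co <- simulate_cohort(sim_config(n_species = 8, seed = 31))
  d <- truth_rate_table(co)
  fit <- fit_lme(d, "inv_lifespan", zero_intercept = TRUE, restarts = 2,
                 seed = 1)
  b1 <- bootstrap_fve(fit, "species", B = 30, seed = 5)
  b2 <- bootstrap_fve(fit, "species", B = 30, seed = 5)
  expect_equal(b1$values, b2$values)
  expect_true(all(b1$values >= 0 & b1$values <= 1, na.rm = TRUE))
  expect_lte(b1$ci[1], b1$ci[2])
})

test_that("PGLS on a star tree equals OLS, and unknown species are named", {
  set.seed(12)
  n <- 12
  star <- ape::read.tree(text = paste0(
    "(", paste0("sp", 1:n, ":1", collapse = ","), ");"))
  d <- data.frame(species = paste0("sp", 1:n),
                  inv_lifespan = runif(n, 0.02, 0.3))
  d$rate_per_year <- 3000 * d$inv_lifespan + rnorm(n, 0, 20)
  pg <- pgls_fit(d, star, "inv_lifespan")
  ols <- lm(rate_per_year ~ inv_lifespan, data = d)
  expect_equal(pg$slope, unname(coef(ols)[2]), tolerance = 1e-9)
  expect_equal(pg$intercept, unname(coef(ols)[1]), tolerance = 1e-9)
  d_bad <- d; d_bad$species[1] <- "yeti"
  expect_error(pgls_fit(d_bad, star, "inv_lifespan"), "yeti")
})

test_that("PGLS covers the true slope under strong phylogenetic signal", {
  set.seed(8)
  hits <- 0
  for (rep in 1:100) {
    tree <- ape::rtree(12)
    C <- ape::vcv(tree)
    x <- runif(12, 0.02, 0.3)
    resid_bm <- as.vector(t(chol(C)) %*% rnorm(12, 0, 15))
    d <- data.frame(species = tree$tip.label, inv_lifespan = x,
                    rate_per_year = 3000 * x + resid_bm)
    pg <- pgls_fit(d, tree, "inv_lifespan")
    if (pg$slope_ci[1] <= 3000 && pg$slope_ci[2] >= 3000) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("fold variation summaries", {
  sv <- summarize_variation(c(4, 2, 8))
  expect_equal(sv$fold, 4)
  expect_equal(summarize_variation(rep(7, 5))$fold, 1)
  expect_error(summarize_variation(c(1, 0)), "positive")
})
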