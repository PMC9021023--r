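# Cross-species comparative analysis: lifespan estimation from mortality
# records, the heteroscedastic linear mixed-effects scaling model (random
# slopes at species and individual level, species-specific residual
# variances, fitted by direct maximum likelihood with the fixed effects
# profiled out), fraction of inter-species variance explained, LRT model
# comparison, allometric and partial-correlation regressions, bootstrap,
# and phylogenetic generalized least squares.

#' Estimate species lifespan from mortality records
#'
#' Lifespan is the age by which a given fraction (default 80\%) of adults
#' has died: the linear-interpolation empirical quantile of adult ages at
#' death, with a percentile-bootstrap confidence interval over animals.
#'
#' @param ages Ages at death (years).
#' @param maturity_age Records below this age are excluded before
#'   estimation (infant/juvenile mortality).
#' @param q Quantile defining lifespan (default 0.8).
#' @param n_boot Bootstrap replicates for the CI.
#' @param seed Integer seed.
#' @param conf Confidence level.
#' @return Object of class "lifespan_estimate": q80, ci_low, ci_high,
#'   n_records.
#' @export
estimate_lifespan <- function(ages, maturity_age = 0, q = 0.8,
                              n_boot = 1000L, seed = 1L, conf = 0.95) {
  adults <- ages[ages >= maturity_age]
  if (length(adults) == 0) stop("no records at or above the maturity age")
  est <- stats::quantile(adults, q, type = 7, names = FALSE)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0 && length(adults) > 1) {
    bs <- with_seed(seed, vapply(seq_len(n_boot), function(b)
      stats::quantile(sample(adults, replace = TRUE), q, type = 7,
                      names = FALSE), 0))
    a <- (1 - conf) / 2
    ci <- stats::quantile(bs, c(a, 1 - a), type = 7, names = FALSE)
  }
  structure(list(q80 = est, ci_low = ci[1], ci_high = ci[2],
                 n_records = length(adults), q = q),
            class = "lifespan_estimate")
}

#' @export
print.lifespan_estimate <- function(x, ...) {
  cat(sprintf("%.0f%% lifespan: %.2f years (95%% CI %.2f-%.2f, n = %d)\n",
              100 * x$q, x$q80, x$ci_low, x$ci_high, x$n_records))
  invisible(x)
}

#' Pool lifespan estimates across cohorts
#'
#' Arithmetic mean of per-cohort quantile estimates (e.g. national census
#' cohorts).
#'
#' @param q80s Per-cohort lifespan estimates (numeric, or a list of
#'   "lifespan_estimate" objects).
#' @return Pooled estimate (years).
#' @export
multi_cohort_lifespan <- function(q80s) {
  if (is.list(q80s)) q80s <- vapply(q80s, `[[`, 0, "q80")
  mean(q80s)
}

# ---------------------------------------------------------------------------
# Heteroscedastic linear mixed-effects scaling model

# Per-species covariance-block structure, built once per fit: the random-
# slope outer products are constant across likelihood evaluations.
#
# When the predictors are species-level constants and the individuals
# within a species are balanced (the usual comparative design), the block
# covariance sigma2 I + a J_n + b bdiag(J_c) has a known eigenstructure
# (grand mean / individual contrasts / within-individual contrasts), so the
# log-determinant and quadratic forms reduce to scalar arithmetic on
# precomputed sums of squares; otherwise a dense Cholesky path is used.
lme_blocks <- function(y, X, x_rand, species, individual) {
  lapply(levels(species), function(sl) {
    I <- which(species == sl)
    xs <- x_rand[I]
    ind <- individual[I]
    sizes <- table(ind)
    const_X <- all(apply(X[I, , drop = FALSE], 2,
                         function(col) max(col) == min(col))) &&
      max(xs) == min(xs)
    balanced <- length(unique(sizes)) == 1
    if (const_X && balanced) {
      m <- length(sizes); cc <- as.integer(sizes[1]); n <- length(I)
      ybar_j <- tapply(y[I], ind, mean)
      ybar <- mean(y[I])
      list(type = "fast", n = n, m = m, c = cc,
           x = xs[1], Xrow = X[I[1], ], ybar = ybar,
           ss_between = cc * sum((ybar_j - ybar)^2),
           ss_within = sum((y[I] - ybar_j[ind])^2))
    } else {
      Mind <- matrix(0, length(I), length(I))
      for (u in unique(ind)) {
        J <- which(ind == u)
        Mind[J, J] <- tcrossprod(xs[J])
      }
      list(type = "dense", y = y[I], X = X[I, , drop = FALSE], n = length(I),
           Msp = tcrossprod(xs), Mind = Mind)
    }
  })
}

# Negative profile log-likelihood over log-variance parameters; fixed
# effects are profiled out by GLS. Returns the components needed for the
# fit when `details = TRUE`.
lme_profile <- function(theta, blocks, het, details = FALSE) {
  S <- length(blocks)
  s2_sp <- exp(theta[1]); s2_ind <- exp(theta[2])
  s2_res <- exp(theta[-(1:2)])
  if (!het) s2_res <- rep(s2_res[1], S)
  p <- if (blocks[[1]]$type == "fast") length(blocks[[1]]$Xrow) else
    ncol(blocks[[1]]$X)
  A <- matrix(0, p, p); b <- numeric(p)
  yVy <- 0; logdet <- 0; n <- 0
  for (si in seq_len(S)) {
    bl <- blocks[[si]]
    if (bl$type == "fast") {
      a_sp <- s2_sp * bl$x^2; b_ind <- s2_ind * bl$x^2
      l_grand <- s2_res[si] + a_sp * bl$n + b_ind * bl$c
      l_btw <- s2_res[si] + b_ind * bl$c
      if (l_grand <= 0 || l_btw <= 0 || s2_res[si] <= 0) {
        return(if (details) NULL else 1e10)
      }
      logdet <- logdet + log(l_grand) + (bl$m - 1) * log(l_btw) +
        (bl$n - bl$m) * log(s2_res[si])
      w <- bl$n / l_grand
      A <- A + tcrossprod(bl$Xrow) * w
      b <- b + bl$Xrow * (w * bl$ybar)
      yVy <- yVy + bl$n * bl$ybar^2 / l_grand + bl$ss_between / l_btw +
        bl$ss_within / s2_res[si]
    } else {
      V <- s2_sp * bl$Msp + s2_ind * bl$Mind + diag(s2_res[si], bl$n)
      ch <- tryCatch(chol(V), error = function(e) NULL)
      if (is.null(ch)) return(if (details) NULL else 1e10)
      logdet <- logdet + 2 * sum(log(diag(ch)))
      Xi <- backsolve(ch, bl$X, transpose = TRUE)
      yi <- backsolve(ch, bl$y, transpose = TRUE)
      A <- A + crossprod(Xi); b <- b + crossprod(Xi, yi)
      yVy <- yVy + sum(yi^2)
    }
    n <- n + bl$n
  }
  Ai <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(Ai)) return(if (details) NULL else 1e10)
  beta <- as.vector(Ai %*% b)
  quad <- yVy - sum(b * beta)
  ll <- -0.5 * (logdet + quad + n * log(2 * pi))
  if (!details) return(-ll)
  list(loglik = ll, beta = beta, vcov_beta = Ai,
       s2_species = s2_sp, s2_individual = s2_ind,
       s2_residual = s2_res)
}

#' Fit the heteroscedastic linear mixed-effects scaling model
#'
#' Regression of per-crypt mutation rates on species-level predictors with
#' random slopes at the individual and species levels and species-specific
#' residual variances, maximized by direct ML: the fixed effects are
#' profiled out by generalized least squares and the log-variances are
#' optimized numerically (quasi-Newton, multiple jittered restarts,
#' variance floor 1e-12).
#'
#' @param data data.frame with the response, predictor columns, and
#'   \code{species} and \code{individual} labels.
#' @param predictors Character vector of predictor column names (e.g.
#'   \code{"inv_lifespan"}, \code{"log_mass"}).
#' @param response Response column name (default "rate_per_year").
#' @param zero_intercept Drop the fixed-effect intercept (the inverse-
#'   lifespan scaling model, whose slope is the cross-species mean
#'   end-of-lifespan burden k).
#' @param heteroscedastic Species-specific residual variances (TRUE) or a
#'   single tied variance.
#' @param random_predictor Predictor carrying the random slopes (defaults
#'   to the first predictor).
#' @param restarts Optimizer restarts.
#' @param conf Confidence level of the Wald slope CI.
#' @param seed Seed for the restart jitters.
#' @param fix_var_species,fix_var_individual Optionally fix a random-slope
#'   variance at a given value instead of estimating it (0 disables that
#'   random effect; with both fixed at 0 and tied residual variances the
#'   model reduces to ordinary least squares).
#' @return Object of class "scaling_lme".
#' @export
fit_lme <- function(data, predictors, response = "rate_per_year",
                    zero_intercept = FALSE, heteroscedastic = TRUE,
                    random_predictor = predictors[1], restarts = 10L,
                    conf = 0.95, seed = 1L,
                    fix_var_species = NULL, fix_var_individual = NULL) {
  stopifnot(all(c(response, predictors, "species", "individual") %in%
                  names(data)))
  species <- factor(data$species)
  if (nlevels(species) < 3) stop("at least 3 species are required")
  individual <- as.character(data$individual)
  y <- data[[response]]
  X <- as.matrix(data[, predictors, drop = FALSE])
  if (!zero_intercept) X <- cbind(`(Intercept)` = 1, X)
  x_rand <- data[[random_predictor]]
  S <- nlevels(species)
  if (heteroscedastic && all(table(species) <= 1)) {
    warning("one observation per species: residual variances tied")
    heteroscedastic <- FALSE
  }
  n_var <- 2L + if (heteroscedastic) S else 1L

  # moment-based starting values
  ols <- stats::lm.fit(X, y)
  r2 <- tapply(ols$residuals^2, species, mean)
  r2[!is.finite(r2) | r2 < 1e-8] <- max(mean(ols$residuals^2), 1e-6)
  th0 <- c(log(stats::var(y) / max(mean(x_rand^2), 1e-12) / 4 + 1e-8),
           log(stats::var(y) / max(mean(x_rand^2), 1e-12) / 4 + 1e-8),
           if (heteroscedastic) log(as.numeric(r2)) else log(mean(r2)))
  lower <- rep(log(1e-12), n_var)
  upper <- rep(50, n_var)
  if (!is.null(fix_var_species)) {
    lower[1] <- upper[1] <- th0[1] <- log(max(fix_var_species, 1e-12))
  }
  if (!is.null(fix_var_individual)) {
    lower[2] <- upper[2] <- th0[2] <- log(max(fix_var_individual, 1e-12))
  }

  blocks <- lme_blocks(y, X, x_rand, species, individual)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(max(1L, restarts))) {
      th_start <- if (r == 1) th0 else th0 + stats::rnorm(n_var, 0, 2)
      th_start <- pmin(pmax(th_start, lower), upper)
      opt <- tryCatch(stats::nlminb(
        th_start, lme_profile, blocks = blocks, het = heteroscedastic,
        lower = lower, upper = upper,
        control = list(rel.tol = 1e-9, iter.max = 500)),
        error = function(e) NULL)
      if (!is.null(opt) && (is.null(best) || opt$objective < best$objective)) {
        best <- opt
      }
    }
  })
  if (is.null(best)) stop("optimization failed for every restart")
  det <- lme_profile(best$par, blocks, heteroscedastic, details = TRUE)
  det$s2_residual <- stats::setNames(det$s2_residual, levels(species))
  beta <- stats::setNames(det$beta, colnames(X))
  se <- sqrt(diag(det$vcov_beta))
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  slope_name <- random_predictor
  ci <- c(beta[slope_name] - zq * se[match(slope_name, colnames(X))],
          beta[slope_name] + zq * se[match(slope_name, colnames(X))])
  structure(list(
    coefficients = beta, vcov = det$vcov_beta,
    var_species = det$s2_species, var_individual = det$s2_individual,
    var_residual = det$s2_residual,
    loglik = det$loglik,
    n_params = length(beta) + n_var,
    predictors = predictors, response = response,
    random_predictor = random_predictor,
    zero_intercept = zero_intercept, heteroscedastic = heteroscedastic,
    slope = unname(beta[slope_name]), slope_ci = unname(ci), conf = conf,
    n_obs = length(y), n_species = S, data = data
  ), class = "scaling_lme")
}

#' @export
print.scaling_lme <- function(x, ...) {
  cat(sprintf(
    "Heteroscedastic LME scaling fit (%s ~ %s%s), %d crypts, %d species\n",
    x$response, paste(x$predictors, collapse = " + "),
    if (x$zero_intercept) ", zero intercept" else "", x$n_obs, x$n_species))
  cat("Fixed effects:\n"); print(round(x$coefficients, 4))
  cat(sprintf("Slope on %s: %.2f (%.0f%% CI %.2f-%.2f)\n",
              x$random_predictor, x$slope, 100 * x$conf,
              x$slope_ci[1], x$slope_ci[2]))
  cat(sprintf("Random-slope variances: species %.3g, individual %.3g\n",
              x$var_species, x$var_individual))
  cat(sprintf("logLik %.2f (%d parameters)\n", x$loglik, x$n_params))
  invisible(x)
}

#' @export
summary.scaling_lme <- function(object, ...) {
  print(object)
  cat("Species residual SDs:\n")
  print(round(sqrt(object$var_residual), 3))
  cat(sprintf("FVE (species means, fixed effects only): %.3f\n",
              fve(object)))
  invisible(object)
}

#' @export
coef.scaling_lme <- function(object, ...) object$coefficients

#' @export
logLik.scaling_lme <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_obs,
            class = "logLik")
}

#' @export
predict.scaling_lme <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  X <- as.matrix(newdata[, object$predictors, drop = FALSE])
  if (!object$zero_intercept) X <- cbind(1, X)
  as.vector(X %*% object$coefficients)
}

#' @export
residuals.scaling_lme <- function(object, ...) {
  object$data[[object$response]] - predict(object)
}

#' Fraction of inter-species variance explained by the fixed effects
#'
#' Predictions use only the fixed effects; observed species means are the
#' mean over individuals of each individual's mean rate (so individuals
#' with more crypts do not dominate). FVE = ESS / (ESS + RSS) over species
#' means.
#'
#' @param fit A "scaling_lme".
#' @param data Optional data (defaults to the fitting data).
#' @return FVE in [0, 1].
#' @export
fve <- function(fit, data = fit$data) {
  ind_mean <- stats::aggregate(
    data[[fit$response]],
    by = list(species = data$species, individual = data$individual),
    FUN = mean)
  obs <- tapply(ind_mean$x, ind_mean$species, mean)
  sp_rows <- data[!duplicated(data$species), , drop = FALSE]
  pred <- stats::setNames(predict(fit, sp_rows), sp_rows$species)
  pred <- pred[names(obs)]
  ybar <- mean(obs)
  ess <- sum((pred - ybar)^2)
  rss <- sum((obs - pred)^2)
  ess / (ess + rss)
}

#' Likelihood-ratio test between nested scaling fits
#'
#' @param fit_reduced,fit_full Nested "scaling_lme" fits (reduced within
#'   full).
#' @return list(statistic, df, p).
#' @export
lrt_models <- function(fit_reduced, fit_full) {
  stat <- max(2 * (fit_full$loglik - fit_reduced$loglik), 0)
  df <- fit_full$n_params - fit_reduced$n_params
  p <- if (df <= 0) {
    if (stat <= 1e-8) 1 else NA_real_
  } else {
    stats::pchisq(stat, df, lower.tail = FALSE)
  }
  list(statistic = stat, df = df, p = p)
}

#' Allometric (log-log) regression of species means
#'
#' Ordinary least squares of log10(y) on log10(x); for simple linear
#' regression FVE equals R-squared.
#'
#' @param x,y Positive species-level values.
#' @return list(slope, intercept, fve, p, fit).
#' @export
allometric_fit <- function(x, y) {
  check_positive(x, "x"); check_positive(y, "y")
  fit <- stats::lm(log10(y) ~ log10(x))
  sm <- summary(fit)
  p <- if (nrow(sm$coefficients) > 1) sm$coefficients[2, 4] else NA_real_
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       fve = sm$r.squared, p = p, fit = fit)
}

#' Partial-correlation analysis via allometric residuals
#'
#' Regresses log10(y) and log10(x) each on log10(z), then regresses the
#' first residuals on the second: the association between y and x after
#' accounting for z.
#'
#' @param y,x,z Positive species-level values.
#' @return list(slope, fve, p, residual_y, residual_x).
#' @export
partial_residual_regression <- function(y, x, z) {
  check_positive(y, "y"); check_positive(x, "x"); check_positive(z, "z")
  ry <- stats::resid(stats::lm(log10(y) ~ log10(z)))
  rx <- stats::resid(stats::lm(log10(x) ~ log10(z)))
  fit <- stats::lm(ry ~ rx)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]), fve = sm$r.squared,
       p = sm$coefficients[2, 4], residual_y = ry, residual_x = rx)
}

#' Bootstrap distribution of FVE for a scaling fit
#'
#' Resamples species or individuals with replacement (resampled units are
#' relabelled so duplicates count as distinct), refits the model, and
#' collects FVE across replicates.
#'
#' @param fit A fitted "scaling_lme" (refit specification is reused).
#' @param level "species" or "individual".
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param conf Confidence level of the percentile interval.
#' @return list(fve, ci, values).
#' @export
bootstrap_fve <- function(fit, level = c("species", "individual"),
                          B = 10000L, seed = 1L, conf = 0.95) {
  level <- match.arg(level)
  data <- fit$data
  vals <- with_seed(seed, vapply(seq_len(B), function(b) {
    units <- unique(data[[if (level == "species") "species" else "individual"]])
    pick <- sample(units, replace = TRUE)
    res <- do.call(rbind, lapply(seq_along(pick), function(i) {
      block <- data[data[[if (level == "species") "species" else
        "individual"]] == pick[i], , drop = FALSE]
      if (level == "species") {
        block$species <- paste0(block$species, "_b", i)
        block$individual <- paste0(block$individual, "_b", i)
      } else {
        block$individual <- paste0(block$individual, "_b", i)
      }
      block
    }))
    if (length(unique(res$species)) < 3) return(NA_real_)
    f <- tryCatch(fit_lme(res, fit$predictors, fit$response,
                          fit$zero_intercept, fit$heteroscedastic,
                          fit$random_predictor, restarts = 2L,
                          seed = seed + b),
                  error = function(e) NULL)
    if (is.null(f)) NA_real_ else fve(f)
  }, 0))
  a <- (1 - conf) / 2
  list(fve = fve(fit),
       ci = stats::quantile(vals, c(a, 1 - a), na.rm = TRUE, names = FALSE),
       values = vals)
}

#' Phylogenetic generalized least squares regression of species means
#'
#' GLS with error covariance proportional to shared branch length under
#' Brownian motion; a star phylogeny reduces exactly to OLS.
#'
#' @param data data.frame with species-level rows: \code{species}, the
#'   predictor column and the response column.
#' @param tree An \code{ape::phylo} tree whose tip labels cover the species.
#' @param predictor,response Column names.
#' @param zero_intercept Drop the intercept.
#' @param conf Confidence level.
#' @return list(slope, intercept, slope_ci, sigma2, loglik).
#' @export
pgls_fit <- function(data, tree, predictor, response = "rate_per_year",
                     zero_intercept = FALSE, conf = 0.95) {
  missing_sp <- setdiff(data$species, tree$tip.label)
  if (length(missing_sp) > 0) {
    stop("species missing from tree: ", paste(missing_sp, collapse = ", "))
  }
  tree <- ape::keep.tip(tree, data$species)
  C <- ape::vcv(tree)[data$species, data$species]
  y <- data[[response]]
  X <- as.matrix(data[, predictor, drop = FALSE])
  if (!zero_intercept) X <- cbind(`(Intercept)` = 1, X)
  ch <- chol(C)
  Xt <- backsolve(ch, X, transpose = TRUE)
  yt <- backsolve(ch, y, transpose = TRUE)
  fit <- stats::lm.fit(Xt, yt)
  n <- length(y); p <- ncol(X)
  sigma2 <- sum(fit$residuals^2) / (n - p)
  vb <- sigma2 * solve(crossprod(Xt))
  beta <- stats::setNames(fit$coefficients, colnames(X))
  se <- sqrt(diag(vb))
  tq <- stats::qt(1 - (1 - conf) / 2, n - p)
  i <- match(predictor, colnames(X))
  ll <- -0.5 * (n * log(2 * pi * sigma2 * (n - p) / n) + n +
                  2 * sum(log(diag(ch))))
  list(slope = unname(beta[i]), intercept = if (zero_intercept) NA_real_
       else unname(beta["(Intercept)"]),
       slope_ci = c(beta[i] - tq * se[i], beta[i] + tq * se[i]),
       sigma2 = sigma2, loglik = ll, coefficients = beta)
}

#' Min, max and fold variation of species-level values
#'
#' @param values Positive species-level summaries.
#' @return list(min, max, fold = max/min).
#' @export
summarize_variation <- function(values) {
  check_positive(values, "values")
  list(min = min(values), max = max(values), fold = max(values) / min(values))
}
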