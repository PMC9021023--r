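# Crypt clonality assessment: a truncated binomial mixture model of the VAF
# distribution, fitted by EM, with cluster number selected by BIC and the
# sample inclusion/exclusion criteria applied on top.
#
# Variant calling requires a minimum number of supporting reads, so the
# binomial distribution of alt counts is truncated at that minimum and
# renormalized; a clonal crypt shows a single cluster near VAF 0.5 while
# polyclonal or contaminated crypts show low-VAF clusters.

#' Truncated binomial log-pmf
#'
#' log of Binom(alt; depth, p) conditioned on alt >= min_alt (renormalized
#' over the truncated support); -Inf below the truncation point.
#'
#' @param alt,depth Integer vectors of alt counts and depths.
#' @param p Success probability in (0, 1).
#' @param min_alt Truncation point (minimum supporting reads to call).
#' @return Numeric vector of log-probabilities.
#' @export
truncated_binomial_logpmf <- function(alt, depth, p, min_alt = 4L) {
  if (any(p <= 0) || any(p >= 1)) stop("p must lie strictly in (0, 1)")
  if (any(min_alt > depth)) stop("min_alt exceeds depth")
  out <- stats::dbinom(alt, depth, p, log = TRUE) -
    stats::pbinom(min_alt - 1L, depth, p, lower.tail = FALSE, log.p = TRUE)
  out[alt < min_alt] <- -Inf
  out
}

logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

em_one_run <- function(alt, depth, K, means0, weights0, min_alt, tol, max_iter) {
  # collapse to unique (alt, depth) pairs with multiplicities: variants with
  # identical counts share responsibilities, so the weighted EM on unique
  # pairs is exactly equivalent and much faster at typical depths
  key <- paste(alt, depth)
  u <- !duplicated(key)
  ua <- alt[u]; ud <- depth[u]
  w_obs <- as.vector(table(factor(key, levels = key[u])))
  nu <- length(ua); n <- length(alt)
  means <- means0; weights <- weights0
  ll_old <- -Inf; trace <- numeric(0)
  converged <- FALSE
  resp_u <- matrix(1 / K, nu, K)
  for (iter in seq_len(max_iter)) {
    lp <- vapply(seq_len(K), function(k)
      log(weights[k]) + truncated_binomial_logpmf(ua, ud, means[k], min_alt),
      numeric(nu))
    lp <- matrix(lp, nu, K)
    lse <- logsumexp_rows(lp)
    ll <- sum(w_obs * lse)
    resp_u <- exp(lp - lse)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    weights <- pmax(colSums(w_obs * resp_u) / n, 1e-12)
    weights <- weights / sum(weights)
    for (k in seq_len(K)) {
      rk <- w_obs * resp_u[, k]
      if (sum(rk) < 1e-10) next
      # no closed form under truncation: bounded 1-D maximization
      means[k] <- stats::optimize(function(pp)
        sum(rk * truncated_binomial_logpmf(ua, ud, pp, min_alt)),
        interval = c(1e-4, 1 - 1e-4), maximum = TRUE, tol = 1e-8)$maximum
    }
  }
  resp <- resp_u[match(key, key[u]), , drop = FALSE]
  list(means = means, weights = weights, resp = resp,
       loglik = trace[length(trace)], n_iter = length(trace),
       converged = converged, trace = trace)
}

#' Fit a K-cluster truncated binomial mixture to a crypt's VAF data by EM
#'
#' E-step responsibilities come from the truncated pmf at each variant's own
#' depth; the M-step updates mixing weights from responsibility means and
#' each cluster mean by bounded 1-D maximization of the truncated
#' likelihood (no closed form exists under truncation). The best of several
#' restarts (quantile-spread initialization plus random jitters) is kept.
#'
#' @param alt,depth Per-variant alt counts and depths (alt >= min_alt).
#' @param K Number of clusters.
#' @param seed Integer seed for the restart jitters.
#' @param min_alt Truncation point.
#' @param tol Convergence tolerance on the log-likelihood increase.
#' @param max_iter Maximum EM iterations per restart.
#' @param restarts Number of EM restarts.
#' @return Object of class "vaf_mixture": cluster means, weights,
#'   responsibilities, loglik, BIC, iteration count and trace.
#' @export
em_fit <- function(alt, depth, K, seed = 1L, min_alt = 4L,
                   tol = 1e-6, max_iter = 500L, restarts = 5L) {
  stopifnot(length(alt) == length(depth))
  n <- length(alt)
  if (n == 0) stop("no variants supplied")
  if (K > n) stop("more clusters than variants")
  if (any(alt < min_alt)) stop("alt counts below min_alt are not callable")
  vaf <- alt / depth
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      means0 <- if (r == 1) {
        stats::quantile(vaf, (seq_len(K)) / (K + 1), names = FALSE, type = 7)
      } else {
        stats::runif(K, 0.02, 0.95)
      }
      means0 <- pmin(pmax(means0, 0.01), 0.99)
      fit <- em_one_run(alt, depth, K, sort(means0), rep(1 / K, K),
                        min_alt, tol, max_iter)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  })
  o <- order(best$means)
  structure(list(
    n_clusters = K, means = best$means[o], weights = best$weights[o],
    responsibilities = best$resp[, o, drop = FALSE],
    loglik = best$loglik,
    bic = -2 * best$loglik + (2 * K - 1) * log(n),
    n_iter = best$n_iter, converged = best$converged,
    loglik_trace = best$trace, min_alt = min_alt, n_variants = n
  ), class = "vaf_mixture")
}

#' Select the number of VAF clusters by BIC
#'
#' Fits the truncated binomial mixture for each K in the range and returns
#' the fit minimizing BIC = -2 loglik + (2K - 1) log(n), ties going to the
#' smaller K.
#'
#' @inheritParams em_fit
#' @param K_range Candidate cluster numbers (default 1 to 5).
#' @return The best "vaf_mixture" fit, with an attribute \code{bic_table}.
#' @export
select_model <- function(alt, depth, K_range = 1:5, seed = 1L, min_alt = 4L,
                         restarts = 5L, ...) {
  K_range <- K_range[K_range <= length(alt)]
  if (length(K_range) == 0) stop("no feasible K in range")
  fits <- lapply(K_range, function(K)
    em_fit(alt, depth, K, seed = seed + K, min_alt = min_alt,
           restarts = if (K == 1) 1L else restarts, ...))
  bics <- vapply(fits, `[[`, 0, "bic")
  best <- fits[[which.min(bics)]]
  attr(best, "bic_table") <- data.frame(K = K_range, bic = bics)
  best
}

#' @export
print.vaf_mixture <- function(x, ...) {
  cat(sprintf("Truncated binomial VAF mixture: K = %d (n = %d, BIC = %.1f)\n",
              x$n_clusters, x$n_variants, x$bic))
  print(data.frame(mean_vaf = round(x$means, 4),
                   weight = round(x$weights, 4)), row.names = FALSE)
  invisible(x)
}

#' @export
logLik.vaf_mixture <- function(object, ...) {
  structure(object$loglik, df = 2 * object$n_clusters - 1,
            nobs = object$n_variants, class = "logLik")
}

#' @export
coef.vaf_mixture <- function(object, ...) {
  c(stats::setNames(object$means, paste0("mean", seq_along(object$means))),
    stats::setNames(object$weights, paste0("weight", seq_along(object$weights))))
}

#' Apply the sample inclusion/exclusion criteria to a fitted crypt
#'
#' A crypt fails with status \code{low_burden} if it carries fewer than 50
#' somatic variants; \code{high_burden} if its burden exceeds 3 times the
#' median burden of same-individual samples (computed over samples with at
#' least 50 variants); \code{low_vaf} if fewer than 70\% of its variants are
#' hard-assigned to clusters with mean VAF >= 0.3 -- unless every sample of
#' the individual has a primary-cluster mean below 0.3, in which case the
#' sample is \code{exempted} (individuals with high non-epithelial cell
#' fractions would otherwise lose all their crypts).
#'
#' @param fit "vaf_mixture" for the sample.
#' @param sibling_burdens Burdens of same-individual samples (>= 50 variants
#'   each); NULL skips the high-burden rule with a warning.
#' @param individual_primary_vafs Primary-cluster mean VAFs of all samples
#'   of the individual (for the exemption clause).
#' @param sample_id Sample label.
#' @param allow_list Sample ids to rescue regardless of the criteria.
#' @return list of class "clonality_verdict": sample_id, status,
#'   fraction_high_vaf, primary_cluster_vaf.
#' @export
classify_sample <- function(fit, sibling_burdens = NULL,
                            individual_primary_vafs = NULL,
                            sample_id = "sample", allow_list = NULL) {
  stopifnot(inherits(fit, "vaf_mixture"))
  n <- fit$n_variants
  assign_k <- apply(fit$responsibilities, 1, which.max)
  frac_high <- mean(fit$means[assign_k] >= 0.3)
  primary <- fit$means[which.max(fit$weights)]
  status <- "pass"
  if (n < 50) {
    status <- "low_burden"
  } else if (!is.null(sibling_burdens) && length(sibling_burdens) > 0 &&
               n > 3 * stats::median(sibling_burdens)) {
    status <- "high_burden"
  } else {
    if (is.null(sibling_burdens)) {
      warning("no sibling burden context: high-burden rule skipped")
    }
    if (frac_high < 0.7) {
      all_low <- !is.null(individual_primary_vafs) &&
        all(individual_primary_vafs < 0.3)
      status <- if (all_low) "exempted" else "low_vaf"
    }
  }
  if (!is.null(allow_list) && sample_id %in% allow_list &&
        status %in% c("low_burden", "high_burden", "low_vaf")) {
    status <- "pass"
  }
  structure(list(sample_id = sample_id, status = status,
                 fraction_high_vaf = frac_high,
                 primary_cluster_vaf = primary),
            class = "clonality_verdict")
}

#' @export
print.clonality_verdict <- function(x, ...) {
  cat(sprintf("%s: %s (%.0f%% of variants in clusters >= 0.3; primary VAF %.2f)\n",
              x$sample_id, x$status, 100 * x$fraction_high_vaf,
              x$primary_cluster_vaf))
  invisible(x)
}
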