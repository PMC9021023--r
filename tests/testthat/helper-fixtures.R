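# Shared fixture builders: everything is generated in code at test time.

# a minimal candidate-variant data.frame with sensible defaults, overridable
# per field; all vectors are recycled to the longest length
make_variants <- function(...) {
  args <- list(...)
  n <- if (length(args)) max(vapply(args, length, 0L)) else 1L
  defaults <- list(
    contig = "chrS01", pos = seq(5000L, by = 5000L, length.out = n),
    ref = "C", alt = "T", var_class = "substitution",
    alt_count = 15L, depth = 30L,
    clipped_fraction = 0, hq_fragments = 15L, secondary_gt_primary = FALSE,
    fwd_alt = 8L, rev_alt = 7L, nearby_indel_reads = 0L,
    caller_flag = "PASS", is_artifact = FALSE
  )
  for (nm in names(args)) defaults[[nm]] <- args[[nm]]
  df <- data.frame(lapply(defaults, rep_len, n), stringsAsFactors = FALSE)
  df$vaf <- df$alt_count / df$depth
  df
}

# per-crypt rate table driven by the simulation ground truth (burden = true
# mutation count, rate = burden / age)
truth_rate_table <- function(cohort) {
  cr <- cohort$crypts; sp <- cohort$species
  i <- match(cr$species, sp$name)
  data.frame(rate_per_year = cr$n_true_mutations / cr$age,
             species = cr$species, individual = cr$individual_id,
             inv_lifespan = 1 / sp$lifespan_true[i],
             log_mass = log10(sp$adult_mass[i]),
             lifespan = sp$lifespan_true[i],
             stringsAsFactors = FALSE)
}

# independent beta-binomial pmf by numerical integration of the binomial
# over its beta mixing density, used as the oracle against the package's
# grid MLE
oracle_betabinom_pmf <- function(x, size, mu, rho) {
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  # substitute u = pbeta(p; a, b) so the integrand stays smooth even when
  # the beta density is a near-point mass (tiny rho)
  vapply(seq_along(x), function(i)
    stats::integrate(function(u)
      stats::dbinom(x[i], size[i], stats::qbeta(u, a, b)),
      0, 1, rel.tol = 1e-10, subdivisions = 500L)$value, 0)
}

oracle_rho_loglik <- function(alt, depth, rho) {
  mu <- sum(alt) / sum(depth)
  sum(log(oracle_betabinom_pmf(alt, depth, mu, rho)))
}

# two-sided Fisher p by direct hypergeometric enumeration
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force per-base interval union size on a small genome
oracle_union_bp <- function(total, exclusions) {
  tot <- 0
  for (ctg in unique(total$contig)) {
    cov <- rep(FALSE, max(total$end[total$contig == ctg]))
    for (i in which(total$contig == ctg)) {
      cov[(total$start[i] + 1):total$end[i]] <- TRUE
    }
    excl <- rep(FALSE, length(cov))
    if (!is.null(exclusions) && nrow(exclusions) > 0) {
      for (i in which(exclusions$contig == ctg)) {
        span <- (exclusions$start[i] + 1):min(exclusions$end[i], length(excl))
        excl[span] <- TRUE
      }
    }
    tot <- tot + sum(cov & !excl)
  }
  tot
}

# simple untruncated binomial-mixture EM (closed-form M-step), the oracle
# for em_fit at min_alt = 0
oracle_binom_mixture <- function(alt, depth, K, means0, max_iter = 2000,
                                 tol = 1e-8) {
  means <- means0; weights <- rep(1 / K, K)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    lp <- sapply(seq_len(K), function(k)
      log(weights[k]) + dbinom(alt, depth, means[k], log = TRUE))
    lp <- matrix(lp, length(alt), K)
    mx <- apply(lp, 1, max)
    lse <- mx + log(rowSums(exp(lp - mx)))
    ll <- sum(lse)
    if (ll - ll_old < tol && it > 1) break
    ll_old <- ll
    r <- exp(lp - lse)
    weights <- colMeans(r)
    means <- pmin(pmax(colSums(r * alt) / colSums(r * depth), 1e-6), 1 - 1e-6)
  }
  list(means = means, weights = weights, loglik = ll)
}
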