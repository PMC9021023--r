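# Internal helpers shared across modules.

#' Derive a named substream seed from a master seed
#'
#' All randomness in the package flows from one master seed through named
#' substreams, so any stage can be regenerated independently of the others.
#' The derived seed is kept strictly below 2^31 - 1.
#'
#' @param seed Integer master seed.
#' @param name Character substream label.
#' @return An integer seed.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (ch in utf8ToInt(paste0(name, ":"))) {
    h <- (h * 31 + ch) %% 2147483563
  }
  as.integer((abs(seed) %% 2147483563 * 69069 + h) %% 2147483562 + 1)
}

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Beta-binomial log-pmf in mean/overdispersion parameterization:
# alpha = mu (1 - rho) / rho, beta = (1 - mu) (1 - rho) / rho.
# rho -> 0 recovers the binomial; mu in {0, 1} is handled as a point mass.
dbetabinom_log <- function(x, size, mu, rho) {
  stopifnot(all(rho > 0), all(rho < 1))
  if (any(mu < 0 | mu > 1)) stop("mu must lie in [0, 1]")
  n <- max(length(x), length(size), length(mu), length(rho))
  x <- rep_len(x, n); size <- rep_len(size, n)
  mu <- rep_len(mu, n); rho <- rep_len(rho, n)
  out <- numeric(n)
  deg <- mu <= 0 | mu >= 1
  if (any(deg)) {
    out[deg] <- ifelse(mu[deg] <= 0,
                       ifelse(x[deg] == 0, 0, -Inf),
                       ifelse(x[deg] == size[deg], 0, -Inf))
  }
  if (any(!deg)) {
    a <- mu[!deg] * (1 - rho[!deg]) / rho[!deg]
    b <- (1 - mu[!deg]) * (1 - rho[!deg]) / rho[!deg]
    out[!deg] <- lchoose(size[!deg], x[!deg]) +
      lbeta(x[!deg] + a, size[!deg] - x[!deg] + b) - lbeta(a, b)
  }
  out
}

rbetabinom <- function(n, size, mu, rho) {
  if (rho <= 0) return(stats::rbinom(n, size, mu))
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  stats::rbinom(n, size, stats::rbeta(n, a, b))
}

# Dirichlet draw via gamma normalization.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("'%s' must be strictly positive", name))
  }
  invisible(x)
}
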