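# Large-scale total and allele-specific copy-number screening from binned
# coverage ratios and heterozygous-SNP BAFs: per-bin joint negative-binomial
# (coverage) / beta-binomial (folded BAF) likelihood over the 15 ordered
# states (major >= minor, each 0-4), a complexity penalty, run-length
# segmentation and cohort-level filtering.

#' The 15 ordered copy-number states (major >= minor, each 0-4)
#' @return data.frame(major, minor, total).
#' @export
cn_states <- function() {
  g <- expand.grid(minor = 0:4, major = 0:4)
  g <- g[g$major >= g$minor, c("major", "minor")]
  g$total <- g$major + g$minor
  rownames(g) <- NULL
  g
}

#' Select heterozygous SNPs from a matched-normal genotype table
#'
#' Inclusive BAF bounds of 0.4-0.6 in the normal, and depth of at least 15
#' reads in both the sample and the normal.
#'
#' @param snps data.frame with normal_alt, normal_depth, sample_depth.
#' @return Subset of rows passing the het-selection rule.
#' @export
select_het_snps <- function(snps) {
  baf <- snps$normal_alt / snps$normal_depth
  keep <- baf >= 0.4 & baf <= 0.6 &
    snps$normal_depth >= 15 & snps$sample_depth >= 15
  snps[keep, , drop = FALSE]
}

#' Expected coverage ratio and folded BAF of a CN state
#'
#' r = (purity * total + (1 - purity) * 2) / 2;
#' f = (purity * major + (1 - purity)) / (purity * total + (1 - purity) * 2),
#' folded as max(f, 1 - f).
#'
#' @param major,minor Allele copy numbers.
#' @param purity Aberrant-cell fraction in (0, 1].
#' @return list(ratio, baf_folded).
#' @export
cn_expectations <- function(major, minor, purity = 1) {
  total <- major + minor
  denom <- purity * total + (1 - purity) * 2
  r <- denom / 2
  f <- if (denom <= 0) 0.5 else (purity * major + (1 - purity)) / denom
  list(ratio = r, baf_folded = max(f, 1 - f))
}

#' Joint log-likelihood of one bin under a CN state
#'
#' Coverage term: negative binomial on the bin's sample read count around
#' baseline * expected ratio. BAF term: a symmetric two-component
#' beta-binomial on the het-SNP alt counts around the expected allele
#' fraction (equivalent to folding, without phasing). Bins without SNPs use
#' the coverage term only, so only total CN is informative there.
#'
#' @param reads_sample Bin read count in the sample.
#' @param baseline Expected diploid read count of the bin (e.g. the
#'   normal count scaled by the genome-wide sample/normal ratio).
#' @param snp_alt,snp_depth Het-SNP counts in the bin (possibly empty).
#' @param major,minor CN state.
#' @param purity Aberrant-cell fraction.
#' @param nb_size Negative-binomial size (coverage dispersion).
#' @param bb_rho Beta-binomial overdispersion (BAF dispersion).
#' @return Log-likelihood.
#' @export
bin_likelihood <- function(reads_sample, baseline, snp_alt, snp_depth,
                           major, minor, purity = 1,
                           nb_size = 50, bb_rho = 0.01) {
  if (purity <= 0 || purity > 1) stop("purity must lie in (0, 1]")
  if (major < 0 || major > 4 || minor < 0 || minor > 4 || major < minor) {
    stop("invalid CN state")
  }
  ex <- cn_expectations(major, minor, purity)
  mu_cov <- max(baseline * ex$ratio, 1e-9)
  ll <- stats::dnbinom(reads_sample, mu = mu_cov, size = nb_size, log = TRUE)
  if (length(snp_alt) > 0) {
    f <- ex$baf_folded
    l1 <- dbetabinom_log(snp_alt, snp_depth, f, bb_rho)
    l2 <- dbetabinom_log(snp_alt, snp_depth, 1 - f, bb_rho)
    mx <- pmax(l1, l2)
    ll <- ll + sum(mx + log(0.5 * exp(l1 - mx) + 0.5 * exp(l2 - mx)))
  }
  ll
}

#' Default complexity penalty for CN states
#'
#' lambda * (|major - 1| + |minor - 1|): zero for the diploid 1/1 state,
#' growing with distance from it. The default lambda of 2 demands about two
#' log-units of evidence per bin for a simple one-allele event.
#'
#' @param lambda Penalty per unit of allele-CN deviation from diploid.
#' @return Numeric vector of penalties over \code{\link{cn_states}()}.
#' @export
cn_penalty <- function(lambda = 2) {
  st <- cn_states()
  lambda * (abs(st$major - 1) + abs(st$minor - 1))
}

#' Call the most likely CN state of every bin
#'
#' Exhaustive search over the 15 ordered states, maximizing the penalized
#' joint likelihood per bin. Bins with coverage below 10 reads in sample or
#' normal are masked (state NA). Dispersions default to method-of-moments
#' estimates from the genome-wide (diploid-dominated) data.
#'
#' @param bins data.frame from \code{\link{simulate_cn_tracks}} (or with the
#'   same columns: reads_sample, reads_normal).
#' @param snps data.frame(bin, alt, depth) of het SNPs.
#' @param purity Aberrant-cell fraction.
#' @param penalty Penalty vector over states (default \code{cn_penalty()}).
#' @param nb_size,bb_rho Dispersions; NULL = estimate from the data.
#' @return data.frame(bin, major, minor, total) of called states.
#' @export
call_bins <- function(bins, snps = NULL, purity = 1,
                      penalty = cn_penalty(), nb_size = NULL, bb_rho = NULL) {
  st <- cn_states()
  n <- nrow(bins)
  ratio_gw <- bins$reads_sample / pmax(bins$reads_normal, 1)
  baseline <- bins$reads_normal * stats::median(ratio_gw)
  if (is.null(nb_size)) {
    # trimmed method of moments: the genome is diploid-dominated, so
    # dropping the extreme bins keeps CN events out of the estimate
    x <- bins$reads_sample
    qs <- stats::quantile(x, c(0.1, 0.9), type = 7)
    x <- x[x >= qs[1] & x <= qs[2]]
    # rescale: the central-80% variance of a (near-)normal is 0.44 sigma^2
    m <- mean(x); v <- stats::var(x) / 0.44
    nb_size <- if (is.finite(v) && v > m) m^2 / (v - m) else 100
    nb_size <- min(max(nb_size, 5), 1000)
  }
  if (is.null(bb_rho)) {
    if (!is.null(snps) && nrow(snps) > 10) {
      # use balanced (diploid-looking) SNPs only, so allelic imbalance in
      # event bins does not inflate the overdispersion estimate
      p_hat <- snps$alt / snps$depth
      bal <- abs(p_hat - 0.5) < 0.25
      if (sum(bal) > 10) {
        v_obs <- stats::var(p_hat[bal])
        v_bin <- mean(0.25 / snps$depth[bal])
        bb_rho <- max((v_obs - v_bin) / 0.25, 1e-4)
        bb_rho <- min(bb_rho, 0.5)
      } else bb_rho <- 0.01
    } else bb_rho <- 0.01
  }
  snp_by_bin <- if (is.null(snps)) list() else split(snps, snps$bin)
  out <- data.frame(bin = bins$bin, major = NA_integer_,
                    minor = NA_integer_, total = NA_integer_)
  masked <- bins$reads_sample < 10 | bins$reads_normal < 10
  for (i in seq_len(n)) {
    if (masked[i]) next
    sb <- snp_by_bin[[as.character(bins$bin[i])]]
    ll <- vapply(seq_len(nrow(st)), function(s)
      bin_likelihood(bins$reads_sample[i], baseline[i],
                     if (is.null(sb)) integer(0) else sb$alt,
                     if (is.null(sb)) integer(0) else sb$depth,
                     st$major[s], st$minor[s], purity,
                     nb_size, bb_rho), 0)
    best <- which.max(ll - penalty)
    out$major[i] <- st$major[best]
    out$minor[i] <- st$minor[best]
    out$total[i] <- st$total[best]
  }
  out
}

#' Merge per-bin CN states into segments
#'
#' Runs of five or more bins with identical states become segments;
#' adjacent same-state segments separated by fewer than five bins are
#' merged (the gap is absorbed). Masked (NA) bins break runs.
#'
#' @param states data.frame(bin, major, minor) from \code{\link{call_bins}}.
#' @param min_bins Minimum run length for a segment.
#' @param merge_gap Segments of equal state closer than this many bins are
#'   merged.
#' @return data.frame(start_bin, end_bin, major, minor, n_bins).
#' @export
segment_states <- function(states, min_bins = 5L, merge_gap = 5L) {
  key <- paste(states$major, states$minor)
  key[is.na(states$major)] <- NA
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= min_bins & !is.na(r$values)
  segs <- data.frame(
    start_bin = states$bin[starts[keep]], end_bin = states$bin[ends[keep]],
    major = states$major[starts[keep]], minor = states$minor[starts[keep]]
  )
  if (nrow(segs) > 1) {
    repeat {
      merged <- FALSE
      for (i in seq_len(nrow(segs) - 1)) {
        gap <- segs$start_bin[i + 1] - segs$end_bin[i] - 1L
        same <- segs$major[i] == segs$major[i + 1] &&
          segs$minor[i] == segs$minor[i + 1]
        if (same && gap < merge_gap) {
          segs$end_bin[i] <- segs$end_bin[i + 1]
          segs <- segs[-(i + 1), , drop = FALSE]
          merged <- TRUE
          break
        }
      }
      if (!merged) break
    }
  }
  segs$n_bins <- segs$end_bin - segs$start_bin + 1L
  rownames(segs) <- NULL
  segs
}

#' Filter CN segments at cohort level
#'
#' Non-diploid segments are retained only if they span at least
#' \code{min_event_bins} bins (1 Mb at 100-kb bins) and are private to a
#' single sample within the species; diploid (1/1) segments are background
#' and dropped from the event list.
#'
#' @param segments data.frame with sample_id, start_bin, end_bin, major,
#'   minor, n_bins (concatenated over the species' samples).
#' @param min_event_bins Minimum event span in bins.
#' @return The retained event segments.
#' @export
filter_segments <- function(segments, min_event_bins = 10L) {
  ev <- segments[!(segments$major == 1 & segments$minor == 1), , drop = FALSE]
  if (nrow(ev) == 0) return(ev)
  ev <- ev[ev$n_bins >= min_event_bins, , drop = FALSE]
  if (nrow(ev) == 0) return(ev)
  key <- paste(ev$start_bin, ev$end_bin, ev$major, ev$minor)
  shared <- key %in% key[duplicated(key)]
  # shared if an identical event occurs in a different sample
  if (!is.null(ev$sample_id)) {
    tab <- tapply(ev$sample_id, key, function(s) length(unique(s)))
    shared <- tab[key] >= 2
  }
  out <- ev[!shared, , drop = FALSE]
  rownames(out) <- NULL
  out
}
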