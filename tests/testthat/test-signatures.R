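# Trinucleotide spectra and signature inference: channel algebra,
# opportunity counting, representation conversion, ML fitting against a
# direct-optimization oracle, joint fit-and-extract, LRTs and Fisher tests.

test_that("substitution classification collapses 192 inputs two-to-one onto
           96 channels", {
  i1 <- classify_substitution("ACA", "T")
  expect_equal(names(i1), "A[C>T]A")
  # purine-strand input maps to the same channel as its reverse complement
  expect_equal(unname(classify_substitution("TGT", "A")), unname(i1))
  bases <- c("A", "C", "G", "T")
  hits <- integer(96)
  for (p5 in bases) for (ref in bases) for (p3 in bases) {
    for (alt in setdiff(bases, ref)) {
      idx <- classify_substitution(paste0(p5, ref, p3), alt)
      hits[idx] <- hits[idx] + 1L
    }
  }
  expect_true(all(hits == 2L))
  expect_error(classify_substitution("ACA", "C"), "alt equals")
})

test_that("trinucleotide opportunities count collapsed contexts inside
           regions", {
  ref <- c(c1 = "ACGT")
  opp <- trinucleotide_opportunities(ref, data.frame(contig = "c1",
                                                     start = 0, end = 4))
  # ACG (centre C) and CGT -> revcomp ACG: both land in class ACG
  expect_equal(unname(opp["ACG"]), 2)
  expect_equal(sum(opp), 2)
  # N-containing windows are skipped
  refn <- c(c1 = "ACNGT")
  oppn <- trinucleotide_opportunities(refn, data.frame(contig = "c1",
                                                       start = 0, end = 5))
  expect_equal(sum(oppn), 0)
  expect_error(trinucleotide_opportunities(ref, data.frame()[0, ]), "empty")
  # agrees with Biostrings on a longer random sequence
  set.seed(3)
  s <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
             collapse = "")
  opp2 <- trinucleotide_opportunities(c(chr = s),
                                      data.frame(contig = "chr", start = 0,
                                                 end = 3000))
  expect_equal(sum(opp2), 2998)
})

test_that("signature conversion between opportunity regimes is exact", {
  sig <- reference_signatures()[, "SBS1"]
  flat <- rep(1, 96)
  expect_equal(convert_signature(sig, flat, flat), sig)
  set.seed(6)
  oppA <- runif(32, 0.5, 2); oppB <- runif(32, 0.5, 2)
  there <- convert_signature(sig, oppA, oppB)
  back <- convert_signature(there, oppB, oppA)
  expect_lt(max(abs(back - sig)), 1e-9)
  # doubling one context's target opportunity doubles its channels'
  # relative mass pre-normalization
  oppC <- oppA; oppC[1] <- 2 * oppA[1]
  pre_ratio <- (sig * expand_opportunities(oppC) /
                  expand_opportunities(oppA))[1:96]
  ch1 <- which(cryptclock:::channel_context() == 1)
  expect_equal(unname(pre_ratio[ch1] / sig[ch1]), rep(2, length(ch1)))
})

test_that("cosine similarity basics", {
  expect_equal(cosine_similarity(c(1, 0), c(1, 0)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  p <- runif(96)
  expect_equal(cosine_similarity(p, 5 * p), 1)
})

test_that("exposure fitting is exact on pure spectra and matches a direct
           optimization oracle", {
  sigs <- reference_signatures()[, c("SBS1", "SBS5", "SBS18")]
  pure <- round(sigs[, 1] * 1e6)
  f <- fit_exposures(pure, sigs)
  expect_gt(f$exposures[1], 1 - 1e-4)
  # zero spectrum yields zero exposures
  f0 <- fit_exposures(integer(96), sigs)
  expect_equal(unname(f0$exposure_counts), c(0, 0, 0))
  # recovery of a known mixture
  sp <- simulate_spectrum(sigs, c(0.6, 0.3, 0.1), rep(1, 96), 1e4, seed = 2)
  fm <- fit_exposures(sp, sigs)
  expect_lt(max(abs(fm$exposures - c(0.6, 0.3, 0.1))), 0.05)
  # oracle: direct likelihood maximization over the simplex (softmax optim)
  set.seed(21)
  for (rep in 1:20) {
    e_true <- rgamma(3, 1) + 0.05; e_true <- e_true / sum(e_true)
    x <- simulate_spectrum(sigs, e_true, rep(1, 96), 2000, seed = 100 + rep)
    fit <- fit_exposures(x, sigs)
    nll <- function(z) {
      e <- exp(c(z, 0)); e <- e / sum(e)
      -sum(x[x > 0] * log(as.vector(sigs %*% e))[x > 0])
    }
    # multi-start bounded optimization oracle on the softmax scale
    orc_best <- min(vapply(1:5, function(s) {
      z0 <- if (s == 1) c(0, 0) else rnorm(2, 0, 2)
      o1 <- optim(z0, nll, method = "Nelder-Mead")
      optim(o1$par, nll, method = "BFGS")$value
    }, 0))
    # the EM solution attains (or exceeds) the oracle's best likelihood
    expect_gte(fit$loglik, -orc_best - 1e-4 * abs(orc_best))
  }
})

test_that("joint extraction reduces to per-row fitting when nothing is
           extracted, and is row-exchangeable", {
  sigs <- reference_signatures()[, c("SBS1", "SBS5", "SBS18")]
  set.seed(4)
  spectra <- t(sapply(1:4, function(g)
    simulate_spectrum(sigs, c(0.5, 0.3, 0.2), rep(1, 96), 3000,
                      seed = 40 + g)))
  ex <- extract_signatures(spectra, n_denovo = 0, fixed_signatures = sigs,
                           seed = 1, restarts = 1)
  per_row <- t(sapply(1:4, function(g)
    fit_exposures(spectra[g, ], sigs)$exposures))
  expect_equal(unname(ex$exposures), unname(per_row), tolerance = 1e-3)
  # permuting input rows permutes exposures, signatures unchanged
  ex2 <- extract_signatures(spectra[c(3, 1, 2, 4), ], n_denovo = 0,
                            fixed_signatures = sigs, seed = 1, restarts = 1)
  expect_equal(unname(ex2$exposures), unname(ex$exposures[c(3, 1, 2, 4), ]),
               tolerance = 1e-3)
  expect_equal(ex2$signatures, ex$signatures)
  expect_error(extract_signatures(spectra, 0), "no signatures")
})

test_that("signature-presence LRT: null statistic vanishes when the base set
           explains the spectrum, and a planted signature is detected", {
  refs <- reference_signatures()
  base <- refs[, c("SBS1", "SBS5", "SBS18", "SBS34")]
  cand <- refs[, "SBS88"]
  exact <- t(replicate(3, round(as.vector(base %*% c(.4, .3, .2, .1)) * 1e5)))
  res0 <- lrt_signature_presence(exact, base, cand)
  expect_true(all(res0$statistic < 1e-3))
  expect_true(all(!res0$positive))
  # 20% planted candidate contribution at n = 5000 is detected
  mix <- cbind(base, cand)
  planted <- t(sapply(1:3, function(g)
    simulate_spectrum(mix, c(.3, .25, .15, .1, .2), rep(1, 96), 5000,
                      seed = g)))
  res1 <- lrt_signature_presence(planted, base, cand)
  expect_true(all(res1$positive))
  expect_true(all(res1$q >= res1$p - 1e-12))
})

test_that("Fisher depletion test matches enumeration and handles symmetric
           tables", {
  expect_equal(fisher_depletion_test(5, 5, 5, 5)$p, 1)
  set.seed(9)
  for (rep in 1:25) {
    a <- sample(0:12, 1); b <- sample(0:12, 1)
    c_ <- sample(0:12, 1); d <- sample(0:12, 1)
    if ((a + b) == 0 || (c_ + d) == 0) next
    expect_equal(fisher_depletion_test(a, b, c_, d)$p,
                 oracle_fisher_p(a, b, c_, d), tolerance = 1e-7)
  }
})

test_that("indel class labels cover type, length class and repeat status", {
  expect_equal(classify_indel("deletion", 3, TRUE), "del_2-4_rep")
  expect_equal(classify_indel("insertion", 1, FALSE), "ins_1_nonrep")
  expect_equal(classify_indel("deletion", 7, FALSE), "del_5+_nonrep")
  expect_error(classify_indel("dupe", 2), "type")
})

test_that("bundled synthetic catalogue is a valid set of profiles", {
  refs <- reference_signatures()
  expect_equal(dim(refs), c(96, 8))
  expect_equal(unname(colSums(refs)), rep(1, 8), tolerance = 1e-6)
  expect_true(all(refs >= 0))
  expect_equal(rownames(refs), sbs96_channels())
})
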