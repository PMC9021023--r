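# Trinucleotide mutation spectra and mutational-signature inference:
# channel classification, opportunity counting, representation conversion,
# maximum-likelihood signature fitting (EM) and joint fit-and-extract
# (ML NMF with frozen components), LRT-based tests for the presence of a
# candidate signature, and the Fisher depletion comparison.

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' The 96 substitution channels in COSMIC order
#'
#' Blocks C>A, C>G, C>T, T>A, T>C, T>G; within each block the 16 trinucleotide
#' contexts ordered by 5' then 3' base (A, C, G, T).
#' @return Character vector like "A[C>A]A".
#' @export
sbs96_channels <- function() {
  out <- character(0)
  for (ref in c("C", "T")) for (alt in setdiff(BASES, ref)) {
    for (p5 in BASES) for (p3 in BASES) {
      out <- c(out, sprintf("%s[%s>%s]%s", p5, ref, alt, p3))
    }
  }
  out
}

#' The 32 pyrimidine-strand-collapsed trinucleotide classes
#' @return Character vector like "ACA" (centre base C or T).
#' @export
trinuc32_classes <- function() {
  out <- character(0)
  for (ref in c("C", "T")) for (p5 in BASES) for (p3 in BASES) {
    out <- c(out, paste0(p5, ref, p3))
  }
  out
}

# index (1..32) of the context of each of the 96 channels
channel_context <- function() {
  ch <- sbs96_channels()
  ctx <- paste0(substr(ch, 1, 1), substr(ch, 3, 3), substr(ch, 7, 7))
  match(ctx, trinuc32_classes())
}

revcomp <- function(s) {
  vapply(strsplit(s, ""), function(x)
    paste(rev(unname(COMPLEMENT[x])), collapse = ""), "")
}

#' Classify a substitution into its 96-channel index
#'
#' Purine-reference mutations are reverse-complemented onto the pyrimidine
#' strand, so all 192 (trinucleotide, alt) inputs map two-to-one onto the 96
#' channels.
#'
#' @param context Trinucleotide string centred on the mutated base.
#' @param alt Alternate base.
#' @return Integer channel index (named by the channel label).
#' @export
classify_substitution <- function(context, alt) {
  stopifnot(nchar(context) == 3L, alt %in% BASES)
  ref <- substr(context, 2, 2)
  if (!ref %in% BASES) stop("invalid reference base: ", ref)
  if (ref == alt) stop("alt equals reference base")
  if (ref %in% c("A", "G")) {
    context <- revcomp(context)
    alt <- unname(COMPLEMENT[alt])
    ref <- substr(context, 2, 2)
  }
  label <- sprintf("%s[%s>%s]%s", substr(context, 1, 1), ref, alt,
                   substr(context, 3, 3))
  idx <- match(label, sbs96_channels())
  names(idx) <- label
  idx
}

#' Trinucleotide opportunities of analysable regions
#'
#' Counts every trinucleotide wholly inside the regions, collapsed onto the
#' pyrimidine strand; windows containing N are skipped.
#'
#' @param reference Named character vector or \code{Biostrings::DNAStringSet}.
#' @param regions data.frame(contig, start, end), 0-based half-open.
#' @return Named 32-element count vector (pyrimidine-strand classes).
#' @export
trinucleotide_opportunities <- function(reference, regions) {
  if (nrow(regions) == 0) stop("empty region set")
  seqs <- if (inherits(reference, "DNAStringSet"))
    reference else Biostrings::DNAStringSet(unlist(reference))
  counts <- stats::setNames(numeric(32), trinuc32_classes())
  cls <- trinuc32_classes()
  for (i in seq_len(nrow(regions))) {
    ctg <- regions$contig[i]
    if (!ctg %in% names(seqs)) stop("unknown contig: ", ctg)
    sub <- Biostrings::subseq(seqs[[ctg]], regions$start[i] + 1, regions$end[i])
    if (length(sub) < 3) next
    tf <- Biostrings::trinucleotideFrequency(sub)
    for (k in names(tf)) {
      if (tf[[k]] == 0 || grepl("[^ACGT]", k)) next
      key <- if (substr(k, 2, 2) %in% c("C", "T")) k else revcomp(k)
      counts[key] <- counts[key] + tf[[k]]
    }
  }
  counts[cls]
}

# Accept a 32- or 96-element opportunity vector; return length 96.
expand_opportunities <- function(opp) {
  if (is.null(opp)) return(rep(1, 96))
  if (length(opp) == 96) return(as.numeric(opp))
  if (length(opp) == 32) return(as.numeric(opp)[channel_context()])
  stop("opportunities must have length 32 or 96")
}

#' Convert a signature between opportunity representations
#'
#' Multiplies each channel by the (target / source) opportunity ratio and
#' renormalizes; converting with equal opportunity vectors is the identity,
#' and A -> B -> A round trips restore the original profile.
#'
#' @param profile 96-element probability vector.
#' @param from_opps,to_opps Opportunity vectors (length 32 or 96) of the
#'   source and target representations.
#' @return 96-element probability vector.
#' @export
convert_signature <- function(profile, from_opps, to_opps) {
  stopifnot(length(profile) == 96)
  fo <- expand_opportunities(from_opps)
  to <- expand_opportunities(to_opps)
  if (any(fo <= 0)) stop("source opportunities must be strictly positive")
  p <- profile * (to / sum(to)) / (fo / sum(fo))
  p / sum(p)
}

#' Cosine similarity between two non-negative profiles
#' @param p,q Numeric vectors.
#' @return Value in [0, 1] (for non-negative inputs).
#' @export
cosine_similarity <- function(p, q) {
  stopifnot(length(p) == length(q))
  np <- sqrt(sum(p^2)); nq <- sqrt(sum(q^2))
  if (np == 0 || nq == 0) return(0)
  sum(p * q) / (np * nq)
}

# effective channel distributions of genome-independent signatures under an
# opportunity vector: q_sc proportional to S_sc * O_c, columns of a 96 x S
# matrix, each summing to 1.
effective_signatures <- function(signatures, opportunities) {
  sig <- as.matrix(signatures)
  opp <- expand_opportunities(opportunities)
  q <- sig * opp
  sweep(q, 2, colSums(q), "/")
}

#' Fit signature exposures to a spectrum by maximum likelihood
#'
#' Maximizes the multinomial log-likelihood of the 96-channel counts under
#' an exposure-weighted mixture of the signatures via EM multiplicative
#' updates; deterministic from a uniform initialization.
#'
#' @param spectrum 96-element count vector.
#' @param signatures 96 x S matrix of signature profiles. If
#'   \code{opportunities} is supplied the profiles are taken as
#'   genome-independent and adjusted to the spectrum's regime first.
#' @param opportunities Optional opportunity vector (length 32 or 96).
#' @param tol Convergence tolerance on the log-likelihood increase.
#' @param max_iter Maximum EM iterations.
#' @return Object of class "signature_fit": exposure fractions and counts,
#'   loglik, fitted spectrum and reconstruction cosine similarity.
#' @export
fit_exposures <- function(spectrum, signatures, opportunities = NULL,
                          tol = 1e-8, max_iter = 5000L) {
  x <- as.numeric(spectrum)
  stopifnot(length(x) == 96, all(x >= 0))
  q <- effective_signatures(signatures, opportunities)
  S <- ncol(q)
  n <- sum(x)
  if (n == 0) {
    e <- rep(0, S)
    return(structure(list(exposures = e, exposure_counts = e, loglik = 0,
                          fitted = rep(0, 96), reconstruction_cosine = NA_real_),
                     class = "signature_fit"))
  }
  e <- rep(1 / S, S)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    p <- as.vector(q %*% e)
    ll <- sum(x[x > 0] * log(p[x > 0]))
    if (ll - ll_old < tol && it > 1) break
    ll_old <- ll
    # E-step responsibilities folded into the multiplicative update
    e <- e * as.vector(t(q) %*% (x / pmax(p, 1e-300))) / n
    e <- pmax(e, 0)
    e <- e / sum(e)
  }
  fitted <- as.vector(q %*% e) * n
  structure(list(
    exposures = stats::setNames(e, colnames(q)),
    exposure_counts = stats::setNames(e * n, colnames(q)),
    loglik = ll_old,
    fitted = fitted,
    reconstruction_cosine = cosine_similarity(x, fitted)
  ), class = "signature_fit")
}

#' @export
print.signature_fit <- function(x, ...) {
  cat("Signature fit (loglik", format(x$loglik, digits = 8), ")\n")
  print(round(x$exposures, 4))
  invisible(x)
}

#' @export
coef.signature_fit <- function(object, ...) object$exposures

#' Joint signature fitting and extraction by maximum-likelihood NMF
#'
#' Alternating EM (multiplicative KL/NMF) updates of exposures and de novo
#' signatures; fixed signatures (supplied in genome-independent
#' representation) are frozen and only their exposures are updated.
#' Opportunities are applied per spectrum row. Multiple seeded restarts
#' keep the best log-likelihood. With \code{n_denovo = 0} the result
#' reduces to per-row \code{\link{fit_exposures}}.
#'
#' @param spectra G x 96 matrix of counts (rows = samples/species).
#' @param n_denovo Number of signatures to extract de novo.
#' @param fixed_signatures Optional 96 x F matrix of frozen profiles
#'   (genome-independent representation).
#' @param opportunities NULL, a single opportunity vector, or a G x 32 /
#'   G x 96 matrix of per-row opportunities.
#' @param seed Integer seed for the restarts.
#' @param restarts Number of random restarts.
#' @param tol,max_iter EM controls.
#' @return Object of class "signature_extraction": \code{signatures}
#'   (96 x (F + n_denovo), genome-independent, columns sum to 1),
#'   \code{exposures} (G x S fractions), \code{loglik}.
#' @export
extract_signatures <- function(spectra, n_denovo, fixed_signatures = NULL,
                               opportunities = NULL, seed = 1L,
                               restarts = 5L, tol = 1e-6, max_iter = 2000L) {
  X <- as.matrix(spectra)
  stopifnot(ncol(X) == 96, n_denovo >= 0)
  G <- nrow(X)
  n_fixed <- if (is.null(fixed_signatures)) 0L else ncol(fixed_signatures)
  S <- n_fixed + n_denovo
  if (S == 0) stop("no signatures to fit or extract")
  O <- if (is.null(opportunities)) {
    matrix(1, G, 96)
  } else if (is.matrix(opportunities)) {
    t(apply(opportunities, 1, expand_opportunities))
  } else {
    matrix(expand_opportunities(opportunities), G, 96, byrow = TRUE)
  }

  mult_loglik <- function(W, H) {
    lam <- (W %*% H) * O
    p <- lam / pmax(rowSums(lam), 1e-300)
    sum(X[X > 0] * log(pmax(p[X > 0], 1e-300)))
  }

  run_once <- function(H0) {
    H <- H0                       # S x 96, rows are signatures
    W <- matrix(rowSums(X) / S, G, S)  # exposures on count scale
    ll_old <- -Inf
    free <- seq_len(S) > n_fixed
    for (it in seq_len(max_iter)) {
      lam <- pmax((W %*% H) * O, 1e-300)
      R <- X / lam
      W <- W * ((R * O) %*% t(H)) / pmax(O %*% t(H), 1e-300)
      lam <- pmax((W %*% H) * O, 1e-300)
      R <- X / lam
      if (any(free)) {
        num <- t(W[, free, drop = FALSE]) %*% (R * O)
        den <- t(W[, free, drop = FALSE]) %*% O
        H[free, ] <- H[free, , drop = FALSE] * num / pmax(den, 1e-300)
        sc <- rowSums(H[free, , drop = FALSE])
        H[free, ] <- H[free, , drop = FALSE] / sc
        W[, free] <- sweep(W[, free, drop = FALSE], 2, sc, "*")
      }
      if (it %% 10 == 0 || it == max_iter) {
        ll <- mult_loglik(W, H)
        if (ll - ll_old < tol && it > 10) break
        ll_old <- ll
      }
    }
    list(W = W, H = H, loglik = mult_loglik(W, H))
  }

  best <- NULL
  with_seed(seed, {
    for (r in seq_len(max(1L, restarts))) {
      H0 <- matrix(0, S, 96)
      if (n_fixed > 0) H0[seq_len(n_fixed), ] <- t(as.matrix(fixed_signatures))
      if (n_denovo > 0) {
        for (s in (n_fixed + seq_len(n_denovo))) {
          H0[s, ] <- if (r == 1) rep(1 / 96, 96) else rdirichlet1(rep(1, 96))
        }
      }
      fit <- run_once(H0)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  })
  # exposure fractions: share of each row's counts attributed to each signature
  lam_s <- lapply(seq_len(S), function(s)
    (best$W[, s, drop = FALSE] %*% best$H[s, , drop = FALSE]) * O)
  lam <- Reduce(`+`, lam_s)
  expo <- vapply(lam_s, function(l)
    rowSums(X * l / pmax(lam, 1e-300)), numeric(G))
  expo <- matrix(expo, G, S)
  expo <- expo / pmax(rowSums(expo), 1e-300)
  sig_names <- c(if (n_fixed > 0) colnames(fixed_signatures)[seq_len(n_fixed)],
                 if (n_denovo > 0) paste0("denovo", seq_len(n_denovo)))
  if (is.null(sig_names)) sig_names <- paste0("sig", seq_len(S))
  sig_names[is.na(sig_names) | sig_names == ""] <-
    paste0("sig", which(is.na(sig_names) | sig_names == ""))
  sigs <- t(best$H)
  colnames(sigs) <- sig_names
  rownames(sigs) <- sbs96_channels()
  colnames(expo) <- sig_names
  structure(list(signatures = sigs, exposures = expo, loglik = best$loglik,
                 n_denovo = n_denovo, n_fixed = n_fixed),
            class = "signature_extraction")
}

#' @export
print.signature_extraction <- function(x, ...) {
  cat(sprintf("Signature extraction: %d fixed + %d de novo, loglik %.2f\n",
              x$n_fixed, x$n_denovo, x$loglik))
  invisible(x)
}

#' Likelihood-ratio test for the presence of a candidate signature
#'
#' For each spectrum, compares the maximized multinomial log-likelihood of
#' a base signature set against the base set plus the candidate signature;
#' the statistic 2 (loglik_ext - loglik_base) is referred to chi-square with
#' 1 df (conservative, since the exposure is boundary-constrained at 0), and
#' Benjamini-Hochberg correction is applied across samples.
#'
#' @param spectra G x 96 count matrix.
#' @param base_signatures 96 x B matrix.
#' @param candidate_signature 96-element profile.
#' @param opportunities Optional opportunity vector or per-row matrix.
#' @param q_threshold Significance level on the BH-adjusted q-values.
#' @return data.frame: loglik_base, loglik_ext, statistic, p, q, positive.
#' @export
lrt_signature_presence <- function(spectra, base_signatures,
                                   candidate_signature,
                                   opportunities = NULL,
                                   q_threshold = 0.05) {
  X <- as.matrix(spectra)
  G <- nrow(X)
  opp_row <- function(g) {
    if (is.null(opportunities)) NULL
    else if (is.matrix(opportunities)) opportunities[g, ]
    else opportunities
  }
  ext_sigs <- cbind(base_signatures, candidate = candidate_signature)
  res <- vapply(seq_len(G), function(g) {
    f0 <- fit_exposures(X[g, ], base_signatures, opp_row(g))
    f1 <- fit_exposures(X[g, ], ext_sigs, opp_row(g))
    c(f0$loglik, f1$loglik)
  }, numeric(2))
  stat <- pmax(2 * (res[2, ] - res[1, ]), 0)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  data.frame(loglik_base = res[1, ], loglik_ext = res[2, ],
             statistic = stat, p = p, q = q, positive = q < q_threshold)
}

#' Fisher exact test for signature depletion between two cohorts
#'
#' Two-sided exact test on the 2 x 2 table of signature-positive /
#' signature-negative sample counts.
#'
#' @param pos_a,neg_a Positive and negative counts in cohort A.
#' @param pos_b,neg_b Positive and negative counts in cohort B.
#' @return list(p, estimate, table).
#' @export
fisher_depletion_test <- function(pos_a, neg_a, pos_b, neg_b) {
  tab <- matrix(c(pos_a, pos_b, neg_a, neg_b), 2, 2,
                dimnames = list(cohort = c("A", "B"),
                                status = c("positive", "negative")))
  ft <- stats::fisher.test(tab)
  list(p = ft$p.value, estimate = unname(ft$estimate), table = tab)
}

#' Minimal indel class labels for summary spectra
#'
#' @param type "insertion" or "deletion".
#' @param length Indel length in bp.
#' @param at_repeat Whether the indel lies in a repeat tract.
#' @return Class label like "del_2-4_rep".
#' @export
classify_indel <- function(type, length, at_repeat = FALSE) {
  stopifnot(type %in% c("insertion", "deletion"), length >= 1)
  len_cl <- if (length == 1) "1" else if (length <= 4) "2-4" else "5+"
  sprintf("%s_%s_%s", substr(type, 1, 3), len_cl,
          if (at_repeat) "rep" else "nonrep")
}

#' Bundled synthetic reference signature profiles
#'
#' Loads the package's synthetic stand-in substitution signature catalogue
#' (see \code{inst/extdata/signatures_synthetic.tsv}). These profiles mimic
#' the qualitative channel structure of well-known COSMIC signatures (SBS1:
#' C>T at NCG; SBS2/13: C>T / C>G at TCN; SBS5/40: flat clock-like; SBS18:
#' C>A; SBS34: T>A; SBS88: characteristic T>C/T>N pattern) but are
#' synthetic constructions, not the COSMIC catalogue; use them for method
#' development and testing only.
#'
#' @return 96 x 8 matrix, columns named after the signature each stand-in
#'   mimics, each column summing to 1.
#' @export
reference_signatures <- function() {
  path <- system.file("extdata", "signatures_synthetic.tsv",
                      package = "cryptclock")
  x <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  as.matrix(x)
}

#' Barplot of a 96-channel spectrum
#'
#' @param spectrum 96-element count or probability vector.
#' @param main Plot title.
#' @export
plot_spectrum96 <- function(spectrum, main = "") {
  cols <- rep(c("#03BCEE", "#010101", "#E32926", "#CAC9C9", "#A1CE63",
                "#EBC6C4"), each = 16)
  graphics::barplot(as.numeric(spectrum), col = cols, border = NA,
                    names.arg = rep("", 96), main = main,
                    ylab = "count / probability")
  invisible(NULL)
}
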