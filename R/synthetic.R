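# Synthetic multi-species crypt cohorts with full ground-truth bookkeeping.
#
# The generator emulates the statistical structure the downstream stages
# assume: clonal (or polyclonal) crypts accumulating mutations linearly with
# age at a species rate k/L, binomial read sampling at ~30x depth, artifact
# sites shared across an individual's samples, Gompertz mortality records and
# binned coverage/BAF tracks with injected copy-number events.

#' Build a simulation configuration
#'
#' Defaults encode the study conditions the rest of the package is tested
#' against: 16 species spanning lifespans of 3-85 years and masses of
#' 20 g - 800 kg, three individuals per species, three crypts per individual,
#' negative-binomial sequencing depth with mean 30, a true end-of-lifespan
#' burden of k = 3000 substitutions per genome, and one artifact site per
#' true mutation.
#'
#' @param n_species,individuals_per_species,crypts_per_individual Cohort design.
#' @param mean_depth,depth_dispersion Negative-binomial depth model
#'   (mean and size parameter).
#' @param artifact_rate Expected artifact sites per true mutation, shared
#'   across all samples of an individual.
#' @param seed Master seed; all generators draw from named substreams of it.
#' @param k True end-of-lifespan burden (substitutions per genome).
#' @param elb_sdlog Species-level lognormal deviation of the true ELB
#'   around \code{k} (0 = all species share \code{k} exactly).
#' @param lifespan_range,mass_range Log-uniform sampling ranges for species
#'   lifespan (years) and adult mass (grams).
#' @param mass_lifespan_cor Correlation between log-mass and log-lifespan
#'   (0 = independent).
#' @param n_contigs,contig_length Synthetic genome map.
#' @param fraction_clustered Fraction of true variants placed in 1-kb clusters
#'   (0 = rejection-sampled to be at least 1 kb apart).
#' @param artifact_vaf_range Uniform range of per-site artifact VAFs.
#' @param min_alt Minimum alt reads for a site to be emitted as a candidate
#'   variant (the caller's detection threshold).
#' @param indel_fraction Fraction of true variants labelled as indels.
#' @param polyclonal_fraction Fraction of crypts simulated as polyclonal
#'   (two low-VAF clusters instead of one clonal cluster).
#' @param clonal_vaf Cluster VAF of clonal crypts.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_species = 16L, individuals_per_species = 3L,
                       crypts_per_individual = 3L, mean_depth = 30,
                       depth_dispersion = 30, artifact_rate = 1,
                       seed = 1L, k = 3000, elb_sdlog = 0,
                       lifespan_range = c(3, 85),
                       mass_range = c(20, 8e5),
                       mass_lifespan_cor = 0,
                       n_contigs = 10L, contig_length = 1e7,
                       fraction_clustered = 0,
                       artifact_vaf_range = c(0.05, 0.30),
                       min_alt = 4L, indel_fraction = 0.1,
                       polyclonal_fraction = 0, clonal_vaf = 0.5) {
  cfg <- list(
    n_species = as.integer(n_species),
    individuals_per_species = as.integer(individuals_per_species),
    crypts_per_individual = as.integer(crypts_per_individual),
    mean_depth = mean_depth, depth_dispersion = depth_dispersion,
    artifact_rate = artifact_rate, seed = as.integer(seed),
    k = k, elb_sdlog = elb_sdlog,
    lifespan_range = lifespan_range, mass_range = mass_range,
    mass_lifespan_cor = mass_lifespan_cor,
    n_contigs = as.integer(n_contigs), contig_length = contig_length,
    fraction_clustered = fraction_clustered,
    artifact_vaf_range = artifact_vaf_range,
    min_alt = as.integer(min_alt), indel_fraction = indel_fraction,
    polyclonal_fraction = polyclonal_fraction, clonal_vaf = clonal_vaf
  )
  check_positive(cfg$n_species, "n_species")
  check_positive(cfg$individuals_per_species, "individuals_per_species")
  check_positive(cfg$crypts_per_individual, "crypts_per_individual")
  check_positive(cfg$mean_depth, "mean_depth")
  check_positive(cfg$depth_dispersion, "depth_dispersion")
  check_positive(cfg$k, "k")
  check_positive(cfg$contig_length, "contig_length")
  if (cfg$artifact_rate < 0) stop("'artifact_rate' must be non-negative")
  if (cfg$elb_sdlog < 0) stop("'elb_sdlog' must be non-negative")
  if (cfg$mass_lifespan_cor < -1 || cfg$mass_lifespan_cor > 1) {
    stop("'mass_lifespan_cor' must lie in [-1, 1]")
  }
  class(cfg) <- "sim_config"
  cfg
}

sim_contigs <- function(config) {
  data.frame(contig = sprintf("chrS%02d", seq_len(config$n_contigs)),
             length = rep(config$contig_length, config$n_contigs),
             stringsAsFactors = FALSE)
}

#' Simulate a multi-species cohort of crypts with ground truth
#'
#' Species lifespans and masses are drawn log-uniformly (optionally
#' correlated), each species carries a true end-of-lifespan burden
#' (\code{k}, optionally with species-level lognormal deviation), individual
#' ages are uniform on (0.1 L, L), and each crypt's true mutation count is
#' Poisson with mean (ELB / L) * age.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A list with \code{species} (one row per species: name, lifespan,
#'   mass, true ELB, genome size, signature exposures, trinucleotide
#'   frequencies as a list column), and \code{crypts} (one row per crypt:
#'   ids, age, true mutation count, clonality flag, VAF clusters as a list
#'   column, artifact-site count).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(substream_seed(config$seed, "cohort"), {
    ns <- config$n_species
    z1 <- stats::rnorm(ns); z2 <- stats::rnorm(ns)
    r <- config$mass_lifespan_cor
    zmass <- r * z1 + sqrt(1 - r^2) * z2
    lr <- log(config$lifespan_range); mr <- log(config$mass_range)
    lifespan <- exp(lr[1] + (lr[2] - lr[1]) * stats::pnorm(z1))
    mass <- exp(mr[1] + (mr[2] - mr[1]) * stats::pnorm(zmass))
    elb <- config$k * stats::rlnorm(ns, -config$elb_sdlog^2 / 2, config$elb_sdlog)
    species <- data.frame(
      name = sprintf("sp%02d", seq_len(ns)),
      lifespan_true = lifespan, adult_mass = mass, true_elb = elb,
      genome_size = config$n_contigs * config$contig_length,
      stringsAsFactors = FALSE
    )
    # wide inter-species contrast in signature activity, as seen in real
    # cohorts (species near-dominated by single processes)
    species$signature_exposures <- lapply(seq_len(ns), function(i)
      rdirichlet1(c(1.2, 1.2, 0.8)))
    species$trinuc_freqs <- lapply(seq_len(ns), function(i)
      rdirichlet1(rep(10, 32)))

    rows <- list()
    for (s in seq_len(ns)) {
      for (ind in seq_len(config$individuals_per_species)) {
        age <- stats::runif(1, 0.1 * lifespan[s], lifespan[s])
        ind_id <- sprintf("%s_i%d", species$name[s], ind)
        for (cr in seq_len(config$crypts_per_individual)) {
          n_true <- stats::rpois(1, elb[s] / lifespan[s] * age)
          poly <- stats::runif(1) < config$polyclonal_fraction
          clusters <- if (poly) {
            data.frame(vaf = c(0.20, 0.10), weight = c(0.6, 0.4))
          } else {
            data.frame(vaf = config$clonal_vaf, weight = 1)
          }
          rows[[length(rows) + 1L]] <- data.frame(
            crypt_id = sprintf("%s_c%d", ind_id, cr),
            individual_id = ind_id, species = species$name[s],
            age = age, n_true_mutations = n_true,
            is_clonal = !poly, stringsAsFactors = FALSE
          )
          attr(rows[[length(rows)]], "clusters") <- clusters
        }
      }
    }
    crypts <- do.call(rbind, rows)
    crypts$clusters <- lapply(rows, attr, "clusters")
    # artifact sites are an individual-level process
    n_art <- tapply(crypts$n_true_mutations, crypts$individual_id, mean)
    crypts$n_artifacts <- stats::rpois(
      length(n_art), config$artifact_rate * n_art
    )[match(crypts$individual_id, names(n_art))]
    rownames(crypts) <- NULL
    list(species = species, crypts = crypts, config = config)
  })
}

# Sample variant positions on the synthetic contig map. When
# fraction_clustered = 0, positions are rejection-sampled so that no two
# variants of the set fall within 1 kb on the same contig.
sample_positions <- function(n, contigs, fraction_clustered = 0) {
  if (n == 0L) {
    return(data.frame(contig = character(0), pos = integer(0)))
  }
  n_clustered <- round(n * fraction_clustered)
  n_free <- n - n_clustered
  idx <- sample.int(nrow(contigs), n_free, replace = TRUE)
  pos <- as.integer(ceiling(stats::runif(n_free) * (contigs$length[idx] - 2000))) + 1000L
  contig <- contigs$contig[idx]
  # enforce >1 kb spacing among the unclustered set
  repeat {
    o <- order(contig, pos)
    bad <- o[which(contig[o][-1] == contig[o][-n_free] &
                     diff(pos[o]) <= 1000) + 1L]
    if (length(bad) == 0L || n_free <= 1L) break
    idx2 <- sample.int(nrow(contigs), length(bad), replace = TRUE)
    pos[bad] <- as.integer(ceiling(stats::runif(length(bad)) *
                                     (contigs$length[idx2] - 2000))) + 1000L
    contig[bad] <- contigs$contig[idx2]
  }
  out <- data.frame(contig = contig, pos = pos, stringsAsFactors = FALSE)
  if (n_clustered > 0L) {
    n_pairs <- ceiling(n_clustered / 2)
    idx <- sample.int(nrow(contigs), n_pairs, replace = TRUE)
    anchor <- as.integer(ceiling(stats::runif(n_pairs) *
                                   (contigs$length[idx] - 4000))) + 2000L
    offs <- sample.int(1000L, n_pairs, replace = TRUE)
    cl <- data.frame(contig = rep(contigs$contig[idx], each = 2),
                     pos = as.vector(rbind(anchor, anchor + offs)),
                     stringsAsFactors = FALSE)
    out <- rbind(out, cl[seq_len(n_clustered), ])
  }
  out
}

rdepth <- function(n, config) {
  d <- stats::rnbinom(n, mu = config$mean_depth, size = config$depth_dispersion)
  while (any(d == 0L)) {
    d[d == 0L] <- stats::rnbinom(sum(d == 0L), mu = config$mean_depth,
                                 size = config$depth_dispersion)
  }
  d
}

# Per-individual artifact sites, regenerated deterministically from the
# individual's substream so every sibling crypt sees the same sites.
artifact_sites <- function(individual_id, cohort) {
  config <- cohort$config
  crypts <- cohort$crypts[cohort$crypts$individual_id == individual_id, ]
  n_sites <- crypts$n_artifacts[1]
  samples <- crypts$crypt_id
  with_seed(substream_seed(config$seed, paste0("artifacts:", individual_id)), {
    contigs <- sim_contigs(config)
    posn <- sample_positions(n_sites, contigs, fraction_clustered = 0)
    if (n_sites == 0L) {
      return(list(sites = posn, alt = matrix(0L, 0, length(samples)),
                  depth = matrix(0L, 0, length(samples)), samples = samples))
    }
    vaf <- stats::runif(n_sites, config$artifact_vaf_range[1],
                        config$artifact_vaf_range[2])
    depth <- matrix(rdepth(n_sites * length(samples), config),
                    nrow = n_sites)
    alt <- matrix(stats::rbinom(length(depth), as.vector(depth),
                                rep(vaf, length(samples))),
                  nrow = n_sites)
    ref <- sample(c("A", "C", "G", "T"), n_sites, replace = TRUE)
    alt_base <- vapply(ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
    list(sites = cbind(posn, ref = ref, alt = alt_base, vaf = vaf),
         alt = alt, depth = depth, samples = samples)
  })
}

#' Simulate the candidate-variant table of one crypt
#'
#' True variants are private to the crypt (binomial alt counts at their VAF
#' cluster in the focal sample, zero expected alt reads in sibling samples);
#' artifact variants are site-level processes shared across all of the
#' individual's samples with low per-site VAFs. A site is emitted as a
#' candidate when its focal alt count reaches the caller's detection
#' threshold (\code{config$min_alt}).
#'
#' @param crypt_id Focal crypt.
#' @param cohort Output of \code{\link{simulate_cohort}}.
#' @param config Optional override of \code{cohort$config}.
#' @return A data.frame of candidate variants with read-level annotation
#'   fields, a \code{cross_sample} list column of per-sample (alt, depth)
#'   tables over all the individual's samples, and a truth label
#'   \code{is_artifact}.
#' @export
simulate_variant_table <- function(crypt_id, cohort, config = cohort$config) {
  crypts <- cohort$crypts
  row <- crypts[crypts$crypt_id == crypt_id, ]
  if (nrow(row) != 1L) stop("unknown crypt_id: ", crypt_id)
  siblings <- crypts$crypt_id[crypts$individual_id == row$individual_id]
  art <- artifact_sites(row$individual_id, cohort)

  with_seed(substream_seed(config$seed, paste0("variants:", crypt_id)), {
    contigs <- sim_contigs(config)
    n_true <- row$n_true_mutations
    clusters <- row$clusters[[1]]
    posn <- sample_positions(n_true, contigs, config$fraction_clustered)
    cl_idx <- sample.int(nrow(clusters), n_true, replace = TRUE,
                         prob = clusters$weight)
    true_vaf <- clusters$vaf[cl_idx]
    depth_true <- matrix(rdepth(n_true * length(siblings), config),
                         nrow = max(n_true, 0))
    focal <- match(crypt_id, siblings)
    alt_true <- matrix(0L, n_true, length(siblings))
    if (n_true > 0) {
      alt_true[, focal] <- stats::rbinom(n_true, depth_true[, focal], true_vaf)
    }
    ref <- sample(c("A", "C", "G", "T"), n_true, replace = TRUE)
    alt_base <- vapply(ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1), "")

    build <- function(sites, alt_mat, depth_mat, is_artifact) {
      keep <- which(alt_mat[, focal] >= config$min_alt &
                      depth_mat[, focal] > 0)
      n <- length(keep)
      if (n == 0L) return(NULL)
      alt_count <- alt_mat[keep, focal]
      depth <- depth_mat[keep, focal]
      fwd <- stats::rbinom(n, alt_count, 0.5)
      df <- data.frame(
        contig = sites$contig[keep], pos = sites$pos[keep],
        ref = sites$ref[keep], alt = sites$alt[keep],
        var_class = ifelse(stats::runif(n) < config$indel_fraction,
                           "indel", "substitution"),
        alt_count = alt_count, depth = depth, vaf = alt_count / depth,
        clipped_fraction = stats::rbeta(n, 1, 40),
        hq_fragments = alt_count,
        secondary_gt_primary = FALSE,
        fwd_alt = fwd, rev_alt = alt_count - fwd,
        nearby_indel_reads = ifelse(stats::runif(n) < 0.95, 0L,
                                    stats::rpois(n, 1)),
        caller_flag = "PASS",
        is_artifact = is_artifact,
        stringsAsFactors = FALSE
      )
      df$cross_sample <- lapply(keep, function(i) data.frame(
        sample = siblings, alt = alt_mat[i, ], depth = depth_mat[i, ],
        stringsAsFactors = FALSE))
      df
    }
    sites_true <- cbind(posn, ref = ref, alt = alt_base)
    out <- rbind(
      build(sites_true, alt_true, depth_true, FALSE),
      if (nrow(art$sites) > 0) build(art$sites, art$alt, art$depth, TRUE)
    )
    if (is.null(out)) return(out)
    out$crypt_id <- crypt_id
    out$individual_id <- row$individual_id
    out$species <- row$species
    rownames(out) <- NULL
    out
  })
}

#' Draw a 96-channel mutation spectrum from a signature mixture
#'
#' Channel probabilities are the exposure-weighted mixture of the signature
#' profiles (genome-independent representation), reweighted by the
#' mutational opportunities and renormalized; counts are one multinomial
#' draw of size \code{n}.
#'
#' @param signatures 96 x S matrix of signature profiles (columns sum to 1).
#' @param exposures Length-S simplex vector.
#' @param opportunities Length-96 (or length-32, expanded by context) vector
#'   of trinucleotide opportunities.
#' @param n Number of mutations to draw.
#' @param seed Integer seed.
#' @return Named integer vector of 96 channel counts summing to \code{n}.
#' @export
simulate_spectrum <- function(signatures, exposures, opportunities, n, seed = 1L) {
  signatures <- as.matrix(signatures)
  stopifnot(nrow(signatures) == 96L, length(exposures) == ncol(signatures))
  if (any(exposures < 0)) stop("exposures must be non-negative")
  if (abs(sum(exposures) - 1) > 1e-6) stop("exposures must sum to 1")
  opp <- expand_opportunities(opportunities)
  p <- as.vector(signatures %*% exposures) * opp
  if (any(p[as.vector(signatures %*% exposures) > 0] == 0) && any(opp == 0)) {
    warning("zero-opportunity channels carry signature mass; renormalizing")
  }
  if (sum(p) <= 0) stop("degenerate mixture: all channel probabilities zero")
  p <- p / sum(p)
  counts <- if (n == 0) integer(96) else
    with_seed(seed, as.integer(stats::rmultinom(1, n, p)))
  names(counts) <- sbs96_channels()
  counts
}

#' Simulate Gompertz mortality records left-truncated at maturity
#'
#' @param n Number of animals.
#' @param shape,rate Gompertz shape (per year) and rate parameters.
#' @param maturity_age Left-truncation age (years); only adult deaths are
#'   recorded.
#' @param seed Integer seed.
#' @return A data.frame with column \code{age} (years at death).
#' @export
simulate_mortality <- function(n, shape, rate, maturity_age = 0, seed = 1L) {
  stopifnot(n >= 1)
  with_seed(seed, {
    p0 <- flexsurv::pgompertz(maturity_age, shape = shape, rate = rate)
    u <- stats::runif(n, p0, 1)
    data.frame(age = flexsurv::qgompertz(u, shape = shape, rate = rate))
  })
}

#' Simulate binned coverage-ratio and SNP BAF tracks with CN events
#'
#' Diploid background everywhere except the supplied events; per-bin sample
#' and normal read counts are negative binomial, with the sample mean scaled
#' by total CN / 2 (mixed with normal cells at the given purity);
#' heterozygous-SNP alt counts are beta-binomial around the allele fraction
#' implied by (major, minor, purity).
#'
#' @param n_bins Number of 100-kb bins.
#' @param events data.frame with columns start, end (bin indices, inclusive),
#'   major, minor; events must not overlap and CN values must lie in 0-4.
#' @param purity Fraction of aberrant cells in (0, 1].
#' @param seed Integer seed.
#' @param baseline Mean reads per bin in the normal.
#' @param nb_size Negative-binomial size of per-bin read counts.
#' @param snps_per_bin Mean heterozygous SNPs per bin (Poisson).
#' @param snp_depth Mean SNP depth.
#' @param bb_rho Beta-binomial overdispersion of SNP alt counts.
#' @return list(bins, snps): per-bin coverage ratios with true states, and
#'   per-SNP (bin, alt, depth) counts.
#' @export
simulate_cn_tracks <- function(n_bins, events = NULL, purity = 1, seed = 1L,
                               baseline = 100, nb_size = 80,
                               snps_per_bin = 2, snp_depth = 30,
                               bb_rho = 0.01) {
  major <- rep(1L, n_bins); minor <- rep(1L, n_bins)
  if (!is.null(events) && nrow(events) > 0) {
    if (any(events$major < 0 | events$major > 4 |
              events$minor < 0 | events$minor > 4)) {
      stop("copy numbers outside 0-4 are not supported")
    }
    if (any(events$major < events$minor)) stop("major CN must be >= minor CN")
    hit <- unlist(lapply(seq_len(nrow(events)), function(i)
      events$start[i]:events$end[i]))
    if (anyDuplicated(hit)) stop("events must not overlap")
    for (i in seq_len(nrow(events))) {
      span <- events$start[i]:events$end[i]
      major[span] <- events$major[i]; minor[span] <- events$minor[i]
    }
  }
  total <- major + minor
  r_exp <- (purity * total + (1 - purity) * 2) / 2
  f_exp <- (purity * major + (1 - purity)) /
    pmax(purity * total + (1 - purity) * 2, 1e-12)
  with_seed(seed, {
    reads_normal <- stats::rnbinom(n_bins, mu = baseline, size = nb_size) + 1L
    reads_sample <- stats::rnbinom(n_bins, mu = baseline * r_exp, size = nb_size)
    bins <- data.frame(
      bin = seq_len(n_bins), contig = "chrS01",
      start = (seq_len(n_bins) - 1L) * 100000L,
      reads_sample = reads_sample, reads_normal = reads_normal,
      coverage_ratio = reads_sample / reads_normal,
      true_major = major, true_minor = minor
    )
    nsnp <- stats::rpois(n_bins, snps_per_bin)
    bin_of <- rep(seq_len(n_bins), nsnp)
    depth <- stats::rnbinom(length(bin_of), mu = snp_depth, size = 30) + 15L
    f <- f_exp[bin_of]
    flip <- stats::runif(length(bin_of)) < 0.5
    f[flip] <- 1 - f[flip]
    alt <- vapply(seq_along(bin_of), function(i)
      rbetabinom(1, depth[i], f[i], bb_rho), 0L)
    snps <- data.frame(bin = bin_of, alt = alt, depth = depth)
    list(bins = bins, snps = snps)
  })
}
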