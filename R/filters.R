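# Post-calling variant filter stack: converts raw candidate variants into
# the somatic call set. Each filter is a pure partition of its input
# (pass + fail = input), and the stack records per-filter attrition.
#
# The central filter is the cross-sample beta-binomial overdispersion test:
# true somatic variants are private to one crypt (present at high VAF in
# some samples of an individual, absent in others), which makes their read
# support highly overdispersed across samples; artifacts recur at low VAF in
# all samples and look binomial. Variants whose estimated overdispersion
# rho exceeds a threshold are kept as somatic.

default_rho_grid <- function(n = 50L) 10^seq(-6, -0.05, length.out = n)

#' Estimate the cross-sample beta-binomial overdispersion of one variant
#'
#' The pooled success fraction mu is fixed at its maximum-likelihood value
#' (total alt / total depth) and the overdispersion rho is maximized over a
#' log-spaced grid of the beta-binomial log-likelihood summed over the
#' individual's samples.
#'
#' @param counts data.frame (or matrix) with columns \code{alt} and
#'   \code{depth}, one row per sample of the individual.
#' @param grid Numeric vector of candidate rho values.
#' @return list(rho, mu, loglik, grid_loglik) of class "betabinom_fit".
#' @export
estimate_rho <- function(counts, grid = default_rho_grid()) {
  counts <- as.data.frame(counts)
  stopifnot(all(c("alt", "depth") %in% names(counts)))
  if (all(counts$depth == 0)) stop("all depths are zero; rho is undefined")
  if (sum(counts$depth > 0) < 2) {
    stop("at least two samples with positive depth are required")
  }
  mu <- sum(counts$alt) / sum(counts$depth)
  if (mu <= 0 || mu >= 1) {
    warning("pooled VAF is degenerate (mu in {0,1}); rho set to grid minimum")
    return(structure(list(rho = min(grid), mu = mu, loglik = 0,
                          grid_loglik = rep(0, length(grid))),
                     class = "betabinom_fit"))
  }
  ll <- vapply(grid, function(r)
    sum(dbetabinom_log(counts$alt, counts$depth, mu, r)), 0)
  i <- which.max(ll)
  structure(list(rho = grid[i], mu = mu, loglik = ll[i], grid_loglik = ll),
            class = "betabinom_fit")
}

partition <- function(variants, keep) {
  list(pass = variants[keep, , drop = FALSE],
       fail = variants[!keep, , drop = FALSE])
}

#' @rdname filter_stack
#' @export
filter_quality_flags <- function(variants) {
  partition(variants, variants$caller_flag == "PASS")
}

#' @rdname filter_stack
#' @export
filter_alignment_quality <- function(variants) {
  is_sub <- variants$var_class == "substitution"
  drop <- variants$hq_fragments < 4 |
    (is_sub & (variants$clipped_fraction > 0.5 | variants$secondary_gt_primary))
  partition(variants, !drop)
}

#' @rdname filter_stack
#' @param sample_depths,normal_depths Depth distributions used to compute the
#'   99th-percentile caps (defaults to the focal depths of the variants).
#' @export
filter_coverage <- function(variants, sample_depths = variants$depth,
                            normal_depths = NULL) {
  cap_s <- stats::quantile(sample_depths, 0.99, type = 7, names = FALSE)
  drop <- variants$depth > cap_s | variants$depth < 10
  if (!is.null(normal_depths) && !is.null(variants$normal_depth)) {
    cap_n <- stats::quantile(normal_depths, 0.99, type = 7, names = FALSE)
    drop <- drop | variants$normal_depth > cap_n | variants$normal_depth < 10
  }
  partition(variants, !drop)
}

#' @rdname filter_stack
#' @export
filter_strand_bias <- function(variants) {
  if (any(variants$fwd_alt == 0 & variants$rev_alt == 0 &
            variants$alt_count > 0)) {
    stop("variant with alt reads but zero strand counts: invariant breach")
  }
  partition(variants, variants$fwd_alt > 0 & variants$rev_alt > 0)
}

#' @rdname filter_stack
#' @export
filter_indel_proximity <- function(variants) {
  drop <- variants$var_class == "substitution" &
    variants$nearby_indel_reads > 3 * variants$alt_count
  partition(variants, !drop)
}

#' @rdname filter_stack
#' @export
filter_spatial_clusters <- function(variants, max_dist = 1000) {
  keep <- rep(TRUE, nrow(variants))
  for (ctg in unique(variants$contig)) {
    idx <- which(variants$contig == ctg)
    if (length(idx) < 2) next
    o <- idx[order(variants$pos[idx])]
    gaps <- diff(variants$pos[o])
    # transitive clustering: adjacent sorted positions within max_dist chain
    cluster <- cumsum(c(0, gaps > max_dist))
    sizes <- table(cluster)
    keep[o] <- sizes[as.character(cluster)] < 2
  }
  partition(variants, keep)
}

#' @rdname filter_stack
#' @param rho_threshold Overdispersion above which a variant is considered a
#'   genuine somatic mutation.
#' @param grid rho grid passed to \code{\link{estimate_rho}}.
#' @export
filter_betabinomial <- function(variants, rho_threshold = 0.3,
                                grid = default_rho_grid()) {
  if (nrow(variants) == 0) return(partition(variants, logical(0)))
  n_samples <- vapply(variants$cross_sample, nrow, 0L)
  if (all(n_samples < 2)) {
    warning("single-sample individual: beta-binomial filter skipped")
    out <- partition(variants, rep(TRUE, nrow(variants)))
    out$pass$rho <- NA_real_
    return(out)
  }
  rho <- vapply(variants$cross_sample, function(cs)
    estimate_rho(cs, grid)$rho, 0)
  variants$rho <- rho
  partition(variants, rho > rho_threshold)
}

#' @rdname filter_stack
#' @param survivor_vafs VAFs of the variants passing the beta-binomial filter
#'   in the same sample; the cutoff is half their median.
#' @export
filter_min_vaf <- function(variants, survivor_vafs, factor = 0.5) {
  if (length(survivor_vafs) == 0) {
    warning("no beta-binomial survivors: minimum-VAF filter skipped")
    return(partition(variants, rep(TRUE, nrow(variants))))
  }
  cutoff <- factor * stats::median(survivor_vafs)
  partition(variants, !(variants$vaf < cutoff))
}

#' @rdname filter_stack
#' @param max_vaf Maximum indel VAF (strictly above is discarded).
#' @export
filter_max_indel_vaf <- function(variants, max_vaf = 0.9) {
  drop <- variants$var_class == "indel" & variants$vaf > max_vaf
  partition(variants, !drop)
}

#' Find tracts of >= min_n consecutive N bases in a reference
#'
#' @param reference A named character vector or \code{Biostrings::DNAStringSet}.
#' @param min_n Minimum tract length.
#' @return data.frame(contig, start, end), 1-based inclusive.
#' @export
find_n_tracts <- function(reference, min_n = 50L) {
  seqs <- if (inherits(reference, "DNAStringSet"))
    as.character(reference) else reference
  out <- lapply(names(seqs), function(nm) {
    m <- gregexpr(sprintf("N{%d,}", min_n), seqs[[nm]])[[1]]
    if (m[1] == -1) return(NULL)
    data.frame(contig = nm, start = as.integer(m),
               end = as.integer(m) + attr(m, "match.length") - 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(contig = character(0), start = integer(0),
                               end = integer(0)) else out
}

#' @rdname filter_stack
#' @param contig_lengths Named vector of contig lengths.
#' @param n_tracts data.frame(contig, start, end) of N tracts (1-based,
#'   inclusive), e.g. from \code{\link{find_n_tracts}}.
#' @param chromosomal_contigs If non-NULL, variants on contigs outside this
#'   set are discarded (chromosome-level assemblies).
#' @param sex,y_contig If \code{sex == "male"} and the Y contig is annotated,
#'   variants on it are discarded.
#' @export
filter_position_masks <- function(variants, contig_lengths,
                                  n_tracts = NULL,
                                  chromosomal_contigs = NULL,
                                  sex = NULL, y_contig = NULL) {
  len <- contig_lengths[variants$contig]
  if (any(is.na(len))) stop("variant on contig with unknown length")
  drop <- variants$pos <= 1000 | (len - variants$pos) < 1000
  if (!is.null(n_tracts) && nrow(n_tracts) > 0) {
    for (i in seq_len(nrow(n_tracts))) {
      drop <- drop | (variants$contig == n_tracts$contig[i] &
                        variants$pos >= n_tracts$start[i] - 1000 &
                        variants$pos <= n_tracts$end[i] + 1000)
    }
  }
  if (!is.null(chromosomal_contigs)) {
    drop <- drop | !(variants$contig %in% chromosomal_contigs)
  }
  if (!is.null(sex) && identical(sex, "male") && !is.null(y_contig)) {
    drop <- drop | variants$contig == y_contig
  }
  partition(variants, !drop)
}

#' Apply the full post-calling filter stack to one sample's variants
#'
#' Filters are applied in a fixed, recorded order: caller quality flags,
#' alignment quality, position masks, sequencing coverage, allelic strand
#' bias, indel proximity, spatial clustering, cross-sample beta-binomial,
#' minimum VAF (half the median VAF of beta-binomial survivors) and maximum
#' indel VAF. Only the minimum-VAF filter depends on another filter's output.
#'
#' @name filter_stack
#' @param variants Candidate-variant data.frame of one focal sample (see
#'   \code{\link{simulate_variant_table}} for the column contract).
#' @param config Optional list overriding thresholds / mask inputs:
#'   \code{rho_threshold}, \code{rho_grid_size}, \code{min_vaf_factor},
#'   \code{max_indel_vaf}, \code{contig_lengths}, \code{n_tracts},
#'   \code{chromosomal_contigs}, \code{sex}, \code{y_contig},
#'   \code{sample_depths} (sample-wide depth distribution for the coverage
#'   caps; defaults to the candidate set's own depths), \code{normal_depths}.
#' @return list of class "filter_report": \code{variants} (survivors),
#'   \code{attrition} data.frame (filter, n_in, n_removed), and the applied
#'   \code{order}.
#' @export
apply_filter_stack <- function(variants, config = list()) {
  cfg <- utils::modifyList(list(
    rho_threshold = 0.3, rho_grid_size = 50L, min_vaf_factor = 0.5,
    max_indel_vaf = 0.9, contig_lengths = NULL, n_tracts = NULL,
    chromosomal_contigs = NULL, sex = NULL, y_contig = NULL,
    sample_depths = NULL, normal_depths = NULL
  ), config)
  # the coverage caps come from the sample-wide depth distribution; the
  # candidate set itself is only a fallback stand-in for it
  if (is.null(cfg$sample_depths)) cfg$sample_depths <- variants$depth
  steps <- list()
  cur <- variants
  run <- function(name, part) {
    steps[[name]] <<- c(n_in = nrow(cur), n_removed = nrow(part$fail))
    cur <<- part$pass
  }
  if (nrow(variants) > 0) {
    run("quality_flags", filter_quality_flags(cur))
    run("alignment_quality", filter_alignment_quality(cur))
    if (!is.null(cfg$contig_lengths)) {
      run("position_masks", filter_position_masks(
        cur, cfg$contig_lengths, cfg$n_tracts, cfg$chromosomal_contigs,
        cfg$sex, cfg$y_contig))
    }
    run("coverage", filter_coverage(cur, sample_depths = cfg$sample_depths,
                                    normal_depths = cfg$normal_depths))
    run("strand_bias", filter_strand_bias(cur))
    run("indel_proximity", filter_indel_proximity(cur))
    run("spatial_clusters", filter_spatial_clusters(cur))
    bb <- filter_betabinomial(cur, cfg$rho_threshold,
                              default_rho_grid(cfg$rho_grid_size))
    run("betabinomial", bb)
    run("min_vaf", filter_min_vaf(cur, bb$pass$vaf, cfg$min_vaf_factor))
    run("max_indel_vaf", filter_max_indel_vaf(cur, cfg$max_indel_vaf))
  }
  attrition <- data.frame(
    filter = names(steps),
    n_in = vapply(steps, `[[`, 0, "n_in"),
    n_removed = vapply(steps, `[[`, 0, "n_removed"),
    row.names = NULL
  )
  structure(list(variants = cur, attrition = attrition,
                 order = names(steps)),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Variant filter report:", sum(x$attrition$n_removed), "removed,",
      nrow(x$variants), "retained\n")
  print(x$attrition, row.names = FALSE)
  invisible(x)
}

#' Concordance between two call sets
#'
#' Calls are matched by (contig, pos, ref, alt); the shared fraction uses
#' the union of both sets as denominator.
#'
#' @param calls_a,calls_b data.frames with contig, pos, ref, alt columns.
#' @return list(shared, total, percent).
#' @export
concordance <- function(calls_a, calls_b) {
  key <- function(x) paste(x$contig, x$pos, x$ref, x$alt, sep = ":")
  a <- unique(key(calls_a)); b <- unique(key(calls_b))
  shared <- length(intersect(a, b))
  total <- length(union(a, b))
  list(shared = shared, total = total,
       percent = if (total == 0) NA_real_ else 100 * shared / total)
}

#' Read / write variant tables in the pipeline TSV dialect
#'
#' The cross-sample counts are serialized as semicolon-separated
#' \code{sample:alt:depth} triplets in a \code{cross_sample} column.
#'
#' @param variants Variant data.frame.
#' @param path File path.
#' @export
write_variants_tsv <- function(variants, path) {
  out <- variants
  if (!is.null(out$cross_sample)) {
    out$cross_sample <- vapply(out$cross_sample, function(cs)
      paste(sprintf("%s:%d:%d", cs$sample, cs$alt, cs$depth),
            collapse = ";"), "")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_variants_tsv
#' @export
read_variants_tsv <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(x$cross_sample)) {
    x$cross_sample <- lapply(strsplit(x$cross_sample, ";", fixed = TRUE),
                             function(tr) {
      parts <- do.call(rbind, strsplit(tr, ":", fixed = TRUE))
      data.frame(sample = parts[, 1], alt = as.integer(parts[, 2]),
                 depth = as.integer(parts[, 3]), stringsAsFactors = FALSE)
    })
  }
  x
}

#' Read a VCF into the minimal variant-table columns
#'
#' Parses CHROM/POS/REF/ALT/FILTER plus AD and DP genotype fields of the
#' first sample column (via vcfR). Read-level annotation columns are not
#' present in VCF and are filled with pass-through defaults; supply the
#' pipeline TSV dialect when those filters matter.
#'
#' @param path VCF file path.
#' @return Variant data.frame (no cross-sample counts).
#' @export
read_variants_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- vcfR::extract.gt(v, "AD")[, 1]
  dp <- as.integer(vcfR::extract.gt(v, "DP")[, 1])
  alt_count <- as.integer(vapply(strsplit(ad, ",", fixed = TRUE),
                                 function(x) x[2], ""))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  n <- nrow(fix)
  data.frame(
    contig = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    var_class = ifelse(nchar(fix$REF) != nchar(fix$ALT), "indel",
                       "substitution"),
    alt_count = alt_count, depth = dp, vaf = alt_count / dp,
    clipped_fraction = 0, hq_fragments = alt_count,
    secondary_gt_primary = FALSE,
    fwd_alt = NA_integer_, rev_alt = NA_integer_,
    nearby_indel_reads = 0L,
    caller_flag = ifelse(is.na(fix$FILTER) | fix$FILTER == ".", "PASS",
                         fix$FILTER),
    stringsAsFactors = FALSE
  )
}

#' Write variants as minimal VCFv4.2
#'
#' One sample column with AD (ref,alt) and DP fields; intended for
#' interoperability, not as the pipeline's native format.
#'
#' @param variants Variant data.frame.
#' @param path Output path.
#' @param sample_name Column header for the genotype column.
#' @export
write_variants_vcf <- function(variants, path, sample_name = "SAMPLE") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  ), con)
  if (nrow(variants) > 0) {
    writeLines(sprintf(
      "%s\t%d\t.\t%s\t%s\t.\t%s\t.\tAD:DP\t%d,%d:%d",
      variants$contig, variants$pos, variants$ref, variants$alt,
      variants$caller_flag, variants$depth - variants$alt_count,
      variants$alt_count, variants$depth), con)
  }
  invisible(path)
}
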