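# Genome-corrected mutation burdens, per-year rates and end-of-lifespan
# burdens, mitochondrial copy number and burden, and cell-division
# arithmetic. Interval arithmetic is 0-based half-open internally.

#' Analysable genome size
#'
#' Total callable span minus the union of the exclusion region sets, with
#' interval merging, as exact integer base pairs. Regions are 0-based
#' half-open (BED convention).
#'
#' @param total_regions data.frame(contig, start, end) of callable regions
#'   (typically whole contigs).
#' @param exclusions List of data.frames (contig, start, end) to exclude.
#' @return Analysable size in bp.
#' @export
analysable_genome_size <- function(total_regions, exclusions = list()) {
  as_grl <- function(df) {
    GenomicRanges::GRanges(df$contig,
                           IRanges::IRanges(start = df$start + 1, end = df$end))
  }
  tot <- GenomicRanges::reduce(as_grl(total_regions))
  if (length(exclusions) > 0 && !is.data.frame(exclusions)) {
    excl_df <- do.call(rbind, exclusions)
  } else if (is.data.frame(exclusions)) {
    excl_df <- exclusions
  } else {
    excl_df <- NULL
  }
  if (is.null(excl_df) || nrow(excl_df) == 0) {
    return(sum(as.numeric(BiocGenerics::width(tot))))
  }
  excl <- as_grl(excl_df)
  out_of_bounds <- length(excl) != length(
    IRanges::findOverlaps(excl, tot, type = "within"))
  excl_in <- GenomicRanges::intersect(GenomicRanges::reduce(excl), tot)
  if (out_of_bounds &&
        sum(as.numeric(BiocGenerics::width(GenomicRanges::reduce(excl)))) >
        sum(as.numeric(BiocGenerics::width(excl_in)))) {
    warning("exclusion regions extend outside callable bounds; clipped")
  }
  sum(as.numeric(BiocGenerics::width(tot))) -
    sum(as.numeric(BiocGenerics::width(excl_in)))
}

#' Genome-size-adjusted mutation burden
#'
#' Mutation density (burden / analysable bp) scaled back to the whole
#' genome: burden_raw * total_genome_bp / analysable_bp.
#'
#' @param burden_raw Number of mutations called.
#' @param analysable_bp,total_genome_bp Analysable and total genome sizes.
#' @return Mutations per whole genome.
#' @export
adjusted_burden <- function(burden_raw, analysable_bp, total_genome_bp) {
  check_positive(analysable_bp, "analysable_bp")
  check_positive(total_genome_bp, "total_genome_bp")
  if (any(analysable_bp > total_genome_bp)) {
    stop("analysable size exceeds total genome size")
  }
  burden_raw * total_genome_bp / analysable_bp
}

#' Mutation rate per year and expected end-of-lifespan burden
#'
#' rate m = adjusted burden / age; ELB = m * lifespan.
#'
#' @param burden_adjusted Genome-adjusted burden (mutations per genome).
#' @param age Age of the individual (years, > 0).
#' @param lifespan Species lifespan estimate (years).
#' @param sample_id Optional label.
#' @return data.frame of class "rate_estimate": burden, age, rate per year,
#'   ELB and the lifespan used.
#' @export
rate_and_elb <- function(burden_adjusted, age, lifespan, sample_id = NA) {
  check_positive(age, "age")
  check_positive(lifespan, "lifespan")
  m <- burden_adjusted / age
  out <- data.frame(sample_id = sample_id, burden_adjusted = burden_adjusted,
                    age = age, rate_per_year = m, lifespan_used = lifespan,
                    elb = m * lifespan)
  class(out) <- c("rate_estimate", "data.frame")
  out
}

#' Mitochondrial copy number per cell
#'
#' depth_mt * ploidy / depth_nuclear; the nuclear mean excludes sex
#' chromosomes by caller contract.
#'
#' @param depth_mt,depth_nuclear Mean coverages of mtDNA and of the
#'   (autosomal) nuclear genome.
#' @param ploidy Nuclear ploidy (2 for normal somatic cells).
#' @return Copies per cell.
#' @export
mtdna_copy_number <- function(depth_mt, depth_nuclear, ploidy = 2) {
  check_positive(depth_nuclear, "depth_nuclear")
  if (any(depth_mt < 0)) stop("'depth_mt' must be non-negative")
  depth_mt * ploidy / depth_nuclear
}

#' Filter mitochondrial variant calls
#'
#' Applies, in order: the minimum-VAF rule (VAF strictly above 0.01), the
#' coverage rule (site depth at least 500x), the D-loop exclusion, and the
#' sample-level high-burden rule (samples with more variants than 4 times
#' the cohort mean burden are dropped).
#'
#' @param variants data.frame with pos, vaf, depth, sample_id columns.
#' @param dloop_intervals data.frame(start, end), 1-based inclusive mtDNA
#'   coordinates of the D-loop.
#' @param cohort_mean_burden Mean per-sample mtDNA burden across the cohort
#'   (computed after the site-level rules if NULL).
#' @return list(variants, dropped_samples).
#' @export
filter_mtdna_variants <- function(variants, dloop_intervals = NULL,
                                  cohort_mean_burden = NULL) {
  v <- variants[variants$vaf > 0.01, , drop = FALSE]
  v <- v[v$depth >= 500, , drop = FALSE]
  if (!is.null(dloop_intervals) && nrow(dloop_intervals) > 0) {
    in_dloop <- rep(FALSE, nrow(v))
    for (i in seq_len(nrow(dloop_intervals))) {
      in_dloop <- in_dloop | (v$pos >= dloop_intervals$start[i] &
                                v$pos <= dloop_intervals$end[i])
    }
    v <- v[!in_dloop, , drop = FALSE]
  }
  burdens <- table(v$sample_id)
  if (is.null(cohort_mean_burden)) cohort_mean_burden <- mean(burdens)
  dropped <- names(burdens)[burdens > 4 * cohort_mean_burden]
  list(variants = v[!(v$sample_id %in% dropped), , drop = FALSE],
       dropped_samples = dropped)
}

#' Mitochondrial mutation burden per genome copy
#'
#' The heteroplasmy-weighted burden: the sum of variant VAFs, scaled from
#' the analysable to the full mtDNA length. Set \code{weighted = FALSE} to
#' count variants instead of summing VAFs.
#'
#' @param vafs VAFs of the filtered mtDNA variants of one sample.
#' @param analysable_mtdna_bp,full_mtdna_bp Analysable and full mtDNA sizes.
#' @param weighted Sum VAFs (TRUE) or count variants (FALSE).
#' @return Mutations per mtDNA copy.
#' @export
mtdna_burden_per_copy <- function(vafs, analysable_mtdna_bp, full_mtdna_bp,
                                  weighted = TRUE) {
  check_positive(analysable_mtdna_bp, "analysable_mtdna_bp")
  check_positive(full_mtdna_bp, "full_mtdna_bp")
  base <- if (weighted) sum(vafs) else length(vafs)
  base * full_mtdna_bp / analysable_mtdna_bp
}

#' Lifetime cell divisions and mutations per division
#'
#' @param lifespan Lifespan in years.
#' @param division_interval_hours Hours per stem-cell division.
#' @param elb End-of-lifespan mutation burden.
#' @return list(n_divisions, mutations_per_division).
#' @export
divisions_and_mutations_per_division <- function(lifespan,
                                                 division_interval_hours,
                                                 elb) {
  check_positive(lifespan, "lifespan")
  check_positive(division_interval_hours, "division_interval_hours")
  n_div <- lifespan * 365.25 * 24 / division_interval_hours
  list(n_divisions = n_div, mutations_per_division = elb / n_div)
}
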