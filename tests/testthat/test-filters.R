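# Variant filter stack: boundary behaviour of every rule, partition
# properties, and the beta-binomial overdispersion filter against an
# independent grid-likelihood oracle.

test_that("rho estimation prefers low overdispersion for homogeneous counts
           and high overdispersion for presence/absence patterns", {
  f_same <- estimate_rho(data.frame(alt = rep(15, 6), depth = rep(30, 6)))
  expect_lt(f_same$rho, 0.01)
  expect_equal(f_same$mu, 0.5)
  f_priv <- estimate_rho(data.frame(alt = c(15, 0, 0, 0, 0, 0),
                                    depth = rep(30, 6)))
  expect_gt(f_priv$rho, 0.3)
  # singleton grid returns that point
  f_one <- estimate_rho(data.frame(alt = c(3, 9), depth = c(30, 30)),
                        grid = 0.07)
  expect_equal(f_one$rho, 0.07)
  expect_error(estimate_rho(data.frame(alt = 0, depth = 0)), "zero")
  expect_warning(estimate_rho(data.frame(alt = c(0, 0), depth = c(30, 30))),
                 "degenerate")
})

test_that("grid MLE of rho matches an exhaustive independent evaluation", {
  grid <- default_rho_grid()
  set.seed(42)
  for (case in 1:20) {
    ns <- sample(3:8, 1)
    depth <- rpois(ns, 30) + 5
    alt <- rbinom(ns, depth, runif(1, 0.05, 0.6)) +
      sample(0:1, ns, replace = TRUE) * rbinom(ns, depth, 0.3)
    alt <- pmin(alt, depth)
    if (sum(alt) == 0 || sum(alt) == sum(depth)) next
    fit <- estimate_rho(data.frame(alt, depth), grid)
    oracle_ll <- vapply(grid, function(r) oracle_rho_loglik(alt, depth, r), 0)
    # the chosen grid point attains the oracle's maximum likelihood
    expect_lt(max(oracle_ll) - oracle_rho_loglik(alt, depth, fit$rho), 1e-6)
  }
})

test_that("beta-binomial log-likelihood is invariant under sample permutation", {
  set.seed(7)
  alt <- c(12, 0, 3, 0, 8); depth <- c(30, 28, 33, 31, 29)
  f <- estimate_rho(data.frame(alt, depth))
  o <- sample(5)
  f2 <- estimate_rho(data.frame(alt = alt[o], depth = depth[o]))
  expect_equal(f$loglik, f2$loglik)
  expect_equal(f$rho, f2$rho)
})

test_that("beta-binomial filter keeps overdispersed (true somatic) variants
           and discards low-rho artifacts, at the 0.3 threshold", {
  # private variant (high rho) and a shared low-VAF artifact (low rho)
  v <- make_variants(alt_count = c(15L, 6L), depth = 30L)
  v$cross_sample <- list(
    data.frame(sample = paste0("s", 1:5), alt = c(15, 0, 0, 0, 0),
               depth = rep(30, 5)),
    data.frame(sample = paste0("s", 1:5), alt = c(6, 5, 7, 4, 6),
               depth = rep(30, 5)))
  out <- filter_betabinomial(v)
  expect_equal(nrow(out$pass), 1)
  expect_equal(out$pass$alt_count, 15L)
  expect_true(all(out$pass$rho > 0.3))
  # the partition rule is exactly rho > 0.3
  both <- rbind(out$pass, out$fail)
  expect_setequal(both$alt_count, v$alt_count)
  expect_true(all((both$rho > 0.3) == (both$alt_count == 15L)))
  # single-sample individuals cannot be filtered
  v1 <- make_variants(alt_count = 10L)
  v1$cross_sample <- list(data.frame(sample = "s1", alt = 10, depth = 30))
  expect_warning(out1 <- filter_betabinomial(v1), "single-sample")
  expect_equal(nrow(out1$pass), 1)
})

test_that("alignment-quality rules apply to substitutions, fragment rule to
           all classes", {
  v <- make_variants(hq_fragments = c(4L, 3L, 15L, 15L, 15L),
                     clipped_fraction = c(0, 0, 0.8, 0.8, 0),
                     var_class = c("substitution", "substitution",
                                   "substitution", "indel", "substitution"),
                     secondary_gt_primary = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  out <- filter_alignment_quality(v)
  expect_equal(out$pass$hq_fragments, c(4L, 15L))   # rows 1 and 4 kept
  expect_true("indel" %in% out$pass$var_class)      # clipping waived for indels
  expect_equal(nrow(out$fail), 3)
})

test_that("coverage filter discards below 10x and strictly above the 99th
           percentile", {
  v <- make_variants(depth = c(9L, 10L, 30L, 200L))
  pool <- c(rep(30L, 98), 150L, 190L)
  out <- filter_coverage(v, sample_depths = pool)
  cap <- quantile(pool, 0.99, type = 7, names = FALSE)
  expect_true(all(out$pass$depth >= 10 & out$pass$depth <= cap))
  expect_true(9 %in% out$fail$depth && 200 %in% out$fail$depth)
  # depth exactly at the percentile is kept
  v2 <- make_variants(depth = as.integer(round(cap)))
  expect_equal(nrow(filter_coverage(v2, sample_depths = pool)$pass), 1)
  # constant-depth sample: only the <10x rule can fire
  v3 <- make_variants(depth = c(30L, 30L))
  expect_equal(nrow(filter_coverage(v3, sample_depths = rep(30L, 100))$fail), 0)
})

test_that("strand-bias filter requires support on both strands", {
  v <- make_variants(fwd_alt = c(1L, 5L), rev_alt = c(1L, 0L),
                     alt_count = c(2L, 5L))
  out <- filter_strand_bias(v)
  expect_equal(nrow(out$pass), 1)
  expect_equal(out$fail$fwd_alt, 5L)
  bad <- make_variants(fwd_alt = 0L, rev_alt = 0L, alt_count = 5L)
  expect_error(filter_strand_bias(bad), "invariant")
})

test_that("indel-proximity filter uses a strict 3x read-support ratio and
           exempts indels", {
  v <- make_variants(alt_count = 5L, nearby_indel_reads = c(15L, 16L, 16L),
                     var_class = c("substitution", "substitution", "indel"))
  out <- filter_indel_proximity(v)
  expect_equal(out$pass$nearby_indel_reads, c(15L, 16L))
  expect_equal(out$fail$var_class, "substitution")
})

test_that("spatial clustering is inclusive at 1 kb and transitive", {
  v <- make_variants(pos = c(100L, 1100L))
  expect_equal(nrow(filter_spatial_clusters(v)$pass), 0)  # distance 1000
  v2 <- make_variants(pos = c(100L, 1101L))
  expect_equal(nrow(filter_spatial_clusters(v2)$pass), 2)
  chain <- make_variants(pos = c(100L, 1000L, 1900L))
  expect_equal(nrow(filter_spatial_clusters(chain)$pass), 0)
  # brute-force pairwise transitive-closure oracle on a random instance
  set.seed(31)
  pos <- sample(1e6, 60)
  vr <- make_variants(pos = as.integer(pos))
  got <- sort(filter_spatial_clusters(vr)$pass$pos)
  adj <- abs(outer(pos, pos, "-")) <= 1000 & diag(length(pos)) == 0
  reach <- adj
  for (i in seq_along(pos)) reach <- reach | (reach %*% adj > 0)
  solo <- rowSums(reach) == 0
  expect_equal(got, sort(pos[solo]))
})

test_that("minimum-VAF filter uses half the median of beta-binomial
           survivors, strictly", {
  v <- make_variants(alt_count = c(6L, 30L, 19L, 20L), depth = c(30L, 100L,
                                                                 100L, 100L))
  out <- filter_min_vaf(v, survivor_vafs = c(0.3, 0.4, 0.5))
  expect_true(all(out$pass$vaf >= 0.2))
  expect_equal(out$fail$vaf, 0.19)
  expect_warning(out2 <- filter_min_vaf(v, numeric(0)), "skipped")
  expect_equal(nrow(out2$pass), nrow(v))
  same <- make_variants(alt_count = rep(12L, 4))
  expect_equal(nrow(filter_min_vaf(same, same$vaf)$fail), 0)
})

test_that("maximum-indel-VAF filter is strict and substitution-exempt", {
  v <- make_variants(alt_count = c(19L, 18L, 19L), depth = 20L,
                     var_class = c("indel", "indel", "substitution"))
  out <- filter_max_indel_vaf(v)
  expect_equal(nrow(out$fail), 1)
  expect_equal(out$fail$vaf, 0.95)
  expect_true(0.9 %in% out$pass$vaf)           # indel at exactly 0.9 kept
  expect_true("substitution" %in% out$pass$var_class)
})

test_that("position masks: contig ends, N tracts, non-chromosomal contigs
           and male Y", {
  lens <- c(chrS01 = 10000, tiny = 1500, scaffold7 = 10000, chrY = 10000)
  v <- make_variants(contig = c("chrS01", "chrS01", "tiny", "scaffold7",
                                "chrY"),
                     pos = c(999L, 1001L, 700L, 5000L, 5000L))
  out <- filter_position_masks(v, lens)
  expect_true(all(c(1001, 5000) %in% out$pass$pos))
  expect_true(999 %in% out$fail$pos)
  expect_true(700 %in% out$fail$pos)            # contig < 2 kb
  # N tracts: >= 50 N within 1 kb masks; a 49-N tract must not
  ref <- c(chrS01 = paste0(strrep("A", 4000), strrep("N", 50),
                           strrep("A", 5950)),
           chrS02 = paste0(strrep("A", 4000), strrep("N", 49),
                           strrep("A", 5951)))
  tracts <- find_n_tracts(ref)
  expect_equal(nrow(tracts), 1)
  v2 <- make_variants(contig = c("chrS01", "chrS02"), pos = c(3500L, 3500L))
  out2 <- filter_position_masks(v2, c(chrS01 = 10000, chrS02 = 10000),
                                n_tracts = tracts)
  expect_equal(out2$pass$contig, "chrS02")
  # chromosome-level and Y rules
  out3 <- filter_position_masks(v, lens,
                                chromosomal_contigs = c("chrS01", "chrY"),
                                sex = "male", y_contig = "chrY")
  expect_false(any(out3$pass$contig %in% c("scaffold7", "chrY")))
})

test_that("the full stack partitions cleanly, records attrition in order,
           and is idempotent up to the min-VAF recomputation", {
  empty <- make_variants()[0, ]
  rep0 <- apply_filter_stack(empty)
  expect_equal(nrow(rep0$variants), 0)
  expect_equal(nrow(rep0$attrition), 0)

  cfg <- sim_config(n_species = 1, individuals_per_species = 1,
                    crypts_per_individual = 4, seed = 21)
  co <- simulate_cohort(cfg)
  tb <- simulate_variant_table(co$crypts$crypt_id[1], co)
  fcfg <- list(sample_depths = tb$depth)  # the sample-wide depth pool
  rep1 <- apply_filter_stack(tb, fcfg)
  expect_equal(rep1$order,
               c("quality_flags", "alignment_quality", "coverage",
                 "strand_bias", "indel_proximity", "spatial_clusters",
                 "betabinomial", "min_vaf", "max_indel_vaf"))
  expect_equal(sum(rep1$attrition$n_removed) + nrow(rep1$variants), nrow(tb))
  # n_in of each filter equals survivors of the previous
  expect_equal(rep1$attrition$n_in[-1],
               (rep1$attrition$n_in - rep1$attrition$n_removed)[-nrow(rep1$attrition)])
  # rerun on own output: no further removals except possibly min-VAF
  rep2 <- apply_filter_stack(rep1$variants, fcfg)
  att2 <- rep2$attrition
  expect_true(all(att2$n_removed[att2$filter != "min_vaf"] == 0))
  # stack precision/recall against truth labels exceeds the 0.9 floors
  kept <- rep1$variants
  recall <- sum(!kept$is_artifact) / sum(!tb$is_artifact)
  precision <- sum(!kept$is_artifact) / nrow(kept)
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
})

test_that("call-set concordance uses the union denominator", {
  a <- make_variants(pos = as.integer(1:100 * 3000))
  expect_equal(concordance(a, a)$percent, 100)
  b <- make_variants(pos = as.integer(101:200 * 3000))
  expect_equal(concordance(a, b)$percent, 0)
  shared <- make_variants(pos = as.integer(1:50 * 3000))
  extra <- make_variants(pos = as.integer(1001:1025 * 3000))
  res <- concordance(rbind(shared, extra[1:10, ]), rbind(shared, extra[11:25, ]))
  expect_equal(res$shared, 50)
  expect_equal(res$total, 75)
  expect_equal(res$percent, 100 * 50 / 75)
})

test_that("variant tables round-trip through the TSV dialect and export to
           VCF", {
  cfg <- sim_config(n_species = 1, individuals_per_species = 1,
                    crypts_per_individual = 2, seed = 33)
  co <- simulate_cohort(cfg)
  tb <- simulate_variant_table(co$crypts$crypt_id[1], co)[1:20, ]
  tmp <- tempfile(fileext = ".tsv")
  write_variants_tsv(tb, tmp)
  back <- read_variants_tsv(tmp)
  expect_equal(back$pos, tb$pos)
  expect_equal(back$cross_sample[[3]]$alt, tb$cross_sample[[3]]$alt)
  vcf <- tempfile(fileext = ".vcf")
  write_variants_vcf(tb, vcf)
  lines <- readLines(vcf)
  expect_equal(sum(!startsWith(lines, "#")), 20)
  expect_true(any(grepl("^##fileformat=VCFv4.2$", lines)))
  back_vcf <- read_variants_vcf(vcf)
  expect_equal(back_vcf$pos, tb$pos)
  expect_equal(back_vcf$alt_count, tb$alt_count)
  expect_equal(back_vcf$depth, tb$depth)
  expect_equal(back_vcf$vaf, tb$vaf)
})
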