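# End-to-end orchestration: a single flat, typed configuration with every
# threshold defaulting to the study value, deterministic named-substream
# seeding, and a run manifest with output checksums.

#' Default pipeline configuration
#'
#' The flat key set consumed by \code{\link{run_pipeline}}. Every analysis
#' threshold appears exactly once here: the 50-variant burden floor, the
#' 3x sibling-median high-burden rule, the 70\%/0.3 clonality rule, the
#' beta-binomial rho cutoff of 0.3, the mtDNA VAF > 0.01 and 500x depth
#' rules, the 0.8 lifespan quantile, 100-kb bins, 5-bin segments and the
#' 10-bin / shared-segment event filters.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    # stages
    stages = c("simulate", "filter", "clonality", "burden", "signatures",
               "cn", "regress"),
    out_dir = tempfile("cryptclock_run_"),
    seed = 1L,
    # simulation design (see sim_config for semantics)
    n_species = 4L, individuals_per_species = 2L, crypts_per_individual = 2L,
    mean_depth = 30, depth_dispersion = 30, artifact_rate = 1,
    k = 3000, elb_sdlog = 0, polyclonal_fraction = 0,
    # variant filtering
    min_alt = 4L, rho_threshold = 0.3, rho_grid_size = 50L,
    min_vaf_factor = 0.5, max_indel_vaf = 0.9,
    # clonality
    kmax = 5L, min_burden = 50L, high_burden_factor = 3,
    low_vaf_fraction = 0.7, vaf_cluster_threshold = 0.3,
    clonality_allow_list = character(0),
    # mtDNA
    mtdna_min_vaf = 0.01, mtdna_min_depth = 500L, mtdna_burden_factor = 4,
    # life history / regression
    lifespan_quantile = 0.8, boot_replicates = 10000L,
    # copy number
    cn_bin_size = 100000L, cn_min_segment_bins = 5L, cn_min_event_bins = 10L,
    cn_min_purity = 0.85
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults, rejects unknown keys (listing the valid ones) and
#' inconsistent or negative settings.
#'
#' @param config Partial configuration list.
#' @return Completed configuration.
#' @export
validate_config <- function(config = list()) {
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         "; valid keys are: ", paste(names(defaults), collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  numeric_keys <- c("n_species", "individuals_per_species",
                    "crypts_per_individual", "mean_depth", "depth_dispersion",
                    "min_alt", "rho_threshold", "min_burden", "kmax",
                    "high_burden_factor", "low_vaf_fraction",
                    "vaf_cluster_threshold", "mtdna_min_vaf",
                    "mtdna_min_depth", "lifespan_quantile", "cn_bin_size",
                    "cn_min_segment_bins", "cn_min_event_bins", "k")
  for (key in numeric_keys) {
    if (!is.numeric(cfg[[key]]) || length(cfg[[key]]) != 1 ||
          cfg[[key]] <= 0) {
      stop("config key '", key, "' must be a positive number")
    }
  }
  bad <- setdiff(cfg$stages, defaults$stages)
  if (length(bad) > 0) stop("unknown stages: ", paste(bad, collapse = ", "))
  if ("regress" %in% cfg$stages && !"burden" %in% cfg$stages) {
    stop("the regression stage requires the burden stage (per-crypt rates)")
  }
  cfg
}

#' Run the pipeline end to end on a synthetic cohort
#'
#' simulate -> filter -> clonality -> burden -> signatures -> cn -> regress,
#' writing TSV/JSON artifacts and a manifest (config, seed, per-output
#' checksums) under \code{config$out_dir}. Stages draw their randomness
#' from named substreams of the master seed, so identical config + seed
#' reproduce identical outputs.
#'
#' @param config Configuration list (see \code{\link{default_config}}).
#' @return Invisibly, a list with the manifest and the in-memory stage
#'   outputs.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  state <- list()
  emit <- function(name, writer) {
    path <- file.path(cfg$out_dir, name)
    writer(path)
    outputs <<- c(outputs, path)
    path
  }
  message("stage: simulate")
  scfg <- sim_config(
    n_species = cfg$n_species,
    individuals_per_species = cfg$individuals_per_species,
    crypts_per_individual = cfg$crypts_per_individual,
    mean_depth = cfg$mean_depth, depth_dispersion = cfg$depth_dispersion,
    artifact_rate = cfg$artifact_rate, seed = cfg$seed, k = cfg$k,
    elb_sdlog = cfg$elb_sdlog, polyclonal_fraction = cfg$polyclonal_fraction,
    min_alt = cfg$min_alt)
  cohort <- simulate_cohort(scfg)
  state$cohort <- cohort
  emit("species_truth.tsv", function(p) utils::write.table(
    cohort$species[, c("name", "lifespan_true", "adult_mass", "true_elb",
                       "genome_size")],
    p, sep = "\t", quote = FALSE, row.names = FALSE))
  emit("crypt_truth.tsv", function(p) utils::write.table(
    cohort$crypts[, c("crypt_id", "individual_id", "species", "age",
                      "n_true_mutations", "n_artifacts", "is_clonal")],
    p, sep = "\t", quote = FALSE, row.names = FALSE))

  tables <- lapply(cohort$crypts$crypt_id, simulate_variant_table, cohort)
  names(tables) <- cohort$crypts$crypt_id

  if ("filter" %in% cfg$stages) {
    message("stage: filter")
    contigs <- sim_contigs(scfg)
    fcfg <- list(rho_threshold = cfg$rho_threshold,
                 rho_grid_size = cfg$rho_grid_size,
                 min_vaf_factor = cfg$min_vaf_factor,
                 max_indel_vaf = cfg$max_indel_vaf,
                 contig_lengths = stats::setNames(contigs$length,
                                                  contigs$contig))
    reports <- lapply(tables, function(tb)
      if (is.null(tb)) NULL else apply_filter_stack(tb, fcfg))
    tables <- lapply(reports, function(r) if (is.null(r)) NULL else r$variants)
    state$filter_reports <- reports
    emit("filter_attrition.tsv", function(p) {
      att <- do.call(rbind, lapply(names(reports), function(id)
        if (is.null(reports[[id]])) NULL else
          cbind(crypt_id = id, reports[[id]]$attrition)))
      utils::write.table(att, p, sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }

  burdens <- vapply(tables, function(tb) if (is.null(tb)) 0L else nrow(tb), 0L)
  keep <- rep(TRUE, length(tables))

  if ("clonality" %in% cfg$stages) {
    message("stage: clonality")
    fits <- lapply(tables, function(tb) {
      if (is.null(tb) || nrow(tb) < 2) return(NULL)
      select_model(tb$alt_count, tb$depth, K_range = seq_len(cfg$kmax),
                   seed = cfg$seed, min_alt = cfg$min_alt, restarts = 2L)
    })
    primary <- vapply(fits, function(f)
      if (is.null(f)) NA_real_ else f$means[which.max(f$weights)], 0)
    verdicts <- lapply(seq_along(fits), function(i) {
      if (is.null(fits[[i]])) return(NULL)
      ind <- cohort$crypts$individual_id[i]
      sib <- which(cohort$crypts$individual_id == ind)
      classify_sample(
        fits[[i]],
        sibling_burdens = burdens[sib][burdens[sib] >= cfg$min_burden],
        individual_primary_vafs = primary[sib][!is.na(primary[sib])],
        sample_id = cohort$crypts$crypt_id[i],
        allow_list = cfg$clonality_allow_list)
    })
    status <- vapply(verdicts, function(v)
      if (is.null(v)) "low_burden" else v$status, "")
    keep <- status %in% c("pass", "exempted")
    state$verdicts <- verdicts
    emit("clonality.tsv", function(p) utils::write.table(
      data.frame(crypt_id = cohort$crypts$crypt_id, status = status),
      p, sep = "\t", quote = FALSE, row.names = FALSE))
  } else if ("burden" %in% cfg$stages) {
    warning("clonality stage disabled: burden stage consumes unfiltered ",
            "samples, including possibly polyclonal crypts")
  }

  rates <- NULL
  if ("burden" %in% cfg$stages) {
    message("stage: burden")
    genome_bp <- cohort$species$genome_size[1]
    idx <- which(keep & burdens > 0)
    rates <- do.call(rbind, lapply(idx, function(i) {
      cr <- cohort$crypts[i, ]
      sp <- cohort$species[cohort$species$name == cr$species, ]
      adj <- adjusted_burden(burdens[i], genome_bp, genome_bp)
      re <- rate_and_elb(adj, cr$age, sp$lifespan_true, cr$crypt_id)
      re$species <- cr$species; re$individual <- cr$individual_id
      re$inv_lifespan <- 1 / sp$lifespan_true
      re$log_mass <- log10(sp$adult_mass)
      re
    }))
    state$rates <- rates
    emit("rates.tsv", function(p) utils::write.table(
      rates, p, sep = "\t", quote = FALSE, row.names = FALSE))
  }

  if ("signatures" %in% cfg$stages) {
    message("stage: signatures")
    refs <- reference_signatures()[, c("SBS1", "SBS5", "SBS18")]
    spectra <- t(vapply(seq_len(nrow(cohort$species)), function(s)
      simulate_spectrum(refs, cohort$species$signature_exposures[[s]],
                        cohort$species$trinuc_freqs[[s]],
                        n = 2000,
                        seed = substream_seed(cfg$seed,
                                              paste0("spectrum:", s))),
      integer(96)))
    expos <- t(vapply(seq_len(nrow(spectra)), function(s)
      fit_exposures(spectra[s, ], refs,
                    cohort$species$trinuc_freqs[[s]])$exposures,
      numeric(3)))
    state$signature_exposures <- expos
    emit("signature_exposures.tsv", function(p) utils::write.table(
      data.frame(species = cohort$species$name, expos),
      p, sep = "\t", quote = FALSE, row.names = FALSE))
  }

  if ("cn" %in% cfg$stages) {
    message("stage: cn")
    tracks <- simulate_cn_tracks(
      n_bins = 200, events = data.frame(start = 50, end = 69,
                                        major = 1, minor = 0),
      purity = 1, seed = substream_seed(cfg$seed, "cn"))
    calls <- call_bins(tracks$bins, tracks$snps, purity = 1)
    segs <- segment_states(calls, cfg$cn_min_segment_bins,
                           cfg$cn_min_segment_bins)
    segs$sample_id <- "demo"
    events <- filter_segments(segs, cfg$cn_min_event_bins)
    state$cn_events <- events
    emit("cn_segments.tsv", function(p) utils::write.table(
      segs, p, sep = "\t", quote = FALSE, row.names = FALSE))
  }

  if ("regress" %in% cfg$stages && !is.null(rates) &&
        length(unique(rates$species)) >= 3) {
    message("stage: regress")
    fit <- fit_lme(rates, "inv_lifespan", "rate_per_year",
                   zero_intercept = TRUE, restarts = 3L, seed = cfg$seed)
    state$scaling_fit <- fit
    emit("regression.json", function(p) jsonlite::write_json(list(
      model = "rate_per_year ~ k / lifespan (zero intercept)",
      k = fit$slope, k_ci = fit$slope_ci, fve = fve(fit),
      loglik = fit$loglik,
      var_species = fit$var_species, var_individual = fit$var_individual
    ), p, auto_unbox = TRUE, digits = NA))
  }

  manifest <- list(
    package = "cryptclock",
    version = as.character(utils::packageVersion("cryptclock")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "out_dir")],
    outputs = stats::setNames(as.list(unname(tools::md5sum(outputs))),
                              basename(outputs)),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(state, list(manifest = manifest, out_dir = cfg$out_dir)))
}
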