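#' Integer percentage of a count over a total
#'
#' The rounding used by every manifest and report in the package when a
#' fraction of loci is stated as a percentage.
#'
#' @param n Numerator count.
#' @param d Denominator count.
#' @return `round(100 * n / d)` as an integer.
#' @examples
#' percent_of(473, 751) # 63
#' @export
percent_of <- function(n, d) {
  if (d <= 0) stop("denominator must be positive")
  as.integer(round(100 * n / d))
}

#' Pipeline configuration
#'
#' All seeds are explicit and every stage's thresholds are carried in one
#' object, so a run is a pure function of (inputs, config).
#'
#' @param out_dir Run directory for stage outputs and the manifest.
#' @param scenario A [simulation_scenario()] used when no input tables are
#'   given.
#' @param counts,survival Optional paths to existing TSV inputs (then no
#'   simulation runs).
#' @param filter A [filter_config()].
#' @param alpha FDR level for the per-locus tests.
#' @param k Cluster count or `"auto"`.
#' @param cluster_seed,cross_seed,forecast_seed Stage seeds.
#' @param n_sims Factorial-cross simulations per locus.
#' @param tolerance,n_accept Forecaster settings.
#' @param forecast_max_loci Cap on forecasted loci (significant loci are
#'   forecast in locus-id order up to the cap); `Inf` forecasts all.
#' @param distortion_level Prediction-interval coverage.
#' @param linkage_map Optional path to a linkage-map TSV
#'   (`scaffold lg cM marker_bp`); when absent on simulated runs a
#'   synthetic map is generated.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir = tempfile("poolsel_run_"),
                            scenario = simulation_scenario(),
                            counts = NULL, survival = NULL,
                            filter = filter_config(), alpha = 0.05,
                            k = "auto", cluster_seed = 11,
                            cross_seed = 12, forecast_seed = 13,
                            n_sims = 50, tolerance = 0.10, n_accept = 50,
                            forecast_max_loci = Inf,
                            distortion_level = 0.95, linkage_map = NULL) {
  problems <- character()
  if (!is.null(counts) && !file.exists(counts)) {
    problems <- c(problems, paste("counts file not found:", counts))
  }
  if (!is.null(survival) && !file.exists(survival)) {
    problems <- c(problems, paste("survival file not found:", survival))
  }
  if (xor(is.null(counts), is.null(survival))) {
    problems <- c(problems,
                  "counts and survival must be given together or not at all")
  }
  if (tolerance <= 0) problems <- c(problems, "tolerance must be positive")
  if (alpha <= 0 || alpha >= 1) {
    problems <- c(problems, "alpha must lie in (0, 1)")
  }
  if (length(problems)) {
    stop("invalid pipeline configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  structure(
    list(out_dir = out_dir, scenario = scenario, counts = counts,
         survival = survival, filter = filter, alpha = alpha, k = k,
         cluster_seed = cluster_seed, cross_seed = cross_seed,
         forecast_seed = forecast_seed, n_sims = n_sims,
         tolerance = tolerance, n_accept = n_accept,
         forecast_max_loci = forecast_max_loci,
         distortion_level = distortion_level, linkage_map = linkage_map),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized top-level keys mirror the arguments of [pipeline_config()];
#' `scenario:` and `filter:` sub-maps mirror [simulation_scenario()] and
#' [filter_config()]. Values passed directly to this function override the
#' file.
#'
#' @param path YAML file path.
#' @param ... Overrides, as named [pipeline_config()] arguments.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$scenario)) {
    args$scenario <- do.call(simulation_scenario, y$scenario)
  }
  if (!is.null(y$filter)) args$filter <- do.call(filter_config, y$filter)
  direct <- intersect(names(y), setdiff(names(formals(pipeline_config)),
                                        c("scenario", "filter")))
  args[direct] <- y[direct]
  overrides <- list(...)
  args[names(overrides)] <- overrides
  do.call(pipeline_config, args)
}

#' Run the full analysis pipeline
#'
#' Stage order: simulate (when no inputs are given) -> filter -> per-locus
#' GLM test -> categorize -> cluster -> egg-pool cross simulation ->
#' forecaster -> distortion analysis -> linkage bridging. Every stage
#' writes its table into the run directory and the manifest records locus
#' counts entering and leaving each stage plus the headline fractions
#' (as integer percentages via [percent_of()]), so the run's summary
#' numbers are recomputable from the manifest alone.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `"pipeline_run"` with each stage's in-memory
#'   result plus `manifest` (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(packageVersion("poolsel")),
    seeds = list(scenario = config$scenario$seed,
                 cluster = config$cluster_seed,
                 cross = config$cross_seed,
                 forecast = config$forecast_seed),
    stages = list()
  )

  # inputs
  if (is.null(config$counts)) {
    sim <- simulate_pool_study(config$scenario)
    counts <- sim$counts
    survival <- sim$survival
    write_pool_study(sim, config$out_dir)
  } else {
    sim <- NULL
    counts <- read_tsv(config$counts)
    survival <- read_tsv(config$survival)
  }

  # filter
  fres <- apply_filters(counts, config$filter)
  write_tsv(fres$table, file.path(config$out_dir, "filtered_counts.tsv"))
  manifest$stages$filter <- unclass(fres$report)

  # per-locus tests
  maf <- compute_maf(fres$table)
  tests <- test_age_effect(fres$table, alpha = config$alpha)
  n_tested <- nrow(tests)
  n_sig <- sum(tests$significant)
  cats <- suppressWarnings(
    categorize_loci(maf$per_sample, tests, alpha = config$alpha)
  )
  results <- merge(tests, cats$categories, by = "locus_id")
  write_tsv(results, file.path(config$out_dir, "locus_tests.tsv"))
  cat_counts <- table(factor(results$category[results$significant],
                             levels = c("G", "UD", "BD")))
  manifest$stages$test <- list(
    loci_tested = n_tested, loci_significant = n_sig,
    pct_significant = percent_of(n_sig, n_tested),
    categories = as.list(cat_counts)
  )

  # clustering of significant loci
  sig_loci <- results$locus_id[results$significant]
  clustering <- NULL
  if (length(sig_loci) >= 25) {
    dmat <- delta_af_matrix(maf$per_day, loci = sig_loci)
    clustering <- cluster_trajectories(dmat, k = config$k,
                                       seed = config$cluster_seed)
    write_tsv(data.frame(locus_id = names(clustering$assignments),
                         cluster = clustering$assignments),
              file.path(config$out_dir, "clusters.tsv"))
    manifest$stages$cluster <- list(k = clustering$k,
                                    sizes = as.list(clustering$sizes))
  }

  # egg-pool genotype composition for significant loci
  egg_maf_tab <- maf$per_day[maf$per_day$day == 0, , drop = FALSE]
  egg_maf <- setNames(egg_maf_tab$maf, egg_maf_tab$locus_id)[sig_loci]
  egg_maf <- egg_maf[!is.na(egg_maf) & egg_maf > 0 & egg_maf < 1]
  eggsim <- simulate_egg_genotypes(egg_maf, n_sims = config$n_sims,
                                   seed = config$cross_seed)
  write_tsv(eggsim, file.path(config$out_dir, "egg_genotypes.tsv"))
  manifest$stages$eggsim <- list(
    n_loci = nrow(eggsim), n_sims = config$n_sims,
    n_families = n_cross_families()
  )

  # forecaster
  fc_loci <- utils::head(sort(eggsim$locus_id[!eggsim$monomorphic]),
                         config$forecast_max_loci)
  init <- as.matrix(eggsim[match(fc_loci, eggsim$locus_id),
                           c("f_AA", "f_AB", "f_BB")])
  rownames(init) <- fc_loci
  fc_days <- intersect(c(2, 6, 10, 14, 22), unique(maf$per_day$day))
  fc <- forecast_loci(init, maf$per_day, survival, days = fc_days,
                      tolerance = config$tolerance,
                      n_accept = config$n_accept,
                      seed = config$forecast_seed)
  manifest$stages$forecast <- list(
    n_loci = length(fc$ensembles), n_accept = config$n_accept,
    n_timepoints = length(fc_days) + 1L,
    n_records = fc$n_records,
    n_records_nominal = forecast_bookkeeping(length(fc$ensembles),
                                             config$n_accept,
                                             length(fc_days) + 1L),
    infeasible_loci = length(fc$infeasible_loci)
  )

  # distortion at the final (spat) day
  ok_loci <- names(fc$ensembles)[
    vapply(fc$ensembles, function(e) e$n_accepted >= 2, TRUE)]
  distortion <- NULL
  if (length(ok_loci) >= 10) {
    last_day <- fc_days[length(fc_days)]
    spat_states <- t(vapply(ok_loci, function(l) {
      s <- fc$summaries[[l]]$genotype
      s$mean[s$day == last_day]
    }, numeric(3)))
    colnames(spat_states) <- c("f_AA", "f_AB", "f_BB")
    pd <- maf$per_day
    spat_maf <- vapply(ok_loci, function(l) {
      pd$maf[pd$locus_id == l & pd$day == last_day]
    }, 0)
    recs <- distortion_records(spat_states, spat_maf,
                               init[ok_loci, , drop = FALSE],
                               egg_maf[ok_loci])
    dfit <- fit_distortion_models(recs)
    flagged <- flag_outliers(dfit, level = config$distortion_level)
    classes <- classify_distortions(flagged)
    write_tsv(flagged, file.path(config$out_dir, "distortion_records.tsv"))
    write_tsv(classes, file.path(config$out_dir, "distortion_classes.tsv"))
    distortion <- list(fit = dfit, flagged = flagged, classes = classes)
    manifest$stages$distortion <- list(
      selected_model = dfit$selected,
      n_outlier_genotypes = sum(flagged$outlier),
      classes = as.list(table(classes$class))
    )
  }

  # linkage bridging
  linkage <- NULL
  snps <- unique(counts[, c("locus_id", "scaffold", "position")])
  map <- if (!is.null(config$linkage_map)) {
    read_tsv(config$linkage_map)
  } else {
    simulate_linkage_map(snps$scaffold, seed = config$scenario$seed + 7L)
  }
  assignments <- bridge_to_map(snps, map)
  dists <- intermarker_distances(assignments)
  write_tsv(assignments, file.path(config$out_dir, "linkage_assignments.tsv"))
  linkage <- list(assignments = assignments, distances = dists)
  manifest$stages$linkage <- list(
    n_snps = nrow(snps), n_assigned = sum(assignments$assigned),
    pct_assigned = percent_of(sum(assignments$assigned), nrow(snps)),
    mean_cM = dists$mean_cM[1]
  )

  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(
    list(config = config, sim = sim, filtered = fres, maf = maf,
         tests = results, clustering = clustering, eggsim = eggsim,
         forecast = fc, distortion = distortion, linkage = linkage,
         manifest = manifest),
    class = "pipeline_run"
  )
}

#' @export
print.pipeline_run <- function(x, ...) {
  m <- x$manifest$stages
  cat("poolsel pipeline run:", x$config$out_dir, "\n")
  cat(sprintf("  filter: %d -> %d loci\n", m$filter$loci_in,
              m$filter$loci_out))
  cat(sprintf("  tests: %d/%d significant (%d%%)\n",
              m$test$loci_significant, m$test$loci_tested,
              m$test$pct_significant))
  if (!is.null(m$cluster)) cat("  clusters: k =", m$cluster$k, "\n")
  cat(sprintf("  forecaster: %d loci, %d records\n",
              m$forecast$n_loci, m$forecast$n_records))
  invisible(x)
}
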