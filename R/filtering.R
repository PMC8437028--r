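#' Filter configuration for pooled allele-count tables
#'
#' Thresholds applied to the merged count table before statistical
#' analysis. Defaults follow the standard pooled 2bRAD filtering recipe:
#' per-sample read depth within \[50, 1000\] (boundaries retained), at most
#' two observed alleles per locus, one SNP per 36-bp tag, at least three
#' replicate cultures with data at every time point, and a minor allele
#' frequency strictly above 1% in the egg pool (day 0).
#'
#' @param min_depth,max_depth Inclusive per-sample depth bounds.
#' @param max_alleles Maximum number of observed alleles per locus.
#' @param min_replicates_per_timepoint Minimum samples per day (> day 0).
#' @param min_egg_maf Strict lower bound on the day-0 minor allele
#'   frequency; must lie in \[0, 0.5).
#' @param one_snp_per_tag Drop every SNP on a tag carrying more than one.
#' @return A list of class `"filter_config"`.
#' @export
filter_config <- function(min_depth = 50, max_depth = 1000, max_alleles = 2,
                          min_replicates_per_timepoint = 3,
                          min_egg_maf = 0.01, one_snp_per_tag = TRUE) {
  if (min_depth > max_depth) stop("min_depth must not exceed max_depth")
  if (min_egg_maf < 0 || min_egg_maf >= 0.5) {
    stop("min_egg_maf must lie in [0, 0.5)")
  }
  structure(
    list(min_depth = min_depth, max_depth = max_depth,
         max_alleles = max_alleles,
         min_replicates_per_timepoint = min_replicates_per_timepoint,
         min_egg_maf = min_egg_maf, one_snp_per_tag = one_snp_per_tag),
    class = "filter_config"
  )
}

#' Apply count-level locus and sample filters
#'
#' Filters are applied in a fixed order:
#' 1. depth: drop samples (locus x replicate x day observations) whose
#'    total depth falls outside `[min_depth, max_depth]`;
#' 2. biallelic: drop loci with more than `max_alleles` observed alleles
#'    (requires per-nucleotide count columns `n_A`, `n_C`, `n_G`, `n_T`;
#'    a pass-through when the table is already biallelic);
#' 3. one SNP per tag: drop all SNPs on any `tag_id` carrying several;
#' 4. presence: drop loci lacking `min_replicates_per_timepoint` surviving
#'    samples at any day (> 0); day 0 requires at least one sample;
#' 5. egg MAF: drop loci whose day-0 minor allele frequency is not strictly
#'    greater than `min_egg_maf`.
#'
#' The egg-pool MAF is computed from day-0 samples only, after fixing the
#' minor-allele designation globally (see [compute_maf()]).
#'
#' @param table Allele-count data frame with columns `locus_id`,
#'   `replicate`, `day`, `n_major`, `n_minor` and optionally `tag_id` and
#'   per-nucleotide counts.
#' @param config A [filter_config()].
#' @return A list of class `"filter_result"`: `table` (the surviving rows)
#'   and `report` (class `"filter_report"`; per-rule removal counts of
#'   samples and loci).
#' @examples
#' sim <- simulate_pool_study(simulation_scenario(n_loci = 10, seed = 3))
#' res <- apply_filters(sim$counts, filter_config())
#' res$report
#' @export
apply_filters <- function(table, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  if (nrow(table) == 0) stop("count table is empty")
  if (!any(table$day == 0)) {
    stop("count table has no day-0 (egg pool) samples; ",
         "the egg MAF filter cannot run")
  }
  n_samples_in <- nrow(table)
  n_loci_in <- length(unique(table$locus_id))
  report <- list()

  # 1. depth (per sample)
  depth <- table$n_major + table$n_minor
  keep <- depth >= config$min_depth & depth <= config$max_depth
  report$depth_samples_removed <- sum(!keep)
  table <- table[keep, , drop = FALSE]

  # 2. biallelic (per locus); needs per-nucleotide counts to be checkable
  nuc_cols <- intersect(c("n_A", "n_C", "n_G", "n_T"), names(table))
  if (length(nuc_cols) == 4) {
    n_alleles <- tapply(seq_len(nrow(table)), table$locus_id, function(ix) {
      sum(colSums(table[ix, nuc_cols, drop = FALSE]) > 0)
    })
    bad <- names(n_alleles)[n_alleles > config$max_alleles]
    report$multiallelic_loci_removed <- length(bad)
    table <- table[!table$locus_id %in% bad, , drop = FALSE]
  } else {
    report$multiallelic_loci_removed <- 0L
    report$biallelic_rule <- "pass-through (input already biallelic)"
  }

  # 3. one SNP per tag
  if (isTRUE(config$one_snp_per_tag) && "tag_id" %in% names(table)) {
    snp_per_tag <- tapply(table$locus_id, table$tag_id,
                          function(x) length(unique(x)))
    bad_tags <- names(snp_per_tag)[snp_per_tag > 1]
    bad <- unique(table$locus_id[table$tag_id %in% bad_tags])
    report$multi_snp_tag_loci_removed <- length(bad)
    table <- table[!table$locus_id %in% bad, , drop = FALSE]
  } else {
    report$multi_snp_tag_loci_removed <- 0L
  }

  # 4. presence: >= min replicates at every day > 0, >= 1 sample at day 0
  days <- sort(unique(table$day))
  need <- ifelse(days == 0, 1L, config$min_replicates_per_timepoint)
  counts_by <- table(table$locus_id, table$day)
  ok <- apply(counts_by[, as.character(days), drop = FALSE], 1,
              function(x) all(x >= need))
  bad <- rownames(counts_by)[!ok]
  report$presence_loci_removed <- length(bad)
  table <- table[!table$locus_id %in% bad, , drop = FALSE]

  # 5. egg-pool MAF (strict >)
  if (nrow(table) > 0 && !any(table$day == 0)) {
    stop("no day-0 (egg pool) samples survive the depth filter; ",
         "the egg MAF filter cannot run")
  }
  if (nrow(table) > 0) {
    maf <- compute_maf(table)
    egg <- maf$per_sample[maf$per_sample$day == 0, , drop = FALSE]
    egg_maf <- tapply(egg$maf, egg$locus_id, mean)
    bad <- names(egg_maf)[!(egg_maf > config$min_egg_maf)]
  } else {
    bad <- character()
  }
  report$egg_maf_loci_removed <- length(bad)
  table <- table[!table$locus_id %in% bad, , drop = FALSE]

  report$samples_in <- n_samples_in
  report$samples_out <- nrow(table)
  report$loci_in <- n_loci_in
  report$loci_out <- length(unique(table$locus_id))
  structure(list(table = table, report = structure(report,
                                                   class = "filter_report")),
            class = "filter_result")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Count-table filter report\n")
  cat(sprintf("  samples: %d in -> %d out (%d failed depth)\n",
              x$samples_in, x$samples_out, x$depth_samples_removed))
  cat(sprintf(
    "  loci: %d in -> %d out (%d multiallelic, %d multi-SNP tag, %d presence, %d egg MAF)\n",
    x$loci_in, x$loci_out, x$multiallelic_loci_removed,
    x$multi_snp_tag_loci_removed, x$presence_loci_removed,
    x$egg_maf_loci_removed))
  invisible(x)
}

#' Per-sample and per-day minor allele frequencies
#'
#' The minor allele is designated once per locus as the allele that is less
#' abundant on average across all samples (mean of per-sample fractions);
#' the designation is then held fixed across days, so per-day values above
#' 0.5 are possible and preserved. Zero-depth samples are excluded from
#' means and flagged.
#'
#' @param table Allele-count data frame (columns `locus_id`, `replicate`,
#'   `day`, `n_major`, `n_minor`).
#' @return A list with `per_sample` (columns `locus_id`, `replicate`,
#'   `day`, `maf`, `flipped`, `zero_depth`) and `per_day` (mean across
#'   replicates: `locus_id`, `day`, `maf`, `n_replicates`).
#' @examples
#' tab <- data.frame(locus_id = "L1", replicate = "R1", day = c(0, 2),
#'                   n_major = c(90, 50), n_minor = c(10, 50))
#' compute_maf(tab)$per_sample$maf # 0.10, 0.50
#' @export
compute_maf <- function(table) {
  depth <- table$n_major + table$n_minor
  zero <- depth == 0
  if (any(zero)) {
    warning(sum(zero), " zero-depth sample(s) excluded from MAF means")
  }
  frac2 <- ifelse(zero, NA_real_, table$n_minor / depth)
  # fix designation per locus: allele 2 stays 'minor' iff its mean
  # per-sample fraction is <= 0.5; otherwise the designation flips
  mean_frac2 <- tapply(frac2, table$locus_id, mean, na.rm = TRUE)
  flipped_locus <- mean_frac2 > 0.5
  flip <- unname(flipped_locus[as.character(table$locus_id)])
  maf <- ifelse(flip, 1 - frac2, frac2)
  per_sample <- data.frame(
    locus_id = table$locus_id, replicate = table$replicate, day = table$day,
    maf = maf, flipped = flip, zero_depth = zero, stringsAsFactors = FALSE
  )
  ok <- !zero
  agg <- aggregate(maf ~ locus_id + day, data = per_sample[ok, ],
                   FUN = mean)
  n_rep <- aggregate(maf ~ locus_id + day, data = per_sample[ok, ],
                     FUN = length)
  per_day <- data.frame(locus_id = agg$locus_id, day = agg$day,
                        maf = agg$maf, n_replicates = n_rep$maf,
                        stringsAsFactors = FALSE)
  per_day <- per_day[order(per_day$locus_id, per_day$day), ]
  rownames(per_day) <- NULL
  list(per_sample = per_sample, per_day = per_day)
}
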