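#' Draw per-locus, per-interval fitness schedules for a selection scenario
#'
#' Generates relative-viability vectors (w_AA, w_AB, w_BB) for every locus
#' and inter-sample interval under one of four genotype-dependent mortality
#' regimes:
#'
#' * `"neutral"`: the three genotypes share one viability per interval, so
#'   allele frequencies drift only through sampling noise.
#' * `"directional"`: a fixed ordering `w_AA >= w_AB >= w_BB` in every
#'   interval; the minor allele behaves as a deleterious (load-like) variant.
#' * `"balanced"`: the favoured homozygote alternates between intervals, so
#'   the ordering of `w_AA` and `w_BB` reverses at least once across
#'   development.
#' * `"overdominant"`: the heterozygote is strictly the fittest genotype in
#'   every interval.
#'
#' Draw ranges are centred so that the per-interval mean fitness is around
#' 0.6, which over the six intervals of the default sampling design yields a
#' type-III survivorship curve declining to roughly 4% of the cohort.
#'
#' @param n_loci Number of loci.
#' @param n_intervals Number of inter-sample intervals.
#' @param scenario One of `"neutral"`, `"directional"`, `"balanced"`,
#'   `"overdominant"`.
#' @param seed Integer seed; the schedule is deterministic given the seed.
#' @return A 3-d array `[locus, interval, genotype]` with genotype slices
#'   `w_AA`, `w_AB`, `w_BB`, all values in \[0, 1\].
#' @examples
#' w <- simulate_fitness_schedule(3, 6, "overdominant", seed = 1)
#' all(w[, , "w_AB"] > pmax(w[, , "w_AA"], w[, , "w_BB"]))
#' @export
simulate_fitness_schedule <- function(n_loci, n_intervals, scenario, seed) {
  stopifnot(n_loci >= 1, n_intervals >= 1)
  scenarios <- c("neutral", "directional", "balanced", "overdominant")
  if (!is.character(scenario) || length(scenario) != 1L ||
      !scenario %in% scenarios) {
    stop("unknown scenario '", paste(scenario, collapse = ","),
         "'; must be one of: ", paste(scenarios, collapse = ", "))
  }
  set.seed(seed)
  w <- array(NA_real_, dim = c(n_loci, n_intervals, 3),
             dimnames = list(NULL, NULL, c("w_AA", "w_AB", "w_BB")))
  n <- n_loci * n_intervals
  if (scenario == "neutral") {
    shared <- matrix(runif(n, 0.4, 0.8), n_loci, n_intervals)
    for (g in 1:3) w[, , g] <- shared
  } else if (scenario == "directional") {
    draws <- array(runif(3 * n, 0.3, 0.9), dim = c(n_loci, n_intervals, 3))
    for (i in seq_len(n_loci)) {
      for (j in seq_len(n_intervals)) {
        w[i, j, ] <- sort(draws[i, j, ], decreasing = TRUE)
      }
    }
  } else if (scenario == "balanced") {
    # favoured homozygote flips every interval; starting side is random
    hi <- matrix(runif(n, 0.65, 0.85), n_loci, n_intervals)
    lo <- matrix(runif(n, 0.35, 0.55), n_loci, n_intervals)
    mid <- lo + (hi - lo) * matrix(runif(n), n_loci, n_intervals)
    start_aa <- sample(c(TRUE, FALSE), n_loci, replace = TRUE)
    for (i in seq_len(n_loci)) {
      aa_favoured <- xor(start_aa[i], seq_len(n_intervals) %% 2 == 0)
      w[i, , "w_AA"] <- ifelse(aa_favoured, hi[i, ], lo[i, ])
      w[i, , "w_BB"] <- ifelse(aa_favoured, lo[i, ], hi[i, ])
      w[i, , "w_AB"] <- mid[i, ]
    }
  } else { # overdominant
    wab <- matrix(runif(n, 0.6, 0.9), n_loci, n_intervals)
    w[, , "w_AB"] <- wab
    w[, , "w_AA"] <- matrix(runif(n, 0.3, as.vector(wab) - 0.05),
                            n_loci, n_intervals)
    w[, , "w_BB"] <- matrix(runif(n, 0.3, as.vector(wab) - 0.05),
                            n_loci, n_intervals)
  }
  w
}

#' Deterministically propagate a genotype state through a fitness schedule
#'
#' Applies the Hardy-Weinberg fitness update expectation interval by
#' interval, recording the true genotype state, minor allele frequency and
#' cumulative survival after each selective episode. This is the ground
#' truth that the stochastic forecaster is validated against.
#'
#' @param initial_state Genotype state at day 0 (fertilized eggs).
#' @param schedule Matrix of fitness vectors, one row per interval, columns
#'   `w_AA`, `w_AB`, `w_BB`.
#' @return A list of class `"locus_truth"` with `states` (matrix, one row
#'   per time point including day 0), `maf` (vector), `survival`
#'   (cumulative, starts at 1) and `w_bar` (per-interval mean fitness).
#' @examples
#' tr <- propagate_truth(hwe_expected(0.4), rbind(c(1, 0.5, 0.25)))
#' tr$maf # declines from 0.4 to 0.25
#' @export
propagate_truth <- function(initial_state, schedule) {
  if (is.null(dim(schedule))) schedule <- matrix(schedule, nrow = 1)
  state <- genotype_state(initial_state[1], initial_state[2], initial_state[3])
  n_int <- nrow(schedule)
  states <- matrix(NA_real_, n_int + 1, 3,
                   dimnames = list(NULL, c("f_AA", "f_AB", "f_BB")))
  states[1, ] <- state
  survival <- numeric(n_int + 1)
  survival[1] <- 1
  w_bar <- numeric(n_int)
  for (j in seq_len(n_int)) {
    step <- advance_interval(states[j, ], schedule[j, ])
    states[j + 1, ] <- step$state
    w_bar[j] <- step$w_bar
    survival[j + 1] <- survival[j] * step$w_bar
  }
  structure(
    list(states = states, maf = state_maf(states), survival = survival,
         w_bar = w_bar),
    class = "locus_truth"
  )
}

#' Define a synthetic pooled-sequencing study
#'
#' Bundles the design of a simulated larval-culture experiment: number of
#' loci and replicate cultures, sampling days, initial minor allele
#' frequencies, the genotype-dependent mortality regime, sequencing depth
#' range and the seed. The defaults mirror a pooled 2bRAD study of larval
#' Pacific oysters: 751 biallelic SNPs, 5 replicate cultures sampled on
#' days 0, 2, 6, 10, 14, 16 and 22 post-fertilization, read depths between
#' 50 and 1000, and type-III survivorship declining to about 4% by day 22.
#' Day 0 is a single unreplicated egg-pool sample.
#'
#' @param n_loci Number of biallelic SNPs.
#' @param n_replicates Number of replicate cultures at days > 0.
#' @param sampling_days Strictly increasing integer days, starting at 0.
#' @param scenario Mortality regime label passed to
#'   [simulate_fitness_schedule()].
#' @param initial_maf Optional per-locus initial minor allele frequency in
#'   (0, 0.5\]; drawn uniformly from \[0.05, 0.5\] when `NULL`.
#' @param depth_range Integer `(min, max)` read depth per sample.
#' @param overdispersion Beta-binomial overdispersion `rho` in \[0, 1);
#'   0 (the default) gives pure binomial read sampling.
#' @param survival_noise_sd Lognormal sigma for replicate-level noise on the
#'   emitted survival series.
#' @param seed Integer seed.
#' @return A list of class `"sim_scenario"`.
#' @export
simulation_scenario <- function(n_loci = 751, n_replicates = 5,
                                sampling_days = c(0, 2, 6, 10, 14, 16, 22),
                                scenario = "balanced", initial_maf = NULL,
                                depth_range = c(50, 1000),
                                overdispersion = 0,
                                survival_noise_sd = 0.05, seed = 1) {
  if (any(diff(sampling_days) <= 0) || sampling_days[1] != 0) {
    stop("sampling_days must be strictly increasing and start at 0")
  }
  if (!is.null(initial_maf)) {
    if (length(initial_maf) != n_loci) {
      stop("initial_maf must have one value per locus")
    }
    if (any(initial_maf <= 0) || any(initial_maf > 0.5)) {
      stop("initial_maf values must lie in (0, 0.5]")
    }
  }
  if (depth_range[1] < 1 || depth_range[1] > depth_range[2]) {
    stop("depth_range must satisfy 1 <= min <= max")
  }
  structure(
    list(n_loci = n_loci, n_replicates = n_replicates,
         sampling_days = as.integer(sampling_days), scenario = scenario,
         initial_maf = initial_maf, depth_range = depth_range,
         overdispersion = overdispersion,
         survival_noise_sd = survival_noise_sd, seed = as.integer(seed)),
    class = "sim_scenario"
  )
}

#' Simulate the ground truth of a synthetic study
#'
#' Draws initial allele frequencies and a fitness schedule for the given
#' scenario, then deterministically propagates every locus through each
#' sampling interval.
#'
#' @param scenario A [simulation_scenario()].
#' @return A list of class `"pool_truth"` with `days`, `states`
#'   (`[locus, day, genotype]` array), `maf` and `survival`
#'   (`locus x day` matrices), `schedule` and `initial_maf`.
#' @export
simulate_truth <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  days <- scenario$sampling_days
  n_int <- length(days) - 1L
  n_loci <- scenario$n_loci
  set.seed(scenario$seed)
  maf0 <- scenario$initial_maf
  if (is.null(maf0)) maf0 <- runif(n_loci, 0.05, 0.5)
  schedule <- simulate_fitness_schedule(n_loci, n_int, scenario$scenario,
                                        seed = scenario$seed + 1L)
  states <- array(NA_real_, c(n_loci, n_int + 1L, 3),
                  dimnames = list(NULL, paste0("day", days),
                                  c("f_AA", "f_AB", "f_BB")))
  maf <- matrix(NA_real_, n_loci, n_int + 1L)
  survival <- matrix(NA_real_, n_loci, n_int + 1L)
  for (i in seq_len(n_loci)) {
    tr <- propagate_truth(hwe_expected(maf0[i]),
                          schedule[i, , , drop = TRUE])
    states[i, , ] <- tr$states
    maf[i, ] <- tr$maf
    survival[i, ] <- tr$survival
  }
  structure(
    list(days = days, states = states, maf = maf, survival = survival,
         schedule = schedule, initial_maf = maf0),
    class = "pool_truth"
  )
}

# beta-binomial draw with mean n*p and pairwise correlation rho; rho = 0
# falls back to plain binomial
rbetabinom <- function(n, size, prob, rho) {
  if (rho <= 0) return(rbinom(n, size, prob))
  shape <- (1 - rho) / rho
  p <- rbeta(n, prob * shape, (1 - prob) * shape)
  rbinom(n, size, p)
}

#' Sample a pooled allele-count table from ground truth
#'
#' Emulates pooled sequencing of each replicate culture at each sampling
#' day: a read depth is drawn uniformly within `depth_range` and the
#' minor-allele read count binomially at the true minor allele frequency
#' (optionally beta-binomially when `overdispersion > 0`). Day 0 is a
#' single unreplicated egg-pool sample (replicate `"egg"`); later days have
#' `n_replicates` samples. Replicates share the true MAF, so all
#' replicate-level variation is sampling noise.
#'
#' @param truth A `"pool_truth"` from [simulate_truth()].
#' @param n_replicates Replicate cultures per day (> day 0).
#' @param depth_range Integer `(min, max)` read depth.
#' @param seed Integer seed.
#' @param overdispersion Beta-binomial `rho`; 0 for pure binomial.
#' @return A data frame with columns `locus_id`, `scaffold`, `position`,
#'   `tag_id`, `replicate`, `day`, `n_major`, `n_minor`.
#' @export
sample_count_table <- function(truth, n_replicates = 5,
                               depth_range = c(50, 1000), seed = 1,
                               overdispersion = 0) {
  stopifnot(inherits(truth, "pool_truth"))
  if (depth_range[1] < 1 || depth_range[1] > depth_range[2]) {
    stop("depth_range must satisfy 1 <= min <= max")
  }
  set.seed(seed)
  days <- truth$days
  n_loci <- nrow(truth$maf)
  reps_by_day <- lapply(days, function(d) {
    if (d == 0) "egg" else paste0("R", seq_len(n_replicates))
  })
  grid <- do.call(rbind, lapply(seq_along(days), function(j) {
    data.frame(day = days[j], replicate = reps_by_day[[j]], day_idx = j,
               stringsAsFactors = FALSE)
  }))
  n_samp <- nrow(grid)
  depths <- seq.int(depth_range[1], depth_range[2])
  out <- do.call(rbind, lapply(seq_len(n_loci), function(i) {
    depth <- depths[sample.int(length(depths), n_samp, replace = TRUE)]
    p <- truth$maf[i, grid$day_idx]
    n_minor <- rbetabinom(n_samp, depth, p, overdispersion)
    data.frame(
      locus_id = sprintf("L%04d", i),
      scaffold = sprintf("scaffold_%03d", ((i - 1L) %/% 4L) + 1L),
      position = 1000L * i,
      tag_id = sprintf("tag_%04d", i),
      replicate = grid$replicate,
      day = grid$day,
      n_major = depth - n_minor,
      n_minor = n_minor,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Emit the replicate-level cumulative survival series
#'
#' The study-level survival at each day is the across-locus mean of the
#' true cumulative survival (the cumulative product of per-interval mean
#' fitness); each replicate's series is that curve perturbed by small
#' lognormal noise and forced non-increasing, with survival 1 at day 0.
#'
#' @param truth A `"pool_truth"`.
#' @param n_replicates Number of replicate cultures.
#' @param noise_sd Lognormal sigma of replicate noise (0 disables it).
#' @param seed Integer seed.
#' @return Data frame `replicate`, `day`, `cum_survival`.
#' @export
sample_survival_series <- function(truth, n_replicates = 5, noise_sd = 0.05,
                                   seed = 1) {
  stopifnot(inherits(truth, "pool_truth"))
  set.seed(seed)
  base <- colMeans(truth$survival)
  out <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
    noise <- c(1, rlnorm(length(base) - 1L, 0, noise_sd))
    s <- cummin(pmin(base * noise, 1))
    data.frame(replicate = paste0("R", r), day = truth$days,
               cum_survival = s, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper running [simulate_truth()], [sample_count_table()]
#' and [sample_survival_series()] for one scenario.
#'
#' @param scenario A [simulation_scenario()].
#' @return A list of class `"pool_sim"` with `counts`, `survival`, `truth`
#'   and the `scenario`.
#' @examples
#' sim <- simulate_pool_study(simulation_scenario(n_loci = 5, seed = 2))
#' head(sim$counts)
#' @export
simulate_pool_study <- function(scenario) {
  truth <- simulate_truth(scenario)
  counts <- sample_count_table(truth, scenario$n_replicates,
                               scenario$depth_range,
                               seed = scenario$seed + 2L,
                               overdispersion = scenario$overdispersion)
  survival <- sample_survival_series(truth, scenario$n_replicates,
                                     scenario$survival_noise_sd,
                                     seed = scenario$seed + 3L)
  structure(list(counts = counts, survival = survival, truth = truth,
                 scenario = scenario),
            class = "pool_sim")
}

#' @export
print.pool_sim <- function(x, ...) {
  sc <- x$scenario
  cat("Synthetic pooled-sequencing study\n")
  cat(sprintf("  scenario: %s | %d loci, %d replicates, days %s\n",
              sc$scenario, sc$n_loci, sc$n_replicates,
              paste(sc$sampling_days, collapse = ",")))
  cat(sprintf("  final mean cumulative survival: %.3f\n",
              mean(x$truth$survival[, ncol(x$truth$survival)])))
  invisible(x)
}

#' Write the tables of a synthetic study to a directory
#'
#' Writes `counts.tsv`, `survival.tsv` and `truth.tsv` (per-locus, per-day
#' true genotype state, MAF and survival, for use as a test oracle).
#'
#' @param sim A `"pool_sim"`.
#' @param dir Output directory, created if missing.
#' @return Invisibly, the paths written.
#' @export
write_pool_study <- function(sim, dir) {
  stopifnot(inherits(sim, "pool_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("counts.tsv", "survival.tsv", "truth.tsv"))
  write_tsv(sim$counts, paths[1])
  write_tsv(sim$survival, paths[2])
  tr <- sim$truth
  truth_df <- do.call(rbind, lapply(seq_len(nrow(tr$maf)), function(i) {
    data.frame(locus_id = sprintf("L%04d", i), day = tr$days,
               f_AA = tr$states[i, , 1], f_AB = tr$states[i, , 2],
               f_BB = tr$states[i, , 3], maf = tr$maf[i, ],
               cum_survival = tr$survival[i, ], stringsAsFactors = FALSE)
  }))
  write_tsv(truth_df, paths[3])
  invisible(paths)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a tab-separated table written by this package
#'
#' @param path Path to a TSV with a header row.
#' @return A data frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
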