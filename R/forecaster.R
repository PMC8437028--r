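#' Empirical constraints for the trajectory forecaster
#'
#' Bundles the per-day empirical targets the rejection sampler must match:
#' the mean minor allele frequency across replicate cultures and the mean
#' cumulative survival, at each constrained day.
#'
#' @param days Constrained sampling days (the default larval design uses
#'   days 2, 6, 10, 14 and 22; day 0 supplies the initial state).
#' @param maf Mean MAF at each day.
#' @param survival Mean cumulative survival at each day (must be positive
#'   and non-increasing).
#' @param tolerance Acceptance tolerance (default 0.10): a proposal is kept
#'   only if its MAF is within `tolerance` of the empirical value on the
#'   absolute scale and its cumulative survival within `tolerance` on the
#'   relative scale. Cumulative survival spans orders of magnitude (about
#'   0.04 by the end of the larval period), so an absolute window there
#'   would be vacuous, while a relative window on MAF would degenerate near
#'   zero; `maf_scale` and `survival_scale` switch either choice.
#' @param maf_scale,survival_scale `"absolute"` or `"relative"`.
#' @return A list of class `"empirical_constraints"`.
#' @export
empirical_constraints <- function(days, maf, survival, tolerance = 0.10,
                                  maf_scale = "absolute",
                                  survival_scale = "relative") {
  stopifnot(length(days) == length(maf), length(days) == length(survival))
  if (tolerance <= 0) stop("tolerance must be positive")
  if (any(maf < 0 | maf > 1)) stop("empirical MAF must lie in [0, 1]")
  if (any(survival <= 0)) {
    stop("empirical cumulative survival must be positive")
  }
  if (any(diff(survival) > 1e-9)) {
    stop("cumulative survival must be non-increasing over days")
  }
  maf_scale <- match.arg(maf_scale, c("absolute", "relative"))
  survival_scale <- match.arg(survival_scale, c("absolute", "relative"))
  structure(
    list(days = days, maf = maf, survival = survival, tolerance = tolerance,
         maf_scale = maf_scale, survival_scale = survival_scale),
    class = "empirical_constraints"
  )
}

#' Check one simulated time point against the empirical constraints
#'
#' @param sim_maf Simulated minor allele frequency.
#' @param sim_survival Simulated cumulative survival.
#' @param constraints An [empirical_constraints()] object.
#' @param day Which constrained day to check against.
#' @return A list `list(ok, reason)`; `reason` is `NA`, `"maf"`,
#'   `"survival"` or `"maf+survival"`.
#' @examples
#' ec <- empirical_constraints(2, maf = 0.45, survival = 0.52)
#' check_constraints(0.30, 0.50, ec, day = 2) # rejected on MAF
#' @export
check_constraints <- function(sim_maf, sim_survival, constraints, day) {
  j <- match(day, constraints$days)
  if (is.na(j)) stop("no constraint defined at day ", day)
  dev <- function(sim, emp, scale) {
    if (scale == "absolute") abs(sim - emp) else abs(sim - emp) / emp
  }
  maf_bad <- dev(sim_maf, constraints$maf[j], constraints$maf_scale) >
    constraints$tolerance
  surv_bad <- dev(sim_survival, constraints$survival[j],
                  constraints$survival_scale) > constraints$tolerance
  reason <- if (maf_bad && surv_bad) "maf+survival"
            else if (maf_bad) "maf"
            else if (surv_bad) "survival"
            else NA_character_
  list(ok = !maf_bad && !surv_bad, reason = reason)
}

# vectorized accept mask over a batch of proposals
.accept_mask <- function(sim_maf, sim_surv, emp_maf, emp_surv, tol,
                         maf_scale, surv_scale) {
  dm <- if (maf_scale == "absolute") abs(sim_maf - emp_maf)
        else abs(sim_maf - emp_maf) / emp_maf
  ds <- if (surv_scale == "absolute") abs(sim_surv - emp_surv)
        else abs(sim_surv - emp_surv) / emp_surv
  dm <= tol & ds <= tol
}

#' Reconstruct genotype and fitness trajectories for one locus
#'
#' Rejection sampling under the Hardy-Weinberg fitness model. Starting
#' from the egg-pool genotype state, each inter-sample interval draws a
#' fitness vector with the three relative viabilities independent
#' uniform(0, 1), advances the state with [advance_interval()], and keeps
#' the draw only if the resulting MAF and cumulative survival both fall
#' within the tolerance of the empirical values at the interval's end day.
#' A rejected interval is re-drawn up to `max_attempts_per_interval` times;
#' exhaustion restarts the whole trajectory from day 0 (up to
#' `max_restarts`, after which the trajectory slot is abandoned with a
#' diagnostic). Collecting `n_accept` full trajectories yields an ensemble
#' of plausible genotype-frequency and fitness histories consistent with
#' the pooled observations.
#'
#' @param initial Genotype state at day 0 (e.g. an egg-pool estimate from
#'   [simulate_egg_genotypes()], or [hwe_expected()] of the egg MAF).
#' @param constraints An [empirical_constraints()] object covering at
#'   least two days.
#' @param n_accept Ensemble size (accepted trajectories).
#' @param max_attempts_per_interval,max_restarts Sampling budgets.
#' @param seed Integer seed; results are deterministic given the seed.
#' @param batch Proposals evaluated per draw (vectorization granularity;
#'   does not change the accepted sample, only speed).
#' @return A list of class `"trajectory_ensemble"`: `days` (day 0 plus the
#'   constrained days), `states` (`[trajectory, day, genotype]`),
#'   `fitness` (`[trajectory, interval, genotype]`), `survival`
#'   (`[trajectory, day]`), `maf`, `n_accepted`, `infeasible`,
#'   `diagnostics` (proposals, restarts, failed slots).
#' @export
forecast_locus <- function(initial, constraints, n_accept = 50,
                           max_attempts_per_interval = 10000,
                           max_restarts = 1000, seed = 1, batch = 256) {
  stopifnot(inherits(constraints, "empirical_constraints"))
  n_days <- length(constraints$days)
  if (n_days < 2) stop("constraints must cover at least two time points")
  initial <- genotype_state(initial[1], initial[2], initial[3])
  tol <- constraints$tolerance
  set.seed(seed)
  states <- array(NA_real_, c(n_accept, n_days + 1L, 3),
                  dimnames = list(NULL, c("day0",
                                          paste0("day", constraints$days)),
                                  c("f_AA", "f_AB", "f_BB")))
  fitness <- array(NA_real_, c(n_accept, n_days, 3),
                   dimnames = list(NULL, NULL, c("w_AA", "w_AB", "w_BB")))
  survival <- matrix(NA_real_, n_accept, n_days + 1L)
  n_proposals <- 0
  n_restarts_total <- 0
  failed_slots <- 0L
  accepted <- 0L
  for (slot in seq_len(n_accept)) {
    restarts <- 0L
    done <- FALSE
    while (!done && restarts <= max_restarts) {
      st <- initial
      surv <- 1
      traj_states <- matrix(NA_real_, n_days, 3)
      traj_fit <- matrix(NA_real_, n_days, 3)
      traj_surv <- numeric(n_days)
      ok_traj <- TRUE
      for (j in seq_len(n_days)) {
        attempts <- 0
        found <- FALSE
        while (!found && attempts < max_attempts_per_interval) {
          b <- min(batch, max_attempts_per_interval - attempts)
          w <- matrix(runif(3L * b), b, 3)
          n_proposals <- n_proposals + b
          attempts <- attempts + b
          wbar <- w[, 1] * st[1] + w[, 2] * st[2] + w[, 3] * st[3]
          valid <- wbar > 0
          f_aa <- ifelse(valid, st[1] * w[, 1] / wbar, NA_real_)
          f_bb <- ifelse(valid, st[3] * w[, 3] / wbar, NA_real_)
          f_ab <- 1 - f_aa - f_bb
          sim_maf <- f_ab / 2 + f_bb
          sim_surv <- surv * wbar
          okv <- valid & .accept_mask(sim_maf, sim_surv,
                                      constraints$maf[j],
                                      constraints$survival[j], tol,
                                      constraints$maf_scale,
                                      constraints$survival_scale)
          hit <- which(okv)
          if (length(hit)) {
            h <- hit[1]
            st <- c(f_aa[h], f_ab[h], f_bb[h])
            surv <- sim_surv[h]
            traj_states[j, ] <- st
            traj_fit[j, ] <- w[h, ]
            traj_surv[j] <- surv
            found <- TRUE
          }
        }
        if (!found) {
          ok_traj <- FALSE
          break
        }
      }
      if (ok_traj) {
        accepted <- accepted + 1L
        states[slot, 1, ] <- initial
        states[slot, -1, ] <- traj_states
        fitness[slot, , ] <- traj_fit
        survival[slot, 1] <- 1
        survival[slot, -1] <- traj_surv
        done <- TRUE
      } else {
        restarts <- restarts + 1L
        n_restarts_total <- n_restarts_total + 1L
      }
    }
    if (!done) {
      failed_slots <- failed_slots + 1L
    }
  }
  keep <- which(!is.na(survival[, n_days + 1L]))
  day_labs <- c("day0", paste0("day", constraints$days))
  colnames(survival) <- day_labs
  structure(
    list(days = c(0, constraints$days),
         states = states[keep, , , drop = FALSE],
         fitness = fitness[keep, , , drop = FALSE],
         survival = survival[keep, , drop = FALSE],
         maf = matrix(states[keep, , 2], length(keep), n_days + 1L) / 2 +
           matrix(states[keep, , 3], length(keep), n_days + 1L,
                  dimnames = list(NULL, day_labs)),
         n_accepted = length(keep),
         infeasible = failed_slots > 0L,
         constraints = constraints,
         diagnostics = list(n_proposals = n_proposals,
                            n_restarts = n_restarts_total,
                            failed_slots = failed_slots)),
    class = "trajectory_ensemble"
  )
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf(
    "Trajectory ensemble: %d accepted trajectories over days %s\n",
    x$n_accepted, paste(x$days, collapse = ", ")))
  cat(sprintf("  proposals: %d | restarts: %d | failed slots: %d%s\n",
              x$diagnostics$n_proposals, x$diagnostics$n_restarts,
              x$diagnostics$failed_slots,
              if (x$infeasible) " [INFEASIBLE]" else ""))
  invisible(x)
}

#' Summarize a trajectory ensemble
#'
#' Per-time-point means and 95% intervals of the three genotype
#' frequencies, cumulative survival and (per interval) the three fitness
#' components, across accepted trajectories. The bookkeeping entry counts
#' one per-time-point simulation record per accepted trajectory and time
#' point.
#'
#' @param ensemble A `"trajectory_ensemble"`.
#' @param level Interval coverage (default 0.95).
#' @return A list of class `"ensemble_summary"`: `genotype` (data frame
#'   `day`, `genotype`, `mean`, `lo`, `hi`), `fitness` (same per
#'   interval), `survival`, and `n_records`.
#' @export
summarize_ensemble <- function(ensemble, level = 0.95) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  if (ensemble$n_accepted < 2) {
    stop("need at least two accepted trajectories to summarize")
  }
  a <- (1 - level) / 2
  probs <- c(a, 1 - a)
  days <- ensemble$days
  gt <- c("AA", "AB", "BB")
  geno <- do.call(rbind, lapply(seq_along(days), function(j) {
    do.call(rbind, lapply(1:3, function(g) {
      v <- ensemble$states[, j, g]
      q <- quantile(v, probs, names = FALSE)
      data.frame(day = days[j], genotype = gt[g], mean = mean(v),
                 lo = q[1], hi = q[2], stringsAsFactors = FALSE)
    }))
  }))
  n_int <- dim(ensemble$fitness)[2]
  fit <- do.call(rbind, lapply(seq_len(n_int), function(j) {
    do.call(rbind, lapply(1:3, function(g) {
      v <- ensemble$fitness[, j, g]
      q <- quantile(v, probs, names = FALSE)
      data.frame(day_from = days[j], day_to = days[j + 1], genotype = gt[g],
                 mean = mean(v), lo = q[1], hi = q[2],
                 stringsAsFactors = FALSE)
    }))
  }))
  surv <- do.call(rbind, lapply(seq_along(days), function(j) {
    v <- ensemble$survival[, j]
    q <- quantile(v, probs, names = FALSE)
    data.frame(day = days[j], mean = mean(v), lo = q[1], hi = q[2])
  }))
  structure(
    list(genotype = geno, fitness = fit, survival = surv,
         n_records = ensemble$n_accepted * length(days), level = level),
    class = "ensemble_summary"
  )
}

#' @export
summary.trajectory_ensemble <- function(object, level = 0.95, ...) {
  summarize_ensemble(object, level = level)
}

#' Total per-time-point simulation records of a forecaster run
#'
#' One record per locus, accepted trajectory and time point, so a run over
#' `n_loci` loci with `n_accept` accepted simulations and `n_timepoints`
#' time points produces `n_loci * n_accept * n_timepoints` records.
#'
#' @param n_loci,n_accept,n_timepoints Run configuration.
#' @return Integer record count.
#' @examples
#' forecast_bookkeeping(473, 50, 6)
#' @export
forecast_bookkeeping <- function(n_loci, n_accept, n_timepoints) {
  as.integer(n_loci) * as.integer(n_accept) * as.integer(n_timepoints)
}

#' Plot a trajectory ensemble
#'
#' Ensemble mean genotype frequencies over development with 95% interval
#' ribbons.
#'
#' @param x A `"trajectory_ensemble"`.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the plotted summary.
#' @export
plot.trajectory_ensemble <- function(x, ...) {
  s <- summarize_ensemble(x)
  gt <- c("AA", "AB", "BB")
  cols <- c("#1b9e77", "#d95f02", "#7570b3")
  m <- sapply(gt, function(g) s$genotype$mean[s$genotype$genotype == g])
  matplot(x$days, m, type = "l", lty = 1, lwd = 2, col = cols,
          xlab = "day post-fertilization", ylab = "genotype frequency",
          ylim = c(0, 1), ...)
  for (g in seq_along(gt)) {
    sub <- s$genotype[s$genotype$genotype == gt[g], ]
    polygon(c(x$days, rev(x$days)), c(sub$lo, rev(sub$hi)),
            col = adjustcolor(cols[g], alpha.f = 0.2), border = NA)
  }
  legend("topright", legend = gt, col = cols, lty = 1, lwd = 2, bty = "n")
  invisible(s)
}

#' Forecast every locus of a study
#'
#' Driver applying [forecast_locus()] across loci, with per-locus
#' constraints assembled from the mean MAF and survival tables.
#'
#' @param initial_states Matrix (loci x 3) of day-0 genotype states,
#'   rownames = locus ids.
#' @param per_day Mean MAF per locus and day (`locus_id`, `day`, `maf`).
#' @param survival Data frame `day`, `cum_survival` (already averaged
#'   across replicates), or per-replicate with a `replicate` column (then
#'   averaged here).
#' @param days Constrained days (default `c(2, 6, 10, 14, 22)`).
#' @param tolerance,n_accept,seed,... Passed to [forecast_locus()]; each
#'   locus gets a seed derived from `seed`.
#' @return A list of class `"forecast_set"`: `ensembles` (named list),
#'   `summaries` (named list of `"ensemble_summary"`), `n_records`,
#'   `infeasible_loci`.
#' @export
forecast_loci <- function(initial_states, per_day, survival,
                          days = c(2, 6, 10, 14, 22), tolerance = 0.10,
                          n_accept = 50, seed = 1, ...) {
  if ("replicate" %in% names(survival)) {
    survival <- aggregate(cum_survival ~ day, data = survival, FUN = mean)
  }
  surv <- survival$cum_survival[match(days, survival$day)]
  if (any(is.na(surv))) stop("survival series lacks some forecast days")
  loci <- rownames(initial_states)
  ensembles <- vector("list", length(loci))
  names(ensembles) <- loci
  for (i in seq_along(loci)) {
    d <- per_day[per_day$locus_id == loci[i], , drop = FALSE]
    maf <- d$maf[match(days, d$day)]
    if (any(is.na(maf))) {
      warning("locus ", loci[i], " lacks MAF at some forecast days; skipped")
      next
    }
    ec <- empirical_constraints(days, maf, surv, tolerance = tolerance)
    ensembles[[i]] <- forecast_locus(initial_states[i, ], ec,
                                     n_accept = n_accept,
                                     seed = seed + i, ...)
  }
  keep <- !vapply(ensembles, is.null, logical(1))
  ensembles <- ensembles[keep]
  summaries <- lapply(ensembles, summarize_ensemble)
  structure(
    list(ensembles = ensembles, summaries = summaries,
         n_records = sum(vapply(ensembles, function(e) {
           e$n_accepted * length(e$days)
         }, 0)),
         infeasible_loci = names(ensembles)[vapply(ensembles,
                                                   `[[`, TRUE,
                                                   "infeasible")]),
    class = "forecast_set"
  )
}
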