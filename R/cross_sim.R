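#' Estimate egg-pool genotype composition by simulated factorial crosses
#'
#' Pooled sequencing yields allele frequencies but not genotypes. When the
#' larval pool descends from a controlled factorial cross, however, the
#' egg-pool allele frequency reflects the complete parental gamete pool,
#' and the genotype composition of the fertilized eggs can be estimated by
#' simulation: for each of `n_sims` replicate simulations, the observed
#' minor-allele copies (`round(q * 2 * n_parents)`, held exact) are placed
#' uniformly at random among the parental allele slots, the parents are
#' split into `n_sires` sires and `n_dams` dams, every sire is paired with
#' every dam (equal-weight full-sibling families), and the Mendelian
#' offspring expectation is averaged over families.
#'
#' @param egg_maf Per-locus minor allele frequency in the egg pool, each in
#'   (0, 1).
#' @param n_sims Simulated broodstock populations per locus.
#' @param n_sires,n_dams Parents of each sex (default 5 x 19, giving 95
#'   families per simulation).
#' @param seed Integer seed.
#' @return A data frame of class `"egg_sim"`, one row per locus:
#'   `locus_id` (names of `egg_maf` or an index), ensemble mean `f_AA`,
#'   `f_AB`, `f_BB`, their across-simulation standard deviations
#'   (`sd_AA`...) and 2.5/97.5% quantiles (`lo_AA`, `hi_AA`, ...),
#'   `n_minor_copies`, and `monomorphic` (true when rounding left no minor
#'   copy; the state is then (1, 0, 0) and a warning is raised).
#' @examples
#' simulate_egg_genotypes(c(L1 = 0.5), n_sims = 20, seed = 1)
#' @export
simulate_egg_genotypes <- function(egg_maf, n_sims = 50, n_sires = 5,
                                   n_dams = 19, seed = 1) {
  if (any(egg_maf <= 0) || any(egg_maf >= 1)) {
    stop("egg_maf values must lie strictly inside (0, 1)")
  }
  set.seed(seed)
  n_parents <- n_sires + n_dams
  n_slots <- 2L * n_parents
  ids <- names(egg_maf)
  if (is.null(ids)) ids <- sprintf("L%04d", seq_along(egg_maf))
  out <- vector("list", length(egg_maf))
  for (i in seq_along(egg_maf)) {
    copies <- round(egg_maf[i] * n_slots)
    if (copies == 0) {
      warning("locus ", ids[i], ": round(q * ", n_slots, ") = 0; ",
              "monomorphic in the simulated parents")
      out[[i]] <- data.frame(
        locus_id = ids[i], f_AA = 1, f_AB = 0, f_BB = 0,
        sd_AA = 0, sd_AB = 0, sd_BB = 0,
        lo_AA = 1, hi_AA = 1, lo_AB = 0, hi_AB = 0, lo_BB = 0, hi_BB = 0,
        n_minor_copies = 0L, monomorphic = TRUE, stringsAsFactors = FALSE
      )
      next
    }
    states <- matrix(NA_real_, n_sims, 3)
    for (s in seq_len(n_sims)) {
      slots <- logical(n_slots)
      slots[sample.int(n_slots, copies)] <- TRUE
      # per-parent minor-copy count -> probability of transmitting B
      copies_per_parent <- slots[seq(1, n_slots, by = 2)] +
        slots[seq(2, n_slots, by = 2)]
      transmit <- copies_per_parent / 2
      sires <- transmit[seq_len(n_sires)]
      dams <- transmit[n_sires + seq_len(n_dams)]
      # equal-weight average over the full n_sires x n_dams family grid:
      # the grid mean of products factorizes into products of means
      ms <- mean(sires)
      md <- mean(dams)
      f_bb <- ms * md
      f_aa <- (1 - ms) * (1 - md)
      states[s, ] <- c(f_aa, 1 - f_aa - f_bb, f_bb)
    }
    qs <- apply(states, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
    out[[i]] <- data.frame(
      locus_id = ids[i],
      f_AA = mean(states[, 1]), f_AB = mean(states[, 2]),
      f_BB = mean(states[, 3]),
      sd_AA = sd(states[, 1]), sd_AB = sd(states[, 2]),
      sd_BB = sd(states[, 3]),
      lo_AA = qs[1, 1], hi_AA = qs[2, 1],
      lo_AB = qs[1, 2], hi_AB = qs[2, 2],
      lo_BB = qs[1, 3], hi_BB = qs[2, 3],
      n_minor_copies = as.integer(copies), monomorphic = FALSE,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_families") <- n_cross_families(n_sires, n_dams)
  attr(res, "n_sims") <- n_sims
  class(res) <- c("egg_sim", "data.frame")
  res
}

#' Number of full-sibling families in one factorial-cross simulation
#'
#' Every sire is paired with every dam, so a 5 x 19 design yields 95
#' equal-weight families.
#'
#' @param n_sires,n_dams Parents of each sex.
#' @return Integer family count.
#' @export
n_cross_families <- function(n_sires = 5, n_dams = 19) {
  as.integer(n_sires) * as.integer(n_dams)
}
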