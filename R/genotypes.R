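#' Genotype states and the Hardy-Weinberg fitness update
#'
#' A genotype state is the composition of a pooled cohort at one locus:
#' the fractions of the three diploid genotypes (AA, AB, BB) for a biallelic
#' SNP with major allele A and minor allele B. States live on the
#' 2-simplex; the minor allele frequency implied by a state is
#' `f_AB / 2 + f_BB`.
#'
#' @param f_aa,f_ab,f_bb Genotype fractions; must be non-negative and sum
#'   to 1 within `tol`.
#' @param tol Numeric tolerance for the simplex check.
#' @return A named numeric vector `c(f_AA, f_AB, f_BB)`.
#' @examples
#' genotype_state(0.25, 0.5, 0.25)
#' @export
genotype_state <- function(f_aa, f_ab, f_bb, tol = 1e-9) {
  s <- c(f_AA = f_aa, f_AB = f_ab, f_BB = f_bb)
  if (any(!is.finite(s)) || any(s < -tol)) {
    stop("genotype fractions must be finite and non-negative")
  }
  if (abs(sum(s) - 1) > tol) {
    stop("genotype fractions must sum to 1 (got ", format(sum(s)), ")")
  }
  pmax(s, 0)
}

#' Minor allele frequency implied by a genotype state
#'
#' @param state Named numeric vector `c(f_AA, f_AB, f_BB)` or a matrix with
#'   those three columns.
#' @return Numeric MAF value(s): `f_AB / 2 + f_BB`.
#' @export
state_maf <- function(state) {
  if (is.matrix(state)) {
    state[, 2] / 2 + state[, 3]
  } else {
    unname(state[2] / 2 + state[3])
  }
}

#' Hardy-Weinberg expected genotype frequencies
#'
#' Genotype composition expected under random mating with no selection:
#' `(p^2, 2pq, q^2)` where `q` is the minor allele frequency and
#' `p = 1 - q`.
#'
#' @param q Minor allele frequency (or a vector of them), in \[0, 1\].
#' @return For scalar `q`, a named state vector; for vector `q`, a matrix
#'   with columns `f_AA`, `f_AB`, `f_BB` (one row per element of `q`).
#' @examples
#' hwe_expected(0.2) # (0.64, 0.32, 0.04)
#' @export
hwe_expected <- function(q) {
  if (any(!is.finite(q)) || any(q < 0) || any(q > 1)) {
    stop("q must lie in [0, 1]")
  }
  p <- 1 - q
  out <- cbind(f_AA = p^2, f_AB = 2 * p * q, f_BB = q^2)
  if (length(q) == 1L) out[1L, ] else out
}

#' Expected offspring genotype composition of a single cross
#'
#' Exact Mendelian expectation for the offspring of two diploid parents at a
#' biallelic locus, assuming no meiotic drive and no differential
#' fertilization success.
#'
#' @param sire,dam Parental genotypes, each one of `"AA"`, `"AB"`, `"BB"`.
#' @return A named genotype state vector.
#' @examples
#' mendelian_offspring("AA", "BB") # all heterozygotes
#' mendelian_offspring("AB", "AB") # 1:2:1
#' @export
mendelian_offspring <- function(sire, dam) {
  transmit <- c(AA = 0, AB = 0.5, BB = 1) # P(transmitting the minor allele)
  if (!sire %in% names(transmit) || !dam %in% names(transmit)) {
    stop("parental genotypes must be one of 'AA', 'AB', 'BB'")
  }
  ts <- transmit[[sire]]
  td <- transmit[[dam]]
  c(
    f_AA = (1 - ts) * (1 - td),
    f_AB = ts * (1 - td) + (1 - ts) * td,
    f_BB = ts * td
  )
}

#' Advance a genotype state through one selective episode
#'
#' Applies the Hardy-Weinberg fitness update for one inter-sample interval:
#' each genotype survives in proportion to its relative viability
#' `w_g`, so the new composition is `f_g * w_g / w_bar` where
#' `w_bar = sum(f_g * w_g)` is the cohort mean fitness (the fraction of the
#' cohort expected to survive the episode). When the state is at
#' Hardy-Weinberg proportions this mean fitness equals the familiar
#' `p^2 w_AA + 2pq w_AB + q^2 w_BB`.
#'
#' @param state Genotype state (named numeric `c(f_AA, f_AB, f_BB)`).
#' @param w Relative viabilities `c(w_AA, w_AB, w_BB)`, each in \[0, 1\].
#' @return A list with `state` (the post-episode composition), `w_bar`
#'   (mean fitness, the survival fraction of the episode) and `maf` (the
#'   implied minor allele frequency).
#' @examples
#' advance_interval(c(0.36, 0.48, 0.16), c(1.0, 0.5, 0.25))
#' @export
advance_interval <- function(state, w) {
  if (length(state) != 3L || length(w) != 3L) {
    stop("state and w must have length 3")
  }
  if (any(w < 0) || any(w > 1)) stop("fitness values must lie in [0, 1]")
  if (any(state < 0) || abs(sum(state) - 1) > 1e-9) {
    stop("state must lie on the simplex")
  }
  w_bar <- sum(state * w)
  if (w_bar <= 0) {
    stop("mean fitness is zero: every genotype present has zero viability")
  }
  new_state <- state * w / w_bar
  names(new_state) <- c("f_AA", "f_AB", "f_BB")
  list(state = new_state, w_bar = w_bar, maf = state_maf(new_state))
}
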